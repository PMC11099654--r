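#' Multiple sequence alignment container
#'
#' An `msa` is a rectangular gapped alignment: a named character vector of
#' equal-length gapped strings (gap character `-`), wrapped in a light S3
#' class. Row names are sequence ids and must be unique. The class invariant
#' maintained by every public operation is *row conservation*: removing the
#' gaps of any row recovers the corresponding input sequence unchanged, and no
#' column consists entirely of gaps.
#'
#' @param rows named character vector of gapped strings of identical length.
#' @return an object of class `msa`.
#' @export
#' @examples
#' m <- msa(c(s1 = "AC-D", s2 = "A-CD"))
#' msa_width(m)
msa <- function(rows) {
  ids <- names(rows)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("msa rows must be named by sequence id")
  if (anyDuplicated(ids))
    stop("duplicate sequence id in msa: ", ids[duplicated(ids)][1])
  w <- unique(nchar(rows))
  if (length(rows) == 0L) w <- 0L
  if (length(w) > 1L)
    stop("ragged msa rows: ", paste(ids, nchar(rows), sep = "=", collapse = ", "))
  structure(list(ids = ids, rows = rows, width = as.integer(w[1] %||% 0L)),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences x %d columns\n", length(x$ids), x$width))
  show <- utils::head(x$ids, 6)
  for (id in show) {
    s <- x$rows[[id]]
    if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
    cat(sprintf("  %-20s %s\n", id, s))
  }
  if (length(x$ids) > 6) cat(sprintf("  ... and %d more\n", length(x$ids) - 6))
  invisible(x)
}

#' @rdname msa
#' @param m an `msa` object.
#' @export
msa_width <- function(m) m$width

#' @rdname msa
#' @export
msa_nrow <- function(m) length(m$ids)

#' Convert an alignment to/from a character matrix
#'
#' @param m an `msa`.
#' @return `msa_matrix`: character matrix (rows = sequences, one character per
#'   cell, rownames = ids). `msa_from_matrix`: an `msa`.
#' @keywords internal
msa_matrix <- function(m) {
  if (m$width == 0L || length(m$ids) == 0L)
    return(matrix(character(0), nrow = length(m$ids), ncol = m$width,
                  dimnames = list(m$ids, NULL)))
  mat <- do.call(rbind, strsplit(m$rows, "", fixed = TRUE))
  rownames(mat) <- m$ids
  mat
}

#' @rdname msa_matrix
#' @param mat character matrix with rownames.
#' @keywords internal
msa_from_matrix <- function(mat) {
  if (ncol(mat) == 0L) {
    rows <- rep("", nrow(mat)); names(rows) <- rownames(mat)
    return(msa(rows))
  }
  rows <- apply(mat, 1L, paste0, collapse = "")
  names(rows) <- rownames(mat)
  msa(rows)
}

#' Drop columns that are gaps in every row
#' @param m an `msa`.
#' @return an `msa` without all-gap columns.
#' @export
drop_allgap_columns <- function(m) {
  if (msa_nrow(m) == 0L || m$width == 0L) return(m)
  mat <- msa_matrix(m)
  keep <- colSums(mat != GAP) > 0L
  if (all(keep)) return(m)
  msa_from_matrix(mat[, keep, drop = FALSE])
}

#' Restrict an alignment to a subset of rows
#'
#' Keeps the given ids (in the order supplied) and, if `drop_gaps`, removes
#' columns that become all-gap in the restriction. This is the operation the
#' merge shape-preservation contract is stated in terms of.
#'
#' @param m an `msa`.
#' @param ids character vector of row ids to keep.
#' @param drop_gaps drop columns that are all-gap after restriction.
#' @return an `msa`.
#' @export
msa_restrict <- function(m, ids, drop_gaps = TRUE) {
  missing <- setdiff(ids, m$ids)
  if (length(missing))
    stop("ids not in msa: ", paste(missing, collapse = ", "))
  out <- msa(m$rows[ids])
  if (drop_gaps) drop_allgap_columns(out) else out
}

#' Per-row residue indices of an alignment
#'
#' @param m an `msa`.
#' @return integer matrix parallel to `msa_matrix(m)`: the 1-based residue
#'   (sequence position) index at each non-gap cell, 0 at gaps.
#' @keywords internal
msa_residue_index <- function(m) {
  mat <- msa_matrix(m)
  idx <- matrix(0L, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  for (r in seq_len(nrow(mat))) {
    ng <- mat[r, ] != GAP
    idx[r, ng] <- seq_len(sum(ng))
  }
  idx
}

#' Count gap characters in an alignment
#' @param m an `msa`.
#' @keywords internal
msa_gap_count <- function(m) sum(msa_matrix(m) == GAP)

#' Test whether two alignments are identical up to row order
#' @param a,b `msa` objects.
#' @return TRUE/FALSE.
#' @export
msa_identical <- function(a, b) {
  identical(a$rows[order(names(a$rows))], b$rows[order(names(b$rows))])
}
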