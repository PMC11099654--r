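#' Annotate alignment columns with secondary-structure conservation
#'
#' For each column, the fraction of structure-bearing, non-gap rows whose
#' residue carries each secondary-structure category is computed. A column
#' is conserved when some requested category reaches `threshold` with at
#' least 2 supporting rows; conserved blocks are maximal runs of conserved
#' columns of length at least `min_block`.
#'
#' @param m an [msa].
#' @param ss_map named list of `ss_string` for the structure-bearing rows.
#' @param categories secondary-structure categories to consider, subset of
#'   `c("H", "E")`.
#' @param threshold conservation threshold in `(0, 1]` (default 0.8).
#' @param min_block minimum conserved-run length to count as a block.
#' @param min_coverage minimum fraction of the structure-bearing rows that
#'   must be non-gap in a column for it to count as conserved (default
#'   0.6). Without this, a column where most rows are gaps but the few
#'   residues agree would freeze mis-stacked loop residues in place and
#'   defeat the squeeze.
#' @return a `column_annotation`: list with `fraction` and `support`
#'   (categories x width matrices), `conserved` (logical), `block_id`
#'   (integer, NA outside blocks), `loop_region` (integer, NA inside
#'   blocks), and `width`.
#' @export
annotate_columns <- function(m, ss_map, categories = c("H", "E"),
                             threshold = 0.8, min_block = 2,
                             min_coverage = 0.6) {
  stopifnot(all(categories %in% c("H", "E")), threshold > 0, threshold <= 1)
  ss_rows <- intersect(m$ids, names(ss_map))
  if (length(ss_rows) == 0L)
    stop("squeeze requires secondary structure: no structure-bearing rows")
  ssm <- ss_aligned_matrix(m, ss_map)
  W <- m$width
  frac <- matrix(0, length(categories), W,
                 dimnames = list(categories, NULL))
  support <- matrix(0L, length(categories), W,
                    dimnames = list(categories, NULL))
  nn <- colSums(!is.na(ssm))
  for (cat in categories) {
    cnt <- colSums(ssm == cat, na.rm = TRUE)
    support[cat, ] <- cnt
    frac[cat, ] <- ifelse(nn > 0, cnt / nn, 0)
  }
  covered <- nn / length(ss_rows) >= min_coverage
  conserved <- rep(FALSE, W)
  for (cat in categories)
    conserved <- conserved |
      (frac[cat, ] >= threshold & support[cat, ] >= 2 & covered)
  block_id <- rep(NA_integer_, W)
  r <- rle(conserved)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  bid <- 0L
  for (k in which(r$values & r$lengths >= min_block)) {
    bid <- bid + 1L
    block_id[starts[k]:ends[k]] <- bid
  }
  loop_region <- rep(NA_integer_, W)
  in_loop <- is.na(block_id)
  r2 <- rle(in_loop)
  ends2 <- cumsum(r2$lengths); starts2 <- ends2 - r2$lengths + 1L
  lid <- 0L
  for (k in which(r2$values)) {
    lid <- lid + 1L
    loop_region[starts2[k]:ends2[k]] <- lid
  }
  structure(list(fraction = frac, support = support, conserved = conserved,
                 block_id = block_id, loop_region = loop_region, width = W,
                 categories = categories, threshold = threshold,
                 min_block = min_block),
            class = "column_annotation")
}

#' @export
print.column_annotation <- function(x, ...) {
  nb <- length(unique(stats::na.omit(x$block_id)))
  cat(sprintf("column_annotation: %d columns, %d conserved, %d block(s)\n",
              x$width, sum(x$conserved), nb))
  invisible(x)
}

# re-align a set of ungapped segments (one per row, possibly empty) with
# sequence-only progressive DP; returns a character matrix of the packed
# region (rows in the input order)
pack_segments <- function(segs, gap_open = 4, gap_extend = 0.5) {
  ids <- names(segs)
  nz <- which(nchar(segs) > 0)
  if (length(nz) == 0L)
    return(matrix(character(0), nrow = length(segs), ncol = 0,
                  dimnames = list(ids, NULL)))
  ord <- nz[order(-nchar(segs[nz]), ids[nz])]
  first <- ord[1]
  rows <- segs[first]; names(rows) <- ids[first]
  prof <- msa(rows)
  for (i in ord[-1]) {
    rows <- segs[i]; names(rows) <- ids[i]
    prof <- profile_align(prof, msa(rows), ss_map = NULL, w_seq = 1,
                          w_ss = 0, gap_open = gap_open,
                          gap_extend = gap_extend)$msa
  }
  prof <- drop_allgap_columns(prof)
  out <- matrix(GAP, length(segs), msa_width(prof),
                dimnames = list(ids, NULL))
  pm <- msa_matrix(prof)
  out[rownames(pm), ] <- pm
  out
}

#' Squeeze loop regions towards conserved secondary-structure blocks
#'
#' Conserved-block columns are copied unchanged. In every loop region
#' between blocks (and at the termini), the per-row residue segments are
#' extracted and re-packed by sequence-only progressive re-alignment (gap
#' open 4 / extend 0.5), then all-gap columns inside the region are
#' dropped. Residues never cross block boundaries, every row still degaps
#' to its input sequence, and the total gap count never increases (a region
#' whose re-packing would widen it is left untouched).
#'
#' @param m an [msa].
#' @param annotation a `column_annotation` computed from `m`.
#' @param gap_open,gap_extend affine gap penalties of the loop re-packing.
#' @return an [msa] of width at most `msa_width(m)`.
#' @export
squeeze_msa <- function(m, annotation, gap_open = 4, gap_extend = 0.5) {
  stopifnot(annotation$width == m$width)
  mat <- msa_matrix(m)
  pieces <- list()
  block_piece <- logical(0)
  W <- m$width
  pos <- 1L
  while (pos <= W) {
    if (!is.na(annotation$block_id[pos])) {
      end <- pos
      while (end < W && !is.na(annotation$block_id[end + 1]) &&
             annotation$block_id[end + 1] == annotation$block_id[pos])
        end <- end + 1L
      pieces <- c(pieces, list(mat[, pos:end, drop = FALSE]))
      block_piece <- c(block_piece, TRUE)
    } else {
      end <- pos
      while (end < W && is.na(annotation$block_id[end + 1])) end <- end + 1L
      region <- mat[, pos:end, drop = FALSE]
      segs <- apply(region, 1, function(r) paste0(r[r != GAP], collapse = ""))
      names(segs) <- rownames(mat)
      packed <- pack_segments(segs, gap_open, gap_extend)
      if (ncol(packed) <= ncol(region)) region <- packed
      pieces <- c(pieces, list(region))
      block_piece <- c(block_piece, FALSE)
    }
    pos <- end + 1L
  }
  out <- do.call(cbind, pieces)
  rownames(out) <- rownames(mat)
  res <- msa_from_matrix(out)
  # new column indices of the (unchanged) conserved-block columns
  widths <- vapply(pieces, ncol, integer(1))
  offs <- cumsum(c(0L, widths[-length(widths)]))
  attr(res, "block_columns") <-
    unlist(lapply(which(block_piece), function(k) offs[k] + seq_len(widths[k])),
           use.names = FALSE)
  res
}
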