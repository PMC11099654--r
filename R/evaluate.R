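# canonical key of one alignment column over a set of rows: the sorted
# "row=residue-index" pairs of its non-gap cells
column_keys <- function(m, ids) {
  idx <- msa_residue_index(m)[ids, , drop = FALSE]
  vapply(seq_len(ncol(idx)), function(j) {
    ng <- idx[, j] > 0
    if (!any(ng)) return("")
    paste(ids[ng], idx[ng, j], sep = "=", collapse = "|")
  }, character(1))
}

#' Column Score of a query alignment against a reference
#'
#' Each reference column is the set of (row, residue-index) pairs it
#' contains (gaps excluded, restricted to the shared rows). A reference
#' column scores 1 when some query column contains exactly that set, 0
#' otherwise; CS is the number of matched reference columns divided by the
#' number of evaluated reference columns `m` (all columns, or those under a
#' region mask, excluding columns that are all-gap in the shared rows).
#' Matching is by residue index, not residue character, so repeated
#' residues cannot produce false matches; CS is invariant under column
#' permutation of the query.
#'
#' @param query an [msa] whose ids include all reference ids.
#' @param reference the reference [msa].
#' @param regions optional named list of logical masks over reference
#'   columns (or integer column vectors); per-region CS is reported for
#'   each.
#' @return a `cs_report`: list with `overall_cs`, `m` (evaluated columns),
#'   `matched` (count), `regions` (per-region list with `cs` and `m`),
#'   `column_score` (0/1 per reference column, NA where not evaluated) and
#'   `gap_stats` for the query.
#' @export
column_score <- function(query, reference, regions = NULL) {
  shared <- intersect(reference$ids, query$ids)
  if (length(shared) == 0L) stop("no shared ids between query and reference")
  shared <- sort(shared)
  ref_keys <- column_keys(reference, shared)
  q_keys <- column_keys(query, shared)
  evaluated <- ref_keys != ""
  score <- rep(NA_integer_, length(ref_keys))
  score[evaluated] <- as.integer(ref_keys[evaluated] %in% q_keys)
  m_eval <- sum(evaluated)
  if (m_eval == 0L) stop("reference has no evaluable columns for shared rows")
  region_out <- NULL
  if (!is.null(regions)) {
    region_out <- lapply(regions, function(mask) {
      if (!is.logical(mask)) {
        v <- rep(FALSE, length(ref_keys)); v[mask] <- TRUE; mask <- v
      }
      sel <- mask & evaluated
      list(cs = if (sum(sel)) mean(score[sel]) else NA_real_, m = sum(sel))
    })
  }
  structure(list(overall_cs = mean(score[evaluated]), m = m_eval,
                 matched = sum(score[evaluated]), regions = region_out,
                 column_score = score, gap_stats = gap_statistics(query)),
            class = "cs_report")
}

#' @export
print.cs_report <- function(x, ...) {
  cat(sprintf("Column Score: %.4f (%d/%d reference columns)\n",
              x$overall_cs, x$matched, x$m))
  for (nm in names(x$regions))
    cat(sprintf("  %-12s CS %.4f (m = %d)\n", nm, x$regions[[nm]]$cs,
                x$regions[[nm]]$m))
  cat(sprintf("  query: %d x %d, %d gaps (%.1f%%)\n",
              x$gap_stats$n_rows, x$gap_stats$width, x$gap_stats$gaps,
              100 * x$gap_stats$gap_fraction))
  invisible(x)
}

#' Descriptive gap statistics of an alignment
#'
#' @param m an [msa].
#' @param region_mask optional logical mask (or integer vector) over
#'   columns restricting the count.
#' @return list with `gaps`, `gap_fraction`, `width`, `n_rows`.
#' @export
gap_statistics <- function(m, region_mask = NULL) {
  mat <- msa_matrix(m)
  if (!is.null(region_mask)) {
    if (!is.logical(region_mask)) {
      v <- rep(FALSE, ncol(mat)); v[region_mask] <- TRUE; region_mask <- v
    }
    mat <- mat[, region_mask, drop = FALSE]
  }
  g <- sum(mat == GAP)
  list(gaps = g,
       gap_fraction = if (length(mat)) g / length(mat) else 0,
       width = ncol(mat), n_rows = nrow(mat))
}

#' Region masks from a reference annotation
#'
#' Convenience wrapper deriving the `conserved` (block columns) and `loop`
#' masks of a reference alignment from [annotate_columns], for
#' region-resolved Column Scores.
#'
#' @param annotation a `column_annotation` of the reference.
#' @return named list of logical masks (`conserved`, `loop`).
#' @export
region_masks <- function(annotation) {
  list(conserved = !is.na(annotation$block_id),
       loop = is.na(annotation$block_id))
}
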