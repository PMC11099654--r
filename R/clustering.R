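#' Pairwise sequence identity
#'
#' Global alignment (BLOSUM62, affine gap open 10 / extend 0.5, alignment
#' only) followed by the CD-HIT-style identity convention: number of
#' identical aligned residue pairs divided by the length of the shorter
#' sequence.
#'
#' @param a,b residue strings (no gaps). `a` may be a character vector, in
#'   which case one identity per element is returned.
#' @return identity fraction(s) in `[0, 1]`.
#' @export
#' @examples
#' pairwise_identity("PELICAN", "PELICANS")  # 1.0
pairwise_identity <- function(a, b) {
  stopifnot(all(nchar(a) > 0), nchar(b) > 0)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = blosum62(),
                                       gapOpening = 10, gapExtension = 0.5)
  Biostrings::nmatch(aln) / pmin(nchar(a), nchar(b))
}

#' Greedy identity clustering (CD-HIT style)
#'
#' Records are sorted by decreasing residue length (ties by id); each record
#' joins the first existing cluster whose *representative* has identity at or
#' above `threshold`, otherwise it founds a new cluster. Deterministic.
#'
#' @param records a `seq_records` data frame ([read_fasta]).
#' @param threshold fractional identity cutoff in `[0.2, 1]`.
#' @return a `cluster_set`: list with `clusters` (each `list(representative,
#'   members)`), `threshold`, `collated` (logical per cluster).
#' @export
greedy_cluster <- function(records, threshold) {
  stopifnot(threshold >= 0.2, threshold <= 1)
  ord <- order(-nchar(records$residues), records$id)
  ids <- records$id[ord]
  seqs <- records$residues[ord]
  reps <- character(0)
  rep_seqs <- character(0)
  members <- list()
  for (i in seq_along(ids)) {
    hit <- 0L
    if (length(reps)) {
      idents <- pairwise_identity(rep_seqs, seqs[i])
      ok <- which(idents >= threshold)
      if (length(ok)) hit <- ok[1]
    }
    if (hit > 0L) {
      members[[hit]] <- c(members[[hit]], ids[i])
    } else {
      reps <- c(reps, ids[i])
      rep_seqs <- c(rep_seqs, seqs[i])
      members <- c(members, list(ids[i]))
    }
  }
  clusters <- Map(function(r, m) list(representative = r, members = m),
                  reps, members)
  names(clusters) <- NULL
  structure(list(clusters = clusters, threshold = threshold,
                 collated = rep(FALSE, length(clusters))),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) length(cl$members), integer(1))
  cat(sprintf("cluster_set: %d clusters at identity >= %.2f (sizes: %s)\n",
              length(x$clusters), x$threshold,
              paste(sort(sizes, decreasing = TRUE), collapse = " ")))
  invisible(x)
}

#' Redundancy reduction by greedy clustering
#'
#' Clusters at `threshold` and keeps only the representatives; the dropped
#' map records which kept id each dropped id collapsed into.
#'
#' @inheritParams greedy_cluster
#' @return list with `kept` (ids), `dropped` (named character vector:
#'   dropped id -> representative id) and the underlying `cluster_set`.
#' @export
reduce_redundancy <- function(records, threshold = 0.9) {
  cs <- greedy_cluster(records, threshold)
  kept <- vapply(cs$clusters, function(cl) cl$representative, character(1))
  dropped <- character(0)
  for (cl in cs$clusters) {
    d <- setdiff(cl$members, cl$representative)
    if (length(d)) {
      v <- rep(cl$representative, length(d)); names(v) <- d
      dropped <- c(dropped, v)
    }
  }
  list(kept = kept, dropped = dropped, cluster_set = cs)
}

#' Build alignment subsets from a cluster set
#'
#' Clusters with at least `min_subset_size` members become subsets. Smaller
#' clusters are either pooled ("collated", largest-first first-fit into bins
#' no larger than the median large-subset size, which keeps the total subset
#' count low) or their members are labelled orphans.
#'
#' @param cluster_set a `cluster_set` from [greedy_cluster] at the subset
#'   threshold.
#' @param min_subset_size minimum members for a standalone subset (>= 2: a
#'   subset must be alignable).
#' @param collate pool small clusters instead of labelling orphans.
#' @return list with `subsets` (list of id vectors) and `orphans` (ids).
#' @export
make_subsets <- function(cluster_set, min_subset_size = 2, collate = FALSE) {
  if (min_subset_size < 2) stop("min_subset_size must be >= 2")
  sizes <- vapply(cluster_set$clusters, function(cl) length(cl$members),
                  integer(1))
  reps <- vapply(cluster_set$clusters, function(cl) cl$representative,
                 character(1))
  big <- which(sizes >= min_subset_size)
  small <- setdiff(seq_along(sizes), big)
  # deterministic order: size desc, then representative id
  big <- big[order(-sizes[big], reps[big])]
  subsets <- lapply(cluster_set$clusters[big], function(cl) cl$members)
  orphans <- character(0)
  if (length(small)) {
    small <- small[order(-sizes[small], reps[small])]
    if (!collate) {
      orphans <- unlist(lapply(cluster_set$clusters[small],
                               function(cl) cl$members), use.names = FALSE)
    } else {
      cap <- if (length(big)) max(floor(median(sizes[big])), min_subset_size)
             else max(max(sizes[small]), min_subset_size)
      bins <- list(); fill <- integer(0)
      for (k in small) {
        s <- sizes[k]
        slot <- which(fill + s <= cap)
        if (length(slot)) {
          slot <- slot[1]
          bins[[slot]] <- c(bins[[slot]], cluster_set$clusters[[k]]$members)
          fill[slot] <- fill[slot] + s
        } else {
          bins <- c(bins, list(cluster_set$clusters[[k]]$members))
          fill <- c(fill, s)
        }
      }
      subsets <- c(subsets, bins)
    }
  }
  list(subsets = subsets, orphans = orphans)
}
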