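#' Merge two alignments, preserving each one's shape
#'
#' Profile-profile global alignment over columns (column score = mean
#' pairwise BLOSUM62/4 over the non-gap residue pairs across the two
#' profiles, plus, when secondary-structure strings are supplied, a
#' weighted mean state-agreement term over the structure-bearing pairs;
#' affine gaps, open 8 / extend 0.5). The only edit applied to either input
#' is insertion of full-height gap columns, so restricting the output to
#' either input's rows and deleting the columns that are all-gap in that
#' restriction reproduces the input exactly.
#'
#' @param msa_a,msa_b [msa] objects with disjoint id sets.
#' @param ss_map optional named list of `ss_string` objects; rows present
#'   in the map contribute the SS-agreement term (weight `w_ss`), which
#'   keeps conserved secondary-structure blocks in register across
#'   low-identity subsets.
#' @param w_ss weight of the SS-agreement term (0 disables).
#' @param coords optional named list of common-frame CA coordinates (see
#'   [common_frame_coords]); rows present contribute a structural
#'   proximity term of weight `w_d` (scale `d0` Angstrom).
#' @param w_d,d0 structural proximity term parameters.
#' @param pair_loops when FALSE (and `ss_map` is given), loop-dominated
#'   columns of the two profiles are never paired with each other: loops
#'   come out as per-input gap bands, mirroring the gap inflation of
#'   joint profile merging, and are left for [squeeze_msa] to re-pack.
#'   Cross-subset loop residue pairings at low identity claim a homology
#'   the data cannot support, so the pipeline merges with
#'   `pair_loops = FALSE` by default.
#' @param gap_open,gap_extend affine gap penalties.
#' @return an [msa] containing all rows of both inputs.
#' @export
merge_two <- function(msa_a, msa_b, ss_map = NULL, w_ss = 2,
                      coords = NULL, w_d = 4, d0 = 5, pair_loops = TRUE,
                      gap_open = 8, gap_extend = 0.5) {
  if (msa_nrow(msa_b) == 0L) return(msa_a)
  if (msa_nrow(msa_a) == 0L) return(msa_b)
  profile_align(msa_a, msa_b, ss_map = ss_map, w_seq = 1,
                w_ss = if (is.null(ss_map)) 0 else w_ss,
                coords = coords, w_d = if (is.null(coords)) 0 else w_d,
                d0 = d0, pair_loops = pair_loops,
                gap_open = gap_open, gap_extend = gap_extend)$msa
}

#' Merge all subset alignments and insert orphan/structureless sequences
#'
#' Subset alignments are merged progressively, largest (row count) first,
#' ties broken by the lexicographically smallest member id; each orphan and
#' then each structureless sequence (both sorted by id) is aligned
#' individually to the growing main alignment by sequence-to-profile DP with
#' the same scoring. Full-height gap-column insertion is the only edit at
#' every step, so the shape of every original subset alignment is preserved
#' recursively. All-gap columns are dropped before returning.
#'
#' @param subset_msas list of [msa] objects (disjoint ids).
#' @param orphans,structureless `seq_records` data frames (zero rows
#'   allowed) of sequences to insert individually.
#' @param ss_map optional named list of `ss_string` objects (see
#'   [merge_two]).
#' @param coords optional named list of common-frame coordinates (see
#'   [merge_two]).
#' @param pair_loops see [merge_two].
#' @param gap_open,gap_extend affine gap penalties.
#' @return list with `msa` (the final alignment) and `origins` (data frame:
#'   id, origin = `subset_NNN` / `orphan` / `structureless`).
#' @export
merge_all <- function(subset_msas, orphans = NULL, structureless = NULL,
                      ss_map = NULL, coords = NULL, pair_loops = TRUE,
                      gap_open = 8, gap_extend = 0.5) {
  if (length(subset_msas) == 0L)
    stop("empty merge plan: no subset alignments")
  key <- vapply(subset_msas, function(m) min(m$ids), character(1))
  sizes <- vapply(subset_msas, msa_nrow, integer(1))
  ord <- order(-sizes, key)
  subset_msas <- subset_msas[ord]
  origins <- do.call(rbind, lapply(seq_along(subset_msas), function(k)
    data.frame(id = subset_msas[[k]]$ids,
               origin = sprintf("subset_%03d", ord[k]),
               stringsAsFactors = FALSE)))
  main <- subset_msas[[1]]
  for (k in seq_along(subset_msas)[-1])
    main <- merge_two(main, subset_msas[[k]], ss_map, coords = coords,
                      pair_loops = pair_loops,
                      gap_open = gap_open, gap_extend = gap_extend)
  insert_records <- function(main, recs, label) {
    if (is.null(recs) || nrow(recs) == 0L) return(main)
    recs <- recs[order(recs$id), , drop = FALSE]
    for (i in seq_len(nrow(recs))) {
      rows <- recs$residues[i]; names(rows) <- recs$id[i]
      main <- merge_two(main, msa(rows), ss_map, coords = coords,
                        pair_loops = pair_loops,
                        gap_open = gap_open, gap_extend = gap_extend)
    }
    origins <<- rbind(origins, data.frame(id = recs$id, origin = label,
                                          stringsAsFactors = FALSE))
    main
  }
  main <- insert_records(main, orphans, "orphan")
  main <- insert_records(main, structureless, "structureless")
  list(msa = drop_allgap_columns(main), origins = origins)
}

#' Check the shape-preservation contract
#'
#' @param merged the merged [msa].
#' @param original an input sub-alignment.
#' @return TRUE iff restricting `merged` to `original`'s rows and dropping
#'   all-gap columns reproduces `original` exactly.
#' @export
shape_preserved <- function(merged, original) {
  r <- msa_restrict(merged, original$ids, drop_gaps = TRUE)
  identical(r$rows[original$ids], original$rows[original$ids])
}
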