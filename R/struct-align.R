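#' Default parameters of the structure-aware aligner
#'
#' @param w_seq weight of the sequence term (BLOSUM62 / 4).
#' @param w_ss weight of the secondary-structure agreement term.
#' @param w_d weight of the structural proximity term
#'   `w_d / (1 + (d/d0)^2)` on superposed CA distances.
#' @param d0 distance scale of the proximity term, Angstrom.
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @param max_iter iteration cap of the superpose/realign loop.
#' @return named list of parameters.
#' @export
align_params <- function(w_seq = 1, w_ss = 2, w_d = 4, d0 = 5,
                         gap_open = 8, gap_extend = 0.5, max_iter = 10) {
  list(w_seq = w_seq, w_ss = w_ss, w_d = w_d, d0 = d0,
       gap_open = gap_open, gap_extend = gap_extend, max_iter = max_iter)
}

# sequence + SS score matrix for two residue strings
seq_ss_score_matrix <- function(res_a, res_b, ss_a = NULL, ss_b = NULL,
                                w_seq = 1, w_ss = 2) {
  ca <- chars(res_a); cb <- chars(res_b)
  S <- w_seq * blosum62_scaled()[ca, cb, drop = FALSE]
  if (!is.null(ss_a) && !is.null(ss_b) && w_ss != 0) {
    sa <- chars(ss_a$states); sb <- chars(ss_b$states)
    S <- S + w_ss * outer(sa, sb, "==")
  }
  unname(S)
}

# extract strictly increasing aligned index pairs from a gotoh path
path_pairs <- function(path) {
  keep <- path[, 1] > 0 & path[, 2] > 0
  path[keep, , drop = FALSE]
}

# project a pairwise path onto two gapped strings
path_to_msa <- function(path, id_a, res_a, id_b, res_b) {
  ca <- chars(res_a); cb <- chars(res_b)
  ra <- ifelse(path[, 1] > 0, ca[pmax(path[, 1], 1)], GAP)
  rb <- ifelse(path[, 2] > 0, cb[pmax(path[, 2], 1)], GAP)
  rows <- c(paste0(ra, collapse = ""), paste0(rb, collapse = ""))
  names(rows) <- c(id_a, id_b)
  msa(rows)
}

#' Iterative structure-aware pairwise alignment
#'
#' Seeds a global affine-gap alignment on sequence + secondary-structure
#' scores, superposes the two CA traces on the currently aligned pairs
#' (Kabsch), adds a structural proximity term on superposed CA distances,
#' realigns, and iterates until the aligned pair set is stable (or
#' `max_iter`). Unresolved positions contribute sequence/SS terms only.
#'
#' @param rec_a,rec_b single rows of a `seq_records` data frame (or lists
#'   with `id` and `residues`).
#' @param struct_a,struct_b `chain_structure` objects (may be NULL for a
#'   sequence-only alignment).
#' @param ss_a,ss_b `ss_string` objects or NULL.
#' @param params see [align_params].
#' @return a `pairwise_alignment`: list with `id_a`, `id_b`, `pairs`
#'   (aligned residue index pairs, strictly increasing in both coordinates),
#'   `path`, `score`, `rmsd` (NA if fewer than 3 resolved pairs), `iterations`.
#' @export
pairwise_struct_align <- function(rec_a, rec_b, struct_a = NULL,
                                  struct_b = NULL, ss_a = NULL, ss_b = NULL,
                                  params = align_params()) {
  S0 <- seq_ss_score_matrix(rec_a$residues, rec_b$residues, ss_a, ss_b,
                            params$w_seq, params$w_ss)
  fit <- gotoh_align(S0, params$gap_open, params$gap_extend)
  pairs <- path_pairs(fit$path)
  iterations <- 0L
  rmsd <- NA_real_
  if (!is.null(struct_a) && !is.null(struct_b)) {
    mask_a <- struct_a$resolved_mask; mask_b <- struct_b$resolved_mask
    repeat {
      iterations <- iterations + 1L
      res_pairs <- pairs[mask_a[pairs[, 1]] & mask_b[pairs[, 2]], ,
                         drop = FALSE]
      if (nrow(res_pairs) < 3 || iterations > params$max_iter) break
      sup <- robust_superpose(struct_a$ca[res_pairs[, 1], , drop = FALSE],
                              struct_b$ca[res_pairs[, 2], , drop = FALSE])
      rmsd <- sup$rmsd
      moved <- apply_superposition(struct_a$ca, sup)
      D2 <- outer(rowSums(moved^2), rowSums(struct_b$ca^2), "+") -
        2 * moved %*% t(struct_b$ca)
      D2[D2 < 0] <- 0
      struct_term <- params$w_d / (1 + D2 / params$d0^2)
      struct_term[is.na(struct_term)] <- 0
      fit <- gotoh_align(S0 + struct_term, params$gap_open, params$gap_extend)
      new_pairs <- path_pairs(fit$path)
      if (nrow(new_pairs) == nrow(pairs) && all(new_pairs == pairs)) {
        pairs <- new_pairs
        break
      }
      pairs <- new_pairs
    }
    res_pairs <- pairs[mask_a[pairs[, 1]] & mask_b[pairs[, 2]], ,
                       drop = FALSE]
    if (nrow(res_pairs) >= 3) {
      a_res <- struct_a$ca[res_pairs[, 1], , drop = FALSE]
      b_res <- struct_b$ca[res_pairs[, 2], , drop = FALSE]
      sup_f <- robust_superpose(a_res, b_res)
      rmsd <- sqrt(mean(rowSums((apply_superposition(a_res, sup_f) -
                                 b_res)^2)))
    }
  }
  if (nrow(pairs) == 0L)
    stop("unalignable pair: ", rec_a$id, " / ", rec_b$id)
  structure(list(id_a = rec_a$id, id_b = rec_b$id, pairs = pairs,
                 path = fit$path, score = fit$score, rmsd = rmsd,
                 iterations = iterations),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise_alignment %s/%s: %d aligned pairs, score %.2f, rmsd %s\n",
              x$id_a, x$id_b, nrow(x$pairs), x$score,
              ifelse(is.na(x$rmsd), "NA", sprintf("%.2f A", x$rmsd))))
  invisible(x)
}

# aligned per-row SS state matrix for an msa (NA at gaps and for rows
# without an SS string)
ss_aligned_matrix <- function(m, ss_map) {
  mat <- msa_matrix(m)
  idx <- msa_residue_index(m)
  out <- matrix(NA_character_, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  for (id in intersect(rownames(mat), names(ss_map))) {
    st <- chars(ss_map[[id]]$states)
    ng <- idx[id, ] > 0
    out[id, ng] <- st[idx[id, ng]]
  }
  out
}

# per-row aligned coordinate arrays (width x 3, NA at gaps/unresolved/rows
# without coordinates)
aligned_coord_rows <- function(m, coords) {
  idx <- msa_residue_index(m)
  out <- lapply(m$ids, function(id) {
    co <- coords[[id]]
    if (is.null(co)) return(NULL)
    a <- matrix(NA_real_, ncol(idx), 3)
    ng <- idx[id, ] > 0
    a[ng, ] <- co[idx[id, ng], , drop = FALSE]
    a
  })
  names(out) <- m$ids
  out
}

# mean-over-pairs profile column score matrix: sequence term over all
# non-gap residue pairs, SS agreement over pairs where both rows carry SS,
# optional structural proximity term over pairs with (common-frame)
# coordinates
profile_score_matrix <- function(mat_a, mat_b, ss_a = NULL, ss_b = NULL,
                                 w_seq = 1, w_ss = 2,
                                 co_a = NULL, co_b = NULL, w_d = 0, d0 = 5) {
  wa <- ncol(mat_a); wb <- ncol(mat_b)
  B <- blosum62_scaled()
  seq_sum <- matrix(0, wa, wb)
  cnt <- outer(colSums(mat_a != GAP), colSums(mat_b != GAP))
  for (r in seq_len(nrow(mat_a))) {
    ra <- mat_a[r, ]; nga <- ra != GAP
    ra[!nga] <- "A"
    Br <- B[ra, , drop = FALSE]
    for (s in seq_len(nrow(mat_b))) {
      rb <- mat_b[s, ]; ngb <- rb != GAP
      rb[!ngb] <- "A"
      M <- Br[, rb, drop = FALSE]
      if (!all(nga)) M[!nga, ] <- 0
      if (!all(ngb)) M[, !ngb] <- 0
      seq_sum <- seq_sum + M
    }
  }
  S <- ifelse(cnt > 0, w_seq * seq_sum / cnt, 0)
  if (!is.null(ss_a) && !is.null(ss_b) && w_ss != 0) {
    ss_sum <- matrix(0, wa, wb)
    ss_cnt <- matrix(0, wa, wb)
    for (r in seq_len(nrow(ss_a))) {
      if (all(is.na(ss_a[r, ]))) next
      oa <- !is.na(ss_a[r, ])
      for (s in seq_len(nrow(ss_b))) {
        if (all(is.na(ss_b[s, ]))) next
        ob <- !is.na(ss_b[s, ])
        both <- outer(oa, ob)
        eq <- outer(ss_a[r, ], ss_b[s, ], "==")
        eq[!both] <- FALSE
        ss_sum <- ss_sum + eq
        ss_cnt <- ss_cnt + both
      }
    }
    # symmetric agreement: +1 match, -1 mismatch (mean over SS-bearing
    # pairs), so placing strand/helix residues against coil is penalised,
    # which keeps block boundaries in register
    S <- S + ifelse(ss_cnt > 0, w_ss * (2 * ss_sum / ss_cnt - 1), 0)
  }
  if (!is.null(co_a) && !is.null(co_b) && w_d != 0) {
    str_sum <- matrix(0, wa, wb)
    str_cnt <- matrix(0, wa, wb)
    for (r in seq_along(co_a)) {
      A <- co_a[[r]]
      if (is.null(A)) next
      oka <- !is.na(A[, 1])
      if (!any(oka)) next
      ra2 <- rowSums(A^2)
      for (s in seq_along(co_b)) {
        B <- co_b[[s]]
        if (is.null(B)) next
        okb <- !is.na(B[, 1])
        if (!any(okb)) next
        D2 <- outer(ra2, rowSums(B^2), "+") - 2 * A %*% t(B)
        term <- w_d / (1 + D2 / d0^2)
        both <- outer(oka, okb)
        term[!both | is.na(term)] <- 0
        str_sum <- str_sum + term
        str_cnt <- str_cnt + both
      }
    }
    S <- S + ifelse(str_cnt > 0, str_sum / str_cnt, 0)
  }
  S
}

# align two profiles (msa objects) by global affine DP over columns; the
# only edit to either input is insertion of full-height gap columns
profile_align <- function(msa_a, msa_b, ss_map = NULL, w_seq = 1, w_ss = 0,
                          gap_open = 8, gap_extend = 0.5,
                          coords = NULL, w_d = 0, d0 = 5,
                          pair_loops = TRUE) {
  if (length(intersect(msa_a$ids, msa_b$ids)))
    stop("overlapping ids: ",
         paste(intersect(msa_a$ids, msa_b$ids), collapse = ", "))
  mat_a <- msa_matrix(msa_a); mat_b <- msa_matrix(msa_b)
  ss_a <- ss_b <- NULL
  if (!is.null(ss_map) && (w_ss != 0 || !pair_loops)) {
    ss_a <- ss_aligned_matrix(msa_a, ss_map)
    ss_b <- ss_aligned_matrix(msa_b, ss_map)
  }
  co_a <- co_b <- NULL
  if (!is.null(coords) && w_d != 0) {
    co_a <- aligned_coord_rows(msa_a, coords)
    co_b <- aligned_coord_rows(msa_b, coords)
  }
  S <- profile_score_matrix(mat_a, mat_b, ss_a, ss_b, w_seq, w_ss,
                            co_a, co_b, w_d, d0)
  if (!pair_loops && !is.null(ss_a)) {
    # do not claim residue homology between loop-dominated columns of the
    # two profiles: leave loops unpaired (full-height gap bands) for the
    # squeeze step to re-pack
    loopish <- function(ssm) {
      n <- colSums(!is.na(ssm))
      ifelse(n > 0, colSums(ssm == "C", na.rm = TRUE) / n >= 0.5, FALSE)
    }
    la <- loopish(ss_a); lb <- loopish(ss_b)
    if (any(la) && any(lb)) S[la, lb] <- S[la, lb] - 25
  }
  fit <- gotoh_align(S, gap_open, gap_extend)
  path <- fit$path
  n_steps <- nrow(path)
  out <- matrix(GAP, nrow(mat_a) + nrow(mat_b), n_steps)
  rownames(out) <- c(rownames(mat_a), rownames(mat_b))
  ia <- path[, 1] > 0
  out[seq_len(nrow(mat_a)), ia] <- mat_a[, path[ia, 1], drop = FALSE]
  ib <- path[, 2] > 0
  out[nrow(mat_a) + seq_len(nrow(mat_b)), ib] <- mat_b[, path[ib, 2],
                                                       drop = FALSE]
  list(msa = msa_from_matrix(out), path = path, score = fit$score)
}

#' Transform structures into a common coordinate frame
#'
#' Superposes every structure onto the lexicographically first structured
#' member: each member is pairwise-aligned to the reference with the
#' iterative structural aligner and fitted on the trimmed core of the
#' aligned resolved pairs. The returned coordinates make structural
#' proximity comparable across members, e.g. for profile-level structural
#' scoring during merges.
#'
#' @param records `seq_records` data frame.
#' @param structures named list of `chain_structure`.
#' @param ss_map named list of `ss_string` (optional).
#' @param params see [align_params].
#' @return named list: id -> length x 3 common-frame CA coordinates (NA
#'   rows at unresolved positions); ids without structures are absent.
#' @export
common_frame_coords <- function(records, structures, ss_map = list(),
                                params = align_params()) {
  ids <- sort(intersect(records$id, names(structures)))
  if (length(ids) == 0L) return(list())
  ref <- ids[1]
  rec <- function(id) records[records$id == id, , drop = FALSE]
  moved <- list()
  moved[[ref]] <- structures[[ref]]$ca
  for (id in ids[-1]) {
    pa <- tryCatch(
      pairwise_struct_align(rec(id), rec(ref), structures[[id]],
                            structures[[ref]], ss_map[[id]], ss_map[[ref]],
                            params),
      error = function(e) NULL)
    if (is.null(pa)) next
    rp <- pa$pairs[structures[[id]]$resolved_mask[pa$pairs[, 1]] &
                   structures[[ref]]$resolved_mask[pa$pairs[, 2]], ,
                   drop = FALSE]
    if (nrow(rp) < 3) next
    sup <- robust_superpose(structures[[id]]$ca[rp[, 1], , drop = FALSE],
                            structures[[ref]]$ca[rp[, 2], , drop = FALSE])
    moved[[id]] <- apply_superposition(structures[[id]]$ca, sup)
  }
  moved
}

#' Structure-informed alignment of one subset
#'
#' Builds a guide tree by average-linkage clustering of pairwise structural
#' alignment scores, then aligns progressively: leaf pairs by the iterative
#' structural aligner, internal nodes by profile-profile DP on mean pairwise
#' sequence + secondary-structure scores plus a structural proximity term
#' computed in a common coordinate frame (every member is superposed onto
#' the lexicographically first member through its pairwise alignment, with
#' trimmed fitting), all under the same affine gap scheme.
#' Deterministic: records are canonicalised by id and guide-tree ties break
#' lexicographically, so the result is independent of input order (rows are
#' returned sorted by id).
#'
#' @param records `seq_records` rows for the subset (>= 2 members; a
#'   singleton returns a 1-row msa with a warning).
#' @param structures named list of `chain_structure` for every member.
#' @param ss_map named list of `ss_string` (may be partial).
#' @param params see [align_params].
#' @return an [msa] over the subset members.
#' @export
align_subset <- function(records, structures, ss_map = list(),
                         params = align_params()) {
  records <- records[order(records$id), , drop = FALSE]
  n <- nrow(records)
  if (n == 0L) stop("empty subset")
  if (n == 1L) {
    warning("singleton subset: ", records$id, call. = FALSE)
    rows <- records$residues; names(rows) <- records$id
    return(msa(rows))
  }
  rec <- function(i) records[i, , drop = FALSE]
  st <- function(i) structures[[records$id[i]]]
  ssx <- function(i) ss_map[[records$id[i]]]
  pair_aln <- vector("list", n * n)
  dim(pair_aln) <- c(n, n)
  score <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pa <- pairwise_struct_align(rec(i), rec(j), st(i), st(j),
                                ssx(i), ssx(j), params)
    pair_aln[[i, j]] <- pa
    score[i, j] <- score[j, i] <- pa$score /
      max(min(nchar(records$residues[c(i, j)])), 1)
  }
  if (n == 2L) {
    pa <- pair_aln[[1, 2]]
    return(path_to_msa(pa$path, records$id[1], records$residues[1],
                       records$id[2], records$residues[2]))
  }
  # common frame: superpose every member onto member 1 through the trimmed
  # core of its pairwise alignment; the structural term of the progressive
  # stage is computed on these transformed coordinates
  moved <- vector("list", n)
  names(moved) <- records$id
  moved[[1]] <- st(1)$ca
  for (j in 2:n) {
    pa <- pair_aln[[1, j]]
    sj <- st(j)
    if (is.null(sj)) next
    rp <- pa$pairs[st(1)$resolved_mask[pa$pairs[, 1]] &
                   sj$resolved_mask[pa$pairs[, 2]], , drop = FALSE]
    if (nrow(rp) >= 3) {
      sup <- robust_superpose(sj$ca[rp[, 2], , drop = FALSE],
                              st(1)$ca[rp[, 1], , drop = FALSE])
      moved[[j]] <- apply_superposition(sj$ca, sup)
    }
  }
  d <- max(score) - score
  diag(d) <- 0
  dimnames(d) <- list(records$id, records$id)
  hc <- hclust(as.dist(d), method = "average")
  nodes <- vector("list", nrow(hc$merge))
  leaf_msa <- function(i) {
    rows <- records$residues[i]; names(rows) <- records$id[i]
    msa(rows)
  }
  for (k in seq_len(nrow(hc$merge))) {
    l <- hc$merge[k, 1]; r <- hc$merge[k, 2]
    if (l < 0 && r < 0) {
      i <- -l; j <- -r
      pa <- if (i < j) pair_aln[[i, j]] else pair_aln[[j, i]]
      nodes[[k]] <- if (i < j)
        path_to_msa(pa$path, records$id[i], records$residues[i],
                    records$id[j], records$residues[j])
      else
        path_to_msa(pa$path, records$id[j], records$residues[j],
                    records$id[i], records$residues[i])
    } else {
      ma <- if (l < 0) leaf_msa(-l) else nodes[[l]]
      mb <- if (r < 0) leaf_msa(-r) else nodes[[r]]
      nodes[[k]] <- profile_align(ma, mb, ss_map, w_seq = params$w_seq,
                                  w_ss = params$w_ss,
                                  gap_open = params$gap_open,
                                  gap_extend = params$gap_extend,
                                  coords = moved, w_d = params$w_d,
                                  d0 = params$d0)$msa
    }
  }
  out <- nodes[[length(nodes)]]
  msa(out$rows[sort(out$ids)])
}
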