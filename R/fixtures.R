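#' Architecture elements for the synthetic family generator
#'
#' A family architecture is an ordered list of secondary-structure blocks
#' (helix or strand, fixed length, no indels) alternating with loops
#' (variable length; loops carry all indels).
#'
#' @param type `"H"` or `"E"`.
#' @param length block length in residues.
#' @return an architecture element.
#' @export
ss_block <- function(type, length) {
  stopifnot(type %in% c("H", "E"), length >= 3)
  list(kind = type, len = as.integer(length))
}

#' @rdname ss_block
#' @param min_len,max_len loop length bounds.
#' @export
ss_loop <- function(min_len, max_len) {
  stopifnot(min_len >= 0, max_len >= min_len)
  list(kind = "loop", min = as.integer(min_len), max = as.integer(max_len))
}

#' @rdname ss_block
#' @param n_units number of strand-loop-helix-loop repeat units before the
#'   closing strand (a beta-alpha-beta repeat architecture, the conserved
#'   core layout of e.g. TIM-barrel-like folds).
#' @export
bab_architecture <- function(n_units = 2) {
  out <- list()
  for (k in seq_len(n_units))
    out <- c(out, list(ss_block("E", 6), ss_loop(2, 6),
                       ss_block("H", 10), ss_loop(2, 6)))
  c(out, list(ss_block("E", 6)))
}

#' Specification of a synthetic protein family
#'
#' The generator emulates a protein family with conserved secondary-
#' structure blocks, loop-borne indels, a planted clade structure, matching
#' ideal backbone coordinates, and a ground-truth alignment. Mean pairwise
#' identity is calibrated by bisection on the per-edge substitution
#' probability, measured with [pairwise_identity].
#'
#' @param n_sequences number of sequences.
#' @param architecture list of [ss_block]/[ss_loop] elements.
#' @param target_identity target mean pairwise identity (all pairs), in
#'   `[0.15, 0.95]`, or 1 for a mutation-free family.
#' @param within_identity,between_identity optional separate identity
#'   targets for within-clade and between-clade pairs (override
#'   `target_identity`).
#' @param n_clades planted clade (subset) count.
#' @param indel_rate expected indel events per loop per sequence (Poisson);
#'   indel lengths are geometric (p = 0.5).
#' @param tree `"balanced"` (default; graded divergence) or `"star"`.
#' @param substitution_prob per-edge per-site substitution probability;
#'   bypasses identity calibration when given (0 = clonal family).
#' @param seed RNG seed; identical spec + seed gives byte-identical output.
#' @return a `family_spec` list.
#' @export
family_spec <- function(n_sequences = 8, architecture = bab_architecture(2),
                        target_identity = 0.3, within_identity = NULL,
                        between_identity = NULL, n_clades = 1,
                        indel_rate = 0.3, tree = c("balanced", "star"),
                        substitution_prob = NULL, seed = 1) {
  tree <- match.arg(tree)
  stopifnot(n_sequences >= 1, n_clades >= 1, n_clades <= n_sequences,
            indel_rate >= 0)
  if (is.null(substitution_prob) && is.null(within_identity))
    stopifnot(target_identity >= 0.15, target_identity <= 1)
  structure(list(n_sequences = as.integer(n_sequences),
                 architecture = architecture,
                 target_identity = target_identity,
                 within_identity = within_identity,
                 between_identity = between_identity,
                 n_clades = as.integer(n_clades), indel_rate = indel_rate,
                 tree = tree, substitution_prob = substitution_prob,
                 seed = as.integer(seed)),
            class = "family_spec")
}

# --- ideal backbone geometry --------------------------------------------

# canonical alpha-helix CA trace: rise 1.5 A/residue, 100 deg/residue,
# radius 2.3 A, axis along x
helix_coords <- function(len, x0) {
  t <- seq_len(len) - 1
  cbind(x0 + 1.5 * t, 2.3 * cos(t * 100 * pi / 180),
        2.3 * sin(t * 100 * pi / 180))
}

# extended strand: zigzag with CA-CA 3.8 A along x
strand_coords <- function(len, x0) {
  t <- seq_len(len) - 1
  cbind(x0 + 3.3 * t, 0.95 * (-1)^t, 0)
}

# self-avoiding random walk, step 3.8 A, from a start point
loop_coords <- function(len, start) {
  if (len == 0L) return(matrix(numeric(0), 0, 3))
  out <- matrix(0, len, 3)
  prev <- start
  for (i in seq_len(len)) {
    for (try in 1:20) {
      v <- stats::rnorm(3)
      cand <- prev + 3.8 * v / sqrt(sum(v^2))
      if (i == 1L || all(sqrt(rowSums(sweep(out[seq_len(i - 1), , drop = FALSE],
                                            2, cand)^2)) > 3.0)) break
    }
    out[i, ] <- cand
    prev <- cand
  }
  out
}

# --- sequence evolution --------------------------------------------------

# substitute each site with probability q, uniformly over the 19 other
# residues; draws a fixed amount of randomness regardless of q so the
# random stream stays aligned across calibration steps
mutate_seq <- function(res, q) {
  L <- length(res)
  u <- runif(L)
  shift <- sample.int(19L, L, replace = TRUE)
  hit <- u < q
  o <- match(res[hit], AA20)
  res[hit] <- AA20[((o - 1L + shift[hit]) %% 20L) + 1L]
  res
}

# balanced-binary (or star) descent from one ancestor to n leaves, one
# mutation edge per tree edge
descend <- function(res, n, q, tree) {
  if (tree == "star")
    return(lapply(seq_len(n), function(i) mutate_seq(res, q)))
  recurse <- function(res, n) {
    if (n == 1L) return(list(res))
    nl <- ceiling(n / 2)
    c(recurse(mutate_seq(res, q), nl), recurse(mutate_seq(res, q), n - nl))
  }
  recurse(res, n)
}

# one deterministic draw of the family for given edge probabilities
generate_raw <- function(spec, q_within, q_between) {
  set.seed(spec$seed)
  arch <- spec$architecture
  n <- spec$n_sequences
  # ancestor: realized loop lengths + residues, per element
  anc <- lapply(arch, function(el) {
    len <- if (el$kind == "loop") {
      if (el$max > el$min) sample(el$min:el$max, 1) else el$min
    } else el$len
    sample(AA20, len, replace = TRUE)
  })
  clade_of <- sort(rep_len(seq_len(spec$n_clades), n))
  clade_sizes <- tabulate(clade_of, spec$n_clades)
  anc_flat <- unlist(anc)
  clade_anc <- lapply(seq_len(spec$n_clades), function(k)
    mutate_seq(anc_flat, q_between))
  leaves <- vector("list", n)
  pos <- 1L
  for (k in seq_len(spec$n_clades)) {
    kids <- descend(clade_anc[[k]], clade_sizes[k], q_within, spec$tree)
    leaves[pos:(pos + clade_sizes[k] - 1L)] <- kids
    pos <- pos + clade_sizes[k]
  }
  el_len <- vapply(anc, length, integer(1))
  el_end <- cumsum(el_len)
  el_start <- el_end - el_len + 1L
  # split each leaf back into elements; apply loop indels at the leaf
  fam <- vector("list", n)
  for (i in seq_len(n)) {
    els <- lapply(seq_along(arch), function(e)
      leaves[[i]][seq(el_start[e], length.out = el_len[e])])
    for (e in seq_along(arch)) {
      el <- arch[[e]]
      if (el$kind != "loop") next
      n_ev <- rpois(1, spec$indel_rate)
      delta <- 0L
      if (n_ev > 0) {
        lens <- rgeom(n_ev, 0.5) + 1L
        signs <- sample(c(-1L, 1L), n_ev, replace = TRUE)
        delta <- sum(signs * lens)
      }
      L_t <- max(el$min, min(el$max, length(els[[e]]) + delta))
      cur <- els[[e]]
      extra <- L_t - length(cur)
      if (extra < 0) cur <- cur[seq_len(L_t)]
      if (extra > 0) cur <- c(cur, sample(AA20, extra, replace = TRUE))
      els[[e]] <- cur
    }
    fam[[i]] <- els
  }
  list(fam = fam, arch = arch, clade_of = clade_of)
}

# mean pairwise identity of a raw family over (a sample of) pairs
realized_identity <- function(fam, pairs) {
  seqs <- vapply(fam, function(els) paste0(unlist(els), collapse = ""),
                 character(1))
  mean(vapply(seq_len(nrow(pairs)), function(k)
    pairwise_identity(seqs[pairs[k, 1]], seqs[pairs[k, 2]]), numeric(1)))
}

pair_sample <- function(idx_a, idx_b = NULL, max_pairs = 36) {
  if (is.null(idx_b)) {
    pr <- t(utils::combn(idx_a, 2))
  } else {
    pr <- as.matrix(expand.grid(idx_a, idx_b))
  }
  if (nrow(pr) > max_pairs)
    pr <- pr[round(seq(1, nrow(pr), length.out = max_pairs)), , drop = FALSE]
  pr
}

calibrate <- function(spec, measure_pairs, target, q_between_of,
                      lo = 0, hi = 0.9, steps = 50, tol = 0.02) {
  f <- function(q) {
    raw <- generate_raw(spec, q, q_between_of(q))
    realized_identity(raw$fam, measure_pairs)
  }
  if (f(lo) < target - 0.05)
    stop("unreachable identity target ", target, ": even zero substitution ",
         "gives identity ", round(f(lo), 3))
  best <- lo
  for (s in seq_len(steps)) {
    mid <- (lo + hi) / 2
    v <- f(mid)
    best <- mid
    if (abs(v - target) <= tol) return(mid)
    if (v > target) lo <- mid else hi <- mid
  }
  v <- f(best)
  if (abs(v - target) > 0.05)
    stop("unreachable identity target ", target, " after ", steps,
         " bisection steps (realized ", round(v, 3), ")")
  best
}

#' Generate a synthetic protein family with ground truth
#'
#' Samples an ancestor under the architecture, evolves descendants along a
#' balanced binary (or star) tree with identity-calibrated per-site
#' substitution, applies loop indels, builds ideal backbone coordinates
#' (canonical helix/strand geometry shared across the family, per-sequence
#' random-walk loops), and returns the true alignment (block columns
#' gapless; loops left-justified, since each loop position k descends from
#' ancestor loop position k).
#'
#' @param spec a [family_spec].
#' @return list with `records` (a `seq_records` data frame) and `truth`
#'   (class `family_truth`): `msa`, `ss` (named `ss_string` list),
#'   `structures` (named `chain_structure` list), `clades` (named integer),
#'   `block_mask` (logical over truth columns), `regions` (element table
#'   with truth column ranges), `q_within`, `q_between`,
#'   `realized_identity`.
#' @export
generate_family <- function(spec) {
  n <- spec$n_sequences
  clade_of <- sort(rep_len(seq_len(spec$n_clades), n))
  if (!is.null(spec$substitution_prob)) {
    q_w <- spec$substitution_prob
    q_b <- min(2 * q_w, 0.95)
  } else if (!is.null(spec$within_identity)) {
    stopifnot(!is.null(spec$between_identity), spec$n_clades >= 2)
    within_pairs <- do.call(rbind, lapply(seq_len(spec$n_clades), function(k) {
      idx <- which(clade_of == k)
      if (length(idx) >= 2) t(utils::combn(idx, 2)) else NULL
    }))
    q_w <- calibrate(spec, within_pairs, spec$within_identity,
                     q_between_of = function(q) 0)
    between_pairs <- pair_sample(which(clade_of == 1),
                                 which(clade_of != 1))
    q_b <- calibrate_between(spec, between_pairs, spec$between_identity, q_w)
  } else if (spec$target_identity >= 0.999) {
    q_w <- 0; q_b <- 0
  } else {
    all_pairs <- pair_sample(seq_len(n))
    q_w <- calibrate(spec, all_pairs, spec$target_identity,
                     q_between_of = function(q) min(2 * q, 0.95))
    q_b <- min(2 * q_w, 0.95)
  }
  raw <- generate_raw(spec, q_w, q_b)
  build_family(spec, raw, q_w, q_b)
}

calibrate_between <- function(spec, pairs, target, q_w,
                              lo = 0, hi = 0.95, steps = 50, tol = 0.02) {
  f <- function(qb) {
    raw <- generate_raw(spec, q_w, qb)
    realized_identity(raw$fam, pairs)
  }
  best <- lo
  for (s in seq_len(steps)) {
    mid <- (lo + hi) / 2
    v <- f(mid)
    best <- mid
    if (abs(v - target) <= tol) return(mid)
    if (v > target) lo <- mid else hi <- mid
  }
  if (abs(f(best) - target) > 0.05)
    stop("unreachable between-clade identity target ", target)
  best
}

build_family <- function(spec, raw, q_w, q_b) {
  n <- spec$n_sequences
  arch <- raw$arch
  ids <- sprintf("seq%03d", seq_len(n))
  # truth region widths
  widths <- vapply(seq_along(arch), function(e) {
    if (arch[[e]]$kind == "loop")
      max(vapply(raw$fam, function(els) length(els[[e]]), integer(1)))
    else arch[[e]]$len
  }, integer(1))
  rows <- character(n)
  ss_strings <- character(n)
  for (i in seq_len(n)) {
    parts <- character(length(arch))
    ssp <- character(length(arch))
    for (e in seq_along(arch)) {
      seg <- paste0(raw$fam[[i]][[e]], collapse = "")
      if (arch[[e]]$kind == "loop") {
        parts[e] <- paste0(seg, strrep(GAP, widths[e] - nchar(seg)))
        ssp[e] <- strrep("C", nchar(seg))
      } else {
        parts[e] <- seg
        ssp[e] <- strrep(arch[[e]]$kind, nchar(seg))
      }
    }
    rows[i] <- paste0(parts, collapse = "")
    ss_strings[i] <- paste0(ssp, collapse = "")
  }
  names(rows) <- ids
  truth_msa <- msa(rows)
  ends <- cumsum(widths); starts <- ends - widths + 1L
  block_mask <- rep(FALSE, sum(widths))
  for (e in seq_along(arch))
    if (arch[[e]]$kind != "loop") block_mask[starts[e]:ends[e]] <- TRUE
  regions <- data.frame(kind = vapply(arch, `[[`, "", "kind"),
                        start = starts, end = ends,
                        stringsAsFactors = FALSE)
  # coordinates: blocks at canonical offsets, loops per-sequence walks
  block_x0 <- numeric(length(arch))
  x <- 0
  for (e in seq_along(arch)) {
    block_x0[e] <- x
    ext <- if (arch[[e]]$kind == "H") 1.5 * arch[[e]]$len
           else if (arch[[e]]$kind == "E") 3.3 * arch[[e]]$len
           else 3.8 * 2   # nominal loop allowance
    x <- x + ext + 12
  }
  structures <- vector("list", n)
  for (i in seq_len(n)) {
    pieces <- vector("list", length(arch))
    prev_end <- c(0, 0, 0)
    for (e in seq_along(arch)) {
      el <- arch[[e]]
      len_e <- length(raw$fam[[i]][[e]])
      pieces[[e]] <- if (el$kind == "H") helix_coords(len_e, block_x0[e])
        else if (el$kind == "E") strand_coords(len_e, block_x0[e])
        else loop_coords(len_e, prev_end)
      if (len_e > 0) prev_end <- pieces[[e]][len_e, ]
    }
    ca <- do.call(rbind, pieces)
    structures[[i]] <- chain_structure(ids[i], ca)
  }
  names(structures) <- ids
  ss <- Map(ss_string, ids, ss_strings)
  names(ss) <- ids
  records <- data.frame(id = ids, description = "synthetic family member",
                        residues = vapply(rows, degap, character(1),
                                          USE.NAMES = FALSE),
                        uniprot_id = NA_character_, status = "unmatched",
                        stringsAsFactors = FALSE)
  class(records) <- c("seq_records", "data.frame")
  clades <- raw$clade_of
  names(clades) <- ids
  truth <- structure(list(msa = truth_msa, ss = ss, structures = structures,
                          clades = clades, block_mask = block_mask,
                          regions = regions, q_within = q_w, q_between = q_b),
                     class = "family_truth")
  list(records = records, truth = truth)
}

#' @export
print.family_truth <- function(x, ...) {
  cat(sprintf("family_truth: %d sequences, %d truth columns (%d block), %d clade(s)\n",
              msa_nrow(x$msa), msa_width(x$msa), sum(x$block_mask),
              max(x$clades)))
  invisible(x)
}

#' Emulate gap inflation of a group-wise profile merge
#'
#' Takes a block-correct alignment and re-lays every loop region so that
#' each group's loop segments occupy their own column band (groups in
#' index order, segments left-justified within the band). This reproduces
#' the loop-gap inflation that joint profile merging of dissimilar
#' subsets produces in practice — conserved blocks stay aligned while
#' loop regions accumulate group-sized gap slabs — and is the canonical
#' slack-bearing input for [squeeze_msa].
#'
#' @param m a block-correct [msa] (e.g. the truth alignment of
#'   [generate_family]).
#' @param block_mask logical mask of conserved-block columns of `m`.
#' @param groups named integer vector (id -> group index).
#' @return an [msa] with identical block columns and strictly more loop
#'   gaps whenever at least two groups carry loop residues in a region.
#' @export
inflate_loops <- function(m, block_mask, groups) {
  mat <- msa_matrix(m)
  groups <- groups[rownames(mat)]
  r <- rle(block_mask)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  pieces <- list()
  for (k in seq_along(r$values)) {
    region <- mat[, starts[k]:ends[k], drop = FALSE]
    if (r$values[k]) {
      pieces <- c(pieces, list(region))
      next
    }
    segs <- apply(region, 1, function(x) paste0(x[x != GAP], collapse = ""))
    bands <- lapply(sort(unique(groups)), function(g) {
      rows <- which(groups == g)
      w <- max(nchar(segs[rows]), 0)
      band <- matrix(GAP, nrow(mat), w)
      for (i in rows) {
        s <- chars(segs[i])
        if (length(s)) band[i, seq_along(s)] <- s
      }
      band
    })
    pieces <- c(pieces, bands)
  }
  out <- do.call(cbind, pieces)
  rownames(out) <- rownames(mat)
  drop_allgap_columns(msa_from_matrix(out))
}

#' Mark a fraction of a structure as unresolved
#'
#' Removes the coordinates of one contiguous segment covering the stated
#' fraction of positions (rounded), emulating a partially resolved model.
#'
#' @param chain a `chain_structure`.
#' @param unresolved_fraction fraction in `[0, 1]`.
#' @param seed RNG seed for the segment placement.
#' @return a degraded `chain_structure`.
#' @export
degrade_structure <- function(chain, unresolved_fraction, seed = 1) {
  stopifnot(unresolved_fraction >= 0, unresolved_fraction <= 1)
  k <- round(unresolved_fraction * chain$length)
  if (k == 0L) return(chain)
  set.seed(seed)
  start <- sample.int(chain$length - k + 1L, 1)
  ca <- chain$ca
  ca[seq(start, length.out = k), ] <- NA_real_
  chain_structure(chain$id, ca)
}

#' Write a complete fixture bundle to a directory
#'
#' Writes `family.fasta`, `truth.aln.fasta`, one CA-trace `<id>.pdb` and one
#' `<id>.ss.fasta` per sequence, and `clades.tsv` — a bundle directly
#' consumable by [run_pipeline] (sequences + structure directory).
#'
#' @param fam output of [generate_family].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_family_bundle <- function(fam, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(fam$records, file.path(dir, "family.fasta"))
  write_msa(fam$truth$msa, file.path(dir, "truth.aln.fasta"))
  for (id in fam$records$id) {
    write_ca_pdb(fam$truth$structures[[id]],
                 fam$records$residues[fam$records$id == id],
                 file.path(dir, paste0(id, ".pdb")))
    write_ss_fasta(fam$truth$ss[[id]], file.path(dir, paste0(id, ".ss.fasta")))
  }
  write.table(data.frame(id = names(fam$truth$clades),
                         clade = as.integer(fam$truth$clades)),
              file.path(dir, "clades.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
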