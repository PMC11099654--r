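# Independent oracles used to freeze expected values. These deliberately
# avoid the code paths they check.

# Horn's closed-form quaternion superposition: returns the least-squares
# rmsd via the largest eigenvalue of the 4x4 profile matrix. Independent of
# the SVD-based Kabsch implementation.
quat_rmsd <- function(A, B) {
  ac <- scale(A, scale = FALSE)
  bc <- scale(B, scale = FALSE)
  M <- t(ac) %*% bc
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE)$values)
  e2 <- sum(ac^2) + sum(bc^2) - 2 * lam
  sqrt(max(e2, 0) / nrow(A))
}

# Brute-force Column Score: every reference column's (row, residue-index)
# set is compared against every query column by set equality. This restates
# the definition directly; no key hashing, no indexing.
cs_oracle <- function(query, reference) {
  shared <- sort(intersect(reference$ids, query$ids))
  col_sets <- function(m) {
    mat <- foldmsa:::msa_matrix(m)[shared, , drop = FALSE]
    idx <- matrix(0L, nrow(mat), ncol(mat))
    for (r in seq_len(nrow(mat))) {
      ng <- mat[r, ] != "-"
      idx[r, ng] <- seq_len(sum(ng))
    }
    lapply(seq_len(ncol(mat)), function(j) {
      rows <- which(idx[, j] > 0L)
      if (!length(rows)) return(NULL)
      cbind(rows, idx[rows, j])
    })
  }
  ref_sets <- col_sets(reference)
  q_sets <- col_sets(query)
  evaluated <- !vapply(ref_sets, is.null, logical(1))
  hits <- vapply(which(evaluated), function(i) {
    any(vapply(q_sets, function(qs)
      !is.null(qs) && nrow(qs) == nrow(ref_sets[[i]]) &&
        all(qs == ref_sets[[i]]), logical(1)))
  }, logical(1))
  list(cs = mean(hits), m = sum(evaluated), matched = sum(hits))
}

# random ungapped protein-like sequences
random_seqs <- function(n, len_range = c(8, 25)) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  seqs <- vapply(seq_len(n), function(i)
    paste0(sample(aa, sample(len_range[1]:len_range[2], 1),
                  replace = TRUE), collapse = ""), character(1))
  names(seqs) <- sprintf("r%02d", seq_len(n))
  seqs
}

# insert random gaps into each sequence up to a common width; rows stay
# row-conserving by construction
random_gapping <- function(seqs, extra = 6) {
  width <- max(nchar(seqs)) + extra
  rows <- vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    pos <- sort(sample(width, length(ch)))
    row <- rep("-", width)
    row[pos] <- ch
    paste0(row, collapse = "")
  }, character(1))
  drop_allgap_columns(msa(rows))
}

# random seq_records data frame
random_records <- function(n, len_range = c(8, 25)) {
  seqs <- random_seqs(n, len_range)
  structure(data.frame(id = names(seqs), description = "",
                       residues = unname(seqs), uniprot_id = NA_character_,
                       status = "unmatched", stringsAsFactors = FALSE),
            class = c("seq_records", "data.frame"))
}
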