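random_rigid <- function() {
  # uniform-ish random rotation from QR of a Gaussian matrix, det +1
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

test_that("kabsch superposition is exact on identical and rigidly moved sets", {
  set.seed(4)
  A <- matrix(rnorm(30), 10)
  s <- kabsch_superpose(A, A)
  expect_equal(s$rmsd, 0)
  expect_equal(s$rotation, diag(3), tolerance = 1e-10)

  B <- A %*% random_rigid() + matrix(rep(c(3, -1, 2), each = 10), 10)
  s2 <- kabsch_superpose(A, B)
  expect_lte(s2$rmsd, 1e-6)
  expect_equal(crossprod(s2$rotation), diag(3), tolerance = 1e-8)
  expect_equal(det(s2$rotation), 1, tolerance = 1e-8)
  expect_error(kabsch_superpose(A[1:2, ], B[1:2, ]), "3")
})

test_that("kabsch rmsd matches the quaternion oracle on random instances", {
  set.seed(11)
  for (i in 1:100) {
    A <- matrix(rnorm(24), 8)
    B <- matrix(rnorm(24), 8)
    expect_equal(kabsch_superpose(A, B)$rmsd, quat_rmsd(A, B),
                 tolerance = 1e-8)
  }
})

test_that("kabsch rmsd on a planted displacement matches direct evaluation", {
  set.seed(5)
  A <- matrix(rnorm(30), 10)
  disp <- matrix(rnorm(30), 10)
  disp <- disp / sqrt(rowSums(disp^2))       # 1 A per-point displacement
  B <- A + disp
  s <- kabsch_superpose(A, B)
  fit <- sweep(A %*% s$rotation, 2, s$translation, "+")
  expect_equal(s$rmsd, sqrt(mean(rowSums((fit - B)^2))), tolerance = 1e-12)
  expect_equal(s$rmsd, quat_rmsd(A, B), tolerance = 1e-8)
})

test_that("a sequence aligned with itself is the identity alignment", {
  fam <- two_clade_family()
  r <- fam$records[1, ]
  r2 <- r; r2$id <- "copy"
  pa <- pairwise_struct_align(r, r2, fam$truth$structures[[r$id]],
                              fam$truth$structures[[r$id]],
                              fam$truth$ss[[r$id]], fam$truth$ss[[r$id]])
  L <- nchar(r$residues)
  expect_equal(pa$pairs, cbind(1:L, 1:L), ignore_attr = TRUE)
  expect_equal(pa$rmsd, 0, tolerance = 1e-9)
})

test_that("pairwise alignments never cross and terminate within the bound", {
  fam <- two_clade_family()
  ids <- fam$records$id
  # same fold, different clades (~low identity, different loop lengths)
  a <- which(fam$truth$clades == 1)[1]
  b <- which(fam$truth$clades == 2)[1]
  pa <- pairwise_struct_align(fam$records[a, ], fam$records[b, ],
                              fam$truth$structures[[ids[a]]],
                              fam$truth$structures[[ids[b]]],
                              fam$truth$ss[[ids[a]]], fam$truth$ss[[ids[b]]])
  expect_true(all(diff(pa$pairs[, 1]) > 0))
  expect_true(all(diff(pa$pairs[, 2]) > 0))
  expect_lte(pa$iterations, 11)

  # unrelated random-walk structures with random sequences still converge
  set.seed(21)
  recs <- random_records(2, c(30, 40))
  st1 <- chain_structure("r01", foldmsa:::loop_coords(nchar(recs$residues[1]),
                                                      c(0, 0, 0)))
  st2 <- chain_structure("r02", foldmsa:::loop_coords(nchar(recs$residues[2]),
                                                      c(0, 0, 0)))
  pa2 <- pairwise_struct_align(recs[1, ], recs[2, ], st1, st2)
  expect_lte(pa2$iterations, 11)
})

test_that("planted homologous block pairs are recovered at low identity", {
  fam <- two_clade_family()
  ids <- fam$records$id
  a <- which(fam$truth$clades == 1)[1]
  b <- which(fam$truth$clades == 2)[1]
  pa <- pairwise_struct_align(fam$records[a, ], fam$records[b, ],
                              fam$truth$structures[[ids[a]]],
                              fam$truth$structures[[ids[b]]],
                              fam$truth$ss[[ids[a]]], fam$truth$ss[[ids[b]]])
  # ground truth correspondence from the true MSA
  idx <- foldmsa:::msa_residue_index(fam$truth$msa)
  block_cols <- which(fam$truth$block_mask)
  truth_pairs <- cbind(idx[ids[a], block_cols], idx[ids[b], block_cols])
  got <- paste(pa$pairs[, 1], pa$pairs[, 2])
  recovered <- mean(paste(truth_pairs[, 1], truth_pairs[, 2]) %in% got)
  expect_gte(recovered, 0.95)
})

test_that("align_subset base case equals the pairwise alignment", {
  fam <- two_clade_family()
  ids <- fam$records$id[1:2]
  m <- align_subset(fam$records[1:2, ], fam$truth$structures[ids],
                    fam$truth$ss[ids])
  pa <- pairwise_struct_align(fam$records[1, ], fam$records[2, ],
                              fam$truth$structures[[ids[1]]],
                              fam$truth$structures[[ids[2]]],
                              fam$truth$ss[[ids[1]]], fam$truth$ss[[ids[2]]])
  proj <- foldmsa:::path_to_msa(pa$path, ids[1],
                                fam$records$residues[1], ids[2],
                                fam$records$residues[2])
  expect_true(msa_identical(m, proj))
})

test_that("subset alignment recovers conserved blocks and is order-independent", {
  fam <- cached_family("subset6", family_spec(
    n_sequences = 6, target_identity = 0.4,
    architecture = bab_architecture(2), indel_rate = 0.3, seed = 19))
  ids <- fam$records$id
  m <- align_subset(fam$records, fam$truth$structures, fam$truth$ss)
  # row conservation
  for (id in ids)
    expect_equal(foldmsa:::degap(m$rows[[id]]),
                 fam$records$residues[fam$records$id == id])
  # every conserved-block column contains >= 5/6 planted homologous residues
  cs <- column_score(m, fam$truth$msa,
                     regions = list(blocks = fam$truth$block_mask))
  expect_gte(cs$regions$blocks$cs, 5 / 6)

  perm <- sample(nrow(fam$records))
  m2 <- align_subset(fam$records[perm, ], fam$truth$structures,
                     fam$truth$ss)
  expect_true(msa_identical(m, m2))

  # singleton subset warns and returns one row
  expect_warning(m1 <- align_subset(fam$records[1, ],
                                    fam$truth$structures[ids[1]],
                                    fam$truth$ss[ids[1]]), "singleton")
  expect_equal(msa_nrow(m1), 1)
})

test_that("subset alignment is invariant under rigid motion of a member", {
  fam <- two_clade_family()
  ids <- fam$records$id[1:4]
  st <- fam$truth$structures[ids]
  m1 <- align_subset(fam$records[1:4, ], st, fam$truth$ss[ids])
  set.seed(33)
  R <- random_rigid()
  st[[2]] <- chain_structure(ids[2],
                             st[[2]]$ca %*% R +
                               matrix(rep(c(12, -5, 8), each = st[[2]]$length),
                                      st[[2]]$length))
  m2 <- align_subset(fam$records[1:4, ], st, fam$truth$ss[ids])
  expect_true(msa_identical(m1, m2))
})
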