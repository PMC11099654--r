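test_that("a mutation-free spec yields a clonal, gapless family", {
  fam <- generate_family(family_spec(
    n_sequences = 5, substitution_prob = 0, indel_rate = 0,
    architecture = bab_architecture(1), seed = 2))
  expect_length(unique(fam$records$residues), 1)
  expect_equal(foldmsa:::msa_gap_count(fam$truth$msa), 0)
})

test_that("realized identity is calibrated to the target", {
  fam <- cached_family("ident8", family_spec(
    n_sequences = 8, target_identity = 0.3,
    architecture = bab_architecture(2), indel_rate = 0.3, seed = 7))
  pr <- t(combn(8, 2))
  idents <- vapply(seq_len(nrow(pr)), function(k)
    pairwise_identity(fam$records$residues[pr[k, 1]],
                      fam$records$residues[pr[k, 2]]), numeric(1))
  expect_gte(mean(idents), 0.25)
  expect_lte(mean(idents), 0.35)
  # targets outside the supported band are rejected up front
  expect_error(family_spec(n_sequences = 4, target_identity = 0.05),
               "target_identity")
})

test_that("planted clade structure separates at the designed thresholds", {
  fam <- cached_family("sep2", family_spec(
    n_sequences = 8, n_clades = 2, within_identity = 0.6,
    between_identity = 0.25, architecture = bab_architecture(2),
    indel_rate = 0.2, tree = "star", seed = 5))
  cl <- fam$truth$clades
  pr <- t(combn(8, 2))
  idents <- vapply(seq_len(nrow(pr)), function(k)
    pairwise_identity(fam$records$residues[pr[k, 1]],
                      fam$records$residues[pr[k, 2]]), numeric(1))
  same <- cl[pr[, 1]] == cl[pr[, 2]]
  expect_gt(min(idents[same]), 0.45)
  expect_lt(max(idents[!same]), 0.45)
  cs <- greedy_cluster(fam$records, 0.45)
  expect_length(cs$clusters, 2)
})

test_that("the truth bundle is internally consistent", {
  fam <- cached_family("ident8", family_spec(
    n_sequences = 8, target_identity = 0.3,
    architecture = bab_architecture(2), indel_rate = 0.3, seed = 7))
  # degapped truth rows equal the emitted sequences
  for (id in fam$records$id)
    expect_equal(foldmsa:::degap(fam$truth$msa$rows[[id]]),
                 fam$records$residues[fam$records$id == id])
  # block columns are gapless
  mat <- foldmsa:::msa_matrix(fam$truth$msa)
  expect_false(any(mat[, fam$truth$block_mask] == "-"))
  # SS strings parallel to sequences; structures fully resolved
  for (id in fam$records$id) {
    L <- nchar(fam$records$residues[fam$records$id == id])
    expect_equal(nchar(fam$truth$ss[[id]]$states), L)
    expect_equal(fam$truth$structures[[id]]$length, L)
    expect_true(all(fam$truth$structures[[id]]$resolved_mask))
  }
})

test_that("generation is deterministic for identical spec and seed", {
  sp <- family_spec(n_sequences = 6, target_identity = 0.4,
                    architecture = bab_architecture(1), indel_rate = 0.3,
                    seed = 11)
  f1 <- generate_family(sp)
  f2 <- generate_family(sp)
  expect_identical(f1$records, f2$records)
  expect_identical(f1$truth$msa$rows, f2$truth$msa$rows)
  expect_identical(f1$truth$structures[[1]]$ca, f2$truth$structures[[1]]$ca)
})

test_that("degrade_structure removes one contiguous segment", {
  fam <- cached_family("ident8", family_spec(
    n_sequences = 8, target_identity = 0.3,
    architecture = bab_architecture(2), indel_rate = 0.3, seed = 7))
  ch <- fam$truth$structures[[1]]
  expect_identical(degrade_structure(ch, 0, seed = 1), ch)
  d3 <- degrade_structure(ch, 0.3, seed = 1)
  expect_equal(sum(!d3$resolved_mask), round(0.3 * ch$length))
  runs <- rle(d3$resolved_mask)
  expect_equal(sum(!runs$values), 1)
  d10 <- degrade_structure(ch, 1, seed = 1)
  expect_equal(sum(d10$resolved_mask), 0)
  expect_equal(filter_unresolved(list(x = d10), 0.99)$excluded, "x")
})

test_that("inflate_loops adds loop gaps but keeps blocks intact", {
  fam <- cached_family("sep2", family_spec(
    n_sequences = 8, n_clades = 2, within_identity = 0.6,
    between_identity = 0.25, architecture = bab_architecture(2),
    indel_rate = 0.2, tree = "star", seed = 5))
  infl <- inflate_loops(fam$truth$msa, fam$truth$block_mask,
                        fam$truth$clades)
  expect_gt(foldmsa:::msa_gap_count(infl),
            foldmsa:::msa_gap_count(fam$truth$msa))
  for (id in fam$records$id)
    expect_equal(foldmsa:::degap(infl$rows[[id]]),
                 fam$records$residues[fam$records$id == id])
  # block CS against the truth is unaffected by the inflation
  cs <- column_score(infl, fam$truth$msa,
                     regions = list(b = fam$truth$block_mask))
  expect_equal(cs$regions$b$cs, 1.0)
})

test_that("fixture bundles round-trip through the file formats", {
  fam <- cached_family("sep2", family_spec(
    n_sequences = 8, n_clades = 2, within_identity = 0.6,
    between_identity = 0.25, architecture = bab_architecture(2),
    indel_rate = 0.2, tree = "star", seed = 5))
  dir <- withr::local_tempdir()
  write_family_bundle(fam, dir)
  recs <- read_fasta(file.path(dir, "family.fasta"))
  expect_identical(recs$residues, fam$records$residues)
  truth <- read_msa(file.path(dir, "truth.aln.fasta"))
  expect_true(msa_identical(truth, fam$truth$msa))
  id <- fam$records$id[1]
  st <- read_structure(file.path(dir, paste0(id, ".pdb")),
                       fam$records$residues[1])
  expect_identical(st$resolved_mask, fam$truth$structures[[id]]$resolved_mask)
  expect_equal(unname(st$ca), unname(fam$truth$structures[[id]]$ca),
               tolerance = 1e-3)
})
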