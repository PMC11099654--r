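mk_records <- function(ids, lens, uniprot = NA_character_) {
  structure(data.frame(
    id = ids, description = "",
    residues = vapply(lens, function(L)
      paste0(sample(c("A","R","N","D","G","K","L","S","T","V"), L,
                    replace = TRUE), collapse = ""), character(1)),
    uniprot_id = rep_len(uniprot, length(ids)), status = "unmatched",
    stringsAsFactors = FALSE), class = c("seq_records", "data.frame"))
}

test_that("acquisition routing follows user file > accession > length rules", {
  set.seed(1)
  dir <- withr::local_tempdir()
  file.create(file.path(dir, "has_file.pdb"))
  idx <- index_structure_dir(dir)
  recs <- mk_records(c("has_file", "sp|P0A6F5|CH60_ECOLI", "short1", "long1"),
                     c(100, 548, 399, 450),
                     uniprot = c(NA, "P0A6F5", NA, NA))
  plan <- plan_structure_acquisition(recs, idx)
  expect_equal(plan$route, c("user_file", "afdb", "esmf", "none"))
  # the 400-residue bound is strict: length 400 is not eligible
  recs2 <- mk_records(c("edge399", "edge400"), c(399, 400))
  expect_equal(plan_structure_acquisition(recs2, character(0))$route,
               c("esmf", "none"))
})

test_that("routing respects provider invariants on randomized records", {
  set.seed(8)
  for (i in 1:25) {
    recs <- mk_records(sprintf("r%d", 1:6),
                       sample(50:600, 6, replace = TRUE),
                       uniprot = ifelse(runif(6) < 0.5, "P12345", NA))
    plan <- plan_structure_acquisition(recs, character(0))
    expect_true(all(!is.na(plan$uniprot_id[plan$route == "afdb"])))
    expect_true(all(plan$length[plan$route == "esmf"] < 400))
  }
})

test_that("resolution is best-effort: match, demote, or structureless", {
  fam <- cached_family("match_fam", family_spec(
    n_sequences = 4, target_identity = 0.5,
    architecture = bab_architecture(1), indel_rate = 0.2, seed = 13))
  dir <- withr::local_tempdir()
  for (i in 1:3)
    write_ca_pdb(fam$truth$structures[[i]], fam$records$residues[i],
                 file.path(dir, paste0(fam$records$id[i], ".pdb")))
  idx <- index_structure_dir(dir)
  plan <- plan_structure_acquisition(fam$records, idx)
  res <- resolve_structures(fam$records, plan)
  expect_setequal(names(res$matched), fam$records$id[1:3])
  expect_equal(res$structureless, fam$records$id[4])

  # a failing provider demotes to structureless without aborting
  plan$route[4] <- "esmf"
  res2 <- resolve_structures(fam$records, plan, providers = list(
    esmf = function(req, rec) stop("service unavailable")))
  expect_equal(res2$structureless, fam$records$id[4])
  expect_match(res2$log$detail[4], "service unavailable")

  # a working provider (local test double) matches it
  pdb4 <- file.path(dir, "double.pdb")
  write_ca_pdb(fam$truth$structures[[4]], fam$records$residues[4], pdb4)
  res3 <- resolve_structures(fam$records, plan, providers = list(
    esmf = function(req, rec) pdb4))
  expect_length(res3$structureless, 0)
})

test_that("unresolved filtering excludes high-unresolved structures", {
  fam <- cached_family("match_fam", family_spec(
    n_sequences = 4, target_identity = 0.5,
    architecture = bab_architecture(1), indel_rate = 0.2, seed = 13))
  st <- fam$truth$structures
  st[[2]] <- degrade_structure(st[[2]], 0.3, seed = 4)
  flt <- filter_unresolved(st, 0.25)
  expect_equal(flt$excluded, fam$records$id[2])
  expect_setequal(names(flt$kept), fam$records$id[-2])
  expect_length(filter_unresolved(st, 1.0)$excluded, 0)
  # exhaustiveness: kept + excluded = input
  expect_setequal(c(names(flt$kept), flt$excluded), names(st))
})
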