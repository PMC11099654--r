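test_that("pairwise identity follows the shorter-sequence convention", {
  expect_equal(pairwise_identity("PELICAN", "PELICAN"), 1.0)
  expect_equal(pairwise_identity("PELICAN", "PELICANS"), 1.0)
  expect_equal(pairwise_identity("AAAA", "CCCC"), 0.0)
  # vectorised over the first argument
  expect_equal(pairwise_identity(c("PELICAN", "AAAA"), "PELICAN"),
               c(1.0, pairwise_identity("AAAA", "PELICAN")))
})

test_that("greedy clustering handles identical and dissimilar inputs", {
  recs <- random_records(1, c(20, 20))
  three <- structure(data.frame(id = c("a", "b", "c"), description = "",
                                residues = rep(recs$residues, 3),
                                uniprot_id = NA, status = "unmatched"),
                     class = c("seq_records", "data.frame"))
  cs <- greedy_cluster(three, 0.9)
  expect_length(cs$clusters, 1)
  expect_setequal(cs$clusters[[1]]$members, c("a", "b", "c"))

  two <- structure(data.frame(id = c("a", "b"), description = "",
                              residues = c("AAAAAAAAAA", "CCCCCCCCCC"),
                              uniprot_id = NA, status = "unmatched"),
                   class = c("seq_records", "data.frame"))
  expect_length(greedy_cluster(two, 0.9)$clusters, 2)
})

test_that("planted 4-group family is recovered at the separating threshold", {
  fam <- four_clade_family()
  # oracle: the full identity matrix must show the planted block structure
  n <- nrow(fam$records)
  idm <- matrix(1, n, n)
  for (i in seq_len(n - 1)) {
    idm[i, (i + 1):n] <- pairwise_identity(
      fam$records$residues[(i + 1):n], fam$records$residues[i])
    idm[(i + 1):n, i] <- idm[i, (i + 1):n]
  }
  same <- outer(fam$truth$clades, fam$truth$clades, "==")
  expect_gt(min(idm[same]), 0.7)
  expect_lt(max(idm[!same]), 0.55)

  cs <- greedy_cluster(fam$records, 0.7)
  expect_length(cs$clusters, 4)
  for (cl in cs$clusters)
    expect_length(unique(fam$truth$clades[cl$members]), 1)
})

test_that("clustering satisfies partition, representative and monotonicity properties", {
  fam <- four_clade_family()
  prev <- Inf
  counts <- integer(0)
  for (th in c(0.3, 0.5, 0.7, 0.9)) {
    cs <- greedy_cluster(fam$records, th)
    all_members <- unlist(lapply(cs$clusters, `[[`, "members"))
    expect_setequal(all_members, fam$records$id)
    expect_equal(anyDuplicated(all_members), 0)
    for (cl in cs$clusters) {
      rep_seq <- fam$records$residues[fam$records$id == cl$representative]
      others <- setdiff(cl$members, cl$representative)
      if (length(others)) {
        seqs <- fam$records$residues[match(others, fam$records$id)]
        expect_true(all(pairwise_identity(seqs, rep_seq) >= th))
      }
    }
    counts <- c(counts, length(cs$clusters))
  }
  expect_true(all(diff(counts) >= 0))
})

test_that("make_subsets partitions ids into subsets and orphans", {
  mk_cluster_set <- function(sizes) {
    off <- 0
    clusters <- lapply(seq_along(sizes), function(k) {
      ids <- sprintf("m%02d", off + seq_len(sizes[k]))
      off <<- off + sizes[k]
      list(representative = ids[1], members = ids)
    })
    structure(list(clusters = clusters, threshold = 0.3,
                   collated = rep(FALSE, length(clusters))),
              class = "cluster_set")
  }
  cs <- mk_cluster_set(c(10, 6, 1, 1))
  off_res <- make_subsets(cs, 2, collate = FALSE)
  expect_length(off_res$subsets, 2)
  expect_length(off_res$orphans, 2)
  on_res <- make_subsets(cs, 2, collate = TRUE)
  expect_length(on_res$subsets, 3)
  expect_length(on_res$orphans, 0)
  # exhaustive either way
  expect_setequal(c(unlist(on_res$subsets)), sprintf("m%02d", 1:18))
  expect_setequal(c(unlist(off_res$subsets), off_res$orphans),
                  sprintf("m%02d", 1:18))

  singles <- mk_cluster_set(rep(1, 5))
  deg <- make_subsets(singles, 2, collate = FALSE)
  expect_length(deg$subsets, 0)
  expect_length(deg$orphans, 5)
  expect_error(make_subsets(cs, 1), "min_subset_size")
})

test_that("redundancy reduction keeps representatives and maps the dropped", {
  recs <- random_records(6, c(25, 40))
  dup <- recs
  dup$id <- paste0(dup$id, "_copy")
  both <- structure(rbind(recs, dup), class = c("seq_records", "data.frame"))
  red <- reduce_redundancy(both, 0.9)
  expect_length(red$kept, 6)
  expect_length(red$dropped, 6)
  expect_true(all(sub("_copy", "", names(red$dropped)) ==
                  sub("_copy", "", unname(red$dropped))))
  # threshold 1.0 on all-distinct sequences keeps everything
  red2 <- reduce_redundancy(recs, 1.0)
  expect_setequal(red2$kept, recs$id)
  # planted 4-group fixture reduces to 4 representatives at 0.7
  fam <- four_clade_family()
  expect_length(reduce_redundancy(fam$records, 0.7)$kept, 4)
})
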