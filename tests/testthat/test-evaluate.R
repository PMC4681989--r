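test_that("column KLD matches closed-form values", {
  bg <- aa_background("uniform")
  m <- msa_from_strings(rep("A", 10L), sprintf("s%d", 1:10))
  expect_equal(kld(m, 1L, bg), log2(20), tolerance = 1e-12)

  m20 <- msa_from_strings(AA20, sprintf("s%d", 1:20))
  expect_equal(kld(m20, 1L, bg), 0, tolerance = 1e-12)

  mac <- msa_from_strings(rep(c("AA", "CC"), each = 5L), sprintf("s%d", 1:10))
  expect_equal(kld(mac, 1:2, bg), 2 * (log2(20) - 1), tolerance = 1e-12)

  expect_error(kld(m, integer(), bg), "empty")
  expect_gte(kld(mac, 1L, aa_background()), 0)
})

test_that("the reporting percentages reproduce the published arithmetic", {
  p <- summary_percentages(14421, 74041, 316119, 389873)
  expect_equal(unname(p["percent_unique_clustered"]), 19.5)
  expect_equal(unname(p["percent_copies_clustered"]), 81.1)
  p2 <- summary_percentages(50, 50, 10, 10)
  expect_equal(unname(p2), c(100, 100))
})

test_that("dataset summaries count clustered sequences and copies correctly", {
  ds <- generate_dataset(list(motif_spec("[RK]LxPxNP", "m1")),
                         n_per_motif = 80L, n_noise = 20L, length = 12L,
                         labels = c(a = 0.5, b = 0.5), seed = 3L)
  u <- deduplicate(ds$occurrences)
  res <- run_clustering(u, clustering_config())
  s <- dataset_summary(res)
  expect_equal(s$n_unique_total, nrow(u))
  expect_equal(s$copy_total, sum(u$total_count))
  expect_equal(s$n_unique_clustered + length(res$unassigned), s$n_unique_total)
  expect_equal(s$percent_unique_clustered,
               round(100 * s$n_unique_clustered / s$n_unique_total, 1))
})

test_that("label matrices are conserved and normalize per label", {
  occ <- data.frame(sequence = c("AAA", "AAA", "AAA", "CCC", "GGG"),
                    count = c(2L, 1L, 1L, 2L, 2L),
                    label = c("S1", "S1", "S2", "S1", "S2"))
  u <- deduplicate(occ)
  cl <- structure(list(id = 1L, msa = msa_from_strings("AAA"),
                       members = "AAA", match_cols = 1:3,
                       provenance = character()), class = "pep_cluster")
  res <- structure(list(clusters = list(cl), unassigned = c("CCC", "GGG"),
                        input = u), class = "slimclust_result")
  m <- label_matrix(res)
  expect_equal(m["1", ], c(S1 = 3, S2 = 1))
  expect_equal(colSums(m), c(S1 = 5, S2 = 3))  # conservation with unassigned
  mn <- label_matrix(res, normalize = TRUE)
  expect_equal(colSums(mn), c(S1 = 1, S2 = 1))
  expect_equal(mn["1", "S1"], 3 / 5)

  res_nolab <- res
  res_nolab$input <- deduplicate(data.frame(sequence = c("AAA", "CCC", "GGG")))
  expect_error(label_matrix(res_nolab), "no labels")
})

test_that("category-profile distance is one minus Pearson correlation", {
  m <- rbind(a = c(1, 0, 1, 0), b = c(1, 0, 1, 0), c = c(0, 1, 0, 1),
             d = c(2, 0, 2, 0))
  expect_equal(profile_correlation(m, "a", "b"), 0)
  expect_equal(profile_correlation(m, "a", "c"), 2)
  expect_equal(profile_correlation(m, "a", "d"), 0)
  mz <- rbind(a = c(1, 1, 1, 1), b = c(1, 0, 1, 0))
  expect_error(profile_correlation(mz, "a", "b"), "zero-variance")
})

test_that("cluster purity counts noise against the majority motif", {
  truth <- data.frame(sequence = sprintf("s%02d", 1:20),
                      motif = c(rep("m1", 9), "noise", rep("noise", 10)))
  mk <- function(members, id) {
    structure(list(id = id, msa = msa_from_strings(rep("ACDE",
                                                       length(members)),
                                                   members),
                   members = members, match_cols = 1:4,
                   provenance = character()), class = "pep_cluster")
  }
  res <- structure(list(clusters = list(mk(sprintf("s%02d", 1:10), 1L),
                                        mk(sprintf("s%02d", 11:20), 2L)),
                        unassigned = character(),
                        input = deduplicate(data.frame(sequence = truth$sequence))),
                   class = "slimclust_result")
  p <- cluster_purity(res, truth)
  expect_equal(p$purity[1L], 0.9)
  expect_equal(p$majority_motif[1L], "m1")
  expect_equal(p$purity[2L], 0)  # all-noise cluster has motif purity 0
})

test_that("restricting KLD to match columns never lowers the per-column mean", {
  set.seed(43)
  ds <- generate_dataset(list(motif_spec("[RK]LxPxNP", "m1")),
                         n_per_motif = 100L, n_noise = 20L, length = 12L,
                         seed = 47L)
  u <- deduplicate(ds$occurrences)
  res <- run_clustering(u, clustering_config())
  for (cl in res$clusters) {
    all_cols <- which(colSums(cl$msa != "-") > 0L)
    per_col_all <- kld(cl$msa, all_cols) / length(all_cols)
    per_col_match <- kld(cl$msa, cl$match_cols) / length(cl$match_cols)
    expect_gte(per_col_match, per_col_all - 1e-9)
  }
  expect_gte(dataset_kld(res, "match"), 0)
})
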