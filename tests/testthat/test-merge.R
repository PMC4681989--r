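near_deterministic_hmm <- function(consensus, eps = 1e-6) {
  K <- nchar(consensus)
  res <- strsplit(consensus, "")[[1L]]
  em <- matrix(eps / 19, K, 20, dimnames = list(NULL, AA20))
  for (k in seq_len(K)) em[k, res[k]] <- 1 - eps
  hmm <- random_hmm(K)
  hmm$match_emissions <- em
  hmm
}

test_that("HMM-HMM self-score approaches the closed form for deterministic models", {
  m <- near_deterministic_hmm("ACDEF")
  s <- hmm_hmm_score(m, m)
  want <- sum(log2(1 / m$background[c("A", "C", "D", "E", "F")]))
  expect_equal(s$score, want, tolerance = 1e-3)
  expect_equal(s$pairing, cbind(1:5, 1:5), ignore_attr = TRUE)

  other <- near_deterministic_hmm("GHIKL")
  expect_gte(hmm_hmm_score(m, m)$score, hmm_hmm_score(m, other)$score)
})

test_that("uniform-emission models score zero under a uniform background", {
  u <- random_hmm(4, background = aa_background("uniform"))
  u$match_emissions[] <- 1 / 20
  expect_equal(hmm_hmm_score(u, u)$score, 0, tolerance = 1e-12)
})

test_that("the HMM-HMM score is symmetric", {
  set.seed(17)
  for (i in 1:25) {
    a <- random_hmm(sample(3:7, 1L))
    b <- random_hmm(sample(3:7, 1L))
    expect_equal(hmm_hmm_score(a, b)$score, hmm_hmm_score(b, a)$score,
                 tolerance = 1e-9)
  }
})

test_that("merging relays rows onto the frame cluster without corrupting them", {
  cfg <- lax_config()
  a <- cluster_from_seqs(c("ACDE", "ACDE"), 1L, cfg)
  b <- cluster_from_seqs(c("ACDE", "ACDE"), 2L, cfg)
  rownames(b$msa) <- b$members <- c("ACDE", "ACDE")  # same sequence twice
  al <- hmm_hmm_score(a$hmm, b$hmm)
  m <- merge_clusters(a, b, al$pairing, cfg, 3L)
  expect_true(m$ok)
  expect_equal(nrow(m$cluster$msa), 4L)
  expect_equal(ncol(m$cluster$msa), 4L)
  expect_equal(length(unique(apply(m$cluster$msa, 1L, paste, collapse = ""))), 1L)
})

test_that("merging offset cores reconstructs the shifted alignment", {
  cfg <- lax_config()
  a <- cluster_from_seqs("ACDE", 1L, cfg)
  b <- cluster_from_seqs("CDEF", 2L, cfg)
  al <- hmm_hmm_score(a$hmm, b$hmm)
  expect_equal(al$pairing, cbind(2:4, 1:3), ignore_attr = TRUE)  # CDE columns
  m <- merge_clusters(a, b, al$pairing, cfg, 3L)
  expect_true(m$ok)
  expect_equal(apply(m$cluster$msa, 1L, paste, collapse = ""),
               c(ACDE = "ACDE-", CDEF = "-CDEF"))
})

test_that("merges violating diversity constraints are rejected, not raised", {
  cfg <- clustering_config(min_match_states = 4L, max_positions = 30L)
  a <- cluster_from_seqs(rep("ACDEF", 5L), 1L, cfg)
  b <- cluster_from_seqs(rep("GHIKL", 5L), 2L, cfg)
  rownames(a$msa) <- a$members <- sprintf("ACDEF%d", 1:5)  # distinct ids
  rownames(b$msa) <- b$members <- sprintf("GHIKL%d", 1:5)
  al <- hmm_hmm_score(a$hmm, b$hmm)
  m <- merge_clusters(a, b, al$pairing, cfg, 3L)
  expect_false(isTRUE(m$ok))
  expect_match(m$reason, "match_states|width|inner")
})

test_that("hierarchical merging runs the queue to its terminal condition", {
  cfg <- lax_config()
  # three clusters: A and B nearly identical, C unrelated; score(A,B) high
  a <- cluster_from_seqs(rep("ACDEFG", 3L), 1L, cfg)
  b <- cluster_from_seqs(rep("ACDEFG", 3L), 2L, cfg)
  cc <- cluster_from_seqs(rep("WYWYWY", 3L), 3L, cfg)
  rownames(a$msa) <- a$members <- sprintf("a%d", 1:3)
  rownames(b$msa) <- b$members <- sprintf("b%d", 1:3)
  rownames(cc$msa) <- cc$members <- sprintf("c%d", 1:3)
  thr <- 10
  out <- hierarchical_merge(list(a, b, cc), thr, cfg)
  expect_length(out, 2L)
  expect_setequal(unlist(lapply(out, `[[`, "members")),
                  c(sprintf("a%d", 1:3), sprintf("b%d", 1:3), sprintf("c%d", 1:3)))
  # terminal condition: no surviving pair at or above threshold
  for (i in seq_along(out)) for (j in seq_len(i - 1L)) {
    expect_lt(hmm_hmm_score(out[[i]]$hmm, out[[j]]$hmm,
                            cfg$hmm_gap_open, cfg$hmm_gap_extend)$score, thr)
  }

  expect_length(hierarchical_merge(list(a), thr, cfg), 1L)
  high <- hierarchical_merge(list(a, b, cc), 1e6, cfg)
  expect_length(high, 3L)
})

test_that("hierarchical merging equals the rescan oracle on random inputs", {
  set.seed(53)
  cfg <- lax_config()
  for (case in 1:40) {
    n <- sample(2:6, 1L)
    base <- vapply(seq_len(n), function(i) random_peptide(6L), "")
    clusters <- lapply(seq_len(n), function(i) {
      seqs <- rep(base[[sample.int(n, 1L)]], 3L)
      cl <- cluster_from_seqs(seqs, i, cfg)
      rownames(cl$msa) <- cl$members <- sprintf("s%d_%d", i, 1:3)
      cl
    })
    thr <- sample(c(5, 10, 15), 1L)
    got <- hierarchical_merge(clusters, thr, cfg)
    want <- oracle_rescan_merge(clusters, thr, cfg)
    expect_equal(member_sets(got), member_sets(want))
  }
})

test_that("similarity grouping is the transitive closure of hit-set overlap", {
  g <- similarity_groups(list(`1` = c("x", "y"), `2` = c("y", "z"),
                              `3` = "w"))
  expect_equal(g, list(c(1L, 2L), 3L), ignore_attr = TRUE)

  g2 <- similarity_groups(list(`1` = "a", `2` = "b", `3` = "c"))
  expect_length(g2, 3L)

  g3 <- similarity_groups(list(`1` = c("s", "a"), `2` = c("s", "b"),
                               `3` = c("s", "c")))
  expect_equal(g3, list(1:3), ignore_attr = TRUE)

  g4 <- similarity_groups(list(`1` = character(), `2` = character()))
  expect_length(g4, 2L)
})

test_that("grouped merging never yields fewer clusters than the full merge", {
  set.seed(59)
  cfg <- lax_config()
  for (case in 1:20) {
    n <- sample(3:6, 1L)
    base <- vapply(seq_len(min(2L, n)), function(i) random_peptide(6L), "")
    clusters <- lapply(seq_len(n), function(i) {
      cl <- cluster_from_seqs(rep(base[[sample.int(length(base), 1L)]], 3L), i, cfg)
      rownames(cl$msa) <- cl$members <- sprintf("s%d_%d", i, 1:3)
      cl
    })
    hits <- setNames(lapply(seq_len(n), function(i) {
      sample(letters, sample(0:4, 1L))
    }), seq_len(n))
    thr <- 8
    full <- hierarchical_merge(clusters, thr, cfg)
    grouped <- heuristic_merge(clusters, hits, thr, cfg)
    expect_gte(length(grouped), length(full))
    # one all-encompassing group reduces to the full merge
    one_group <- setNames(rep(list("shared"), n), seq_len(n))
    expect_equal(member_sets(heuristic_merge(clusters, one_group, thr, cfg)),
                 member_sets(full))
    # all-singleton groups perform no merges
    singletons <- setNames(lapply(seq_len(n), function(i) sprintf("u%d", i)),
                           seq_len(n))
    expect_length(heuristic_merge(clusters, singletons, thr, cfg), n)
  }
})

test_that("unique sequences are conserved across any merge", {
  set.seed(61)
  cfg <- lax_config()
  clusters <- lapply(1:4, function(i) {
    cl <- cluster_from_seqs(rep(random_peptide(6L), 2L), i, cfg)
    rownames(cl$msa) <- cl$members <- sprintf("m%d_%d", i, 1:2)
    cl
  })
  out <- hierarchical_merge(clusters, 3, cfg)
  expect_setequal(unlist(lapply(out, `[[`, "members")),
                  unlist(lapply(clusters, `[[`, "members")))
})
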