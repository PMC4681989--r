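test_that("core alignments place members by shift with no inner gaps", {
  cl <- structure(list(id = 1L, representative = "ACDE",
                       members = data.frame(sequence = c("ACDE", "CDEF"),
                                            shift = c(0L, 1L),
                                            score = c(4, 3))),
                  class = "greedy_cluster")
  m <- core_msa(cl)
  expect_equal(apply(m, 1L, paste, collapse = ""),
               c(ACDE = "ACDE-", CDEF = "-CDEF"))
  expect_equal(ncol(m), 5L)
  expect_equal(inner_gap_count(m), 0L)

  single <- structure(list(id = 1L, representative = "ACDE",
                           members = data.frame(sequence = "ACDE", shift = 0L,
                                                score = 4)),
                      class = "greedy_cluster")
  expect_equal(unname(as.vector(core_msa(single))), c("A", "C", "D", "E"))

  # negative shifts are normalized so no column index is lost
  cl2 <- structure(list(id = 1L, representative = "CDEF",
                        members = data.frame(sequence = c("CDEF", "ACDE"),
                                             shift = c(0L, -1L),
                                             score = c(4, 3))),
                   class = "greedy_cluster")
  expect_true(degaps_ok(core_msa(cl2)))
})

test_that("column information content matches closed-form values", {
  m <- msa_from_strings(rep("A", 10L), ids = sprintf("s%d", 1:10))
  expect_equal(column_information_content(m, 1L), log2(20), tolerance = 1e-12)

  m20 <- msa_from_strings(AA20, ids = sprintf("s%d", 1:20))
  expect_equal(column_information_content(m20, 1L), 0, tolerance = 1e-12)

  mac <- msa_from_strings(rep(c("A", "C"), each = 5L), ids = sprintf("s%d", 1:10))
  expect_equal(column_information_content(mac, 1L), log2(20) - 1,
               tolerance = 1e-12)

  expect_error(column_information_content(msa_from_strings("-", "x"), 1L),
               "all-gap")
})

test_that("the match-column rule is strict on gaps and inclusive on IC", {
  # 100 rows, column 1 with exactly 5 gaps: excluded by the strict < rule
  rows <- c(rep("-A", 5L), rep("AA", 95L))
  m <- msa_from_strings(rows, ids = sprintf("s%d", 1:100))
  expect_equal(match_columns(m, 0.05, 1.2), 2L)
  expect_equal(match_columns(m, 0.051, 1.2), c(1L, 2L))

  all_same <- msa_from_strings(rep("AC", 10L), ids = sprintf("s%d", 1:10))
  expect_equal(match_columns(all_same), c(1L, 2L))

  uniform <- msa_from_strings(paste0(AA20, "A"), ids = sprintf("s%d", 1:20))
  expect_equal(match_columns(uniform), 2L)  # column 1 has IC 0
})

test_that("match_columns is monotone in the IC threshold", {
  set.seed(13)
  for (i in 1:20) {
    rows <- vapply(1:8, function(j) random_peptide(6L), "")
    m <- msa_from_strings(rows, ids = sprintf("s%d", 1:8))
    prev <- match_columns(m, ic_threshold = 0)
    for (th in c(0.5, 1.2, 2, 3)) {
      cur <- match_columns(m, ic_threshold = th)
      expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("inner gaps count only gaps flanked by residues in their own row", {
  expect_equal(inner_gap_count(msa_from_strings("-ACD-", "x")), 0L)
  expect_equal(inner_gap_count(msa_from_strings("AC-DE", "x")), 1L)
  m <- msa_from_strings(c("AC-DE", "A--CE"), c("x", "y"))
  expect_equal(inner_gap_count(m), 3L)
})

test_that("HMM-path insertion preserves existing rows and degapping", {
  base <- msa_from_strings(rep("ACDEF", 4L))
  cfg <- clustering_config()
  hmm <- build_phmm(base, 1:5, min_match = 4L)

  # all-match path: width unchanged
  hit <- viterbi_local(hmm, "ACDEF")
  expect_true(all(hit$path$state == 1L))
  ins <- insert_sequence(base, "ACDEF", hit, 1:5)
  expect_equal(ncol(ins$msa), 5L)
  expect_equal(nrow(ins$msa), 5L)
  expect_true(degaps_ok(ins$msa))

  # unaligned flanks open columns; old rows only gain gap columns
  hit2 <- viterbi_local(hmm, "GGACDEFGG")
  ins2 <- insert_sequence(base, "GGACDEFGG", hit2, 1:5)
  expect_true(degaps_ok(ins2$msa))
  expect_gt(ncol(ins2$msa), 5L)
  stripped <- ins2$msa[1:4, ins2$match_cols[1:5]]
  expect_equal(unname(apply(stripped, 1L, paste, collapse = "")),
               rep("ACDEF", 4L))

  # inserting the consensus reproduces the majority string on match columns
  ins3 <- insert_sequence(base, "ACDEF", viterbi_local(hmm, "ACDEF"), 1:5)
  expect_equal(paste(ins3$msa[5L, ins3$match_cols], collapse = ""),
               msa_consensus(base, 1:5))
})

test_that("insertion with an internal insert state adds an all-gap column for old rows", {
  base <- msa_from_strings(rep("ACDEFG", 5L))
  hmm <- build_phmm(base, 1:6, min_match = 4L)
  hit <- viterbi_local(hmm, "ACDWEFG")  # W must sit between D and E
  ins <- insert_sequence(base, "ACDWEFG", hit, 1:6)
  expect_true(degaps_ok(ins$msa))
  expect_equal(ncol(ins$msa), 7L)
  new_col <- setdiff(seq_len(7L), ins$match_cols)
  expect_true(all(ins$msa[1:5, new_col] == "-"))
  expect_equal(unname(ins$msa[6L, new_col]), "W")
})

test_that("logo frequencies follow the sub-50%-gap display rule", {
  m <- msa_from_strings(c("AC", "A-", "A-", "A-", "A-"), sprintf("s%d", 1:5))
  lf <- logo_frequencies(m)
  expect_equal(unique(lf$column), 1L)  # column 2 has 80% gaps

  full <- msa_from_strings(rep("ACD", 4L), sprintf("s%d", 1:4))
  expect_setequal(unique(logo_frequencies(full)$column), 1:3)

  m10 <- msa_from_strings(c(rep("AC", 6L), rep("A-", 4L)), sprintf("s%d", 1:10))
  expect_true(2L %in% logo_frequencies(m10)$column)  # 40% gaps < 50%
  freqs <- logo_frequencies(m10)
  expect_equal(sum(freqs$frequency[freqs$column == 2L]), 1)
})
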