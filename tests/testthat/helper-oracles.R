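# Shared fixtures and independent oracles used across the suite. The oracles
# deliberately re-derive results from first principles (enumeration, naive
# rescanning) rather than calling the implementation they check.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

identity_matrix <- function(match = 1, mismatch = 0) {
  m <- matrix(mismatch, 20, 20, dimnames = list(AA20, AA20))
  diag(m) <- match
  m
}

msa_from_strings <- function(strings, ids = NULL) {
  if (is.null(ids)) ids <- gsub("-", "", strings)
  m <- do.call(rbind, strsplit(strings, ""))
  rownames(m) <- ids
  class(m) <- c("pep_msa", class(m))
  m
}

degaps_ok <- function(msa) {
  all(apply(msa, 1L, function(r) paste(r[r != "-"], collapse = "")) ==
        rownames(msa))
}

random_peptide <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

# Brute-force gapless shift alignment: enumerate every shift, score the
# overlap directly, apply the documented tie rules (smaller |s|, then
# negative s).
oracle_shift <- function(a, b, mat, max_shift) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  best <- NULL
  for (s in -max_shift:max_shift) {
    js <- seq_along(cb)
    keep <- js + s >= 1L & js + s <= length(ca)
    if (!any(keep)) next
    sc <- sum(mat[cbind(ca[js[keep] + s], cb[js[keep]])])
    better <- is.null(best) || sc > best$score ||
      (sc == best$score && (abs(s) < abs(best$shift) ||
                              (abs(s) == abs(best$shift) && s < best$shift)))
    if (better) best <- list(score = sc, shift = s, overlap = sum(keep))
  }
  best
}

# A random, properly normalized profile HMM (concentrated Dirichlet-style
# emissions so consensus structure exists).
random_hmm <- function(K, background = aa_background("uniform"),
                       concentration = 0.3) {
  em <- t(vapply(seq_len(K), function(k) {
    g <- stats::rgamma(20, concentration)
    g / sum(g)
  }, numeric(20)))
  colnames(em) <- AA20
  tr <- matrix(0, K, 7, dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II",
                                                "DM", "DD")))
  for (k in seq_len(K)) {
    m3 <- stats::rgamma(3, 1); tr[k, 1:3] <- m3 / sum(m3)
    i2 <- stats::rgamma(2, 1); tr[k, 4:5] <- i2 / sum(i2)
    d2 <- stats::rgamma(2, 1); tr[k, 6:7] <- d2 / sum(d2)
  }
  structure(list(n_match = K, match_emissions = em,
                 insert_emissions = background, transitions = tr,
                 match_column_map = seq_len(K), background = background),
            class = "profile_hmm")
}

# Independent R re-implementation of the local Viterbi recurrence (plain
# loops over an explicit three-matrix lattice).
oracle_viterbi_dp <- function(hmm, seq) {
  codes <- match(strsplit(seq, "")[[1L]], AA20)
  K <- hmm$n_match; L <- length(codes)
  lo <- log2(sweep(hmm$match_emissions, 2L, hmm$background, "/"))
  tr <- log2(hmm$transitions)
  entry <- -log2(K)
  M <- matrix(-Inf, L, K); I <- matrix(-Inf, L, K); D <- matrix(-Inf, L, K)
  for (i in seq_len(L)) {
    for (k in seq_len(K)) {
      cand <- entry
      if (i > 1 && k > 1) {
        cand <- max(cand,
                    M[i - 1, k - 1] + tr[k - 1, "MM"],
                    I[i - 1, k - 1] + tr[k - 1, "IM"],
                    D[i - 1, k - 1] + tr[k - 1, "DM"])
      }
      M[i, k] <- lo[k, codes[i]] + cand
      if (i > 1 && k < K) {
        I[i, k] <- max(M[i - 1, k] + tr[k, "MI"], I[i - 1, k] + tr[k, "II"])
      }
      if (k > 1) {
        D[i, k] <- max(M[i, k - 1] + tr[k - 1, "MD"], D[i, k - 1] + tr[k - 1, "DD"])
      }
    }
  }
  max(M)
}

# Exhaustive enumeration over all legal local alignment paths (entry at any
# match cell, match-to-match moves optionally through insert or delete runs,
# exit at any match cell). Exponential; only for tiny models.
oracle_viterbi_enum <- function(hmm, seq) {
  codes <- match(strsplit(seq, "")[[1L]], AA20)
  K <- hmm$n_match; L <- length(codes)
  lo <- log2(sweep(hmm$match_emissions, 2L, hmm$background, "/"))
  tr <- log2(hmm$transitions)
  rec <- function(i, k) {
    e <- lo[k, codes[i]]
    best <- 0  # exit here
    if (i < L && k < K) {
      best <- max(best, tr[k, "MM"] + rec(i + 1, k + 1))
      m <- 1L
      while (i + m + 1L <= L) {
        best <- max(best, tr[k, "MI"] + (m - 1L) * tr[k, "II"] +
                      tr[k, "IM"] + rec(i + m + 1L, k + 1L))
        m <- m + 1L
      }
    }
    if (i < L && k + 2L <= K) {
      for (d in seq_len(K - k - 1L)) {
        dd <- if (d > 1L) sum(tr[(k + 1L):(k + d - 1L), "DD"]) else 0
        best <- max(best, tr[k, "MD"] + dd + tr[k + d, "DM"] +
                      rec(i + 1L, k + 1L + d))
      }
    }
    e + best
  }
  best <- -Inf
  for (i in seq_len(L)) for (k in seq_len(K)) {
    best <- max(best, -log2(K) + rec(i, k))
  }
  best
}

# Naive agglomeration oracle: recompute every pair score from scratch at
# each step (no queue), pick the best above-threshold pair with the same tie
# rule, merge with the same machinery, stop when no pair qualifies.
oracle_rescan_merge <- function(clusters, threshold, config) {
  byid <- setNames(clusters, vapply(clusters, `[[`, 0L, "id"))
  next_id <- max(as.integer(names(byid))) + 1L
  norm <- function(a, b) {
    al <- hmm_hmm_score(a$hmm, b$hmm, config$hmm_gap_open, config$hmm_gap_extend)
    d <- switch(config$merge_normalization, none = 1,
                min_states = min(a$hmm$n_match, b$hmm$n_match),
                pairs = max(1L, nrow(al$pairing)))
    al$score / d
  }
  repeat {
    ids <- as.integer(names(byid))
    if (length(ids) < 2L) break
    best <- NULL
    cmb <- utils::combn(ids, 2L)
    for (p in seq_len(ncol(cmb))) {
      i <- cmb[1L, p]; j <- cmb[2L, p]
      s <- norm(byid[[as.character(i)]], byid[[as.character(j)]])
      if (s >= threshold &&
          (is.null(best) || s > best$s ||
           (s == best$s && (i < best$i || (i == best$i && j < best$j))))) {
        best <- list(i = i, j = j, s = s)
      }
    }
    if (is.null(best)) break
    a <- byid[[as.character(best$i)]]
    b <- byid[[as.character(best$j)]]
    if (length(b$members) > length(a$members)) { tmp <- a; a <- b; b <- tmp }
    al <- hmm_hmm_score(a$hmm, b$hmm, config$hmm_gap_open, config$hmm_gap_extend)
    m <- merge_clusters(a, b, al$pairing, config, next_id)
    stopifnot(m$ok)  # oracle is used with constraints disabled
    byid[[as.character(best$i)]] <- NULL
    byid[[as.character(best$j)]] <- NULL
    byid[[as.character(next_id)]] <- m$cluster
    next_id <- next_id + 1L
  }
  unname(byid[order(as.integer(names(byid)))])
}

# Configuration with diversity constraints effectively disabled, for merge
# oracle tests.
lax_config <- function(...) {
  clustering_config(min_match_states = 1L, max_positions = 10000L,
                    max_inner_gap_frac = 1e6, ...)
}

# A cluster built directly from equal-length unaligned sequences.
cluster_from_seqs <- function(seqs, id, config) {
  msa <- msa_from_strings(seqs)
  slimclust:::new_cluster(id, msa, config)
}

member_sets <- function(clusters) {
  sets <- lapply(clusters, function(cl) sort(cl$members))
  sets[order(vapply(sets, `[`, "", 1L))]
}
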