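# Cluster-cluster comparison and agglomerative merging.
#
# Whole clusters are compared by local alignment of their profile HMMs'
# match states under the log-sum-of-odds co-emission column score
#   s(i, j) = log2( sum_r Pa_i(r) * Pb_j(r) / bg(r) )
# with affine gap penalties. Above-threshold pairs are agglomerated
# best-pair-first through a lazily pruned queue, exactly the bottom-up
# scheme that guarantees no above-threshold pair is left unmerged. A
# union-find grouping over shared distant-hit sets provides the heuristic
# speedup: merging is then confined to groups of potentially similar
# clusters.

#' Local HMM-HMM alignment score of two profile HMMs
#'
#' Aligns the match states of `a` against those of `b` locally (any
#' contiguous block of states may align, unaligned states are free) with
#' affine gap penalties, scoring each aligned state pair by the log odds of
#' co-emitting the same residue.
#'
#' @param a,b `profile_hmm` objects (backgrounds must agree).
#' @param gap_open,gap_extend Affine gap penalties in bits (defaults -1.5,
#'   -0.5).
#' @return List with `score` (total bits over the best local alignment;
#'   0 with an empty pairing if no positive-scoring alignment exists) and
#'   `pairing`, an n x 2 matrix of aligned (state of `a`, state of `b`)
#'   index pairs in increasing order.
#' @export
hmm_hmm_score <- function(a, b, gap_open = -1.5, gap_extend = -0.5) {
  Ka <- a$n_match; Kb <- b$n_match
  bg <- a$background
  S <- log2(a$match_emissions %*% (t(b$match_emissions) / bg))
  # Local affine Smith-Waterman over the state-pair score matrix. Matrices
  # are 1-offset; H = best alignment ending in pair (i, j), X = gap run in b
  # (a's state unpaired), Y = gap run in a.
  H <- matrix(0, Ka + 1L, Kb + 1L)
  X <- matrix(-Inf, Ka + 1L, Kb + 1L)
  Y <- matrix(-Inf, Ka + 1L, Kb + 1L)
  ptrH <- matrix(0L, Ka + 1L, Kb + 1L)  # 0 fresh start, 1 H, 2 X, 3 Y
  ptrX <- matrix(0L, Ka + 1L, Kb + 1L)  # 1 opened from H, 2 extended from X
  ptrY <- matrix(0L, Ka + 1L, Kb + 1L)
  best <- 0; bi <- 0L; bj <- 0L
  for (i in seq_len(Ka)) {
    for (j in seq_len(Kb)) {
      xo <- H[i, j + 1L] + gap_open
      xe <- X[i, j + 1L] + gap_extend
      X[i + 1L, j + 1L] <- max(xo, xe)
      ptrX[i + 1L, j + 1L] <- if (xo >= xe) 1L else 2L
      yo <- H[i + 1L, j] + gap_open
      ye <- Y[i + 1L, j] + gap_extend
      Y[i + 1L, j + 1L] <- max(yo, ye)
      ptrY[i + 1L, j + 1L] <- if (yo >= ye) 1L else 2L
      prev <- c(0, H[i, j], X[i, j], Y[i, j])
      w <- which.max(prev)
      H[i + 1L, j + 1L] <- S[i, j] + prev[w]
      ptrH[i + 1L, j + 1L] <- w - 1L
      if (H[i + 1L, j + 1L] > best) {
        best <- H[i + 1L, j + 1L]; bi <- i; bj <- j
      }
    }
  }
  if (bi == 0L) {
    return(list(score = 0, pairing = matrix(integer(), ncol = 2L)))
  }
  pairs <- list()
  state <- "H"; i <- bi; j <- bj
  repeat {
    if (state == "H") {
      pairs[[length(pairs) + 1L]] <- c(i, j)
      p <- ptrH[i + 1L, j + 1L]
      if (p == 0L) break
      state <- c("H", "X", "Y")[p]
      i <- i - 1L; j <- j - 1L
    } else if (state == "X") {
      state <- if (ptrX[i + 1L, j + 1L] == 1L) "H" else "X"
      i <- i - 1L
    } else {
      state <- if (ptrY[i + 1L, j + 1L] == 1L) "H" else "Y"
      j <- j - 1L
    }
  }
  pairing <- do.call(rbind, rev(pairs))
  list(score = best, pairing = pairing)
}

# Pair score used against merge thresholds. Normalization modes:
# "none" (absolute bits, the default), "min_states" (bits per match state of
# the smaller model), "pairs" (bits per aligned state pair).
merge_pair_score <- function(a, b, normalization = "none",
                             gap_open = -1.5, gap_extend = -0.5) {
  al <- hmm_hmm_score(a$hmm, b$hmm, gap_open, gap_extend)
  denom <- switch(normalization,
                  none = 1,
                  min_states = min(a$hmm$n_match, b$hmm$n_match),
                  pairs = max(1L, nrow(al$pairing)),
                  stop("unknown merge normalization: ", normalization))
  list(norm = al$score / denom, raw = al)
}

#' Merge two clusters along an HMM-HMM column pairing
#'
#' Re-lays every row of `b`'s alignment onto `a`'s column frame: residues at
#' paired match columns of `b` go to the corresponding match columns of `a`,
#' all other residues (unpaired match columns, spacers) become insert-region
#' residues. The merged alignment satisfies the degapping invariant. The
#' candidate is checked against the diversity constraints; on violation a
#' rejection signal (not an error) is returned.
#'
#' @param a,b `pep_cluster` objects.
#' @param pairing Pairing matrix from [hmm_hmm_score()] of `a$hmm`, `b$hmm`.
#' @param config A [clustering_config()].
#' @param new_id Id for the merged cluster.
#' @return On success `list(ok = TRUE, cluster = <pep_cluster>)`; on a
#'   diversity violation `list(ok = FALSE, reason = <string>)`.
#' @export
merge_clusters <- function(a, b, pairing, config, new_id) {
  msa <- a$msa
  match_cols <- a$match_cols
  b_match <- b$match_cols
  for (ri in seq_len(nrow(b$msa))) {
    row <- b$msa[ri, ]
    K <- length(match_cols)
    match_res <- rep(NA_character_, K)
    regions <- rep(list(character()), K + 1L)
    region_of <- 0L  # index of last a-match state passed
    for (j in seq_len(length(row))) {
      kb <- match(j, b_match)
      ka <- if (!is.na(kb) && nrow(pairing)) {
        hit <- pairing[pairing[, 2L] == kb, 1L]
        if (length(hit)) hit else NA_integer_
      } else NA_integer_
      if (!is.na(ka)) {
        if (row[j] != GAP) match_res[ka] <- row[j]
        region_of <- ka
      } else if (row[j] != GAP) {
        regions[[region_of + 1L]] <- c(regions[[region_of + 1L]], row[j])
      }
    }
    placed <- msa_place_row(msa, match_cols, rownames(b$msa)[ri],
                            match_res, regions)
    msa <- placed$msa
    match_cols <- placed$match_cols
  }
  div <- diversity_ok(msa, config, n_members = nrow(msa))
  if (!div$ok) return(list(ok = FALSE, reason = div$reason))
  cl <- new_cluster(new_id, msa, config,
                    provenance = c(a$provenance, b$provenance,
                                   sprintf("merge(%d,%d)", a$id, b$id)))
  list(ok = TRUE, cluster = cl)
}

queue_order <- function(q) {
  lo <- pmin(q$i, q$j); hi <- pmax(q$i, q$j)
  order(-q$score, lo, hi)
}

#' Agglomerative best-pair-first cluster merging
#'
#' Implements the bottom-up scheme over a set of clusters: all-vs-all
#' HMM-HMM scores, a queue of above-threshold pairs, then repeatedly pop the
#' best pair (ties: lexicographic smaller id pair), discard stale entries
#' referencing retired clusters, merge, rescore the merged cluster against
#' all survivors, and push new above-threshold pairs. Pairs whose merge
#' would violate the diversity constraints are discarded permanently. On
#' termination no remaining pair scores at or above the threshold except
#' constraint-rejected ones.
#'
#' @param clusters List of `pep_cluster` objects.
#' @param threshold Merge threshold, in the units set by the config's
#'   `merge_normalization` (absolute bits by default).
#' @param config A [clustering_config()].
#' @return List of `pep_cluster` objects after merging.
#' @export
hierarchical_merge <- function(clusters, threshold, config) {
  if (length(clusters) <= 1L) return(clusters)
  byid <- setNames(clusters, vapply(clusters, `[[`, 0L, "id"))
  ids <- as.integer(names(byid))
  next_id <- max(ids) + 1L
  q <- data.frame(i = integer(), j = integer(), score = numeric())
  pairs <- utils::combn(ids, 2L)
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    sc <- merge_pair_score(byid[[as.character(i)]], byid[[as.character(j)]],
                           config$merge_normalization,
                           config$hmm_gap_open, config$hmm_gap_extend)
    if (sc$norm >= threshold) {
      q <- rbind(q, data.frame(i = i, j = j, score = sc$norm))
    }
  }
  retired <- integer()
  rejected <- character()
  while (nrow(q) > 0L) {
    q <- q[queue_order(q), , drop = FALSE]
    top <- q[1L, ]
    q <- q[-1L, , drop = FALSE]
    if (top$i %in% retired || top$j %in% retired) next
    if (paste(top$i, top$j) %in% rejected) next
    a <- byid[[as.character(top$i)]]
    b <- byid[[as.character(top$j)]]
    if (length(b$members) > length(a$members)) { tmp <- a; a <- b; b <- tmp }
    al <- hmm_hmm_score(a$hmm, b$hmm, config$hmm_gap_open, config$hmm_gap_extend)
    m <- merge_clusters(a, b, al$pairing, config, next_id)
    if (!m$ok) {
      rejected <- c(rejected, paste(top$i, top$j))
      next
    }
    retired <- c(retired, top$i, top$j)
    byid[[as.character(top$i)]] <- NULL
    byid[[as.character(top$j)]] <- NULL
    for (id in names(byid)) {
      sc <- merge_pair_score(m$cluster, byid[[id]], config$merge_normalization,
                             config$hmm_gap_open, config$hmm_gap_extend)
      if (sc$norm >= threshold) {
        q <- rbind(q, data.frame(i = next_id, j = as.integer(id),
                                 score = sc$norm))
      }
    }
    byid[[as.character(next_id)]] <- m$cluster
    next_id <- next_id + 1L
  }
  unname(byid[order(as.integer(names(byid)))])
}

#' Group clusters by overlapping distant-hit sets
#'
#' Two clusters are directly similar when their distant-hit sets share a
#' sequence; groups are the connected components of this relation
#' (transitive closure), computed with union-find. Clusters with empty hit
#' sets form singleton groups.
#'
#' @param distant_hit_sets Named list: cluster id -> character vector of
#'   distantly similar pool sequences.
#' @return List of integer vectors of cluster ids (each sorted; groups
#'   ordered by smallest member).
#' @export
similarity_groups <- function(distant_hit_sets) {
  ids <- names(distant_hit_sets)
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  union_ <- function(x, y) {
    rx <- find(x); ry <- find(y)
    if (rx != ry) parent[max(rx, ry)] <<- min(rx, ry)
  }
  seq_owner <- new.env(hash = TRUE, parent = emptyenv())
  for (x in seq_len(n)) {
    for (s in distant_hit_sets[[x]]) {
      prev <- seq_owner[[s]]
      if (is.null(prev)) assign(s, x, envir = seq_owner) else union_(prev, x)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  groups <- split(as.integer(ids), roots)
  groups <- lapply(groups, sort)
  groups[order(vapply(groups, min, 0L))]
}

#' Heuristic grouped merging
#'
#' Applies [hierarchical_merge()] independently within each similarity group
#' from [similarity_groups()]; singleton groups are passed through with no
#' comparisons. May merge fewer pairs than the full procedure (never more),
#' which is why the final round uses the full merge.
#'
#' @param clusters List of `pep_cluster` objects.
#' @param distant_hit_sets Named list: cluster id -> distant-hit sequences.
#' @param threshold Merge threshold (bits per match state of the smaller
#'   model).
#' @param config A [clustering_config()].
#' @return List of `pep_cluster` objects.
#' @export
heuristic_merge <- function(clusters, distant_hit_sets, threshold, config) {
  ids <- vapply(clusters, `[[`, 0L, "id")
  groups <- similarity_groups(distant_hit_sets[as.character(ids)])
  out <- list()
  for (g in groups) {
    sub <- clusters[ids %in% g]
    out <- c(out, if (length(sub) > 1L) {
      hierarchical_merge(sub, threshold, config)
    } else sub)
  }
  out[order(vapply(out, `[[`, 0L, "id"))]
}
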