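# Orchestration of the progressive-growth loop: greedy seeding, core
# selection, then alternating profile-HMM extension and cluster merging over
# several rounds with relaxing thresholds, the full (non-heuristic) merge in
# the last round, and result assembly. Diversity constraints are enforced at
# every alignment mutation.

#' Configuration for a clustering run
#'
#' @param n_rounds Number of extension/merge rounds (default 3).
#' @param extension_thresholds Per-round extension cutoffs in absolute bits,
#'   non-increasing; a pool sequence may enter a cluster only if its local
#'   Viterbi bit score against that cluster's HMM reaches the cutoff.
#' @param merge_thresholds Per-round merge cutoffs, non-increasing, in the
#'   units set by `merge_normalization`.
#' @param merge_normalization How HMM-HMM scores are compared to the merge
#'   threshold: `"none"` (absolute bits, default), `"min_states"` (bits per
#'   match state of the smaller model), or `"pairs"` (bits per aligned state
#'   pair).
#' @param distant_offset Offset in bits subtracted from the extension
#'   threshold to form the distant-hit threshold that drives the heuristic
#'   merge grouping.
#' @param matrix Substitution matrix for greedy seeding.
#' @param greedy_theta Per-residue greedy joining threshold; the absolute
#'   threshold is `round(greedy_theta * median sequence length)`.
#' @param max_shift Maximum shift of the gapless pairwise alignment.
#' @param order Greedy pass ordering (see [sort_unique()]).
#' @param core_fraction,core_max,core_min_size Core selection (see
#'   [select_cores()]).
#' @param min_match_states Minimum number of HMM match states (default 4).
#' @param gap_threshold,ic_threshold Match-column rule (defaults 0.05, 1.2).
#' @param max_positions Cap on alignment width; `NULL` means the maximum
#'   input sequence length plus 8, fixed at run start.
#' @param max_inner_gap_frac Inner-gap cap as a fraction of the member count
#'   (`round(frac * n_members)`, default 2).
#' @param hmm_gap_open,hmm_gap_extend Affine gap penalties (bits) of the
#'   HMM-HMM local alignment used for merging.
#' @param pseudocount_weight Emission pseudocount weight for HMM building.
#' @param background Null-model residue frequencies.
#' @param seed Seed for any randomized ordering.
#' @param validate Run internal consistency checks (sequence-partition and
#'   row-degapping invariants) at every round boundary; for debugging and
#'   tests.
#' @return A `clustering_config` list.
#' @export
clustering_config <- function(n_rounds = 3L,
                              extension_thresholds = c(8, 6.5, 5.5),
                              merge_thresholds = c(10, 8, 6),
                              merge_normalization = "none",
                              distant_offset = 2,
                              matrix = blosum62(),
                              greedy_theta = 2.5,
                              max_shift = 1L,
                              order = "copy_number",
                              core_fraction = 0.025,
                              core_max = 250L,
                              core_min_size = 2L,
                              min_match_states = 4L,
                              gap_threshold = 0.05,
                              ic_threshold = 1.2,
                              max_positions = NULL,
                              max_inner_gap_frac = 2,
                              hmm_gap_open = -1.5,
                              hmm_gap_extend = -0.5,
                              pseudocount_weight = 3,
                              background = aa_background(),
                              seed = 1L,
                              validate = FALSE) {
  stopifnot(n_rounds >= 1L,
            length(extension_thresholds) == n_rounds,
            length(merge_thresholds) == n_rounds,
            all(diff(extension_thresholds) <= 0),
            all(diff(merge_thresholds) <= 0),
            core_fraction > 0, core_fraction <= 1,
            min_match_states >= 1L)
  structure(list(n_rounds = as.integer(n_rounds),
                 extension_thresholds = extension_thresholds,
                 merge_thresholds = merge_thresholds,
                 merge_normalization = match.arg(merge_normalization,
                                                 c("none", "min_states", "pairs")),
                 distant_offset = distant_offset,
                 matrix = matrix,
                 greedy_theta = greedy_theta,
                 max_shift = as.integer(max_shift),
                 order = order,
                 core_fraction = core_fraction,
                 core_max = as.integer(core_max),
                 core_min_size = as.integer(core_min_size),
                 min_match_states = as.integer(min_match_states),
                 gap_threshold = gap_threshold,
                 ic_threshold = ic_threshold,
                 max_positions = max_positions,
                 max_inner_gap_frac = max_inner_gap_frac,
                 hmm_gap_open = hmm_gap_open,
                 hmm_gap_extend = hmm_gap_extend,
                 pseudocount_weight = pseudocount_weight,
                 background = background,
                 seed = as.integer(seed),
                 validate = isTRUE(validate)),
            class = "clustering_config")
}

#' Check the diversity constraints of a candidate alignment
#'
#' A candidate cluster alignment is acceptable when it still has at least
#' `min_match_states` match columns, its width does not exceed
#' `max_positions`, and its inner-gap count does not exceed
#' `round(max_inner_gap_frac * n_members)`. All bounds are inclusive.
#'
#' @param msa Candidate `pep_msa`.
#' @param config A [clustering_config()] (with `max_positions` resolved).
#' @param n_members Number of member sequences (defaults to `nrow(msa)`).
#' @return List with `ok` (logical) and, when `FALSE`, `reason`.
#' @export
diversity_ok <- function(msa, config, n_members = nrow(msa)) {
  mc <- match_columns(msa, config$gap_threshold, config$ic_threshold)
  if (length(mc) < config$min_match_states) {
    return(list(ok = FALSE, reason = sprintf("match_states %d < %d",
                                             length(mc), config$min_match_states)))
  }
  maxp <- config$max_positions
  if (!is.null(maxp) && ncol(msa) > maxp) {
    return(list(ok = FALSE, reason = sprintf("width %d > %d", ncol(msa), maxp)))
  }
  max_ig <- round(config$max_inner_gap_frac * n_members)
  ig <- inner_gap_count(msa)
  if (ig > max_ig) {
    return(list(ok = FALSE, reason = sprintf("inner_gaps %d > %d", ig, max_ig)))
  }
  list(ok = TRUE, reason = NULL)
}

new_cluster <- function(id, msa, config, provenance = character()) {
  mc <- match_columns(msa, config$gap_threshold, config$ic_threshold)
  hmm <- build_phmm(msa, mc, config$pseudocount_weight, config$background,
                    min_match = config$min_match_states)
  structure(list(id = as.integer(id),
                 msa = msa,
                 match_cols = mc,
                 members = rownames(msa),
                 hmm = hmm,
                 provenance = provenance),
            class = "pep_cluster")
}

#' @export
print.pep_cluster <- function(x, ...) {
  cat(sprintf("pep_cluster %d: %d sequences, width %d, %d match states (%s)\n",
              x$id, length(x$members), ncol(x$msa), length(x$match_cols),
              msa_consensus(x$msa, x$match_cols)))
  invisible(x)
}

#' One extension round
#'
#' Scores every pool sequence against every cluster's pre-round HMM. A
#' sequence is assigned to the cluster giving its highest bit score among
#' clusters where the score reaches `threshold` (ties: larger cluster, then
#' smaller id). Assigned sequences are inserted in descending
#' score order (ties alphabetic); each insertion is checked with
#' [diversity_ok()] and a rejected sequence returns to the pool. HMMs are
#' rebuilt once per modified cluster at the end of the round.
#'
#' @param clusters List of `pep_cluster` objects.
#' @param pool Character vector of unassigned sequences.
#' @param threshold Extension threshold in absolute bits.
#' @param config A [clustering_config()].
#' @return List with updated `clusters`, `pool`, and `distant_hits` (named
#'   list: cluster id -> sequences scoring above the relaxed distant
#'   threshold, reused by the heuristic merge grouping).
#' @export
extension_round <- function(clusters, pool, threshold, config) {
  n_cl <- length(clusters)
  distant <- setNames(vector("list", n_cl),
                      vapply(clusters, `[[`, 0L, "id"))
  if (length(pool) == 0L || n_cl == 0L) {
    return(list(clusters = clusters, pool = pool,
                distant_hits = lapply(distant, function(x) character())))
  }
  enc <- aa_encode(pool)
  scores <- matrix(-Inf, nrow = length(pool), ncol = n_cl)
  abs_thr <- numeric(n_cl)
  for (c in seq_len(n_cl)) {
    hmm <- clusters[[c]]$hmm
    scores[, c] <- cpp_viterbi_score_many(hmm_log_odds(hmm),
                                          hmm_log_trans(hmm), enc)
    abs_thr[c] <- threshold
    dist_thr <- threshold - config$distant_offset
    distant[[c]] <- pool[scores[, c] >= dist_thr]
  }
  sizes <- vapply(clusters, function(cl) length(cl$members), 0L)
  ids <- vapply(clusters, `[[`, 0L, "id")
  eligible <- sweep(scores, 2L, abs_thr, ">=")
  assign_to <- integer(length(pool))
  best_score <- numeric(length(pool))
  for (s in seq_along(pool)) {
    ok <- which(eligible[s, ])
    if (length(ok) == 0L) next
    sc <- scores[s, ok]
    pick <- ok[order(-sc, -sizes[ok], ids[ok])][1L]
    assign_to[s] <- pick
    best_score[s] <- scores[s, pick]
  }
  chosen <- which(assign_to > 0L)
  chosen <- chosen[order(-best_score[chosen], pool[chosen])]
  rejected <- character()
  modified <- logical(n_cl)
  for (s in chosen) {
    c <- assign_to[s]
    cl <- clusters[[c]]
    hit <- viterbi_local(cl$hmm, pool[s])
    cand <- insert_sequence(cl$msa, pool[s], hit, cl$match_cols)
    div <- diversity_ok(cand$msa, config, n_members = nrow(cand$msa))
    if (!div$ok) {
      rejected <- c(rejected, pool[s])
      next
    }
    cl$msa <- cand$msa
    cl$match_cols <- cand$match_cols
    cl$members <- rownames(cand$msa)
    clusters[[c]] <- cl
    modified[c] <- TRUE
  }
  for (c in which(modified)) {
    cl <- clusters[[c]]
    clusters[[c]] <- new_cluster(cl$id, cl$msa, config,
                                 provenance = c(cl$provenance,
                                                sprintf("extend(+%d)",
                                                        length(cl$members))))
  }
  assigned <- pool[assign_to > 0L]
  new_pool <- sort(c(setdiff(pool, assigned), rejected))
  list(clusters = clusters, pool = new_pool, distant_hits = distant)
}

#' Run the full progressive clustering pipeline
#'
#' Executes greedy seeding on the ordered unique sequences, size-based core
#' selection, then `n_rounds` alternations of extension and merging with the
#' configured relaxing thresholds; the last round uses the full
#' (non-heuristic) merge. Cores whose alignment cannot satisfy the diversity
#' constraints are dissolved into the pool.
#'
#' @param useqs A `unique_seqs` data frame from [deduplicate()].
#' @param config A [clustering_config()].
#' @return A `slimclust_result`: list with `clusters` (list of
#'   `pep_cluster`), `unassigned` (character vector), `input` (the
#'   `unique_seqs`), `config`, and `log` (per-round event data frame).
#' @export
run_clustering <- function(useqs, config = clustering_config()) {
  stopifnot(nrow(useqs) > 0L)
  check_state <- function(clusters, pool, stage) {
    if (!isTRUE(config$validate)) return(invisible())
    assigned <- unlist(lapply(clusters, `[[`, "members"))
    all_seqs <- sort(c(assigned, pool))
    if (anyDuplicated(all_seqs) || !identical(all_seqs, sort(useqs$sequence))) {
      stop("partition invariant violated after ", stage)
    }
    for (cl in clusters) {
      degapped <- apply(cl$msa, 1L, function(r) paste(r[r != GAP], collapse = ""))
      if (!identical(unname(degapped), rownames(cl$msa))) {
        stop("degapping invariant violated after ", stage)
      }
    }
    invisible()
  }
  if (is.null(config$max_positions)) {
    config$max_positions <- max(nchar(useqs$sequence)) + 8L
  }
  ordered <- sort_unique(useqs, config$order, config$seed)
  thr <- greedy_threshold(ordered$sequence, config$greedy_theta)
  gcl <- greedy_cluster(ordered, config$matrix, thr, config$max_shift)
  sel <- select_cores(gcl, useqs, config$core_fraction, config$core_max,
                      config$core_min_size)
  pool <- sel$pool
  clusters <- list()
  log <- data.frame(stage = character(), round = integer(),
                    n_clusters = integer(), n_pool = integer())
  for (core in sel$cores) {
    msa <- core_msa(core)
    div <- diversity_ok(msa, config, n_members = nrow(msa))
    if (div$ok) {
      clusters[[length(clusters) + 1L]] <-
        new_cluster(length(clusters) + 1L, msa, config,
                    provenance = sprintf("core(greedy %d)", core$id))
    } else {
      pool <- sort(c(pool, core$members$sequence))
    }
  }
  log <- rbind(log, data.frame(stage = "seeding", round = 0L,
                               n_clusters = length(clusters),
                               n_pool = length(pool)))
  check_state(clusters, pool, "seeding")
  for (r in seq_len(config$n_rounds)) {
    ext <- extension_round(clusters, pool,
                           config$extension_thresholds[r], config)
    clusters <- ext$clusters
    pool <- ext$pool
    log <- rbind(log, data.frame(stage = "extension", round = r,
                                 n_clusters = length(clusters),
                                 n_pool = length(pool)))
    check_state(clusters, pool, paste0("extension round ", r))
    clusters <- if (r < config$n_rounds) {
      heuristic_merge(clusters, ext$distant_hits,
                      config$merge_thresholds[r], config)
    } else {
      hierarchical_merge(clusters, config$merge_thresholds[r], config)
    }
    log <- rbind(log, data.frame(stage = "merging", round = r,
                                 n_clusters = length(clusters),
                                 n_pool = length(pool)))
    check_state(clusters, pool, paste0("merging round ", r))
  }
  structure(list(clusters = clusters,
                 unassigned = pool,
                 input = useqs,
                 config = config,
                 log = log),
            class = "slimclust_result")
}

#' @export
print.slimclust_result <- function(x, ...) {
  cat(sprintf("slimclust_result: %d clusters, %d of %d unique sequences unassigned\n",
              length(x$clusters), length(x$unassigned), nrow(x$input)))
  for (cl in x$clusters) print(cl)
  invisible(x)
}
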