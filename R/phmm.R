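# Profile hidden Markov models built from cluster alignments, and local
# Viterbi search of the sequence pool. This replaces external hmmbuild /
# hmmsearch machinery with a native implementation: match states with
# position-specific emissions, shared-background insert states, and
# position-specific transitions estimated from the alignment with
# add-one transition pseudocounts and Dirichlet-style background-proportional
# emission pseudocounts. Scoring is local log2-odds Viterbi with uniform
# entry over match states, free exit, and unpenalized flanks.

#' Build a profile HMM from an alignment
#'
#' @param msa A `pep_msa`.
#' @param match_cols Alignment columns acting as match states (see
#'   [match_columns()]); must number at least `min_match`.
#' @param pseudocount_weight Total background-proportional pseudo-observations
#'   added per match column (default 1).
#' @param background Null-model residue frequencies ([aa_background()]).
#' @param min_match Minimum number of match states (default 4).
#' @return A `profile_hmm`: list with `n_match`, `match_emissions`
#'   (`n_match` x 20), `insert_emissions`, `transitions` (`n_match` x 7
#'   probability matrix, columns MM, MI, MD, IM, II, DM, DD; row k describes
#'   transitions leaving position k, last row unused), `match_column_map`,
#'   and `background`.
#' @export
build_phmm <- function(msa, match_cols, pseudocount_weight = 1,
                       background = aa_background(), min_match = 4L) {
  K <- length(match_cols)
  if (K < min_match) {
    stop("cluster has ", K, " match columns; minimum is ", min_match)
  }
  stopifnot(all(diff(match_cols) > 0), pseudocount_weight >= 0)
  em <- matrix(0, nrow = K, ncol = 20, dimnames = list(NULL, AA))
  for (k in seq_len(K)) {
    res <- msa[, match_cols[k]]
    res <- res[res != GAP]
    cnt <- table(factor(res, levels = AA))
    v <- as.numeric(cnt) + pseudocount_weight * background
    em[k, ] <- v / sum(v)
  }
  # Transition counts from each row's implied path over the match columns.
  # A row's path runs from its first to its last non-gap match column
  # (leading/trailing gaps at match columns are unaligned flanks, not
  # deletions); interior gaps at match columns are delete states and
  # residues strictly between consecutive match columns are insert states.
  tc <- matrix(1, nrow = K, ncol = 7,
               dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II", "DM", "DD")))
  for (i in seq_len(nrow(msa))) {
    row <- msa[i, ]
    at_match <- row[match_cols] != GAP
    if (!any(at_match)) next
    k0 <- which(at_match)[1L]
    k1 <- rev(which(at_match))[1L]
    if (k1 == k0) next
    for (k in k0:(k1 - 1L)) {
      n_ins <- if (match_cols[k + 1L] - match_cols[k] > 1L) {
        sum(row[(match_cols[k] + 1L):(match_cols[k + 1L] - 1L)] != GAP)
      } else 0L
      from_m <- at_match[k]
      to_m <- at_match[k + 1L]
      if (n_ins > 0L) {
        if (from_m) tc[k, "MI"] <- tc[k, "MI"] + 1 else {
          # delete state emitting into an insert region is collapsed to D->M
          # via the insert (rare with shift-based alignments); count as DM.
          tc[k, "DM"] <- tc[k, "DM"] + 1
        }
        tc[k, "II"] <- tc[k, "II"] + (n_ins - 1L)
        tc[k, "IM"] <- tc[k, "IM"] + 1
        if (!to_m) tc[k, "MD"] <- tc[k, "MD"] + 0  # I->D not modelled
      } else {
        key <- paste0(if (from_m) "M" else "D", if (to_m) "M" else "D")
        tc[k, key] <- tc[k, key] + 1
      }
    }
  }
  tr <- tc
  tr[, c("MM", "MI", "MD")] <- tc[, c("MM", "MI", "MD")] /
    rowSums(tc[, c("MM", "MI", "MD"), drop = FALSE])
  tr[, c("IM", "II")] <- tc[, c("IM", "II")] /
    rowSums(tc[, c("IM", "II"), drop = FALSE])
  tr[, c("DM", "DD")] <- tc[, c("DM", "DD")] /
    rowSums(tc[, c("DM", "DD"), drop = FALSE])
  structure(list(n_match = K,
                 match_emissions = em,
                 insert_emissions = background,
                 transitions = tr,
                 match_column_map = as.integer(match_cols),
                 background = background),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cons <- AA[apply(x$match_emissions, 1L, which.max)]
  cat(sprintf("profile_hmm: %d match states, consensus %s\n",
              x$n_match, paste(cons, collapse = "")))
  invisible(x)
}

hmm_log_odds <- function(hmm) {
  log2(sweep(hmm$match_emissions, 2L, hmm$background, "/"))
}

hmm_log_trans <- function(hmm) {
  log2(hmm$transitions)
}

#' Local Viterbi alignment of a peptide against a profile HMM
#'
#' Computes the maximum log2-odds local alignment: entry into any match state
#' with probability `1/n_match`, free exit from any match state, insert
#' emissions equal to the background (log-odds 0), and unaligned flanking
#' residues unpenalized.
#'
#' @param hmm A `profile_hmm`.
#' @param sequence Peptide string.
#' @return A `scored_hit`: list with `sequence`, `bit_score`, `path` (data
#'   frame `state` in \{1 = match, 2 = insert, 3 = delete\}, `k` model
#'   position, `i` consumed sequence position or 0 for deletes), and `span`,
#'   the half-open interval `[start, end)` of aligned sequence positions.
#' @export
viterbi_local <- function(hmm, sequence) {
  enc <- aa_encode(sequence)[[1L]]
  res <- cpp_viterbi_path(hmm_log_odds(hmm), hmm_log_trans(hmm), enc)
  consumed <- res$i[res$state != 3L]
  structure(list(sequence = sequence,
                 bit_score = res$score,
                 path = data.frame(state = res$state, k = res$k, i = res$i),
                 span = c(min(consumed), max(consumed) + 1L)),
            class = "scored_hit")
}

#' Score every pool sequence against a profile HMM
#'
#' @param hmm A `profile_hmm`.
#' @param pool Character vector of pool sequences.
#' @param threshold Bit-score cutoff (absolute bits).
#' @return Data frame `sequence`, `bit_score` for all pool sequences scoring
#'   at least `threshold`, sorted by score descending (ties alphabetic). The
#'   pool itself is not modified.
#' @export
search_pool <- function(hmm, pool, threshold) {
  if (length(pool) == 0L) {
    return(data.frame(sequence = character(), bit_score = numeric()))
  }
  sc <- cpp_viterbi_score_many(hmm_log_odds(hmm), hmm_log_trans(hmm),
                               aa_encode(pool))
  keep <- sc >= threshold
  out <- data.frame(sequence = pool[keep], bit_score = sc[keep],
                    stringsAsFactors = FALSE)
  out[order(-out$bit_score, out$sequence), , drop = FALSE]
}

#' Distantly similar pool sequences of a cluster
#'
#' The relaxed-threshold hit set used by the merge-grouping heuristic; a
#' superset of the extension hits whenever `distant_threshold` does not
#' exceed the extension threshold.
#'
#' @param hmm A `profile_hmm`.
#' @param pool Character vector of pool sequences.
#' @param distant_threshold Bit-score cutoff (absolute bits).
#' @return Character vector of sequences scoring at least the cutoff.
#' @export
distant_hits <- function(hmm, pool, distant_threshold) {
  search_pool(hmm, pool, distant_threshold)$sequence
}
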