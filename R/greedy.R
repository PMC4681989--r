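# Initial greedy incremental clustering: a single ordered pass in which each
# sequence either joins the best-scoring existing representative or founds a
# new cluster, followed by size-based selection of cluster cores.

#' Order unique sequences for the greedy pass
#'
#' @param useqs A `unique_seqs` data frame (see [deduplicate()]).
#' @param order `"copy_number"` (total count descending, ties alphabetic),
#'   `"alphabetic"`, or `"random"`.
#' @param seed Integer seed used only for `order = "random"`.
#' @return The reordered `unique_seqs` data frame.
#' @export
sort_unique <- function(useqs, order = c("copy_number", "alphabetic", "random"),
                        seed = 1L) {
  order <- match.arg(order)
  idx <- switch(order,
    copy_number = order(-useqs$total_count, useqs$sequence),
    alphabetic = order(useqs$sequence),
    random = {
      rng <- local({
        set.seed(seed)
        sample.int(nrow(useqs))
      })
      rng
    })
  out <- useqs[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy incremental clustering
#'
#' Processes sequences in their given order. The first founds cluster 1;
#' each subsequent sequence is scored with [gapless_shift_score()] against
#' all current representatives and joins the best-scoring one if that score
#' reaches `threshold` (ties: earliest-created cluster), else founds a new
#' cluster. Representatives never change after creation.
#'
#' @param ordered A `unique_seqs` data frame in insertion order.
#' @param matrix Substitution matrix.
#' @param threshold Absolute joining threshold in matrix units.
#' @param max_shift Maximum shift for the pairwise alignment.
#' @return List of `greedy_cluster` objects: each has `id`, `representative`,
#'   and `members` (data frame `sequence`, `shift`, `score`, representative
#'   first with shift 0).
#' @export
greedy_cluster <- function(ordered, matrix = blosum62(), threshold,
                           max_shift = 1L) {
  stopifnot(nrow(ordered) > 0L)
  enc <- aa_encode(ordered$sequence)
  if (max_shift < 0L || max_shift >= min(lengths(enc))) {
    stop("max_shift must be smaller than the shortest sequence")
  }
  res <- cpp_greedy(enc, matrix, threshold, as.integer(max_shift))
  ids <- sort(unique(res$cluster))
  lapply(ids, function(id) {
    sel <- which(res$cluster == id)
    members <- data.frame(sequence = ordered$sequence[sel],
                          shift = res$shift[sel],
                          score = res$score[sel],
                          stringsAsFactors = FALSE)
    structure(list(id = id,
                   representative = members$sequence[1L],
                   members = members),
              class = "greedy_cluster")
  })
}

#' Select cluster cores by size
#'
#' Sorts greedy clusters by unique-member count descending (ties: total copy
#' count descending, then id ascending) and promotes the top
#' `min(max_count, ceiling(fraction * n_clusters))` clusters of size at least
#' `min_size` to cores. All sequences of unselected clusters are dissolved
#' into the sequence pool.
#'
#' @param clusters List of `greedy_cluster` objects.
#' @param useqs The `unique_seqs` data frame (for copy-count tie-breaks).
#' @param fraction Proportion of clusters to keep (default 0.025).
#' @param max_count Hard cap on the number of cores (default 250).
#' @param min_size Minimum unique-member count of a core (default 2).
#' @return List with `cores` (list of `greedy_cluster`) and `pool`
#'   (character vector of pooled sequences).
#' @export
select_cores <- function(clusters, useqs, fraction = 0.025, max_count = 250L,
                         min_size = 2L) {
  stopifnot(fraction > 0, fraction <= 1)
  n_unique <- vapply(clusters, function(cl) nrow(cl$members), 0L)
  n_total <- vapply(clusters, function(cl) {
    sum(useqs$total_count[match(cl$members$sequence, useqs$sequence)])
  }, 0)
  ids <- vapply(clusters, `[[`, 0L, "id")
  ord <- order(-n_unique, -n_total, ids)
  n_keep <- min(max_count, ceiling(fraction * length(clusters)))
  keep <- head(ord[n_unique[ord] >= min_size], n_keep)
  cores <- clusters[keep]
  pooled <- clusters[setdiff(seq_along(clusters), keep)]
  pool <- unlist(lapply(pooled, function(cl) cl$members$sequence))
  list(cores = cores, pool = sort(as.character(pool)))
}
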