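# Clustering-quality metrics: Kullback-Leibler divergence of alignment
# columns from background, dataset summary statistics, per-label copy-count
# matrices, and purity against a synthetic ground truth.

#' Kullback-Leibler divergence of alignment columns from background
#'
#' Sums, over the given columns, the KL divergence of the column's non-gap
#' residue frequencies from the background distribution:
#' `sum_r f(r) * log2(f(r) / bg(r))` with the `0 * log 0 = 0` convention and
#' no pseudocounts.
#'
#' @param msa A `pep_msa`.
#' @param columns Column indices (each must contain a residue).
#' @param background Background residue frequencies.
#' @return Total divergence in bits (non-negative).
#' @export
kld <- function(msa, columns, background = aa_background()) {
  if (length(columns) == 0L) stop("empty column set")
  sum(vapply(columns, function(j) {
    res <- msa[, j]
    res <- res[res != GAP]
    if (length(res) == 0L) stop("all-gap column: ", j)
    f <- column_freqs(msa, j)
    nz <- f > 0
    sum(f[nz] * log2(f[nz] / background[nz]))
  }, 0))
}

#' Dataset-level KLD over clusters
#'
#' Combines per-cluster KLD values into a dataset score as the
#' sequence-count-weighted mean over clusters (weights: unique member
#' counts), or the unweighted mean.
#'
#' @param result A `slimclust_result`.
#' @param which `"match"` (over match columns) or `"all"` (every column).
#' @param weighted Weight clusters by unique-sequence count (default TRUE).
#' @param background Background residue frequencies.
#' @return Dataset KLD in bits; `NA` if there are no clusters.
#' @export
dataset_kld <- function(result, which = c("match", "all"), weighted = TRUE,
                        background = aa_background()) {
  which <- match.arg(which)
  if (length(result$clusters) == 0L) return(NA_real_)
  vals <- vapply(result$clusters, function(cl) {
    cols <- if (which == "match") cl$match_cols else {
      which(colSums(cl$msa != GAP) > 0L)
    }
    kld(cl$msa, cols, background)
  }, 0)
  w <- if (weighted) {
    vapply(result$clusters, function(cl) length(cl$members), 0L)
  } else rep(1L, length(vals))
  sum(vals * w) / sum(w)
}

#' Summary statistics of a clustering result
#'
#' @param result A `slimclust_result`.
#' @return A `dataset_summary` list: `n_unique_total`, `n_unique_clustered`,
#'   `copy_total`, `copy_clustered`, `n_clusters`, `cluster_sizes`, and the
#'   derived `percent_unique_clustered` and `percent_copies_clustered`
#'   (rounded to one decimal for reporting).
#' @export
dataset_summary <- function(result) {
  useqs <- result$input
  clustered <- unlist(lapply(result$clusters, `[[`, "members"))
  idx <- match(clustered, useqs$sequence)
  n_unique_total <- nrow(useqs)
  n_unique_clustered <- length(clustered)
  copy_total <- sum(useqs$total_count)
  copy_clustered <- sum(useqs$total_count[idx])
  structure(list(
    n_unique_total = n_unique_total,
    n_unique_clustered = n_unique_clustered,
    copy_total = copy_total,
    copy_clustered = copy_clustered,
    n_clusters = length(result$clusters),
    cluster_sizes = vapply(result$clusters, function(cl) length(cl$members), 0L),
    percent_unique_clustered = round(100 * n_unique_clustered / n_unique_total, 1L),
    percent_copies_clustered = round(100 * copy_clustered / copy_total, 1L)),
    class = "dataset_summary")
}

#' Percentage identities of clustered counts
#'
#' Direct computation of the two reporting percentages from raw counts,
#' usable without a full result object.
#'
#' @param n_unique_clustered,n_unique_total Unique-sequence counts.
#' @param copy_clustered,copy_total Copy-number sums.
#' @return Named vector `percent_unique_clustered`,
#'   `percent_copies_clustered`, rounded to one decimal.
#' @export
summary_percentages <- function(n_unique_clustered, n_unique_total,
                                copy_clustered, copy_total) {
  c(percent_unique_clustered = round(100 * n_unique_clustered / n_unique_total, 1L),
    percent_copies_clustered = round(100 * copy_clustered / copy_total, 1L))
}

#' Per-label copy-count matrix of a clustering result
#'
#' One row per cluster, one column per label; entry = total copy count of
#' the cluster's members under that label. With `normalize = TRUE` each
#' column is divided by its label's dataset-wide copy total, so column sums
#' (including the `unassigned` pseudo-row) equal 1.
#'
#' @param result A `slimclust_result`.
#' @param normalize Divide columns by dataset-wide label totals.
#' @param include_unassigned Append an `unassigned` pseudo-row.
#' @return Numeric matrix with cluster ids (and optionally `unassigned`) as
#'   row names and labels as column names.
#' @export
label_matrix <- function(result, normalize = FALSE,
                         include_unassigned = TRUE) {
  useqs <- result$input
  labels <- all_labels(useqs)
  if (length(labels) == 0L || identical(labels, NO_LABEL)) {
    stop("input has no labels; use dataset_summary() for unlabeled data")
  }
  counts_for <- function(seqs) {
    idx <- match(seqs, useqs$sequence)
    v <- setNames(numeric(length(labels)), labels)
    for (i in idx) {
      ci <- useqs$counts[[i]]
      v[names(ci)] <- v[names(ci)] + ci
    }
    v
  }
  rows <- lapply(result$clusters, function(cl) counts_for(cl$members))
  ids <- vapply(result$clusters, `[[`, 0L, "id")
  m <- do.call(rbind, c(rows, if (include_unassigned)
    list(counts_for(result$unassigned))))
  rownames(m) <- c(as.character(ids), if (include_unassigned) "unassigned")
  if (normalize) {
    totals <- counts_for(useqs$sequence)
    m <- sweep(m, 2L, totals, "/")
  }
  m
}

#' Category-profile distance between two clusters
#'
#' One minus the Pearson correlation of two rows of the (normalized) label
#' matrix; ranges over `[0, 2]`.
#'
#' @param m A matrix from [label_matrix()].
#' @param a,b Row names or indices.
#' @return Distance in `[0, 2]`.
#' @export
profile_correlation <- function(m, a, b) {
  va <- m[a, ]; vb <- m[b, ]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("zero-variance category profile; correlation undefined")
  }
  1 - stats::cor(va, vb)
}

#' Cluster purity against a ground-truth assignment
#'
#' For each cluster, the fraction of member unique sequences whose true
#' motif equals the cluster's majority motif. Noise sequences always count
#' against purity: a cluster whose majority class is noise has purity 0.
#'
#' @param result A `slimclust_result`.
#' @param truth Data frame `sequence`, `motif` (the generator's sidecar;
#'   noise sequences labelled `"noise"`).
#' @return Data frame `cluster_id`, `majority_motif`, `purity`, `n`.
#' @export
cluster_purity <- function(result, truth) {
  stopifnot(all(unlist(lapply(result$clusters, `[[`, "members")) %in%
                  truth$sequence))
  out <- lapply(result$clusters, function(cl) {
    cls <- truth$motif[match(cl$members, truth$sequence)]
    tab <- sort(table(cls), decreasing = TRUE)
    motifs <- tab[setdiff(names(tab), "noise")]
    if (length(motifs) == 0L) {
      return(data.frame(cluster_id = cl$id, majority_motif = "noise",
                        purity = 0, n = length(cls)))
    }
    maj <- names(tab)[1L]
    if (maj == "noise") {
      return(data.frame(cluster_id = cl$id, majority_motif = "noise",
                        purity = 0, n = length(cls)))
    }
    data.frame(cluster_id = cl$id, majority_motif = maj,
               purity = as.numeric(tab[maj]) / length(cls), n = length(cls))
  })
  do.call(rbind, out)
}

#' Write per-cluster metrics to TSV
#'
#' @param result A `slimclust_result`.
#' @param path Output file.
#' @param background Background residue frequencies.
#' @return Invisibly, the metrics data frame.
#' @export
write_metrics <- function(result, path, background = aa_background()) {
  df <- do.call(rbind, lapply(result$clusters, function(cl) {
    all_cols <- which(colSums(cl$msa != GAP) > 0L)
    data.frame(cluster_id = cl$id,
               size_unique = length(cl$members),
               n_match_states = length(cl$match_cols),
               kld_match = kld(cl$msa, cl$match_cols, background),
               kld_all = kld(cl$msa, all_cols, background))
  }))
  if (is.null(df)) {
    df <- data.frame(cluster_id = integer(), size_unique = integer(),
                     n_match_states = integer(), kld_match = numeric(),
                     kld_all = numeric())
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
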