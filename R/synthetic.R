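# Planted-motif synthetic peptide datasets with display-like structure:
# degenerate motif patterns embedded in background flanks, i.i.d. background
# noise, power-law copy numbers, optional label mixtures, and a ground-truth
# sidecar. Every pipeline stage is testable against these without external
# data.

#' Define a motif pattern
#'
#' Patterns use a compact string language: one uppercase residue fixes a
#' position, `[RK]` samples uniformly from the bracketed set, and `x` (or
#' `.`) draws from the background. Per-position weight vectors may also be
#' supplied directly as a list (named numeric vectors summing to 1; `NULL`
#' elements mean background).
#'
#' @param pattern Pattern string such as `"[RK]xxPxxP"`, or a list of weight
#'   vectors.
#' @param name Motif name used in the ground truth.
#' @return A `motif_spec` list with `name` and `positions` (list of named
#'   weight vectors; `NULL` = background).
#' @export
motif_spec <- function(pattern, name) {
  positions <- if (is.list(pattern)) {
    lapply(pattern, function(p) {
      if (is.null(p)) return(NULL)
      stopifnot(abs(sum(p) - 1) < 1e-9, all(names(p) %in% AA))
      p
    })
  } else {
    toks <- regmatches(pattern,
                       gregexpr("\\[[A-Z]+\\]|[A-Zx.]", pattern))[[1L]]
    if (sum(nchar(toks)) != nchar(pattern)) stop("unparseable pattern: ", pattern)
    lapply(toks, function(t) {
      if (t %in% c("x", ".")) return(NULL)
      res <- strsplit(gsub("\\[|\\]", "", t), "")[[1L]]
      stopifnot(all(res %in% AA))
      setNames(rep(1 / length(res), length(res)), res)
    })
  }
  if (length(positions) < 4L) stop("pattern length must be at least 4")
  structure(list(name = name, positions = positions), class = "motif_spec")
}

sample_background <- function(n, background) {
  sample(AA, n, replace = TRUE, prob = background)
}

sample_power_law <- function(n, alpha, kmax) {
  k <- seq_len(kmax)
  sample(k, n, replace = TRUE, prob = k^(-alpha))
}

#' Generate a planted-motif peptide dataset
#'
#' Motif-bearing sequences consist of background flanks with the sampled
#' pattern placed at a random (uniform) feasible offset; noise sequences are
#' i.i.d. background residues. Copy numbers follow a discrete power law
#' `P(k) ~ k^-alpha` truncated at `copy_max`. Output is fully determined by
#' `seed`.
#'
#' @param motifs List of [motif_spec()] objects.
#' @param n_per_motif Integer vector, sequences per motif.
#' @param n_noise Number of noise sequences.
#' @param length Peptide length (must be at least the longest pattern).
#' @param labels Optional named numeric vector of label mixing weights; each
#'   record samples one label. `NULL` leaves records unlabeled.
#' @param copy_alpha Power-law exponent (default 2).
#' @param copy_max Copy-number truncation point (default 1e4).
#' @param seed Integer seed.
#' @param fixed_offset Optional fixed motif offset (0-based) instead of a
#'   uniform draw, for deterministic unit fixtures.
#' @return List with `occurrences` (data frame `sequence`, `count`, `label`)
#'   and `truth` (data frame `sequence`, `motif`; noise rows say
#'   `"noise"`). If one sequence is generated under two classes (vanishingly
#'   rare for realistic lengths), the first class wins.
#' @export
generate_dataset <- function(motifs, n_per_motif, n_noise, length = 12L,
                             labels = NULL, copy_alpha = 2, copy_max = 10000L,
                             seed = 1L, fixed_offset = NULL) {
  stopifnot(base::length(motifs) == base::length(n_per_motif))
  plens <- vapply(motifs, function(m) base::length(m$positions), 0L)
  if (any(plens > length)) stop("pattern longer than peptide length")
  set.seed(seed)
  bg <- aa_background()
  seqs <- character()
  cls <- character()
  for (mi in seq_along(motifs)) {
    m <- motifs[[mi]]
    plen <- plens[mi]
    for (s in seq_len(n_per_motif[mi])) {
      chars <- sample_background(length, bg)
      off <- if (is.null(fixed_offset)) {
        sample.int(length - plen + 1L, 1L) - 1L
      } else fixed_offset
      for (p in seq_len(plen)) {
        w <- m$positions[[p]]
        if (!is.null(w)) {
          chars[off + p] <- sample(names(w), 1L, prob = w)
        }
      }
      seqs <- c(seqs, paste(chars, collapse = ""))
      cls <- c(cls, m$name)
    }
  }
  if (n_noise > 0L) {
    noise <- vapply(seq_len(n_noise), function(i) {
      paste(sample_background(length, bg), collapse = "")
    }, "")
    seqs <- c(seqs, noise)
    cls <- c(cls, rep("noise", n_noise))
  }
  counts <- sample_power_law(base::length(seqs), copy_alpha, copy_max)
  lab <- if (is.null(labels)) rep(NA_character_, base::length(seqs)) else {
    sample(names(labels), base::length(seqs), replace = TRUE, prob = labels)
  }
  occurrences <- data.frame(sequence = seqs, count = as.integer(counts),
                            label = lab, stringsAsFactors = FALSE)
  truth <- data.frame(sequence = seqs, motif = cls, stringsAsFactors = FALSE)
  truth <- truth[!duplicated(truth$sequence), , drop = FALSE]
  rownames(truth) <- NULL
  list(occurrences = occurrences, truth = truth)
}

#' Two-motif polyproline fixture
#'
#' A structural mimic of a classic Src-SH3 phage display selection: 2457
#' length-12 peptides of which 1738 carry the class I polyproline ligand
#' `[R/K]xxPxxP`, 415 carry the class II ligand `PxxPx[R/K]`, and 304 are
#' background noise (about 12 percent).
#'
#' @param seed Integer seed (default 42).
#' @return As [generate_dataset()].
#' @export
sh3_like_fixture <- function(seed = 42L) {
  generate_dataset(
    motifs = list(motif_spec("[RK]xxPxxP", "class_I"),
                  motif_spec("PxxPx[RK]", "class_II")),
    n_per_motif = c(1738L, 415L),
    n_noise = 304L,
    length = 12L,
    seed = seed)
}

#' Write a generated dataset to disk
#'
#' Writes the tabular input dialect (`sequence<TAB>count<TAB>label`) plus a
#' `truth.tsv` sidecar (`sequence`, `motif`).
#'
#' @param dataset A list from [generate_dataset()].
#' @param data_path Path for the tabular occurrence file.
#' @param truth_path Path for the ground-truth sidecar.
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(dataset, data_path, truth_path) {
  occ <- dataset$occurrences
  occ$label[is.na(occ$label)] <- ""
  write.table(occ, data_path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  write.table(dataset$truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(data_path, truth_path))
}
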