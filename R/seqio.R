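# Reading peptide datasets (FASTA / tabular / plain), deduplication into
# unique sequences with per-label copy counts, and writing result files.

NO_LABEL <- "_nolabel"

validate_peptides <- function(seqs, lines, strict) {
  seqs <- toupper(seqs)
  ok <- grepl(paste0("^[", paste(AA, collapse = ""), "]+$"), seqs) &
    nzchar(seqs)
  if (any(!ok)) {
    msg <- sprintf(
      "%d record(s) with non-canonical or empty sequence skipped (first at line %d)",
      sum(!ok), lines[which(!ok)[1L]])
    if (strict) stop(msg) else warning(msg, call. = FALSE)
  }
  list(seqs = seqs, keep = ok)
}

#' Read peptide occurrences from a file
#'
#' Supports three input dialects:
#' \describe{
#'   \item{fasta}{One peptide per record. Header fields after the identifier
#'     are `|`-separated in the order `id|count|label`; missing fields default
#'     to count 1 and no label.}
#'   \item{tabular}{Tab-separated columns `sequence`, `count`, `label`
#'     (header row optional; `count` and `label` columns optional).}
#'   \item{plain}{One sequence per line, count 1, no label.}
#' }
#' Sequences are upper-cased on read. Records containing residues outside the
#' 20-letter canonical alphabet (B, J, O, U, X, Z, `*`, ...) are skipped with
#' a warning, or rejected with an error when `strict = TRUE`: ambiguous
#' translations carry no motif information.
#'
#' @param path Input file path.
#' @param format One of `"fasta"`, `"tabular"`, `"plain"`.
#' @param strict Error instead of warn-and-skip on non-canonical residues.
#' @return A data frame of occurrences with columns `sequence`, `count`
#'   (integer, per-record multiplicity), `label` (character, `NA` if absent).
#' @export
read_sequences <- function(path, format = c("fasta", "tabular", "plain"),
                           strict = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  occ <- switch(format,
    fasta = {
      set <- Biostrings::readAAStringSet(path)
      if (length(set) == 0L) stop("empty input: ", path)
      parts <- strsplit(sub("\\s.*$", "", names(set)), "|", fixed = TRUE)
      count <- vapply(parts, function(p) {
        if (length(p) >= 2L && nzchar(p[2L])) suppressWarnings(as.integer(p[2L])) else 1L
      }, 1L)
      if (anyNA(count)) {
        stop("malformed FASTA count field in record ",
             which(is.na(count))[1L])
      }
      label <- vapply(parts, function(p) {
        if (length(p) >= 3L && nzchar(p[3L])) p[3L] else NA_character_
      }, "")
      data.frame(sequence = as.character(set), count = count, label = label,
                 line = seq_along(set), stringsAsFactors = FALSE)
    },
    tabular = {
      lines <- readLines(path)
      lines <- lines[nzchar(trimws(lines))]
      if (length(lines) == 0L) stop("empty input: ", path)
      fields <- strsplit(lines, "\t", fixed = TRUE)
      first <- fields[[1L]]
      has_header <- tolower(trimws(first[1L])) %in% c("sequence", "seq", "peptide")
      lineno <- seq_along(lines)
      if (has_header) {
        fields <- fields[-1L]
        lineno <- lineno[-1L]
        if (length(fields) == 0L) stop("empty input: ", path)
      }
      seqs <- vapply(fields, function(f) trimws(f[1L]), "")
      count <- vapply(fields, function(f) {
        if (length(f) >= 2L && nzchar(trimws(f[2L])))
          suppressWarnings(as.integer(trimws(f[2L]))) else 1L
      }, 1L)
      if (anyNA(count) || any(count < 1L)) {
        bad <- which(is.na(count) | count < 1L)[1L]
        stop("malformed count at line ", lineno[bad])
      }
      label <- vapply(fields, function(f) {
        if (length(f) >= 3L && nzchar(trimws(f[3L]))) trimws(f[3L]) else NA_character_
      }, "")
      data.frame(sequence = seqs, count = count, label = label,
                 line = lineno, stringsAsFactors = FALSE)
    },
    plain = {
      lines <- readLines(path)
      keep <- nzchar(trimws(lines))
      if (!any(keep)) stop("empty input: ", path)
      data.frame(sequence = trimws(lines[keep]), count = 1L,
                 label = NA_character_, line = which(keep),
                 stringsAsFactors = FALSE)
    })
  v <- validate_peptides(occ$sequence, occ$line, strict)
  occ$sequence <- v$seqs
  occ <- occ[v$keep, c("sequence", "count", "label")]
  rownames(occ) <- NULL
  if (nrow(occ) == 0L) stop("no valid sequences in ", path)
  occ
}

#' Deduplicate occurrences into unique sequences
#'
#' Collapses an occurrence table into one row per distinct sequence,
#' preserving per-label copy counts. Occurrences without a label are
#' accumulated under the reserved label `"_nolabel"`.
#'
#' @param occurrences Data frame with columns `sequence`, `count` (optional,
#'   default 1), `label` (optional).
#' @return A `unique_seqs` data frame with columns `sequence`, `total_count`,
#'   and a list-column `counts` of named per-label count vectors. Rows are
#'   ordered by first appearance.
#' @export
deduplicate <- function(occurrences) {
  if (nrow(occurrences) == 0L) {
    out <- data.frame(sequence = character(), total_count = integer())
    out$counts <- list()
    class(out) <- c("unique_seqs", "data.frame")
    return(out)
  }
  seqs <- occurrences$sequence
  cnt <- if (is.null(occurrences$count)) rep(1L, length(seqs)) else occurrences$count
  lab <- if (is.null(occurrences$label)) rep(NA_character_, length(seqs)) else occurrences$label
  lab[is.na(lab)] <- NO_LABEL
  agg <- tapply(cnt, list(seqs, lab), sum, default = 0L)
  first <- seqs[!duplicated(seqs)]
  agg <- agg[first, , drop = FALSE]
  counts <- lapply(seq_len(nrow(agg)), function(i) {
    v <- setNames(as.numeric(agg[i, ]), colnames(agg))
    v[v > 0]
  })
  out <- data.frame(sequence = first,
                    total_count = as.integer(rowSums(agg)),
                    stringsAsFactors = FALSE)
  out$counts <- counts
  class(out) <- c("unique_seqs", "data.frame")
  out
}

#' @export
print.unique_seqs <- function(x, ...) {
  cat(sprintf("unique_seqs: %d unique sequences, %d total copies, %d label(s)\n",
              nrow(x), sum(x$total_count),
              length(unique(unlist(lapply(x$counts, names))))))
  print(utils::head(data.frame(sequence = x$sequence,
                               total_count = x$total_count), 10L))
  invisible(x)
}

all_labels <- function(useqs) {
  sort(unique(unlist(lapply(useqs$counts, names))))
}

#' Write clustering results to a directory
#'
#' Emits `clusters.tsv` (one row per cluster: id, unique and total sizes,
#' per-label copy totals, consensus over match columns, number of match
#' states), one aligned FASTA `cluster_<id>.afa` per cluster (gap character
#' `-`, headers `sequence|total_count`), `unassigned.tsv`, and
#' `label_matrix.tsv` (clusters x labels copy-count matrix with an
#' `unassigned` pseudo-row).
#'
#' @param result A `slimclust_result` from [run_clustering()].
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
export_results <- function(result, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  useqs <- result$input
  labels <- all_labels(useqs)
  count_of <- function(seqs) {
    idx <- match(seqs, useqs$sequence)
    m <- matrix(0, nrow = length(seqs), ncol = length(labels),
                dimnames = list(seqs, labels))
    for (i in seq_along(idx)) {
      v <- useqs$counts[[idx[i]]]
      m[i, names(v)] <- v
    }
    m
  }
  paths <- character()
  rows <- list()
  lm <- matrix(0, nrow = 0, ncol = length(labels))
  for (cl in result$clusters) {
    lc <- count_of(cl$members)
    lm <- rbind(lm, colSums(lc))
    rows[[length(rows) + 1L]] <- data.frame(
      cluster_id = cl$id,
      size_unique = length(cl$members),
      size_total = sum(lc),
      t(setNames(colSums(lc), paste0("count_", labels))),
      consensus = msa_consensus(cl$msa, cl$match_cols),
      n_match_states = length(cl$match_cols),
      stringsAsFactors = FALSE)
    afa <- file.path(out_dir, sprintf("cluster_%d.afa", cl$id))
    totals <- useqs$total_count[match(cl$members, useqs$sequence)]
    write_afa(cl$msa, afa, sprintf("%s|%d", rownames(cl$msa),
                                   totals[match(rownames(cl$msa), cl$members)]))
    paths <- c(paths, afa)
  }
  summary_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = integer(), size_unique = integer(),
               size_total = integer(), consensus = character(),
               n_match_states = integer())
  f <- file.path(out_dir, "clusters.tsv")
  write.table(summary_df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, f)

  un <- result$unassigned
  un_counts <- count_of(un)
  un_df <- data.frame(sequence = un,
                      total_count = useqs$total_count[match(un, useqs$sequence)],
                      stringsAsFactors = FALSE)
  f <- file.path(out_dir, "unassigned.tsv")
  write.table(un_df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, f)

  ids <- vapply(result$clusters, `[[`, 0L, "id")
  lmat <- rbind(lm, colSums(un_counts))
  dimnames(lmat) <- list(c(as.character(ids), "unassigned"), labels)
  f <- file.path(out_dir, "label_matrix.tsv")
  write.table(data.frame(cluster = rownames(lmat), lmat, check.names = FALSE),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, f)
  invisible(paths)
}

#' Write an alignment as aligned FASTA
#'
#' @param msa Alignment character matrix (see [core_msa()]).
#' @param path Output path.
#' @param headers Optional record headers; defaults to row names.
#' @export
write_afa <- function(msa, path, headers = rownames(msa)) {
  rows <- apply(msa, 1L, paste, collapse = "")
  set <- Biostrings::AAStringSet(setNames(rows, headers))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read an aligned FASTA file into an alignment matrix
#'
#' @param path Path to a `.afa` file written by [write_afa()].
#' @return Alignment character matrix with headers as row names.
#' @export
read_afa <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  rows <- as.character(set)
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("aligned FASTA rows differ in length: ", path)
  m <- do.call(rbind, strsplit(rows, ""))
  rownames(m) <- names(set)
  class(m) <- c("pep_msa", class(m))
  m
}
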