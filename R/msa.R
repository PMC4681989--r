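# Per-cluster multiple sequence alignments.
#
# An alignment is a character matrix (class "pep_msa"): one row per member
# sequence (row name = the sequence string, which is unique within a
# dataset), one column per alignment position, gap character "-". Two
# construction routes exist: rigid-shift core alignments from greedy
# clustering, and HMM-path-guided insertion of further rows. Both maintain
# the degapping invariant: deleting "-" from any row reproduces the member
# sequence exactly.

GAP <- "-"

as_msa <- function(m) {
  if (!inherits(m, "pep_msa")) class(m) <- c("pep_msa", class(m))
  m
}

#' @export
print.pep_msa <- function(x, ...) {
  cat(sprintf("pep_msa: %d rows x %d columns\n", nrow(x), ncol(x)))
  rows <- apply(x, 1L, paste, collapse = "")
  show <- utils::head(rows, 12L)
  cat(sprintf("  %s  %s\n", format(show), format(names(show))), sep = "")
  if (length(rows) > 12L) cat(sprintf("  ... %d more rows\n", length(rows) - 12L))
  invisible(x)
}

#' Build the core alignment of a greedy cluster
#'
#' Places each member at its stored shift against the representative and pads
#' with leading/trailing gaps; no inner gaps are introduced.
#'
#' @param cluster A `greedy_cluster` (see [greedy_cluster()]).
#' @return A `pep_msa` character matrix; row names are member sequences.
#' @export
core_msa <- function(cluster) {
  m <- cluster$members
  stopifnot(nrow(m) >= 1L)
  off <- m$shift - min(m$shift)
  len <- nchar(m$sequence)
  width <- max(off + len)
  rows <- matrix(GAP, nrow = nrow(m), ncol = width,
                 dimnames = list(m$sequence, NULL))
  for (i in seq_len(nrow(m))) {
    rows[i, (off[i] + 1L):(off[i] + len[i])] <- strsplit(m$sequence[i], "")[[1L]]
  }
  as_msa(rows)
}

msa_gap_fraction <- function(msa) {
  colMeans(msa == GAP)
}

column_freqs <- function(msa, col) {
  res <- msa[, col]
  res <- res[res != GAP]
  tab <- table(factor(res, levels = AA))
  as.numeric(tab) / length(res)
}

#' Information content of an alignment column
#'
#' `log2(20)` minus the Shannon entropy (bits) of the non-gap residue
#' frequencies in the column; no small-sample correction or pseudocounts.
#'
#' @param msa A `pep_msa`.
#' @param col Column index (1-based).
#' @return Information content in bits, in `[0, log2(20)]`.
#' @export
column_information_content <- function(msa, col) {
  res <- msa[, col]
  res <- res[res != GAP]
  if (length(res) == 0L) stop("all-gap column: ", col)
  f <- column_freqs(msa, col)
  f <- f[f > 0]
  log2(20) + sum(f * log2(f))
}

msa_column_ic <- function(msa) {
  vapply(seq_len(ncol(msa)), function(j) {
    if (all(msa[, j] == GAP)) 0 else column_information_content(msa, j)
  }, 0)
}

#' Match columns of an alignment
#'
#' Columns qualifying as profile-HMM match states: gap fraction strictly
#' below `gap_threshold` and information content at least `ic_threshold`.
#'
#' @param msa A `pep_msa`.
#' @param gap_threshold Strict upper bound on the column gap fraction
#'   (default 0.05).
#' @param ic_threshold Inclusive lower bound on information content in bits
#'   (default 1.2).
#' @return Increasing integer vector of column indices (1-based).
#' @export
match_columns <- function(msa, gap_threshold = 0.05, ic_threshold = 1.2) {
  gf <- msa_gap_fraction(msa)
  cand <- which(gf < gap_threshold)
  cand[vapply(cand, function(j) column_information_content(msa, j), 0) >=
         ic_threshold]
}

#' Count inner gaps of an alignment
#'
#' An inner gap is a gap character with at least one residue on each side
#' within its own row; leading and trailing gap runs are not counted.
#'
#' @param msa A `pep_msa`.
#' @return Total inner-gap count over all rows.
#' @export
inner_gap_count <- function(msa) {
  sum(apply(msa, 1L, function(row) {
    res <- which(row != GAP)
    if (length(res) < 2L) return(0L)
    sum(row[res[1L]:res[length(res)]] == GAP)
  }))
}

#' Consensus sequence over match columns
#'
#' @param msa A `pep_msa`.
#' @param cols Columns to report (default: all).
#' @return Single string of per-column majority residues (ties: alphabetic).
#' @export
msa_consensus <- function(msa, cols = seq_len(ncol(msa))) {
  if (length(cols) == 0L) return("")
  paste(vapply(cols, function(j) {
    res <- msa[, j]
    res <- res[res != GAP]
    if (length(res) == 0L) return(GAP)
    tab <- sort(table(res), decreasing = TRUE)
    names(tab)[1L]
  }, ""), collapse = "")
}

#' Column statistics for sequence-logo export
#'
#' Reports per-column residue frequencies, gap fraction, and information
#' content for the columns a logo would display: gap fraction strictly
#' below 0.5.
#'
#' @param msa A `pep_msa`.
#' @param max_gap_fraction Display cutoff (default 0.5).
#' @return Data frame with columns `column`, `residue`, `frequency`,
#'   `gap_fraction`, `ic`, ordered by column then residue.
#' @export
logo_frequencies <- function(msa, max_gap_fraction = 0.5) {
  gf <- msa_gap_fraction(msa)
  cols <- which(gf < max_gap_fraction)
  if (length(cols) == 0L) {
    return(data.frame(column = integer(), residue = character(),
                      frequency = numeric(), gap_fraction = numeric(),
                      ic = numeric()))
  }
  do.call(rbind, lapply(cols, function(j) {
    f <- column_freqs(msa, j)
    data.frame(column = j, residue = AA, frequency = f,
               gap_fraction = gf[j],
               ic = column_information_content(msa, j))
  }))
}

# --- path-guided row placement ----------------------------------------------
#
# Internal machinery shared by HMM-guided insertion and cluster merging. A
# new row is described relative to the alignment's current match columns as
# (i) residues assigned to match states and (ii) ordered insert runs in the
# regions between consecutive match states (region r lies between match
# state r and r+1; region 0 precedes the first match state, region K follows
# the last). Insert-run residues reuse existing spacer columns in their
# region where the region has room (region 0 right-justified against the
# first match column, all others left-justified), and new all-gap columns
# are created otherwise, so repeated insertions share columns and width
# growth stays bounded.

msa_place_row <- function(msa, match_cols, id, match_res, regions) {
  K <- length(match_cols)
  stopifnot(length(regions) == K + 1L)
  need <- integer(K + 1L)
  avail <- integer(K + 1L)
  bounds_l <- c(0L, match_cols)
  bounds_r <- c(match_cols, ncol(msa) + 1L)
  for (r in seq_len(K + 1L)) {
    need[r] <- length(regions[[r]])
    avail[r] <- bounds_r[r] - bounds_l[r] - 1L
  }
  extra <- pmax(0L, need - avail)
  # Build final column layout: for each region needing columns, new all-gap
  # columns are created adjacent to the region's justification edge.
  old_w <- ncol(msa)
  new_w <- old_w + sum(extra)
  # Map old column -> new column.
  ins_at <- integer(old_w + 1L)  # new columns inserted before old column j
  for (r in seq_len(K + 1L)) {
    if (extra[r] == 0L) next
    at <- if (r == 1L) bounds_r[1L] else bounds_l[r] + 1L
    # region 0: immediately before first match col; else immediately after
    # the left match col.
    ins_at[at] <- ins_at[at] + extra[r]
  }
  old2new <- integer(old_w)
  shift <- 0L
  for (j in seq_len(old_w)) {
    shift <- shift + ins_at[j]
    old2new[j] <- j + shift
  }
  out <- matrix(GAP, nrow = nrow(msa) + 1L, ncol = new_w,
                dimnames = list(c(rownames(msa), id), NULL))
  if (nrow(msa) > 0L && old_w > 0L) out[seq_len(nrow(msa)), old2new] <- msa
  new_match <- old2new[match_cols]
  i <- nrow(out)
  # Match-state residues.
  for (k in seq_len(K)) {
    if (!is.na(match_res[k])) out[i, new_match[k]] <- match_res[k]
  }
  # Insert runs.
  nb_l <- c(0L, new_match)
  nb_r <- c(new_match, new_w + 1L)
  for (r in seq_len(K + 1L)) {
    if (need[r] == 0L) next
    slots_l <- nb_l[r] + 1L
    slots_r <- nb_r[r] - 1L
    slots <- slots_r - slots_l + 1L
    stopifnot(slots >= need[r])
    cols <- if (r == 1L) {
      seq(slots_r - need[r] + 1L, slots_r)      # right-justify before first match
    } else {
      seq(slots_l, slots_l + need[r] - 1L)      # left-justify after match r-1
    }
    out[i, cols] <- regions[[r]]
  }
  # Drop all-gap columns that placement may have left behind (none should
  # arise from placement itself, but merged inputs may carry them).
  keep <- colSums(out != GAP) > 0L
  if (!all(keep)) {
    new_match <- vapply(new_match, function(j) sum(keep[seq_len(j)]), 0L)
    out <- out[, keep, drop = FALSE]
  }
  list(msa = as_msa(out), match_cols = new_match)
}

#' Insert a sequence into an alignment along its HMM hit path
#'
#' Adds one row whose residues are placed according to the Viterbi path of a
#' [viterbi_local()] hit against the HMM built from this alignment:
#' match-state residues go to the existing match columns, insert-state and
#' unaligned flanking residues occupy spacer columns (new all-gap-elsewhere
#' columns are created when a region lacks room), and deletions leave gaps.
#' Existing rows' residue content is never changed.
#'
#' @param msa A `pep_msa`.
#' @param sequence The peptide to insert (also used as the new row name).
#' @param hit A `scored_hit` from [viterbi_local()] for `sequence` against
#'   the HMM whose match states map to `match_cols`.
#' @param match_cols Current alignment columns of the HMM's match states.
#' @return List with the updated `msa` and the updated `match_cols`.
#' @export
insert_sequence <- function(msa, sequence, hit, match_cols) {
  K <- length(match_cols)
  chars <- strsplit(sequence, "")[[1L]]
  L <- length(chars)
  st <- hit$path$state
  pk <- hit$path$k
  pi_ <- hit$path$i
  if (any(st == 1L & (pk < 1L | pk > K))) {
    stop("hit path inconsistent with the alignment's match columns")
  }
  match_res <- rep(NA_character_, K)
  regions <- rep(list(character()), K + 1L)
  first_i <- pi_[st != 3L][1L]
  last_i <- rev(pi_[st != 3L])[1L]
  k_first <- pk[1L]
  k_last <- pk[length(pk)]
  # Unaligned prefix enters the region immediately left of the first aligned
  # match state; suffix the region right of the last.
  if (first_i > 1L) regions[[k_first]] <- chars[seq_len(first_i - 1L)]
  for (p in seq_along(st)) {
    if (st[p] == 1L) {
      match_res[pk[p]] <- chars[pi_[p]]
    } else if (st[p] == 2L) {
      r <- pk[p] + 1L
      regions[[r]] <- c(regions[[r]], chars[pi_[p]])
    }
  }
  if (last_i < L) {
    r <- k_last + 1L
    regions[[r]] <- c(regions[[r]], chars[seq(last_i + 1L, L)])
  }
  msa_place_row(msa, match_cols, sequence, match_res, regions)
}
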