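# Clade-discriminative amplification primers and predator-blocking primers.
#
# Strategy: scan all windows of a target-clade alignment profile whose
# consensus is well conserved, score each candidate oligo against the
# excluded clade's consensus, and rank by 3'-terminal discrimination —
# mismatches (and insertion/deletion differences) at or around the 3' end
# prevent polymerase extension on the excluded clade. Blocking primers do
# the converse: they match the excluded (predator) clade perfectly across
# an indel anchor, mismatch the target near their 3' end, and carry a
# non-extendable C3 spacer.

#' Score a primer against an aligned site
#'
#' Position-wise IUPAC comparison of a primer (5'->3') with a same-length
#' site given in primer orientation. A position matches iff the site residue
#' is covered by the primer code's base set; a gap in the site counts as a
#' mismatch and flags `indel_overlap`.
#'
#' @param primer IUPAC string, 5'->3'.
#' @param site same-length string from the alignment (may contain `-`).
#' @param k_3prime number of 3'-terminal positions scored separately
#'   (default 3).
#' @param strict_n should a site `N` match nothing? Default `TRUE`.
#' @return a `mismatch_report`: list with `aligned_length`,
#'   `total_mismatches`, `three_prime_mismatches`, `indel_overlap` and
#'   `per_position` (character vector of `"match"`, `"mismatch"`, `"gap"`).
#' @examples
#' match_primer("TCCTCCGCTTATTAATATGC", "TCCTCCGCTTATTTATATGC")
#' @export
match_primer <- function(primer, site, k_3prime = 3, strict_n = TRUE) {
  pc <- strsplit(toupper(primer), "", fixed = TRUE)[[1]]
  sc <- strsplit(toupper(site), "", fixed = TRUE)[[1]]
  if (length(pc) == 0 || length(sc) == 0) stop("empty primer or site")
  if (length(pc) != length(sc)) {
    stop("windowing error: primer and site lengths differ (",
         length(pc), " vs ", length(sc), ")")
  }
  L <- length(pc)
  per <- character(L)
  for (i in seq_len(L)) {
    if (sc[i] == "-") {
      per[i] <- "gap"
    } else if (iupac_match(pc[i], sc[i], strict_n = strict_n)) {
      per[i] <- "match"
    } else {
      per[i] <- "mismatch"
    }
  }
  tail_idx <- seq.int(max(1L, L - k_3prime + 1L), L)
  structure(
    list(aligned_length = L,
         total_mismatches = sum(per != "match"),
         three_prime_mismatches = sum(per[tail_idx] != "match"),
         indel_overlap = any(per == "gap"),
         per_position = per),
    class = "mismatch_report"
  )
}

#' @export
print.mismatch_report <- function(x, ...) {
  cat("mismatch_report: length", x$aligned_length, "| mismatches",
      x$total_mismatches, "| 3' mismatches", x$three_prime_mismatches,
      "| indel overlap", x$indel_overlap, "\n")
  invisible(x)
}

# consensus coverage of a window: per-position sum of target base
# frequencies covered by the candidate's code, averaged over the window
window_conservation <- function(profile, cols, codes) {
  cov <- vapply(seq_along(cols), function(i) {
    sum(profile$freq[IUPAC_SETS[[codes[i]]], cols[i]])
  }, numeric(1))
  mean(cov)
}

candidate_row <- function(sequence, direction, start, end, conservation,
                          report, indel3, ndeg, is_blocking = FALSE) {
  data.frame(
    sequence = sequence, direction = direction,
    window_start = start, window_end = end,
    target_conservation = conservation,
    excl_total_mismatches = report$total_mismatches,
    excl_three_prime_mismatches = report$three_prime_mismatches,
    indel_overlap_3prime = indel3,
    n_degenerate = ndeg,
    is_blocking = is_blocking,
    three_prime_modification = if (is_blocking) "C3_spacer" else "none",
    stringsAsFactors = FALSE
  )
}

rank_candidates <- function(df) {
  if (nrow(df) == 0) return(df)
  o <- order(-df$excl_three_prime_mismatches, -df$indel_overlap_3prime,
             -df$excl_total_mismatches, -df$target_conservation,
             df$window_start, df$window_end, df$direction)
  out <- df[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate and rank clade-discriminative primer windows
#'
#' Scans every window (all starts, all lengths in `length_range`) of the
#' target profile; windows whose target consensus is gap-free, within the
#' degeneracy budget and conserved at or above `min_target_conservation`
#' yield candidates, scored against the excluded clade's consensus.
#' Candidates with no mismatch to the excluded consensus are dropped
#' (they cannot discriminate). Ranking key, descending: 3'-terminal
#' mismatches, indel overlap at the 3' terminus, total mismatches, target
#' conservation; ties are broken by window start, length and direction so
#' the order is total.
#'
#' Both orientations are enumerated: a reverse candidate is the
#' reverse-complement of the window consensus, so its 3' terminus sits at
#' the window start.
#'
#' @param target,excluded `alignment_profile`s on a common column system.
#' @param length_range integer vector `c(min, max)` primer length
#'   (default 17–25).
#' @param min_target_conservation minimum mean consensus coverage in the
#'   target clade (default 0.9).
#' @param k_3prime 3'-terminal region length (default 3).
#' @param max_degenerate maximum degenerate positions per candidate
#'   (default 2).
#' @param gap_diff_threshold minimum between-clade difference in
#'   gap fraction for a column to count as an indel signal (default 0.3).
#' @param directions orientations to enumerate.
#' @return a ranked `data.frame` of candidates (columns as in
#'   [match_primer()] plus window coordinates, 0-based half-open).
#' @export
find_discriminative_windows <- function(target, excluded,
                                        length_range = c(17L, 25L),
                                        min_target_conservation = 0.9,
                                        k_3prime = 3, max_degenerate = 2,
                                        gap_diff_threshold = 0.3,
                                        directions = c("forward",
                                                       "reverse")) {
  stopifnot(inherits(target, "alignment_profile"),
            inherits(excluded, "alignment_profile"))
  if (target$n_columns != excluded$n_columns) {
    stop("coordinate error: profiles have different column counts")
  }
  L <- target$n_columns
  gap_diff <- abs(target$gap_fraction - excluded$gap_fraction)
  rows <- list()
  for (len in seq.int(length_range[1], length_range[2])) {
    if (len > L) next
    for (start in 0:(L - len)) {
      cols <- seq.int(start + 1L, start + len)
      codes <- target$consensus[cols]
      if (any(codes == "-")) next
      ndeg <- n_degenerate(codes)
      if (ndeg > max_degenerate) next
      cons <- window_conservation(target, cols, codes)
      if (cons < min_target_conservation) next
      site <- excluded$consensus[cols]
      for (dir in directions) {
        if (dir == "forward") {
          pseq <- paste(codes, collapse = "")
          psite <- paste(site, collapse = "")
          tail_cols <- cols[seq.int(len - k_3prime + 1L, len)]
        } else {
          pseq <- revcomp_iupac(paste(codes, collapse = ""))
          psite <- revcomp_iupac(paste(site, collapse = ""))
          # revcomp of '-' is '-' (chartr leaves it); 3' end = window start
          tail_cols <- cols[seq_len(min(k_3prime, len))]
        }
        rep <- match_primer(pseq, psite, k_3prime = k_3prime)
        if (rep$total_mismatches < 1) next
        indel3 <- any(gap_diff[tail_cols] >= gap_diff_threshold)
        rows[[length(rows) + 1L]] <- candidate_row(
          pseq, dir, start, start + len, cons, rep, indel3, ndeg)
      }
    }
  }
  df <- if (length(rows) == 0) candidate_row(
    "A", "forward", 0L, 1L, 0,
    list(total_mismatches = 0L, three_prime_mismatches = 0L), FALSE, 0L
  )[0, ] else do.call(rbind, rows)
  rank_candidates(df)
}

#' Design predator-blocking primers across an indel anchor
#'
#' Enumerates windows overlapping `anchor_window` (typically the columns of
#' an insertion/deletion separating the clades). A candidate is the excluded
#' (predator) clade's consensus over the window; it must match that
#' consensus perfectly, be within the degeneracy budget, and mismatch the
#' target consensus at one or more of its `k_3prime` 3'-terminal positions
#' (a gap in the target there counts as a mismatch). Candidates are flagged
#' `is_blocking` and carry a C3 spacer as their 3' modification, rendering
#' them non-extendable.
#'
#' @inheritParams find_discriminative_windows
#' @param anchor_window 0-based half-open column interval `c(start, end)`
#'   that candidates must overlap.
#' @return a ranked `data.frame` of blocking candidates (possibly empty).
#' @export
design_blocking_primers <- function(excluded, target, anchor_window,
                                    length_range = c(17L, 25L),
                                    k_3prime = 3, max_degenerate = 2,
                                    gap_diff_threshold = 0.3) {
  stopifnot(inherits(target, "alignment_profile"),
            inherits(excluded, "alignment_profile"))
  if (target$n_columns != excluded$n_columns) {
    stop("coordinate error: profiles have different column counts")
  }
  L <- target$n_columns
  if (anchor_window[1] < 0 || anchor_window[2] > L ||
      anchor_window[1] >= anchor_window[2]) {
    stop("coordinate error: anchor window outside alignment bounds")
  }
  gap_diff <- abs(target$gap_fraction - excluded$gap_fraction)
  rows <- list()
  for (len in seq.int(length_range[1], length_range[2])) {
    if (len > L) next
    for (start in 0:(L - len)) {
      end <- start + len
      if (end <= anchor_window[1] || start >= anchor_window[2]) next
      cols <- seq.int(start + 1L, end)
      codes <- excluded$consensus[cols]
      if (any(codes == "-")) next
      ndeg <- n_degenerate(codes)
      if (ndeg > max_degenerate) next
      pseq <- paste(codes, collapse = "")
      self_rep <- match_primer(pseq, pseq, k_3prime = k_3prime)
      if (self_rep$total_mismatches != 0) next
      target_site <- paste(target$consensus[cols], collapse = "")
      rep <- match_primer(pseq, target_site, k_3prime = k_3prime)
      if (rep$three_prime_mismatches < 1) next
      tail_cols <- cols[seq.int(len - k_3prime + 1L, len)]
      indel3 <- any(gap_diff[tail_cols] >= gap_diff_threshold)
      # conservation here is within the excluded clade the primer blocks
      cons <- window_conservation(excluded, cols, codes)
      rows[[length(rows) + 1L]] <- candidate_row(
        pseq, "forward", start, end, cons, rep, indel3, ndeg,
        is_blocking = TRUE)
    }
  }
  df <- if (length(rows) == 0) {
    candidate_row(
      "A", "forward", 0L, 1L, 0,
      list(total_mismatches = 0L, three_prime_mismatches = 0L), FALSE, 0L,
      is_blocking = TRUE)[0, ]
  } else {
    do.call(rbind, rows)
  }
  rank_candidates(df)
}

#' Write primer candidates to TSV and FASTA
#'
#' @param candidates data.frame from [find_discriminative_windows()] or
#'   [design_blocking_primers()].
#' @param tsv,fasta output paths (either may be `NULL` to skip).
#' @return invisibly, the candidate table.
#' @export
write_candidates <- function(candidates, tsv = NULL, fasta = NULL) {
  if (!is.null(tsv)) {
    utils::write.table(candidates, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(fasta) && nrow(candidates) > 0) {
    ids <- sprintf("cand_%03d %s %d:%d%s", seq_len(nrow(candidates)),
                   candidates$direction, candidates$window_start,
                   candidates$window_end,
                   ifelse(candidates$is_blocking, " C3_spacer", ""))
    writeLines(paste0(">", ids, "\n", candidates$sequence), fasta)
  }
  invisible(candidates)
}
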