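# Demultiplexing and quality control of forward reads.
#
# The filter cascade mirrors a strict amplicon QC dialect: (1) discard
# reads with any index base below Q30, (2) discard reads whose index pair
# matches no sample-sheet entry exactly, (3) peel low-quality bases off the
# 3' end until the terminal five-base window is clean, (4) discard reads
# shorter than 170 bp or with >= 10% sub-Q30 bases. Every input read lands
# in exactly one class; only forward reads are handled.

#' Demultiplex indexed reads against a sample sheet
#'
#' A read is first discarded if any of its index base qualities falls below
#' `min_index_q`; surviving reads are assigned to the sheet entry whose
#' index pair matches with at most `allowed_mismatches` differences
#' (default 0 = exact); unassignable reads are discarded and counted.
#'
#' @param reads read `data.table` (see [read_fastq()]).
#' @param sheet validated sample sheet (see [read_sample_sheet()]).
#' @param min_index_q minimum index base quality (default 30).
#' @param allowed_mismatches index mismatches tolerated (default 0).
#' @return list with `reads` (assigned reads plus a `sample_id` column) and
#'   `stats` (named integer vector: `n_input`, `n_index_lowq`,
#'   `n_index_mismatch`, `n_assigned`).
#' @export
demultiplex <- function(reads, sheet, min_index_q = 30,
                        allowed_mismatches = 0) {
  sheet <- validate_sheet(sheet)
  if (nrow(sheet) == 0) stop("configuration error: empty sample sheet")
  reads <- data.table::as.data.table(reads)
  n_input <- nrow(reads)

  minq <- pmin(cpp_min_qual(reads$fwd_index_qual),
               cpp_min_qual(reads$rev_index_qual))
  lowq <- minq < min_index_q
  cand <- reads[!lowq]

  key <- paste0(sheet$fwd_index, "+", sheet$rev_index)
  hit <- match(paste0(cand$fwd_index, "+", cand$rev_index), key)
  if (allowed_mismatches > 0 && anyNA(hit)) {
    # slow path for inexact matching; default pipeline never enters it
    miss <- which(is.na(hit))
    for (i in miss) {
      mm <- mapply(function(f, r) {
        sum(strsplit(f, "")[[1]] != strsplit(cand$fwd_index[i], "")[[1]]) +
          sum(strsplit(r, "")[[1]] != strsplit(cand$rev_index[i], "")[[1]])
      }, sheet$fwd_index, sheet$rev_index)
      ok <- which(mm <= allowed_mismatches)
      if (length(ok) == 1) hit[i] <- ok
      else if (length(ok) > 1 && mm[ok[1]] < min(mm[ok[-1]])) hit[i] <- ok[1]
    }
  }
  assigned <- cand[!is.na(hit)]
  assigned$sample_id <- sheet$sample_id[hit[!is.na(hit)]]
  stats <- c(n_input = n_input,
             n_index_lowq = sum(lowq),
             n_index_mismatch = sum(is.na(hit)),
             n_assigned = nrow(assigned))
  list(reads = assigned, stats = stats)
}

#' Trim low-quality 3' ends
#'
#' Repeatedly removes the 3'-terminal base while the last `window` base
#' qualities contain any value below `min_q`; stops when the terminal
#' window is clean or fewer than `window` bases remain (such reads are
#' retained as-is and left to the length filter). Never lengthens a read
#' and is idempotent.
#'
#' @param reads read `data.table`.
#' @param window terminal window size (default 5).
#' @param min_q quality threshold (default 30).
#' @return the reads with `bases` and `qual` trimmed together.
#' @export
trim_3prime <- function(reads, window = 5, min_q = 30) {
  reads <- data.table::copy(data.table::as.data.table(reads))
  keep <- cpp_trim_lengths(reads$qual, window, min_q)
  reads[, `:=`(bases = substring(bases, 1L, keep),
               qual = substring(qual, 1L, keep))]
  reads
}

#' Length and quality-fraction filter
#'
#' Rejects reads shorter than `min_len`, then reads whose fraction of
#' sub-`q_thresh` bases is at least `max_lowq_fraction` (so exactly 10%
#' low-quality bases is rejected at the defaults). Expects 3'-trimmed
#' input.
#'
#' @param reads read `data.table`.
#' @param min_len minimum length in bp (default 170).
#' @param max_lowq_fraction rejection threshold on the low-quality base
#'   fraction (default 0.10).
#' @param q_thresh per-base quality threshold (default 30).
#' @return list with `keep` (logical) and `reason` (`"kept"`, `"length"`
#'   or `"quality"`).
#' @export
quality_filter <- function(reads, min_len = 170, max_lowq_fraction = 0.10,
                           q_thresh = 30) {
  reads <- data.table::as.data.table(reads)
  len <- nchar(reads$bases)
  short <- len < min_len
  lowq_n <- cpp_count_lowq(reads$qual, q_thresh)
  frac_bad <- !short & (lowq_n / pmax(len, 1L)) >= max_lowq_fraction
  reason <- rep("kept", nrow(reads))
  reason[frac_bad] <- "quality"
  reason[short] <- "length"
  list(keep = !short & !frac_bad, reason = reason)
}

#' Remove the 5' pad and primer from reads
#'
#' Locates the amplification primer (IUPAC-aware, up to `max_mismatch`
#' mismatches) behind a variable 0..`max_pad` base pad and removes both.
#' Reads without a recognizable primer are dropped and counted.
#'
#' @param reads read `data.table`.
#' @param primer primer sequence, 5'->3'.
#' @param max_pad maximum pad length ahead of the primer (default 6).
#' @param max_mismatch mismatches tolerated in the primer (default 1).
#' @return list with `reads` (trimmed) and `n_failed`.
#' @export
primer_trim <- function(reads, primer, max_pad = 6, max_mismatch = 1) {
  reads <- data.table::copy(data.table::as.data.table(reads))
  off <- cpp_primer_offset(reads$bases, toupper(primer), max_pad,
                           max_mismatch)
  ok <- off > 0
  out <- reads[ok]
  cut <- off[ok]
  out[, `:=`(bases = substring(bases, cut + 1L),
             qual = substring(qual, cut + 1L))]
  list(reads = out, n_failed = sum(!ok))
}

#' Run the full read-processing cascade
#'
#' Demultiplexes, 3'-trims, applies the length/quality filters and
#' (optionally) removes the pad+primer prefix. Rejection classes are
#' mutually exclusive and checked in order: index quality, index mismatch,
#' length, quality fraction.
#'
#' @inheritParams demultiplex
#' @inheritParams trim_3prime
#' @inheritParams quality_filter
#' @param primer amplification primer to strip after filtering, or `NULL`
#'   to skip primer removal.
#' @param max_pad,max_mismatch see [primer_trim()].
#' @return list with `reads` (kept reads with `sample_id`) and `stats`
#'   (one-row `data.frame` with the FilterStats counts plus
#'   `n_primer_fail`).
#' @export
process_reads <- function(reads, sheet, min_index_q = 30,
                          allowed_mismatches = 0, window = 5, min_q = 30,
                          min_len = 170, max_lowq_fraction = 0.10,
                          q_thresh = 30, primer = NULL, max_pad = 6,
                          max_mismatch = 1) {
  dm <- demultiplex(reads, sheet, min_index_q, allowed_mismatches)
  trimmed <- trim_3prime(dm$reads, window, min_q)
  qf <- quality_filter(trimmed, min_len, max_lowq_fraction, q_thresh)
  kept <- trimmed[qf$keep]
  n_primer_fail <- 0L
  if (!is.null(primer)) {
    pt <- primer_trim(kept, primer, max_pad, max_mismatch)
    kept <- pt$reads
    n_primer_fail <- pt$n_failed
  }
  stats <- data.frame(
    n_input = unname(dm$stats["n_input"]),
    n_index_lowq = unname(dm$stats["n_index_lowq"]),
    n_index_mismatch = unname(dm$stats["n_index_mismatch"]),
    n_assigned = unname(dm$stats["n_assigned"]),
    n_trimmed_short = sum(qf$reason == "length"),
    n_lowq_frac = sum(qf$reason == "quality"),
    n_kept = unname(dm$stats["n_assigned"]) -
      sum(qf$reason == "length") - sum(qf$reason == "quality"),
    n_primer_fail = n_primer_fail
  )
  list(reads = kept, stats = stats)
}

#' Split processed reads by sample
#' @param reads read `data.table` carrying a `sample_id` column.
#' @return named list of per-sample `data.table`s.
#' @export
reads_by_sample <- function(reads) {
  split(data.table::as.data.table(reads), by = "sample_id")
}
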