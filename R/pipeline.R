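# End-to-end orchestration: QC -> pooled clustering -> abundance filter ->
# taxonomy -> clade retention -> per-setting tables, summaries and
# interaction matrices -> cross-setting union.

#' Run the full analysis pipeline
#'
#' @param reads read `data.table` (e.g. from [read_fastq()] or
#'   [generate_reads()]).
#' @param sheet sample sheet.
#' @param refs lineage-annotated reference `data.table`.
#' @param primer amplification primer to strip (default: the simulator's
#'   primer; pass `NULL` to skip primer removal).
#' @param identity_cutoff OTU clustering identity (default 0.97).
#' @param min_otu_reads minimum OTU read total (default 11).
#' @param epsilon,min_identity taxonomy parameters, see
#'   [assign_taxonomy()].
#' @param mode interaction-matrix mode (default `"by_species"`).
#' @param min_index_q,min_len,max_lowq_fraction,q_thresh QC thresholds,
#'   see [process_reads()].
#' @return list with `stats` (read-filter counts), `otu_table` (clade
#'   filtered), `n_otus_preclade` (OTU count before clade retention),
#'   `assignments`, `clades`, `discard_report`, `summaries` (per-setting
#'   `setting_summary` rows plus a combined specimen-level row),
#'   `matrices` (per-setting interaction matrices), `union_matrix`.
#' @export
run_pipeline <- function(reads, sheet, refs, primer = SIM_PRIMER,
                         identity_cutoff = 0.97, min_otu_reads = 11,
                         epsilon = 0.01, min_identity = 0.8,
                         mode = "by_species", min_index_q = 30,
                         min_len = 170, max_lowq_fraction = 0.10,
                         q_thresh = 30) {
  sheet <- validate_sheet(sheet)
  proc <- process_reads(reads, sheet, min_index_q = min_index_q,
                        min_len = min_len,
                        max_lowq_fraction = max_lowq_fraction,
                        q_thresh = q_thresh, primer = primer)
  drp <- dereplicate(proc$reads)
  clst <- greedy_cluster(drp, identity_cutoff)
  table <- build_otu_table(clst, sheet$sample_id)
  table <- filter_min_abundance(table, min_otu_reads)
  asg <- assign_taxonomy(table$centroids, refs, epsilon, min_identity)
  ret <- retain_target_clades(table, asg)

  settings <- unique(sheet$setting)
  tables <- lapply(settings, function(s)
    subset_otus(ret$table, samples = sheet$sample_id[sheet$setting == s]))
  names(tables) <- settings
  summaries <- do.call(rbind, lapply(settings, function(s)
    setting_summary(tables[[s]], ret$clades, sheet, s)))
  summaries <- rbind(summaries,
                     combined_summary(ret$table, ret$clades, sheet))
  matrices <- lapply(tables, interaction_matrix, clades = ret$clades,
                     sheet = sheet, mode = mode)
  union_m <- union_across_settings(matrices)

  list(stats = proc$stats, otu_table = ret$table,
       n_otus_preclade = length(table$otu_ids), assignments = asg,
       clades = ret$clades, discard_report = ret$discard_report,
       summaries = summaries, matrices = matrices, union_matrix = union_m)
}

# combined row: specimen-level positives pooled over settings (a specimen
# is Hexapoda-positive if any of its setting libraries is); mean-reads
# fields are undefined at this level and reported NA
combined_summary <- function(table, clades, sheet) {
  sheet <- validate_sheet(sheet)
  sh <- sheet[match(table$samples, sheet$sample_id)]
  cl <- clades[table$otu_ids]
  hex_per <- rowSums(table$counts[, cl == "Hexapoda", drop = FALSE])
  ara_per <- rowSums(table$counts[, cl == "Araneae", drop = FALSE])
  ok <- !sh$is_negative_control
  spec <- sh$specimen[ok]
  any_reads <- tapply(hex_per[ok] + ara_per[ok] > 0, spec, any)
  hex_pos <- tapply(hex_per[ok] > 0, spec, any)
  n_with <- sum(any_reads)
  n_hex <- sum(hex_pos)
  tot_hex <- sum(hex_per[ok])
  tot_ara <- sum(ara_per[ok])
  out <- data.frame(
    setting_label = "combined",
    n_samples_with_reads = n_with,
    n_samples_hexapoda = n_hex,
    pct_samples_hexapoda =
      round_half_up(100 * if (n_with > 0) n_hex / n_with else NA_real_, 1),
    mean_hexapoda_reads_per_positive_sample = NA_real_,
    mean_araneae_reads_per_sample = NA_real_,
    total_hexapoda_reads = tot_hex,
    total_araneae_reads = tot_ara,
    pct_hexapoda_reads = round_half_up(
      100 * if (tot_ara > 0) tot_hex / tot_ara else NA_real_, 2),
    negative_control_read_counts =
      sum(table$counts[!ok, , drop = FALSE]))
  class(out) <- c("setting_summary", class(out))
  out
}
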