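# Food-web construction and per-PCR-setting summaries.
#
# Interaction matrices: rows are Araneae entities (OTUs or the sample's
# spider species label), columns are Hexapoda OTUs, and a cell counts the
# samples in which the pair co-occurred. The cross-setting union counts
# each physical specimen once however many settings detected the pair.

#' Build a predator-by-prey interaction matrix
#'
#' For each non-control sample, every (Araneae entity, Hexapoda OTU) pair
#' with positive counts increments its cell by one. In `by_species` mode
#' the predator entity is the sample's species label from the sheet, so a
#' sample contributes at most one increment per pair.
#'
#' @param table an `otu_table`, typically restricted to one PCR setting.
#' @param clades named character vector OTU -> clade (`"Araneae"` or
#'   `"Hexapoda"`), e.g. from [retain_target_clades()].
#' @param sheet sample sheet covering the table's samples.
#' @param mode `"by_otu"` or `"by_species"`.
#' @return object of class `interaction_matrix`: `predators`, `prey`,
#'   `cells` (integer matrix), `edges` (`data.table(predator, prey,
#'   specimen)`, one row per supporting physical sample), `mode`,
#'   `settings`.
#' @export
interaction_matrix <- function(table, clades, sheet,
                               mode = c("by_otu", "by_species")) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "otu_table"))
  sheet <- validate_sheet(sheet)
  miss <- setdiff(table$otu_ids, names(clades))
  if (length(miss) > 0) {
    stop("consistency error: OTUs without a clade: ",
         paste(miss, collapse = ", "))
  }
  bad <- !clades[table$otu_ids] %in% c("Araneae", "Hexapoda")
  if (any(bad)) {
    stop("consistency error: OTUs with neither target clade present")
  }
  sh <- sheet[match(table$samples, sheet$sample_id)]
  if (anyNA(sh$sample_id)) stop("samples missing from sheet")
  use <- which(!sh$is_negative_control)
  ara <- table$otu_ids[clades[table$otu_ids] == "Araneae"]
  hex <- table$otu_ids[clades[table$otu_ids] == "Hexapoda"]
  rows <- list()
  for (i in use) {
    cnt <- table$counts[i, ]
    prey_here <- hex[cnt[hex] > 0]
    if (length(prey_here) == 0) next
    preds_here <- if (mode == "by_otu") ara[cnt[ara] > 0] else
      sh$species[i]
    if (length(preds_here) == 0) next
    rows[[length(rows) + 1L]] <- data.table::CJ(
      predator = preds_here, prey = prey_here)[
        , specimen := sh$specimen[i]]
  }
  edges <- if (length(rows) == 0) {
    data.table::data.table(predator = character(0), prey = character(0),
                           specimen = character(0))
  } else {
    unique(data.table::rbindlist(rows))
  }
  new_interaction_matrix(edges, mode, unique(sh$setting[use]))
}

new_interaction_matrix <- function(edges, mode, settings) {
  support <- edges[, list(n = length(unique(specimen))),
                   by = c("predator", "prey")]
  predators <- sort(unique(edges$predator))
  prey <- sort(unique(edges$prey))
  cells <- matrix(0L, nrow = length(predators), ncol = length(prey),
                  dimnames = list(predators, prey))
  if (nrow(support) > 0) {
    cells[cbind(match(support$predator, predators),
                match(support$prey, prey))] <- support$n
  }
  structure(list(predators = predators, prey = prey, cells = cells,
                 edges = edges, mode = mode, settings = settings),
            class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat("interaction_matrix (", x$mode, "): ", length(x$predators),
      " predators x ", length(x$prey), " prey, ",
      sum(x$cells > 0), " edges [settings: ",
      paste(x$settings, collapse = ","), "]\n", sep = "")
  invisible(x)
}

#' Union of interaction matrices across PCR settings
#'
#' Combines per-setting matrices; a physical specimen supporting a pair in
#' several settings is counted once, so a union cell is the number of
#' distinct specimens supporting the pair in any setting.
#'
#' @param matrices list of `interaction_matrix` objects in the same mode.
#' @return an `interaction_matrix` spanning the union of labels.
#' @export
union_across_settings <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  modes <- vapply(matrices, `[[`, character(1), "mode")
  if (length(unique(modes)) != 1) {
    stop("configuration error: matrices differ in mode")
  }
  edges <- unique(data.table::rbindlist(lapply(matrices, `[[`, "edges")))
  settings <- unique(unlist(lapply(matrices, `[[`, "settings")))
  new_interaction_matrix(edges, modes[1], settings)
}

#' Edge list of an interaction matrix
#' @param im an `interaction_matrix`.
#' @return `data.table(predator, prey, n_samples)`.
#' @export
edge_list <- function(im) {
  im$edges[, list(n_samples = length(unique(specimen))),
           by = c("predator", "prey")]
}

#' Per-setting summary statistics
#'
#' Computes, over the non-control samples of one PCR setting: the number of
#' samples with any reads of either clade, the number and percentage of
#' Hexapoda-positive samples, mean Hexapoda reads per positive sample,
#' mean Araneae reads per sample with reads, clade read totals, the
#' Hexapoda read percentage (Hexapoda reads relative to Araneae reads,
#' matching how such summaries are conventionally tabulated), and total
#' reads observed in negative-control samples. Percentages are rounded
#' half-up (samples to 1 decimal, read percentage to 2); means to the
#' nearest integer. Ratios with a zero denominator are reported as `NA`.
#'
#' @param table an `otu_table` restricted to one setting (controls may be
#'   included; they are excluded from sample statistics and reported
#'   separately).
#' @param clades named character vector OTU -> clade.
#' @param sheet sample sheet covering the table's samples.
#' @param setting_label label stored in the summary (default: the single
#'   setting present in the sheet rows used).
#' @return a one-row `data.frame` (class `setting_summary`).
#' @export
setting_summary <- function(table, clades, sheet, setting_label = NULL) {
  stopifnot(inherits(table, "otu_table"))
  sheet <- validate_sheet(sheet)
  sh <- sheet[match(table$samples, sheet$sample_id)]
  if (anyNA(sh$sample_id)) stop("samples missing from sheet")
  if (is.null(setting_label)) {
    setting_label <- paste(unique(sh$setting), collapse = "+")
  }
  cl <- clades[table$otu_ids]
  hexm <- table$counts[, cl == "Hexapoda", drop = FALSE]
  aram <- table$counts[, cl == "Araneae", drop = FALSE]
  ctrl <- sh$is_negative_control
  hex_per <- rowSums(hexm)[!ctrl]
  ara_per <- rowSums(aram)[!ctrl]
  n_with <- sum(hex_per + ara_per > 0)
  n_hex <- sum(hex_per > 0)
  tot_hex <- sum(hex_per)
  tot_ara <- sum(ara_per)
  div <- function(num, den) if (den > 0) num / den else NA_real_
  out <- data.frame(
    setting_label = setting_label,
    n_samples_with_reads = n_with,
    n_samples_hexapoda = n_hex,
    pct_samples_hexapoda = round_half_up(100 * div(n_hex, n_with), 1),
    mean_hexapoda_reads_per_positive_sample =
      round_half_up(div(tot_hex, n_hex), 0),
    mean_araneae_reads_per_sample = round_half_up(div(tot_ara, n_with), 0),
    total_hexapoda_reads = tot_hex,
    total_araneae_reads = tot_ara,
    pct_hexapoda_reads = round_half_up(100 * div(tot_hex, tot_ara), 2),
    negative_control_read_counts = sum(table$counts[ctrl, , drop = FALSE])
  )
  class(out) <- c("setting_summary", class(out))
  out
}

#' Expected OTU richness under rarefaction
#'
#' Closed-form expectation of the number of OTUs observed when `n` reads
#' are drawn without replacement from a sample with counts `counts`:
#' `E(S_n) = sum_i (1 - choose(N - N_i, n) / choose(N, n))`, evaluated
#' with log-gamma for numerical stability.
#'
#' @param counts one sample's OTU count vector.
#' @param depths draw sizes; all must be between 1 and `sum(counts)`.
#' @return numeric vector of expected richness, one value per depth.
#' @export
rarefaction_curve <- function(counts, depths) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (any(depths > N)) stop("depth exceeds total count (", N, ")")
  if (any(depths < 1)) stop("depths must be >= 1")
  vapply(depths, function(n) {
    sum(1 - exp(lchoose(N - counts, n) - lchoose(N, n)))
  }, numeric(1))
}

#' Write food-web artifacts
#' @param im an `interaction_matrix`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @export
write_interaction_matrix <- function(im, dir, prefix = "interactions") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(predator = im$predators, im$cells, check.names = FALSE)
  utils::write.table(df, file.path(dir, paste0(prefix, "_matrix.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  data.table::fwrite(edge_list(im),
                     file.path(dir, paste0(prefix, "_edges.tsv")),
                     sep = "\t")
  invisible(dir)
}
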