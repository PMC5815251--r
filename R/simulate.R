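# Ground-truthed amplicon simulator.
#
# The generator emulates the structure of a spider gut-content ITS2
# metabarcoding run: per-sample template pools dominated by the predator's
# own intragenomic ITS2 variants, a small weight of consumed prey
# templates, blocking-primer suppression as a multiplicative factor
# (1 - beta) on the predator weight, four PCR settings sequenced from the
# same specimens under distinct index pairs, per-base substitution error
# with a positional Phred profile, index sequencing errors, optional
# two-template chimeras, and negative-control samples carrying a trace of
# predator contamination. All randomness flows from the single seed in
# `sim_params()`.

SIM_PRIMER <- "TGTGAACTGCAGGACACATGA"

#' Simulation parameters
#'
#' Defaults state the simulated world: 50 specimens sequenced under each
#' of four PCR settings at 5,000 reads per library gives 200 sample
#' libraries; the predator template weight of 0.99 puts the Hexapoda read
#' percentage in the ~1% regime observed in real spider runs; error and
#' quality parameters approximate a well-behaved 300-cycle forward read
#' whose tail decays below Q30.
#'
#' @param n_samples number of physical specimens (default 50).
#' @param reads_per_sample reads per sample library, i.e. per specimen per
#'   setting (default 5000).
#' @param predator_weight template-pool weight of the predator before
#'   blocking (default 0.99).
#' @param per_base_error substitution probability per sequenced base
#'   (default 0.005).
#' @param q_mean,q_sd,decay_start,decay_rate positional quality profile:
#'   Phred mean and sd, position where linear 3' decay begins, decay per
#'   base (defaults 36, 4, 180, 0.06).
#' @param read_len forward read length in cycles (default 300).
#' @param chimera_rate fraction of reads replaced by two-template joins at
#'   a uniform breakpoint (default 0.01).
#' @param index_q_mean,index_q_sd quality profile of the 8-mer index reads
#'   (defaults 37, 3).
#' @param n_controls negative-control libraries per setting (default 2).
#' @param control_read_lambda Poisson mean of contaminating predator reads
#'   in a control library (default 5).
#' @param seed mandatory integer seed.
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_samples = 50, reads_per_sample = 5000,
                       predator_weight = 0.99, per_base_error = 0.005,
                       q_mean = 36, q_sd = 4, decay_start = 180,
                       decay_rate = 0.06, read_len = 300,
                       chimera_rate = 0.01, index_q_mean = 37,
                       index_q_sd = 3, n_controls = 2,
                       control_read_lambda = 5, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  rates <- c(predator_weight, per_base_error, chimera_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  structure(as.list(environment()), class = "sim_params")
}

#' Default PCR-setting table
#'
#' Four settings: no blocking, blocking primer A, blocking primer B, and
#' both primers, with per-setting blocking efficiency beta (fraction of
#' predator template weight suppressed).
#' @param beta_block blocking efficiency of the blocking settings
#'   (default 0.5).
#' @export
default_settings <- function(beta_block = 0.5) {
  data.frame(label = c("noblock", "blockA", "blockB", "blockAB"),
             beta = c(0, beta_block, beta_block, beta_block),
             stringsAsFactors = FALSE)
}

random_core <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
        collapse = "")
}

# substitute exactly n_mut distinct positions, guaranteeing bounded
# divergence between co-variants of one species
mutate_core <- function(core, n_mut) {
  ch <- strsplit(core, "", fixed = TRUE)[[1]]
  pos <- sample(length(ch), n_mut)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

hamming_identity <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  L <- min(length(av), length(bv))
  sum(av[seq_len(L)] == bv[seq_len(L)]) / L
}

INSECT_ORDERS <- c("Coleoptera", "Diptera", "Hemiptera", "Hymenoptera",
                   "Lepidoptera", "Thysanoptera")

#' Simulate a ground-truth world
#'
#' Draws predator species with 2-3 intragenomic ITS2 variants each
#' (pairwise >= 97% identical by construction, so they co-cluster), prey
#' taxa with mutually distinct templates (< 97% identity, so each founds
#' its own OTU), a predator-by-prey diet matrix at the configured
#' connectance, a per-specimen species assignment and consumed-prey set,
#' and a lineage-annotated reference set for the taxonomy module.
#'
#' @param params a [sim_params()] object (supplies `n_samples` and the
#'   seed).
#' @param n_predators,n_prey numbers of predator species and prey taxa
#'   (defaults 15 and 50, the scale of a moderate field study).
#' @param template_len template length including the primer (default 330,
#'   matching a ~350 bp amplicon marker; must be >= 90 so the identity
#'   constraints are satisfiable).
#' @param variants_range inclusive range of intragenomic variant counts
#'   per predator species (default 2-3).
#' @param variant_divergence per-variant substitution fraction
#'   (default 0.01; pairwise variant divergence is at most twice this).
#' @param connectance probability of each predator-prey diet edge
#'   (default 0.15; every predator is guaranteed at least one edge).
#' @param meal_prob probability that a diet edge is expressed (prey
#'   actually consumed) in a given specimen (default 0.35).
#' @param settings PCR-setting table (see [default_settings()]).
#' @return object of class `truth_set`.
#' @export
simulate_truth <- function(params, n_predators = 15, n_prey = 50,
                           template_len = 330, variants_range = c(2, 3),
                           variant_divergence = 0.01, connectance = 0.15,
                           meal_prob = 0.35,
                           settings = default_settings()) {
  stopifnot(inherits(params, "sim_params"),
            n_predators >= 1, n_prey >= 1)
  core_len <- template_len - nchar(SIM_PRIMER)
  if (core_len < 90) {
    stop("parameter error: template_len too small to satisfy the ",
         "identity constraints between taxa")
  }
  set.seed(params$seed)

  pred_species <- sprintf("Araneae_sp%02d", seq_len(n_predators))
  n_mut <- max(1L, round(core_len * variant_divergence))
  variants <- vector("list", n_predators)
  variant_props <- vector("list", n_predators)
  for (p in seq_len(n_predators)) {
    base <- random_core(core_len)
    nv <- sample(seq.int(variants_range[1], variants_range[2]), 1)
    vs <- c(base, vapply(seq_len(nv - 1), function(i)
      mutate_core(base, n_mut), character(1)))
    variants[[p]] <- vs
    w <- stats::rgamma(nv, shape = 2)
    variant_props[[p]] <- w / sum(w)
  }

  prey_taxa <- sprintf("Hexapoda_sp%02d", seq_len(n_prey))
  prey_cores <- character(n_prey)
  for (h in seq_len(n_prey)) {
    repeat {
      cand <- random_core(core_len)
      clash <- h > 1 && any(vapply(prey_cores[seq_len(h - 1)],
                                   hamming_identity, numeric(1),
                                   b = cand) >= 0.97)
      if (!clash) { prey_cores[h] <- cand; break }
    }
  }
  is_collembola <- stats::runif(n_prey) < 0.3
  prey_lineage <- lapply(seq_len(n_prey), function(h) {
    cls <- if (is_collembola[h]) "Collembola" else "Insecta"
    ord <- if (is_collembola[h]) {
      sample(c("Entomobryomorpha", "Poduromorpha"), 1)
    } else {
      sample(INSECT_ORDERS, 1)
    }
    c(superkingdom = "Eukaryota", phylum = "Arthropoda", class = cls,
      order = ord, family = sprintf("famH%02d", h),
      genus = sprintf("genH%02d", h), species = prey_taxa[h])
  })

  diet <- matrix(stats::runif(n_predators * n_prey) < connectance,
                 nrow = n_predators,
                 dimnames = list(pred_species, prey_taxa))
  for (p in seq_len(n_predators)) {
    if (!any(diet[p, ])) diet[p, sample(n_prey, 1)] <- TRUE
  }

  specimens <- sprintf("S%03d", seq_len(params$n_samples))
  species_of <- rep_len(pred_species, params$n_samples)
  consumed <- lapply(seq_len(params$n_samples), function(s) {
    edges <- prey_taxa[diet[species_of[s], ]]
    edges[stats::runif(length(edges)) < meal_prob]
  })
  samples <- data.table::data.table(specimen = specimens,
                                    species = species_of,
                                    consumed = consumed)

  pred_lineage <- lapply(seq_len(n_predators), function(p) {
    c(superkingdom = "Eukaryota", phylum = "Arthropoda",
      class = "Arachnida", order = "Araneae",
      family = sprintf("famA%02d", p), genus = sprintf("genA%02d", p),
      species = pred_species[p])
  })
  refs <- data.table::data.table(
    ref_id = c(paste0("REF_", pred_species), paste0("REF_", prey_taxa)),
    sequence = c(vapply(variants, `[`, character(1), 1), prey_cores),
    lineage = c(pred_lineage, prey_lineage)
  )

  structure(
    list(predator_species = pred_species, variants = variants,
         variant_props = variant_props, prey_taxa = prey_taxa,
         prey_cores = prey_cores, prey_lineage = prey_lineage,
         diet = diet, samples = samples, settings = settings,
         refs = refs, primer = SIM_PRIMER, params = params),
    class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat("truth_set:", length(x$predator_species), "predator species,",
      length(x$prey_taxa), "prey taxa,", nrow(x$samples), "specimens,",
      nrow(x$settings), "settings;", sum(x$diet), "diet edges\n")
  invisible(x)
}

random_indexes <- function(n) {
  repeat {
    f <- vapply(seq_len(n), function(i) random_core(8), character(1))
    r <- vapply(seq_len(n), function(i) random_core(8), character(1))
    if (!anyDuplicated(paste(f, r))) return(list(fwd = f, rev = r))
  }
}

#' Generate an indexed amplicon read set from a truth set
#'
#' Builds the sample sheet (one library per specimen per setting plus
#' negative controls), mixes each library's template pool — predator
#' variants at weight `predator_weight * (1 - beta)`, consumed prey
#' splitting `1 - predator_weight` uniformly — draws reads multinomially,
#' injects chimeras, and synthesizes bases, read qualities and index reads
#' (indexes are themselves sequenced with errors, so index-mismatch and
#' low-quality-index rejections occur at realistic rates).
#'
#' @param truth a [simulate_truth()] result.
#' @param params a [sim_params()] object (normally the one inside
#'   `truth`).
#' @return list with `reads` (read `data.table` as from [read_fastq()]),
#'   `sheet` (sample sheet with `specimen` column), `refs` (reference
#'   `data.table`), and `origin` (`data.table(sample_id, setting,
#'   specimen, species, kind, taxon, n_reads)` — the filtered truth of
#'   what was sequenced).
#' @export
generate_reads <- function(truth, params = truth$params) {
  stopifnot(inherits(truth, "truth_set"), inherits(params, "sim_params"))
  set.seed(params$seed + 1L)

  np <- length(truth$predator_species)
  pred_tpl <- unlist(truth$variants)
  tpl_species <- rep(seq_len(np), lengths(truth$variants))
  templates <- paste0(truth$primer, c(pred_tpl, truth$prey_cores))
  prey_off <- length(pred_tpl)
  tpl_name <- c(truth$predator_species[tpl_species], truth$prey_taxa)

  settings <- truth$settings
  entries <- list()
  for (s in seq_len(nrow(settings))) {
    lab <- settings$label[s]
    entries[[length(entries) + 1L]] <- data.table::data.table(
      sample_id = paste0(truth$samples$specimen, ".", lab),
      species = truth$samples$species, setting = lab,
      is_negative_control = FALSE, specimen = truth$samples$specimen,
      beta = settings$beta[s], sample_row = seq_len(nrow(truth$samples)))
    if (params$n_controls > 0) {
      nc <- sprintf("NC%02d", seq_len(params$n_controls))
      entries[[length(entries) + 1L]] <- data.table::data.table(
        sample_id = paste0(nc, ".", lab), species = "none",
        setting = lab, is_negative_control = TRUE,
        specimen = paste0(nc, ".", lab), beta = settings$beta[s],
        sample_row = NA_integer_)
    }
  }
  sheet <- data.table::rbindlist(entries)
  idx <- random_indexes(nrow(sheet))
  sheet$fwd_index <- idx$fwd
  sheet$rev_index <- idx$rev

  tpl_of_read <- integer(0)
  entry_of_read <- integer(0)
  extra_templates <- character(0)
  origin <- list()
  for (e in seq_len(nrow(sheet))) {
    if (sheet$is_negative_control[e]) {
      n_reads <- stats::rpois(1, params$control_read_lambda)
      if (n_reads == 0) next
      tpls <- sample(seq_len(prey_off), n_reads, replace = TRUE)
      tpl_of_read <- c(tpl_of_read, tpls)
      entry_of_read <- c(entry_of_read, rep(e, n_reads))
      origin[[length(origin) + 1L]] <- data.table::data.table(
        sample_id = sheet$sample_id[e], setting = sheet$setting[e],
        specimen = sheet$specimen[e], species = "none",
        kind = "control", taxon = tpl_name[tpls], n_reads = 1L)
      next
    }
    srow <- sheet$sample_row[e]
    sp <- match(sheet$species[e], truth$predator_species)
    consumed <- truth$samples$consumed[[srow]]
    vidx <- which(tpl_species == sp)
    w <- numeric(length(templates))
    w[vidx] <- params$predator_weight * (1 - sheet$beta[e]) *
      truth$variant_props[[sp]]
    if (length(consumed) > 0) {
      hidx <- prey_off + match(consumed, truth$prey_taxa)
      w[hidx] <- (1 - params$predator_weight) / length(consumed)
    }
    n_total <- params$reads_per_sample
    n_chim <- stats::rbinom(1, n_total, params$chimera_rate)
    n_plain <- n_total - n_chim
    cnt <- as.integer(stats::rmultinom(1, n_plain, w))
    tpls <- rep(seq_along(templates), cnt)
    if (n_chim > 0) {
      pa <- sample(seq_along(templates), n_chim, replace = TRUE, prob = w)
      pb <- sample(seq_along(templates), n_chim, replace = TRUE, prob = w)
      chim <- vapply(seq_len(n_chim), function(i) {
        la <- nchar(templates[pa[i]]); lb <- nchar(templates[pb[i]])
        bp <- sample(seq_len(min(la, lb) - 1L), 1)
        paste0(substr(templates[pa[i]], 1, bp),
               substr(templates[pb[i]], bp + 1, lb))
      }, character(1))
      cidx <- length(templates) + length(extra_templates) +
        seq_len(n_chim)
      extra_templates <- c(extra_templates, chim)
      tpls <- c(tpls, cidx)
    }
    tpl_of_read <- c(tpl_of_read, tpls)
    entry_of_read <- c(entry_of_read, rep(e, length(tpls)))
    plain_kind <- ifelse(rep(seq_along(templates), cnt) > prey_off,
                         "prey", "predator")
    og <- data.table::data.table(
      taxon = c(tpl_name[rep(seq_along(templates), cnt)],
                rep("chimera", n_chim)),
      kind = c(plain_kind, rep("chimera", n_chim)))
    og <- og[, list(n_reads = .N), by = c("kind", "taxon")]
    og[, `:=`(sample_id = sheet$sample_id[e],
              setting = sheet$setting[e],
              specimen = sheet$specimen[e],
              species = sheet$species[e])]
    origin[[length(origin) + 1L]] <- og
  }
  origin <- data.table::rbindlist(origin, use.names = TRUE)
  data.table::setcolorder(origin, c("sample_id", "setting", "specimen",
                                    "species", "kind", "taxon",
                                    "n_reads"))

  all_templates <- c(templates, extra_templates)
  sim <- cpp_sim_reads(all_templates, tpl_of_read, params$read_len,
                       params$per_base_error, params$q_mean, params$q_sd,
                       params$decay_start, params$decay_rate, 3L, 6L)
  fwd <- cpp_sim_reads(sheet$fwd_index, entry_of_read, 8L,
                       params$per_base_error, params$index_q_mean,
                       params$index_q_sd, 8L, 0, 0L, 0L)
  rev <- cpp_sim_reads(sheet$rev_index, entry_of_read, 8L,
                       params$per_base_error, params$index_q_mean,
                       params$index_q_sd, 8L, 0, 0L, 0L)
  reads <- data.table::data.table(
    read_id = sprintf("R%07d", seq_along(tpl_of_read)),
    bases = sim$bases, qual = sim$quals,
    fwd_index = fwd$bases, rev_index = rev$bases,
    fwd_index_qual = fwd$quals, rev_index_qual = rev$quals)

  sheet_out <- sheet[, c("sample_id", "species", "setting", "fwd_index",
                         "rev_index", "is_negative_control", "specimen")]
  list(reads = reads, sheet = sheet_out, refs = truth$refs,
       origin = origin)
}

#' Write a simulated data set to disk
#'
#' Emits `reads.fastq.gz`, `sheet.tsv`, `refs.fasta`, `diet_matrix.tsv`
#' and `per_sample_truth.tsv` under `outdir`.
#'
#' @param sim a [generate_reads()] result.
#' @param truth the matching [simulate_truth()] result.
#' @param outdir output directory (created if absent).
#' @export
write_simulation <- function(sim, truth, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_fastq(sim$reads, file.path(outdir, "reads.fastq.gz"))
  write_sample_sheet(sim$sheet, file.path(outdir, "sheet.tsv"))
  write_reference_fasta(sim$refs, file.path(outdir, "refs.fasta"))
  diet <- data.frame(species = rownames(truth$diet), truth$diet + 0L,
                     check.names = FALSE)
  utils::write.table(diet, file.path(outdir, "diet_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pst <- truth$samples[, list(
    specimen = specimen, species = species,
    consumed = vapply(consumed, paste, character(1), collapse = ","))]
  data.table::fwrite(pst, file.path(outdir, "per_sample_truth.tsv"),
                     sep = "\t")
  invisible(outdir)
}

#' Realized (consumed-in-some-specimen) truth edges
#' @param truth a `truth_set`.
#' @return `data.table(predator, prey)` of unique realized species-prey
#'   pairs.
#' @export
realized_edges <- function(truth) {
  rows <- truth$samples[, list(prey = unlist(consumed)), by = "species"]
  unique(rows[, list(predator = species, prey = prey)])
}

#' Score a recovered food web against the truth
#'
#' Maps each Hexapoda OTU to its truth prey taxon through the assigned
#' lineage's species name, forms the unique predicted (species, prey
#' taxon) pairs of a by-species interaction matrix, and compares them with
#' the realized truth edges.
#'
#' @param im a by-species `interaction_matrix` (typically the
#'   cross-setting union).
#' @param assignments [assign_taxonomy()] result for the OTUs in `im`.
#' @param truth the `truth_set`.
#' @return list with `recall`, `precision`, `n_truth`, `n_predicted`,
#'   `n_correct`.
#' @export
evaluate_recovery <- function(im, assignments, truth) {
  stopifnot(im$mode == "by_species")
  tr <- realized_edges(truth)
  truth_keys <- paste(tr$predator, tr$prey)
  otu_taxon <- vapply(seq_len(nrow(assignments)), function(i) {
    l <- assignments$lineage[[i]]
    if ("species" %in% names(l) && l[["species"]] %in% truth$prey_taxa) {
      l[["species"]]
    } else {
      NA_character_
    }
  }, character(1))
  names(otu_taxon) <- assignments$otu_id
  ed <- unique(im$edges[, list(predator, prey)])
  pred_keys <- unique(paste(ed$predator, otu_taxon[ed$prey]))
  n_correct <- sum(pred_keys %in% truth_keys)
  list(recall = n_correct / length(truth_keys),
       precision = if (length(pred_keys) > 0)
         n_correct / length(pred_keys) else NA_real_,
       n_truth = length(truth_keys), n_predicted = length(pred_keys),
       n_correct = n_correct)
}
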