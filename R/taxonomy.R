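# Taxonomic assignment of OTU centroids: nearest-neighbor retrieval in an
# identity band below the best hit, then lowest-common-ancestor consensus
# over the neighbors' lineages, then retention of the target clades
# (Hexapoda prey, Araneae predators).
#
# The neighbor rule approximates query-centric auto-k-nearest-neighbor
# selection with a fixed identity band: all references within `epsilon` of
# the best identity vote, which keeps the neighbor set a function of the
# identities alone (input order never matters).

#' Default clade mapping for target-clade retention
#'
#' Reference lineages rarely carry "Hexapoda" as an explicit rank, so the
#' Hexapoda target is resolved through its constituent classes.
#' @return named list mapping target clade name to the lineage names that
#'   imply membership.
#' @export
default_clade_map <- function() {
  list(Hexapoda = c("Hexapoda", "Insecta", "Collembola", "Protura",
                    "Diplura"),
       Araneae = "Araneae")
}

lca_lineage <- function(lineages) {
  if (length(lineages) == 0) return(character(0))
  out <- character(0)
  for (r in RANKS) {
    vals <- vapply(lineages, function(l)
      if (r %in% names(l)) l[[r]] else NA_character_, character(1))
    if (anyNA(vals) || length(unique(vals)) != 1) break
    out[r] <- vals[1]
  }
  out
}

#' Assign lineages to query sequences by banded-neighbor LCA
#'
#' For each query, identities to every reference are computed with the same
#' identity definition as OTU clustering. Queries whose best identity falls
#' below `min_identity` stay unassigned; otherwise all references within
#' `epsilon` of the best identity form the neighbor set and the deepest
#' rank on which all neighbors agree is returned.
#'
#' @param queries named character vector of sequences (names become
#'   `otu_id`s).
#' @param refs reference `data.table` (see [read_reference_fasta()]).
#' @param epsilon identity band below the best hit (default 0.01).
#' @param min_identity minimum best identity for assignment (default 0.8).
#' @return a `data.table` with `otu_id`, `best_identity`, `n_neighbors`,
#'   `lineage` (list-column of named rank vectors; empty = unassigned) and
#'   `lineage_string` (semicolon-joined, `""` = unassigned).
#' @export
assign_taxonomy <- function(queries, refs, epsilon = 0.01,
                            min_identity = 0.8) {
  if (is.null(refs) || nrow(refs) == 0) {
    stop("configuration error: empty reference set")
  }
  ids <- names(queries)
  if (is.null(ids)) ids <- sprintf("Q%04d", seq_along(queries))
  res <- lapply(seq_along(queries), function(i) {
    idv <- cpp_identity_to_refs(toupper(queries[[i]]),
                                toupper(refs$sequence))
    b <- max(idv)
    if (b < min_identity) {
      return(list(best = b, n = 0L, lineage = character(0)))
    }
    nb <- which(idv >= b - epsilon)
    list(best = b, n = length(nb), lineage = lca_lineage(refs$lineage[nb]))
  })
  data.table::data.table(
    otu_id = ids,
    best_identity = vapply(res, `[[`, numeric(1), "best"),
    n_neighbors = vapply(res, `[[`, integer(1), "n"),
    lineage = lapply(res, `[[`, "lineage"),
    lineage_string = vapply(res, function(r)
      paste(r$lineage, collapse = ";"), character(1))
  )
}

resolve_clade <- function(lineage, clade_map) {
  if (length(lineage) == 0) return(NA_character_)
  for (target in names(clade_map)) {
    if (any(lineage %in% clade_map[[target]])) return(target)
  }
  NA_character_
}

#' Retain only target-clade OTUs
#'
#' Keeps OTUs whose lineage contains a name implying membership of one of
#' the target clades (via `clade_map`); all others — including unassigned
#' OTUs — are discarded and tallied.
#'
#' @param table an `otu_table`.
#' @param assignments result of [assign_taxonomy()] covering the table's
#'   OTUs.
#' @param targets clade names to keep (default Hexapoda and Araneae).
#' @param clade_map see [default_clade_map()].
#' @return list with `table` (filtered), `clades` (named character,
#'   OTU -> clade) and `discard_report` (named counts: kept, discarded,
#'   discarded_unassigned).
#' @export
retain_target_clades <- function(table, assignments,
                                 targets = c("Hexapoda", "Araneae"),
                                 clade_map = default_clade_map()) {
  stopifnot(inherits(table, "otu_table"))
  clade_map <- clade_map[targets]
  idx <- match(table$otu_ids, assignments$otu_id)
  if (anyNA(idx)) stop("every OTU needs an assignment row")
  clades <- vapply(assignments$lineage[idx], resolve_clade, character(1),
                   clade_map = clade_map)
  names(clades) <- table$otu_ids
  keep <- !is.na(clades)
  unassigned <- lengths(assignments$lineage[idx]) == 0
  report <- c(kept = sum(keep), discarded = sum(!keep),
              discarded_unassigned = sum(unassigned))
  list(table = subset_otus(table, table$otu_ids[keep]),
       clades = clades[keep], discard_report = report)
}

#' Write taxonomic assignments as TSV
#' @param assignments [assign_taxonomy()] result.
#' @param path output file.
#' @export
write_assignments <- function(assignments, path) {
  out <- assignments[, c("otu_id", "best_identity", "n_neighbors",
                         "lineage_string")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
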