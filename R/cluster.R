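# Dereplication, abundance-ordered greedy centroid clustering at 97%
# identity, and the minimum-abundance OTU filter.
#
# Identity between two sequences is computed from a free-end-gap global
# alignment (match +1, mismatch -1, gap -2): matching columns divided by
# aligned columns, with terminal overhangs excluded and internal gaps
# counting as non-matching columns. Clustering is performed once on the
# pooled data across samples and settings; per-setting tables are obtained
# afterwards by row selection.

#' Pairwise sequence identity
#'
#' @param a,b sequences (character scalars).
#' @param band half-width of the alignment band; `-1` (default) picks a
#'   width generous enough for identities down to ~0.8.
#' @return named numeric vector `identity`, `matches`, `columns`.
#' @export
pair_identity <- function(a, b, band = -1L) {
  cpp_pair_identity(toupper(a), toupper(b), band)
}

#' Dereplicate reads into unique sequences
#'
#' Groups exactly identical sequences, keeping per-sample counts. Output
#' order is the clustering input order: abundance descending, then
#' sequence lexicographically ascending — this makes downstream clustering
#' independent of read-file ordering.
#'
#' @param reads read `data.table` with `bases` and `sample_id` columns.
#' @return object of class `derep`: list with `uniques`
#'   (`data.table(sequence, abundance)`, sorted) and `counts`
#'   (`data.table(sequence, sample_id, count)`).
#' @export
dereplicate <- function(reads) {
  reads <- data.table::as.data.table(reads)
  if (nrow(reads) == 0) {
    return(structure(list(
      uniques = data.table::data.table(sequence = character(0),
                                       abundance = integer(0)),
      counts = data.table::data.table(sequence = character(0),
                                      sample_id = character(0),
                                      count = integer(0))),
      class = "derep"))
  }
  counts <- reads[, list(count = .N), by = list(sequence = bases,
                                                sample_id = sample_id)]
  uniques <- counts[, list(abundance = sum(count)), by = "sequence"]
  data.table::setorderv(uniques, c("abundance", "sequence"),
                        order = c(-1L, 1L))
  structure(list(uniques = uniques, counts = counts), class = "derep")
}

#' Greedy centroid clustering of unique sequences
#'
#' Processes the dereplicated sequences in order (abundance descending);
#' each sequence joins the best-scoring existing centroid with identity at
#' or above `identity_cutoff` (boundary inclusive, ties resolved to the
#' earliest-created centroid) or founds a new OTU with itself as centroid.
#' Because input is abundance-sorted, every centroid is its OTU's most
#' abundant member.
#'
#' @param derep a [dereplicate()] result.
#' @param identity_cutoff minimum identity to join a centroid
#'   (default 0.97).
#' @return object of class `otu_clustering`: list with `otu_ids`,
#'   `centroids` (named character), `membership`
#'   (`data.table(sequence, otu_id)`) and `counts` (per sample, per unique
#'   sequence, carried over).
#' @export
greedy_cluster <- function(derep, identity_cutoff = 0.97) {
  stopifnot(inherits(derep, "derep"))
  uq <- derep$uniques
  if (nrow(uq) == 0) {
    assign <- integer(0)
  } else {
    assign <- cpp_greedy_cluster(uq$sequence, identity_cutoff)
  }
  n_otu <- if (length(assign)) max(assign) else 0L
  otu_ids <- sprintf("OTU_%04d", seq_len(n_otu))
  centroid_idx <- match(seq_len(n_otu), assign)  # founding member
  centroids <- stats::setNames(uq$sequence[centroid_idx], otu_ids)
  membership <- data.table::data.table(sequence = uq$sequence,
                                       otu_id = otu_ids[assign])
  structure(list(otu_ids = otu_ids, centroids = centroids,
                 membership = membership, counts = derep$counts,
                 identity_cutoff = identity_cutoff),
            class = "otu_clustering")
}

#' Build the sample-by-OTU count table
#'
#' @param clustering an [greedy_cluster()] result.
#' @param samples ordered sample ids defining the table rows; sample ids
#'   present in the clustering but absent here raise a consistency error.
#' @return object of class `otu_table`: list with `samples`, `otu_ids`,
#'   `counts` (integer matrix, rows = samples, columns = OTUs) and
#'   `centroids`.
#' @export
build_otu_table <- function(clustering, samples) {
  stopifnot(inherits(clustering, "otu_clustering"))
  long <- merge(clustering$counts, clustering$membership, by = "sequence")
  if (nrow(long) > 0) {
    unknown <- setdiff(unique(long$sample_id), samples)
    if (length(unknown) > 0) {
      stop("consistency error: sample ids not in table rows: ",
           paste(unknown, collapse = ", "))
    }
  }
  agg <- long[, list(count = sum(count)), by = c("sample_id", "otu_id")]
  counts <- matrix(0L, nrow = length(samples),
                   ncol = length(clustering$otu_ids),
                   dimnames = list(samples, clustering$otu_ids))
  if (nrow(agg) > 0) {
    counts[cbind(match(agg$sample_id, samples),
                 match(agg$otu_id, clustering$otu_ids))] <- agg$count
  }
  structure(list(samples = samples, otu_ids = clustering$otu_ids,
                 counts = counts, centroids = clustering$centroids),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat("otu_table:", length(x$samples), "samples x", length(x$otu_ids),
      "OTUs,", sum(x$counts), "reads\n")
  invisible(x)
}

#' Total read count per OTU
#' @param table an `otu_table`.
#' @export
otu_totals <- function(table) colSums(table$counts)

#' Remove low-abundance OTUs
#'
#' OTUs with fewer than `min_reads` total reads are removed (at the
#' default, OTUs of ten or fewer reads go; eleven survives). Samples are
#' retained even if emptied.
#'
#' @param table an `otu_table`.
#' @param min_reads minimum total read count to keep an OTU (default 11).
#' @return the filtered `otu_table`.
#' @export
filter_min_abundance <- function(table, min_reads = 11) {
  stopifnot(inherits(table, "otu_table"))
  keep <- otu_totals(table) >= min_reads
  subset_otus(table, table$otu_ids[keep])
}

#' Subset an OTU table
#' @param table an `otu_table`.
#' @param otu_ids,samples ids to keep (either may be `NULL` = keep all).
#' @export
subset_otus <- function(table, otu_ids = NULL, samples = NULL) {
  if (is.null(otu_ids)) otu_ids <- table$otu_ids
  if (is.null(samples)) samples <- table$samples
  structure(list(
    samples = samples, otu_ids = otu_ids,
    counts = table$counts[samples, otu_ids, drop = FALSE],
    centroids = table$centroids[otu_ids]),
    class = "otu_table")
}

#' Write OTU artifacts
#' @param table an `otu_table`.
#' @param dir output directory (created if absent).
#' @export
write_otu_table <- function(table, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(sample_id = table$samples, table$counts,
                   check.names = FALSE)
  utils::write.table(df, file.path(dir, "otu_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(paste0(">", names(table$centroids), "\n", table$centroids),
             file.path(dir, "centroids.fasta"))
  invisible(dir)
}
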