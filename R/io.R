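# File I/O: FASTQ (Phred+33) with index pairs carried in the description
# line, sample sheets, and lineage-annotated reference FASTA.
#
# Read records travel through the pipeline as a data.table with columns
# read_id, bases, qual (Phred+33 string), fwd_index, rev_index,
# fwd_index_qual, rev_index_qual. The FASTQ description encodes the index
# pair as "idx=FFFFFFFF+RRRRRRRR iq=<q8>+<q8>" (qualities Phred+33).

SHEET_COLS <- c("sample_id", "species", "setting", "fwd_index",
                "rev_index", "is_negative_control")

#' Read an indexed FASTQ file
#'
#' Parses a Phred+33 FASTQ (optionally gzipped) whose description lines
#' carry the demultiplexing indexes as `idx=FWD+REV iq=QF+QR`.
#'
#' @param path FASTQ file.
#' @return a `data.table` of read records.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  desc <- names(x)
  qual <- as.character(S4Vectors::mcols(x)$qualities)
  parts <- strsplit(desc, " ", fixed = TRUE)
  read_id <- vapply(parts, `[`, character(1), 1)
  grab <- function(tag) {
    vapply(parts, function(p) {
      hit <- p[startsWith(p, tag)]
      if (length(hit) == 0) NA_character_ else substring(hit[1],
                                                         nchar(tag) + 1)
    }, character(1))
  }
  idx <- grab("idx=")
  iq <- grab("iq=")
  split2 <- function(v) {
    s <- strsplit(v, "+", fixed = TRUE)
    list(vapply(s, function(z) if (length(z) >= 1) z[1] else
      NA_character_, character(1)),
      vapply(s, function(z) if (length(z) >= 2) z[2] else
        NA_character_, character(1)))
  }
  i2 <- split2(idx)
  q2 <- split2(iq)
  data.table::data.table(
    read_id = read_id, bases = as.character(x), qual = qual,
    fwd_index = i2[[1]], rev_index = i2[[2]],
    fwd_index_qual = q2[[1]], rev_index_qual = q2[[2]]
  )
}

#' Write read records as indexed FASTQ
#'
#' @param reads a read `data.table` (see [read_fastq()]).
#' @param path output file (`.gz` for compressed output).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  desc <- paste0(reads$read_id, " idx=", reads$fwd_index, "+",
                 reads$rev_index, " iq=", reads$fwd_index_qual, "+",
                 reads$rev_index_qual)
  x <- Biostrings::DNAStringSet(reads$bases)
  names(x) <- desc
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual),
    compress = endsWith(path, ".gz"))
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-separated with header columns `sample_id species setting fwd_index
#' rev_index is_negative_control` and an optional trailing `specimen`
#' column identifying the physical sample when the same specimen was
#' sequenced under several PCR settings (defaults to `sample_id`).
#'
#' @param path TSV file.
#' @return a validated `data.table`.
#' @export
read_sample_sheet <- function(path) {
  dt <- data.table::fread(path, sep = "\t", colClasses = "character")
  validate_sheet(dt)
}

validate_sheet <- function(dt) {
  dt <- data.table::as.data.table(dt)
  missing <- setdiff(SHEET_COLS, names(dt))
  if (length(missing) > 0) {
    stop("sample sheet is missing columns: ",
         paste(missing, collapse = ", "))
  }
  if (!"specimen" %in% names(dt)) dt$specimen <- dt$sample_id
  dt$is_negative_control <- as.logical(dt$is_negative_control)
  if (anyNA(dt$is_negative_control)) {
    stop("is_negative_control must be TRUE/FALSE")
  }
  if (any(nchar(dt$fwd_index) != 8) || any(nchar(dt$rev_index) != 8)) {
    stop("indexes must be 8-mers")
  }
  key <- paste(dt$fwd_index, dt$rev_index)
  if (anyDuplicated(key)) {
    stop("configuration error: duplicate index pairs in sample sheet")
  }
  if (anyDuplicated(dt$sample_id)) {
    stop("configuration error: duplicate sample ids in sample sheet")
  }
  dt
}

#' @rdname read_sample_sheet
#' @param sheet sample sheet `data.table`.
#' @export
write_sample_sheet <- function(sheet, path) {
  data.table::fwrite(sheet, path, sep = "\t")
  invisible(path)
}

#' Read a lineage-annotated reference FASTA
#'
#' Headers follow `>ref_id;tax=superkingdom,phylum,class,order,family,
#' genus,species`; a missing tail of ranks is allowed.
#'
#' @param path FASTA file.
#' @return a `data.table` with `ref_id`, `sequence` and a `lineage`
#'   list-column of named rank vectors.
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  parse_reference_headers(names(x), as.character(x))
}

parse_reference_headers <- function(headers, sequences) {
  ref_id <- sub(";tax=.*$", "", headers)
  taxf <- ifelse(grepl(";tax=", headers, fixed = TRUE),
                 sub("^.*;tax=", "", headers), "")
  lineage <- lapply(taxf, function(s) {
    if (!nzchar(s)) return(character(0))
    parts <- strsplit(s, ",", fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    stats::setNames(parts, RANKS[seq_along(parts)])
  })
  if (any(nchar(sequences) == 0)) stop("empty reference sequence")
  if (any(lengths(lineage) == 0)) {
    stop("reference records must carry a ;tax= lineage")
  }
  data.table::data.table(ref_id = ref_id, sequence = sequences,
                         lineage = lineage)
}

#' @rdname read_reference_fasta
#' @param refs reference `data.table` (as returned by
#'   [read_reference_fasta()]).
#' @export
write_reference_fasta <- function(refs, path) {
  tax <- vapply(refs$lineage, paste, character(1), collapse = ",")
  writeLines(paste0(">", refs$ref_id, ";tax=", tax, "\n", refs$sequence),
             path)
  invisible(path)
}
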