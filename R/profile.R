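# Per-column summaries of a clade alignment: base frequencies, gap fraction
# and an IUPAC consensus. These profiles are the coordinate system on which
# discriminative and blocking primers are designed.

#' Build a per-column profile of a clade alignment
#'
#' Computes, for every column of a gapped multiple alignment, the base
#' frequencies over non-gap residues (IUPAC residues distribute fractional
#' weight over their base sets), the gap fraction, and an IUPAC consensus:
#' the minimal code covering all bases at or above `inclusion_threshold`,
#' or `"-"` when the gap fraction reaches `gap_majority`.
#'
#' @param alignment a gapped alignment: `Biostrings::DNAStringSet`, a named
#'   character vector of equal-length aligned sequences, or the path to an
#'   aligned FASTA file.
#' @param clade_label label stored with the profile (e.g. `"Hexapoda"`).
#' @param inclusion_threshold minimum base frequency for inclusion in the
#'   consensus code (default 0.2).
#' @param gap_majority gap fraction at or above which the consensus is a gap
#'   (default 0.5).
#' @return an object of class `alignment_profile` with elements
#'   `clade_label`, `n_sequences`, `n_columns`, `freq` (4 x L matrix, rows
#'   A/C/G/T, frequencies over non-gap residues), `gap_fraction` (length-L
#'   vector) and `consensus` (length-L character vector of IUPAC codes or
#'   `"-"`).
#' @examples
#' p <- build_profile(c(s1 = "ACGT", s2 = "A-GT"), "demo")
#' p$consensus
#' @export
build_profile <- function(alignment, clade_label = "target",
                          inclusion_threshold = 0.2, gap_majority = 0.5) {
  if (is.character(alignment) && length(alignment) == 1 &&
      file.exists(alignment)) {
    alignment <- Biostrings::readDNAStringSet(alignment)
  }
  if (inherits(alignment, "XStringSet")) {
    alignment <- as.character(alignment)
  }
  if (length(alignment) == 0) stop("empty alignment input")
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1) {
    stop("alignment-shape error: records have unequal aligned lengths")
  }
  L <- lens[1]
  n <- length(alignment)
  mat <- matrix(unlist(strsplit(toupper(alignment), "", fixed = TRUE)),
                nrow = n, byrow = TRUE)
  mat[mat == "."] <- "-"
  bad <- setdiff(unique(as.vector(mat)), c(names(IUPAC_SETS), "-"))
  if (length(bad) > 0) {
    stop("unsupported residues in alignment: ", paste(bad, collapse = ", "))
  }

  freq <- matrix(0, nrow = 4, ncol = L,
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  gap_fraction <- numeric(L)
  consensus <- character(L)
  for (j in seq_len(L)) {
    col <- mat[, j]
    gap_fraction[j] <- mean(col == "-")
    res <- col[col != "-"]
    w <- c(A = 0, C = 0, G = 0, T = 0)
    for (r in res) {
      s <- IUPAC_SETS[[r]]
      w[s] <- w[s] + 1 / length(s)
    }
    if (length(res) > 0) w <- w / length(res)
    freq[, j] <- w
    if (gap_fraction[j] >= gap_majority) {
      consensus[j] <- "-"
    } else {
      consensus[j] <- iupac_code(names(w)[w >= inclusion_threshold])
    }
  }
  structure(
    list(clade_label = clade_label, n_sequences = n, n_columns = L,
         freq = freq, gap_fraction = gap_fraction, consensus = consensus),
    class = "alignment_profile"
  )
}

#' @export
print.alignment_profile <- function(x, ...) {
  cat("alignment_profile:", x$clade_label, "-", x$n_sequences,
      "sequences,", x$n_columns, "columns\n")
  cat("consensus:", paste(x$consensus, collapse = ""), "\n")
  invisible(x)
}
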