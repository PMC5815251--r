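# IUPAC nucleotide code arithmetic used by the primer-design operations.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

RANKS <- c("superkingdom", "phylum", "class", "order", "family",
           "genus", "species")

#' Minimal IUPAC code covering a set of bases
#'
#' @param bases character vector drawn from A, C, G, T.
#' @return a single IUPAC letter, or `"-"` for an empty set.
#' @keywords internal
iupac_code <- function(bases) {
  bases <- sort(unique(bases))
  if (length(bases) == 0) return("-")
  key <- paste(bases, collapse = "")
  hit <- names(IUPAC_SETS)[vapply(IUPAC_SETS, function(s)
    identical(sort(s), bases), logical(1))]
  if (length(hit) == 0) stop("no IUPAC code for base set: ", key)
  hit[1]
}

#' Does a site residue satisfy a (possibly degenerate) primer code?
#'
#' Matching is set containment: the site residue's base set must be a subset
#' of the primer code's base set, so a plain site base matches iff it is a
#' member of the code. In strict mode an `N` in the site matches nothing
#' (conservative scoring of uncertain references). Gaps never match.
#'
#' @param code single IUPAC letter from the primer.
#' @param site single residue from the aligned site (IUPAC letter or `-`).
#' @param strict_n reject site `N` outright (default `TRUE`).
#' @return logical.
#' @keywords internal
iupac_match <- function(code, site, strict_n = TRUE) {
  if (site == "-" || site == ".") return(FALSE)
  if (site == "N") return(!strict_n)  # lenient mode: N is a wildcard
  cs <- IUPAC_SETS[[code]]
  ss <- IUPAC_SETS[[site]]
  if (is.null(cs) || is.null(ss)) return(FALSE)
  all(ss %in% cs)
}

#' Reverse-complement an IUPAC string
#' @param x character scalar.
#' @keywords internal
revcomp_iupac <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  vapply(comp, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

n_degenerate <- function(codes) sum(!codes %in% c("A", "C", "G", "T"))

# round-half-up, used for all human-facing report numbers
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
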