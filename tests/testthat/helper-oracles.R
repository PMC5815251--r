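# Independent oracles used to cross-check the package's own
# implementations. They deliberately take different routes: identity via
# Biostrings' aligner, the greedy rule as a plain double loop, the QC
# cascade as per-read base-R logic.

# identity by global alignment through Biostrings::pairwiseAlignment,
# same scoring as the package core (match +1, mismatch -1, linear gap -2);
# terminal gap runs are excluded from the identity denominator
oracle_identity <- function(a, b) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix = sm,
                                      gapOpening = 0, gapExtension = 2)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  gap <- p == "-" | s == "-"
  i1 <- 1
  while (i1 <= length(p) && gap[i1]) i1 <- i1 + 1
  i2 <- length(p)
  while (i2 >= i1 && gap[i2]) i2 <- i2 - 1
  if (i2 < i1) return(0)
  sum(p[i1:i2] == s[i1:i2] & p[i1:i2] != "-") / (i2 - i1 + 1)
}

# brute-force greedy clustering over the sorted unique sequences
oracle_greedy <- function(seqs, cutoff = 0.97) {
  assign <- integer(length(seqs))
  centroids <- character(0)
  for (i in seq_along(seqs)) {
    best_id <- -1
    best_c <- 0L
    for (c in seq_along(centroids)) {
      id <- oracle_identity(seqs[i], centroids[c])
      if (id >= cutoff && id > best_id + 1e-12) {
        best_id <- id
        best_c <- c
      }
    }
    if (best_c > 0) {
      assign[i] <- best_c
    } else {
      centroids <- c(centroids, seqs[i])
      assign[i] <- length(centroids)
    }
  }
  assign
}

# per-read QC labelling: index quality -> index mismatch -> length ->
# quality fraction
oracle_qc_labels <- function(reads, sheet, min_index_q = 30,
                             min_len = 170, max_lowq_fraction = 0.10,
                             q_thresh = 30, window = 5) {
  phred <- function(q) utf8ToInt(q) - 33L
  key <- paste0(sheet$fwd_index, "+", sheet$rev_index)
  vapply(seq_len(nrow(reads)), function(i) {
    iq <- c(phred(reads$fwd_index_qual[i]), phred(reads$rev_index_qual[i]))
    if (any(iq < min_index_q)) return("index_lowq")
    hit <- match(paste0(reads$fwd_index[i], "+", reads$rev_index[i]), key)
    if (is.na(hit)) return("index_mismatch")
    q <- phred(reads$qual[i])
    len <- length(q)
    while (len >= window && any(q[(len - window + 1):len] < q_thresh)) {
      len <- len - 1
    }
    if (len < min_len) return("length")
    if (sum(q[seq_len(len)] < q_thresh) / len >= max_lowq_fraction) {
      return("quality")
    }
    paste0("kept:", sheet$sample_id[hit])
  }, character(1))
}

# manual lowest common ancestor over named rank vectors
oracle_lca <- function(lineages) {
  ranks <- c("superkingdom", "phylum", "class", "order", "family",
             "genus", "species")
  out <- character(0)
  for (r in ranks) {
    vals <- sapply(lineages, function(l) l[r])
    if (any(is.na(vals)) || length(unique(vals)) > 1) break
    out[r] <- vals[[1]]
  }
  out
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# substitute exactly n distinct positions
substitute_at <- function(seq, pos) {
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# a minimal read table for QC tests
make_reads <- function(bases, quals, fwd = "AAAAAAAA", rev = "CCCCCCCC",
                       iq = "IIIIIIII") {
  data.table::data.table(
    read_id = sprintf("r%03d", seq_along(bases)),
    bases = bases, qual = quals,
    fwd_index = rep_len(fwd, length(bases)),
    rev_index = rep_len(rev, length(bases)),
    fwd_index_qual = rep_len(iq, length(bases)),
    rev_index_qual = rep_len(iq, length(bases)))
}

make_sheet <- function(n = 1, settings = "noblock") {
  idx <- c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG", "TTTTTTTT",
           "ACACACAC", "GTGTGTGT", "AGAGAGAG", "CTCTCTCT")
  data.table::data.table(
    sample_id = sprintf("s%02d", seq_len(n)),
    species = sprintf("sp%02d", seq_len(n)),
    setting = rep_len(settings, n),
    fwd_index = idx[seq_len(n)],
    rev_index = rev(idx)[seq_len(n)],
    is_negative_control = FALSE)
}

qstr <- function(quals) intToUtf8(quals + 33L)
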