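# Primer-design module: profiles, primer scoring, discriminative window
# ranking, blocking primers.

ITS3_HEXA_F <- "TGTGAACTGCAGGACACATGA"
ITS4_HEXA_R <- "TCCTCCGCTTATTAATATGC"
ITS4_ARA_R <- "TCCTCCGCTTATTTATATGC"
ITS3_ARA_F <- "TGTGAATTGCAGGACACATYG"
BLOCK_A <- "ATTGCAGGACACATTGAGC"

test_that("build_profile computes frequencies, gaps and IUPAC consensus", {
  p <- build_profile(c(s = "ACGT"), "one")
  expect_equal(p$consensus, c("A", "C", "G", "T"))
  expect_equal(unname(p$freq["A", 1]), 1)
  expect_equal(p$gap_fraction, rep(0, 4))

  # A/C split column -> M
  p2 <- build_profile(c(a = "AA", b = "CA"), "two")
  expect_equal(p2$consensus[1], "M")

  # 10 sequences, 6 gapped at column 7 -> gap consensus there
  base <- "ACGTACGTAC"
  seqs <- c(rep(base, 4),
            rep(paste0(substr(base, 1, 6), "-", substr(base, 8, 10)), 6))
  names(seqs) <- sprintf("q%02d", 1:10)
  p3 <- build_profile(seqs, "gapped")
  expect_equal(p3$gap_fraction[7], 0.6)
  expect_equal(p3$consensus[7], "-")
  # non-gap columns keep unit base frequency sums
  expect_true(all(abs(colSums(p3$freq)[-7] - 1) < 1e-9))

  # minority base below inclusion threshold stays out of the consensus
  p4 <- build_profile(c(a = "A", b = "A", c = "A", d = "A", e = "A",
                        f = "C"), "thr")
  expect_equal(p4$consensus, "A")

  expect_error(build_profile(c(a = "ACGT", b = "ACG")), "alignment-shape")
  expect_error(build_profile(character(0)), "empty")
})

test_that("match_primer scores IUPAC matches, 3' region and gaps", {
  # the two published reverse primers differ at exactly position 14,
  # outside the 3'-terminal 3
  rep1 <- match_primer(ITS4_HEXA_R, ITS4_ARA_R)
  expect_equal(rep1$total_mismatches, 1)
  expect_equal(which(rep1$per_position == "mismatch"), 14L)
  expect_equal(rep1$three_prime_mismatches, 0)
  expect_false(rep1$indel_overlap)

  # identity
  expect_equal(match_primer(ITS3_ARA_F, ITS3_ARA_F)$total_mismatches, 0)

  # degenerate Y matches C at the primer's position 20
  site <- sub("Y", "C", ITS3_ARA_F)
  expect_equal(match_primer(ITS3_ARA_F, site)$total_mismatches, 0)

  # gap counts as mismatch and flags indel overlap
  repg <- match_primer("ACGT", "AC-T")
  expect_equal(repg$total_mismatches, 1)
  expect_true(repg$indel_overlap)

  # site N matches nothing in strict mode, matches under lenient mode
  expect_equal(match_primer("ACGT", "ACGN")$total_mismatches, 1)
  expect_equal(match_primer("ACGT", "ACGN",
                            strict_n = FALSE)$total_mismatches, 0)

  expect_error(match_primer("ACGT", "ACG"), "windowing")
})

test_that("blocking primer A is a sub-sequence of the Araneae primer", {
  # first 14 nt of the blocking primer equal positions 6-19 (1-based) of
  # the Araneae forward primer
  expect_equal(match_primer(substr(BLOCK_A, 1, 14),
                            substr(ITS3_ARA_F, 6, 19))$total_mismatches,
               0)
})

# shared fixtures: 60-column alignments, excluded clade with a deletion
make_indel_profiles <- function(gap_in = "excluded", gap_cols = 41) {
  set.seed(402)
  base <- random_seq(60)
  tgt <- rep(base, 4)
  exc <- rep(base, 4)
  gapped <- base
  for (g in gap_cols) {
    substr(gapped, g, g) <- "-"
  }
  if (gap_in == "excluded") exc <- rep(gapped, 4) else tgt <- rep(gapped, 4)
  list(target = build_profile(setNames(tgt, paste0("t", 1:4)), "target"),
       excluded = build_profile(setNames(exc, paste0("e", 1:4)),
                                "excluded"))
}

test_that("find_discriminative_windows ranks 3'-anchored indel windows", {
  prof <- make_indel_profiles()  # excluded deleted at column 41 (1-based)
  cands <- find_discriminative_windows(prof$target, prof$excluded)
  expect_gt(nrow(cands), 0)
  fwd <- cands[cands$direction == "forward", ]
  # top forward candidate ends right after the deleted column (0-based 40)
  expect_equal(fwd$window_end[1] - 1L, 40L)
  expect_true(fwd$indel_overlap_3prime[1])
  expect_gte(fwd$excl_three_prime_mismatches[1], 1)
  expect_true(all(cands$target_conservation >= 0.9))
  expect_true(all(cands$excl_total_mismatches >= 1))
})

test_that("identical profiles yield no discriminative candidates", {
  set.seed(403)
  seqs <- setNames(rep(random_seq(60), 3), paste0("s", 1:3))
  p <- build_profile(seqs, "same")
  expect_equal(nrow(find_discriminative_windows(p, p)), 0L)
  expect_error(find_discriminative_windows(
    p, build_profile(setNames(rep(random_seq(50), 2), c("a", "b")), "x")),
    "coordinate")
})

test_that("more 3'-terminal mismatches rank first", {
  set.seed(404)
  base <- random_seq(60)
  alt <- substitute_at(base, c(20, 21))   # double site
  alt <- substitute_at(alt, 45)           # single site
  tgt <- build_profile(setNames(rep(base, 3), paste0("t", 1:3)), "t")
  exc <- build_profile(setNames(rep(alt, 3), paste0("e", 1:3)), "e")
  cands <- find_discriminative_windows(tgt, exc)
  expect_equal(cands$excl_three_prime_mismatches[1], 2)
})

test_that("ranking is a total order: enumeration order cannot matter", {
  prof <- make_indel_profiles()
  c1 <- find_discriminative_windows(prof$target, prof$excluded,
                                    length_range = c(17, 20))
  # re-running is deterministic, and no two rows share the full ranking key
  c2 <- find_discriminative_windows(prof$target, prof$excluded,
                                    length_range = c(17, 20))
  expect_identical(c1, c2)
  key <- paste(c1$excl_three_prime_mismatches, c1$indel_overlap_3prime,
               c1$excl_total_mismatches, c1$target_conservation,
               c1$window_start, c1$window_end, c1$direction)
  expect_false(anyDuplicated(key) > 0)
})

test_that("exhaustive window-scan oracle reproduces the candidate set", {
  # independent enumeration over all windows and both orientations,
  # filtered and ranked by the documented key
  prof <- make_indel_profiles()
  tgt <- prof$target
  exc <- prof$excluded
  lr <- c(17, 19)
  gap_diff <- abs(tgt$gap_fraction - exc$gap_fraction)
  rows <- list()
  for (len in lr[1]:lr[2]) {
    for (start in 0:(tgt$n_columns - len)) {
      cols <- (start + 1):(start + len)
      codes <- tgt$consensus[cols]
      if (any(codes == "-")) next
      if (sum(!codes %in% c("A", "C", "G", "T")) > 2) next
      cons <- mean(vapply(seq_along(cols), function(i)
        sum(tgt$freq[preyweb:::IUPAC_SETS[[codes[i]]], cols[i]]),
        numeric(1)))
      if (cons < 0.9) next
      for (dir in c("forward", "reverse")) {
        if (dir == "forward") {
          pseq <- paste(codes, collapse = "")
          psite <- paste(exc$consensus[cols], collapse = "")
          tail_cols <- cols[(len - 2):len]
        } else {
          pseq <- preyweb:::revcomp_iupac(paste(codes, collapse = ""))
          psite <- preyweb:::revcomp_iupac(
            paste(exc$consensus[cols], collapse = ""))
          tail_cols <- cols[1:3]
        }
        rep <- match_primer(pseq, psite)
        if (rep$total_mismatches < 1) next
        rows[[length(rows) + 1]] <- data.frame(
          sequence = pseq, direction = dir, window_start = start,
          window_end = start + len,
          tp = rep$three_prime_mismatches,
          i3 = any(gap_diff[tail_cols] >= 0.3),
          tot = rep$total_mismatches, cons = cons,
          stringsAsFactors = FALSE)
      }
    }
  }
  oracle <- do.call(rbind, rows)
  oracle <- oracle[order(-oracle$tp, -oracle$i3, -oracle$tot,
                         -oracle$cons, oracle$window_start,
                         oracle$window_end, oracle$direction), ]
  got <- find_discriminative_windows(tgt, exc, length_range = lr)
  expect_equal(got$sequence, oracle$sequence)
  expect_equal(got$window_start, oracle$window_start)
  expect_equal(got$direction, oracle$direction)
})

test_that("design_blocking_primers spans the indel and carries C3", {
  # excluded (predator) clade has bases where the target is deleted
  prof <- make_indel_profiles(gap_in = "target", gap_cols = 39:41)
  bl <- design_blocking_primers(prof$excluded, prof$target,
                                anchor_window = c(38, 41))
  expect_gt(nrow(bl), 0)
  expect_true(all(bl$is_blocking))
  expect_true(all(bl$three_prime_modification == "C3_spacer"))
  expect_true(all(bl$excl_three_prime_mismatches >= 1))
  # every candidate overlaps the anchor
  expect_true(all(bl$window_start < 41 & bl$window_end > 38))
  # blocking candidates match the excluded consensus perfectly
  for (i in seq_len(nrow(bl))) {
    cols <- (bl$window_start[i] + 1):bl$window_end[i]
    site <- paste(prof$excluded$consensus[cols], collapse = "")
    expect_equal(match_primer(bl$sequence[i], site)$total_mismatches, 0)
  }
})

test_that("blocking design returns empty when clades are identical", {
  set.seed(405)
  seqs <- setNames(rep(random_seq(60), 3), paste0("s", 1:3))
  p <- build_profile(seqs, "same")
  expect_equal(nrow(design_blocking_primers(p, p, c(30, 35))), 0L)
  expect_error(design_blocking_primers(p, p, c(55, 70)), "coordinate")
})
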