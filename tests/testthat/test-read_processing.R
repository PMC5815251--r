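# Read-processing module: demultiplexing, 3' trimming, length/quality
# filters, primer removal.

test_that("demultiplex assigns exact index pairs and rejects in order", {
  sheet <- make_sheet(2)
  reads <- make_reads(
    bases = rep("ACGT", 4), quals = rep("IIII", 4),
    fwd = c(sheet$fwd_index[1], sheet$fwd_index[2], "AAAAAAAT",
            sheet$fwd_index[1]),
    rev = c(sheet$rev_index[1], sheet$rev_index[2], sheet$rev_index[1],
            sheet$rev_index[1]))
  # read 4: one index base at Q29 -> index_lowq even though indexes match
  reads$fwd_index_qual[4] <- paste0(qstr(rep(35, 7)), qstr(29))
  dm <- demultiplex(reads, sheet)
  expect_equal(unname(dm$stats),
               c(n_input = 4, n_index_lowq = 1, n_index_mismatch = 1,
                 n_assigned = 2) |> unname())
  expect_equal(dm$reads$sample_id, c("s01", "s02"))
  # boundary: Q30 index bases pass
  reads$fwd_index_qual[4] <- qstr(rep(30, 8))
  expect_equal(unname(demultiplex(reads, sheet)$stats["n_assigned"]), 3)

  dup <- rbind(sheet, sheet[1])
  dup$sample_id[3] <- "s99"
  expect_error(demultiplex(reads, dup), "duplicate index pairs")
})

test_that("trim_3prime peels until the terminal window is clean", {
  # clean read untouched
  r1 <- make_reads("A", qstr(rep(35, 1)))
  r1$bases <- paste(rep("A", 200), collapse = "")
  r1$qual <- qstr(rep(35, 200))
  expect_equal(nchar(trim_3prime(r1)$bases), 200)

  # 200 x Q35 then 5 x Q20 -> trimmed to 200
  r2 <- r1
  r2$bases <- paste(rep("A", 205), collapse = "")
  r2$qual <- qstr(c(rep(35, 200), rep(20, 5)))
  expect_equal(nchar(trim_3prime(r2)$bases), 200)

  # cascade: [35 x10, 20, 35,35,35,35] -> 10 (low base must exit window)
  r3 <- r1
  r3$bases <- paste(rep("A", 15), collapse = "")
  r3$qual <- qstr(c(rep(35, 10), 20, 35, 35, 35, 35))
  expect_equal(nchar(trim_3prime(r3)$bases), 10)

  # shorter than the window: retained as-is
  r4 <- r1
  r4$bases <- "ACG"
  r4$qual <- qstr(c(10, 10, 10))
  expect_equal(nchar(trim_3prime(r4)$bases), 3)

  # idempotence and monotonicity on random quality strings
  set.seed(11)
  n <- 50
  quals <- vapply(seq_len(n), function(i)
    qstr(sample(18:40, 120, replace = TRUE)), character(1))
  rr <- make_reads(strrep("A", 120), quals)
  t1 <- trim_3prime(rr)
  t2 <- trim_3prime(t1)
  expect_true(all(nchar(t1$bases) <= 120))
  expect_identical(t1$bases, t2$bases)
  expect_identical(nchar(t1$bases), nchar(t1$qual))
})

test_that("quality_filter applies the strict length and 10% rules", {
  r <- make_reads(
    bases = c(strrep("A", 169), strrep("A", 170), strrep("A", 200),
              strrep("A", 200)),
    quals = c(qstr(rep(40, 169)), qstr(rep(40, 170)),
              qstr(c(rep(29, 20), rep(40, 180))),   # exactly 10% low
              qstr(c(rep(29, 19), rep(40, 181)))))  # 9.5% low
  qf <- quality_filter(r)
  expect_equal(qf$reason, c("length", "kept", "quality", "kept"))
  expect_equal(qf$keep, c(FALSE, TRUE, FALSE, TRUE))
})

test_that("primer_trim strips pad plus primer, IUPAC-aware", {
  primer <- "TGTGAATTGCAGGACACATYG"  # contains Y
  insert <- strrep("G", 30)
  r <- make_reads(
    bases = c(paste0("ACT", primer, insert),            # pad 3, but Y->?
              paste0("ACGTAC", sub("Y", "C", primer), insert),
              paste0(strrep("T", 9), sub("Y", "T", primer), insert),
              strrep("A", 60)),
    quals = strrep("I", c(54, 57, 60, 60)))
  # replace Y in read 1 too (reads hold plain bases)
  r$bases[1] <- paste0("ACT", sub("Y", "T", primer), insert)
  pt <- primer_trim(r, primer, max_pad = 6, max_mismatch = 1)
  expect_equal(pt$n_failed, 2)  # pad 9 is beyond max_pad; poly-A read
  expect_equal(pt$reads$bases, rep(insert, 2))
  expect_equal(nchar(pt$reads$qual), nchar(pt$reads$bases))
})

test_that("process_reads partitions every read into exactly one class", {
  set.seed(21)
  sheet <- make_sheet(3)
  n <- 300
  pick <- sample(3, n, replace = TRUE)
  miss <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(.15, .85))
  lens <- sample(c(150, 200, 260), n, replace = TRUE)
  reads <- data.table::data.table(
    read_id = sprintf("r%04d", 1:n),
    bases = vapply(lens, function(L) random_seq(L), character(1)),
    qual = vapply(lens, function(L)
      qstr(sample(c(25, 31, 36, 40), L, replace = TRUE,
                  prob = c(.08, .2, .4, .32))), character(1)),
    fwd_index = ifelse(miss, strrep("A", 8), sheet$fwd_index[pick]),
    rev_index = sheet$rev_index[pick],
    fwd_index_qual = vapply(1:n, function(i)
      qstr(sample(c(29, 33, 38), 8, replace = TRUE,
                  prob = c(.05, .3, .65))), character(1)),
    rev_index_qual = vapply(1:n, function(i)
      qstr(sample(c(29, 33, 38), 8, replace = TRUE,
                  prob = c(.05, .3, .65))), character(1)))
  # note: a "missing" fwd index AAAAAAAA can coincide with sheet entry 1;
  # the oracle and the implementation must agree regardless
  res <- process_reads(reads, sheet)
  s <- res$stats
  expect_equal(s$n_assigned, s$n_input - s$n_index_lowq -
                 s$n_index_mismatch)
  expect_equal(s$n_kept + s$n_primer_fail,
               s$n_assigned - s$n_trimmed_short - s$n_lowq_frac)

  labels <- oracle_qc_labels(reads, sheet)
  expect_equal(s$n_index_lowq, sum(labels == "index_lowq"))
  expect_equal(s$n_index_mismatch, sum(labels == "index_mismatch"))
  expect_equal(s$n_trimmed_short, sum(labels == "length"))
  expect_equal(s$n_lowq_frac, sum(labels == "quality"))
  kept_oracle <- sub("^kept:", "", labels[startsWith(labels, "kept:")])
  kept_ids <- reads$read_id[startsWith(labels, "kept:")]
  expect_equal(sort(paste(res$reads$read_id, res$reads$sample_id)),
               sort(paste(kept_ids, kept_oracle)))
})

test_that("processing is order-stable", {
  set.seed(22)
  sheet <- make_sheet(2)
  n <- 120
  reads <- data.table::data.table(
    read_id = sprintf("r%04d", 1:n),
    bases = replicate(n, random_seq(220)),
    qual = replicate(n, qstr(sample(c(26, 34, 40), 220, replace = TRUE,
                                    prob = c(.1, .3, .6)))),
    fwd_index = sheet$fwd_index[rep(1:2, length.out = n)],
    rev_index = sheet$rev_index[rep(1:2, length.out = n)],
    fwd_index_qual = strrep("I", 8), rev_index_qual = strrep("I", 8))
  a <- process_reads(reads, sheet)
  b <- process_reads(reads[sample(n)], sheet)
  expect_equal(a$stats, b$stats)
  expect_equal(
    a$reads[order(read_id), c("read_id", "sample_id", "bases")],
    b$reads[order(read_id), c("read_id", "sample_id", "bases")])
})
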