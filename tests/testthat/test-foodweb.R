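# Interaction matrices, cross-setting union, per-setting summaries,
# rarefaction.

fw_fixture <- function(counts, sheet, clades) {
  structure(list(samples = rownames(counts), otu_ids = colnames(counts),
                 counts = counts,
                 centroids = setNames(rep("ACGT", ncol(counts)),
                                      colnames(counts))),
            class = "otu_table")
}

fw_sheet <- function(ids, species, setting = "blockA",
                     specimen = NULL, control = FALSE) {
  data.table::data.table(
    sample_id = ids, species = species,
    setting = rep_len(setting, length(ids)),
    fwd_index = vapply(seq_along(ids), function(i)
      paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE),
            collapse = ""), character(1)),
    rev_index = vapply(seq_along(ids), function(i)
      paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE),
            collapse = ""), character(1)),
    is_negative_control = rep_len(control, length(ids)),
    specimen = if (is.null(specimen)) ids else specimen)
}

test_that("interaction_matrix counts co-occurring samples", {
  set.seed(61)
  counts <- rbind(s1 = c(a1 = 10L, h1 = 3L, h2 = 1L),
                  s2 = c(a1 = 8L, h1 = 2L, h2 = 0L),
                  s3 = c(a1 = 5L, h1 = 0L, h2 = 0L))
  clades <- c(a1 = "Araneae", h1 = "Hexapoda", h2 = "Hexapoda")
  sheet <- fw_sheet(rownames(counts), c("spA", "spA", "spB"))
  im <- interaction_matrix(fw_fixture(counts), clades, sheet,
                           mode = "by_otu")
  expect_equal(im$cells["a1", "h1"], 2L)
  expect_equal(im$cells["a1", "h2"], 1L)
  # by_species: predator entity is the sheet's species label
  ims <- interaction_matrix(fw_fixture(counts), clades, sheet,
                            mode = "by_species")
  expect_equal(ims$predators, "spA")
  expect_equal(ims$cells["spA", "h1"], 2L)
  # cells never exceed the number of non-control samples
  expect_true(all(im$cells <= 3))
})

test_that("by_species increments at most once per sample per pair", {
  set.seed(62)
  counts <- rbind(s1 = c(a1 = 4L, a2 = 9L, h1 = 2L),
                  s2 = c(a1 = 3L, a2 = 0L, h1 = 5L))
  clades <- c(a1 = "Araneae", a2 = "Araneae", h1 = "Hexapoda")
  sheet <- fw_sheet(c("s1", "s2"), c("spA", "spA"))
  ims <- interaction_matrix(fw_fixture(counts), clades, sheet,
                            mode = "by_species")
  expect_equal(ims$cells["spA", "h1"], 2L)  # one per sample, not per OTU
  # when each sample holds exactly one Araneae OTU, by_otu column
  # marginals match
  counts2 <- rbind(s1 = c(a1 = 4L, h1 = 2L), s2 = c(a1 = 3L, h1 = 5L))
  imo <- interaction_matrix(fw_fixture(counts2),
                            clades[c("a1", "h1")], sheet,
                            mode = "by_otu")
  expect_equal(unname(colSums(imo$cells)), unname(colSums(ims$cells)))
})

test_that("negative controls are excluded and foreign clades rejected", {
  set.seed(63)
  counts <- rbind(s1 = c(a1 = 4L, h1 = 2L), nc = c(a1 = 7L, h1 = 3L))
  clades <- c(a1 = "Araneae", h1 = "Hexapoda")
  sheet <- fw_sheet(c("s1", "nc"), c("spA", "none"),
                    control = c(FALSE, TRUE))
  im <- interaction_matrix(fw_fixture(counts), clades, sheet)
  expect_equal(sum(im$cells), 1L)
  expect_error(interaction_matrix(fw_fixture(counts),
                                  c(a1 = "Araneae", h1 = "Fungi"),
                                  sheet), "consistency")
})

test_that("union across settings deduplicates by physical specimen", {
  set.seed(64)
  clades <- c(a1 = "Araneae", h1 = "Hexapoda")
  mk <- function(samples, specimens, setting) {
    counts <- matrix(c(5L, 2L), nrow = length(samples), ncol = 2,
                     byrow = TRUE,
                     dimnames = list(samples, c("a1", "h1")))
    sheet <- fw_sheet(samples, rep("spA", length(samples)), setting,
                      specimen = specimens)
    interaction_matrix(fw_fixture(counts), clades, sheet,
                       mode = "by_species")
  }
  mA <- mk("s1.A", "s1", "A")
  mB <- mk(c("s1.B", "s2.B"), c("s1", "s2"), "B")
  # identity on a single matrix
  u1 <- union_across_settings(list(mA))
  expect_equal(u1$cells, mA$cells)
  # same specimen in two settings counts once; distinct specimens add
  u <- union_across_settings(list(mA, mB))
  expect_equal(u$cells["spA", "h1"], 2L)
  expect_setequal(u$settings, c("A", "B"))
  # mode mismatch rejected
  mOtu <- interaction_matrix(
    fw_fixture(matrix(c(5L, 2L), 1, 2,
                      dimnames = list("s1.A", c("a1", "h1")))),
    clades, fw_sheet("s1.A", "spA", "A"), mode = "by_otu")
  expect_error(union_across_settings(list(mA, mOtu)), "mode")
})

test_that("setting_summary arithmetic matches the documented rules", {
  set.seed(65)
  # 4 samples with (Araneae, Hexapoda) = (100,0),(50,50),(0,0),(200,100)
  counts <- rbind(s1 = c(a1 = 100L, h1 = 0L), s2 = c(a1 = 50L, h1 = 50L),
                  s3 = c(a1 = 0L, h1 = 0L), s4 = c(a1 = 200L, h1 = 100L))
  clades <- c(a1 = "Araneae", h1 = "Hexapoda")
  sheet <- fw_sheet(rownames(counts), rep("spA", 4))
  ss <- setting_summary(fw_fixture(counts), clades, sheet, "blockA")
  expect_equal(ss$n_samples_with_reads, 3)
  expect_equal(ss$n_samples_hexapoda, 2)
  expect_equal(ss$pct_samples_hexapoda, 66.7)
  expect_equal(ss$mean_hexapoda_reads_per_positive_sample, 75)
  expect_equal(ss$mean_araneae_reads_per_sample, 117)
  expect_equal(ss$total_hexapoda_reads, 150)
  expect_equal(ss$total_araneae_reads, 350)
  # Hexapoda reads relative to Araneae reads
  expect_equal(ss$pct_hexapoda_reads, round(100 * 150 / 350, 2))

  # all-zero table: counts zero, ratios undefined
  z <- counts; z[] <- 0L
  ss0 <- setting_summary(fw_fixture(z), clades, sheet, "blockA")
  expect_equal(ss0$n_samples_with_reads, 0)
  expect_true(is.na(ss0$pct_samples_hexapoda))
  expect_true(is.na(ss0$mean_araneae_reads_per_sample))
})

test_that("rarefaction closed forms, bounds and monotonicity", {
  expect_equal(rarefaction_curve(c(2, 2), 2), 5 / 3)
  counts <- c(10, 5, 3, 1, 1)
  N <- sum(counts)
  expect_equal(rarefaction_curve(counts, 1), 1)
  expect_equal(rarefaction_curve(counts, N), 5)   # observed richness
  curve <- rarefaction_curve(counts, 1:N)
  expect_true(all(diff(curve) >= -1e-12))
  expect_true(all(curve <= 5 + 1e-12))
  expect_error(rarefaction_curve(counts, N + 1), "depth")
})

test_that("rarefaction matches vegan::rarefy", {
  set.seed(66)
  counts <- c(40, 25, 10, 8, 5, 3, 2, 1, 1, 1)
  depths <- c(5, 20, 50, 96)
  want <- as.numeric(vegan::rarefy(counts, depths))
  expect_equal(rarefaction_curve(counts, depths), want,
               tolerance = 1e-10)
})
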