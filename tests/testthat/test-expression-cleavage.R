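atp1_region <- function() {
  transcript_region("BK010421-like", 66938, 68982, "-",
                    binding_site = c(67277, 67293),
                    cleavage_site = c(67227, 67228))
}

test_that("region length is the inclusive coordinate count", {
  expect_equal(region_length(atp1_region()), 2045L)
  expect_equal(region_length(transcript_region("g", 5, 5, "+")), 1L)
  set.seed(71)
  for (i in 1:20) {
    a <- sample.int(100000, 1)
    b <- a + sample.int(500, 1) - 1L
    expect_equal(region_length(transcript_region("g", a, b, "+")),
                 length(seq.int(a, b)))  # counting-loop oracle
  }
})

test_that("the atp1-like cut gives a 289 nt gel fragment conserving 2045 nt", {
  fr <- cleavage_fragments(atp1_region())
  expect_equal(fr$three_prime_len + fr$five_prime_len, 2045L)
  expect_equal(fr$three_prime_len, 290L)  # inclusive count
  expect_equal(fr$gel_size_nt, 67227L - 66938L)  # 289, coordinate difference
  expect_equal(fr$gel_convention, "coordinate_difference")
  expect_false(fr$degenerate)
})

test_that("fragment lengths are conserved under random cuts", {
  set.seed(72)
  for (i in 1:100) {
    a <- sample.int(50000, 1)
    b <- a + sample.int(3000, 1)
    strand <- sample(c("+", "-"), 1)
    reg <- transcript_region("g", a, b, strand)
    cuts <- seq.int(a, b - 1L)
    p <- cuts[sample.int(length(cuts), 1)]
    fr <- cleavage_fragments(reg, c(p, p + 1L))
    expect_equal(fr$five_prime_len + fr$three_prime_len, region_length(reg))
    expect_gte(fr$five_prime_len, 1L)
    expect_gte(fr$three_prime_len, 1L)
  }
})

test_that("flipping strand swaps the two fragment lengths", {
  plus <- cleavage_fragments(transcript_region("g", 100, 400, "+"), c(180, 181))
  minus <- cleavage_fragments(transcript_region("g", 100, 400, "-"), c(180, 181))
  expect_equal(plus$five_prime_len, minus$three_prime_len)
  expect_equal(plus$three_prime_len, minus$five_prime_len)
})

test_that("boundary cuts are flagged degenerate and outside cuts rejected", {
  reg <- transcript_region("g", 100, 400, "+")
  fr <- cleavage_fragments(reg, c(99, 100))  # cut at the region start boundary
  expect_true(fr$degenerate)
  expect_equal(fr$five_prime_len, 0L)
  expect_equal(fr$three_prime_len, 301L)
  expect_error(cleavage_fragments(reg, c(500, 501)), "outside")
  expect_error(transcript_region("g", 100, 400, "+", cleavage_site = c(400, 401)),
               "within")
})

test_that("equal Ct everywhere gives log2 fold zero for every transcript", {
  d <- expand.grid(sample = c("WT", "line"), transcript = c("atp1", "ref"),
                   bio_rep = 1:3, tech_rep = 1:3, stringsAsFactors = FALSE)
  d$ct <- 21
  res <- relative_expression(ct_table(d, reference = "ref", calibrator = "WT"))
  expect_true(all(res$log2fc == 0))
  expect_true(all(res$sd == 0))
})

test_that("a noise-free 4-fold depletion is recovered exactly", {
  ct <- make_ct_table(73, fold_changes = c(atp1 = 0.25, atp6 = 2), noise_sd = 0)
  res <- relative_expression(ct)
  expect_equal(res$log2fc[res$transcript == "atp1"], -2)
  expect_equal(res$log2fc[res$transcript == "atp6"], 1)
  expect_equal(res$n_bio, rep(3L, nrow(res)))
})

test_that("a one-sample self-calibrated table gives zero", {
  d <- data.frame(sample = "WT", transcript = c("t", "ref"),
                  bio_rep = 1L, tech_rep = 1L, ct = c(25, 20))
  res <- relative_expression(ct_table(d, reference = "ref", calibrator = "WT"))
  expect_equal(nrow(res), 0L)  # calibrator compared with itself only
  d2 <- rbind(d, transform(d, sample = "lineA"))
  res2 <- relative_expression(ct_table(d2, reference = "ref", calibrator = "WT"))
  expect_equal(res2$log2fc, c(0, 0))
})

test_that("relative expression is invariant to a constant Ct shift", {
  ct <- make_ct_table(74, fold_changes = c(atp1 = 0.5, cox3 = 3), noise_sd = 0.2)
  shifted <- ct
  shifted$data$ct <- shifted$data$ct + 7.5
  expect_equal(relative_expression(shifted)$log2fc,
               relative_expression(ct)$log2fc)
})

test_that("technical replicates are averaged before the delta-Ct step", {
  # one wild technical outlier must enter only through its bio-rep mean
  d <- expand.grid(sample = c("WT", "line"), transcript = c("t", "ref"),
                   bio_rep = 1:2, tech_rep = 1:2, stringsAsFactors = FALSE)
  d$ct <- 20
  d$ct[d$sample == "line" & d$transcript == "t" & d$bio_rep == 1 & d$tech_rep == 1] <- 24
  res <- relative_expression(ct_table(d, reference = "ref", calibrator = "WT"))
  # bio rep 1 mean Ct = 22 -> dCt 2 -> log2fc -2; bio rep 2 -> 0; mean -1
  expect_equal(res$log2fc[res$transcript == "t"], -1)
})

test_that("samples lacking a reference measurement are excluded with a warning", {
  d <- expand.grid(sample = c("WT", "lineA", "lineB"), transcript = c("t", "ref"),
                   bio_rep = 1L, tech_rep = 1L, stringsAsFactors = FALSE)
  d$ct <- 20
  d <- d[!(d$sample == "lineB" & d$transcript == "ref"), ]
  expect_warning(
    res <- relative_expression(ct_table(d, reference = "ref", calibrator = "WT")),
    "lineB")
  expect_false("lineB" %in% res$sample)
})

test_that("Ct tables round-trip through CSV", {
  ct <- make_ct_table(75, fold_changes = c(atp1 = 0.25))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(ct$data, path, row.names = FALSE)
  back <- read_ct_table(path, reference = "ref", calibrator = "WT")
  expect_equal(relative_expression(back), relative_expression(ct))
})

test_that("clone-end tallies report totals, modes and ties", {
  t1 <- tally_clone_ends(c(67228, 67230), counts = c(7, 1))
  expect_equal(t1$total, 8L)
  expect_equal(t1$modes, 67228L)
  expect_equal(tally_clone_ends(12345)$modes, 12345L)
  ties <- tally_clone_ends(c(10, 20), counts = c(3, 3))
  expect_equal(ties$modes, c(10L, 20L))
  # per-clone positions are aggregated
  t2 <- tally_clone_ends(c(5, 5, 5, 9))
  expect_equal(t2$histogram$count, c(3L, 1L))
  expect_error(tally_clone_ends(50, region = transcript_region("g", 100, 200, "+")),
               "outside")
})

test_that("region files round-trip with the explicit coordinate flag", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("genome_id\tstart\tend\tstrand",
               "BK\t66938\t68982\t-",
               "BK\t99\t400\t+"), path)
  regs <- read_regions(path, one_based = TRUE)
  expect_equal(region_length(regs[[1]]), 2045L)
  regs0 <- read_regions(path, one_based = FALSE)
  expect_equal(region_length(regs0[[1]]), 2044L)
})
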