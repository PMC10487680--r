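test_that("a planted consensus site is the rank-1 hit at the planted start", {
  sc <- synth_scaffold(seed = 21)
  pssm <- build_pssm(sc)
  cons <- consensus_site(sc)
  set.seed(42)
  bg <- paste(sample(c("A", "C", "G", "U"), 300, replace = TRUE), collapse = "")
  rna <- paste0(substr(bg, 1, 120), cons, substr(bg, 121, 300))
  ts <- transcript_set(c(t1 = rna))
  hits <- scan(pssm, ts, top_k = 1)
  expect_equal(hits$start, 121L)
  expect_equal(hits$site_seq, cons)
  # brute-force confirmation that no window scores higher
  oracle <- brute_force_scan(pssm, rna)
  expect_equal(hits$score, max(oracle$score, na.rm = TRUE))
  expect_equal(oracle$start[which.max(oracle$score)], 121L)
})

test_that("scan output matches an exhaustive per-window loop on short sequences", {
  sc <- synth_scaffold(seed = 22)
  pssm <- build_pssm(sc)
  set.seed(7)
  for (rep in 1:10) {
    L <- sample(30:200, 1)
    rna <- paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
    hits <- scan(pssm, transcript_set(c(x = rna)), top_k = Inf, min_score = -Inf)
    oracle <- brute_force_scan(pssm, rna)
    oracle <- oracle[order(-oracle$score, oracle$start), ]
    expect_equal(hits$start, oracle$start)
    expect_equal(hits$score, oracle$score)
  }
})

test_that("minus-strand hits match the brute-force scan of the reverse complement", {
  sc <- synth_scaffold(seed = 23)
  pssm <- build_pssm(sc)
  set.seed(8)
  rna <- paste(sample(c("A", "C", "G", "U"), 150, replace = TRUE), collapse = "")
  hits <- scan(pssm, transcript_set(c(x = rna)), top_k = Inf, min_score = -Inf,
               both_strands = TRUE)
  L <- nchar(rna)
  fwd <- brute_force_scan(pssm, rna)
  rev <- brute_force_scan(pssm, rc_rna(rna))
  minus <- hits[hits$strand == "-", ]
  # a minus hit reported at original coordinate p scored the reverse-
  # complement window starting at L - p + 1
  expect_equal(sort(L - minus$start + 1L), sort(rev$start))
  expect_equal(minus$score[order(L - minus$start + 1L)],
               rev$score[order(rev$start)])
  expect_equal(nrow(hits), nrow(fwd) + nrow(rev))
})

test_that("site scores are additive over per-motif log-odds terms", {
  sc <- synth_scaffold(seed = 24)
  pssm <- build_pssm(sc)
  rna <- consensus_site(sc)
  hit <- scan(pssm, transcript_set(c(x = rna)), top_k = 1)
  terms <- vapply(seq_len(nrow(pssm)), function(k) {
    pssm[k, substr(rna, k, k)]
  }, numeric(1))
  expect_equal(hit$score, sum(terms))
})

test_that("a uniform scoring matrix yields all-zero scores in tie-break order", {
  pssm <- matrix(0, nrow = 4, ncol = 4,
                 dimnames = list(NULL, c("A", "C", "G", "U")))
  ts <- transcript_set(c(a = "ACGUACGUAC", b = "GGGGGGGG"))
  hits <- scan(pssm, ts, top_k = 5, min_score = 0)
  expect_true(all(hits$score == 0))
  expect_equal(hits$transcript_id, c("a", "a", "a", "a", "a"))
  expect_equal(hits$start, 1:5)
})

test_that("the 20-nt probe admits exactly five 16-row scan windows", {
  sc <- synth_scaffold(seed = 1)
  probe <- transcript_set(c(cox3_probe = "AGGAAAUACGAACCCUCCAA"))
  hits <- scan(build_pssm(sc), probe, top_k = 100, min_score = -Inf)
  expect_equal(nrow(hits), 20 - 16 + 1)
  expect_setequal(hits$start, 1:5)
})

test_that("rotating a circular sequence shifts hit starts without changing scores", {
  sc <- synth_scaffold(seed = 25)
  pssm <- build_pssm(sc)
  set.seed(9)
  rna <- paste(sample(c("A", "C", "G", "U"), 120, replace = TRUE), collapse = "")
  L <- nchar(rna)
  h0 <- scan(pssm, transcript_set(c(x = rna), circular = TRUE),
             top_k = Inf, min_score = -Inf, both_strands = TRUE)
  expect_equal(nrow(h0), 2L * L)  # every start, both strands
  r <- 37L
  rot <- paste0(substr(rna, r + 1, L), substr(rna, 1, r))
  h1 <- scan(pssm, transcript_set(c(x = rot), circular = TRUE),
             top_k = Inf, min_score = -Inf, both_strands = TRUE)
  key <- function(h, shift = 0L) {
    s <- (h$start - 1L - shift) %% L + 1L
    o <- order(h$strand, s)
    paste(h$strand[o], s[o], round(h$score[o], 9))
  }
  expect_equal(key(h1), key(h0, shift = r))
})

test_that("degenerate inputs warn and return empty or trimmed results", {
  sc <- synth_scaffold(seed = 1)
  pssm <- build_pssm(sc)
  empty <- transcript_set(character(0) |> stats::setNames(character(0)))
  expect_warning(h <- scan(pssm, empty), "empty")
  expect_equal(nrow(h), 0L)
  short <- transcript_set(c(tiny = "ACGUACGU", ok = paste(rep("ACGU", 10), collapse = "")))
  expect_warning(h2 <- scan(pssm, short, top_k = Inf, min_score = -Inf), "skipped")
  expect_true(all(h2$transcript_id == "ok"))
})

test_that("offset5 = 1 prepends one unscored base without changing scores", {
  sc <- synth_scaffold(seed = 26)
  pssm <- build_pssm(sc)
  set.seed(10)
  rna <- paste(sample(c("A", "C", "G", "U"), 80, replace = TRUE), collapse = "")
  h0 <- scan(pssm, transcript_set(c(x = rna)), top_k = Inf, min_score = -Inf)
  h1 <- scan(pssm, transcript_set(c(x = rna)), top_k = Inf, min_score = -Inf,
             offset5 = 1)
  expect_equal(nchar(h1$site_seq[1]), nrow(pssm) + 1L)
  # scored windows at starts >= 1 survive, with start shifted to the
  # unscored 5' base and the same score
  m0 <- h0[h0$start >= 2, ]
  expect_equal(sort(h1$start), sort(m0$start - 1L))
  merged <- merge(data.frame(start = h1$start, s1 = h1$score),
                  data.frame(start = m0$start - 1L, s0 = m0$score))
  expect_equal(merged$s1, merged$s0)
})

test_that("library-wide prediction recovers each variant's planted target", {
  sc <- synth_scaffold(seed = 27)
  v280 <- apply_edits(sc, atp1_retarget_edits(), name = "v280")
  gen <- make_genome(27, length = 8000,
                     sites = data.frame(name = "atp1_like", position = 6200,
                                        strand = "-",
                                        site_seq = rna_to_dna(consensus_site(v280))))
  res <- predict_library_targets(list(wt = sc, v280 = v280), gen$genome,
                                 top_k = 1, both_strands = TRUE)
  hit <- res[res$variant_id == "v280", ]
  expect_equal(hit$start, 6200L)
  expect_equal(hit$strand, "-")
})

test_that("a batch of one variant reproduces a plain scan", {
  sc <- synth_scaffold(seed = 28)
  ts <- transcript_set(c(x = paste(rep("ACGU", 30), collapse = "")))
  single <- scan(build_pssm(sc), ts, top_k = 3, min_score = -Inf)
  batch <- predict_library_targets(list(only = sc), ts, top_k = 3, min_score = -Inf)
  expect_equal(batch$start, single$start)
  expect_equal(batch$score, single$score)
})

test_that("the score difference between two variants is window-independent per motif", {
  sc <- synth_scaffold(seed = 29)
  v <- apply_edits(sc, motif_edit(8, 5, "S", "N"))
  p0 <- build_pssm(sc); p1 <- build_pssm(v)
  set.seed(11)
  rna <- paste(sample(c("A", "C", "G", "U"), 100, replace = TRUE), collapse = "")
  ts <- transcript_set(c(x = rna))
  h0 <- scan(p0, ts, top_k = Inf, min_score = -Inf)
  h1 <- scan(p1, ts, top_k = Inf, min_score = -Inf)
  m <- merge(data.frame(start = h0$start, s0 = h0$score),
             data.frame(start = h1$start, s1 = h1$score))
  # only row 8 differs between the matrices, so the per-window score
  # difference equals that row's log-odds difference on the base at
  # window offset 8
  base8 <- substring(rna, m$start + 7L, m$start + 7L)
  expect_equal(m$s1 - m$s0, p1[8, base8] - p0[8, base8],
               ignore_attr = TRUE)
})

test_that("hits export to TSV and BED with the stated coordinate conversion", {
  sc <- synth_scaffold(seed = 30)
  gen <- make_genome(30, length = 4000,
                     sites = data.frame(name = "s", position = 1000, strand = "+",
                                        site_seq = rna_to_dna(consensus_site(sc))))
  hits <- scan(build_pssm(sc), gen$genome, top_k = 2, both_strands = TRUE)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_hits_tsv(hits, tsv)
  back <- read.delim(tsv)
  expect_equal(back$start, hits$start)
  write_hits_bed(hits, bed)
  b <- read.delim(bed, header = FALSE, comment.char = "#")
  top <- hits[1, ]
  left0 <- if (top$strand == "+") top$start - 1L else top$start - 16L
  expect_equal(b$V2[1], left0)
  expect_equal(b$V3[1] - b$V2[1], 16L)
})
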