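test_that("the canonical code maps the four standard residue pairs to their bases", {
  tab <- ppr_code_table()
  expect_equal(code_lookup("N", "D", tab)$preferred, "U")
  expect_equal(code_lookup("N", "N", tab)$preferred, "C")
  expect_equal(code_lookup("S", "D", tab)$preferred, "G")
  expect_equal(code_lookup("S", "N", tab)$preferred, "A")
  for (pair in list(c("N", "D"), c("N", "N"), c("S", "D"), c("S", "N"))) {
    lk <- code_lookup(pair[1], pair[2], tab)
    expect_true(lk$canonical)
    expect_equal(sum(lk$weights), 1)
  }
})

test_that("pairs absent from the table score uniformly and are flagged non-canonical", {
  lk <- code_lookup("G", "G", ppr_code_table())
  expect_false(lk$canonical)
  expect_equal(unname(lk$weights), rep(0.25, 4))
  expect_error(code_lookup("B", "D", ppr_code_table()), "amino-acid")
})

test_that("external frequency tables round-trip through TSV and override the default", {
  tab <- ppr_code_table(data.frame(
    res5 = c("N", "T"), res35 = c("D", "N"),
    wA = c(0, 0.2), wC = c(0, 0.2), wG = c(0, 0.2), wU = c(1, 0.4)
  ))
  expect_equal(code_lookup("T", "N", tab)$preferred, "U")
  expect_false(code_lookup("S", "N", tab)$canonical)  # default pair gone
  path <- withr::local_tempfile(fileext = ".tsv")
  write_code_table(tab, path)
  tab2 <- read_code_table(path)
  lk <- code_lookup("N", "D", tab2)
  expect_equal(lk$preferred, "U")
  expect_gt(lk$weights[["U"]], 0.9)
})

test_that("canonicalisation and retargeting edits produce the documented codes", {
  rpf2 <- synth_scaffold(seed = 11, variant = "RPF2")
  expect_equal(paste0(rpf2$motifs$res5[6], rpf2$motifs$res35[6]), "GG")
  expect_equal(paste0(rpf2$motifs$res5[9], rpf2$motifs$res35[9]), "SS")
  m <- apply_edits(rpf2, mrpf2_edits())
  expect_equal(paste0(m$motifs$res5[6], m$motifs$res35[6]), "SN")
  expect_equal(paste0(m$motifs$res5[9], m$motifs$res35[9]), "SN")
  # library-variant retargeting on the canonicalised scaffold
  v280 <- apply_edits(m, atp1_retarget_edits())
  expect_equal(paste0(v280$motifs$res5[8], v280$motifs$res35[8]), "ND")
  expect_equal(v280$motifs$res35[15], "D")
  full <- apply_edits(m, atp1_retarget_edits(full = TRUE))
  expect_equal(paste0(full$motifs$res5[13], full$motifs$res35[13]), "SN")
})

test_that("applying an empty edit list is the identity", {
  sc <- synth_scaffold(seed = 2)
  expect_identical(apply_edits(sc, list())$cds, sc$cds)
  expect_identical(apply_edits(sc, list())$motifs, sc$motifs)
})

test_that("edits only touch the targeted codon and are compositional", {
  sc <- synth_scaffold(seed = 3)
  edits <- atp1_retarget_edits()
  batch <- apply_edits(sc, edits)
  stepwise <- Reduce(function(s, e) apply_edits(s, e), edits, sc)
  expect_identical(batch$cds, stepwise$cds)
  # all bases outside the two edited codons are untouched
  diff <- which(strsplit(batch$cds, "")[[1]] != strsplit(sc$cds, "")[[1]])
  st8 <- sc$motif_spans$start[8] + 12
  st15 <- sc$motif_spans$start[15] + 102
  expect_true(all(diff %in% c(st8:(st8 + 2), st15:(st15 + 2))))
})

test_that("stale and out-of-range edits are rejected", {
  sc <- synth_scaffold(seed = 4)
  expect_error(apply_edits(sc, motif_edit(8, 5, "G", "N")), "stale")
  expect_error(apply_edits(sc, motif_edit(40, 5, "S", "N")), "out of range")
  expect_error(motif_edit(8, 5, "S", "S"), "must differ")
  expect_error(motif_edit(8, 7, "S", "N"), "5 or 35")
})

test_that("codon replacement uses the minimal-change codon with lexicographic ties", {
  sc <- synth_scaffold(seed = 5)
  # default position-5 serine codon is AGC; asparagine's nearest is AAC
  expect_equal(pprdesign:::motif_codon(sc, 8, 5), "AGC")
  v <- apply_edits(sc, motif_edit(8, 5, "S", "N"))
  expect_equal(pprdesign:::motif_codon(v, 8, 5), "AAC")
  # N (AAC) -> D: GAC and GAT both exist; GAC is 1 change, chosen
  v2 <- apply_edits(v, motif_edit(8, 5, "N", "D"))
  expect_equal(pprdesign:::motif_codon(v2, 8, 5), "GAC")
})

test_that("translating the CDS codons at offsets 5/35 reproduces the motif codes", {
  for (seed in c(1, 9, 23)) {
    sc <- synth_scaffold(seed = seed)
    v <- apply_edits(sc, atp1_retarget_edits())
    got <- pprdesign:::scaffold_codes_from_cds(v)
    expect_identical(got$res5, v$motifs$res5)
    expect_identical(got$res35, v$motifs$res35)
  }
})

test_that("the scoring matrix equals hand-computed log-odds on a 2-motif toy", {
  toy <- toy_two_motif_scaffold()
  tab <- ppr_code_table(pseudocount = 0.01)
  m <- build_pssm(toy, tab)
  expect_equal(dim(m), c(2L, 4L))
  # hand arithmetic: preferred 0.9, others 0.1/3, pseudocount 0.01,
  # rows renormalised by 1.04, background 0.25
  hi <- log(((0.9 + 0.01) / 1.04) / 0.25)
  lo <- log(((0.1 / 3 + 0.01) / 1.04) / 0.25)
  expect_equal(unname(m[1, ]), c(lo, lo, lo, hi))  # ND -> U
  expect_equal(unname(m[2, ]), c(hi, lo, lo, lo))  # SN -> A
})

test_that("a uniform table over a uniform background gives an all-zero matrix", {
  uni <- ppr_code_table(data.frame(
    res5 = c("N", "N", "S", "S"), res35 = c("D", "N", "D", "N"),
    wA = 0.25, wC = 0.25, wG = 0.25, wU = 0.25
  ))
  m <- build_pssm(synth_scaffold(seed = 1), uni)
  expect_true(all(abs(m) < 1e-12))
})

test_that("the retargeting edit flips the P8 row preference from G to U", {
  sc <- synth_scaffold(seed = 6)
  before <- build_pssm(sc)
  after <- build_pssm(apply_edits(sc, atp1_retarget_edits()))
  expect_equal(colnames(before)[which.max(before[8, ])], "G")
  expect_equal(colnames(after)[which.max(after[8, ])], "U")
})

test_that("scaffold definition files round-trip through TSV + FASTA", {
  sc <- synth_scaffold(seed = 8)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_scaffold(sc, tsv, fa)
  back <- read_scaffold(tsv, fa)
  expect_identical(back$cds, sc$cds)
  expect_identical(back$motifs, sc$motifs)
  expect_identical(back$motif_spans$start, sc$motif_spans$start)
})

test_that("scaffold invariants are enforced at construction", {
  sc <- synth_scaffold(seed = 1)
  # truncated motif span
  bad_spans <- sc$motif_spans
  bad_spans$end[1] <- bad_spans$end[1] - 3L
  expect_error(ppr_scaffold("x", sc$motifs, sc$cds, bad_spans), "105")
  # residue/CDS disagreement
  bad_motifs <- sc$motifs
  bad_motifs$res5[1] <- if (bad_motifs$res5[1] == "N") "S" else "N"
  expect_error(ppr_scaffold("x", bad_motifs, sc$cds, sc$motif_spans),
               "do not translate")
})
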