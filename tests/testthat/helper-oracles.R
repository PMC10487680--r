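# Independent oracles used across the suite. These deliberately avoid
# the package's scanning/Tm code paths: plain loops over published
# constants and explicit per-window arithmetic.

# Exhaustive per-window scorer: every linear window of `rna` against
# `pssm`, one base at a time.
brute_force_scan <- function(pssm, rna) {
  bases <- c("A", "C", "G", "U")
  ch <- strsplit(rna, "")[[1]]
  W <- nrow(pssm)
  L <- length(ch)
  if (L < W) return(data.frame(start = integer(0), score = numeric(0)))
  starts <- seq_len(L - W + 1)
  score <- vapply(starts, function(s) {
    tot <- 0
    for (k in seq_len(W)) {
      b <- match(ch[s + k - 1], bases)
      if (is.na(b)) return(NA_real_)
      tot <- tot + pssm[k, b]
    }
    tot
  }, numeric(1))
  data.frame(start = starts, score = score)
}

rc_rna <- function(rna) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  paste(rev(comp[strsplit(rna, "")[[1]]]), collapse = "")
}

# Independent nearest-neighbour Tm: literal unified parameter table
# (Allawi & SantaLucia 1997), summed step by step.
oracle_tm <- function(seq, Na = 50, ct_nM = 250) {
  dh_tab <- list(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
                 CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
                 CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
                 CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
  ds_tab <- list(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
                 CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
                 CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
                 CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  dh <- 0; ds <- 0
  for (i in seq_len(n - 1)) {
    key <- paste0(ch[i], ch[i + 1])
    dh <- dh + dh_tab[[key]]
    ds <- ds + ds_tab[[key]]
  }
  for (term in c(ch[1], ch[n])) {
    if (term %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * (n - 1) * log(Na / 1000)
  1000 * dh / (ds + 1.987 * log(ct_nM * 1e-9 / 4)) - 273.15
}

# A tiny fixed 2-motif scaffold for hand-arithmetic checks: built from
# real codons so the object validates.
toy_two_motif_scaffold <- function() {
  codon_for <- function(aa) sort(names(Biostrings::GENETIC_CODE)[
    Biostrings::GENETIC_CODE == aa])[1]
  motif <- function(res5, res35) {
    cods <- rep("GCT", 35)  # Ala filler
    cods[5] <- codon_for(res5)
    cods[35] <- codon_for(res35)
    paste(cods, collapse = "")
  }
  cds <- paste0(motif("N", "D"), motif("S", "N"))
  ppr_scaffold("toy2",
               data.frame(index = 1:2, res5 = c("N", "S"), res35 = c("D", "N")),
               cds,
               data.frame(start = c(1L, 106L), end = c(105L, 210L)))
}
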