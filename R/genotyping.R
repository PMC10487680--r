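## Nearest-neighbour duplex parameters (unified oligonucleotide set:
## Allawi & SantaLucia 1997). dH in kcal/mol, dS in cal/(mol K),
## keyed by the top-strand dinucleotide 5'->3'.
NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
           CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
           TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2,
           CC = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
           CC = -19.9)

#' Nearest-neighbour melting temperature
#'
#' Duplex melting temperature of a primer against its perfect
#' complement, from the unified nearest-neighbour parameter set
#' (Allawi & SantaLucia 1997) with terminal initiation terms, the
#' entropic salt correction 0.368 (N-1) ln\[Na+\], and the two-state
#' formula Tm = 1000 dH / (dS + R ln(CT/4)) - 273.15 for
#' non-self-complementary oligos.
#'
#' @param seq Primer DNA sequence, 5' to 3'.
#' @param Na Monovalent cation concentration in mM (default 50).
#' @param primer_nM Total primer strand concentration in nM
#'   (default 250).
#' @return Melting temperature in degrees Celsius.
#' @examples
#' tm_nn("ACGTACGTACGTACGTACGT")
#' @export
tm_nn <- function(seq, Na = 50, primer_nM = 250) {
  seq <- assert_dna(seq, "primer")
  n <- nchar(seq)
  if (n < 8L) stop("primer too short for a nearest-neighbour estimate", call. = FALSE)
  ch <- seq_chars(seq)
  steps <- paste0(ch[-n], ch[-1L])
  dh <- sum(NN_DH[steps])
  ds <- sum(NN_DS[steps])
  for (term in c(ch[1L], ch[n])) {
    if (term %in% c("G", "C")) {
      dh <- dh + 0.1; ds <- ds - 2.8
    } else {
      dh <- dh + 2.3; ds <- ds + 4.1
    }
  }
  ds <- ds + 0.368 * (n - 1L) * log(Na / 1000)
  ct <- primer_nM * 1e-9
  1000 * dh / (ds + 1.987 * log(ct / 4)) - 273.15
}

transversion_of <- function(base, avoid = character(0)) {
  primary <- c(A = "C", C = "A", G = "T", T = "G")
  fallback <- c(A = "T", C = "G", G = "C", T = "A")
  cand <- primary[[base]]
  if (cand %in% avoid) cand <- fallback[[base]]
  if (cand %in% avoid) {
    stop("no transversion base differs from both alleles", call. = FALSE)
  }
  cand
}

undesignable <- function(msg) {
  stop(structure(
    class = c("pprdesign_undesignable", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

## Tune a primer ending at template position `end3` for the target Tm.
## Returns sequence (with optional penultimate mismatch applied), length
## and Tm of the synthesized oligo.
tune_primer <- function(template, end3, tm_target, len_range, mismatch_base = NULL) {
  if (len_range[2L] < len_range[1L]) {
    undesignable("no admissible primer length in the allowed range")
  }
  best <- NULL
  for (l in seq.int(len_range[1L], len_range[2L])) {
    if (end3 - l + 1L < 1L) break
    p <- substr(template, end3 - l + 1L, end3)
    if (!is.null(mismatch_base)) substr(p, l - 1L, l - 1L) <- mismatch_base
    tm <- tm_nn(p)
    if (is.null(best) || abs(tm - tm_target) < abs(best$tm - tm_target)) {
      best <- list(sequence = p, length = l, tm = tm)
    }
  }
  if (is.null(best)) undesignable("template too short for any primer length")
  best
}

#' Simple self-complementarity check
#'
#' Longest exact complementary match between a primer and its own
#' reverse, a coarse hairpin/self-dimer indicator.
#'
#' @param seq Primer DNA string.
#' @return Length in bp of the longest self-complementary run.
#' @export
self_complementarity <- function(seq) {
  seq <- assert_dna(seq, "primer")
  rc <- reverse_complement_dna(seq)
  n <- nchar(seq)
  best <- 0L
  a <- seq_chars(seq)
  b <- seq_chars(rc)
  for (off in seq.int(-(n - 1L), n - 1L)) {
    run <- 0L
    for (i in seq_len(n)) {
      j <- i + off
      if (j >= 1L && j <= n && a[i] == b[j]) {
        run <- run + 1L
        best <- max(best, run)
      } else {
        run <- 0L
      }
    }
  }
  best
}

#' Design allele-discriminating qPCR primers for a motif edit
#'
#' Builds the two forward genotyping primers that distinguish the
#' wild-type and edited alleles of one motif codon, plus a shared
#' downstream reverse primer. Each forward primer ends (3') exactly on
#' the most 3' base that differs between the two alleles, and carries a
#' deliberate mismatch at the penultimate position (a transversion of
#' the template base, chosen to differ from both alleles) to sharpen
#' allele discrimination. Primer lengths are tuned between 18 and 30 nt
#' toward the target melting temperature; amplicon length is kept
#' within `amplicon_range`.
#'
#' @param scaffold Wild-type `ppr_scaffold`.
#' @param edit A [motif_edit()]; a synonymous edit (no CDS change) is
#'   undesignable and raises a condition of class
#'   `pprdesign_undesignable`.
#' @param tm_target Target melting temperature in degrees Celsius
#'   (default 60).
#' @param tm_tol Acceptable deviation from `tm_target` (default 3); a
#'   larger best-attempt deviation is kept but flagged with a warning.
#' @param len_range Allowed primer lengths (default 18-30 nt).
#' @param amplicon_range Allowed amplicon lengths (default 80-250 bp).
#' @return An object of class `allele_primer_set`: lists `wt_primer`,
#'   `variant_primer` (sequence, allele, 3' template position,
#'   penultimate mismatch, tm, tm_ok) and `common_reverse`, plus
#'   `amplicon_len`, `motif_index`, `position`.
#' @export
design_allele_primers <- function(scaffold, edit, tm_target = 60,
                                  tm_tol = 3, len_range = c(18L, 30L),
                                  amplicon_range = c(80L, 250L)) {
  stopifnot(inherits(scaffold, "ppr_scaffold"), inherits(edit, "motif_edit"))
  variant <- apply_edits(scaffold, edit)
  wt_cds <- scaffold$cds
  var_cds <- variant$cds
  ds <- which(seq_chars(wt_cds) != seq_chars(var_cds))
  if (length(ds) == 0L) {
    undesignable(sprintf("edit P%d pos%d %s>%s is synonymous: no discriminating base",
                         edit$motif_index, edit$position, edit$from_res, edit$to_res))
  }
  d <- max(ds)
  pd <- d - 1L
  wt_b <- substr(wt_cds, pd, pd)
  var_b <- substr(var_cds, pd, pd)
  mismatch_base <- transversion_of(wt_b, avoid = unique(c(wt_b, var_b)))

  wt_best <- tune_primer(wt_cds, d, tm_target, len_range, mismatch_base)
  # same length for both alleles so the primers differ only at the
  # discriminated positions (and share the deliberate mismatch)
  var_seq <- substr(var_cds, d - wt_best$length + 1L, d)
  substr(var_seq, wt_best$length - 1L, wt_best$length - 1L) <- mismatch_base
  var_tm <- tm_nn(var_seq)

  fwd_start <- d - wt_best$length + 1L
  L <- nchar(wt_cds)
  avail <- L - fwd_start + 1L
  if (avail < amplicon_range[1L]) {
    undesignable(sprintf("only %d bp downstream of the discriminating base; amplicon bound is %d",
                         avail, amplicon_range[1L]))
  }
  amp <- min(max(amplicon_range[1L], min(150L, avail)), amplicon_range[2L], avail)
  a_end <- fwd_start + amp - 1L
  # reverse primer: reverse complement of the top strand ending at the
  # amplicon end; its 3' end (top-strand position a_end - l + 1) must
  # stay clear of the discriminated base
  rev_max_len <- min(len_range[2L], a_end - d)
  if (rev_max_len < len_range[1L]) {
    undesignable("no room for a reverse primer clear of the discriminating base")
  }
  rev_best <- NULL
  for (l in seq.int(len_range[1L], rev_max_len)) {
    p <- reverse_complement_dna(substr(wt_cds, a_end - l + 1L, a_end))
    tm <- tm_nn(p)
    if (is.null(rev_best) || abs(tm - tm_target) < abs(rev_best$tm - tm_target)) {
      rev_best <- list(sequence = p, length = l, tm = tm)
    }
  }

  mk <- function(seqc, allele, tm) {
    list(sequence = seqc, allele = allele, end3 = d,
         deliberate_mismatch = list(offset = 2L, base = mismatch_base),
         tm = tm, tm_ok = abs(tm - tm_target) <= tm_tol,
         length = nchar(seqc))
  }
  res <- structure(
    list(
      wt_primer = mk(wt_best$sequence, "WT", wt_best$tm),
      variant_primer = mk(var_seq, "variant", var_tm),
      common_reverse = list(sequence = rev_best$sequence, tm = rev_best$tm,
                            tm_ok = abs(rev_best$tm - tm_target) <= tm_tol,
                            end3 = a_end - rev_best$length + 1L,
                            length = rev_best$length),
      amplicon_len = amp,
      motif_index = edit$motif_index,
      position = edit$position,
      tm_target = tm_target
    ),
    class = "allele_primer_set"
  )
  if (!res$wt_primer$tm_ok || !res$variant_primer$tm_ok || !res$common_reverse$tm_ok) {
    warning(sprintf(
      "Tm window +/-%g degC around %g unsatisfiable for P%d pos%d; best attempt reported",
      tm_tol, tm_target, edit$motif_index, edit$position))
  }
  res
}

#' @export
print.allele_primer_set <- function(x, ...) {
  cat(sprintf("allele primers for P%d pos%d (amplicon %d bp):\n",
              x$motif_index, x$position, x$amplicon_len))
  for (nm in c("wt_primer", "variant_primer")) {
    p <- x[[nm]]
    cat(sprintf("  %-8s 5'-%s-3'  (%d nt, Tm %.1f degC, penultimate mismatch %s)\n",
                p$allele, p$sequence, p$length, p$tm, p$deliberate_mismatch$base))
  }
  cat(sprintf("  reverse  5'-%s-3'  (%d nt, Tm %.1f degC)\n",
              x$common_reverse$sequence, x$common_reverse$length, x$common_reverse$tm))
  invisible(x)
}

#' Tabulate primer sets
#'
#' @param x One `allele_primer_set` or a list of them.
#' @return A data.frame with one row per oligo (allele, sequence, Tm,
#'   amplicon length).
#' @export
primer_table <- function(x) {
  if (inherits(x, "allele_primer_set")) x <- list(x)
  do.call(rbind, lapply(x, function(s) {
    data.frame(
      motif_index = s$motif_index,
      position = s$position,
      allele = c("WT", "variant", "common"),
      primer_seq = c(s$wt_primer$sequence, s$variant_primer$sequence,
                     s$common_reverse$sequence),
      tm = round(c(s$wt_primer$tm, s$variant_primer$tm, s$common_reverse$tm), 2),
      amplicon_len = s$amplicon_len
    )
  }))
}

#' qPCR thermal program used for SNP genotyping assays
#'
#' Returns (and optionally writes) the cycling program documented with
#' the genotyping assay: 95 degC for 10 min, then 45 cycles of 95 degC
#' for 10 s, 60 degC for 10 s and 72 degC for 20 s.
#'
#' @param path Optional file to write the program to.
#' @return The program lines, invisibly when written.
#' @export
qpcr_protocol <- function(path = NULL) {
  lines <- c(
    "qPCR SNP genotyping thermal program",
    "  1. 95 degC  10 min   (initial denaturation)",
    "  2. 95 degC  10 s  \\",
    "  3. 60 degC  10 s   | 45 cycles",
    "  4. 72 degC  20 s  /"
  )
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
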