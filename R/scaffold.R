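#' PPR scaffold objects
#'
#' A scaffold couples the motif-level view of a P-class PPR protein (an
#' ordered list of position 5/35 residue codes) with the nucleotide CDS
#' that encodes it. Every motif spans exactly 105 bp (35 codons) of the
#' CDS; the codons at intra-motif codon offsets 5 and 35 (1-based) must
#' translate to the recorded residues. The CDS may carry constant arms
#' before the first and after the last motif (vector-homology sequence
#' used by the assembly-fragment designer).
#'
#' @param name Scaffold identifier.
#' @param motifs data.frame with columns `index` (1-based from the
#'   N-terminus), `res5`, `res35`.
#' @param cds DNA string.
#' @param motif_spans data.frame with columns `start`, `end` (1-based
#'   inclusive coordinates in `cds`), one row per motif, ascending and
#'   non-overlapping.
#' @return An object of class `ppr_scaffold`.
#' @export
ppr_scaffold <- function(name, motifs, cds, motif_spans) {
  cds <- assert_dna(cds, "cds")
  motifs <- as.data.frame(motifs)
  motif_spans <- as.data.frame(motif_spans)
  stopifnot(
    all(c("index", "res5", "res35") %in% names(motifs)),
    all(c("start", "end") %in% names(motif_spans)),
    nrow(motifs) >= 1L, nrow(motifs) == nrow(motif_spans)
  )
  motifs$res5 <- vapply(motifs$res5, assert_aa, "", what = "res5")
  motifs$res35 <- vapply(motifs$res35, assert_aa, "", what = "res35")
  if (any(motifs$index != seq_len(nrow(motifs)))) {
    stop("motif indices must be 1..n in order", call. = FALSE)
  }
  len <- motif_spans$end - motif_spans$start + 1L
  if (any(len != 105L)) stop("every motif span must be exactly 105 bp", call. = FALSE)
  if (any(len %% 3L != 0L)) stop("motif spans must be codon-aligned", call. = FALSE)
  if (any(motif_spans$start < 1L) || any(motif_spans$end > nchar(cds))) {
    stop("motif spans exceed the CDS", call. = FALSE)
  }
  if (nrow(motif_spans) > 1L) {
    if (any(diff(motif_spans$start) <= 0) ||
        any(motif_spans$start[-1L] <= motif_spans$end[-nrow(motif_spans)])) {
      stop("motif spans must be ascending and non-overlapping", call. = FALSE)
    }
  }
  obj <- structure(
    list(name = as.character(name), motifs = motifs, cds = cds,
         motif_spans = motif_spans),
    class = "ppr_scaffold"
  )
  got <- scaffold_codes_from_cds(obj)
  if (!identical(got$res5, motifs$res5) || !identical(got$res35, motifs$res35)) {
    stop("CDS codons at intra-motif offsets 5/35 do not translate to the recorded residues",
         call. = FALSE)
  }
  obj
}

## Residue codes read back off the CDS (the round-trip view).
scaffold_codes_from_cds <- function(scaffold) {
  s <- scaffold$motif_spans$start
  res5 <- vapply(s, function(st) translate_codon(substr(scaffold$cds, st + 12L, st + 14L)), "")
  res35 <- vapply(s, function(st) translate_codon(substr(scaffold$cds, st + 102L, st + 104L)), "")
  data.frame(index = seq_along(s), res5 = res5, res35 = res35, stringsAsFactors = FALSE)
}

motif_codon <- function(scaffold, motif_index, position) {
  st <- scaffold$motif_spans$start[motif_index]
  off <- if (position == 5L) 12L else 102L
  substr(scaffold$cds, st + off, st + off + 2L)
}

#' @export
print.ppr_scaffold <- function(x, ...) {
  codes <- paste0(x$motifs$res5, x$motifs$res35, collapse = " ")
  cat(sprintf("PPR scaffold '%s': %d motifs, CDS %d bp\n",
              x$name, nrow(x$motifs), nchar(x$cds)))
  cat(sprintf("  position 5/35 codes: %s\n", codes))
  invisible(x)
}

#' @export
summary.ppr_scaffold <- function(object, table = ppr_code_table(), ...) {
  pref <- vapply(seq_len(nrow(object$motifs)), function(i) {
    code_lookup(object$motifs$res5[i], object$motifs$res35[i], table)$preferred
  }, "")
  out <- cbind(object$motifs, object$motif_spans, preferred_base = pref)
  class(out) <- c("summary.ppr_scaffold", "data.frame")
  out
}

#' Generate a deterministic synthetic PPR scaffold
#'
#' Builds a seeded 16-motif restorer-of-fertility-like scaffold: each
#' motif is 105 bp (35 codons); the codons at offsets 5 and 35 encode
#' configurable residue codes; all remaining codons are random non-stop
#' codons; short constant arms flank the motif array. Default codes are
#' canonical pairs drawn at random, with the positions the retargeting
#' examples rely on fixed (P6 = SN, P8 = SD, P9 = SN, P13 = NT, P15
#' position 35 = N). A `variant = "RPF2"` scaffold instead carries the
#' non-standard pre-canonicalisation codes P6 = GG and P9 = SS.
#'
#' @param seed Integer seed; the generator is a pure function of
#'   `(seed, parameters)`.
#' @param n_motifs Number of motifs (default 16).
#' @param codes Optional data.frame (`index`, `res5`, `res35`)
#'   overriding the generated codes.
#' @param variant `"mRPF2"` (canonicalised codes, default) or `"RPF2"`.
#' @param arm5,arm3 Lengths in bp of the constant arms (codon-aligned).
#' @param name Scaffold name.
#' @return A `ppr_scaffold`.
#' @examples
#' sc <- synth_scaffold(seed = 1)
#' sc$motifs[6, ]  # P6 codes SN
#' @export
synth_scaffold <- function(seed = 1L, n_motifs = 16L, codes = NULL,
                           variant = c("mRPF2", "RPF2"),
                           arm5 = 30L, arm3 = 30L,
                           name = NULL) {
  variant <- match.arg(variant)
  stopifnot(n_motifs >= 1L, arm5 %% 3L == 0L, arm3 %% 3L == 0L)
  name <- name %||% sprintf("synth-%s-s%d", variant, as.integer(seed))
  with_seed(substream_seed(seed, "scaffold"), {
    if (is.null(codes)) {
      canonical <- matrix(c("N", "D", "N", "N", "S", "D", "S", "N"),
                          ncol = 2L, byrow = TRUE)
      pick <- canonical[sample.int(4L, n_motifs, replace = TRUE), , drop = FALSE]
      codes <- data.frame(index = seq_len(n_motifs),
                          res5 = pick[, 1L], res35 = pick[, 2L],
                          stringsAsFactors = FALSE)
      fix <- function(i, r5 = NULL, r35 = NULL) {
        if (i <= n_motifs) {
          if (!is.null(r5)) codes$res5[i] <<- r5
          if (!is.null(r35)) codes$res35[i] <<- r35
        }
      }
      fix(6L, "S", "N"); fix(8L, "S", "D"); fix(9L, "S", "N")
      fix(13L, "N", "T"); fix(15L, r35 = "N")
      if (variant == "RPF2") {
        fix(6L, "G", "G")
        fix(9L, "S", "S")
      }
    } else {
      codes <- as.data.frame(codes)
    }
    tab <- codon_table()
    sense <- sort(tab$codon[tab$aa != "*"])
    rand_codons <- function(n) paste(sample(sense, n, replace = TRUE), collapse = "")
    motif_seq <- function(i) {
      cods <- character(35L)
      for (j in seq_len(35L)) cods[j] <- sample(sense, 1L)
      cods[5L] <- sort(codons_for(codes$res5[i]))[1L]
      cods[35L] <- sort(codons_for(codes$res35[i]))[1L]
      paste(cods, collapse = "")
    }
    body <- vapply(seq_len(n_motifs), motif_seq, "")
    cds <- paste0(rand_codons(arm5 / 3L), paste(body, collapse = ""),
                  rand_codons(arm3 / 3L))
    starts <- arm5 + 1L + (seq_len(n_motifs) - 1L) * 105L
    spans <- data.frame(start = starts, end = starts + 104L)
    ppr_scaffold(name, codes, cds, spans)
  })
}

#' Describe a single residue edit at a motif's position 5 or 35
#'
#' @param motif_index Motif position, 1-based from the N-terminus.
#' @param position Either 5 or 35.
#' @param from_res Current one-letter residue (checked against the
#'   scaffold when applied).
#' @param to_res Replacement residue; must differ from `from_res`.
#' @return An object of class `motif_edit`.
#' @export
motif_edit <- function(motif_index, position, from_res, to_res) {
  position <- as.integer(position)
  if (!position %in% c(5L, 35L)) stop("position must be 5 or 35", call. = FALSE)
  from_res <- assert_aa(from_res, "from_res")
  to_res <- assert_aa(to_res, "to_res")
  if (from_res == to_res) stop("from_res and to_res must differ", call. = FALSE)
  structure(
    list(motif_index = as.integer(motif_index), position = position,
         from_res = from_res, to_res = to_res),
    class = "motif_edit"
  )
}

#' @export
print.motif_edit <- function(x, ...) {
  cat(sprintf("P%d pos%d %s>%s\n", x$motif_index, x$position, x$from_res, x$to_res))
  invisible(x)
}

#' Apply residue edits to a scaffold
#'
#' Rewrites the position 5/35 codons named by each edit using the
#' minimal-nucleotide-change codon for the new residue (ties broken by
#' the lexicographically smallest codon), leaving every other base of
#' the CDS untouched. Each edit's `from_res` must match the scaffold's
#' current residue — a stale edit is an error, so edit lists cannot be
#' silently applied to the wrong scaffold.
#'
#' @param scaffold A `ppr_scaffold`.
#' @param edits A `motif_edit`, a list of them, or a data.frame with
#'   columns `motif_index`, `position`, `from_res`, `to_res`.
#' @param name Optional name for the edited scaffold.
#' @return A new `ppr_scaffold`.
#' @examples
#' rpf2 <- synth_scaffold(seed = 1, variant = "RPF2")
#' mrpf2 <- apply_edits(rpf2, mrpf2_edits())
#' @export
apply_edits <- function(scaffold, edits, name = NULL) {
  stopifnot(inherits(scaffold, "ppr_scaffold"))
  edits <- as_edit_list(edits)
  cds <- scaffold$cds
  motifs <- scaffold$motifs
  for (e in edits) {
    if (e$motif_index < 1L || e$motif_index > nrow(motifs)) {
      stop(sprintf("motif_index %d out of range (1..%d)", e$motif_index, nrow(motifs)),
           call. = FALSE)
    }
    cur <- if (e$position == 5L) motifs$res5[e$motif_index] else motifs$res35[e$motif_index]
    if (cur != e$from_res) {
      stop(sprintf("stale edit: motif %d position %d is %s, not %s",
                   e$motif_index, e$position, cur, e$from_res), call. = FALSE)
    }
    st <- scaffold$motif_spans$start[e$motif_index]
    off <- if (e$position == 5L) 12L else 102L
    old_codon <- substr(cds, st + off, st + off + 2L)
    new_codon <- minimal_change_codon(old_codon, e$to_res)
    substr(cds, st + off, st + off + 2L) <- new_codon
    if (e$position == 5L) motifs$res5[e$motif_index] <- e$to_res
    else motifs$res35[e$motif_index] <- e$to_res
  }
  nm <- name %||% if (length(edits)) paste0(scaffold$name, "*") else scaffold$name
  ppr_scaffold(nm, motifs, cds, scaffold$motif_spans)
}

as_edit_list <- function(edits) {
  if (inherits(edits, "motif_edit")) return(list(edits))
  if (is.data.frame(edits)) {
    return(lapply(seq_len(nrow(edits)), function(i) {
      motif_edit(edits$motif_index[i], edits$position[i],
                 edits$from_res[i], edits$to_res[i])
    }))
  }
  if (is.list(edits)) {
    if (!all(vapply(edits, inherits, TRUE, what = "motif_edit"))) {
      stop("edits must be motif_edit objects", call. = FALSE)
    }
    return(edits)
  }
  stop("edits must be a motif_edit, a list of them, or a data.frame", call. = FALSE)
}

#' Canonical edit sets from the retargeting examples
#'
#' `mrpf2_edits()` canonicalises the non-standard P6 (GG) and P9 (SS)
#' codes of the natural scaffold to SN. `atp1_retarget_edits()` returns
#' the edits that redirect the canonicalised scaffold to the atp1
#' transcript: the library variant (#280) changes P8 position 5 S to N
#' and P15 position 35 N to D; `full = TRUE` adds the two extra P13
#' edits (position 5 N to S, position 35 T to N) carried by the directly
#' engineered construct.
#'
#' @param full Include the P13 edits.
#' @return A list of [motif_edit()] objects.
#' @export
mrpf2_edits <- function() {
  list(
    motif_edit(6L, 5L, "G", "S"),
    motif_edit(6L, 35L, "G", "N"),
    motif_edit(9L, 35L, "S", "N")
  )
}

#' @rdname mrpf2_edits
#' @export
atp1_retarget_edits <- function(full = FALSE) {
  edits <- list(
    motif_edit(8L, 5L, "S", "N"),
    motif_edit(15L, 35L, "N", "D")
  )
  if (full) {
    edits <- c(edits, list(
      motif_edit(13L, 5L, "N", "S"),
      motif_edit(13L, 35L, "T", "N")
    ))
  }
  edits
}

#' Build the position-specific scoring matrix of a scaffold
#'
#' Row i holds the log-odds (natural log of affinity weight over
#' background) of motif i against the four RNA bases; the N-terminal
#' motif is row 1 and aligns with the 5'-most bound base of the RNA
#' site.
#'
#' @param scaffold A `ppr_scaffold`.
#' @param table A [ppr_code_table()].
#' @return A numeric matrix with one row per motif and columns
#'   A, C, G, U; attribute `non_canonical` lists motifs whose residue
#'   pair is absent from the table (scored uniformly, i.e. all-zero
#'   log-odds under a uniform background).
#' @export
build_pssm <- function(scaffold, table = ppr_code_table()) {
  stopifnot(inherits(scaffold, "ppr_scaffold"), nrow(scaffold$motifs) >= 1L)
  n <- nrow(scaffold$motifs)
  m <- matrix(0, nrow = n, ncol = 4L, dimnames = list(NULL, PPR_BASES))
  noncan <- integer(0)
  for (i in seq_len(n)) {
    lk <- code_lookup(scaffold$motifs$res5[i], scaffold$motifs$res35[i], table)
    m[i, ] <- log(lk$weights / table$background)
    if (!lk$canonical) noncan <- c(noncan, i)
  }
  rownames(m) <- sprintf("P%d", seq_len(n))
  attr(m, "non_canonical") <- noncan
  m
}

#' Consensus RNA site of a scaffold
#'
#' The per-motif argmax base of the scaffold's scoring matrix, 5' to 3'.
#'
#' @inheritParams build_pssm
#' @return A single RNA string, one base per motif.
#' @export
consensus_site <- function(scaffold, table = ppr_code_table()) {
  m <- build_pssm(scaffold, table)
  paste(PPR_BASES[apply(m, 1L, which.max)], collapse = "")
}

#' Read and write scaffold definition files
#'
#' A scaffold is stored as a tab-separated motif table (`motif_index`,
#' `res5`, `res35`, `start`, `end`) plus a FASTA file holding the CDS.
#'
#' @param tsv Path of the motif table.
#' @param fasta Path of the CDS FASTA (the first record is used).
#' @param name Optional scaffold name (default: the FASTA record name).
#' @return `read_scaffold()` returns a `ppr_scaffold`;
#'   `write_scaffold()` returns the paths invisibly.
#' @export
read_scaffold <- function(tsv, fasta, name = NULL) {
  df <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) < 1L) stop("no sequence in FASTA", call. = FALSE)
  ppr_scaffold(
    name %||% names(seqs)[1L],
    data.frame(index = df$motif_index, res5 = df$res5, res35 = df$res35),
    as.character(seqs[[1L]]),
    data.frame(start = df$start, end = df$end)
  )
}

#' @rdname read_scaffold
#' @param scaffold A `ppr_scaffold` to write.
#' @export
write_scaffold <- function(scaffold, tsv, fasta) {
  stopifnot(inherits(scaffold, "ppr_scaffold"))
  df <- data.frame(
    motif_index = scaffold$motifs$index,
    res5 = scaffold$motifs$res5, res35 = scaffold$motifs$res35,
    start = scaffold$motif_spans$start, end = scaffold$motif_spans$end
  )
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  seqs <- Biostrings::DNAStringSet(stats::setNames(scaffold$cds, scaffold$name))
  Biostrings::writeXStringSet(seqs, fasta)
  invisible(c(tsv = tsv, fasta = fasta))
}
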