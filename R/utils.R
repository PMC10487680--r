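#' @keywords internal
"_PACKAGE"

## RNA/DNA alphabets used throughout; scoring is always over RNA bases.
PPR_BASES <- c("A", "C", "G", "U")
DNA_BASES <- c("A", "C", "G", "T")
AA_LETTERS <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporary RNG state
#'
#' Seeds the R RNG, evaluates `code`, and restores the previous
#' `.Random.seed`, so seeded generators never disturb the caller's
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## Deterministic per-generator substream: one scenario seed fans out to
## fixed small offsets so the generators are independent but reproducible.
substream_seed <- function(seed, stream = c("genome", "plate", "ct", "clones", "scaffold")) {
  stream <- match.arg(stream)
  offset <- c(genome = 101L, plate = 202L, ct = 303L, clones = 404L, scaffold = 505L)[[stream]]
  (as.integer(seed) %% 20000000L) * 100L + offset
}

reverse_complement_dna <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Transcribe between DNA and RNA alphabets
#'
#' In-place T/U exchange (uppercasing); no complementing.
#'
#' @param x Sequence string(s).
#' @return The converted string(s).
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' @rdname dna_to_rna
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", toupper(x))

## Split a sequence string into single characters.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

assert_aa <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || !(toupper(x) %in% AA_LETTERS)) {
    stop(sprintf("%s must be a one-letter amino-acid code, got '%s'", what, paste(x, collapse = ",")),
         call. = FALSE)
  }
  toupper(x)
}

assert_dna <- function(x, what = "sequence") {
  x <- toupper(x)
  if (!grepl("^[ACGT]+$", x)) {
    stop(sprintf("%s must be a non-empty DNA string over ACGT", what), call. = FALSE)
  }
  x
}

## Codon tables derived from the standard genetic code.
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  data.frame(codon = names(gc), aa = unname(gc), stringsAsFactors = FALSE)
}

codons_for <- function(aa) {
  tab <- codon_table()
  sort(tab$codon[tab$aa == aa])
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[[toupper(codon)]])
}

## Minimal-nucleotide-change codon encoding `to_aa`, starting from
## `codon`; ties broken by the lexicographically smallest codon.
minimal_change_codon <- function(codon, to_aa) {
  cands <- codons_for(to_aa)
  if (length(cands) == 0L) stop(sprintf("no codon encodes '%s'", to_aa), call. = FALSE)
  from <- seq_chars(toupper(codon))
  dist <- vapply(cands, function(cd) sum(seq_chars(cd) != from), integer(1))
  cands <- cands[dist == min(dist)]
  sort(cands)[1L]
}
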