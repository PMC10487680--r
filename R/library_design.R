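#' Variable-motif plan for a combinatorial library
#'
#' Defines which motifs vary, at which residue position, and what the
#' alternative residue at each is. The default plan mirrors the
#' five-fragment, 16-motif design: motifs 2, 5, 8, 11 and 14 vary at
#' position 35 and motifs 3, 6, 9, 12 and 15 at position 5, giving a
#' 2^10 = 1024-variant design space. When `alt_residues` is not given,
#' the alternative residue is the canonical-code swap (S/N exchanged at
#' position 5, D/N exchanged at position 35), which keeps every variant
#' motif on a canonical recognition pair.
#'
#' @param pos35_motifs Motif indices varied at position 35.
#' @param pos5_motifs Motif indices varied at position 5; must be
#'   disjoint from `pos35_motifs`.
#' @param alt_residues Optional named list/vector mapping motif index
#'   (as character) to the alternative residue.
#' @return An object of class `variable_plan`.
#' @export
variable_plan <- function(pos35_motifs = c(2L, 5L, 8L, 11L, 14L),
                          pos5_motifs = c(3L, 6L, 9L, 12L, 15L),
                          alt_residues = NULL) {
  pos35_motifs <- sort(unique(as.integer(pos35_motifs)))
  pos5_motifs <- sort(unique(as.integer(pos5_motifs)))
  if (length(intersect(pos35_motifs, pos5_motifs))) {
    stop("pos35_motifs and pos5_motifs must be disjoint", call. = FALSE)
  }
  structure(
    list(pos35_motifs = pos35_motifs, pos5_motifs = pos5_motifs,
         alt_residues = alt_residues),
    class = "variable_plan"
  )
}

#' @export
print.variable_plan <- function(x, ...) {
  cat(sprintf("variable_plan: pos35 at {%s}, pos5 at {%s} (%d variable motifs)\n",
              paste(x$pos35_motifs, collapse = ","),
              paste(x$pos5_motifs, collapse = ","),
              length(x$pos35_motifs) + length(x$pos5_motifs)))
  invisible(x)
}

plan_motifs <- function(plan) {
  sort(c(plan$pos35_motifs, plan$pos5_motifs))
}

## One motif_edit per variable motif of the plan, against a scaffold.
plan_edits <- function(scaffold, plan) {
  idx <- plan_motifs(plan)
  if (length(idx) && max(idx) > nrow(scaffold$motifs)) {
    stop("plan indices exceed the scaffold's motif count", call. = FALSE)
  }
  lapply(idx, function(i) {
    pos <- if (i %in% plan$pos35_motifs) 35L else 5L
    from <- if (pos == 5L) scaffold$motifs$res5[i] else scaffold$motifs$res35[i]
    to <- plan$alt_residues[[as.character(i)]] %||% switch(
      from,
      S = "N", N = if (pos == 5L) "S" else "D", D = "N",
      stop(sprintf(
        "no default alternative residue for %s at motif %d position %d; supply alt_residues",
        from, i, pos), call. = FALSE)
    )
    motif_edit(i, pos, from, to)
  })
}

#' Enumerate the combinatorial variant library
#'
#' Every variable motif of the plan is independently wild type or
#' altered, yielding 2^k variants for k variable motifs. Variant ids
#' are the zero-padded decimal value of the bitmask whose bit 1 (least
#' significant) corresponds to the lowest-index variable motif; id 0 is
#' the unedited scaffold.
#'
#' @param scaffold A `ppr_scaffold`.
#' @param plan A [variable_plan()].
#' @return A named list of `ppr_scaffold` objects (names are the
#'   variant ids), with attribute `plan`.
#' @examples
#' v <- enumerate_variants(synth_scaffold(seed = 1), variable_plan(2, 3))
#' length(v)  # 4
#' @export
enumerate_variants <- function(scaffold, plan = variable_plan()) {
  stopifnot(inherits(scaffold, "ppr_scaffold"), inherits(plan, "variable_plan"))
  edits <- plan_edits(scaffold, plan)
  k <- length(edits)
  n <- 2^k
  if (n > 2^20) stop("plan too large to enumerate", call. = FALSE)
  width <- max(1L, nchar(as.character(n - 1)))
  ids <- sprintf(paste0("%0", width, "d"), seq_len(n) - 1L)
  out <- vector("list", n)
  for (mask in seq_len(n) - 1L) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
    out[[mask + 1L]] <- apply_edits(scaffold, edits[sel],
                                    name = paste0(scaffold$name, "_v", ids[mask + 1L]))
  }
  names(out) <- ids
  attr(out, "plan") <- plan
  out
}

#' Tile a scaffold into overlapping assembly fragments
#'
#' Cuts the motif array into windows of `window` motifs advancing by
#' `step`, so consecutive fragments share one boundary motif (for a
#' 16-motif scaffold with the defaults: P1-P4, P4-P7, P7-P10, P10-P13,
#' P13-P16). Fragment ends are extended into the adjacent constant CDS
#' until the terminal fixed-motif block reaches `min_flank` bp, since a
#' single 105 bp motif cannot satisfy the 125 bp fixed-end requirement
#' on its own; terminal fragments absorb the whole constant arm (the
#' vector-homology sequence). Every fragment must respect the synthesis
#' bounds `min_len`/`max_len` and keep all variable codon bases outside
#' both fixed flanks, otherwise the violated bound is reported.
#'
#' @param scaffold A `ppr_scaffold`.
#' @param window Motifs per fragment (default 4).
#' @param step Motif advance between fragments (default 3).
#' @param plan A [variable_plan()] naming the variable motifs (used to
#'   locate variable codon bases); motifs outside the scaffold are
#'   ignored.
#' @param min_len,max_len Synthesis length bounds in bp (defaults 251
#'   and 500).
#' @param min_flank Minimum invariant bp at each fragment end
#'   (default 125).
#' @param max_variable Maximum variable bases per fragment (default 18).
#' @return A list of `gblock_fragment` objects (class `gblock_set`),
#'   each with `id`, `sequence`, `motif_span`, `fixed_flank5`,
#'   `fixed_flank3` and `variable_positions` (1-based bp offsets within
#'   the fragment).
#' @export
design_fragments <- function(scaffold, window = 4L, step = 3L,
                             plan = variable_plan(),
                             min_len = 251L, max_len = 500L,
                             min_flank = 125L, max_variable = 18L) {
  stopifnot(inherits(scaffold, "ppr_scaffold"))
  n <- nrow(scaffold$motifs)
  window <- as.integer(window); step <- as.integer(step)
  if (window < 1L || step < 1L || window > n) stop("invalid window/step", call. = FALSE)
  if ((n - window) %% step != 0L) {
    stop(sprintf("(motif count - window) = %d is not divisible by step %d",
                 n - window, step), call. = FALSE)
  }
  n_frag <- (n - window) %/% step + 1L
  spans <- scaffold$motif_spans
  L <- nchar(scaffold$cds)
  ext <- max(0L, min_flank - 105L)
  var_idx <- plan_motifs(plan)
  var_idx <- var_idx[var_idx <= n]
  frags <- vector("list", n_frag)
  for (i in seq_len(n_frag)) {
    a <- 1L + (i - 1L) * step
    b <- a + window - 1L
    start <- if (i == 1L) 1L else spans$start[a] - ext
    end <- if (i == n_frag) L else spans$end[b] + ext
    if (start < 1L) {
      stop(sprintf("fragment %d needs %d bp of constant sequence 5' of motif %d; only %d available",
                   i, ext, a, spans$start[a] - 1L), call. = FALSE)
    }
    if (end > L) {
      stop(sprintf("fragment %d needs %d bp of constant sequence 3' of motif %d; only %d available",
                   i, ext, b, L - spans$end[b]), call. = FALSE)
    }
    len <- end - start + 1L
    if (len < min_len || len > max_len) {
      stop(sprintf("fragment %d length %d bp violates the [%d, %d] bp synthesis bound",
                   i, len, min_len, max_len), call. = FALSE)
    }
    vp <- integer(0)
    for (m in intersect(seq.int(a, b), var_idx)) {
      pos <- if (m %in% plan$pos35_motifs) 35L else 5L
      c0 <- spans$start[m] + (if (pos == 5L) 12L else 102L)
      vp <- c(vp, (c0:(c0 + 2L)) - start + 1L)
    }
    vp <- sort(vp)
    if (length(vp) > max_variable) {
      stop(sprintf("fragment %d carries %d variable bases, above the %d-base bound",
                   i, length(vp), max_variable), call. = FALSE)
    }
    flank5 <- if (length(vp)) min(vp) - 1L else len
    flank3 <- if (length(vp)) len - max(vp) else len
    if (flank5 < min_flank || flank3 < min_flank) {
      stop(sprintf("fragment %d fixed flanks (%d, %d bp) fall below the %d bp bound",
                   i, flank5, flank3, min_flank), call. = FALSE)
    }
    frags[[i]] <- structure(
      list(id = sprintf("F%d", i),
           sequence = substr(scaffold$cds, start, end),
           motif_span = c(a, b),
           cds_span = c(start, end),
           fixed_flank5 = flank5, fixed_flank3 = flank3,
           variable_positions = vp),
      class = "gblock_fragment"
    )
  }
  structure(frags, class = "gblock_set", scaffold_name = scaffold$name)
}

#' @export
print.gblock_fragment <- function(x, ...) {
  cat(sprintf("%s: motifs P%d-P%d, %d bp, flanks %d/%d bp, %d variable base(s)\n",
              x$id, x$motif_span[1], x$motif_span[2], nchar(x$sequence),
              x$fixed_flank5, x$fixed_flank3, length(x$variable_positions)))
  invisible(x)
}

#' @export
print.gblock_set <- function(x, ...) {
  cat(sprintf("gblock_set for '%s': %d fragments\n",
              attr(x, "scaffold_name") %||% "?", length(x)))
  for (f in x) print(f)
  invisible(x)
}

#' Reassemble fragments in silico
#'
#' Joins consecutive fragments through their shared terminal sequence,
#' the way an isothermal (Gibson) assembly would: the longest exact
#' suffix/prefix match of at least `min_overlap` bp is collapsed once at
#' each junction. Any sequence disagreement in a shared region makes
#' the junction unassemblable and is reported with the fragment ids.
#'
#' @param fragments A `gblock_set` or list of `gblock_fragment` objects
#'   (or plain character sequences), in order.
#' @param min_overlap Minimum exact overlap in bp (default 20).
#' @return The assembled DNA string, with attribute `overlaps` giving
#'   the collapsed overlap length at each junction.
#' @export
assemble_in_silico <- function(fragments, min_overlap = 20L) {
  seqs <- lapply(fragments, function(f) if (is.character(f)) f else f$sequence)
  ids <- vapply(seq_along(fragments), function(i) {
    f <- fragments[[i]]
    if (is.character(f)) sprintf("F%d", i) else f$id
  }, "")
  if (length(seqs) == 0L) stop("no fragments", call. = FALSE)
  asm <- seqs[[1L]]
  overlaps <- integer(0)
  for (i in seq_along(seqs)[-1L]) {
    b <- seqs[[i]]
    kmax <- min(nchar(asm), nchar(b))
    found <- 0L
    for (k in seq.int(kmax, min_overlap)) {
      if (substr(asm, nchar(asm) - k + 1L, nchar(asm)) == substr(b, 1L, k)) {
        found <- k
        break
      }
    }
    if (found == 0L) {
      stop(sprintf("incompatible fragments at junction %s/%s: no exact overlap of >= %d bp",
                   ids[i - 1L], ids[i], min_overlap), call. = FALSE)
    }
    asm <- paste0(asm, substr(b, found + 1L, nchar(b)))
    overlaps <- c(overlaps, found)
  }
  attr(asm, "overlaps") <- overlaps
  asm
}

#' Write fragments as FASTA plus a TSV manifest
#'
#' @param fragments A `gblock_set`.
#' @param fasta,tsv Output paths.
#' @return The paths, invisibly.
#' @export
write_fragments <- function(fragments, fasta, tsv) {
  seqs <- Biostrings::DNAStringSet(vapply(fragments, function(f) f$sequence, ""))
  names(seqs) <- vapply(fragments, function(f) f$id, "")
  Biostrings::writeXStringSet(seqs, fasta)
  df <- do.call(rbind, lapply(fragments, function(f) {
    data.frame(id = f$id, first_motif = f$motif_span[1], last_motif = f$motif_span[2],
               length = nchar(f$sequence),
               fixed_flank5 = f$fixed_flank5, fixed_flank3 = f$fixed_flank3,
               variable_positions = paste(f$variable_positions, collapse = ","))
  }))
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, tsv = tsv))
}

#' Write a variant library as a motif-code table
#'
#' One row per variant with the full position 5/35 code string and the
#' altered motifs.
#'
#' @param variants Output of [enumerate_variants()].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  base <- variants[[1L]]
  df <- do.call(rbind, lapply(names(variants), function(id) {
    v <- variants[[id]]
    altered <- which(v$motifs$res5 != base$motifs$res5 |
                     v$motifs$res35 != base$motifs$res35)
    data.frame(
      variant_id = id,
      codes = paste(paste0(v$motifs$res5, v$motifs$res35), collapse = " "),
      altered_motifs = paste(altered, collapse = ",")
    )
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
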