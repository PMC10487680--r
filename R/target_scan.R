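#' Transcript and genome sequence sets
#'
#' A light container for the sequences a scan runs over. Sequences are
#' stored as RNA (DNA input is transcribed in place, T to U) so scoring
#' is always over \{A, C, G, U\}; each record carries a topology flag
#' (`circular = TRUE` allows scan windows to wrap around the origin, as
#' on a plant mitochondrial genome).
#'
#' @param seqs Named character vector, `DNAStringSet` or
#'   `RNAStringSet`; names are the record ids.
#' @param circular Logical, recycled over records.
#' @return An object of class `transcript_set`.
#' @export
transcript_set <- function(seqs, circular = FALSE) {
  if (inherits(seqs, "XStringSet")) {
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  }
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)) || any(names(seqs) == "")) {
    stop("sequences must have unique non-empty names", call. = FALSE)
  }
  seqs <- vapply(seqs, function(s) dna_to_rna(toupper(s)), "")
  if (any(nchar(seqs) == 0L)) stop("sequences must be non-empty", call. = FALSE)
  bad <- grepl("[^ACGUN]", seqs)
  if (any(bad)) {
    stop("sequences must be over the ACGU(T) alphabet (N allowed)", call. = FALSE)
  }
  circular <- rep_len(as.logical(circular), length(seqs))
  structure(
    list(records = data.frame(id = names(seqs), circular = circular,
                              stringsAsFactors = FALSE),
         seqs = unname(seqs)),
    class = "transcript_set"
  )
}

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("transcript_set: %d record(s)\n", nrow(x$records)))
  n <- min(6L, nrow(x$records))
  for (i in seq_len(n)) {
    cat(sprintf("  %s: %d nt%s\n", x$records$id[i], nchar(x$seqs[i]),
                if (x$records$circular[i]) " (circular)" else ""))
  }
  if (nrow(x$records) > n) cat("  ...\n")
  invisible(x)
}

#' Read sequences from FASTA into a transcript set
#'
#' @param path FASTA file.
#' @param circular Topology flag for all records.
#' @return A [transcript_set()].
#' @export
read_transcripts <- function(path, circular = FALSE) {
  seqs <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(seqs))
  transcript_set(stats::setNames(as.character(seqs), nm), circular = circular)
}

## Score every window of one (already strand-resolved) RNA string.
## Returns scored start positions in that strand's own 1-based
## coordinates together with window scores and site sequences.
scan_one_strand <- function(pssm, s, circular, offset5) {
  W <- nrow(pssm)
  L <- nchar(s)
  site_len <- W + offset5
  if (L < site_len) return(NULL)
  if (circular) {
    # rotate in the 5' pad for the unscored offset base and the 3'
    # wraparound tail, so every start 1..L has a full site
    pad5 <- if (offset5 > 0L) substr(s, L - offset5 + 1L, L) else ""
    ext <- paste0(pad5, s, substr(s, 1L, W - 1L))
    starts <- seq_len(L)                 # scored start, original coords
    pos0 <- starts + offset5             # scored start within ext
  } else {
    starts <- seq.int(1L + offset5, L - W + 1L)
    if (length(starts) == 0L) return(NULL)
    ext <- s
    pos0 <- starts
  }
  idx <- match(seq_chars(ext), PPR_BASES)   # N etc. -> NA
  scores <- numeric(length(starts))
  ok <- rep(TRUE, length(starts))
  for (k in seq_len(W)) {
    b <- idx[pos0 + k - 1L]
    ok <- ok & !is.na(b)
    contrib <- pssm[k, ]
    scores <- scores + ifelse(is.na(b), 0, contrib[ifelse(is.na(b), 1L, b)])
  }
  site <- substring(ext, pos0 - offset5, pos0 + W - 1L)
  data.frame(scored_start = starts, score = scores, site_seq = site,
             ok = ok, stringsAsFactors = FALSE)
}

#' Scan sequences with a PPR scoring matrix
#'
#' Slides the scaffold's position-specific scoring matrix over every
#' record of a [transcript_set()] and returns the highest-scoring
#' candidate binding sites. Scores are additive log-odds over the
#' matrix rows (N-terminal motif against the 5'-most bound base). With
#' `both_strands = TRUE` (genome scans) the reverse complement is
#' scanned as well; transcript scans score only the given strand.
#' Windows containing ambiguous bases are skipped.
#'
#' @param pssm Matrix from [build_pssm()].
#' @param transcripts A [transcript_set()].
#' @param top_k Maximum number of hits returned (default 5).
#' @param min_score Minimum log-odds score retained (default 0, i.e.
#'   better than background).
#' @param both_strands Scan the reverse complement too.
#' @param offset5 0 (default) or 1; with 1, one additional unscored 5'
#'   base is included in each reported site sequence, for scaffolds
#'   whose footprint is one base longer than the motif count.
#' @return A data.frame of class `ppr_hits` with columns
#'   `transcript_id`, `start` (1-based position of the 5'-most bound
#'   base on the hit's own strand, i.e. the larger coordinate for minus
#'   strand hits), `strand`, `score`, `site_seq`. Sorted by descending
#'   score, ties broken by (transcript_id, start, strand) ascending.
#' @examples
#' sc <- synth_scaffold(seed = 1)
#' ts <- transcript_set(c(t1 = paste0("AAAA", rna_to_dna(consensus_site(sc)), "AAAA")))
#' scan(build_pssm(sc), ts, top_k = 1)
#' @export
scan <- function(pssm, transcripts, top_k = 5L, min_score = 0,
                 both_strands = FALSE, offset5 = 0L) {
  stopifnot(is.matrix(pssm), ncol(pssm) == 4L,
            inherits(transcripts, "transcript_set"))
  offset5 <- as.integer(offset5)
  if (!offset5 %in% c(0L, 1L)) stop("offset5 must be 0 or 1", call. = FALSE)
  colnames(pssm) <- PPR_BASES
  W <- nrow(pssm)
  site_len <- W + offset5
  empty <- data.frame(transcript_id = character(0), start = integer(0),
                      strand = character(0), score = numeric(0),
                      site_seq = character(0), stringsAsFactors = FALSE)
  if (nrow(transcripts$records) == 0L) {
    warning("empty transcript set: no sequences to scan")
    class(empty) <- c("ppr_hits", "data.frame")
    return(empty)
  }
  out <- list()
  for (i in seq_len(nrow(transcripts$records))) {
    id <- transcripts$records$id[i]
    circ <- transcripts$records$circular[i]
    s <- transcripts$seqs[i]
    L <- nchar(s)
    if (L < site_len) {
      warning(sprintf("record '%s' (%d nt) shorter than the %d nt site; skipped",
                      id, L, site_len))
      next
    }
    fwd <- scan_one_strand(pssm, s, circ, offset5)
    if (!is.null(fwd)) {
      fwd <- fwd[fwd$ok, , drop = FALSE]
      if (nrow(fwd)) {
        out[[length(out) + 1L]] <- data.frame(
          transcript_id = id,
          start = as.integer((fwd$scored_start - offset5 - 1L) %% L + 1L),
          strand = "+", score = fwd$score, site_seq = fwd$site_seq,
          stringsAsFactors = FALSE
        )
      }
    }
    if (both_strands) {
      rc <- dna_to_rna(reverse_complement_dna(rna_to_dna(s)))
      rev <- scan_one_strand(pssm, rc, circ, offset5)
      if (!is.null(rev)) {
        rev <- rev[rev$ok, , drop = FALSE]
        if (nrow(rev)) {
          # 5'-most bound base of a minus-strand site maps to original
          # coordinate L - (scored_start - offset5) + 1
          out[[length(out) + 1L]] <- data.frame(
            transcript_id = id,
            start = as.integer((L - (rev$scored_start - offset5)) %% L + 1L),
            strand = "-", score = rev$score, site_seq = rev$site_seq,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  hits <- if (length(out)) do.call(rbind, out) else empty
  hits <- hits[hits$score >= min_score, , drop = FALSE]
  ord <- order(-hits$score, hits$transcript_id, hits$start, hits$strand)
  hits <- hits[ord, , drop = FALSE]
  hits <- utils::head(hits, top_k)
  rownames(hits) <- NULL
  class(hits) <- c("ppr_hits", "data.frame")
  hits
}

#' Predict targets for a whole variant library
#'
#' Builds each variant's scoring matrix and scans the same sequence set,
#' returning the best hits per variant in one table.
#'
#' @param variants A list of `ppr_scaffold` objects (named, or using
#'   each scaffold's own name).
#' @param transcripts A [transcript_set()].
#' @param table A [ppr_code_table()].
#' @inheritParams scan
#' @return A data.frame with a `variant_id` column followed by the
#'   [scan()] hit columns; one block of up to `top_k` rows per variant.
#' @export
predict_library_targets <- function(variants, transcripts,
                                    table = ppr_code_table(),
                                    top_k = 1L, min_score = -Inf,
                                    both_strands = FALSE, offset5 = 0L) {
  if (inherits(variants, "ppr_scaffold")) variants <- list(variants)
  if (length(variants) < 1L) stop("need at least one variant", call. = FALSE)
  ids <- names(variants) %||% vapply(variants, function(v) v$name, "")
  if (is.null(names(variants))) names(variants) <- ids
  ids[ids == ""] <- vapply(variants[ids == ""], function(v) v$name, "")
  out <- lapply(seq_along(variants), function(i) {
    h <- scan(build_pssm(variants[[i]], table), transcripts, top_k = top_k,
              min_score = min_score, both_strands = both_strands,
              offset5 = offset5)
    if (nrow(h) == 0L) return(NULL)
    cbind(variant_id = ids[i], as.data.frame(h), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(variant_id = character(0), transcript_id = character(0),
                      start = integer(0), strand = character(0),
                      score = numeric(0), site_seq = character(0))
  }
  rownames(res) <- NULL
  res
}

#' Write scan hits to TSV or BED
#'
#' The TSV mirrors the hit table. The BED writer converts the hits'
#' 1-based strand-aware coordinates into 0-based half-open intervals on
#' the forward strand (the conversion is stated in the file header);
#' wrapped circular hits are skipped with a warning.
#'
#' @param hits A `ppr_hits` data.frame (optionally with a `variant_id`
#'   column).
#' @param path Output file.
#' @param site_len Site length in bp (matrix rows + offset); inferred
#'   from `site_seq` when missing.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(as.data.frame(hits), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
write_hits_bed <- function(hits, path, site_len = NULL) {
  hits <- as.data.frame(hits)
  site_len <- site_len %||% (if (nrow(hits)) nchar(hits$site_seq[1]) else 0L)
  left <- ifelse(hits$strand == "-", hits$start - site_len + 1L, hits$start)
  keep <- left >= 1L
  if (any(!keep)) warning("dropping hits wrapping the circular origin from BED output")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# BED (0-based half-open) converted from 1-based inclusive hit coordinates", con)
  h <- hits[keep, , drop = FALSE]
  if (nrow(h)) {
    bed <- data.frame(h$transcript_id, left[keep] - 1L, left[keep] - 1L + site_len,
                      if ("variant_id" %in% names(h)) h$variant_id else ".",
                      round(h$score, 4), h$strand)
    utils::write.table(bed, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
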