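#' Genomic transcript regions
#'
#' A transcript region on a (mitochondrial) genome: 1-based inclusive
#' coordinates, a strand, and optional named annotations (a binding
#' site span, a cleavage site encoded as the ordered pair of flanking
#' positions).
#'
#' @param genome_id Genome/record identifier.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @param binding_site Optional `c(start, end)` within the region.
#' @param cleavage_site Optional `c(p, p + 1)` between-base site within
#'   the region.
#' @return An object of class `transcript_region`.
#' @examples
#' atp1 <- transcript_region("BK010421-like", 66938, 68982, "-",
#'                           binding_site = c(67277, 67293),
#'                           cleavage_site = c(67227, 67228))
#' region_length(atp1)  # 2045
#' @export
transcript_region <- function(genome_id, start, end, strand = c("+", "-"),
                              binding_site = NULL, cleavage_site = NULL) {
  strand <- match.arg(strand)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start > end) {
    stop("need start <= end (1-based inclusive)", call. = FALSE)
  }
  if (!is.null(binding_site)) {
    if (length(binding_site) != 2L || binding_site[1L] < start || binding_site[2L] > end) {
      stop("binding_site must lie within the region", call. = FALSE)
    }
  }
  if (!is.null(cleavage_site)) {
    if (length(cleavage_site) != 2L || cleavage_site[2L] != cleavage_site[1L] + 1L) {
      stop("cleavage_site must be the ordered pair of flanking positions (p, p+1)",
           call. = FALSE)
    }
    if (cleavage_site[1L] < start || cleavage_site[1L] >= end) {
      stop("cleavage site must lie within [start, end)", call. = FALSE)
    }
  }
  structure(
    list(genome_id = genome_id, start = start, end = end, strand = strand,
         binding_site = binding_site, cleavage_site = cleavage_site),
    class = "transcript_region"
  )
}

#' @export
print.transcript_region <- function(x, ...) {
  cat(sprintf("region %s:%d-%d (%s), %d nt\n", x$genome_id, x$start, x$end,
              x$strand, region_length(x)))
  if (!is.null(x$binding_site)) {
    cat(sprintf("  binding site %d-%d\n", x$binding_site[1], x$binding_site[2]))
  }
  if (!is.null(x$cleavage_site)) {
    cat(sprintf("  cleavage site between %d and %d\n",
                x$cleavage_site[1], x$cleavage_site[2]))
  }
  invisible(x)
}

#' Length of a transcript region
#'
#' @param region A [transcript_region()].
#' @return Inclusive length in nt (`end - start + 1`).
#' @export
region_length <- function(region) {
  stopifnot(inherits(region, "transcript_region"))
  region$end - region$start + 1L
}

#' Fragment lengths after cleavage of a transcript region
#'
#' Splits a region at a between-base cleavage site and assigns the two
#' fragments to the transcript's 5' and 3' sides according to strand:
#' on the minus strand the 3' fragment runs from the cut toward the
#' lower-coordinate terminus. Inclusive fragment lengths always sum to
#' the region length. Because a gel ladder is read against coordinate
#' differences rather than inclusive base counts, the 3' fragment's
#' size is additionally reported as `gel_size_nt` = inclusive length
#' minus one (the cut-position-to-terminus coordinate difference); for
#' the 2045 nt atp1-like region cut between 67,227 and 67,228 on the
#' minus strand this is 67,227 - 66,938 = 289 while the inclusive count
#' is 290.
#'
#' @param region A [transcript_region()].
#' @param cut_between The ordered pair `c(p, p + 1)`; defaults to the
#'   region's annotated cleavage site. `p = start - 1` or `p = end`
#'   denote the degenerate boundary cuts and are flagged.
#' @return A list with `five_prime_len`, `three_prime_len` (inclusive
#'   nt, summing to [region_length()]), `gel_size_nt`,
#'   `gel_convention = "coordinate_difference"` and `degenerate`.
#' @export
cleavage_fragments <- function(region, cut_between = region$cleavage_site) {
  stopifnot(inherits(region, "transcript_region"))
  if (is.null(cut_between)) stop("no cleavage site given or annotated", call. = FALSE)
  p <- as.integer(cut_between[1L])
  if (length(cut_between) != 2L || as.integer(cut_between[2L]) != p + 1L) {
    stop("cut_between must be the ordered pair (p, p+1)", call. = FALSE)
  }
  if (p < region$start - 1L || p > region$end) {
    stop(sprintf("cut between %d and %d lies outside region %d-%d",
                 p, p + 1L, region$start, region$end), call. = FALSE)
  }
  low_len <- p - region$start + 1L          # fragment on the lower-coordinate side
  high_len <- region$end - p                # fragment on the higher-coordinate side
  if (region$strand == "+") {
    five <- low_len; three <- high_len
  } else {
    five <- high_len; three <- low_len
  }
  list(
    five_prime_len = five,
    three_prime_len = three,
    gel_size_nt = three - 1L,
    gel_convention = "coordinate_difference",
    degenerate = (low_len == 0L || high_len == 0L)
  )
}

#' Ct tables for relative quantification
#'
#' Holds raw qPCR cycle-threshold values with their replicate
#' structure, the reference transcript(s) used for normalisation and
#' the calibrator sample.
#'
#' @param data data.frame with columns `sample`, `transcript`,
#'   `bio_rep`, `tech_rep`, `ct`.
#' @param reference Character vector of reference transcript ids
#'   (at least one).
#' @param calibrator Calibrator sample id.
#' @return An object of class `ct_table`.
#' @export
ct_table <- function(data, reference, calibrator) {
  data <- as.data.frame(data)
  need <- c("sample", "transcript", "bio_rep", "tech_rep", "ct")
  if (!all(need %in% names(data))) {
    stop("data must have columns sample, transcript, bio_rep, tech_rep, ct",
         call. = FALSE)
  }
  if (length(reference) < 1L) stop("need at least one reference transcript", call. = FALSE)
  if (!all(reference %in% data$transcript)) {
    stop("reference transcript(s) absent from the table", call. = FALSE)
  }
  if (!calibrator %in% data$sample) stop("calibrator sample absent from the table", call. = FALSE)
  structure(
    list(data = data, reference = reference, calibrator = calibrator),
    class = "ct_table"
  )
}

#' Read a Ct table from CSV
#'
#' @param path CSV with columns `sample`, `transcript`, `bio_rep`,
#'   `tech_rep`, `ct`.
#' @inheritParams ct_table
#' @return A [ct_table()].
#' @export
read_ct_table <- function(path, reference, calibrator) {
  ct_table(utils::read.csv(path, stringsAsFactors = FALSE), reference, calibrator)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Technical replicates are averaged first; within each biological
#' replicate of each sample, delta-Ct is the transcript Ct minus the
#' mean Ct of the reference transcript(s); delta-delta-Ct subtracts the
#' calibrator sample's mean delta-Ct, and the reported log2 fold change
#' is its negative. The spread across biological replicates is reported
#' as a standard deviation. Samples with no reference measurement are
#' excluded with a warning.
#'
#' @param ct A [ct_table()].
#' @return A data.frame with one row per (sample, transcript) for every
#'   non-calibrator sample: `log2fc`, `sd` (across biological
#'   replicates), `n_bio`.
#' @export
relative_expression <- function(ct) {
  stopifnot(inherits(ct, "ct_table"))
  d <- ct$data
  # technical replicates first
  tech <- stats::aggregate(ct ~ sample + transcript + bio_rep, data = d, FUN = mean)
  refm <- stats::aggregate(ct ~ sample + bio_rep,
                           data = tech[tech$transcript %in% ct$reference, ],
                           FUN = mean)
  names(refm)[names(refm) == "ct"] <- "ref_ct"
  m <- merge(tech, refm, by = c("sample", "bio_rep"))
  dropped <- setdiff(unique(tech$sample), unique(m$sample))
  if (length(dropped)) {
    warning(sprintf("sample(s) without reference Ct excluded: %s",
                    paste(dropped, collapse = ", ")))
  }
  m$dct <- m$ct - m$ref_ct
  cal <- m[m$sample == ct$calibrator, ]
  cal_dct <- stats::aggregate(dct ~ transcript, data = cal, FUN = mean)
  names(cal_dct)[names(cal_dct) == "dct"] <- "cal_dct"
  x <- merge(m[m$sample != ct$calibrator, ], cal_dct, by = "transcript")
  if (nrow(x) == 0L) {
    return(data.frame(sample = character(0), transcript = character(0),
                      log2fc = numeric(0), sd = numeric(0), n_bio = integer(0)))
  }
  x$log2fc_rep <- -(x$dct - x$cal_dct)
  out <- stats::aggregate(log2fc_rep ~ sample + transcript, data = x,
                          FUN = function(v) c(mean(v), stats::sd(v), length(v)))
  res <- data.frame(
    sample = out$sample, transcript = out$transcript,
    log2fc = out$log2fc_rep[, 1L], sd = out$log2fc_rep[, 2L],
    n_bio = as.integer(out$log2fc_rep[, 3L])
  )
  res[order(res$sample, res$transcript), , drop = FALSE]
}

#' Tally the 5' ends of circular RT-PCR clones
#'
#' @param positions Mapped 5'-end genomic positions, either one entry
#'   per clone or unique positions accompanied by `counts`.
#' @param counts Optional clone counts per position.
#' @param region Optional [transcript_region()]; positions outside it
#'   are an error.
#' @return A list with `histogram` (data.frame `position`, `count`,
#'   ascending), `total` and `modes` (all positions sharing the maximum
#'   count).
#' @examples
#' tally_clone_ends(c(67228, 67230), counts = c(7, 1))$modes  # 67228
#' @export
tally_clone_ends <- function(positions, counts = NULL, region = NULL) {
  if (length(positions) < 1L) stop("need at least one clone", call. = FALSE)
  positions <- as.integer(positions)
  if (is.null(counts)) {
    tab <- table(positions)
    hist <- data.frame(position = as.integer(names(tab)), count = as.integer(tab))
  } else {
    if (length(counts) != length(positions) || any(counts < 1L)) {
      stop("counts must be positive and match positions", call. = FALSE)
    }
    hist <- stats::aggregate(count ~ position,
                             data = data.frame(position = positions,
                                               count = as.integer(counts)),
                             FUN = sum)
  }
  if (!is.null(region)) {
    stopifnot(inherits(region, "transcript_region"))
    if (any(hist$position < region$start | hist$position > region$end)) {
      stop("clone end position outside the parent region", call. = FALSE)
    }
  }
  hist <- hist[order(hist$position), , drop = FALSE]
  rownames(hist) <- NULL
  list(histogram = hist, total = sum(hist$count),
       modes = hist$position[hist$count == max(hist$count)])
}

#' Read transcript regions from a BED-like TSV
#'
#' Tab-separated columns `genome_id`, `start`, `end`, `strand`, with an
#' explicit `one_based` flag stating the coordinate convention of the
#' file (when `FALSE`, 0-based half-open intervals are converted on
#' read).
#'
#' @param path Input file.
#' @param one_based Whether coordinates in the file are 1-based
#'   inclusive (default `TRUE`).
#' @return A list of [transcript_region()] objects.
#' @export
read_regions <- function(path, one_based = TRUE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    s <- df$start[i]; e <- df$end[i]
    if (!one_based) s <- s + 1L
    transcript_region(df$genome_id[i], s, e, df$strand[i])
  })
}
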