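#' PPR-code affinity tables
#'
#' A code table maps the amino-acid pair at PPR motif positions 5 and 35
#' to affinity weights over the four RNA bases \{A, C, G, U\}. The
#' canonical P-class code covers four pairs: ND recognises U, NN
#' recognises C, SD recognises G and SN recognises A. The default table
#' places weight 0.9 on the preferred base and 0.1/3 on each other base;
#' an external frequency table (e.g. one derived from published
#' motif/base alignment counts) can be supplied instead.
#'
#' Weights are pseudocount-regularised and renormalised so each row sums
#' to 1; pairs absent from the table score as the uniform distribution
#' and are flagged non-canonical when looked up.
#'
#' @param weights A data.frame with columns `res5`, `res35`, `wA`, `wC`,
#'   `wG`, `wU` (non-negative, rows need not be normalised), or `NULL`
#'   for the canonical 4-pair default.
#' @param pseudocount Small positive value added to every weight before
#'   renormalisation.
#' @param background Base composition used for log-odds scoring; must be
#'   positive and is renormalised to sum to 1.
#' @return An object of class `ppr_code_table`.
#' @examples
#' tab <- ppr_code_table()
#' code_lookup("N", "D", tab)$preferred  # "U"
#' @export
ppr_code_table <- function(weights = NULL,
                           pseudocount = 0.01,
                           background = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25)) {
  if (is.null(weights)) {
    weights <- data.frame(
      res5  = c("N", "N", "S", "S"),
      res35 = c("D", "N", "D", "N"),
      wA = c(0.1 / 3, 0.1 / 3, 0.1 / 3, 0.9),
      wC = c(0.1 / 3, 0.9, 0.1 / 3, 0.1 / 3),
      wG = c(0.1 / 3, 0.1 / 3, 0.9, 0.1 / 3),
      wU = c(0.9, 0.1 / 3, 0.1 / 3, 0.1 / 3),
      stringsAsFactors = FALSE
    )
  }
  need <- c("res5", "res35", "wA", "wC", "wG", "wU")
  if (!all(need %in% names(weights))) {
    stop("weights must have columns res5, res35, wA, wC, wG, wU", call. = FALSE)
  }
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    stop("pseudocount must be a small positive number", call. = FALSE)
  }
  w <- as.matrix(weights[, c("wA", "wC", "wG", "wU")])
  if (any(w < 0) || any(!is.finite(w))) stop("weights must be finite and non-negative", call. = FALSE)
  w <- w + pseudocount
  w <- w / rowSums(w)
  colnames(w) <- PPR_BASES
  rownames(w) <- paste(toupper(weights$res5), toupper(weights$res35), sep = "")
  if (anyDuplicated(rownames(w))) stop("duplicate (res5, res35) pairs in weights", call. = FALSE)
  if (length(background) != 4L || any(background <= 0)) {
    stop("background must be four positive frequencies", call. = FALSE)
  }
  background <- background / sum(background)
  names(background) <- PPR_BASES
  structure(
    list(weights = w, pseudocount = pseudocount, background = background),
    class = "ppr_code_table"
  )
}

#' Read a PPR-code frequency table from TSV
#'
#' Expects tab-separated columns `res5`, `res35`, `wA`, `wC`, `wG`, `wU`.
#'
#' @param path File path.
#' @inheritParams ppr_code_table
#' @return A `ppr_code_table`.
#' @export
read_code_table <- function(path, pseudocount = 0.01,
                            background = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  ppr_code_table(df, pseudocount = pseudocount, background = background)
}

#' Write a PPR-code table to TSV
#'
#' @param table A `ppr_code_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_code_table <- function(table, path) {
  stopifnot(inherits(table, "ppr_code_table"))
  df <- data.frame(
    res5 = substr(rownames(table$weights), 1, 1),
    res35 = substr(rownames(table$weights), 2, 2),
    wA = table$weights[, "A"], wC = table$weights[, "C"],
    wG = table$weights[, "G"], wU = table$weights[, "U"]
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.ppr_code_table <- function(x, ...) {
  cat(sprintf("PPR code table: %d residue pairs, pseudocount %.3g\n",
              nrow(x$weights), x$pseudocount))
  print(round(x$weights, 3))
  invisible(x)
}

#' Look up the base affinities of a position 5/35 residue pair
#'
#' @param res5,res35 One-letter amino-acid codes at motif positions 5
#'   and 35.
#' @param table A [ppr_code_table()].
#' @return A list with `weights` (normalised over A, C, G, U),
#'   `preferred` (the argmax base; ties resolved to the alphabetically
#'   first base), and `canonical` (`FALSE` when the pair is absent from
#'   the table, in which case the weights are uniform).
#' @examples
#' code_lookup("S", "N", ppr_code_table())$preferred  # "A"
#' @export
code_lookup <- function(res5, res35, table = ppr_code_table()) {
  stopifnot(inherits(table, "ppr_code_table"))
  res5 <- assert_aa(res5, "res5")
  res35 <- assert_aa(res35, "res35")
  key <- paste0(res5, res35)
  if (key %in% rownames(table$weights)) {
    w <- table$weights[key, ]
    canonical <- TRUE
  } else {
    w <- stats::setNames(rep(0.25, 4L), PPR_BASES)
    canonical <- FALSE
  }
  list(weights = w, preferred = PPR_BASES[which.max(w)], canonical = canonical)
}
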