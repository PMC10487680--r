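#' Synthetic circular genome with planted PPR binding sites
#'
#' Generates a random circular DNA genome and plants the consensus
#' binding site of named scaffolds (or explicit RNA/DNA site sequences)
#' at chosen positions on either strand, recording a queryable truth
#' table. Background bases are i.i.d. at a configurable composition.
#' The generator is a pure function of `(seed, parameters)`: the same
#' seed yields byte-identical output.
#'
#' @param seed Integer seed.
#' @param length Genome length in bp.
#' @param sites A data.frame with columns `name`, `position` (1-based
#'   position of the site's 5'-most bound base on its strand) and
#'   `strand`, plus either a `scaffold` list-column of `ppr_scaffold`
#'   objects or a `site_seq` character column; or `NULL` for no planted
#'   sites.
#' @param composition Background base probabilities over A, C, G, T.
#' @param table Code table used to derive scaffold consensus sites.
#' @return A list with `genome` (a single-record circular
#'   [transcript_set()] named `id`), `truth` (data.frame `name`,
#'   `position`, `strand`, `site_seq`), and `id`.
#' @export
make_genome <- function(seed, length = 20000L, sites = NULL,
                        composition = c(A = 0.28, C = 0.22, G = 0.22, T = 0.28),
                        table = ppr_code_table()) {
  length <- as.integer(length)
  stopifnot(length > 0L)
  composition <- composition / sum(composition)
  with_seed(substream_seed(seed, "genome"), {
    g <- sample(DNA_BASES, length, replace = TRUE, prob = composition)
    truth <- data.frame(name = character(0), position = integer(0),
                        strand = character(0), site_seq = character(0))
    if (!is.null(sites) && nrow(sites) > 0L) {
      occupied <- integer(0)
      for (i in seq_len(nrow(sites))) {
        site_rna <- if ("site_seq" %in% names(sites)) {
          dna_to_rna(sites$site_seq[i])
        } else {
          consensus_site(sites$scaffold[[i]], table)
        }
        w <- nchar(site_rna)
        strand <- sites$strand[i]
        pos <- as.integer(sites$position[i])
        # genome interval covered by the site (5'-most bound base at
        # `pos` on the site's own strand)
        iv <- if (strand == "+") seq.int(pos, pos + w - 1L) else seq.int(pos - w + 1L, pos)
        iv <- (iv - 1L) %% length + 1L
        if (any(iv %in% occupied)) {
          stop(sprintf("planted site '%s' overlaps a previous site", sites$name[i]),
               call. = FALSE)
        }
        occupied <- c(occupied, iv)
        ins <- rna_to_dna(site_rna)
        if (strand == "-") ins <- reverse_complement_dna(ins)
        g[iv] <- seq_chars(ins)  # element-wise: iv follows the forward-strand order of ins
        truth <- rbind(truth, data.frame(name = sites$name[i], position = pos,
                                         strand = strand, site_seq = site_rna))
      }
    }
    id <- sprintf("synth_mito_s%d", as.integer(seed))
    genome <- transcript_set(stats::setNames(paste(g, collapse = ""), id),
                             circular = TRUE)
    list(genome = genome, truth = truth, id = id)
  })
}

#' Synthetic plate photograph with dark-green seedling discs
#'
#' Paints dark-green discs (colour jittered around the leaf reference
#' `#003300`) on a light agar-coloured background with Gaussian pixel
#' noise, and records each disc's exact painted pixel area as ground
#' truth. Same seed, same image.
#'
#' @param seed Integer seed.
#' @param discs data.frame with columns `x`, `y` (centres, pixels) and
#'   `r` (radius, pixels); `NULL` for an empty plate.
#' @param dim Image side in pixels (square plate).
#' @param agar Background colour (hex).
#' @param leaf Disc colour (hex).
#' @param noise_sd Gaussian noise s.d. on each channel (0-1 scale).
#' @param jitter_sd Colour jitter s.d. applied to disc pixels.
#' @return A list with `image` (dim x dim x 3 array in \[0, 1\]) and
#'   `truth` (data.frame `disc`, `area_px`).
#' @export
make_plate_image <- function(seed, discs = NULL, dim = 400L,
                             agar = "#D8D2B8", leaf = "#003300",
                             noise_sd = 0.015, jitter_sd = 0.01) {
  dim <- as.integer(dim)
  stopifnot(dim > 0L, noise_sd >= 0, jitter_sd >= 0)
  with_seed(substream_seed(seed, "plate"), {
    bg <- grDevices::col2rgb(agar)[, 1L] / 255
    fg <- grDevices::col2rgb(leaf)[, 1L] / 255
    img <- array(0, dim = c(dim, dim, 3L))
    for (ch in 1:3) {
      img[, , ch] <- bg[ch] + stats::rnorm(dim * dim, 0, noise_sd)
    }
    truth <- data.frame(disc = integer(0), area_px = integer(0))
    if (!is.null(discs) && nrow(discs) > 0L) {
      xs <- matrix(rep(seq_len(dim), each = dim), nrow = dim)   # column index
      ys <- matrix(rep(seq_len(dim), times = dim), nrow = dim)  # row index
      for (i in seq_len(nrow(discs))) {
        if (discs$x[i] - discs$r[i] < 1 || discs$x[i] + discs$r[i] > dim ||
            discs$y[i] - discs$r[i] < 1 || discs$y[i] + discs$r[i] > dim) {
          stop(sprintf("disc %d extends beyond the plate", i), call. = FALSE)
        }
        m <- (xs - discs$x[i])^2 + (ys - discs$y[i])^2 <= discs$r[i]^2
        npx <- sum(m)
        for (ch in 1:3) {
          v <- img[, , ch]
          v[m] <- fg[ch] + stats::rnorm(npx, 0, jitter_sd)
          img[, , ch] <- v
        }
        truth <- rbind(truth, data.frame(disc = i, area_px = npx))
      }
    }
    img[img < 0] <- 0
    img[img > 1] <- 1
    list(image = img, truth = truth)
  })
}

#' Write a plate image to PNG
#'
#' @param plate Output of [make_plate_image()] (or a raw array).
#' @param path PNG path.
#' @return `path`, invisibly.
#' @export
write_plate_png <- function(plate, path) {
  img <- if (is.list(plate)) plate$image else plate
  png::writePNG(img, path)
  invisible(path)
}

#' Synthetic Ct table with known fold changes
#'
#' Emulates a relative-expression experiment: for each transcript the
#' treated sample's Ct is the base Ct minus log2(fold change), plus
#' Gaussian noise per technical measurement; the calibrator sample sits
#' at the base Ct. Reference transcripts are added at fold change 1.
#' The true fold changes are retained as an attribute.
#'
#' @param seed Integer seed.
#' @param fold_changes Named numeric vector: true linear fold change of
#'   each transcript in the treated sample vs the calibrator.
#' @param sample_id,calibrator Sample names (defaults `"line"`, `"WT"`).
#' @param reference Name(s) of the reference transcript(s) (added with
#'   fold change 1).
#' @param n_bio,n_tech Biological and technical replicate counts
#'   (defaults 3 and 3).
#' @param noise_sd Gaussian Ct noise s.d. per technical measurement.
#' @param base_ct Baseline Ct for every transcript.
#' @return A [ct_table()] with attribute `truth_log2fc`.
#' @export
make_ct_table <- function(seed, fold_changes, sample_id = "line",
                          calibrator = "WT", reference = "ref",
                          n_bio = 3L, n_tech = 3L, noise_sd = 0.2,
                          base_ct = 22) {
  stopifnot(noise_sd >= 0, n_bio >= 1L, n_tech >= 1L,
            !is.null(names(fold_changes)), all(fold_changes > 0))
  fc <- c(fold_changes, stats::setNames(rep(1, length(reference)), reference))
  with_seed(substream_seed(seed, "ct"), {
    rows <- expand.grid(
      sample = c(calibrator, sample_id), transcript = names(fc),
      bio_rep = seq_len(n_bio), tech_rep = seq_len(n_tech),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    shift <- ifelse(rows$sample == sample_id, -log2(fc[rows$transcript]), 0)
    rows$ct <- base_ct + shift + stats::rnorm(nrow(rows), 0, noise_sd)
    out <- ct_table(rows, reference = reference, calibrator = calibrator)
    attr(out, "truth_log2fc") <- log2(fold_changes)
    out
  })
}

#' Synthetic circular RT-PCR clone ends
#'
#' Draws clone 5'-end positions concentrated at a known cleavage
#' position: each clone sits at the cleavage-product 5' end with
#' probability `1 - dispersion`, otherwise at a small geometric offset.
#'
#' @param seed Integer seed.
#' @param cleavage_pos True 5'-end position of the cleavage product.
#' @param n_clones Number of clones.
#' @param dispersion Probability of an offset end (default 0.15).
#' @return A list with `positions` (integer vector, one per clone) and
#'   `truth_pos`.
#' @export
make_clone_ends <- function(seed, cleavage_pos, n_clones = 8L, dispersion = 0.15) {
  stopifnot(n_clones >= 1L, dispersion >= 0, dispersion < 1)
  with_seed(substream_seed(seed, "clones"), {
    off <- ifelse(stats::runif(n_clones) < dispersion,
                  (stats::rgeom(n_clones, 0.5) + 1L) *
                    sample(c(-1L, 1L), n_clones, replace = TRUE),
                  0L)
    list(positions = as.integer(cleavage_pos + off),
         truth_pos = as.integer(cleavage_pos))
  })
}

#' Write a complete synthetic scenario to disk
#'
#' Materialises one seeded scenario — scaffold definition (TSV +
#' FASTA), a circular genome FASTA with a planted retargeted-variant
#' site, a plate PNG, a Ct CSV and a truth JSON — so every pipeline
#' stage can be exercised from files alone.
#'
#' @param seed Integer seed driving every generator substream.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named vector of the file paths written.
#' @export
write_scenario <- function(seed, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  sc <- synth_scaffold(seed = seed)
  v280 <- apply_edits(sc, atp1_retarget_edits(), name = paste0(sc$name, "_280"))
  write_scaffold(sc, p("scaffold.tsv"), p("scaffold.fasta"))
  gen <- make_genome(seed, length = 20000L,
                     sites = data.frame(name = "atp1_site", position = 15000L,
                                        strand = "-",
                                        site_seq = rna_to_dna(consensus_site(v280))))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(rna_to_dna(gen$genome$seqs[1]), gen$id)),
    p("genome.fasta"))
  plate <- make_plate_image(seed, discs = data.frame(x = 120, y = 150, r = 40))
  write_plate_png(plate, p("plate.png"))
  ct <- make_ct_table(seed, fold_changes = c(atp1 = 0.25, atp6 = 1.3))
  utils::write.csv(ct$data, p("ct_table.csv"), row.names = FALSE)
  clones <- make_clone_ends(seed, cleavage_pos = 14000L)
  truth <- list(
    seed = seed,
    planted_sites = gen$truth,
    plate_disc_area_px = plate$truth,
    ct_truth_log2fc = as.list(attr(ct, "truth_log2fc")),
    clone_truth_pos = clones$truth_pos,
    clone_positions = clones$positions
  )
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(c(scaffold_tsv = p("scaffold.tsv"), scaffold_fasta = p("scaffold.fasta"),
              genome = p("genome.fasta"), plate = p("plate.png"),
              ct = p("ct_table.csv"), truth = p("truth.json")))
}
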