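#' Read a plate photograph
#'
#' Reads a PNG or TIFF image into an H x W x 3 array of values in
#' \[0, 1\]; an alpha channel is dropped, greyscale is replicated to
#' three channels.
#'
#' @param path Image file (`.png`, `.tif`/`.tiff`).
#' @return Numeric array, height x width x 3.
#' @export
read_plate_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '.%s'", ext), call. = FALSE)
  )
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Linear contrast normalisation
#'
#' Stretches each channel linearly so the observed minimum maps to 0
#' and the maximum to 1 (the default linear-stretching contrast
#' adjustment). Constant channels are left unchanged.
#'
#' @param image Numeric array, height x width x 3, values in \[0, 1\].
#' @return Array of the same shape.
#' @export
normalize_contrast <- function(image) {
  stopifnot(is.array(image), length(dim(image)) == 3L)
  for (ch in seq_len(dim(image)[3L])) {
    v <- image[, , ch]
    rng <- range(v)
    if (rng[2L] > rng[1L]) {
      image[, , ch] <- (v - rng[1L]) / (rng[2L] - rng[1L])
    }
  }
  image
}

#' Per-pixel colour difference from a reference colour
#'
#' Computes the difference of every pixel from a reference colour
#' (default the dark leaf green `#003300`). The default metric is the
#' perceptual CIEDE2000 distance computed in CIE Lab (sRGB decoding,
#' D65 white point); `method = "euclidean"` uses plain RGB Euclidean
#' distance on the 0-255 scale for speed.
#'
#' @param image Numeric array, height x width x 3, values in \[0, 1\]
#'   (normalise first; see [normalize_contrast()]).
#' @param reference Reference colour as a hex string.
#' @param method `"cie2000"` (default) or `"euclidean"`.
#' @return A height x width matrix of non-negative differences; 0 only
#'   where a pixel equals the reference.
#' @export
colordiff_map <- function(image, reference = "#003300",
                          method = c("cie2000", "euclidean")) {
  stopifnot(is.array(image), length(dim(image)) == 3L, dim(image)[3L] == 3L)
  method <- match.arg(method)
  d <- dim(image)
  rgb255 <- cbind(as.vector(image[, , 1L]), as.vector(image[, , 2L]),
                  as.vector(image[, , 3L])) * 255
  ref <- t(grDevices::col2rgb(reference))
  if (method == "cie2000") {
    diff <- farver::compare_colour(rgb255, ref, from_space = "rgb",
                                   method = "cie2000")
  } else {
    diff <- sqrt((rgb255[, 1L] - ref[1L])^2 + (rgb255[, 2L] - ref[2L])^2 +
                 (rgb255[, 3L] - ref[3L])^2)
  }
  matrix(as.numeric(diff), nrow = d[1L], ncol = d[2L])
}

#' Threshold a colour-difference map into a leaf mask
#'
#' A pixel is a leaf pixel when its difference from the reference
#' colour is strictly less than half the median difference over the
#' whole image. On an image with no leaf material (an all-equal
#' difference map) no pixel can be below half the median, so the mask
#' is empty.
#'
#' @param diff_map Matrix from [colordiff_map()].
#' @return A logical matrix with attribute `threshold` (the value of
#'   half the median difference).
#' @export
segment_leaf <- function(diff_map) {
  stopifnot(is.matrix(diff_map), length(diff_map) > 0L)
  thr <- 0.5 * stats::median(diff_map)
  mask <- diff_map < thr
  if (!any(mask)) message("no pixel below half the median difference: empty leaf mask")
  attr(mask, "threshold") <- thr
  mask
}

#' Convert a leaf mask into physical areas
#'
#' Pixel counts are converted with the plate calibration: a square
#' plate of `plate_cm2` photographed as a `plate_px` x `plate_px` grid
#' gives a per-pixel area of (10 sqrt(plate_cm2) / plate_px)^2 mm^2
#' (with the defaults, (1000/2278)^2, about 0.1927 mm^2 per pixel).
#'
#' @param mask Logical matrix from [segment_leaf()] (or a pixel count).
#' @param plate_cm2 Physical plate area in cm^2 (default 100).
#' @param plate_px Pixels along the plate side (default 2278, taken
#'   from the mask's side length when the mask is square and this is
#'   `NULL`).
#' @param n_seedlings Manually counted seedlings on the plate; the per
#'   seedling mean is `NA` (flagged) when 0 or missing.
#' @return A `leaf_area_result` list: `leaf_pixel_count`, `area_mm2`,
#'   `mean_area_per_seedling_mm2`, `threshold_used`, `px_per_mm2`
#'   calibration.
#' @export
area_from_mask <- function(mask, plate_cm2 = 100, plate_px = NULL,
                           n_seedlings = NA_integer_) {
  if (is.matrix(mask)) {
    count <- sum(mask)
    if (is.null(plate_px)) {
      plate_px <- if (nrow(mask) == ncol(mask)) nrow(mask) else
        stop("plate_px must be given for non-square masks", call. = FALSE)
    }
    thr <- attr(mask, "threshold") %||% NA_real_
  } else {
    count <- as.integer(mask)
    if (is.null(plate_px)) plate_px <- 2278L
    thr <- NA_real_
  }
  if (!is.numeric(plate_cm2) || plate_cm2 <= 0 || plate_px <= 0) {
    stop("invalid plate calibration", call. = FALSE)
  }
  side_mm <- 10 * sqrt(plate_cm2)
  px_area_mm2 <- (side_mm / plate_px)^2
  area <- count * px_area_mm2
  mean_area <- if (!is.na(n_seedlings) && n_seedlings > 0) area / n_seedlings else NA_real_
  structure(
    list(leaf_pixel_count = as.integer(count), area_mm2 = area,
         mean_area_per_seedling_mm2 = mean_area,
         threshold_used = thr, px_area_mm2 = px_area_mm2,
         n_seedlings = n_seedlings),
    class = "leaf_area_result"
  )
}

#' @export
print.leaf_area_result <- function(x, ...) {
  cat(sprintf("leaf area: %d px = %.1f mm^2", x$leaf_pixel_count, x$area_mm2))
  if (!is.na(x$mean_area_per_seedling_mm2)) {
    cat(sprintf(" (%.1f mm^2/seedling over %d seedlings)",
                x$mean_area_per_seedling_mm2, x$n_seedlings))
  }
  cat(sprintf(", threshold %.3g\n", x$threshold_used))
  invisible(x)
}

#' Measure leaf area on a plate image
#'
#' Full pipeline: contrast normalisation, colour difference from dark
#' green, half-median thresholding and calibration to mm^2.
#'
#' @param image An image array or a PNG/TIFF path.
#' @inheritParams colordiff_map
#' @inheritParams area_from_mask
#' @return A `leaf_area_result`.
#' @export
measure_leaf_area <- function(image, plate_cm2 = 100, plate_px = NULL,
                              n_seedlings = NA_integer_,
                              reference = "#003300",
                              method = c("cie2000", "euclidean")) {
  if (is.character(image)) image <- read_plate_image(image)
  img <- normalize_contrast(image)
  dm <- colordiff_map(img, reference = reference, method = method)
  mask <- segment_leaf(dm)
  area_from_mask(mask, plate_cm2 = plate_cm2,
                 plate_px = plate_px %||% nrow(dm),
                 n_seedlings = n_seedlings)
}

#' Classify lines into slow and fast growth groups
#'
#' One-dimensional 2-means partition of per-line mean leaf areas
#' (week-3 values drive the classification), with deterministic
#' initialisation at the observed minimum and maximum. Optional
#' reference lines (a known slow and a known fast control) are checked
#' to fall in opposite groups; a warning is raised otherwise. With
#' fewer than two distinct values the partition degenerates to a single
#' group (with a warning).
#'
#' @param areas Named numeric vector of per-line mean areas (mm^2),
#'   typically week-3 values.
#' @param slow_ref,fast_ref Optional names of control lines.
#' @return A list with `labels` (data.frame: line, area, group),
#'   `centers` (slow/fast group means) and `boundary` (midpoint between
#'   the centers; `NA` for the single-group fallback).
#' @export
classify_growth <- function(areas, slow_ref = NULL, fast_ref = NULL) {
  if (length(areas) < 2L) stop("need at least 2 lines", call. = FALSE)
  lines <- names(areas) %||% as.character(seq_along(areas))
  if (length(unique(areas)) < 2L) {
    warning("fewer than 2 distinct area values: single-group fallback")
    return(list(
      labels = data.frame(line = lines, area = as.numeric(areas), group = "slow"),
      centers = c(slow = mean(areas), fast = NA_real_),
      boundary = NA_real_
    ))
  }
  if (length(areas) == 2L) {
    # kmeans needs k < n; two lines split trivially
    group <- ifelse(areas == min(areas), "slow", "fast")
    centers <- sort(as.numeric(areas))
  } else {
    km <- stats::kmeans(as.numeric(areas),
                        centers = matrix(c(min(areas), max(areas)), ncol = 1L))
    slow_cluster <- which.min(km$centers)
    group <- ifelse(km$cluster == slow_cluster, "slow", "fast")
    centers <- sort(as.numeric(km$centers))
  }
  names(centers) <- c("slow", "fast")
  res <- list(
    labels = data.frame(line = lines, area = as.numeric(areas), group = group),
    centers = centers,
    boundary = mean(centers)
  )
  get_group <- function(nm) res$labels$group[match(nm, res$labels$line)]
  if (!is.null(slow_ref) && !is.null(fast_ref)) {
    if (identical(get_group(slow_ref), get_group(fast_ref))) {
      warning("slow and fast reference lines fall in the same growth group")
    }
  }
  res
}
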