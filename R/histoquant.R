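#' Classify iron blobs as single MPIO or aggregations
#'
#' A blob is an `aggregation` when its area is at least
#' `aggregation_factor` times the area of one bead
#' (`pi * (single_bead_diameter / 2)^2`), i.e. the smallest area
#' inconsistent with a single bead; otherwise it is a `single_mpio`.
#' The boundary belongs to `aggregation` (`>=`).
#'
#' @param area_um2 Blob areas in um^2 (vectorised).
#' @param single_bead_diameter Bead diameter in um, default 1.
#' @param aggregation_factor Multiple of the bead area at which a blob
#'   stops being a plausible single bead, default 2.
#' @return Character vector, `"single_mpio"` or `"aggregation"`.
#' @export
classify_blob <- function(area_um2, single_bead_diameter = 1,
                          aggregation_factor = 2) {
  if (any(area_um2 <= 0)) stop_mq("blob areas must be positive")
  thr <- aggregation_factor * bead_area_um2(single_bead_diameter)
  ifelse(area_um2 >= thr, "aggregation", "single_mpio")
}

#' Segment blue-stained iron blobs
#'
#' Segments the Prussian-blue colour class of an RGB micrograph: a pixel is
#' blue-stained when its blue channel dominates, `B - max(R, G) > margin`.
#' Connected components (4-connectivity) become blobs with centroid and
#' area in physical units; each blob is classified by [classify_blob()].
#'
#' @param image RGB array `height x width x 3`, values in \[0, 1\] or
#'   0-255.
#' @param pixel_size_um Pixel size in um/px; taken from the image's
#'   `pixel_size_um` attribute when absent, and required (an image without
#'   pixel-size metadata is an error).
#' @param blue_margin Dominance margin on the \[0, 1\] scale, default 0.12.
#' @param min_area_um2 Discard components smaller than this, default 0.
#' @param single_bead_diameter,aggregation_factor Passed to
#'   [classify_blob()].
#' @return A `data.frame` of class `iron_blobs`: columns `blob`, `x_um`,
#'   `y_um` (centroid), `area_um2`, `n_pixels`, `class`.
#' @export
segment_iron <- function(image, pixel_size_um = NULL, blue_margin = 0.12,
                         min_area_um2 = 0, single_bead_diameter = 1,
                         aggregation_factor = 2) {
  pixel_size_um <- pixel_size_um %||% attr(image, "pixel_size_um")
  if (is.null(pixel_size_um)) {
    stop_mq("pixel size metadata is required (pass `pixel_size_um` or set the attribute)")
  }
  assert_scalar_pos(pixel_size_um, "pixel_size_um")
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) stop_mq("`image` must be an RGB array")
  if (max(image) > 1) image <- image / 255
  mask <- image[, , 3] - pmax(image[, , 1], image[, , 2]) > blue_margin
  empty <- data.frame(blob = integer(), x_um = numeric(), y_um = numeric(),
                      area_um2 = numeric(), n_pixels = integer(),
                      class = character(), stringsAsFactors = FALSE)
  class(empty) <- c("iron_blobs", "data.frame")
  if (!any(mask)) return(empty)
  lbl <- EBImage::bwlabel(mask)
  idx <- which(lbl > 0, arr.ind = TRUE)
  labs <- lbl[lbl > 0]
  npx <- tabulate(labs)
  # centroid in physical um: pixel (row, col) centre at ((col-.5), (row-.5))*psz
  cx <- (tapply(idx[, 2], labs, mean) - 0.5) * pixel_size_um
  cy <- (tapply(idx[, 1], labs, mean) - 0.5) * pixel_size_um
  out <- data.frame(blob = seq_along(npx),
                    x_um = as.numeric(cx), y_um = as.numeric(cy),
                    area_um2 = npx * pixel_size_um^2,
                    n_pixels = npx, stringsAsFactors = FALSE)
  out <- out[out$area_um2 >= min_area_um2, , drop = FALSE]
  out$class <- if (nrow(out)) {
    classify_blob(out$area_um2, single_bead_diameter, aggregation_factor)
  } else character()
  rownames(out) <- NULL
  class(out) <- c("iron_blobs", "data.frame")
  out
}

#' Nearest-lumen-centre distance statistics
#'
#' Euclidean distance from each macrophage centre to the nearest vessel
#' lumen centre (2D, centre-to-centre; the lumen radius is not
#' subtracted), with the summary statistics reported for perivascular
#' macrophages: the median distance, the fraction within 25 um, and a
#' cumulative histogram.
#'
#' @param macrophage_centres Two-column matrix or data frame of (x, y)
#'   in um.
#' @param vessel_lumen_centres Two-column matrix or data frame of (x, y)
#'   in um; at least one vessel is required.
#' @param within_um Proximity cutoff for the reported fraction, default 25.
#' @param bin_width_um Cumulative histogram bin width, default 5.
#' @return An object of class `distance_stats`: `distances` (um),
#'   `median_um`, `frac_within_25um` (fraction with distance <=
#'   `within_um`), and `cumulative` (data frame `edge_um`, `cum_frac`).
#' @examples
#' vessel_distance_stats(cbind(0, 0), cbind(3, 4))$distances  # 5
#' @export
vessel_distance_stats <- function(macrophage_centres, vessel_lumen_centres,
                                  within_um = 25, bin_width_um = 5) {
  v <- as.matrix(vessel_lumen_centres)
  if (nrow(v) == 0L) stop_mq("at least one vessel lumen centre is required")
  m <- as.matrix(macrophage_centres)
  if (nrow(m) == 0L) {
    dists <- numeric(0)
  } else {
    d2 <- Reduce(pmin, lapply(seq_len(nrow(v)), function(j) {
      (m[, 1] - v[j, 1])^2 + (m[, 2] - v[j, 2])^2
    }))
    dists <- sqrt(d2)
  }
  n_bins <- max(1, ceiling(max(dists, within_um) / bin_width_um))
  edges <- seq_len(n_bins) * bin_width_um
  cum <- vapply(edges, function(e) mean(dists <= e), numeric(1))
  structure(
    list(distances = dists,
         median_um = if (length(dists)) median(dists) else NA_real_,
         frac_within_25um = if (length(dists)) mean(dists <= within_um)
                            else NA_real_,
         cumulative = data.frame(edge_um = edges, cum_frac = cum)),
    class = "distance_stats")
}

#' @export
print.distance_stats <- function(x, ...) {
  cat(sprintf(
    "distance_stats: n = %d, median %.2f um, %.1f%% within 25 um\n",
    length(x$distances), x$median_um, 100 * x$frac_within_25um))
  invisible(x)
}

#' Endothelium-normalised single-MPIO density
#'
#' Count of blobs classified `single_mpio` per mm^2 of endothelium.
#'
#' @param blobs An `iron_blobs` table from [segment_iron()].
#' @param endothelium_area_mm2 Endothelial reference area in mm^2 (> 0).
#' @return Beads per mm^2.
#' @export
mpio_density <- function(blobs, endothelium_area_mm2) {
  assert_scalar_pos(endothelium_area_mm2, "endothelium_area_mm2")
  sum(blobs$class == "single_mpio") / endothelium_area_mm2
}

#' Blob counts per field of view
#'
#' Segments each image with [segment_iron()] and tabulates per-FOV blob
#' counts (total, single MPIO, aggregations) plus the mean and sample SD
#' of the total count.
#'
#' @param images List of RGB arrays (each carrying `pixel_size_um` unless
#'   supplied here).
#' @param pixel_size_um Pixel size applied to every image, um/px.
#' @param ... Passed to [segment_iron()].
#' @return List with `per_fov` (`data.frame`: `fov`, `n_blobs`,
#'   `n_single`, `n_aggregation`), `mean` and `sd` of `n_blobs`.
#' @export
count_per_fov <- function(images, pixel_size_um = NULL, ...) {
  if (length(images) == 0L) stop_mq("at least one image is required")
  rows <- lapply(seq_along(images), function(i) {
    b <- segment_iron(images[[i]], pixel_size_um = pixel_size_um, ...)
    data.frame(fov = i, n_blobs = nrow(b),
               n_single = sum(b$class == "single_mpio"),
               n_aggregation = sum(b$class == "aggregation"))
  })
  per_fov <- do.call(rbind, rows)
  list(per_fov = per_fov, mean = mean(per_fov$n_blobs),
       sd = if (nrow(per_fov) >= 2) sd(per_fov$n_blobs) else NA_real_)
}

#' Positive-pixel-count intensity windows
#'
#' Intensity windows on the 0-255 scale used for staining area fractions:
#' moderately stained pixels fall in \[185, 202\] and strongly stained
#' pixels below 10.
#'
#' @param moderate_window Closed intensity interval for moderate staining.
#' @param strong_max Strict upper bound for strong staining.
#' @return An object of class `positive_pixel_params`.
#' @export
positive_pixel_params <- function(moderate_window = c(185, 202),
                                  strong_max = 10) {
  moderate_window <- sort(as.numeric(moderate_window))
  if (any(moderate_window < 0) || any(moderate_window > 255) ||
      strong_max < 0 || strong_max > 255) {
    stop_mq("intensity windows must lie within the 0-255 scale")
  }
  if (strong_max >= moderate_window[1]) {
    stop_mq("`strong_max` must be below the moderate window")
  }
  structure(list(moderate_window = moderate_window, strong_max = strong_max),
            class = "positive_pixel_params")
}

#' Positive-pixel staining area fractions
#'
#' Classifies ROI pixels by intensity into moderately and strongly stained
#' windows and reports the area fractions. Intensity is the luma
#' `0.299 R + 0.587 G + 0.114 B` on the 0-255 scale (the published
#' algorithm's full hue/saturation logic is proprietary; only its intensity
#' windows are public, and they are applied verbatim). Grayscale input is
#' used as intensity directly.
#'
#' @param image RGB array (`h x w x 3`) or intensity matrix, values in
#'   \[0, 1\] or 0-255.
#' @param params A [positive_pixel_params()].
#' @param roi_mask Optional logical matrix restricting the pixels counted;
#'   must select at least one pixel.
#' @return List with fractions `moderate` (intensity in the closed moderate
#'   window), `strong` (intensity strictly below `strong_max`), `positive`
#'   (their sum) and `n_pixels`.
#' @export
positive_pixel_fraction <- function(image, params = positive_pixel_params(),
                                    roi_mask = NULL) {
  stopifnot(inherits(params, "positive_pixel_params"))
  d <- dim(image)
  if (length(d) == 3L && d[3] == 3L) {
    if (max(image) <= 1) image <- image * 255
    intensity <- 0.299 * image[, , 1] + 0.587 * image[, , 2] +
      0.114 * image[, , 3]
  } else if (length(d) == 2L) {
    intensity <- if (max(image) <= 1) image * 255 else image
  } else {
    stop_mq("`image` must be an RGB array or an intensity matrix")
  }
  if (!is.null(roi_mask)) {
    if (!identical(dim(roi_mask), dim(intensity))) {
      stop_mq("`roi_mask` does not match the image")
    }
    intensity <- intensity[roi_mask]
  }
  if (length(intensity) == 0L) stop_mq("ROI contains no pixels")
  moderate <- mean(intensity >= params$moderate_window[1] &
                   intensity <= params$moderate_window[2])
  strong <- mean(intensity < params$strong_max)
  list(moderate = moderate, strong = strong, positive = moderate + strong,
       n_pixels = length(intensity))
}
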