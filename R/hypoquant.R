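#' Ipsilateral / contralateral ROI mask pair
#'
#' Co-registered binary masks for the tumour-bearing (ipsilateral) and
#' normal (contralateral) striatum. Masks must live on the same grid as the
#' analysis volume, be disjoint and non-empty; no resampling is performed.
#'
#' @param ipsi,contra Logical arrays of identical dimension.
#' @param voxel_mm Optional voxel size carried as grid metadata.
#' @return An object of class `roi_mask_set`.
#' @export
roi_mask_set <- function(ipsi, contra, voxel_mm = NULL) {
  if (!is.logical(ipsi) || !is.logical(contra)) {
    stop_mq("masks must be logical arrays")
  }
  if (!identical(dim(ipsi), dim(contra))) {
    stop_mq("ipsi and contra masks must share one grid")
  }
  if (any(ipsi & contra)) stop_mq("ipsi and contra masks overlap")
  if (!any(ipsi) || !any(contra)) stop_mq("masks must be non-empty")
  structure(list(ipsi = ipsi, contra = contra, voxel_mm = voxel_mm),
            class = "roi_mask_set")
}

#' Mean and standard deviation over an ROI
#'
#' Summary statistics of a volume restricted to a mask. The SD uses the
#' sample (n − 1) definition.
#'
#' @param volume Numeric array.
#' @param mask Logical array of the same dimension; must select at least
#'   one voxel (at least two for the SD to be defined).
#' @return An object of class `roi_stats`: list with `mean`, `sd` and
#'   `n_voxels`.
#' @export
roi_stats <- function(volume, mask) {
  if (!identical(dim(volume), dim(mask))) {
    stop_mq("`volume` and `mask` must share one grid")
  }
  vals <- volume[mask]
  if (length(vals) == 0L) stop_mq("ROI mask is empty")
  structure(list(mean = mean(vals),
                 sd = if (length(vals) >= 2L) sd(vals) else NA_real_,
                 n_voxels = length(vals)),
            class = "roi_stats")
}

#' Detect hypointense voxels against a contralateral reference
#'
#' A voxel is hypointense when its signal lies more than `k` standard
#' deviations below the contralateral-ROI mean, i.e. strictly
#' `value < mean - k * sd`. With `sd = 0` (e.g. a noiseless constant
#' reference) a voxel exactly at the mean is therefore not flagged.
#'
#' @param volume Analysis volume (one echo or echo combination).
#' @param contra_stats A [roi_stats()] object for the contralateral ROI.
#' @param target_mask Logical array; the count is restricted to this mask
#'   while the returned map covers the whole volume.
#' @param k Threshold multiplier (> 0), default 3.
#' @return List with `count` (flagged voxels inside `target_mask`),
#'   `threshold` (`mean - k * sd`) and `mask` (logical array of flagged
#'   voxels within `target_mask`).
#' @export
detect_hypointense <- function(volume, contra_stats, target_mask, k = 3) {
  assert_scalar_pos(k, "k")
  stopifnot(inherits(contra_stats, "roi_stats"))
  if (!identical(dim(volume), dim(target_mask))) {
    stop_mq("`volume` and `target_mask` must share one grid")
  }
  s <- contra_stats$sd
  if (is.na(s)) stop_mq("contralateral SD undefined (fewer than 2 voxels)")
  thr <- contra_stats$mean - k * s
  flagged <- (volume < thr) & target_mask
  list(count = sum(flagged), threshold = thr, mask = flagged)
}

#' MPIO-induced hypointense voxels: post minus pre, clipped at zero
#'
#' The core statistic: each scan is thresholded against its *own*
#' contralateral-striatum statistics (scanner drift between scans is
#' absorbed by the per-scan calibration; no inter-scan intensity
#' normalisation is applied), hypointense voxels are counted per hemisphere,
#' and the MPIO-induced count is the post-contrast minus pre-contrast
#' difference. Tumours contain naturally hypointense areas pre-contrast, so
#' an apparently negative difference carries no physical meaning and is
#' clipped to zero (`diff_clipped = max(diff_raw, 0)`); the raw difference
#' is retained for noise-floor estimation.
#'
#' Counting is voxelwise: no connectivity or cluster filtering is applied.
#'
#' @param pre_volume,post_volume Analysis volumes on a common grid.
#' @param masks A [roi_mask_set()] on the same grid.
#' @param k Threshold multiplier, default 3 (strict `<` at the boundary).
#' @return An object of class `hypo_result`: thresholds per scan, counts
#'   `n_hypo_{ipsi,contra}_{pre,post}`, per-hemisphere `diff_raw` and
#'   `diff_clipped`, and the flagged-voxel maps in `hypo_masks`.
#' @export
mpio_induced_voxels <- function(pre_volume, post_volume, masks, k = 3) {
  stopifnot(inherits(masks, "roi_mask_set"))
  if (!identical(dim(pre_volume), dim(post_volume)) ||
      !identical(dim(pre_volume), dim(masks$ipsi))) {
    stop_mq("pre/post volumes and masks must share one grid")
  }
  stats_pre <- roi_stats(pre_volume, masks$contra)
  stats_post <- roi_stats(post_volume, masks$contra)
  pre_ipsi <- detect_hypointense(pre_volume, stats_pre, masks$ipsi, k)
  pre_contra <- detect_hypointense(pre_volume, stats_pre, masks$contra, k)
  post_ipsi <- detect_hypointense(post_volume, stats_post, masks$ipsi, k)
  post_contra <- detect_hypointense(post_volume, stats_post, masks$contra, k)
  diff_raw <- c(ipsi = post_ipsi$count - pre_ipsi$count,
                contra = post_contra$count - pre_contra$count)
  structure(
    list(k = k,
         threshold_pre = pre_ipsi$threshold,
         threshold_post = post_ipsi$threshold,
         n_hypo_ipsi_pre = pre_ipsi$count,
         n_hypo_ipsi_post = post_ipsi$count,
         n_hypo_contra_pre = pre_contra$count,
         n_hypo_contra_post = post_contra$count,
         diff_raw = diff_raw,
         diff_clipped = pmax(diff_raw, 0L),
         hypo_masks = list(pre = pre_ipsi$mask | pre_contra$mask,
                           post = post_ipsi$mask | post_contra$mask),
         contra_stats = list(pre = stats_pre, post = stats_post)),
    class = "hypo_result")
}

#' @export
print.hypo_result <- function(x, ...) {
  cat(sprintf(
    "hypo_result (k = %g): ipsi pre/post %d/%d (diff %d, clipped %d); contra pre/post %d/%d\n",
    x$k, x$n_hypo_ipsi_pre, x$n_hypo_ipsi_post,
    x$diff_raw[["ipsi"]], x$diff_clipped[["ipsi"]],
    x$n_hypo_contra_pre, x$n_hypo_contra_post))
  invisible(x)
}

#' Noise floor of the differencing technique
#'
#' Summarises post-minus-pre raw differences from control (non-binding)
#' animals or simulations: their mean and sample SD define the detection
#' limit of the technique, optionally expressed as a fraction of the
#' contralateral ROI volume.
#'
#' @param control_diffs Numeric vector of raw differences, length >= 2.
#' @param contra_n_voxels Optional contralateral-ROI voxel count used to
#'   express the mean as a fraction of the ROI.
#' @return List with `mean`, `sd`, `n` and `fraction_of_roi` (NA when
#'   `contra_n_voxels` is missing).
#' @export
noise_floor <- function(control_diffs, contra_n_voxels = NULL) {
  if (length(control_diffs) == 0L) stop_mq("no control differences supplied")
  if (length(control_diffs) < 2L) {
    stop_mq("at least two control differences are required")
  }
  m <- mean(control_diffs)
  list(mean = m, sd = sd(control_diffs), n = length(control_diffs),
       fraction_of_roi = if (is.null(contra_n_voxels)) NA_real_ else
         m / contra_n_voxels)
}

#' Tidy cohort table of hypointensity results
#'
#' One row per case per hemisphere, in case order then (ipsi, contra)
#' order, ready for CSV export and group summaries.
#'
#' @param results List of [mpio_induced_voxels()] results.
#' @param ids Case identifiers, recycled against `results`.
#' @param scenario Scenario labels, recycled against `results`.
#' @return A `data.frame` with columns `id`, `scenario`, `hemisphere`,
#'   `n_hypo_pre`, `n_hypo_post`, `diff_raw`, `diff_clipped`,
#'   `threshold_pre`, `threshold_post`. An empty input yields a zero-row
#'   table with the full header.
#' @export
cohort_table <- function(results, ids = seq_along(results),
                         scenario = NA_character_) {
  header <- data.frame(id = character(), scenario = character(),
                       hemisphere = character(),
                       n_hypo_pre = integer(), n_hypo_post = integer(),
                       diff_raw = integer(), diff_clipped = integer(),
                       threshold_pre = numeric(), threshold_post = numeric(),
                       stringsAsFactors = FALSE)
  if (length(results) == 0L) return(header)
  ids <- rep_len(as.character(ids), length(results))
  scenario <- rep_len(as.character(scenario), length(results))
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    stopifnot(inherits(r, "hypo_result"))
    data.frame(
      id = ids[i], scenario = scenario[i],
      hemisphere = c("ipsi", "contra"),
      n_hypo_pre = c(r$n_hypo_ipsi_pre, r$n_hypo_contra_pre),
      n_hypo_post = c(r$n_hypo_ipsi_post, r$n_hypo_contra_post),
      diff_raw = as.integer(r$diff_raw[c("ipsi", "contra")]),
      diff_clipped = as.integer(r$diff_clipped[c("ipsi", "contra")]),
      threshold_pre = r$threshold_pre, threshold_post = r$threshold_post,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
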