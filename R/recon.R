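#' Square-root of sum-of-squares combination
#'
#' Combines an array along one axis as `sqrt(sum(|x|^2))`, the standard
#' magnitude combination of multi-channel MRI data. The reducer is generic:
#' the same operator serves receive-channel combination (axis = channel of
#' a channel stack) and optional echo combination.
#'
#' @param x Numeric or complex array with at least one dimension.
#' @param axis Index of the dimension to combine (default 1, the leading
#'   channel axis of a channel stack).
#' @return Array with dimension `dim(x)[-axis]` (a scalar when `x` has one
#'   dimension); always non-negative. Invariant to permutation of entries
#'   along `axis` and, for complex input, to per-channel global phase.
#' @examples
#' sqrt_sos(array(c(3, 4), dim = c(2, 1)))  # 5
#' @export
sqrt_sos <- function(x, axis = 1L) {
  d <- dim(x) %||% length(x)
  axis <- as.integer(axis)
  if (axis < 1L || axis > length(d)) stop_mq("`axis` is out of range")
  if (d[axis] < 1L) stop_mq("cannot combine along an empty axis")
  perm <- c(axis, setdiff(seq_along(d), axis))
  m <- aperm(array(x, dim = d), perm)
  dim(m) <- c(d[axis], prod(d[-axis]))
  out <- sqrt(colSums(Mod(m)^2))
  if (length(d) == 1L) return(out[[1L]])
  if (length(d) == 2L) return(as.vector(out))
  array(out, dim = d[-axis])
}

# --- k-space helpers -------------------------------------------------------
# Centring convention: the DC coefficient sits at index floor(n/2) + 1 on
# every axis (array centre). fftshift moves DC from index 1 to the centre;
# ifftshift is its exact inverse, including odd sizes.

shift_nd <- function(x, amounts) {
  d <- dim(x) %||% length(x)
  idx <- lapply(seq_along(d), function(a) {
    ((seq_len(d[a]) - 1 - amounts[a]) %% d[a]) + 1
  })
  do.call(`[`, c(list(array(x, dim = d)), idx, list(drop = FALSE)))
}

#' Shift the zero-frequency coefficient to the array centre
#'
#' @param x Array (any dimensionality).
#' @return Array of the same shape with DC at index `floor(n/2) + 1` per
#'   axis. `ifftshift()` undoes `fftshift()` for both even and odd sizes.
#' @export
fftshift <- function(x) {
  d <- dim(x) %||% length(x)
  shift_nd(x, floor(d / 2))
}

#' @rdname fftshift
#' @export
ifftshift <- function(x) {
  d <- dim(x) %||% length(x)
  shift_nd(x, -floor(d / 2))
}

#' Image to centred k-space and back
#'
#' `volume_to_kspace()` returns the discrete Fourier transform of a volume
#' with DC at the array centre. `kspace_to_volume()` inverts it; the inverse
#' is normalised by `source_n` (the number of samples actually acquired)
#' rather than the current array length, so that zero-fill interpolation
#' preserves image amplitudes.
#'
#' @param vol Numeric or complex array.
#' @param k Centred k-space array.
#' @param source_n Normalisation count for the inverse transform; defaults
#'   to `length(k)`.
#' @return Complex array.
#' @export
volume_to_kspace <- function(vol) {
  fftshift(fft(vol))
}

#' @rdname volume_to_kspace
#' @export
kspace_to_volume <- function(k, source_n = NULL) {
  fft(ifftshift(k), inverse = TRUE) / (source_n %||% length(k))
}

#' Centred zero-filling of k-space
#'
#' Embeds a centred k-space array in a larger zero-initialised array so
#' that the DC coefficient stays at the array centre. Padding is split as
#' `floor((target - source) / 2)` low-index rows and the remainder
#' high-index rows on each axis; with the DC-at-`floor(n/2)+1` convention
#' this keeps the embedding exactly invertible by [crop_kspace()]. Total
#' k-space energy is conserved (only zeros are added).
#'
#' @param k Centred k-space array.
#' @param target_matrix Target size per axis; each entry must be >= the
#'   corresponding source size.
#' @return Array of dimension `target_matrix`.
#' @export
zero_fill <- function(k, target_matrix) {
  d <- dim(k) %||% length(k)
  target <- as.integer(target_matrix)
  if (length(target) != length(d)) {
    stop_mq("`target_matrix` must give one size per axis")
  }
  if (any(target < d)) stop_mq("`target_matrix` must be >= the source size")
  if (all(target == d)) return(array(k, dim = d))
  out <- array(if (is.complex(k)) 0 + 0i else 0, dim = target)
  off <- floor((target - d) / 2)
  idx <- lapply(seq_along(d), function(a) off[a] + seq_len(d[a]))
  out <- do.call(`[<-`, c(list(out), idx, list(array(k, dim = d))))
  out
}

#' @rdname zero_fill
#' @param target_matrix For `crop_kspace()`, the size to crop back to;
#'   `crop_kspace(zero_fill(k, m), dim(k))` is the identity.
#' @export
crop_kspace <- function(k, target_matrix) {
  d <- dim(k) %||% length(k)
  target <- as.integer(target_matrix)
  if (any(target > d)) stop_mq("`target_matrix` must be <= the source size")
  off <- floor((d - target) / 2)
  idx <- lapply(seq_along(d), function(a) off[a] + seq_len(target[a]))
  do.call(`[`, c(list(array(k, dim = d)), idx, list(drop = FALSE)))
}

#' Zero-fill interpolation of an image volume
#'
#' Transforms a volume to k-space, zero-fills to `target_matrix` and
#' transforms back, normalising by the source sample count so grid-aligned
#' features keep their magnitude. Returns the magnitude image.
#'
#' @param vol Numeric array.
#' @param target_matrix Target grid per axis.
#' @return Numeric (magnitude) array of dimension `target_matrix`.
#' @export
zero_fill_volume <- function(vol, target_matrix) {
  k <- volume_to_kspace(vol)
  Mod(kspace_to_volume(zero_fill(k, target_matrix), source_n = length(vol)))
}

#' Select or combine echoes into one analysis volume
#'
#' The hypointensity statistic operates on a single T2*-weighted volume.
#' The default is the last echo (TE = 22.5 ms under the default
#' acquisition), where T2* hypointensity contrast is strongest; the mean
#' across echoes or their root-sum-of-squares are available as alternatives.
#'
#' @param series An `echo_series` from [simulate_mge3d()] or a 4D array
#'   (x, y, z, echo).
#' @param echo Echo selector for `combine = "single"`: an index or
#'   `"last"`.
#' @param combine `"single"`, `"mean"` or `"sos"`.
#' @return 3D numeric array.
#' @export
select_echo <- function(series, echo = "last",
                        combine = c("single", "mean", "sos")) {
  combine <- match.arg(combine)
  data <- if (inherits(series, "echo_series")) series$data else series
  d <- dim(data)
  if (length(d) != 4L) stop_mq("`series` must be a 4D (x, y, z, echo) array")
  n_echo <- d[4]
  if (combine == "single") {
    idx <- if (identical(echo, "last")) n_echo else as.integer(echo)
    if (is.na(idx) || idx < 1L || idx > n_echo) {
      stop_mq(sprintf("echo index %s out of range 1..%d", echo, n_echo))
    }
    return(array(data[, , , idx], dim = d[1:3]))
  }
  if (combine == "mean") {
    out <- array(0, dim = d[1:3])
    for (i in seq_len(n_echo)) out <- out + data[, , , i]
    return(out / n_echo)
  }
  sqrt_sos(data, axis = 4L)
}
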