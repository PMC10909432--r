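#' Multi-gradient-echo acquisition parameters
#'
#' Container for the parameters of a 3D multi-gradient-echo (MGE3D)
#' T2*-weighted acquisition. Defaults reproduce the in vivo protocol the
#' quantification was designed around: TR = 32.55 ms, first TE = 2.5 ms,
#' echo spacing 4 ms, 6 echoes, flip angle 13 degrees, acquired matrix
#' 256 x 192 x 192 zero-filled to 256^3, FOV 22.5 mm isotropic.
#'
#' @param tr Repetition time in seconds.
#' @param te_first First echo time in seconds.
#' @param te_spacing Echo spacing in seconds.
#' @param n_echoes Number of echoes (>= 1).
#' @param flip_angle Excitation flip angle in degrees.
#' @param matrix_size Acquired matrix size, 3 integers.
#' @param recon_matrix Reconstructed matrix after zero-filling, 3 integers,
#'   componentwise >= `matrix_size`.
#' @param fov_mm Field of view in mm per axis.
#'
#' @return An object of class `acq_params`.
#' @examples
#' acq <- acq_params()
#' echo_times(acq) * 1000  # 2.5 6.5 10.5 14.5 18.5 22.5 ms
#' @export
acq_params <- function(tr = 0.03255, te_first = 0.0025, te_spacing = 0.004,
                       n_echoes = 6L, flip_angle = 13,
                       matrix_size = c(256L, 192L, 192L),
                       recon_matrix = c(256L, 256L, 256L),
                       fov_mm = c(22.5, 22.5, 22.5)) {
  assert_scalar_pos(tr, "tr")
  assert_scalar_pos(te_first, "te_first")
  assert_scalar_pos(te_spacing, "te_spacing")
  n_echoes <- as.integer(n_echoes)
  if (n_echoes < 1L) stop_mq("`n_echoes` must be >= 1")
  if (length(matrix_size) != 3L || length(recon_matrix) != 3L) {
    stop_mq("`matrix_size` and `recon_matrix` must each have 3 entries")
  }
  if (any(recon_matrix < matrix_size)) {
    stop_mq("`recon_matrix` must be >= `matrix_size` on every axis")
  }
  structure(
    list(tr = tr, te_first = te_first, te_spacing = te_spacing,
         n_echoes = n_echoes, flip_angle = flip_angle,
         matrix_size = as.integer(matrix_size),
         recon_matrix = as.integer(recon_matrix),
         fov_mm = as.numeric(fov_mm)),
    class = "acq_params")
}

#' Echo times of an acquisition
#'
#' @param acq An [acq_params()] object.
#' @return Numeric vector of echo times in seconds,
#'   `te_first + (i - 1) * te_spacing`.
#' @export
echo_times <- function(acq) {
  stopifnot(inherits(acq, "acq_params"))
  acq$te_first + (seq_len(acq$n_echoes) - 1) * acq$te_spacing
}

#' @export
print.acq_params <- function(x, ...) {
  cat(sprintf(
    "MGE3D acquisition: TR %.4g ms, TE %s ms, FA %g deg, matrix %s -> %s\n",
    x$tr * 1000, paste(format(echo_times(x) * 1000), collapse = "/"),
    x$flip_angle, paste(x$matrix_size, collapse = "x"),
    paste(x$recon_matrix, collapse = "x")))
  invisible(x)
}
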