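#' Spoiled gradient-echo steady-state signal
#'
#' Noiseless magnitude signal of a spoiled gradient-recalled echo at one
#' echo time:
#' `S(TE) = PD * sin(FA) * (1 - E1) / (1 - cos(FA) * E1) * exp(-TE * R2*)`
#' with `E1 = exp(-TR / T1)`.
#'
#' @param r2star Effective transverse relaxation rate in 1/s (scalar or
#'   array).
#' @param te Echo time in seconds.
#' @param tr Repetition time in seconds (> 0).
#' @param t1 Longitudinal relaxation time in seconds (> 0).
#' @param flip_angle Flip angle in degrees.
#' @param proton_density Proton density, arbitrary units.
#' @return Signal in the shape of `r2star`.
#' @export
spgr_signal <- function(r2star, te, tr, t1, flip_angle, proton_density = 1) {
  assert_scalar_pos(tr, "tr")
  assert_scalar_pos(t1, "t1")
  fa <- flip_angle * pi / 180
  e1 <- exp(-tr / t1)
  base <- proton_density * sin(fa) * (1 - e1) / (1 - cos(fa) * e1)
  base * exp(-te * r2star)
}

#' Add Rician noise to a magnitude volume
#'
#' Magnitude-image noise model: each voxel value `s` is replaced by
#' `sqrt((s + n1)^2 + n2^2)` with `n1, n2 ~ Normal(0, sigma)`, the
#' magnitude of complex Gaussian noise added to a real signal. `sigma = 0`
#' returns the input unchanged.
#'
#' @param x Numeric array of noiseless magnitudes.
#' @param sigma Noise standard deviation per quadrature channel (>= 0).
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @return Array of the same shape.
#' @export
add_rician_noise <- function(x, sigma, seed = NULL) {
  assert_scalar_pos(sigma, "sigma", strict = FALSE)
  if (sigma == 0) return(x)
  with_seed_or_current(seed, {
    n1 <- rnorm(length(x), 0, sigma)
    n2 <- rnorm(length(x), 0, sigma)
    out <- sqrt((x + n1)^2 + n2^2)
    array(out, dim = dim(x) %||% length(x))
  })
}

#' Simulate a multi-gradient-echo acquisition of a phantom state
#'
#' Evaluates the spoiled gradient-echo signal of one R2* map at every echo
#' time of `acq` and corrupts each echo volume with Rician noise. SNR is
#' defined against the noiseless mean signal of the reference region
#' (normally the contralateral striatum) at the first echo:
#' `sigma = mean(S_echo1[reference]) / snr`. `snr = Inf` gives a noiseless
#' series. This is where the hypointensity detection threshold is later
#' estimated, so simulated SNR and detection operate on the same footing.
#'
#' @param r2star R2* map in 1/s (3D array), e.g. one state of
#'   [generate_phantom()].
#' @param acq An [acq_params()] object.
#' @param t1 Tissue T1 in seconds.
#' @param proton_density Proton density, arbitrary units.
#' @param snr Signal-to-noise ratio (> 0, may be `Inf`).
#' @param seed Optional integer seed for the noise.
#' @param reference_mask Logical array selecting the SNR reference region;
#'   defaults to the whole volume.
#' @return An object of class `echo_series`: list with `data` (4D array,
#'   x-y-z-echo), `te` (seconds), `sigma` (noise SD used) and `acq`.
#' @examples
#' acq <- acq_params()
#' r2 <- array(25, dim = c(8, 8, 8))
#' es <- simulate_mge3d(r2, acq, t1 = 1.7, snr = Inf)
#' dim(es$data)
#' @export
simulate_mge3d <- function(r2star, acq, t1 = 1.7, proton_density = 100,
                           snr = Inf, seed = NULL, reference_mask = NULL) {
  stopifnot(inherits(acq, "acq_params"))
  assert_scalar_pos(t1, "t1")
  assert_scalar_pos(snr, "snr")
  d <- dim(r2star)
  if (length(d) != 3L) stop_mq("`r2star` must be a 3D array")
  te <- echo_times(acq)
  data <- array(0, dim = c(d, acq$n_echoes))
  for (i in seq_along(te)) {
    data[, , , i] <- spgr_signal(r2star, te[i], acq$tr, t1,
                                 acq$flip_angle, proton_density)
  }
  sigma <- 0
  if (is.finite(snr)) {
    ref <- if (is.null(reference_mask)) rep(TRUE, prod(d)) else {
      if (!identical(dim(reference_mask), d)) {
        stop_mq("`reference_mask` does not match the phantom grid")
      }
      reference_mask
    }
    first <- data[, , , 1, drop = FALSE]
    sigma <- mean(first[ref]) / snr
    data <- add_rician_noise(data, sigma, seed = seed)
  }
  structure(list(data = data, te = te, sigma = sigma, acq = acq),
            class = "echo_series")
}

#' @export
print.echo_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("echo_series: %s voxels x %d echoes (TE %s ms), sigma = %.4g\n",
              paste(d[1:3], collapse = "x"), d[4],
              paste(format(x$te * 1000), collapse = "/"), x$sigma))
  invisible(x)
}
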