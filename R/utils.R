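#' @keywords internal
"_PACKAGE"

## Small shared helpers.  Conventions used throughout the package:
##  - FIDs are complex vectors sampled at t_n = n / spectral_width, n = 0..N-1.
##  - Spectra are fftshift(fft(fid)) on an ascending ppm axis
##    ppm = ref_ppm + f / larmor_freq with f in Hz.

fftshift <- function(x) {
  n <- length(x)
  c(x[(n %/% 2 + 1):n], x[1:(n %/% 2)])
}

ifftshift <- function(x) {
  n <- length(x)
  c(x[(n - n %/% 2 + 1):n], x[1:(n - n %/% 2)])
}

#' Acquisition parameters for a simulated MRS experiment
#'
#' @param larmor_freq Proton resonance frequency in MHz (default 127.73,
#'   i.e. 3 T).
#' @param spectral_width Sampling bandwidth in Hz.
#' @param n_points Number of complex FID samples; must be a power of two.
#' @param ref_ppm Chemical shift of the carrier (water, 4.70 ppm).
#' @return An object of class `acq_params`.
#' @export
acq_params <- function(larmor_freq = 127.73, spectral_width = 2000,
                       n_points = 2048, ref_ppm = 4.70) {
  stopifnot(larmor_freq > 0, spectral_width > 0, n_points >= 2)
  if (bitwAnd(n_points, n_points - 1L) != 0L)
    stop("n_points must be a power of two")
  structure(list(larmor_freq = larmor_freq, spectral_width = spectral_width,
                 n_points = as.integer(n_points), ref_ppm = ref_ppm),
            class = "acq_params")
}

#' Time axis (s) for an acquisition
#' @param acq An [acq_params()] object.
#' @return Numeric vector of sample times starting at 0.
#' @export
time_axis <- function(acq) {
  (seq_len(acq$n_points) - 1) / acq$spectral_width
}

#' Chemical-shift axis (ppm, ascending) for an acquisition
#' @param acq An [acq_params()] object.
#' @return Numeric vector of length `n_points`.
#' @export
ppm_axis <- function(acq) {
  n <- acq$n_points
  f <- (seq_len(n) - 1 - n %/% 2) * acq$spectral_width / n
  acq$ref_ppm + f / acq$larmor_freq
}

same_acq <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b)))
}

## Derive a reproducible child seed below 2^31 from a base seed and a tag.
child_seed <- function(seed, tag) {
  s <- sum(utf8ToInt(as.character(tag))) * 2654435761
  as.integer((as.numeric(seed) * 69069 + s) %% 2147483647)
}
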