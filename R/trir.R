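#' Azide reporter band model
#'
#' Gaussian absorption band of the azide stretch whose center red-shifts
#' linearly with the local vibrational energy: at sensor energy `E` the band
#' sits at `nu0 - c_nu * E`. The difference signal of a shift much smaller
#' than the width is proportional to the shift, which is the regime the
#' analysis assumes.
#'
#' @param nu0 band center (cm^-1, default 2120).
#' @param sigma Gaussian standard deviation (cm^-1).
#' @param amplitude peak absorbance (mOD).
#' @param c_nu red-shift coefficient (cm^-1 per unit sensor energy).
#' @return An object of class `band_model`.
#' @export
band_model <- function(nu0 = 2120, sigma = 8, amplitude = 10, c_nu = 1) {
  if (sigma <= 0) stop("band width sigma must be > 0")
  if (amplitude <= 0) stop("band amplitude must be > 0")
  structure(list(nu0 = nu0, sigma = sigma, amplitude = amplitude, c_nu = c_nu),
            class = "band_model")
}

band_profile <- function(band, nu, center = band$nu0)
  band$amplitude * exp(-(nu - center)^2 / (2 * band$sigma^2))

new_spectrum2d <- function(wavenumbers, delays, dA) {
  if (is.unsorted(wavenumbers, strictly = TRUE) &&
      is.unsorted(rev(wavenumbers), strictly = TRUE))
    stop("wavenumbers must be strictly monotone")
  if (!all(is.finite(dA))) stop("non-finite spectrum values")
  structure(list(wavenumbers = wavenumbers, delays = delays, dA = dA),
            class = "spectrum2d")
}

#' @export
print.spectrum2d <- function(x, ...) {
  cat(sprintf("<spectrum2d> %d pixels (%.1f..%.1f cm-1) x %d delays (%.3g..%.3g ps)\n",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers),
              length(x$delays), min(x$delays), max(x$delays)))
  invisible(x)
}

#' Synthesize a transient IR difference spectrum
#'
#' Forward model of the pump-probe difference map: at each delay the reporter
#' band is red-shifted by `c_nu * E(t)` and the pump-off band subtracted,
#' `dA(nu, t) = band(nu; nu0 - c_nu E(t)) - band(nu; nu0)`, sampled on the
#' detector pixels, plus optional white noise. A pure band shift conserves
#' the integrated area, producing the characteristic positive lobe on the
#' low-wavenumber side and negative lobe on the high side.
#'
#' @param band a [band_model].
#' @param sensor_energy data.frame with columns `time` (ps) and `energy`
#'   (e.g. from [sensor_transient()]).
#' @param wavenumbers pixel wavenumber grid (cm^-1); default 32 pixels
#'   spanning +/- 2.5 sigma around the band center.
#' @param noise_sigma white-noise standard deviation (mOD).
#' @param seed RNG seed for the noise.
#' @return A `spectrum2d` (rows = delays, columns = pixels).
#' @export
synth_trir <- function(band, sensor_energy, wavenumbers = NULL,
                       noise_sigma = 0, seed = 1) {
  if (is.null(wavenumbers))
    wavenumbers <- seq(band$nu0 - 2.5 * band$sigma, band$nu0 + 2.5 * band$sigma,
                       length.out = 32)
  E <- sensor_energy$energy
  shift_max <- band$c_nu * max(abs(E))
  if (shift_max > 0.5 * band$sigma)
    warning("band shift is not small against the band width; difference signal no longer linear in the shift")
  dA <- vapply(seq_along(E), function(k)
    band_profile(band, wavenumbers, band$nu0 - band$c_nu * E[k]) -
      band_profile(band, wavenumbers),
    numeric(length(wavenumbers)))
  dA <- t(dA)  # delays x pixels
  if (noise_sigma > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    dA <- dA + matrix(rnorm(length(dA), sd = noise_sigma), nrow(dA), ncol(dA))
  }
  new_spectrum2d(wavenumbers, sensor_energy$time, dA)
}

#' Subtract a scaled reference spectrum
#'
#' Background subtraction (e.g. of the pure-solvent response) on identical
#' pixel/delay grids: `sample - scale * reference`.
#'
#' @param sample,reference `spectrum2d` objects on identical grids.
#' @param scale scaling of the reference.
#' @return A `spectrum2d`.
#' @export
background_subtract <- function(sample, reference, scale = 1) {
  if (!isTRUE(all.equal(sample$wavenumbers, reference$wavenumbers)) ||
      !isTRUE(all.equal(sample$delays, reference$delays)))
    stop("sample and reference grids differ")
  new_spectrum2d(sample$wavenumbers, sample$delays,
                 sample$dA - scale * reference$dA)
}

#' Extract the scalar VET transient from a difference spectrum
#'
#' Sums the absolute absorption changes over the pixels carrying the signal,
#' `S(t) = sum_pixels |dA(nu, t)|`, and locates its peak time by the same
#' quadratic interpolation used for residue-energy peaks. With
#' `pixel_window = "auto"` the window is all pixels whose time-averaged
#' `|dA|` exceeds 10% of the maximal pixel's.
#'
#' @param spectrum a `spectrum2d`.
#' @param pixel_window integer vector of pixel indices, or `"auto"`.
#' @return An object of class `vet_transient`: data.frame-backed list with
#'   `delays`, `signal` (mOD), `peak_time` (ps), `peak_signal`, `window`.
#' @export
vet_transient <- function(spectrum, pixel_window = "auto") {
  if (identical(pixel_window, "auto")) {
    m <- colMeans(abs(spectrum$dA))
    pixel_window <- which(m >= 0.1 * max(m))
  }
  if (length(pixel_window) == 0L) stop("empty pixel window")
  sig <- rowSums(abs(spectrum$dA[, pixel_window, drop = FALSE]))
  pk <- quad_peak(spectrum$delays, sig)
  structure(list(delays = spectrum$delays, signal = sig,
                 peak_time = unname(pk["time"]), peak_signal = unname(pk["value"]),
                 window = pixel_window),
            class = "vet_transient")
}

#' @export
print.vet_transient <- function(x, ...) {
  cat(sprintf("<vet_transient> %d delays; peak %.3f mOD at %.3f ps (%d pixels)\n",
              length(x$delays), x$peak_signal, x$peak_time, length(x$window)))
  invisible(x)
}

#' Write a 2D spectrum as CSV
#'
#' First row holds the pixel wavenumbers, first column the delays.
#' @param spectrum a `spectrum2d`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, file) {
  df <- data.frame(delay = spectrum$delays, spectrum$dA, check.names = FALSE)
  colnames(df) <- c("delay_ps", sprintf("%.3f", spectrum$wavenumbers))
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Read a 2D spectrum CSV written by [write_spectrum_csv()]
#' @param file path.
#' @return A `spectrum2d`.
#' @export
read_spectrum_csv <- function(file) {
  df <- read.csv(file, check.names = FALSE)
  new_spectrum2d(as.numeric(colnames(df)[-1]), df[[1]],
                 as.matrix(df[, -1, drop = FALSE]))
}
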