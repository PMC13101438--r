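# Pulse and spectrum calculations for spectral-focusing CARS.
#
# Conventions: wavelengths in nm, durations in fs (intensity FWHM), group
# delay dispersion in fs^2, Raman shifts in cm^-1. Pulses are Gaussian with
# time-bandwidth product 0.441 unless stated otherwise.

SPEED_OF_LIGHT <- 299792458  # m/s

#' Laser pulse description
#'
#' @param center_wavelength Center wavelength, nm.
#' @param spectral_fwhm Spectral intensity FWHM, nm (optional if a duration
#'   is given directly).
#' @param duration_fwhm Temporal intensity FWHM, fs; defaults to the
#'   transform-limited duration for the stated bandwidth.
#' @param tbp Time-bandwidth product (0.441 Gaussian, 0.315 sech^2).
#' @return An object of class `laser_pulse` with a resolved `duration_fwhm`.
#' @export
laser_pulse <- function(center_wavelength, spectral_fwhm = NULL,
                        duration_fwhm = NULL, tbp = 0.441) {
  if (center_wavelength <= 0) stopf("center_wavelength must be > 0")
  if (is.null(spectral_fwhm) && is.null(duration_fwhm))
    stopf("give spectral_fwhm or duration_fwhm")
  tl <- if (!is.null(spectral_fwhm))
    transform_limited_duration(spectral_fwhm, center_wavelength, tbp)
  else NA_real_
  if (is.null(duration_fwhm)) duration_fwhm <- tl
  if (!is.na(tl) && duration_fwhm < tl - 1e-9)
    stopf("duration (%.1f fs) below the transform limit (%.1f fs)",
          duration_fwhm, tl)
  structure(list(center_wavelength = center_wavelength,
                 spectral_fwhm = spectral_fwhm,
                 duration_fwhm = duration_fwhm,
                 transform_limit = tl, tbp = tbp),
            class = "laser_pulse")
}

#' Raman shift probed by a pump/Stokes wavelength pair
#'
#' `shift = 1e7 * (1/pump - 1/stokes)` in cm^-1 for wavelengths in nm. The
#' 805 / 1045 nm pair targets the symmetric CH2 stretch near 2845 cm^-1.
#'
#' @param pump_nm,stokes_nm Wavelengths in nm, `stokes_nm >= pump_nm`.
#' @return Raman shift in cm^-1.
#' @examples
#' raman_shift(805, 1045)  # ~2853 cm^-1
#' @export
raman_shift <- function(pump_nm, stokes_nm) {
  if (pump_nm <= 0) stopf("wavelengths must be > 0")
  if (stokes_nm < pump_nm) stopf("stokes wavelength must be >= pump")
  1e7 * (1 / pump_nm - 1 / stokes_nm)
}

#' Transform-limited pulse duration from spectral bandwidth
#'
#' `delta_nu = c * delta_lambda / lambda^2`, `tau = tbp / delta_nu`.
#'
#' @param spectral_fwhm_nm Spectral intensity FWHM, nm.
#' @param center_nm Center wavelength, nm.
#' @param tbp Time-bandwidth product; Gaussian default 0.441 (use 0.315 for
#'   sech^2 pulses).
#' @return Duration (intensity FWHM) in fs.
#' @examples
#' transform_limited_duration(9.0, 805)  # ~106 fs
#' @export
transform_limited_duration <- function(spectral_fwhm_nm, center_nm,
                                       tbp = 0.441) {
  if (spectral_fwhm_nm <= 0 || center_nm <= 0) stopf("inputs must be > 0")
  dnu <- SPEED_OF_LIGHT * (spectral_fwhm_nm * 1e-9) / (center_nm * 1e-9)^2
  tbp / dnu * 1e15
}

#' Group delay dispersion of a dispersive element
#'
#' `|phi2| = D * lambda^2 * L / (2 pi c)`; the sign (negative for the
#' glass-rod "negative chirp" configuration) is carried explicitly.
#'
#' @param dispersion_ps_nm_km Dispersion parameter D, ps/(nm km).
#' @param length_cm Material length, cm.
#' @param wavelength_nm Wavelength, nm.
#' @param sign +1 or -1 chirp sign (default -1).
#' @return Signed GDD in fs^2.
#' @examples
#' group_delay_dispersion(103, 19.6, 805)  # ~ -6.9e3 fs^2
#' @export
group_delay_dispersion <- function(dispersion_ps_nm_km, length_cm,
                                   wavelength_nm, sign = -1) {
  if (length_cm < 0) stopf("length must be >= 0")
  D <- dispersion_ps_nm_km * 1e-12 / (1e-9 * 1e3)   # s/m^2
  lam <- wavelength_nm * 1e-9
  L <- length_cm * 1e-2
  phi2 <- D * lam^2 * L / (2 * pi * SPEED_OF_LIGHT)  # s^2
  sign * abs(phi2) * 1e30                            # fs^2
}

#' Duration of a Gaussian pulse after dispersive stretching
#'
#' Gaussian chirp law `tau_out = tau * sqrt(1 + (4 ln2 phi2 / tau^2)^2)`;
#' always >= the input duration, with equality iff the GDD is zero.
#'
#' @param tl_duration_fs Transform-limited (input) duration, fs.
#' @param gdd_fs2 Group delay dispersion, fs^2 (sign irrelevant).
#' @return List with `duration_fs` and `stretch_factor`.
#' @export
chirped_duration <- function(tl_duration_fs, gdd_fs2) {
  if (tl_duration_fs <= 0) stopf("tl_duration_fs must be > 0")
  f <- sqrt(1 + (4 * log(2) * abs(gdd_fs2) / tl_duration_fs^2)^2)
  list(duration_fs = tl_duration_fs * f, stretch_factor = f)
}

#' Read a two-column Raman spectrum from text
#'
#' Whitespace- or comma-separated columns: wavenumber (cm^-1, ascending) and
#' intensity.
#'
#' @param path File path.
#' @return Data frame with columns `wavenumber`, `intensity`.
#' @export
read_spectrum <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  x <- utils::read.table(path, sep = sep, header = grepl("[A-Za-z]", first))
  x <- x[, 1:2]
  names(x) <- c("wavenumber", "intensity")
  if (any(diff(x$wavenumber) <= 0))
    stopf("wavenumber axis must be strictly increasing")
  x
}

#' Peak FWHM of a spectrum after baseline correction
#'
#' Subtracts a linear baseline fitted to the flanking points outside
#' `window`, normalizes the in-window peak to 1, and returns the full width
#' at half maximum from linearly interpolated half-maximum crossings.
#'
#' @param spectrum Data frame with ascending `wavenumber` (cm^-1) and
#'   `intensity` columns.
#' @param window Length-2 numeric, cm^-1 window containing the peak
#'   (default the CH stretching region 2800-3100 cm^-1).
#' @return FWHM in cm^-1. Errors if no half-maximum crossing lies inside the
#'   window (non-peaked spectrum).
#' @export
spectral_fwhm <- function(spectrum, window = c(2800, 3100)) {
  wn <- spectrum$wavenumber
  it <- spectrum$intensity
  if (any(!is.finite(it)) || any(diff(wn) <= 0))
    stopf("spectrum must have finite intensities on an ascending axis")
  if (window[1] < min(wn) || window[2] > max(wn))
    stopf("window outside the spectrum's wavenumber range")
  flank <- wn < window[1] | wn > window[2]
  if (sum(flank) >= 2) {
    base <- stats::lm(it[flank] ~ wn[flank])
    it <- it - (stats::coef(base)[1] + stats::coef(base)[2] * wn)
  }
  inw <- wn >= window[1] & wn <= window[2]
  wni <- wn[inw]; iti <- it[inw]
  pk <- which.max(iti)
  if (max(iti) <= 0) stopf("no peak inside the window")
  iti <- iti / max(iti)
  half <- 0.5
  cross <- function(ord) {
    # walk outward from the peak; interpolate the first drop below half-max
    j <- which(iti[ord] < half)[1]
    if (is.na(j) || j == 1) return(NA_real_)
    i_hi <- ord[j - 1]; i_lo <- ord[j]
    wni[i_lo] + (half - iti[i_lo]) * (wni[i_hi] - wni[i_lo]) /
      (iti[i_hi] - iti[i_lo])
  }
  left <- cross(pk:1)
  right <- cross(pk:length(wni))
  if (is.na(left) || is.na(right))
    stopf("no half-maximum crossing inside the window (non-peaked spectrum)")
  abs(right - left)
}

#' CARS delay-scan cross-correlation of two pulses
#'
#' Models the delay dependence of the total CARS intensity,
#' `I(tau) proportional to integral I_pump(t)^2 * I_stokes(t - tau) dt`
#' (two pump photons, one Stokes photon), for Gaussian intensity envelopes
#' with the pulses' resolved durations. Evaluated by trapezoidal
#' integration on a dense time grid and normalized to peak 1.
#'
#' @param pump,stokes [laser_pulse()] objects with resolved durations.
#' @param delays Numeric vector of delays, fs (non-empty).
#' @return Data frame with columns `delay_fs`, `intensity`.
#' @export
cross_correlation_scan <- function(pump, stokes, delays) {
  stopifnot(inherits(pump, "laser_pulse"), inherits(stokes, "laser_pulse"))
  if (length(delays) == 0) stopf("delay grid is empty")
  tp <- pump$duration_fwhm; ts <- stokes$duration_fwhm
  k <- 4 * log(2)
  span <- 3 * (tp + ts) + max(abs(delays))
  t <- seq(-span, span, length.out = 4001)
  dt <- t[2] - t[1]
  ip2 <- exp(-2 * k * t^2 / tp^2)            # pump intensity squared
  inten <- vapply(delays, function(tau) {
    is_ <- exp(-k * (t - tau)^2 / ts^2)
    sum((ip2 * is_)[-1] + (ip2 * is_)[-length(t)]) * dt / 2
  }, numeric(1))
  data.frame(delay_fs = delays, intensity = inten / max(inten))
}
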