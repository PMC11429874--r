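#' Single-fluorophore intensity model
#'
#' The integrated intensity of a single membrane-bound fluorophore imaged in
#' TIRF is well described by a lognormal law; `fluorophore_model()` bundles
#' its parameters together with the per-frame photobleaching probability.
#'
#' @param log_mean Mean of the log-intensity (log ADU). Default `log(500)`.
#' @param log_sd Standard deviation of the log-intensity. Default `0.3`.
#' @param bleach_rate Per-frame probability that a fluorophore bleaches,
#'   in `[0, 1]`. Default `0` (no bleaching).
#' @return An object of class `fluorophore_model`.
#' @examples
#' fm <- fluorophore_model(log_mean = log(500), log_sd = 0.3)
#' @export
fluorophore_model <- function(log_mean = log(500), log_sd = 0.3,
                              bleach_rate = 0) {
  stopifnot(is.numeric(log_mean), length(log_mean) == 1L, is.finite(log_mean))
  if (!is.numeric(log_sd) || length(log_sd) != 1L || log_sd < 0)
    stop("`log_sd` must be a single non-negative number")
  if (!is.numeric(bleach_rate) || length(bleach_rate) != 1L ||
      bleach_rate < 0 || bleach_rate > 1)
    stop("`bleach_rate` must be a single probability in [0, 1]")
  structure(list(log_mean = log_mean, log_sd = log_sd,
                 bleach_rate = bleach_rate),
            class = "fluorophore_model")
}

#' Camera acquisition model
#'
#' Describes an sCMOS-style detector: a constant digital offset, Gaussian
#' read noise and a linear gain mapping photoelectrons to analog-digital
#' units (ADU). Pixel values are clipped to the detector bit depth.
#'
#' @param offset Digital offset, ADU. Default 100.
#' @param read_noise_sd Read-noise standard deviation, ADU. Default 1.6.
#' @param gain ADU per photoelectron. Default 1.
#' @param bit_depth Integer bit depth, 12 or 16. Default 16.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(offset = 100, read_noise_sd = 1.6, gain = 1,
                         bit_depth = 16) {
  stopifnot(offset >= 0, read_noise_sd >= 0, gain > 0,
            bit_depth %in% c(8L, 12L, 16L))
  structure(list(offset = offset, read_noise_sd = read_noise_sd,
                 gain = gain, bit_depth = as.integer(bit_depth)),
            class = "camera_model")
}

#' TIRF scene geometry and acquisition settings
#'
#' Defaults reflect a 100x/1.45 NA objective with a 1.5x magnifier and a
#' 6.5 um camera pixel at 2x binning (0.0867 um/pixel), and a PSF standard
#' deviation of 0.09 um (Airy diameter 0.21 um ~ 2.33 sigma).
#'
#' @param field_size Field of view in um; scalar (square) or length-2 vector.
#' @param pixel_size Pixel pitch, um. Default 0.0867.
#' @param psf_sigma PSF Gaussian sigma, um. Default 0.09.
#' @param background Background fluorescence level, ADU. Default 20.
#' @param frame_interval Time between frames, seconds. Default 0.05 (20 Hz).
#' @param n_frames Number of frames. Default 1.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(field_size = 13.005, pixel_size = 0.0867,
                       psf_sigma = 0.09, background = 20,
                       frame_interval = 0.05, n_frames = 1L) {
  stopifnot(pixel_size > 0, psf_sigma > 0, n_frames >= 1, background >= 0,
            frame_interval > 0)
  if (length(field_size) == 1L) field_size <- c(field_size, field_size)
  stopifnot(all(field_size > 0))
  dim_px <- pmax(1L, as.integer(round(field_size / pixel_size)))
  structure(list(field_size = dim_px * pixel_size, pixel_size = pixel_size,
                 psf_sigma = psf_sigma, background = background,
                 frame_interval = frame_interval,
                 n_frames = as.integer(n_frames),
                 dim_px = dim_px),
            class = "scene_spec")
}

#' Two-phase kinetic parameter set
#'
#' Parameters of the cooperative synthesis/degradation model used for
#' biosensor translocation time courses. Rate constants are exact
#' reciprocals of the characteristic times: `k_syn = 1/tau_syn`,
#' `k_deg = 1/tau_deg`.
#'
#' @param F0 Pre-stimulus level (dimensionless). Default 0.
#' @param Fmax Amplitude of the response (dimensionless). Default 1.
#' @param n_syn,n_deg Hill coefficients of the synthesis and degradation
#'   phases; must be positive. Default 2.
#' @param tau_syn,tau_deg Characteristic times, minutes; must be positive.
#' @param ci95 Optional named list of per-parameter `c(lo, hi)` intervals.
#' @return An object of class `kinetic_params` with derived `k_syn`, `k_deg`.
#' @examples
#' kp <- kinetic_params(tau_syn = 1 / 1.09, tau_deg = 1 / 0.34)
#' kp$k_syn # 1.09
#' @export
kinetic_params <- function(F0 = 0, Fmax = 1, n_syn = 2, n_deg = 2,
                           tau_syn = 1 / 1.09, tau_deg = 1 / 0.34,
                           ci95 = NULL) {
  if (tau_syn <= 0 || tau_deg <= 0) stop("tau_syn and tau_deg must be > 0")
  if (n_syn <= 0 || n_deg <= 0) stop("n_syn and n_deg must be > 0")
  structure(list(F0 = F0, Fmax = Fmax, n_syn = n_syn, n_deg = n_deg,
                 tau_syn = tau_syn, tau_deg = tau_deg,
                 k_syn = 1 / tau_syn, k_deg = 1 / tau_deg, ci95 = ci95),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Two-phase kinetic parameters\n")
  cat(sprintf("  Fmax = %.4g, F0 = %.4g\n", x$Fmax, x$F0))
  cat(sprintf("  synthesis:   n = %.3g, tau = %.4g min, k = %.4g min^-1\n",
              x$n_syn, x$tau_syn, x$k_syn))
  cat(sprintf("  degradation: n = %.3g, tau = %.4g min, k = %.4g min^-1\n",
              x$n_deg, x$tau_deg, x$k_deg))
  if (!is.null(x$ci95)) {
    for (nm in names(x$ci95))
      cat(sprintf("  95%% CI %-8s [%.4g, %.4g]\n", nm,
                  x$ci95[[nm]][1], x$ci95[[nm]][2]))
  }
  invisible(x)
}

#' Time series container for translocation traces
#'
#' @param t Time in minutes, strictly increasing; stimulus at t = 0,
#'   pre-stimulus samples carry negative t.
#' @param value Normalized fluorescence or molecule density per 100 um^2.
#' @param se Optional per-point standard errors (used as fit weights).
#' @param n_cells Optional number of cells averaged per point.
#' @return A `time_series` object (data.frame-like list).
#' @export
time_series <- function(t, value, se = NULL, n_cells = NULL) {
  stopifnot(is.numeric(t), is.numeric(value), length(t) == length(value))
  if (is.unsorted(t, strictly = TRUE)) stop("`t` must be strictly increasing")
  if (!is.null(se)) stopifnot(length(se) == length(t), all(se >= 0))
  structure(list(t = as.numeric(t), value = as.numeric(value),
                 se = se, n_cells = n_cells),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("time_series: %d points, t in [%.3g, %.3g] min\n",
              length(x$t), min(x$t), max(x$t)))
  invisible(x)
}

#' @export
as.data.frame.time_series <- function(x, ...) {
  out <- data.frame(t = x$t, value = x$value)
  if (!is.null(x$se)) out$se <- x$se
  out
}
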