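#' Sample single-fluorophore spot intensities
#'
#' Draws i.i.d. integrated spot intensities from the lognormal
#' single-fluorophore law of a [fluorophore_model()].
#'
#' @param n Number of draws (>= 0).
#' @param model A [fluorophore_model()].
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of `n` intensities (ADU).
#' @export
sample_fluorophore_intensities <- function(n, model = fluorophore_model(),
                                           seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n))
    stop("`n` must be a single non-negative integer")
  stopifnot(inherits(model, "fluorophore_model"))
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(numeric(0))
  stats::rlnorm(n, meanlog = model$log_mean, sdlog = model$log_sd)
}

#' Sample intensities from a mixture of c-mer spots
#'
#' Each spot's oligomeric order c is drawn from `proportions`; a c-mer
#' intensity is the sum of c independent single-fluorophore draws (physical
#' emitter model: c fluorophores in one diffraction-limited punctum).
#'
#' @param n Number of spots.
#' @param proportions Simplex vector of length M; `proportions[c]` is the
#'   probability that a spot contains c fluorophores.
#' @param model A [fluorophore_model()].
#' @param seed Optional integer seed.
#' @return A list with numeric `intensities` and integer `orders`.
#' @examples
#' s <- sample_multimer_intensities(1000, c(0.98, 0.02, 0), seed = 1)
#' mean(s$orders == 1)
#' @export
sample_multimer_intensities <- function(n, proportions,
                                        model = fluorophore_model(),
                                        seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n))
    stop("`n` must be a single non-negative integer")
  check_simplex(proportions)
  if (!is.null(seed)) set.seed(seed)
  M <- length(proportions)
  if (n == 0) return(list(intensities = numeric(0), orders = integer(0)))
  orders <- sample.int(M, size = n, replace = TRUE, prob = proportions)
  total <- sum(orders)
  mono <- stats::rlnorm(total, meanlog = model$log_mean, sdlog = model$log_sd)
  grp <- rep.int(seq_len(n), orders)
  intensities <- as.numeric(rowsum(mono, grp, reorder = TRUE))
  list(intensities = intensities, orders = as.integer(orders))
}

check_simplex <- function(p, tol = 1e-9) {
  if (!is.numeric(p) || length(p) < 1L || any(p < -tol) ||
      abs(sum(p) - 1) > tol)
    stop("`proportions` must be non-negative and sum to 1")
  invisible(TRUE)
}

#' Render one TIRF camera frame from ground-truth spots
#'
#' Each spot is an integrated symmetric 2D Gaussian whose pixel sums equal
#' the spot's total intensity (up to truncation at the field edges).
#' A constant background is added, Poisson shot noise is applied to the
#' expected photoelectron image, Gaussian read noise and the camera offset
#' are added, and the result is clipped to the detector bit depth.
#'
#' @param truth Data frame with columns `x_um`, `y_um`, `intensity`
#'   (total integrated ADU). May have zero rows.
#' @param scene A [scene_spec()].
#' @param camera A [camera_model()].
#' @param seed Optional integer seed.
#' @param shot_noise,read_noise Logical switches for the two noise sources
#'   (both `TRUE` by default); disabling both gives the noiseless expectation.
#' @return Numeric matrix (rows = y, cols = x) of pixel values in ADU.
#' @export
render_frame <- function(truth, scene = scene_spec(),
                         camera = camera_model(), seed = NULL,
                         shot_noise = TRUE, read_noise = TRUE) {
  stopifnot(inherits(scene, "scene_spec"), inherits(camera, "camera_model"))
  if (is.null(truth)) truth <- data.frame(x_um = numeric(0),
                                          y_um = numeric(0),
                                          intensity = numeric(0))
  if (!is.null(seed)) set.seed(seed)
  nx <- scene$dim_px[1]; ny <- scene$dim_px[2]
  if (nrow(truth) > 0) {
    if (any(truth$x_um < 0 | truth$x_um > scene$field_size[1] |
            truth$y_um < 0 | truth$y_um > scene$field_size[2]))
      stop("spot positions must lie inside the field")
  }
  img <- matrix(scene$background, nrow = ny, ncol = nx)
  s_px <- scene$psf_sigma / scene$pixel_size
  for (i in seq_len(nrow(truth))) {
    xc <- truth$x_um[i] / scene$pixel_size
    yc <- truth$y_um[i] / scene$pixel_size
    # only render a window of +/- 5 sigma around the spot
    r <- ceiling(5 * s_px)
    jx <- max(1L, floor(xc) - r):min(nx, ceiling(xc) + r)
    jy <- max(1L, floor(yc) - r):min(ny, ceiling(yc) + r)
    fx <- stats::pnorm(jx, mean = xc, sd = s_px) -
      stats::pnorm(jx - 1, mean = xc, sd = s_px)
    fy <- stats::pnorm(jy, mean = yc, sd = s_px) -
      stats::pnorm(jy - 1, mean = yc, sd = s_px)
    img[jy, jx] <- img[jy, jx] + truth$intensity[i] * outer(fy, fx)
  }
  if (shot_noise) {
    electrons <- img / camera$gain
    img <- matrix(stats::rpois(length(electrons), lambda = electrons),
                  nrow = ny) * camera$gain
  }
  img <- img + camera$offset
  if (read_noise && camera$read_noise_sd > 0)
    img <- img + matrix(stats::rnorm(length(img), sd = camera$read_noise_sd),
                        nrow = ny)
  vmax <- 2^camera$bit_depth - 1
  img[img < 0] <- 0
  img[img > vmax] <- vmax
  img
}

#' Simulate a stimulus-driven single-molecule time-lapse scene
#'
#' The expected molecule count in frame j (time t_j, minutes, stimulus at
#' t = 0) is `area * (baseline + peak_delta * Fhat(t_j)) / 100`, where
#' `Fhat` is the two-phase kinetic model rescaled so its peak equals 1
#' (so the peak expected density is `baseline + peak_delta`). With a
#' positive `bleach_rate` the expectation is further attenuated by the
#' survival factor `(1 - bleach_rate)^j`, the marginal law of per-spot
#' geometric photobleaching. Realized counts are Poisson; spots are placed
#' uniformly with fresh single-fluorophore intensities each frame
#' (densities are counted, molecules are not tracked).
#'
#' @param kinetics A [kinetic_params()] object defining the response shape.
#' @param baseline_density Pre-stimulus density, molecules per 100 um^2.
#' @param peak_delta_density Peak increase over baseline, per 100 um^2.
#' @param scene A [scene_spec()]; `frame_interval` is in seconds.
#' @param model A [fluorophore_model()]; its `bleach_rate` drives decay.
#' @param stimulus_frame 1-based frame index at which t = 0. Default 1.
#' @param seed Optional integer seed.
#' @param render If `TRUE` (default) camera frames are rendered; if
#'   `FALSE` only the ground truth is returned (fast).
#' @param camera A [camera_model()] used when rendering.
#' @return A list with `frames` (list of matrices or `NULL`), `truth`
#'   (data frame: frame, t_min, x_um, y_um, intensity, order),
#'   `expected_density` (per-frame expected molecules per 100 um^2),
#'   `t_min`, and the generating `kinetics`.
#' @export
simulate_timecourse_scene <- function(kinetics = kinetic_params(),
                                      baseline_density = 5,
                                      peak_delta_density = 20,
                                      scene = scene_spec(),
                                      model = fluorophore_model(),
                                      stimulus_frame = 1L,
                                      seed = NULL, render = TRUE,
                                      camera = camera_model()) {
  stopifnot(baseline_density >= 0, peak_delta_density >= 0,
            stimulus_frame >= 1, stimulus_frame <= scene$n_frames)
  if (!is.null(seed)) set.seed(seed)
  area <- prod(scene$field_size)
  nfr <- scene$n_frames
  t_min <- (seq_len(nfr) - stimulus_frame) * scene$frame_interval / 60
  fhat <- two_phase_model(t_min, kinetics)
  pk <- peak_response(kinetics)
  fhat <- if (pk > 0) pmax(fhat, 0) / pk else fhat * 0
  dens <- (baseline_density + peak_delta_density * fhat) *
    (1 - model$bleach_rate)^(seq_len(nfr) - 1)
  lambda <- area * dens / 100
  counts <- stats::rpois(nfr, lambda)
  n_tot <- sum(counts)
  truth <- data.frame(
    frame = rep.int(seq_len(nfr), counts),
    t_min = rep.int(t_min, counts),
    x_um = stats::runif(n_tot, 0, scene$field_size[1]),
    y_um = stats::runif(n_tot, 0, scene$field_size[2]),
    intensity = stats::rlnorm(n_tot, model$log_mean, model$log_sd),
    order = rep.int(1L, max(n_tot, 0L)))
  frames <- NULL
  if (render) {
    frames <- vector("list", nfr)
    for (j in seq_len(nfr))
      frames[[j]] <- render_frame(truth[truth$frame == j, , drop = FALSE],
                                  scene, camera)
  }
  list(frames = frames, truth = truth, expected_density = dens,
       t_min = t_min, kinetics = kinetics)
}

#' Peak value of the two-phase response
#'
#' Maximum of [two_phase_model()] over t >= 0, located by dense grid search
#' refined with [stats::optimize()].
#'
#' @param p A [kinetic_params()].
#' @param t_max Upper end of the search window, minutes.
#' @return Scalar peak value (same units as `Fmax`).
#' @export
peak_response <- function(p, t_max = 50 * max(p$tau_syn, p$tau_deg)) {
  grid <- seq(0, t_max, length.out = 2000)
  v <- two_phase_model(grid, p)
  i <- which.max(v)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  if (lo == hi) return(v[i])
  opt <- stats::optimize(function(t) two_phase_model(t, p),
                         interval = c(lo, hi), maximum = TRUE)
  max(opt$objective, v[i])
}
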