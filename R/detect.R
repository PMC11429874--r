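#' Detect diffraction-limited spots in a TIRF frame or stack
#'
#' Per frame, a difference-of-Gaussians band-pass filter (scales ~1 and
#' ~2 px) is applied; candidate spots are 8-connected local maxima of the
#' filtered frame above `threshold_k` times its robust standard deviation
#' (1.4826 x MAD). Each candidate is refined by least-squares fitting of an
#' integrated symmetric 2D Gaussian plus constant offset inside
#' `fit_window` x `fit_window` pixels. Candidates whose band-pass
#' (matched-filter) response falls below `min_significance` robust SDs are
#' discarded as noise, as are fits whose center leaves the window or whose
#' sigma falls outside `sigma_bounds` times the PSF expectation; surviving
#' localizations closer than one fit radius keep only the brighter spot.
#'
#' @param stack A matrix (one frame) or list of matrices.
#' @param scene A [scene_spec()] supplying `pixel_size` and `psf_sigma`.
#' @param threshold_k Threshold in robust SDs of the filtered frame
#'   (default 1.5).
#' @param filter_scales Length-2 vector of DoG sigmas in pixels
#'   (default `c(1, 2)`).
#' @param fit_window Odd window size in pixels for the Gaussian fit
#'   (default 7).
#' @param sigma_bounds Acceptable fitted sigma, as multiples of the PSF
#'   sigma (default `c(0.5, 3)`).
#' @param min_significance Minimum band-pass response of an accepted spot,
#'   in robust SDs of the filtered frame (default 5); suppresses fits to
#'   noise maxima that clear the candidate threshold.
#' @param offset Constant camera offset subtracted before fitting; if `NULL`
#'   each window's fitted offset absorbs it (intensities are always
#'   background-subtracted by the local fit).
#' @return A `spot_table`: data frame with columns `frame`, `x_um`, `y_um`,
#'   `intensity` (integrated, background-subtracted ADU), `sigma_um`, plus
#'   attributes `pixel_size` and `frame_interval`.
#' @export
detect_spots <- function(stack, scene = scene_spec(), threshold_k = 1.5,
                         filter_scales = c(1, 2), fit_window = 7L,
                         sigma_bounds = c(0.5, 3), min_significance = 5,
                         offset = NULL) {
  if (is.matrix(stack)) stack <- list(stack)
  if (!is.list(stack) || length(stack) == 0)
    stop("`stack` must be a matrix or non-empty list of matrices")
  fit_window <- as.integer(fit_window)
  if (fit_window %% 2L == 0L) fit_window <- fit_window + 1L
  res <- vector("list", length(stack))
  for (f in seq_along(stack)) {
    loc <- detect_frame(stack[[f]], scene, threshold_k, filter_scales,
                        fit_window, sigma_bounds, min_significance)
    if (nrow(loc)) loc$frame <- f
    res[[f]] <- loc
  }
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0)
    out <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0), sigma_um = numeric(0),
                      frame = integer(0))
  out <- out[, c("frame", "x_um", "y_um", "intensity", "sigma_um")]
  rownames(out) <- NULL
  attr(out, "pixel_size") <- scene$pixel_size
  attr(out, "frame_interval") <- scene$frame_interval
  class(out) <- c("spot_table", "data.frame")
  out
}

detect_frame <- function(img, scene, threshold_k, filter_scales, fit_window,
                         sigma_bounds, min_significance) {
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0), sigma_um = numeric(0))
  ny <- nrow(img); nx <- ncol(img)
  filt <- gaussian_blur(img, filter_scales[1]) -
    gaussian_blur(img, filter_scales[2])
  sd_rob <- 1.4826 * stats::mad(filt, center = stats::median(filt),
                                constant = 1)
  thr <- max(threshold_k, min_significance) * sd_rob
  cand <- local_maxima(filt)
  cand <- cand[filt[cand] > thr]
  if (!length(cand)) return(empty)
  rr <- ((cand - 1L) %% ny) + 1L
  cc <- ((cand - 1L) %/% ny) + 1L
  half <- (fit_window - 1L) %/% 2L
  keep <- rr > half & rr <= ny - half & cc > half & cc <= nx - half
  rr <- rr[keep]; cc <- cc[keep]
  if (!length(rr)) return(empty)
  s_px <- scene$psf_sigma / scene$pixel_size
  fits <- vector("list", length(rr))
  for (i in seq_along(rr)) {
    win <- img[(rr[i] - half):(rr[i] + half), (cc[i] - half):(cc[i] + half)]
    fit <- fit_gaussian_window(win, s_px)
    if (is.null(fit)) next
    if (fit$sigma < sigma_bounds[1] * s_px || fit$sigma > sigma_bounds[2] * s_px)
      next
    if (abs(fit$x0) > half + 0.5 || abs(fit$y0) > half + 0.5) next
    if (fit$intensity <= 0) next
    fits[[i]] <- data.frame(
      x_um = (cc[i] - 0.5 + fit$x0) * scene$pixel_size,
      y_um = (rr[i] - 0.5 + fit$y0) * scene$pixel_size,
      intensity = fit$intensity,
      sigma_um = fit$sigma * scene$pixel_size)
  }
  loc <- do.call(rbind, fits)
  if (is.null(loc) || nrow(loc) == 0) return(empty)
  # duplicates: refits of the same emitter collapse onto (almost) the same
  # center; one fitted-Gaussian radius separates them from resolvable pairs
  merge_duplicates(loc, radius_um = stats::median(loc$sigma_um))
}

# integrated symmetric 2D Gaussian + constant offset on a square window;
# returns NULL on failure. Center coordinates are offsets from the window
# center in pixels.
fit_gaussian_window <- function(win, s_px) {
  n <- nrow(win)
  half <- (n - 1) / 2
  ax <- seq_len(n) - half - 1 # pixel centers relative to window center
  bg0 <- stats::median(win)
  amp0 <- max(sum(win - bg0), 1)
  model <- function(par) {
    # par: x0, y0, log sigma, intensity, offset
    s <- exp(par[3])
    fx <- stats::pnorm(ax + 0.5, par[1], s) - stats::pnorm(ax - 0.5, par[1], s)
    fy <- stats::pnorm(ax + 0.5, par[2], s) - stats::pnorm(ax - 0.5, par[2], s)
    par[4] * outer(fy, fx) + par[5]
  }
  fit <- tryCatch(suppressWarnings(
    minpack.lm::nls.lm(par = c(0, 0, log(s_px), amp0, bg0),
                       fn = function(p) as.numeric(win - model(p)),
                       control = minpack.lm::nls.lm.control(maxiter = 80))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  list(x0 = fit$par[1], y0 = fit$par[2], sigma = exp(fit$par[3]),
       intensity = fit$par[4], offset = fit$par[5])
}

# 8-connected strict local maxima (interior pixels only); linear indices
local_maxima <- function(img) {
  ny <- nrow(img); nx <- ncol(img)
  if (ny < 3 || nx < 3) return(integer(0))
  core <- img[2:(ny - 1), 2:(nx - 1)]
  ok <- core > img[1:(ny - 2), 2:(nx - 1)] & core > img[3:ny, 2:(nx - 1)] &
    core > img[2:(ny - 1), 1:(nx - 2)] & core > img[2:(ny - 1), 3:nx] &
    core > img[1:(ny - 2), 1:(nx - 2)] & core > img[1:(ny - 2), 3:nx] &
    core > img[3:ny, 1:(nx - 2)] & core > img[3:ny, 3:nx]
  idx <- which(ok)
  r <- ((idx - 1L) %% (ny - 2L)) + 2L
  c <- ((idx - 1L) %/% (ny - 2L)) + 2L
  (c - 1L) * ny + r
}

# separable Gaussian convolution with replicate padding
gaussian_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(m) {
    n <- nrow(m)
    mp <- rbind(m[rep(1L, r), , drop = FALSE], m,
                m[rep(n, r), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * mp[j:(j + n - 1L), , drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(img))))
}

merge_duplicates <- function(loc, radius_um) {
  o <- order(-loc$intensity)
  loc <- loc[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(loc))
  for (i in seq_len(nrow(loc))) {
    if (!keep[i]) next
    if (i < nrow(loc)) {
      j <- (i + 1):nrow(loc)
      d2 <- (loc$x_um[j] - loc$x_um[i])^2 + (loc$y_um[j] - loc$y_um[i])^2
      keep[j[d2 < radius_um^2]] <- FALSE
    }
  }
  out <- loc[keep, , drop = FALSE]
  out[order(out$x_um, out$y_um), , drop = FALSE]
}

#' Count molecule density in a region of interest
#'
#' @param spots A `spot_table` from [detect_spots()] (or any data frame
#'   with `frame`, `x_um`, `y_um`).
#' @param roi An ROI created with [roi_rect()] or [roi_mask()].
#' @param n_frames Total number of frames (defaults to `max(spots$frame)`);
#'   frames with zero spots still appear with density 0.
#' @return Data frame with `frame` and `density` (molecules per 100 um^2).
#' @export
count_density <- function(spots, roi, n_frames = NULL) {
  stopifnot(is.data.frame(spots))
  if (roi$area <= 0) stop("ROI area must be positive")
  if (is.null(n_frames))
    n_frames <- if (nrow(spots)) max(spots$frame) else 1L
  inside <- roi_contains(roi, spots$x_um, spots$y_um)
  tab <- tabulate(spots$frame[inside], nbins = n_frames)
  data.frame(frame = seq_len(n_frames), density = 100 * tab / roi$area)
}

#' Rectangular region of interest
#'
#' @param x0,y0 Lower-left corner, um.
#' @param width,height Side lengths, um. The default 10 x 10 um rectangle
#'   is the 100 um^2 counting region used for density measurements.
#' @return An object of class `roi`.
#' @export
roi_rect <- function(x0 = 0, y0 = 0, width = 10, height = 10) {
  stopifnot(width > 0, height > 0)
  structure(list(type = "rect", x0 = x0, y0 = y0, width = width,
                 height = height, area = width * height), class = "roi")
}

#' Mask-based region of interest
#'
#' @param mask Logical matrix (rows = y, cols = x); `TRUE` pixels belong to
#'   the ROI.
#' @param pixel_size Pixel pitch, um.
#' @return An object of class `roi` with `area` in um^2.
#' @export
roi_mask <- function(mask, pixel_size) {
  stopifnot(is.matrix(mask), pixel_size > 0)
  mask <- mask != 0
  area <- sum(mask) * pixel_size^2
  if (area <= 0) stop("ROI mask is empty")
  structure(list(type = "mask", mask = mask, pixel_size = pixel_size,
                 area = area), class = "roi")
}

roi_contains <- function(roi, x, y) {
  if (!length(x)) return(logical(0))
  if (roi$type == "rect") {
    x >= roi$x0 & x < roi$x0 + roi$width &
      y >= roi$y0 & y < roi$y0 + roi$height
  } else {
    i <- floor(y / roi$pixel_size) + 1L
    j <- floor(x / roi$pixel_size) + 1L
    ok <- i >= 1L & i <= nrow(roi$mask) & j >= 1L & j <= ncol(roi$mask)
    ins <- rep(FALSE, length(x))
    ins[ok] <- roi$mask[cbind(i[ok], j[ok])]
    ins
  }
}

#' Centered rolling average of a uniformly sampled trace
#'
#' The window is `round(window / frame_interval)` samples; at the edges the
#' mean is taken over the samples actually available.
#'
#' @param trace A [time_series()] with uniform sampling (minutes).
#' @param window Window length in the same time unit as `frame_interval`.
#' @param frame_interval Sampling interval; defaults to the median spacing
#'   of `trace$t`.
#' @return A [time_series()] of the smoothed values.
#' @export
rolling_average <- function(trace, window, frame_interval = NULL) {
  stopifnot(inherits(trace, "time_series"))
  dt <- diff(trace$t)
  if (length(dt) && (max(dt) - min(dt)) > 1e-6 * stats::median(dt))
    stop("rolling_average requires uniform sampling")
  if (is.null(frame_interval)) frame_interval <- stats::median(dt)
  w <- round(window / frame_interval)
  if (w < 1) {
    warning("window shorter than one sample; returning trace unchanged")
    return(trace)
  }
  n <- length(trace$value)
  lo_off <- (w - 1L) %/% 2L
  hi_off <- w - 1L - lo_off
  cs <- cumsum(c(0, trace$value))
  i <- seq_len(n)
  lo <- pmax(1L, i - lo_off)
  hi <- pmin(n, i + hi_off)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  time_series(trace$t, sm, n_cells = trace$n_cells)
}

#' Background-subtracted, baseline-normalized membrane intensity trace
#'
#' Per frame the modal pixel intensity of the whole frame (1-ADU bins) is
#' subtracted as background — the mode corresponds to sensor area outside
#' cells — then the mean within the ROI is taken and divided by the mean of
#' the pre-stimulus frames, so the pre-stimulus mean of the output is 1.
#'
#' @param stack List of matrices (frames).
#' @param roi An ROI from [roi_rect()] or [roi_mask()] (um coordinates).
#' @param pre_frames Integer indices of pre-stimulus frames.
#' @param pixel_size Pixel pitch, um.
#' @param frame_interval Sampling interval, seconds.
#' @param stimulus_frame Frame at which t = 0 (default
#'   `max(pre_frames) + 1`).
#' @return A [time_series()] (t in minutes) with attribute `"f0"` holding
#'   the pre-stimulus mean used for normalization. If the pre-stimulus ROI
#'   signal is zero after background subtraction the unnormalized trace is
#'   returned with attribute `"normalized" = FALSE` and a warning.
#' @export
measure_membrane_trace <- function(stack, roi, pre_frames,
                                   pixel_size, frame_interval,
                                   stimulus_frame = max(pre_frames) + 1L) {
  if (is.matrix(stack)) stack <- list(stack)
  stopifnot(length(pre_frames) >= 1, all(pre_frames >= 1),
            all(pre_frames <= length(stack)))
  vals <- vapply(stack, function(img) {
    bg <- modal_intensity(img)
    net <- img - bg
    mask <- roi_pixel_mask(roi, dim(img), pixel_size)
    mean(net[mask])
  }, numeric(1))
  f0 <- mean(vals[pre_frames])
  t_min <- (seq_along(stack) - stimulus_frame) * frame_interval / 60
  if (f0 == 0) {
    warning("pre-stimulus ROI intensity is zero after background ",
            "subtraction; returning unnormalized trace")
    out <- time_series(t_min, vals)
    attr(out, "normalized") <- FALSE
    return(out)
  }
  out <- time_series(t_min, vals / f0)
  attr(out, "f0") <- f0
  attr(out, "normalized") <- TRUE
  out
}

#' Modal pixel intensity of an image (1-ADU bins)
#'
#' @param img Numeric matrix.
#' @return The most frequent integer-binned pixel value (bin center).
#' @export
modal_intensity <- function(img) {
  v <- floor(as.numeric(img))
  tab <- table(v)
  as.numeric(names(tab)[which.max(tab)])
}

roi_pixel_mask <- function(roi, dims, pixel_size) {
  if (roi$type == "mask") {
    stopifnot(all(dim(roi$mask) == dims))
    return(roi$mask)
  }
  yc <- (seq_len(dims[1]) - 0.5) * pixel_size
  xc <- (seq_len(dims[2]) - 0.5) * pixel_size
  outer(yc >= roi$y0 & yc < roi$y0 + roi$height,
        xc >= roi$x0 & xc < roi$x0 + roi$width, FUN = "&")
}

#' Bin per-cell responses by expression level
#'
#' Cells are assigned to half-open bins `[lo, hi)` of the expression value;
#' cells outside all bins are collected in an `"overflow"` bin.
#'
#' @param expression Numeric vector of per-cell expression (ADU).
#' @param response Numeric vector of per-cell responses.
#' @param bin_edges Strictly increasing numeric vector of bin edges.
#' @return Data frame with one row per bin: `bin`, `lo`, `hi`, `n`,
#'   `mean`, `ci_lo`, `ci_hi` (t-based 95% CI of the mean).
#' @export
bin_by_expression <- function(expression, response, bin_edges) {
  stopifnot(length(expression) == length(response))
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("`bin_edges` must be strictly increasing")
  nb <- length(bin_edges) - 1L
  idx <- findInterval(expression, bin_edges, rightmost.closed = FALSE,
                      left.open = FALSE)
  idx[idx == length(bin_edges) & expression >= bin_edges[length(bin_edges)]] <-
    NA_integer_ # beyond last edge -> overflow
  idx[idx == 0L] <- NA_integer_ # below first edge -> overflow
  rows <- lapply(seq_len(nb), function(b) {
    r <- response[!is.na(idx) & idx == b]
    summarize_bin(sprintf("[%g,%g)", bin_edges[b], bin_edges[b + 1]),
                  bin_edges[b], bin_edges[b + 1], r)
  })
  ov <- response[is.na(idx)]
  if (length(ov))
    rows <- c(rows, list(summarize_bin("overflow", NA_real_, NA_real_, ov)))
  do.call(rbind, rows)
}

summarize_bin <- function(label, lo, hi, r) {
  n <- length(r)
  m <- if (n) mean(r) else NA_real_
  ci <- c(NA_real_, NA_real_)
  if (n >= 2) {
    se <- stats::sd(r) / sqrt(n)
    ci <- m + c(-1, 1) * stats::qt(0.975, n - 1) * se
  }
  data.frame(bin = label, lo = lo, hi = hi, n = n, mean = m,
             ci_lo = ci[1], ci_hi = ci[2])
}
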