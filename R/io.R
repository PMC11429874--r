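#' Read and write spot tables, traces, stacks and fit reports
#'
#' Plain-text and TIFF interchange: spot tables and density traces as CSV,
#' image stacks as multi-page TIFF (one page per frame, 16-bit), fit
#' results as JSON.
#'
#' @name tirfquant_io
NULL

#' @describeIn tirfquant_io Write a spot table to CSV
#'   (`frame, x_um, y_um, intensity_adu, sigma_um`).
#' @param spots A `spot_table` from [detect_spots()].
#' @param path Output file path.
#' @export
write_spot_table <- function(spots, path) {
  df <- data.frame(frame = spots$frame, x_um = spots$x_um,
                   y_um = spots$y_um, intensity_adu = spots$intensity,
                   sigma_um = spots$sigma_um)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @describeIn tirfquant_io Read a spot table written by
#'   [write_spot_table()].
#' @param pixel_size,frame_interval Acquisition metadata to attach.
#' @export
read_spot_table <- function(path, pixel_size = NA_real_,
                            frame_interval = NA_real_) {
  df <- utils::read.csv(path)
  out <- data.frame(frame = df$frame, x_um = df$x_um, y_um = df$y_um,
                    intensity = df$intensity_adu, sigma_um = df$sigma_um)
  attr(out, "pixel_size") <- pixel_size
  attr(out, "frame_interval") <- frame_interval
  class(out) <- c("spot_table", "data.frame")
  out
}

#' @describeIn tirfquant_io Write a density or fluorescence trace
#'   (`t_min, value[, se]`).
#' @param ts A [time_series()].
#' @export
write_trace <- function(ts, path) {
  utils::write.csv(as.data.frame(ts), path, row.names = FALSE)
  invisible(path)
}

#' @describeIn tirfquant_io Read a trace CSV with columns `t` (or
#'   `t_min`) and `value` (optional `se`).
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  tcol <- intersect(c("t", "t_min", "t_s"), names(df))[1]
  if (is.na(tcol)) stop("no time column (t / t_min / t_s) in ", path)
  t <- df[[tcol]]
  if (tcol == "t_s") t <- t / 60
  time_series(t, df$value, se = df$se)
}

#' @describeIn tirfquant_io Write a list of frames as a multi-page TIFF.
#'   Values are scaled by `2^bit_depth - 1` into `[0, 1]` as the tiff
#'   format expects.
#' @param frames Matrix or list of matrices.
#' @param bit_depth Integer bit depth used for scaling. Default 16.
#' @export
write_stack <- function(frames, path, bit_depth = 16L) {
  if (is.matrix(frames)) frames <- list(frames)
  vmax <- 2^bit_depth - 1
  imgs <- lapply(frames, function(m) {
    m <- pmin(pmax(m, 0), vmax) / vmax
    m
  })
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L)
  invisible(path)
}

#' @describeIn tirfquant_io Read a multi-page TIFF back into a list of
#'   ADU matrices (inverse of [write_stack()]).
#' @export
read_stack <- function(path, bit_depth = 16L) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  vmax <- 2^bit_depth - 1
  lapply(imgs, function(m) m * vmax)
}

#' @describeIn tirfquant_io Write a kinetic or multimer fit as JSON.
#' @param fit A [kinetic_params()] (from [fit_kinetics()]) or
#'   `multimer_fit` object.
#' @export
write_fit_json <- function(fit, path) {
  x <- unclass(fit)
  x$ci95 <- lapply(x$ci95, as.numeric)
  attributes(x) <- list(names = names(x))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
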