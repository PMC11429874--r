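#' Huang fuzzy-entropy automatic threshold
#'
#' Computes the Huang–Wang minimum-fuzziness threshold on a 256-bin
#' histogram scaled to the image min–max range (the ImageJ convention for
#' images deeper than 8 bits). For each candidate threshold the image is
#' fuzzified by the membership `u(g) = 1 / (1 + |g - mu| / C)` toward the
#' below/above-threshold class means `mu`, with `C` the grey-level range;
#' the threshold minimizing the total Shannon fuzziness
#' `sum h(g) * S(u(g))`, `S(u) = -u log u - (1-u) log(1-u)`, is returned.
#'
#' @param image Numeric matrix (or vector) of pixel values.
#' @param n_bins Number of histogram bins. Default 256.
#' @return The threshold in the units of `image` (upper edge of the
#'   selected bin): pixels with values strictly greater are foreground.
#' @export
huang_threshold <- function(image, n_bins = 256L) {
  v <- as.numeric(image)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) stop("constant image: threshold undefined")
  h <- histogram_counts(v, lo, hi, n_bins)
  t_bin <- huang_best_bin(h)
  # map back to intensity: upper edge of bin t_bin (0-based bin index)
  lo + (t_bin + 1) * (hi - lo) / n_bins
}

histogram_counts <- function(v, lo, hi, n_bins) {
  b <- floor((v - lo) / (hi - lo) * n_bins)
  b[b >= n_bins] <- n_bins - 1L
  tabulate(b + 1L, nbins = n_bins)
}

# 0-based bin index minimizing the Huang fuzziness over candidate
# thresholds; candidates span first..last occupied bin
huang_best_bin <- function(h) {
  n_bins <- length(h)
  g <- seq_len(n_bins) - 1
  first <- min(which(h > 0)) - 1L
  last <- max(which(h > 0)) - 1L
  if (first == last) stop("constant image: threshold undefined")
  C <- last - first
  W <- cumsum(h)
  S <- cumsum(h * g)
  Wt <- W[n_bins]; St <- S[n_bins]
  shannon <- function(u) {
    s <- numeric(length(u))
    ok <- u > 1e-12 & u < 1 - 1e-12
    s[ok] <- -u[ok] * log(u[ok]) - (1 - u[ok]) * log(1 - u[ok])
    s
  }
  best <- Inf; best_t <- first
  for (t in first:(last - 1L)) {
    w0 <- W[t + 1L]; s0 <- S[t + 1L]
    w1 <- Wt - w0; s1 <- St - s0
    if (w0 == 0 || w1 == 0) next
    mu0 <- s0 / w0; mu1 <- s1 / w1
    gl <- g[1:(t + 1L)]
    gh <- g[(t + 2L):n_bins]
    u0 <- 1 / (1 + abs(gl - mu0) / C)
    u1 <- 1 / (1 + abs(gh - mu1) / C)
    ent <- sum(h[1:(t + 1L)] * shannon(u0)) +
      sum(h[(t + 2L):n_bins] * shannon(u1))
    if (ent < best) { best <- ent; best_t <- t }
  }
  best_t
}

#' Assemble a four-channel immunofluorescence stack
#'
#' @param dapi,cellmask,egfp,ps473 Numeric matrices of identical size,
#'   12-bit ADU.
#' @param pixel_size Pixel pitch, um.
#' @return An object of class `channel_stack`.
#' @export
channel_stack <- function(dapi, cellmask, egfp, ps473, pixel_size) {
  dims <- dim(dapi)
  for (m in list(cellmask, egfp, ps473))
    if (!identical(dim(m), dims)) stop("channels must share dimensions")
  if (any(vapply(list(dapi, cellmask, egfp, ps473),
                 function(m) any(m < 0 | m > 4095), logical(1))))
    stop("channel values must lie in the 12-bit range [0, 4095]")
  stopifnot(pixel_size > 0)
  structure(list(dapi = dapi, cellmask = cellmask, egfp = egfp,
                 ps473 = ps473, pixel_size = pixel_size),
            class = "channel_stack")
}

#' Segment cells from DAPI nuclei and CellMask cytoplasm
#'
#' Nuclei are the Huang-thresholded DAPI foreground, split by watershed on
#' the distance transform (h-maxima suppression via the watershed
#' tolerance, default 2 px). Cell territories are the Huang-thresholded
#' CellMask foreground (united with the nuclei) partitioned along the
#' Voronoi boundaries of the nucleus labels — implemented as geometric
#' propagation of the nucleus labels across the foreground — so each cell
#' label contains exactly one nucleus.
#'
#' @param stack A [channel_stack()].
#' @param watershed_tolerance h-maxima depth for nucleus splitting, px.
#' @return List with integer matrices `cells` and `nuclei` (0 =
#'   background) and `n_cells`.
#' @export
segment_cells <- function(stack, watershed_tolerance = 2) {
  stopifnot(inherits(stack, "channel_stack"))
  dapi_ok <- tryCatch(huang_threshold(stack$dapi), error = function(e) NULL)
  if (is.null(dapi_ok))
    return(list(cells = zero_labels(stack$dapi),
                nuclei = zero_labels(stack$dapi), n_cells = 0L))
  nuc_bin <- fill_holes(stack$dapi > dapi_ok)
  if (!any(nuc_bin))
    return(list(cells = zero_labels(stack$dapi),
                nuclei = zero_labels(stack$dapi), n_cells = 0L))
  dm <- EBImage::distmap(EBImage::Image(nuc_bin * 1))
  nuc_lab <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1)
  nuc_lab <- matrix(as.integer(EBImage::imageData(nuc_lab)),
                    nrow = nrow(stack$dapi))
  cm_thr <- tryCatch(huang_threshold(stack$cellmask), error = function(e) NULL)
  cm_bin <- if (is.null(cm_thr)) nuc_bin
            else fill_holes(stack$cellmask > cm_thr) | nuc_bin
  cells <- EBImage::propagate(
    x = EBImage::Image(matrix(0, nrow(cm_bin), ncol(cm_bin))),
    seeds = EBImage::Image(nuc_lab),
    mask = EBImage::Image(cm_bin), lambda = 1e4)
  cells <- matrix(as.integer(EBImage::imageData(cells)), nrow = nrow(cm_bin))
  list(cells = cells, nuclei = nuc_lab, n_cells = max(cells))
}

zero_labels <- function(template)
  matrix(0L, nrow(template), ncol(template))

# close single-pixel noise holes inside thresholded objects
fill_holes <- function(bin) {
  filled <- EBImage::fillHull(EBImage::Image(bin * 1))
  matrix(as.numeric(EBImage::imageData(filled)) > 0, nrow(bin))
}

#' Filter segmented cells and measure channel intensities
#'
#' Keeps cells strictly larger than `min_area` um^2 with no pixel on the
#' image border, and measures per-cell mean EGFP (raw) and mean pS473
#' (background-subtracted, clamped at zero).
#'
#' @param labels Integer cell-label matrix from [segment_cells()].
#' @param stack A [channel_stack()].
#' @param min_area Minimum cell area, um^2 (strict). Default 10.
#' @param ps473_background Background staining level (ADU), the mean of
#'   cells processed without primary antibody. Default 0.
#' @return Data frame of cell records: `cell_id`, `area_um2`,
#'   `touches_border`, `mean_egfp`, `mean_ps473` (only retained cells).
#' @export
filter_and_measure <- function(labels, stack, min_area = 10,
                               ps473_background = 0) {
  stopifnot(inherits(stack, "channel_stack"),
            identical(dim(labels), dim(stack$egfp)))
  ids <- setdiff(sort(unique(as.integer(labels))), 0L)
  if (!length(ids))
    return(data.frame(cell_id = integer(0), area_um2 = numeric(0),
                      touches_border = logical(0), mean_egfp = numeric(0),
                      mean_ps473 = numeric(0)))
  ps <- stack$pixel_size
  border_ids <- unique(c(labels[1, ], labels[nrow(labels), ],
                         labels[, 1], labels[, ncol(labels)]))
  lv <- as.integer(labels)
  npx <- tabulate(lv, nbins = max(ids))
  egfp_sum <- rowsum_by_label(stack$egfp, lv, max(ids))
  ps_sum <- rowsum_by_label(stack$ps473, lv, max(ids))
  rec <- data.frame(
    cell_id = ids,
    area_um2 = npx[ids] * ps^2,
    touches_border = ids %in% border_ids,
    mean_egfp = egfp_sum[ids] / npx[ids],
    mean_ps473 = pmax(ps_sum[ids] / npx[ids] - ps473_background, 0))
  rec[rec$area_um2 > min_area & !rec$touches_border, , drop = FALSE]
}

rowsum_by_label <- function(img, labels_vec, n) {
  keep <- labels_vec > 0L
  s <- rowsum(as.numeric(img)[keep], labels_vec[keep])
  out <- numeric(n)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Classify transfected (EGFP-positive) cells
#'
#' A cell is EGFP-positive when its raw mean EGFP exceeds `cutoff`
#' (strictly). When reference EGFP values from known untransfected cells
#' are supplied, the cutoff is checked against their mean + 3 SD and a
#' warning is issued if it does not exceed that bound.
#'
#' @param records Cell-record data frame from [filter_and_measure()].
#' @param cutoff Positivity cutoff, 12-bit ADU. Default 100.
#' @param reference_untransfected Optional numeric vector of mean EGFP
#'   values of untransfected cells.
#' @return `records` with a logical `egfp_positive` column added.
#' @export
classify_transfected <- function(records, cutoff = 100,
                                 reference_untransfected = NULL) {
  stopifnot(is.data.frame(records), "mean_egfp" %in% names(records))
  if (!is.null(reference_untransfected) &&
      length(reference_untransfected) >= 2) {
    bound <- mean(reference_untransfected) + 3 * stats::sd(reference_untransfected)
    if (cutoff <= bound)
      warning(sprintf(
        "cutoff %.3g does not exceed mean + 3 SD of the untransfected reference (%.3g)",
        cutoff, bound))
  }
  records$egfp_positive <- records$mean_egfp > cutoff
  records
}

#' Summarize grouped single-cell measurements
#'
#' Reports per-group medians with exact order-statistic (binomial) 95%
#' confidence intervals — the appropriate summary for the typically
#' non-normal staining intensity distributions — together with a standard
#' omnibus comparison: Kruskal-Wallis with Holm-adjusted pairwise Wilcoxon
#' post-hoc tests (`parametric = FALSE`, default), or one-way ANOVA with
#' Tukey HSD (`parametric = TRUE`).
#'
#' @param values Numeric vector of per-cell measurements.
#' @param groups Factor (or coercible) of condition labels.
#' @param parametric Use ANOVA/Tukey instead of rank tests.
#' @param min_n Minimum group size for a median CI. Default 8.
#' @return List with `summary` (data frame: group, n, median, ci_lo,
#'   ci_hi, ci_defined), `omnibus` (htest or aov summary), `posthoc`.
#' @export
summarize_groups <- function(values, groups, parametric = FALSE, min_n = 8L) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  summ <- do.call(rbind, lapply(levels(groups), function(g) {
    x <- values[groups == g]
    n <- length(x)
    ci <- c(NA_real_, NA_real_)
    defined <- FALSE
    if (n >= min_n) {
      ci <- median_ci(x)
      defined <- TRUE
    }
    data.frame(group = g, n = n, median = stats::median(x),
               ci_lo = ci[1], ci_hi = ci[2], ci_defined = defined)
  }))
  omnibus <- NULL; posthoc <- NULL
  if (nlevels(groups) >= 2) {
    if (parametric) {
      fit <- stats::aov(values ~ groups)
      omnibus <- summary(fit)
      posthoc <- stats::TukeyHSD(fit)
    } else {
      omnibus <- stats::kruskal.test(values, groups)
      posthoc <- suppressWarnings(
        stats::pairwise.wilcox.test(values, groups, p.adjust.method = "holm"))
    }
  }
  list(summary = summ, omnibus = omnibus, posthoc = posthoc)
}

#' Exact order-statistic confidence interval for the median
#'
#' Distribution-free CI from the binomial distribution of the sign of
#' deviations from the median: the interval is
#' `(x_(l), x_(n - l + 1))` with `l` the largest integer such that
#' `P(Binom(n, 1/2) < l) <= alpha / 2`.
#'
#' @param x Numeric sample (n >= 6 recommended).
#' @param conf Confidence level. Default 0.95.
#' @return `c(lo, hi)`.
#' @export
median_ci <- function(x, conf = 0.95) {
  n <- length(x)
  if (n < 3) return(c(NA_real_, NA_real_))
  alpha <- 1 - conf
  s <- sort(x)
  l <- stats::qbinom(alpha / 2, n, 0.5)
  if (stats::pbinom(l - 1, n, 0.5) > alpha / 2) l <- l - 1L
  l <- max(l, 0L)
  lo <- s[max(l, 1L)]
  hi <- s[min(n - l + 1L, n)]
  c(lo, hi)
}
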