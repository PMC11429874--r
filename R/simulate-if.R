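#' Simulate a four-channel immunofluorescence scene
#'
#' Generates a 12-bit test field mimicking fixed-cell staining: disk
#' nuclei (DAPI), roughly circular cytoplasm territories around each
#' nucleus (CellMask), per-cell EGFP expression (lognormal for transfected
#' cells, dim lognormal for the untransfected fraction), and a pS473 stain
#' whose per-cell mean depends on the treatment flag and can optionally be
#' suppressed in high-EGFP cells to emulate inhibition of AKT activation
#' by an over-expressed biosensor. Cells never overlap; by default they
#' are placed away from the image border so ground-truth counts match the
#' border-filtered segmentation output.
#'
#' @param n_cells Number of cells to place (>= 0).
#' @param treated Logical: stimulated (high pS473) or serum-starved.
#' @param inhibition If `TRUE` and `treated`, the pS473 mean decreases
#'   with EGFP expression through an inhibitory Hill curve (IC50
#'   `inhibition_ic50`, coefficient 2).
#' @param transfected_fraction Fraction of cells drawing from the bright
#'   EGFP law. Default 0.6.
#' @param dim_px Image size in pixels (square). Default 256.
#' @param pixel_size Pixel pitch, um. Default 0.65 (20x air objective).
#' @param nucleus_radius_um,cyto_radius_um Mean nucleus / cell radii, um.
#' @param egfp_law,egfp_dim_law Lognormal `c(meanlog, sdlog)` for
#'   transfected and untransfected per-cell EGFP means.
#' @param ps473_treated,ps473_basal Mean pS473 stain for treated /
#'   untreated cells, ADU.
#' @param inhibition_ic50 EGFP level halving the pS473 response, ADU.
#' @param noise_sd Gaussian pixel noise, ADU. Default 3.
#' @param channel_offset Stain-free background level, ADU. Default 8.
#' @param allow_border Place cells uniformly, allowing border contact.
#'   Default `FALSE`.
#' @param seed Optional integer seed.
#' @return List with `stack` (a [channel_stack()]) and `truth` (data
#'   frame: cell_id, x_px, y_px, nucleus_radius_px, cell_radius_px,
#'   area_um2, transfected, true_egfp, true_ps473, touches_border).
#' @export
render_if_scene <- function(n_cells, treated = TRUE, inhibition = FALSE,
                            transfected_fraction = 0.6,
                            dim_px = 256L, pixel_size = 0.65,
                            nucleus_radius_um = 3.5, cyto_radius_um = 7,
                            egfp_law = c(log(600), 0.5),
                            egfp_dim_law = c(log(25), 0.4),
                            ps473_treated = 400, ps473_basal = 30,
                            inhibition_ic50 = 300,
                            noise_sd = 3, channel_offset = 8,
                            allow_border = FALSE, seed = NULL) {
  stopifnot(n_cells >= 0)
  if (!is.null(seed)) set.seed(seed)
  d <- as.integer(dim_px)
  blank <- function() matrix(0, d, d)
  dapi <- blank(); cm <- blank(); egfp <- blank(); ps <- blank()
  r_nuc <- nucleus_radius_um / pixel_size
  r_cyt <- cyto_radius_um / pixel_size
  centers <- place_centers(n_cells, d, r_cyt, allow_border)
  n_placed <- nrow(centers)
  truth <- data.frame(cell_id = integer(0), x_px = numeric(0),
                      y_px = numeric(0), nucleus_radius_px = numeric(0),
                      cell_radius_px = numeric(0), area_um2 = numeric(0),
                      transfected = logical(0), true_egfp = numeric(0),
                      true_ps473 = numeric(0), touches_border = logical(0))
  if (n_placed > 0) {
    transfected <- stats::runif(n_placed) < transfected_fraction
    egfp_mean <- ifelse(transfected,
                        stats::rlnorm(n_placed, egfp_law[1], egfp_law[2]),
                        stats::rlnorm(n_placed, egfp_dim_law[1],
                                      egfp_dim_law[2]))
    base_ps <- if (treated) ps473_treated else ps473_basal
    ps_mean <- rep(base_ps, n_placed)
    if (inhibition && treated)
      ps_mean <- ps473_basal + (ps473_treated - ps473_basal) /
        (1 + (egfp_mean / inhibition_ic50)^2)
    rows <- matrix(seq_len(d), d, d)
    cols <- matrix(seq_len(d), d, d, byrow = TRUE)
    for (i in seq_len(n_placed)) {
      rn <- r_nuc * stats::runif(1, 0.85, 1.15)
      rc <- max(r_cyt * stats::runif(1, 0.85, 1.15), rn + 2)
      d2 <- (rows - centers[i, 2])^2 + (cols - centers[i, 1])^2
      nuc <- d2 <= rn^2
      cell <- d2 <= rc^2
      dapi[nuc] <- dapi[nuc] + 900
      cm[cell] <- cm[cell] + 350
      egfp[cell] <- egfp[cell] + egfp_mean[i]
      ps[cell] <- ps[cell] + ps_mean[i]
      touches <- centers[i, 1] - rc <= 1 || centers[i, 1] + rc >= d ||
        centers[i, 2] - rc <= 1 || centers[i, 2] + rc >= d
      truth[i, ] <- list(i, centers[i, 1], centers[i, 2], rn, rc,
                         sum(cell) * pixel_size^2, transfected[i],
                         egfp_mean[i], ps_mean[i], touches)
    }
  }
  finish <- function(m) {
    m <- m + channel_offset +
      matrix(stats::rnorm(d * d, sd = noise_sd), d, d)
    m[m < 0] <- 0
    m[m > 4095] <- 4095
    m
  }
  list(stack = channel_stack(finish(dapi), finish(cm), finish(egfp),
                             finish(ps), pixel_size),
       truth = truth)
}

# rejection-sample non-overlapping centers (x, y in pixel units)
place_centers <- function(n, d, r_cyt, allow_border) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  margin <- if (allow_border) 0 else ceiling(r_cyt * 1.2) + 2
  lo <- 1 + margin; hi <- d - margin
  if (hi <= lo) stop("field too small for the requested cell size")
  centers <- matrix(NA_real_, n, 2)
  placed <- 0L
  for (attempt in seq_len(n * 400L)) {
    cand <- stats::runif(2, lo, hi)
    if (placed > 0) {
      dmin <- min(sqrt((centers[seq_len(placed), 1] - cand[1])^2 +
                         (centers[seq_len(placed), 2] - cand[2])^2))
      if (dmin < 2.45 * r_cyt) next
    }
    placed <- placed + 1L
    centers[placed, ] <- cand
    if (placed == n) break
  }
  centers[seq_len(placed), , drop = FALSE]
}
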