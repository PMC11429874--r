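#' Build an intensity histogram on a fixed uniform grid
#'
#' @param samples Numeric intensities (ADU).
#' @param edges Strictly increasing, uniformly spaced bin edges; samples
#'   outside the grid are counted into the first/last bin.
#' @return An `intensity_histogram`: list with `edges`, `mids`, `width`,
#'   `counts`, `N`.
#' @export
intensity_histogram <- function(samples, edges) {
  check_grid(edges)
  idx <- findInterval(samples, edges, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > length(edges) - 1L] <- length(edges) - 1L
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  structure(list(edges = edges, mids = (edges[-1] + edges[-length(edges)]) / 2,
                 width = edges[2] - edges[1], counts = counts,
                 N = length(samples)),
            class = "intensity_histogram")
}

check_grid <- function(edges) {
  if (length(edges) < 3 || is.unsorted(edges, strictly = TRUE))
    stop("`edges` must be a strictly increasing vector (>= 3 values)")
  w <- diff(edges)
  if ((max(w) - min(w)) > 1e-8 * mean(w))
    stop("`edges` must be uniformly spaced")
  invisible(TRUE)
}

#' Build c-mer basis densities from a monomer calibration sample
#'
#' The c = 1 basis is the normalized histogram density of a known monomeric
#' reporter. Higher orders are derived by the intensity scaling transform
#' with its change-of-variables Jacobian, `rho_c(x) = rho_1(x / c) / c`
#' (mode `"scaling"`, the default), or by c-fold self-convolution of the
#' monomer density (mode `"convolution"`, the physically exact law for c
#' independent emitters). Every basis density is renormalized to integrate
#' to 1 on the grid.
#'
#' @param monomer_samples Intensities of the monomeric calibration
#'   reporter (>= 100 values).
#' @param M Maximum multimer order (>= 1). Default 3.
#' @param edges Optional uniform bin edges; by default a grid with
#'   Freedman-Diaconis width on the calibration sample, spanning
#'   `[0, M * max(sample) * 1.05]` so all c-mer masses fit.
#' @param mode `"scaling"` or `"convolution"`.
#' @return A `basis_set`: list with `edges`, `mids`, `width`, `M`, `mode`,
#'   and `density` (matrix, bins x M, each column integrating to 1).
#' @export
build_basis <- function(monomer_samples, M = 3L, edges = NULL,
                        mode = c("scaling", "convolution")) {
  mode <- match.arg(mode)
  if (length(monomer_samples) < 100)
    stop("need >= 100 monomer calibration samples")
  M <- as.integer(M)
  if (M < 1) stop("M must be >= 1")
  if (is.null(edges)) {
    w <- 2 * stats::IQR(monomer_samples) / length(monomer_samples)^(1 / 3)
    hi <- M * max(monomer_samples) * 1.05
    edges <- seq(0, hi + w, by = w)
  }
  check_grid(edges)
  h <- intensity_histogram(monomer_samples, edges)
  rho1 <- h$counts / (h$N * h$width)
  dens <- matrix(0, nrow = length(h$mids), ncol = M)
  dens[, 1] <- normalize_density(rho1, h$width)
  if (M > 1) {
    for (c_ord in 2:M) {
      rc <- if (mode == "scaling") {
        stats::approx(h$mids, dens[, 1], xout = h$mids / c_ord,
                      yleft = 0, yright = 0, rule = 2)$y / c_ord
      } else {
        self_convolve(dens[, 1], c_ord, h$width)
      }
      dens[, c_ord] <- normalize_density(rc, h$width)
    }
  }
  structure(list(edges = edges, mids = h$mids, width = h$width,
                 M = M, mode = mode, density = dens),
            class = "basis_set")
}

normalize_density <- function(d, width) {
  d[d < 0] <- 0
  s <- sum(d) * width
  if (s <= 0) stop("degenerate density: zero mass on grid")
  d / s
}

# c-fold self-convolution of a density sampled at bin midpoints.
# Bin k of the convolution of two grids both starting at width/2
# corresponds to midpoint offset; renormalization absorbs the half-bin
# alignment error.
self_convolve <- function(d, c_ord, width) {
  out <- d
  n <- length(d)
  for (i in seq_len(c_ord - 1L)) {
    full <- stats::convolve(out, rev(d), type = "open") * width
    out <- full[seq_len(n)]
  }
  out
}

#' Mixture density from a basis set and multimer proportions
#'
#' @param basis A [build_basis()] result.
#' @param proportions Simplex vector of length `basis$M`.
#' @return Numeric density on `basis$mids`, integrating to 1.
#' @export
mixture_density <- function(basis, proportions) {
  stopifnot(inherits(basis, "basis_set"))
  if (length(proportions) != basis$M)
    stop("`proportions` must have length basis$M")
  check_simplex(proportions)
  as.numeric(basis$density %*% proportions)
}

#' Reduced chi-squared between an observed histogram and expected counts
#'
#' Bins with expected counts below `pool_min` are pooled into their left
#' neighbor (scanning left to right; a deficient tail is merged into the
#' last pooled bin). The statistic is
#' `sum((obs - exp)^2 / pmax(exp, 1)) / (B - n_fit_params - 1)` over the
#' `B` pooled bins.
#'
#' @param observed An [intensity_histogram()] (or a counts vector).
#' @param expected_counts Expected counts per bin on the same grid.
#' @param n_fit_params Number of fitted parameters consumed by the model.
#' @param pool_min Minimum expected count per pooled bin. Default 5.
#' @return Scalar reduced chi-squared with attributes `chisq` and `dof`.
#' @export
reduced_chisq <- function(observed, expected_counts, n_fit_params = 0L,
                          pool_min = 5) {
  obs <- if (inherits(observed, "intensity_histogram")) observed$counts
         else as.numeric(observed)
  if (length(obs) != length(expected_counts))
    stop("observed and expected must share the same grid")
  if (any(expected_counts < 0)) stop("expected counts must be >= 0")
  pooled <- pool_bins(obs, expected_counts, pool_min)
  B <- length(pooled$exp)
  dof <- B - n_fit_params - 1L
  if (dof <= 0) stop("not enough pooled bins for the requested parameters")
  chisq <- sum((pooled$obs - pooled$exp)^2 / pmax(pooled$exp, 1))
  structure(chisq / dof, chisq = chisq, dof = dof)
}

pool_bins <- function(obs, expc, pool_min) {
  po <- numeric(0); pe <- numeric(0)
  acc_o <- 0; acc_e <- 0
  for (i in seq_along(obs)) {
    acc_o <- acc_o + obs[i]; acc_e <- acc_e + expc[i]
    if (acc_e >= pool_min) {
      po <- c(po, acc_o); pe <- c(pe, acc_e)
      acc_o <- 0; acc_e <- 0
    }
  }
  if (acc_e > 0 || acc_o > 0) {
    if (length(pe)) {
      po[length(po)] <- po[length(po)] + acc_o
      pe[length(pe)] <- pe[length(pe)] + acc_e
    } else {
      po <- acc_o; pe <- acc_e
    }
  }
  list(obs = po, exp = pe)
}

#' Fit multimer proportions to an observed intensity histogram
#'
#' Deconvolves an observed spot-intensity histogram into c-mer fractions
#' A_c by minimizing the reduced chi-squared against the basis mixture.
#' The deterministic objective compares the observed counts with expected
#' counts `N * integral of the mixture over each bin`. The stochastic
#' objective (the default, `n_resamples > 0`) instead draws `N` samples
#' from the candidate mixture `n_resamples` times (common random numbers
#' from `seed`, so the objective is smooth in A) and averages the reduced
#' chi-squared of those synthetic histograms against the observation.
#' Optimization is a coarse simplex grid (step `grid_step`, evaluated on
#' the cheap deterministic objective) followed by local refinement of the
#' selected objective down to step 0.0025.
#'
#' @param observed An [intensity_histogram()] on the basis grid
#'   (`N >= 100`), e.g. from [intensity_histogram()] with
#'   `edges = basis$edges`.
#' @param basis A [build_basis()] result on the same grid.
#' @param n_resamples Monte-Carlo resamples (default 25); `0` selects the
#'   purely deterministic expected-count objective.
#' @param seed Integer seed for the resampling stream. Default 1.
#' @param grid_step Coarse simplex grid step. Default 0.01.
#' @return A `multimer_fit`: list with `proportions` (A_c, summing to 1),
#'   `counts_per_order` (A_c * N), `reduced_chisq`, `n_resamples`, `seed`,
#'   `M`, `N`.
#' @examples
#' \donttest{
#' mono <- sample_fluorophore_intensities(5000, seed = 1)
#' basis <- build_basis(mono, M = 2)
#' mix <- sample_multimer_intensities(5000, c(0.7, 0.3), seed = 2)
#' obs <- intensity_histogram(mix$intensities, basis$edges)
#' fit_proportions(obs, basis, n_resamples = 0)
#' }
#' @export
fit_proportions <- function(observed, basis, n_resamples = 25L, seed = 1L,
                            grid_step = 0.01) {
  stopifnot(inherits(observed, "intensity_histogram"),
            inherits(basis, "basis_set"))
  if (!isTRUE(all.equal(observed$edges, basis$edges)))
    stop("observed histogram must be binned on the basis grid")
  if (observed$N < 100) stop("need N >= 100 observed spots")
  if (sum(observed$counts > 0) < 2)
    stop("degenerate observation: a single occupied bin cannot be fit")
  M <- basis$M
  n_par <- M - 1L

  det_obj <- function(A) {
    expc <- observed$N * mixture_density(basis, A) * basis$width
    as.numeric(reduced_chisq(observed, expc, n_fit_params = n_par))
  }
  obj <- det_obj
  if (n_resamples > 0) {
    # common random numbers: one uniform matrix reused for every candidate
    u <- withr_seed(seed, stats::runif(observed$N * n_resamples))
    u <- matrix(u, nrow = observed$N)
    obj <- function(A) {
      dens <- mixture_density(basis, A)
      cdf <- c(0, cumsum(dens * basis$width))
      cdf <- cdf / cdf[length(cdf)]
      vals <- 0
      for (r in seq_len(n_resamples)) {
        smp <- inverse_cdf_sample(u[, r], cdf, basis$edges)
        h <- intensity_histogram(smp, basis$edges)
        vals <- vals + as.numeric(
          reduced_chisq(observed, h$counts, n_fit_params = n_par))
      }
      vals / n_resamples
    }
  }

  best <- grid_search_simplex(det_obj, M, grid_step)
  best <- refine_simplex(obj, best$A, grid_step)
  best <- refine_simplex(obj, best$A, grid_step / 4)
  A <- best$A
  # report the conventional goodness of fit (observed vs expected counts at
  # the fitted proportions); the Monte-Carlo criterion compares two noisy
  # histograms and sits near 2 even for a perfect model
  structure(list(proportions = A, counts_per_order = A * observed$N,
                 reduced_chisq = det_obj(A),
                 n_resamples = as.integer(n_resamples),
                 seed = as.integer(seed), M = M, N = observed$N),
            class = "multimer_fit")
}

#' @export
print.multimer_fit <- function(x, ...) {
  cat("Multimer proportion fit (M =", x$M, ", N =", x$N, ")\n")
  for (c_ord in seq_len(x$M))
    cat(sprintf("  A_%d = %.4f (%.1f spots)\n", c_ord,
                x$proportions[c_ord], x$counts_per_order[c_ord]))
  cat(sprintf("  reduced chi-squared = %.3f\n", x$reduced_chisq))
  invisible(x)
}

# evaluate f on all simplex points with the given step; returns the best
grid_search_simplex <- function(f, M, step) {
  pts <- simplex_grid(M, step)
  vals <- apply(pts, 1, f)
  i <- which.min(vals)
  list(A = pts[i, ], value = vals[i])
}

#' Enumerate the probability simplex on a regular grid
#'
#' @param M Dimension (number of proportions).
#' @param step Grid step; `1/step` should be (close to) an integer.
#' @return Matrix with `M` columns; rows sum to 1.
#' @export
simplex_grid <- function(M, step) {
  k <- round(1 / step)
  if (M == 1) return(matrix(1, 1, 1))
  combs <- compositions(k, M)
  combs / k
}

# all M-part compositions of k (including zeros), rows
compositions <- function(k, M) {
  if (M == 1) return(matrix(k, 1, 1))
  out <- NULL
  for (i in 0:k) {
    rest <- compositions(k - i, M - 1)
    out <- rbind(out, cbind(i, rest))
  }
  unname(out)
}

# hill-climbing over simplex directions (+step on c1, -step on c2)
refine_simplex <- function(f, A, step) {
  M <- length(A)
  val <- f(A)
  repeat {
    improved <- FALSE
    for (i in seq_len(M)) for (j in seq_len(M)) {
      if (i == j) next
      if (A[j] < step - 1e-12) next
      cand <- A
      cand[i] <- cand[i] + step
      cand[j] <- cand[j] - step
      cv <- f(cand)
      if (cv < val - 1e-12) {
        A <- cand; val <- cv; improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(A = A, value = val)
}

inverse_cdf_sample <- function(u, cdf, edges) {
  idx <- findInterval(u, cdf, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > length(edges) - 1L] <- length(edges) - 1L
  p0 <- cdf[idx]
  p1 <- cdf[idx + 1L]
  frac <- ifelse(p1 > p0, (u - p0) / (p1 - p0), 0.5)
  edges[idx] + frac * (edges[idx + 1L] - edges[idx])
}

# run code under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Pool per-experiment multimer fractions
#'
#' @param fractions Numeric vector of per-experiment fractions (any scale;
#'   percentages in, percentages out).
#' @return List with `mean`, `sd`, `se`, `ci95` (t-interval on the mean;
#'   may exceed 100% for percentages near saturation), `n`. With a single
#'   value the CI is `c(NA, NA)` and `ci_defined` is `FALSE`.
#' @export
pool_fraction <- function(fractions) {
  n <- length(fractions)
  if (n < 1) stop("need at least one fraction")
  m <- mean(fractions)
  if (n == 1)
    return(list(mean = m, sd = NA_real_, se = NA_real_,
                ci95 = c(NA_real_, NA_real_), ci_defined = FALSE, n = 1L))
  s <- stats::sd(fractions)
  se <- s / sqrt(n)
  ci <- m + c(-1, 1) * stats::qt(0.975, n - 1) * se
  list(mean = m, sd = s, se = se, ci95 = ci, ci_defined = TRUE, n = n)
}
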