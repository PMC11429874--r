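test_that("basis histograms obey the scaling transform", {
  fm <- test_fluorophore()
  mono <- sample_fluorophore_intensities(1e4, fm, seed = 41)

  expect_error(build_basis(mono[1:50]), "100")
  expect_error(build_basis(mono, M = 0), "M")

  b1 <- build_basis(mono, M = 1)
  h <- intensity_histogram(mono, b1$edges)
  expect_equal(b1$density[, 1], h$counts / (h$N * h$width))

  b3 <- build_basis(mono, M = 3)
  # every basis density integrates to one
  for (cc in 1:3)
    expect_lt(abs(sum(b3$density[, cc]) * b3$width - 1), 1e-6)
  # scaling law: mean of rho_c is c times the monomer mean
  m1 <- sum(b3$mids * b3$density[, 1]) * b3$width
  for (cc in 2:3) {
    mc <- sum(b3$mids * b3$density[, cc]) * b3$width
    expect_lt(abs(mc / (cc * m1) - 1), 0.02)
  }
  # convolution mode shares the mean law (exact for sums of iid draws)
  bc <- build_basis(mono, M = 2, mode = "convolution")
  m2c <- sum(bc$mids * bc$density[, 2]) * bc$width
  expect_lt(abs(m2c / (2 * m1) - 1), 0.05)
})

test_that("mixture densities are convex combinations of the basis", {
  mono <- sample_fluorophore_intensities(1e4, test_fluorophore(), seed = 42)
  basis <- build_basis(mono, M = 3)

  expect_equal(mixture_density(basis, c(1, 0, 0)), basis$density[, 1])
  expect_error(mixture_density(basis, c(0.5, 0.5)), "length")

  set.seed(43)
  for (i in 1:5) {
    a <- stats::runif(3)
    a <- a / sum(a)
    dens <- mixture_density(basis, a)
    expect_lt(abs(sum(dens) * basis$width - 1), 1e-6)
    # linearity of expectation across the mixture
    m1 <- sum(basis$mids * basis$density[, 1]) * basis$width
    mmix <- sum(basis$mids * dens) * basis$width
    expect_lt(abs(mmix / (sum(a * (1:3)) * m1) - 1), 0.03)
  }
})

test_that("reduced chi-squared matches counting statistics", {
  expect_equal(as.numeric(reduced_chisq(c(10, 20, 30), c(10, 20, 30))), 0)

  # Poisson-sampled observations give mean chi2_red near one
  set.seed(44)
  expc <- rep(20, 100)
  vals <- replicate(200, as.numeric(
    reduced_chisq(stats::rpois(100, expc), expc)))
  dof <- 99
  se <- stats::sd(vals) / sqrt(200)
  expect_lt(abs(mean(vals) - 100 / dof), 3 * se)

  # halving the expectation changes the statistic exactly per formula
  obs <- stats::rpois(50, 30)
  expc2 <- rep(30, 50)
  direct <- sum((obs - expc2 / 2)^2 / pmax(expc2 / 2, 1)) / (50 - 1)
  expect_equal(as.numeric(reduced_chisq(obs, expc2 / 2)), direct)

  # pooling: bins under the minimum expected count are merged leftward
  r <- reduced_chisq(c(3, 2, 8), c(2, 4, 9), pool_min = 5)
  expect_equal(attr(r, "dof"), 1L)
  expect_equal(attr(r, "chisq"), (5 - 6)^2 / 6 + (8 - 9)^2 / 9)

  expect_error(reduced_chisq(c(10, 10), c(10, 10), n_fit_params = 5),
               "pooled")
})

test_that("proportion fitting recovers known mixtures", {
  fm <- test_fluorophore()
  mono <- sample_fluorophore_intensities(2e4, fm, seed = 45)
  basis <- build_basis(mono, M = 2)

  # self-fit: a sample drawn from the monomer basis is called monomeric
  set.seed(46)
  self_smp <- sample_from_density(1e4, basis$density[, 1], basis$edges)
  f_self <- fit_proportions(intensity_histogram(self_smp, basis$edges),
                            basis, n_resamples = 0)
  expect_gte(f_self$proportions[1], 0.97)
  expect_gt(f_self$reduced_chisq, 0.7)
  expect_lt(f_self$reduced_chisq, 1.3)

  # 70/30 scaled-basis mixture against a 1%-step brute-force oracle
  set.seed(47)
  mix_dens <- mixture_density(basis, c(0.7, 0.3))
  obs <- intensity_histogram(
    sample_from_density(1e4, mix_dens, basis$edges), basis$edges)
  fit <- fit_proportions(obs, basis, n_resamples = 0)
  expect_lt(max(abs(fit$proportions - c(0.7, 0.3))), 0.05)

  oracle <- sapply(seq(0, 1, by = 0.01), function(a1) {
    expc <- obs$N * (a1 * basis$density[, 1] +
                       (1 - a1) * basis$density[, 2]) * basis$width
    pooled_o <- c()
    pooled_e <- c()
    ao <- ae <- 0
    for (i in seq_along(expc)) {
      ao <- ao + obs$counts[i]
      ae <- ae + expc[i]
      if (ae >= 5) {
        pooled_o <- c(pooled_o, ao)
        pooled_e <- c(pooled_e, ae)
        ao <- ae <- 0
      }
    }
    if (ae > 0 || ao > 0) {
      pooled_o[length(pooled_o)] <- pooled_o[length(pooled_o)] + ao
      pooled_e[length(pooled_e)] <- pooled_e[length(pooled_e)] + ae
    }
    sum((pooled_o - pooled_e)^2 / pmax(pooled_e, 1)) /
      (length(pooled_e) - 1 - 1)
  })
  a1_oracle <- seq(0, 1, by = 0.01)[which.min(oracle)]
  expect_lt(abs(fit$proportions[1] - a1_oracle), 0.011)

  expect_error(
    fit_proportions(intensity_histogram(rep(basis$mids[5], 200),
                                        basis$edges), basis),
    "degenerate")
})

test_that("stochastic and deterministic objectives agree on dimer calls", {
  fm <- test_fluorophore()
  mono <- sample_fluorophore_intensities(2e4, fm, seed = 48)
  basis <- build_basis(mono, M = 2)
  set.seed(49)
  obs <- intensity_histogram(
    sample_from_density(1e4, mixture_density(basis, c(0.6, 0.4)),
                        basis$edges), basis$edges)
  f_det <- fit_proportions(obs, basis, n_resamples = 0)
  f_mc <- fit_proportions(obs, basis, n_resamples = 100, seed = 50)
  expect_lt(abs(f_det$proportions[1] - f_mc$proportions[1]), 0.03)
})

test_that("estimated dimer fraction rises with the true dimer fraction", {
  fm <- test_fluorophore()
  mono <- sample_fluorophore_intensities(2e4, fm, seed = 51)
  basis <- build_basis(mono, M = 2)
  set.seed(52)
  mean_a2 <- sapply(c(0.1, 0.3, 0.5), function(a2) {
    mean(replicate(5, {
      smp <- sample_from_density(
        4e3, mixture_density(basis, c(1 - a2, a2)), basis$edges)
      fit_proportions(intensity_histogram(smp, basis$edges), basis,
                      n_resamples = 0)$proportions[2]
    }))
  })
  expect_true(all(diff(mean_a2) > 0))
})

test_that("physically summed dimers are recovered through the scaled basis", {
  fm <- test_fluorophore() # log_sd = 0.3, the regime where the
  mono <- sample_fluorophore_intensities(2e4, fm, seed = 53) # mismatch is small
  basis <- build_basis(mono, M = 2)
  mix <- sample_multimer_intensities(1e4, c(0.7, 0.3), fm, seed = 54)
  fit <- fit_proportions(intensity_histogram(mix$intensities, basis$edges),
                         basis, n_resamples = 0)
  expect_lt(max(abs(fit$proportions - c(0.7, 0.3))), 0.07)
})

test_that("per-experiment fractions pool into t-intervals", {
  same <- pool_fraction(c(97.5, 97.5, 97.5))
  expect_equal(same$ci95[2] - same$ci95[1], 0)

  p <- pool_fraction(c(95, 98, 101))
  expect_equal(p$mean, 98)
  se <- stats::sd(c(95, 98, 101)) / sqrt(3)
  expect_equal(p$ci95, 98 + c(-1, 1) * stats::qt(0.975, 2) * se)

  single <- pool_fraction(98.1)
  expect_false(single$ci_defined)
  expect_equal(single$mean, 98.1)
})
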