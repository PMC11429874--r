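test_that("single-fluorophore sampling follows the lognormal law", {
  fm <- test_fluorophore()

  expect_identical(sample_fluorophore_intensities(0, fm), numeric(0))
  expect_error(sample_fluorophore_intensities(-1, fm), "non-negative")

  degenerate <- sample_fluorophore_intensities(
    5, fluorophore_model(log_mean = log(250), log_sd = 0), seed = 1)
  expect_equal(degenerate, rep(250, 5))

  # closed-form lognormal mean as oracle
  x <- sample_fluorophore_intensities(
    1e5, fluorophore_model(log(100), 0.3), seed = 11)
  expect_lt(abs(mean(x) / (100 * exp(0.3^2 / 2)) - 1), 0.01)

  # identical seeds give bit-identical output
  expect_identical(sample_fluorophore_intensities(100, fm, seed = 3),
                   sample_fluorophore_intensities(100, fm, seed = 3))

  # Kolmogorov-Smirnov distance against the specified CDF
  d <- suppressWarnings(stats::ks.test(
    x, stats::plnorm, meanlog = log(100), sdlog = 0.3))$statistic
  expect_lt(as.numeric(d), 0.01)
})

test_that("multimer mixtures sum independent monomer draws", {
  fm <- test_fluorophore()
  expect_error(sample_multimer_intensities(10, c(0.5, 0.4), fm),
               "sum to 1")

  # pure monomer case equals the monomer law (KS on large samples)
  pure <- sample_multimer_intensities(2e4, c(1, 0, 0), fm, seed = 5)
  expect_true(all(pure$orders == 1L))
  mono <- sample_fluorophore_intensities(2e4, fm, seed = 6)
  d <- suppressWarnings(stats::ks.test(pure$intensities, mono))$statistic
  expect_lt(as.numeric(d), 0.02)

  # mixture-mean closed form: 50/50 monomer/dimer averages 1.5 monomers
  mix <- sample_multimer_intensities(5e4, c(0.5, 0.5, 0), fm, seed = 7)
  mono_mean <- exp(fm$log_mean + fm$log_sd^2 / 2)
  expect_lt(abs(mean(mix$intensities) / (1.5 * mono_mean) - 1), 0.01)

  # order frequencies follow binomial sampling (99% bounds around 0.98)
  sparse <- sample_multimer_intensities(1e4, c(0.98, 0.02, 0), fm, seed = 8)
  half_width <- stats::qnorm(0.995) * sqrt(0.98 * 0.02 / 1e4)
  expect_lt(abs(mean(sparse$orders == 1L) - 0.98), half_width)
})

test_that("rendered frames integrate spots onto a noisy camera image", {
  sc <- scene_spec(field_size = 5)
  cam <- camera_model(offset = 100, read_noise_sd = 0)

  # identity background with all noise disabled
  blank <- render_frame(NULL, sc, cam, shot_noise = FALSE,
                        read_noise = FALSE)
  expect_true(all(blank == sc$background + cam$offset))

  # analytic Gaussian integral: pixel sums recover the spot intensity
  tr <- data.frame(x_um = 2.5, y_um = 2.5, intensity = 1000)
  img <- render_frame(tr, sc, cam, shot_noise = FALSE, read_noise = FALSE)
  expect_lt(abs(sum(img - sc$background - cam$offset) / 1000 - 1), 0.005)

  # symmetry: argmax lands on the center pixel
  peak <- which(img == max(img), arr.ind = TRUE)
  ctr <- ceiling(sc$dim_px / 2)
  expect_equal(as.integer(peak[1, ]), as.integer(ctr))

  expect_error(render_frame(data.frame(x_um = 99, y_um = 1, intensity = 1),
                            sc, cam), "inside the field")

  # reproducibility of the noisy render
  expect_identical(render_frame(tr, sc, cam, seed = 4),
                   render_frame(tr, sc, cam, seed = 4))
})

test_that("time-lapse scenes follow the requested density law", {
  sc <- scene_spec(field_size = 13, n_frames = 200, frame_interval = 0.05)
  area <- prod(sc$field_size)

  # null stimulus: iid Poisson counts around the baseline
  null_scene <- simulate_timecourse_scene(
    baseline_density = 5, peak_delta_density = 0, scene = sc,
    seed = 21, render = FALSE)
  counts <- tabulate(null_scene$truth$frame, nbins = 200)
  lambda <- area * 5 / 100
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 200))
  expect_equal(nrow(null_scene$truth), sum(counts))

  # ground-truth density rises ~5-fold to ~25 per 100 um^2 at the peak
  sc2 <- scene_spec(field_size = 13, n_frames = 40, frame_interval = 30)
  stim <- simulate_timecourse_scene(
    kinetic_params(tau_syn = 1 / 1.09, tau_deg = 1 / 0.34),
    baseline_density = 5, peak_delta_density = 20, scene = sc2,
    stimulus_frame = 5, seed = 22, render = FALSE)
  # the 30-s frame grid straddles the model's peak; ~25 at the sampled max
  expect_equal(max(stim$expected_density), 25, tolerance = 0.01)
  expect_equal(stim$expected_density[1], 5, tolerance = 1e-6)
  expect_gt(max(stim$expected_density) / stim$expected_density[1], 4.9)

  # photobleaching: counts decay geometrically at the bleach rate
  bleach <- simulate_timecourse_scene(
    baseline_density = 40, peak_delta_density = 0, scene = sc,
    model = fluorophore_model(bleach_rate = 0.01),
    seed = 23, render = FALSE)
  cnt <- tabulate(bleach$truth$frame, nbins = 200)
  fit <- stats::glm(cnt ~ seq_along(cnt), family = stats::poisson())
  slope <- unname(stats::coef(fit)[2])
  se <- sqrt(diag(stats::vcov(fit)))[2]
  expect_lt(abs(slope - log(0.99)), 3 * se)
})

test_that("immunofluorescence scenes encode per-cell ground truth", {
  empty <- render_if_scene(0, seed = 1)
  expect_equal(nrow(empty$truth), 0)
  expect_true(all(empty$stack$dapi < 100))

  # untransfected-only scenes stay below the positivity cutoff
  dim_only <- render_if_scene(10, transfected_fraction = 0, seed = 2)
  expect_true(all(dim_only$truth$true_egfp < 100))

  # inhibition couples high EGFP to suppressed pS473 (negative rank corr.)
  inh <- render_if_scene(25, treated = TRUE, inhibition = TRUE,
                         transfected_fraction = 0.8, seed = 3)
  rho <- stats::cor(inh$truth$true_egfp, inh$truth$true_ps473,
                    method = "spearman")
  expect_lt(rho, 0)

  # reproducibility
  a <- render_if_scene(8, seed = 9)
  b <- render_if_scene(8, seed = 9)
  expect_identical(a$stack$egfp, b$stack$egfp)
  expect_identical(a$truth, b$truth)
})
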