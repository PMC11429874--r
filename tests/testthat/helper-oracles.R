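# shared fixtures and independent oracle helpers, built in code

test_fluorophore <- function() fluorophore_model(log_mean = log(500),
                                                 log_sd = 0.3)

# greedy one-to-one matching of detections to ground truth
match_detections <- function(det, truth, tol_um) {
  used <- rep(FALSE, nrow(det))
  tp <- 0L
  for (i in seq_len(nrow(truth))) {
    if (!nrow(det)) break
    d2 <- (det$x_um - truth$x_um[i])^2 + (det$y_um - truth$y_um[i])^2
    j <- which.min(ifelse(used, Inf, d2))
    if (length(j) && !used[j] && d2[j] < tol_um^2) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  list(tp = tp, fp = nrow(det) - tp, fn = nrow(truth) - tp)
}

# draw n samples from a binned density by inverse-CDF (independent of the
# package's internal sampler)
sample_from_density <- function(n, dens, edges) {
  w <- diff(edges)[1]
  cdf <- c(0, cumsum(dens * w))
  cdf <- cdf / cdf[length(cdf)]
  u <- stats::runif(n)
  idx <- findInterval(u, cdf, rightmost.closed = TRUE)
  idx[idx < 1] <- 1
  idx[idx > length(edges) - 1] <- length(edges) - 1
  frac <- (u - cdf[idx]) / pmax(cdf[idx + 1] - cdf[idx], 1e-300)
  edges[idx] + frac * w
}

# Huang fuzzy-entropy functional computed directly from first principles,
# scanning every candidate threshold (brute-force oracle)
huang_oracle_bin <- function(h) {
  n_bins <- length(h)
  g <- seq_len(n_bins) - 1
  occ <- which(h > 0)
  first <- min(occ) - 1
  last <- max(occ) - 1
  C <- last - first
  best <- Inf
  best_t <- first
  for (t in first:(last - 1)) {
    lo <- 1:(t + 1)
    hi <- (t + 2):n_bins
    mu0 <- sum(h[lo] * g[lo]) / sum(h[lo])
    mu1 <- sum(h[hi] * g[hi]) / sum(h[hi])
    u <- c(1 / (1 + abs(g[lo] - mu0) / C), 1 / (1 + abs(g[hi] - mu1) / C))
    sfun <- ifelse(u <= 1e-12 | u >= 1 - 1e-12, 0,
                   -u * log(u) - (1 - u) * log(1 - u))
    ent <- sum(h * sfun)
    if (ent < best) {
      best <- ent
      best_t <- t
    }
  }
  best_t
}

# two-disk synthetic nucleus/cytoplasm stack
two_nucleus_stack <- function(sep_diameters, r = 8, dim = 96) {
  c1 <- c(40, 48)
  c2 <- c(40 + sep_diameters * 2 * r, 48)
  rows <- matrix(seq_len(dim), dim, dim)
  cols <- t(rows)
  dapi <- matrix(10, dim, dim)
  n1 <- (cols - c1[1])^2 + (rows - c1[2])^2 <= r^2
  n2 <- (cols - c2[1])^2 + (rows - c2[2])^2 <= r^2
  dapi[n1 | n2] <- 900
  cm <- matrix(10, dim, dim)
  cm[(cols - (c1[1] + c2[1]) / 2)^2 + (rows - 48)^2 <= (3 * r)^2] <- 350
  flat <- matrix(12, dim, dim)
  channel_stack(dapi, cm, flat, flat, pixel_size = 0.65)
}

# spot intensity giving a peak-pixel SNR of `snr` against the combined
# background shot + read noise of the default camera/scene
intensity_for_snr <- function(snr, scene, camera) {
  s_px <- scene$psf_sigma / scene$pixel_size
  noise_sd <- sqrt(scene$background + camera$read_noise_sd^2)
  snr * noise_sd * 2 * pi * s_px^2
}
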