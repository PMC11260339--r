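# preprocessing stages: despiking, baselines, SG filtering, normalization,
# cropping, CO2 flattening, PCA denoising, S/N, ROIs, outlier rejection

test_that("despiking removes injected spikes and leaves other channels bit-exact", {
  set.seed(42)
  wn <- seq(700, 1700)
  clean <- gauss_band(wn, 1200, 30) + rnorm(length(wn), 0, 0.01)
  spiked <- clean
  spiked[500] <- spiked[500] + 50 * 0.01 * 50   # huge single-channel spike
  s <- spectrum(wn, spiked, modality = "RAMAN")
  out <- remove_cosmic_rays(s)
  expect_true(500 %in% out$meta$despiked_channels)
  other <- setdiff(seq_along(wn), out$meta$despiked_channels)
  expect_identical(out$intensity[other], spiked[other])
  expect_lt(abs(out$intensity[500] - clean[500]), 0.1)
})

test_that("a spike-free spectrum passes through despiking unchanged", {
  set.seed(1)
  s <- toy_spectrum(301, 700, 1000, "RAMAN",
                    intensity = gauss_band(seq(700, 1000, length.out = 301),
                                           850, 30) + rnorm(301, 0, 0.01))
  out <- remove_cosmic_rays(s)
  expect_identical(out$intensity, s$intensity)
  expect_length(out$meta$despiked_channels, 0)
})

test_that("two adjacent spikes narrower than the filter are both removed", {
  set.seed(7)
  wn <- seq(700, 1300)
  clean <- gauss_band(wn, 1000, 40) + rnorm(length(wn), 0, 0.01)
  spiked <- clean
  spiked[300:301] <- spiked[300:301] + c(2.4, 3.0)
  out <- remove_cosmic_rays(spectrum(wn, spiked, modality = "RAMAN"))
  expect_true(all(c(300, 301) %in% out$meta$despiked_channels))
  expect_lt(max(abs(out$intensity[300:301] - clean[300:301])), 0.15)
  # brute-force detection oracle: the taller spike sticks out of the running
  # median by far more than 8 robust-noise units, so the pair must be found
  resid <- spiked - stats::runmed(spiked, 3)
  expect_gt(abs(resid[301]), 8 * mad(diff(spiked)) / sqrt(2))
})

test_that("iterative polynomial baseline recovers pure polynomials and band areas", {
  wn <- seq(700, 3050, by = 1)
  x <- (wn - mean(wn)) / 1000
  cubic <- 0.5 + 0.3 * x - 0.2 * x^2 + 0.4 * x^3
  out <- polynomial_baseline(spectrum(wn, cubic, modality = "RAMAN"))
  expect_lt(max(abs(out$intensity)), 1e-6 * max(abs(cubic)))

  withband <- cubic + gauss_band(wn, 1450, 25, 0.8)
  corr <- polynomial_baseline(spectrum(wn, withband, modality = "RAMAN"))
  area <- integrate_band(corr, 1450 - 100, 1450 + 100, mode = "ZERO_BASELINE")
  expect_equal(area, gauss_area(0.8, 25), tolerance = 0.02)

  flat <- polynomial_baseline(spectrum(wn, rep(0, length(wn)) + 1e-15,
                                       modality = "RAMAN"))
  expect_lt(max(abs(flat$intensity)), 1e-12)
  expect_error(polynomial_baseline(toy_spectrum(3), degree = 5), "degree")
})

test_that("rubber-band baseline is non-negative, idempotent, peak-preserving", {
  wn <- seq(700, 3050)
  bowl <- 2 + ((wn - 1800) / 1000)^2
  y <- bowl + gauss_band(wn, 1200, 25, 1) + gauss_band(wn, 2900, 40, 0.7)
  s <- spectrum(wn, y, modality = "RAMAN")
  out <- rubberband_baseline(s)
  expect_gte(min(out$intensity), -1e-9)
  again <- rubberband_baseline(out)
  expect_equal(again$intensity, out$intensity, tolerance = 1e-9)
  # band maxima positions survive a linear ramp baseline
  ramp <- 0.001 * wn + gauss_band(wn, 1200, 25, 1)
  corr <- rubberband_baseline(spectrum(wn, ramp, modality = "RAMAN"))
  expect_equal(wn[which.max(corr$intensity)], 1200)
  expect_error(rubberband_baseline(spectrum(1:2 + 700, c(1, 2))), ">= 3")
})

test_that("Savitzky-Golay reproduces polynomials and analytic derivatives", {
  wn <- seq(1000, 1200, by = 0.5)
  quad <- 3 + 0.5 * wn - 0.01 * wn^2
  d2 <- savgol(spectrum(wn, quad), window_pts = 13, polyorder = 2, deriv = 2)
  interior <- 13:(length(wn) - 12)
  expect_equal(d2$intensity[interior], rep(-0.02, length(interior)),
               tolerance = 1e-9)
  sm <- savgol(spectrum(wn, quad), window_pts = 9, polyorder = 3, deriv = 0)
  expect_equal(sm$intensity, quad, tolerance = 1e-9)

  # second derivative of a Gaussian vs the analytic expression
  g <- gauss_band(wn, 1100, 40)
  k <- 4 * log(2) / 40^2
  analytic <- (4 * k^2 * (wn - 1100)^2 - 2 * k) * g
  d2g <- savgol(spectrum(wn, g), window_pts = 13, polyorder = 2, deriv = 2)
  err <- abs(d2g$intensity[interior] - analytic[interior])
  expect_lt(max(err) / max(abs(analytic)), 0.01)

  expect_error(savgol(spectrum(c(1, 2, 4, 8, 16, 32, 64, 128, 256), rnorm(9))),
               "uniform")
  expect_error(savgol(toy_spectrum(), window_pts = 9, polyorder = 2, deriv = 3),
               "deriv")
})

test_that("vector normalization: unit norm, idempotent, affine-invariant", {
  s <- toy_spectrum(201, 1000, 1200)
  n1 <- vector_normalize(s)
  expect_equal(sqrt(sum(n1$intensity^2)), 1, tolerance = 1e-12)
  expect_equal(mean(n1$intensity), 0, tolerance = 1e-12)
  n2 <- vector_normalize(n1)
  expect_equal(n2$intensity, n1$intensity, tolerance = 1e-12)
  aff <- s; aff$intensity <- 3.7 * s$intensity + 11
  expect_equal(vector_normalize(aff)$intensity, n1$intensity, tolerance = 1e-9)
  # region-restricted: norm over the region is 1
  nr <- vector_normalize(s, region = c(1050, 1150))
  idx <- which(s$wavenumber >= 1050 & s$wavenumber <= 1150)
  expect_equal(sqrt(sum(nr$intensity[idx]^2)), 1, tolerance = 1e-12)
  expect_error(vector_normalize(spectrum(1:10 + 999, rep(2, 10))), "constant")
})

test_that("crop keeps exactly the closed-interval channels", {
  s <- spectrum(1:10 + 0, 1:10)
  expect_length(crop(s, 3, 5)$wavenumber, 3)
  expect_equal(crop(s, 0.5, 11)$intensity, s$intensity)
  wide <- spectrum(seq(900, 4000), rnorm(3101), modality = "IR")
  expect_length(crop(wide, 920, 3700)$wavenumber, 2781)
  expect_error(crop(s, 20, 30), "no channels")
})

test_that("CO2 flattening replaces the band by the boundary chord exactly", {
  wn <- seq(1800, 2800)
  y <- 0.2 + 1e-4 * wn + gauss_band(wn, 2350, 35, 0.5)
  s <- spectrum(wn, y, modality = "IR")
  out <- flatten_co2(s)
  idx <- which(wn >= 2200 & wn <= 2400)
  line <- approx(wn[c(idx[1], idx[length(idx)])],
                 y[c(idx[1], idx[length(idx)])], xout = wn[idx])$y
  expect_equal(out$intensity[idx], line, tolerance = 1e-12)
  expect_identical(out$intensity[-idx], y[-idx])
  expect_equal(out$intensity[idx[1]], y[idx[1]])
  # a spectrum already linear there is unchanged
  lin <- spectrum(wn, 0.1 + 2e-4 * wn, modality = "IR")
  expect_equal(flatten_co2(lin)$intensity, lin$intensity, tolerance = 1e-12)
  expect_error(flatten_co2(crop(s, 1800, 2100)), "CO2")
})

test_that("PCA denoising reconstructs low-rank cubes and reduces noise", {
  set.seed(5)
  wn <- seq(1000, 1500, by = 5)
  # rank-2 noiseless cube: two pixel archetypes
  p1 <- gauss_band(wn, 1200, 30); p2 <- gauss_band(wn, 1400, 25)
  arr <- array(0, dim = c(4, 4, length(wn)))
  truth <- arr
  for (r in 1:4) for (cc in 1:4) {
    truth[r, cc, ] <- if ((r + cc) %% 2) p1 else p2
    arr[r, cc, ] <- truth[r, cc, ]
  }
  cube <- hypercube(arr, wn)
  rec <- pca_denoise(cube, n_pcs = 13)
  expect_equal(rec$data, cube$data, tolerance = 1e-6)
  noisy <- hypercube(arr + array(rnorm(length(arr), 0, 0.05), dim = dim(arr)), wn)
  den <- pca_denoise(noisy, n_pcs = 2)
  mse_before <- mean((noisy$data - truth)^2)
  mse_after <- mean((den$data - truth)^2)
  expect_lt(mse_after, mse_before)
  # full-rank reconstruction is the identity
  full <- pca_denoise(noisy, n_pcs = 16)
  expect_equal(full$data, noisy$data, tolerance = 1e-6)
  one <- hypercube(array(1, dim = c(1, 1, length(wn))), wn)
  expect_error(pca_denoise(one), ">= 2 pixels")
})

test_that("S/N estimation scales as constructed and flags degenerate input", {
  set.seed(8)
  wn <- seq(1500, 2000)
  noise_sd <- 0.01
  y <- gauss_band(wn, 1650, 25, 100 * noise_sd) + rnorm(length(wn), 0, noise_sd)
  snr <- estimate_snr(spectrum(wn, y, modality = "IR"))
  expect_gt(snr, 80); expect_lt(snr, 120)
  flat <- spectrum(wn, rep(1, length(wn)), modality = "IR")
  expect_identical(estimate_snr(flat), Inf)
  expect_error(estimate_snr(spectrum(1:100 + 699, rnorm(100))), "window")
})

test_that("ROI selection tiles the cube, ranks by S/N, and errors when short", {
  cfg <- generator_config(seed = 6, modality = "IR", axis_lo = 1500,
                          axis_hi = 2000, axis_step = 10)
  cube <- generate_cube("H6", 8, 8, cell_fraction = 0, config = cfg)
  # plant cells only in the top-left 4x4 quadrant
  patch <- generate_cube("H6", 4, 4, cell_fraction = 1, config = cfg)
  cube$data[1:4, 1:4, ] <- patch$data
  rois <- select_rois(cube, n_rois = 4)
  expect_length(rois, 4)
  origins <- sapply(rois, function(r) c(r$row0, r$col0))
  expect_setequal(paste(origins[1, ], origins[2, ]), c("0 0", "0 4", "4 0", "4 4"))
  best <- select_rois(cube, n_rois = 1)
  expect_equal(c(best[[1]]$row0, best[[1]]$col0), c(0, 0))
  expect_error(select_rois(cube, n_rois = 5), "candidate")
})

test_that("ROI averaging is the unweighted pixel mean", {
  arr <- array(0, dim = c(2, 2, 3))
  arr[1, 1, ] <- 0; arr[1, 2, ] <- 2; arr[2, , ] <- 5
  cube <- hypercube(arr, 1:3 + 999)
  expect_equal(average_roi(cube, roi(0, 0, 1, 2))$intensity, rep(1, 3))
  expect_equal(average_roi(cube, roi(0, 0, 2, 2))$intensity, rep(3, 3))
  expect_error(average_roi(cube, roi(1, 1, 2, 2)), "exceeds")
})

test_that("outlier rejection removes exactly the planted noise spectrum", {
  cfg <- generator_config(seed = 10, n_per_group = 10, modality = "RAMAN",
                          axis_step = 4)
  # spike-free noise: rejection runs after despiking in the real chain
  g <- generate_group("H6", cfg, noise = noise_model(spike_rate = 0))
  clean <- reject_outliers(g)
  expect_length(attr(clean, "rejected"), 0)
  bad <- g
  set.seed(3)
  bad$intensity[4, ] <- rnorm(ncol(bad$intensity))
  out <- reject_outliers(bad)
  expect_identical(attr(out, "rejected"), 4L)
  expect_equal(n_spectra(out), 9)
  all_kept <- reject_outliers(bad, min_correlation = 0)
  expect_equal(n_spectra(all_kept), 10)
  expect_error(reject_outliers(get_spectrum(g, 1)))
})

test_that("IR pipeline output count is n_cubes x n_rois with unit-norm spectra", {
  cfg0 <- generator_config(seed = 20, modality = "IR", axis_step = 8)
  cubes <- lapply(1:3, function(i) {
    ci <- generator_config(seed = 20 + i, modality = "IR", axis_step = 8)
    generate_cube("D2", 8, 8, cell_fraction = 0.6, config = ci)
  })
  out <- preprocess_ir(cubes, config = list(n_pcs = 10), group = "D2")
  expect_equal(n_spectra(out), 3 * 4)
  expect_equal(out$form, "SECOND_DERIVATIVE")
  norms <- sqrt(rowSums(out$intensity^2))
  expect_equal(norms, rep(1, 12), tolerance = 1e-9)
  one <- preprocess_ir(cubes[[1]], config = list(n_pcs = 10))
  expect_equal(n_spectra(one), 4)
})

test_that("Raman pipeline yields unit-norm spectra and a sane group mean", {
  cfg <- generator_config(seed = 21, n_per_group = 12, modality = "RAMAN",
                          axis_step = 2)
  g <- generate_group("D7", cfg)
  res <- preprocess_raman(g)
  expect_lte(n_spectra(res$set), 12)
  expect_s3_class(res$mean, "vib_spectrum")
  norms <- sqrt(rowSums(res$set$intensity^2))
  expect_equal(norms, rep(1, n_spectra(res$set)), tolerance = 1e-9)
  # the group mean correlates strongly with the noiseless processed model
  nm <- noise_model(additive_sd = 1e-6, spike_rate = 0,
                    baseline_coeffs = c(0.1, 0.05, -0.03, 0.02))
  g0 <- generate_group("D7", generator_config(seed = 22, n_per_group = 1,
                                              modality = "RAMAN", axis_step = 2),
                       noise = nm)
  m0 <- preprocess_raman(g0, config = list(despike = FALSE))$mean
  expect_gt(cor(res$mean$intensity, m0$intensity), 0.97)
})

test_that("pipeline re-runs are bit-identical", {
  cfg <- generator_config(seed = 30, n_per_group = 4, modality = "RAMAN",
                          axis_step = 4)
  g <- generate_group("D2", cfg)
  r1 <- preprocess_raman(g); r2 <- preprocess_raman(g)
  expect_identical(r1$set$intensity, r2$set$intensity)
})
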