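# band libraries, stage profiles and the spectra/cube generator

test_that("band libraries hold the marker bands inside the processing windows", {
  ir <- default_ir_band_library()
  ir_names <- vapply(ir, `[[`, character(1), "name")
  ir_centers <- vapply(ir, `[[`, numeric(1), "center")
  expect_equal(ir_centers[ir_names == "TAG_ester"], 1742)
  expect_equal(ir_centers[ir_names == "DNA_970"], 970)
  expect_true(all(c(2960, 2924, 2852, 1742, 1726, 1651, 1632, 1547, 1514,
                    1421, 1236, 1084, 970) %in% ir_centers))
  expect_true(all(ir_centers >= 920 & ir_centers <= 3700))

  rs <- default_raman_band_library()
  rs_names <- vapply(rs, `[[`, character(1), "name")
  rs_centers <- vapply(rs, `[[`, numeric(1), "center")
  expect_equal(rs_centers[rs_names == "Phe_total_1007"], 1007)
  expect_equal(rs_centers[rs_names == "phospholipid_724"], 724)
  expect_true(all(c(3014, 2930, 2853, 1660, 1587, 1449, 1340, 1311, 1306,
                    1267, 1130, 1038, 1007, 790, 756, 724) %in% rs_centers))
  expect_true(all(rs_centers >= 700 & rs_centers <= 3050))
})

test_that("stage profiles encode the differentiation trends as orderings", {
  p <- default_stage_profiles("IR")
  tag <- vapply(p, function(x) x$multipliers[["TAG_ester"]], numeric(1))
  expect_lt(tag["D2"], tag["H6"])
  expect_lt(tag["H6"], tag["D7"])
  expect_lte(tag["D7"], tag["D14"])
  acyl <- vapply(p, function(x) x$multipliers[["FA_acyl_1421"]], numeric(1))
  expect_equal(unname(acyl["D2"]), 0)
  expect_gt(acyl["D7"], acyl["H6"])
  dna <- vapply(p, function(x) x$multipliers[["DNA_970"]], numeric(1))
  expect_equal(names(which.max(dna)), "D2")

  r <- default_stage_profiles("RAMAN")
  uns <- vapply(r, function(x) x$multipliers[["CH_unsat_1267"]], numeric(1))
  expect_equal(names(which.max(uns[c("H6", "D2", "D7", "D14")])), "D7")
  cyt <- vapply(r, function(x) x$multipliers[["cytochrome_1587"]], numeric(1))
  expect_true(min(cyt[c("D7", "D14")]) > max(cyt[c("H6", "D2")]))
  phe <- vapply(r, function(x) x$multipliers[["Phe_crosslink_1038"]], numeric(1))
  expect_true(all(phe[c("D7", "D14")] < phe["H6"]))
  expect_error(default_stage_profiles("XRF"))
})

test_that("a noiseless unit-area Gaussian band integrates to 1", {
  fwhm <- 15
  amp <- 1 / gauss_area(1, fwhm)   # scale so analytic area is 1
  lib <- list(vibrostage:::band("u", 1500, fwhm, amp))
  prof <- list(stage = "H6", multipliers = c(u = 1))
  cfg <- generator_config(seed = 1, modality = "IR", axis_lo = 1300,
                          axis_hi = 1700, axis_step = 0.5)
  s <- generate_spectrum(lib, prof, noise_model(additive_sd = 0,
                                                baseline_coeffs = 0,
                                                co2_amplitude = 0), cfg)
  area <- integrate_band(s, 1500 - 4 * fwhm, 1500 + 4 * fwhm)
  expect_equal(area, 1.0, tolerance = 1e-3)
})

test_that("generation is deterministic in (seed, stage, index)", {
  cfg <- generator_config(seed = 5, n_per_group = 3, modality = "RAMAN")
  lib <- default_raman_band_library()
  prof <- default_stage_profiles("RAMAN")$D2
  s1 <- generate_spectrum(lib, prof, noise_model(), cfg, index = 2)
  s2 <- generate_spectrum(lib, prof, noise_model(), cfg, index = 2)
  expect_identical(s1$intensity, s2$intensity)
  s3 <- generate_spectrum(lib, prof, noise_model(), cfg, index = 3)
  expect_false(identical(s1$intensity, s3$intensity))
  g1 <- generate_group("D2", cfg); g2 <- generate_group("D2", cfg)
  expect_identical(g1$intensity, g2$intensity)
})

test_that("mean injected spike count matches the configured rate", {
  cfg <- generator_config(seed = 9, n_per_group = 1000, modality = "RAMAN",
                          axis_step = 10)  # coarse axis; spikes are per spectrum
  lib <- default_raman_band_library()
  prof <- default_stage_profiles("RAMAN")$H6
  nm <- noise_model(spike_rate = 2)
  counts <- vapply(1:1000, function(i)
    length(generate_spectrum(lib, prof, nm, cfg, index = i)$meta$spike_channels),
    numeric(1))
  expect_gte(mean(counts), 1.8)
  expect_lte(mean(counts), 2.2)
})

test_that("with vanishing noise the group mean equals the model spectrum", {
  cfg <- generator_config(seed = 3, n_per_group = 5, modality = "IR",
                          axis_step = 4)
  nm <- noise_model(additive_sd = 0, baseline_coeffs = 0, co2_amplitude = 0)
  g <- generate_group("D7", cfg, noise = nm)
  model <- vibrostage:::model_intensity(default_ir_band_library(),
                                        default_stage_profiles("IR")$D7,
                                        vibrostage:::config_axis(cfg))
  expect_equal(colMeans(g$intensity), model, tolerance = 1e-9)
})

test_that("groups of different stages differ at band channels, not in noise", {
  cfg <- generator_config(seed = 12, n_per_group = 30, modality = "IR",
                          axis_step = 2)
  g1 <- generate_group("H6", cfg); g2 <- generate_group("D2", cfg)
  wn <- g1$wavenumber
  tag_idx <- which(wn >= 1735 & wn <= 1750)
  expect_gt(mean(g1$intensity[, tag_idx]) - mean(g2$intensity[, tag_idx]), 0.2)
  # residual noise scale matches between groups (signal-free region 3400-3600)
  bg <- which(wn >= 3400 & wn <= 3600)
  sd1 <- mean(apply(g1$intensity[, bg], 2, sd))
  sd2 <- mean(apply(g2$intensity[, bg], 2, sd))
  expect_equal(sd1, sd2, tolerance = 0.15)
})

test_that("cube geometry: cell_fraction extremes and pixel counts", {
  cfg <- generator_config(seed = 2, modality = "IR", axis_lo = 1500,
                          axis_hi = 2000, axis_step = 10)
  empty <- generate_cube("H6", 8, 8, cell_fraction = 0, config = cfg)
  expect_false(any(empty$mask))
  full <- generate_cube("H6", 8, 8, cell_fraction = 1, config = cfg)
  expect_true(all(full$mask))
  expect_equal(dim(full$data), c(8, 8, length(vibrostage:::config_axis(cfg))))
  # amide-I S/N separates cell from background pixels
  half <- generate_cube("H6", 12, 12, cell_fraction = 0.4, config = cfg)
  snr <- matrix(NA_real_, 12, 12)
  for (r in 0:11) for (cc in 0:11)
    snr[r + 1, cc + 1] <- estimate_snr(extract_pixel(half, r, cc))
  expect_gt(min(snr[half$mask]), max(snr[!half$mask]))
})
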