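# analysis matrices, Ward HCA, PCA, NIPALS PLSR, profile splitting

test_that("build_matrix counts closed-interval channels in the bio-regions", {
  n <- 40
  wn <- seq(700, 3700)
  set <- spectrum_set(matrix(rnorm(n * length(wn)), nrow = n), wavenumber = wn,
                      modality = "IR")
  dm <- build_matrix(set, list(c(2800, 3050), c(920, 1750)))
  expect_equal(ncol(dm$x), 251 + 831)   # 1082 channels over a 1080 cm^-1 span
  expect_equal(nrow(dm$x), n)
  full <- build_matrix(set, list(range(wn)))
  expect_equal(ncol(full$x), length(wn))
  expect_error(build_matrix(set, list()), "region")
})

test_that("Ward clustering merges in the forced order on 1-d points", {
  x <- matrix(c(0, 1, 10), ncol = 1)
  d <- hca_ward(x)
  expect_equal(sort(d$merge[1, ]), c(-2, -1))    # 0 and 1 merge first
  expect_gt(d$height[2], d$height[1])
})

test_that("Ward linkage equals the brute-force Lance-Williams oracle (n <= 6)", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(4:6, 1)
    x <- matrix(rnorm(n * 3), nrow = n)
    got <- hca_ward(x)
    oracle <- brute_ward(x)
    expect_equal(got$height, oracle$height, tolerance = 1e-9)
    # same partition sequence (merge rows as unordered pairs)
    expect_equal(lapply(seq_len(n - 1), function(i) sort(got$merge[i, ])),
                 lapply(seq_len(n - 1), function(i) sort(oracle$merge[i, ])))
  }
})

test_that("merge heights are monotone and duplicated rows merge first", {
  set.seed(9)
  x <- matrix(rnorm(8 * 5), nrow = 8)
  x[5, ] <- x[2, ]   # exact duplicate
  d <- hca_ward(x)
  expect_true(all(diff(d$height) >= -1e-12))
  expect_equal(sort(d$merge[1, ]), c(-5, -2))
  expect_lt(d$height[1], 1e-9)
})

test_that("cutting the synthetic tree isolates the day-2 group exactly", {
  cfg <- generator_config(seed = 17, n_per_group = 8, modality = "IR")
  sets <- lapply(c("H6", "D2", "NC2D"), function(st)
    preprocess_ir_spectra(generate_group(st, cfg)))
  all <- do.call(bind_sets, sets)
  dm <- build_matrix(all, list(c(2800, 3050), c(920, 1750)))
  cl <- cut_dendrogram(hca_ward(dm), k = 2)
  is_d2 <- all$meta$group == "D2"
  # Rand index 1: the 2-cluster cut coincides with D2 vs rest
  expect_length(unique(cl[is_d2]), 1)
  expect_length(unique(cl[!is_d2]), 1)
  expect_false(unique(cl[is_d2]) == unique(cl[!is_d2]))
})

test_that("PCA: rank-1 data, completeness, ordered variance, sign convention", {
  set.seed(4)
  t <- rnorm(12)
  line <- cbind(2 * t, -t, 0.5 * t)        # exactly rank 1
  suppressWarnings(p1 <- spectra_pca(line, 1))
  expect_equal(p1$explained[1], 1, tolerance = 1e-9)
  x <- matrix(rnorm(10 * 6), nrow = 10)
  pf <- spectra_pca(x, 6)
  rec <- sweep(pf$scores %*% t(pf$loadings), 2, pf$center, `+`)
  expect_equal(rec, x, tolerance = 1e-6)
  expect_true(all(diff(pf$explained) <= 1e-12))
  expect_lte(sum(pf$explained), 1 + 1e-9)
  # orthonormal loadings, deterministic sign
  expect_equal(crossprod(pf$loadings), diag(6), tolerance = 1e-6)
  for (j in 1:6) expect_gt(pf$loadings[which.max(abs(pf$loadings[, j])), j], 0)
  expect_warning(spectra_pca(line, 3), "rank")
})

test_that("synthetic two-group IR matrix separates along PC-1", {
  cfg <- generator_config(seed = 18, n_per_group = 10, modality = "IR")
  a <- preprocess_ir_spectra(generate_group("H6", cfg))
  b <- preprocess_ir_spectra(generate_group("D2", cfg))
  dm <- build_matrix(bind_sets(a, b), list(c(950, 3050)))
  p <- spectra_pca(dm, 3)
  s1 <- p$scores[1:10, 1]; s2 <- p$scores[11:20, 1]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))
})

test_that("NIPALS PLS1: exact linear case, OLS at full rank, orthogonal scores", {
  set.seed(6)
  x <- matrix(rnorm(12 * 3), nrow = 12)
  y01 <- as.numeric(x[, 2] > 0)
  # y exactly linear in one column -> near-perfect fit
  ybin <- rep(c(0, 1), 6)
  xlin <- cbind(ybin, rnorm(12, 0, 1e-8))
  m1 <- plsr_calibrate(xlin, ybin, n_factors = 2, cross_validate = FALSE)
  expect_lt(m1$rmsec, 1e-6)
  expect_gt(m1$r2c, 1 - 1e-9)
  # full-rank factors reproduce least squares
  m <- plsr_calibrate(x, y01, n_factors = 3, cross_validate = FALSE)
  ols <- stats::lm.fit(cbind(1, x), y01)
  pred_ols <- drop(cbind(1, x) %*% ols$coefficients)
  expect_equal(m$fitted, pred_ols, tolerance = 1e-6)
  # factor scores are mutually orthogonal
  g <- crossprod(m$scores)
  expect_equal(g - diag(diag(g)), matrix(0, 3, 3), tolerance = 1e-6)
  expect_error(plsr_calibrate(x, rep(1, 12)), "both classes")
  expect_error(plsr_calibrate(x, y01 + 0.5), "0/1")
})

test_that("first PLS factor follows the dominant covariance direction", {
  set.seed(13)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  x <- cbind(y + rnorm(n, 0, 0.05), rnorm(n, 0, 1))
  m <- plsr_calibrate(x, y, n_factors = 1, cross_validate = FALSE)
  # the first weight vector is the normalized X'y covariance direction
  xc <- scale(x, scale = FALSE); yc <- y - mean(y)
  w_oracle <- drop(crossprod(xc, yc)); w_oracle <- w_oracle / sqrt(sum(w_oracle^2))
  expect_equal(abs(drop(m$weights[, 1])), abs(w_oracle), tolerance = 1e-9)
  # and it is dominated by the informative column
  expect_gt(abs(m$weights[1, 1]), 0.9)
})

test_that("permuted labels yield no cross-validated explanatory power", {
  cfg <- generator_config(seed = 19, n_per_group = 12, modality = "IR",
                          axis_step = 4)
  a <- preprocess_ir_spectra(generate_group("H6", cfg))
  b <- preprocess_ir_spectra(generate_group("D2", cfg))
  dm <- build_matrix(bind_sets(a, b), list(c(950, 3050)))
  y <- rep(c(0, 1), each = 12)
  r2vs <- vapply(1:20, function(i) {
    set.seed(100 + i)
    yp <- sample(y)
    plsr_calibrate(dm$x, yp, n_factors = 5)$r2v
  }, numeric(1))
  expect_true(all(r2vs <= 0.2))
})

test_that("classification: self-test TPR 100, counting vs hand tally", {
  set.seed(23)
  x <- matrix(rnorm(20 * 4), nrow = 20)
  y <- rep(c(0, 1), 10)
  x[, 1] <- y + rnorm(20, 0, 0.01)
  m <- plsr_calibrate(x, y, n_factors = 2, cross_validate = FALSE)
  self <- plsr_classify(m, x, y)
  expect_equal(self$tpr, 100)
  # all-one-class test input: TPR equals the predicted-positive fraction
  ones <- x[y == 1, , drop = FALSE]
  rep1 <- plsr_classify(m, ones, rep(1, nrow(ones)))
  expect_equal(rep1$tpr,
               100 * sum(rep1$predicted_class == 1) / nrow(ones))
  expect_error(plsr_classify(m, x[, 1:3], y), "columns")
})

test_that("stratified split keeps both classes and the requested fraction", {
  y <- rep(c(0, 1), each = 50)
  sp <- stratified_split(y, 0.2, seed = 3)
  expect_length(sp$test, 20)
  expect_equal(sum(y[sp$test]), 10)
  expect_setequal(c(sp$test, sp$calibration), seq_along(y))
  sp2 <- stratified_split(y, 0.2, seed = 3)
  expect_identical(sp$test, sp2$test)
})

test_that("the profile split recovers the generator's ground-truth labels", {
  cfg <- generator_config(seed = 24, n_per_group = 8, modality = "RAMAN",
                          axis_step = 2)
  lip <- preprocess_raman(generate_group("D7", cfg, profile_label = "LIPIDIC"))$set
  pro <- preprocess_raman(generate_group("D7", cfg,
                                         profile_label = "PROTEINACEOUS"))$set
  sl <- split_raman_profiles(lip)
  sp <- split_raman_profiles(pro)
  expect_true(all(sl$profile == "LIPIDIC"))
  expect_true(all(sp$profile == "PROTEINACEOUS"))
  # an infinite threshold sends everything to proteinaceous
  expect_true(all(split_raman_profiles(lip, threshold = Inf)$profile ==
                    "PROTEINACEOUS"))
  # axis must cover the high-wavenumber CH region
  low <- vibrostage:::map_spectra(pro, crop, 700, 2000)
  expect_error(split_raman_profiles(low), "high-wavenumber")
})
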