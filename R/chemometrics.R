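# Multivariate layer: analysis matrices, Ward/Euclidean HCA, mean-centered
# PCA, NIPALS PLS1 regression with leave-one-out cross-validation, held-out
# classification, and the lipidic/proteinaceous Raman profile split.

#' Build an analysis matrix from a spectrum set
#'
#' Rows are spectra (observations), columns the union of axis channels that
#' fall inside any of the requested closed regions, in ascending wavenumber
#' order. Row labels carry `(group, id)`.
#'
#' @param set a [spectrum_set()]
#' @param regions list of `c(lo, hi)` windows (cm^-1); e.g. the HCA
#'   bio-regions `list(c(2800, 3050), c(920, 1750))`
#' @return object of class `vib_data_matrix`: `x` (numeric matrix),
#'   `wavenumber` (column wavenumbers), `meta` (row metadata)
#' @export
build_matrix <- function(set, regions) {
  stopifnot(inherits(set, "vib_spectrum_set"))
  if (!length(regions)) stop_contract("at least one region is required")
  idx <- sort(unique(unlist(lapply(regions, function(r)
    axis_window_idx(set$wavenumber, r[1], r[2])))))
  if (!length(idx)) stop_contract("no axis channels fall inside the regions")
  x <- set$intensity[, idx, drop = FALSE]
  if (anyNA(x)) stop_contract("analysis matrix contains missing values")
  structure(list(x = x, wavenumber = set$wavenumber[idx], meta = set$meta),
            class = "vib_data_matrix")
}

#' @export
print.vib_data_matrix <- function(x, ...) {
  cat(sprintf("<vib_data_matrix> %d spectra x %d channels (%.0f-%.0f cm^-1)\n",
              nrow(x$x), ncol(x$x), min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}

#' Ward/Euclidean hierarchical clustering
#'
#' Agglomerative clustering of the matrix rows with Euclidean distances and
#' Ward's minimum-variance linkage (the `ward.D2` criterion, i.e. the
#' Lance-Williams update on squared distances with heights on the distance
#' scale). Merge heights are monotone non-decreasing and are reported as the
#' heterogeneity scale of the dendrogram.
#'
#' @param m a [build_matrix()] result or plain numeric matrix (>= 2 rows)
#' @return object of class `vib_dendrogram` wrapping the `hclust` fit:
#'   `merge`, `height`, `labels`, and `$hclust` for plotting
#' @export
hca_ward <- function(m) {
  x <- if (inherits(m, "vib_data_matrix")) m$x else as.matrix(m)
  if (nrow(x) < 2L) stop_contract("clustering needs >= 2 rows")
  labels <- if (inherits(m, "vib_data_matrix"))
    paste(m$meta$group, m$meta$id, sep = ":") else rownames(x) %||%
      as.character(seq_len(nrow(x)))
  hc <- stats::hclust(stats::dist(x, method = "euclidean"), method = "ward.D2")
  hc$labels <- labels
  structure(list(merge = hc$merge, height = hc$height, labels = labels,
                 hclust = hc), class = "vib_dendrogram")
}

#' @export
print.vib_dendrogram <- function(x, ...) {
  cat(sprintf("<vib_dendrogram> %d leaves, max heterogeneity %.3g\n",
              length(x$labels), max(x$height)))
  invisible(x)
}

#' @export
plot.vib_dendrogram <- function(x, ...) {
  plot(x$hclust, ylab = "heterogeneity", ...)
  invisible(x)
}

#' Cut a dendrogram into k clusters
#' @param dend a [hca_ward()] result
#' @param k number of clusters
#' @return integer cluster assignment per leaf
#' @export
cut_dendrogram <- function(dend, k) {
  stats::cutree(dend$hclust, k = k)
}

#' Mean-centered principal component analysis
#'
#' SVD of the column-centered matrix. Loading signs are fixed so each
#' loading's largest-magnitude element is positive, making scores
#' reproducible across runs and platforms. If `n_components` exceeds the
#' matrix rank it is truncated with a warning.
#'
#' @param m a [build_matrix()] result or numeric matrix (>= 2 rows)
#' @param n_components number of components retained (default 7)
#' @return object of class `vib_pca`: `scores` (obs x comp), `loadings`
#'   (channel x comp), `center`, `explained` (variance fractions,
#'   non-increasing), `wavenumber` when available
#' @export
spectra_pca <- function(m, n_components = 7L) {
  x <- if (inherits(m, "vib_data_matrix")) m$x else as.matrix(m)
  if (nrow(x) < 2L) stop_contract("PCA needs >= 2 rows")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sv <- svd(xc)
  pos <- sv$d > max(dim(xc)) * .Machine$double.eps * max(sv$d, 1)
  rank <- sum(pos)
  if (n_components > rank) {
    warning(sprintf("n_components (%d) exceeds rank (%d); truncated",
                    n_components, rank))
    n_components <- rank
  }
  k <- seq_len(n_components)
  load <- sv$v[, k, drop = FALSE]
  # deterministic sign: largest |element| of each loading is positive
  flip <- vapply(k, function(j) sign(load[which.max(abs(load[, j])), j]),
                 numeric(1))
  load <- sweep(load, 2, flip, `*`)
  scores <- xc %*% load
  var_all <- sum(sv$d^2)
  structure(list(scores = scores, loadings = load, center = mu,
                 sdev = sv$d[k] / sqrt(max(1, nrow(x) - 1)),
                 explained = sv$d[k]^2 / var_all,
                 wavenumber = if (inherits(m, "vib_data_matrix")) m$wavenumber else NULL,
                 meta = if (inherits(m, "vib_data_matrix")) m$meta else NULL),
            class = "vib_pca")
}

#' @export
print.vib_pca <- function(x, ...) {
  cat(sprintf("<vib_pca> %d components, explained: %s\n", ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", ")))
  invisible(x)
}

# core NIPALS PLS1 on centered data; returns factors and coefficients
nipals_pls1 <- function(xc, yc, n_factors) {
  n <- nrow(xc); p <- ncol(xc)
  n_factors <- min(n_factors, n - 1L, p)
  W <- matrix(0, p, n_factors); P <- matrix(0, p, n_factors)
  Tm <- matrix(0, n, n_factors); q <- numeric(n_factors)
  X <- xc; y <- yc
  used <- 0L
  for (a in seq_len(n_factors)) {
    w <- crossprod(X, y)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-300) break
    w <- w / wn
    t <- X %*% w
    tt <- sum(t^2)
    if (tt < 1e-300) break
    pv <- crossprod(X, t) / tt
    qa <- sum(y * t) / tt
    X <- X - t %*% t(pv)
    y <- y - qa * t
    W[, a] <- w; P[, a] <- pv; Tm[, a] <- t; q[a] <- qa
    used <- a
  }
  if (used == 0L) stop_contract("NIPALS extracted no factors (degenerate input)")
  W <- W[, 1:used, drop = FALSE]; P <- P[, 1:used, drop = FALSE]
  Tm <- Tm[, 1:used, drop = FALSE]; q <- q[1:used]
  coef <- W %*% solve(t(P) %*% W, q)
  list(W = W, P = P, scores = Tm, q = q, coef = drop(coef), n_factors = used)
}

#' Calibrate a NIPALS PLS regression model
#'
#' PLS1 on the centered predictor matrix and a 0/1 dummy response (one
#' factor extracted per deflation step; fully deterministic). Calibration
#' statistics (RMSEC, R2C) come from the fit; validation statistics (RMSEV,
#' R2V) from leave-one-out cross-validation (the deterministic reading of
#' "full cross-validation").
#'
#' @param m a [build_matrix()] result or numeric matrix
#' @param y binary response (0/1, both classes present), one value per row
#' @param n_factors maximum number of PLS factors (default 10)
#' @param cross_validate set `FALSE` to skip the leave-one-out pass
#' @return object of class `vib_plsr`: `coef`, `intercept`, `x_center`,
#'   `y_center`, `scores`, `weights`, `loadings`, `fitted`, `rmsec`, `r2c`,
#'   `rmsev`, `r2v`, `cv_predictions`, `threshold` (0.5)
#' @export
plsr_calibrate <- function(m, y, n_factors = 10L, cross_validate = TRUE) {
  x <- if (inherits(m, "vib_data_matrix")) m$x else as.matrix(m)
  y <- as.numeric(y)
  if (length(y) != nrow(x)) stop_contract("y length must match rows of m")
  if (!all(y %in% c(0, 1))) stop_contract("y must be a 0/1 dummy response")
  if (length(unique(y)) < 2L) stop_contract("both classes must be present in y")
  mu_x <- colMeans(x); mu_y <- mean(y)
  fit <- nipals_pls1(sweep(x, 2, mu_x), y - mu_y, n_factors)
  pred <- drop(sweep(x, 2, mu_x) %*% fit$coef) + mu_y
  rmsec <- sqrt(mean((pred - y)^2))
  r2c <- 1 - sum((pred - y)^2) / sum((y - mu_y)^2)
  rmsev <- r2v <- NA_real_
  cvp <- NULL
  if (cross_validate) {
    n <- nrow(x)
    cvp <- numeric(n)
    for (i in seq_len(n)) {
      xi <- x[-i, , drop = FALSE]; yi <- y[-i]
      if (length(unique(yi)) < 2L) { cvp[i] <- mean(yi); next }
      mx <- colMeans(xi); my <- mean(yi)
      f <- nipals_pls1(sweep(xi, 2, mx), yi - my, n_factors)
      cvp[i] <- drop((x[i, ] - mx) %*% f$coef) + my
    }
    rmsev <- sqrt(mean((cvp - y)^2))
    r2v <- 1 - sum((cvp - y)^2) / sum((y - mu_y)^2)
  }
  structure(list(coef = fit$coef, intercept = mu_y - sum(mu_x * fit$coef),
                 x_center = mu_x, y_center = mu_y,
                 wavenumber = if (inherits(m, "vib_data_matrix")) m$wavenumber else NULL,
                 scores = fit$scores, weights = fit$W, loadings = fit$P,
                 n_factors = fit$n_factors, fitted = pred,
                 rmsec = rmsec, r2c = r2c, rmsev = rmsev, r2v = r2v,
                 cv_predictions = cvp, threshold = 0.5),
            class = "vib_plsr")
}

#' @export
print.vib_plsr <- function(x, ...) {
  cat(sprintf("<vib_plsr> %d factors | RMSEC %.3g, R2C %.3g | RMSEV %.3g, R2V %.3g\n",
              x$n_factors, x$rmsec, x$r2c, x$rmsev, x$r2v))
  invisible(x)
}

#' Predict the PLSR response for new spectra
#' @param object a [plsr_calibrate()] model
#' @param newdata a [build_matrix()] result or numeric matrix with the
#'   training columns
#' @param ... unused
#' @return numeric predicted response per row
#' @export
predict.vib_plsr <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "vib_data_matrix")) newdata$x else as.matrix(newdata)
  if (ncol(x) != length(object$coef))
    stop_contract("test matrix has %d columns; model expects %d",
                  ncol(x), length(object$coef))
  drop(sweep(x, 2, object$x_center) %*% object$coef) + object$y_center
}

#' Classify held-out spectra with a PLSR model
#'
#' Thresholds the predicted dummy response at the model threshold (0.5):
#' predictions above it are assigned the positive class. The true positive
#' rate is the percentage of true positives (rows of `y_true == 1`) that are
#' predicted positive.
#'
#' @param model a [plsr_calibrate()] model
#' @param m_test test matrix (same columns as training)
#' @param y_true 0/1 reference labels for the test rows
#' @return list: `predicted_response`, `predicted_class` (0/1), `tpr`
#'   (percent), `counts` (predicted counts per class), `n_positive`
#' @export
plsr_classify <- function(model, m_test, y_true) {
  pred <- predict(model, m_test)
  y_true <- as.numeric(y_true)
  if (length(y_true) != length(pred))
    stop_contract("y_true length must match test rows")
  cls <- as.integer(pred > model$threshold)
  pos <- y_true == 1
  tpr <- if (any(pos)) 100 * sum(cls[pos] == 1) / sum(pos) else NA_real_
  list(predicted_response = pred, predicted_class = cls, tpr = tpr,
       counts = c(negative = sum(cls == 0), positive = sum(cls == 1)),
       n_positive = sum(pos))
}

#' Split Raman spectra into lipidic and proteinaceous profiles
#'
#' Labels each spectrum by the ratio of the lipid CH2 stretch area
#' (2840-2870 cm^-1) to the protein CH3 stretch area (2920-2940 cm^-1),
#' chord-corrected: ratios above `threshold` (default 1) are lipid-body
#' ("LIPIDIC") spectra, the rest cytoplasm/nucleus ("PROTEINACEOUS").
#'
#' @param set a preprocessed Raman [spectrum_set()] whose axis covers the
#'   high-wavenumber CH region
#' @param threshold decision ratio
#' @return data frame: `id`, `group`, `criterion`, `profile`
#' @export
split_raman_profiles <- function(set, threshold = 1.0) {
  stopifnot(inherits(set, "vib_spectrum_set"))
  if (set$modality != "RAMAN") stop_contract("profile split expects Raman spectra")
  if (max(set$wavenumber) < 2940 || min(set$wavenumber) > 2840)
    stop_contract("axis does not cover the high-wavenumber CH region (2840-2940)")
  crit <- vapply(seq_len(n_spectra(set)), function(i) {
    s <- get_spectrum(set, i)
    integrate_band(s, 2840, 2870, mode = "LOCAL_LINEAR") /
      integrate_band(s, 2920, 2940, mode = "LOCAL_LINEAR")
  }, numeric(1))
  data.frame(id = set$meta$id, group = set$meta$group, criterion = crit,
             profile = ifelse(crit > threshold, "LIPIDIC", "PROTEINACEOUS"),
             stringsAsFactors = FALSE)
}

#' Stratified calibration/test split
#'
#' Splits row indices into a calibration and a held-out test part, sampling
#' `1 - test_fraction` of each class for calibration (stratified, so neither
#' part can lose a class at small n).
#'
#' @param y class labels (one per row)
#' @param test_fraction held-out fraction (default 0.2)
#' @param seed RNG seed controlling the split
#' @return list with integer index vectors `calibration` and `test`
#' @export
stratified_split <- function(y, test_fraction = 0.2, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop_contract("test_fraction must be in (0, 1)")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(seed, "split"))
  test <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_test <- max(1L, round(length(idx) * test_fraction))
    test <- c(test, sample(idx, n_test))
  }
  test <- sort(test)
  list(calibration = setdiff(seq_along(y), test), test = test)
}
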