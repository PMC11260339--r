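# Per-spectrum and per-cube preprocessing stages. Each stage is a pure
# function of its inputs; the full chains are assembled in pipelines.R.

#' Cosmic-ray (spike) removal
#'
#' Flags channels whose residual against a running median of `filter_size`
#' points exceeds `dynamic_factor` times the robust scale (MAD) of the
#' residuals, and replaces them by linear interpolation from the nearest
#' unflagged channels. Flagging/replacement is iterated until no new channel
#' is flagged, so spike clusters narrower than the filter are also removed.
#' Unflagged channels are returned bit-exactly unchanged.
#'
#' @param s a Raman [spectrum()]
#' @param filter_size odd running-median window in points (default 3)
#' @param dynamic_factor robust z-score threshold (default 8)
#' @param max_iter safety cap on flagging passes
#' @return the despiked [spectrum()]; `meta$despiked_channels` lists the
#'   replaced channel indices
#' @export
remove_cosmic_rays <- function(s, filter_size = 3L, dynamic_factor = 8,
                               max_iter = 10L) {
  stopifnot(inherits(s, "vib_spectrum"))
  if (filter_size %% 2 == 0 || filter_size < 3)
    stop_contract("filter_size must be odd and >= 3")
  if (dynamic_factor <= 0) stop_contract("dynamic_factor must be > 0")
  n <- length(s$intensity)
  if (filter_size > n) stop_contract("filter window (%d) larger than spectrum (%d)",
                                     filter_size, n)
  y <- s$intensity
  flagged <- logical(n)
  for (iter in seq_len(max_iter)) {
    med <- stats::runmed(y, filter_size, endrule = "median")
    resid <- y - med
    # robust noise scale from first differences: the running-median residuals
    # are zero-inflated (the center point is its own median 1/3 of the time),
    # which would bias a direct MAD low and over-flag plain noise
    scale <- stats::mad(diff(y)) / sqrt(2)
    if (scale <= 0) scale <- stats::sd(resid)
    if (!is.finite(scale) || scale <= 0) break
    new_flags <- abs(resid) > dynamic_factor * scale & !flagged
    if (!any(new_flags)) break
    flagged <- flagged | new_flags
    good <- which(!flagged)
    if (length(good) < 2L) stop_contract("despiking flagged nearly all channels")
    y[flagged] <- stats::approx(s$wavenumber[good], s$intensity[good],
                                xout = s$wavenumber[flagged], rule = 2)$y
  }
  out <- s
  if (any(flagged)) {
    good <- which(!flagged)
    out$intensity[flagged] <- stats::approx(s$wavenumber[good], s$intensity[good],
                                            xout = s$wavenumber[flagged], rule = 2)$y
  }
  out$meta$despiked_channels <- which(flagged)
  out
}

#' Iterative polynomial baseline correction
#'
#' Fits a polynomial of the given degree, clips the working spectrum to the
#' fit wherever it lies above it, and refits until convergence (the standard
#' iterative polynomial fit for fluorescence backgrounds). The converged
#' baseline is subtracted from the original intensities.
#'
#' @param s a [spectrum()]
#' @param degree polynomial degree (default 3)
#' @param max_iter,tol convergence controls
#' @return baseline-corrected [spectrum()] (`form = "BASELINE_CORRECTED"`)
#' @export
polynomial_baseline <- function(s, degree = 3L, max_iter = 50L, tol = 1e-8) {
  stopifnot(inherits(s, "vib_spectrum"))
  n <- length(s$intensity)
  if (degree < 0) stop_contract("degree must be >= 0")
  if (degree >= n) stop_contract("degree (%d) must be < number of points (%d)", degree, n)
  x <- 2 * (s$wavenumber - min(s$wavenumber)) / diff(range(s$wavenumber)) - 1
  X <- outer(x, 0:degree, `^`)
  y_work <- s$intensity
  fit <- NULL
  scale <- max(abs(s$intensity), 1e-12)
  for (i in seq_len(max_iter)) {
    coef <- qr.coef(qr(X), y_work)
    fit <- drop(X %*% coef)
    y_new <- pmin(y_work, fit)
    if (max(abs(y_new - y_work)) < tol * scale) { y_work <- y_new; break }
    y_work <- y_new
  }
  out <- s
  out$intensity <- s$intensity - fit
  out$form <- "BASELINE_CORRECTED"
  out
}

# lower convex envelope through the data points (monotone chain on the
# lower hull), evaluated on the full axis
lower_hull_envelope <- function(x, y) {
  n <- length(x)
  hull <- integer(0)
  for (i in seq_len(n)) {
    while (length(hull) >= 2L) {
      a <- hull[length(hull) - 1L]; b <- hull[length(hull)]
      # drop b if it lies on or above segment a-i
      if ((y[b] - y[a]) * (x[i] - x[a]) >= (y[i] - y[a]) * (x[b] - x[a]))
        hull <- hull[-length(hull)]
      else break
    }
    hull <- c(hull, i)
  }
  stats::approx(x[hull], y[hull], xout = x)$y
}

#' Rubber-band baseline correction
#'
#' Subtracts the lower convex envelope (the "rubber band" stretched under the
#' spectrum). The pass is applied `iterations` times; after the first pass the
#' envelope of the corrected spectrum is the zero line, so further passes are
#' no-ops and the operation is idempotent. Output is >= -1e-9 everywhere.
#'
#' @param s a [spectrum()] with at least 3 points
#' @param iterations number of envelope passes (default 10)
#' @return baseline-corrected [spectrum()]
#' @export
rubberband_baseline <- function(s, iterations = 10L) {
  stopifnot(inherits(s, "vib_spectrum"))
  if (iterations < 1) stop_contract("iterations must be >= 1")
  if (length(s$intensity) < 3L) stop_contract("rubber-band needs >= 3 points")
  y <- s$intensity
  for (i in seq_len(iterations)) {
    env <- lower_hull_envelope(s$wavenumber, y)
    y <- y - env
    if (max(abs(env)) < 1e-12) break
  }
  out <- s
  out$intensity <- y
  out$form <- "BASELINE_CORRECTED"
  out
}

#' Savitzky-Golay smoothing / differentiation
#'
#' Least-squares convolution filter (delegated to [signal::sgolayfilt()]);
#' derivatives are scaled by the axis step so a second derivative is in units
#' per (cm^-1)^2. Edges are handled by the off-center polynomial fits of the
#' first/last full window. Requires a uniformly spaced axis.
#'
#' @param s a [spectrum()]
#' @param window_pts odd window length in points (9 for the Raman smooth,
#'   13 for the IR smooth and second derivative)
#' @param polyorder polynomial order (< `window_pts`)
#' @param deriv derivative order (0 = smoothing; must be <= `polyorder`)
#' @return filtered [spectrum()]; `form` becomes `"SECOND_DERIVATIVE"` when
#'   `deriv == 2`
#' @export
savgol <- function(s, window_pts = 9L, polyorder = 3L, deriv = 0L) {
  stopifnot(inherits(s, "vib_spectrum"))
  if (window_pts %% 2 == 0) stop_contract("window_pts must be odd")
  if (polyorder >= window_pts) stop_contract("polyorder must be < window_pts")
  if (deriv > polyorder) stop_contract("deriv (%d) must be <= polyorder (%d)",
                                       deriv, polyorder)
  if (window_pts > length(s$intensity))
    stop_contract("window (%d points) larger than spectrum (%d points)",
                  window_pts, length(s$intensity))
  if (!axis_is_uniform(s$wavenumber))
    stop_contract("Savitzky-Golay requires a uniform axis; resample first")
  step <- if (length(s$wavenumber) > 1) diff(s$wavenumber[1:2]) else 1
  out <- s
  out$intensity <- as.numeric(signal::sgolayfilt(s$intensity, p = polyorder,
                                                 n = window_pts, m = deriv,
                                                 ts = step))
  if (deriv == 2L) out$form <- "SECOND_DERIVATIVE"
  out
}

#' Vector normalization
#'
#' Subtracts the mean over the normalization region and scales the whole
#' spectrum so the Euclidean norm over that region is 1. Idempotent, and
#' invariant to affine transforms `a*x + b` (a > 0) of the input.
#'
#' @param s a [spectrum()]
#' @param region optional `c(lo, hi)` window (cm^-1); default the full axis
#' @return normalized [spectrum()] (`form = "NORMALIZED"` unless the input was
#'   a second derivative, which it remains)
#' @export
vector_normalize <- function(s, region = NULL) {
  stopifnot(inherits(s, "vib_spectrum"))
  idx <- if (is.null(region)) seq_along(s$wavenumber)
         else axis_window_idx(s$wavenumber, region[1], region[2])
  if (length(idx) < 2L) stop_contract("normalization region holds < 2 channels")
  y <- s$intensity
  m <- mean(y[idx])
  centered <- y - m
  nrm <- sqrt(sum(centered[idx]^2))
  if (nrm < 1e-300 || stats::sd(y[idx]) == 0)
    stop_contract("cannot vector-normalize a constant region")
  out <- s
  out$intensity <- centered / nrm
  if (out$form != "SECOND_DERIVATIVE") out$form <- "NORMALIZED"
  out
}

#' Crop a spectrum to a closed wavenumber window
#'
#' @param s a [spectrum()]
#' @param lo,hi window bounds; channels with `lo <= wavenumber <= hi` are kept
#' @return cropped [spectrum()]
#' @export
crop <- function(s, lo, hi) {
  stopifnot(inherits(s, "vib_spectrum"))
  idx <- axis_window_idx(s$wavenumber, lo, hi)
  if (!length(idx)) stop_contract("window [%g, %g] contains no channels", lo, hi)
  out <- s
  out$wavenumber <- s$wavenumber[idx]
  out$intensity <- s$intensity[idx]
  out
}

#' Flatten the atmospheric CO2 band
#'
#' Replaces the intensities between 2200 and 2400 cm^-1 by the straight line
#' joining the boundary channel values, removing the CO2 asymmetric-stretch
#' artefact from transmission FTIR spectra. Channels outside the range are
#' untouched; the boundary channels keep their values exactly.
#'
#' @param s an IR [spectrum()] whose axis covers \[2200, 2400\]
#' @param lo,hi replacement range (cm^-1)
#' @return corrected [spectrum()]
#' @export
flatten_co2 <- function(s, lo = 2200, hi = 2400) {
  stopifnot(inherits(s, "vib_spectrum"))
  idx <- axis_window_idx(s$wavenumber, lo, hi)
  if (length(idx) < 2L)
    stop_contract("axis does not cover the CO2 range [%g, %g]", lo, hi)
  i0 <- idx[1]; i1 <- idx[length(idx)]
  x <- s$wavenumber
  line <- s$intensity[i0] + (s$intensity[i1] - s$intensity[i0]) *
    (x[idx] - x[i0]) / (x[i1] - x[i0])
  out <- s
  out$intensity[idx] <- line
  out
}

#' PCA noise reduction of a hyperspectral cube
#'
#' Reconstructs every pixel spectrum from the leading principal components of
#' the mean-centered pixel x channel matrix (13 components by default),
#' discarding the noise-dominated minor components.
#'
#' @param cube a [hypercube()] with at least 2 pixels
#' @param n_pcs number of components retained
#' @return the denoised [hypercube()]
#' @export
pca_denoise <- function(cube, n_pcs = 13L) {
  stopifnot(inherits(cube, "vib_hypercube"))
  m <- cube_matrix(cube)
  if (nrow(m) < 2L) stop_contract("PCA denoising needs >= 2 pixels")
  if (n_pcs > min(dim(m)))
    stop_contract("n_pcs (%d) exceeds min(n_pixels, n_channels) = %d",
                  n_pcs, min(dim(m)))
  mu <- colMeans(m)
  mc <- sweep(m, 2, mu)
  sv <- svd(mc, nu = n_pcs, nv = n_pcs)
  rec <- sv$u %*% (sv$d[seq_len(n_pcs)] * t(sv$v))
  matrix_to_cube(sweep(rec, 2, mu, `+`), cube)
}

#' Amide-I signal-to-noise ratio of a spectrum
#'
#' S/N = (maximum over the signal window minus the local linear baseline
#' across it) divided by the standard deviation of the linearly detrended
#' noise window. The default windows are the amide I region (1620-1680 cm^-1,
#' protein signal) and a signal-free region (1800-1900 cm^-1).
#'
#' @param s a [spectrum()]
#' @param signal_window,noise_window `c(lo, hi)` windows (cm^-1), both inside
#'   the axis
#' @return non-negative S/N value (`Inf` when the noise window is exactly
#'   linear, e.g. on noiseless synthetic input)
#' @export
estimate_snr <- function(s, signal_window = c(1620, 1680),
                         noise_window = c(1800, 1900)) {
  stopifnot(inherits(s, "vib_spectrum"))
  si <- axis_window_idx(s$wavenumber, signal_window[1], signal_window[2])
  ni <- axis_window_idx(s$wavenumber, noise_window[1], noise_window[2])
  if (length(si) < 2L || length(ni) < 3L)
    stop_contract("S/N windows fall outside the spectrum axis")
  xs <- s$wavenumber[si]; ys <- s$intensity[si]
  chord <- ys[1] + (ys[length(ys)] - ys[1]) * (xs - xs[1]) / (xs[length(xs)] - xs[1])
  peak <- max(ys - chord)
  xn <- s$wavenumber[ni]; yn <- s$intensity[ni]
  res <- stats::lm.fit(cbind(1, xn), yn)$residuals
  noise_sd <- stats::sd(res)
  if (noise_sd <= 1e-12 * max(abs(yn), 1)) return(Inf)  # noiseless input
  max(peak, 0) / noise_sd
}

# vectorized per-ROI mean pixel S/N (same definition as estimate_snr)
snr_cube_means <- function(cube, rois, signal_window, noise_window) {
  wn <- cube$wavenumber
  si <- axis_window_idx(wn, signal_window[1], signal_window[2])
  ni <- axis_window_idx(wn, noise_window[1], noise_window[2])
  if (length(si) < 2L || length(ni) < 3L)
    stop_contract("S/N windows fall outside the cube axis")
  xs <- wn[si]
  w <- (xs - xs[1]) / (xs[length(xs)] - xs[1])
  Xn <- cbind(1, wn[ni])
  Pn <- Xn %*% solve(crossprod(Xn), t(Xn))  # symmetric projector
  vapply(rois, function(r) {
    sub <- cube$data[r$row0 + seq_len(r$height), r$col0 + seq_len(r$width), ,
                     drop = FALSE]
    d <- dim(sub)
    m <- matrix(aperm(sub, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
    S <- m[, si, drop = FALSE]
    chord <- outer(S[, 1], 1 - w) + outer(S[, length(si)], w)
    peak <- pmax(apply(S - chord, 1, max), 0)
    Nw <- m[, ni, drop = FALSE]
    res <- Nw - Nw %*% Pn
    noise_sd <- sqrt(rowSums(res^2) / (length(ni) - 1))
    snr <- ifelse(noise_sd == 0, Inf, peak / noise_sd)
    fin <- snr[is.finite(snr)]
    if (!length(fin)) Inf else mean(fin)
  }, numeric(1))
}

#' Select regions of interest by signal-to-noise
#'
#' Tiles the cube into non-overlapping candidate ROIs of `roi_shape` pixels,
#' ranks candidates by their mean pixel S/N in the amide I region, and
#' returns the top `n_rois`. By default the tile is half the cube in each
#' dimension, matching one FPA tile within a 2 x 2 mosaic (four 700 um x
#' 700 um ROIs per 1400 um x 1400 um image). Ties are broken in a
#' seed-determined order. Set `random = TRUE` to sample candidates uniformly
#' instead of ranking by S/N.
#'
#' @param cube a [hypercube()]
#' @param n_rois number of ROIs returned (default 4)
#' @param roi_shape `c(height, width)` in pixels; default `dim/2`
#' @param signal_window,noise_window passed to [estimate_snr()]
#' @param seed tie-break / sampling seed
#' @param random sample candidates uniformly instead of ranking by S/N
#' @return list of [roi()] objects
#' @export
select_rois <- function(cube, n_rois = 4L, roi_shape = NULL,
                        signal_window = c(1620, 1680),
                        noise_window = c(1800, 1900),
                        seed = 1L, random = FALSE) {
  stopifnot(inherits(cube, "vib_hypercube"))
  roi_shape <- roi_shape %||% c(max(1L, cube$n_rows %/% 2L),
                                max(1L, cube$n_cols %/% 2L))
  th <- roi_shape[1]; tw <- roi_shape[2]
  nr <- cube$n_rows %/% th; nc <- cube$n_cols %/% tw
  cand <- list()
  for (i in seq_len(nr) - 1L) for (j in seq_len(nc) - 1L)
    cand[[length(cand) + 1L]] <- roi(i * th, j * tw, th, tw)
  if (length(cand) < n_rois)
    stop_contract("only %d candidate ROIs of %d x %d fit the cube; %d requested",
                  length(cand), th, tw, n_rois)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(seed, "select_rois"))
  if (random) return(cand[sample.int(length(cand), n_rois)])
  score <- snr_cube_means(cube, cand, signal_window, noise_window)
  ord <- order(-score, sample.int(length(cand)))
  cand[ord[seq_len(n_rois)]]
}

#' Average the pixel spectra of an ROI
#'
#' @param cube a [hypercube()]
#' @param r a [roi()] inside the cube
#' @return a [spectrum()]; `meta` records the ROI origin/extent and pixel count
#' @export
average_roi <- function(cube, r) {
  check_roi(cube, r)
  sub <- cube$data[r$row0 + seq_len(r$height), r$col0 + seq_len(r$width), ,
                   drop = FALSE]
  y <- apply(sub, 3, mean)
  spectrum(cube$wavenumber, y, modality = cube$modality,
           meta = list(roi = sprintf("r%d_c%d_%dx%d", r$row0, r$col0,
                                     r$height, r$width),
                       n_pixels = r$height * r$width))
}

#' Reject outlier spectra by correlation to the median spectrum
#'
#' Removes spectra whose Pearson correlation with the point-wise median
#' spectrum falls below `min_correlation` (default 0.95).
#'
#' @param set a [spectrum_set()] with at least 3 spectra
#' @param min_correlation correlation threshold in \[0, 1\]
#' @return the retained [spectrum_set()]; attribute `"rejected"` lists the
#'   removed row indices and `attr(, "correlations")` all correlations
#' @export
reject_outliers <- function(set, min_correlation = 0.95) {
  stopifnot(inherits(set, "vib_spectrum_set"))
  if (n_spectra(set) < 3L) stop_contract("outlier rejection needs >= 3 spectra")
  med <- apply(set$intensity, 2, stats::median)
  cors <- apply(set$intensity, 1, function(r) stats::cor(r, med))
  keep <- cors >= min_correlation
  if (!any(keep)) stop_contract("outlier rejection removed every spectrum")
  out <- spectrum_set(set$intensity[keep, , drop = FALSE],
                      wavenumber = set$wavenumber, modality = set$modality,
                      form = set$form, meta = set$meta[keep, , drop = FALSE])
  attr(out, "rejected") <- which(!keep)
  attr(out, "correlations") <- cors
  out
}
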