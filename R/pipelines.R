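# The two full preprocessing chains, assembled from the stage functions.

# Savitzky-Golay applied to a pixels x channels matrix (precomputed
# projection matrix; same edge handling as signal::sgolayfilt).
savgol_matrix <- function(m, step, window_pts = 13L, polyorder = 2L, deriv = 0L) {
  n <- ncol(m)
  if (window_pts > n) stop_contract("SG window larger than channel count")
  F <- signal::sgolay(p = polyorder, n = window_pts, m = deriv, ts = step)
  F <- unclass(F)
  k <- (window_pts - 1L) %/% 2L
  centre <- F[k + 1L, ]
  out <- matrix(0, nrow(m), n)
  core <- (k + 1L):(n - k)
  for (j in seq_len(window_pts))
    out[, core] <- out[, core] + centre[j] * m[, core + j - k - 1L, drop = FALSE]
  out[, 1:k] <- m[, 1:window_pts, drop = FALSE] %*% t(F[1:k, , drop = FALSE])
  out[, (n - k + 1L):n] <- m[, (n - window_pts + 1L):n, drop = FALSE] %*%
    t(F[(k + 2L):window_pts, , drop = FALSE])
  out
}

#' Smooth or differentiate every pixel of a cube (Savitzky-Golay)
#'
#' @param cube a [hypercube()] on a uniform axis
#' @param window_pts,polyorder,deriv as in [savgol()]
#' @return filtered [hypercube()]
#' @export
savgol_cube <- function(cube, window_pts = 13L, polyorder = 2L, deriv = 0L) {
  stopifnot(inherits(cube, "vib_hypercube"))
  if (!axis_is_uniform(cube$wavenumber))
    stop_contract("Savitzky-Golay requires a uniform axis")
  step <- diff(cube$wavenumber[1:2])
  m <- savgol_matrix(cube_matrix(cube), step, window_pts, polyorder, deriv)
  matrix_to_cube(m, cube)
}

#' Default preprocessing parameters
#'
#' All stage parameters of the two chains with their reference values:
#' Raman — despike (window 3, dynamic factor 8), degree-3 polynomial
#' baseline, truncation to 700-3050 cm^-1, 10 rubber-band iterations,
#' 9-point third-order smoothing, vector normalization, outlier correlation
#' threshold 0.95; IR — 13-component PCA denoising, crop to 920-3700 cm^-1,
#' 13-point second-order smoothing, amide-I S/N ROI selection (4 ROIs),
#' CO2 flattening over 2200-2400 cm^-1, 13-point second-order second
#' derivative, vector normalization.
#'
#' @return named list of parameters, suitable for the `config` argument of
#'   [preprocess_ir()] / [preprocess_raman()]
#' @export
preprocess_defaults <- function() {
  list(
    raman = list(despike = TRUE,
                 despike_filter_size = 3L, despike_dynamic_factor = 8,
                 baseline_degree = 3L, crop = c(700, 3050),
                 rubberband_iterations = 10L,
                 smooth_window = 9L, smooth_polyorder = 3L,
                 min_correlation = 0.95),
    ir = list(n_pcs = 13L, crop = c(920, 3700),
              smooth_window = 13L, smooth_polyorder = 2L,
              n_rois = 4L, roi_shape = NULL,
              snr_signal_window = c(1620, 1680),
              snr_noise_window = c(1800, 1900),
              co2_range = c(2200, 2400),
              deriv_window = 13L, deriv_polyorder = 2L,
              roi_random = FALSE, seed = 1L)
  )
}

merge_params <- function(defaults, override) {
  if (is.null(override)) return(defaults)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown))
    stop_contract("unknown preprocessing parameter(s): %s",
                  paste(unknown, collapse = ", "))
  defaults[names(override)] <- override
  defaults
}

# spectrum-level tail of the IR chain (applied to ROI means and to single
# synthetic spectra): CO2 flatten -> SG second derivative -> vector normalize
ir_spectrum_tail <- function(s, p) {
  s <- flatten_co2(s, p$co2_range[1], p$co2_range[2])
  s <- savgol(s, window_pts = p$deriv_window, polyorder = p$deriv_polyorder,
              deriv = 2L)
  vector_normalize(s)
}

#' IR imaging preprocessing chain
#'
#' Per cube: PCA denoising (13 components) -> crop to 920-3700 cm^-1 ->
#' 13-point Savitzky-Golay smoothing -> S/N-ranked selection of 4 ROIs ->
#' ROI averaging; then per ROI mean: CO2-band flattening -> 13-point
#' second-order Savitzky-Golay second derivative -> vector normalization.
#' With 10 cubes per experimental group this yields the reference scale of
#' 40 mean spectra per group; in general the output count is
#' `n_cubes * n_rois` always.
#'
#' @param cubes a [hypercube()] or list of them (one experimental group)
#' @param config named list overriding entries of `preprocess_defaults()$ir`
#' @param group group label stamped on the output spectra
#' @return a [spectrum_set()] of vector-normalized second-derivative ROI-mean
#'   spectra; `meta` records source cube and ROI
#' @export
preprocess_ir <- function(cubes, config = NULL, group = "all") {
  if (inherits(cubes, "vib_hypercube")) cubes <- list(cubes)
  stopifnot(length(cubes) >= 1L)
  p <- merge_params(preprocess_defaults()$ir, config)
  out <- list()
  for (ci in seq_along(cubes)) {
    cube <- cubes[[ci]]
    step <- tryCatch({
      cube <- pca_denoise(cube, n_pcs = p$n_pcs)
      cube <- crop_cube(cube, p$crop[1], p$crop[2])
      cube <- savgol_cube(cube, window_pts = p$smooth_window,
                          polyorder = p$smooth_polyorder, deriv = 0L)
      rois <- select_rois(cube, n_rois = p$n_rois, roi_shape = p$roi_shape,
                          signal_window = p$snr_signal_window,
                          noise_window = p$snr_noise_window,
                          seed = p$seed, random = p$roi_random)
      for (ri in seq_along(rois)) {
        s <- average_roi(cube, rois[[ri]])
        s <- ir_spectrum_tail(s, p)
        s$meta$group <- group
        s$meta$id <- sprintf("cube%d_roi%d", ci, ri)
        out[[length(out) + 1L]] <- s
      }
    }, error = function(e)
      stop_contract("IR preprocessing failed on cube %d: %s", ci, conditionMessage(e)))
  }
  spectrum_set(out)
}

#' Spectrum-level IR preprocessing chain
#'
#' The IR chain for inputs that are already single spectra rather than
#' imaging cubes (e.g. synthetic single-spectrum experiments): 13-point
#' smoothing -> CO2 flattening -> 13-point second-order second derivative ->
#' vector normalization.
#'
#' @param set an IR [spectrum_set()]
#' @param config named list overriding entries of `preprocess_defaults()$ir`
#' @return a [spectrum_set()] of normalized second-derivative spectra
#' @export
preprocess_ir_spectra <- function(set, config = NULL) {
  stopifnot(inherits(set, "vib_spectrum_set"))
  if (set$modality != "IR") stop_contract("preprocess_ir_spectra expects IR spectra")
  p <- merge_params(preprocess_defaults()$ir, config)
  map_spectra(set, function(s) {
    s <- crop(s, p$crop[1], p$crop[2])
    s <- savgol(s, window_pts = p$smooth_window, polyorder = p$smooth_polyorder,
                deriv = 0L)
    ir_spectrum_tail(s, p)
  })
}

#' Raman preprocessing chain
#'
#' Per spectrum: cosmic-ray removal (window 3, dynamic factor 8; set
#' `despike = FALSE` for spike-free input such as noiseless references, whose
#' sharp bands would otherwise be mistaken for spikes) -> degree-3
#' iterative polynomial baseline -> truncation to 700-3050 cm^-1 ->
#' rubber-band baseline (10 iterations) -> 9-point Savitzky-Golay smoothing
#' -> vector normalization; then correlation-based outlier rejection across
#' the set, and the group mean of the retained spectra.
#'
#' @param set a Raman [spectrum_set()]
#' @param config named list overriding entries of `preprocess_defaults()$raman`
#' @return list with `set` (retained preprocessed spectra), `mean` (their
#'   point-wise mean [spectrum()]) and `rejected` (indices removed)
#' @export
preprocess_raman <- function(set, config = NULL) {
  stopifnot(inherits(set, "vib_spectrum_set"))
  if (set$modality != "RAMAN") stop_contract("preprocess_raman expects Raman spectra")
  p <- merge_params(preprocess_defaults()$raman, config)
  proc <- map_spectra(set, function(s) {
    if (isTRUE(p$despike))
      s <- remove_cosmic_rays(s, filter_size = p$despike_filter_size,
                              dynamic_factor = p$despike_dynamic_factor)
    s <- polynomial_baseline(s, degree = p$baseline_degree)
    s <- crop(s, p$crop[1], p$crop[2])
    s <- rubberband_baseline(s, iterations = p$rubberband_iterations)
    s <- savgol(s, window_pts = p$smooth_window, polyorder = p$smooth_polyorder,
                deriv = 0L)
    vector_normalize(s)
  }, form = "NORMALIZED")
  rejected <- integer(0)
  if (n_spectra(proc) >= 3L) {
    proc <- reject_outliers(proc, min_correlation = p$min_correlation)
    rejected <- attr(proc, "rejected")
  }
  list(set = proc, mean = mean_spectrum(proc), rejected = rejected)
}
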