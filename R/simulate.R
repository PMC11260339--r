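# Synthetic spectra and cube generator. Every draw is a pure function of
# (seed, stage, index): a substream seed is derived per spectrum, so groups
# and cubes are reproducible element-wise regardless of evaluation order.

#' Noise and artefact model for the synthetic generator
#'
#' @param additive_sd standard deviation of additive Gaussian noise (a.u.)
#' @param baseline_coeffs polynomial coefficients (constant first, degree
#'   <= 3) evaluated on the axis rescaled to \[-1, 1\]
#' @param spike_rate expected cosmic-ray spikes per spectrum (Raman only)
#' @param spike_amplitude_range two-vector, uniform spike amplitude range
#' @param co2_amplitude amplitude of the atmospheric CO2 band at 2350 cm^-1
#'   (IR only)
#' @return list with class `vib_noise_model`
#' @export
noise_model <- function(additive_sd = 0.02,
                        baseline_coeffs = c(0.10, 0.05, -0.03, 0.02),
                        spike_rate = 0.5,
                        spike_amplitude_range = c(1, 5),
                        co2_amplitude = 0.35) {
  if (additive_sd < 0) stop_contract("additive_sd must be >= 0")
  if (spike_rate < 0) stop_contract("spike_rate must be >= 0")
  if (length(baseline_coeffs) > 4L)
    stop_contract("baseline polynomial degree must be <= 3")
  structure(list(additive_sd = additive_sd, baseline_coeffs = baseline_coeffs,
                 spike_rate = spike_rate,
                 spike_amplitude_range = spike_amplitude_range,
                 co2_amplitude = co2_amplitude),
            class = "vib_noise_model")
}

#' Generator configuration
#'
#' Defaults match the processing windows of the two modalities at 1 cm^-1
#' spacing: 920-3700 cm^-1 for IR, 700-3050 cm^-1 for Raman.
#'
#' @param seed integer master seed
#' @param n_per_group spectra per experimental group
#' @param modality `"IR"` or `"RAMAN"`
#' @param axis_lo,axis_hi,axis_step axis bounds and spacing (cm^-1); defaults
#'   depend on modality
#' @return list with class `vib_generator_config`
#' @export
generator_config <- function(seed = 1L, n_per_group = 40L,
                             modality = c("IR", "RAMAN"),
                             axis_lo = NULL, axis_hi = NULL, axis_step = 1) {
  modality <- match.arg(modality)
  axis_lo <- axis_lo %||% if (modality == "IR") 920 else 700
  axis_hi <- axis_hi %||% if (modality == "IR") 3700 else 3050
  if (axis_lo >= axis_hi) stop_contract("axis_lo must be < axis_hi")
  if (axis_step <= 0) stop_contract("axis_step must be > 0")
  if (n_per_group < 1) stop_contract("n_per_group must be >= 1")
  structure(list(seed = as.integer(seed), n_per_group = as.integer(n_per_group),
                 modality = modality, axis_lo = axis_lo, axis_hi = axis_hi,
                 axis_step = axis_step),
            class = "vib_generator_config")
}

config_axis <- function(config) seq(config$axis_lo, config$axis_hi, by = config$axis_step)

# band profile evaluated on an axis
band_shape <- function(b, wavenumber, amplitude = NULL) {
  a <- amplitude %||% b$base_amplitude
  if (b$shape == "GAUSSIAN") {
    a * exp(-4 * log(2) * (wavenumber - b$center)^2 / b$fwhm^2)
  } else {
    hw <- b$fwhm / 2
    a * hw^2 / ((wavenumber - b$center)^2 + hw^2)
  }
}

# noiseless model spectrum: sum of profile-scaled library bands
model_intensity <- function(library, profile, wavenumber,
                            profile_adjustment = list()) {
  check_profile(profile, library)
  y <- numeric(length(wavenumber))
  for (b in library) {
    m <- profile$multipliers[[b$name]]
    adj <- profile_adjustment[[b$name]] %||% 1
    y <- y + band_shape(b, wavenumber, amplitude = b$base_amplitude * m * adj)
  }
  y
}

eval_baseline <- function(coeffs, wavenumber) {
  if (!length(coeffs)) return(numeric(length(wavenumber)))
  x <- 2 * (wavenumber - min(wavenumber)) / diff(range(wavenumber)) - 1
  drop(outer(x, seq_along(coeffs) - 1, `^`) %*% coeffs)
}

#' Generate one synthetic spectrum
#'
#' intensity = sum of profile-scaled library bands + polynomial baseline +
#' additive Gaussian noise, plus Poisson-count cosmic-ray spikes (Raman) or
#' the atmospheric CO2 band at 2350 cm^-1 (IR). The draw is fully determined
#' by `(config$seed, stage, index)`.
#'
#' @param library band library ([default_ir_band_library()] /
#'   [default_raman_band_library()])
#' @param profile a stage profile (one element of [default_stage_profiles()])
#' @param noise a [noise_model()]
#' @param config a [generator_config()]
#' @param index replicate index within the group
#' @param profile_label Raman spot character, `"PROTEINACEOUS"` (cytoplasm /
#'   nucleus) or `"LIPIDIC"` (lipid body); ignored for IR
#' @return a [spectrum()]; `meta` records group, id, profile and, for Raman,
#'   the injected spike channels
#' @export
generate_spectrum <- function(library, profile, noise, config, index = 1L,
                              profile_label = c("PROTEINACEOUS", "LIPIDIC")) {
  profile_label <- match.arg(profile_label)
  wn <- config_axis(config)
  centers <- vapply(library, `[[`, numeric(1), "center")
  if (min(centers) < min(wn) || max(centers) > max(wn))
    stop_contract("generator axis [%g, %g] does not cover band centers [%g, %g]",
                  min(wn), max(wn), min(centers), max(centers))
  adj <- if (config$modality == "RAMAN") raman_profile_adjustment(profile_label) else list()
  y <- model_intensity(library, profile, wn, profile_adjustment = adj)
  y <- y + eval_baseline(noise$baseline_coeffs, wn)
  sub_seed <- derive_seed(config$seed, profile$stage, index, profile_label)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(sub_seed)
  spikes <- integer(0)
  if (config$modality == "RAMAN" && noise$spike_rate > 0) {
    k <- stats::rpois(1, noise$spike_rate)
    if (k > 0) {
      spikes <- sample.int(length(wn), k)
      y[spikes] <- y[spikes] + stats::runif(k, noise$spike_amplitude_range[1],
                                            noise$spike_amplitude_range[2])
    }
  }
  if (config$modality == "IR" && noise$co2_amplitude > 0) {
    co2 <- band("CO2_2350", 2350, 35, noise$co2_amplitude)
    y <- y + band_shape(co2, wn)
  }
  if (noise$additive_sd > 0) y <- y + stats::rnorm(length(wn), 0, noise$additive_sd)
  spectrum(wn, y, modality = config$modality, form = "RAW",
           meta = list(group = profile$stage, id = as.character(index),
                       profile = profile_label,
                       spike_channels = spikes))
}

#' Generate a synthetic experimental group
#'
#' `n_per_group` spectra for one differentiation stage (the study scale is
#' ~400 single Raman spectra per time point; 40 is the default desk scale).
#'
#' @inheritParams generate_spectrum
#' @param stage stage label (see [stage_levels()])
#' @param library,noise,profiles optional overrides; defaults are the
#'   modality's library, [noise_model()] and [default_stage_profiles()]
#' @return a [spectrum_set()] with `meta$group = stage`
#' @export
generate_group <- function(stage, config, library = NULL, noise = noise_model(),
                           profiles = NULL,
                           profile_label = c("PROTEINACEOUS", "LIPIDIC")) {
  profile_label <- match.arg(profile_label)
  library <- library %||% if (config$modality == "IR") default_ir_band_library()
                          else default_raman_band_library()
  profiles <- profiles %||% default_stage_profiles(config$modality)
  if (!stage %in% names(profiles)) stop_contract("unknown stage '%s'", stage)
  sp <- lapply(seq_len(config$n_per_group), function(i)
    generate_spectrum(library, profiles[[stage]], noise, config, index = i,
                      profile_label = profile_label))
  spectrum_set(sp)
}

# deterministic elliptical cell mask covering ~ cell_fraction of the grid
cell_mask <- function(n_rows, n_cols, cell_fraction, seed) {
  mask <- matrix(FALSE, n_rows, n_cols)
  if (cell_fraction <= 0) return(mask)
  if (cell_fraction >= 1) return(!mask)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(seed, "cell_mask", n_rows, n_cols))
  target <- cell_fraction * n_rows * n_cols
  rc <- expand.grid(r = seq_len(n_rows), c = seq_len(n_cols))
  guard <- 0
  while (sum(mask) < target && guard < 1000) {
    guard <- guard + 1
    cr <- stats::runif(1, 1, n_rows); cc <- stats::runif(1, 1, n_cols)
    a <- stats::runif(1, 0.08, 0.25) * n_rows
    b <- stats::runif(1, 0.08, 0.25) * n_cols
    th <- stats::runif(1, 0, pi)
    dr <- rc$r - cr; dc <- rc$c - cc
    u <- dr * cos(th) + dc * sin(th); v <- -dr * sin(th) + dc * cos(th)
    inside <- (u / a)^2 + (v / b)^2 <= 1
    mask[cbind(rc$r[inside], rc$c[inside])] <- TRUE
  }
  mask
}

#' Generate a synthetic hyperspectral cube
#'
#' Emulates a focal-plane-array image of a cell monolayer: elliptical cell
#' patches covering about `cell_fraction` of the grid carry the stage's model
#' spectrum; background pixels carry baseline and noise only, so the amide-I
#' signal-to-noise ratio is high only on cell pixels. The cell mask is
#' attached to the returned cube (`$mask`) as generator ground truth.
#'
#' @inheritParams generate_group
#' @param n_rows,n_cols pixel grid (128 x 128 for a single FPA tile; a 2 x 2
#'   mosaic is 256 x 256)
#' @param cell_fraction fraction of pixels covered by cells, in \[0, 1\]
#' @param pixel_size pixel edge (um)
#' @return a [hypercube()] with the cell mask attached
#' @export
generate_cube <- function(stage, n_rows, n_cols, cell_fraction = 0.4,
                          config = generator_config(), library = NULL,
                          noise = noise_model(), profiles = NULL,
                          pixel_size = 5.5) {
  if (cell_fraction < 0 || cell_fraction > 1)
    stop_contract("cell_fraction must be in [0, 1]")
  library <- library %||% if (config$modality == "IR") default_ir_band_library()
                          else default_raman_band_library()
  profiles <- profiles %||% default_stage_profiles(config$modality)
  if (!stage %in% names(profiles)) stop_contract("unknown stage '%s'", stage)
  wn <- config_axis(config)
  signal <- model_intensity(library, profiles[[stage]], wn)
  base <- eval_baseline(noise$baseline_coeffs, wn)
  if (config$modality == "IR" && noise$co2_amplitude > 0)
    base <- base + band_shape(band("CO2_2350", 2350, 35, noise$co2_amplitude), wn)
  mask <- cell_mask(n_rows, n_cols, cell_fraction, config$seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(config$seed, "cube", stage, n_rows, n_cols))
  n_chan <- length(wn)
  arr <- array(stats::rnorm(n_rows * n_cols * n_chan, 0, noise$additive_sd),
               dim = c(n_rows, n_cols, n_chan))
  arr <- sweep(arr, 3, base, `+`)
  if (any(mask)) {
    idx <- which(mask)
    flat <- matrix(arr, nrow = n_rows * n_cols, ncol = n_chan)
    flat[idx, ] <- sweep(flat[idx, , drop = FALSE], 2, signal, `+`)
    arr <- array(flat, dim = dim(arr))
  }
  hypercube(arr, wn, pixel_size = pixel_size, modality = config$modality,
            mask = mask)
}
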