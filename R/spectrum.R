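#' Single spectrum container
#'
#' A spectrum couples a strictly increasing wavenumber axis (cm^-1) with one
#' intensity vector, the acquisition modality, the processing form, and
#' free-form metadata (group label, replicate id, profile label, pixel
#' coordinates...). All computation in the package runs on ascending axes;
#' files stored descending are reordered on read.
#'
#' @param wavenumber numeric vector of wavenumbers (cm^-1), strictly
#'   increasing, all positive. Spacing may be non-uniform.
#' @param intensity numeric vector of intensities (arbitrary units), same
#'   length as `wavenumber`, all finite.
#' @param modality `"IR"` or `"RAMAN"`.
#' @param form processing state: `"RAW"`, `"BASELINE_CORRECTED"`,
#'   `"SECOND_DERIVATIVE"` or `"NORMALIZED"`.
#' @param meta named list of metadata.
#' @return An object of class `vib_spectrum`.
#' @examples
#' s <- spectrum(1000:1010, rnorm(11), modality = "RAMAN")
#' s
#' @export
spectrum <- function(wavenumber, intensity, modality = c("IR", "RAMAN"),
                     form = c("RAW", "BASELINE_CORRECTED", "SECOND_DERIVATIVE",
                              "NORMALIZED"),
                     meta = list()) {
  modality <- match.arg(modality)
  form <- match.arg(form)
  check_axis(wavenumber)
  if (!is.numeric(intensity) || length(intensity) != length(wavenumber))
    stop_contract("intensity length (%d) must equal axis length (%d)",
                  length(intensity), length(wavenumber))
  if (anyNA(intensity) || any(!is.finite(intensity)))
    stop_contract("intensities must be finite")
  structure(list(wavenumber = as.numeric(wavenumber),
                 intensity = as.numeric(intensity),
                 modality = modality, form = form, meta = meta),
            class = "vib_spectrum")
}

#' @export
print.vib_spectrum <- function(x, ...) {
  cat(sprintf("<vib_spectrum> %s/%s, %d channels, %.1f-%.1f cm^-1\n",
              x$modality, x$form, length(x$wavenumber),
              min(x$wavenumber), max(x$wavenumber)))
  if (length(x$meta)) {
    kv <- vapply(names(x$meta), function(n) paste0(n, "=", format(x$meta[[n]])[1]),
                 character(1))
    cat("  meta:", paste(kv, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Collection of spectra sharing one axis
#'
#' The working set for group-level operations (averaging, outlier rejection,
#' metric panels, chemometrics). Intensities are stored as a spectra x channel
#' matrix; per-spectrum metadata live in a data frame with at least `group`
#' and `id` columns.
#'
#' @param spectra list of [spectrum()] objects with identical axes, modality
#'   and form, or an intensity matrix (rows = spectra).
#' @param wavenumber axis, required when `spectra` is a matrix.
#' @param modality,form as in [spectrum()]; taken from members when a list is
#'   given.
#' @param meta data frame with one row per spectrum; defaults to
#'   `group = "all"`, `id = seq_len(n)`.
#' @return An object of class `vib_spectrum_set`.
#' @export
spectrum_set <- function(spectra, wavenumber = NULL, modality = NULL,
                         form = NULL, meta = NULL) {
  if (is.list(spectra) && !is.data.frame(spectra)) {
    if (length(spectra) < 1L) stop_contract("a spectrum set needs at least one spectrum")
    stopifnot(all(vapply(spectra, inherits, logical(1), "vib_spectrum")))
    ax <- spectra[[1]]$wavenumber
    for (s in spectra) {
      if (length(s$wavenumber) != length(ax) || any(s$wavenumber != ax))
        stop_contract("all member spectra must share one wavenumber axis")
    }
    intensity <- do.call(rbind, lapply(spectra, `[[`, "intensity"))
    modality <- modality %||% spectra[[1]]$modality
    form <- form %||% spectra[[1]]$form
    if (is.null(meta)) {
      grp <- vapply(spectra, function(s) as.character(s$meta$group %||% "all"), character(1))
      id <- vapply(spectra, function(s) as.character(s$meta$id %||% NA_character_), character(1))
      id[is.na(id)] <- as.character(seq_along(spectra))[is.na(id)]
      prof <- vapply(spectra, function(s) as.character(s$meta$profile %||% NA_character_), character(1))
      meta <- data.frame(group = grp, id = id, stringsAsFactors = FALSE)
      if (!all(is.na(prof))) meta$profile <- prof
    }
    wavenumber <- ax
  } else {
    intensity <- as.matrix(spectra)
    if (is.null(wavenumber)) stop_contract("wavenumber axis required with a matrix input")
    check_axis(wavenumber)
    if (ncol(intensity) != length(wavenumber))
      stop_contract("intensity matrix has %d columns but axis has %d points",
                    ncol(intensity), length(wavenumber))
    modality <- modality %||% "IR"
    form <- form %||% "RAW"
  }
  n <- nrow(intensity)
  if (n < 1L) stop_contract("a spectrum set needs at least one spectrum")
  if (is.null(meta))
    meta <- data.frame(group = rep("all", n), id = as.character(seq_len(n)),
                       stringsAsFactors = FALSE)
  if (nrow(meta) != n) stop_contract("meta must have one row per spectrum")
  if (is.null(meta$group)) meta$group <- "all"
  if (is.null(meta$id)) meta$id <- as.character(seq_len(n))
  dimnames(intensity) <- NULL
  structure(list(wavenumber = as.numeric(wavenumber), intensity = intensity,
                 modality = modality, form = form, meta = meta),
            class = "vib_spectrum_set")
}

#' @export
print.vib_spectrum_set <- function(x, ...) {
  cat(sprintf("<vib_spectrum_set> %s/%s, %d spectra x %d channels, groups: %s\n",
              x$modality, x$form, nrow(x$intensity), length(x$wavenumber),
              paste(unique(x$meta$group), collapse = ", ")))
  invisible(x)
}

#' Number of spectra in a set
#' @param set a [spectrum_set()]
#' @return integer count
#' @export
n_spectra <- function(set) nrow(set$intensity)

#' Extract one spectrum from a set
#' @param set a [spectrum_set()]
#' @param i row index
#' @return a [spectrum()]
#' @export
get_spectrum <- function(set, i) {
  if (i < 1 || i > n_spectra(set)) stop_contract("spectrum index %d out of range", i)
  spectrum(set$wavenumber, set$intensity[i, ], modality = set$modality,
           form = set$form, meta = as.list(set$meta[i, , drop = FALSE]))
}

# apply a spectrum -> spectrum function over every member; the result must
# share one axis. Used to lift per-spectrum preprocessing onto sets.
map_spectra <- function(set, f, ..., form = NULL) {
  out <- lapply(seq_len(n_spectra(set)), function(i) f(get_spectrum(set, i), ...))
  res <- spectrum_set(out, meta = set$meta)
  if (!is.null(form)) res$form <- form
  res
}

#' Point-wise mean spectrum of a set
#' @param set a [spectrum_set()]
#' @param group optional group label to restrict to
#' @return a [spectrum()] with `meta$group` set when `group` was given
#' @export
mean_spectrum <- function(set, group = NULL) {
  idx <- seq_len(n_spectra(set))
  if (!is.null(group)) {
    idx <- which(set$meta$group == group)
    if (!length(idx)) stop_contract("no spectra with group '%s'", group)
  }
  spectrum(set$wavenumber, colMeans(set$intensity[idx, , drop = FALSE]),
           modality = set$modality, form = set$form,
           meta = list(group = group %||% "all", n = length(idx)))
}

#' Combine spectrum sets sharing one axis
#' @param ... sets to row-bind
#' @return a [spectrum_set()]
#' @export
bind_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !inherits(sets[[1]], "vib_spectrum_set"))
    sets <- sets[[1]]
  stopifnot(length(sets) >= 1L)
  ax <- sets[[1]]$wavenumber
  for (s in sets)
    if (length(s$wavenumber) != length(ax) || any(s$wavenumber != ax))
      stop_contract("all sets must share one wavenumber axis")
  metas <- lapply(sets, `[[`, "meta")
  cols <- Reduce(union, lapply(metas, names))
  metas <- lapply(metas, function(m) { m[setdiff(cols, names(m))] <- NA; m[cols] })
  spectrum_set(do.call(rbind, lapply(sets, `[[`, "intensity")), wavenumber = ax,
               modality = sets[[1]]$modality, form = sets[[1]]$form,
               meta = do.call(rbind, metas))
}
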