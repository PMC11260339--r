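# Band integration, the nine-metric panel, group statistics and chemical maps.

#' Integrate a spectral band
#'
#' Trapezoidal area of the intensity over the closed window `[lo, hi]`.
#' Modes: `"ZERO_BASELINE"` integrates the raw intensity; `"LOCAL_LINEAR"`
#' first subtracts the chord joining the window's boundary channels (so a
#' straight-line segment integrates to 0); `"ABS_ZERO"` integrates the
#' absolute intensity, the appropriate reading for second-derivative spectra
#' whose bands are negative lobes.
#'
#' @param s a [spectrum()]
#' @param lo,hi window bounds (cm^-1); at least 2 channels must fall inside
#' @param mode integration mode
#' @return band area (a.u. x cm^-1)
#' @export
integrate_band <- function(s, lo, hi,
                           mode = c("ZERO_BASELINE", "LOCAL_LINEAR", "ABS_ZERO")) {
  mode <- match.arg(mode)
  stopifnot(inherits(s, "vib_spectrum"))
  idx <- axis_window_idx(s$wavenumber, lo, hi)
  if (length(idx) < 2L)
    stop_contract("window [%g, %g] holds %d channel(s); need >= 2", lo, hi, length(idx))
  x <- s$wavenumber[idx]
  y <- s$intensity[idx]
  y <- switch(mode,
    ZERO_BASELINE = y,
    ABS_ZERO = abs(y),
    LOCAL_LINEAR = y - (y[1] + (y[length(y)] - y[1]) *
                          (x - x[1]) / (x[length(x)] - x[1]))
  )
  pracma::trapz(x, y)
}

metric_def <- function(name, modality, spectral_form, numerator,
                       denominator = NULL, profile_constraint = NA_character_) {
  stopifnot(length(numerator) >= 1L)
  list(name = name, modality = modality, spectral_form = spectral_form,
       numerator = numerator, denominator = denominator,
       profile_constraint = profile_constraint)
}

#' The nine-metric panel
#'
#' Band-integration metric definitions for staging adipogenesis. IR metrics
#' are read from vector-normalized second-derivative spectra (absolute-value
#' integration); Raman metrics from baseline-corrected normalized spectra
#' (local-linear integration). Raman metrics carry a profile constraint:
#' lipid unsaturation is evaluated on lipidic (lipid-body) spectra, the
#' phospholipid, phenylalanine and cytochrome metrics on proteinaceous ones.
#'
#' \describe{
#'   \item{fa_chain_shortening (IR)}{A(2944-2989) / A(2837-2868): CH3/CH2
#'     stretch ratio, acyl-chain shortening of fatty acids}
#'   \item{tag (IR)}{A(1727-1761): triacylglycerol ester carbonyl}
#'   \item{fa_acylation (IR)}{A(1410-1430): alpha-CH2 acyl conformation}
#'   \item{amide_ratio (IR)}{A(1482-1595) / A(1609-1708): amide II / amide I,
#'     protein secondary-structure change}
#'   \item{dna (IR)}{A(949-990): DNA backbone}
#'   \item{lipid_unsaturation (Raman, lipidic)}{A(1250-1280) / A(1285-1320):
#'     =CH / CH2 ratio}
#'   \item{phospholipids (Raman, proteinaceous)}{A(715-730)}
#'   \item{phe_crosslink (Raman, proteinaceous)}{A(1026-1050) / A(994-1020):
#'     cross-linked / total phenylalanine}
#'   \item{cytochromes (Raman, proteinaceous)}{A(1575-1595) + A(1120-1140) +
#'     A(740-760)}
#' }
#'
#' @return list of 9 metric definitions (5 IR + 4 Raman)
#' @export
metric_panel <- function() {
  list(
    metric_def("fa_chain_shortening", "IR", "SECOND_DERIVATIVE",
               list(c(2944, 2989)), list(c(2837, 2868))),
    metric_def("tag", "IR", "SECOND_DERIVATIVE", list(c(1727, 1761))),
    metric_def("fa_acylation", "IR", "SECOND_DERIVATIVE", list(c(1410, 1430))),
    metric_def("amide_ratio", "IR", "SECOND_DERIVATIVE",
               list(c(1482, 1595)), list(c(1609, 1708))),
    metric_def("dna", "IR", "SECOND_DERIVATIVE", list(c(949, 990))),
    metric_def("lipid_unsaturation", "RAMAN", "BASELINE_CORRECTED",
               list(c(1250, 1280)), list(c(1285, 1320)),
               profile_constraint = "LIPIDIC"),
    metric_def("phospholipids", "RAMAN", "BASELINE_CORRECTED",
               list(c(715, 730)), profile_constraint = "PROTEINACEOUS"),
    metric_def("phe_crosslink", "RAMAN", "BASELINE_CORRECTED",
               list(c(1026, 1050)), list(c(994, 1020)),
               profile_constraint = "PROTEINACEOUS"),
    metric_def("cytochromes", "RAMAN", "BASELINE_CORRECTED",
               list(c(1575, 1595)), profile_constraint = "PROTEINACEOUS",
               denominator = NULL)
  ) -> defs
  # cytochromes sums three windows
  defs[[9]]$numerator <- list(c(1575, 1595), c(1120, 1140), c(740, 760))
  defs
}

sum_areas <- function(s, windows, mode) {
  sum(vapply(windows, function(w) integrate_band(s, w[1], w[2], mode = mode),
             numeric(1)))
}

#' Compute a metric table for a spectrum set
#'
#' Evaluates every applicable panel definition on every spectrum. A
#' definition applies when the modality matches and, for Raman metrics with a
#' profile constraint, when the spectrum's `meta$profile` matches (spectra
#' without a profile label are included). Ratio metrics whose denominator
#' area falls below `denom_floor` are flagged undefined (`defined = FALSE`,
#' value `NA`) rather than propagating division blow-ups. Integration mode
#' follows the definition's spectral form: absolute-value for second
#' derivatives, local-linear otherwise.
#'
#' @param set a [spectrum_set()]
#' @param panel list of metric definitions, default [metric_panel()]
#' @param denom_floor numeric floor below which a denominator is undefined
#' @return data frame with columns `group`, `spectrum_id`, `metric`, `value`,
#'   `defined`
#' @export
compute_metrics <- function(set, panel = metric_panel(), denom_floor = 1e-12) {
  stopifnot(inherits(set, "vib_spectrum_set"))
  panel <- Filter(function(d) d$modality == set$modality, panel)
  if (!length(panel)) {
    warning("no panel definition matches modality ", set$modality)
    return(data.frame(group = character(0), spectrum_id = character(0),
                      metric = character(0), value = numeric(0),
                      defined = logical(0)))
  }
  rows <- list()
  profiles <- set$meta$profile %||% rep(NA_character_, n_spectra(set))
  for (i in seq_len(n_spectra(set))) {
    s <- get_spectrum(set, i)
    for (d in panel) {
      if (!is.na(d$profile_constraint) && !is.na(profiles[i]) &&
          profiles[i] != d$profile_constraint) next
      mode <- if (d$spectral_form == "SECOND_DERIVATIVE") "ABS_ZERO" else "LOCAL_LINEAR"
      num <- sum_areas(s, d$numerator, mode)
      if (is.null(d$denominator)) {
        val <- num; ok <- TRUE
      } else {
        den <- sum_areas(s, d$denominator, mode)
        if (abs(den) < denom_floor) { val <- NA_real_; ok <- FALSE }
        else { val <- num / den; ok <- TRUE }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = set$meta$group[i], spectrum_id = set$meta$id[i],
        metric = d$name, value = val, defined = ok, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

star_level <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' One-way ANOVA with Tukey HSD for one metric
#'
#' Fits a one-way ANOVA of the metric across groups and runs Tukey's honest
#' significant difference test (Tukey-Kramer for unequal group sizes) on all
#' pairwise comparisons, assigning significance stars at the 0.05 / 0.01 /
#' 0.001 levels.
#'
#' @param table metric table from [compute_metrics()]
#' @param metric metric name to test
#' @return list with `metric`, `anova` (`F`, `p`) and `comparisons` (data
#'   frame: pair, difference, adjusted p, stars)
#' @export
anova_tukey <- function(table, metric) {
  sub <- table[table$metric == metric & table$defined, , drop = FALSE]
  if (!nrow(sub)) stop_contract("no defined values for metric '%s'", metric)
  counts <- table(sub$group)
  if (length(counts) < 2L) stop_contract("ANOVA needs >= 2 groups")
  if (any(counts < 2L)) stop_contract("every group needs >= 2 values")
  sub$group <- factor(sub$group)
  fit <- stats::aov(value ~ group, data = sub)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  comp <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                     p_adj = tk[, "p adj"], stars = star_level(tk[, "p adj"]),
                     row.names = NULL, stringsAsFactors = FALSE)
  list(metric = metric,
       anova = list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1]),
       comparisons = comp)
}

# adjusted p for one pair from a Tukey report, regardless of label order
tukey_pair <- function(report, a, b) {
  hit <- report$comparisons$pair %in% c(paste0(a, "-", b), paste0(b, "-", a))
  if (!any(hit)) stop_contract("pair %s/%s not in report", a, b)
  report$comparisons[hit, , drop = FALSE][1, ]
}

#' Integral-intensity chemical map
#'
#' Integrates one band window at every pixel of a cube, producing the
#' spatial distribution of the corresponding component (e.g. the
#' triacylglycerol ester band for lipid droplets).
#'
#' @param cube a [hypercube()]
#' @param lo,hi band window (cm^-1)
#' @param mode integration mode, see [integrate_band()]
#' @param label band label carried on the map
#' @return object of class `vib_chemical_map`: `values` matrix
#'   (`n_rows x n_cols`), `pixel_size`, `label`, `window`
#' @export
chemical_map <- function(cube, lo, hi, mode = "ZERO_BASELINE", label = NULL) {
  stopifnot(inherits(cube, "vib_hypercube"))
  idx <- axis_window_idx(cube$wavenumber, lo, hi)
  if (length(idx) < 2L) stop_contract("map window [%g, %g] holds < 2 channels", lo, hi)
  x <- cube$wavenumber[idx]
  m <- cube_matrix(cube)[, idx, drop = FALSE]
  if (mode == "ABS_ZERO") m <- abs(m)
  if (mode == "LOCAL_LINEAR") {
    w <- (x - x[1]) / (x[length(x)] - x[1])
    m <- m - (outer(m[, 1], 1 - w) + outer(m[, ncol(m)], w))
  }
  # trapezoid weights on the (possibly non-uniform) grid
  dw <- diff(x)
  wts <- c(dw[1] / 2, (dw[-length(dw)] + dw[-1]) / 2, dw[length(dw)] / 2)
  vals <- matrix(drop(m %*% wts), nrow = cube$n_rows, byrow = TRUE)
  structure(list(values = vals, n_rows = cube$n_rows, n_cols = cube$n_cols,
                 pixel_size = cube$pixel_size, label = label %||%
                   sprintf("%g-%g cm^-1", lo, hi), window = c(lo, hi)),
            class = "vib_chemical_map")
}

#' @export
print.vib_chemical_map <- function(x, ...) {
  cat(sprintf("<vib_chemical_map> %s, %d x %d pixels, range [%.3g, %.3g]\n",
              x$label, x$n_rows, x$n_cols, min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.vib_chemical_map <- function(x, ...) {
  graphics::image(t(x$values)[, rev(seq_len(x$n_rows)), drop = FALSE],
                  main = x$label, axes = FALSE, ...)
  invisible(x)
}
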