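# Stage profiles: per-band amplitude multipliers encoding the biochemical
# trajectory of adipogenic differentiation (6 h; days 2, 7, 14) and the
# negative-control (NC) cultures. The multipliers realize, as strict
# orderings, the qualitative stage trends the metric panel is built to
# detect; effect sizes sit in the 30-60% range around 1 (0 for the
# day-2-vanishing 1421 cm^-1 band), large enough for Tukey significance at
# n = 40 spectra/group under the default noise model.

#' Differentiation stage labels
#' @return character vector of the eight stage labels: 6 h, day 2/7/14 and
#'   their negative controls
#' @export
stage_levels <- function() c("H6", "D2", "D7", "D14", "NC6H", "NC2D", "NC7D", "NC14D")

#' Default stage profiles
#'
#' One amplitude multiplier per library band per stage. Trends encoded:
#' triacylglycerols dip at day 2 then rise past baseline; the 1421 cm^-1
#' acyl-conformation band vanishes at day 2 and overshoots later; DNA peaks
#' at day 2 (replication burst); lipid unsaturation peaks at day 7;
#' cytochromes rise from day 7; the Phe cross-link ratio falls at days 7/14;
#' negative controls stay flat apart from a gradual CH3/CH2 drift and slow
#' membrane decline.
#'
#' @param modality `"IR"` or `"RAMAN"`
#' @return named list: stage label -> list with `stage` and `multipliers`
#'   (named numeric vector covering every band of the matching library)
#' @examples
#' p <- default_stage_profiles("IR")
#' p$D2$multipliers[["TAG_ester"]] < p$H6$multipliers[["TAG_ester"]]
#' @export
default_stage_profiles <- function(modality = c("IR", "RAMAN")) {
  modality <- match.arg(modality)
  if (modality == "IR") {
    tab <- rbind(
      #                     H6    D2    D7   D14   NC6H  NC2D  NC7D NC14D
      CH3_asym_2960    = c(1.00, 0.95, 1.35, 1.45, 1.00, 1.07, 1.15, 1.25),
      CH2_asym_2924    = c(1.00, 1.20, 1.10, 1.05, 1.00, 1.00, 1.00, 1.00),
      CH2_sym_2852     = c(1.00, 1.15, 1.05, 1.00, 1.00, 1.00, 1.00, 1.00),
      TAG_ester        = c(1.00, 0.45, 1.35, 1.50, 1.00, 1.00, 1.00, 1.00),
      FA_carbonyl_1726 = c(1.00, 1.40, 1.20, 1.15, 1.00, 1.00, 1.00, 1.00),
      amide_I_1651     = c(1.00, 0.95, 1.00, 1.00, 1.00, 1.00, 1.00, 1.00),
      amide_I_beta_1632= c(1.00, 1.50, 1.25, 1.30, 1.00, 1.00, 1.00, 1.00),
      amide_II_1547    = c(1.00, 0.75, 0.95, 0.95, 1.00, 1.00, 1.00, 1.00),
      Tyr_1514         = c(1.00, 0.50, 0.90, 0.90, 1.00, 1.00, 1.00, 1.00),
      FA_acyl_1421     = c(1.00, 0.00, 1.40, 1.30, 1.00, 0.90, 0.80, 0.70),
      nucleic_1236     = c(1.00, 1.45, 0.90, 0.85, 1.00, 1.00, 1.00, 1.00),
      nucleic_1084     = c(1.00, 1.40, 0.90, 0.85, 1.00, 1.00, 1.00, 1.00),
      DNA_970          = c(1.00, 1.60, 0.70, 0.60, 1.00, 1.00, 1.00, 1.00)
    )
  } else {
    tab <- rbind(
      #                     H6    D2    D7   D14   NC6H  NC2D  NC7D NC14D
      CH_unsat_3014    = c(1.00, 1.00, 1.60, 0.85, 1.00, 1.00, 1.00, 1.00),
      CH3_2930         = c(1.00, 1.00, 1.00, 1.00, 1.00, 1.00, 1.00, 1.00),
      CH2_2853         = c(1.00, 1.00, 1.15, 1.10, 1.00, 1.00, 1.00, 1.00),
      amide_I_1660     = c(1.00, 1.00, 1.00, 1.00, 1.00, 1.00, 1.00, 1.00),
      cytochrome_1587  = c(0.90, 1.00, 1.50, 1.60, 0.90, 0.95, 1.00, 1.00),
      CH_def_1449      = c(1.00, 1.00, 1.00, 1.00, 1.00, 1.00, 1.00, 1.00),
      FA_1340          = c(1.00, 1.00, 1.30, 1.30, 1.00, 1.00, 1.00, 1.00),
      G_1311           = c(1.00, 1.00, 1.15, 1.15, 1.00, 1.00, 1.00, 1.00),
      lipid_1306       = c(1.00, 1.05, 1.40, 1.30, 1.00, 1.00, 1.00, 1.00),
      CH_unsat_1267    = c(1.00, 1.00, 1.60, 0.85, 1.00, 1.00, 1.00, 1.00),
      cytochrome_1130  = c(0.90, 1.00, 1.50, 1.60, 0.90, 0.95, 1.00, 1.00),
      Phe_crosslink_1038=c(1.00, 0.95, 0.70, 0.55, 1.00, 1.00, 1.00, 1.00),
      Phe_total_1007   = c(1.00, 1.00, 1.00, 1.00, 1.00, 1.00, 1.00, 1.00),
      nucleic_790      = c(1.00, 1.30, 0.90, 0.85, 1.00, 1.00, 1.00, 1.00),
      cytochrome_756   = c(0.90, 1.00, 1.50, 1.60, 0.90, 0.95, 1.00, 1.00),
      phospholipid_724 = c(1.00, 0.92, 0.84, 0.75, 1.00, 0.95, 0.90, 0.85)
    )
  }
  colnames(tab) <- stage_levels()
  lib_names <- band_names(if (modality == "IR") default_ir_band_library()
                          else default_raman_band_library())
  stopifnot(setequal(rownames(tab), lib_names))
  out <- lapply(stage_levels(), function(st) {
    list(stage = st, multipliers = tab[lib_names, st])
  })
  names(out) <- stage_levels()
  out
}

check_profile <- function(profile, lib) {
  m <- profile$multipliers
  missing <- setdiff(band_names(lib), names(m))
  if (length(missing))
    stop_contract("stage profile '%s' lacks multipliers for: %s",
                  profile$stage %||% "?", paste(missing, collapse = ", "))
  if (any(!is.finite(m)) || any(m < 0))
    stop_contract("stage profile multipliers must be finite and >= 0")
  invisible(profile)
}
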