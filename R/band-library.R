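# Band libraries: the vibrational components the synthetic generator builds
# cell spectra from. Centers follow the standard assignments for fixed cells;
# widths and base amplitudes are generator choices (Gaussian by default, with
# sharp ring-breathing Raman lines narrower than the broad CH/amide envelopes).

band <- function(name, center, fwhm, base_amplitude, shape = "GAUSSIAN") {
  if (fwhm <= 0) stop_contract("band %s: fwhm must be > 0", name)
  if (base_amplitude < 0) stop_contract("band %s: base amplitude must be >= 0", name)
  if (!shape %in% c("GAUSSIAN", "LORENTZIAN"))
    stop_contract("band %s: unknown shape '%s'", name, shape)
  list(name = name, center = center, fwhm = fwhm, shape = shape,
       base_amplitude = base_amplitude)
}

band_df <- function(lib) {
  data.frame(name = vapply(lib, `[[`, character(1), "name"),
             center = vapply(lib, `[[`, numeric(1), "center"),
             fwhm = vapply(lib, `[[`, numeric(1), "fwhm"),
             shape = vapply(lib, `[[`, character(1), "shape"),
             base_amplitude = vapply(lib, `[[`, numeric(1), "base_amplitude"),
             stringsAsFactors = FALSE)
}

#' Default IR band library
#'
#' The infrared components of a fixed-cell absorbance spectrum used by the
#' synthetic generator: CH3/CH2 stretches (2960/2924/2852), the
#' triacylglycerol ester carbonyl (1742), free fatty-acid carbonyl (1726),
#' amide I alpha-helix and beta-sheet (1651/1632), amide II (1547), tyrosine
#' ring (1514), the alpha-CH2 fatty-acyl deformation (1421), nucleic-acid
#' phosphate bands (1236/1084) and the DNA backbone band (970).
#'
#' @return list of band components (`name`, `center` cm^-1, `fwhm` cm^-1,
#'   `shape`, `base_amplitude`)
#' @examples
#' lib <- default_ir_band_library()
#' lib[[which(vapply(lib, `[[`, character(1), "name") == "TAG_ester")]]$center
#' @export
default_ir_band_library <- function() {
  list(
    band("CH3_asym_2960",    2960, 22, 0.55),
    band("CH2_asym_2924",    2924, 24, 0.85),
    band("CH2_sym_2852",     2852, 20, 0.60),
    band("TAG_ester",        1742, 18, 0.90),
    band("FA_carbonyl_1726", 1726, 16, 0.35),
    band("amide_I_1651",     1651, 30, 1.50),
    band("amide_I_beta_1632",1632, 22, 0.55),
    band("amide_II_1547",    1547, 28, 1.00),
    band("Tyr_1514",         1514, 14, 0.30),
    band("FA_acyl_1421",     1421, 14, 0.40),
    band("nucleic_1236",     1236, 24, 0.45),
    band("nucleic_1084",     1084, 22, 0.50),
    band("DNA_970",           970, 16, 0.35)
  )
}

#' Default Raman band library
#'
#' The Raman components of a cell spectrum used by the synthetic generator:
#' =CH unsaturation stretch (3014), CH3/CH2 stretches (2930/2853), amide
#' I / C=C (1660), cytochrome bands (1587/1130/756), CH deformation (1449),
#' fatty-acid band (1340), guanine (1311), lipid CH2 twist (1306), =CH
#' unsaturation deformation (1267), phenylalanine cross-link and ring-breathing
#' bands (1038/1007), nucleic-acid band (790) and the phospholipid band (724).
#'
#' @return list of band components, as in [default_ir_band_library()]
#' @export
default_raman_band_library <- function() {
  list(
    band("CH_unsat_3014",   3014, 16, 0.35),
    band("CH3_2930",        2930, 14, 1.00),
    band("CH2_2853",        2853, 14, 0.45),
    band("amide_I_1660",    1660, 24, 0.70),
    band("cytochrome_1587", 1587, 12, 0.35),
    band("CH_def_1449",     1449, 18, 0.80),
    band("FA_1340",         1340, 16, 0.30),
    band("G_1311",          1311, 12, 0.25),
    band("lipid_1306",      1306, 14, 0.40),
    band("CH_unsat_1267",   1267, 14, 0.35),
    band("cytochrome_1130", 1130, 10, 0.30),
    band("Phe_crosslink_1038", 1038, 8, 0.30, shape = "LORENTZIAN"),
    band("Phe_total_1007",  1007,  8, 0.60, shape = "LORENTZIAN"),
    band("nucleic_790",      790, 12, 0.30),
    band("cytochrome_756",   756, 10, 0.30),
    band("phospholipid_724", 724, 10, 0.30)
  )
}

# multiplicative adjustment distinguishing lipid-body pixels/spots from the
# proteinaceous cytoplasm/nucleus profile: lipid droplets boost the CH2/CH
# lipid bands and dilute the protein markers
raman_profile_adjustment <- function(profile = c("PROTEINACEOUS", "LIPIDIC")) {
  profile <- match.arg(profile)
  if (profile == "PROTEINACEOUS") return(list())
  list(CH2_2853 = 2.8, lipid_1306 = 2.0, CH_unsat_1267 = 2.0,
       CH_unsat_3014 = 2.0, Phe_total_1007 = 0.6, CH_def_1449 = 0.6)
}

band_names <- function(lib) vapply(lib, `[[`, character(1), "name")

band_by_name <- function(lib, name) {
  i <- match(name, band_names(lib))
  if (is.na(i)) stop_contract("band '%s' not in library", name)
  lib[[i]]
}
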