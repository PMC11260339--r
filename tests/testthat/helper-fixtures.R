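# shared fixtures and independent oracles

# analytic Gaussian band on an axis
gauss_band <- function(wn, center, fwhm, amp = 1) {
  amp * exp(-4 * log(2) * (wn - center)^2 / fwhm^2)
}

# analytic area of a Gaussian band: amp * fwhm * sqrt(pi / (4 ln 2))
gauss_area <- function(amp, fwhm) amp * fwhm * sqrt(pi / (4 * log(2)))

toy_spectrum <- function(n = 101, lo = 1000, hi = 1100, modality = "IR",
                         intensity = NULL) {
  wn <- seq(lo, hi, length.out = n)
  spectrum(wn, intensity %||% gauss_band(wn, (lo + hi) / 2, 20),
           modality = modality)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force Ward clustering (Lance-Williams update on squared Euclidean
# distances, heights reported on the distance scale as in ward.D2) -- the
# independent oracle for hca_ward on tiny inputs
brute_ward <- function(x) {
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  active <- seq_len(n)
  sizes <- rep(1, n)
  id <- -seq_len(n)          # hclust convention: negative = singleton
  merges <- matrix(0L, n - 1, 2)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(active)[-length(active)])
      for (j in (i + 1):length(active)) {
        a <- active[i]; b <- active[j]
        if (d2[a, b] < best_d) { best_d <- d2[a, b]; best <- c(i, j) }
      }
    i <- best[1]; j <- best[2]
    a <- active[i]; b <- active[j]
    heights[step] <- sqrt(best_d)
    merges[step, ] <- sort(c(id[a], id[b]))
    # Lance-Williams Ward update of squared distances to the new cluster
    for (k in active) {
      if (k == a || k == b) next
      d2_new <- ((sizes[a] + sizes[k]) * d2[a, k] +
                 (sizes[b] + sizes[k]) * d2[b, k] -
                 sizes[k] * d2[a, b]) / (sizes[a] + sizes[b] + sizes[k])
      d2[a, k] <- d2[k, a] <- d2_new
    }
    sizes[a] <- sizes[a] + sizes[b]
    id[a] <- step
    active <- active[-j]
  }
  list(merge = merges, height = heights)
}

small_ir_group <- function(stage, n = 6, seed = 11, step = 1) {
  cfg <- generator_config(seed = seed, n_per_group = n, modality = "IR",
                          axis_step = step)
  generate_group(stage, cfg)
}

# compact nine-trend recovery report: generator -> preprocess -> metrics ->
# Tukey, returning one pass/fail per encoded stage trend (mean ordering AND
# Tukey p < 0.05 on the key pair)
nine_trend_report <- function(n = 40, seed_ir = 101, seed_rs = 102) {
  gm <- function(tab, metric) {
    sub <- tab[tab$metric == metric & tab$defined, ]
    tapply(sub$value, sub$group, mean)
  }
  sig <- function(tab, metric, a, b)
    vibrostage:::tukey_pair(anova_tukey(tab, metric), a, b)$p_adj < 0.05
  cfg_ir <- generator_config(seed = seed_ir, n_per_group = n, modality = "IR")
  ir <- do.call(bind_sets, lapply(c("H6", "D2", "D7", "D14"), function(st)
    preprocess_ir_spectra(generate_group(st, cfg_ir))))
  ti <- compute_metrics(ir)
  cfg_rs <- generator_config(seed = seed_rs, n_per_group = n, modality = "RAMAN")
  rs <- do.call(bind_sets, unlist(lapply(c("H6", "D2", "D7", "D14"), function(st)
    lapply(c("PROTEINACEOUS", "LIPIDIC"), function(pf)
      preprocess_raman(generate_group(st, cfg_rs, profile_label = pf))$set)),
    recursive = FALSE))
  tr <- compute_metrics(rs)
  c(
    tag_dip_d2 = {m <- gm(ti, "tag"); m["D2"] < m["H6"] && m["H6"] < m["D7"] &&
        sig(ti, "tag", "D2", "H6")},
    acylation_vanishes_d2 = {m <- gm(ti, "fa_acylation")
        names(which.min(m)) == "D2" && m["D7"] > m["H6"] &&
        sig(ti, "fa_acylation", "D2", "H6")},
    dna_peak_d2 = {m <- gm(ti, "dna"); names(which.max(m)) == "D2" &&
        sig(ti, "dna", "D2", "H6")},
    amide_shift_d2 = {m <- gm(ti, "amide_ratio"); m["D2"] < m["H6"] &&
        sig(ti, "amide_ratio", "D2", "H6")},
    chain_shortening_after_d2 = {m <- gm(ti, "fa_chain_shortening")
        m["D7"] > m["D2"] && sig(ti, "fa_chain_shortening", "D7", "D2")},
    unsaturation_peak_d7 = {m <- gm(tr, "lipid_unsaturation")
        names(which.max(m)) == "D7" && sig(tr, "lipid_unsaturation", "D7", "D14")},
    phospholipid_decline = {m <- gm(tr, "phospholipids"); m["D14"] < m["H6"] &&
        sig(tr, "phospholipids", "D14", "H6")},
    phe_ratio_decline = {m <- gm(tr, "phe_crosslink")
        m["D7"] < m["H6"] && m["D14"] < m["D7"] &&
        sig(tr, "phe_crosslink", "D7", "H6")},
    cytochromes_rise_d7 = {m <- gm(tr, "cytochromes")
        min(m[c("D7", "D14")]) > max(m[c("H6", "D2")]) &&
        sig(tr, "cytochromes", "D7", "H6")}
  )
}
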