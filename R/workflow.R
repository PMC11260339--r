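# End-to-end orchestration: a validated run configuration drives
# simulate -> preprocess -> metrics/statistics -> chemometrics, with all
# artifacts and a run report written to an output directory. Every stage is
# also callable standalone; the workflow only sequences them.

#' Default run configuration
#'
#' All knobs of the end-to-end workflow with their reference defaults:
#' two-group IR experiment (6 h vs day 2), 10 cubes of 64 x 64 pixels per
#' group with 4 ROIs each (40 ROI means per group), the default generator,
#' preprocessing, metric panel and chemometric settings.
#'
#' @return named list (a run configuration)
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    output_dir = NULL,
    modality = "IR",
    groups = c("H6", "D2"),
    input = "simulate",           # "simulate" or "spectra" (paths per group)
    spectra_paths = NULL,
    n_cubes_per_group = 10L,
    cube_rows = 64L, cube_cols = 64L, cell_fraction = 0.4,
    n_per_group = 40L,
    axis_step = 1,
    preprocess = NULL,            # overrides for preprocess_defaults()
    metrics = TRUE,
    hca = TRUE, hca_regions = list(c(2800, 3050), c(920, 1750)),
    pca = TRUE, pca_region = list(c(950, 3050)), pca_components = 7L,
    plsr = TRUE, plsr_region = list(c(950, 3050)), plsr_factors = 10L,
    plsr_test_fraction = 0.2
  )
}

#' Validate a run configuration
#'
#' Reads a JSON or YAML configuration file (or takes a list), fills defaults
#' from [default_run_config()], rejects unknown keys and checks field
#' constraints. An empty file yields the all-defaults configuration.
#'
#' @param config path to a `.json`/`.yaml`/`.yml` file, or a named list
#' @return the validated, defaulted configuration list
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    path <- config
    if (!file.exists(path)) stop_contract("config file not found: %s", path)
    config <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      if (file.info(path)$size == 0) list()
      else jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path) %||% list()
    }
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) stop_contract("config must be a file path or a list")
  defaults <- default_run_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop_contract("unknown config key(s): %s", paste(unknown, collapse = ", "))
  for (k in names(config)) defaults[[k]] <- config[[k]]
  cfg <- defaults
  if (cfg$n_per_group < 1) stop_contract("n_per_group must be >= 1")
  if (cfg$n_cubes_per_group < 0)
    stop_contract("n_cubes_per_group must be >= 0 (0 = simulate single spectra)")
  if (cfg$cell_fraction < 0 || cfg$cell_fraction > 1)
    stop_contract("cell_fraction must be in [0, 1]")
  if (!cfg$modality %in% c("IR", "RAMAN"))
    stop_contract("modality must be IR or RAMAN")
  if (length(cfg$groups) < 1) stop_contract("at least one group is required")
  if (cfg$plsr && length(cfg$groups) != 2)
    stop_contract("PLSR classification needs exactly 2 groups")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

write_metric_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full workflow
#'
#' Executes, per the configuration: synthetic data generation (or spectrum
#' table ingestion), the modality's preprocessing chain, the metric panel
#' with ANOVA/Tukey statistics, and the enabled chemometric analyses (HCA,
#' PCA, PLSR with a stratified held-out split). Artifacts (metric table,
#' Tukey reports, dendrogram, PCA scores, PLSR summary) are written under
#' `config$output_dir` when set. Identical config and seed give identical
#' artifacts.
#'
#' @param config a configuration accepted by [validate_config()]
#' @return a run report: per-stage input/output counts, parameters, config
#'   hash, and the in-memory results (`$results`)
#' @export
run_workflow <- function(config = list()) {
  cfg <- validate_config(config)
  t0 <- Sys.time()
  report <- list(config = cfg, config_hash = config_hash(cfg), stages = list())
  results <- list()
  out_dir <- cfg$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  # --- acquire spectra -------------------------------------------------
  gen_cfg <- generator_config(seed = cfg$seed, n_per_group = cfg$n_per_group,
                              modality = cfg$modality, axis_step = cfg$axis_step)
  sets <- list()
  if (identical(cfg$input, "spectra") && !is.null(cfg$spectra_paths)) {
    for (g in names(cfg$spectra_paths)) {
      s <- read_spectrum_table(cfg$spectra_paths[[g]], modality = cfg$modality)
      s$meta$group <- g
      sets[[g]] <- s
    }
    report$stages$ingest <- list(groups = length(sets),
                                 n_in = sum(vapply(sets, n_spectra, numeric(1))))
  } else if (cfg$modality == "IR" && cfg$input == "simulate" && cfg$n_cubes_per_group > 0) {
    for (g in cfg$groups) {
      cubes <- lapply(seq_len(cfg$n_cubes_per_group), function(i) {
        ci <- generator_config(seed = derive_seed(cfg$seed, g, "cube", i),
                               n_per_group = 1L, modality = "IR",
                               axis_step = cfg$axis_step)
        generate_cube(g, cfg$cube_rows, cfg$cube_cols,
                      cell_fraction = cfg$cell_fraction, config = ci)
      })
      sets[[g]] <- preprocess_ir(cubes, config = cfg$preprocess, group = g)
    }
    report$stages$simulate <- list(groups = length(cfg$groups),
                                   cubes = cfg$n_cubes_per_group * length(cfg$groups))
    report$stages$preprocess <- list(
      n_out_per_group = vapply(sets, n_spectra, numeric(1)))
    processed <- bind_sets(sets)
  } else {
    for (g in cfg$groups)
      sets[[g]] <- generate_group(g, gen_cfg)
    report$stages$simulate <- list(groups = length(cfg$groups),
                                   n_per_group = cfg$n_per_group)
  }
  if (!exists("processed", inherits = FALSE)) {
    if (cfg$modality == "IR") {
      sets <- lapply(sets, preprocess_ir_spectra, config = cfg$preprocess)
      processed <- bind_sets(sets)
      report$stages$preprocess <- list(n_out = n_spectra(processed))
    } else {
      rej <- 0L
      sets <- lapply(sets, function(s) {
        r <- preprocess_raman(s, config = cfg$preprocess)
        rej <<- rej + length(r$rejected)
        r$set
      })
      processed <- bind_sets(sets)
      report$stages$preprocess <- list(n_out = n_spectra(processed),
                                       rejected = rej)
    }
  }
  results$processed <- processed

  # --- metrics ---------------------------------------------------------
  if (isTRUE(cfg$metrics)) {
    tab <- compute_metrics(processed)
    results$metrics <- tab
    reports <- list()
    if (length(unique(processed$meta$group)) >= 2 &&
        min(table(processed$meta$group)) >= 2) {
      for (mname in unique(tab$metric))
        reports[[mname]] <- tryCatch(anova_tukey(tab, mname), error = function(e) NULL)
    }
    results$tukey <- reports
    report$stages$metrics <- list(n_values = nrow(tab),
                                  n_metrics = length(unique(tab$metric)))
    if (!is.null(out_dir))
      write_metric_table(tab, file.path(out_dir, "metrics.tsv"))
  }

  # --- chemometrics ----------------------------------------------------
  if (isTRUE(cfg$hca) && n_spectra(processed) >= 2) {
    dm <- build_matrix(processed, cfg$hca_regions)
    results$hca <- hca_ward(dm)
    report$stages$hca <- list(n_leaves = length(results$hca$labels),
                              n_variables = ncol(dm$x))
  } else report$stages$hca <- list(skipped = TRUE)

  if (isTRUE(cfg$pca) && n_spectra(processed) >= 2) {
    dm <- build_matrix(processed, cfg$pca_region)
    results$pca <- spectra_pca(dm, n_components = cfg$pca_components)
    report$stages$pca <- list(n_components = ncol(results$pca$scores),
                              explained = results$pca$explained)
    if (!is.null(out_dir)) {
      sc <- data.frame(group = processed$meta$group, id = processed$meta$id,
                       results$pca$scores)
      write_metric_table(sc, file.path(out_dir, "pca_scores.tsv"))
    }
  } else report$stages$pca <- list(skipped = TRUE)

  if (isTRUE(cfg$plsr) && length(cfg$groups) == 2) {
    dm <- build_matrix(processed, cfg$plsr_region)
    y <- as.integer(processed$meta$group == cfg$groups[2])
    sp <- stratified_split(y, test_fraction = cfg$plsr_test_fraction,
                           seed = cfg$seed)
    cal <- list(x = dm$x[sp$calibration, , drop = FALSE])
    model <- plsr_calibrate(cal$x, y[sp$calibration],
                            n_factors = cfg$plsr_factors)
    cls <- plsr_classify(model, dm$x[sp$test, , drop = FALSE], y[sp$test])
    results$plsr <- list(model = model, classification = cls,
                         split = sp, positive_class = cfg$groups[2])
    report$stages$plsr <- list(n_cal = length(sp$calibration),
                               n_test = length(sp$test),
                               rmsec = model$rmsec, r2c = model$r2c,
                               rmsev = model$rmsev, r2v = model$r2v,
                               tpr = cls$tpr)
    if (!is.null(out_dir))
      jsonlite::write_json(report$stages$plsr,
                           file.path(out_dir, "plsr_summary.json"),
                           auto_unbox = TRUE, digits = NA)
  } else report$stages$plsr <- list(skipped = TRUE)

  report$wall_time_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  report$results <- results
  if (!is.null(out_dir)) {
    slim <- report[setdiff(names(report), c("results", "config"))]
    jsonlite::write_json(slim, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
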