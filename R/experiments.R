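# Canned end-to-end experiment: the scaled-down two-class staging benchmark.

#' Two-class staging classification benchmark
#'
#' Runs the full synthetic classification experiment used to benchmark the
#' pipeline's staging power: for each seed, generate IR groups for two
#' differentiation stages (default 6 h vs day 2, 50 spectra per class), run
#' the spectrum-level IR preprocessing chain, build the analysis matrix over
#' the bio-region (950-3050 cm^-1 by default), calibrate a NIPALS PLS
#' regression on a stratified 80% of the data (10 factors, dummy 0/1
#' response) and classify the held-out 20%, scoring the true positive rate
#' of the second stage.
#'
#' @param stages two stage labels, `c(negative, positive)`
#' @param n_per_class spectra generated per class
#' @param seeds integer vector; one experiment per seed (generation and the
#'   stratified split both derive from it)
#' @param n_factors PLS factors
#' @param test_fraction held-out fraction
#' @param region analysis window (cm^-1)
#' @param axis_step generator axis spacing (cm^-1)
#' @param cross_validate run the leave-one-out pass per model (slower; the
#'   TPR does not depend on it)
#' @return data frame with one row per seed: `seed`, `tpr`, `rmsec`, `r2c`,
#'   `rmsev`, `r2v`, `n_cal`, `n_test`
#' @examples
#' \donttest{
#' res <- classification_experiment(seeds = 1:2, n_per_class = 20)
#' mean(res$tpr)
#' }
#' @export
classification_experiment <- function(stages = c("H6", "D2"), n_per_class = 50L,
                                      seeds = 1:10, n_factors = 10L,
                                      test_fraction = 0.2,
                                      region = c(950, 3050), axis_step = 1,
                                      cross_validate = FALSE) {
  stopifnot(length(stages) == 2L)
  rows <- lapply(seeds, function(sd) {
    cfg <- generator_config(seed = sd, n_per_group = n_per_class,
                            modality = "IR", axis_step = axis_step)
    neg <- preprocess_ir_spectra(generate_group(stages[1], cfg))
    pos <- preprocess_ir_spectra(generate_group(stages[2], cfg))
    all <- bind_sets(neg, pos)
    dm <- build_matrix(all, list(region))
    y <- as.integer(all$meta$group == stages[2])
    sp <- stratified_split(y, test_fraction = test_fraction, seed = sd)
    model <- plsr_calibrate(dm$x[sp$calibration, , drop = FALSE],
                            y[sp$calibration], n_factors = n_factors,
                            cross_validate = cross_validate)
    cls <- plsr_classify(model, dm$x[sp$test, , drop = FALSE], y[sp$test])
    data.frame(seed = sd, tpr = cls$tpr, rmsec = model$rmsec, r2c = model$r2c,
               rmsev = model$rmsev, r2v = model$r2v,
               n_cal = length(sp$calibration), n_test = length(sp$test))
  })
  do.call(rbind, rows)
}
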