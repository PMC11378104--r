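#' Run the full surrogate pipeline on a (typically simulated) dataset
#'
#' Convenience driver wiring the modules end to end: metabolomics QC on the
#' raw scale, phenotype-matched calibration to a reference cohort, log + z
#' standardization, surrogate training for chosen targets on the training
#' cohorts, projection onto a held-out cohort, within-dataset z-scaling and
#' an age/sex-adjusted Cox mortality scan.
#'
#' @param data a `multi_cohort_dataset` (see [simulate_dataset()]).
#' @param reference_cohort cohort used as calibration reference.
#' @param train_cohorts two or more cohorts used for surrogate training.
#' @param targets metabolite names to train surrogates for.
#' @param qc a [qc_config()].
#' @param training a [training_config()].
#' @param caliper matching caliper in pooled-SD units.
#' @return list: `qc` (matrix + report), `calibration` (map + calibrated
#'   matrix + standardized matrix), `matches`, `surrogates` (per-target
#'   nested-CV results), `scores` (held-out projections, z-scaled), `scan`
#'   (mortality scan on the held-out cohort), `holdout_cohort`.
#' @export
run_pipeline <- function(data, reference_cohort, train_cohorts, targets,
                         qc = qc_config(), training = training_config(),
                         caliper = 0.5) {
  ph <- data$phenotypes
  qc_res <- run_metabo_qc(data$metabolites, ph$cohort, qc,
                          standardize = FALSE)
  x <- qc_res$matrix
  ph2 <- ph[rownames(x), , drop = FALSE]
  cohorts <- unique(ph2$cohort)
  others <- setdiff(cohorts, reference_cohort)
  ref_ph <- ph2[ph2$cohort == reference_cohort, , drop = FALSE]
  matches <- lapply(others, function(co) {
    match_samples(ref_ph, ph2[ph2$cohort == co, , drop = FALSE], caliper)
  })
  names(matches) <- others
  cmap <- fit_calibration(x, matches, reference_cohort)
  xcal <- floor_detection_limit(apply_calibration(x, cmap, ph2$cohort))
  xstd <- log_standardize(xcal)

  tr_rows <- ph2$cohort %in% train_cohorts
  surrogates <- lapply(targets, function(tg) {
    nested_cv_train(stats::setNames(xstd[tr_rows, tg], rownames(xstd)[tr_rows]),
                    data$betas[rownames(xstd)[tr_rows], , drop = FALSE],
                    ph2$cohort[tr_rows], training)
  })
  names(surrogates) <- targets

  holdout <- setdiff(cohorts, train_cohorts)
  ho_rows <- ph2$cohort %in% holdout
  models <- lapply(surrogates, `[[`, "model")
  for (tg in targets) models[[tg]]$name <- tg
  scores <- project_surrogates(models, data$betas[rownames(xstd)[ho_rows], ,
                                                  drop = FALSE])
  keep <- apply(scores, 2, function(v) stats::sd(v) > 0)
  scan <- NULL
  zsc <- NULL
  if (any(keep)) {
    zsc <- zscale_within_dataset(scores[, keep, drop = FALSE],
                                 ph2$cohort[ho_rows])
    surv <- data$survival[match(rownames(zsc), data$survival$sample_id), ]
    covs <- cbind(age = ph2$age[ho_rows], sex = ph2$sex[ho_rows])
    scan <- univariate_scan(zsc, covs, surv)
  }
  list(qc = qc_res, calibration = list(map = cmap, calibrated = xcal,
                                       standardized = xstd),
       matches = matches, surrogates = surrogates, scores = zsc,
       scan = scan, holdout_cohort = holdout)
}
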