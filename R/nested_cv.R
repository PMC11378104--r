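#' Training configuration for surrogate models
#'
#' @param alpha elastic-net mixing parameter, fixed at 0.5 by default.
#' @param n_outer_folds,n_inner_folds fold counts of the nested
#'   cross-validation (default 5 and 5).
#' @param preselect_p nominal EWAS pre-selection threshold (default 0.05).
#' @param variance_prefilter_sd optional minimum beta SD; CpGs below it are
#'   excluded before the EWAS (default `NULL`, off).
#' @param n_lambda,lambda_min_ratio penalty grid controls: `n_lambda`
#'   log-spaced values from `lambda_max` down to
#'   `lambda_max * lambda_min_ratio`.
#' @param preselect_in_inner_folds if `TRUE`, the EWAS pre-selection is
#'   recomputed inside every inner fold (stricter nesting); default `FALSE`
#'   computes it once per outer-training set.
#' @param seed fold-assignment seed.
#' @return list of class `training_config`.
#' @export
training_config <- function(alpha = 0.5, n_outer_folds = 5, n_inner_folds = 5,
                            preselect_p = 0.05, variance_prefilter_sd = NULL,
                            n_lambda = 100, lambda_min_ratio = 1e-4,
                            preselect_in_inner_folds = FALSE, seed = 1L) {
  stopifnot(alpha >= 0, alpha <= 1, n_outer_folds >= 2, n_inner_folds >= 2,
            preselect_p > 0, preselect_p < 1, n_lambda >= 2)
  structure(list(alpha = alpha, n_outer_folds = as.integer(n_outer_folds),
                 n_inner_folds = as.integer(n_inner_folds),
                 preselect_p = preselect_p,
                 variance_prefilter_sd = variance_prefilter_sd,
                 n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio,
                 preselect_in_inner_folds = preselect_in_inner_folds,
                 seed = as.integer(seed)),
            class = "training_config")
}

## Cohort-stratified fold assignment: within each cohort, samples are
## shuffled (seeded) and dealt round-robin, so each fold preserves cohort
## proportions.
stratified_folds <- function(cohort_labels, n_folds, seed) {
  set.seed(seed)
  folds <- integer(length(cohort_labels))
  for (co in unique(cohort_labels)) {
    idx <- which(cohort_labels == co)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

## EWAS in each cohort of the training rows, then cross-cohort consistent
## pre-selection (pairwise intersection over all cohorts present).
preselect_on_rows <- function(target, betas, cohort_labels, rows, preselect_p) {
  cohorts <- unique(cohort_labels[rows])
  tabs <- lapply(cohorts, function(co) {
    run_ewas(target[rows], betas[rows, , drop = FALSE],
             cohort_labels[rows], co)
  })
  sel <- preselect_cpgs(tabs[[1]], tabs[[2]], preselect_p)
  if (length(tabs) > 2) {
    for (i in 3:length(tabs)) {
      keep <- tabs[[i]][match(sel, tabs[[i]]$cpg), ]
      first <- tabs[[1]][match(sel, tabs[[1]]$cpg), ]
      ok <- !is.na(keep$p) & keep$p < preselect_p &
        sign(keep$slope) == sign(first$slope)
      sel <- sel[ok]
    }
  }
  sel
}

## Inner CV over the lambda grid: mean validation MSE per grid point.
inner_cv_lambda <- function(X, y, cohort_labels, alpha, grid, n_inner, seed) {
  folds <- stratified_folds(cohort_labels, n_inner, seed)
  mse <- matrix(NA_real_, n_inner, length(grid))
  for (f in seq_len(n_inner)) {
    tr <- folds != f
    fit <- fit_elastic_net(X[tr, , drop = FALSE], y[tr], alpha, grid)
    pred <- sweep(X[!tr, , drop = FALSE] %*% fit$weights, 2, fit$intercepts, "+")
    mse[f, ] <- colMeans((pred - y[!tr])^2)
  }
  colMeans(mse)
}

#' Train a DNA-methylation surrogate under nested cross-validation
#'
#' Outer folds (stratified by cohort) estimate generalization; everything
#' fitted - the per-cohort EWAS, the cross-cohort pre-selection and the inner
#' cross-validated choice of the penalty - is recomputed inside each
#' outer-training set, so outer-test samples never influence model building.
#' Per outer fold the model is refit at the chosen penalty and evaluated on
#' the fold's test samples (Pearson R and RMSE). The final model repeats
#' pre-selection and inner CV on all samples and is refit at that penalty.
#'
#' @param target numeric vector named by sample id.
#' @param betas samples x CpGs matrix.
#' @param cohort_labels per-row cohort labels; at least two cohorts are
#'   required for the consistency pre-selection.
#' @param config a [training_config()].
#' @return list with `model` (class `surrogate_model`: `target`, `intercept`,
#'   `weights` sparse named vector, `lambda`, `alpha`, `n_preselected`,
#'   `n_selected`, `cohorts`, `intercept_only`), `performance` (class
#'   `performance_report`: per-fold table, `mean_R`, `tier`) and `audit`
#'   (per fold: test ids plus ids used for EWAS and penalty tuning).
#' @export
nested_cv_train <- function(target, betas, cohort_labels,
                            config = training_config()) {
  stopifnot(length(target) == nrow(betas),
            length(cohort_labels) == nrow(betas))
  if (length(unique(cohort_labels)) < 2)
    stop("pre-selection needs at least two training cohorts")
  if (is.null(names(target))) names(target) <- rownames(betas)
  ids <- rownames(betas)
  if (!is.null(config$variance_prefilter_sd)) {
    sds <- sqrt(colMeans(betas^2) - colMeans(betas)^2)
    betas <- betas[, sds >= config$variance_prefilter_sd, drop = FALSE]
  }
  folds <- stratified_folds(cohort_labels, config$n_outer_folds, config$seed)
  perf <- data.frame()
  audit <- list()
  for (f in seq_len(config$n_outer_folds)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    sel <- preselect_on_rows(target, betas, cohort_labels, tr,
                             config$preselect_p)
    audit[[f]] <- list(test_ids = ids[te], ewas_ids = ids[tr],
                       tuning_ids = ids[tr])
    if (length(sel) == 0) {
      pred <- rep(mean(target[tr]), length(te))
      ev <- evaluate_predictions(pred, target[te])
      perf <- rbind(perf, data.frame(fold = f, R = ev$R, RMSE = ev$RMSE,
                                     n = length(te), n_selected = 0L))
      next
    }
    Xtr <- betas[tr, sel, drop = FALSE]
    ytr <- target[tr]
    lmax <- enet_lambda_max(Xtr, ytr, config$alpha)
    grid <- enet_lambda_grid(lmax, config$n_lambda, config$lambda_min_ratio)
    cv <- inner_cv_lambda(Xtr, ytr, cohort_labels[tr], config$alpha, grid,
                          config$n_inner_folds, config$seed + f)
    best <- grid[which.min(cv)]
    fit <- fit_elastic_net(Xtr, ytr, config$alpha, grid)
    wcol <- which(grid == best)[1]
    w <- fit$weights[, wcol]
    b0 <- fit$intercepts[wcol]
    pred <- as.vector(betas[te, sel, drop = FALSE] %*% w) + b0
    ev <- evaluate_predictions(pred, target[te])
    perf <- rbind(perf, data.frame(fold = f, R = ev$R, RMSE = ev$RMSE,
                                   n = length(te), n_selected = sum(w != 0)))
  }
  ## final model on all data
  all_rows <- seq_along(ids)
  sel <- preselect_on_rows(target, betas, cohort_labels, all_rows,
                           config$preselect_p)
  if (length(sel) == 0) {
    model <- structure(list(target = attr(target, "name"),
                            intercept = mean(target), weights = numeric(0),
                            lambda = NA_real_, alpha = config$alpha,
                            n_preselected = 0L, n_selected = 0L,
                            cohorts = unique(cohort_labels),
                            intercept_only = TRUE),
                       class = "surrogate_model")
  } else {
    X <- betas[, sel, drop = FALSE]
    lmax <- enet_lambda_max(X, target, config$alpha)
    grid <- enet_lambda_grid(lmax, config$n_lambda, config$lambda_min_ratio)
    cv <- inner_cv_lambda(X, target, cohort_labels, config$alpha, grid,
                          config$n_inner_folds, config$seed)
    best <- grid[which.min(cv)]
    fit <- fit_elastic_net(X, target, config$alpha, grid)
    wcol <- which(grid == best)[1]
    w <- fit$weights[, wcol]
    w <- w[w != 0]
    model <- structure(list(target = "target", intercept = fit$intercepts[wcol],
                            weights = w, lambda = best, alpha = config$alpha,
                            n_preselected = length(sel),
                            n_selected = length(w),
                            cohorts = unique(cohort_labels),
                            intercept_only = FALSE),
                       class = "surrogate_model")
  }
  mean_R <- if (all(is.na(perf$R))) NA_real_ else mean(perf$R, na.rm = TRUE)
  performance <- structure(list(folds = perf, mean_R = mean_R,
                                tier = assign_tier(mean_R)),
                           class = "performance_report")
  list(model = model, performance = performance, audit = audit)
}

#' Pearson correlation and RMSE of predictions against observations
#'
#' @param pred,obs equal-length finite numeric vectors (length >= 3).
#' @return list `R` (NA when either vector has zero variance) and `RMSE`.
#' @export
evaluate_predictions <- function(pred, obs) {
  stopifnot(length(pred) == length(obs), length(pred) >= 3,
            all(is.finite(pred)), all(is.finite(obs)))
  rmse <- sqrt(mean((pred - obs)^2))
  R <- if (stats::sd(pred) == 0 || stats::sd(obs) == 0) NA_real_
       else stats::cor(pred, obs)
  list(R = R, RMSE = rmse)
}

#' Accuracy tier of a surrogate from its mean test-set correlation
#'
#' `accurate` for R > 0.35, `mild` for 0.2 < R <= 0.35, `low` for R <= 0.2,
#' `undefined` for missing R. The band edges are half-open with the boundary
#' value falling in the lower tier.
#'
#' @param mean_R mean Pearson R across test sets.
#' @export
assign_tier <- function(mean_R) {
  if (is.na(mean_R)) return("undefined")
  if (mean_R > 0.35) "accurate" else if (mean_R > 0.2) "mild" else "low"
}
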