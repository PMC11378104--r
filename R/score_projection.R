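#' A pretrained linear score
#'
#' Generic container for linear combinations of named features: multi-analyte
#' metabolite scores (MetaboHealth-style), CpG-based surrogates and
#' clock-style scores all fit this shape. The preprocessing spec records
#' whether features are log-transformed and at which scope they are z-scaled
#' before the weighted sum.
#'
#' @param name score name.
#' @param weights named numeric vector of feature weights (finite, unique
#'   names).
#' @param intercept additive constant (default 0).
#' @param log log-transform features first? (default `FALSE`).
#' @param zscale_scope `"none"`, `"per_dataset"` (within each cohort
#'   separately, the classic meta-analysis mode) or `"pooled"` (across all
#'   samples, the calibrated-data mode).
#' @return list of class `linear_score`.
#' @export
linear_score <- function(name, weights, intercept = 0, log = FALSE,
                         zscale_scope = c("none", "per_dataset", "pooled")) {
  zscale_scope <- match.arg(zscale_scope)
  stopifnot(all(is.finite(weights)), !is.null(names(weights)),
            !anyDuplicated(names(weights)))
  structure(list(name = name, intercept = intercept, weights = weights,
                 preprocessing = list(log = log, zscale_scope = zscale_scope)),
            class = "linear_score")
}

#' Apply a metabolite-based linear score to a concentration matrix
#'
#' Features are preprocessed per the score's spec (optional log, then
#' z-scaling at the requested scope), then combined as
#' `intercept + sum_f w_f z_f`.
#'
#' @param score a [linear_score()].
#' @param metabolites samples x features matrix.
#' @param dataset_labels per-row labels, required for
#'   `zscale_scope = "per_dataset"`.
#' @return named numeric vector of scores.
#' @export
apply_metabolite_score <- function(score, metabolites, dataset_labels = NULL) {
  feats <- names(score$weights)
  miss <- setdiff(feats, colnames(metabolites))
  if (length(miss) > 0)
    stop("score features missing from matrix: ", paste(miss, collapse = ", "))
  X <- metabolites[, feats, drop = FALSE]
  if (isTRUE(score$preprocessing$log)) X <- log(X)
  scope <- score$preprocessing$zscale_scope
  if (scope == "pooled") {
    X <- scale(X)
  } else if (scope == "per_dataset") {
    if (is.null(dataset_labels))
      stop("per_dataset z-scaling requires dataset_labels")
    for (d in unique(dataset_labels)) {
      r <- dataset_labels == d
      X[r, ] <- scale(X[r, , drop = FALSE])
    }
  }
  out <- as.vector(X %*% score$weights) + score$intercept
  names(out) <- rownames(metabolites)
  out
}

#' Project CpG-based surrogate models onto a beta matrix
#'
#' `score = intercept + sum_j w_j beta_j` per model. CpGs absent from the
#' matrix are imputed with their reference mean beta (the standard recourse
#' when array versions drop probes); a CpG absent from both the matrix and
#' the reference is an error.
#'
#' @param models list of `surrogate_model` / `linear_score` objects (a single
#'   model is accepted).
#' @param betas samples x CpGs matrix.
#' @param reference optional named vector of reference mean betas in `[0,1]`.
#' @return samples x models score matrix with attribute `n_imputed_cpgs`
#'   (named per model).
#' @export
project_surrogates <- function(models, betas, reference = NULL) {
  if (inherits(models, c("surrogate_model", "linear_score")))
    models <- list(models)
  nm <- vapply(seq_along(models), function(i) {
    m <- models[[i]]
    if (!is.null(m$name)) m$name else if (!is.null(m$target)) m$target
    else paste0("model_", i)
  }, character(1))
  out <- matrix(NA_real_, nrow(betas), length(models),
                dimnames = list(rownames(betas), nm))
  n_imp <- stats::setNames(integer(length(models)), nm)
  for (i in seq_along(models)) {
    m <- models[[i]]
    w <- m$weights
    have <- names(w) %in% colnames(betas)
    absent <- names(w)[!have]
    if (length(absent) > 0) {
      known <- absent %in% names(reference)
      if (!all(known))
        stop(sprintf("model '%s': CpG '%s' absent from betas and reference",
                     nm[i], absent[!known][1]))
    }
    sc <- rep(m$intercept, nrow(betas))
    if (any(have))
      sc <- sc + as.vector(betas[, names(w)[have], drop = FALSE] %*% w[have])
    if (length(absent) > 0)
      sc <- sc + sum(w[absent] * reference[absent])
    out[, i] <- sc
    n_imp[i] <- length(absent)
  }
  attr(out, "n_imputed_cpgs") <- n_imp
  out
}

#' z-scale score columns within each dataset
#'
#' Each score column is centred and scaled to unit SD within every dataset
#' label separately, the convention used before per-SD hazard modelling.
#'
#' @param scores samples x scores matrix.
#' @param dataset_labels per-row labels (each with >= 2 samples).
#' @return scaled matrix.
#' @export
zscale_within_dataset <- function(scores, dataset_labels) {
  scores <- as.matrix(scores)
  stopifnot(length(dataset_labels) == nrow(scores))
  out <- scores
  for (d in unique(dataset_labels)) {
    r <- dataset_labels == d
    if (sum(r) < 2) stop("dataset '", d, "' has fewer than 2 samples")
    block <- scores[r, , drop = FALSE]
    sds <- apply(block, 2, stats::sd)
    if (any(sds == 0))
      stop("zero-variance score '", colnames(scores)[sds == 0][1],
           "' within dataset '", d, "'")
    out[r, ] <- scale(block)
  }
  out
}
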