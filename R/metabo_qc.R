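#' Quality-control configuration for the metabolomics matrix
#'
#' @param outlier_z_threshold robust z cutoff on the log scale (default 5).
#' @param max_outliers_per_sample samples with strictly more flagged cells
#'   than this are removed (default 1, i.e. removal from 2 flags).
#' @param feature_missingness_threshold per-cohort missing fraction above
#'   which (strictly) a feature is dropped (default 0.3).
#' @param detection_limit_policy `"keep"` leaves zeros in place (they error
#'   later at the log step), `"set_missing"` converts them to missing before
#'   imputation.
#' @param nipals_components,nipals_tol,nipals_max_iter NIPALS imputation
#'   controls.
#' @return list of class `qc_config`.
#' @export
qc_config <- function(outlier_z_threshold = 5,
                      max_outliers_per_sample = 1,
                      feature_missingness_threshold = 0.3,
                      detection_limit_policy = c("keep", "set_missing"),
                      nipals_components = 5,
                      nipals_tol = 1e-6,
                      nipals_max_iter = 500) {
  detection_limit_policy <- match.arg(detection_limit_policy)
  stopifnot(outlier_z_threshold > 0, max_outliers_per_sample >= 0,
            feature_missingness_threshold > 0,
            feature_missingness_threshold <= 1,
            nipals_components >= 1, nipals_tol > 0, nipals_max_iter >= 1)
  structure(list(outlier_z_threshold = outlier_z_threshold,
                 max_outliers_per_sample = max_outliers_per_sample,
                 feature_missingness_threshold = feature_missingness_threshold,
                 detection_limit_policy = detection_limit_policy,
                 nipals_components = nipals_components,
                 nipals_tol = nipals_tol,
                 nipals_max_iter = nipals_max_iter),
            class = "qc_config")
}

#' Drop features with high per-cohort missingness
#'
#' A feature is removed iff its missing fraction in ANY cohort strictly
#' exceeds `threshold` (a feature missing exactly at the threshold is
#' retained). This generalizes the panel rule under which an analyte missing
#' in 80% of one cohort is excluded outright.
#'
#' @param metabolites samples x features matrix (missing allowed).
#' @param cohort_labels per-row cohort labels.
#' @param threshold fraction in (0, 1].
#' @return list `matrix` (filtered) and `report` (data.frame: feature, cohort,
#'   missing fraction, dropped flag).
#' @export
drop_high_missingness_features <- function(metabolites, cohort_labels,
                                           threshold = 0.3) {
  if (length(metabolites) == 0) stop("empty metabolite matrix")
  stopifnot(threshold > 0, threshold <= 1)
  cohorts <- unique(cohort_labels)
  frac <- sapply(cohorts, function(co) {
    colMeans(is.na(metabolites[cohort_labels == co, , drop = FALSE]))
  })
  if (is.null(dim(frac))) frac <- matrix(frac, ncol = length(cohorts),
                                         dimnames = list(colnames(metabolites), cohorts))
  worst <- apply(frac, 1, max)
  drop <- worst > threshold
  report <- data.frame(feature = rep(rownames(frac), length(cohorts)),
                       cohort = rep(cohorts, each = nrow(frac)),
                       missing_fraction = as.vector(frac),
                       dropped = rep(drop, length(cohorts)),
                       stringsAsFactors = FALSE)
  list(matrix = metabolites[, !drop, drop = FALSE], report = report)
}

#' Flag outlying cells by robust z-score on the log scale
#'
#' A cell is flagged iff `|log x - median_f| / (1.4826 * MAD_f) >
#' z_threshold`, with the per-feature median and MAD of log values computed
#' ignoring missing cells. Constant features (MAD 0) produce no flags.
#' Non-positive values cannot be logged and are never flagged here (they are
#' handled by the detection-limit policy and the log step).
#'
#' @param metabolites samples x features matrix.
#' @param z_threshold robust z cutoff.
#' @return logical matrix of flags, same shape as the input.
#' @export
flag_outliers <- function(metabolites, z_threshold = 5) {
  lx <- suppressWarnings(log(metabolites))
  lx[!is.finite(lx)] <- NA
  med <- apply(lx, 2, stats::median, na.rm = TRUE)
  madv <- apply(lx, 2, stats::mad, na.rm = TRUE)  # 1.4826 * MAD
  z <- sweep(lx, 2, med, "-")
  z <- sweep(z, 2, ifelse(madv > 0, madv, Inf), "/")
  flags <- abs(z) > z_threshold
  flags[is.na(flags)] <- FALSE
  flags
}

#' Samples to remove for carrying multiple outlying cells
#'
#' @param flags logical matrix from [flag_outliers()].
#' @param max_outliers_per_sample removal iff flag count strictly exceeds this
#'   (default 1: a sample with 2 or more outliers is removed, one is kept).
#' @return character vector of sample ids (row names) to remove.
#' @export
remove_outlier_samples <- function(flags, max_outliers_per_sample = 1) {
  counts <- rowSums(flags)
  rownames(flags)[counts > max_outliers_per_sample]
}

#' Impute missing cells by missing-aware NIPALS
#'
#' Computes a rank-`ncomp` reconstruction with NIPALS iterations whose inner
#' products skip missing cells, then fills ONLY the missing cells from the
#' reconstruction (scores x loadings); observed cells are returned unchanged.
#' The decomposition is computed on the uncentred matrix (the mean structure
#' is absorbed by the leading component), so low-rank matrices are recovered
#' exactly. Each component iterates until the score vector changes by less
#' than `tol` (relative L2) or `max_iter` sweeps.
#'
#' @param metabolites samples x features matrix with missing cells.
#' @param ncomp number of components (default 5).
#' @param tol convergence tolerance on the score vector (default 1e-6).
#' @param max_iter maximum sweeps per component (default 500).
#' @return the imputed matrix, with attributes `n_imputed` and `converged`.
#' @export
nipals_impute <- function(metabolites, ncomp = 5, tol = 1e-6, max_iter = 500) {
  x <- metabolites
  miss <- is.na(x)
  if (!any(miss)) {
    attr(x, "n_imputed") <- 0L
    attr(x, "converged") <- TRUE
    return(x)
  }
  bad_col <- colSums(!miss) == 0
  if (any(bad_col))
    stop("all-missing column(s): ", paste(colnames(x)[bad_col], collapse = ", "))
  bad_row <- rowSums(!miss) == 0
  if (any(bad_row))
    stop("all-missing row(s): ", paste(rownames(x)[bad_row], collapse = ", "))
  ncomp <- min(ncomp, nrow(x) - 1L, ncol(x))
  recon <- matrix(0, nrow(x), ncol(x))
  converged <- TRUE
  xw <- x
  xw[miss] <- 0
  obs <- !miss
  storage.mode(obs) <- "double"
  for (h in seq_len(ncomp)) {
    j0 <- which.max(colSums(xw^2))
    t_vec <- xw[, j0]
    for (it in seq_len(max_iter)) {
      # loadings: missing-aware projection of columns on t
      p <- as.vector(crossprod(xw, t_vec)) / as.vector(crossprod(obs, t_vec^2))
      p[!is.finite(p)] <- 0
      p <- p / sqrt(sum(p^2))
      # sign convention (largest loading positive) so the iteration cannot
      # oscillate between the two equivalent sign choices
      if (p[which.max(abs(p))] < 0) p <- -p
      t_new <- as.vector(xw %*% p) / as.vector(obs %*% p^2)
      t_new[!is.finite(t_new)] <- 0
      delta <- sqrt(sum((t_new - t_vec)^2)) / max(sqrt(sum(t_new^2)), 1e-12)
      t_vec <- t_new
      if (delta < tol) break
    }
    if (delta >= tol) converged <- FALSE
    recon <- recon + tcrossprod(t_vec, p)
    xw <- xw - tcrossprod(t_vec, p)
    xw[miss] <- 0
  }
  if (!converged)
    warning("NIPALS did not converge within max_iter; best estimate returned")
  x[miss] <- recon[miss]
  attr(x, "n_imputed") <- sum(miss)
  attr(x, "converged") <- converged
  x
}

#' Floor non-positive concentrations at a per-feature detection limit
#'
#' Replaces cells at or below zero with half the feature's smallest positive
#' value. Affine calibration maps and low-rank imputation can push the
#' extreme low tail of a positive concentration below zero; flooring mimics
#' the detection-limit convention of concentration assays and keeps the
#' matrix valid for the log step.
#'
#' @param metabolites numeric matrix; each feature must have at least one
#'   positive value.
#' @return the floored matrix.
#' @export
floor_detection_limit <- function(metabolites) {
  for (j in seq_len(ncol(metabolites))) {
    bad <- metabolites[, j] <= 0
    bad[is.na(bad)] <- FALSE
    if (any(bad)) {
      pos <- metabolites[!bad & !is.na(metabolites[, j]), j]
      metabolites[bad, j] <- min(pos[pos > 0]) / 2
    }
  }
  metabolites
}

#' Log-transform and z-standardize a metabolite matrix across all samples
#'
#' `y = (log x - mean_f(log x)) / sd_f(log x)` with moments pooled over every
#' sample; each output column has mean 0 and SD 1.
#'
#' @param metabolites strictly positive matrix (post-imputation).
#' @return standardized matrix.
#' @export
log_standardize <- function(metabolites) {
  bad <- which(!(metabolites > 0), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    b <- bad[1, ]
    stop(sprintf("non-positive concentration at sample '%s', feature '%s'",
                 rownames(metabolites)[b[1]], colnames(metabolites)[b[2]]))
  }
  lx <- log(metabolites)
  scale(lx)[, , drop = FALSE]
}

#' Run the full metabolomics QC chain
#'
#' Fixed order: panel filter (per-cohort missingness) -> outlier flagging ->
#' sample removal -> NIPALS imputation -> log + z standardization. The chain
#' is idempotent: a second pass on the output drops and flags nothing.
#' Imputed cells that land at or below zero are floored at half the
#' feature's smallest positive observed value, so concentrations stay
#' positive for the log step.
#'
#' @param metabolites raw concentration matrix.
#' @param cohort_labels per-row cohort labels (named by sample id or in row
#'   order).
#' @param config a [qc_config()].
#' @param standardize set `FALSE` to stop before the log+z step (e.g. when
#'   cross-cohort calibration is still to be applied on the raw scale).
#' @return list `matrix` and `report` (class `qc_report`): dropped features,
#'   flagged cells, removed samples, imputation counts.
#' @export
run_metabo_qc <- function(metabolites, cohort_labels, config = qc_config(),
                          standardize = TRUE) {
  stopifnot(length(cohort_labels) == nrow(metabolites))
  step1 <- drop_high_missingness_features(
    metabolites, cohort_labels, config$feature_missingness_threshold)
  x <- step1$matrix
  if (config$detection_limit_policy == "set_missing") x[x <= 0] <- NA
  flags <- flag_outliers(x, config$outlier_z_threshold)
  removed <- remove_outlier_samples(flags, config$max_outliers_per_sample)
  keep <- !(rownames(x) %in% removed)
  x <- x[keep, , drop = FALSE]
  flagged_cells <- which(flags[keep, , drop = FALSE], arr.ind = TRUE)
  n_missing <- sum(is.na(x))
  miss_cells <- is.na(x)
  x <- nipals_impute(x, config$nipals_components, config$nipals_tol,
                     config$nipals_max_iter)
  n_imputed <- attr(x, "n_imputed")
  ## imputed cells can land at or below zero; apply the detection-limit floor
  x <- floor_detection_limit(x)
  if (standardize) x <- log_standardize(x)
  report <- structure(list(
    dropped_features = unique(step1$report$feature[step1$report$dropped]),
    feature_missingness = step1$report,
    flagged_outlier_cells = data.frame(
      sample = rownames(step1$matrix)[keep][flagged_cells[, 1]],
      feature = colnames(step1$matrix)[flagged_cells[, 2]],
      stringsAsFactors = FALSE),
    removed_samples = removed,
    n_imputed = n_imputed,
    imputed_fraction = if (length(x) > 0) n_imputed / length(x) else 0,
    cohort_labels = cohort_labels[keep]), class = "qc_report")
  stopifnot(n_imputed == n_missing)
  list(matrix = x, report = report)
}
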