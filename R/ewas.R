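#' Per-CpG univariate association scan (EWAS) within one cohort
#'
#' For every CpG, fits the simple regression `target ~ beta` on the samples
#' of one cohort and reports slope, standard error, t statistic (slope / SE)
#' and the two-sided p from the t distribution with n - 2 degrees of freedom.
#' No covariates are included, matching the deliberately permissive
#' pre-selection philosophy of surrogate training. Zero-variance CpGs are
#' omitted from the table.
#'
#' @param target numeric vector named by sample id (complete for the cohort).
#' @param betas samples x CpGs matrix.
#' @param cohort_labels per-row cohort labels of `betas`.
#' @param cohort the cohort to scan.
#' @return data.frame of class `ewas_table`: `cpg`, `slope`, `se`, `t`, `p`,
#'   `n`, plus attributes `cohort` and `target`.
#' @export
run_ewas <- function(target, betas, cohort_labels, cohort) {
  rows <- which(cohort_labels == cohort)
  if (length(rows) < 3) stop("need at least 3 samples for an EWAS")
  X <- betas[rows, , drop = FALSE]
  y <- target[rownames(X)]
  if (anyNA(y)) stop("target must be complete for cohort samples")
  n <- length(y)
  xbar <- colMeans(X)
  ybar <- mean(y)
  sxx <- colSums(X^2) - n * xbar^2
  sxy <- as.vector(crossprod(X, y)) - n * xbar * ybar
  syy <- sum(y^2) - n * ybar^2
  keep <- sxx > 0
  slope <- sxy[keep] / sxx[keep]
  sse <- pmax(syy - slope * sxy[keep], 0)
  se <- sqrt(sse / (n - 2) / sxx[keep])
  tstat <- slope / se
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  out <- data.frame(cpg = colnames(X)[keep], slope = slope, se = se,
                    t = tstat, p = p, n = n, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "cohort") <- cohort
  class(out) <- c("ewas_table", "data.frame")
  out
}

#' Pre-select CpGs consistent across two cohort EWAS tables
#'
#' A CpG is selected iff its slopes have the same sign in both cohorts and
#' both p values are below the nominal threshold. The selection is returned
#' in deterministic (sorted CpG id) order.
#'
#' @param ewas_a,ewas_b [run_ewas()] tables for the same target in two
#'   cohorts.
#' @param preselect_p nominal significance threshold (default 0.05, strict
#'   `<`).
#' @return character vector of selected CpG ids.
#' @export
preselect_cpgs <- function(ewas_a, ewas_b, preselect_p = 0.05) {
  stopifnot(preselect_p > 0, preselect_p < 1)
  common <- intersect(ewas_a$cpg, ewas_b$cpg)
  if (length(common) == 0) stop("EWAS tables have disjoint CpG universes")
  a <- ewas_a[match(common, ewas_a$cpg), ]
  b <- ewas_b[match(common, ewas_b$cpg), ]
  sel <- sign(a$slope) == sign(b$slope) & a$slope != 0 &
    a$p < preselect_p & b$p < preselect_p
  sort(common[sel])
}
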