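#' k-nearest-neighbour batch-mixing test
#'
#' For `n_draws` randomly chosen samples, compares the cohort composition of
#' the sample's k nearest Euclidean neighbours (self excluded) against the
#' global cohort proportions with a chi-square goodness-of-fit test. The
#' rejection rate - the fraction of tested neighbourhoods with p < 0.05 - is
#' near the test level when cohorts are well mixed and approaches 1 when they
#' separate. This is a fixed-k reimplementation of the kNN batch-effect test
#' idea used purely as a mixing diagnostic (no k adaptation).
#'
#' @param x samples x features numeric matrix.
#' @param cohort_labels per-row labels.
#' @param k neighbourhood size (default 50); must be < number of samples.
#' @param n_draws number of tested neighbourhoods (default 500, capped at n).
#' @param seed RNG seed for the draw.
#' @return list of class `batch_mixing_report`: `rejection_rate`, `k`,
#'   `n_tested`, `p_values`.
#' @export
batch_mixing_test <- function(x, cohort_labels, k = 50, n_draws = 500,
                              seed = 1L) {
  n <- nrow(x)
  stopifnot(k < n)
  cohorts <- sort(unique(cohort_labels))
  if (length(cohorts) < 2) {
    warning("single cohort: batch mixing rejection rate defined as 0")
    return(structure(list(rejection_rate = 0, k = k, n_tested = 0L,
                          p_values = numeric(0)),
                     class = "batch_mixing_report"))
  }
  props <- as.vector(table(factor(cohort_labels, cohorts))) / n
  set.seed(seed)
  n_draws <- min(n_draws, n)
  draws <- sample.int(n, n_draws)
  sq <- rowSums(x^2)
  pvals <- vapply(draws, function(i) {
    d2 <- sq - 2 * as.vector(x %*% x[i, ]) + sum(x[i, ]^2)
    d2[i] <- Inf
    nb <- order(d2)[seq_len(k)]
    counts <- as.vector(table(factor(cohort_labels[nb], cohorts)))
    suppressWarnings(stats::chisq.test(counts, p = props)$p.value)
  }, numeric(1))
  structure(list(rejection_rate = mean(pvals < 0.05), k = k,
                 n_tested = n_draws, p_values = pvals),
            class = "batch_mixing_report")
}

#' Principal-component variance decomposition over phenotype factors
#'
#' Retains principal components up to a cumulative variance fraction, fits
#' each PC score vector on every factor separately (continuous factors as-is,
#' categorical factors one-hot), attributes the PC's variance to factors by
#' the fit R-squared with residual `1 - sum(R2)` clipped at zero, renormalizes
#' per PC, and averages across PCs with eigenvalue weights. A fixed-effects
#' R-squared approximation of principal variance component analysis: factor
#' fractions sum to one but overlapping factors share credit.
#'
#' @param x samples x features matrix.
#' @param factor_table data.frame of factors (e.g. cohort, age, sex, bmi),
#'   rows aligned with `x`.
#' @param variance_kept cumulative variance fraction of retained PCs
#'   (default 0.9).
#' @return list of class `variance_components_report`: named `fractions`
#'   (factors + residual, summing to 1), `n_components`.
#' @export
variance_components <- function(x, factor_table, variance_kept = 0.9) {
  stopifnot(variance_kept > 0, variance_kept <= 1,
            nrow(factor_table) == nrow(x))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  cum <- cumsum(ev) / sum(ev)
  ncomp <- max(1L, which(cum >= variance_kept)[1])
  ncomp <- min(ncomp, ncol(pc$x))
  fac_names <- names(factor_table)
  r2 <- matrix(0, ncomp, length(fac_names),
               dimnames = list(NULL, fac_names))
  for (f in fac_names) {
    v <- factor_table[[f]]
    if (length(unique(v)) < 2) {
      warning("factor '", f, "' is constant; contributes 0")
      next
    }
    if (is.character(v) || is.factor(v) || length(unique(v)) == 2)
      v <- factor(v)
    for (j in seq_len(ncomp)) {
      fit <- stats::lm(pc$x[, j] ~ v)
      r2[j, f] <- summary(fit)$r.squared
    }
  }
  resid <- pmax(0, 1 - rowSums(r2))
  full <- cbind(r2, residual = resid)
  full <- full / rowSums(full)
  w <- ev[seq_len(ncomp)] / sum(ev[seq_len(ncomp)])
  fractions <- colSums(full * w)
  structure(list(fractions = fractions, n_components = ncomp),
            class = "variance_components_report")
}
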