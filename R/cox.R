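#' Fit a Cox proportional-hazards model
#'
#' Wraps [survival::coxph()] with Efron tie correction (the survival
#' ecosystem default, appropriate for the moderately tied follow-up times of
#' population cohorts) and packages the quantities the rest of the module
#' needs: per-covariate coefficients with Wald tests, hazard ratios with 95%
#' CIs, the partial log-likelihood and the Harrell C-index on the fitting
#' data.
#'
#' @param X covariate matrix or data.frame (numeric, complete).
#' @param survival data.frame with columns `time` (> 0) and `event` (0/1),
#'   rows aligned with `X`.
#' @return list of class `cox_fit`: `coefficients` table (beta, se, z, p, hr,
#'   hr_lo, hr_hi), `loglik`, `n`, `n_events`, `c_index`, `linear_predictor`
#'   and the underlying `coxph` object.
#' @export
fit_cox <- function(X, survival) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  stopifnot(nrow(X) == nrow(survival), all(survival$time > 0),
            all(survival$event %in% c(0, 1)))
  if (sum(survival$event) < 1) stop("need at least one event")
  const <- apply(X, 2, function(v) stats::sd(v) == 0)
  if (any(const))
    stop("constant covariate(s): ", paste(colnames(X)[const], collapse = ", "))
  df <- data.frame(X, check.names = FALSE)
  df$.time <- survival$time
  df$.event <- survival$event
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron",
                         control = survival::coxph.control(eps = 1e-10, iter.max = 50))
  if (any(!is.finite(coef(fit))) || any(abs(coef(fit)) > 50))
    stop("Cox fit did not converge (monotone likelihood?); consider penalization")
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  lp <- as.vector(X %*% beta)
  cc <- harrell_c_cpp(lp, survival$time, as.integer(survival$event))
  structure(list(
    coefficients = data.frame(term = colnames(X), beta = beta, se = se,
                              z = z, p = p, hr = exp(beta),
                              hr_lo = exp(beta - 1.96 * se),
                              hr_hi = exp(beta + 1.96 * se),
                              row.names = NULL, stringsAsFactors = FALSE),
    loglik = fit$loglik[length(fit$loglik)],
    n = nrow(X), n_events = sum(survival$event),
    c_index = cc$C, linear_predictor = lp, coxph = fit),
    class = "cox_fit")
}

#' Harrell concordance index of a risk score
#'
#' Among usable pairs - those where the subject with the earlier observed
#' time is an event (pairs with equal times and both events are unusable) -
#' the fraction in which the higher risk score belongs to the
#' shorter-surviving subject, with tied scores counting one half.
#'
#' @param scores numeric risk scores (higher = riskier).
#' @param survival data.frame with `time` and `event`.
#' @return list `C`, `n_usable_pairs`, and per-subject `conc` / `usable`
#'   counts (used by [compare_concordance()]).
#' @export
concordance_index <- function(scores, survival) {
  stopifnot(all(is.finite(scores)), length(scores) == nrow(survival))
  out <- harrell_c_cpp(as.numeric(scores), survival$time,
                       as.integer(survival$event))
  if (out$n_usable_pairs == 0) stop("no usable pairs for concordance")
  out
}

#' Univariate covariate-adjusted Cox scan across scores
#'
#' Fits one Cox model per score column, each adjusted for the same covariate
#' set (age and sex by default usage), and corrects the score p values across
#' the scan with Benjamini-Hochberg. Scores should be z-scaled so hazard
#' ratios are per SD. Subgroup scans (e.g. sex-stratified) are obtained by
#' subsetting rows before the call. Per-feature fit failures are reported in
#' the table, not fatal.
#'
#' @param scores samples x scores matrix.
#' @param covariates covariate matrix/data.frame (may be NULL for unadjusted).
#' @param survival data.frame with `time`, `event`.
#' @param fdr_level significance level on adjusted p (default 0.05).
#' @return data.frame of class `scan_result`: per score `hr`, `hr_lo`,
#'   `hr_hi`, `p`, `p_adj`, `significant`, `error`.
#' @export
univariate_scan <- function(scores, covariates, survival, fdr_level = 0.05) {
  scores <- as.matrix(scores)
  res <- lapply(colnames(scores), function(s) {
    X <- cbind(scores[, s, drop = FALSE], covariates)
    out <- tryCatch({
      fit <- fit_cox(X, survival)
      row <- fit$coefficients[1, ]
      data.frame(score = s, beta = row$beta, hr = row$hr, hr_lo = row$hr_lo,
                 hr_hi = row$hr_hi, p = row$p, error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(score = s, beta = NA_real_, hr = NA_real_, hr_lo = NA_real_,
                 hr_hi = NA_real_, p = NA_real_, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    out
  })
  tab <- do.call(rbind, res)
  tab$p_adj <- stats::p.adjust(tab$p, method = "BH")
  tab$significant <- !is.na(tab$p_adj) & tab$p_adj < fdr_level
  tab$covariates <- paste(colnames(covariates), collapse = "+")
  class(tab) <- c("scan_result", "data.frame")
  tab
}

#' Compare the concordance of two risk models on the same samples
#'
#' Computes each subject's per-pair concordance contribution under both
#' models (concordant pairs + half ties over usable pairs involving the
#' subject) and compares the two contribution vectors with a paired t test on
#' their differences, which accounts for the correlation between the models.
#' Identical score vectors return `delta_C = 0, p = 1` by convention.
#'
#' @param scores_a,scores_b risk score vectors of the two models.
#' @param survival data.frame with `time`, `event`.
#' @return list `delta_C` (`C_a - C_b`), `p` (two-sided), `C_a`, `C_b`.
#' @export
compare_concordance <- function(scores_a, scores_b, survival) {
  a <- concordance_index(scores_a, survival)
  b <- concordance_index(scores_b, survival)
  delta <- a$C - b$C
  if (isTRUE(all.equal(as.numeric(scores_a), as.numeric(scores_b))))
    return(list(delta_C = 0, p = 1, C_a = a$C, C_b = b$C))
  use <- a$usable > 0 & b$usable > 0
  da <- a$conc[use] / a$usable[use]
  db <- b$conc[use] / b$usable[use]
  d <- da - db
  if (stats::sd(d) == 0) {
    p <- if (mean(d) == 0) 1 else 0
  } else {
    p <- stats::t.test(d)$p.value
  }
  list(delta_C = delta, p = p, C_a = a$C, C_b = b$C)
}

#' Schoenfeld-residual test of proportional hazards
#'
#' Per-covariate score test of the Grambsch-Therneau form: scaled Schoenfeld
#' residuals at event times regressed on Kaplan-Meier-transformed time (via
#' [survival::cox.zph()]).
#'
#' @param fit a [fit_cox()] result.
#' @return data.frame with `term`, `chisq`, `df`, `p`.
#' @export
schoenfeld_test <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  if (fit$n_events < 2) stop("need at least 2 events for the Schoenfeld test")
  z <- survival::cox.zph(fit$coxph, transform = "km", global = FALSE)
  tab <- as.data.frame(z$table)
  data.frame(term = rownames(tab), chisq = tab$chisq, df = tab$df,
             p = tab$p, row.names = NULL, stringsAsFactors = FALSE)
}
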