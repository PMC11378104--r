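#' Time-dependent cumulative/dynamic AUC at a fixed horizon
#'
#' Discrimination of events-by-horizon cases from at-risk-beyond-horizon
#' controls, with inverse-probability-of-censoring weights (IPCW) from the
#' Kaplan-Meier estimate of the censoring distribution: cases (event with
#' `time <= horizon`) are weighted `1 / G(t_i-)`, controls (`time > horizon`)
#' are weighted `1 / G(horizon)`. Under zero censoring all weights are 1 and
#' the estimate reduces to the plain binary AUC of (event by horizon) against
#' the score. Tied scores count one half.
#'
#' @param scores numeric risk scores (higher = riskier).
#' @param survival data.frame with `time`, `event`.
#' @param horizon_years evaluation horizon; needs at least one case and one
#'   control.
#' @return the AUC (scalar).
#' @export
td_auc <- function(scores, survival, horizon_years) {
  time <- survival$time
  event <- survival$event
  stopifnot(length(scores) == length(time))
  cases <- which(time <= horizon_years & event == 1)
  controls <- which(time > horizon_years)
  if (length(cases) < 1 || length(controls) < 1)
    stop("need at least one event before and one survivor past the horizon")
  ## KM of the censoring distribution G(t) = P(C > t)
  km <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  Gfun <- stats::stepfun(km$time, c(1, km$surv), right = FALSE)
  G <- function(t) pmax(Gfun(t), 1e-10)
  w_case <- 1 / G(pmax(time[cases] - 1e-10, 0))
  w_ctrl <- rep(1 / G(horizon_years), length(controls))
  sc <- scores[cases]
  st <- scores[controls]
  cmp <- outer(sc, st, function(a, b) (a > b) + 0.5 * (a == b))
  W <- outer(w_case, w_ctrl)
  sum(W * cmp) / sum(W)
}
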