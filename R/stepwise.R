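#' Stepwise forward/backward Cox model composition driven by the C-index
#'
#' Starting from the base covariates (always retained), iterates rounds of:
#' forward - add the candidate giving the largest C-index increase, provided
#' the increase exceeds `tol_C` and the candidate's Wald p in the enlarged
#' model is below `p_in`; backward - remove any included candidate whose p
#' exceeds `p_out` and whose removal costs at most `tol_C` of C-index.
#' Stops when no action qualifies, after `max_rounds`, or if a state repeats
#' (cycling guard). The trace is deterministic given the candidate column
#' order and replayable from the recorded actions.
#'
#' @param candidates samples x candidates score matrix.
#' @param base_covariates matrix/data.frame of always-kept covariates (e.g.
#'   age, sex); may be `NULL`.
#' @param survival data.frame with `time`, `event`.
#' @param tol_C minimal C-index improvement (default 0.001).
#' @param p_in,p_out Wald significance thresholds (default 0.05).
#' @param max_rounds cap on add/remove rounds (default 100).
#' @return list of class `stepwise_trace`: `trace` data.frame (action,
#'   variable, C_before, C_after, p), `selected` variables, `final_fit`
#'   ([fit_cox()] on base + selected), `base_C`.
#' @export
stepwise_select <- function(candidates, base_covariates, survival,
                            tol_C = 0.001, p_in = 0.05, p_out = 0.05,
                            max_rounds = 100) {
  candidates <- as.matrix(candidates)
  cand_names <- colnames(candidates)
  stopifnot(!is.null(cand_names))
  fit_state <- function(included) {
    X <- cbind(base_covariates, candidates[, included, drop = FALSE])
    if (is.null(X) || ncol(X) == 0) return(NULL)
    fit_cox(X, survival)
  }
  state_c <- function(included) {
    f <- fit_state(included)
    if (is.null(f)) 0.5 else f$c_index
  }
  included <- character(0)
  cur_C <- state_c(included)
  base_C <- cur_C
  trace <- data.frame()
  seen <- paste(sort(included), collapse = ",")
  for (round in seq_len(max_rounds)) {
    acted <- FALSE
    ## forward
    avail <- setdiff(cand_names, included)
    if (length(avail) > 0) {
      gains <- rep(NA_real_, length(avail)); pvals <- rep(NA_real_, length(avail))
      for (i in seq_along(avail)) {
        f <- tryCatch(fit_state(c(included, avail[i])), error = function(e) NULL)
        if (is.null(f)) next
        gains[i] <- f$c_index - cur_C
        pvals[i] <- f$coefficients$p[f$coefficients$term == avail[i]]
      }
      ok <- !is.na(gains) & gains > tol_C & pvals < p_in
      if (any(ok)) {
        i <- which(ok)[which.max(gains[ok])]
        newC <- cur_C + gains[i]
        trace <- rbind(trace, data.frame(action = "add", variable = avail[i],
                                         C_before = cur_C, C_after = newC,
                                         p = pvals[i], stringsAsFactors = FALSE))
        included <- c(included, avail[i])
        cur_C <- newC
        acted <- TRUE
      }
    }
    ## backward
    if (length(included) > 0) {
      f_full <- fit_state(included)
      repeat {
        ps <- f_full$coefficients[f_full$coefficients$term %in% included, ]
        weak <- ps$term[ps$p > p_out]
        if (length(weak) == 0) break
        dropped <- FALSE
        for (v in weak[order(-ps$p[match(weak, ps$term)])]) {
          rest <- setdiff(included, v)
          newC <- state_c(rest)
          if (cur_C - newC <= tol_C) {
            trace <- rbind(trace, data.frame(action = "remove", variable = v,
                                             C_before = cur_C, C_after = newC,
                                             p = ps$p[ps$term == v],
                                             stringsAsFactors = FALSE))
            included <- rest
            cur_C <- newC
            f_full <- fit_state(included)
            acted <- TRUE
            dropped <- TRUE
            break
          }
        }
        if (!dropped || length(included) == 0) break
      }
    }
    key <- paste(sort(included), collapse = ",")
    if (acted && key %in% seen) {
      warning("stepwise selection cycled; stopping")
      break
    }
    seen <- c(seen, key)
    if (!acted) break
  }
  final_fit <- if (length(included) > 0 || !is.null(base_covariates))
    fit_state(included) else NULL
  structure(list(trace = trace, selected = included, final_fit = final_fit,
                 base_C = base_C),
            class = "stepwise_trace")
}
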