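## Elastic-net fitting by cyclic coordinate descent (compiled core in
## src/enet.cpp). Predictors are standardized internally with population
## (1/n) variances; coefficients are returned on the original scale.

enet_standardize <- function(X, y) {
  n <- nrow(X)
  xm <- colMeans(X)
  xs <- sqrt(colMeans(X^2) - xm^2)
  if (any(xs == 0)) stop("constant column(s) in predictor matrix")
  Xs <- sweep(sweep(X, 2, xm, "-"), 2, xs, "/")
  ym <- mean(y)
  list(Xs = Xs, yc = y - ym, xm = xm, xs = xs, ym = ym, n = n)
}

#' Smallest penalty with an all-zero elastic-net solution
#'
#' `lambda_max = max_j |(1/n) x_j' y_c| / alpha` on standardized predictors.
#'
#' @param X predictor matrix, `y` response, `alpha` mixing parameter.
#' @export
enet_lambda_max <- function(X, y, alpha = 0.5) {
  s <- enet_standardize(X, y)
  max(abs(as.vector(crossprod(s$Xs, s$yc))) / s$n) / max(alpha, 1e-3)
}

#' Default decreasing log-spaced lambda grid
#'
#' @param lambda_max largest grid value; the grid descends to
#'   `lambda_max * eps`.
#' @param n_lambda grid length (default 100).
#' @param eps ratio of smallest to largest value (default 1e-4).
#' @export
enet_lambda_grid <- function(lambda_max, n_lambda = 100, eps = 1e-4) {
  exp(seq(log(lambda_max), log(lambda_max * eps), length.out = n_lambda))
}

#' Fit the elastic net at one or more penalty values
#'
#' Minimizes `(1/2n) sum (y - b0 - X b)^2 + lambda * (alpha ||b||_1 +
#' (1 - alpha)/2 ||b||_2^2)` by cyclic coordinate descent to tolerance
#' `tol` (default 1e-7 on the maximum standardized-coefficient update), with
#' warm starts along a decreasing lambda path. At `lambda >= lambda_max` all
#' weights are zero and the intercept equals `mean(y)`; at `lambda = 0` with
#' `n > p` the solution converges to OLS.
#'
#' @param X predictor matrix (no constant columns), `y` numeric response.
#' @param alpha mixing parameter in `[0, 1]` (default 0.5).
#' @param lambda single penalty or decreasing vector of penalties.
#' @param tol,max_iter convergence controls.
#' @return for a single lambda, a list `intercept`, `weights` (original
#'   scale), `weights_std`, `lambda`, `alpha`; for a path, a list with
#'   `intercepts`, `weights` (p x L matrix), `weights_std`, `lambda`.
#' @export
fit_elastic_net <- function(X, y, alpha = 0.5, lambda, tol = 1e-7,
                            max_iter = 100000L) {
  if (!all(is.finite(X)) || !all(is.finite(y))) stop("non-finite inputs")
  stopifnot(alpha >= 0, alpha <= 1, all(lambda >= 0))
  s <- enet_standardize(X, y)
  B <- enet_cd_path(s$Xs, s$yc, alpha, as.numeric(lambda), tol,
                    as.integer(max_iter))
  Borig <- B / s$xs
  b0 <- s$ym - as.vector(crossprod(Borig, s$xm))
  rownames(B) <- rownames(Borig) <- colnames(X)
  if (length(lambda) == 1) {
    w <- Borig[, 1]
    list(intercept = b0[1], weights = w, weights_std = B[, 1],
         lambda = lambda, alpha = alpha)
  } else {
    list(intercepts = b0, weights = Borig, weights_std = B, lambda = lambda,
         alpha = alpha)
  }
}

#' Karush-Kuhn-Tucker residuals of an elastic-net solution
#'
#' On standardized predictors with centred response, stationarity requires
#' `(1/n) x_j' r = lambda * alpha * sign(b_j) + lambda * (1 - alpha) * b_j`
#' for active coefficients and `|(1/n) x_j' r| <= lambda * alpha` for zero
#' ones. Returns the worst violation over all coordinates (0 for an exact
#' solution).
#'
#' @param X,y original-scale data used in the fit.
#' @param fit single-lambda result of [fit_elastic_net()].
#' @export
enet_kkt_residual <- function(X, y, fit) {
  s <- enet_standardize(X, y)
  b <- fit$weights_std
  r <- s$yc - as.vector(s$Xs %*% b)
  g <- as.vector(crossprod(s$Xs, r)) / s$n
  lam <- fit$lambda; al <- fit$alpha
  active <- b != 0
  v_active <- if (any(active))
    max(abs(abs(g[active] - lam * (1 - al) * b[active]) - lam * al)) else 0
  v_zero <- if (any(!active)) max(0, max(abs(g[!active])) - lam * al) else 0
  max(v_active, v_zero)
}
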