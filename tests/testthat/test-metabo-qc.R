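make_qc_matrix <- function(n = 60, p = 6, seed = 2) {
  set.seed(seed)
  x <- matrix(exp(rnorm(n * p, 0, 0.3)), n, p,
              dimnames = list(sprintf("s%03d", seq_len(n)),
                              sprintf("f%02d", seq_len(p))))
  x
}

test_that("per-cohort missingness rule drops features strictly above threshold", {
  x <- make_qc_matrix()
  lab <- rep(c("A", "B"), each = 30)
  ## feature 1: 80% missing in cohort B only
  x[31:54, 1] <- NA
  out <- drop_high_missingness_features(x, lab, 0.3)
  expect_false("f01" %in% colnames(out$matrix))
  expect_true(all(paste0("f0", 2:6) %in% colnames(out$matrix)))

  ## fully observed: nothing dropped
  out2 <- drop_high_missingness_features(make_qc_matrix(), lab, 0.3)
  expect_equal(ncol(out2$matrix), 6)

  ## exactly at threshold: retained (strict inequality)
  x3 <- make_qc_matrix()
  x3[31:39, 2] <- NA  # 9/30 = 0.3 exactly
  out3 <- drop_high_missingness_features(x3, lab, 0.3)
  expect_true("f02" %in% colnames(out3$matrix))

  expect_error(drop_high_missingness_features(x[0, , drop = FALSE][, 0], lab),
               "empty")
})

test_that("outlier flags match the robust-z definition and degenerate features are safe", {
  x <- make_qc_matrix(n = 100)
  x[7, 3] <- exp(10)           # ~30 robust SD on the log scale
  x[, 6] <- 2                   # constant feature
  flags <- flag_outliers(x, 5)
  expect_true(flags[7, 3])
  expect_equal(sum(flags[, 6]), 0)

  ## brute-force recomputation
  lx <- log(x)
  brute <- matrix(FALSE, nrow(x), ncol(x))
  for (j in seq_len(ncol(x))) {
    m <- median(lx[, j]); s <- mad(lx[, j])
    if (s > 0) brute[, j] <- abs(lx[, j] - m) / s > 5
  }
  expect_equal(unname(flags), brute)
})

test_that("samples are removed only when carrying more than the allowed outliers", {
  flags <- matrix(FALSE, 4, 5, dimnames = list(paste0("s", 1:4), NULL))
  flags[1, c(1, 2)] <- TRUE   # 2 flags -> removed
  flags[2, 3] <- TRUE         # 1 flag  -> retained
  expect_equal(remove_outlier_samples(flags, 1), "s1")
  expect_equal(remove_outlier_samples(matrix(FALSE, 3, 3,
                                             dimnames = list(paste0("s", 1:3), NULL))),
               character(0))
})

test_that("NIPALS imputation recovers structure and touches only missing cells", {
  ## complete matrix passes through unchanged
  x <- make_qc_matrix()
  out <- nipals_impute(x)
  expect_equal(out, x, ignore_attr = TRUE)

  ## rank-1 deletion recovery
  set.seed(9)
  t_vec <- rnorm(40); w <- runif(8, 0.5, 2)
  r1 <- tcrossprod(t_vec, w)
  dimnames(r1) <- list(paste0("s", 1:40), paste0("f", 1:8))
  x1 <- r1
  x1[5, 3] <- NA
  imp <- nipals_impute(x1, ncomp = 1, tol = 1e-10)
  expect_lt(abs(imp[5, 3] - r1[5, 3]), 1e-4)
  imp[5, 3] <- r1[5, 3]
  expect_equal(imp, r1, ignore_attr = TRUE)

  ## 5-factor matrix: NIPALS beats column-mean fill
  set.seed(10)
  n <- 200; p <- 30
  S <- matrix(rnorm(n * 5), n, 5); L <- matrix(rnorm(5 * p), 5, p)
  xf <- S %*% L + matrix(rnorm(n * p, 0, 0.3), n, p)
  dimnames(xf) <- list(paste0("s", 1:n), paste0("f", 1:p))
  holdout <- sample(length(xf), round(0.002 * length(xf)) + 10)
  xm <- xf; xm[holdout] <- NA
  imp5 <- nipals_impute(xm, ncomp = 5)
  rmse_nipals <- sqrt(mean((imp5[holdout] - xf[holdout])^2))
  colmean <- xm
  for (j in seq_len(p)) colmean[is.na(colmean[, j]), j] <- mean(xm[, j], na.rm = TRUE)
  rmse_mean <- sqrt(mean((colmean[holdout] - xf[holdout])^2))
  expect_lt(rmse_nipals, rmse_mean)

  ## degenerate inputs
  bad <- make_qc_matrix(); bad[, 2] <- NA
  expect_error(nipals_impute(bad), "all-missing column")
  bad2 <- make_qc_matrix(); bad2[3, ] <- NA
  expect_error(nipals_impute(bad2), "all-missing row")
})

test_that("NIPALS agrees with an established missing-aware PCA imputation", {
  set.seed(12)
  n <- 80; p <- 12
  S <- matrix(rnorm(n * 3), n, 3); L <- matrix(rnorm(3 * p), 3, p)
  x <- S %*% L + matrix(rnorm(n * p, 0, 0.2), n, p)
  dimnames(x) <- list(paste0("s", 1:n), paste0("f", 1:p))
  xm <- x; holdout <- sample(length(x), 25); xm[holdout] <- NA
  mine <- nipals_impute(xm, ncomp = 3, tol = 1e-9)
  ref <- suppressWarnings(mixOmics::impute.nipals(xm, ncomp = 3))
  expect_lt(sqrt(mean((mine[holdout] - ref[holdout])^2)),
            0.5 * sd(x))
})

test_that("log standardization matches the closed form and rejects bad cells", {
  x <- matrix(c(1, exp(1), exp(2)), 3, 1,
              dimnames = list(paste0("s", 1:3), "f1"))
  z <- log_standardize(x)
  expect_equal(as.vector(z), c(-1, 0, 1), tolerance = 1e-12)

  y <- make_qc_matrix()
  zs <- log_standardize(y)
  expect_true(all(abs(colMeans(zs)) < 1e-10))
  expect_true(all(abs(apply(zs, 2, sd) - 1) < 1e-10))

  y[4, 2] <- 0
  expect_error(log_standardize(y), "s004.*f02")
})

test_that("the QC chain is idempotent and reports imputation counts", {
  sim <- calibration_fixture(seed = 13)
  x <- sim$data$metabolites
  lab <- sim$data$phenotypes$cohort
  res <- run_metabo_qc(x, lab, standardize = FALSE)
  expect_equal(res$report$n_imputed, sum(is.na(x)) )
  expect_false(anyNA(res$matrix))

  ## second pass: nothing left to drop, flag, remove or impute
  res2 <- run_metabo_qc(res$matrix, res$report$cohort_labels,
                        standardize = FALSE)
  expect_equal(length(res2$report$dropped_features), 0)
  expect_equal(length(res2$report$removed_samples), 0)
  expect_equal(res2$report$n_imputed, 0)
  expect_equal(res2$matrix, res$matrix, ignore_attr = TRUE)
})
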