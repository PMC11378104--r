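test_that("the EWAS matches the closed-form simple-regression t test", {
  set.seed(31)
  n <- 20
  X <- matrix(runif(n * 5, 0.2, 0.8), n, 5,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("cg%d", 1:5)))
  X[, 5] <- 0.4  # constant CpG
  y <- setNames(2 * X[, 1] + rnorm(n, 0, 0.5), rownames(X))
  tab <- run_ewas(y, X, rep("A", n), "A")

  expect_false("cg5" %in% tab$cpg)
  for (j in 1:4) {
    fit <- summary(lm(y ~ X[, j]))$coefficients
    row <- tab[tab$cpg == paste0("cg", j), ]
    expect_equal(row$slope, fit[2, 1], tolerance = 1e-10)
    expect_equal(row$se, fit[2, 2], tolerance = 1e-10)
    expect_equal(row$p, fit[2, 4], tolerance = 1e-10)
  }

  ## target identical to a CpG: essentially zero p, positive slope
  y2 <- setNames(X[, 2], rownames(X))
  tab2 <- run_ewas(y2, X, rep("A", n), "A")
  expect_lt(tab2$p[tab2$cpg == "cg2"], 1e-200)
  expect_gt(tab2$slope[tab2$cpg == "cg2"], 0)

  expect_error(run_ewas(y[1:2], X[1:2, ], rep("A", 2), "A"), "3 samples")
})

test_that("pre-selection requires consistent sign and dual nominal significance", {
  mk <- function(cpg, slope, p) {
    structure(data.frame(cpg = cpg, slope = slope, se = 1, t = slope, p = p,
                         n = 100, stringsAsFactors = FALSE),
              class = c("ewas_table", "data.frame"))
  }
  a <- mk(c("c1", "c2", "c3"), c(1, 1, 1), c(0.01, 0.04, 0.06))
  b <- mk(c("c1", "c2", "c3"), c(-1, 1, 1), c(0.01, 0.03, 0.01))
  sel <- preselect_cpgs(a, b, 0.05)
  expect_equal(sel, "c2")  # c1 sign-discordant, c3 above threshold in a

  expect_error(preselect_cpgs(a, mk("zz", 1, 0.01)), "disjoint")
})

test_that("elastic net satisfies its optimality conditions and limiting cases", {
  set.seed(33)
  X <- matrix(rnorm(50 * 5), 50, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- as.vector(X %*% c(1, -2, 0, 0.5, 3) + rnorm(50))

  ## lambda = 0, n > p: OLS
  f0 <- fit_elastic_net(X, y, alpha = 0.5, lambda = 0)
  ols <- coef(lm(y ~ X))
  expect_lt(max(abs(c(f0$intercept, f0$weights) - ols)), 1e-6)

  ## lambda >= lambda_max: exact null model
  lmax <- enet_lambda_max(X, y, 0.5)
  fn <- fit_elastic_net(X, y, 0.5, lmax * 1.0001)
  expect_true(all(fn$weights == 0))
  expect_equal(fn$intercept, mean(y))

  ## KKT residuals along the whole grid
  grid <- enet_lambda_grid(lmax, 30)
  kkt <- vapply(grid, function(l)
    enet_kkt_residual(X, y, fit_elastic_net(X, y, 0.5, l)), numeric(1))
  expect_lt(max(kkt), 1e-6)

  ## support size is non-increasing in lambda along the path
  path <- fit_elastic_net(X, y, 0.5, grid)
  nnz <- colSums(abs(path$weights) > 1e-8)
  expect_true(all(diff(nnz) >= 0))  # grid descends, support grows

  expect_error(fit_elastic_net(cbind(X, x6 = c(NA, rep(1, 49))), y, 0.5, 0.1),
               "non-finite")
})

test_that("the lasso special case agrees with an independent solver", {
  set.seed(34)
  X <- matrix(rnorm(80 * 10), 80, 10)
  y <- as.vector(X[, 1] - 2 * X[, 2] + rnorm(80))
  lam <- c(0.8, 0.4, 0.2, 0.1)
  g <- glmnet::glmnet(X, y, alpha = 1, lambda = lam, thresh = 1e-14)
  mine <- fit_elastic_net(X, y, 1, lam)
  expect_lt(max(abs(as.matrix(g$beta) - mine$weights)), 1e-6)
  expect_lt(max(abs(g$a0 - mine$intercepts)), 1e-6)
})

test_that("prediction metrics follow their definitions", {
  obs <- c(0.3, -1.2, 2.2, 0.1, -0.4)
  pred <- c(0.5, -1.0, 1.8, 0.3, -0.2)
  ev <- evaluate_predictions(pred, obs)
  expect_equal(ev$R, cor(pred, obs), tolerance = 1e-12)
  expect_equal(ev$RMSE, sqrt(mean((pred - obs)^2)), tolerance = 1e-12)

  ev1 <- evaluate_predictions(obs, obs)
  expect_equal(ev1$R, 1)
  expect_equal(ev1$RMSE, 0)
  centred <- obs - mean(obs)
  expect_equal(evaluate_predictions(-centred, centred)$R, -1)

  ev2 <- evaluate_predictions(rep(1, 5), obs)
  expect_true(is.na(ev2$R))
  expect_false(is.na(ev2$RMSE))
})

test_that("accuracy tiers honour the band boundaries", {
  expect_equal(assign_tier(0.40), "accurate")
  expect_equal(assign_tier(0.30), "mild")
  expect_equal(assign_tier(0.35), "mild")   # boundary falls in lower tier
  expect_equal(assign_tier(0.20), "low")
  expect_equal(assign_tier(NA_real_), "undefined")
})

test_that("nested CV is leakage-free and reproducible", {
  cfg <- strong_signal_config(seed = 41, n_per_cohort = 150, n_cpgs = 600,
                              causal_k = 50)
  sim <- simulate_dataset(cfg)
  y <- log_standardize(sim$data$metabolites)[, 1]
  names(y) <- rownames(sim$data$metabolites)
  tc <- training_config(n_lambda = 40, seed = 5)
  res <- nested_cv_train(y, sim$data$betas, sim$data$phenotypes$cohort, tc)

  ## outer-test samples never enter their fold's EWAS or lambda tuning
  for (f in res$audit) {
    expect_length(intersect(f$test_ids, f$ewas_ids), 0)
    expect_length(intersect(f$test_ids, f$tuning_ids), 0)
  }
  all_test <- unlist(lapply(res$audit, `[[`, "test_ids"))
  expect_setequal(all_test, rownames(sim$data$betas))
  expect_false(any(duplicated(all_test)))

  ## identical config and seed reproduce lambda and weights exactly
  res2 <- nested_cv_train(y, sim$data$betas, sim$data$phenotypes$cohort, tc)
  expect_identical(res$model$lambda, res2$model$lambda)
  expect_identical(res$model$weights, res2$model$weights)

  expect_error(nested_cv_train(y, sim$data$betas,
                               rep("A", nrow(sim$data$betas)), tc),
               "two training cohorts")
})
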