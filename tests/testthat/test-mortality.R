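test_that("Cox estimates maximize the written-out partial likelihood", {
  x <- c(1, 0, 1, 0, 1, 0, 1, 0)
  tm <- c(1.1, 2.3, 3.2, 4.5, 5.1, 6.7, 7.2, 8.9)
  ev <- c(1, 1, 0, 1, 1, 0, 1, 1)
  surv <- data.frame(time = tm, event = ev)
  f <- fit_cox(matrix(x, dimnames = list(NULL, "x")), surv)

  pl <- function(b) {
    s <- 0
    for (i in which(ev == 1)) {
      rs <- which(tm >= tm[i])
      s <- s + b * x[i] - log(sum(exp(b * x[rs])))
    }
    s
  }
  brute <- stats::optimize(pl, c(-5, 5), maximum = TRUE, tol = 1e-10)$maximum
  expect_lt(abs(f$coefficients$beta - brute), 1e-6)
  expect_equal(f$coefficients$hr, exp(f$coefficients$beta))
  expect_true(f$coefficients$hr_lo < f$coefficients$hr &
                f$coefficients$hr < f$coefficients$hr_hi)

  expect_error(fit_cox(matrix(1, 8, 1, dimnames = list(NULL, "c")), surv),
               "constant")
  expect_error(fit_cox(matrix(x, dimnames = list(NULL, "x")),
                       data.frame(time = tm, event = rep(0, 8))), "event")
})

test_that("concordance equals the exhaustive pairwise enumeration", {
  ## perfectly rank-ordered risks, no censoring
  tm <- c(5, 4, 3, 2, 1)
  sc <- 1:5
  ci <- concordance_index(sc, data.frame(time = tm, event = rep(1, 5)))
  expect_equal(ci$C, 1)

  ## censored fixture with ties in times and scores
  set.seed(61)
  tm2 <- c(1, 2, 2, 3, 4, 4)
  ev2 <- c(1, 1, 0, 0, 1, 1)
  sc2 <- c(3, 2, 2, 1, 2, 0)
  ci2 <- concordance_index(sc2, data.frame(time = tm2, event = ev2))
  expect_equal(ci2$C, harrell_c_oracle(sc2, tm2, ev2))

  ## random fixtures against the oracle and the survival package
  for (s in 1:3) {
    set.seed(s)
    n <- 40
    tmr <- rexp(n); evr <- rbinom(n, 1, 0.6); scr <- rnorm(n)
    ci3 <- concordance_index(scr, data.frame(time = tmr, event = evr))
    expect_equal(ci3$C, harrell_c_oracle(scr, tmr, evr))
    ref <- survival::concordance(survival::Surv(tmr, evr) ~ scr,
                                 reverse = TRUE)$concordance
    expect_equal(ci3$C, unname(ref))
  }
})

test_that("the univariate scan adjusts p across features and survives failures", {
  set.seed(62)
  n <- 400
  Z <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("s", 1:5)))
  surv <- make_survival(Z, c(0.8, 0, 0, 0, 0), 1.3, 30, 0.3, seed = 63)
  covs <- cbind(age = rnorm(n, 50, 10), sex = rbinom(n, 1, 0.5))
  scan <- univariate_scan(Z, covs, surv)
  expect_equal(nrow(scan), 5)
  expect_true(all(scan$p_adj >= scan$p, na.rm = TRUE))
  expect_true(all(scan$p_adj <= 1, na.rm = TRUE))
  expect_true(scan$significant[scan$score == "s1"])
  ## BH preserves the p-value ordering
  ok <- !is.na(scan$p)
  expect_equal(order(scan$p[ok]), order(scan$p_adj[ok], scan$p[ok]))

  ## a score duplicating a covariate is reported as a failure, not fatal
  Z2 <- cbind(Z, dup_age = covs[, "age"])
  scan2 <- univariate_scan(Z2, covs, surv)
  expect_equal(nrow(scan2), 6)
})

test_that("concordance comparison is a paired test with exact conventions", {
  set.seed(64)
  n <- 300
  x <- rnorm(n)
  surv <- make_survival(matrix(x), 0.8, 1.3, 30, 0.3, seed = 65)
  cmp_self <- compare_concordance(x, x, surv)
  expect_equal(cmp_self$delta_C, 0)
  expect_equal(cmp_self$p, 1)

  noise <- rnorm(n)
  cmp <- compare_concordance(x, noise, surv)
  expect_equal(cmp$delta_C > 0, cmp$C_a > cmp$C_b)
  expect_lt(cmp$p, 0.05)  # informative vs pure-noise score
})

test_that("stepwise selection acts only on qualifying candidates and replays", {
  set.seed(66)
  n <- 500
  Z <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("s", 1:6)))
  surv <- make_survival(Z, c(0.7, rep(0, 5)), 1.3, 30, 0.4, seed = 67)
  sw <- stepwise_select(Z, NULL, surv)
  expect_true("s1" %in% sw$selected)
  expect_true(all(sw$trace$action[1] == "add"))
  ## each retained add improves C by more than the tolerance
  adds <- sw$trace[sw$trace$action == "add", ]
  expect_true(all(adds$C_after - adds$C_before > 0.001))

  ## pure noise candidates: base model returned, empty trace
  Znull <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("z", 1:4)))
  survnull <- make_survival(matrix(rnorm(n)), 0.8, 1.3, 30, 0.4, seed = 68)
  base <- cbind(age = rnorm(n, 60, 8))
  sw0 <- stepwise_select(Znull, base, survnull, tol_C = 0.01)
  expect_equal(nrow(sw0$trace), 0)
  expect_length(sw0$selected, 0)

  ## determinism
  sw2 <- stepwise_select(Z, NULL, surv)
  expect_identical(sw$trace, sw2$trace)
  expect_identical(sw$selected, sw2$selected)
})

test_that("time-dependent AUC handles separation, censoring weights and edge cases", {
  ## perfect separator
  tm <- c(1, 2, 3, 10, 11, 12)
  ev <- c(1, 1, 1, 0, 0, 0)
  sc <- c(9, 8, 7, 1, 2, 3)
  expect_equal(td_auc(sc, data.frame(time = tm, event = ev), 5), 1)

  ## zero censoring reduces to the plain binary AUC
  set.seed(71)
  n <- 300
  scn <- rnorm(n)
  tmn <- rexp(n, exp(0.8 * scn))
  surv <- data.frame(time = tmn, event = rep(1, n))
  a <- td_auc(scn, surv, 1)
  lab <- as.integer(tmn <= 1)
  cases <- scn[lab == 1]; ctrls <- scn[lab == 0]
  cmp <- outer(cases, ctrls, function(u, v) (u > v) + 0.5 * (u == v))
  expect_equal(a, mean(cmp), tolerance = 1e-12)

  expect_error(td_auc(sc, data.frame(time = tm, event = ev), 100),
               "horizon")
})

test_that("the Schoenfeld test flags time-varying effects and guards edge cases", {
  set.seed(72)
  n <- 1000
  x <- rnorm(n)
  ## hazard with a sign-flipping effect: beta = +0.8 before t0, -0.8 after
  h0 <- 0.1; t0 <- 2
  E <- rexp(n)
  h1 <- h0 * exp(0.8 * x); h2 <- h0 * exp(-0.8 * x)
  tme <- ifelse(E < h1 * t0, E / h1, t0 + (E - h1 * t0) / h2)
  surv <- data.frame(time = tme, event = rep(1L, n))
  f <- fit_cox(matrix(x, dimnames = list(NULL, "x")), surv)
  expect_lt(schoenfeld_test(f)$p, 0.05)

  one_ev <- data.frame(time = c(1, 2, 3), event = c(1, 0, 0))
  f1 <- fit_cox(matrix(c(1, 0, 2), dimnames = list(NULL, "x")), one_ev)
  expect_error(schoenfeld_test(f1), "2 events")
})
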