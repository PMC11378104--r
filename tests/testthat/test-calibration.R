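toy_pheno <- function(ids, age, sex, bmi, cohort = "X") {
  data.frame(sample_id = ids, cohort = cohort, age = age, sex = sex,
             bmi = bmi, stringsAsFactors = FALSE)
}

test_that("matching self-pairs an identical cohort and picks nearest neighbours", {
  set.seed(4)
  ref <- toy_pheno(sprintf("r%02d", 1:40), rnorm(40, 50, 8),
                   rep(0:1, 20), rnorm(40, 25, 3))
  pairs <- match_samples(ref, transform(ref, sample_id = sprintf("t%02d", 1:40)))
  expect_true(all(pairs$distance == 0))
  expect_equal(sub("t", "r", pairs$target_id), pairs$ref_id)

  ## 41-year-old male matches the 40-year-old, not the 60-year-old
  ref2 <- toy_pheno(c("r1", "r2", "f1", "f2"), c(40, 60, 45, 50),
                    c(1, 1, 0, 0), c(25, 25, 25, 25))
  tgt2 <- toy_pheno(c("t1", "f3"), c(41, 46), c(1, 0), c(25, 25))
  p2 <- match_samples(ref2, tgt2, caliper = 3)
  expect_equal(p2$ref_id[p2$target_id == "t1"], "r1")
})

test_that("pair counts are balanced across sexes by dropping worst excess pairs", {
  set.seed(6)
  ref <- toy_pheno(sprintf("r%02d", 1:34), rnorm(34, 50, 5),
                   rep(c(1, 0), c(20, 14)), rnorm(34, 25, 2))
  tgt <- toy_pheno(sprintf("t%02d", 1:17), rnorm(17, 50, 5),
                   rep(c(1, 0), c(10, 7)), rnorm(17, 25, 2))
  pairs <- match_samples(ref, tgt, caliper = 10)
  expect_equal(sum(pairs$sex == 1), 7)
  expect_equal(sum(pairs$sex == 0), 7)
  expect_false(any(duplicated(pairs$target_id)))
  expect_false(any(duplicated(pairs$ref_id)))
  expect_error(match_samples(ref, tgt[tgt$sex == 1, ]), "sex stratum")
})

test_that("calibration maps are exact affine transforms", {
  set.seed(7)
  x <- matrix(exp(rnorm(200, 0, 0.3)), 100, 2,
              dimnames = list(c(sprintf("a%02d", 1:50), sprintf("b%02d", 1:50)),
                              c("f1", "f2")))
  lab <- rep(c("A", "B"), each = 50)
  pairs <- data.frame(ref_id = sprintf("a%02d", 1:30),
                      target_id = sprintf("b%02d", 1:30),
                      sex = rep(0:1, 15), distance = 0)
  map <- fit_calibration(x, list(B = pairs), "A")

  ## reference cohort entry is the identity
  expect_equal(map$maps$A$mu_target, rep(0, 2))
  expect_equal(map$maps$A$sd_ref, rep(1, 2))

  cal <- apply_calibration(x, map, lab)
  expect_equal(cal[lab == "A", ], x[lab == "A", ])
  ## post-calibration matched-subset moments equal reference moments exactly
  xt <- cal[pairs$target_id, ]; xr <- cal[pairs$ref_id, ]
  expect_lt(max(abs(colMeans(xt) - colMeans(xr))), 1e-10)
  expect_lt(max(abs(apply(xt, 2, sd) - apply(xr, 2, sd))), 1e-10)

  ## hand-computed affine example
  m <- map
  m$maps$B <- data.frame(feature = c("f1", "f2"), mu_target = 1, sd_target = 1,
                         mu_ref = 10, sd_ref = 2, stringsAsFactors = FALSE)
  toy <- matrix(c(0, 1, 2), 3, 1, dimnames = list(paste0("s", 1:3), "f1"))
  toy <- cbind(toy, f2 = c(0, 1, 2))
  out <- apply_calibration(toy, m, rep("B", 3))
  expect_equal(as.vector(out[, "f1"]), c(8, 10, 12))

  ## degenerate matched subset
  xz <- x; xz[pairs$target_id, "f1"] <- 1
  expect_error(fit_calibration(xz, list(B = pairs), "A"), "f1.*B")
  expect_error(apply_calibration(x, map, rep("Z", 100)), "Z")
})

test_that("injected batch shifts are recovered from matched subsets", {
  sim <- calibration_fixture(seed = 17)
  qc <- run_metabo_qc(sim$data$metabolites, sim$data$phenotypes$cohort,
                      standardize = FALSE)
  ph <- sim$data$phenotypes[rownames(qc$matrix), ]
  ms <- lapply(c("B", "C"), function(co)
    match_samples(ph[ph$cohort == "A", ], ph[ph$cohort == co, ]))
  names(ms) <- c("B", "C")
  expect_gte(nrow(ms$B), 140)
  map <- fit_calibration(qc$matrix, ms, "A")
  mB <- map$maps$B
  expect_lt(abs(mean(mB$mu_target - mB$mu_ref) - 0.5), 0.05)
  expect_lt(abs(mean(mB$sd_target / mB$sd_ref) - 1.3), 0.1)
  mC <- map$maps$C
  expect_lt(abs(mean(mC$mu_target - mC$mu_ref) - (-0.3)), 0.05)
  expect_lt(abs(mean(mC$sd_target / mC$sd_ref) - 0.8), 0.1)
})

test_that("batch mixing test separates mixed from shifted cohorts", {
  set.seed(19)
  n <- 1000
  x_null <- matrix(rnorm(n * 5), n, 5)
  lab <- rep(c("A", "B"), each = n / 2)
  r_null <- batch_mixing_test(x_null, lab, k = 50, n_draws = 200, seed = 2)
  expect_lte(r_null$rejection_rate, 0.15)

  x_sep <- x_null
  x_sep[lab == "B", ] <- x_sep[lab == "B", ] + 5
  r_sep <- batch_mixing_test(x_sep, lab, k = 50, n_draws = 200, seed = 2)
  expect_gte(r_sep$rejection_rate, 0.9)

  expect_warning(r1 <- batch_mixing_test(x_null, rep("A", n), k = 50),
                 "single cohort")
  expect_equal(r1$rejection_rate, 0)
})

test_that("variance decomposition attributes structure to the right factors", {
  set.seed(23)
  n <- 600
  lab <- rep(c("A", "B", "C"), each = n / 3)
  shift <- c(A = 0, B = 3, C = -3)[lab]
  x <- matrix(rnorm(n * 6, 0, 0.5), n, 6) + shift
  fac <- data.frame(cohort = lab, age = rnorm(n), sex = rbinom(n, 1, 0.5))
  vc <- variance_components(x, fac)
  expect_gte(vc$fractions["cohort"], 0.8)
  expect_equal(sum(vc$fractions), 1, tolerance = 1e-6)

  ## pure noise with random factors: residual dominates
  x0 <- matrix(rnorm(1000 * 6), 1000, 6)
  fac0 <- data.frame(cohort = sample(c("A", "B"), 1000, TRUE),
                     age = rnorm(1000))
  vc0 <- variance_components(x0, fac0)
  expect_gte(vc0$fractions["residual"], 0.8)

  ## single-level factor contributes exactly 0 with a warning
  expect_warning(vc1 <- variance_components(x0, data.frame(batch = rep("Z", 1000),
                                                           age = rnorm(1000))),
                 "constant")
  expect_equal(unname(vc1$fractions["batch"]), 0)
})
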