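## Shared fixture builders. All fixtures are generated in code at test time;
## sizes are kept small enough for a single-CPU run while preserving the
## study-like structure (multiple cohorts, batch shifts, sparse CpG signal).

three_cohort_spec <- function() {
  data.frame(name = c("A", "B", "C"),
             n = c(400, 400, 300),
             age_mean = c(45, 49, 52), age_sd = c(10, 10, 10),
             bmi_mean = c(25, 25.8, 26.4), bmi_sd = c(3.5, 3.5, 3.5),
             male_fraction = c(0.5, 0.5, 0.45))
}

## 3 cohorts with the reference untouched and known injected shifts:
## B: +0.5 mean, x1.3 SD; C: -0.3 mean, x0.8 SD.
calibration_fixture <- function(seed = 7) {
  cfg <- simulation_config(
    three_cohort_spec(),
    n_metabolites = 16, n_cpgs = 800, causal_cpgs_per_metabolite = 20,
    cpg_effect_sd = 0.03, n_age_cpgs = 50, n_sex_cpgs = 50,
    noise_sd = list(metabolite = 0.5, cpg = 0.3),
    hazard_coefs = c(0.5, rep(0, 15)),
    batch_shift = list(B = list(delta = 0.5, factor = 1.3),
                       C = list(delta = -0.3, factor = 0.8)),
    seed = seed)
  simulate_dataset(cfg)
}

## 2 training cohorts, strong CpG signal tuned for generating R2 ~ 0.5
## (200 causal CpGs, per-CpG weight sd = eps_sd / sqrt(200)).
strong_signal_config <- function(seed = 11, n_per_cohort = 750,
                                 n_cpgs = 4000, causal_k = 200) {
  simulation_config(
    data.frame(name = c("A", "B"), n = c(n_per_cohort, n_per_cohort),
               age_mean = c(45, 50), age_sd = c(10, 10),
               bmi_mean = c(25, 26), bmi_sd = c(3.5, 3.5),
               male_fraction = c(0.5, 0.5)),
    n_metabolites = 4, n_cpgs = n_cpgs,
    causal_cpgs_per_metabolite = causal_k,
    cpg_effect_sd = 0.3 / sqrt(causal_k),
    n_age_cpgs = 50, n_sex_cpgs = 50,
    noise_sd = list(metabolite = 0.3, cpg = 0.3),
    missing_rate = 0, seed = seed)
}

## Weibull PH survival with a single informative score, for mortality tests.
single_driver_survival <- function(n, beta = 0.5, censor = 0.3, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n), dimnames = list(NULL, "x"))
  surv <- make_survival(x, beta, 1.3, 30, censor, seed = seed + 1)
  list(x = x, surv = surv)
}

## Exhaustive pairwise Harrell C oracle following the usable-pair rules:
## the earlier observed time must be an event; equal times with both events
## are unusable; equal times with exactly one event treat the event subject
## as the earlier one; tied scores count one half.
harrell_c_oracle <- function(scores, time, event) {
  num <- 0; den <- 0
  n <- length(scores)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (time[i] < time[j]) { a <- i; b <- j }
    else if (time[j] < time[i]) { a <- j; b <- i }
    else if (event[i] + event[j] == 1) {
      a <- if (event[i] == 1) i else j; b <- setdiff(c(i, j), a)
    } else next
    if (event[a] != 1) next
    den <- den + 1
    num <- num + if (scores[a] > scores[b]) 1
      else if (scores[a] == scores[b]) 0.5 else 0
  }
  num / den
}

## Two-sided Fisher p by exhaustive hypergeometric enumeration over all
## tables with the same margins (tables at most as probable as the observed
## one, with a small tolerance as in fisher.test).
fisher_p_oracle <- function(a, b, c, d) {
  m <- a + b; n_ <- c + d; k <- a + c
  lo <- max(0, k - n_); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n_, k)
  p_obs <- stats::dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
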