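#' Simulation configuration for multi-cohort omics data
#'
#' Assembles and validates the parameters of the synthetic multi-cohort
#' generator. The generator emulates the heterogeneity of population biobanks:
#' cohorts differ in age, BMI and sex composition; metabolite concentrations
#' are positive and log-normal-like with age/sex/BMI effects; a sparse set of
#' CpGs encodes each metabolite on the logit-beta scale; survival follows a
#' Weibull-baseline proportional-hazards model driven by a subset of
#' metabolites.
#'
#' @param cohort_specs data.frame with columns `name`, `n`, `age_mean`,
#'   `age_sd`, `bmi_mean`, `bmi_sd`, `male_fraction`. One row per cohort.
#' @param n_metabolites number of metabolic features.
#' @param n_cpgs size of the CpG universe.
#' @param causal_cpgs_per_metabolite number of CpGs with nonzero generating
#'   weight per metabolite (causal sets are disjoint across metabolites).
#' @param cpg_effect_sd SD of the per-CpG weight on the z-scored metabolite,
#'   on the logit-beta scale.
#' @param metabolite_pheno_effects optional `n_metabolites x 3` matrix of
#'   (age, sex, BMI) coefficients on the log-concentration scale; drawn from
#'   the seed when `NULL`.
#' @param batch_shift optional named list (one entry per non-reference cohort)
#'   of lists with elements `delta` and `factor` (scalar or per-feature).
#' @param noise_sd list with elements `metabolite` (residual SD of
#'   log-concentration) and `cpg` (residual SD on the logit-beta scale).
#' @param hazard_coefs numeric vector of per-metabolite log hazard ratios per
#'   SD (length `n_metabolites`); zeros for non-driver metabolites.
#' @param weibull_shape,weibull_scale baseline Weibull hazard parameters
#'   (scale in years).
#' @param censor_rate target fraction of administratively censored samples.
#' @param missing_rate fraction of metabolite cells set missing at random.
#' @param n_age_cpgs,n_sex_cpgs number of non-causal CpGs carrying an age or
#'   sex signal.
#' @param age_effect_sd,sex_effect_sd SD of the age (per year) and sex effects
#'   on associated CpGs, logit scale.
#' @param seed integer RNG seed.
#'
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(cohort_specs,
                              n_metabolites = 16,
                              n_cpgs = 20000,
                              causal_cpgs_per_metabolite = 200,
                              cpg_effect_sd = 0.021,
                              metabolite_pheno_effects = NULL,
                              batch_shift = NULL,
                              noise_sd = list(metabolite = 0.3, cpg = 0.3),
                              hazard_coefs = NULL,
                              weibull_shape = 1.3,
                              weibull_scale = 40,
                              censor_rate = 0.7,
                              missing_rate = 0.002,
                              n_age_cpgs = 200,
                              n_sex_cpgs = 200,
                              age_effect_sd = 0.01,
                              sex_effect_sd = 0.2,
                              seed = 1L) {
  cfg <- list(cohort_specs = as.data.frame(cohort_specs),
              n_metabolites = as.integer(n_metabolites),
              n_cpgs = as.integer(n_cpgs),
              causal_cpgs_per_metabolite = as.integer(causal_cpgs_per_metabolite),
              cpg_effect_sd = cpg_effect_sd,
              metabolite_pheno_effects = metabolite_pheno_effects,
              batch_shift = batch_shift,
              noise_sd = noise_sd,
              hazard_coefs = hazard_coefs,
              weibull_shape = weibull_shape,
              weibull_scale = weibull_scale,
              censor_rate = censor_rate,
              missing_rate = missing_rate,
              n_age_cpgs = as.integer(n_age_cpgs),
              n_sex_cpgs = as.integer(n_sex_cpgs),
              age_effect_sd = age_effect_sd,
              sex_effect_sd = sex_effect_sd,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  spec <- cfg$cohort_specs
  need <- c("name", "n", "age_mean", "age_sd", "bmi_mean", "bmi_sd", "male_fraction")
  miss <- setdiff(need, names(spec))
  if (length(miss) > 0)
    stop("invalid config: cohort_specs missing column(s) ", paste(miss, collapse = ", "))
  if (nrow(spec) < 1 || any(spec$n <= 0))
    stop("invalid config: cohort_specs$n must be positive")
  if (any(spec$male_fraction < 0 | spec$male_fraction > 1))
    stop("invalid config: male_fraction must be in [0,1]")
  for (f in c("n_metabolites", "n_cpgs", "causal_cpgs_per_metabolite")) {
    if (cfg[[f]] <= 0) stop("invalid config: ", f, " must be > 0")
  }
  if (cfg$causal_cpgs_per_metabolite * cfg$n_metabolites +
      cfg$n_age_cpgs + cfg$n_sex_cpgs > cfg$n_cpgs)
    stop("invalid config: n_cpgs too small for causal + age/sex CpG sets")
  if (cfg$weibull_shape <= 0) stop("invalid config: weibull_shape must be > 0")
  if (cfg$weibull_scale <= 0) stop("invalid config: weibull_scale must be > 0")
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1)
    stop("invalid config: censor_rate must be in [0,1)")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("invalid config: missing_rate must be in [0,1)")
  if (!is.null(cfg$hazard_coefs) && length(cfg$hazard_coefs) != cfg$n_metabolites)
    stop("invalid config: hazard_coefs must have length n_metabolites")
  invisible(cfg)
}

#' Simulate a multi-cohort phenotype / metabolomics / methylation / survival
#' dataset with known ground truth
#'
#' Metabolite log-concentrations are linear in centred age, sex and centred
#' BMI plus Gaussian noise, then exponentiated, so concentrations are positive
#' and right-skewed and a downstream log transform recovers Gaussian
#' structure. Causal CpG beta values are `plogis(b0 + w * z_metab + eps)`
#' where `z_metab` is the pooled z-score of the log metabolite; age- and
#' sex-associated CpGs add `a * age` or `s * sex` terms; remaining CpGs are
#' pure noise. Batch effects from `config$batch_shift` are injected on the raw
#' concentration scale, after which `missing_rate` cells are set missing at
#' random. Survival is generated from the clean (pre-batch) z-scored log
#' metabolites via [make_survival()].
#'
#' The ground-truth sidecar reports, per metabolite, the causal CpG ids, the
#' drawn generating weights and the closed-form variance fraction of the
#' metabolite explainable from its causal CpGs on the (locally linear) logit
#' scale: `r2 = S / (1 + S)` with `S = sum(w^2) / sd_eps^2`.
#'
#' @param config a [simulation_config()].
#' @return list with elements `data` (class `multi_cohort_dataset`: tables
#'   `phenotypes`, `metabolites`, `betas`, `survival`, `cohort_labels`) and
#'   `truth` (class `ground_truth`: `causal_cpg_sets`, `causal_weights`,
#'   `true_batch_shifts`, `true_log_hrs`, `generating_r2`, `age_cpgs`,
#'   `sex_cpgs`, `clean_metabolites`).
#' @export
simulate_dataset <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed)
  spec <- config$cohort_specs
  K <- config$n_metabolites
  J <- config$n_cpgs

  ## phenotypes
  ph <- do.call(rbind, lapply(seq_len(nrow(spec)), function(i) {
    s <- spec[i, ]
    n <- s$n
    data.frame(sample_id = sprintf("%s_%05d", s$name, seq_len(n)),
               cohort = s$name,
               age = stats::rnorm(n, s$age_mean, s$age_sd),
               sex = stats::rbinom(n, 1, s$male_fraction),
               bmi = stats::rnorm(n, s$bmi_mean, s$bmi_sd),
               stringsAsFactors = FALSE)
  }))
  rownames(ph) <- ph$sample_id
  n <- nrow(ph)

  ## metabolite effect coefficients
  eff <- config$metabolite_pheno_effects
  if (is.null(eff)) {
    eff <- cbind(age = stats::rnorm(K, 0, 0.01),
                 sex = stats::rnorm(K, 0, 0.2),
                 bmi = stats::rnorm(K, 0, 0.02))
  }
  met_names <- sprintf("met_%02d", seq_len(K))
  age_c <- ph$age - 50
  bmi_c <- ph$bmi - 25
  lin <- cbind(age_c, ph$sex, bmi_c) %*% t(eff)
  logx <- sweep(lin, 2, stats::rnorm(K, 0, 0.2), "+") +
    matrix(stats::rnorm(n * K, 0, config$noise_sd$metabolite), n, K)
  clean <- exp(logx)
  dimnames(clean) <- list(ph$sample_id, met_names)
  z_met <- scale(logx)  # pooled z-scores drive CpGs and survival

  ## CpG universe: disjoint causal sets, then age/sex sets, rest noise
  cpg_names <- sprintf("cg%07d", seq_len(J))
  k <- config$causal_cpgs_per_metabolite
  causal_idx <- matrix(sample.int(J, K * k), nrow = k)  # column per metabolite
  remaining <- setdiff(seq_len(J), as.vector(causal_idx))
  age_idx <- remaining[seq_len(config$n_age_cpgs)]
  sex_idx <- remaining[config$n_age_cpgs + seq_len(config$n_sex_cpgs)]

  b0 <- stats::rnorm(J, 0, 1)
  eta <- matrix(stats::rnorm(n * J, 0, config$noise_sd$cpg), n, J)
  eta <- sweep(eta, 2, b0, "+")
  W <- matrix(stats::rnorm(K * k, 0, config$cpg_effect_sd), nrow = k)
  for (m in seq_len(K)) {
    eta[, causal_idx[, m]] <- eta[, causal_idx[, m]] +
      tcrossprod(z_met[, m], W[, m])
  }
  a_eff <- stats::rnorm(config$n_age_cpgs, 0, config$age_effect_sd)
  s_eff <- stats::rnorm(config$n_sex_cpgs, 0, config$sex_effect_sd)
  eta[, age_idx] <- eta[, age_idx] + tcrossprod(age_c, a_eff)
  eta[, sex_idx] <- eta[, sex_idx] + tcrossprod(ph$sex, s_eff)
  betas <- stats::plogis(eta)
  dimnames(betas) <- list(ph$sample_id, cpg_names)

  ## survival from clean z-scored metabolites
  hz <- config$hazard_coefs
  if (is.null(hz)) hz <- numeric(K)
  surv_seed <- config$seed + 104729L
  survival <- make_survival(z_met, hz, config$weibull_shape,
                            config$weibull_scale, config$censor_rate,
                            seed = surv_seed)
  survival$sample_id <- ph$sample_id
  survival <- survival[, c("sample_id", "time", "event")]

  ## batch effects on raw concentrations, then missingness
  metab <- clean
  true_shifts <- NULL
  if (!is.null(config$batch_shift)) {
    metab <- inject_batch_effects(metab, ph$cohort, config$batch_shift)
    true_shifts <- config$batch_shift
    ## a strong negative shift can push the low tail of a concentration
    ## below zero; apply the detection-limit floor
    metab <- floor_detection_limit(metab)
  }
  if (config$missing_rate > 0) {
    nmiss <- round(config$missing_rate * length(metab))
    if (nmiss > 0) metab[sample.int(length(metab), nmiss)] <- NA_real_
  }

  causal_sets <- lapply(seq_len(K), function(m) cpg_names[causal_idx[, m]])
  names(causal_sets) <- met_names
  weights <- lapply(seq_len(K), function(m) {
    w <- W[, m]; names(w) <- cpg_names[causal_idx[, m]]; w
  })
  names(weights) <- met_names
  s2 <- colSums(W^2) / config$noise_sd$cpg^2
  gen_r2 <- s2 / (1 + s2)
  names(gen_r2) <- met_names
  names(hz) <- met_names

  data <- structure(list(phenotypes = ph,
                         metabolites = metab,
                         betas = betas,
                         survival = survival,
                         cohort_labels = stats::setNames(ph$cohort, ph$sample_id)),
                    class = "multi_cohort_dataset")
  truth <- structure(list(causal_cpg_sets = causal_sets,
                          causal_weights = weights,
                          true_batch_shifts = true_shifts,
                          true_log_hrs = hz,
                          generating_r2 = gen_r2,
                          age_cpgs = cpg_names[age_idx],
                          sex_cpgs = cpg_names[sex_idx],
                          clean_metabolites = clean),
                     class = "ground_truth")
  list(data = data, truth = truth)
}

#' Inject per-cohort batch effects into a metabolite matrix
#'
#' For cohort `c` and feature `f`, `x' = (x - m_cf) * factor_cf + m_cf +
#' delta_cf`, where `m_cf` is the cohort-feature mean: the additive shift
#' moves the cohort mean by `delta` and the multiplicative factor scales the
#' cohort SD without moving the mean. Cohorts absent from `batch_shift` are
#' left untouched (delta 0, factor 1).
#'
#' @param metabolites samples x features numeric matrix.
#' @param cohort_labels character vector, one label per row.
#' @param batch_shift named list: per cohort a list with `delta` and `factor`,
#'   each scalar or per-feature vector.
#' @return the shifted matrix.
#' @export
inject_batch_effects <- function(metabolites, cohort_labels, batch_shift) {
  stopifnot(is.matrix(metabolites), length(cohort_labels) == nrow(metabolites))
  unknown <- setdiff(names(batch_shift), unique(cohort_labels))
  if (length(unknown) > 0)
    stop("unknown cohort label(s) in batch_shift: ", paste(unknown, collapse = ", "))
  out <- metabolites
  for (co in names(batch_shift)) {
    rows <- which(cohort_labels == co)
    bs <- batch_shift[[co]]
    delta <- rep_len(bs$delta, ncol(out))
    fac <- rep_len(bs$factor, ncol(out))
    m <- colMeans(out[rows, , drop = FALSE], na.rm = TRUE)
    centred <- sweep(out[rows, , drop = FALSE], 2, m, "-")
    out[rows, ] <- sweep(sweep(centred, 2, fac, "*"), 2, m + delta, "+")
  }
  out
}

#' Generate Weibull proportional-hazards survival data
#'
#' Event times invert the Weibull-baseline proportional-hazards survival
#' function `S(t | x) = exp(-(t/scale)^shape * exp(lp))` at a uniform random
#' quantile, with linear predictor `lp = Z \%*\% hazard_coefs` on column
#' z-scored metabolites. Censoring is administrative and uniform on
#' `[0, t_max]`, independent of covariates, with `t_max` solved numerically so
#' that the expected censored fraction approximates `censor_rate` for the
#' drawn event times; the realised rate is therefore approximate.
#'
#' @param metabolites samples x features matrix; z-scored internally so
#'   `hazard_coefs` are log hazard ratios per SD.
#' @param hazard_coefs numeric vector, one per feature.
#' @param weibull_shape,weibull_scale baseline parameters, both > 0.
#' @param censor_rate target censored fraction in `[0,1)`; 0 disables
#'   censoring.
#' @param seed RNG seed.
#' @return data.frame with columns `time` (> 0, years) and `event` (0/1).
#' @export
make_survival <- function(metabolites, hazard_coefs, weibull_shape,
                          weibull_scale, censor_rate, seed = 1L) {
  if (weibull_shape <= 0 || weibull_scale <= 0)
    stop("weibull_shape and weibull_scale must be positive")
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must be in [0,1)")
  Z <- scale(metabolites)
  Z[is.na(Z)] <- 0  # constant columns carry no hazard signal
  lp <- as.vector(Z %*% hazard_coefs)
  set.seed(seed)
  u <- stats::runif(length(lp))
  t_event <- weibull_scale * (-log(u) * exp(-lp))^(1 / weibull_shape)
  t_event <- pmax(t_event, 1e-8)
  if (censor_rate == 0) {
    return(data.frame(time = t_event, event = 1L))
  }
  f <- function(tmax) mean(pmin(t_event / tmax, 1)) - censor_rate
  upper <- max(t_event) * 2
  t_max <- stats::uniroot(f, lower = min(t_event) / 2, upper = upper,
                          extendInt = "downX")$root
  cens <- stats::runif(length(lp), 0, t_max)
  data.frame(time = pmax(pmin(t_event, cens), 1e-8),
             event = as.integer(t_event <= cens))
}

#' Write a simulated dataset to TSV files (plus ground truth as JSON)
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- sim$data
  write_tsv_matrix(d$metabolites, file.path(dir, "metabolites.tsv"))
  write_tsv_matrix(d$betas, file.path(dir, "betas.tsv"))
  utils::write.table(d$phenotypes, file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(d$survival, file.path(dir, "survival.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- sim$truth
  tr$clean_metabolites <- NULL
  jsonlite::write_json(tr, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
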