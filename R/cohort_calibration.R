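#' Phenotype-matched sample pairs between a reference and a target cohort
#'
#' Greedy nearest-neighbour matching without replacement, exact on sex, on
#' Euclidean distance over (age, BMI) standardized by the reference cohort's
#' SDs. Candidate pairs within the caliper are accepted in order of
#' (distance, reference id, target id), so the result is deterministic. The
#' final list is truncated so the male and female pair counts are equal,
#' dropping the worst-distance excess pairs of the larger sex.
#'
#' @param ref_pheno,target_pheno data.frames with columns `sample_id`, `age`,
#'   `sex` (0/1), `bmi`; no missing values.
#' @param caliper maximum acceptable distance in pooled-SD units (default 0.5).
#' @return data.frame of class `matched_pairs`: `ref_id`, `target_id`, `sex`,
#'   `distance`.
#' @export
match_samples <- function(ref_pheno, target_pheno, caliper = 0.5) {
  for (df in list(ref_pheno, target_pheno)) {
    stopifnot(all(c("sample_id", "age", "sex", "bmi") %in% names(df)))
    if (anyNA(df[, c("age", "sex", "bmi")]))
      stop("matching phenotypes must not contain missing values")
  }
  sd_age <- stats::sd(ref_pheno$age)
  sd_bmi <- stats::sd(ref_pheno$bmi)
  if (sd_age == 0) sd_age <- 1
  if (sd_bmi == 0) sd_bmi <- 1
  match_one_sex <- function(sx) {
    r <- ref_pheno[ref_pheno$sex == sx, , drop = FALSE]
    t <- target_pheno[target_pheno$sex == sx, , drop = FALSE]
    if (nrow(r) == 0 || nrow(t) == 0) return(NULL)
    d <- outer(r$age / sd_age, t$age / sd_age, "-")^2 +
      outer(r$bmi / sd_bmi, t$bmi / sd_bmi, "-")^2
    d <- sqrt(d)
    cand <- which(d <= caliper, arr.ind = TRUE)
    if (nrow(cand) == 0) return(NULL)
    ord <- order(d[cand], r$sample_id[cand[, 1]], t$sample_id[cand[, 2]])
    cand <- cand[ord, , drop = FALSE]
    used_r <- logical(nrow(r)); used_t <- logical(nrow(t))
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      ri <- cand[i, 1]; ti <- cand[i, 2]
      if (!used_r[ri] && !used_t[ti]) {
        used_r[ri] <- TRUE; used_t[ti] <- TRUE; keep[i] <- TRUE
      }
    }
    cand <- cand[keep, , drop = FALSE]
    data.frame(ref_id = r$sample_id[cand[, 1]],
               target_id = t$sample_id[cand[, 2]],
               sex = sx, distance = d[cand], stringsAsFactors = FALSE)
  }
  males <- match_one_sex(1)
  females <- match_one_sex(0)
  if (is.null(males) || is.null(females) || nrow(males) == 0 || nrow(females) == 0)
    stop("no acceptable matched pairs in at least one sex stratum")
  m <- min(nrow(males), nrow(females))
  trim <- function(df) df[order(df$distance)[seq_len(m)], , drop = FALSE]
  out <- rbind(trim(males), trim(females))
  rownames(out) <- NULL
  class(out) <- c("matched_pairs", "data.frame")
  out
}

#' Fit per-cohort per-feature affine calibration maps to a reference cohort
#'
#' For every non-reference cohort, stores the matched-subset mean and SD of
#' each feature in the target cohort and in the reference cohort (over that
#' cohort's own matched reference samples). The reference cohort maps to the
#' identity transform.
#'
#' @param metabolites complete (post-imputation) concentration matrix with
#'   sample ids as row names.
#' @param pairs_by_cohort named list of [match_samples()] results, one per
#'   non-reference cohort.
#' @param reference_cohort name of the reference cohort.
#' @return list of class `calibration_map`: per cohort a data.frame
#'   (`feature`, `mu_target`, `sd_target`, `mu_ref`, `sd_ref`).
#' @export
fit_calibration <- function(metabolites, pairs_by_cohort, reference_cohort) {
  maps <- list()
  feats <- colnames(metabolites)
  maps[[reference_cohort]] <- data.frame(
    feature = feats, mu_target = 0, sd_target = 1, mu_ref = 0, sd_ref = 1,
    stringsAsFactors = FALSE)
  for (co in names(pairs_by_cohort)) {
    pr <- pairs_by_cohort[[co]]
    xt <- metabolites[pr$target_id, , drop = FALSE]
    xr <- metabolites[pr$ref_id, , drop = FALSE]
    mu_t <- colMeans(xt); sd_t <- apply(xt, 2, stats::sd)
    mu_r <- colMeans(xr); sd_r <- apply(xr, 2, stats::sd)
    if (any(sd_t == 0) || any(sd_r == 0)) {
      f <- feats[which(sd_t == 0 | sd_r == 0)[1]]
      stop(sprintf("matched-subset SD is zero for feature '%s' in cohort '%s'",
                   f, co))
    }
    maps[[co]] <- data.frame(feature = feats, mu_target = mu_t,
                             sd_target = sd_t, mu_ref = mu_r, sd_ref = sd_r,
                             stringsAsFactors = FALSE)
  }
  structure(list(reference = reference_cohort, maps = maps),
            class = "calibration_map")
}

#' Apply a calibration map to all samples of each cohort
#'
#' `x' = (x - mu_target) / sd_target * sd_ref + mu_ref` per cohort-feature,
#' applied to every sample of the cohort, matched or not. The reference
#' cohort (identity map) passes through unchanged. The transform is affine
#' with positive slope, hence order-preserving within each cohort-feature.
#'
#' @param metabolites concentration matrix, sample ids as row names.
#' @param map a [fit_calibration()] result.
#' @param cohort_labels per-row cohort labels.
#' @return calibrated matrix.
#' @export
apply_calibration <- function(metabolites, map, cohort_labels) {
  stopifnot(inherits(map, "calibration_map"),
            length(cohort_labels) == nrow(metabolites))
  out <- metabolites
  for (co in unique(cohort_labels)) {
    m <- map$maps[[co]]
    if (is.null(m)) stop("no calibration map entry for cohort '", co, "'")
    miss <- setdiff(colnames(metabolites), m$feature)
    if (length(miss) > 0)
      stop("calibration map for cohort '", co, "' lacks feature(s): ",
           paste(miss, collapse = ", "))
    rows <- which(cohort_labels == co)
    idx <- match(colnames(metabolites), m$feature)
    x <- out[rows, , drop = FALSE]
    x <- sweep(x, 2, m$mu_target[idx], "-")
    x <- sweep(x, 2, m$sd_ref[idx] / m$sd_target[idx], "*")
    out[rows, ] <- sweep(x, 2, m$mu_ref[idx], "+")
  }
  out
}
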