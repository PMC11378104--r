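## Genomic coordinate convention (used throughout this module): CpG
## positions are 1-based; region intervals (islands, genes) are 1-based
## half-open [start, end), i.e. a region covers positions start .. end-1.

interval_distance <- function(pos, start, end) {
  # distance of a point to a half-open interval; 0 inside
  pmax(start - pos, pos - (end - 1), 0)
}

#' Classify CpGs by CpG-island context
#'
#' Island if the position falls inside an island interval; shore if within
#' 2 kb of the nearest island edge; shelf if within 2-4 kb (the 2 kb flanking
#' the shores); open sea otherwise. The nearest island governs, and every CpG
#' receives exactly one of the four labels. CpGs on chromosomes without any
#' island default to open sea with a warning.
#'
#' @param cpg_positions data.frame `cpg`, `chrom`, `pos` (1-based).
#' @param island_intervals data.frame `chrom`, `start`, `end` (1-based
#'   half-open, non-overlapping after merge).
#' @param shore_width,shelf_width widths in bp (defaults 2000 each).
#' @return data.frame `cpg`, `chrom`, `pos`, `cgi_context`.
#' @export
annotate_cgi_context <- function(cpg_positions, island_intervals,
                                 shore_width = 2000, shelf_width = 2000) {
  out <- cpg_positions
  out$cgi_context <- "open_sea"
  warned <- character(0)
  for (ch in unique(cpg_positions$chrom)) {
    rows <- which(cpg_positions$chrom == ch)
    isl <- island_intervals[island_intervals$chrom == ch, , drop = FALSE]
    if (nrow(isl) == 0) {
      warned <- c(warned, ch)
      next
    }
    for (i in rows) {
      d <- min(interval_distance(cpg_positions$pos[i], isl$start, isl$end))
      out$cgi_context[i] <-
        if (d == 0) "island"
        else if (d <= shore_width) "shore"
        else if (d <= shore_width + shelf_width) "shelf"
        else "open_sea"
    }
  }
  if (length(warned) > 0)
    warning("no island intervals on chromosome(s): ",
            paste(warned, collapse = ", "), "; CpGs set to open_sea")
  out
}

#' Fisher exact enrichment of a CpG selection against annotation sets
#'
#' For each annotation label builds the 2x2 table (selected & annotated,
#' selected & not, annotated & not selected, neither) over the universe,
#' computes the two-sided Fisher exact p (hypergeometric) and the odds ratio
#' `ad / bc` with the Haldane-Anscombe 0.5 correction applied to all cells
#' when any cell is zero, then adjusts p values across labels with
#' Benjamini-Hochberg.
#'
#' @param selected CpG id set (subset of `universe`), non-empty.
#' @param universe full CpG id set.
#' @param annotation_sets named list: label -> CpG id set.
#' @param fdr_level significance level on adjusted p (default 0.05).
#' @return data.frame of class `enrichment_table`: label, a, b, c, d,
#'   odds_ratio, p, p_adj, significant.
#' @export
fisher_enrichment <- function(selected, universe, annotation_sets,
                              fdr_level = 0.05) {
  if (length(selected) == 0) stop("empty selected CpG set")
  stopifnot(all(selected %in% universe))
  sel <- unique(selected)
  uni <- unique(universe)
  rows <- lapply(names(annotation_sets), function(lab) {
    ann <- intersect(unique(annotation_sets[[lab]]), uni)
    a <- length(intersect(sel, ann))
    b <- length(sel) - a
    c <- length(ann) - a
    d <- length(uni) - a - b - c
    p <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
    or <- if (a == 0 || b == 0 || c == 0 || d == 0)
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
    else (a * d) / (b * c)
    data.frame(label = lab, a = a, b = b, c = c, d = d, odds_ratio = or,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < fdr_level
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Load and filter a trait catalogue of CpG-trait associations
#'
#' Keeps only associations significant after Bonferroni correction at the
#' array level: `p < alpha / array_size`. Returns the trait -> CpG set map
#' used by [fisher_enrichment()].
#'
#' @param catalog data.frame `cpg`, `trait`, `p`.
#' @param array_size number of probes on the array (default 480000).
#' @param alpha base significance level (default 0.05).
#' @return named list: trait -> character vector of CpGs.
#' @export
trait_catalog_sets <- function(catalog, array_size = 480000, alpha = 0.05) {
  keep <- catalog[catalog$p < alpha / array_size, , drop = FALSE]
  split(keep$cpg, keep$trait)
}

#' Genes in cis of each CpG
#'
#' Links a gene to a CpG iff the minimum distance between the CpG position
#' and the gene interval is at most `max_dist` (inclusive boundary; distance
#' 0 inside the gene).
#'
#' @param cpg_positions data.frame `cpg`, `chrom`, `pos`.
#' @param gene_intervals data.frame `chrom`, `start`, `end`, `name` (1-based
#'   half-open).
#' @param max_dist maximum distance in bp (default 100000).
#' @return named list: cpg -> character vector of gene names (possibly
#'   empty).
#' @export
genes_in_cis <- function(cpg_positions, gene_intervals, max_dist = 100000) {
  if (any(gene_intervals$start > gene_intervals$end))
    stop("malformed gene interval (start > end)")
  out <- stats::setNames(vector("list", nrow(cpg_positions)),
                         cpg_positions$cpg)
  for (ch in unique(cpg_positions$chrom)) {
    rows <- which(cpg_positions$chrom == ch)
    g <- gene_intervals[gene_intervals$chrom == ch, , drop = FALSE]
    for (i in rows) {
      if (nrow(g) == 0) { out[[cpg_positions$cpg[i]]] <- character(0); next }
      d <- interval_distance(cpg_positions$pos[i], g$start, g$end)
      out[[cpg_positions$cpg[i]]] <- g$name[d <= max_dist]
    }
  }
  out
}

#' Pairwise CpG-selection overlap between surrogate models
#'
#' `overlap(i, j) = |W_i intersect W_j| / min(|W_i|, |W_j|)` over the
#' nonzero-weight CpG sets; the min-normalized overlap makes near-duplicate
#' models (one selection nested in the other) score near 1. The Jaccard index
#' is returned alongside. Models with empty selections overlap 0 with a
#' warning.
#'
#' @param models list of `surrogate_model`s (>= 2), named or not.
#' @return list with matrices `overlap` and `jaccard` (diagonal 1).
#' @export
model_overlap <- function(models) {
  stopifnot(length(models) >= 2)
  sets <- lapply(models, function(m) names(m$weights)[m$weights != 0])
  nm <- names(models)
  if (is.null(nm)) nm <- paste0("model_", seq_along(models))
  if (any(lengths(sets) == 0))
    warning("model(s) with empty weight set; overlap defined as 0")
  k <- length(sets)
  ov <- jc <- matrix(0, k, k, dimnames = list(nm, nm))
  diag(ov) <- diag(jc) <- 1
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    inter <- length(intersect(sets[[i]], sets[[j]]))
    mn <- min(length(sets[[i]]), length(sets[[j]]))
    un <- length(union(sets[[i]], sets[[j]]))
    ov[i, j] <- ov[j, i] <- if (mn > 0) inter / mn else 0
    jc[i, j] <- jc[j, i] <- if (un > 0) inter / un else 0
  }
  list(overlap = ov, jaccard = jc)
}

#' CpGs recurrently selected across many surrogate models
#'
#' Reports CpGs with nonzero weight in strictly more than `min_models`
#' models, the fraction of those models sharing the majority coefficient
#' sign, and the median across models of the CpG's absolute-weight rank
#' (1 = largest |weight| in its model) as a cross-model importance summary.
#'
#' @param models list of `surrogate_model`s.
#' @param min_models strict threshold on the number of models (default 2).
#' @return data.frame: `cpg`, `n_models`, `sign_agreement`,
#'   `median_weight_rank`.
#' @export
recurrent_cpgs <- function(models, min_models = 2) {
  stopifnot(min_models >= 2)
  per_model <- lapply(models, function(m) m$weights[m$weights != 0])
  all_cpgs <- unlist(lapply(per_model, names))
  counts <- table(all_cpgs)
  hits <- names(counts)[counts > min_models]
  rows <- lapply(hits, function(cg) {
    w <- unlist(lapply(per_model, function(v) unname(v[cg])))
    w <- w[!is.na(w)]
    ranks <- vapply(per_model, function(v) {
      if (!cg %in% names(v)) return(NA_real_)
      rank(-abs(v))[cg]
    }, numeric(1))
    data.frame(cpg = cg, n_models = length(w),
               sign_agreement = max(mean(w > 0), mean(w < 0)),
               median_weight_rank = stats::median(ranks, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0) {
    return(data.frame(cpg = character(0), n_models = integer(0),
                      sign_agreement = numeric(0),
                      median_weight_rank = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(-out$n_models, out$cpg), , drop = FALSE]
}
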