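## TSV / JSON helpers shared across modules. All tables use a leading
## sample_id column; matrices are written with row names in that column.

#' Write a numeric matrix as TSV with a sample_id column
#' @param x matrix with row and column names.
#' @param path output file.
#' @export
write_tsv_matrix <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_matrix()] back into a matrix
#' @param path input file.
#' @export
read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Serialize a surrogate model (or any linear score) to JSON
#'
#' Schema: `{name, target, intercept, alpha, lambda, preprocessing, weights:
#' {feature: coef}}`. Numbers are written at full precision so a round trip
#' projects identically.
#'
#' @param model a `surrogate_model` or `linear_score`.
#' @param path output file.
#' @export
write_score_json <- function(model, path) {
  obj <- unclass(model)
  obj$weights <- as.list(obj$weights)
  # 17 significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a linear score / surrogate model from JSON or two-column TSV
#'
#' JSON follows the [write_score_json()] schema. A TSV is interpreted as
#' (feature, weight) pairs with intercept 0 and no preprocessing.
#'
#' @param path input file.
#' @export
read_score_json <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path)) {
    df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    w <- stats::setNames(as.numeric(df[[2]]), df[[1]])
    return(linear_score(name = basename(path), weights = w))
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- unlist(obj$weights)
  cls <- if (!is.null(obj$target)) "surrogate_model" else "linear_score"
  out <- obj
  out$weights <- w
  structure(out, class = cls)
}
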