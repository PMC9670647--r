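#' Pearson correlation with pairwise deletion
#'
#' Product-moment correlation over pairwise-complete observations. Returns
#' `NA` when fewer than `min_pairs` complete pairs remain or either variable
#' is constant on the complete pairs. Missing exposure values are never
#' imputed; pairwise deletion is the only missing-data policy in the
#' pipeline.
#'
#' @param x,y numeric vectors of equal length.
#' @param min_pairs minimum number of complete pairs required (default 3).
#' @return the correlation, or `NA_real_` when undefined.
#' @export
pearson_cor <- function(x, y, min_pairs = 3L) {
  if (length(x) != length(y)) {
    stop("x and y must have the same length", call. = FALSE)
  }
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < max(min_pairs, 2L)) return(NA_real_)
  xs <- x[ok]; ys <- y[ok]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
  stats::cor(xs, ys)
}

#' Pairwise-complete correlation matrix of an exposome table
#'
#' @param table an `exposome_table`, or a numeric matrix with column names.
#' @param min_pairs minimum complete pairs per variable pair; entries with
#'   fewer are set to `NA`.
#' @return symmetric correlation matrix with unit diagonal where defined.
#' @export
correlation_matrix <- function(table, min_pairs = 30L) {
  values <- if (inherits(table, "exposome_table")) table$values else as.matrix(table)
  r <- suppressWarnings(stats::cor(values, use = "pairwise.complete.obs"))
  npairs <- crossprod(!is.na(values))
  r[npairs < min_pairs] <- NA_real_
  r
}

#' Number of complete pairs per variable pair
#' @param table an `exposome_table` or numeric matrix.
#' @return integer matrix of pairwise-complete counts.
#' @export
pair_counts <- function(table) {
  values <- if (inherits(table, "exposome_table")) table$values else as.matrix(table)
  crossprod(!is.na(values))
}
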