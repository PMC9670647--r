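#' Supervised correlation screening against an outcome
#'
#' Computes the pairwise-complete Pearson correlation of every non-outcome
#' variable with the outcome column, sorts by |r| descending (ties broken
#' alphabetically by variable name), and flags retention at |r| strictly
#' greater than `retention_r`. The retention rule is on magnitude because
#' strong inverse correlates (e.g. life expectancy vs a mortality ratio) are
#' as informative as positive ones.
#'
#' @param table an `exposome_table` with the outcome column linked (see
#'   [link_outcomes()]).
#' @param outcome_name name of the outcome column.
#' @param retention_r retention threshold on |r| (default 0.15, strict).
#' @param min_pairs minimum complete pairs per variable; variables with
#'   fewer are dropped from the list with a message (default 30).
#' @return a `screen_result`: list with `outcome`, `retention_r`, and
#'   `entries` - a data.frame (name, domain, r, n_pairs, retained) in sort
#'   order.
#' @export
screen_correlates <- function(table, outcome_name, retention_r = 0.15,
                              min_pairs = 30L) {
  stopifnot(inherits(table, "exposome_table"))
  if (!outcome_name %in% variables(table)) {
    stop("outcome column '", outcome_name, "' not in table", call. = FALSE)
  }
  y <- table$values[, outcome_name]
  if (stats::sd(y, na.rm = TRUE) == 0 || all(is.na(y))) {
    stop("outcome is constant; screening correlations undefined", call. = FALSE)
  }
  is_outcome <- table$meta$domain == "outcome" | variables(table) == outcome_name
  vars <- variables(table)[!is_outcome]
  r <- vapply(vars, function(v) {
    pearson_cor(table$values[, v], y, min_pairs = min_pairs)
  }, numeric(1))
  n_pairs <- vapply(vars, function(v) {
    sum(!is.na(table$values[, v]) & !is.na(y))
  }, integer(1))
  dropped <- vars[is.na(r)]
  if (length(dropped)) {
    message(length(dropped), " variable(s) dropped from screen (",
            "undefined correlation under min_pairs = ", min_pairs, ")")
  }
  keep <- !is.na(r)
  entries <- data.frame(
    name = vars[keep],
    domain = table$meta$domain[!is_outcome][keep],
    r = unname(r[keep]),
    n_pairs = unname(n_pairs[keep])
  )
  entries <- entries[order(-abs(entries$r), entries$name), , drop = FALSE]
  entries$retained <- abs(entries$r) > retention_r
  rownames(entries) <- NULL
  structure(list(outcome = outcome_name, retention_r = retention_r,
                 entries = entries), class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result> outcome ", x$outcome, ": ", nrow(x$entries),
      " variables, ", sum(x$entries$retained), " retained at |r| > ",
      x$retention_r, "\n", sep = "")
  print(utils::head(x$entries, 10))
  invisible(x)
}

#' Split a screen result into the five PHE domain sublists
#'
#' Each sublist is the combined list filtered to one domain, preserving order
#' and retention flags; the concatenation of the five sublists is a
#' permutation of the combined list. Empty domains yield empty sublists, not
#' errors.
#'
#' @param result a `screen_result`.
#' @return named list of five `screen_result`s (built, social, natural,
#'   health, policy).
#' @export
domain_sublists <- function(result) {
  stopifnot(inherits(result, "screen_result"))
  bad <- setdiff(unique(result$entries$domain), PHE_DOMAINS)
  if (length(bad)) {
    stop("unknown domain label(s) in screen result: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- lapply(PHE_DOMAINS, function(d) {
    sub <- result$entries[result$entries$domain == d, , drop = FALSE]
    rownames(sub) <- NULL
    structure(list(outcome = result$outcome, retention_r = result$retention_r,
                   entries = sub), class = "screen_result")
  })
  stats::setNames(out, PHE_DOMAINS)
}

#' Top-k variables of a screen result
#'
#' First `min(k, length)` entries in the established sort order (|r|
#' descending, alphabetical tie-break), optionally restricted to retained
#' entries.
#'
#' @param result a `screen_result`.
#' @param k number of variables (default 20).
#' @param retained_only restrict to entries passing the retention rule
#'   (default FALSE).
#' @return character vector of variable names.
#' @export
top_k <- function(result, k = 20, retained_only = FALSE) {
  stopifnot(inherits(result, "screen_result"))
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  entries <- result$entries
  if (retained_only) entries <- entries[entries$retained, , drop = FALSE]
  utils::head(entries$name, k)
}

#' Write screening lists to delimited text
#'
#' Writes the combined list and the five domain sublists as six CSVs named
#' `screen_<outcome>_combined.csv` and `screen_<outcome>_<domain>.csv`.
#'
#' @param result a `screen_result`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of paths written.
#' @export
write_screen_lists <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, sprintf("screen_%s_combined.csv", result$outcome))
  utils::write.csv(result$entries, paths, row.names = FALSE)
  subs <- domain_sublists(result)
  for (d in names(subs)) {
    p <- file.path(dir, sprintf("screen_%s_%s.csv", result$outcome, d))
    utils::write.csv(subs[[d]]$entries, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
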