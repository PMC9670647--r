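OUTCOME_STRATA <- c("total", "nh_white", "nh_black", "hispanic")

#' Pregnancy-related mortality ratio per 100,000 live births
#'
#' The outcome is a 4-year count ratio: deaths related to or aggravated by
#' pregnancy per 100,000 live births over the same window. The numerator is
#' multiplied out before the division so the result is exact integer
#' arithmetic up to the final floating-point quotient.
#'
#' @param deaths_4yr non-negative integer count of deaths over the window.
#' @param births_4yr positive integer count of live births over the window.
#' @return the ratio, deaths per 100,000 live births.
#' @examples
#' compute_prm(3, 7000) # 42.857143
#' @export
compute_prm <- function(deaths_4yr, births_4yr) {
  if (any(births_4yr <= 0)) {
    stop("ratio undefined: births_4yr must be positive", call. = FALSE)
  }
  if (any(deaths_4yr < 0)) {
    stop("negative death count", call. = FALSE)
  }
  (deaths_4yr * 1e5) / births_4yr
}

#' Construct an outcome set
#'
#' A long table of per-county, per-stratum 4-year death and birth counts.
#' Strata are `total`, `nh_white`, `nh_black`, `hispanic`. The ratio and
#' inclusion columns are filled in by [apply_inclusion()].
#'
#' @param df data.frame with columns `fips`, `stratum`, `deaths_4yr`,
#'   `births_4yr` (and optionally `prm_ratio`, `included`).
#' @return an `outcome_set` (a validated data.frame).
#' @export
outcome_set <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("fips", "stratum", "deaths_4yr", "births_4yr")
  if (!all(need %in% names(df))) {
    stop("outcome set needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  df$fips <- pad_fips(df$fips)
  bad <- setdiff(unique(df$stratum), OUTCOME_STRATA)
  if (length(bad)) {
    stop("unknown stratum label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(df$deaths_4yr < 0, na.rm = TRUE) || any(df$births_4yr < 0, na.rm = TRUE)) {
    stop("negative counts in outcome set", call. = FALSE)
  }
  if (any(df$deaths_4yr != floor(df$deaths_4yr)) ||
      any(df$births_4yr != floor(df$births_4yr))) {
    stop("counts must be integers", call. = FALSE)
  }
  key <- paste(df$fips, df$stratum)
  if (anyDuplicated(key)) {
    stop("duplicate (fips, stratum) pairs: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  if (!"prm_ratio" %in% names(df)) df$prm_ratio <- NA_real_
  if (!"included" %in% names(df)) df$included <- NA
  rownames(df) <- NULL
  class(df) <- c("outcome_set", "data.frame")
  df
}

#' Apply the minimum-births inclusion rule and compute ratios
#'
#' A county-stratum is included when its 4-year live-birth count is at least
#' `min_births` ("minimum of 1000 live births" read inclusively). Inclusion
#' never depends on the death count: counties with zero deaths are retained.
#' The mortality ratio is computed only for included rows; excluded rows get
#' a missing ratio.
#'
#' @param outcomes an `outcome_set` or a data.frame acceptable to
#'   [outcome_set()].
#' @param min_births inclusion threshold on 4-year births (default 1000).
#' @return the `outcome_set` with `included` and `prm_ratio` filled in.
#' @export
apply_inclusion <- function(outcomes, min_births = 1000) {
  outcomes <- outcome_set(outcomes)
  if (min_births < 0) stop("min_births must be non-negative", call. = FALSE)
  outcomes$included <- outcomes$births_4yr >= min_births
  outcomes$prm_ratio <- NA_real_
  inc <- outcomes$included & outcomes$births_4yr > 0
  outcomes$prm_ratio[inc] <- compute_prm(outcomes$deaths_4yr[inc],
                                         outcomes$births_4yr[inc])
  outcomes
}

#' Per-stratum inclusion counts
#'
#' @param outcomes an `outcome_set` processed by [apply_inclusion()].
#' @return named integer vector: number of included counties per stratum.
#' @export
inclusion_counts <- function(outcomes) {
  stopifnot(inherits(outcomes, "outcome_set"))
  strata <- intersect(OUTCOME_STRATA, unique(outcomes$stratum))
  vapply(strata, function(s) {
    sum(outcomes$included[outcomes$stratum == s], na.rm = TRUE)
  }, integer(1))
}

#' Read an outcome set from delimited text
#' @param path CSV with columns fips, stratum, deaths_4yr, births_4yr
#'   (optionally prm_ratio, included).
#' @return an `outcome_set`.
#' @export
read_outcome_set <- function(path) {
  df <- utils::read.csv(path, colClasses = c(fips = "character"))
  outcome_set(df)
}

#' Write an outcome set to delimited text
#' @param outcomes an `outcome_set`.
#' @param path output CSV path.
#' @return invisibly, `outcomes`.
#' @export
write_outcome_set <- function(outcomes, path) {
  stopifnot(inherits(outcomes, "outcome_set"))
  utils::write.csv(as.data.frame(outcomes), path, row.names = FALSE)
  invisible(outcomes)
}

#' Link outcome ratios onto an exposome table
#'
#' Restricts the table to counties included for the requested stratum and
#' appends one outcome column named `prm_<stratum>` (pseudo-domain
#' `outcome`). Outcome counties absent from the exposome table are dropped
#' with a warning; the output row keys are always a subset of the
#' intersection of the two inputs.
#'
#' @param table an `exposome_table`.
#' @param outcomes an `outcome_set` processed by [apply_inclusion()].
#' @param stratum one of `total`, `nh_white`, `nh_black`, `hispanic`.
#' @return an `exposome_table` on the included counties with the outcome
#'   column appended.
#' @export
link_outcomes <- function(table, outcomes, stratum) {
  stopifnot(inherits(table, "exposome_table"))
  outcomes <- outcome_set(outcomes)
  if (!stratum %in% outcomes$stratum) {
    stop("stratum '", stratum, "' not present in outcome set", call. = FALSE)
  }
  if (any(is.na(outcomes$included))) {
    stop("outcome set has no inclusion flags; run apply_inclusion() first",
         call. = FALSE)
  }
  sub <- outcomes[outcomes$stratum == stratum & outcomes$included, , drop = FALSE]
  keep <- intersect(fips_keys(table), sub$fips)
  if (!length(keep)) {
    stop("no overlapping FIPS between exposome table and outcome set",
         call. = FALSE)
  }
  dropped <- setdiff(sub$fips, fips_keys(table))
  if (length(dropped)) {
    warning(length(dropped), " outcome count(ies) absent from exposome table, dropped",
            call. = FALSE)
  }
  out_col <- paste0("prm_", stratum)
  vals <- cbind(table$values[keep, , drop = FALSE],
                sub$prm_ratio[match(keep, sub$fips)])
  colnames(vals)[ncol(vals)] <- out_col
  meta <- rbind(table$meta,
                data.frame(name = out_col, domain = "outcome", year = NA,
                           source = "linked outcome",
                           description = paste("PRM ratio,", stratum, "stratum")))
  exposome_table(vals, meta)
}
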