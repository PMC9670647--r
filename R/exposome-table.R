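#' @keywords internal
"_PACKAGE"

PHE_DOMAINS <- c("built", "social", "natural", "health", "policy")

#' Normalise county FIPS codes
#'
#' County FIPS codes are 5-digit strings (2-digit state + 3-digit county).
#' Inputs read from delimited text frequently arrive as integers with the
#' leading zero stripped; this pads them back. Codes are stored as character,
#' never integer, so leading-zero states are lossless.
#'
#' @param x character or numeric vector of candidate FIPS codes.
#' @return character vector of zero-padded 5-character codes.
#' @examples
#' pad_fips(c(1001, "06037"))
#' @export
pad_fips <- function(x) {
  x <- trimws(as.character(x))
  if (any(is.na(x) | x == "")) {
    stop("missing FIPS code", call. = FALSE)
  }
  if (any(!grepl("^[0-9]+$", x))) {
    bad <- x[!grepl("^[0-9]+$", x)]
    stop("non-numeric FIPS code(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  if (any(nchar(x) > 5)) {
    stop("FIPS code longer than 5 digits", call. = FALSE)
  }
  paste0(strrep("0", pmax(0L, 5L - nchar(x))), x)
}

#' Construct a validated exposome table
#'
#' An exposome table is a counties x variables numeric matrix keyed by 5-digit
#' FIPS codes, together with per-variable metadata. Missing values are allowed
#' in the matrix and are propagated to correlation routines by pairwise
#' deletion; they are never imputed.
#'
#' @param values numeric matrix, rows = counties (rownames are FIPS codes),
#'   columns = variables (colnames are variable names).
#' @param meta data.frame with one row per column of `values`, containing at
#'   least `name` and `domain`; optional `year`, `source`, `description`.
#'   `domain` must be one of `built`, `social`, `natural`, `health`, `policy`,
#'   or the pseudo-domain `outcome` used for appended outcome columns.
#' @return an object of class `exposome_table`: a list with elements `values`
#'   and `meta`.
#' @export
exposome_table <- function(values, meta) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have FIPS rownames and variable colnames", call. = FALSE)
  }
  rownames(values) <- pad_fips(rownames(values))
  if (anyDuplicated(rownames(values))) {
    stop("duplicate FIPS row keys: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate variable names", call. = FALSE)
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!all(c("name", "domain") %in% names(meta))) {
    stop("meta must contain columns 'name' and 'domain'", call. = FALSE)
  }
  for (col in c("year", "source", "description")) {
    if (!col %in% names(meta)) meta[[col]] <- NA
  }
  meta <- meta[, c("name", "domain", "year", "source", "description")]
  if (nrow(meta) != ncol(values)) {
    stop("metadata rows (", nrow(meta), ") do not match variable count (",
         ncol(values), ")", call. = FALSE)
  }
  missing_meta <- setdiff(colnames(values), meta$name)
  if (length(missing_meta)) {
    stop("variables without metadata: ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  }
  meta <- meta[match(colnames(values), meta$name), , drop = FALSE]
  rownames(meta) <- NULL
  ok_domains <- c(PHE_DOMAINS, "outcome")
  bad <- setdiff(unique(meta$domain), ok_domains)
  if (length(bad)) {
    stop("unknown domain label(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(ok_domains, collapse = ", "), call. = FALSE)
  }
  structure(list(values = values, meta = meta), class = "exposome_table")
}

#' @export
dim.exposome_table <- function(x) dim(x$values)

#' @export
print.exposome_table <- function(x, ...) {
  cat("<exposome_table> ", nrow(x$values), " counties x ", ncol(x$values),
      " variables\n", sep = "")
  tab <- table(x$meta$domain)
  cat("  domains:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  n_na <- sum(is.na(x$values))
  cat("  missing cells:", n_na, "\n")
  invisible(x)
}

#' Variable names of an exposome table
#' @param x an `exposome_table`.
#' @return character vector of variable names.
#' @export
variables <- function(x) colnames(x$values)

#' County FIPS keys of an exposome table
#' @param x an `exposome_table`.
#' @return character vector of 5-digit FIPS codes.
#' @export
fips_keys <- function(x) rownames(x$values)

#' Restrict an exposome table to a subset of variables
#' @param x an `exposome_table`.
#' @param keep character vector of variable names to retain.
#' @return an `exposome_table` with only the requested columns.
#' @export
select_variables <- function(x, keep) {
  stopifnot(inherits(x, "exposome_table"))
  missing <- setdiff(keep, variables(x))
  if (length(missing)) {
    stop("unknown variable(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  exposome_table(x$values[, keep, drop = FALSE],
                 x$meta[match(keep, x$meta$name), , drop = FALSE])
}

#' Read an exposome table from delimited text
#'
#' The data file must be comma-separated with a header row and a `fips`
#' column (case-insensitive); every other column is a variable. The metadata
#' file must be comma-separated with `name` and `domain` columns covering
#' every data column. Non-numeric data cells become missing values; FIPS codes
#' are zero-padded to 5 characters.
#'
#' @param path path to the data CSV.
#' @param meta_path path to the variable-metadata CSV.
#' @return an `exposome_table`.
#' @export
read_exposome_table <- function(path, meta_path) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  fips_col <- which(tolower(names(raw)) == "fips")
  if (length(fips_col) != 1) {
    stop("data file must have exactly one 'fips' column", call. = FALSE)
  }
  fips <- pad_fips(raw[[fips_col]])
  if (anyDuplicated(fips)) {
    stop("duplicate FIPS in ", path, ": ",
         paste(unique(fips[duplicated(fips)]), collapse = ", "), call. = FALSE)
  }
  dat <- raw[, -fips_col, drop = FALSE]
  values <- vapply(dat, function(col) suppressWarnings(as.numeric(col)),
                   numeric(nrow(raw)))
  values <- matrix(values, nrow = nrow(raw),
                   dimnames = list(fips, names(dat)))
  meta <- utils::read.csv(meta_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  missing_meta <- setdiff(names(dat), meta$name)
  if (length(missing_meta)) {
    stop("column(s) without metadata: ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  }
  exposome_table(values, meta[meta$name %in% names(dat), , drop = FALSE])
}

#' Write an exposome table to delimited text
#'
#' Inverse of [read_exposome_table()]: writes the value matrix with a leading
#' `fips` column and the metadata dictionary as two CSVs.
#'
#' @param x an `exposome_table`.
#' @param path output path for the data CSV.
#' @param meta_path output path for the metadata CSV.
#' @return invisibly, `x`.
#' @export
write_exposome_table <- function(x, path, meta_path) {
  stopifnot(inherits(x, "exposome_table"))
  out <- data.frame(fips = fips_keys(x), x$values, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  utils::write.csv(x$meta, meta_path, row.names = FALSE, na = "")
  invisible(x)
}
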