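#' Describe a synthetic exposome study design
#'
#' The generator emulates the statistical structure the screening pipeline
#' assumes in real county-level exposure data: blocks of near-duplicate
#' variables (equicorrelated above the autocorrelation threshold),
#' latent-factor-driven dense variable clusters, background noise variables,
#' domain labels, and Poisson death counts whose log-rate is driven by a
#' latent "deprivation" factor shared with planted cluster 1.
#'
#' Every variable is built as x = sqrt(r) * factor + sqrt(1 - r) * noise with
#' standard-normal factor and noise, so pairwise correlations inside blocks
#' and clusters are analytically known and the planted truth is checkable.
#'
#' @param n_counties number of counties (default 2000).
#' @param n_blocks number of autocorrelate blocks (default 8).
#' @param block_size variables per block (default 4).
#' @param within_block_r equicorrelation inside blocks; must exceed 0.9 so
#'   blocks form autocorrelation-graph components (default 0.95).
#' @param n_clusters number of planted dense clusters (default 2); cluster 1
#'   shares its latent factor with the outcome.
#' @param cluster_size variables per cluster (default 8).
#' @param cluster_r pairwise correlation inside clusters, in
#'   (0, within_block_r) (default 0.3).
#' @param outcome_effect coefficient of the deprivation factor in the
#'   log-rate of the mortality ratio (default 0.32).
#' @param log_noise_sd standard deviation of the extra log-rate noise
#'   (default 0.10).
#' @param n_noise_vars independent standard-normal background variables
#'   (default 30).
#' @param births_range integer (min, max) of the uniform 4-year live-birth
#'   counts (default c(250, 60000)).
#' @param base_ratio baseline mortality ratio per 100,000 live births
#'   (default 17.2).
#' @param strata_props named proportions of births in the nh_white, nh_black
#'   and hispanic strata (remainder is other races, counted in total only).
#' @param domain_assignment optional named character vector mapping variable
#'   name to PHE domain; by default domains are assigned round-robin.
#' @param seed integer seed; all randomness flows from it.
#' @return a `synthetic_design` list.
#' @export
synthetic_design <- function(n_counties = 2000, n_blocks = 8, block_size = 4,
                             within_block_r = 0.95, n_clusters = 2,
                             cluster_size = 8, cluster_r = 0.3,
                             outcome_effect = 0.32, log_noise_sd = 0.10,
                             n_noise_vars = 30,
                             births_range = c(250, 60000),
                             base_ratio = 17.2,
                             strata_props = c(nh_white = 0.55, nh_black = 0.18,
                                              hispanic = 0.20),
                             domain_assignment = NULL, seed = 1L) {
  if (within_block_r <= 0.9 || within_block_r >= 1) {
    stop("within_block_r must lie in (0.9, 1) so blocks are autocorrelation components",
         call. = FALSE)
  }
  if (cluster_r <= 0 || cluster_r >= within_block_r) {
    stop("cluster_r must lie in (0, within_block_r); the equicorrelated ",
         "construction is otherwise infeasible", call. = FALSE)
  }
  if (base_ratio <= 0) stop("base_ratio must be positive", call. = FALSE)
  if (births_range[1] < 0 || births_range[2] < births_range[1]) {
    stop("births_range must be a non-negative (min, max) pair", call. = FALSE)
  }
  if (log_noise_sd < 0) stop("log_noise_sd must be non-negative", call. = FALSE)
  if (sum(strata_props) > 1) stop("strata proportions exceed 1", call. = FALSE)
  structure(list(
    n_counties = as.integer(n_counties), n_blocks = as.integer(n_blocks),
    block_size = as.integer(block_size), within_block_r = within_block_r,
    n_clusters = as.integer(n_clusters), cluster_size = as.integer(cluster_size),
    cluster_r = cluster_r, outcome_effect = outcome_effect,
    log_noise_sd = log_noise_sd, n_noise_vars = as.integer(n_noise_vars),
    births_range = as.integer(births_range), base_ratio = base_ratio,
    strata_props = strata_props, domain_assignment = domain_assignment,
    seed = as.integer(seed)
  ), class = "synthetic_design")
}

# Analytic correlation between a planted cluster-1 variable and the realized
# mortality ratio R = deaths / births * 1e5 over counties with births >= the
# inclusion floor. Exact under the generator: lognormal moments for the rate
# r = b0 * exp(a*d + e), Stein covariance cov(d, r) = a * E[r], and the
# Poisson variance decomposition Var(R) = Var(r) + 1e5 * E[r] * E[1/B].
design_outcome_correlation <- function(design, min_births = 1000) {
  a <- design$outcome_effect
  s <- design$log_noise_sd
  b0 <- design$base_ratio
  lo <- max(design$births_range[1], min_births, 1L)
  hi <- design$births_range[2]
  if (lo > hi) return(NA_real_)
  e_inv_b <- mean(1 / seq.int(lo, hi))
  e_r <- b0 * exp((a^2 + s^2) / 2)
  var_r <- e_r^2 * (exp(a^2 + s^2) - 1)
  cor_d_r <- a * e_r / sqrt(var_r + 1e5 * e_r * e_inv_b)
  sqrt(design$cluster_r) * cor_d_r
}

#' Generate a synthetic exposome table, outcome counts, and truth record
#'
#' See [synthetic_design()] for the model. Per county, 4-year births are
#' uniform integers on `births_range`, split into strata by `strata_props`;
#' deaths per stratum are Poisson with mean births x ratio / 100000 where
#' log(ratio) = log(base_ratio) + outcome_effect x deprivation + noise.
#' The total-stratum death count is the sum over strata, hence itself
#' Poisson at the county rate. An identical seed yields bit-identical output.
#'
#' @param design a `synthetic_design`.
#' @return a list with `table` (an `exposome_table`), `outcomes` (an
#'   `outcome_set`, inclusion not yet applied), and `truth` - a record of
#'   block memberships, cluster memberships, the latent deprivation factor,
#'   and for cluster-1 variables both the design correlation with the latent
#'   factor (sqrt(cluster_r)) and the analytic design correlation with the
#'   realized included-county mortality ratio.
#' @export
generate_synthetic <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  set.seed(design$seed)
  n <- design$n_counties
  fips <- formatC(seq_len(n), width = 5, flag = "0")

  deprivation <- stats::rnorm(n)
  cols <- list(); blocks <- list(); clusters <- list()

  for (b in seq_len(design$n_blocks)) {
    f <- stats::rnorm(n)
    r <- design$within_block_r
    nm <- sprintf("block%02d_var%d", b, seq_len(design$block_size))
    for (j in seq_len(design$block_size)) {
      cols[[nm[j]]] <- sqrt(r) * f + sqrt(1 - r) * stats::rnorm(n)
    }
    blocks[[sprintf("block%02d", b)]] <- nm
  }
  for (cc in seq_len(design$n_clusters)) {
    f <- if (cc == 1) deprivation else stats::rnorm(n)
    r <- design$cluster_r
    nm <- sprintf("cluster%d_var%d", cc, seq_len(design$cluster_size))
    for (j in seq_len(design$cluster_size)) {
      cols[[nm[j]]] <- sqrt(r) * f + sqrt(1 - r) * stats::rnorm(n)
    }
    clusters[[sprintf("cluster%d", cc)]] <- nm
  }
  if (design$n_noise_vars > 0) {
    nm <- sprintf("background_var%02d", seq_len(design$n_noise_vars))
    for (j in seq_len(design$n_noise_vars)) {
      cols[[nm[j]]] <- stats::rnorm(n)
    }
  }
  values <- do.call(cbind, cols)
  rownames(values) <- fips

  vn <- colnames(values)
  if (is.null(design$domain_assignment)) {
    domain <- PHE_DOMAINS[(seq_along(vn) - 1L) %% length(PHE_DOMAINS) + 1L]
  } else {
    domain <- unname(design$domain_assignment[vn])
    if (anyNA(domain)) stop("domain_assignment does not cover every variable",
                            call. = FALSE)
  }
  meta <- data.frame(name = vn, domain = domain, year = 2016L,
                     source = "synthetic generator",
                     description = "synthetic standardized exposure")
  table <- exposome_table(values, meta)

  births_total <- sample.int(design$births_range[2] - design$births_range[1] + 1L,
                             n, replace = TRUE) + design$births_range[1] - 1L
  log_ratio <- log(design$base_ratio) +
    design$outcome_effect * deprivation +
    stats::rnorm(n, sd = design$log_noise_sd)
  ratio <- exp(log_ratio)

  props <- design$strata_props
  births <- list(
    nh_white = as.integer(floor(births_total * props[["nh_white"]])),
    nh_black = as.integer(floor(births_total * props[["nh_black"]])),
    hispanic = as.integer(floor(births_total * props[["hispanic"]]))
  )
  births$other <- births_total - births$nh_white - births$nh_black - births$hispanic
  deaths <- lapply(births, function(b) stats::rpois(n, b * ratio / 1e5))
  deaths_total <- deaths$nh_white + deaths$nh_black + deaths$hispanic + deaths$other

  rows <- rbind(
    data.frame(fips = fips, stratum = "total", deaths_4yr = deaths_total,
               births_4yr = births_total),
    data.frame(fips = fips, stratum = "nh_white", deaths_4yr = deaths$nh_white,
               births_4yr = births$nh_white),
    data.frame(fips = fips, stratum = "nh_black", deaths_4yr = deaths$nh_black,
               births_4yr = births$nh_black),
    data.frame(fips = fips, stratum = "hispanic", deaths_4yr = deaths$hispanic,
               births_4yr = births$hispanic)
  )
  outcomes <- outcome_set(rows)

  truth <- list(
    blocks = blocks,
    clusters = clusters,
    deprivation = stats::setNames(deprivation, fips),
    latent_log_ratio = stats::setNames(log_ratio, fips),
    design_cor_latent = stats::setNames(
      rep(sqrt(design$cluster_r), design$cluster_size), clusters$cluster1),
    design_cor_outcome = stats::setNames(
      rep(design_outcome_correlation(design), design$cluster_size),
      clusters$cluster1),
    moe_planted = character(),
    design = design
  )
  list(table = table, outcomes = outcomes, truth = truth)
}

#' Plant margin-of-error duplicate variables
#'
#' Appends exact copies of randomly chosen variables renamed with "margin of
#' error" / "95% confidence limit" patterns, giving the reduction stage's
#' name filter known targets. The planted names are recorded in the
#' `planted_moe` attribute of the returned table.
#'
#' @param table an `exposome_table`.
#' @param fraction fraction of existing variables to copy, in \[0, 1).
#' @param seed integer seed for the choice of source variables.
#' @return the `exposome_table` with planted columns appended and attribute
#'   `planted_moe` naming them (empty when `fraction = 0`).
#' @export
plant_moe_variables <- function(table, fraction, seed = 1L) {
  stopifnot(inherits(table, "exposome_table"))
  if (fraction < 0 || fraction >= 1) {
    stop("fraction must lie in [0, 1)", call. = FALSE)
  }
  n_new <- round(fraction * ncol(table$values))
  if (n_new == 0) {
    attr(table, "planted_moe") <- character()
    return(table)
  }
  set.seed(seed)
  src <- sample(variables(table), n_new)
  suffix <- rep_len(c("margin of error", "95% confidence limit"), n_new)
  new_names <- paste(src, suffix)
  vals <- cbind(table$values, table$values[, src, drop = FALSE])
  colnames(vals) <- c(variables(table), new_names)
  src_meta <- table$meta[match(src, table$meta$name), , drop = FALSE]
  src_meta$name <- new_names
  src_meta$description <- paste("planted duplicate of", src)
  out <- exposome_table(vals, rbind(table$meta, src_meta))
  attr(out, "planted_moe") <- new_names
  out
}

#' Write a synthetic truth record as plain key-value text
#' @param truth truth record from [generate_synthetic()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_truth_record <- function(truth, path) {
  lines <- c(
    sprintf("seed: %d", truth$design$seed),
    sprintf("block %s: %s", names(truth$blocks),
            vapply(truth$blocks, paste, "", collapse = ",")),
    sprintf("cluster %s: %s", names(truth$clusters),
            vapply(truth$clusters, paste, "", collapse = ",")),
    sprintf("design_cor_latent %s: %.6f", names(truth$design_cor_latent),
            truth$design_cor_latent),
    sprintf("design_cor_outcome %s: %.6f", names(truth$design_cor_outcome),
            truth$design_cor_outcome),
    if (length(truth$moe_planted)) {
      sprintf("moe_planted: %s", paste(truth$moe_planted, collapse = ","))
    }
  )
  writeLines(lines, path)
  invisible(path)
}
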