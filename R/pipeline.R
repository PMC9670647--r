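#' Build a run configuration
#'
#' Collects every numeric parameter of the pipeline in one validated list so
#' that each value printed in the run report traces to the configuration.
#' Either a `synthetic_design` or input paths (`table_path`, `meta_path`,
#' `outcomes_path`) must be supplied.
#'
#' @param design a `synthetic_design`, or NULL when reading from files.
#' @param table_path,meta_path,outcomes_path input CSVs (ignored when
#'   `design` is given).
#' @param strata strata to analyse (default all four).
#' @param autocorr_threshold autocorrelation threshold (default 0.9).
#' @param autocorr_mode `"signed"` or `"absolute"` (default signed).
#' @param retention_r supervised retention threshold (default 0.15).
#' @param top_k variables per domain network (default 20).
#' @param paraclique_thresholds absolute-correlation thresholds for the
#'   unsupervised stage (default c(0.15, 0.2, 0.3, 0.5, 0.7, 0.8)).
#' @param glom_terms glom terms to sweep (default 1:3).
#' @param min_clique smallest seed clique (default 3).
#' @param min_births inclusion floor on 4-year births (default 1000).
#' @param min_pairs minimum overlapping counties per correlation (default
#'   30).
#' @param moe_fraction fraction of margin-of-error duplicates to plant in a
#'   synthetic run (default 0.1).
#' @param seed run seed (default: the design's seed, else 1).
#' @param output_dir where artifacts are written, or NULL for none.
#' @return a `run_config` list.
#' @export
run_config <- function(design = NULL, table_path = NULL, meta_path = NULL,
                       outcomes_path = NULL,
                       strata = c("total", "nh_white", "nh_black", "hispanic"),
                       autocorr_threshold = 0.9,
                       autocorr_mode = c("signed", "absolute"),
                       retention_r = 0.15, top_k = 20,
                       paraclique_thresholds = c(0.15, 0.2, 0.3, 0.5, 0.7, 0.8),
                       glom_terms = 1:3, min_clique = 3,
                       min_births = 1000, min_pairs = 30L,
                       moe_fraction = 0.1, seed = NULL,
                       output_dir = NULL) {
  autocorr_mode <- match.arg(autocorr_mode)
  if (is.null(design) && (is.null(table_path) || is.null(meta_path) ||
                          is.null(outcomes_path))) {
    stop("supply either a synthetic design or all three input paths",
         call. = FALSE)
  }
  thr <- c(autocorr_threshold, retention_r, paraclique_thresholds)
  if (any(thr <= 0 | thr >= 1)) {
    stop("all thresholds must lie in (0, 1)", call. = FALSE)
  }
  if (min_births < 0) stop("min_births must be non-negative", call. = FALSE)
  if (is.null(seed)) seed <- if (!is.null(design)) design$seed else 1L
  structure(list(
    design = design, table_path = table_path, meta_path = meta_path,
    outcomes_path = outcomes_path, strata = match.arg(strata, several.ok = TRUE),
    autocorr_threshold = autocorr_threshold, autocorr_mode = autocorr_mode,
    retention_r = retention_r, top_k = top_k,
    paraclique_thresholds = paraclique_thresholds, glom_terms = glom_terms,
    min_clique = min_clique, min_births = min_births,
    min_pairs = as.integer(min_pairs), moe_fraction = moe_fraction,
    seed = as.integer(seed), output_dir = output_dir
  ), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; a `design` mapping
#' is passed to [synthetic_design()].
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  spec <- yaml::read_yaml(path)
  if (!is.null(spec$design)) {
    spec$design <- do.call(synthetic_design, spec$design)
  }
  do.call(run_config, spec)
}

#' Run the full screening pipeline
#'
#' Executes the stages in order: generate or load inputs; apply the
#' inclusion rule and compute mortality ratios; reduce variables
#' (normality screen, autocorrelation graph, minimum dominating set, name
#' filter); link each stratum's outcome; supervised correlation screening
#' into one combined and five domain lists per stratum; unsupervised
#' paraclique extraction over the thresholded correlation graphs of the
#' total-population county set with all outcome columns as vertices; and
#' per-domain Bayesian-network learning on the top-k screened variables.
#' Identical configuration and seed give a byte-identical report.
#'
#' @param config a `run_config`.
#' @return a `pipeline_run`: list with `config`, `truth` (synthetic runs),
#'   `inclusion`, `reduction`, `screens`, `paracliques`, `networks`, and a
#'   text `report` with its md5 `digest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()

  # --- stage 1: inputs -------------------------------------------------
  if (!is.null(config$design)) {
    gen <- generate_synthetic(config$design)
    table <- gen$table
    if (config$moe_fraction > 0) {
      table <- plant_moe_variables(table, config$moe_fraction,
                                   seed = config$seed)
      gen$truth$moe_planted <- attr(table, "planted_moe")
    }
    outcomes <- gen$outcomes
    truth <- gen$truth
  } else {
    table <- read_exposome_table(config$table_path, config$meta_path)
    outcomes <- read_outcome_set(config$outcomes_path)
    truth <- NULL
  }

  # --- stage 2: outcomes ----------------------------------------------
  outcomes <- apply_inclusion(outcomes, min_births = config$min_births)
  incl <- inclusion_counts(outcomes)

  # --- stage 3: reduction ---------------------------------------------
  reduction <- reduce_variables(
    table,
    threshold = config$autocorr_threshold,
    threshold_mode = config$autocorr_mode,
    min_pairs = config$min_pairs
  )

  # --- stage 4 + 5: linking and supervised screening -------------------
  screens <- list(); linked <- list()
  for (s in config$strata) {
    lt <- link_outcomes(reduction$table, outcomes, s)
    linked[[s]] <- lt
    screens[[s]] <- screen_correlates(lt, paste0("prm_", s),
                                      retention_r = config$retention_r,
                                      min_pairs = config$min_pairs)
  }

  # --- stage 6: unsupervised paraclique sweep --------------------------
  # correlation graph over the total-population included county set, with
  # every analysed outcome ratio as a vertex (missing where not included)
  base <- link_outcomes(reduction$table, outcomes, "total")
  uns_values <- base$values
  for (s in setdiff(config$strata, "total")) {
    sub <- outcomes[outcomes$stratum == s & outcomes$included, , drop = FALSE]
    col <- rep(NA_real_, nrow(uns_values))
    hit <- match(rownames(uns_values), sub$fips)
    col[!is.na(hit)] <- sub$prm_ratio[hit[!is.na(hit)]]
    uns_values <- cbind(uns_values, col)
    colnames(uns_values)[ncol(uns_values)] <- paste0("prm_", s)
  }
  outcome_cols <- paste0("prm_", config$strata)
  cm <- correlation_matrix(uns_values, min_pairs = config$min_pairs)
  paracliques <- list()
  for (t in config$paraclique_thresholds) {
    g_t <- threshold_graph(cm, t)
    for (g in config$glom_terms) {
      key <- sprintf("t%.2f_g%d", t, g)
      paracliques[[key]] <- extract_paracliques(
        g_t, g = g, min_clique = config$min_clique,
        require_outcome_vertex = TRUE, outcome_vertices = outcome_cols
      )
    }
  }

  # --- stage 7: Bayesian networks --------------------------------------
  networks <- list()
  for (s in config$strata) {
    networks[[s]] <- run_per_domain(linked[[s]], screens[[s]],
                                    paste0("prm_", s), k = config$top_k)
  }

  run <- structure(list(
    config = config, truth = truth, outcomes = outcomes, inclusion = incl,
    reduction = reduction, linked = linked, screens = screens,
    unsupervised_cor = cm, paracliques = paracliques, networks = networks
  ), class = "pipeline_run")
  run$report <- render_report(run)
  run$digest <- report_digest(run$report)

  if (!is.null(config$output_dir)) write_run_artifacts(run, config$output_dir)
  attr(run, "elapsed_s") <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  run
}

render_report <- function(run) {
  cfg <- run$config
  lines <- c(
    "== exposome screening run report ==",
    sprintf("seed: %d", cfg$seed),
    sprintf("strata: %s", paste(cfg$strata, collapse = ", ")),
    sprintf("autocorrelation threshold: %g (%s)", cfg$autocorr_threshold,
            cfg$autocorr_mode),
    sprintf("retention |r| >: %g ; top-k: %d", cfg$retention_r, cfg$top_k),
    sprintf("paraclique thresholds: %s ; glom terms: %s ; min clique: %d",
            paste(cfg$paraclique_thresholds, collapse = ","),
            paste(cfg$glom_terms, collapse = ","), cfg$min_clique),
    sprintf("inclusion floor: %d births ; min pairs: %d", cfg$min_births,
            cfg$min_pairs),
    "",
    "[inclusion] included counties per stratum:",
    sprintf("  %s: %d", names(run$inclusion), run$inclusion),
    "",
    sprintf("[reduction] variables: %d -> %d (dominating set) -> %d (name filter)",
            run$reduction$n_input, run$reduction$n_after_mds,
            run$reduction$n_after_name_filter),
    sprintf("[reduction] flagged non-normal: %d of %d evaluable",
            sum(run$reduction$normality$flagged),
            sum(run$reduction$normality$evaluable)),
    ""
  )
  for (s in names(run$screens)) {
    e <- run$screens[[s]]$entries
    lines <- c(lines, sprintf(
      "[screen %s] %d variables, %d retained; strongest |r| = %.4f (%s)",
      s, nrow(e), sum(e$retained), abs(e$r[1]), e$name[1]))
  }
  lines <- c(lines, "")
  for (key in names(run$paracliques)) {
    ps <- run$paracliques[[key]]
    sizes <- vapply(ps$retained, function(pc) length(pc$members), integer(1))
    lines <- c(lines, sprintf(
      "[paraclique %s] extracted %d, retained %d%s", key, length(ps$all),
      length(ps$retained),
      if (length(sizes)) paste0(" (sizes: ", paste(sizes, collapse = ","), ")") else ""))
  }
  lines <- c(lines, "")
  for (s in names(run$networks)) {
    for (d in names(run$networks[[s]])) {
      dag <- run$networks[[s]][[d]]
      dp <- direct_predictors(dag, paste0("prm_", s))
      lines <- c(lines, sprintf(
        "[bayesnet %s/%s] %d nodes, %d arcs; direct predictors: %s",
        s, d, length(dag$nodes), nrow(dag$arcs),
        if (length(dp$predictors)) paste(dp$predictors, collapse = ", ") else "none"))
    }
  }
  lines
}

report_digest <- function(report_lines) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(report_lines, tmp)
  unname(tools::md5sum(tmp))
}

write_run_artifacts <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c(run$report, "", sprintf("digest: %s", run$digest)),
             file.path(dir, "report.txt"))
  write_outcome_set(run$outcomes, file.path(dir, "outcomes.csv"))
  write_exposome_table(run$reduction$table, file.path(dir, "reduced_table.csv"),
                       file.path(dir, "reduced_meta.csv"))
  write_correlation_graph(run$reduction$graph,
                          file.path(dir, "autocorrelation_graph.txt"))
  for (s in names(run$screens)) {
    write_screen_lists(run$screens[[s]], file.path(dir, "screens"))
  }
  pc_dir <- file.path(dir, "paracliques")
  dir.create(pc_dir, showWarnings = FALSE)
  for (key in names(run$paracliques)) {
    ps <- run$paracliques[[key]]
    for (i in seq_along(ps$retained)) {
      pc <- ps$retained[[i]]
      writeLines(c(
        sprintf("# paraclique %s #%d threshold=%s glom=%d density=%.6f",
                key, i, format(pc$threshold), pc$glom_term, pc$density),
        sprintf("seed: %s", paste(pc$seed_clique, collapse = ",")),
        sprintf("glommed: %s", paste(pc$glommed, collapse = ",")),
        "members:", pc$members
      ), file.path(pc_dir, sprintf("paraclique_%s_%02d.txt", key, i)))
    }
  }
  bn_dir <- file.path(dir, "networks")
  dir.create(bn_dir, showWarnings = FALSE)
  for (s in names(run$networks)) {
    for (d in names(run$networks[[s]])) {
      write_dag_dot(run$networks[[s]][[d]],
                    file.path(bn_dir, sprintf("dag_%s_%s.dot", s, d)))
    }
  }
  if (!is.null(run$truth)) {
    write_truth_record(run$truth, file.path(dir, "truth_record.txt"))
  }
  invisible(dir)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(x$report, sep = "\n")
  cat("\ndigest:", x$digest, "\n")
  invisible(x)
}
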