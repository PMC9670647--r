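# Stage 5: Bayesian-network identification of direct predictors.
#
# For each stratum, learns one Gaussian-BIC network per PHE domain (top-20
# retained correlates plus the outcome) and one overall network, then reads
# off the parents of the outcome node - the direct predictors.

source("analysis/00_settings.R")

red <- read_exposome_table(file.path(OUT, "reduced.csv"),
                           file.path(OUT, "reduced_meta.csv"))
outcomes <- read_outcome_set(file.path(OUT, "outcomes_included.csv"))

bn_dir <- file.path(OUT, "networks")
dir.create(bn_dir, showWarnings = FALSE)
rows <- list()
for (s in STRATA) {
  linked <- link_outcomes(red, outcomes, s)
  out_col <- paste0("prm_", s)
  sc <- screen_correlates(linked, out_col, retention_r = 0.15, min_pairs = 30)
  nets <- run_per_domain(linked, sc, out_col, k = 20)
  for (d in names(nets)) {
    dag <- nets[[d]]
    write_dag_dot(dag, file.path(bn_dir, sprintf("dag_%s_%s.dot", s, d)))
    dp <- direct_predictors(dag, out_col)
    rows[[length(rows) + 1]] <- data.frame(
      stratum = s, domain = d,
      predictor = if (length(dp$predictors)) dp$predictors else "None")
    cat(sprintf("[%s/%s] %d arcs; direct predictors: %s\n", s, d,
                nrow(dag$arcs),
                if (length(dp$predictors)) {
                  paste(dp$predictors, collapse = ", ")
                } else "None"))
  }
}
predictors <- do.call(rbind, rows)
utils::write.csv(predictors, file.path(OUT, "direct_predictors.csv"),
                 row.names = FALSE)
cat(sprintf("summary of direct predictors written to %s\n",
            file.path(OUT, "direct_predictors.csv")))
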