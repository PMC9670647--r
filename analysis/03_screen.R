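# Stage 3: supervised screening.
#
# Links each stratum's mortality ratio onto the reduced table by FIPS code
# and computes the sorted correlation lists: one combined and five domain
# sublists per stratum, retention at |r| > 0.15.

source("analysis/00_settings.R")

red <- read_exposome_table(file.path(OUT, "reduced.csv"),
                           file.path(OUT, "reduced_meta.csv"))
outcomes <- read_outcome_set(file.path(OUT, "outcomes_included.csv"))

for (s in STRATA) {
  linked <- link_outcomes(red, outcomes, s)
  sc <- screen_correlates(linked, paste0("prm_", s), retention_r = 0.15,
                          min_pairs = 30)
  write_screen_lists(sc, file.path(OUT, "screens"))
  e <- sc$entries
  cat(sprintf("[%s] %d variables screened over %d counties; %d retained; strongest: %s (r = %.3f)\n",
              s, nrow(e), nrow(linked$values), sum(e$retained),
              e$name[1], e$r[1]))
}
cat(sprintf("wrote %d screening lists under %s\n",
            length(STRATA) * 6, file.path(OUT, "screens")))
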