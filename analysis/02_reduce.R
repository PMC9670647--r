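# Stage 2: outcome inclusion and variable reduction.
#
# Applies the 1000-births inclusion rule, then reduces the variable set:
# Shapiro-Wilk normality screen (advisory), autocorrelation graph at
# r >= 0.9, exact minimum dominating set, and the margin-of-error name
# filter.

source("analysis/00_settings.R")

table <- read_exposome_table(file.path(OUT, "exposome.csv"),
                             file.path(OUT, "exposome_meta.csv"))
outcomes <- apply_inclusion(read_outcome_set(file.path(OUT, "outcome_counts.csv")),
                            min_births = 1000)
write_outcome_set(outcomes, file.path(OUT, "outcomes_included.csv"))

counts <- inclusion_counts(outcomes)
cat("included counties per stratum:\n")
print(counts)

red <- reduce_variables(table, threshold = 0.9, threshold_mode = "signed",
                        min_pairs = 30)
print(red)

write_exposome_table(red$table,
                     file.path(OUT, "reduced.csv"),
                     file.path(OUT, "reduced_meta.csv"))
write_correlation_graph(red$graph, file.path(OUT, "autocorrelation_graph.txt"))
utils::write.csv(red$normality, file.path(OUT, "normality_screen.csv"),
                 row.names = FALSE)
writeLines(red$removed_by_pattern, file.path(OUT, "removed_by_name_filter.txt"))

cat(sprintf("reduction: %d -> %d (dominating set) -> %d (name filter)\n",
            red$n_input, red$n_after_mds, red$n_after_name_filter))
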