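# Stage 1: simulate the study inputs.
#
# Generates the synthetic exposome table and 4-year death/birth counts,
# plants margin-of-error duplicate variables for the name filter to find,
# and writes everything (plus the planted-truth record) under results/.

source("analysis/00_settings.R")

gen <- generate_synthetic(DESIGN)
table <- plant_moe_variables(gen$table, fraction = 0.1, seed = SEED)
gen$truth$moe_planted <- attr(table, "planted_moe")

write_exposome_table(table,
                     file.path(OUT, "exposome.csv"),
                     file.path(OUT, "exposome_meta.csv"))
write_outcome_set(gen$outcomes, file.path(OUT, "outcome_counts.csv"))
write_truth_record(gen$truth, file.path(OUT, "truth_record.txt"))

cat(sprintf("simulated %d counties x %d variables (+%d planted MOE duplicates)\n",
            nrow(table$values), ncol(gen$table$values),
            length(gen$truth$moe_planted)))
cat(sprintf("planted cluster-1 design correlation with realized PRM: %.3f\n",
            gen$truth$design_cor_outcome[[1]]))
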