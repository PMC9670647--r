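# Shared settings for the numbered analysis scripts. Each script can be run
# from the repository root in order:
#   Rscript analysis/01_simulate.R
#   Rscript analysis/02_reduce.R
#   ...
# Artifacts accumulate under results/analysis/.

library(phescreen)

SEED <- 1L
OUT <- "results/analysis"
dir.create(OUT, showWarnings = FALSE, recursive = TRUE)

# The study design: county-level exposures with 8 autocorrelate blocks
# (r = 0.95), two dense clusters (r = 0.3, cluster 1 driven by the latent
# deprivation factor that also drives the mortality ratio), 30 background
# variables, and 4-year Poisson death counts at a baseline of 17.2 deaths
# per 100,000 live births.
DESIGN <- synthetic_design(seed = SEED)

STRATA <- c("total", "nh_white", "nh_black", "hispanic")
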