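---
title: "Graph-theoretical screening of a county-level exposome: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-theoretical screening of a county-level exposome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phescreen)
```

## The problem

Ecological studies of rare reproductive outcomes face a double bind: the
outcome (here, pregnancy-related deaths per 100,000 live births over a 4-year
window, computed per county and per race/ethnicity stratum) is too rare to
analyse below the county level, while the candidate exposure set — a
"public health exposome" of county-level measures spanning the built, social,
natural, health, and policy environments — runs to tens of thousands of
variables, rife with near-duplicate and collinear measures. `phescreen`
implements a screening pipeline for this setting:

1. **Outcome construction.** 4-year death counts over 4-year live births,
   scaled to 100,000; a county-stratum enters the analysis only with at
   least 1,000 live births (an inclusive floor, and deliberately independent
   of the death count, so zero-death counties are retained).
2. **Variable reduction.** An *autocorrelation graph* joins variable pairs
   whose Pearson correlation reaches 0.9; an exact *minimum dominating set*
   (MDS) picks one representative per redundancy neighbourhood; a
   name-pattern filter then removes margin-of-error and confidence-limit
   variables.
3. **Supervised screening.** Per stratum, the sorted list of correlations
   between every surviving variable and the outcome, split into five domain
   sublists, with retention at |r| > 0.15.
4. **Unsupervised mining.** Thresholded correlation graphs at
   |r| ≥ t, t ∈ {0.15, 0.2, 0.3, 0.5, 0.7, 0.8}; iterated exact maximum
   clique plus *glom* expansion extracts dense, noise-tolerant subgraphs
   (paracliques); a paraclique is kept when it contains an outcome vertex.
5. **Network identification.** Greedy hill-climbing on the decomposable
   linear-Gaussian BIC learns a directed acyclic graph over each domain's
   top-20 retained correlates plus the outcome; the outcome node's parents
   are reported as its *direct predictors*.

The restricted vital-records files and the full exposome repository that
motivate this design are not distributable, so the package ships a
synthetic-data generator that reproduces the statistical structure the
pipeline assumes; every stage is tested against that generator's planted
truth.

## The synthetic study design

`synthetic_design()` builds variables as
$x = \sqrt{r}\,f + \sqrt{1-r}\,\varepsilon$ with standard-normal factor $f$
and noise $\varepsilon$, so every planted pairwise correlation is known
exactly:

* **Blocks** (default 8 blocks of 4 variables at $r = 0.95$) emulate
  near-duplicate measures; because $0.95 > 0.9$ each block should become one
  connected component of the autocorrelation graph and collapse to a single
  representative under MDS.
* **Clusters** (default 2 clusters of 8 variables at $r = 0.3$) emulate
  latent-factor-driven variable groups. Cluster 1's factor is the
  "deprivation" factor that also drives the outcome.
* **Outcome.** Per county, 4-year births are uniform integers on
  (250, 60000); deaths are Poisson with mean births × ratio / 100,000 and
  $\log(\text{ratio}) = \log(17.2) + 0.32\,d + \eta$, $\eta \sim N(0, 0.1^2)$,
  where $d$ is the deprivation factor. The baseline 17.2 per 100,000 is the
  national pregnancy-related mortality ratio scale; the log-linear link
  keeps rates positive (the pipeline itself still consumes raw ratios).
  The effect size 0.32 was chosen so that the planted cluster-1 variables
  have a *design* correlation of roughly 0.25 with the realized ratio,
  the magnitude at which real county-level screens of this outcome operate.
* **Strata.** Births are split 55% / 18% / 20% into NH-White / NH-Black /
  Hispanic strata (remainder "other", counted in the total only); stratum
  deaths are Poisson at the county rate, so the total count is itself
  Poisson.

The truth record stores two design correlations per planted signal
variable: with the latent factor ($\sqrt{0.3} \approx 0.548$) and with the
realized ratio. The latter is computed analytically — lognormal moments give
$\mathrm{cov}(d, r) = a\,E[r]$ and the Poisson layer adds
$10^5 E[r]\,E[1/B]$ to the variance, with $E[1/B]$ summed exactly over the
truncated births support — so parameter-recovery tests compare sample
correlations to a true population value, not to a simulation.

What the generator does **not** emulate: the real repository's scale
(62,000+ variables), non-Gaussian marginals (rates, percentages, skewed
counts), spatial autocorrelation between neighbouring counties, and
systematically missing exposures. Passing tests therefore certify the
algorithms and their contracts, not robustness to real-data pathology.

A note on resolution: at the default 2,000 counties the sampling standard
deviation of a screened correlation is $(1-\rho^2)/\sqrt{n} \approx 0.022$,
so a ±0.05 recovery band is a ≈2.2σ statement per variable. Checks over
many variables and seeds should be read with that in mind: occasional
excursions slightly past 0.05 are expected from a perfectly calibrated
generator, and the test suite's strict per-variable recovery check is
documented as operating at the edge of this Monte-Carlo resolution.

## Numerical and algorithmic choices

**Correlation.** Pearson throughout (the normality screen — Shapiro–Wilk
with Benjamini–Hochberg adjustment across variables — is advisory and logged,
matching the setting where all variables pass). Missing values are handled by
pairwise deletion with a minimum-overlap rule (default 30 counties); pairs
with fewer complete observations, or a constant margin, yield no edge and no
list entry. Nothing is imputed.

**Autocorrelation threshold mode.** "Correlation at least 0.9" is read
literally as signed $r \ge 0.9$ (the default); an `absolute` mode is
available because a variable and its negation arguably carry the same
information. Both boundaries are inclusive.

**Minimum dominating set.** Solved exactly per connected component by a
set-cover branch and bound (greedy upper bound, covering lower bound,
branching on the vertex with the fewest candidate dominators). Among optimal
sets the lexicographically smallest by variable name is returned —
a deterministic, seed-free tie-break. Every output is re-checked by an
independent domination certificate, and a greedy
$1 + \ln(\Delta + 1)$-approximation is available behind a flag for graphs
whose components exceed the exact-search budget (default 64 vertices).

**Maximum clique.** Tomita-style branch and bound with a greedy-colouring
upper bound; candidates are explored highest-colour-first with ties by
vertex name, so the first optimum found — and hence the output — is
deterministic, and an edgeless graph yields the lexicographically first
vertex.

**Glom.** The one-pass rule adds every outside vertex adjacent to at least
$|S| - g$ members of the seed clique $S$, evaluated against the seed only.
This preserves the analytic density lower bound
$[\binom{s}{2} + m(s-g)]/\binom{s+m}{2}$, which is asserted on every output.
An iterated variant (re-evaluating against the growing member set) exists
behind a flag for comparison; its density is not guaranteed. The glom term
is capped at $g < |S|$, and the extraction floor is a seed clique of 3 —
anything smaller is not a dense subgraph in a useful sense.

**BIC score.** Per node, the linear-Gaussian score
$\log L - \frac{p}{2}\ln N$ with $p = |\text{parents}| + 2$ and the MLE
residual variance floored at $10^{-12}$ (guarding exact collinearity).
The score is decomposable, and Markov-equivalent structures score
identically to numerical precision — which is why the hill climber treats
move gains within a relative $10^{-8}$ window as *ties* and resolves them
lexicographically (add < delete < reverse, then parent, then child name).
Without that window, floating-point noise of order $10^{-12}$ would pick
arc orientations effectively at random and occasionally strand the search
in a complete-DAG local optimum. Search starts from the empty graph,
applies the steepest single-arc addition/deletion/reversal under an
acyclicity check, and stops at a certified local optimum (re-verified
independently of the search bookkeeping). Rows with missing values are
dropped per network (complete-case), and row counts are reported.
Variables enter untransformed by default; a standardization flag exists but
is off, since the BIC search is location/scale equivariant apart from the
variance floor.

**Determinism.** All randomness flows from one seed through one generator
instance; identical configuration and seed give a byte-identical run report
(md5-digested). Sorting tie-breaks are alphabetical everywhere.

## Scope decisions

* Counties are keyed by 5-digit zero-padded FIPS strings, never integers.
* The pipeline consumes pre-aggregated 4-year death/birth counts; parsing
  vital-records files, ICD-10 case selection, and geographic crosswalks are
  out of scope.
* Screening reports no p-values: the retention rule is the correlation
  threshold itself, and the downstream network stage is the multivariate
  follow-up.
* How margin-of-error variables are recognised is configurable (name
  patterns), since metadata conventions vary by repository; the default
  pattern list covers margin-of-error, confidence-limit/interval, and
  bound-style names.
* The outcome linkage exposes the missing-exposure policy (pairwise
  deletion) rather than guessing an imputation scheme.

## Problem sizes in the test suite

The suite exercises: exactness of MDS and maximum clique against brute-force
subset enumeration on 100 random graphs each (≤ 15 vertices); paraclique
certificates across the full threshold × glom sweep on the default design
(2,000 counties, ~80 variables); planted-structure recovery over 5 seeds at
the default design; 3-node exhaustive-search equivalence over 50 random
simulations; and the pipeline end-to-end at a 400-county scale for
structural and determinism contracts. These sizes were chosen to make each
property decidable in seconds while keeping every combinatorial check
against an exact, independent oracle.

## Known limitations

* Hill climbing is a local search; on ~10% of adversarial small problems it
  stops at a genuine local optimum (the test suite counts and bounds these,
  never hides them). No random restarts are used, by design, to keep runs
  deterministic.
* The exact MDS is exponential in the worst case; it is intended for the
  post-threshold autocorrelation graphs whose components are small. The
  greedy fallback loses optimality but keeps the domination certificate.
* An ecological screen cannot support individual-level or causal claims;
  the pipeline ranks and structures correlations, nothing more.
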