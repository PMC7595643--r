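# clinedrift

Drift-aware analysis of ancestry clines in replicated hybrid zones.

When two diverged lineages meet and interbreed along a geographic
transect, the frequency of each ancestry forms a *cline*. The Africanized
honey bee invasion of the Americas produced two such hybrid zones — one
in California, one in Argentina — where African (A) ancestry from
*Apis mellifera scutellata* grades into European (C and M) ancestry over
hundreds of kilometres. Questions that arise in any such system:

* Where do the clines sit, how wide are they, and does geography or
  climate predict them better?
* Which loci deviate from genome-wide ancestry patterns enough to
  implicate selection — once you account for the *drift* in ancestry
  frequencies that populations share through their invasion history?
* Are steep single-locus clines enriched in low-recombination regions,
  as predicted for polygenic barriers to gene flow?
* Did the rapid expansion erode genetic diversity?
* Does local ancestry at any locus predict a phenotype (admixture
  mapping), and what is a genome-wide significance threshold?

`clinedrift` implements this entire workflow for population-level
ancestry data, plus a seeded synthetic-data generator that emulates a
two-continent hybrid-zone study with known truth, so every stage can be
validated end to end.

## The core models

**Logistic cline** (fit by multi-start nonlinear least squares):

    A_i = M / (1 + exp(-b (x_i - c)))

with `M` the asymptotic maximum ancestry proportion toward the equator,
`c` the cline center, `b` the slope and width `w = 4/|b|` (the inverse of
the steepest gradient at the center). Predictors `x` (absolute latitude,
geodesic distance from the point of introduction, climate covariates)
are compared by gaussian-error AIC.

**Drift null for outlier scans.** The empirical population ancestry
variance–covariance matrix

    K[i,j] = (1/L) * sum_l (anc_il - alpha_i)(anc_jl - alpha_j)

captures how populations co-deviate from their genome-wide mean ancestry
`alpha`. Neutral locus frequencies are simulated as
`A ~ MVN(alpha, K)`, truncated to [0, 1] (with Poisson-binomial and
variance-only MVN nulls available for comparison), and one-tailed false
discovery rates for high/low-A outliers are calibrated per continent
against the simulated ensemble. Significant SNPs expand to
midpoint-bounded windows and merge (< 10 kb gaps) into regions that can
be intersected with gene annotations.

**Steepness and recombination.** Per-SNP clines (`M = 1`) fit to
population ancestry frequencies give a genome-wide slope distribution;
its null is obtained by refitting the same model to MVN-simulated loci.
Enrichment of the empirical top-5% steepest clines across
recombination-rate quintiles is assessed with a 0.2 cM block bootstrap
(basic intervals, fixed top-5% membership).

**Diversity and differentiation.** Per-SNP heterozygosity
`2p(1-p) n/(n-1)` (with `n` haplotypes with data) scaled by SNP density
gives per-bp diversity, with 1 cM block-bootstrap percentile intervals;
within-ancestry estimates mask to high-confidence homozygous tracts
(posterior > 0.8) under a block/chromosome inclusion rule. Hudson's
F_ST is averaged in sliding windows, and ancestry-informative markers
require > 0.95 frequency differences between the focal and both other
reference panels.

**Admixture mapping.** Wing length is residualised on genome-wide
ancestry, residuals are regressed on per-SNP ancestry dosage, and the
genome-wide p-value threshold comes from an Ornstein–Uhlenbeck
crossing approximation parameterised by generations since admixture and
total map length.

## Worked example

```r
library(clinedrift)

ds  <- simulate_hybrid_zones(synth_config(n_loci = 2000), seed = 1)
ind <- ds$individuals

# genome-wide clines per continent (M fixed at 0.84)
fit_logistic_cline(abs(ind$latitude[ind$continent == "N"]),
                   ind$A[ind$continent == "N"], M = 0.84,
                   n_starts = 50, seed = 1)
#> logistic cline fit [x]: M = 0.84, b = -0.7627, c = 32.67, width = 5.244
#>   rss = 0.239172, n = 131, AIC = -820.1, converged = TRUE
fit_logistic_cline(abs(ind$latitude[ind$continent == "S"]),
                   ind$A[ind$continent == "S"], M = 0.84,
                   n_starts = 50, seed = 2)
#> logistic cline fit [x]: M = 0.84, b = -0.785, c = 32.29, width = 5.095
#>   rss = 0.394709, n = 182, AIC = -1110, converged = TRUE

# wing length vs genome-wide ancestry
w <- fit_wing_ancestry_lm(ind)
sprintf("slope %.3f mm per unit A, R2 = %.2f, n = %d", w$slope, w$r2, w$n)
#> "slope -0.680 mm per unit A, R2 = 0.30, n = 269"

# drift null from the empirical ancestry covariance
km  <- compute_K(ds$freqs, ds$populations$alpha)
ens <- simulate_null("mvn-full", k_model = km, n_loci = 20000, seed = 3)
ens
#> null_ensemble [mvn-full]: 20000 loci x 39 populations (truncated: 11% low, 0.56% high)

# genome-wide admixture-mapping threshold at 47.6 generations
admixture_threshold(47.6, honeybee_layout())
#> [1] 1.013543e-06
```

The two fitted centers sit within a tenth of a degree of the generative
truth (32.72°N / 32.26°S absolute latitude); the cline width of ~5
degrees corresponds to roughly 550 km at 111 km per degree. The wing
model recovers the generative −0.72 mm effect of full A ancestry within
sampling error, with ancestry explaining ~31% of wing-length variance
among the 269 bees with intact wings. The truncation asymmetry of the
MVN null (many more frequencies clipped at 0 than at 1) reflects the
many low-A populations near the cline tails.

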