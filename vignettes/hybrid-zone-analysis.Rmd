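---
title: "Ancestry clines, drift nulls and admixture mapping with clinedrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestry clines, drift nulls and admixture mapping with clinedrift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinedrift)
```

`clinedrift` analyses ancestry variation across replicated admixture
hybrid zones: logistic cline fitting, a multivariate-normal drift null
for local-ancestry outlier scans, recombination-rate enrichment of steep
clines, diversity and differentiation estimators, and admixture mapping.
This vignette explains the models, their assumptions, the tunable
parameters, and the design decisions behind the implementation. The
package's frame of reference is the Africanized honey bee expansion —
African (A) ancestry meeting eastern (C) and western (M) European
ancestry along latitudinal transects in North and South America — but
every routine is generic over populations, loci and predictors.

## The logistic cline model

Genome-wide ancestry of individual *i* is modelled as
$$A_i = \frac{M}{1 + e^{-b (x_i - c)}},$$
where $x_i$ is a spatial or environmental predictor (absolute latitude
by default, so the two hemispheres can share one axis), $M$ is the
asymptotic maximum ancestry toward the equator, $c$ the cline center and
$b$ the slope. The cline width is defined as the inverse of the maximum
ancestry gradient at the center, $w = 4/|b|$, in predictor units; at
111 km per degree latitude a width of 5 degrees is roughly 550 km.

Estimation is by nonlinear least squares rather than a likelihood with a
parametric error model: the residual variance at a site mixes binomial
sampling noise with unknown drift variance, and least squares stays
agnostic about that mixture while simulation (below) quantifies its
consequences. The objective is non-convex, so `fit_logistic_cline()`
runs `n_starts` random starts with $b \sim \mathrm{Unif}(-5, 5)$ and
$c \sim \mathrm{Unif}(\min x, \max x)$, takes the best RSS
(box-constrained quasi-Newton per start, $|b| \le 50$, followed by a
Nelder–Mead polish at relative tolerance $10^{-14}$), and reports a
convergence flag. One hundred starts is the default for genome-wide
fits; per-SNP fits (`fit_snp_clines()`) use 4 starts plus a warm start
from the previous locus, which is ample for a 2-parameter fit to ~20
population means. Noiseless data are recovered to $10^{-6}$ (a test
asserts this). Degenerate inputs error early: fewer than 4 points, a
constant predictor, or ancestry outside $[0,1]$.

Model comparison across predictors uses the gaussian-error closed form
$\mathrm{AIC} = n \log(\mathrm{RSS}/n) + 2k$, counting the error
variance in $k$ — the convention of standard statistical software, so
rankings are comparable to packaged NLS fits. AIC is invariant to affine
rescaling of a predictor (tested), which is why a single-continent
design cannot distinguish latitude from distance travelled: within one
transect the two are nearly affine. Two continents break the tie,
because one dispersal rate cannot place both clines correctly.

Choices worth noting:

* $M$ is fixed at 0.84 for genome-wide fits — the ancestry plateau of
  the Brazilian source population — and at 1 for per-SNP fits, where a
  locus can in principle fix for either ancestry. `M = "free"` estimates
  it (one more AIC parameter).
* Fits weight individuals equally (the model is indexed by individual);
  population-level fits weight populations equally.
* Per-SNP centers are bounded to the sampled latitude range widened by
  one range-width per side: a drifting locus with no latitudinal signal
  otherwise sends $c$ to infinity, and the bound keeps such fits finite
  without affecting loci whose center lies inside the sampled range.
* Geodesic distances use the ellipsoidal `distGeo`, in km.

`predict_phenotype_cline()` composes a fitted ancestry cline with a
linear ancestry–phenotype model, giving the phenotype cline expected if
the trait tracked genome-wide ancestry exactly — the null against which
phenotype-specific selection would show up as a deviation.

## The ancestry covariance matrix and the drift null

Locus-wise ancestry frequencies deviate from a population's genome-wide
mean through sampling noise, drift along the invasion route, and
selection. Crucially these deviations are *correlated between
populations* that share history. `compute_K()` estimates
$$K[i,j] = \frac{1}{L} \sum_{l=1}^{L}
  (\mathrm{anc}_{i,l} - \alpha_i)(\mathrm{anc}_{j,l} - \alpha_j),$$
deviations taken from the genome-wide means $\alpha$, not from
column means — $K$'s diagonal absorbs both drift and finite-sample
noise, exactly the variance a null for observed frequencies needs.

`simulate_null()` offers three nulls, in increasing order of realism:

1. `"poisson-binomial"` — resamples alleles from each individual's
   genome-wide proportion: pure sampling variance, no drift;
2. `"mvn-variance-only"` — independent normals with $K$'s diagonal:
   drift within populations, no shared drift;
3. `"mvn-full"` — $\mathrm{MVN}(\alpha, K)$: shared drift included.

MVN draws are clipped to $[0,1]$ and the clipped fractions reported;
clipping only moves mass inward, so it raises ensemble means for
populations with $\alpha$ near 0 and leaves the upper tail essentially
untouched — an asymmetry a test asserts. A non-positive-definite $K$ is
repaired with a $10^{-10}$ ridge (warning) before failing hard.

False-discovery rates are simulation-calibrated rather than analytic:
for a candidate threshold $t$ scanned over the observed order
statistics, $\widehat{\mathrm{FDR}}(t) = P_{\mathrm{null}}(\text{beyond
} t)\, L_{\mathrm{obs}} / \#\{\text{observed beyond } t\}$. The raw
curve is noisy and non-monotone, so it is monotonised q-value style —
each candidate gets the minimum estimated FDR over thresholds *no more
extreme* than it — and the least extreme threshold at or below the
target (1, 5, 10%) is chosen. The suffix direction matters: taking the
minimum over *more* extreme thresholds instead would let the empty far
tail (zero null exceedances) declare everything significant. Tests on
null-generated "observed" data confirm near-zero flagging, and scans
with planted outliers confirm the realized false-discovery proportion
honours the 10% target per continent. The union of the two continents'
10% scans is not itself a 10% procedure; shared outliers are defined as
loci meeting 10% FDR in the same direction in both continents, with no
combined statistic invented.

Continental mean frequencies are unweighted means over populations (a
sample-size-weighted option exists but is off by default, matching how
the two-zone comparison treats populations as exchangeable units).

Outlier SNPs expand to midpoint-bounded windows — an ancestry call is
taken to represent its SNP's neighbourhood up to halfway to the next
call — and windows closer than 10 kb merge into regions labelled with
the best FDR class inside. Region/gene overlap (half-open BED
coordinates, ≥ 1 bp) is computed with `IRanges`; a brute-force
all-pairs oracle backs it in the tests. For counting *shared* regions,
the shared-SNP set is merged directly (the alternative — intersecting
per-continent region sets — can be built from the same primitives).

`group_correlation_contrast()` formalises the comparison of ancestry
correlations between population groups (e.g. the climatically similar
low-A ends of both zones vs geographic neighbours): mean pairwise
correlation per comparison type per stratum (chromosomes or
recombination quintiles), then a two-sided paired t-test across strata.

## Steep clines and recombination

The per-SNP steepness statistic is $|b|$ — the genome-wide cline fixes
the direction; magnitude is what selection against gene flow changes.
The null $|b|$ distribution comes from refitting the same per-SNP model
to full-MVN simulated loci, and the same FDR machinery applies
(upper tail).

Enrichment of steep clines in low-recombination regions uses the
empirical top 5% of $|b|$ (exactly $\lceil 0.05 L \rceil$ SNPs, ties
broken by position order) across recombination-rate quintiles, with a
0.2 cM block bootstrap: contiguous per-chromosome blocks (final partial
block kept) resampled with replacement, 10,000 replicates by default,
basic bootstrap intervals $[2\hat\theta - q_{0.975},\; 2\hat\theta -
q_{0.025}]$ (widened, rarely, to contain the point estimate when a
sparse bin's resampling distribution is strongly skewed). The top-5%
membership is held fixed from the original data and only the per-bin
proportions are recomputed per replicate — recomputing the cutoff
inside each replicate (available via `recompute_top = TRUE`) would
conflate changes in the cutoff with changes in the spatial arrangement.
SNPs take the recombination rate of their containing map window; bin
edges default to genome quintiles of the per-SNP rates.

## Diversity, F_ST and AIMs

Population allele frequencies are read-count weighted (pooled alternate
fraction), requiring at least two covered individuals per site, with
$n = 2 \times$ individuals with data. Per-SNP heterozygosity
$2p(1-p)\,n/(n-1)$ averaged over included SNPs and scaled by SNP density
(included SNPs / mappable sites — the global included-SNP count, not a
per-population recount) gives per-bp $\pi$. Uncertainty comes from a
1 cM block bootstrap; *percentile* intervals are the diversity default,
*basic* intervals the enrichment default — both live in
`block_bootstrap_ci()` and a coverage test holds the percentile
interval near its nominal 95%.

Predicted diversity under admixture alone replaces $p$ with the
panel-frequency mixture $\bar p = \sum_k w_k p_k$: the no-drift
expectation against which an observed diversity deficit indicates a
bottleneck. A mixture of two diverged panels is at least as diverse as
either panel (tested) — the reason admixed populations can exceed their
sources. Within-ancestry $\pi$ masks data to tracts of consecutive SNPs
with posterior > 0.8 for the homozygous focal state and reports a
population only if data cover ≥ 75 one-cM blocks across ≥ 15 of 16
chromosomes; on the reduced synthetic genomes used in tests these
thresholds scale down proportionally (they are arguments, not
constants). Unavailability is a value, not an error — tail populations
with little of an ancestry simply have no estimate.

Hudson's per-SNP $F_{ST}$,
$$\hat F = \frac{(p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1}
  - \frac{p_2(1-p_2)}{n_2-1}}{p_1(1-p_2) + p_2(1-p_1)},$$
is averaged within sliding windows (50 kb stepping 1 kb by default;
windows under 10 usable SNPs dropped). The window value is the mean of
per-SNP ratios, following the wording of the field's standard recipe
for this analysis; a ratio-of-averages variant would be a
straightforward switch. $\hat F$ is invariant to swapping allele labels
in both groups and may go slightly negative at $p_1 \approx p_2$.

Ancestry-informative markers require ≥ 5 covered individuals in every
reference panel and > 0.95 frequency difference between the focal panel
and *both* others, with alleles polarised so the focal panel carries
the high-frequency variant.

## Wing models and admixture mapping

`fit_wing_ancestry_lm()` is ordinary least squares of wing length (mm)
on genome-wide A proportion, optionally with a continent main effect
and interaction; bees with missing wings are excluded and counted
(damage flags are an input, not re-derived). `feral_nest_glm()` checks
a sampling covariate: gaussian GLM of logit ancestry (clamped to
$[10^{-3}, 1-10^{-3}]$ so boundary proportions stay finite) on absolute
latitude and the feral-nest flag.

Admixture mapping is two-stage: residualise wing length on genome-wide
ancestry, then regress residuals on the 0/1/2 A-dosage at each SNP
(two-tailed t test; monomorphic dosages give missing p). The two-stage
p-value ranks track the joint model's closely (tested), and the scan is
vectorised so a genome of hundreds of thousands of SNPs is a single
matrix product.

The genome-wide threshold treats the Z statistic along the genome as an
Ornstein–Uhlenbeck process whose autocorrelation decays at rate $g$ per
Morgan ($g$ = generations since admixture — the rate at which
recombination has broken ancestry blocks). The two-tailed family-wise
error at threshold $z$ is approximated by the expected crossing count
$$\alpha(z) \approx m\left[\,C \cdot 2\Phi(-z) +
  2\,g\,G\,z\,\phi(z)\,\right],$$
with $C$ chromosomes, $G$ the map length in Morgans and
$m = (\text{ancestries} - 1)$ parallel dosage scans (default 1: a
single focal ancestry). `admixture_threshold()` solves
$\alpha(z^*) = 0.05$ and returns $p^* = 2\Phi(-z^*)$. For
$g = 47.6$ generations on `honeybee_layout()` — 16 chromosomes,
~220 Mb, 19 cM/Mb genome-wide average (~42 Morgans, the scale of
published honey-bee linkage maps) — this gives $p^* \approx 10^{-6}$.
The map length is the one genuinely uncertain input; the threshold
scales roughly inversely with it. Two calibration facts from the test
suite: the threshold is conservative on a *discrete* marker set (the
continuum approximation counts crossings between markers), with
realized FWER around half nominal on a reduced 2-Morgan genome at 300
markers/Morgan, and it sits within a factor ~2 of a phenotype-
permutation oracle's 5% min-p quantile there. Conservatism shrinks as
marker density and the threshold $z^*$ grow toward genome scale.

## The synthetic-data generator

`simulate_hybrid_zones()` emulates the two-transect study design and is
the source of truth for every downstream validation. Its defaults *are*
the emulated study conditions:

* 12 northern populations over 32.7–38.5° (the northern transect covers
  only the upper half of its cline) and 21 southern populations over
  28–36° spanning the full cline; 278 current-study bees (8–9 per
  population) plus 35 "prior" northern bees without wing measurements;
* logistic clines with $M = 0.84$, centers 32.72°N / 32.26°S, slope
  −0.8 per degree (width 5°, matching ancestry running from ~0.8 to
  ~0.04 across the southern transect);
* wing model: intercept 9.0 mm, slope −0.72 mm per unit A, residual sd
  0.30 mm and 9 damaged wings, leaving 269 measured bees. The residual
  sd is derived, not free: with the design's ancestry spread
  (sd $\approx$ 0.28) and slope −0.72, $\sigma = |b|\,\mathrm{sd}_A
  \sqrt{(1-R^2)/R^2}$ at $R^2 = 0.31$ gives 0.30 mm;
* a generative covariance $K$: diagonal $v\,\alpha_i(1-\alpha_i)$ with
  $v = 0.03$, within-continent correlation $e^{-d/3^\circ}$, and an
  extra 0.1 correlation coupling low-A populations across continents
  (emulating the observed similarity of the climatically matched cline
  ends). The scale $v$ was set so the full-MVN null's truncation
  fractions on this design (~5% at zero, < 0.1% at one) match the
  reported magnitudes for the emulated study; the empirical $K$ of a
  generated dataset is larger than the construction $K$ because
  binomial sampling of 8–9 bees per population adds variance, as it
  does in real data;
* individual proportions normal around the population mean (sd 0.05,
  clamped), per-locus dosages Binomial(2, latent frequency), reference
  panels Balding–Nichols ($F = 0.35$) around shared ancestral
  frequencies, and a 16-chromosome genome scaled to 2 Mb per chromosome
  with Gamma-distributed window recombination rates (mean ~27 cM/Mb).

What the generator deliberately does **not** emulate: linkage between
loci (dosages are independent given the latent frequency — downstream
tests treat loci exchangeably, and the block bootstrap is exercised via
genetic positions, not via actual LD), HMM posterior uncertainty in
local ancestry, within-ancestry haplotype structure, and secular
climate covariates. Passing tests therefore certify the estimators and
their calibration under the stated generative model, not robustness to
every feature of real sequence data.

`simulate_read_counts()` adds the sequencing layer where needed:
negative-binomial depth with variance three times the mean and a 1%
read error rate by default.

## Problem sizes and reproducibility

Simulation sizes in the test-suite and acceptance script are the
package's own desk-scale choices: null ensembles of 10–50k loci
(the `simulate_null()` default remains 100,000), 100 replicate outlier
scans at $L = 10{,}000$, per-SNP cline fits at a few thousand loci
(≈ 3 ms per locus), 200-replicate coverage checks with a few hundred
bootstrap resamples, and a reduced 2-chromosome genome for FWER
calibration. Every stochastic routine takes an explicit seed and
restores the caller's RNG state; `run_pipeline()` writes a checksum
manifest and identical configuration plus seed reproduces identical
checksums.

## Known limitations

* The MVN drift null is a moment approximation; near-boundary
  populations are handled by truncation rather than a bounded
  likelihood, so extreme low-ancestry outliers are conservatively
  under-produced by the null.
* NLS cline fits carry no parametric error model, so per-fit standard
  errors are not reported; uncertainty statements route through
  simulation or the bootstrap.
* The admixture-mapping threshold inherits the continuum approximation's
  conservatism at sparse marker spacing, and its absolute value depends
  on the supplied total map length.
* The two-stage admixture scan ignores uncertainty in local-ancestry
  dosages (MAP estimates are taken as observed).
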