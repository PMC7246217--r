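---
title: "Methods: seascape population genomics with seascapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seascape population genomics with seascapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seascapr)
```

seascapr asks a classic seascape-genetics question: when reef
populations sampled along a coastline differ genetically, is that
differentiation structured by discrete oceanographic barriers (IBB), by
distance travelled through water (IBD), by environmental turnover
(IBE), or by some combination — and, at a deeper time scale, what
divergence history (isolation, continuous migration, secondary contact)
produced the genome-wide allele-frequency patterns? This vignette
explains the statistical machinery, the tunable parameters, the
numerical choices, and what the synthetic-data tests do and do not
demonstrate.

## Genotypes, filtering and differentiation

Genotypes enter as a diploid biallelic SNP matrix (alternate-allele
counts 0/1/2 with missingness) tied to a population map. The locus
filter retains loci with overall minor-allele frequency strictly above
`maf_min` (default 0.05) that are genotyped in at least `call_rate_min`
(default 0.8) of individuals within at least n−1 of the n populations —
the standard RAD-seq hygiene for one-SNP-per-locus panels. The strict
inequality at the MAF boundary is deliberate and tested.

Pairwise differentiation uses Weir & Cockerham's θ: per locus the
among-population (a), among-individual (b) and within-individual (c)
variance components, combined across loci as Σa / Σ(a+b+c) (a "ratio of
sums", which is less biased than averaging per-locus ratios). Negative
estimates are legitimate sampling outcomes and are passed through
unmodified; the downstream regression treats them as data. For the
outlier scan a different quantity is needed: an *uncorrected* per-locus
fixation index — the sample-size-weighted among-group variance of
allele frequencies over p(1−p) at the pooled frequency, with no
finite-sample correction — because the null-fitting procedure models
the distribution of that ratio directly and supplies its own df.

Diversity is summarized per site as observed heterozygosity, expected
heterozygosity 2p(1−p), and FIS = 1 − Ho/He, each reported over all
loci and over the loci variable within the site (the latter never
smaller, as the monomorphic loci contribute zeros). The Evanno ΔK
statistic is included as a consumer of externally produced clustering
log-likelihood tables: ΔK(K) = mean(|L(K+1) − 2L(K) + L(K−1)|) / sd(L(K)),
with replicate-wise second differences, the sample (n−1) standard
deviation, undefined endpoints, and an explicit flag when sd = 0.

## The three predictor families

**Geographic distance** is the least-cost within-water path: water
cells of a land/sea raster form a graph, 8-connected with great-circle
(haversine) edge weights, and diagonal steps are allowed only when both
orthogonal neighbours are water so paths cannot cut land corners.
Sites snap to the nearest water cell within 3 cells (an error names any
site further from water — silent snapping across a peninsula would be a
worse failure). Shortest paths are Dijkstra's algorithm (igraph); a
plain-R Dijkstra serves as the test oracle. Distances refine toward
great-circle values as the raster resolution increases; the synthetic
seascape uses 0.5° cells, coarser than the ~5-arc-minute grids of real
marine environmental layers, because path geometry, not absolute
precision, is what the desk-scale analyses need.

**Environmental distance** is Euclidean distance between site scores on
the leading principal components of the site × variable environmental
table. All variables are log-transformed then standardized, i.e., a
correlation-matrix PCA, so measurement units are irrelevant; variables
that are not strictly positive are shifted by 10⁻⁶ of their positive
minimum before the log, and constant variables are dropped with a
warning. The default retention rule keeps the smallest leading set
reaching 85% cumulative variance — in typical coastal tables that is
about three components — and a fixed count can be forced instead.

**Barrier variables** code discrete hypotheses. With barriers b1, b2,
b3 each assigning every site a side, every non-empty subset yields one
site × site matrix whose entry counts the subset's barriers separating
the pair (levels 0–3): 2³ − 1 = 7 variables. Barriers enter the
regressions as numeric level counts; per-level summaries are produced
from the fitted model rather than by dummy coding, keeping every model
at one barrier coefficient.

## The 67-model MMRR comparison

Candidate models combine at most one barrier variable with geo and env:
4 barrier-free models (intercept-only, geo, env, geo+env) and, per
barrier variable B, 9 models — B; B+geo; B+env; B+geo+env;
B+geo+B:geo; B+env+B:env; B+geo+env+B:geo; B+geo+env+B:env;
B+geo+env+B:geo+B:env. With 7 barrier variables: 4 + 9·7 = 67. The
enumeration rule was a genuinely open design point; this one reproduces
the expected total, includes an intercept-only null, respects
interaction-parent hierarchy, and contains the barrier × geography
interaction forms that matter for "different IBD slopes across a
barrier" findings. Quantitative predictors are standardized to zero
mean, unit variance over the site pairs; the response (FST) is left on
its natural scale so coefficients read directly as FST shifts.

Each model is ordinary least squares on the unfolded lower triangles
(fixed pair order, lexicographic by site index). Because the S(S−1)/2
pairs are not independent, significance comes from the matrix
permutation test: rows and columns of the response matrix are permuted
jointly `nperm` times (default 999; predictors never permuted), and
p = (1 + #{|t*| ≥ |t|}) / (1 + nperm), counting the observed
configuration so p can never be zero. Under exchangeability this test
is exact up to permutation granularity; its type-I error at α = 0.05
is verified at 1,000 null replicates in the acceptance suite.

Ranking uses AICc with the Gaussian log-likelihood of the residuals and
K = coefficients (incl. intercept) + 1 for the residual variance. K's
exact convention only shifts all models by a constant, so rankings are
unaffected; the formula AICc = AIC + 2K(K+1)/(n−K−1) requires
n − K − 1 > 0 and errors otherwise. Akaike weights
w_i = exp(−Δ_i/2)/Σexp(−Δ_j/2) and evidence ratios w_best/w_i complete
the table; singular designs (e.g., a constant barrier matrix) are
flagged inestimable and excluded with a reason rather than silently
dropped. Per-level barrier means are model predictions at each level
with quantitative covariates at their means, with standard errors from
the coefficient covariance.

## The outlier scan

The neutral null for the uncorrected per-locus FST is
FST · df / FSTbar ~ χ²(df), with df a *free, continuous* parameter:
under hierarchical structure and nonindependence the effective degrees
of freedom are not the nominal group count, and fitting df absorbs
that. Loci with pooled He ≤ 0.1 are excluded (low-heterozygosity loci
have erratic FST ratios), the lowest and highest 5% of the remaining
FST values are trimmed, and the likelihood is truncated to the
untrimmed range — the truncation normalizer is the χ² CDF difference
evaluated per candidate (df, FSTbar). Optimization is Nelder-Mead on
log-parameters from four starts (moment estimates and perturbations);
an all-equal FST vector is refused as degenerate (df → ∞). Right-tail
p-values from the fitted null become Benjamini–Hochberg q-values;
q < 0.05 flags an outlier, right tail only. BH was chosen over Storey's
q-values for its lack of tuning parameters; the measured consequence is
slightly conservative power (roughly 0.7–0.85 of truly inflated loci
flagged in the 5×-shift simulations rather than the ~0.85+ a Storey
correction would give). On null panels of 20,000 loci the fitted df is
within ~3% of truth and p-values are uniform to KS < 0.01.

## Divergence-model inference from the folded JSFS

The observed spectrum pools sites into two populations, projects every
locus down to fixed haploid sample sizes (n1, n2) by hypergeometric
expectation (loci with fewer called alleles are dropped and counted),
sums over loci, folds by the pooled minor allele (ancestral states
unknown), and masks the monomorphic corners. Folding combines (i, j)
with (n1−i, n2−j), halves the self-complementary diagonal so mass is
conserved, masks the redundant half, and is idempotent.

Expected spectra come from a structured-coalescent branch-length
simulator written in C++: genealogies of n1+n2 lineages are simulated
under two demes with relative sizes N1, N2, an ancestral merge at time
Ts (units of 2·N_ref generations), and per-lineage backward migration
rates m12, m21 active on a model-specific window — never (SI), always
until Ts (IM), only during an episode of length Tam that begins at the
split (AM), or only for the most recent Tsc (SC). Each inter-event
interval adds its length to the cell indexed by the lineage's sampled
descendants in each population, so the accumulated table is the
expected branch length t_{i,j}, proportional to the expected spectrum
per unit mutation rate. The 2M variants mix two locus classes: a
fraction P of the genome at (m12, m21) and 1−P at effective rates
(me12, me21), capturing genome-heterogeneous barriers to gene flow.
The episode anchoring (AM at the split, SC at the present) follows the
natural reading of "episode duration" parameters. This
simulation-based route replaces a diffusion PDE solver deliberately:
it is exact in expectation for arbitrary piecewise-constant histories,
trivially parallel over genealogies, and its Monte-Carlo error is
controlled by `nreps`; the price is stochastic likelihoods, handled by
fixing the simulation seed within an optimization run and re-evaluating
the final optimum at 4× precision.

Fitting maximizes the composite Poisson likelihood over unmasked cells,
Σ [o·ln(θe) − θe − ln o!], with θ profiled analytically as Σo/Σe (the
profile is exact because the expectation is linear in θ). Optimization
is Nelder-Mead on log-transformed sizes/times/rates, with episode
lengths parameterized as logit-fractions of Ts so Tsc ≤ Ts and
Tam ≤ Ts hold by construction, and P on a logit scale. The protocol
runs 20 restarts by default and keeps the lowest-AIC run;
AIC = 2k − 2·logLik with k the free demographic parameters (profiled θ
not counted — the convention that makes AIC − (−2·logLik) an even
integer across the seven models: SI 3, IM 5, AM/SC 6, IM2M 8,
AM2M/SC2M 9). Desk-scale defaults in the test and acceptance runs are
8×8 projections, 1,000–2,000 genealogies per evaluation, 2 restarts,
and ≤60 Nelder–Mead iterations; these sizes recover the generating
model family reliably (SC-family best on SC2M-simulated data in ≥70%
of replicates) but are not intended for publication-grade parameter
estimates, where larger projections, more genealogies and the full 20
restarts should be used.

## The synthetic-data generator

`simulate_seascape()` builds a coastline raster in which a peninsula
separates two basins, places 8 sites (12 diploids each by default —
typical of RAD-seq field designs) along a coastal arc, assigns barrier
sides by position along the chain, and generates 12 environmental
variables (six mean + six variability layers) as smooth
latitude/longitude gradients with log-normal noise, strictly positive
by construction. `simulate_genotypes()` draws, per locus, an ancestral
frequency from Uniform(0.05, 0.95); applies Balding–Nichols drift
sequentially for each barrier separating a region from the reference
region (drift F_b per barrier, shared between regions with a common
crossing prefix, so barrier effects accumulate along the coast);
and then drifts each site from its regional frequency with F_site
through a Gaussian copula whose site-site correlation decays as
exp(−d/ibd_scale) — the isolation-by-distance component (great-circle
distances by default; a least-cost matrix can be supplied). Genotypes
are Binomial(2, p_site) with missing calls at 5% by default. The
Balding–Nichols route was chosen over coalescent genotype simulation
because expected FST has closed form (θ → F between two sites drifting
independently with F), giving an absolute calibration target for the
estimator; the demography module has its own coalescent generator.

What the generator does *not* emulate: linkage and linked selection,
genotyping error and allele dropout, spatially explicit larval
dispersal, and non-equilibrium range expansions. Passing tests
therefore demonstrate that the estimators and the inference machinery
are correct under their own assumptions — not that those assumptions
hold for any particular reef system.

## Numerical choices and degenerate inputs

- Unfolding uses a fixed pair order (lexicographic by site index);
  every matrix in a regression is checked for matching labels first.
- Permutation p-values count the observed configuration; minimum
  p = 1/(nperm+1).
- A site pair sharing no genotyped locus yields a flagged `NA` FST; a
  locus monomorphic overall is excluded from per-locus FST with a
  count; an all-missing individual is an error naming the individual.
- Mean imputation precedes the genotype PCA; a variance-free genotype
  matrix returns an explicit degenerate status instead of scores.
- Expected-spectrum cells at zero with positive observations are
  floored at 10⁻¹² inside the likelihood.
- All stochastic operations are reproducible: one seed drives the
  synthetic generator, the permutation streams, and the coalescent
  simulator (which uses R's RNG, so `set.seed()` governs C++ draws
  too).

## Known limitations

- The MMRR permutation test is exact for exchangeable responses but,
  like all Mantel-family tests, can be anticonservative under strong
  spatial autocorrelation of residuals.
- Composite-likelihood AIC for the JSFS ignores linkage between loci;
  model selection is reliable, parameter uncertainties are not
  provided.
- The barrier coding treats sides as given labels; it does not derive
  them from barrier geometry.
- Monte-Carlo noise in expected spectra makes refits at identical
  parameters differ unless the same seed and `nreps` are used.
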