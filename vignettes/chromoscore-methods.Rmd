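---
title: "Methods: chromothripsis scoring and its immune correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromothripsis scoring and its immune correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

Chromothripsis — the catastrophic shattering and re-ligation of one or a
few chromosomes — leaves two footprints that are visible in integer
copy-number (CN) segment profiles alone: breakpoints concentrated in a
confined region, and copy number oscillating regularly among a small
number of states. `chromoscore` implements, end to end:

1. a criteria-based **chromothripsis caller** on CN profiles;
2. a **copy-number signature** pipeline that turns six per-sample CN feature
   distributions into mixture-model categories, extracts signatures by
   non-negative decomposition, and maps signature exposures to a
   **chromothripsis probability score (CPS)** through a logistic GLM with
   cross-validated AUC;
3. **genomic covariates** (TMB, CNA burden, wGII, key-gene mutation
   frequencies);
4. **immune microenvironment scores** (ssGSEA, geometric-mean signature
   scores, cell-type and cytokine ratios, two-group pathway
   differentials);
5. **survival analysis** (median grouping, Kaplan–Meier/log-rank,
   univariate Cox, IPCW time-dependent AUC, RECIST-style response rates);
6. a **synthetic-data generator** that plants known ground truth for every
   stage.

# The chromothripsis caller

Dedicated callers exist for microarray and WGS rearrangement data, but
their decision rules are not reproducible from CN-only input. This
package instead defines an explicit caller over the two CN-visible
criteria, with every threshold surfaced in `ct_thresholds()`:

* **Clustering.** For each chromosome with at least `min_breakpoints`
  (default 10) breakpoints in some window of width `window` (default
  50 Mb), the probability of seeing a window count at least that large
  under uniform breakpoint placement is estimated by a Monte-Carlo scan
  statistic (`n_sim` = 2000 draws). The scan count is discrete, so null
  p-values are super-uniform (conservative); the per-chromosome
  false-flag rate is therefore at most `alpha` (default 0.05).
* **Oscillation.** Over the segments intersecting the densest window, the
  caller requires at most `max_states` (default 3) distinct CN values and
  an oscillation fraction of at least `min_osc` (default 0.5), where an
  interior segment oscillates when its CN differs from both neighbors and
  the neighbors agree.

Criteria that require haplotype phase, fragment-join order or SV
orientation are structurally unavailable from CN segments and are
deliberately not emulated; the caller documents this rather than
approximating them. The breakpoint minimum of 10 is consistent with
published minimums for confident calls; raising it can only shrink the
flagged set (a tested monotonicity property).

# Copy-number signatures and the CPS

Six per-sample feature distributions are extracted from filtered
profiles: segment size, absolute CN, CN change at breakpoints, breakpoint
count per chromosome arm, oscillating-chain length (maximal two-state
alternating runs of ≥ 3 segments), and breakpoint count per 10 Mb bin
(bins tiled from position 1; partial terminal bins kept; counts not
length-normalized). Arms and bins without breakpoints contribute no
events, so a quiet genome produces a nearly empty feature set — which is
itself informative downstream. Profiles are first preprocessed by
dropping the X chromosome (and, on real data, immunoglobulin loci, which
rearrange somatically in normal B cells) and reverting CN changes shorter
than 50 kb; "change" is measured against the sample's length-weighted
median ploidy computed before filtering, and reversion/merging is
iterated to a fixed point so the filter is idempotent.

Each feature is categorized by univariate Gaussian mixtures (equal- and
free-variance families, BIC selection over 2..6 components; segment size
on log10 scale because it spans orders of magnitude; EM initialized on a
seeded 2000-point subsample when features are large). The samples ×
categories count matrix is decomposed by multiplicative-update NMF under
generalized Kullback–Leibler divergence, restarted from seeded random
initializations with the best objective kept. KL-NMF is used as a
deterministic, seedable extraction engine with the same input/output
contract as hierarchical Dirichlet process samplers: non-negative
signatures on the category simplex with non-negative per-sample
exposures. K defaults to 3 on synthetic cohorts (the planted structure is
low-rank); `K = "auto"` selects K at the elbow of the reconstruction
error.

The CPS is the fitted probability of a logistic GLM of chromothripsis
labels on signature exposures. Two details matter:

* **Exposure consistency.** After extraction, training exposures are
  recomputed by non-negative least squares against the frozen signatures —
  the same operation used at scoring time — so scoring a training sample
  reproduces its in-sample fitted probability exactly.
* **Separation.** Synthetic cohorts separate almost perfectly, where the
  unpenalized GLM diverges; the fit falls back to an L2-penalized
  (ridge, lambda = 0.01) fit and records the penalty in the model file.
  Raw (unnormalized) exposures enter the GLM.

The reported AUC is from stratified k-fold cross-validation (default 10),
with fold assignment keyed on sorted sample names so it is invariant to
the order samples arrive in. Models persist as a single JSON file
(registry, mixture parameters, signatures, GLM coefficients, seed) at
full precision, so a reload scores identically.

# Genomic covariates

* **Variant filter.** Confidence (coverage ≥ 5 **or** allele fraction
  > 0.05 — the disjunction is kept as such deliberately, although a
  conjunction might look more natural), nonsilent classification
  (missense, nonsense, frameshift, splice site), and rarity (< 0.005 in
  every supplied population-frequency column).
* **TMB** = qualifying mutations per Mb of assayed territory (default
  30 Mb, configurable).
* **CNA burden** counts genes overlapping (≥ 1 bp) any segment above or
  below ploidy, via IRanges interval overlap; each gene counts once per
  direction.
* **Ploidy** is the length-weighted median integer CN over autosomes;
  exact half-weight ties take the lower value (deterministic and
  conservative).
* **wGII** is the unweighted mean over covered autosomes of the fraction
  of covered bases at CN ≠ ploidy. Only covered bases enter the
  denominator so sparse profiles are not penalized.

Fisher tests on the key-gene panel are two-sided and reported raw, with
BH q-values alongside for transparency.

# Immune scoring

ssGSEA ranks genes per sample (descending, gene-name tie-break for
determinism) and integrates the difference between the weighted in-set
ECDF (weights `|rank|^0.25`) and the unweighted out-of-set ECDF; scores
are normalized by the range of the running statistic so they are
comparable across samples. Because enrichment scores can be negative,
cell-type **ratios** (CD8/Treg, CD8/TAM, CD8/MDSC) are taken on
geometric-mean scores instead (pseudocount 1 on linear scale), which are
strictly positive and scale-equivariant, so ratios are invariant to
global multiplicative normalization. The cytokine ratio is
`log2(gm(IFNG, IL1A, IL1B, IL2) / gm(IL4, IL10, IL11, TGFB1))`.

Pathway activity differences between groups are summarized by Welch t
statistics on ssGSEA scores (positive = higher without chromothripsis)
with BH adjustment. This substitutes for kernel-CDF pathway variance
analysis: the scientific contract — the direction and strength of
group-level pathway enrichment — is unchanged, while the statistic is
simpler and exactly testable. The "total infiltration score" is the mean
over the 28 cell-type sets (configurable to the sum; the mean is used so
the score does not scale with the number of panels supplied).

Gene-set contents are **not** hard-coded: cell-type panels, pathway sets
and ICB-responsiveness signatures are consumed as GMT files; the
synthetic generator emits placeholder panels with the canonical set names.

# Survival analysis

Biomarkers are dichotomized at the cohort median (strictly greater =
high; ties go low, so the high group is never inflated by a heavy median
mass). Cox fits use Efron tie handling (Breslow available) on the binary
indicator by default — comparable across biomarkers — with continuous
fits exposed. The time-dependent AUC uses the
inverse-probability-of-censoring-weighted cumulative-case /
dynamic-control estimator with weights from the left-continuous
Kaplan–Meier estimate of the censoring distribution; without censoring it
reduces exactly to pairwise concordance, which is how it is tested.
Months are the canonical time unit. Responders are CR, PR, or SD
sustained ≥ 6 months; objective responders are CR or PR; SD records
without a duration are excluded from the responder comparison with a
warning.

# The synthetic generator

The generator's defaults are the package's study conditions: cohorts of
200 samples (400 for the score model), half carrying one planted event;
diploid baseline on a compact nine-chromosome genome; planted events of
20 breakpoints oscillating deterministically between two CN states within
a 40 Mb region (deterministic alternation makes the oscillation criterion
unambiguous in ground truth; the breakpoint count must be even so the
region closes back to baseline and the planted breakpoints are exactly
the configured number); background CNAs as ±1-copy single segments of
1–10 Mb at 0.01 events/Mb — the simplest null that still exercises the
50 kb filter and the clustering test. Expression carries a +2 log2-unit
shift on cytotoxic-set and proinflammatory-cytokine genes in samples
*without* chromothripsis, reproducing the direction of reduced cytotoxic
infiltration with chromothripsis; survival times are exponential under a
proportional-hazards model with log HR log(1.9) per standardized CPS,
24-month baseline median, independent exponential censoring calibrated to
20%, and a logistic response model with a 35% responder base rate
(a plausible ICB response rate; the tests only need a fixed value).
Effect sizes for the immune contrasts are free parameters of the
generator, not estimates of any real cohort.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: allele-specific CN, tumor purity and
subclonality, read-level noise, segmentation error, correlated
background CNAs, and real gene-set biology. Closure results (detector
sensitivity/specificity, CPS AUC) are statements about the generator's
conditions, not about any published cohort.

# Numerical choices and problem sizes

Monte-Carlo scan tests use 2000 null draws and are only run where they
can change a call (chromosomes reaching the breakpoint minimum). KL-NMF
runs 10 restarts, up to 2000 iterations, relative tolerance 1e-9.
Mixture EM runs on all events with subsampled initialization beyond 2000
points. Exposures at scoring time come from `pracma::lsqnonneg`. The
test suite exercises cohorts of 40–400 samples, 500-replicate Cox
calibration, a 1000-replicate log-rank size check, and 100-trial oracle
sweeps for ssGSEA, CNA burden, AUC(t) and Fisher p-values; these sizes
make each check statistically meaningful while keeping a full run on one
CPU within a coffee break. All randomness descends from a single root
seed through fixed substreams; reruns are byte-identical.

# Known limitations

* The caller sees only criteria A–B; chromoplexy or breakage-fusion-bridge
  events with clustered oscillating CN profiles would be indistinguishable.
* CN-signature categories are cohort-dependent; scoring new samples uses
  the frozen training mixtures and will error on a registry mismatch
  rather than silently re-deriving categories.
* The Wald CI of the univariate Cox fit and the log-rank test assume
  proportional hazards, which the generator satisfies by construction.
* Cohort-level chromothripsis prevalence depends on caller thresholds and
  is not a calibrated estimate of prevalence in any tumor type.
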