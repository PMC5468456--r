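---
title: "Methods: functional-gene biogeography along an elevation gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional-gene biogeography along an elevation gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, and the choices made where the
methodology left room.

## 1. Signal preprocessing

A GeoChip experiment yields, per probe and sample, a fluorescence intensity
and a signal-to-noise ratio (SNR).  The chain is fixed and order-enforced:

1. **SNR filter** — spots with SNR strictly below 2.0 are set undetected,
   per spot and per sample.  The threshold is an argument (`snr_min`) but
   2.0 is the conventional array cutoff.
2. **Replicate-singleton filter** — within each elevation's replicate group,
   a probe detected in exactly one replicate is set undetected *in that
   replicate*.  We deliberately do not delete the probe row globally:
   detections at other elevations are real data and the filter is a
   within-group reproducibility screen.  Groups need at least two
   replicates, otherwise the filter is undefined and the run errors.
3. **Total-signal normalization** — each detected spot is divided by its
   sample's total detected signal and multiplied by one shared constant.
   The constant defaults to the mean of the per-sample totals
   (`constant_rule = "mean_total"`), which keeps values near the raw scale;
   a fixed constant is available.  Post-normalization totals agree across
   samples to a relative 1e-9.
4. **Natural logarithm** — `ln(x + 1)` by default (`offset = "plus1"`),
   uniformly, so values below 1 cannot produce negative abundances that
   would distort similarity and ordination; plain `ln` with a
   positivity guard is available.  The offset rule is recorded in the
   output provenance along with per-step removal counts.

Presence/absence for all downstream set-based statistics comes from the
detection matrix (SNR pass AND replicate support), never from thresholding
log abundances: "a gene detected" means a probe that survived the filters.
A probe counts as present at an elevation if it is detected in at least one
retained replicate there.

Diversity indices and Bray–Curtis distances are computed on the *pre-log*
normalized proportions (they are then invariant to the shared constant);
ordination uses the ln-transformed values.  Both matrices travel in the
`geochip_abund` container, so the choice is explicit and revisable.

## 2. The elevation-decay relationship

For every unordered sample pair we compute Sorensen similarity
`S = 2|A∩B|/(|A|+|B|)` and the elevation difference `D` in metres.
Same-elevation pairs have `D = 0` and are substituted by `D = 0.01` before
taking logarithms; the substitution applies only to exact zeros and is
flagged per pair.  The decay model `log S = c − 2 z log D` is fitted by
ordinary least squares; `z = −slope/2`.  Numerical notes:

* the slope, `z` and the log–log correlation `r` are invariant to the
  logarithm base; base 10 is the default and only the intercept depends on
  it;
* zero-similarity pairs cannot enter a log fit; they are excluded and
  counted in the fit object (`n_zero_dropped`) — exclusion is the only
  log-consistent option;
* a pair table whose distances are all equal is a degenerate regression and
  errors rather than returning a meaningless slope.

Because the `C(n,2)` pairs share samples, they are not independent;
inference uses a row bootstrap (resampling pairs with replacement, 999
replicates by default, deterministic under a seed).  Two assessments are
reported side by side, because both readings of the procedure are
defensible: the bootstrap slope distribution against **zero** (percentile
interval and an add-one two-sided p-value) and a one-sample t-test of the
bootstrap slopes against the **observed** slope.  Degenerate bootstrap
replicates are redrawn with a hard cap and a logged count.  On noiseless
input every bootstrap slope equals the observed slope; the t statistic is
then reported as 0 with p = 1.

The 12 substituted pairs sit far to the left of the real distances on the
log axis (log10 0.01 = −2 versus 2.3–2.8) and therefore dominate the fitted
slope.  `edr_sensitivity()` refits `z` over a grid of substitution values so
every report can expose this dependence; moving the substituted distance
toward the real distances compresses the log-distance axis and steepens the
fitted slope.

Per-category fits restrict the probe universe to one functional category
before presence sets are formed; p-values are BH-adjusted across the family,
and per-category failures (an empty category, say) are flagged rows rather
than aborts.

## 3. The synthetic-data generator

The generator is first-class code: it defines the study conditions every
recovery test runs under.  Its default design is a four-elevation transect
(3200/3400/3600/3800 m asl) with biological triplicates and 5,000 probes in
nine functional categories.

**Occupancy model.**  Each probe is either a regional generalist (present at
every elevation) or carries a triangular elevation niche of random width;
niche widths follow a small mixture distribution.  An elevation-level
thinning layer (probability `ell`) and a regional-pool indicator
(probability `g`) sit on top.  Replicate-level detection is independent with
probability `d = (1 − replicate_dropout) · P(SNR ≥ 2)`, and a
`singleton_rate` fraction of probe-by-elevation detections is planted in
exactly one replicate, which the replicate filter then removes — so the
filter has real work in every run and its effect is part of the calibration.

The width mixture, `ell` and `g` are not free knobs: they are solved exactly
so that the *expected post-preprocessing* Sorensen similarity of sample
pairs lies on the target power-law line at every pairwise distance.  The
solve decomposes the required convex similarity-versus-distance profile into
a hinge basis (one triangular niche kernel per slope change, plus an
everywhere-present atom) — mixture weights are just the slope changes of the
piecewise-linear interpolant, so the calibration is closed-form and exact.
A single niche bandwidth cannot do this: one width gives a linear, not
power-law, decay and cannot hit three target distances at once, which is why
the mixture exists.

**Anchoring.**  The replicate filter couples same-elevation samples: if two
replicates both detect a spot they rescue each other, so the expected
within-elevation similarity is `1/(2 − d)` for triplicates — always above
any attainable between-elevation similarity.  Under the default
(`anchor = "auto"`, resolving to `"within"` when feasible) the decay line is
anchored *at* that within-elevation point at `D = 0.01`, so the full
pipeline — including the influential substituted pairs — sees expectations
exactly on the line and the fitted exponent is unbiased.  This anchoring is
infeasible for very small true exponents (the line would demand
between-elevation similarity above its structural ceiling); `true_z = 0` in
particular cannot be realised through the replicate filter.  The generator
then falls back to anchoring at a reference between-elevation similarity
(`sorensen_ref` at the smallest nonzero distance): between-elevation
expectations are exactly equal, while the within-elevation point sits above
the line, which is the honest structural picture.  For the type-I-error
study of the bootstrap test, the null is therefore simulated at the pair
table level (iid log-similarity noise with no distance dependence on the
12-sample pair design), which is the direct input type of the statistic
under test.

**Intensities.**  Detected spots draw log-normal intensities around
`signal_mu`; probes belong to latent co-abundance modules (25 by default)
whose per-sample factors partly track the elevation gradient
(`module_sd = 1.2` on the log scale against a residual `signal_sigma =
0.6`).  This is what gives Spearman co-occurrence networks modular structure
and gives category abundances genuine environmental correlations.  SNR for
real spots is log-normal (`snr_shape`, about 1% naturally below 2.0);
missed and absent spots carry sub-threshold SNR and faint background signal.

**Sample sheet.**  Per-elevation means of the environmental covariates
follow smooth configured trends (temperature and pH strictly decreasing;
moisture, nitrate and deep total nitrogen increasing; several hump-shaped
variables), with replicate-level Gaussian noise (`env_noise = 0` puts
replicates exactly on the trend lines).  Greenhouse-gas fluxes are missing
at the third elevation by default, to exercise pairwise-complete handling.
Soil inorganic nitrogen is the sum of the nitrate and ammonium columns.

**What it does not emulate.**  No hybridisation physics, cross-
hybridisation, dye chemistry or scanner behaviour; no spatial autocorrelation
beyond the elevation axis; no phylogenetic structure among probes; the
within-elevation replicate similarity is a parameter, not an estimate from
any dataset.  Passing recovery tests therefore demonstrates correctness of
the estimators under this generative model, not robustness to every artefact
of real arrays.

## 4. Environment linkage

Mantel tests, PERMANOVA (adonis-style), CCA and the distance computations
are delegated to vegan; the module contributes the missing-data policy, the
single-variable environmental distances (Euclidean on the standardized
column), star thresholds (0.05/0.01/0.001 — conventional, since the
underlying tables rarely state them) and the variation partitioning.
Variables with missing values are handled by pairwise-complete deletion with
the reduced `n` reported; the community distance matrix is subset to the
same samples so the matrices stay aligned.

VIF screening iteratively removes the variable with the highest variance
inflation factor (`1/(1 − R²)` against the other candidates) until all fall
below 20; perfect collinearity surfaces as infinite VIF and is dropped
first, and the drop order is logged.

Variation partitioning takes three disjoint variable groups (the default
grouping — climate/pH, soil chemistry, vegetation — is a package convention,
not a claim about any dataset) and computes the seven pure/shared components
by inclusion–exclusion over constrained-ordination explained-inertia
fractions of every nonempty group union.  The components sum to the
full-model fraction by construction (asserted to 1e-8); small negative
shared components are legitimate, as in any variation partitioning.

## 5. The co-occurrence network

Networks are built on a user-selected probe subset (category filter,
prevalence floor, top-N by abundance), since the probe count far exceeds the
sample count.  The similarity matrix is `|Spearman rho|` with mid-ranked
ties and pairwise-complete observations; constant nodes are dropped with a
warning; environmental variables may enter as distinctly labelled nodes.

The threshold is chosen by the random-matrix-theory transition: scanning an
ascending grid, zeroing sub-threshold entries, and testing the unfolded
eigenvalue nearest-neighbour spacing distribution (NNSD).  The chosen
threshold is the smallest at which a chi-squared goodness-of-fit test (on
equal-probability bins) stops rejecting the Poisson form while still
rejecting the GOE/Wigner form, and which sustains that state for two
consecutive grid points (the persistence guard absorbs isolated
goodness-of-fit flukes).  Numerical choices: the spectrum is unfolded with a
smoothing-spline fit of the cumulative spectral density (df 10) after
trimming the top 10% of eigenvalues, which are Perron/global modes that
distort any smooth density fit; spacings are normalized to mean 1; at least
30 connected nodes and 15 usable spacings are required; degenerate spectra
(an identity-like matrix) raise a typed error, and a scan with no qualifying
threshold raises a no-transition error that carries the full scan trace.
The exact transition criterion of published RMT network pipelines is not
restated in the literature this module follows; the chi-squared-vs-Poisson
rule here is a documented stand-in with the same intent, not a claim about
any original implementation.

Topology diagnostics: OLS power-law fit of the degree distribution on
log–log axes (log-binned above 200 nodes, degree-0 nodes excluded), average
shortest path on the largest connected component (with the component
coverage reported), greedy-agglomerative modularity, and the average local
clustering coefficient with degree-deficient nodes counted as zero.

## 6. Problem sizes and determinism

The test suite runs everything at desk scale, chosen so the full suite stays
well inside a coffee break on one CPU: recovery studies use the full
5,000-probe design over 20 seeds per true exponent; calibration studies use
200–400 simulations; module unit tests use toy fixtures of tens of probes.
The acceptance script simulates one full default study plus a 30-run
recovery study and a 200-run null study.  Every stochastic step — generation,
bootstrap, permutation tests, network scans — takes an explicit integer seed
and is bit-reproducible given it; the pipeline serializes its configuration
(seeds included) next to its outputs.

## 7. Known limitations

* Deposited GeoChip exports usually contain already-filtered intensities
  without SNR columns; the loader reproduces the deposited detection
  pattern by assigning passing SNR to present cells, so the SNR filter
  cannot be re-applied to such data, only inherited from it.
* The decay exponent estimate is dominated by the within/between similarity
  contrast via the substituted pairs; treat `z` comparisons across studies
  that used different substitution constants with care, and look at the
  sensitivity diagnostic.
* Simpson's index and "evenness" each have several variants in common use;
  the defaults (Gini–Simpson, Pielou) are stated in the function signatures
  and the alternatives are offered, because the source tables for such
  analyses rarely say which was used.
* With 12 samples, Spearman correlations are coarse (granularity ~0.1);
  network results on real designs of this size are qualitative.
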