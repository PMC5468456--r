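# geochipr

Functional-gene biogeography from GeoChip microarray signals, in R.

## The problem

GeoChip is a functional gene microarray: each probe targets a gene involved in
biogeochemical cycling (carbon degradation and fixation, methane cycling,
nitrogen transformations, stress response, metal resistance, ...), and a
hybridised soil sample yields one fluorescence intensity plus a
signal-to-noise ratio (SNR) per probe.  Along an environmental gradient —
here, an alpine-pasture elevation transect with several biological replicates
per site — the questions are:

* How does the functional diversity of the soil community change along the
  gradient?
* How fast does community similarity decay with elevation difference
  (the elevation-decay relationship), and does the decay differ among
  functional categories?
* Which genes are ubiquitous across all elevations, which are unique to one,
  and how does gene sharing fall off with distance?
* Which environmental variables covary with community structure, and how much
  community variation do they jointly explain?
* What does the gene co-occurrence network look like, and how do we pick its
  similarity threshold without choosing it by eye?

`geochipr` implements that full analysis as a tested pipeline, together with
a calibrated synthetic-data generator so every stage can be exercised against
known ground truth without any external download.

## The core statistic

Community similarity between two samples is Sorensen's index on
post-preprocessing presence/absence,

    S_S = 2 |A ∩ B| / (|A| + |B|),

and the elevation-decay relationship (EDR) is the power law

    log(S_S) = constant − 2 z · log(D),

with `D` the elevation difference in metres (same-elevation pairs, `D = 0`,
are substituted by `D = 0.01` so the logarithm is defined) and `z` the decay
exponent, estimated as `−slope/2` of the ordinary least-squares log–log fit.
Because sample pairs are not independent, inference uses a bootstrap over
pair rows (999 replicates): the bootstrap slope distribution is assessed
against zero, and a one-sample t-test compares bootstrap slopes with the
observed slope.  Per-category exponents are fitted the same way and their
p-values adjusted by Benjamini–Hochberg.

Around this sit the standard stages: the four-step GeoChip signal chain
(SNR < 2 spot removal, removal of spots detected in only one of the
replicates of an elevation, total-signal normalization with a shared
constant, natural-log transform), Shannon/Simpson/Pielou diversity,
ubiquitous/unique gene accounting, Mantel tests and PERMANOVA against
environmental variables, VIF-screened canonical correspondence analysis with
three-group variation partitioning, and random-matrix-theory (RMT)
threshold selection for the Spearman co-occurrence network (the threshold is
placed where the eigenvalue nearest-neighbour spacing distribution switches
from the Gaussian-orthogonal-ensemble form to the Poisson form).

## Worked example

```r
library(geochipr)

design <- synthetic_design(true_z = 0.01, n_probes = 5000, rng_seed = 42)
sim    <- simulate_geochip(design)           # truth + signals + sample sheet
abund  <- preprocess_geochip(sim$signals, sim$samples)
abund
#> <geochip_abund>: 5000 probes x 12 samples
#>   detected spots : 17579
#>   normalization  : 7089748 (shared constant)
#>   log offset     : plus1
#>    filter_snr : removed 41911 spots
#>    filter_replicate_singletons : removed 510 spots

edr(abund, n_boot = 999, seed = 7)
#> <edr_fit>  log(S) = constant - 2 z log(D)
#>   z = 0.0106   r = -0.997   n_pairs = 66 (zero-similarity dropped: 0)
#>   bootstrap (n = 999): slope CI [-0.02136, -0.02085], p(slope = 0) = 0.002
#>   one-sample t vs observed slope: t = 0.000644, p = 0.999

glance(classify_overlap(abund))
#> # A tibble: 1 × 6
#>   union_detected ubiquitous ubiquitous_fraction unique_total unique_fraction
#>            <int>      <int>               <dbl>        <int>           <dbl>
#> 1           2024        850               0.420          128          0.0632
```

Reading this: the generator planted a true decay exponent of `z = 0.01`; the
fitted exponent on the preprocessed data is `0.0106` with an almost perfectly
linear log–log relationship (`r = −0.997`).  The bootstrap slope interval
excludes zero, so the decay is significant.  Of the 2,024 probes detected
anywhere, 42% are present at all four elevations and 6% at exactly one.

The same analysis runs from one configuration:

```r
report <- run_pipeline(list(synthetic = list(true_z = 0.01, rng_seed = 42),
                            out_dir = "run1"))
```

which writes the abundance matrix, diversity table, decay fits, overlap
accounting, Mantel/PERMANOVA/CCA/VPA tables and the thresholded network
(edge list, GraphML, topology report) as TSV/JSON under `run1/`.  A thin
command-line wrapper lives in `inst/scripts/geochip-pipeline.R`.

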