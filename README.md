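# callscape

Where does identity information live in a learned vocalization? Parrots and
other open-ended vocal learners use short contact calls that can be
individually distinctive (an individual vocal signature), shared within a
nesting site, or shared across a whole region (a vocal dialect).
`callscape` quantifies this **hierarchical mapping**: the profile of
relative acoustic convergence across nested social scales, used to infer
which scale carries the most salient identity information. It is aimed at
bioacousticians analysing repeatedly sampled individuals and site surveys
of unmarked birds, and at methodologists who want the whole inference chain
testable against synthetic populations with known ground truth.

## What it computes

**Similarity.** Two complementary pairwise call-similarity measures:

- *Spectrographic cross-correlation (SPCC)*: spectrograms (Hanning window,
  378 samples, 90% overlap, 0.5–9 kHz bandpass) slide along each other in
  single-frame steps; the similarity is `max_lag r(lag)` (Pearson, floored
  at 0), computed in C++.
- *Random-forest proximity*: a forest trained to classify calls back to
  repeatedly sampled individuals (features: spectral statistics, MFCC
  descriptive statistics, spectrogram texture, and SPCC/DTW embedding
  coordinates); `proximity(i, j)` = fraction of trees where calls *i* and
  *j* share a terminal node.

**Convergence.** For a similarity matrix `S` and a social scale with
categories `c(·)`, pairwise values split into *within* (`c(i) = c(j)`) and
*among* (`c(i) ≠ c(j)`) sets. Convergence at the scale is the histogram
Earth Mover's Distance between the two distributions on `[0, 1]`
(16 bins),

```
EMD = sum_k |CDF_within(k) − CDF_among(k)| × bin width,
```

computed under a balanced resampling routine (100 iterations, 4 categories
× 100 values per class per iteration) so scales with very different pair
counts are comparable. Larger EMD = stronger convergence. Bootstrap
similarity ratios (5 within / 5 among values per iteration, 200
iterations, 1000 ratios) and Mantel permutation tests support the same
comparisons. Gaussian-mixture duplicate filtering flags likely repeated
sampling of unmarked birds, and non-metric MDS embeds calls into acoustic
space for visual diagnostics.

**Ground truth.** A synthetic call generator plants convergence causally:
each bird's frequency-contour template is a weighted blend of an
individual-unique perturbation, its site template, and its region template,
so the scale that should win is known by construction and every stage is
testable as parameter recovery.

## Worked example

Simulate a population with strong individual signatures and no site-level
convergence, run the full pipeline (QC → SPCC → duplicate filtering →
EMD/ratios/Mantel at each scale), and read off the winning scale:

```r
library(callscape)

cfg <- experiment_config(
  population = population_config(
    n_sites_per_region = 3, n_individuals_per_site = 5,
    calls_per_individual = c(4, 5), signature_strength = 800,
    call_jitter = 100, duration_range = c(0.1, 0.25),
    sample_rate = 22050, seed = 31
  ),
  methods = "spcc", n_iter = 30, n_categories = 3, n_per_class = 12,
  ratio_iter = 50, mantel_perm = 99, seed = 7
)
report <- run_experiment(cfg)
report$results
#> # A tibble: 3 × 9
#>   scale      method variant   n_calls emd_mean emd_ci_low emd_ci_high ratio_mean
#>   <chr>      <chr>  <chr>       <int>    <dbl>      <dbl>       <dbl>      <dbl>
#> 1 individual SPCC   full           69   0.451      0.371       0.555        2.78
#> 2 site       SPCC   full           15   0.0483     0.0142      0.0943       1.32
#> 3 site       SPCC   clusteri…      14   0.0451     0.0208      0.0853       1.21
report$winning
#> # A tibble: 2 × 5
#>   group     method variant             winning_scale emd_scale_ratio
#>   <chr>     <chr>  <chr>               <chr>                   <dbl>
#> 1 synthetic SPCC   clustering-filtered individual               9.98
#> 2 synthetic SPCC   full                individual               9.33
```

The report says: within-individual calls are far more similar than
among-individual calls (mean EMD 0.451), while within-site similarity is
barely distinguishable from among-site similarity (mean EMD ≈ 0.05, about
an order of magnitude lower) — the planted individual-signature structure,
recovered. The same conclusion holds on the duplicate-filtered site
dataset, and the bootstrap ratio (2.78 at the individual scale vs ≈ 1.2–1.3
at the site scale) and Mantel tests agree. `plot_convergence_profile(report)`
draws the profile; `autoplot(nmds_embed(...))` shows calls in acoustic
space.

Lower-level functions expose every stage: `generate_population()`,
`qc_filter()`, `spcc_matrix()`, `call_feature_table()`,
`train_individual_classifier()`, `proximity_matrix()`,
`partition_similarities()`, `histogram_emd()`, `emd_convergence()`,
`bootstrap_similarity_ratio()`, `mantel_test()`, `flag_repeats()`,
`filter_dataset()`, `nmds_embed()`, `hull_metrics()`. Results tidy into
tibbles with `tidy()`/`glance()`. A thin command-line wrapper lives in
`inst/cli/callscape.R` (`simulate`, `run`, `converge` subcommands). The
methods vignette (`vignettes/hierarchical-mapping.Rmd`) documents the
models, parameter choices and limitations.

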