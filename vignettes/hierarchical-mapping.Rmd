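---
title: "Hierarchical mapping of identity information in contact calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical mapping of identity information in contact calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(callscape)
```

Many parrots and other open-ended vocal learners use short, learned contact
calls to mediate social life. The information a call carries can sit at
different levels of social organization: a call can be individually
distinctive (an individual vocal signature), shared within a nesting site,
or shared across a whole region (a vocal dialect). `callscape` implements a
*hierarchical mapping* analysis: it measures pairwise call similarity,
quantifies the strength of acoustic convergence at each nested social scale
(individual, site, region), and identifies the scale at which identity
information is most strongly encoded.

This vignette explains the models and procedures, the parameters that
matter, what the synthetic call generator does and does not emulate, and
the numerical choices made where the underlying methods literature leaves
the design open.

## The analysis in one paragraph

Calls pass a signal-to-noise quality filter, then enter two complementary
similarity measurements: spectrographic cross-correlation (SPCC), an
unsupervised method that slides one spectrogram along another and records
the best Pearson correlation, and random-forest proximity, a supervised
method in which a forest trained to classify repeatedly sampled individuals
judges two calls similar when they co-occur in terminal nodes. Pairwise
similarity values are then partitioned, at each social scale, into
within-category and among-category sets; the separation between the two
distributions is summarized by a histogram-based Earth Mover's Distance
(EMD) under a balanced resampling routine, supported by bootstrap
similarity ratios and Mantel permutation tests. The scale with the largest
mean EMD carries the most salient identity information.

## Quality control

The SNR of a selected call is the linear RMS ratio between the call extent
and flanking noise-only margins (0.1 s per side by default; both sides
averaged when available). Calls with SNR below 7 — i.e., less than 7 times
louder than background noise — are rejected; the boundary itself is
retained. The ratio is reported on the linear scale because the cut-off is
naturally phrased that way; `snr_to_db()` converts for reporting. Rejection
of calls overlapped by other loud sounds is not automated: it is a manual
judgement, represented as an `overlap_flag` metadata column that
`qc_filter()` honors.

## Spectrograms and SPCC

Spectrograms use a Hanning window of 378 samples with 90% window overlap
(hop 38 samples) and a 0.5–9 kHz bandpass; magnitudes are dB re the
spectrogram peak, floored at −60 dB so silent cells cannot dominate the
correlation. Two conventions circulate for "an overlap of 90": a
percentage and a literal sample count. The default here is 90% (the
convention of the spectrogram tooling this parameterization comes from),
with `overlap_samples = 90` available as a switch; every spectrogram
records its parameters so the choice is auditable.

`spcc_pair()` slides the shorter spectrogram along the longer in
single-frame steps, computing Pearson's correlation over co-occurring
cells at each lag, and returns the maximum over lags floored at 0 so
similarity lives in `[0, 1]` (the domain the EMD statistic assumes). Only
lags where the shorter spectrogram fully overlaps the longer are scored:
partial-overlap lags correlate very few cells and are high-variance. A
zero-variance window scores 0 at that lag (the correlation is undefined
there, and such a window carries no signal). Correlations are computed on
dB magnitudes; whether the original SPCC literature correlated linear or
log magnitudes is not stated, and dB is the stabler choice against
silent-cell dominance.

One subtlety of full-overlap scoring: appending silence to a call leaves
its similarities essentially unchanged (the aligned lag is still scored)
*as long as the padded call remains the longer member of its pairs*. If
padding flips which call is shorter, the scored lag set changes and
similarities can move by a few hundredths. The test suite pins the
invariance in the form in which it holds.

## The acoustic feature table and random-forest similarity

Each call contributes: duration; aggregate-spectrum statistics (peak,
mean, median frequency, frequency quartiles, IQR, spectral entropy);
dominant-frequency contour summaries (mean, extremes, range,
least-squares slope, modulation index); spectrogram texture statistics
(energy moments and contrast of the dB matrix), which stand in for the
image-analysis features sometimes used in this literature; per-coefficient
descriptive statistics (mean, variance, skewness, kurtosis) of 12
mel-frequency cepstral coefficients and their first differences, with the
0th coefficient dropped so the cepstral features are exactly invariant to
recording level; and 2-D embedding coordinates of the SPCC similarity
matrix and of a dynamic-time-warping (DTW) distance matrix over
dominant-frequency contours.

The embedding coordinates matter more than they may look: nMDS coordinates
are only defined up to rotation within one embedding, so the feature table
must be assembled **jointly** over every call that will ever be pushed
through the forest (training, validation, and site-scale calls), exactly
as the SPCC matrix is computed over all calls at once. `run_experiment()`
does this; if you assemble tables manually, embed once and subset rows.

Feature selection is a shadow-feature procedure: each round appends a
permuted copy of every feature, fits a forest, and scores a hit for every
real feature whose impurity importance exceeds the maximum shadow
importance; features with significantly more hits than a fair coin
(one-sided binomial, 5%) over 20 rounds are retained. If nothing survives
— the expected outcome under shuffled labels — the procedure warns and
falls back to the top features by mean importance rather than failing.

The classifier is a 500-tree random forest (`ranger`), `sqrt(p)` features
per split. Training accuracy is reported from out-of-bag predictions with
an exact binomial (Clopper–Pearson) 95% CI: in-sample accuracy of a random
forest is degenerately near 100% and would overstate performance, and the
resampling scheme behind published training accuracies of this kind is
rarely printed. Per-class balanced accuracy (mean of sensitivity and
specificity) is reported alongside. Proximity between two calls is the
fraction of trees in which they share a terminal node, computed from
terminal-node ids of the persisted model so that validation and site-scale
calls are scored by the same final forest. Validation clusters held-out
individuals (never seen in training; the id sets are asserted disjoint) by
Gaussian mixtures on a 2-D embedding of their proximity matrix, components
selected by BIC between 1 and the number of individuals plus 2, agreement
reported as the adjusted Rand index.

## Acoustic space

`nmds_embed()` converts similarity to dissimilarity (`1 − s`; `sqrt(1−s)`
exposed as an alternative) and minimizes Kruskal stress-1 with
`vegan::monoMDS` over a metric-scaling start plus 20 random restarts,
keeping the best solution. Duplicate calls (zero dissimilarity) are
collapsed before embedding and re-expanded afterwards so they land on
coincident coordinates. Restart initializations are drawn for calls in
sorted-id order, which makes the search — and therefore the embedding, up
to rigid motion — invariant to the order of the input matrix.
`hull_metrics()` summarizes per-category occupancy (convex-hull area) and
pairwise overlap (intersection over union, by Sutherland–Hodgman convex
clipping).

## Convergence statistics

**Partitioning.** At a given scale, each unordered pair of calls
contributes one similarity value to the within set (same category) or the
among set (different categories). Two optional constraints: at the
individual scale, among-individual pairs can be restricted to individuals
from *different* sites, removing shared site membership as a confound; and
at the individual or site scale, among pairs can be restricted to the
*same* region (`within_region`). The latter is how the package balances
geographic breadth when comparing a dialect-structured species across
scales: without it, among-individual comparisons absorb cross-dialect
dissimilarity and the individual-scale statistic conflates the two scales.

**Histogram EMD.** Both sets are binned into 16 equal-width bins on
`[0, 1]` and normalized to unit mass; the EMD on the shared grid is the
integrated absolute CDF difference, `sum(|CDF_w − CDF_a|) × bin width`,
which on the unit domain lies in `[0, 15/16]`. Unit-mass normalization
means unequal raw sample sizes never distort the statistic beyond what the
resampling balances. The test suite holds this implementation to the exact
1-D Wasserstein distance (computed independently by step-function
integration) at `1e-12` on a thousand random set pairs, and a bin-count
grid (4–64, headline 16) is provided to show conclusions do not hinge on
histogram resolution.

**Balanced resampling.** Scales differ enormously in how many pairwise
values they generate, and EMD between empirical distributions has a
finite-sample floor that depends on sample size. Per iteration (100 by
default), the routine draws `n_categories` categories (default 4,
matching the four-individual and four-site comparisons typical of this
design) and then `n_per_class` values (default 100) from each of the
within and among pools, without replacement within the iteration, and
computes the histogram EMD; the mean and percentile 95% CI over
iterations are reported. Under a true null (within and among identically
distributed) the mean sits near the finite-sample floor — below 0.05 at
`n_per_class = 100` — so order-of-magnitude contrasts between scales are
far outside null variation.

**Bootstrap similarity ratios.** Per iteration, 5 within and 5 among
values are drawn with replacement and divided element-wise; 200 iterations
give exactly 1000 ratios. Ratios near 1 indicate weak convergence. Two
numerical notes: a zero denominator (possible because SPCC floors at 0) is
redrawn and the event counted, rather than propagating an infinite ratio;
and because `E[w/a] = E[w]·E[1/a]` exceeds `E[w]/E[a]` (Jensen), the mean
ratio has an upward bias that grows with the spread of the denominator
pool — with diffuse similarity distributions the null mean ratio sits
visibly above 1. The package's null checks therefore use a null that is
exact by construction (full site convergence, where within- and
among-individual similarities are identically distributed and
concentrated), and ratio results should be read comparatively across
scales rather than against an absolute threshold of 1.

**Mantel tests.** The Mantel statistic correlates the off-diagonal upper
triangles of the similarity matrix and a binary same-category membership
matrix; the null is built by jointly permuting rows and columns of the
membership matrix. The test is one-sided (greater), since convergence
predicts positive correlation, with the add-one convention
`p = (1 + #{r_perm ≥ r_obs}) / (1 + n_perm)`. For seven or fewer calls the
permutation group is enumerated exhaustively and the p-value is exact.
Constant matrices are rejected rather than returning an undefined
statistic.

## Duplicate filtering

Unmarked birds recorded once per site can still be sampled twice, inflating
apparent within-site convergence. `flag_repeats_gmm()` embeds each site's
similarity sub-matrix in 2-D and fits Gaussian mixtures with 1..n
components, selecting by BIC with ties broken toward fewer components;
clusters of two or more calls are flagged, and `filter_dataset()` keeps
one call per flagged cluster (lowest id by default; medoid available).
Two deliberate choices: the embedding here is classical (metric) MDS, not
the non-metric embedding used for acoustic-space figures, because
detecting near-identical calls depends on similarity *magnitudes*, which
rank-only embeddings can distort at small site sizes; and the mixtures are
fit with a conjugate prior (`mclust::priorControl()`), without which the
likelihood of tight duplicate clusters diverges and BIC runs away toward
one component per call. Filtering never removes the last call of a site
and is idempotent. The analogous manually-curated filter (visual
classification) is supported as an externally supplied assignment table in
the same format.

## The synthetic call generator

The generator is the package's ground-truth instrument: downstream claims
are tested as parameter recovery on populations whose convergence
structure is planted causally, not tuned to match a target statistic.

Each call is a tonal FM chirp. A species-mean contour (7 control points;
base frequency uniform in 2.8–4.2 kHz, shape spread 900 Hz) anchors the
population. Regions and sites draw template perturbations around it
(`group_spread`, default 800 Hz). Each individual draws a unique
perturbation with scale `signature_strength` (default 600 Hz) and blends:

```
template_ind = (1 − w_site − w_region) · unique + w_site · site + w_region · region
```

on control-point frequencies **and on call duration** (durations drawn
uniformly from 0.1–0.4 s and blended with the same weights). Blending
duration matters: duration is a strong SPCC cue, and if it stayed purely
individual, a "dialect" population would still leak individual identity
through duration alone, contradicting the planted structure. With
`site_weight = 1` every individual reproduces its site template exactly —
and with full convergence, within- and among-individual similarities are
identically distributed, which the null-calibration tests exploit.

Per call, control points are jittered (`call_jitter`, default 150 Hz), the
contour is interpolated with a monotone cubic scheme (smooth FM without
overshoot outside the band), the instantaneous phase is integrated, a
raised-cosine fade covers 10% of each end, the peak is normalized to
−3 dBFS (removing amplitude as a confound), white Gaussian noise is added
at a target SNR (default 24 dB ≈ linear 15.8, comfortably above the QC
cut), and 0.15 s noise-only margins are synthesized on each side so the
SNR is re-estimable from the clip itself. All contours are clamped inside
0.5–9 kHz so the analysis bandpass never removes signal energy. Identical
configurations generate bit-identical datasets.

What the generator does **not** emulate: harmonic stacks, reverberation,
overlapping callers, amplitude modulation, microphone or recorder
response, and any quantitative acoustics of a real species — the
literature this analysis serves does not publish call durations or
bandwidths, so the defaults are plausible for small-parrot contact calls
rather than estimates of any species' parameters. Tests passing on this
generator show the *pipeline* recovers planted structure; they do not
show that any real population has that structure.

## Study conditions and problem sizes

The packaged property checks use, as their standing conditions: a
signature regime (strong individual signatures, `signature_strength`
900 Hz, `call_jitter` 80 Hz, no site/region blending) with 8 repeatedly
sampled birds × 12 calls and a site-scale survey of 6 sites × 15 unmarked
birds; a dialect regime (3 regions × 2 sites × 4 birds × 6 calls,
`region_weight` 0.8, `site_weight` 0.1, `signature_strength` 150 Hz); a
classifier design of 16 birds × 12 calls trained on 8 and validated by
clustering the unseen 8, mirroring the train-on-known /
cluster-the-unknown workflow this analysis family uses; and 20 replicate
sites of 6 birds with one planted duplicate for the repeat-sampling
filter. Synthetic audio in tests is generated at 22050 Hz — the analysis
band ends at 9 kHz, so nothing is lost relative to the 44.1 kHz default —
and call durations follow the generator defaults. EMD resampling uses 4
categories × 100 values per class (3 × 40 in the dialect regime, whose
individual-scale pools are smaller) over 100 iterations.

## Known limitations

- SPCC compares time-frequency magnitudes only; frequency-lag (2-D)
  cross-correlation is out of scope, so transposed-but-shape-identical
  contours score as dissimilar.
- The mean bootstrap ratio is upward-biased under diffuse similarity
  distributions (see above); it is a comparative, not absolute, measure.
- Random-forest proximity is relative to the trained forest: holdout
  individuals that the forest's features do not separate can collapse in
  proximity space even when SPCC separates them. The joint feature table
  (including SPCC/DTW embedding coordinates) mitigates but does not
  eliminate this.
- EMD magnitudes depend on the balanced-resampling settings; compare
  values only across scales computed with identical settings.
- Statistical significance of EMD *differences* between groups is not
  computed (CIs are reported and compared descriptively).
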