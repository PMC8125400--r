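---
title: "Methods: pure ion chromatograms and boosted discriminant models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pure ion chromatograms and boosted discriminant models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

picboost implements an untargeted LC-MS metabolomics workflow built around
*pure ion chromatograms* (PICs): ion traces carrying at most one intensity
per scan, each attributed to a single metabolite-derived ion species. The
pipeline is

1. read centroided mzML/mzXML runs (`read_run`),
2. extract PICs by deterministic clustering in the m/z dimension
   (`extract_pics`),
3. detect and integrate chromatographic peaks on each PIC with a
   continuous wavelet transform (`detect_peaks`),
4. align and group peaks across samples, annotate isotopes and adducts,
   fill missing values, and normalize the resulting peak table
   (`group_across_samples`, `fill_missing`, `normalize_table`),
5. visualize the table in two dimensions (`pca_embed`, `tsne_embed`,
   `umap_embed`), and
6. fit a reference second-order gradient-boosted tree classifier
   (`gbtree`) evaluated by confusion-matrix metrics and one-vs-rest ROC
   curves.

A synthetic-data module (`simulate_run`, `simulate_cohort`,
`simulate_table`) plants metabolite features with complete ground truth so
every stage is testable without instrument data.

# PIC extraction

## Model and assumptions

Centroided high-resolution data place the ions of one analyte at almost
the same m/z in consecutive scans, with per-point mass error at the ppm
scale. Extraction therefore works purely in the m/z dimension:

* **Candidate regions.** Points are sliced into coarse slabs of
  `coarse_width` (default 0.1 Da); neighbouring slabs whose nearest points
  are closer than half a slab merge (single linkage), so a trace that
  straddles a slab boundary is not cut.
* **Bisecting 2-means.** A region whose relative m/z spread (maximum
  deviation from the intensity-weighted mean, over that mean) is within
  `mz_tol_ppm` (default 15 ppm) is pure. Otherwise a 2-means on m/z
  proposes a split. Centers are initialized at the two extreme m/z values
  and centroids are updated with intensity weights, which makes the
  procedure fully deterministic and lets intense ions dominate the cluster
  centers. Defining the spread as the maximum deviation from the weighted
  mean makes the stopping rule and the PIC purity invariant (observed m/z
  range at most twice the tolerance) exactly consistent.
* **Unimodality guard.** A proposed split is accepted only when the two
  children are genuinely separated populations: the distance between the
  child centers must be at least four times the larger within-child
  spread. Without this guard, a single ion whose jitter range reaches the
  tolerance is chopped by m/z into *time-interleaved* fragments, which
  truncates every downstream peak. When the split is rejected the few
  outlying points are trimmed (dropped entirely) until the spread
  invariant holds; a trace keeps its time course and the invariant keeps
  its guarantee. Two real ions closer than roughly four jitter standard
  deviations are merged — they are unresolvable at that mass accuracy
  anyway.
* **One intensity per scan.** Within a cluster, the strongest point per
  scan wins; intensity ties go to the point nearest the weighted mean m/z,
  then to the lowest m/z.
* **Gap splitting and filters.** Runs of more than `max_gap` (default 2)
  empty scans split a trace; traces shorter than `min_length` (default 5)
  scans or with apex below `min_apex` (default 3x the run's median
  non-zero intensity, a cheap global noise proxy) are dropped. Surviving
  gaps stay absent — no zero-filling — so peak detection sees the true
  sampling.

# Peak detection

Each PIC is resampled onto a uniform retention-time grid (linear
interpolation across gaps, grid step = median scan interval) and
transformed with a Mexican-hat wavelet over eight log-spaced scales
between 2 and 30 s — the plausible chromatographic peak widths for the
short gradients this package targets. Local maxima per scale are linked
into ridge lines from the largest scale down; a ridge needs support at two
or more scales. The apex is the raw-signal maximum near the strongest
ridge response; boundaries are the nearest flanking local minima of a
lightly smoothed copy (or effective zero-crossings), falling back to the
trace ends.

The noise level is the median absolute deviation of the residual after
subtracting a 3-point moving average, scaled by `sqrt(3/2)` so it
estimates the per-point noise standard deviation, and floored at 1 count
so noiseless synthetic signals keep a finite SNR. The SNR is the
baseline-corrected apex height over this noise. Because the wavelet and
the residual both have zero response to a constant, detection is invariant
to baseline shifts; because SNR is a ratio of intensity-scaled quantities,
it is invariant to rescaling all intensities. Peaks need `snr_min`
(default 3) and at least three observed scans. Areas come from the
trapezoid rule over *observed* points only.

# Feature table construction

* **RT shift correction** estimates one global shift per sample as the
  median apex offset of unambiguous (mutually unique within doubled
  tolerances) matches against a reference sample. This deliberately
  simple stand-in for warping-based alignment suits the short, stable
  gradients the generator emulates.
* **Grouping** is greedy and density-based: the strongest unassigned peak
  seeds a group, peaks within `mz_tol_ppm` (10) and `rt_tol_s` (10 s)
  join (one per sample, strongest wins), and a second absorption pass
  re-collects unassigned peaks around the group *consensus* (median m/z
  and RT). The absorption pass exists because a seed at the RT edge of
  its feature would otherwise split the feature in two. Groups below
  `min_frac` (0.5) detection in every class are dropped.
* **Isotope/adduct annotation**: companions at `k * 1.00336 / z` (k = 1..3,
  z in {1, 2}) with lower intensity are tagged against their parent;
  co-eluting pairs whose m/z difference matches a difference of adduct
  shifts ([M+H]+, [M+NH4]+, [M+Na]+, [M+K]+ by default) share an inferred
  neutral mass. Tags are annotations only — tagged features stay in the
  table, since collapsing them is a separate scientific decision.
* **Missing-value filling** re-integrates the raw signal in the feature's
  m/z window (PIC tolerance) and `rt_consensus` +/- 15 s. The window must
  cover roughly +/-2 sigma of the widest expected peaks (the generator
  plants sigma up to 8 s); windows much narrower clip wide peaks. With
  fewer than two raw points there is nothing to integrate and the entry
  falls back to half the group's minimum observed area, a conventional
  floor that keeps the table free of zeros. Detected entries are never
  altered.
* **Normalization** is per-feature autoscaling (zero mean, unit
  variance). By default the statistics are fit on the training split only
  and applied to all samples, avoiding train/test leakage; fitting on all
  samples before splitting (the conventional order in many metabolomics
  studies) is available via the `normalize_at = "table"` config switch.
  Zero-variance features are centered, scaled by 1, and flagged.

# Visualization

PCA is computed from first principles (column-centered SVD) with a fixed
sign convention (largest-magnitude loading positive) so coordinates are
reproducible across platforms. t-SNE and UMAP are delegated to the
established Rtsne and uwot implementations — the package uses them only
for visualization, so re-deriving them would be out of proportion — with
contracts limited to shape, finiteness and seeded determinism
(single-threaded, fixed seed). Defaults: `n_neighbors = 15`,
`min_dist = 0.1`, `perplexity = min(30, (n-1)/3)`.

# The boosted-tree learner

The classifier is an additive ensemble of regression trees fit by
second-order gradient boosting. Per round the loss is expanded to second
order around the current scores; for leaf gradient/hessian sums G and H
the optimal leaf weight is `-G / (H + lambda)` and a split is scored by

    Gain = 1/2 [ GL^2/(HL+lambda) + GR^2/(HR+lambda)
                 - (GL+GR)^2/(HL+HR+lambda) ] - gamma.

Implementation choices:

* **Exact greedy split search** over every (feature, midpoint between
  consecutive distinct values) candidate; ties broken by lowest feature
  index, then lowest threshold. Histogram approximations and
  sparsity-aware splitting are deliberately out of scope (tables are
  filled upstream).
* **Multiclass = one tree per class per round** under the softmax loss
  (`g = p - onehot(y)`, `h = p(1-p)`); the initial score is the log class
  prior. Squared-error regression (`g = s - y`, `h = 1`, base = mean) is
  kept because depth-1, one-round, unshrunk fits have a useful closed
  form: the least-squares decision stump.
* **`min_child_weight`** is enforced as a feasibility constraint on
  candidate splits (children below the hessian floor are not considered),
  as the field's learners do. Note a practical consequence: with softmax
  hessians near 0.25 per sample, cohorts with fewer than about 8 training
  samples cannot split at the default `min_child_weight = 1`; study-scale
  designs (24+ training samples) are unaffected.
* **Objective trace.** The recorded objective adds the loss and the
  regularizer of the *shrunk* trees (`gamma T + lambda/2 * (lr * w)^2`),
  i.e. of the sub-models actually added to the ensemble. Evaluated on the
  stored (unshrunk) weights the objective is provably non-monotone under
  shrinkage once gradients saturate; on the shrunk weights it is
  non-increasing for `gamma = 0`, `lr <= 1`, which the tests assert.
* **Defaults** (100 rounds, lr 0.1, depth 3, gamma 0, lambda 1,
  min_child_weight 1, subsample 1, colsample 1) follow the common
  conventions for this family of learners; the grid-search helper
  (stratified k-fold, k reduced to the smallest class count with a
  warning) tunes them when asked.

Comparators (PLS-DA via in-house NIPALS on one-hot targets; RBF-SVM via
e1071; random forest via randomForest) share the same predict contract so
the metric pipeline downstream is identical for every model.

## A known property of gain importance

Feature importance is the summed split gain per feature. When several
planted markers each separate the classes almost perfectly (fold-change 4
at CV 0.3 puts each marker ~4.7 sd between classes), the exact greedy
search concentrates *all* importance on the single best marker: gradients
stay ordered by that feature, so every node of every round splits on it
again. The cross-check test against the established boosting library shows
the same winner-takes-all behaviour with matched parameters. Redundant
markers are therefore recovered one-at-a-time, not as a ranked list; the
honest guarantee, asserted in the tests, is that every feature with
*positive* importance is a planted marker.

# Evaluation

Accuracy, precision, recall, specificity and F1 are computed from the
confusion matrix; 0/0 denominators return 0 with a `degenerate` flag
rather than raising, because tiny test sets make them reachable. ROC
curves use descending score thresholds with tied scores collapsed (step
convention) and trapezoidal AUC, which equals the Mann-Whitney rank
statistic. Multiclass problems are aggregated one-vs-rest with
*unweighted (macro)* means — the study designs this package emulates are
near-balanced, so macro and weighted averages almost coincide while macro
stays interpretable under mild imbalance.

# Synthetic data: what it emulates, and what it does not

`simulate_run` renders Gaussian elution profiles (default sigma 3-8 s) on
a 0.5 s scan grid over a 600 s gradient, m/z 100-1000, heights log-uniform
between 1e4 and 1e6 counts, with per-point Gaussian m/z jitter (5 ppm sd),
isotope envelopes (M+1 at 10-30%, M+2 at 1-8%), and Poisson noise points
(exponential intensities, mean 5% of the median planted height).
`simulate_cohort` adds log-normal between-sample intensity variation
(CV 0.3), per-sample RT jitter (3 s sd), and multiplicative class effects
on designated marker features. `simulate_table` draws the same intensity
model straight into a table, bypassing chromatography, for modeling
studies.

These defaults emulate a small QTOF discovery cohort. The generator does
*not* model peak tailing (a config switch for exponentially modified
Gaussians is left open), matrix effects, batch drift, correlated noise, or
instrument-specific mass-error structure. Passing tests therefore
demonstrate correctness of the algorithms under idealized chromatography,
not performance on real acquisitions — on real data, expect alignment and
grouping to be the fragile stages.

Test problem sizes are chosen to exercise each property at the smallest
scale where it is meaningful: one 50-ion run with 20 noise points per scan
for extraction and quantification; a 12-sample, 40-feature raw cohort for
grouping and filling; 2 x 30-sample, 200-feature tables over 10 split
seeds for discrimination; and a 6-class x 6-replicate raw cohort for the
end-to-end determinism check.

# Numerical choices and degenerate inputs

* All extraction is deterministic (extreme-point k-means initialization;
  fixed tie-breaks), so identical inputs give identical outputs with no
  seed.
* Empty spectra, empty regions, single-point clusters, constant signals,
  single-class truth vectors and zero-variance features are all handled
  explicitly (empty results, flagged zeros, or informative errors — never
  NaN).
* `split_gain` treats a childless side as contributing zero even at
  `lambda = 0` (0/0 -> 0), matching the degenerate-split convention.
* The mzML writer emits no timestamps and fixed-precision retention
  times, so pipeline re-runs are byte-identical; RT units are seconds
  everywhere (mzR normalizes minutes on input).

# Limitations

* The global-shift RT correction cannot follow non-linear drift.
* Overlapping co-eluting peaks on one PIC are not deconvolved into
  components.
* Gain importance concentrates under redundant markers (see above); use
  repeated subsampled fits if a ranked marker list is needed.
* The learner does not handle missing feature values by design — tables
  are filled upstream.
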