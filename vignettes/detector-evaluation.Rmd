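---
title: "Evaluating multiclass wildlife detectors at the image level"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating multiclass wildlife detectors at the image level}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camtrapeval)
```

## The evaluation problem

Camera-trap programs that train custom multiclass detectors (YOLO-family
models producing bounding boxes, class labels, and confidence scores in
[0,1]) face a characteristic evaluation situation: the raw archive is
dominated by empty false-trigger images, reviewing ground truth is the
main cost, and the quantities practitioners actually care about are not
box-localization scores but image-level answers — *does this image
contain an animal at all*, *which species is in it*, *how many
individuals*, and *what does site-level species richness look like if we
trust the model*. camtrapeval implements that evaluation surface on
tabular inputs only: detector predictions, verified annotations, and an
image manifest mapping images to stations and deployments. Localization
quality (IoU) is deliberately not assessed.

All thresholding in the package is **inclusive**: a prediction with
score exactly equal to a threshold survives it.

## Empty-image filtering

All animal classes are collapsed to a single "animal" label. For each
reviewed image the maximum score over its animal-role predictions is
compared to a threshold grid (0.25 to 0.95 by 0.10 by default), and
image-level sensitivity and specificity are computed as

$$\mathrm{Sensitivity} = \frac{TP}{TP+FN}, \qquad
  \mathrm{Specificity} = \frac{TN}{TN+FP},$$

where a TP is a truly occupied image predicted occupied and a TN a truly
empty image predicted empty. Images whose only content (true or
predicted) is a human or vehicle, and images with more than one true
class, are excluded by default — the binary question is posed on
single-class animal images and confirmed-empty images; a
`keep_excluded` switch retains them with non-animal content treated as
empty. `compare_detectors()` cross-tabulates two detectors' predicted
states at a threshold, stratified by the true state, for
agreement analysis against a generic baseline such as MegaDetector
(whose batch JSON `read_megadetector_json()` ingests directly).

`plan_review()` encodes the review protocol that produces the evaluated
subset in large campaigns: every image with an animal prediction at or
above a floor (default 0.25) is reviewed, except that any
deployment-by-class stratum larger than an overflow trigger (default
2000 images) is instead sampled at a fixed number of images (default
50) from each of four score bins (0–0.25, 0.26–0.50, 0.51–0.75,
0.76–1.0); and a fixed number (default 100) of predicted-empty images
is sampled per deployment, or all of them when fewer exist. An image
with predictions of several classes is assigned to the stratum of its
highest-scoring animal prediction; the protocol itself does not fix
this, and the top-class assignment keeps strata disjoint.

## Image-level species classification

For species $s$ at threshold $t$, predictions with score below $t$ are
discarded (per class, the highest score among an image's boxes of that
class is what survives or not — the per-class maximum, not the overall
image maximum, which is the reading consistent with per-class tallies;
the alternative could be emulated by pre-filtering predictions). Then:

* an image confirmed to contain $s$ whose surviving predicted label set
  includes $s$ is a **TP**; otherwise it is an **FN**;
* any other image whose surviving predicted set includes $s$ is an
  **FP**;
* true negatives are not defined.

Images with several true species contribute independently to each of
their true classes. Precision $TP/(TP+FP)$, recall $TP/(TP+FN)$ and
$F_1$ are recomputed along a grid of thresholds from 0.25 to 1.0 by
0.05. The grid is generated from integer steps divided by 100, so 0.65
and 1.0 are exact and no tally can shift through floating-point
accumulation at a boundary.

**Undefined metric points.** At high thresholds a class may have no
surviving predictions, leaving precision (and hence $F_1$) with a zero
denominator. Such points are *omitted* from that metric's threshold
average rather than imputed as zero: the metric is simply not defined
there, and imputation would deflate averages by an amount determined by
the grid rather than by the detector. `average_metrics()` exposes
`undefined_as_zero = TRUE` for the harsher convention. Recall is always
defined for a class with at least one confirmed image.

Class summaries are macro-averaged over classes with at least 10 images
in **both** the training and the test set (both conditions, since a
tiny test set makes the estimate unstable and a tiny training set makes
the class an outlier of the learning curve); the cutoff is a parameter.
When training counts are not supplied, classes are excluded on test-set
size only. `fit_size_effect()` regresses the threshold-averaged metrics
on the number of training images per class, or its log10, by ordinary
least squares, reporting slope, intercept, $R^2$, and a t-based 95% CI
half-width on the slope.

## Ecological concordance

**Species richness.** Per station, richness is the number of distinct
species with at least one qualifying detection; predicted richness is
computed at each threshold of the 0.25–0.95 by 0.10 grid and regressed
on observed richness (predicted as the response, following the
established concordance protocol). Labels for humans, vehicles, and
unidentifiable content are excluded from richness by default
(configurable — non-species classes are not part of an ecological
richness count). Stations with zero observed species are retained: they
are genuine sites and dropping them would censor exactly the cases
where false positives inflate predicted richness. Bias is reported as
the per-station difference (predicted − observed), summarized by mean
and SD.

**Animal counts.** Count models use only true-positive images with a
single true species, since a per-image count comparison is only
meaningful when the predicted boxes can be attributed to one species
without guessing; `count_pred` counts the surviving boxes of the *true*
species only, so that stray misclassified boxes of other species do not
contaminate a species-specific count. Three model forms:

* **difference** — $\mathrm{Count_{true}} - \mathrm{Count_{pred}}$ on
  species class;
* **ratio** — $\mathrm{Count_{pred}} / \mathrm{Count_{true}}$ on
  species class (a coefficient of 0.78 is a 22% mean undercount);
* **Poisson GLM** — $\mathrm{Count_{true}} \sim
  \mathrm{Poisson}(\exp(a_i + b_i \ln \mathrm{Count_{pred}}))$ with a
  separate intercept and slope per class.

The difference and ratio models use a cell-means (no global intercept)
parameterization so each coefficient *is* the per-class estimate with
its CI, the form in which such results are plotted; a treatment-contrast
fit is a reparameterization of the same model and can be obtained from
the coefficients directly. The GLM interaction is implemented in nested
form (per-class intercept plus per-class slope on the natural log of
the predicted count) because per-class prediction curves
$\exp(a_i + b_i \ln x)$ are the quantity of interest; main-effect
parameterizations are equivalent up to reparameterization. The GLM is
fitted by iteratively reweighted least squares to relative tolerance
1e-8; a class in which every record has the same predicted count has an
inestimable slope and is reported as an error rather than silently
dropped.

## The synthetic study generator

Because the package's claims must be checkable without any real images,
`simulate_study()` generates a full study whose expected metrics are
known in closed form. The truth layer lays out stations × deployments ×
images, marks each image empty with probability `empty_fraction`,
assigns each occupied image **one** species by abundance weight, and
draws a group size from a zero-truncated geometric distribution (mean
parameter per species; one-parameter, long right tail — group sizes up
to ~19 occur for plausible means, matching what group-living species
show in the field). The detector-error model then:

* detects each individual animal independently with a per-species
  probability $p_{det}$ (no per-image correlation — this is what makes
  image-level recall tractable in closed form);
* labels each detected individual from a row-stochastic confusion
  matrix $C$;
* draws true-detection scores from a Beta distribution (or a point
  mass), false-detection scores from a second Beta;
* adds a Poisson number of false boxes to each empty image (and only to
  empty images by default, isolating specificity; a switch extends them
  to occupied images).

For a single-species image with $g$ individuals the probability that at
least one survives at threshold $t$ with the correct label is

$$R(t) = 1 - \left(1 - p_{det}\, C_{ss}\, S_{tp}(t)\right)^{g},$$

with $S_{tp}$ the upper tail of the true-score distribution
(`expected_image_recall()`). The acceptance suite checks empirical
recall against this within three binomial standard errors, and checks
the fitted ratio coefficient against the truncated-binomial mean
$E[X \mid X \ge 1]/g$, $X \sim \mathrm{Bin}(g, p_{det})$, computed by
direct summation.

**Default conditions** (`default_synth_config()`): 15 stations × 2
deployments × 60 images (1800 images), 55% empty, six species with
abundance weights 40:20:10:8:4:1 (a long-tailed community in which the
most and least abundant classes differ by a factor of 40, echoing the
severe class imbalance of real training sets), group-size means between
1 and 2.5, per-species detection probabilities 0.60–0.95, confusion
diagonals 0.80–0.97, 0.4 false boxes per empty image, and Beta(5, 1.5)
vs Beta(1.2, 3) score distributions so true detections score visibly
higher than false ones. These sizes keep the full pipeline and its
tests comfortably in seconds while leaving every per-class estimate
non-degenerate.

**What the generator does not emulate:** burst/sequence structure and
temporal autocorrelation, day/night covariates, multi-species images
(off by default; the count models exclude them anyway),
score–box-geometry dependence, spatially correlated detector
failures, and station-level heterogeneity in community composition —
every station draws from the same species pool, so observed richness
varies across stations only by sampling noise and the richness
regression is weakly identified at the default scale (its exact
identities are exercised with the perfect detector instead). Tests passing on synthetic data therefore validate the
*bookkeeping and the statistics* of the evaluation, not any claim about
how a particular real detector behaves.

## Numerical choices and degenerate inputs

* Score distributions may be degenerate (`score_fixed()`), which gives
  exact perfect-detector identities: sensitivity = specificity = 1 at
  all thresholds, every defined per-class metric 1, richness regression
  (slope, $R^2$, bias) = (1, 1, 0), count coefficients (0, 1), GLM
  $(a_i, b_i) = (0, 1)$.
* $R^2$ and CI half-widths are computed directly from residual sums of
  squares, so exact fits return exactly 1 (or 0 for a constant
  response, where the usual $R^2$ is indeterminate) without the
  perfect-fit warnings of `summary.lm`.
* A metric whose denominator is zero is `NA`, never 0 or 1.
* Result tables are written with deterministic row order (class, then
  threshold) and 15 significant digits, so a write–read round trip
  preserves values to at least 12 significant digits.
* Richness regressions require at least 3 stations and nonzero variance
  in observed richness; degenerate inputs error rather than returning a
  meaningless fit.

## A worked run

```{r example, eval = FALSE}
cfg <- default_synth_config(seed = 1)
study <- simulate_study(cfg)
vocab <- synth_vocabulary(cfg)
report <- run_full_evaluation(study$predictions, study$truth,
                              study$manifest, vocab,
                              train_counts = c(baboon = 7000,
                                               bushbuck = 2500,
                                               elephant = 900,
                                               guineafowl = 600,
                                               zebra = 300,
                                               leopard = 150))
report$macro
report$richness$fits
fit_count_ratio(report$count_records)
```

The problem sizes used throughout the test suite are the generator's
defaults (1800 images) and two purpose-built recovery studies of 2000
single-species images each, sizes at which three-standard-error
stochastic bands are a few percentage points wide.

## Known limitations

* The evaluation is image-level throughout; nothing here scores box
  localization, and `count_pred` can silently benefit from a wrong box
  in the right class.
* Threshold-averaged metrics depend on the grid; they are comparable
  only between runs using the same grid.
* The review planner reproduces a specific protocol (floor + overflow
  bins + per-deployment empty samples); other allocation schemes are
  out of scope.
* Occupancy modelling, density estimation, and sequence-level counting
  are downstream analyses the package does not perform.
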