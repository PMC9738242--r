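---
title: "Detecting Parkinson's disease from passive wrist accelerometry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting Parkinson's disease from passive wrist accelerometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Parkinson's disease (PD) changes how people move: rest tremor in the
4--6 Hz band, reduced movement amplitude (bradykinesia), and altered
activity patterns.  A wrist-worn accelerometer worn continuously for a
week records these changes without asking the wearer to perform any
task.  `wristbow` implements a complete analysis pipeline that turns
such *passive monitoring* recordings into a PD-vs-healthy classification
and into the statistical comparisons that typically accompany it: which
window length works best, whether a bag-of-words representation beats
averaged statistical features, and how many days of recording are
enough.

Because week-long clinical accelerometer datasets are rarely shareable,
the package includes a seeded synthetic cohort generator that carries
the statistical structure the analysis assumes.  Every empirical claim
in the test suite is made about these synthetic cohorts, not about
clinical data.

## Pipeline overview

1. **Segmentation.** Each tri-axial recording (g units, nominal
   100 Hz, ±8 g) is cut into half-overlapping windows of length
   $S \in \{3, 10, 60, 300, 900\}$ s.  A recording of duration $t$
   yields $\lfloor 2t/S\rfloor - 1$ complete windows; trailing partial
   windows are dropped because every descriptor assumes a full window.
2. **Descriptors (SDS).** Each window is summarised by ten values:
   the mean per-sample vector magnitude
   $\overline{\sqrt{x^2+y^2+z^2}}$; the normalised RMS per axis
   $\mathrm{RMSR}_d = \mathrm{RMS}_d / \sqrt{\sum_{d'} \mathrm{RMS}_{d'}^2}$
   (the squares sum to 1); the movement dispersion per axis (the mean
   absolute pairwise difference of within-window z-scores over
   non-outlier samples, where a sample is an outlier if $|z| > 2$ on any
   axis); and the per-axis acceleration range (max − min).  All ten are
   either axis-symmetric or normalised, so the pipeline does not depend
   on how the device was oriented on the wrist.
3. **Statistical features.** Per subject, the unweighted mean of each
   descriptor over all windows of a given length: 10 features per
   strategy, 50 for all five.
4. **Document of words.** All subjects' descriptors at one window
   length are pooled and clustered with K-medoids (PAM); the number of
   words $k$ is chosen from candidates $\{4, 8, \dots, 32\}$ by an
   automated elbow rule on the within-cluster sum of squares.  Each
   window is then assigned its nearest medoid ("word"), each subject
   becomes a document, and term frequencies
   $d_i = \text{count}_i / \text{total}$ are the features.
   Concatenating all five strategies gives the combined document.
5. **Feature selection.** A genetic algorithm over binary feature masks
   (population 40, 50 generations, 20 parents of which half are the
   fittest and half random, 4 uniform crossovers, 14% per-individual
   mutation) maximises mean cross-validated accuracy with a small
   sparsity penalty.
6. **Evaluation.** Each feature set × classifier (RBF SVM, naive Bayes,
   decision tree, random forest, 5-NN, AdaBoost) is scored by 100 runs
   of stratified 10-fold cross-validation; per run, held-out predictions
   are pooled into one accuracy, and AUCs are averaged over runs.
7. **Hypothesis tests.** Windowing strategies are compared by one-way
   ANOVA with Tukey HSD after a Shapiro–Wilk gate; the two
   feature-engineering methods by a one-sided paired t-test (word >
   statistical), with a Welch test as sensitivity analysis; the
   days-of-data experiment by Kruskal–Wallis with Dunn–Bonferroni post
   hoc (21 pairs for 7 day counts) after normality (Shapiro–Wilk) and
   homogeneity (Levene) gates, reporting the smallest day count not
   significantly different from seven days.

## Numerical and design choices

Several details are genuinely open in the protocol the package
implements; the choices made here are:

* **Partial windows** are dropped (the count formula is used with a
  floor), since descriptors assume complete windows.  Indexing is
  0-based with half-open sample blocks.
* **z-scores** use the population (n-denominator) SD within the window.
  The dispersion of a window with fewer than two non-outlier samples,
  or of a zero-variance axis, is defined as 0 rather than NaN so that
  rest windows — common and informative — do not poison subject means.
  A window that is identically zero has no defined normalised RMS; it
  is flagged and excluded from subject averages.
* **Two "vector magnitude" quantities** exist and are kept distinct:
  the per-sample mean magnitude (a descriptor) and the root of summed
  squared RMS values (the RMSR denominator).
* **Descriptor standardisation before clustering.** The ten SDS
  components mix units (g and z-units); Euclidean distances are
  computed after centring/scaling by the vocabulary-building set, and
  those parameters are stored in the vocabulary and reused at encoding
  time.
* **PAM at scale.** Exact PAM on millions of descriptors is infeasible,
  so vocabularies are built CLARA-style: PAM on a seeded subsample
  (default 20,000 descriptors, 5 restarts), then every descriptor is
  assigned to its nearest medoid for the WCSS evaluation.  PAM's swap
  phase is a local search; `kmedoids()` therefore adds a few seeded
  random restarts to the deterministic build start, which makes it
  exhaustively optimal on all small instances we test.  Because a
  subsampled fit does not guarantee that the full-set WCSS decreases
  with $k$, candidate solutions are repaired by nested refinement
  (augmenting the previous candidate's medoids with farthest-point
  medoids, which can only lower the WCSS), so the curve handed to the
  elbow rule is non-increasing by construction.
* **Elbow automation.** The visual elbow is replaced by the maximum
  perpendicular distance to the chord joining the WCSS curve's
  endpoints, after rescaling both axes to [0, 1] (otherwise the WCSS
  units dominate).  Ties resolve to the smaller $k$; an increasing
  curve is treated as a clustering-instability error.
* **Vocabulary scope.** The faithful procedure builds the vocabulary
  on the whole cohort, which leaks evaluation subjects into the
  vocabulary (not the labels).  A leak-free mode restricted to training
  subjects is available (`train_subjects` / a CV `builder`), and the
  tests verify that leak-free vocabularies depend only on training-fold
  membership.
* **GA details.** The fitness is
  $\text{mean accuracy} - \lambda\,(\text{selected}/\text{total})$ with
  $\lambda = 0.05$, ties broken towards fewer features; the best
  individual is carried into the next generation, so the reported
  optimum is non-decreasing.  The next generation is assembled as
  {best} ∪ offspring ∪ mutated parents ∪ fresh random individuals.
  The fitness CV uses a fixed fold seed so masks compete on identical
  resampling noise.
* **Classifier hyperparameters** are pinned library defaults: RBF SVM
  with cost 1 and the $1/p$ bandwidth heuristic, 5-NN on standardised
  features, random forest with 100 trees, rpart defaults, naive Bayes
  defaults, and an AdaBoost.M1 implementation with 50 exhaustive-search
  decision stumps.  They are recorded in every result object.
* **Paired-test structure.** The method comparison is reported both as
  a one-sided paired t-test (pairing accuracies by classifier and run)
  and as a Welch two-sample test, because the published description of
  this comparison mixes the two (a "paired" test with a Welch-like
  degrees-of-freedom value); the package reports both rather than
  resolving the ambiguity.
* **Days experiment.** Vocabularies are rebuilt for every day count
  (the alternative — reusing the seven-day vocabulary — is possible by
  passing `vocabs`).  One vocabulary subsampling seed is shared across
  day counts so conditions differ only in the amount of data.

## The synthetic cohort generator

`generate_subject()` builds a signal as

> fixed per-subject gravity vector (small random tilt) + bout-structured
> movement + rest tremor + white sensor noise, clipped to ±8 g.

Movement is low-pass-filtered Gaussian noise (AR(1), ~1.5 Hz bandwidth,
baseline SD 0.35 g) gated by an alternating active/rest process with
exponential bout durations.  Each active bout carries a mean-one
lognormal intensity multiplier (`bout_intensity_sd`), which changes the
*distribution* of window descriptors without moving their within-window
means — the kind of structure a word histogram can see but a
segment-mean feature cannot.  Tremor is a 4–6 Hz sinusoid (default
5 Hz) with random spatial direction, added to each rest bout with
probability `tremor_rate`.  Each simulated day has its own RNG stream,
so truncating a recording to its first $d$ days is identical to
generating $d$ days — the property the days experiment relies on — and
per-day lognormal activity/tremor multipliers (`day_effect_sd`) make
single days noisy summaries of a subject, so accumulating days
genuinely adds information.

The default PD profile emulates a mild-to-moderate cohort: activity
scale 0.8, shorter bouts (60 s vs 90 s), tremor in 40% of rest bouts at
0.15 g.  Between-subject heterogeneity is deliberately large
(`subject_sd = 0.35`) because free-living activity varies far more
between people than between diagnostic groups.  These values were
calibrated once for testability — strong enough that the pipeline
should recover the group difference, weak enough that classification
is not trivially perfect — not for biomechanical fidelity.  The
generator makes no attempt at realistic gait, medication cycles, or
device firmware filtering; consequently, passing tests demonstrate that
the pipeline recovers the structure this generator plants, not that it
would achieve any particular accuracy on clinical recordings.

### Desk-scale preset

Full scale (60 subjects × 7 days × 86,400 s × 100 Hz) is ~10^10
samples.  The default `"desk"` preset compresses a day to 1800 s at
32 Hz while keeping the window lengths in physical seconds, so
per-strategy segment counts shrink by the compression factor while
their ratios across strategies (∝ 1/S) are preserved.  Scaling the
window lengths *with* the day length was rejected: it would either
preserve full-scale segment counts (defeating the compression) or,
at 32 Hz, produce sub-second windows of two samples, which cannot
carry dispersion or tremor structure.  The `"paper"` preset (86,400-s
days, 100 Hz) keeps the full-scale geometry configurable.

## Problem sizes used by the tests and the acceptance script

All simulation-based checks run at desk scale: null-calibration and
signal-recovery cohorts use the full study composition (32 + 28
subjects, 7 compressed days); the directional comparison of feature
sets uses twenty 24-subject, 2-day cohorts; the days experiment uses
40 subjects with 600-s day units and windows {3, 10, 60, 120} s; GA and
vocabulary checks use planted-structure instances (a perfectly
predictive feature among 30 noise features; four well-separated
descriptor modes).  Vocabulary building in these runs uses smaller
CLARA subsamples (400–2000 descriptors) and the GA a reduced budget
(populations 10–20, 3–8 generations); both are ordinary scalings of the
same code paths exercised by the defaults.

## Known limitations

* The generator's group structure is low-dimensional by design; real
  cohorts have confounders (age, comorbidity, wear time) that the
  pipeline does not model.
* The faithful vocabulary scope and the GA both see evaluation subjects
  during feature construction/selection (though never their labels at
  encoding time); the leak-free and nested modes exist precisely
  because the faithful protocol is optimistic.
* Repeated cross-validation on one cohort concentrates around that
  cohort's idiosyncratic separability, so run-to-run spread understates
  cohort-to-cohort uncertainty; the tests therefore aggregate over
  cohort seeds wherever a claim is distributional.
* AUCs are computed from pooled held-out decision scores per run, which
  assumes scores are comparable across folds; for the SVM this holds
  only approximately.

## A minimal session

```{r, eval = FALSE}
library(wristbow)
cfg <- cohort_config(n_he = 8, n_pd = 8, days = 2, seed = 1)
cd  <- cohort_descriptors(cfg)
x   <- word_features(cd, subsample = 1000, restarts = 1, seed = 1)
cv  <- run_cv(x, cd$roster$group, "svm", n_runs = 20, folds = 8, seed = 1)
summary(cv)
```
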