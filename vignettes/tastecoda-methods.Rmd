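---
title: "Methods: taste-population coding analysis across conditioned taste aversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: taste-population coding analysis across conditioned taste aversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tastecoda)
```

# The scientific setting

Conditioned taste aversion (CTA) is the learned avoidance of a taste — the
conditioned stimulus, CS — after it is paired with gastric malaise. This
package analyses single-cell calcium imaging of gustatory cortex (GC)
recorded with head-mounted miniscopes while mice lick taste stimuli in a
brief-access lickometer, before and after a CTA to 0.3 M NaCl. The question
it is built to answer is *where* the learning shows up: not in how many GC
cells respond or how strongly (those are expected to be unchanged), but in
the *population geometry* — the CS representation leaving the cluster of
consumed ("accepted") stimuli and approaching the representation of avoided
high-concentration quinine, and returning during extinction.

The pipeline has six stages, each usable on its own: synthetic-cohort
generation, trial-aligned response extraction, tuning analysis, population
geometry, SVM decoding, and lickometer behaviour. All stages operate on
tidy data frames; the end-to-end runner is `run_cta_pipeline()`.

# Response extraction

**Windows.** The response measure is trial-wise dF: the maximum fluorescence
in the 5 s from the trial's *first lick*, minus the mean fluorescence in the
5 s immediately before it. dF rather than dF/F is used because extracted
traces are already scaled against background. Frames are 0-based, windows
half-open, and second-to-frame conversion is `floor(t * frame_rate)`.

*Zero-lick trials.* Post-CTA animals sometimes refuse to lick the CS, and
those trials carry exactly the signal under study, so they cannot be
dropped: windows fall back to the trial (shutter) onset, and each trial
records which anchor was used.

**Responsiveness.** A response is *excited* when `delta_plus >= 3 * SD` of
the baseline window and *suppressed* when `delta_minus <= -3 * SD`
(inclusive thresholds). When one window satisfies both, the excited call
wins and the dual count is logged — the choice is arbitrary but rare and
recorded. The baseline SD is per-trial by default (switchable to a pooled
per-session SD via `baseline_scope`), floored at `1e-6` times the trace
dynamic range so noiseless synthetic traces cannot divide by zero.

**Day level.** Where a stimulus is presented several times in a session the
per-trial dF values are averaged to one value per cell, stimulus and day;
day-level "perturbed" calls are made on that averaged response against 3x
the cell's mean baseline SD. Only cells identifiable on *all* imaging days
("tracked cells", the cross-day registration criterion) enter any analysis;
an animal losing all cells is dropped with a warning.

# Tuning

Breadth of tuning uses the taste-literature entropy
\[
H = -K \sum_i p_i \log_{10} p_i,\qquad K = 1/\log_{10}(n),
\]
over the 4 basic tastes (sucrose, NaCl, citric acid, high quinine;
`K = 1.661` for n = 4). Responses are clipped at zero before normalising to
proportions; cells with no positive response have undefined H and are
excluded from entropy means (a documented choice — the convention source is
silent on suppressed-only cells). Stimulus-best units (S-/N-/C-/Q-Units)
are assigned by the argmax over the 4 basic tastes on the second
pre-conditioning day; exact ties break by fixed panel order and are
counted. Because accepted-taste responses are near-ties under acceptance
coding, argmax labels of broadly tuned appetitive cells are only partly
recoverable from data (~80%); the recovery guarantee the suite enforces
(> 90%) applies to distinctly tuned cells and to Q-Units, the class the
CTA analyses lean on. The CTA signature at the cell level is the
dissociation measured
by `tuning_shift_table()`: post-conditioning, previously Q-best cells
acquire a CS response and previously N-best cells lose theirs, while
quinine responses stay put.

# Population geometry

Population vectors pool tracked cells across all animals of a group: one
stimulus x day row, one cell column, entries the per-day mean dF.

**Joint embedding.** All stimulus x day objects of one group enter a single
principal coordinates analysis (classical MDS: double-centre the squared
distance matrix, eigendecompose, coordinates are eigenvectors scaled by
root eigenvalues). A per-day embedding would make across-day trajectories
incomparable — each day's axes would be arbitrary — so the joint embedding
is chosen and flagged as a design decision. Negative eigenvalues are
reported and their axes discarded. Dimensionality comes from the scree
rule (largest second difference of the eigenvalue sequence, defaulting to
2 when ambiguous); the headline analyses use the 2-D solution.

**Readouts.** `euclidean_distance()` is the plain Euclidean norm in the
embedding's arbitrary units. `cs_divergence()` reports, per day, the mean
distance from the CS to the behaviourally accepted set (default: sucrose,
KCl, citric acid, low quinine, water — every stimulus with high pretest
licking except the CS) plus the companion CS-to-quinine distance.
`orient_and_correlate()` fixes the sign convention: dimension 1 is flipped
if needed so its correlation with mean licks is positive (positive =
appetitive), then the Pearson r and simple-regression fit are reported.
Axis signs are otherwise meaningless in MDS, so only dimension 1 gets a
convention and only via behaviour.

Hierarchical clustering of lick counts and responses uses the
Lance–Williams dissimilarity update with complete-linkage coefficients
(alpha = 0.5, beta = 0, gamma = 0.5); the suite proves it identical to a
naive max-linkage recomputation on random instances.

# Decoding

A linear soft-margin SVM is implemented in-package (dual coordinate
descent, one-vs-one multiclass with class-weighted costs so unbalanced
training folds do not bias the margin, features standardised inside each
training fold). Linear is the conservative choice with tens of observations against
hundreds of cell features; the original "optimizable" kernel search is not
reproducible from its description. The cost parameter defaults to a fixed
C = 1; passing a vector of costs enables an inner 3-fold CV grid search.
The fixed default is a deliberate deviation from a per-fold nested search,
which multiplies fit counts roughly tenfold for no measurable change in the
margin solution at this n/p ratio.

Two protocols:

* `loocv_svm()` — leave-one-out cross-validation, with a shuffled-label
  null and a bootstrap over observations. The null is a *null-model
  benchmark*: each repetition permutes training labels within day
  (preserving day structure), refits the whole LOOCV, and scores the
  resulting predictions against the **true** classes. Scoring against the
  permuted labels instead would embed a permutation anti-correlation (in
  an 8-trial day a same-class neighbour's shuffled label matches at 1/7,
  not 1/4) that pushes the null visibly below chance at desk scale.
  Analysis-scale runs use 1,000 repetitions; the test suite uses 100.
  Whether the original benchmark shuffled once per bootstrap or ran
  separate repetitions is unstated; separate repetitions are implemented.
* `pre2post_svm()` — one model fitted on the two pre-conditioning days,
  tested on post-conditioning observations, summarised as a row-normalised
  confusion matrix. Day-averaged assembly yields too few observations to
  train on (2 days x 4 stimuli), so pre2post defaults to trial-level
  observations; trial-level pooling across animals aligns same-rank
  presentations of a stimulus within a day.

Binary palatability labels call a stimulus "high" when its cross-animal
mean lick count on a day exceeds the median lick count of all that day's
trials; ties go to "low" and are counted.

# The synthetic cohort: what it emulates

The source recordings are not deposited, so the generator is a first-class
module: every analysis stage is exercised against data whose ground truth
is known, and every CTA claim the pipeline recovers is a *generator
constraint recovered through the full pipeline*, not a re-measurement of
the original data.

**Sessions.** The schedule constants are exact: 5-s trials, 60-s ITI, six
taste stimuli alternating with water in 2 pseudorandom blocks (12 stimulus
+ 12 water trials); conditioning is a single access period stopped at
1,000 licks or 20 min; extinction-format days open with 12 forced NaCl
trials ("NaCl-Force", a distinct stimulus in analysis) followed by one
randomized block.

**Coding model.** Each cell's gain for each stimulus combines (i) an
acceptance component — a logistic map of mean licks onto (0, 1); most
cells load on the accepted pole and respond near-equally to every consumed
stimulus; an `aversive_pole_fraction` (default 0.3) loads on the rejected
pole with individually stronger gains, balancing pole mass so the
population-mean response carries no palatability signal of its own (the
regression of trial-mean response on lick count must come out null) —
and (ii) a Gaussian identity-tuned component on a latent 1-D identity
axis, plus per-cell-per-stimulus lognormal heterogeneity, a taste-silent
cell fraction, and a gamma per-cell scale. Near-binary acceptance coding
is the modelled system's own headline: the population codes licked vs
not-licked far more strongly than chemical identity. An earlier prototype
with a *linear* palatability loading was rejected during development
because it concentrated gain mass on the lone avoided stimulus, making
magnitude-conserving re-tuning arithmetically impossible.

**Traces.** GCaMP6s-like transients: a Poisson event train during each
trial's lick window, rate proportional to the cell's gain, convolved with
a difference-of-exponentials kernel (rise 0.2 s, decay 1.5 s), on Gaussian
noise at 10 frames/s. The trace model is plumbing, not a claim about
indicator biophysics.

**CTA re-tuning.** On post-conditioning days of CTA animals, a
`cta_retune_fraction` of Q-best cells has its CS gain raised to its
quinine gain and the same fraction of N-best cells has its CS gain cut to
10%; with `magnitude_preserving` (default), raised gains are rescaled so
the pooled CS gain mass is conserved *exactly*, encoding the observed null
on response magnitudes as a constraint. Partial strengths blend linearly
(conservation is strength-invariant); extinction recovery ramps strength
0.85 / 1 / 0.5 / 0 across the post days so divergence peaks on post-test
day 2 and returns to baseline, and the CS lick deficit follows the same
profile.

**Behaviour.** Per-trial lick counts are negative binomial around each
stimulus's palatability score (defaults: accepted stimuli 21–26 licks per
5-s trial, high quinine 4.6, matching the reported day-2 pattern;
dispersion size 20, reflecting stereotyped ~8 Hz rhythmic licking in
trained water-restricted animals), with timestamps jittered around the
8 Hz rhythm. Conditioning: both groups lick avidly for the first minute;
controls sustain and always hit the 1,000-lick cap within minutes, CTA
animals (LiCl) decay exponentially with an animal-level time constant
chosen so most miss the cap — the reported pattern.

**Determinism.** One master seed expands into per-animal, per-day,
per-purpose substreams (`substream_seed()`, 32-bit modular mixing), so
enlarging a cohort never perturbs existing animals' data.

**What a green test does not establish.** The generator contains no
within-trial response latencies or time-epoch coding dynamics, no motion
artifacts, no registration errors (the synthetic registry is perfect
unless degraded deliberately), no day-1 neophobia trend, and no
magnitude–lick coupling. Recovering the CTA signatures here validates the
*pipeline logic* — that the statistics detect exactly the structure the
generator encodes, through trace synthesis and extraction — not the
biological claims themselves.

# Scale and default choices

Defaults are desk-scale: 4 animals per group x 50 tracked cells (200
pooled cells per group, above the 100-cell floor the acceptance analyses
assume) — the experiment-scale cohort (7–8 animals, ~140 cells each) is a
configuration away but multiplies runtime by ~10. Sizes, weights, noise
levels and the lick model were fixed once against the modelled system's
reported behaviour and are not tuned per analysis.

Numerical conventions collected in one place: inclusive +/-3 SD
thresholds; baseline-SD floor `1e-6` x dynamic range; `0 log 0 = 0` in
entropy; argmax ties by fixed panel order, logged; scree ties default to
d = 2; PCoA eigenvalue positivity tolerance `1e-9` relative; SVM
coordinate-descent tolerance `1e-4`, max 200 passes; clustering ties to
the first minimal pair in row-major order.

# Known limitations

* Group-level mixed ANOVAs (with sphericity corrections) are out of scope;
  the package emits tidy per-animal tables for external tools and builds in
  only paired/unpaired t-tests, Pearson correlation and OLS.
* Whether the original baseline SD was per-trial or session-pooled is not
  documented; per-trial is the default, both are implemented.
* The joint embedding (all days in one PCoA) is an assumption; the
  alternative — independent per-day embeddings — cannot support across-day
  distance trajectories at all.
* Trial-level pooling across animals by presentation rank is a modelling
  convenience; rank has no biological meaning beyond session position.
* The identity axis is 1-D; real taste-quality similarity structure is
  richer. Identity decoding on synthetic data is therefore easier than on
  real recordings, and decoding accuracies here should not be read as
  forecasts of accuracies on real data.
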