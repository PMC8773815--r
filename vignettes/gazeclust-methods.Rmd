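---
title: "Spatio-temporal analysis of horizontal gaze bias: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatio-temporal analysis of horizontal gaze bias: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeclust)
```

## The scientific problem

Healthy observers freely exploring naturalistic pictures show a small,
time-dependent horizontal asymmetry of gaze: the left side of a picture is
explored first (pseudoneglect), the right side afterwards, with a return
towards the centre late in the trial. Experiments that try to shift this
bias — for instance with anodal transcranial direct current stimulation
(tDCS) over right-hemisphere nodes of the dorsal attention network (frontal
eye field, FEF; posterior parietal cortex, PPC) — face two analysis
problems at once:

1. **Spatial**: does stimulation shift the average horizontal gaze position
   at all, and does the answer survive conditioning on each participant's
   baseline bias?
2. **Temporal**: if an effect exists, *when* during the 7-s exploration
   does it occur? Testing 70 separate 100-ms time bins requires a
   multiple-comparison correction that respects the temporal adjacency of
   real effects.

`gazeclust` implements both analyses as a reusable, fully testable
pipeline, together with a synthetic scanpath generator so that every stage
can be validated without access to recorded eye-tracking data.

## Data model and units

A **fixation table** has one row per fixation: participant, stimulation
session (FEF, PPC, SHAM), timepoint (T0 = baseline, T1 = post, T2 =
delayed), picture, start time in ms from picture onset, duration in ms, and
screen coordinates in pixels (origin top-left). A **screen geometry**
object (default: 1680 x 1050 px subtending 35 x 22 degrees at 83 cm)
carries all conversions. The horizontal coordinate of interest is the
*centred* position `x_px - width_px / 2`: negative is left of the picture
centre.

Pixel-to-degree conversion is **linear** by default,
`deg = px * width_deg / width_px` (about 0.0208 deg/px). This is the scale
implied by describing the display as spanning a fixed visual angle and it
reproduces the conventional reported values for shifts of tens of pixels;
a trigonometric conversion from the viewing distance is available as an
explicit opt-in (`px_to_deg(..., method = "trig")`) and differs in the
second decimal for such displacements. Electrode dose arithmetic
(`electrode_spec()`, `current_density()`) covers rectangle, disc and ring
electrodes: a 5 x 5 cm pad at 1 mA gives 0.04 mA/cm²; a 25-mm disc
(4.91 cm²) gives 0.20 mA/cm².

## Event detection

When only raw gaze samples are available, `detect_events()` classifies a
sample as saccadic when its angular velocity exceeds 30 deg/s or its
angular acceleration exceeds 8000 deg/s² — the standard cognitive-research
thresholds. Velocity and acceleration are estimated by central finite
differences on the regular sample grid (one-sided at run boundaries).
Maximal runs of non-saccadic samples become fixations (start = first
sample, duration = number of samples x sampling interval, position = mean
of member samples). Three numerical choices matter:

* **Track loss splits events** — a fixation interrupted by invalid samples
  yields two fixations; unclassifiable runs (< 3 valid samples) count as
  gaps, so fixation + saccade + gap durations partition the recording.
* **Boundary fixations are kept** in `filter_out_of_bounds()`: the picture
  area is treated as a closed region, and exclusion requires the mean
  position to fall strictly outside it.
* **No minimum-duration filter** is applied by default; the thresholds
  themselves already suppress very short fixations, and a
  `min_fixation_ms` filter is available but off.

## Design balancing

Stimuli sets are balanced for lateral content before any experiment:
`lr_saliency_ratio()` computes mean-left / mean-right saliency per picture
(centre column excluded for odd widths so the halves stay disjoint), and
`assign_balanced_blocks()` partitions pictures into equal blocks,
verifying by one-way ANOVA that no block differs in mean ratio. Because a
random partition occasionally lands unbalanced, balance is enforced by
rejection sampling: redraw until the ANOVA p-value exceeds 0.2 (retry cap
1000, both reported in the output). The degenerate all-equal case is
defined as F = 0, p = 1. Mirroring utilities (`mirror_x()`,
`mirror_fixations()`, `mirror_saliency()`) support presenting mirrored
blocks to half of the participants.

## Spatial models

`average_gaze_table()` collapses fixations to the mean centred horizontal
position per participant x stimulation x timepoint. Two linear mixed
models are provided, both estimated by REML with `lme4`, with type-III
F-tests using Satterthwaite denominator degrees of freedom (`lmerTest`)
and Bonferroni-corrected post-hoc contrasts (`emmeans`); factor contrasts
are sum-coded so the type-III tests are meaningful.

**Pre-post model.** `mean_x ~ stimulation * timepoint + n_fixations`
with by-participant random intercepts plus participant-within-stimulation
and participant-within-timepoint intercept deviations. In a single-group
repeated-measures design the factors themselves cannot carry random
intercepts; the participant-within-factor deviations are the closest
faithful structure, and `random = "participant"` gives the simpler
variant. The fixation-count covariate controls for exploration style
(many short vs few long fixations) and is dropped automatically (with a
note) when constant.

**Baseline model.** Pre-post comparisons are vulnerable to
regression-to-the-mean, so the second model conditions on the baseline:
the post-stimulation average gaze position is regressed on
`stimulation * baseline` (baseline = the same session's T0 value), with
by-participant random intercepts. Requesting the richer
participant-within-stimulation structure is allowed, but with one
observation per participant-session it is degenerate by construction;
when the fit is singular, non-identifiable, or any variance component
falls below `1e-6` x residual variance, the model is automatically
refitted with participant-only intercepts and the event is recorded in
the result (`$reduced`, `$notes`). Degenerate noiseless fits fall back to
ordinary least squares with an explicit note; fixed-effect estimates are
unchanged by that fallback on balanced data.

## The temporal cluster-mass permutation analysis

This is the core of the package. The chain is:

1. **Binning** (`bin_fixations()`): each fixation joins the single 100-ms
   bin containing its start time (`floor(start_ms / 100)`, 0-based,
   half-open bins; 70 bins for 7 s). The cell value is the unweighted mean
   of centred x over all contributing fixations, pooled across pictures.
   Cells with no fixation start are *missing*, not zero: fabricating
   values would bias the null.
2. **Bin-wise tests** (`binwise_tests()`): for each bin, an F statistic
   for the stimulation-by-timepoint interaction (or a main effect) from a
   fully-within repeated-measures ANOVA — each effect tested against its
   interaction with participants — using the participants whose condition
   cells are all present in that bin. Bins with fewer than 2 complete
   participants are untestable (`NA`). A per-bin linear mixed model
   (`method = "lmm"`, participant random intercept, Satterthwaite df) is
   also provided; the two coincide on balanced complete data under
   compound symmetry, but the ANOVA decomposition is orders of magnitude
   faster, which is what makes a 5000-permutation null practical — hence
   it is the default.
3. **Cluster formation** (`form_clusters()`): maximal runs of adjacent
   bins with p below the forming threshold (default 0.05) become
   clusters; member F values are summed into the *cluster mass*. A single
   significant bin is a cluster of one; untestable bins break adjacency.
4. **Permutation null** (`permutation_null()`): under the null of no
   stimulation-by-timepoint effect, each participant's set of condition
   bin series is exchangeable. Every permutation therefore re-randomises
   the cell labels independently within each participant (whole series
   move together, preserving temporal autocorrelation), re-runs the
   *entire* test-and-cluster chain at the same forming threshold, and
   records the maximum cluster mass (0 when none forms). Using the
   maximum over the whole timeline controls the family-wise error rate.
   Cluster p-values use the `(b + 1) / (B + 1)` estimator, so `p_perm`
   is never exactly zero and equals `1/(B+1)` when the observed mass
   beats every permutation. The missingness pattern, the complete-case
   participant sets, and therefore the set of testable bins are invariant
   under this scheme, which keeps observed and permuted statistics
   exactly comparable; the identity relabeling reproduces the observed
   statistics bitwise. The scheme label, B and seed are recorded in every
   result. Alternative schemes (e.g. sign-flipping of within-participant
   differences) would be valid for restricted designs but are not
   implemented; requesting an unknown scheme is an error rather than a
   silent fallback.
5. **Window post-hoc** (`window_posthoc()`): for each significant
   cluster, gaze positions of fixations starting inside the cluster
   window are averaged per cell and the stimulation-by-timepoint mixed
   model is refitted on that window, with Bonferroni post-hocs, giving
   interpretable contrasts in px (and degrees).

`run_pipeline()` orchestrates ingest → exclusion → spatial models →
binning → permutation → window post-hocs under one `run_config()` (or a
YAML file), seeds every random stage, and writes TSV tables plus a
plain-text summary; identical config and seed give byte-identical output.

## The synthetic generator and what it does (not) show

`simulate_dataset()` generates the full factorial (participant x
stimulation x timepoint x picture) with the statistical structure the
analysis assumes:

* **Timing**: fixation durations are gamma-distributed (shape 4, mean
  300 ms), drawn sequentially and truncated at 7 s — about 23 fixation
  starts per trial, matching the order of magnitude reported for this
  kind of task (~22 per image). The gamma family is a standard positive,
  right-skewed choice for fixation durations; only the mean is
  contractual.
* **Trajectory**: the population mean position follows smooth half-cosine
  interpolation through anchors (0 px at 0 ms, −50 px at 1 s, +30 px at
  3.5 s, 0 px at 7 s) — the left-early / right-mid / centre-late pattern.
  Only the anchors are contractual; the interpolant is swappable.
* **Heterogeneity**: each participant carries a constant horizontal bias,
  SD 40 px, reflecting the large between-subject spread seen in free
  exploration; per-fixation horizontal noise has SD 100 px. The noise SD
  was fixed a priori by a power calculation: with 25 pictures and ~8
  fixation starts per bin-cell, a −40 px shift in one condition cell
  yields a per-bin interaction noncentrality of about 12 at n = 22, which
  makes a 500-ms effect detectable by the cluster chain with high
  probability while leaving single bins individually uncertain — the
  regime the method is designed for.
* **Effect injection**: an `injected_effect()` adds a constant shift to
  fixations of one stimulation x timepoint cell whose start time falls in
  a half-open window, providing exact ground truth for recovery tests.
* **Reproducibility**: a single seed drives L'Ecuyer-CMRG streams, one
  per participant and one substream per trial, so enlarging the sample
  leaves existing participants' data bit-identical, and the caller's RNG
  state is never disturbed.

The generator emulates the *statistical* structure only. It does not model
saliency-driven scanpaths, vertical bias, saccade dynamics, drift or
calibration error, inter-picture content differences, or serial dependence
of successive fixations beyond the shared trajectory. Passing the
validation suite therefore shows that the inference machinery is correct
under its stated assumptions — not that those assumptions hold for any
particular recorded dataset.

## Validation settings and known limitations

The automated checks run at deliberately chosen problem sizes: family-wise
error is estimated on 500 null datasets (8 participants, 2 timepoints, 12
pictures, B = 200) and must stay inside the 99% binomial band around 0.05;
power and coverage are estimated on 100 datasets at the full design size
(22 participants, 3 x 3 cells, 25 pictures) with a −40 px, 500-ms injected
effect, requiring a significant overlapping cluster in at least 80% and
window-contrast CI coverage of the true shift in at least 90%. These sizes
are the package's own validation design choices.

Known limitations:

* The per-bin parametric p-values entering cluster formation assume
  homoscedastic cell means; unequal per-cell fixation counts make this
  approximate. The *cluster-level* inference does not inherit this
  approximation — the permutation distribution re-runs the same statistic
  — but the forming threshold is effectively a tuning constant, as in all
  cluster-mass methods.
* Cluster p-values are interpretable at the cluster level only; neither
  the exact onset nor the offset of an effect is localised beyond the
  cluster extent.
* The complete-case rule per bin discards participants with any missing
  condition cell in that bin; with sparse data this can make late bins
  untestable rather than weakly tested.
* `fit_prepost_model()`'s full random structure is frequently singular on
  small designs; results carry explicit `singular` / `converged` flags and
  are never silently replaced.

## A worked example

```{r, eval = FALSE}
cfg <- run_config(
  sim_config = simulation_config(
    seed = 1, effect = injected_effect("FEF", "T1", c(5700, 5900), -40)),
  B = 1000, seed = 1)
bundle <- run_pipeline(cfg)
bundle$clusters          # clusters with mass and p_perm
bundle$window_results    # per-cluster post-hoc mixed models
```

With the default generator and an injected −40 px effect between 5700 and
5900 ms, the pipeline typically reports a significant cluster overlapping
that window and a window post-hoc FEF T1−T0 contrast within a few px of
−40; the acceptance script (`scripts/acceptance.R`) recomputes exactly
these quantities from scratch.
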