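---
title: "Detecting attention decrement from fNIRS signals: models and methods"
author: "nirsvigilance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting attention decrement from fNIRS signals: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsvigilance)
```

## The scientific problem

Attention cannot be sustained indefinitely: during a long, monotonous
reaction-time task, performance degrades with time on task (the
*vigilance decrement*), behaviorally visible as lengthening reaction
times. A passive brain-computer interface that could flag this
decrement from cortical activity would be valuable wherever lapses are
dangerous. Continuous-wave functional near-infrared spectroscopy
(fNIRS) is a candidate sensing modality: it tracks changes in oxy- and
deoxy-hemoglobin concentration (\[O~2~Hb\], \[HHb\], in µM) over
cortex, cheaply and wearably.

This package implements, end to end, the analysis such a study runs:

1. **simulate** a multi-subject experiment — seven subjects, a 2-min
   rest baseline, then a 30-min psychomotor-vigilance task (150 ms
   flashes, uniform 2–15 s inter-stimulus intervals), recorded over
   seven channels (three frontopolar PFC channels at Fp1/Fpz/Fp2 and
   four around the right parietal P6 position) at 10 Hz;
2. **preprocess** the signals — 4th-order Butterworth low-pass at
   0.1 Hz, movement-artifact reduction by moving-SD detection plus
   spline correction, then z-normalization;
3. **featurize** — one-second epoch means per channel and chromophore,
   the first ten task minutes labelled *full attention* and the last
   ten *attention decrement* (600 epochs per class per subject);
4. **classify** — a linear soft-margin SVM (C = 1) under
   leave-one-subject-out (LOSO) cross-validation, over the
   3 × 3 design space {PFC, parietal, both} × {O2Hb, HHb, both}
   (feature dimensions 3–14);
5. **behavior** — first-versus-last ten-minute reaction-time block
   means, a paired Student t-test and Cohen's d of change.

No real recordings ship with the package: the synthetic-data module is
a first-class, tested component that generates cohorts with known
ground truth, so every downstream stage can be scored against the
truth that produced its input.

## The synthetic cohort model

Each channel's O~2~Hb series is a sum of interpretable components:

* a stimulus-locked response train: the canonical double-gamma
  hemodynamic response (positive lobe peaking near 5 s, undershoot
  near 15 s), scaled to a configurable peak (default 0.3 µM, a typical
  event-related amplitude) with a per-channel gain in [0.8, 1.2] and
  lognormal trial-to-trial amplitude variability (CV 0.3, drawn
  independently per channel) — channels share stimulus timing but not
  the exact evoked fluctuation, as regional responses do in practice.
  Within a channel the HHb series scales the same response train, so
  the chromophores stay neurovascularly coupled;
* the **attention effect**: a region-specific mean shift that ramps
  linearly from task minute 10 to minute 20 and then holds, so the
  first and last task thirds differ by exactly the configured amount.
  The contrast only constrains the first/last ten minutes; the
  transition shape in between is this package's choice. Defaults:
  +0.4 µM over right parietal channels, +0.2 µM over the PFC —
  parietal dominance reflects that area's stronger association with
  sustained attention;
* cardiac (1.1 Hz, 0.15 µM) and respiratory (0.3 Hz, 0.1 µM)
  sinusoids with random phase per channel — exactly what the 0.1 Hz
  low-pass is there to remove (at 10 Hz sampling the cardiac line is
  below Nyquist, but the generator stays well-defined even when it
  aliases);
* a slow baseline wander (standardized Gaussian random walk, default
  SD 0.05 µM) and white measurement noise (default SD 0.15 µM);
* movement artifacts: spikes (1–10 samples, amplitude 5–20 × the noise
  SD, windowed excursion) and baseline shifts (persistent steps),
  Poisson-placed at a default 0.2 events/min/channel — sparse, as
  appropriate for a seated, head-supported task. Every injected
  artifact is recorded in a ground-truth segment table so the
  correction stage can be scored.

The HHb series scales the functional components (evoked response and
attention shift) by a negative ratio (default −0.3, reflecting the
smaller, inverted deoxy-hemoglobin response of neurovascular
coupling), with its own smaller oscillations, drift and noise. An
explicit `attentionEffectHhb` override lets tests inject an effect
into one chromophome only. Artifacts are common-mode across
chromophores.

Reaction times are lognormal (right-skewed, as empirical RT
distributions are; a truncated-normal switch is provided),
moment-matched to a target mean and SD (defaults 300 ms and 50 ms).
The target mean is flat over the first task third, ramps linearly over
the middle third, and holds at the late value over the final third.
Two sources of variability matter here:

* within subject: trial-to-trial RT scatter (50 ms);
* between subjects: each subject's *own* mean slowing is drawn around
  the population value (default +40 ms) with SD 35 ms
  (`rtSlowingSdBetween`). Individual differences in vigilance
  decrement are large in practice; without this term every simulated
  cohort produces implausibly enormous standardized effect sizes
  (d ≈ 4), whereas with it cohort-level t and d land in the
  moderate-to-large range typical of 30-minute vigilance protocols.

A configurable fraction of trials (default 5%) are programmed lapses:
half omissions, half slow responses beyond 600 ms, exercising the
validity filter.

Determinism: per-subject seeds are derived arithmetically from the
master seed and the subject index, so a cohort is bit-reproducible and
can be extended with new subjects without reshuffling existing ones.

### What the generator does *not* emulate

Superficial (scalp blood flow) contamination, region-dependent optical
pathlength, heteroscedastic or 1/f instrument noise, learning or
circadian effects on RT, and any coupling between behavioral lapses
and momentary hemodynamics. Passing tests on this generator therefore
demonstrate that the *pipeline machinery* is correct and that effects
of the assumed form are recoverable — not that the classifier would
reach any particular accuracy on real recordings.

## Preprocessing

**Optical conversion.** The modified Beer–Lambert law relates
optical-density changes at the instrument's two wavelengths (763 and
855 nm) to chromophore concentration changes:
ΔOD(λ) = (ε~O2Hb~(λ)·Δ\[O~2~Hb\] + ε~HHb~(λ)·Δ\[HHb\]) · L · DPF,
with L the 3.5 cm emitter–detector separation and DPF the
differential pathlength factor. The DPF is subject-specific via the
age formula DPF = 4.99 + 0.067·age^0.814^ (the standard adult
age-dependence; e.g. a 29-year-old has DPF ≈ 6.03). `mbllConvert()`
solves the 2 × 2 system exactly, so the forward/inverse round trip is
identity to numerical precision. The extinction table is
configuration; the default is interpolated from the standard compiled
hemoglobin absorption spectra. The simulator generates concentrations
directly — optical densities appear only when testing this conversion,
by forward-applying the model.

**Filtering.** `lowpassFilter()` takes Butterworth coefficients from
the `signal` package. Zero-phase (forward–backward) filtering is the
default because the analysis is offline; a causal mode is provided for
real-time-style use. Edge handling is explicit: the demeaned series is
extended by odd reflection over 6/f~c~ seconds before the two passes,
long enough that start-up transients decay below numerical noise. This
gives exactly unit DC gain on constants, linearity to 1e-9, and
squared-magnitude stopband behaviour |H(f)|² = (1+(f/f~c~)^2n^)^−1^ —
at 1 Hz with the default 4th order and f~c~ = 0.1 Hz, far beyond 60 dB
attenuation.

**Movement-artifact reduction.** Real studies often identify artifact
channels by eye; an automated rule replaces visual identification here
because a reproducible artifact needs one. Detection runs on the
*unfiltered* series, where an abrupt spike or step stands out sharply
against the white measurement noise: samples whose centered 1-s
moving SD exceeds 3 × its median are flagged (an absolute floor
handles the constant-series degenerate case: no detection, no
exception), each flagged run is extended by half a window — a flagged
sample indicts its whole window, and without the extension the two
transition edges of a sustained excursion would register as separate
events — and runs closer than 0.5 s are merged. Applying the same
detector to the low-pass-filtered trace instead would flag smooth
physiological slopes against a near-zero noise floor and let false
corrections erase genuine slow structure, including the attention
effect itself.

Correction is applied to the filtered trace, over each detected
segment dilated by 10 s per side (one cutoff period — the zero-phase
filter smears an abrupt artifact symmetrically by about that much):
fit a smoothing spline to the segment and subtract it, seat the
residual on a linear extrapolation of the local trend fitted on the
flanking data (window at least ten moving-SD windows and twice the
segment length, stopping at neighbouring segments, so slow evoked
fluctuations average out of the slope estimate), and shift everything
after the segment by the constant offset between that extrapolated
trend and the data that follows. Baseline steps vanish, trends across
the segment are carried through rather than flattened, and samples
outside segments change only by constant offsets. The smoothing
parameter in [0, 1] (default 0.99, follow the artifact tightly) is
mapped linearly onto `smooth.spline`'s `spar` scale; segments shorter
than 8 samples fall back to a linear fit. The method's published
parameters are not fixed by the study this design follows, so window,
threshold, smoothing, merge distance and dilation are all configurable
with the defaults above.

**Normalization.** z-normalization is applied per subject × channel ×
chromophore over the full recording (baseline + task). The source
narrative is ambiguous on the normalization scope — its methods state
z-normalization while its discussion speaks of percentage changes —
and does not say whether the 2-min baseline served as reference; this
package implements the methods-section z-normalization over the whole
recording and exposes nothing else. The chain order is fixed and
regression-tested: filter → artifact correction → z-norm (permuting
the order demonstrably changes the output).

## Classification

The classifier is a linear soft-margin SVM: minimize
½‖w‖² + C·Σ~i~ max(0, 1 − y~i~(w·x~i~ + b)), with C = 1 as in the
study design (its original analysis used a desktop SMO implementation
whose internals are not reproduced — any exact solver of the same
convex problem is equivalent at the optimum). The solver here is
sequential minimal optimization on the dual with an unregularized bias
(equality constraint), maximal-violating-pair selection with a
second-order gain criterion, and a duality-gap stopping rule at 1e-8.
With a linear kernel every gradient update is O(nd) via the explicit
weight delta, so no kernel cache is needed; the inner loops run in
C++. Correctness is certified two ways in the tests: analytic
solutions of hand-solvable margin geometries, and objective
equivalence (within 1e-6) with a brute-force QP oracle — an exhaustive
KKT active-set enumeration — on random small instances, both separable
and not.

Class encoding is full_attention = −1, attention_decrement = +1; ties
(decision value exactly 0) go to +1, a convention the study leaves
unstated. No feature scaling happens inside the classifier — inputs
are already z-normalized upstream, matching the pipeline order.

LOSO cross-validation trains each fold on six subjects (3600 epochs
per class at the default design) and scores the held-out subject's
1200 epochs, reporting percent correct overall and per class period;
fold accuracies are aggregated by unweighted mean (folds are balanced
by construction) and the train/test subject sets are asserted disjoint
on every fold. `evaluateDesignSpace()` runs all nine
region × chromophore cells.

Interpreting LOSO accuracies on synthetic cohorts deserves care: after
0.1 Hz low-pass filtering, consecutive 1-s epoch means are strongly
autocorrelated, and each subject contributes idiosyncratic slow
structure (drift, residual artifact steps). Fold accuracies therefore
scatter far more than a binomial count of independent epochs would
suggest. The package's null-cohort checks therefore (i) switch off
the slow subject-idiosyncratic components (drift, artifacts) so the
check targets classifier calibration rather than those confounds,
(ii) average over several seeds, and (iii) compare the grand mean
against the binomial band for a single cohort evaluation's epoch
count — the seed average stabilizes the estimate; the band is not
shrunk with the pooled count, precisely because epoch decisions are
not independent. A related consequence of plentiful training data:
grid cells whose feature set contains the informative channels tie
with the minimal informative cell (extra noise dimensions cost a
linear SVM essentially nothing), so grid comparisons in the tests pit
signal-bearing cells against signal-free ones rather than asserting a
strict global argmax.

## Behavioral analysis

Responses are valid when they fall 150–600 ms after stimulus onset
(a ±1e-6 ms tolerance guards the window edges against floating-point
subtraction); omissions and out-of-window responses are excluded from
block means. For force recordings, `extractResponseOnset()` finds the
first crossing of baseline mean + 5 SD (baseline = the 500 ms
pre-stimulus window) within 1.5 s of the stimulus — the acquisition
software rule the original protocol delegated is made explicit here.
Block means over the first and last ten task minutes feed a two-sided
paired Student t-test (sidedness is this package's choice; the design
only states a significance level) and Cohen's d of change — mean
change divided by the SD of change — which makes t = d·√n an algebraic
identity that the tests assert to 1e-9. Skewness/kurtosis of the
change scores are reported as diagnostics only, never used as a gate.

## Worked example

A compact cohort (three subjects, 20-minute task — the shortest for
which the class windows are defined) keeps this vignette fast; the
package default is the full seven-subject, 30-minute design.

```{r example, eval = FALSE}
cfg <- simConfig(nSubjects = 3, taskDuration = 1200, seed = 7)
cohort <- preprocessCohort(simulateCohort(cfg))

tab <- buildFeatureTable(cohort, "parietal", "O2Hb")
losoCrossValidate(tab)

behaviorAnalysis(cohort)

# the full nine-cell design space (about a minute at this size)
gridSummary(evaluateDesignSpace(cohort))
```

`runPipeline()` chains all stages, writes every intermediate artifact
(long-format `signals.csv`, `events.tsv`, `trials.tsv`,
`truth_artifacts.tsv`, per-cell `features_*.csv`, `results.csv`,
`behavior.csv`, `report.yaml`), and stamps each output with a hash of
the configuration so mismatched intermediates are refused on re-reads.
A thin command-line wrapper over these functions is installed at
`inst/cli/nirs-vigilance.R`.

## Numerical choices and problem sizes

* SMO tolerance 1e-8 (duality gap); oracle-equivalence tests run at
  1e-10 on small instances.
* Filter edge padding 6/f~c~ s, odd reflection about the endpoints of
  the demeaned series.
* Artifact detection floor 1e-10 on the moving-SD threshold
  (degenerate constant series flag nothing).
* Epoch intervals are half-open [t, t+1 s) anchored at the window
  start; a trailing incomplete epoch is dropped. Epochs overlapping
  corrected artifact segments are retained — the design's 600 epochs
  per class per subject implies no epoch exclusion.
* Test problem sizes: most unit and property tests use 3–4 subject
  cohorts with 20-minute tasks (600 epochs per class, the same class
  geometry as the full design at a quarter of the training cost); the
  structural bookkeeping checks use the full 7-subject, 30-minute
  design; stochastic calibration checks use 4-subject cohorts over
  20 seeds (classifier ordering) and trial-level simulation over 500
  seeds (t-test calibration).

## Known limitations

* The generator's attention effect is a smooth deterministic ramp;
  real decrements fluctuate and partially recover (e.g. after brief
  rest or motivation changes).
* Artifact correction erases true signal variation inside corrected
  segments and can accumulate small re-leveling offsets across many
  segments; at high artifact rates this residual can rival a small
  attention effect, which is visible in grid accuracies as fold-level
  scatter.
* LOSO with seven subjects is high-variance; single-seed grid
  orderings should not be over-interpreted (the tests therefore
  average over seeds).
* The SVM is linear only, by design; no other kernels or
  hyperparameter searches are provided.
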