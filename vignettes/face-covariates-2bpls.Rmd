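---
title: "From facial action-unit tracking to design covariates: the two-block PLS pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From facial action-unit tracking to design covariates: the two-block PLS pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plsface)
```

## The problem

Resting-state neurocognitive recordings (EEG with eyes open in front of a
blank screen or a face video) come with no behavioural task, so there is no
response accuracy or latency to anchor the analysis on. One usable
behavioural signal that *is* recorded is the participant's face. Frame-level
face tracking (OpenFace-style output) provides, per video frame, the
intensity of FACS action units (AUs) on a 0–5 regression scale, gaze angles,
and a tracking confidence. `plsface` turns those frame streams into
per-trial behavioural covariates and asks, in one joint decomposition, how
they covary with the experimental design: the subject's gender, the stimulus
on the screen (blank / own face / other face), the trial's position in its
condition, and the subject's identity.

## Per-trial covariates

Each eyes-open trial (about two minutes of near-still sitting) is reduced to:

* **AU expression range**: `max − min` of each AU's intensity over the
  trial's retained frames. During quiet sitting the mean and standard
  deviation of an AU track are dominated by many small tracking
  fluctuations; the few genuine expression excursions are what differ
  between conditions, and the range is the statistic that captures them.
* **Gaze-on-screen proportion**: the fraction of retained frames whose
  gaze-angle magnitude $\sqrt{g_x^2+g_y^2}$ is at or below an angular
  threshold (default 0.1745 rad = 10°). Participants are free to look away,
  so this proportion is informative rather than a compliance check. The
  threshold is a configuration knob and is recorded in the run metadata;
  results should be read as conditional on it.

Quality control precedes both: frames must have a raised success flag and
confidence ≥ 0.75 (a conventional tracking cut; the source studies list
behavioural exclusions, not a numeric threshold, so this is a package
default exposed in `qc_config()`). A trial is flagged *excluded* — never
silently dropped — when fewer than half of its frames survive QC or fewer
than `min_frames` (default 300, ≈10 s at 30 fps) remain.

## The two blocks

The model's objects are trials, not subjects: trial-order features only vary
within a subject. Block 1 (instrumental) holds the 13 behavioural variables:
the gaze proportion plus 12 AU ranges. The default AU set
(`default_au_set()`) is a documented reconstruction covering the muscles
the fitted structures are usually read on (brow raisers, brow lowerer /
depressor glabellae, cheek raiser, nose wrinkler, upper-lip raiser, lip
corner puller and depressor, dimpler/buccinator, risorius, chin raiser,
lips part); it is configurable and deliberately not hard-coded as canonical.

Block 2 (features) one-hot encodes the design: one indicator per subject
(individual specificity), per gender, per stimulus type, and per trial
position — with the full 18-subject design, 18 + 2 + 3 + 3 = 26 binary
columns. This composition is itself a reconstruction that reproduces the
published column count and contains every feature the structures are
interpreted on. Redundant indicator groups (both genders, all three
conditions) are kept instead of reference coding: the decomposition
tolerates exact collinearity, and full coding keeps every loading directly
interpretable. Excluded trials are removed from both blocks pairwise, so
rows stay aligned.

## The model

Write $X_1$ ($n \times p_1$) and $X_2$ ($n \times p_2$) for the two blocks
after column preprocessing. Two-block PLS seeks unit vectors $u_k, v_k$
maximising the covariance of the projected scores
$\mathrm{cov}(X_1 u_k,\, X_2 v_k)$, successive pairs being orthogonal to the
earlier ones. All pairs at once are the singular value decomposition of the
cross-product matrix:

$$X_1^\top X_2 = U\, D\, V^\top,$$

with $K = \min(p_1, p_2)$ latent structures; $U, V$ are the orthonormal
weight matrices, the scores are $T_1 = X_1 U$, $T_2 = X_2 V$, and
$\mathrm{cov}(t_{1k}, t_{2k}) = d_k/(n-1)$. This one-shot SVD (the
symmetric, inter-battery form of two-block PLS) coincides with iterative
NIPALS-with-deflation for this case and is deterministic, which is why it
is the implementation; the choice is recorded in the model's preprocessing
metadata. The SVD view also makes the method indifferent to $p > n$ and to
exactly collinear columns — both facts are exercised in the tests.

**Preprocessing.** Both blocks are centered and, by default, scaled to unit
column variance (`mode = "center_scale"`): a binary feature block has far
smaller raw variance than an instrumental block, and without scaling the
instrumental block would dominate the cross-covariance by units alone.
Binary columns are scaled like any others. Zero-variance columns are left
centered (all zeros) and flagged rather than producing NaNs. For data whose
columns already share a scale (e.g. the block-level simulator's output,
which has unit noise everywhere), `mode = "center"` is the better choice
and is what the weight-recovery tests use, because per-column rescaling
distorts the planted direction.

**Variance shares.** The scree quantity is
$d_k^2 / \sum_j d_j^2$ — structure $k$'s share of the total squared
cross-block covariance. Shares sum to one by construction. No automated
"elbow" detection is attempted; the scree table is exported for visual
reading.

**Correlation loadings.** The reported per-variable quantity is the Pearson
correlation between the *original* (un-preprocessed) variable and its own
block's score. Unlike weights, correlation loadings are invariant to
whether scores are rescaled, so they are comparable across conventions;
both conventions of score normalisation would give identical loading plots,
which is why loadings are the exported quantity.

**Significance.** Each correlation loading is tested against zero with the
two-sided t-test, $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom;
the mask marks $p \le \alpha$ (default 0.05). On a paired loading plot the
non-significant region is the square of half-width `critical_r(n, alpha)`
around the origin ($\approx 0.154$ at $n = 162$). A permutation alternative
is built in: row-shuffling block 2 (`n_perm` times, seeded) yields a null
distribution for the first structure's variance share and a p-value; when
an interval is needed from such a null, the package's tests use exact
inclusive order-statistic bounds rather than interpolated quantiles, the
standard exact-permutation construction.

**Sign convention.** SVD columns are sign-ambiguous; each structure is
flipped so the largest-magnitude element of its block-1 weight vector is
positive. This makes refits, and therefore all written outputs,
byte-reproducible.

## The synthetic cohort generator

Real tracked videos of this kind are not publicly deposited, so the package
ships a generator that emulates the study design end to end: 18 subjects
(8 men, 10 women), 3 stimulus conditions × 3 eyes-open trials of 120 s at
30 fps (all configurable in `cohort_spec()`), one OpenFace-style CSV per
trial plus the annotation table.

Frame-level AU series are built as *baseline + AR(1) tracking noise +
sparse expression events*:

* AR(1) noise (lag-1 correlation 0.9, innovation sd 0.03): frame-to-frame
  AU estimates are strongly autocorrelated; white noise would make the
  range statistic grow degenerately with trial length.
* Expression events: raised-cosine bumps of 0.5–2 s at ~3 events/min with
  mean amplitude 0.6. Because the trial statistic is the *range*, which is
  driven by excursions rather than baseline level, every planted effect
  acts on event amplitude.

Planted effects (directions follow the narrative the model is meant to
recover; magnitudes are package calibration, below):

* **Gender** on the dimpler/buccinator (AU14) and risorius (AU20): a main
  amplitude shift (women up, men down) in all trials plus an extra
  first-trial shift in the same directions, mirrored with opposite sign in
  the gaze dwell probability.
* **Stimulus type** on the cheek raiser (AU06) and gaze dwell: own face up,
  blank screen down.
* **Third trial** on brow lowerer (AU04), chin raiser (AU17) and lips part
  (AU25): amplitude up.
* **Individual specificity**: a per-subject, per-AU random amplitude effect.

Gaze is simulated as i.i.d. per-frame on-screen membership at the trial's
dwell probability, with on-screen angle magnitudes strictly inside the
10° threshold and off-screen magnitudes strictly outside. Real gaze has
dwell persistence; independence is a deliberate simplification that keeps
the observed proportion a plain binomial mean of its planted probability,
which the tests verify to ±0.02 at 6000 frames. Consequently the generator
validates the *proportion pipeline*, not models of fixation dynamics.

**Calibration.** Default effect magnitudes were fixed once so that the
first structure's variance share lands in 40–60% of the total. With only a
gender × first-trial interaction the first share plateaus near a third of
the total, so the defaults include the gender *main* effect described
above; after that single calibration the defaults were frozen. This is a
design target for realism of the dominance pattern, not a reproduction of
any particular dataset. The gender main effect is also what makes the
gender contrast, rather than the stimulus contrast, the expected carrier of
the leading structure.

What the generator does **not** emulate: facial appearance (it emits
tracker output, not video), eyes-closed segments, dwell persistence,
cross-AU coupling of events, and non-stationarity within a trial. Passing
tests therefore demonstrate the pipeline's statistical behaviour under a
plausible data-generating process, not performance on real tracked faces.

## Numerical and testing choices

* Orthonormality, share-sum, and score-cross-covariance diagonality are
  asserted at 1e-10 on every fit the tests make.
* The brute-force oracle for the leading covariance pair scans 1°-step
  grids of unit-vector pairs (blocks of up to 3 columns); agreement is
  asserted at 1e-3, the grid's own resolution bound.
* Weight recovery on planted rank-1 blocks ($n = 162$, $p_1 = 13$,
  $p_2 = 26$, default signal-to-noise 2) requires $|r| > 0.9$ against the
  planted pair in ≥95% of 100 seeded replicates.
* Null calibration: with nothing planted, the observed first share must sit
  inside the exact central 95% permutation interval in ≥90% of 20 seeded
  replicates (the permutation interval uses 199 shuffles).
* End-to-end tests run the full 18-subject design with 15-second trials —
  the block shapes and structure count are what matter there, and they are
  independent of trial length; the full 120-second default is exercised by
  the direction-recovery test and the acceptance script.
* Degenerate inputs: empty frame sets and all-excluded trials raise typed
  errors ("insufficient data", alignment errors) rather than propagating
  NA; constant columns are flagged, loaded as 0, and never scaled.

## Limitations

* The 26-column feature block and the 12-AU instrumental set are documented
  reconstructions of a published block design whose exact table is not
  machine-readable; both are configurable, and the structure count simply
  follows $K = \min(p_1, p_2)$ for whatever sets are configured.
* The t-test on correlation loadings treats trials as independent objects;
  trials within a subject are not strictly independent, which is precisely
  why subject indicators are included in the feature block and why the
  permutation option exists.
* The scree is exported, not interpreted: choosing how many structures to
  read is left to the analyst.
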