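---
title: "Sweet-spot mapping and fiber filtering: models, assumptions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sweet-spot mapping and fiber filtering: models, assumptions, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimmap)
```

## The scientific problem

Deep brain stimulation (DBS) of the subthalamic nucleus treats the motor
symptoms of Parkinson's disease, but outcomes vary with exactly *where*
in and around the nucleus the stimulation acts. Two complementary
population-level models formalise this:

* a **sweet-spot map** (R-map): at every voxel of a common template
  space, the across-patient correlation between the local electric-field
  (E-field) magnitude and the clinical outcome;
* a **fiber-filtering model**: for every streamline of a tract atlas,
  the across-patient correlation between the streamline's stimulation
  exposure (peak E-field magnitude along it) and the outcome — its
  *Fiber-R-Score*.

Both models are fitted on a training cohort and then used
*out-of-sample*: a new patient's E-field is summarised into a single
scalar per model — a spatial Spearman correlation with the R-map (the
*Sweet Spot Score*), and a stimulation-weighted mean of the
Fiber-R-Scores of the streamlines the field reaches (the *Weighted Mean
of Fiber R-Scores*). Validation asks whether these scalars correlate
with the new cohort's clinical improvements.

`stimmap` implements this pipeline end to end, together with a
synthetic two-cohort generator that plants a known target so that every
stage can be checked against ground truth.

## The sweet-spot model

Let $e_{iv}$ be patient $i$'s E-field magnitude (V/mm) at voxel $v$ and
$y_i$ the outcome in improvement polarity (higher = better). The
support mask keeps voxels where at least `min_n = 3` patients exceed
the activation threshold `efield_threshold = 0.2` V/mm (strictly; a
magnitude of exactly 0.2 does not count). On the support,

$$ R(v) = \mathrm{Spearman}_i\,(e_{iv},\, y_i), $$

with $R(v) = 0$ by convention where the magnitudes have zero variance.
The 0.2 V/mm threshold is the conventional activation estimate for
typical stimulation parameters; `min_n` guards against voxels whose
correlation would rest on one or two patients.

Scoring a held-out patient computes the Spearman correlation between
their magnitudes and $R(v)$ over the support restricted to voxels their
own field activates (`support = "thresholded"`). Rank correlation makes
the score invariant to any strictly increasing transform of the
magnitudes, so a crude field model and a finite-element solution that
agree in rank ordering give identical scores. Supports smaller than 10
voxels yield an explicitly undefined score — never a silent 0, because
0 is a meaningful rank correlation. Undefined scores are excluded (and
counted) by `validate_cohort()`.

Two genuinely open choices are exposed as configuration: the voxel-wise
statistic (`spearman`, the default, matching the rank-based validation
arm; or `pearson`) and the scoring support (`thresholded`, `mask`,
`nonzero`). The R-map keeps signed values rather than being clipped to
positive voxels.

## The fiber-filtering model

For streamline $s$ with peak interpolated magnitude $p_{is}$ in patient
$i$,

$$ r_s = \mathrm{Spearman}_i\,(p_{is},\, y_i), $$

computed only for streamlines exposed (peak $> 0.2$ V/mm) in at least
`min_exposed = 3` patients; under-exposed or zero-variance streamlines
are flagged `unscored` with $r_s = 0$. Model fitting uses *peak*
magnitudes; validation weighting uses *average* magnitudes $m_s$ along
each intersected streamline:

$$ W_i = \frac{\sum_{s \in I_i} m_{is}\, r_s}{\sum_{s \in I_i} m_{is}},
   \qquad I_i = \{ s : p_{is} > 0.2 \}. $$

"Intersected" is operationalised as the same 0.2 V/mm exposure rule, so
one activation concept serves both models. The normalisation by
$\sum m_{is}$ makes $W_i$ a proper convex mean of the intersected
$r_s$; the unnormalised weighted sum is reported alongside
(`weighted_sum_r`) for sensitivity analyses, since the phrase "weighted
mean" admits both readings. A patient who intersects nothing gets an
undefined score. Both samplers share trilinear interpolation, with
out-of-grid points reading 0 (fields decay to zero far from the
contact).

## The simplified E-field model

The package deliberately replaces patient-specific finite-element field
solving with an isotropic point source,

$$ |E|(r) = \frac{A \, k_\mathrm{cal}}{\max(r, r_\mathrm{min})^2}, $$

with amplitude $A$ (V), calibration constant $k_\mathrm{cal} = 1$ mm,
and singularity clamp $r_\mathrm{min} = 0.5$ mm (roughly an electrode
contact radius). Every downstream statistic consumes only magnitudes,
ranks, or threshold crossings, so any smooth monotone radial field
preserves the pipeline's logic; with $k_\mathrm{cal} = 1$ a 2 V
stimulation crosses 0.2 V/mm at $\sqrt{10} \approx 3.2$ mm, a
physiologically plausible stimulation extent. Current-controlled
amplitudes (mA) are placed on the V scale by a configurable 1 mA = 1 V
default, since no principled conversion exists without impedance data.
Bilateral implants are handled by mirroring contacts across the
midsagittal plane into one hemisphere (`mirror_to_hemisphere()`);
`pool_bilateral()` offers voxel-wise `max` (default reading:
stimulation reaches a voxel from either side) or `mean` pooling for
workflows that keep both hemispheres.

Out of scope by design: tissue conductivity, directional leads,
multi-contact fractionation, and axon-cable activation models.

## Clinical outcomes and polarity

Two outcome conventions coexist in this literature: a *progression*
change score (follow-up minus baseline on the UPDRS-III motor scale,
measured OFF therapy after washout; higher = worse) and a long-term
*percent improvement* (higher = better). All correlations in `stimmap`
are computed after conversion to improvement polarity
(`cohort_improvement()`), so a positive map value, Fiber-R-Score, or
validation correlation always means "stimulation here associates with
better outcomes". Levodopa-equivalent daily doses are computed from a
shipped, editable conversion-factor table (`ledd_factors()`); the table
covers single-agent factors and does not model COMT-inhibitor
multipliers.

Inference: the asymptotic p-value for a Spearman correlation uses the
t-approximation with average-rank ties. Because the cohorts of interest
are small (n = 14 and 29), a Monte-Carlo permutation p with add-one
smoothing, $(1 + \#\{|\rho_\pi| \ge |\rho_{obs}|\})/(B + 1)$, is always
computed alongside; two-sided is the default. Undefined patient scores
are excluded and counted, never imputed.

## What the synthetic generator emulates

`synth_config()` fixes the study conditions:

* **Cohorts.** A 14-patient training cohort (amplitudes 1.9 ± 0.3 V,
  60 µs, 130 Hz, washout change-score outcome) and a 29-patient
  validation cohort (21 voltage-controlled patients at 2.9 ± 0.9 V and
  8 current-controlled at 3.0 ± 0.6 mA, percent-change outcome),
  mirroring the headline characteristics of the early-stage and
  advanced-stage STN-DBS cohorts this design emulates. Baseline
  UPDRS-III draws are 28.0 ± 10.2 (training) and 20.6 ± 9.3
  (validation), clipped at 0; scores are kept continuous rather than
  integer-rounded.
* **Geometry.** A 24 mm box at 0.5 mm isotropic resolution around a
  planted target at (12, −13, −6) mm — a dorsolateral-STN-like site in
  the mirrored (right) hemisphere. Active contacts scatter around the
  target with isotropic σ = 2 mm truncated at 5 mm (electrodes aimed at
  a nucleus do not miss by a centimetre); alternating patients are
  labelled left-hemisphere and stored mirrored.
* **Outcome model.** improvement $= a - b \cdot d + \mathcal N(0, sd)$
  with $d$ the contact-to-target distance: training $a = 2$ points,
  $b = 3$ points/mm, $sd = 1.5$ points; validation $a = 30$\%,
  $b = 12$\%/mm, $sd = 12$\%. The linear-in-distance form is the
  simplest model under which "proximity implies better outcome" holds
  and recovery is analyzable. The noise levels are calibrated to a
  moderate effect: strong enough that a 14-patient cohort identifies
  the target, weak enough that validation correlations land in the
  0.3–0.6 range typical of published cohort-level results. Setting
  $b = 0$ yields null cohorts for calibration studies.
* **Tractogram.** Three on-target bundles traverse the target along
  different axes (analogues of beneficial motor pathways converging on
  the sensorimotor target) and five off-target bundles surround it at
  5 mm offsets (analogues of detrimental neighbouring pathways, which
  displaced stimulation reaches). On-target bundles are short (6 mm
  half-length) so exposure falls off with displacement in *every*
  direction; construction guarantees on-target streamlines pass within
  `target_sigma` = 1 mm of the target and off-target streamlines stay
  beyond 4 mm (violating jitter draws are rejected and redrawn).
  Streamlines are cubic-spline interpolations of five jittered control
  points.

Determinism: the full dataset is a pure function of `seed`; training,
validation, and tractogram generation use independent substreams, so
changing `n_valid` never alters the training cohort.

**What passing tests do not show.** The generator has no anatomy
(no nucleus boundary, no tissue anisotropy), isotropic fields, a single
effective contact per patient, outcome noise that is Gaussian and
independent across patients, and bundles that are geometric primitives.
Recovery and validation-power results on these data demonstrate that
the *pipeline's statistics* behave as designed — not that any specific
clinical dataset would yield the same correlations.

## Numerical choices and degenerate inputs

* Ranks use the average-rank tie convention throughout.
* Zero-variance vectors: voxel/streamline correlations are 0 by
  convention (flagged unscored for streamlines); cohort-level
  correlations return an explicit `NA`.
* Perfect correlations report an asymptotic p of 0 rather than a
  divide-by-zero `t`.
* Trilinear interpolation clamps the floor index so points exactly on
  the upper grid face remain valid; outside points read 0.
* Volumes must have an invertible affine; E-field cohorts must share a
  grid exactly (tolerance 1e-6 on affine entries).
* Streamlines need ≥ 2 points with consecutive points distinct; TCK
  files are read/written in native mm with float32 precision (~1e-4 mm
  round-trip tolerance); TRK is refused because its on-disk coordinate
  convention varies by writer.

## Problem sizes used in the shipped checks

The test suite and the acceptance script exercise the pipeline at the
default study conditions: 20-seed sweeps for target recovery and
out-of-sample validation power, 200 null cohorts at $b = 0$ for the
size of the permutation test (199 permutations each), and 999
permutations for single-study reports. A full single study takes a few
seconds; the complete simulation battery runs in a few minutes on one
core.

## Known limitations

* The point-source field is rank-faithful but not calibrated in
  absolute V/mm; `k_cal` only sets the activation radius scale.
* The mA-to-V conversion default (1:1) is a convention, not physics.
* The LEDD table omits combination-drug multipliers.
* Fiber-R-Scores inherit the instability of small-sample rank
  correlations; with n = 14 training patients, occasional off-target
  bundles acquire non-zero medians by sampling accident (the shipped
  defaults keep this rare but cannot eliminate it).
* No cluster-level correction or permutation thresholding of the R-map
  is provided; the map is used for scoring, not for voxel-wise
  inference.
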