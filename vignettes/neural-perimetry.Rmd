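---
title: "Neural perimetry and training-effect inference: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural perimetry and training-effect inference: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroreserve)
```

This vignette documents the scientific model behind `neuroreserve`, the
tunable parameters and their defaults, what the synthetic-data generator
does and does not emulate, and the numerical and design choices that were
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The pipeline

Behavioural perimetry (Humphrey SITA 30-2) asks where a patient *reports*
seeing light; neural perimetry asks where visual cortex *responds* to
stimulation. After post-chiasmatic stroke these maps can disagree, and the
disagreement is the quantity of interest: a location that is behaviourally
blind but cortically responsive ("neural reserve", Hum−/Ret+) is a
candidate substrate for training-induced recovery. The pipeline:

1. **Stimulus apertures** — binary occupancy movies of a rotating wedge and
   an expanding ring (64 s/cycle, one frame per 2 s TR) on a ±45°, 0.5°/px
   raster.
2. **pRF fitting** — circular Gaussian (x₀, y₀, σ) per voxel, grid search +
   local refinement, non-negative amplitude and free baseline in closed
   form; variance-explained (VE) filter at 0.20.
3. **Coverage** — per-pixel max over voxels of the unit-amplitude Gaussian
   profile; max per 6°×6° Humphrey cell; global-max renormalisation;
   binarisation at 0.5.
4. **Classification** — four Humphrey × retinotopy categories; blind spot
   excluded first; rare Hum+/Ret− excluded from statistics (reversibly).
5. **Statistics** — per-category mean dB change (per-patient-then-mean
   pooling), within-patient permutation null, GAS association,
   trained-vs-untrained comparison.

## 2. Key parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| raster `half_extent`, `step` | 45, 0.5 | deg | wide-field stimulation; sub-degree accuracy at tractable cost |
| wedge width | 45 | deg | constant-width reading of the "maximum ~45°" wedge |
| cycle length | 64 | s | one rotation/expansion per cycle |
| `e2` (magnification constant) | 0.75 | deg | inverse-linear cortical magnification scaling of ring width |
| HRF | double gamma, peak 6 s, undershoot 16 s, ratio 1/6 | — | canonical BOLD impulse response; unit-sum at TR |
| search grid | 11 eccentricities × 16 angles; 8 σ log-spaced 0.5–15° | deg | covers the stimulated field; log spacing matches σ's multiplicative role |
| `ve_min` | 0.20 | fraction | standard coverage-map inclusion criterion (boundary inclusive) |
| coverage threshold | 0.5 | fraction | binarisation default; 0.25/0.75 for robustness checks |
| Hum+ rule | dB > 0 (strict) | dB | 0 dB = unseen at maximum intensity, read as blind |
| blind-spot QC gate | > 0.20 | fraction | standard clinical exclusion on blind-spot false detections (strictly greater) |
| improvement threshold | 1 | dB | perimeter's effective resolution; inclusive (≥ 1 dB) |
| permutation iterations | 10,000 | — | Monte-Carlo p with +1 smoothing |

## 3. Design choices in the open points

**Wedge geometry.** The wedge is treated as a constant 45°-wide binary
sector ("maximum angular width" read as constant width). Its leading edge
starts on the positive horizontal meridian — the source does not state the
start angle — and the choice is recorded in the aperture metadata. The
checkerboard texture and 2 Hz contrast reversal are not modelled: they are
sub-TR and only spatial occupancy enters the pRF forward model.

**Ring geometry.** Only "scaled by eccentricity in accordance with the
cortical magnification factor" is specified, so the functional form was
open. We use ring width w(e) = c·(e + e2) with e2 = 0.75° and centres
advancing linearly from fixation to 45° over one cycle; c is fixed by
requiring the first two annuli to exactly abut, which (i) guarantees that
one cycle's rings cover the full disc, (ii) degenerates to constant-width
rings as e2 → ∞, and (iii) leaves no free tuning. The implied rings are
wide; an experiment with a log-position sweep (constant cortical speed)
produces sub-pixel foveal rings that violate the no-empty-frame invariant
at the default raster, so the linear sweep was kept.

**Joint wedge+ring fitting.** Wedge and ring runs are concatenated and
fitted jointly (convolution never crosses the run boundary); separate
fitting is available by passing a single aperture. Acquisition-matched runs
are ~4.5 min, i.e. 4 cycles per stimulus at TR 2 s.

**Linear terms.** Amplitude β is constrained non-negative (negative visual
responses are out of model scope and would corrupt coverage maps); the
baseline is free. Both are profiled in closed form inside the search.

**Tie-breaking.** Exact (within 1e−9·TSS) RSS ties resolve to the smallest
σ, then smallest eccentricity, then lexicographic position — the candidate
grid is pre-sorted in that order, so "first minimum" implements the rule
deterministically.

**Refinement.** Nelder–Mead on (x₀, y₀, log σ) from the best grid candidate
at each of the three lowest-RSS σ values (multi-start, because the RSS
surface trades σ against radial position), relative tolerance 1e−6, hard
bounds: centre eccentricity ≤ 45°, σ ∈ [0.05°, 180°]. `refine = FALSE`
reproduces the pure grid solution exactly.

**Normalisation order.** Coverage uses unit-amplitude Gaussians (per-voxel
peak normalisation) *and* the downsampled map is divided by its global
maximum across locations. The two readings differ only when no location
reaches 1; `binarize_coverage()` emits a message whenever the
renormalisation changes any binary call.

**Grid construction.** The 30-2 lattice is the 10×10 grid at ±{3,9,15,21,27}°
minus six corner points per quadrant; the removal rule — drop a point iff
its eccentricity exceeds 30° or both |x| ≥ 21° and |y| ≥ 21° — is the
unique simple rule reproducing the canonical 76 locations (38 per
hemifield). The blind-spot candidate is the single temporal location
(±15°, −3°) of the tested eye; only the blind-spot false-detection index
gates QC (strictly > 20%), other indices are reported but not gating.

**Pooling and permutation unit.** Published dispersions are compatible with
either per-location or per-patient pooling; the default pools patients
first (per-patient category means, then mean ± SE across patients), and the
permutation shuffles labels *within* patient, preserving each patient's
category composition and all between-patient heterogeneity. Location-level
pooling is available. Tests are one-sided for the directional hypothesis
(reserve > other); two-sided is a flag.

**"Changed-only" effects.** The changed-only variant keeps locations with
change ≥ 1 dB (the perimeter's resolution); a strict ≠ 0 variant is
available (`changed_rule = "nonzero"`).

## 4. What the generator emulates — and what it does not

`simulate_cohort()` produces, per patient: a hemianopia or quadrantanopia
(7:3 by default), spared islands (2 × 6° radius at scotoma test locations)
and a 7° reserve margin (both neural-reserve mechanisms are implemented:
islands of surviving tissue, and behavioural scotomas that exceed the
neural scotoma); a hill-of-vision pre map (peak 33 dB, −0.3 dB/deg, 1.5 dB
measurement noise, 35 dB ceiling); per-location coverage values (Ret+ truth
uniform on (0.55, 1), Ret− on (0, 0.45), so the 0.5 threshold reproduces
truth exactly and 0.25/0.75 perturb it); category-dependent training
effects; and GAS scores linked to the count of recovered reserve locations.

Effect defaults are the published cohort-level means — 1.34 dB (reserve),
0.76 dB (seen), 0.22 dB (blind-blind) — with *synthetic* location-level SDs
of 1.0/0.8/0.3 dB (no location-level dispersions are published; these sit at
clinical test-retest scale and keep dB-floor truncation bias well below the
recovery tolerance). A zero-inflated mixture mode reproduces the
changed-only reading: a location improves with probability mean/9.12 by a
draw from N(9.12, 0.93²) dB, so the category mean is preserved while
improved locations average ~9 dB. A per-patient offset (SD 0.3 dB) adds
between-patient heterogeneity; an untrained mode draws category-independent
drift (0.11 ± 0.5 dB).

Deliberate idealisations: no SITA staircase simulation (the 0 dB floor is
treated as absorbing and *reliable* — deep defects reproduce exactly, and
measurement noise applies only where sensitivity is non-zero); no
hemodynamic nonlinearity, physiological noise spectra or anatomical
realism; coverage values are drawn directly at cohort level rather than
re-derived from voxels for every patient (the fMRI route is exercised
separately and in the acceptance script); GAS goal scores are real-valued
within the −3…+2 scale rather than integer-rounded, so a noise-free linkage
is exactly linear. A green cohort-level test therefore establishes that the
*estimator chain* recovers the stated world — not that the generator
matches every property of patient data.

**The calibration null.** For type-I-error calibration the generator must
embody its own null: "category-independent effects". Because the dB floor
censors changes only where pre = 0 dB, drawing Gaussian changes and
clamping would make *realised* changes category-dependent — a violation of
the null by construction, discovered and fixed during development. In
`null_effects` mode the realised change itself is drawn identically for
every location (floor censoring inside the draw), making within-patient
labels genuinely exchangeable.

## 5. Numerical choices and degenerate inputs

* Flat (zero-variance) voxel series return `ve = 0` with a `degenerate`
  flag instead of erroring.
* An empty estimate set yields an all-zero coverage map with a warning; an
  empty VE filter result warns but is returned.
* Negative device dB ("<0") is coerced to 0 with a warning; dB > 50 is
  rejected.
* Missing reliability indices make QC "indeterminate" (`pass = NA`), not a
  failure.
* Permutation p-values use (1 + #{null ≥ obs})/(1 + B): never exactly zero,
  standard for Monte-Carlo tests.
* All simulators take a `seed` and restore the ambient RNG state; cohort
  generation derives per-patient sub-seeds from the master seed and records
  them, so every cohort is bit-reproducible.

## 6. Known limitations

* **σ recovery at low SNR.** With acquisition-matched data (two 4-cycle
  runs = 256 volumes) at SNR 3 (amplitude / noise SD), the median relative
  σ error of the full fit is ~0.17. This is an information limit, not an
  estimator defect: an oracle that knows the true pRF position and profiles
  σ alone achieves ~0.13–0.17 across the eccentricity range under identical
  conditions, so targets much below that are unreachable at this SNR and
  scan length. Position recovery is far better behaved (median error
  ≲ 0.4°). Users who need tight σ estimates should average more runs.
* Coverage values across grid locations are not quantitatively comparable
  (SNR and magnification vary across cortex and are deliberately not
  modelled); only the binary Ret± call is used downstream.
* No spatial modelling of category borders; no mixed-effects models; no
  multiple-testing correction beyond reporting both pairwise p-values.
* The pipeline assumes preprocessed (motion-corrected, run-averaged) BOLD
  input; only optional linear detrending is provided.
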