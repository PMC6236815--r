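---
title: "Evaluating adaptive radiotherapy replan flags with artflag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating adaptive radiotherapy replan flags with artflag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(artflag)
```

## The framework

Adaptive radiotherapy (ART) protocols replan a treatment course in response
to anatomical change. The flag evaluated here is the common institutional
trigger for head-and-neck courses: a per-fraction change in external body
contour exceeding 1.5 cm. `artflag` quantifies how well such a flag
identifies the fractions that actually carry clinically significant dose
deviations, in four stages:

1. **Contour change** (`body_contour_change()`): on every axial slice where
   both the planning and current external contours exist, the symmetric
   Hausdorff distance between the two boundary point sets; the flag value
   is the maximum over slices. The comparator is strictly greater
   ("exceeding"), so a change of exactly 1.5 cm does not flag.
2. **Per-fraction dosimetry** (`dvh_parameter()`,
   `extract_fraction_parameters()`): DVH statistics of each structure on
   the per-fraction dose grid; course-level accumulation
   (`interpolate_series()`) linearly interpolates parameter values between
   CBCT-assessed fractions and averages over all fractions.
3. **Grading** (`grade_fraction()`): each parameter against a criterion —
   reference × (1 ± v/100), v the median of physician survey responses
   (`aggregate_survey()`); strict breach; severity class is a property of
   the criterion, not of the breach magnitude.
4. **Assessment** (`assess_categories()`, `diagnostic_metrics()`): truth
   tables per violation category, each assessed fraction counted
   independently, plus the random-flag baseline
   (`random_flag_sensitivity()`).

## Model assumptions

* All masks and dose grids live on one voxel grid in the bony (room) frame;
  rigid bony registration is upstream and assumed done. Voxel membership is
  center-inside; distances are in cm, doses in Gy, fraction indices
  1-based.
* The symmetric Hausdorff distance is used (the directed current-to-plan
  variant is available via `directed = TRUE`, with no claim about which the
  manual clinical measurement corresponds to).
* Boundary points are centers of boundary voxels (mask voxels with a
  non-mask in-slice 4-neighbor), so contour measurements carry a sampling
  tolerance of up to one in-plane voxel diagonal.
* `Dx%` is the k-th highest voxel dose with k = ceiling(x/100·N) — no
  fractional interpolation; `VxGy` and dose-at-volume counting are
  inclusive (≥). Dmax is the single hottest voxel. The low-dose PTV is
  evaluated excluding the high-dose PTV volume (mask subtraction before the
  DVH).
* Accumulation holds the nearest assessed value constant before the first
  and after the last CBCT (interpolation is only defined between assessed
  fractions; extrapolating a trend before the first CBCT would invent
  data). Accumulated estimates are graded against the same criteria as
  single fractions; this is configurable and deliberately conservative,
  since per-parameter averaging assumes e.g. Dmax recurs at the same
  location.

## Violation criteria

The shipped default criteria (`inst/extdata/default_criteria.yaml`,
`default_criteria()`) are a documented reconstruction: the institutional
table is not fully recoverable. Anchored values: spinal-cord Dmax objective
48 Gy with a 3% major margin, i.e. a 49.4 Gy threshold; GTV/CTV criteria
copied from PTV criteria (no formal GTV/CTV objectives exist); target
coverage and brainstem/cord sparing major-class; target hot spot and
parotid sparing minor-class. The percent margins without a recoverable
value are package choices: 5% for target coverage and hot spot, 10% for
parotid mean dose. Parotid criteria are referenced to the planned value
rather than an absolute objective because the phantom's parotids deliberately
overlap the elective volume, as real parotids often do — an absolute
26 Gy-type objective would be violated at baseline. Optic structures are
major-class clinically but absent from the default phantom, hence absent
from the default file.

A criterion with `reference: planned` resolves against the course's planned
parameter values at grading time. Undefined diagnostic ratios
(zero denominators) are reported absent (`NA`), never zero, to avoid
silently deflating averages.

## The random-flag baseline

Under independence — each of k assessed fractions flagged with probability
p and violating with probability q — and a cohort retained only when a
patient has at least one flag (the inclusion bias of a flagged-only study
cohort), the pooled sensitivity is

E[TP] / E[TP + FN] = q·E[#flags | ≥1 flag] / (q·k) = p / (1 − (1 − p)^k),

independent of q. At p = 0.20 and k = 6 (a 33-fraction course imaged every
five fractions) this is 0.271 — the 27% bar. The exact derivation behind
the published figure is not reproducible from the available text, so k is
exposed as a parameter (the closed form spans ~25–30% for k in 5–7) and the
Monte-Carlo path (`random_flag_sensitivity()`) constructs per-patient
truth tables and pools them, converging to the closed form.

## The synthetic cohort

`build_phantom()` rasterizes an analytic anatomy: an elliptic-cylinder neck
(semi-axes 5.5 × 4.5 cm) over wider shoulder slices, a 1 cm-radius
spherical GTV, a posterior spinal-cord cylinder (bony frame — never moves),
a superior brainstem and lateral parotids, on a 0.25 cm grid. Margins
follow the clinical recipe: CTV = GTV + 7.5 mm (midpoint of the quoted
5–10 mm range), PTV = CTV + 3 mm, PRVs of 3 mm (brainstem) and 5 mm
(cord); the elective (nodal) CTV is a 10 mm further expansion, a phantom
construction choice. Target margins are applied analytically (the exact
Euclidean dilation of a sphere is a larger sphere) so planning and
per-fraction masks share one voxelization convention and an unchanged
anatomy reproduces the planned parameters exactly; the general-mask
operation `expand_margin()` implements the same contract on arbitrary masks
and is cross-checked against brute-force distance oracles. Note that
digital dilation under-fills an analytic sphere by roughly half a voxel per
stage (about −4 to −5% in volume at 0.1 cm spacing for the two-stage
recipe): the voxel-center convention can only reach the outermost *centers*
of the input mask.

The dose engine is deliberately simple, not a TPS surrogate: planned dose
is, per voxel, the maximum over prescription levels (70 / 59.4 Gy) of the
prescription times a conformity factor — 1 inside the level's PTV, a
Gaussian penumbra falloff outside it. The penumbra sigma defaults to
0.3 cm: at 0.5 cm the stated edema volume ratios (peak 1.256, a 1.4 mm CTV
radius change) produce no measurable coverage degradation at all, and
0.3 cm is the more realistic 6 MV penumbra width. Delivered dose per
fraction is the planned field, held fixed in the bony frame, rescaled by
`exp(μ · mean path-length reduction)` along the two lateral beams with
μ = 0.035/cm — calibrated so a 1.5 cm depth reduction gives the classic
~5% central-axis increase.

Scenario trajectories (`scenario_config()`):

* **weight_loss** — radial erosion of the external at `shrink_rate`
  cm/fraction (default 0.05), angularly weighted: full rate laterally, 15%
  posteriorly over the spine. Uniform erosion at realistic total losses
  would push the posterior surface inside the cord; lateral weighting keeps
  the bony frame embedded while the flag, a maximum over the slice, still
  measures rate × fraction exactly at the lateral axis. Soft-tissue
  structures (targets, parotids) are advected toward the eroded surface in
  proportion to their relative radial depth; the cord is fixed.
* **localized_edema** — tumor volume follows the piecewise-linear ratio
  trajectory 1 → 1.256 (fraction 8) → 0.598 (fraction 33); target radii
  scale by the cube root. Because the peak CTV radius change (1.4 mm) is
  sub-voxel, two gain parameters translate it into resolvable effects:
  `edema_bulge_gain` (8) scales the matching local external bulge
  (peritumoral soft-tissue swelling; deflation leaves a 0.3× shallower
  indentation, so the contour-change trajectory peaks at the peak
  fraction), and `edema_shift_gain` (3) displaces the target center toward
  the nearest surface — the asymmetric growth that actually degrades
  coverage.
* **shoulder_shift** — the shoulder slices' external displaced by a
  constant setup-error vector from fraction 1.
* **composite** — weight loss plus a constant systematic target shift in
  the bony frame (coverage loss by non-coincidence of target and dose,
  which dominates the simultaneous hot-spot increase).

Measured contour change optionally carries zero-mean Gaussian noise
(σ = 0.1 cm, the therapist measurement uncertainty). The CBCT schedule
defaults to every five fractions (fractions 5, 10, …, 30, so k = 6), with
roughly a third of simulated patients also imaged at fractions 1–3.
`simulate_cohort()` draws scenario kinds from a mix (default 35% weight
loss, 25% edema, 20% shoulder, 10% composite, 10% no change) with
magnitudes in clinically plausible ranges (weight-loss rates 0.03–0.09
cm/fraction, shoulder shifts 0.5–1.2 cm, composite target shifts
0.3–0.8 cm); everything is reproducible from the master seed.

What a green test does — and does not — establish: the generator reproduces
the *directional* phenomena (hot spots rise under shrinkage, coverage falls
under geometric shifts, contour change tracks the configured trajectories)
and the framework's arithmetic end to end. It does not reproduce CBCT image
content, deformable-registration error, multi-beam fluence, or the
correlation structure of real clinical violations; published clinical
counts are therefore used as fixed fixtures in tests, never regenerated.

## Numerical choices

* Strict inequalities at the flag threshold and at violation thresholds
  (a value exactly at threshold does not flag / violate).
* Contour-measurement tolerance: one in-plane voxel diagonal.
* Degenerate inputs error loudly and name the offending structure,
  parameter or row: empty contours, empty masks, missing parameters,
  schema-version mismatches, flags on unassessed fractions.
* Seeds: every stochastic routine takes a seed, restores the caller's RNG
  state, and records the seed in its outputs; output files embed an MD5
  hash of their configuration.

## Limitations

* Dose is never warped or re-optimized; accumulation is per-parameter
  interpolation, a conservative estimate.
* The phantom's dose engine has no build-up region, scatter, or beam
  modulation; absolute OAR doses (e.g. brainstem) are not realistic, only
  their trends under anatomy change are meaningful.
* DICOM-RT and NIfTI ingestion are not provided; cohorts interchange as
  CSV/JSON/YAML, and masks are in-memory arrays.
* Minor-violation assessment reuses the same machinery with minor
  thresholds; no claim is made about reproducing any published
  minor-violation average.
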