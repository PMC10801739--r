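---
title: "Modeling lumbar decompression surgery with forward-dynamic multibody simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling lumbar decompression surgery with forward-dynamic multibody simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinedyn)
```

## The question

Decompression of a stenotic lumbar spinal canal removes passive
stabilizers. An interlaminar fenestration (laminotomy) sacrifices the
ligamentum flavum at the index level on one side (uILF) or both sides
(bILF); a laminectomy (LAM) additionally removes the spinous process with
its inter- and supraspinous ligaments and the flava of the adjacent upper
level. How much each technique destabilizes the spine — and how the
internal disc loads redistribute — cannot be observed in static clinical
imaging. `spinedyn` answers this *in silico*: it builds subject-specific
six-body lumbar spine models (L1–sacrum), drives them through a
standardized flexion with a forward-dynamic simulation, performs the
three virtual surgeries by deleting the corresponding ligaments, and
quantifies the changes in intervertebral kinetics with endpoint
normalization, level-wise t-tests and one-dimensional statistical
parametric mapping (SPM).

Forward dynamics is the essential choice: motion is not prescribed but
*emerges* from the applied loads and the passive elements, so the same
loading protocol can be replayed after a virtual surgery and the altered
kinematics and kinetics are predictions, not inputs.

## Synthetic anatomy

Patient CT segmentations are not distributable, so the package generates
parametric landmark-based geometry that emulates them. Each vertebra
carries exactly 47 labelled landmarks in its body frame (+X anterior, +Y
left, +Z superior, millimetres): 36 facet points (3×3 grids on the four
articular surfaces), two endplate centres, the spinous process tip, and
eight ligament insertion points (ALL, PLL, left/right flavum, ISL, SSL,
left/right intertransverse). The capsular ligaments share facet points —
anatomically adjacent insertions are represented by a single landmark —
routing from the caudal edge of an inferior facet to the cranial edge of
the opposing superior facet. The published total of 47 points per
vertebra fixes the budget; its partition is this package's convention,
chosen so every landmark count is testable.

`generate_spine()` stacks the six bodies with segmental lordosis wedges
(default 45° total, distributed 10/14/19/25/32% from L1/L2 to L5/SA),
disc heights of 9–11 mm, and a 3 mm anterior slip of L4 over L5
emulating the grade-I degenerative spondylolisthesis of the target
population. Two alignment steps follow: the whole assembly is rotated so
the upper endplate of L3 is exactly horizontal (the standardized initial
position), and the inferior facet points of each vertebra are projected
onto the superior facet plane of the vertebra below at a 1 mm articular
clearance, making the joint surfaces congruent ("alignment of the joint
in each motion segment"). The sacrum is fixed.

`sample_cohort()` draws subject-specific lordosis (CV 8%), per-level disc
heights (CV 10%), global body dimensions (CV 5%) and facet orientation
(SD ≈ 0.8° per CV unit) from truncated normal distributions (±3 SD) so
no subject receives non-physical geometry (e.g. inverted disc heights).
The default cohort of 15 subjects mirrors the size of the modeled patient
collective. Landmark positions within a subject are deterministic; a
`jitter_mm` parameter can add surface-point placement noise.

What the generator does *not* emulate: osteophytes and irregular bone
shape, segmental asymmetry (defaults are exactly mirror-symmetric, which
the symmetry tests exploit), varying vertebral body wedge shapes, and the
correlation structure of real anatomical covariation. Passing cohort
tests therefore demonstrate the mechanical and statistical machinery
under controlled variability, not anatomical realism.

## Passive elements

**Ligaments** are tension-only cables between landmarks with a C1
force–strain law: zero below the slack length, a power-law toe
(exponent 2 by default) up to the toe strain, then linear with stiffness
`k` (newtons per unit strain). At the toe transition the tension is
`k * toe_strain / 2`. Slack lengths are set to the assembly-posture
lengths (`slack_ratio = 1`), so the neutral stacked spine is exactly in
equilibrium — a property the integrator tests assert. Left and right
flavum, intertransverse and capsular fascicles are separate elements so
unilateral fenestration can remove one side only. Default stiffnesses
(N/strain: ALL 1300, PLL 800, LF 650 per fascicle, ISL 600, SSL 1000,
ITL 600, CL 800) are at the stiffer end of the published lumbar range;
they were chosen so that the posterior ligament complex carries the
dominant share of the flexion moment at the end of the loaded protocol,
consistent with transection experiments and with the small in-disc
moments (≈ −1 to −7 Nm) reported for comparable intact models.

**Intervertebral discs** are six degree-of-freedom bushings at the
mid-disc point: tabulated nonlinear moment–angle curves about the
flexion–extension, lateral-bending and axial-rotation axes and
force–displacement curves along the anterior–posterior, medio-lateral
and superior–inferior axes, each interpolated with monotone
(Fritsch–Carlson) cubics and continued linearly with the end slope
outside the tabulated range. Lateral bending and axial rotation tables
are odd-symmetric by construction and validated as such. Small linear
viscous damping (1.5 Nm·s/rad, 1000–1500 N·s/m) is a numerical-settling
device, not a physiological claim. The default tables span ±12°
(FE/LB), ±6° (AR) and include strain-stiffening tails; lateral bending
and axial rotation are stiffer than flexion, which also keeps the
straight configuration of the column elastically stable under the
500 N dead load (see *Numerical choices*).

**Facet joints** are frictionless point-on-plane penalty contacts: the
nine probe points of the cranial vertebra's inferior facet against the
total-least-squares regression plane of the caudal vertebra's nine
superior facet points. The normal force is zero at separation, rises
quadratically over a 0.1 mm smoothing zone and then linearly at
600 N/mm; contact damping fades in over the same zone so the force is
continuous at touchdown, and the total is clamped non-negative
(unilaterality). Facet planes are oriented 25°–50° from the sagittal
plane (more coronal caudally), so anterior shear of a vertebra engages
its facets — the load path that matters in spondylolisthesis.

## Loading protocols and integration

Two protocols are preconfigured. The **main flexion protocol** applies a
7.5 Nm flexion couple at L1 about the instantaneous disc ML axis plus a
500 N vertical force at L1 (a generic upper-body weight, deliberately
*not* a follower load: its lever arm grows as the spine flexes), sacrum
fixed, 3 s duration. The **validation protocol** applies a pure ±7.5 Nm
moment at L1 with L5 fixed and no preload; the flexion-extension range
of motion (RoM) it produces is compared with the published corridor of
22.3°–30.9° from in vitro experiments and finite-element models.

Both loads ramp linearly over the first 90% of the duration and are then
held, so the endpoint (t = 3 s) is quasi-static: terminal kinetic energy
below 10⁻⁴ J and net body wrench residuals below 0.5% of the applied
loads are asserted. Ramping the preload together with the moment (rather
than pre-settling under the preload alone) is the package default: a
passive, unmuscled spine settles deeply under a 500 N dead load, and
measuring RoM from the neutral posture keeps the outcome a stable,
interpretable quantity. A `presettle` switch provides the settle-first
variant.

The equations of motion are Newton–Euler for each free body (unit
quaternion orientation state with norm stabilization and per-step
renormalization; world-frame angular dynamics with the gyroscopic term),
evaluated in compiled code and integrated with the stiff-capable
adaptive `lsoda` solver onto a fixed 101-node output grid for SPM
compatibility. A pure-R reference implementation of the same
right-hand side is part of the package and the test suite asserts
agreement to 10⁻⁹ on random states. Intervertebral angles are extracted
with a fixed Cardan x–y–z sequence (lateral, flexion, axial).

Masses (1 kg per vertebra) and box-approximation inertia tensors are
plumbing for the dynamic formulation; the measured endpoint is
quasi-static, so their values only affect the transient, and the
solver-tolerance-refinement test verifies the endpoint changes by less
than 0.1% when tolerances are tightened tenfold.

## Calibration

Absolute stiffness values differ widely across published sources, so
the model follows the calibration-by-validation approach:
`calibrate_stiffness_scale()` bisects (on a log scale, deterministic) a
single global factor multiplying all ligament stiffnesses and the disc
rotational curves until the intact template's validation RoM falls
inside the target corridor, 22.3°–30.9° by default. RoM is monotone
decreasing in the scale, which the test suite verifies by simulation.
With the shipped defaults the template lands inside the corridor at
scale 1.0 (22.8°), so calibration is a verified no-op rather than a
correction.

## Virtual surgery

Techniques are pure ligament-removal sets (bone carries no load in the
model, exactly as in the source experiment): uILF removes the left
flavum fascicle at L4/L5; bILF both fascicles; LAM additionally removes
both fascicles at L3/L4 and the inter- and supraspinous ligaments. Since
a laminectomy of L4 removes the L4 spinous process, the ISL/SSL are
removed at *both* adjacent spans (L3/L4 and L4/L5) by default — an
anatomically forced reading; a `lam_isl_spans = "upper"` variant
restricts them to the upper span. The sets are strictly nested
(INTACT ⊂ uILF ⊂ bILF ⊂ LAM), so per-subject RoM and flexion-moment
magnitudes are non-decreasing along the sequence — asserted per subject
in the acceptance suite. Capsular ligaments are never resected.

## Outcome measures and statistics

`joint_load()` reduces the wrench transmitted across a level to the
mid-disc origin, expressed in the instantaneous disc frame of the caudal
vertebra: superior–inferior force (compression positive),
anterior–posterior shear (anterior positive), flexion–extension moment
(flexion negative). Two components are available: `"total"` (every
element crossing the cut — the default for `joint_load`, and the correct
notion of the transmitted wrench) and `"ivd"` (the disc bushing alone).
The cohort outcome tables report the `"ivd"` component: the published
in-disc loads are far smaller than the total transmitted moment must be
under a 7.5 Nm couple plus the preload lever, which identifies them as
disc-borne loads, with the remainder carried by the posterior ligaments
and facets. Capsular ligament forces are reported at L3/L4–L5/SA only,
with not-evaluated markers (NA) at the two uppermost levels.

The statistical pipeline normalizes each operated endpoint outcome to
the subject's intact value (intact ≡ 100%; zero references are flagged
undefined rather than dropped), tests each technique × level × quantity
against 100 with a two-sided one-sample t-test, and maps p-values to the
three significance tiers (tendency 0.05 ≤ p ≤ 0.1; significant
0.001 ≤ p < 0.05; highly significant p < 0.001). The description of an
"unpaired" test against a zero-variance reference column is statistically
degenerate; the one-sample formulation is the well-defined reading and
the default, with the two-sample variant available for procedural
fidelity.

`spm_paired_ttest()` runs node-wise paired t-tests over the 101-node
curves, converts to z-scores by probability transform, and thresholds
with a random-field-theory critical value: residual smoothness (FWHM) is
estimated from the gradients of the variance-normalized residual curves
and the two-tailed critical level solves the expected-Euler-characteristic
equation for a smooth 1D t-field. Critical values are therefore
data-dependent outputs (not constants), exceed the pointwise 1.96 for
any multi-node field, and grow as the field gets rougher. A
1000-replicate null simulation in the test suite confirms a field-wise
false-positive rate within Monte-Carlo error of the nominal 5%. No
correction is applied across levels and quantities beyond SPM's
field-wise control, matching the source analysis.

## Numerical choices

* Units: millimetres in geometry files and landmark tables, SI
  internally; conversions live at the module boundary.
* Solver: `lsoda`, rtol 10⁻⁶; absolute tolerance 10⁻⁸ on positions and
  quaternions and 10⁻⁵ on velocities (velocity transients are orders of
  magnitude above the pose scales; a uniform tight tolerance forces
  thousands of needless Jacobian refactorizations).
* Contact and ligament laws are C1 everywhere, and contact damping fades
  in over the smoothing zone — discontinuous right-hand sides destroy
  the step-size control of stiff multistep solvers.
* Stability under the dead load: an unmuscled lordotic column under
  500 N is near its lateral Euler buckling load if lateral-bending
  stiffness is set to the soft end of the literature; the defaults use
  the stiff end (plus intertransverse/capsular fascicles) so the
  symmetric equilibrium is stable and the symmetric-response invariant
  (out-of-plane motion < 10⁻⁶ of in-plane for symmetric models) holds.
* Degenerate inputs are errors, not warnings: collinear facet points,
  non-monotone or non-odd disc tables, negative disc heights,
  out-of-bounds shape parameters (named in the message), removal sets
  referencing absent elements, and non-finite solver states (reported
  with the failure time).

## Problem sizes

The shipped experiment is sized for a workstation: 15 subjects × 4
techniques × one 3 s flexion each (about 0.2 s of wall time per
simulation with the compiled core), 101 output nodes, and 1000-replicate
SPM null calibrations. All cohort-level results in the tests and the
acceptance script are computed at exactly these sizes.

## Known limitations

* No musculature, thorax or pelvis: the 500 N dead load stands in for
  the upper body, and absolute RoM under the main protocol (≈ 36–41°
  intact) is accordingly larger than muscled in vivo flexion at equal
  load. Percent changes between techniques are the designed outcome.
* In-disc AP shear at the lower levels is sensitive to how much shear
  the facets carry (clearance, orientation); its absolute magnitude
  should not be over-interpreted, though its redistribution after LAM
  (decrease at L3/L4 and L4/L5, increase above) is robust in the cohort.
* The disc model has no poroelasticity, osmotic swelling or
  intradiscal pressure field; ligaments have no viscoelasticity or
  pre-strain; facet cartilage geometry is reduced to a plane.
* Cohort variability is parametric and uncorrelated; real anatomies
  covary.

## A minimal session

```{r example, eval = FALSE}
template <- generate_spine()
config <- calibrate_stiffness_scale(template)$config

intact <- run_protocol(template, "INTACT", "flexion_main", config)
lam <- run_protocol(template, "LAM", "flexion_main", config)
rom(lam)$rom_deg / rom(intact)$rom_deg

cohort <- sample_cohort(cohort_spec(n_subjects = 15, seed = 42))
runs <- dplyr::bind_rows(lapply(cohort, function(sp) {
  dplyr::bind_rows(lapply(c("INTACT", "UILF", "BILF", "LAM"), function(tech)
    tibble::tibble(subject = sp$subject_id, technique = tech,
                   traj = list(run_protocol(sp, tech, "flexion_main",
                                            config)))))
}))
outcomes <- outcome_table(runs)
level_ttest(normalize_to_intact(outcomes))

curves <- extract_level_curves(runs, "M_FE", "L4-L5")
spm <- spm_paired_ttest(curves$INTACT, curves$LAM, times = curves$times)
autoplot(spm)
```
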