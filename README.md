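# spinedyn

Forward-dynamic multibody simulation of lumbar spine decompression
surgery.

## What this package is for

In degenerative spondylolisthesis with spinal stenosis (most often at
L4/L5), surgeons choose between decompression techniques of increasing
invasiveness: unilateral interlaminar fenestration (uILF, removing the
ligamentum flavum on one side), bilateral fenestration (bILF), and
laminectomy (LAM, removing the lamina and spinous process with the
flava and the inter-/supraspinous ligaments). Static imaging cannot show
how each choice changes the internal forces and moments of the spine.
`spinedyn` is an *in silico* laboratory for this question, aimed at
biomechanists and methodologically minded clinicians: it

1. generates synthetic subject-specific lumbar spine geometries
   (L1–sacrum, 47 labelled landmarks per vertebra, lordosis / disc
   height / size / facet-orientation variability, a grade-I-like
   anterior slip of L4);
2. assembles a forward-dynamic multibody model per subject: six rigid
   bodies with unconstrained 6-DOF joints, stabilized only by passive
   elements — tension-only ligaments with a nonlinear (quadratic-toe)
   force–strain law, six-DOF intervertebral disc bushings with tabulated
   nonlinear characteristics, and frictionless facet contacts (nine
   probe points against a least-squares facet plane);
3. simulates a standardized flexion — 7.5 Nm at L1 plus a 500 N vertical
   preload, sacrum fixed, 3 s — with a stiff ODE solver (compiled
   Newton–Euler core, quaternion states), before and after each virtual
   surgery, which is performed purely by ligament removal;
4. extracts the published outcome measures per level: superior–inferior
   compression `F_SI`, anterior–posterior shear `F_AP` and
   flexion–extension moment `M_FE` in the instantaneous disc frame
   (compression positive, anterior shear positive, flexion negative),
   ligament forces and the L1 range of motion (RoM);
5. runs the cohort statistics: normalization of each operated outcome to
   the subject's intact value (intact ≡ 100%), level-wise t-tests with
   tendency / significant / highly-significant tiers, and 1D statistical
   parametric mapping (node-wise paired t-tests over the full curves
   with a random-field-theory threshold estimated from residual
   smoothness).

The model reproduces the characteristic clinical-biomechanical pattern:
RoM and flexion moment magnitudes grow monotonically with invasiveness
(intact → uILF → bILF → LAM, per subject), fenestration changes are
small (≪ 2%) while laminectomy destabilizes markedly, and anterior shear
*decreases* at the decompressed and adjacent level after laminectomy
while increasing above.

## Worked example

```r
library(spinedyn)

template <- generate_spine()                   # default synthetic subject
cal <- calibrate_stiffness_scale(template)     # land in the published
config <- cal$config                           # flexion-extension corridor
cal$rom_deg
#> [1] 22.82757

intact <- run_protocol(template, "INTACT", "flexion_main", config)
lam    <- run_protocol(template, "LAM",    "flexion_main", config)
c(rom(intact)$rom_deg, rom(lam)$rom_deg)
#> [1] 39.00487 49.47715

joint_load(intact, "L4-L5", t = 3, component = "ivd")
#> # A tibble: 1 × 6
#>   level  time component  F_SI  F_AP  M_FE
#>   <chr> <dbl> <chr>     <dbl> <dbl> <dbl>
#> 1 L4-L5     3 ivd        868.  81.2 -18.6

joint_load(lam, "L4-L5", t = 3, component = "ivd")
#> # A tibble: 1 × 6
#>   level  time component  F_SI  F_AP  M_FE
#>   <chr> <dbl> <chr>     <dbl> <dbl> <dbl>
#> 1 L4-L5     3 ivd        471. -17.1 -45.0
```

Reading this output: the calibrated intact template moves 22.8° under
the pure-moment validation protocol (inside the 22.3°–30.9° corridor
from cadaver and finite-element studies). Under the loaded flexion
protocol the template flexes 39.0° intact and 49.5° after virtual
laminectomy (+26.9%). At the decompressed L4/L5 disc the flexion moment
magnitude more than doubles (−18.6 → −45.0 Nm) while the anterior shear
carried by the disc drops and reverses (+81 → −17 N): with the posterior
tension band gone, the segment rotates further but shears less through
the disc.

Cohort-level analysis chains the same verbs over a sampled population:

```r
cohort <- sample_cohort(cohort_spec(n_subjects = 15, seed = 42))
runs <- dplyr::bind_rows(lapply(cohort, function(sp)
  dplyr::bind_rows(lapply(c("INTACT", "UILF", "BILF", "LAM"), function(tech)
    tibble::tibble(subject = sp$subject_id, technique = tech,
                   traj = list(run_protocol(sp, tech, "flexion_main", config)))))))

outcomes <- outcome_table(runs)                 # 15 × 4 × 5 = 300 rows
tests <- level_ttest(normalize_to_intact(outcomes))

curves <- extract_level_curves(runs, "M_FE", "L4-L5")
spm <- spm_paired_ttest(curves$INTACT, curves$LAM, times = curves$times)
autoplot(spm)                                   # z-curve, threshold, clusters
```

`tidy()` / `glance()` methods return tibbles for every result type, and
`write_run()` exports a long-format CSV plus a JSON manifest (model
hash, protocol, solver settings) per simulation. Geometries round-trip
through versioned JSON (`write_spine_geometry()` /
`read_spine_geometry()`; schema in `inst/extdata/`); element parameters
ship as a versioned YAML file.

The methods vignette
(`vignettes/lumbar-decompression-model.Rmd`) documents the model
assumptions, parameter choices, numerical decisions and limitations.

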