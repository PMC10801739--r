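# Shared fixtures, computed once per test run and cached. The cohort runs
# (15 subjects x 4 techniques) are the expensive part; several test files
# reuse them.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

cached_config <- function() cached("config", load_element_config())

cached_template <- function() cached("template", generate_spine())

cached_template_runs <- function() {
  cached("template_runs", {
    sp <- cached_template()
    cfg <- cached_config()
    lapply(setNames(nm = c("INTACT", "UILF", "BILF", "LAM")), function(tech)
      run_protocol(sp, tech, "flexion_main", cfg))
  })
}

cached_cohort <- function() {
  cached("cohort", sample_cohort(cohort_spec(n_subjects = 15, seed = 42)))
}

cached_cohort_runs <- function() {
  cached("cohort_runs", {
    cohort <- cached_cohort()
    cfg <- cached_config()
    rows <- list()
    for (sp in cohort) {
      for (tech in c("INTACT", "UILF", "BILF", "LAM")) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          subject = sp$subject_id, technique = tech,
          traj = list(run_protocol(sp, tech, "flexion_main", cfg)))
      }
    }
    dplyr::bind_rows(rows)
  })
}

cached_outcomes <- function() {
  cached("outcomes", outcome_table(cached_cohort_runs()))
}

# minimal single-free-body model (no elements) for integrator oracles
make_point_model <- function(mass = 1.3) {
  cfg <- cached_config()
  structure(list(
    spine = NULL, config = cfg, technique = "TEST",
    removal_set = tibble::tibble(name = character(), level = character()),
    levels = "L1", fixed = FALSE,
    masses = mass, inertias = list(diag(3) * 1e-3),
    poses = list(list(R = diag(3), p = c(0, 0, 0))),
    ligaments = list(), bushings = list(), facets = list(),
    model_hash = "point-test"
  ), class = "spinedyn_model")
}

# free body on a linear torsional spring-damper bushing anchored to ground
make_oscillator_model <- function(k_nm_deg = 0.6, c_rot = 0.02,
                                  inertia = 2e-3) {
  cfg <- cached_config()
  cfg$ivd$curves <- list(
    FE = list(angle_deg = c(-30, 0, 30),
              moment_nm = c(-30 * k_nm_deg, 0, 30 * k_nm_deg)),
    LB = list(angle_deg = c(-30, 0, 30), moment_nm = c(-60, 0, 60)),
    AR = list(angle_deg = c(-30, 0, 30), moment_nm = c(-60, 0, 60)),
    AP = list(disp_mm = c(-5, 0, 5), force_n = c(-5000, 0, 5000)),
    ML = list(disp_mm = c(-5, 0, 5), force_n = c(-5000, 0, 5000)),
    SI = list(disp_mm = c(-5, 0, 5), force_n = c(-5000, 0, 5000))
  )
  cfg$ivd$rot_damping <- rep(c_rot, 3)
  cfg$ivd$trans_damping <- rep(100, 3)
  cfg <- spinedyn:::validate_element_config(unclass(cfg))
  b <- ivd_bushing("L1-GND", cfg)
  b$body_caudal <- 2L; b$body_cranial <- 1L
  b$u_ca <- c(0, 0, 0); b$u_cr <- c(0, 0, 0)   # anchored at the body COM
  b$A_ca <- diag(3); b$A_cr <- diag(3)
  structure(list(
    spine = NULL, config = cfg, technique = "TEST",
    removal_set = tibble::tibble(name = character(), level = character()),
    levels = c("L1", "GND"), fixed = c(FALSE, TRUE),
    masses = c(1, 1), inertias = list(diag(3) * inertia, diag(3)),
    poses = list(list(R = diag(3), p = c(0, 0, 0)),
                 list(R = diag(3), p = c(0, 0, 0))),
    ligaments = list(), bushings = list(b), facets = list(),
    model_hash = "oscillator-test"
  ), class = "spinedyn_model")
}

zero_protocol <- function(duration = 3) {
  list(kind = "settle", applied_moment = 0, vertical_force = 0,
       vforce_ramped = FALSE, duration = duration, ramp_fraction = 1)
}
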