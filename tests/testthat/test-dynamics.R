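# Forward-dynamic integration: analytic oracles for the integrator,
# equivalence of the compiled and reference right-hand sides, equilibrium
# preservation, determinism, symmetry, quasi-static endpoint quality and
# solver-tolerance robustness.

test_that("zero applied loads preserve the assembly equilibrium", {
  sp <- cached_template()
  m <- assemble_model(sp, cached_config(), "INTACT")
  tr <- integrate_model(m, zero_protocol())
  y0 <- spinedyn:::state_vector_from_poses(m)
  yT <- tr$states[nrow(tr$states), ]
  for (s in 0:4) {
    expect_lt(max(abs(yT[13 * s + 1:3] - y0[13 * s + 1:3])), 1e-6)  # m
    q0 <- y0[13 * s + 4:7]; qT <- yT[13 * s + 4:7]
    expect_lt(2 * acos(min(1, abs(sum(q0 * qT)))), 1e-6)            # rad
  }
})

test_that("a free body under constant force follows uniform acceleration", {
  m <- make_point_model(mass = 1.3)
  proto <- list(kind = "settle", applied_moment = 0, vertical_force = 2.6,
                vforce_ramped = FALSE, duration = 2, ramp_fraction = 1)
  tr <- integrate_model(m, proto, settings = list(rtol = 1e-10, atol = 1e-12,
                                                  atol_vel = 1e-10))
  z <- tr$states[, 3]
  t <- tr$times
  expect_equal(z, -0.5 * (2.6 / 1.3) * t^2, tolerance = 1e-8)
})

test_that("a torsional spring-damper matches the damped-oscillator solution", {
  k_deg <- 0.6; c_rot <- 0.02; inertia <- 2e-3
  m <- make_oscillator_model(k_deg, c_rot, inertia)
  th0 <- spinedyn:::deg2rad(5)
  y0 <- c(0, 0, 0, cos(th0 / 2), 0, sin(th0 / 2), 0, numeric(6))
  tr <- integrate_model(m, zero_protocol(duration = 1), y0 = y0,
                        settings = list(rtol = 1e-10, atol = 1e-13,
                                        atol_vel = 1e-11, n_out = 51))
  # closed form: I th'' + c th' + k th = 0, underdamped
  k <- k_deg * 180 / pi                      # Nm/rad
  wn <- sqrt(k / inertia)
  zeta <- c_rot / (2 * sqrt(k * inertia))
  wd <- wn * sqrt(1 - zeta^2)
  th_exact <- th0 * exp(-zeta * wn * tr$times) *
    (cos(wd * tr$times) + zeta * wn / wd * sin(wd * tr$times))
  th_sim <- vapply(seq_along(tr$times), function(i) {
    R1 <- spinedyn:::quat_to_rotmat(tr$states[i, 4:7])
    spinedyn:::cardan_xyz(R1)[2]
  }, 0)
  expect_equal(th_sim, th_exact, tolerance = 1e-6)
})

test_that("compiled and reference right-hand sides agree on random states", {
  sp <- cached_template()
  cfg <- cached_config()
  m <- assemble_model(sp, cfg, "BILF")
  proto <- list(kind = "flexion_main", applied_moment = 7.5,
                vertical_force = 500, vforce_ramped = TRUE,
                duration = 3, ramp_fraction = 0.9)
  spinedyn:::dyn_set_model(spinedyn:::flatten_model(m))
  spinedyn:::dyn_set_protocol(0L, 0L, 7.5, 500, 2.7, 1, 1L)
  y0 <- spinedyn:::state_vector_from_poses(m)
  set.seed(41)
  for (rep in 1:5) {
    y <- y0 + rnorm(length(y0), 0, 0.003)
    for (s in 0:4) {
      qi <- 13 * s + 4:7
      y[qi] <- y[qi] / sqrt(sum(y[qi]^2))
    }
    t <- runif(1, 0, 3)
    d_cpp <- spinedyn:::dyn_rhs(t, y)
    d_ref <- spinedyn:::reference_rhs(m, proto, t, y)
    expect_equal(d_cpp, d_ref, tolerance = 1e-9)
  }
})

test_that("trajectories are deterministic and quaternions stay unit", {
  tr1 <- cached_template_runs()$INTACT
  tr2 <- run_protocol(cached_template(), "INTACT", "flexion_main",
                      cached_config())
  expect_identical(tr1$states, tr2$states)
  for (s in 0:4) {
    nrm <- sqrt(rowSums(tr1$states[, 13 * s + 4:7]^2))
    expect_equal(nrm, rep(1, length(nrm)), tolerance = 1e-9)
  }
})

test_that("the flexion endpoint is quasi-static with a balanced wrench", {
  tr <- cached_template_runs()$INTACT
  expect_true(tr$quasi_static)
  expect_lt(tr$kinetic_energy, 1e-4)
  kin <- spinedyn:::trajectory_state(tr, length(tr$times))
  bw <- spinedyn:::body_wrenches(tr$model, kin, max(tr$times), tr$protocol)
  free <- which(!tr$model$fixed)
  expect_lt(max(abs(bw$force[free, ])), 0.005 * 500)
  expect_lt(max(abs(bw$torque[free, ])), 0.005 * 7.5)
})

test_that("symmetric models respond in-plane; uILF breaks the symmetry", {
  sp <- generate_spine(spine_params(l4_slip_mm = 0))
  cfg <- cached_config()
  ti <- run_protocol(sp, "INTACT", "flexion_main", cfg)
  tu <- run_protocol(sp, "UILF", "flexion_main", cfg)
  out_of_plane <- function(tr) {
    yT <- tr$states[nrow(tr$states), ]
    max(abs(yT[seq(2, by = 13, length.out = 5)]))
  }
  in_plane <- max(abs(ti$states[nrow(ti$states),
                                seq(1, by = 13, length.out = 5)]))
  expect_lt(out_of_plane(ti), 1e-6 * in_plane)
  expect_gt(out_of_plane(tu), 1e-6)
})

test_that("RoM grows with applied moment and shrinks with tighter tolerances", {
  sp <- cached_template()
  cfg <- cached_config()
  roms <- vapply(c(0, 4, 7.5), function(mm) {
    cfg2 <- cfg
    cfg2$simulation$applied_moment_nm <- mm
    rom(run_protocol(sp, "INTACT", "flexion_main", cfg2))$rom_deg
  }, 0)
  expect_true(all(diff(roms) > 0))
  # the preload alone already produces flexion through its lever arm,
  # strictly less than with the added moment
  expect_gt(roms[1], 0)
  expect_lt(roms[1], roms[3])

  # refining solver tolerances by 10x changes the endpoint by < 0.1%
  r_def <- rom(cached_template_runs()$INTACT)$rom_deg
  r_tight <- rom(run_protocol(sp, "INTACT", "flexion_main", cfg,
                              settings = list(rtol = 1e-7, atol = 1e-9,
                                              atol_vel = 1e-6)))$rom_deg
  expect_lt(abs(r_tight - r_def) / r_def, 0.001)
})

test_that("removing any single ligament group never decreases flexion RoM", {
  sp <- cached_template()
  cfg <- cached_config()
  base <- rom(cached_template_runs()$INTACT)$rom_deg
  for (nm in c("ALL", "PLL", "LF_left", "ISL", "SSL", "CL_left")) {
    rs <- tibble::tibble(name = nm, level = "L4-L5")
    tr <- run_protocol(sp, rs, "flexion_main", cfg)
    # within solver accuracy (relative tolerance 1e-6 on ~40 degrees)
    expect_gte(rom(tr)$rom_deg, base - 1e-3)
  }
})

test_that("validation protocol uses the fixed L5 and lands in a plausible range", {
  vr <- validation_rom(cached_template(), cached_config())
  expect_gt(vr$flexion_deg, 0)
  expect_lt(vr$extension_deg, 0)
  expect_equal(vr$rom_deg, vr$flexion_deg - vr$extension_deg)
})

test_that("run manifests and long CSVs are written and readable", {
  tr <- cached_template_runs()$INTACT
  dir <- withr::local_tempdir()
  paths <- write_run(tr, dir)
  df <- read.csv(paths[["csv"]])
  expect_true(all(c("time", "level", "quantity", "value") %in% names(df)))
  man <- jsonlite::read_json(paths[["manifest"]])
  expect_equal(man$model_hash, tr$model_hash)
  expect_equal(man$technique, "INTACT")
})
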