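# Constitutive laws of the passive elements: tension-only ligaments with
# a quadratic toe, disc bushings interpolating tabulated characteristics,
# and the C1 penalty facet contact.

test_that("ligament law: slack, toe transition, monotone, errors", {
  lg <- ligament("PLL", c("L4", "L5"), "PLL", "PLL", slack_length = 30,
                 linear_stiffness = 400, toe_strain = 0.05)
  expect_equal(ligament_force(lg, 27), 0)            # below slack
  expect_equal(ligament_force(lg, 30), 0)            # exactly slack
  # closed-form toe value k * toe_strain / 2 at the transition strain
  expect_equal(ligament_force(lg, 30 * 1.05), 400 * 0.05 / 2)
  # linear region: slope k per unit strain
  f1 <- ligament_force(lg, 30 * 1.10)
  expect_equal(f1, 400 * 0.05 / 2 + 400 * 0.05)
  # monotone non-decreasing on random length pairs
  set.seed(31)
  l <- sort(runif(50, 20, 45))
  expect_true(all(diff(ligament_force(lg, l)) >= 0))
  expect_error(ligament_force(lg, 0), "positive")
  expect_error(ligament("X", c("L1", "L2"), "a", "b", slack_length = -1,
                        linear_stiffness = 1), "slack_length")
})

test_that("disc bushing wrench: zero state, odd symmetry, knot values", {
  cfg <- cached_config()
  # table straight out of a three-point compression characteristic
  cfg$ivd$curves$SI <- list(disp_mm = c(0, 1, 2), force_n = c(0, 400, 1000))
  cfg <- spinedyn:::validate_element_config(unclass(cfg))
  b <- ivd_bushing("L4-L5", cfg)

  w0 <- ivd_wrench(b)
  expect_equal(w0$force, c(0, 0, 0))
  expect_equal(w0$moment, c(0, 0, 0))

  # lateral bending is odd: moment at -theta is minus the moment at +theta
  wp <- ivd_wrench(b, rel_rotation = c(0, 3, 0))
  wm <- ivd_wrench(b, rel_rotation = c(0, -3, 0))
  expect_equal(wm$moment[2], -wp$moment[2])

  # 1 mm superior-inferior compression on the 3-point table -> 400 N
  wc <- ivd_wrench(b, rel_translation = c(0, 0, -1))
  expect_equal(wc$force[3], 400)

  # restoring sign: positive flexion angle gives a negative FE moment
  wf <- ivd_wrench(b, rel_rotation = c(4, 0, 0))
  expect_lt(wf$moment[1], 0)
})

test_that("malformed disc tables are rejected at construction", {
  cfg <- cached_config()
  cfg$ivd$curves$AP <- list(disp_mm = c(-1, 0, 1), force_n = c(10, 0, 5))
  expect_error(spinedyn:::validate_element_config(unclass(cfg)), "AP")
  cfg <- cached_config()
  cfg$ivd$curves$LB <- list(angle_deg = c(-2, 0, 2), moment_nm = c(-1, 0, 5))
  expect_error(spinedyn:::validate_element_config(unclass(cfg)),
               "odd-symmetric")
  cfg <- cached_config()
  cfg$ivd$curves$FE <- list(angle_deg = c(-2, 1, 2), moment_nm = c(-1, 1, 5))
  expect_error(spinedyn:::validate_element_config(unclass(cfg)), "origin")
})

make_flat_contact <- function(stiffness = 1000, damping = 0,
                              probe_z = rep(0.5, 9)) {
  grid <- as.matrix(expand.grid(x = c(-4, 0, 4), y = c(-4, 0, 4)))
  plane <- fit_facet_plane(cbind(grid, 0))
  facet_contact(
    pair = list(caudal = "L5", cranial = "L4", side = "left",
                level = "L4-L5"),
    plane = plane, probe_points = cbind(grid, probe_z),
    penalty_stiffness = stiffness, contact_damping = damping,
    smoothing = 0.1)
}

test_that("facet contact: separation, penalty magnitude, action-reaction", {
  id_pose <- list(R = diag(3), p = c(0, 0, 0))
  fc <- make_flat_contact()
  res <- facet_force(fc, id_pose, id_pose)
  expect_equal(res$point_forces, rep(0, 9))
  expect_equal(res$wrench_cranial$force, c(0, 0, 0))

  # one point penetrating 1 mm beyond the smoothing zone: force within 5%
  # of stiffness x depth, directed along the plane normal
  z <- rep(0.5, 9); z[5] <- -1
  fc1 <- make_flat_contact(probe_z = z)
  res1 <- facet_force(fc1, id_pose, id_pose)
  expect_equal(sum(res1$point_forces > 0), 1)
  expect_equal(res1$point_forces[5], 1000, tolerance = 0.0501)
  expect_equal(res1$wrench_cranial$force / sum(res1$point_forces),
               res1$normal, tolerance = 1e-12)

  # Newton's third law on randomly posed bodies, wrenches reduced to a
  # common point
  set.seed(33)
  for (rep in 1:5) {
    pose_a <- list(R = spinedyn:::quat_to_rotmat(rnorm(4)),
                   p = rnorm(3, sd = 0.01))
    pose_b <- list(R = spinedyn:::quat_to_rotmat(rnorm(4) + c(4, 0, 0, 0)),
                   p = pose_a$p + rnorm(3, sd = 0.002))
    res <- facet_force(fc1, pose_a, pose_b)
    expect_equal(res$wrench_cranial$force, -res$wrench_caudal$force)
    # torque about the world origin must cancel
    t_cr <- res$wrench_cranial$torque +
      spinedyn:::cross3(pose_b$p, res$wrench_cranial$force)
    t_ca <- res$wrench_caudal$torque +
      spinedyn:::cross3(pose_a$p, res$wrench_caudal$force)
    expect_equal(t_cr, -t_ca, tolerance = 1e-9)
  }
})

test_that("contact force is never attractive, even with damping", {
  id_pose <- list(R = diag(3), p = c(0, 0, 0))
  z <- rep(0.5, 9); z[5] <- -0.5
  fc <- make_flat_contact(damping = 5000, probe_z = z)
  # probe body moving rapidly away from the plane: damping would exceed
  # the elastic force, the law clamps at zero
  res <- facet_force(fc, id_pose, id_pose,
                     vel_caudal = list(v = c(0, 0, 0), w = c(0, 0, 0)),
                     vel_cranial = list(v = c(0, 0, 1), w = c(0, 0, 0)))
  expect_true(all(res$point_forces >= 0))
  expect_equal(res$point_forces[5], 0)
})

test_that("elastic parts store no energy over a closed loading cycle", {
  lg <- ligament("SSL", c("L4", "L5"), "SSL", "SSL", slack_length = 40,
                 linear_stiffness = 800, toe_strain = 0.04)
  path <- c(seq(40, 48, length.out = 200), seq(48, 40, length.out = 200))
  f <- ligament_force(lg, path)
  # trapezoidal work over the closed loop, normalized by peak stored energy
  w <- sum((f[-1] + f[-length(f)]) / 2 * diff(path))
  peak <- sum((f[1:200][-1] + f[1:200][-200]) / 2 * diff(path[1:200]))
  expect_lt(abs(w) / peak, 1e-6)

  b <- ivd_bushing("L4-L5", cached_config())
  th <- c(seq(0, 6, length.out = 200), seq(6, 0, length.out = 200))
  m <- vapply(th, function(a) ivd_wrench(b, rel_rotation = c(a, 0, 0))$moment[1], 0)
  w <- sum((m[-1] + m[-length(m)]) / 2 * diff(th))
  peak <- abs(sum((m[1:200][-1] + m[1:200][-200]) / 2 * diff(th[1:200])))
  expect_lt(abs(w) / peak, 1e-6)
})
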