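# Transmitted-load reduction, range of motion, and the cohort outcome
# table.

test_that("a static two-body stack transmits exactly the vertical load", {
  m <- make_oscillator_model()
  # place the free body 50 mm above the fixed base, bushing at mid-height
  m$poses[[1]]$p <- c(0, 0, 0.05)
  b <- m$bushings[[1]]
  b$u_ca <- c(0, 0, 0.025)    # disc origin in the ground frame
  b$u_cr <- c(0, 0, -0.025)   # and in the free-body frame
  m$bushings[[1]] <- b
  W <- 300
  proto <- list(kind = "settle", applied_moment = 0, vertical_force = W,
                vforce_ramped = FALSE, duration = 3, ramp_fraction = 1)
  tr <- integrate_model(m, proto)
  tr$reference_body <- "GND"
  for (cmp in c("ivd", "total")) {
    jl <- joint_load(tr, "L1-GND", 3, cmp)
    expect_equal(jl$F_SI, W, tolerance = 1e-6)
    expect_equal(jl$F_AP, 0, tolerance = 1e-6)
    expect_equal(jl$M_FE, 0, tolerance = 1e-6)
  }
  expect_error(joint_load(tr, "L4-L5", 3), "unknown level")
  expect_error(joint_load(tr, "L1-GND", 99), "outside")
})

test_that("joint_load equals a brute-force element sum at arbitrary states", {
  tr <- cached_template_runs()$BILF
  model <- tr$model
  set.seed(51)
  for (i in sample(seq_along(tr$times), 3)) {
    kin <- spinedyn:::trajectory_state(tr, i)
    for (lv in c("L1-L2", "L4-L5")) {
      bi <- match(lv, vapply(model$bushings, `[[`, "", "level"))
      b <- model$bushings[[bi]]
      ca <- b$body_caudal; cr <- b$body_cranial
      D <- kin[[ca]]$R %*% b$A_ca
      origin <- as.numeric(kin[[ca]]$p + kin[[ca]]$R %*% b$u_ca)

      # brute force: accumulate every element force crossing the cut onto
      # the caudal body, reduced to the disc origin point by point
      Fw <- c(0, 0, 0); Mw <- c(0, 0, 0)
      for (l in model$ligaments) {
        if (l$level != lv) next
        pa <- as.numeric(kin[[l$body_cranial]]$p +
                           kin[[l$body_cranial]]$R %*% (l$pa / 1000))
        pb <- as.numeric(kin[[l$body_caudal]]$p +
                           kin[[l$body_caudal]]$R %*% (l$pb / 1000))
        L <- sqrt(sum((pa - pb)^2))
        f <- ligament_force(l, 1000 * L)
        u <- (pa - pb) / L
        Fw <- Fw + f * u
        Mw <- Mw + spinedyn:::cross3(pb - origin, f * u)
      }
      for (fc in model$facets) {
        if (fc$pair$level != lv) next
        res <- facet_force(fc, kin[[fc$body_caudal]], kin[[fc$body_cranial]],
                           vel_caudal = list(v = kin[[fc$body_caudal]]$v,
                                             w = kin[[fc$body_caudal]]$w),
                           vel_cranial = list(v = kin[[fc$body_cranial]]$v,
                                              w = kin[[fc$body_cranial]]$w))
        # per-point forces applied at the probe points
        qw <- t(kin[[fc$body_cranial]]$R %*% t(fc$probe_points / 1000)) +
          matrix(kin[[fc$body_cranial]]$p, 9, 3, byrow = TRUE)
        for (j in 1:9) {
          fj <- -res$point_forces[j] * res$normal
          Fw <- Fw + fj
          Mw <- Mw + spinedyn:::cross3(qw[j, ] - origin, fj)
        }
      }
      ev <- spinedyn:::eval_model_state(model, kin)
      br <- ev$bushings[[bi]]
      Fw_t <- Fw - br$force_world
      Mw_t <- Mw - br$moment_world +
        spinedyn:::cross3(br$midpoint - origin, -br$force_world)
      expected_total <- spinedyn:::load_components(Fw_t, Mw_t, D)
      got <- joint_load(tr, lv, tr$times[i], "total")
      scale <- max(abs(expected_total), 1)
      expect_equal(c(got$F_SI, got$F_AP, got$M_FE),
                   unname(expected_total), tolerance = 1e-9 * scale)
    }
  }
})

test_that("flexion moments are negative at every level at the end of flexion", {
  tr <- cached_template_runs()$INTACT
  for (lv in vapply(tr$model$bushings, `[[`, "", "level")) {
    expect_lt(joint_load(tr, lv, 3, "ivd")$M_FE, 0)
    expect_lt(joint_load(tr, lv, 3, "total")$M_FE, 0)
  }
})

test_that("range of motion: zero-load null, exact prescribed rotation", {
  sp <- cached_template()
  m <- assemble_model(sp, cached_config(), "INTACT")
  tr0 <- integrate_model(m, zero_protocol())
  tr0$reference_body <- "SA"
  expect_lt(abs(rom(tr0)$rom_deg), 1e-4)

  # rigidly prescribe an additional 10 degree flexion of L1
  y0 <- spinedyn:::state_vector_from_poses(m)
  R_ref <- m$poses[[match("SA", m$levels)]]$R
  a0 <- spinedyn:::cardan_xyz(crossprod(R_ref, m$poses[[1]]$R))[2]
  R_new <- R_ref %*% spinedyn:::axis_rotmat(2, a0 + spinedyn:::deg2rad(10))
  y1 <- y0
  y1[4:7] <- spinedyn:::rotmat_to_quat(R_new)
  fake <- tr0
  fake$states <- rbind(y0, y1)
  fake$times <- c(0, 1)
  expect_equal(rom(fake)$rom_deg, 10, tolerance = 1e-9)
  fake$times <- 0
  fake$states <- fake$states[1, , drop = FALSE]
  expect_error(rom(fake), "incomplete")
})

test_that("level loads are invariant under a rigid world rotation", {
  tr <- cached_template_runs()$LAM
  ref <- joint_load(tr, "L4-L5", 3, "total")
  Q <- spinedyn:::axis_rotmat(3, 0.7) %*% spinedyn:::axis_rotmat(1, -0.3)
  qQ <- spinedyn:::rotmat_to_quat(Q)
  rot <- tr
  rot$model$poses <- lapply(tr$model$poses, function(ps)
    list(R = Q %*% ps$R, p = as.numeric(Q %*% ps$p)))
  Y <- tr$states
  for (s in 0:4) {
    off <- 13 * s
    Y[, off + 1:3] <- t(Q %*% t(Y[, off + 1:3]))
    for (i in seq_len(nrow(Y))) {
      Y[i, off + 4:7] <- spinedyn:::quat_mult(qQ, Y[i, off + 4:7])
      Y[i, off + 8:10] <- Q %*% Y[i, off + 8:10]
      Y[i, off + 11:13] <- Q %*% Y[i, off + 11:13]
    }
  }
  rot$states <- Y
  got <- joint_load(rot, "L4-L5", 3, "total")
  expect_equal(c(got$F_SI, got$F_AP, got$M_FE),
               c(ref$F_SI, ref$F_AP, ref$M_FE), tolerance = 1e-9)
})

test_that("the cohort outcome table has full cardinality and Table-style content", {
  outcomes <- cached_outcomes()
  expect_equal(nrow(outcomes), 15 * 4 * 5)
  expect_setequal(unique(outcomes$technique),
                  c("INTACT", "UILF", "BILF", "LAM"))
  # capsular ligament forces are not evaluated at the two uppermost levels
  expect_true(all(is.na(outcomes$F_CL[outcomes$level %in%
                                        c("L1-L2", "L2-L3")])))
  expect_true(all(!is.na(outcomes$F_CL[outcomes$level == "L4-L5"])))
  expect_true(all(outcomes$F_PLL >= 0))
  # compressive load accumulates caudally in the cohort mean
  mean_si <- function(lv) mean(outcomes$F_SI[outcomes$technique == "INTACT" &
                                               outcomes$level == lv])
  expect_gte(mean_si("L5-SA"), mean_si("L1-L2"))

  # missing combinations are reported
  short <- cached_cohort_runs()[-1, ]
  expect_error(outcome_table(short), "missing runs")
})

test_that("outcome summaries reproduce mean, SD and range", {
  toy <- tidyr::expand_grid(subject = c("a", "b", "c"),
                            technique = "LAM", level = "L4-L5")
  toy$F_SI <- c(10, 12, 14); toy$F_AP <- 5; toy$M_FE <- -1
  toy$F_PLL <- 0; toy$F_CL <- 0; toy$rom_deg <- 20
  sm <- summarize_outcomes(toy)
  r <- sm[sm$quantity == "F_SI", ]
  expect_equal(r$mean, 12)
  expect_equal(r$sd, 2)
  expect_equal(c(r$min, r$max), c(10, 14))
  const <- sm[sm$quantity == "F_AP", ]
  expect_equal(const$sd, 0)
  expect_equal(const$mean, 5)
})
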