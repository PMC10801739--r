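# Synthetic geometry: landmark schema, mirror symmetry, facet plane
# fitting against an SVD total-least-squares oracle, spine stacking and
# alignment, cohort sampling.

test_that("a lumbar vertebra carries the full 47-landmark budget", {
  v <- generate_vertebra("L4", vertebra_shape_params("L4"), seed = 1)
  expect_equal(nrow(v$landmarks), 47)
  expect_equal(sum(v$landmarks$role == "facet_point"), 36)
  expect_equal(sum(v$landmarks$role == "ligament_insertion"), 8)
  expect_equal(sum(v$landmarks$role == "endplate_point"), 2)
  expect_equal(sum(v$landmarks$role == "spinous_tip"), 1)
  # inertia symmetric positive definite
  expect_equal(v$inertia, t(v$inertia))
  expect_true(all(eigen(v$inertia, symmetric = TRUE)$values > 0))
})

test_that("zero-asymmetry vertebrae are exactly mirror-symmetric", {
  v <- generate_vertebra("L4", vertebra_shape_params("L4"), seed = 3)
  lm <- v$landmarks
  for (i in seq_len(nrow(lm))) {
    id <- lm$id[i]
    mirror_id <- if (grepl("left", id)) {
      sub("left", "right", id)
    } else if (grepl("right", id)) {
      sub("right", "left", id)
    } else {
      id
    }
    j <- match(mirror_id, lm$id)
    expect_equal(c(lm$x[i], -lm$y[i], lm$z[i]),
                 c(lm$x[j], lm$y[j], lm$z[j]),
                 tolerance = 1e-12)
  }
})

test_that("out-of-bounds shape parameters are rejected by name", {
  expect_error(
    generate_vertebra("L4", vertebra_shape_params("L4", body_width = 200)),
    "body_width")
  expect_error(
    generate_vertebra("L2", vertebra_shape_params("L2", mass_kg = -1)),
    "mass_kg")
})

test_that("facet plane fit recovers exact planes and centroid offsets", {
  # coplanar points
  set.seed(21)
  pts <- cbind(runif(9, -5, 5), runif(9, -5, 5), 0)
  fp <- fit_facet_plane(pts)
  expect_equal(abs(fp$normal), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(fp$residual, 0, tolerance = 1e-9)

  # 8 points on a ring at z = 0 plus one 9 mm above the centroid: the
  # total-least-squares plane stays horizontal at the mean height z = 1
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  ring <- cbind(10 * cos(th), 10 * sin(th), 0)
  pts <- rbind(ring, c(0, 0, 9))
  fp <- fit_facet_plane(pts)
  oracle_sv <- svd(sweep(pts, 2, colMeans(pts)))$v[, 3]
  expect_equal(abs(sum(fp$normal * oracle_sv)), 1, tolerance = 1e-9)
  expect_equal(abs(fp$normal[3]), 1, tolerance = 1e-9)
  expect_equal(fp$point[3], 1)
})

test_that("facet plane fit equals the SVD oracle on random clouds", {
  set.seed(22)
  for (rep in 1:20) {
    pts <- matrix(rnorm(27, sd = 4), 9, 3)
    pts[, 3] <- 0.3 * pts[, 1] - 0.5 * pts[, 2] + rnorm(9, sd = 0.3)
    fp <- fit_facet_plane(pts)
    v3 <- svd(sweep(pts, 2, colMeans(pts)))$v[, 3]
    expect_equal(abs(sum(fp$normal * v3)), 1, tolerance = 1e-9)
    expect_equal(fp$point, colMeans(pts))
  }
})

test_that("degenerate (collinear) facet points raise an error", {
  pts <- cbind(1:9, 2 * (1:9), 3 * (1:9))
  expect_error(fit_facet_plane(pts), "collinear")
})

test_that("spine generation is deterministic and validates its inputs", {
  s1 <- generate_spine(spine_params(), seed = 7)
  s2 <- generate_spine(spine_params(), seed = 7)
  expect_identical(s1, s2)
  expect_error(generate_spine(spine_params(disc_heights = c(9, -1, 10, 11, 10))),
               "disc height")
})

test_that("equal lordosis partition yields equal segmental wedges", {
  sp <- generate_spine(spine_params(lordosis_deg = 40,
                                    seg_fractions = rep(0.2, 5),
                                    l4_slip_mm = 0))
  for (k in 1:5) {
    Rrel <- crossprod(sp$vertebrae[[k + 1]]$pose$R, sp$vertebrae[[k]]$pose$R)
    ang <- spinedyn:::cardan_xyz(Rrel)
    expect_equal(spinedyn:::rad2deg(ang[2]), -8, tolerance = 1e-9)
  }
})

test_that("the upper endplate of L3 is horizontal after alignment", {
  sp <- generate_spine()
  n3 <- sp$vertebrae[["L3"]]$pose$R %*% c(0, 0, 1)
  # antiparallel to gravity (-Z): normal is +Z within 1e-9 rad
  expect_lt(acos(min(1, n3[3])), 1e-9)
  expect_identical(sp$fixed_body, "SA")
})

test_that("geometry JSON round-trips losslessly", {
  sp <- generate_spine(spine_params(subject_id = "rt"), seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_spine_geometry(sp, path)
  sp2 <- read_spine_geometry(path)
  expect_equal(sp2$subject_id, sp$subject_id)
  for (lev in names(sp$vertebrae)) {
    expect_equal(sp2$vertebrae[[lev]]$landmarks, sp$vertebrae[[lev]]$landmarks)
    expect_equal(sp2$vertebrae[[lev]]$pose$R, sp$vertebrae[[lev]]$pose$R)
  }
  for (lv in names(sp$disc_frames)) {
    expect_equal(sp2$disc_frames[[lv]]$origin, sp$disc_frames[[lv]]$origin)
    expect_equal(sp2$disc_frames[[lv]]$axes, sp$disc_frames[[lv]]$axes)
  }
})

test_that("cohort sampling: zero variance copies, determinism, CV recovery", {
  spec0 <- cohort_spec(n_subjects = 5,
                       cv = list(lordosis = 0, disc_height = 0,
                                 body_dims = 0, facet_angle = 0),
                       seed = 3)
  cohort0 <- sample_cohort(spec0)
  base <- generate_spine(spine_params(subject_id = "S01"), seed = 4)
  for (s in cohort0) {
    expect_equal(s$lordosis_deg, base$lordosis_deg)
    expect_equal(s$params$disc_heights, base$params$disc_heights)
  }

  c1 <- sample_cohort(cohort_spec(n_subjects = 4, seed = 3))
  c2 <- sample_cohort(cohort_spec(n_subjects = 4, seed = 3))
  expect_identical(c1, c2)

  # Monte-Carlo check of the truncated-normal sampler
  big <- sample_cohort(cohort_spec(n_subjects = 500, seed = 9))
  lords <- vapply(big, `[[`, 0, "lordosis_deg")
  cv_hat <- sd(lords) / mean(lords)
  expect_lt(abs(cv_hat - 0.08) / 0.08, 0.2)
  # truncation bounds respected
  expect_true(all(abs(lords / 45 - 1) <= 3 * 0.08 + 1e-9))
})

test_that("every ligament routing resolves to existing landmarks", {
  sp <- cached_template()
  m <- assemble_model(sp, cached_config(), "INTACT")
  expect_length(m$ligaments, 50)
  expect_length(m$bushings, 5)
  expect_length(m$facets, 10)
})
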