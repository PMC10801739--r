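#' Kinetics extraction
#'
#' Outcome measures of a simulated flexion: the wrench transmitted across
#' each spinal level reduced to the mid-disc origin and expressed in the
#' instantaneous disc frame of the caudal vertebra (superior-inferior
#' compression positive, anterior shear positive, flexion moment negative),
#' ligament tension records, and the range of motion of L1 relative to the
#' fixed base.
#'
#' Two load components are available: `"total"` sums every element crossing
#' the level (disc bushing, ligaments, facet contacts); `"ivd"` is the disc
#' bushing wrench alone, the in-disc loads that the cohort outcome tables
#' report.
#'
#' @name kinetics
NULL

#' Evaluate every passive element at one kinematic state
#'
#' Pure function of the body poses and velocities; used for trajectory
#' force records, transmitted-load reduction, and as the reference
#' implementation cross-checking the compiled right-hand side.
#'
#' @param model a `spinedyn_model`.
#' @param kin list per body with `R`, `p`, `v`, `w`.
#' @param damp_mult damping multiplier (velocities are scaled, which is
#'   equivalent for linear damping).
#' @return list with `ligaments`, `facets`, `bushings` tibbles.
#' @keywords internal
eval_model_state <- function(model, kin, damp_mult = 1) {
  lig <- model$ligaments
  lig_rows <- lapply(lig, function(l) {
    A <- kin[[l$body_cranial]]; B <- kin[[l$body_caudal]]
    pa <- as.numeric(A$p + A$R %*% mm2m(l$pa))
    pb <- as.numeric(B$p + B$R %*% mm2m(l$pb))
    d <- pb - pa
    L <- sqrt(sum(d^2))
    f <- ligament_force(l, m2mm(L))
    u <- d / L
    list(name = l$name, level = l$level, tension = f,
         force_caudal = -f * u, point_caudal = pb,
         force_cranial = f * u, point_cranial = pa)
  })

  facet_rows <- lapply(model$facets, function(fc) {
    A <- kin[[fc$body_caudal]]; B <- kin[[fc$body_cranial]]
    vel_a <- list(v = A$v * damp_mult, w = A$w * damp_mult)
    vel_b <- list(v = B$v * damp_mult, w = B$w * damp_mult)
    # velocity scaling emulates a damping multiplier; elastic term unaffected
    res <- facet_force(fc, pose_caudal = A, pose_cranial = B,
                       vel_caudal = vel_a, vel_cranial = vel_b)
    list(level = fc$pair$level, side = fc$pair$side,
         total_force = sum(res$point_forces),
         point_forces = res$point_forces,
         wrench_caudal = res$wrench_caudal,
         wrench_cranial = res$wrench_cranial,
         body_caudal = fc$body_caudal, body_cranial = fc$body_cranial)
  })

  bush_rows <- lapply(model$bushings, function(b) {
    A <- kin[[b$body_caudal]]; B <- kin[[b$body_cranial]]
    D_ca <- A$R %*% b$A_ca
    D_cr <- B$R %*% b$A_cr
    Rrel <- crossprod(D_ca, D_cr)
    ang <- cardan_xyz(Rrel)             # (lateral, flexion, axial), rad
    p_ca <- as.numeric(A$p + A$R %*% b$u_ca)
    p_cr <- as.numeric(B$p + B$R %*% b$u_cr)
    dd <- as.numeric(crossprod(D_ca, p_cr - p_ca))       # m, disc axes
    v_ca <- A$v + cross3(A$w, p_ca - A$p)
    v_cr <- B$v + cross3(B$w, p_cr - B$p)
    dvd <- as.numeric(crossprod(D_ca, v_cr - v_ca)) * damp_mult
    wd <- as.numeric(crossprod(D_ca, B$w - A$w)) * damp_mult
    wr <- ivd_wrench(
      b,
      rel_rotation = rad2deg(c(ang[2], ang[1], ang[3])),
      rel_translation = m2mm(dd),
      rot_velocity = c(wd[2], wd[1], wd[3]),
      trans_velocity = dvd
    )
    frc_disc <- wr$force                       # (AP, ML, SI) on cranial
    mom_disc <- c(wr$moment[2], wr$moment[1], wr$moment[3])  # about x,y,z
    frc_w <- as.numeric(D_ca %*% frc_disc)
    mom_w <- as.numeric(D_ca %*% mom_disc)
    midpoint <- (p_ca + p_cr) / 2
    list(level = b$level,
         angles_deg = rad2deg(c(ang[2], ang[1], ang[3])),
         disp_mm = m2mm(dd),
         force_disc = frc_disc, moment_disc = mom_disc,
         force_world = frc_w, moment_world = mom_w,
         midpoint = midpoint, disc_axes = D_ca,
         body_caudal = b$body_caudal, body_cranial = b$body_cranial)
  })

  list(ligaments = lig_rows, facets = facet_rows, bushings = bush_rows)
}

#' Net wrench on each body from elements plus applied loads
#'
#' Reference-path assembly of the body force balance, mirroring the
#' compiled core; used for residual checks and solver verification.
#'
#' @keywords internal
body_wrenches <- function(model, kin, t, protocol, damp_mult = 1) {
  ev <- eval_model_state(model, kin, damp_mult)
  nb <- length(model$levels)
  Fm <- matrix(0, nb, 3); Tm <- matrix(0, nb, 3)
  for (i in seq_along(ev$ligaments)) {
    row <- ev$ligaments[[i]]
    l <- model$ligaments[[i]]
    a <- l$body_cranial; b <- l$body_caudal
    Fm[a, ] <- Fm[a, ] + row$force_cranial
    Tm[a, ] <- Tm[a, ] + cross3(row$point_cranial - kin[[a]]$p,
                                row$force_cranial)
    Fm[b, ] <- Fm[b, ] + row$force_caudal
    Tm[b, ] <- Tm[b, ] + cross3(row$point_caudal - kin[[b]]$p,
                                row$force_caudal)
  }
  for (fr in ev$facets) {
    cr <- fr$body_cranial; ca <- fr$body_caudal
    Fm[cr, ] <- Fm[cr, ] + fr$wrench_cranial$force
    Tm[cr, ] <- Tm[cr, ] + fr$wrench_cranial$torque
    Fm[ca, ] <- Fm[ca, ] + fr$wrench_caudal$force
    Tm[ca, ] <- Tm[ca, ] + fr$wrench_caudal$torque
  }
  for (br in ev$bushings) {
    cr <- br$body_cranial; ca <- br$body_caudal
    Fm[cr, ] <- Fm[cr, ] + br$force_world
    Tm[cr, ] <- Tm[cr, ] + cross3(br$midpoint - kin[[cr]]$p, br$force_world) +
      br$moment_world
    Fm[ca, ] <- Fm[ca, ] - br$force_world
    Tm[ca, ] <- Tm[ca, ] + cross3(br$midpoint - kin[[ca]]$p, -br$force_world) -
      br$moment_world
  }
  ramp <- min(max(t / (protocol$ramp_fraction * protocol$duration), 0), 1)
  if (protocol$applied_moment != 0) {
    b1 <- model$bushings[[1]]
    axis <- (kin[[b1$body_caudal]]$R %*% b1$A_ca)[, 2]
    Tm[1, ] <- Tm[1, ] + protocol$applied_moment * ramp * axis
  }
  Fm[1, 3] <- Fm[1, 3] - protocol$vertical_force *
    (if (isTRUE(protocol$vforce_ramped)) ramp else 1)
  list(force = Fm, torque = Tm)
}

#' Per-node force and load records of a trajectory
#'
#' @param traj a `spinedyn_trajectory`.
#' @return list: `ligaments` (tibble time x element tension), `facets`
#'   (tibble of resultant contact forces), `level_loads` (tibble with both
#'   `"ivd"` and `"total"` components).
#' @export
trajectory_records <- function(traj) {
  model <- traj$model
  n_out <- length(traj$times)
  lig_names <- vapply(model$ligaments, function(l)
    paste(l$name, l$level, sep = "@"), "")
  lig_mat <- matrix(0, n_out, length(lig_names),
                    dimnames = list(NULL, lig_names))
  facet_names <- vapply(model$facets, function(f)
    paste(f$pair$side, f$pair$level, sep = "@"), "")
  facet_mat <- matrix(0, n_out, length(facet_names),
                      dimnames = list(NULL, facet_names))
  levels <- vapply(model$bushings, `[[`, "", "level")
  loads <- vector("list", 2 * length(levels) * n_out)
  li <- 0
  for (i in seq_len(n_out)) {
    kin <- trajectory_state(traj, i)
    ev <- eval_model_state(model, kin)
    lig_mat[i, ] <- vapply(ev$ligaments, `[[`, 0, "tension")
    facet_mat[i, ] <- vapply(ev$facets, `[[`, 0, "total_force")
    red <- reduce_level_loads(model, kin, ev)
    for (cmp in c("ivd", "total")) {
      for (lv in levels) {
        li <- li + 1
        r <- red[[cmp]][[lv]]
        loads[[li]] <- tibble::tibble(
          time = traj$times[i], level = lv, component = cmp,
          F_SI = r[1], F_AP = r[2], M_FE = r[3])
      }
    }
  }
  list(
    ligaments = lig_mat,
    facets = facet_mat,
    level_loads = dplyr::bind_rows(loads),
    times = traj$times
  )
}

#' Reduce transmitted loads at every level for one state
#'
#' @keywords internal
reduce_level_loads <- function(model, kin, ev = NULL) {
  if (is.null(ev)) ev <- eval_model_state(model, kin)
  out <- list(ivd = list(), total = list())
  for (bi in seq_along(ev$bushings)) {
    br <- ev$bushings[[bi]]
    lv <- br$level
    D <- br$disc_axes
    ca <- br$body_caudal
    origin <- (kin[[ca]]$p + kin[[ca]]$R %*% model$bushings[[bi]]$u_ca)
    origin <- as.numeric(origin)
    # bushing contribution on the caudal body
    Fb <- -br$force_world
    Mb <- -br$moment_world + cross3(br$midpoint - origin, Fb)
    out$ivd[[lv]] <- load_components(Fb, Mb, D)
    Ft <- Fb; Mt <- Mb
    for (i in seq_along(ev$ligaments)) {
      row <- ev$ligaments[[i]]
      if (row$level != lv) next
      Ft <- Ft + row$force_caudal
      Mt <- Mt + cross3(row$point_caudal - origin, row$force_caudal)
    }
    for (fr in ev$facets) {
      if (fr$level != lv) next
      Ft <- Ft + fr$wrench_caudal$force
      # torque recorded about the caudal body origin; shift to disc origin
      Mt <- Mt + fr$wrench_caudal$torque +
        cross3(kin[[fr$body_caudal]]$p - origin, fr$wrench_caudal$force)
    }
    out$total[[lv]] <- load_components(Ft, Mt, D)
  }
  out
}

load_components <- function(F_w, M_w, D) {
  fd <- as.numeric(crossprod(D, F_w))
  md <- as.numeric(crossprod(D, M_w))
  c(F_SI = -fd[3], F_AP = fd[1], M_FE = -md[2])
}

#' Transmitted load at one level and time
#'
#' The wrench transmitted across a level (all elements crossing it, or the
#' disc bushing alone), reduced to the mid-disc origin and expressed in the
#' instantaneous caudal disc frame. Sign convention: compression positive,
#' anterior shear positive, flexion moment negative.
#'
#' @param traj a `spinedyn_trajectory`.
#' @param level e.g. `"L4-L5"`.
#' @param t time (s); evaluated at the nearest output node.
#' @param component `"total"` (default) or `"ivd"`.
#' @return tibble with `level`, `time`, `F_SI` (N), `F_AP` (N),
#'   `M_FE` (Nm).
#' @export
joint_load <- function(traj, level, t = max(traj$times),
                       component = c("total", "ivd")) {
  component <- match.arg(component)
  levels <- vapply(traj$model$bushings, `[[`, "", "level")
  if (!level %in% levels) {
    stop("unknown level '", level, "'; expected one of ",
         paste(levels, collapse = ", "), call. = FALSE)
  }
  if (t < min(traj$times) - 1e-9 || t > max(traj$times) + 1e-9) {
    stop("time outside trajectory span", call. = FALSE)
  }
  i <- which.min(abs(traj$times - t))
  kin <- trajectory_state(traj, i)
  red <- reduce_level_loads(traj$model, kin)
  r <- red[[component]][[level]]
  tibble::tibble(level = level, time = traj$times[i], component = component,
                 F_SI = r[["F_SI"]], F_AP = r[["F_AP"]], M_FE = r[["M_FE"]])
}

#' Flexion-extension angle curve of L1 relative to the fixed base
#' @keywords internal
fe_angle_curve <- function(traj) {
  ref <- traj$reference_body %||% "SA"
  ref_i <- match(ref, traj$model$levels)
  vapply(seq_along(traj$times), function(i) {
    kin <- trajectory_state(traj, i)
    Rrel <- crossprod(kin[[ref_i]]$R, kin[[1]]$R)
    rad2deg(cardan_xyz(Rrel)[2])
  }, 0)
}

#' Range of motion of a trajectory
#'
#' Flexion-extension Cardan angle of L1 relative to the fixed body at the
#' end of the movement minus its initial value, degrees (flexion
#' positive).
#'
#' @param traj a `spinedyn_trajectory`.
#' @return list of class `spinedyn_rom` with `rom_deg` and the angle
#'   curve.
#' @export
rom <- function(traj) {
  if (length(traj$times) < 2) {
    stop("incomplete trajectory", call. = FALSE)
  }
  ang <- fe_angle_curve(traj)
  structure(list(rom_deg = ang[length(ang)] - ang[1], angle_deg = ang,
                 times = traj$times),
            class = "spinedyn_rom")
}

#' Cohort outcome table
#'
#' One row per subject, technique and level with the end-of-flexion in-disc
#' loads (F_SI, F_AP, M_FE), the posterior longitudinal ligament force,
#' the summed left+right capsular ligament force (not evaluated at L1-L2
#' and L2-L3, reported as NA), and the subject's range of motion.
#'
#' @param runs tibble with columns `subject`, `technique` and a list
#'   column `traj` of `spinedyn_trajectory` objects (all four techniques
#'   per subject), or a plain list of trajectories carrying `subject_id`
#'   and `technique`.
#' @param component load component reported, default `"ivd"` (the in-disc
#'   loads).
#' @param cl_levels levels at which capsular ligament forces are
#'   evaluated.
#' @return long tibble: subject, technique, level, F_SI, F_AP, M_FE,
#'   F_PLL, F_CL, rom_deg.
#' @export
outcome_table <- function(runs, component = "ivd",
                          cl_levels = c("L3-L4", "L4-L5", "L5-SA")) {
  if (!tibble::is_tibble(runs)) {
    runs <- tibble::tibble(
      subject = vapply(runs, function(x) x$subject_id %||% NA_character_, ""),
      technique = vapply(runs, function(x) x$technique %||% NA_character_, ""),
      traj = runs
    )
  }
  combos <- tidyr::expand_grid(subject = unique(runs$subject),
                               technique = TECHNIQUES)
  have <- paste(runs$subject, runs$technique)
  absent <- combos[!paste(combos$subject, combos$technique) %in% have, ]
  if (nrow(absent) > 0) {
    stop("missing runs for: ",
         paste(paste(absent$subject, absent$technique), collapse = "; "),
         call. = FALSE)
  }
  rows <- purrr::pmap(runs, function(subject, technique, traj, ...) {
    rec <- trajectory_records(traj)
    t_end <- max(rec$times)
    rd <- rom(traj)$rom_deg
    loads <- dplyr::filter(rec$level_loads,
                           .data$component == !!component,
                           .data$time == t_end)
    lig <- rec$ligaments[nrow(rec$ligaments), ]
    per_level <- lapply(unique(loads$level), function(lv) {
      pll <- lig[paste0("PLL@", lv)]
      if (length(pll) == 0 || is.na(pll)) pll <- 0
      cl <- if (lv %in% cl_levels) {
        sum(lig[paste0(c("CL_left@", "CL_right@"), lv)], na.rm = TRUE)
      } else {
        NA_real_
      }
      li <- loads[loads$level == lv, ]
      tibble::tibble(
        subject = subject, technique = technique, level = lv,
        F_SI = li$F_SI, F_AP = li$F_AP, M_FE = li$M_FE,
        F_PLL = unname(pll), F_CL = cl, rom_deg = rd)
    })
    dplyr::bind_rows(per_level)
  })
  dplyr::bind_rows(rows)
}

#' Mean, SD and range summaries per technique and level
#'
#' @param outcomes tibble from [outcome_table()].
#' @return long tibble: quantity, technique, level, mean, sd, min, max.
#' @export
summarize_outcomes <- function(outcomes) {
  outcomes |>
    tidyr::pivot_longer(cols = c("F_SI", "F_AP", "M_FE", "F_PLL", "F_CL",
                                 "rom_deg"),
                        names_to = "quantity", values_to = "value") |>
    dplyr::group_by(.data$quantity, .data$technique, .data$level) |>
    dplyr::summarise(
      mean = mean(.data$value), sd = stats::sd(.data$value),
      min = min(.data$value), max = max(.data$value),
      n = dplyr::n(), .groups = "drop")
}

#' Write a run to disk (long-format CSV plus JSON manifest)
#'
#' The CSV holds one row per time, level and quantity (level loads for
#' both components plus ligament tensions); the manifest records the
#' model hash, protocol, solver settings and technique so a run can be
#' audited and reproduced.
#'
#' @param traj a `spinedyn_trajectory`.
#' @param dir output directory (created if needed).
#' @param name base file name; defaults to subject and technique.
#' @return paths of the two files, invisibly.
#' @export
write_run <- function(traj, dir, name = NULL) {
  if (is.null(name)) {
    name <- paste(traj$subject_id %||% "run", traj$technique %||% "NA",
                  sep = "_")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- trajectory_records(traj)
  loads <- rec$level_loads |>
    tidyr::pivot_longer(cols = c("F_SI", "F_AP", "M_FE"),
                        names_to = "quantity", values_to = "value") |>
    dplyr::mutate(quantity = paste(.data$quantity, .data$component,
                                   sep = "_")) |>
    dplyr::select("time", "level", "quantity", "value")
  lig <- tibble::as_tibble(rec$ligaments) |>
    dplyr::mutate(time = rec$times) |>
    tidyr::pivot_longer(cols = -"time", names_to = "element",
                        values_to = "value") |>
    tidyr::separate_wider_delim("element", "@",
                                names = c("quantity", "level")) |>
    dplyr::select("time", "level", "quantity", "value")
  csv_path <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(dplyr::bind_rows(loads, lig), csv_path,
                   row.names = FALSE)
  manifest <- list(
    model_hash = traj$model_hash,
    subject = traj$subject_id, technique = traj$technique,
    protocol = traj$protocol, settings = traj$settings,
    removal_set = as.list(traj$model$removal_set),
    rom_deg = rom(traj)$rom_deg,
    kinetic_energy = traj$kinetic_energy,
    quasi_static = traj$quasi_static
  )
  json_path <- file.path(dir, paste0(name, "_manifest.json"))
  jsonlite::write_json(manifest, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv_path, manifest = json_path))
}
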