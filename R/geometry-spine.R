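#' Stacked spine geometry
#'
#' [generate_spine()] stacks the six bodies L1-sacrum in a world frame
#' (gravity along -Z), applying segmental lordosis wedge angles, disc
#' heights, an optional grade-I-like anterior slip of L4 over L5, and two
#' alignment steps: the whole assembly is rotated so the upper endplate of
#' L3 is exactly horizontal, and the inferior facet points of each vertebra
#' are articulated onto the superior facet planes of the vertebra below at
#' a fixed neutral clearance (joint alignment in each motion segment).
#'
#' @name spine-geometry
NULL

#' Default subject-level spine parameters
#'
#' @param ... named overrides. Segmental lordosis fractions are ordered
#'   L1/L2 to L5/SA and must sum to 1; disc heights are mm per level.
#' @return named list.
#' @export
spine_params <- function(...) {
  base <- list(
    lordosis_deg = 45,
    seg_fractions = c(0.10, 0.14, 0.19, 0.25, 0.32),
    disc_heights = c(9, 10, 11, 11, 10),
    l4_slip_mm = 3,
    size_factor = 1,
    facet_angle_offset_deg = 0,
    facet_clearance_mm = 1.0,
    sacral_slope_frac = 0.88,
    subject_id = "template"
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(base))
  if (length(unknown) > 0) {
    stop("unknown spine parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  utils::modifyList(base, override)
}

validate_spine_params <- function(p) {
  if (any(p$disc_heights <= 0)) {
    stop("impossible stack: disc heights must be positive", call. = FALSE)
  }
  if (length(p$disc_heights) != 5 || length(p$seg_fractions) != 5) {
    stop("disc_heights and seg_fractions must have length 5", call. = FALSE)
  }
  if (abs(sum(p$seg_fractions) - 1) > 1e-8) {
    stop("seg_fractions must sum to 1", call. = FALSE)
  }
  if (p$lordosis_deg < 0 || p$lordosis_deg > 90) {
    stop("lordosis_deg outside physiologic bounds [0, 90]", call. = FALSE)
  }
  if (p$size_factor < 0.7 || p$size_factor > 1.3) {
    stop("size_factor outside bounds [0.7, 1.3]", call. = FALSE)
  }
  invisible(p)
}

#' Generate a stacked synthetic lumbar spine
#'
#' @param params list from [spine_params()].
#' @param seed integer; forwarded to [generate_vertebra()] (consumed only
#'   when landmark jitter is enabled). The geometry is deterministic for a
#'   fixed seed and parameter set.
#' @return A `spinedyn_spine`: vertebrae with world poses (`R` rotation,
#'   `p` origin, metres), disc frames, facet contact definitions, and the
#'   generating parameters.
#' @export
generate_spine <- function(params = spine_params(), seed = 1L) {
  p <- validate_spine_params(params)

  vertebrae <- lapply(ALL_LEVELS, function(lev) {
    sp <- vertebra_shape_params(lev)
    sp$body_width <- sp$body_width * p$size_factor
    sp$body_depth <- sp$body_depth * p$size_factor
    sp$body_height <- sp$body_height * p$size_factor
    sp$facet_angle_deg <- sp$facet_angle_deg + p$facet_angle_offset_deg
    generate_vertebra(lev, sp, seed = seed)
  })
  names(vertebrae) <- ALL_LEVELS

  heights <- vapply(vertebrae, function(v) v$shape_params$body_height, 0)
  wedges <- deg2rad(p$lordosis_deg * p$seg_fractions)   # L1/L2 .. L5/SA

  # body tilt about +Y (positive tips anterior down); lordosis decreases the
  # tilt going cranially from the sacral slope
  tau <- numeric(6); names(tau) <- ALL_LEVELS
  tau["SA"] <- deg2rad(p$lordosis_deg * p$sacral_slope_frac)
  for (k in 5:1) tau[k] <- tau[k + 1] - wedges[k]

  pose_R <- lapply(tau, function(t) axis_rotmat(2, t))
  pose_p <- vector("list", 6); names(pose_p) <- ALL_LEVELS
  pose_p[["SA"]] <- c(0, 0, 0)
  for (k in 5:1) {
    ca <- k + 1
    e_sup <- pose_p[[ca]] + pose_R[[ca]] %*% c(0, 0, mm2m(heights[ca] / 2))
    Rmid <- axis_rotmat(2, tau[ca] - wedges[k] / 2)
    n_mid <- Rmid %*% c(0, 0, 1)
    x_mid <- Rmid %*% c(1, 0, 0)
    slip <- if (ALL_LEVELS[k] == "L4") mm2m(p$l4_slip_mm) else 0
    e_inf <- e_sup + mm2m(p$disc_heights[k]) * n_mid + slip * x_mid
    pose_p[[k]] <- as.numeric(e_inf + pose_R[[k]] %*%
                                c(0, 0, mm2m(heights[k] / 2)))
  }

  # align the upper endplate of L3 horizontally (rotate the whole assembly)
  n3 <- pose_R[["L3"]] %*% c(0, 0, 1)
  beta <- atan2(n3[1], n3[3])
  Ralign <- axis_rotmat(2, -beta)
  for (k in 1:6) {
    pose_R[[k]] <- Ralign %*% pose_R[[k]]
    pose_p[[k]] <- as.numeric(Ralign %*% pose_p[[k]])
  }
  shift <- pose_p[["SA"]]
  for (k in 1:6) pose_p[[k]] <- pose_p[[k]] - shift

  for (k in 1:6) {
    vertebrae[[k]]$pose <- list(R = pose_R[[k]], p = pose_p[[k]])
  }

  # disc frames: origin mid-disc, axes taken from the caudal vertebra
  disc_frames <- vector("list", 5)
  for (k in 1:5) {
    ca <- k + 1
    R_ca <- pose_R[[ca]]; p_ca <- pose_p[[ca]]
    R_cr <- pose_R[[k]]; p_cr <- pose_p[[k]]
    e_sup <- p_ca + R_ca %*% c(0, 0, mm2m(heights[ca] / 2))
    e_inf <- p_cr + R_cr %*% c(0, 0, -mm2m(heights[k] / 2))
    origin <- as.numeric((e_sup + e_inf) / 2)
    D <- R_ca
    disc_frames[[k]] <- list(
      level = paste0(ALL_LEVELS[k], "-", ALL_LEVELS[ca]),
      cranial = ALL_LEVELS[k], caudal = ALL_LEVELS[ca],
      origin = origin, axes = D,
      u_ca = as.numeric(crossprod(R_ca, origin - p_ca)),
      u_cr = as.numeric(crossprod(R_cr, origin - p_cr)),
      A_ca = diag(3),
      A_cr = crossprod(R_cr, D)
    )
  }
  names(disc_frames) <- vapply(disc_frames, `[[`, "", "level")

  # articulate inferior facets onto the caudal superior facet planes
  clearance <- mm2m(p$facet_clearance_mm)
  facet_contacts <- list()
  for (k in 1:5) {
    ca <- k + 1
    R_ca <- pose_R[[ca]]; p_ca <- pose_p[[ca]]
    R_cr <- pose_R[[k]]; p_cr <- pose_p[[k]]
    for (side in c("left", "right")) {
      ids_sup <- sprintf("facet_sup_%s_%d", side, 1:9)
      pts_local <- as.matrix(
        vertebrae[[ca]]$landmarks[
          match(ids_sup, vertebrae[[ca]]$landmarks$id), c("x", "y", "z")])
      plane <- fit_facet_plane(pts_local)
      ang <- vertebrae[[ca]]$shape_params$facet_angle_deg +
        if (side == "left") vertebrae[[ca]]$shape_params$facet_angle_asym_deg else 0
      nominal <- facet_normal(ang, side)
      nrm <- plane$normal
      if (sum(nrm * nominal) < 0) nrm <- -nrm
      pts_world <- t(R_ca %*% t(mm2m(pts_local))) +
        matrix(p_ca, 9, 3, byrow = TRUE)
      n_world <- as.numeric(R_ca %*% nrm)
      probe_world <- pts_world + clearance *
        matrix(n_world, 9, 3, byrow = TRUE)
      probe_local <- m2mm(t(crossprod(R_cr,
        t(probe_world - matrix(p_cr, 9, 3, byrow = TRUE)))))
      colnames(probe_local) <- c("x", "y", "z")
      ids_inf <- sprintf("facet_inf_%s_%d", side, 1:9)
      rows <- match(ids_inf, vertebrae[[k]]$landmarks$id)
      vertebrae[[k]]$landmarks[rows, c("x", "y", "z")] <-
        as.data.frame(probe_local)
      facet_contacts[[length(facet_contacts) + 1]] <- list(
        level = disc_frames[[k]]$level, side = side,
        caudal = ALL_LEVELS[ca], cranial = ALL_LEVELS[k],
        plane_point = plane$point, plane_normal = nrm,
        probe_ids = ids_inf
      )
    }
  }

  structure(list(
    subject_id = p$subject_id, seed = as.integer(seed),
    lordosis_deg = p$lordosis_deg,
    vertebrae = vertebrae, disc_frames = disc_frames,
    facet_contacts = facet_contacts,
    fixed_body = "SA", params = p
  ), class = "spinedyn_spine")
}

#' @export
print.spinedyn_spine <- function(x, ...) {
  cat("<spinedyn_spine> subject", x$subject_id,
      sprintf("| lordosis %.1f deg | seed %d\n", x$lordosis_deg, x$seed))
  cat("  bodies:", paste(names(x$vertebrae), collapse = " "),
      "| sacrum fixed\n")
  invisible(x)
}

#' Cohort specification
#'
#' Per-parameter coefficients of variation for the synthetic cohort,
#' emulating the between-patient variability of CT-derived subject-specific
#' models. Draws are truncated normal (+-3 SD) so that no subject receives
#' non-physical geometry (e.g. inverted disc heights).
#'
#' @param n_subjects number of subjects (>= 1).
#' @param cv named list of coefficients of variation: `lordosis`,
#'   `disc_height`, `body_dims`, `facet_angle` (the latter applied as an
#'   angular SD in degrees via a 10-degree reference scale).
#' @param seed integer RNG seed.
#' @param template template parameters from [spine_params()].
#' @return object of class `spinedyn_cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 15,
                        cv = list(lordosis = 0.08, disc_height = 0.10,
                                  body_dims = 0.05, facet_angle = 0.08),
                        seed = 42L,
                        template = spine_params()) {
  stopifnot(n_subjects >= 1)
  cv_full <- utils::modifyList(
    list(lordosis = 0.08, disc_height = 0.10, body_dims = 0.05,
         facet_angle = 0.08), cv)
  if (any(unlist(cv_full) < 0)) {
    stop("coefficients of variation must be >= 0", call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects), cv = cv_full,
                 seed = as.integer(seed), template = template),
            class = "spinedyn_cohort_spec")
}

#' Truncated standard normal draws (+-3 SD)
#' @keywords internal
rtruncnorm3 <- function(n) {
  lo <- stats::pnorm(-3); hi <- stats::pnorm(3)
  stats::qnorm(stats::runif(n, lo, hi))
}

#' Sample a synthetic cohort of spine geometries
#'
#' Draws subject-specific lordosis, disc heights, body dimensions and facet
#' orientations around the template with the requested coefficients of
#' variation. Reproducible for a fixed seed; zero variability yields
#' identical copies of the template.
#'
#' @param spec a [cohort_spec()].
#' @return list of `spinedyn_spine`, one per subject.
#' @export
sample_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "spinedyn_cohort_spec"))
  rs <- local_rng(spec$seed)
  on.exit(restore_rng(rs), add = TRUE)
  tmpl <- spec$template
  cv <- spec$cv
  lapply(seq_len(spec$n_subjects), function(i) {
    z <- rtruncnorm3(8)
    p <- tmpl
    p$subject_id <- sprintf("S%02d", i)
    p$lordosis_deg <- tmpl$lordosis_deg * (1 + cv$lordosis * z[1])
    p$disc_heights <- tmpl$disc_heights * (1 + cv$disc_height * z[2:6])
    p$size_factor <- tmpl$size_factor * (1 + cv$body_dims * z[7])
    p$facet_angle_offset_deg <- tmpl$facet_angle_offset_deg +
      10 * cv$facet_angle * z[8]
    generate_spine(p, seed = spec$seed + i)
  })
}

#' Write a spine geometry to JSON
#'
#' Landmark positions are written in millimetres at full precision so the
#' file round-trips losslessly through [read_spine_geometry()].
#'
#' @param spine a `spinedyn_spine`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spine_geometry <- function(spine, path) {
  stopifnot(inherits(spine, "spinedyn_spine"))
  obj <- list(
    schema = "spine_geometry", schema_version = 1L,
    subject_id = spine$subject_id, seed = spine$seed,
    lordosis_deg = spine$lordosis_deg,
    fixed_body = spine$fixed_body,
    params = spine$params,
    vertebrae = lapply(spine$vertebrae, function(v) {
      list(level = v$level, mass = v$mass,
           inertia = as.numeric(v$inertia),
           shape_params = v$shape_params,
           pose = list(R = as.numeric(v$pose$R), p = v$pose$p),
           landmarks = v$landmarks)
    }),
    disc_frames = lapply(spine$disc_frames, function(d) {
      list(level = d$level, cranial = d$cranial, caudal = d$caudal,
           origin = d$origin, axes = as.numeric(d$axes),
           u_ca = d$u_ca, u_cr = d$u_cr,
           A_ca = as.numeric(d$A_ca), A_cr = as.numeric(d$A_cr))
    }),
    facet_contacts = lapply(spine$facet_contacts, function(f) {
      list(level = f$level, side = f$side, caudal = f$caudal,
           cranial = f$cranial, plane_point = f$plane_point,
           plane_normal = f$plane_normal, probe_ids = f$probe_ids)
    })
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = FALSE)
  invisible(path)
}

#' Read a spine geometry from JSON
#'
#' @param path file written by [write_spine_geometry()].
#' @return A `spinedyn_spine`.
#' @export
read_spine_geometry <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(obj$schema, "spine_geometry")) {
    stop("not a spine_geometry JSON file", call. = FALSE)
  }
  vertebrae <- lapply(obj$vertebrae, function(v) {
    structure(list(
      level = v$level,
      landmarks = dplyr::bind_rows(lapply(v$landmarks, tibble::as_tibble)),
      mass = v$mass,
      inertia = matrix(v$inertia, 3, 3),
      shape_params = v$shape_params,
      pose = list(R = matrix(v$pose$R, 3, 3), p = as.numeric(v$pose$p))
    ), class = "spinedyn_vertebra")
  })
  disc_frames <- lapply(obj$disc_frames, function(d) {
    list(level = d$level, cranial = d$cranial, caudal = d$caudal,
         origin = as.numeric(d$origin), axes = matrix(d$axes, 3, 3),
         u_ca = as.numeric(d$u_ca), u_cr = as.numeric(d$u_cr),
         A_ca = matrix(d$A_ca, 3, 3), A_cr = matrix(d$A_cr, 3, 3))
  })
  facet_contacts <- lapply(obj$facet_contacts, function(f) {
    list(level = f$level, side = f$side, caudal = f$caudal,
         cranial = f$cranial, plane_point = as.numeric(f$plane_point),
         plane_normal = as.numeric(f$plane_normal),
         probe_ids = as.character(f$probe_ids))
  })
  structure(list(
    subject_id = obj$subject_id, seed = as.integer(obj$seed),
    lordosis_deg = obj$lordosis_deg,
    vertebrae = vertebrae, disc_frames = disc_frames,
    facet_contacts = facet_contacts,
    fixed_body = obj$fixed_body,
    params = obj$params
  ), class = "spinedyn_spine")
}
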