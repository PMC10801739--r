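#' Passive element constitutive models
#'
#' Three passive element families stabilize the six-body model:
#' tension-only ligaments with a quadratic-toe / linear force-strain law,
#' six degree-of-freedom intervertebral disc bushings with tabulated
#' nonlinear elastic characteristics plus linear viscous damping, and
#' frictionless facet contacts penalizing penetration of nine probe points
#' into the opposing regression plane with a C1-smoothed force onset.
#' All elastic parts are pure functions of the relative configuration
#' (path-independent, no hysteresis).
#'
#' @name passive-elements
NULL

#' Load an element parameter configuration
#'
#' Reads the versioned YAML parameter file shipped with the package (or a
#' user file with the same schema) and validates it: ligament stiffnesses
#' must be non-negative, disc curves monotone through the origin, and the
#' lateral-bending and axial-rotation curves odd-symmetric.
#'
#' @param path YAML file; `NULL` for the packaged defaults.
#' @return A validated config list of class `spinedyn_config`.
#' @export
load_element_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_elements.yaml",
                        package = "spinedyn")
  }
  cfg <- yaml::read_yaml(path)
  validate_element_config(cfg)
}

validate_element_config <- function(cfg) {
  need <- c("ligaments", "ivd", "facet", "simulation", "scale")
  missing <- setdiff(need, names(cfg))
  if (length(missing) > 0) {
    stop("element config is missing section(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (nm in names(cfg$ligaments)) {
    lg <- cfg$ligaments[[nm]]
    if (lg$k < 0) stop("ligament ", nm, " stiffness must be >= 0",
                       call. = FALSE)
    if (lg$toe_strain <= 0) stop("ligament ", nm, " toe_strain must be > 0",
                                 call. = FALSE)
    if (lg$slack_ratio <= 0) stop("ligament ", nm, " slack_ratio must be > 0",
                                  call. = FALSE)
  }
  if (any(unlist(cfg$ivd$rot_damping) < 0) ||
      any(unlist(cfg$ivd$trans_damping) < 0)) {
    stop("damping coefficients must be >= 0", call. = FALSE)
  }
  cfg$ivd$curve_objs <- build_ivd_curves(cfg$ivd$curves)
  class(cfg) <- "spinedyn_config"
  cfg
}

build_ivd_curves <- function(curves) {
  rot_axes <- c("FE", "LB", "AR"); trans_axes <- c("AP", "ML", "SI")
  out <- list()
  for (ax in rot_axes) {
    cv <- curves[[ax]]
    x <- unlist(cv$angle_deg); y <- unlist(cv$moment_nm)
    if (!any(x == 0) || y[x == 0] != 0) {
      stop("IVD ", ax, " curve must pass through the origin", call. = FALSE)
    }
    obj <- tryCatch(monotone_curve(x, y), error = function(e) {
      stop("IVD ", ax, " curve: ", conditionMessage(e), call. = FALSE)
    })
    if (ax %in% c("LB", "AR") && !curve_is_odd(obj)) {
      stop("IVD ", ax, " curve must be odd-symmetric", call. = FALSE)
    }
    out[[ax]] <- obj
  }
  for (ax in trans_axes) {
    cv <- curves[[ax]]
    x <- unlist(cv$disp_mm); y <- unlist(cv$force_n)
    if (!any(x == 0) || y[x == 0] != 0) {
      stop("IVD ", ax, " curve must pass through the origin", call. = FALSE)
    }
    out[[ax]] <- tryCatch(monotone_curve(x, y), error = function(e) {
      stop("IVD ", ax, " curve: ", conditionMessage(e), call. = FALSE)
    })
  }
  out
}

#' Construct a ligament element
#'
#' @param name one of ALL, PLL, LF_left, LF_right, ISL, SSL, ITL_left,
#'   ITL_right, CL_left, CL_right.
#' @param span character(2), cranial and caudal vertebra levels.
#' @param origin,insertion landmark ids on the cranial / caudal vertebra.
#' @param slack_length mm, length below which tension is zero (> 0).
#' @param linear_stiffness N per unit strain (>= 0).
#' @param toe_strain strain at the toe-to-linear transition.
#' @param toe_shape curvature exponent of the toe region (2 = quadratic).
#' @return object of class `spinedyn_ligament`.
#' @export
ligament <- function(name, span, origin, insertion, slack_length,
                     linear_stiffness, toe_strain = 0.05, toe_shape = 2) {
  if (slack_length <= 0) stop("slack_length must be > 0", call. = FALSE)
  if (linear_stiffness < 0) stop("linear_stiffness must be >= 0",
                                 call. = FALSE)
  structure(list(name = name, span = span, origin = origin,
                 insertion = insertion, slack_length = slack_length,
                 linear_stiffness = linear_stiffness,
                 toe_strain = toe_strain, toe_shape = toe_shape),
            class = "spinedyn_ligament")
}

#' Tension of a ligament at a given length
#'
#' Tension-only, C1 law: zero below the slack length, a power-law toe of
#' exponent `toe_shape` up to `toe_strain`, then linear with slope
#' `linear_stiffness` (N per unit strain). At the toe transition with a
#' quadratic toe the tension equals `k * toe_strain / 2`.
#'
#' @param lig a [ligament()].
#' @param current_length mm (> 0); vectorized.
#' @return tension in N (>= 0).
#' @export
ligament_force <- function(lig, current_length) {
  if (any(current_length <= 0)) {
    stop("ligament length must be positive", call. = FALSE)
  }
  eps <- (current_length - lig$slack_length) / lig$slack_length
  ligament_force_strain(eps, lig$linear_stiffness, lig$toe_strain,
                        lig$toe_shape)
}

#' @keywords internal
ligament_force_strain <- function(eps, k, eps_t, p = 2) {
  f <- numeric(length(eps))
  toe <- eps > 0 & eps < eps_t
  lin <- eps >= eps_t
  f[toe] <- k * eps_t / p * (eps[toe] / eps_t)^p
  f[lin] <- k * eps_t / p + k * (eps[lin] - eps_t)
  f
}

#' Construct an intervertebral disc bushing
#'
#' @param level character level label, e.g. `"L4-L5"`.
#' @param config element configuration from [load_element_config()]
#'   supplying the tabulated curves and damping.
#' @return object of class `spinedyn_ivd`.
#' @export
ivd_bushing <- function(level, config = load_element_config()) {
  structure(list(level = level,
                 curves = config$ivd$curve_objs,
                 rot_damping = unlist(config$ivd$rot_damping),
                 trans_damping = unlist(config$ivd$trans_damping),
                 rot_scale = config$scale$ivd_rot),
            class = "spinedyn_ivd")
}

#' Wrench produced by a disc bushing
#'
#' Elastic moments come from the tabulated moment-angle curves (FE, LB, AR,
#' degrees), elastic forces from the force-displacement curves (AP, ML in
#' displacement convention, SI in compression-positive convention, mm);
#' damping is linear in the relative velocities. The returned wrench acts on
#' the cranial vertebra, expressed in the disc frame, and is restoring:
#' positive flexion angle yields a negative (extending) FE moment on the
#' cranial body; zero state yields a zero wrench.
#'
#' @param ivd an [ivd_bushing()].
#' @param rel_rotation numeric(3), degrees `(FE, LB, AR)`.
#' @param rel_translation numeric(3), mm `(AP, ML, SI)` displacement of the
#'   cranial body in disc axes (SI positive = distraction).
#' @param rot_velocity numeric(3), rad/s.
#' @param trans_velocity numeric(3), m/s.
#' @return list with `force` (N, disc axes, on the cranial body) and
#'   `moment` (Nm).
#' @export
ivd_wrench <- function(ivd, rel_rotation = c(0, 0, 0),
                       rel_translation = c(0, 0, 0),
                       rot_velocity = c(0, 0, 0),
                       trans_velocity = c(0, 0, 0)) {
  cv <- ivd$curves
  s <- ivd$rot_scale
  moment <- c(
    -s * curve_eval(cv$FE, rel_rotation[1]),
    -s * curve_eval(cv$LB, rel_rotation[2]),
    -s * curve_eval(cv$AR, rel_rotation[3])
  ) - ivd$rot_damping * rot_velocity
  f_ap <- -curve_eval(cv$AP, rel_translation[1])
  f_ml <- -curve_eval(cv$ML, rel_translation[2])
  f_si <- curve_eval(cv$SI, -rel_translation[3])  # compression positive
  force <- c(f_ap, f_ml, f_si) - ivd$trans_damping * trans_velocity
  list(force = force, moment = moment)
}

#' Construct a facet contact element
#'
#' @param pair list with `caudal`, `cranial` levels and `side`.
#' @param plane a `spinedyn_facet_plane` in the caudal body frame (mm).
#' @param probe_points 9 x 3 matrix, probe points in the cranial body
#'   frame (mm).
#' @param penalty_stiffness N/mm.
#' @param contact_damping N s/m.
#' @param smoothing mm over which the force onset is C1-smoothed.
#' @return object of class `spinedyn_facet_contact`.
#' @export
facet_contact <- function(pair, plane, probe_points,
                          penalty_stiffness = 600, contact_damping = 800,
                          smoothing = 0.1) {
  stopifnot(nrow(probe_points) == 9)
  structure(list(pair = pair, plane = plane,
                 probe_points = as.matrix(probe_points),
                 penalty_stiffness = penalty_stiffness,
                 contact_damping = contact_damping,
                 smoothing = smoothing),
            class = "spinedyn_facet_contact")
}

#' C1 penalty force law
#'
#' Zero for separation, quadratic over the smoothing zone, then linear:
#' at 1 mm penetration with 0.1 mm smoothing the force is within 5% of the
#' raw `stiffness * depth` penalty.
#'
#' @param depth penetration depth (mm), vectorized.
#' @param stiffness N/mm.
#' @param smoothing mm.
#' @return force in N (>= 0).
#' @keywords internal
penalty_force <- function(depth, stiffness, smoothing) {
  f <- numeric(length(depth))
  toe <- depth > 0 & depth < smoothing
  lin <- depth >= smoothing
  f[toe] <- stiffness * depth[toe]^2 / (2 * smoothing)
  f[lin] <- stiffness * (depth[lin] - smoothing / 2)
  f
}

#' Facet contact forces between two posed bodies
#'
#' Evaluates the frictionless point-on-plane penalty contact for the nine
#' probe points given the world poses of the plane-carrying (caudal) and
#' probe-carrying (cranial) bodies. Forces act along the plane normal, are
#' non-negative, vanish at separation, and load the two bodies with equal
#' and opposite wrenches at the probe points.
#'
#' @param fc a [facet_contact()].
#' @param pose_caudal,pose_cranial lists with rotation `R` (3x3) and origin
#'   `p` (m, world).
#' @param vel_caudal,vel_cranial optional lists with `v` (m/s) and
#'   `w` (rad/s) for the damping term; `NULL` for statics.
#' @return list: `point_forces` (N, length 9), `normal` (world),
#'   `wrench_cranial` and `wrench_caudal` (`force` N, `torque` Nm about the
#'   respective body origin).
#' @export
facet_force <- function(fc, pose_caudal, pose_cranial,
                        vel_caudal = NULL, vel_cranial = NULL) {
  R_a <- pose_caudal$R; p_a <- pose_caudal$p
  R_b <- pose_cranial$R; p_b <- pose_cranial$p
  pt_w <- as.numeric(p_a + R_a %*% mm2m(fc$plane$point))
  n_w <- as.numeric(R_a %*% fc$plane$normal)
  q_w <- t(R_b %*% t(mm2m(fc$probe_points))) +
    matrix(p_b, 9, 3, byrow = TRUE)
  gap <- as.numeric((q_w - matrix(pt_w, 9, 3, byrow = TRUE)) %*% n_w)
  depth_mm <- m2mm(-gap)
  f_el <- penalty_force(depth_mm, fc$penalty_stiffness, fc$smoothing)
  f <- f_el
  if (!is.null(vel_caudal) && !is.null(vel_cranial)) {
    pen <- depth_mm > 0
    if (any(pen)) {
      for (j in which(pen)) {
        vq <- vel_cranial$v + cross3(vel_cranial$w, q_w[j, ] - p_b)
        vp <- vel_caudal$v + cross3(vel_caudal$w, q_w[j, ] - p_a)
        gap_rate <- sum((vq - vp) * n_w) +
          sum((q_w[j, ] - pt_w) * cross3(vel_caudal$w, n_w))
        wd <- min(depth_mm[j] / fc$smoothing, 1)
        f[j] <- max(0, f_el[j] - wd * fc$contact_damping * gap_rate)
      }
    }
  }
  force_cr <- colSums(f * matrix(n_w, 9, 3, byrow = TRUE))
  torque_cr <- c(0, 0, 0); torque_ca <- c(0, 0, 0)
  for (j in 1:9) {
    if (f[j] > 0) {
      fj <- f[j] * n_w
      torque_cr <- torque_cr + cross3(q_w[j, ] - p_b, fj)
      torque_ca <- torque_ca + cross3(q_w[j, ] - p_a, -fj)
    }
  }
  list(point_forces = f, normal = n_w,
       wrench_cranial = list(force = force_cr, torque = torque_cr),
       wrench_caudal = list(force = -force_cr, torque = torque_ca))
}
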