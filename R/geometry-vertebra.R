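#' Parametric vertebra geometry
#'
#' Each vertebra carries a fixed budget of 47 labelled landmarks in its own
#' body frame (+X anterior, +Y left, +Z superior, origin at the vertebral
#' body centre, coordinates in millimetres):
#'
#' * 36 facet points: 9 points per articular surface on the four facet
#'   surfaces (superior/inferior x left/right), laid out as a 3x3 grid on
#'   the facet plane;
#' * 2 endplate centres (superior, inferior);
#' * 1 spinous process tip (doubles as the supraspinous ligament insertion
#'   region marker for visualization; the SSL routes through its own point);
#' * 8 ligament insertion points: ALL, PLL, LF left/right, ISL, SSL,
#'   ITL left/right. The capsular ligaments (CL) share facet points
#'   (caudal edge of the inferior facet to cranial edge of the opposing
#'   superior facet), anatomically adjacent insertions being represented
#'   by one landmark.
#'
#' The sacrum is generated with the subset of landmarks it needs (superior
#' facets, superior endplate, ligament insertions); the 47-landmark budget
#' applies to L1-L5.
#'
#' @name vertebra-geometry
NULL

LUMBAR_LEVELS <- c("L1", "L2", "L3", "L4", "L5")
ALL_LEVELS <- c(LUMBAR_LEVELS, "SA")

#' Default shape parameters for one vertebra
#'
#' Level-dependent physiologic default dimensions (mm). All parameters are
#' checked against documented physiologic bounds by [generate_vertebra()].
#'
#' @param level `"L1"`..`"L5"` or `"SA"`.
#' @param ... named overrides of individual parameters.
#' @return named list of shape parameters.
#' @export
vertebra_shape_params <- function(level, ...) {
  level <- match.arg(level, ALL_LEVELS)
  i <- match(level, ALL_LEVELS)
  base <- list(
    body_width      = c(42, 44, 46, 48, 50, 55)[i],
    body_depth      = c(30, 31, 32, 33, 34, 34)[i],
    body_height     = c(27, 28, 28, 29, 28, 30)[i],
    spinous_length  = c(45, 46, 46, 44, 40, 30)[i],
    transverse_width = c(82, 86, 90, 92, 94, 80)[i],
    lamina_offset   = 14,
    lf_halfwidth    = 12,
    facet_post_offset = 9,
    facet_lat_offset  = 15,
    facet_rise        = 5,
    facet_angle_deg = c(25, 30, 37, 44, 50, 55)[i],
    facet_angle_asym_deg = 0,
    facet_grid_mm   = 4,
    jitter_mm       = 0,
    mass_kg         = 1.0
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(base))
  if (length(unknown) > 0) {
    stop("unknown shape parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  utils::modifyList(base, override)
}

shape_param_bounds <- function() {
  list(
    body_width = c(32, 68), body_depth = c(22, 45), body_height = c(18, 38),
    spinous_length = c(25, 65), transverse_width = c(60, 110),
    lamina_offset = c(8, 22), lf_halfwidth = c(6, 20),
    facet_post_offset = c(4, 16), facet_lat_offset = c(8, 24),
    facet_rise = c(2, 10), facet_angle_deg = c(10, 70),
    facet_angle_asym_deg = c(-15, 15), facet_grid_mm = c(2, 7),
    jitter_mm = c(0, 2), mass_kg = c(0.2, 3)
  )
}

validate_shape_params <- function(params) {
  bounds <- shape_param_bounds()
  for (nm in names(bounds)) {
    v <- params[[nm]]
    if (is.null(v) || !is.finite(v)) {
      stop("shape parameter '", nm, "' is missing or non-finite",
           call. = FALSE)
    }
    b <- bounds[[nm]]
    if (v < b[1] || v > b[2]) {
      stop(sprintf(
        "shape parameter '%s' = %.6g outside physiologic bounds [%g, %g]",
        nm, v, b[1], b[2]), call. = FALSE)
    }
  }
  invisible(params)
}

facet_surface_ids <- function() {
  expand.grid(side = c("left", "right"), sup = c("sup", "inf"),
              stringsAsFactors = FALSE)
}

#' Nominal facet plane normal in the body frame
#'
#' Facet surfaces are modelled as vertical planes rotated by the facet
#' angle away from the sagittal plane; the normal of a superior facet
#' points posteromedially (toward the opposing inferior facet of the
#' vertebra above), so anterior translation of the cranial vertebra drives
#' the surfaces into contact.
#'
#' @keywords internal
facet_normal <- function(angle_deg, side) {
  phi <- deg2rad(angle_deg)
  s <- if (side == "left") 1 else -1
  c(-sin(phi), -s * cos(phi), 0)
}

facet_points_local <- function(params, sup, side) {
  D <- params$body_depth; H <- params$body_height
  ang <- params$facet_angle_deg +
    if (side == "left") params$facet_angle_asym_deg else 0
  n <- facet_normal(ang, side)
  sy <- if (side == "left") 1 else -1
  sz <- if (sup == "sup") 1 else -1
  centre <- c(-(D / 2 + params$facet_post_offset),
              sy * params$facet_lat_offset,
              sz * (H / 2 + params$facet_rise))
  e1 <- c(0, 0, 1)
  e2 <- cross3(n, e1)
  g <- params$facet_grid_mm
  # reverse the in-plane ordering on the right so that equal indices are
  # exact mirror images across the mid-sagittal plane
  us <- if (side == "left") c(-g, 0, g) else c(g, 0, -g)
  offs <- expand.grid(u = us, v = c(-g, 0, g))
  pts <- t(apply(offs, 1, function(o) centre + o[["u"]] * e2 + o[["v"]] * e1))
  list(points = pts, normal = n, centre = centre)
}

#' Generate a parametric synthetic vertebra
#'
#' Builds the full landmark set for one vertebra from shape parameters.
#' With zero asymmetry parameters and zero jitter, every left-side landmark
#' is the exact mirror image of its right-side counterpart across the
#' mid-sagittal plane.
#'
#' @param level `"L1"`..`"L5"` or `"SA"`.
#' @param shape_params list from [vertebra_shape_params()].
#' @param seed integer; only consumed when `jitter_mm > 0` adds surface
#'   placement noise to the landmarks.
#' @return A `spinedyn_vertebra`: list with `level`, `landmarks` (tibble of
#'   id, role, x, y, z in mm), `mass` (kg), `inertia` (3x3, kg m^2), and
#'   `shape_params`.
#' @examples
#' v <- generate_vertebra("L4", vertebra_shape_params("L4"), seed = 1)
#' nrow(v$landmarks)  # 47
#' @export
generate_vertebra <- function(level,
                              shape_params = vertebra_shape_params(level),
                              seed = 1L) {
  level <- match.arg(level, ALL_LEVELS)
  p <- validate_shape_params(shape_params)
  D <- p$body_depth; W <- p$body_width; H <- p$body_height

  lm <- list()
  add <- function(id, role, pos) {
    lm[[length(lm) + 1]] <<- list(id = id, role = role,
                                  x = pos[1], y = pos[2], z = pos[3])
  }

  add("endplate_sup", "endplate_point", c(0, 0, H / 2))
  if (level != "SA") add("endplate_inf", "endplate_point", c(0, 0, -H / 2))
  add("spinous_tip", "spinous_tip", c(-(D / 2 + p$spinous_length), 0, -6))

  add("ALL", "ligament_insertion", c(D / 2, 0, 0))
  add("PLL", "ligament_insertion", c(-D / 2, 0, 0))
  add("LF_left", "ligament_insertion", c(-(D / 2 + p$lamina_offset),
                                         p$lf_halfwidth, 0))
  add("LF_right", "ligament_insertion", c(-(D / 2 + p$lamina_offset),
                                          -p$lf_halfwidth, 0))
  add("ISL", "ligament_insertion", c(-(D / 2 + 0.6 * p$spinous_length), 0, -3))
  add("SSL", "ligament_insertion", c(-(D / 2 + p$spinous_length) + 1.5, 0, -4))
  add("ITL_left", "ligament_insertion", c(-4, p$transverse_width / 2, 0))
  add("ITL_right", "ligament_insertion", c(-4, -p$transverse_width / 2, 0))

  surfaces <- facet_surface_ids()
  if (level == "SA") surfaces <- surfaces[surfaces$sup == "sup", ]
  for (r in seq_len(nrow(surfaces))) {
    sup <- surfaces$sup[r]; side <- surfaces$side[r]
    fp <- facet_points_local(p, sup, side)
    for (j in 1:9) {
      add(sprintf("facet_%s_%s_%d", sup, side, j), "facet_point",
          fp$points[j, ])
    }
  }

  df <- dplyr::bind_rows(lapply(lm, tibble::as_tibble))
  if (anyDuplicated(df$id) > 0) {
    stop("internal error: duplicated landmark ids", call. = FALSE)
  }
  if (p$jitter_mm > 0) {
    rs <- local_rng(seed)
    on.exit(restore_rng(rs), add = TRUE)
    df$x <- df$x + stats::rnorm(nrow(df), 0, p$jitter_mm)
    df$y <- df$y + stats::rnorm(nrow(df), 0, p$jitter_mm)
    df$z <- df$z + stats::rnorm(nrow(df), 0, p$jitter_mm)
  }
  if (level != "SA" && nrow(df) != 47) {
    stop("internal error: lumbar vertebra must carry 47 landmarks, got ",
         nrow(df), call. = FALSE)
  }

  m <- p$mass_kg
  d <- mm2m(D); w <- mm2m(W); h <- mm2m(H)
  inertia <- m / 12 * diag(c(w^2 + h^2, d^2 + h^2, w^2 + d^2))

  structure(list(level = level, landmarks = df, mass = m, inertia = inertia,
                 shape_params = p),
            class = "spinedyn_vertebra")
}

#' Landmark position lookup
#' @keywords internal
landmark_pos <- function(vertebra, id) {
  i <- match(id, vertebra$landmarks$id)
  if (is.na(i)) {
    stop("vertebra ", vertebra$level, " has no landmark '", id, "'",
         call. = FALSE)
  }
  as.numeric(vertebra$landmarks[i, c("x", "y", "z")])
}

#' Fit a least-squares plane to facet points
#'
#' Total-least-squares plane through a point cloud: the plane passes through
#' the centroid and its normal is the eigenvector of the scatter matrix
#' belonging to the smallest eigenvalue (minimizing the sum of squared
#' orthogonal point-plane distances).
#'
#' @param points numeric matrix, n x 3 (n >= 3), mm.
#' @return list with `point` (centroid), `normal` (unit), `residual`
#'   (root-mean-square orthogonal distance) and `source_points`.
#' @export
fit_facet_plane <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 3 || nrow(points) < 3) {
    stop("facet plane fit needs an n x 3 matrix with n >= 3", call. = FALSE)
  }
  ctr <- colMeans(points)
  X <- sweep(points, 2, ctr)
  S <- crossprod(X)
  eg <- eigen(S, symmetric = TRUE)
  # eigenvalues descending; collinear clouds have two vanishing ones
  scale2 <- max(eg$values[1], .Machine$double.eps)
  if (eg$values[2] / scale2 < 1e-12) {
    stop("degenerate facet geometry: points are collinear", call. = FALSE)
  }
  n <- eg$vectors[, 3]
  if (n[3] < 0 || (n[3] == 0 && n[1] < 0)) n <- -n
  residual <- sqrt(max(eg$values[3], 0) / nrow(points))
  structure(list(point = ctr, normal = n, residual = residual,
                 source_points = points),
            class = "spinedyn_facet_plane")
}

local_rng <- function(seed) {
  state <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(as.integer(seed))
  state
}

restore_rng <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
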