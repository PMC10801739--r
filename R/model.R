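#' Multibody model assembly
#'
#' [assemble_model()] turns a spine geometry, an element configuration and
#' a decompression technique into a simulation-ready model: six rigid
#' bodies connected by six degree-of-freedom joints (unconstrained relative
#' motion), a roster of 10 ligament fascicles per level, one disc bushing
#' per level and two facet contacts per level, minus the resected
#' ligaments. The sacrum (and optionally L5, for the validation protocol)
#' is fixed.
#'
#' @name model-assembly
NULL

LIGAMENT_ROSTER <- list(
  ALL       = list(origin = "ALL", insertion = "ALL", cfg = "ALL"),
  PLL       = list(origin = "PLL", insertion = "PLL", cfg = "PLL"),
  LF_left   = list(origin = "LF_left", insertion = "LF_left", cfg = "LF"),
  LF_right  = list(origin = "LF_right", insertion = "LF_right", cfg = "LF"),
  ISL       = list(origin = "ISL", insertion = "ISL", cfg = "ISL"),
  SSL       = list(origin = "SSL", insertion = "SSL", cfg = "SSL"),
  ITL_left  = list(origin = "ITL_left", insertion = "ITL_left", cfg = "ITL"),
  ITL_right = list(origin = "ITL_right", insertion = "ITL_right",
                   cfg = "ITL"),
  # capsular ligaments share facet points: routed from the caudal edge of
  # the inferior facet to the cranial edge of the opposing superior facet,
  # spanning the joint like the capsule (the two central points coincide up
  # to the articulation clearance and cannot carry a finite-length fibre)
  CL_left   = list(origin = "facet_inf_left_2", insertion = "facet_sup_left_8",
                   cfg = "CL"),
  CL_right  = list(origin = "facet_inf_right_2",
                   insertion = "facet_sup_right_8", cfg = "CL")
)

#' Assemble a simulation model
#'
#' @param spine a `spinedyn_spine` from [generate_spine()].
#' @param config element configuration from [load_element_config()].
#' @param technique a technique name (`"INTACT"`, `"UILF"`, `"BILF"`,
#'   `"LAM"`), a [technique()] object, or a removal-set tibble.
#' @param fixed_bodies character vector of fixed body levels; the sacrum is
#'   always fixed.
#' @return object of class `spinedyn_model`.
#' @export
assemble_model <- function(spine, config = load_element_config(),
                           technique = "INTACT",
                           fixed_bodies = "SA") {
  stopifnot(inherits(spine, "spinedyn_spine"))
  if (is.character(technique)) technique <- technique(technique)
  if (inherits(technique, "spinedyn_technique")) {
    removal <- technique$removal_set
    tech_name <- technique$name
  } else {
    removal <- technique
    tech_name <- "CUSTOM"
  }
  fixed_bodies <- union(fixed_bodies, "SA")
  if (!all(fixed_bodies %in% ALL_LEVELS)) {
    stop("unknown fixed body", call. = FALSE)
  }

  poses <- lapply(spine$vertebrae, `[[`, "pose")
  levels <- ALL_LEVELS

  # --- ligaments ------------------------------------------------------
  ligaments <- list()
  for (k in 1:5) {
    cranial <- spine$vertebrae[[k]]
    caudal <- spine$vertebrae[[k + 1]]
    level <- paste0(levels[k], "-", levels[k + 1])
    for (nm in names(LIGAMENT_ROSTER)) {
      rt <- LIGAMENT_ROSTER[[nm]]
      lc <- config$ligaments[[rt$cfg]]
      pa <- tryCatch(landmark_pos(cranial, rt$origin), error = function(e) {
        stop("element ", nm, " @ ", level, ": ", conditionMessage(e),
             call. = FALSE)
      })
      pb <- tryCatch(landmark_pos(caudal, rt$insertion), error = function(e) {
        stop("element ", nm, " @ ", level, ": ", conditionMessage(e),
             call. = FALSE)
      })
      pa_w <- poses[[k]]$p + poses[[k]]$R %*% mm2m(pa)
      pb_w <- poses[[k + 1]]$p + poses[[k + 1]]$R %*% mm2m(pb)
      neutral_len <- m2mm(sqrt(sum((pa_w - pb_w)^2)))
      lg <- ligament(
        name = nm, span = c(levels[k], levels[k + 1]),
        origin = rt$origin, insertion = rt$insertion,
        slack_length = neutral_len * lc$slack_ratio,
        linear_stiffness = lc$k * config$scale$ligament,
        toe_strain = lc$toe_strain, toe_shape = lc$toe_shape
      )
      lg$level <- level
      lg$body_cranial <- k
      lg$body_caudal <- k + 1
      lg$pa <- pa; lg$pb <- pb
      ligaments[[length(ligaments) + 1]] <- lg
    }
  }

  # --- resection ------------------------------------------------------
  if (nrow(removal) > 0) {
    keys <- vapply(ligaments, function(l) paste(l$name, l$level), "")
    drop <- paste(removal$name, removal$level)
    missing <- setdiff(drop, keys)
    if (length(missing) > 0) {
      stop("removal set references unknown element(s): ",
           paste(missing, collapse = "; "), call. = FALSE)
    }
    ligaments <- ligaments[!keys %in% drop]
  }

  # --- disc bushings --------------------------------------------------
  bushings <- lapply(seq_along(spine$disc_frames), function(k) {
    d <- spine$disc_frames[[k]]
    b <- ivd_bushing(d$level, config)
    b$body_caudal <- match(d$caudal, levels)
    b$body_cranial <- match(d$cranial, levels)
    b$u_ca <- d$u_ca; b$u_cr <- d$u_cr
    b$A_ca <- d$A_ca; b$A_cr <- d$A_cr
    b
  })

  # --- facet contacts -------------------------------------------------
  facets <- lapply(spine$facet_contacts, function(fcdef) {
    cr <- spine$vertebrae[[fcdef$cranial]]
    probe <- as.matrix(
      cr$landmarks[match(fcdef$probe_ids, cr$landmarks$id),
                   c("x", "y", "z")])
    if (anyNA(probe)) {
      stop("element facet @ ", fcdef$level, ": missing probe landmark",
           call. = FALSE)
    }
    fc <- facet_contact(
      pair = list(caudal = fcdef$caudal, cranial = fcdef$cranial,
                  side = fcdef$side, level = fcdef$level),
      plane = structure(list(point = fcdef$plane_point,
                             normal = fcdef$plane_normal),
                        class = "spinedyn_facet_plane"),
      probe_points = probe,
      penalty_stiffness = config$facet$penalty_stiffness_n_mm,
      contact_damping = config$facet$damping_n_s_m,
      smoothing = config$facet$smoothing_mm
    )
    fc$body_caudal <- match(fcdef$caudal, levels)
    fc$body_cranial <- match(fcdef$cranial, levels)
    fc
  })

  model <- structure(list(
    spine = spine, config = config, technique = tech_name,
    removal_set = removal,
    levels = levels,
    fixed = levels %in% fixed_bodies,
    masses = vapply(spine$vertebrae, `[[`, 0, "mass"),
    inertias = lapply(spine$vertebrae, `[[`, "inertia"),
    poses = poses,
    ligaments = ligaments,
    bushings = bushings,
    facets = facets
  ), class = "spinedyn_model")
  model$model_hash <- model_hash(model)
  model
}

#' @export
print.spinedyn_model <- function(x, ...) {
  cat("<spinedyn_model>", x$technique, "|",
      length(x$ligaments), "ligaments,",
      length(x$bushings), "disc bushings,",
      length(x$facets), "facet contacts |",
      sum(!x$fixed), "free bodies\n")
  cat("  hash:", x$model_hash, "\n")
  invisible(x)
}

#' Deterministic model hash
#'
#' MD5 digest over the canonical JSON serialization of the model-defining
#' inputs (geometry, configuration, technique, fixed bodies), so identical
#' inputs always map to an identical hash.
#'
#' @keywords internal
model_hash <- function(model) {
  cfg <- model$config
  cfg$ivd$curve_objs <- NULL
  payload <- list(
    subject = model$spine$subject_id,
    seed = model$spine$seed,
    landmarks = lapply(model$spine$vertebrae, function(v)
      round(as.matrix(v$landmarks[, c("x", "y", "z")]), 9)),
    poses = lapply(model$poses, function(p)
      list(R = round(p$R, 12), p = round(p$p, 12))),
    config = unclass(cfg),
    technique = model$technique,
    removal = as.list(model$removal_set),
    fixed = model$fixed
  )
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  jsonlite::write_json(payload, tf, digits = NA, auto_unbox = TRUE)
  unname(tools::md5sum(tf))
}

#' Flatten a model into numeric arrays for the compiled dynamics core
#' @keywords internal
flatten_model <- function(model) {
  nb <- length(model$levels)
  pose0 <- numeric(0)
  for (k in 1:nb) {
    q <- rotmat_to_quat(model$poses[[k]]$R)
    pose0 <- c(pose0, model$poses[[k]]$p, q)
  }
  lig <- model$ligaments
  nl <- length(lig)
  bus <- model$bushings
  fc <- model$facets
  cv <- model$config$ivd$curve_objs
  curve_pack <- function(obj) list(x = obj$x, y = obj$y, m = obj$m)
  list(
    nb = nb,
    free = as.integer(!model$fixed),
    mass = as.numeric(model$masses),
    inertia = as.numeric(unlist(model$inertias)),
    pose0 = pose0,
    n_lig = nl,
    lig_a = vapply(lig, function(l) as.integer(l$body_cranial) - 1L, 0L),
    lig_b = vapply(lig, function(l) as.integer(l$body_caudal) - 1L, 0L),
    lig_pa = as.numeric(vapply(lig, function(l) mm2m(l$pa), numeric(3))),
    lig_pb = as.numeric(vapply(lig, function(l) mm2m(l$pb), numeric(3))),
    lig_L0 = vapply(lig, function(l) mm2m(l$slack_length), 0),
    lig_k = vapply(lig, function(l) l$linear_stiffness, 0),
    lig_eps_t = vapply(lig, function(l) l$toe_strain, 0),
    lig_shape = vapply(lig, function(l) as.numeric(l$toe_shape), 0),
    n_facet = length(fc),
    fc_ca = vapply(fc, function(f) as.integer(f$body_caudal) - 1L, 0L),
    fc_cr = vapply(fc, function(f) as.integer(f$body_cranial) - 1L, 0L),
    fc_pt = as.numeric(vapply(fc, function(f) mm2m(f$plane$point),
                              numeric(3))),
    fc_n = as.numeric(vapply(fc, function(f) f$plane$normal, numeric(3))),
    fc_probes = as.numeric(vapply(fc, function(f)
      as.numeric(t(mm2m(f$probe_points))), numeric(27))),
    fc_k = vapply(fc, function(f) f$penalty_stiffness * 1000, 0),  # N/m
    fc_d0 = vapply(fc, function(f) mm2m(f$smoothing), 0),
    fc_cd = vapply(fc, function(f) f$contact_damping, 0),
    n_bush = length(bus),
    bu_ca = vapply(bus, function(b) as.integer(b$body_caudal) - 1L, 0L),
    bu_cr = vapply(bus, function(b) as.integer(b$body_cranial) - 1L, 0L),
    bu_uca = as.numeric(vapply(bus, function(b) b$u_ca, numeric(3))),
    bu_ucr = as.numeric(vapply(bus, function(b) b$u_cr, numeric(3))),
    bu_Aca = as.numeric(vapply(bus, function(b) as.numeric(b$A_ca),
                               numeric(9))),
    bu_Acr = as.numeric(vapply(bus, function(b) as.numeric(b$A_cr),
                               numeric(9))),
    bu_crot = as.numeric(vapply(bus, function(b) b$rot_damping, numeric(3))),
    bu_ctrans = as.numeric(vapply(bus, function(b) b$trans_damping,
                                  numeric(3))),
    rot_scale = model$config$scale$ivd_rot,
    curves = list(
      FE = curve_pack(cv$FE), LB = curve_pack(cv$LB), AR = curve_pack(cv$AR),
      AP = curve_pack(cv$AP), ML = curve_pack(cv$ML), SI = curve_pack(cv$SI)
    )
  )
}
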