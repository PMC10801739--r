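#' Broom-style tidiers
#'
#' `tidy()` returns per-observation tibbles, `glance()` one-row model
#' summaries, for the package's result objects.
#'
#' @name tidiers
NULL

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a spine geometry into a landmark table
#'
#' @param x a `spinedyn_spine`.
#' @param ... unused.
#' @return tibble: level, id, role, x, y, z (mm, body frame).
#' @export
tidy.spinedyn_spine <- function(x, ...) {
  purrr::map_dfr(x$vertebrae, function(v) {
    dplyr::mutate(v$landmarks, level = v$level, .before = 1)
  })
}

#' Tidy a trajectory into a long state table
#'
#' @param x a `spinedyn_trajectory`.
#' @param ... unused.
#' @return tibble: time, level, quantity, value (positions in m, flexion
#'   angles in degrees).
#' @export
tidy.spinedyn_trajectory <- function(x, ...) {
  ref <- rom(x)
  angle_tbl <- tibble::tibble(time = x$times, level = "L1",
                              quantity = "fe_angle_deg",
                              value = ref$angle_deg)
  model <- x$model
  rows <- list(angle_tbl)
  s <- 0
  for (k in seq_along(model$levels)) {
    if (model$fixed[k]) next
    off <- 13 * s
    for (j in 1:3) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        time = x$times, level = model$levels[k],
        quantity = paste0("pos_", c("x", "y", "z")[j]),
        value = x$states[, off + j])
    }
    s <- s + 1
  }
  dplyr::bind_rows(rows)
}

#' Tidy an SPM result
#'
#' @param x a `spinedyn_spm`.
#' @param ... unused.
#' @return tibble: time, z, significant.
#' @export
tidy.spinedyn_spm <- function(x, ...) {
  tibble::tibble(time = x$times, z = x$z,
                 significant = abs(x$z) > x$z_crit)
}

#' One-row SPM summary
#'
#' @param x a `spinedyn_spm`.
#' @param ... unused.
#' @return tibble: n, df, fwhm, resels, z_crit, alpha, n_clusters.
#' @export
glance.spinedyn_spm <- function(x, ...) {
  tibble::tibble(n = x$n, df = x$df, fwhm = x$fwhm, resels = x$resels,
                 z_crit = x$z_crit, alpha = x$alpha,
                 n_clusters = nrow(x$clusters))
}

#' One-row trajectory summary
#'
#' @param x a `spinedyn_trajectory`.
#' @param ... unused.
#' @return tibble: subject, technique, rom_deg, kinetic_energy,
#'   quasi_static, model_hash.
#' @export
glance.spinedyn_trajectory <- function(x, ...) {
  tibble::tibble(
    subject = x$subject_id %||% NA_character_,
    technique = x$technique %||% NA_character_,
    rom_deg = rom(x)$rom_deg,
    kinetic_energy = x$kinetic_energy,
    quasi_static = x$quasi_static,
    model_hash = x$model_hash)
}
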