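#' Cohort statistics
#'
#' The statistical pipeline of the cohort experiment: endpoint
#' normalization of each operated outcome to the subject's intact value
#' (intact = 100%), a level-wise two-sided t-test of the normalized values
#' against the 100% reference with the three-tier significance mapping
#' (`tendency` 0.05 <= p <= 0.1, `significant` 0.001 <= p < 0.05,
#' `highly_significant` p < 0.001), and one-dimensional statistical
#' parametric mapping: node-wise paired t-tests over the full time curves,
#' converted to z-scores and thresholded with a random-field-theory
#' critical value computed from the estimated residual smoothness.
#'
#' @name cohort-statistics
NULL

#' Normalize endpoint outcomes to the intact state
#'
#' `percent = 100 * operated / intact` per subject, level and quantity at
#' the end of the simulated flexion. Rows whose intact reference is zero
#' are flagged undefined (`defined = FALSE`) rather than silently dropped.
#'
#' @param outcomes tibble from [outcome_table()].
#' @param quantities outcome columns to normalize.
#' @return long tibble: subject, technique, level, quantity,
#'   percent_of_intact, defined.
#' @export
normalize_to_intact <- function(outcomes,
                                quantities = c("F_SI", "F_AP", "M_FE")) {
  long <- outcomes |>
    tidyr::pivot_longer(cols = dplyr::all_of(quantities),
                        names_to = "quantity", values_to = "value") |>
    dplyr::select("subject", "technique", "level", "quantity", "value")
  intact <- long |>
    dplyr::filter(.data$technique == "INTACT") |>
    dplyr::select("subject", "level", "quantity", intact_value = "value")
  missing_ref <- dplyr::anti_join(
    dplyr::distinct(long, .data$subject, .data$level, .data$quantity),
    intact, by = c("subject", "level", "quantity"))
  if (nrow(missing_ref) > 0) {
    stop("intact reference missing for ", nrow(missing_ref),
         " subject x level x quantity combination(s)", call. = FALSE)
  }
  long |>
    dplyr::left_join(intact, by = c("subject", "level", "quantity")) |>
    dplyr::mutate(
      defined = .data$intact_value != 0,
      # ratio first: an operated value equal to its reference is exactly 100
      percent_of_intact = dplyr::if_else(
        .data$defined, 100 * (.data$value / .data$intact_value), NA_real_)
    ) |>
    dplyr::select("subject", "technique", "level", "quantity",
                  "percent_of_intact", "defined")
}

#' Significance tier of a p-value
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return factor with levels none, tendency, significant,
#'   highly_significant.
#' @export
significance_tier <- function(p) {
  tier <- dplyr::case_when(
    p < 0.001 ~ "highly_significant",
    p < 0.05 ~ "significant",
    p <= 0.1 ~ "tendency",
    TRUE ~ "none"
  )
  factor(tier, levels = c("none", "tendency", "significant",
                          "highly_significant"))
}

#' Level-wise t-test of normalized outcomes against the intact reference
#'
#' Two-sided one-sample t-test of the normalized percentages against 100.
#' (Testing the operated percentages against the intact column — which is
#' identically 100 — with an unpaired two-sample test is statistically
#' degenerate because the reference has zero variance; the one-sample
#' formulation is the well-defined reading and is the default. The
#' two-sample variant is available for strict procedural fidelity.)
#'
#' @param normalized tibble from [normalize_to_intact()]; undefined rows
#'   are excluded with a message count.
#' @param variant `"one_sample"` (default) or `"two_sample"`.
#' @return tibble: technique, level, quantity, n, mean_percent, p_value,
#'   tier.
#' @export
level_ttest <- function(normalized, variant = c("one_sample", "two_sample")) {
  variant <- match.arg(variant)
  dropped <- sum(!normalized$defined)
  if (dropped > 0) {
    message(dropped, " undefined normalized value(s) excluded from tests")
  }
  dat <- normalized |>
    dplyr::filter(.data$defined, .data$technique != "INTACT")
  dat |>
    dplyr::group_by(.data$technique, .data$level, .data$quantity) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 2) {
        stop("level_ttest requires n >= 2 per technique x level x quantity",
             call. = FALSE)
      }
      x <- d$percent_of_intact
      p <- if (stats::sd(x) == 0 && variant == "one_sample") {
        if (isTRUE(all.equal(mean(x), 100))) 1 else 0
      } else if (variant == "one_sample") {
        stats::t.test(x, mu = 100)$p.value
      } else {
        stats::t.test(x, rep(100, length(x)))$p.value
      }
      tibble::tibble(n = length(x), mean_percent = mean(x), p_value = p)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(tier = significance_tier(.data$p_value))
}

#' One-dimensional SPM paired t-test over time curves
#'
#' Node-wise paired two-sided t-tests of operated minus intact curves,
#' converted to z-scores by probability transform, thresholded with the
#' Euler-characteristic expectation of a smooth one-dimensional Gaussian
#' field whose smoothness (FWHM) is estimated from the normalized
#' residuals. Maximal contiguous runs beyond the two-tailed critical value
#' are reported as suprathreshold clusters.
#'
#' @param curves_intact,curves_operated n x T matrices (subjects x time
#'   nodes) on a common time grid, matched by row (subject).
#' @param times optional time grid (length T) used for cluster extents.
#' @param alpha field-wise two-tailed significance level.
#' @return object of class `spinedyn_spm`: `z` (length T), `z_crit`,
#'   `fwhm`, `resels`, `clusters` (tibble start/end), `df`, `alpha`.
#' @export
spm_paired_ttest <- function(curves_intact, curves_operated, times = NULL,
                             alpha = 0.05) {
  A <- as.matrix(curves_intact); B <- as.matrix(curves_operated)
  if (!all(dim(A) == dim(B))) {
    stop("curve matrices must share dimensions (matched subjects, common grid)",
         call. = FALSE)
  }
  n <- nrow(A); Tn <- ncol(A)
  if (n < 3) stop("SPM paired t-test requires n >= 3 subjects",
                  call. = FALSE)
  if (is.null(times)) times <- seq_len(Tn)
  if (length(times) != Tn) stop("time grid length mismatch", call. = FALSE)
  D <- B - A
  mu <- colMeans(D)
  sdv <- apply(D, 2, stats::sd)
  tstat <- ifelse(sdv > 0, mu / (sdv / sqrt(n)), 0)
  df <- n - 1
  z <- t_to_z(tstat, df)
  if (all(abs(mu) < .Machine$double.eps * 100) && all(sdv == 0)) {
    z[] <- 0
  }
  # residual smoothness (FWHM in node units) from normalized residuals
  R <- sweep(D, 2, mu)
  fwhm <- residual_fwhm(R)
  resels <- (Tn - 1) / fwhm
  t_crit <- rft_t_threshold(alpha, resels, df)
  z_crit <- t_to_z(t_crit, df)
  above <- abs(z) > z_crit & sdv > 0
  clusters <- cluster_runs(above, times, z)
  structure(list(z = z, times = times, z_crit = z_crit, fwhm = fwhm,
                 resels = resels, clusters = clusters, df = df,
                 alpha = alpha, n = n),
            class = "spinedyn_spm")
}

#' @keywords internal
t_to_z <- function(tstat, df) {
  # probability transform, numerically stable in both tails
  z <- numeric(length(tstat))
  pos <- tstat >= 0
  z[pos] <- -stats::qnorm(stats::pt(tstat[pos], df, lower.tail = FALSE,
                                    log.p = TRUE), log.p = TRUE)
  z[!pos] <- stats::qnorm(stats::pt(tstat[!pos], df, log.p = TRUE),
                          log.p = TRUE)
  z
}

#' Estimate field smoothness from residual curves
#'
#' FWHM of the equivalent Gaussian smoothing kernel, from the mean squared
#' gradient of the subject-normalized residuals (node units).
#'
#' @keywords internal
residual_fwhm <- function(R) {
  s <- sqrt(colSums(R^2))                # variance-normalize at each node
  if (all(s == 0)) return(Inf)
  s[s == 0] <- Inf
  U <- sweep(R, 2, s, "/")
  G <- t(diff(t(U)))                     # node-to-node gradient
  v <- mean(colSums(G^2))
  if (v <= 0) return(Inf)
  sqrt(4 * log(2) / v)
}

#' Two-tailed RFT critical value for a smooth 1D t-field
#'
#' Solves `alpha = 2 * (P(T > u) + resels * rho_1(u))` with the
#' one-dimensional Euler-characteristic density of a t-field with `df`
#' degrees of freedom, `rho_1(u) = sqrt(4 log 2) / (2 pi) *
#' (1 + u^2 / df)^(-(df - 1) / 2)` — the expected number of upcrossings of
#' level `u` on `resels` resolution elements. The critical value exceeds
#' the pointwise 97.5% quantile for any multi-node field and grows as the
#' estimated smoothness decreases.
#'
#' @keywords internal
rft_t_threshold <- function(alpha, resels, df) {
  if (!is.finite(resels) || resels <= 0) {
    return(stats::qt(1 - alpha / 2, df))
  }
  f <- function(u) {
    2 * (stats::pt(u, df, lower.tail = FALSE) +
           resels * sqrt(4 * log(2)) / (2 * pi) *
             (1 + u^2 / df)^(-(df - 1) / 2)) - alpha
  }
  stats::uniroot(f, c(stats::qt(1 - alpha / 2, df), 50))$root
}

cluster_runs <- function(above, times, z) {
  if (!any(above)) {
    return(tibble::tibble(start = numeric(0), end = numeric(0),
                          peak_z = numeric(0), sign = integer(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  purrr::map2_dfr(starts[keep], ends[keep], function(s, e) {
    zi <- z[s:e]
    tibble::tibble(start = times[s], end = times[e],
                   peak_z = zi[which.max(abs(zi))],
                   sign = as.integer(sign(zi[which.max(abs(zi))])))
  })
}

#' @export
print.spinedyn_spm <- function(x, ...) {
  cat(sprintf(
    "<spinedyn_spm> n = %d | FWHM %.1f nodes | critical z = +-%.2f | %d cluster(s)\n",
    x$n, x$fwhm, x$z_crit, nrow(x$clusters)))
  invisible(x)
}

#' Extract matched outcome curves for SPM from cohort runs
#'
#' @param runs tibble with `subject`, `technique`, `traj` list column.
#' @param quantity `"F_SI"`, `"F_AP"` or `"M_FE"`.
#' @param level spinal level.
#' @param component `"ivd"` (default) or `"total"`.
#' @return list of per-technique matrices (subjects x nodes) plus `times`.
#' @export
extract_level_curves <- function(runs, quantity = "M_FE", level = "L4-L5",
                                 component = "ivd") {
  stopifnot(tibble::is_tibble(runs))
  subjects <- unique(runs$subject)
  techniques <- unique(runs$technique)
  times <- NULL
  mats <- list()
  for (tech in techniques) {
    rows <- list()
    for (s in subjects) {
      tr <- runs$traj[runs$subject == s & runs$technique == tech][[1]]
      rec <- trajectory_records(tr)
      ll <- rec$level_loads
      sel <- ll[ll$level == level & ll$component == component, ]
      sel <- sel[order(sel$time), ]
      if (is.null(times)) times <- sel$time
      rows[[s]] <- sel[[quantity]]
    }
    mats[[tech]] <- do.call(rbind, rows)
  }
  mats$times <- times
  mats
}
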