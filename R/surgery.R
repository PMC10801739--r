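#' Virtual decompression surgery
#'
#' The three decompression techniques are represented purely as ligament
#' removal sets applied to the model roster (bone is not a force-bearing
#' entity in the model, so no bony resection is simulated):
#'
#' * `INTACT` removes nothing;
#' * `UILF` (unilateral interlaminar fenestration) removes the left
#'   ligamentum flavum fascicle at the index level;
#' * `BILF` removes both flavum fascicles at the index level;
#' * `LAM` (laminectomy) additionally removes both flavum fascicles at the
#'   level above and the inter- and supraspinous ligaments at both spans
#'   adjacent to the resected spinous process.
#'
#' The removal sets are strictly nested INTACT < UILF < BILF < LAM. Facet
#' capsular ligaments are never removed.
#'
#' @name virtual-surgery
NULL

TECHNIQUES <- c("INTACT", "UILF", "BILF", "LAM")

#' Ligament removal set for a decompression technique
#'
#' @param technique `"INTACT"`, `"UILF"`, `"BILF"` or `"LAM"`
#'   (case-insensitive).
#' @param index_level decompressed level, default `"L4-L5"`.
#' @param lam_isl_spans `"both"` (default) removes the inter-/supraspinous
#'   ligaments at the spans above and below the resected spinous process;
#'   `"upper"` restricts them to the upper span only.
#' @return tibble with columns `name` (ligament) and `level` (span).
#' @examples
#' resection_set("LAM")   # 8 removed elements
#' @export
resection_set <- function(technique, index_level = "L4-L5",
                          lam_isl_spans = c("both", "upper")) {
  technique <- toupper(technique)
  if (!technique %in% TECHNIQUES) {
    stop("unknown technique '", technique, "'; expected one of ",
         paste(TECHNIQUES, collapse = ", "), call. = FALSE)
  }
  lam_isl_spans <- match.arg(lam_isl_spans)
  lv <- strsplit(index_level, "-")[[1]]
  if (length(lv) != 2 || !all(lv %in% ALL_LEVELS)) {
    stop("invalid index_level '", index_level, "'", call. = FALSE)
  }
  i <- match(lv[1], ALL_LEVELS)
  if (i < 2) stop("index_level has no level above it", call. = FALSE)
  upper_level <- paste0(ALL_LEVELS[i - 1], "-", ALL_LEVELS[i])

  empty <- tibble::tibble(name = character(), level = character())
  uilf <- tibble::tibble(name = "LF_left", level = index_level)
  bilf <- dplyr::bind_rows(uilf,
    tibble::tibble(name = "LF_right", level = index_level))
  isl_levels <- if (lam_isl_spans == "both") {
    c(upper_level, index_level)
  } else {
    upper_level
  }
  lam <- dplyr::bind_rows(
    bilf,
    tibble::tibble(name = c("LF_left", "LF_right"), level = upper_level),
    tidyr::expand_grid(name = c("ISL", "SSL"), level = isl_levels)
  )
  switch(technique, INTACT = empty, UILF = uilf, BILF = bilf, LAM = lam)
}

#' Technique definition object
#'
#' @inheritParams resection_set
#' @return list of class `spinedyn_technique` with the removal set.
#' @export
technique <- function(technique = "INTACT", index_level = "L4-L5",
                      lam_isl_spans = "both") {
  structure(list(name = toupper(technique), index_level = index_level,
                 removal_set = resection_set(technique, index_level,
                                             lam_isl_spans)),
            class = "spinedyn_technique")
}
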