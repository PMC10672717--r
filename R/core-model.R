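# UCEIS scoring model: three ordinal descriptors, total on the 0-8 scale,
# and the mapping from totals to clinical severity categories.

#' Severity category levels
#'
#' Four-class severity levels (`remission`, `mild`, `moderate`, `severe`) and
#' the treatment-relevant three-class coarsening in which remission and mild
#' are merged.
#'
#' @format Character vectors of factor levels, in increasing severity order.
#' @export
severity_levels4 <- c("remission", "mild", "moderate", "severe")

#' @rdname severity_levels4
#' @export
severity_levels3 <- c("remission_mild", "moderate", "severe")

subscore_max <- c(vascular_pattern = 2L, bleeding = 3L, erosions_ulcers = 3L)

check_subscore <- function(x, name) {
  if (length(x) == 0L) abort(sprintf("`%s` must be non-empty.", name))
  if (anyNA(x) || any(x != as.integer(x))) {
    abort(sprintf("`%s` must be whole numbers without missing values.", name))
  }
  if (any(x < 0L) || any(x > subscore_max[[name]])) {
    abort(sprintf(
      "`%s` out of range: values must lie in 0..%d.", name, subscore_max[[name]]
    ))
  }
  as.integer(x)
}

#' Total UCEIS score from the three descriptor subscores
#'
#' The Ulcerative Colitis Endoscopic Index of Severity (UCEIS) grades an
#' endoscopic frame by three ordinal descriptors: vascular pattern (0 =
#' normal, 1 = patchy obliteration, 2 = obliterated), bleeding (0 = none to
#' 3 = luminal moderate/severe) and erosions/ulcers (0 = none to 3 = deep
#' ulcer).  The total is their sum, on the 0-8 scale.  Subscores are encoded
#' 0-based so totals span 0-8; some descriptor listings number the levels
#' from 1, which would shift the sum to 3-11 and is not used here.
#'
#' @param vascular_pattern Integer vector in 0..2.
#' @param bleeding Integer vector in 0..3.
#' @param erosions_ulcers Integer vector in 0..3.
#' @return An integer vector of totals in 0..8.
#' @examples
#' uceis_total(2, 3, 3)  # maximal severity, 8
#' uceis_total(c(0, 1), c(0, 2), c(0, 1))
#' @export
uceis_total <- function(vascular_pattern, bleeding, erosions_ulcers) {
  v <- check_subscore(vascular_pattern, "vascular_pattern")
  b <- check_subscore(bleeding, "bleeding")
  e <- check_subscore(erosions_ulcers, "erosions_ulcers")
  if (length(unique(c(length(v), length(b), length(e)))) != 1L) {
    abort("Subscore vectors must have equal length.")
  }
  v + b + e
}

#' Build a tibble of UCEIS scores
#'
#' Convenience constructor that validates the three subscores and returns a
#' tidy score table with the recomputed total.
#'
#' @inheritParams uceis_total
#' @param image_id Optional identifier vector recycled against the subscores.
#' @return A tibble with columns `image_id` (if given), the three subscores
#'   and `total`.
#' @export
uceis_score <- function(vascular_pattern, bleeding, erosions_ulcers,
                        image_id = NULL) {
  total <- uceis_total(vascular_pattern, bleeding, erosions_ulcers)
  out <- tibble(
    vascular_pattern = as.integer(vascular_pattern),
    bleeding = as.integer(bleeding),
    erosions_ulcers = as.integer(erosions_ulcers),
    total = total
  )
  if (!is.null(image_id)) out <- dplyr::mutate(out, image_id = image_id, .before = 1)
  out
}

#' Severity cutpoints on the UCEIS total scale
#'
#' The five-expert panels in this workflow grade severity from the UCEIS
#' total through three cutpoints: totals up to `remission_max` are remission,
#' up to `mild_max` mild, up to `moderate_max` moderate, and anything above
#' severe.  The defaults (remission 0-1, mild 2-4, moderate 5-6, severe 7-8)
#' are the conventional UCEIS bands; pass explicit values to study other
#' conventions.
#'
#' @param remission_max,mild_max,moderate_max Integer cutpoints on the 0-8
#'   scale, strictly increasing with `moderate_max < 8`.
#' @return A `severity_cutpoints` object (named integer vector).
#' @examples
#' severity_cutpoints()
#' severity_cutpoints(1, 3, 6)
#' @export
severity_cutpoints <- function(remission_max = 1L, mild_max = 4L,
                               moderate_max = 6L) {
  cp <- c(
    remission_max = as.integer(remission_max),
    mild_max = as.integer(mild_max),
    moderate_max = as.integer(moderate_max)
  )
  if (anyNA(cp)) abort("Cutpoints must be integers.")
  if (!(cp[1] >= 0L && cp[1] < cp[2] && cp[2] < cp[3] && cp[3] < 8L)) {
    abort("Invalid cutpoints: need 0 <= remission_max < mild_max < moderate_max < 8.")
  }
  structure(cp, class = "severity_cutpoints")
}

#' @export
print.severity_cutpoints <- function(x, ...) {
  cat(sprintf(
    "UCEIS severity cutpoints: remission 0-%d, mild %d-%d, moderate %d-%d, severe %d-8\n",
    x[1], x[1] + 1L, x[2], x[2] + 1L, x[3], x[3] + 1L
  ))
  invisible(x)
}

#' Map UCEIS totals to severity categories
#'
#' @param total Integer vector of UCEIS totals in 0..8.
#' @param cutpoints A [severity_cutpoints()] object.
#' @return A factor with levels `remission`, `mild`, `moderate`, `severe`.
#' @examples
#' map_severity(0:8)
#' @export
map_severity <- function(total, cutpoints = severity_cutpoints()) {
  if (!inherits(cutpoints, "severity_cutpoints")) {
    cutpoints <- do.call(severity_cutpoints, as.list(cutpoints))
  }
  if (anyNA(total) || any(total < 0) || any(total > 8)) {
    abort("`total` must lie in 0..8 with no missing values.")
  }
  idx <- 1L + (total > cutpoints[1]) + (total > cutpoints[2]) + (total > cutpoints[3])
  factor(severity_levels4[idx], levels = severity_levels4)
}

#' Merge four-class severity to the three-class scale
#'
#' Collapses `remission` and `mild` into `remission_mild`; `moderate` and
#' `severe` are unchanged.  The merge is the treatment-relevant coarsening:
#' patients in remission or with mild disease are managed alike.
#'
#' @param category A factor or character vector on the four-class scale.
#' @return A factor with levels `remission_mild`, `moderate`, `severe`.
#' @examples
#' merge_severity3(map_severity(0:8))
#' @export
merge_severity3 <- function(category) {
  category <- as.character(category)
  bad <- setdiff(unique(category), severity_levels4)
  if (length(bad)) abort(sprintf("Unknown severity category: %s", bad[1]))
  out <- ifelse(category %in% c("remission", "mild"), "remission_mild", category)
  factor(out, levels = severity_levels3)
}

#' Read or write a UCEIS score table
#'
#' Score tables are delimited text with columns `image_id`, `rater_id`,
#' `vascular_pattern`, `bleeding`, `erosions_ulcers`, `total` and `severity`.
#' On read, totals are recomputed from the subscores and any mismatch is an
#' error; the severity column is recomputed from `total` and `cutpoints`.
#'
#' @param path File path (CSV or TSV decided from the extension).
#' @param cutpoints A [severity_cutpoints()] object used to (re)derive the
#'   severity column.
#' @return `read_score_table()` returns a tibble; `write_score_table()`
#'   returns `path` invisibly.
#' @export
read_score_table <- function(path, cutpoints = severity_cutpoints()) {
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  df <- reader(path, show_col_types = FALSE)
  need <- c("image_id", "rater_id", "vascular_pattern", "bleeding", "erosions_ulcers")
  missing <- setdiff(need, names(df))
  if (length(missing)) abort(sprintf("Score table lacks column(s): %s",
                                     paste(missing, collapse = ", ")))
  recomputed <- uceis_total(df$vascular_pattern, df$bleeding, df$erosions_ulcers)
  if ("total" %in% names(df) && any(df$total != recomputed)) {
    bad <- which(df$total != recomputed)[1]
    abort(sprintf(
      "Stored total disagrees with subscore sum at row %d (%s / %s).",
      bad, df$image_id[bad], df$rater_id[bad]
    ))
  }
  df$total <- recomputed
  df$severity <- map_severity(df$total, cutpoints)
  as_tibble(df)
}

#' @rdname read_score_table
#' @param scores A data frame with the subscore columns (totals and severity
#'   are recomputed before writing).
#' @export
write_score_table <- function(scores, path, cutpoints = severity_cutpoints()) {
  scores$total <- uceis_total(
    scores$vascular_pattern, scores$bleeding, scores$erosions_ulcers
  )
  scores$severity <- as.character(map_severity(scores$total, cutpoints))
  writer <- if (grepl("\\.tsv$", path)) readr::write_tsv else readr::write_csv
  writer(scores, path)
  invisible(path)
}
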