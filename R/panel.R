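# Rater panels: long tables of (image_id, rater_id, label) that must form a
# complete image-by-rater grid.  Both the consensus and the agreement modules
# consume this representation.

#' Validate a rater panel
#'
#' A rater panel is a long-format data frame with one row per (image, rater)
#' pair and a `label` column holding either UCEIS totals (0-8) or severity
#' categories.  The panel must be complete: every rater labels every image,
#' with no duplicates or missing entries, and at least two raters.
#'
#' @param panel A data frame with columns `image_id`, `rater_id`, `label`.
#' @param scale Either `"total"` (labels must be integers in 0..8),
#'   `"severity"` (labels must be known severity categories) or `"any"`.
#' @return The panel as a tibble, invisibly validated.
#' @export
as_rater_panel <- function(panel, scale = c("any", "total", "severity")) {
  scale <- match.arg(scale)
  need <- c("image_id", "rater_id", "label")
  missing <- setdiff(need, names(panel))
  if (length(missing)) {
    abort(sprintf("Panel lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  panel <- as_tibble(panel[need])
  if (anyNA(panel$label)) abort("Panel contains missing labels.")
  n_img <- dplyr::n_distinct(panel$image_id)
  n_rat <- dplyr::n_distinct(panel$rater_id)
  if (n_rat < 2L) abort("A rater panel needs at least 2 raters.")
  counts <- dplyr::count(panel, .data$image_id, .data$rater_id)
  if (any(counts$n > 1L)) abort("Panel has duplicate (image, rater) entries.")
  if (nrow(counts) != n_img * n_rat) {
    abort("Incomplete panel: every rater must label every image exactly once.")
  }
  if (scale == "total") {
    lab <- panel$label
    if (!is.numeric(lab) || any(lab != as.integer(lab)) || any(lab < 0) || any(lab > 8)) {
      abort("Totals panel labels must be integers in 0..8.")
    }
  } else if (scale == "severity") {
    known <- c(severity_levels4, severity_levels3)
    bad <- setdiff(unique(as.character(panel$label)), known)
    if (length(bad)) abort(sprintf("Unknown severity label: %s", bad[1]))
  }
  panel
}

# image x rater matrix view of a long panel (row/col order = first appearance)
panel_matrix <- function(panel) {
  panel <- as_rater_panel(panel)
  images <- unique(panel$image_id)
  raters <- unique(panel$rater_id)
  m <- matrix(
    panel$label[order(match(panel$rater_id, raters), match(panel$image_id, images))],
    nrow = length(images), ncol = length(raters),
    dimnames = list(as.character(images), as.character(raters))
  )
  m
}

#' Read or write a rater panel CSV
#'
#' Long-format CSV with columns `image_id`, `rater_id`, `label`.
#'
#' @param path File path.
#' @param scale Passed to [as_rater_panel()].
#' @return A validated panel tibble.
#' @export
read_panel <- function(path, scale = "any") {
  as_rater_panel(readr::read_csv(path, show_col_types = FALSE), scale = scale)
}

#' @rdname read_panel
#' @param panel A rater panel data frame.
#' @export
write_panel <- function(panel, path) {
  readr::write_csv(as_rater_panel(panel), path)
  invisible(path)
}
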