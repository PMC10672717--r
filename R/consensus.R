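# Majority-vote consensus over a multi-expert panel.  An image's label is
# adopted only when at least `threshold` raters assign the same label; with
# the default majority threshold (floor(k/2) + 1, "more than half") the
# qualifying label is necessarily unique.

#' Majority-vote consensus labels for a rater panel
#'
#' For each image the modal label and its count are found; the image is
#' retained with that consensus label when the modal count reaches the
#' threshold, and discarded otherwise.  The default threshold is a strict
#' majority of the raters, `floor(n_raters / 2) + 1` (3 of 5 for a
#' five-expert panel), which guarantees the qualifying label is unique.
#'
#' @param panel A rater panel (see [as_rater_panel()]).
#' @param threshold Minimum number of agreeing raters; default strict
#'   majority.
#' @return A `consensus_result`: a list with `images` (tibble of `image_id`,
#'   `modal_label`, `modal_count`, `retained`, `consensus_label`), and scalars
#'   `threshold`, `n_raters`, `n_retained`, `n_discarded`.
#' @examples
#' panel <- tibble::tibble(
#'   image_id = rep(1:2, each = 5),
#'   rater_id = rep(letters[1:5], 2),
#'   label = c(2, 2, 2, 5, 7, 1, 2, 3, 4, 5)
#' )
#' consensus_vote(panel)
#' @export
consensus_vote <- function(panel, threshold = NULL) {
  panel <- as_rater_panel(panel)
  n_raters <- dplyr::n_distinct(panel$rater_id)
  threshold <- threshold %||% (n_raters %/% 2L + 1L)
  if (length(threshold) != 1L || is.na(threshold) || threshold < 1L ||
      threshold > n_raters) {
    abort(sprintf("`threshold` must be a single integer in 1..%d.", n_raters))
  }
  threshold <- as.integer(threshold)

  images <- panel |>
    dplyr::count(.data$image_id, .data$label, name = "votes") |>
    dplyr::group_by(.data$image_id) |>
    # modal label; ties broken by label order, irrelevant once votes >= majority
    dplyr::slice_max(.data$votes, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::rename(modal_label = "label", modal_count = "votes") |>
    dplyr::mutate(
      retained = .data$modal_count >= threshold,
      consensus_label = dplyr::if_else(.data$retained, .data$modal_label,
                                       .data$modal_label[NA_integer_])
    )

  structure(
    list(
      images = images,
      threshold = threshold,
      n_raters = n_raters,
      n_retained = sum(images$retained),
      n_discarded = sum(!images$retained)
    ),
    class = "consensus_result"
  )
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf(
    "Consensus vote: %d raters, threshold %d -> %d of %d images retained\n",
    x$n_raters, x$threshold, x$n_retained, x$n_retained + x$n_discarded
  ))
  print(x$images, n = 6)
  invisible(x)
}

#' @export
tidy.consensus_result <- function(x, ...) x$images

#' @export
glance.consensus_result <- function(x, ...) {
  tibble(
    n_images = x$n_retained + x$n_discarded,
    n_raters = x$n_raters,
    threshold = x$threshold,
    n_retained = x$n_retained,
    n_discarded = x$n_discarded,
    retention = x$n_retained / (x$n_retained + x$n_discarded)
  )
}

#' Retention as a function of the agreement threshold
#'
#' Counts, for every threshold from 1 to the number of raters, how many
#' images would be retained by [consensus_vote()].  The curve is monotone
#' non-increasing and equals the number of images at threshold 1.
#'
#' @inheritParams consensus_vote
#' @return A tibble with columns `threshold` and `n_retained`, of class
#'   `retention_curve`.
#' @export
retention_curve <- function(panel) {
  panel <- as_rater_panel(panel)
  n_raters <- dplyr::n_distinct(panel$rater_id)
  modal <- panel |>
    dplyr::count(.data$image_id, .data$label) |>
    dplyr::group_by(.data$image_id) |>
    dplyr::summarise(modal_count = max(.data$n))
  out <- tibble(
    threshold = seq_len(n_raters),
    n_retained = vapply(seq_len(n_raters),
                        function(t) sum(modal$modal_count >= t), integer(1))
  )
  class(out) <- c("retention_curve", class(out))
  out
}

#' @export
autoplot.retention_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$threshold, y = .data$n_retained)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$threshold) +
    ggplot2::labs(
      x = "agreement threshold (raters)", y = "images retained",
      title = "Consensus retention by threshold"
    )
}

#' Write consensus results to disk
#'
#' Writes the per-image table as CSV and the summary as JSON.
#'
#' @param result A `consensus_result`.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return `result`, invisibly.
#' @export
write_consensus <- function(result, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(result, "consensus_result"))
  if (!is.null(csv_path)) {
    out <- dplyr::select(result$images, "image_id", "consensus_label",
                         "modal_count", "retained")
    readr::write_csv(out, csv_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(threshold = result$threshold, n_raters = result$n_raters,
           n_retained = result$n_retained, n_discarded = result$n_discarded),
      json_path, auto_unbox = TRUE, pretty = TRUE
    )
  }
  invisible(result)
}
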