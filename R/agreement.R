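# Interobserver agreement statistics implemented from first principles:
# two-way random-effects intraclass correlation for ordinal/continuous
# scores and Fleiss' kappa for categorical labels, plus the conventional
# interpretation bands.

new_agreement_report <- function(statistic, estimate, band, components, n_images,
                                 n_raters) {
  structure(
    list(statistic = statistic, estimate = estimate, band = band,
         components = components, n_images = n_images, n_raters = n_raters),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("%s = %.4f (%s agreement; %d images, %d raters)\n",
              x$statistic, x$estimate, x$band, x$n_images, x$n_raters))
  invisible(x)
}

#' @export
tidy.agreement_report <- function(x, ...) {
  tibble(statistic = x$statistic, estimate = x$estimate, band = x$band)
}

#' @export
glance.agreement_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble(statistic = x$statistic, estimate = x$estimate, band = x$band,
           n_images = x$n_images, n_raters = x$n_raters),
    as_tibble(as.list(x$components))
  )
}

#' Intraclass correlation ICC(2,1) for a rater panel
#'
#' Quantifies the consistency of ordinal or continuous scores (here, UCEIS
#' totals) assigned by the same fixed set of raters to every image, as the
#' ratio of between-image variance to total variance.  The default form is
#' ICC(2,1): two-way random effects, absolute agreement, single measurement,
#'
#' \deqn{ICC(2,1) = \frac{MS_B - MS_E}{MS_B + (k-1) MS_E + \frac{k}{n}(MS_R - MS_E)}}
#'
#' with \eqn{n} images, \eqn{k} raters and \eqn{MS_B}, \eqn{MS_R},
#' \eqn{MS_E} the between-image, between-rater and residual mean squares of
#' the two-way decomposition.  The consistency form ICC(3,1), which drops
#' the rater variance term, is available for sensitivity analysis.
#'
#' @param panel A rater panel of numeric scores (see [as_rater_panel()]).
#' @param form `"ICC(2,1)"` (absolute agreement, default) or `"ICC(3,1)"`
#'   (consistency).
#' @return An `agreement_report` with the point estimate, interpretation
#'   band, and mean-square components (`ms_between`, `ms_rater`, `ms_error`).
#'   Negative estimates are reported as computed, not truncated at zero.
#' @examples
#' panel <- tidyr::expand_grid(image_id = 1:6, rater_id = 1:3)
#' panel$label <- rep(1:6, each = 3) + rep(c(0, 1, 0), 6)
#' icc_two_way(panel)
#' @export
icc_two_way <- function(panel, form = c("ICC(2,1)", "ICC(3,1)")) {
  form <- match.arg(form)
  m <- panel_matrix(panel)
  storage.mode(m) <- "double"
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2L) abort("ICC needs at least 2 images.")
  if (anyNA(m)) abort("ICC needs a complete numeric panel.")

  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_total <- sum((m - grand)^2)
  if (ss_total == 0) {
    abort("ICC undefined: all scores identical (zero total variance).")
  }
  ss_between <- k * sum((row_means - grand)^2)
  ss_rater <- n * sum((col_means - grand)^2)
  ss_error <- ss_total - ss_between - ss_rater
  msb <- ss_between / (n - 1)
  msr <- ss_rater / (k - 1)
  mse <- ss_error / ((n - 1) * (k - 1))

  est <- if (form == "ICC(2,1)") {
    (msb - mse) / (msb + (k - 1) * mse + (k / n) * (msr - mse))
  } else {
    (msb - mse) / (msb + (k - 1) * mse)
  }

  new_agreement_report(
    statistic = form, estimate = est,
    band = interpret_band("icc", est),
    components = c(ms_between = msb, ms_rater = msr, ms_error = mse),
    n_images = n, n_raters = k
  )
}

#' Fleiss' kappa for a categorical rater panel
#'
#' Chance-corrected agreement among two or more raters assigning categorical
#' labels (here, severity categories).  With \eqn{n_{ij}} the number of
#' raters placing image \eqn{i} in category \eqn{j} and \eqn{k} raters:
#' per-image agreement \eqn{P_i = (\sum_j n_{ij}^2 - k) / (k(k-1))}, observed
#' agreement \eqn{\bar P} the mean of \eqn{P_i}, category marginals
#' \eqn{p_j = \sum_i n_{ij} / (nk)}, expected agreement
#' \eqn{\bar P_e = \sum_j p_j^2}, and
#' \eqn{\kappa = (\bar P - \bar P_e) / (1 - \bar P_e)}.
#'
#' @param panel A rater panel of categorical labels.
#' @param categories Optional ordered vector of category labels; defaults to
#'   the sorted set of labels observed in the panel.
#' @return An `agreement_report` whose components hold the observed and
#'   expected agreement (`p_bar`, `p_e`) and the per-category marginal
#'   proportions.
#' @examples
#' panel <- tidyr::expand_grid(image_id = 1:4, rater_id = 1:3)
#' panel$label <- c("a", "a", "a", "a", "a", "b", "b", "b", "b", "c", "c", "c")
#' fleiss_kappa(panel)
#' @export
fleiss_kappa <- function(panel, categories = NULL) {
  m <- panel_matrix(panel)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2L) abort("Fleiss' kappa needs at least 2 images.")
  labs <- as.character(m)
  categories <- as.character(categories %||% sort(unique(labs)))
  bad <- setdiff(unique(labs), categories)
  if (length(bad)) abort(sprintf("Label outside the category set: %s", bad[1]))

  # n_ij: images x categories count matrix
  nij <- t(apply(m, 1L, function(row) tabulate(match(row, categories),
                                               nbins = length(categories))))
  if (length(categories) == 1L) nij <- matrix(nij, ncol = 1L)

  p_i <- (rowSums(nij^2) - k) / (k * (k - 1))
  p_bar <- mean(p_i)
  p_j <- colSums(nij) / (n * k)
  p_e <- sum(p_j^2)
  if (p_e >= 1) {
    abort("Fleiss' kappa undefined: every rating is the same single category.")
  }
  kappa <- (p_bar - p_e) / (1 - p_e)

  new_agreement_report(
    statistic = "Fleiss kappa", estimate = kappa,
    band = interpret_band("kappa", kappa),
    components = c(p_bar = p_bar, p_e = p_e,
                   setNames(p_j, paste0("p_", categories))),
    n_images = n, n_raters = k
  )
}

icc_bands <- tibble(
  lower = c(-Inf, 0.5, 0.75, 0.9),
  band = c("Poor", "Moderate", "Good", "Excellent")
)

kappa_bands <- tibble(
  lower = c(0, 0.10, 0.21, 0.41, 0.61, 0.81, 1.00),
  band = c("Equivalent to chance", "Slight", "Fair", "Moderate",
           "Substantial", "Near perfect", "Perfect")
)

#' Interpretation band for an agreement statistic
#'
#' Looks up the conventional qualitative band for an ICC or kappa value
#' (ICC: < 0.5 Poor, 0.5-0.75 Moderate, 0.75-0.9 Good, 0.9-1 Excellent;
#' kappa: 0 Equivalent to chance, 0.10-0.20 Slight, 0.21-0.40 Fair,
#' 0.41-0.60 Moderate, 0.61-0.80 Substantial, 0.81-0.99 Near perfect,
#' 1 Perfect).  Shared boundary values go to the upper band.  A negative
#' kappa, below-chance agreement, is outside the conventional scale and is
#' reported as `"Below chance"`.
#'
#' @param statistic `"icc"` or `"kappa"` (the reports' statistic names also
#'   work).
#' @param value The point estimate.
#' @return A single band label.
#' @examples
#' interpret_band("icc", 0.8431)
#' interpret_band("kappa", 0.4916)
#' @export
interpret_band <- function(statistic, value) {
  stopifnot(length(value) == 1L, is.finite(value))
  stat <- if (grepl("icc", tolower(statistic))) "icc" else
    if (grepl("kappa", tolower(statistic))) "kappa" else
      abort(sprintf("Unknown statistic: %s", statistic))
  if (stat == "icc") {
    if (value > 1) abort("ICC cannot exceed 1.")
    icc_bands$band[max(which(value >= icc_bands$lower))]
  } else {
    if (value > 1) abort("Kappa cannot exceed 1.")
    if (value < 0) return("Below chance")
    kappa_bands$band[max(which(value >= kappa_bands$lower))]
  }
}

#' Write an agreement report to JSON with a one-line text summary
#'
#' @param report An `agreement_report`.
#' @param json_path Output JSON path (or `NULL`).
#' @return The summary line, invisibly.
#' @export
write_agreement <- function(report, json_path = NULL) {
  stopifnot(inherits(report, "agreement_report"))
  line <- sprintf("The %s was %.4f, indicating %s agreement among the observers.",
                  report$statistic, report$estimate, tolower(report$band))
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(statistic = report$statistic, estimate = report$estimate,
           band = report$band, components = as.list(report$components),
           n_images = report$n_images, n_raters = report$n_raters,
           summary = line),
      json_path, auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
  }
  invisible(line)
}
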