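# Simulated expert panels.  Each image carries a latent true severity class
# and a latent UCEIS total drawn inside that class's cutpoint band; each
# rater observes the latent total plus an integer error in {-2..+2} (zero
# with probability `p_agree`, symmetric tails), clipped to 0..8.  Severity
# labels are derived from the observed totals through the cutpoints, so
# category disagreement emerges naturally at band boundaries — which is why
# score-level agreement (ICC) exceeds category-level agreement (kappa) in
# this model, as it does for real expert panels.

#' Configuration for the simulated rater panel
#'
#' @param n_images Number of images in the panel.
#' @param class_prior Probabilities over the three severity classes
#'   (`remission_mild`, `moderate`, `severe`); the default is proportional
#'   to a 269:192:60 class mix.
#' @param n_raters Number of simulated experts (default 5).
#' @param p_agree Probability a rater observes the latent total exactly.
#'   The remaining mass is split symmetrically: each side gets 80% on the
#'   +/-1 error and 20% on the +/-2 error.
#' @param cutpoints [severity_cutpoints()] used both to place latent totals
#'   inside class bands and to derive severity labels from observed totals.
#' @param severity_scale `"four"` (remission/mild/moderate/severe, the scale
#'   on which kappa is usually reported) or `"three"` (merged
#'   remission_mild).
#' @return A `rater_sim_config` object.
#' @export
rater_sim_config <- function(n_images = 254L,
                             class_prior = c(269, 192, 60) / 521,
                             n_raters = 5L, p_agree = 0.8,
                             cutpoints = severity_cutpoints(),
                             severity_scale = c("four", "three")) {
  severity_scale <- match.arg(severity_scale)
  if (length(class_prior) != 3L || any(class_prior < 0)) {
    abort("`class_prior` must be 3 non-negative weights.")
  }
  class_prior <- class_prior / sum(class_prior)
  if (p_agree < 0 || p_agree > 1) abort("`p_agree` must lie in [0, 1].")
  if (n_raters < 2L) abort("Need at least 2 raters.")
  structure(
    list(n_images = as.integer(n_images), class_prior = class_prior,
         n_raters = as.integer(n_raters), p_agree = p_agree,
         cutpoints = cutpoints, severity_scale = severity_scale),
    class = "rater_sim_config"
  )
}

# integer error distribution on {-2..2}: P(0) = p_agree, tails 80/20 per side
rater_error_probs <- function(p_agree) {
  side <- (1 - p_agree) / 2
  c(`-2` = 0.2 * side, `-1` = 0.8 * side, `0` = p_agree,
    `1` = 0.8 * side, `2` = 0.2 * side)
}

# class band boundaries (inclusive) for the three-class scale
class_bands <- function(cutpoints) {
  list(
    remission_mild = c(0L, cutpoints[["mild_max"]]),
    moderate = c(cutpoints[["mild_max"]] + 1L, cutpoints[["moderate_max"]]),
    severe = c(cutpoints[["moderate_max"]] + 1L, 8L)
  )
}

#' Simulate a multi-expert UCEIS panel with tunable agreement
#'
#' Draws a latent class and latent total per image, then independent
#' per-rater observed totals under the error model described in
#' [rater_sim_config()], and derives severity labels from the observed
#' totals through the configured cutpoints.
#'
#' @param config A [rater_sim_config()].
#' @param seed Optional integer seed.
#' @return A list with elements `totals` (rater panel of observed UCEIS
#'   totals), `severities` (rater panel of derived severity labels) and
#'   `truth` (tibble of `image_id`, `class`, `total` — the latent truth).
#' @examples
#' sim <- simulate_panel(rater_sim_config(n_images = 20), seed = 1)
#' fleiss_kappa(sim$severities)
#' icc_two_way(sim$totals)
#' @export
simulate_panel <- function(config = rater_sim_config(), seed = NULL) {
  stopifnot(inherits(config, "rater_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_images
  k <- config$n_raters
  bands <- class_bands(config$cutpoints)

  classes <- sample(severity_levels3, n, replace = TRUE, prob = config$class_prior)
  latent <- vapply(classes, function(cl) {
    b <- bands[[cl]]
    sample(b[1]:b[2], 1L)
  }, integer(1), USE.NAMES = FALSE)

  probs <- rater_error_probs(config$p_agree)
  errors <- matrix(
    sample(-2:2, n * k, replace = TRUE, prob = probs), nrow = n, ncol = k
  )
  observed <- pmin(pmax(latent + errors, 0L), 8L)

  image_ids <- sprintf("img%04d", seq_len(n))
  rater_ids <- sprintf("rater%d", seq_len(k))
  totals <- tibble(
    image_id = rep(image_ids, times = k),
    rater_id = rep(rater_ids, each = n),
    label = as.integer(observed)
  )
  sev4 <- map_severity(totals$label, config$cutpoints)
  severities <- dplyr::mutate(
    totals,
    label = if (config$severity_scale == "four") as.character(sev4)
            else as.character(merge_severity3(sev4))
  )
  list(
    totals = totals,
    severities = severities,
    truth = tibble(image_id = image_ids,
                   class = factor(classes, levels = severity_levels3),
                   total = latent)
  )
}

#' Exact consensus-retention probability under the rater error model
#'
#' For a latent total, enumerates every joint outcome of the raters' error
#' draws (after clipping to 0..8) and sums the probability that some
#' observed value is shared by at least `threshold` raters.  This is the
#' closed-form counterpart of the retention rate that [consensus_vote()]
#' measures on simulated panels.
#'
#' @param latent_total Integer in 0..8 (vectorised).
#' @param n_raters,p_agree,threshold Error-model and voting parameters.
#' @return Numeric vector of retention probabilities.
#' @export
retention_probability <- function(latent_total, n_raters = 5L, p_agree = 0.8,
                                  threshold = 3L) {
  probs <- rater_error_probs(p_agree)
  vapply(latent_total, function(t) {
    vals <- pmin(pmax(t + (-2:2), 0L), 8L)
    support <- sort(unique(vals))
    q <- vapply(support, function(v) sum(probs[vals == v]), numeric(1))
    m <- length(support)
    outcomes <- as.matrix(expand.grid(rep(list(seq_len(m)), n_raters)))
    p_out <- apply(outcomes, 1L, function(o) prod(q[o]))
    modal <- apply(outcomes, 1L, function(o) max(tabulate(o, nbins = m)))
    sum(p_out[modal >= threshold])
  }, numeric(1))
}
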