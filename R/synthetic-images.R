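# Synthetic endoscopic-like frames with known ground truth.  Tissue is a
# smooth pink-red HSV field sampled strictly inside the valid artifact
# ranges; severity-dependent lesions (vessel curves, erosion blobs, ulcer
# regions) are drawn with colours that also stay inside the valid ranges;
# specular highlights (low S, high V) and unlit dark patches (low V) are
# injected strictly outside them.  By construction the ground-truth mask is
# exactly the set of out-of-range pixels, so threshold masking can be tested
# pixel-for-pixel, and the pre-injection clean frame is retained as the
# inpainting oracle.

#' Configuration for the synthetic frame generator
#'
#' Tissue HSV sampling boxes must sit strictly inside the valid `ranges`
#' (with a 5-unit margin for 8-bit quantisation), and the artifact
#' generators strictly outside, so recovered masks are exact.  Highlight and
#' dark-region counts are drawn uniformly from the given integer ranges.
#'
#' @param width,height Frame size in pixels (defaults mirror the 543 x 475
#'   clinical frames).
#' @param tissue_h,tissue_s,tissue_v Tissue sampling box: hue in degrees,
#'   saturation/value on 0..255.
#' @param n_highlights,highlight_radius Count range and radius range (px) of
#'   specular highlights.
#' @param highlight_s,highlight_v HSV box for highlight pixels (low
#'   saturation, high value).
#' @param n_dark,dark_radius,dark_v Count range, radius range and value box
#'   for unlit dark regions.
#' @param ranges The valid [hsv_ranges()] the frames are generated against.
#' @return An `image_gen_config` object.
#' @export
image_gen_config <- function(width = 543, height = 475,
                             tissue_h = c(5, 25),
                             tissue_s = c(110, 190),
                             tissue_v = c(125, 205),
                             n_highlights = c(3, 8),
                             highlight_radius = c(3, 10),
                             highlight_s = c(0, 60),
                             highlight_v = c(240, 255),
                             n_dark = c(1, 3),
                             dark_radius = c(8, 20),
                             dark_v = c(0, 40),
                             ranges = hsv_ranges()) {
  stopifnot(inherits(ranges, "hsv_ranges"))
  margin <- 5
  if (tissue_s[1] < ranges$s[1] + margin || tissue_s[2] > ranges$s[2]) {
    abort("Tissue saturation box must sit strictly inside the valid S range.")
  }
  if (tissue_v[1] < ranges$v[1] + margin || tissue_v[2] > ranges$v[2] - margin) {
    abort("Tissue value box must sit strictly inside the valid V range.")
  }
  if (highlight_s[2] > ranges$s[1] - margin) {
    abort("Highlight saturation must lie strictly below the valid S range.")
  }
  if (dark_v[2] > ranges$v[1] - margin) {
    abort("Dark-region value must lie strictly below the valid V range.")
  }
  structure(
    list(width = as.integer(width), height = as.integer(height),
         tissue_h = tissue_h, tissue_s = tissue_s, tissue_v = tissue_v,
         n_highlights = as.integer(n_highlights),
         highlight_radius = highlight_radius,
         highlight_s = highlight_s, highlight_v = highlight_v,
         n_dark = as.integer(n_dark), dark_radius = dark_radius,
         dark_v = dark_v, ranges = ranges),
    class = "image_gen_config"
  )
}

# bilinear upsampling of a coarse grid to (h, w) — smooth tissue field
upsample_grid <- function(g, h, w) {
  gh <- nrow(g); gw <- ncol(g)
  ys <- seq(0, gh - 1, length.out = h)
  xs <- seq(0, gw - 1, length.out = w)
  y0 <- pmin(floor(ys), gh - 2); x0 <- pmin(floor(xs), gw - 2)
  fy <- ys - y0; fx <- xs - x0
  a <- g[cbind(rep(y0 + 1, times = w), rep(x0 + 1, each = h))]
  b <- g[cbind(rep(y0 + 1, times = w), rep(x0 + 2, each = h))]
  cc <- g[cbind(rep(y0 + 2, times = w), rep(x0 + 1, each = h))]
  d <- g[cbind(rep(y0 + 2, times = w), rep(x0 + 2, each = h))]
  wfx <- rep(fx, each = h); wfy <- rep(fy, times = w)
  matrix(a * (1 - wfx) * (1 - wfy) + b * wfx * (1 - wfy) +
           cc * (1 - wfx) * wfy + d * wfx * wfy, nrow = h, ncol = w)
}

disc_mask <- function(h, w, cx, cy, r, irregular = FALSE) {
  x <- matrix(rep(seq_len(w), each = h), h, w)
  y <- matrix(rep(seq_len(h), times = w), h, w)
  dx <- x - cx; dy <- y - cy
  if (!irregular) return(dx^2 + dy^2 <= r^2)
  theta <- atan2(dy, dx)
  a1 <- runif(1, 0.05, 0.25); a2 <- runif(1, 0.05, 0.2)
  p1 <- runif(1, 0, 2 * pi); p2 <- runif(1, 0, 2 * pi)
  rr <- r * (1 + a1 * sin(2 * theta + p1) + a2 * sin(3 * theta + p2))
  dx^2 + dy^2 <= rr^2
}

vessel_mask <- function(h, w, n_curves = 3L, steps = 250L) {
  m <- matrix(FALSE, h, w)
  for (i in seq_len(n_curves)) {
    x <- runif(1, 5, w - 5); y <- runif(1, 5, h - 5)
    dir <- runif(1, 0, 2 * pi)
    for (s in seq_len(steps)) {
      dir <- dir + rnorm(1, 0, 0.25)
      x <- x + cos(dir); y <- y + sin(dir)
      if (x < 2 || x > w - 1 || y < 2 || y > h - 1) break
      xi <- round(x); yi <- round(y)
      m[yi + (-1:1), xi + (-1:0)] <- TRUE
    }
  }
  m
}

runif_int <- function(range) {
  if (range[1] >= range[2]) return(as.integer(range[1]))
  sample(range[1]:range[2], 1L)
}

# paint lesion HSV values for one class onto the tissue field (in place)
paint_lesions <- function(H, S, V, class, h, w) {
  lesion <- switch(
    as.character(class),
    remission_mild = {
      m <- vessel_mask(h, w, n_curves = sample(2:4, 1))
      list(mask = m, h = runif(1, 0, 10), s = runif(1, 200, 235),
           v = runif(1, 110, 140))
    },
    moderate = {
      m <- matrix(FALSE, h, w)
      for (i in seq_len(sample(10:18, 1))) {
        m <- m | disc_mask(h, w, runif(1, 1, w), runif(1, 1, h),
                           runif(1, 0.03, 0.07) * min(h, w))
      }
      list(mask = m, h = runif(1, 0, 6), s = runif(1, 215, 245),
           v = runif(1, 205, 230))
    },
    severe = {
      m <- matrix(FALSE, h, w)
      for (i in seq_len(sample(2:4, 1))) {
        m <- m | disc_mask(h, w, runif(1, w * 0.2, w * 0.8),
                           runif(1, h * 0.2, h * 0.8),
                           runif(1, min(h, w) * 0.15, min(h, w) * 0.28),
                           irregular = TRUE)
      }
      list(mask = m, h = runif(1, 0, 8), s = runif(1, 210, 245),
           v = runif(1, 75, 105))
    },
    abort(sprintf("Unknown synthetic class: %s", class))
  )
  m <- lesion$mask
  H[m] <- lesion$h; S[m] <- lesion$s; V[m] <- lesion$v
  list(H = H, S = S, V = V)
}

generate_one_frame <- function(config, class) {
  h <- config$height; w <- config$width
  field <- function(box) {
    g <- matrix(runif(36, box[1], box[2]), 6, 6)
    f <- upsample_grid(g, h, w) + rnorm(h * w, 0, 1.5)
    pmin(pmax(f, box[1]), box[2])
  }
  H <- field(config$tissue_h)
  S <- field(config$tissue_s)
  V <- field(config$tissue_v)
  les <- paint_lesions(H, S, V, class, h, w)
  H <- les$H; S <- les$S; V <- les$V
  clean <- hsv255_to_rgb(H, S, V, dim = c(h, w))

  gt <- matrix(0L, h, w)
  for (i in seq_len(runif_int(config$n_highlights))) {
    m <- disc_mask(h, w, runif(1, 1, w), runif(1, 1, h),
                   runif(1, config$highlight_radius[1], config$highlight_radius[2]))
    S[m] <- runif(1, config$highlight_s[1], config$highlight_s[2])
    V[m] <- runif(1, max(config$highlight_v[1], 245), config$highlight_v[2])
    gt[m] <- 1L
  }
  for (i in seq_len(runif_int(config$n_dark))) {
    m <- disc_mask(h, w, runif(1, 1, w), runif(1, 1, h),
                   runif(1, config$dark_radius[1], config$dark_radius[2]),
                   irregular = TRUE)
    V[m] <- runif(1, config$dark_v[1], config$dark_v[2])
    gt[m] <- 1L
  }
  corrupted <- clean
  if (any(gt == 1L)) {
    art <- hsv255_to_rgb(H, S, V, dim = c(h, w))
    idx <- which(gt == 1L)
    for (c in 1:3) {
      ch <- corrupted[, , c]; ch[idx] <- art[, , c][idx]
      corrupted[, , c] <- ch
    }
  }
  list(clean = clean, corrupted = corrupted,
       mask = new_artifact_mask(gt, config$ranges))
}

#' Generate synthetic endoscopic frames with ground truth
#'
#' Produces, for each requested severity class, a clean frame, the same
#' frame corrupted with specular highlights and dark regions, and the exact
#' ground-truth artifact mask.  The corrupted frame equals the clean frame
#' outside the mask.
#'
#' @param config An [image_gen_config()].
#' @param labels Character/factor vector of three-class severity labels
#'   (`remission_mild`, `moderate`, `severe`), one frame per element.
#' @param seed Optional integer seed for reproducible generation.
#' @return A tibble with columns `image_id`, `label` and list-columns
#'   `clean`, `corrupted`, `mask`.
#' @examples
#' frames <- generate_images(image_gen_config(width = 64, height = 64),
#'                           labels = c("remission_mild", "severe"), seed = 1)
#' frames
#' @export
generate_images <- function(config = image_gen_config(), labels, seed = NULL) {
  stopifnot(inherits(config, "image_gen_config"))
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), severity_levels3)
  if (length(bad)) abort(sprintf("Unknown class label: %s", bad[1]))
  if (!is.null(seed)) set.seed(seed)
  frames <- purrr::map(labels, function(cl) generate_one_frame(config, cl))
  tibble(
    image_id = sprintf("img%04d", seq_along(labels)),
    label = factor(labels, levels = severity_levels3),
    clean = purrr::map(frames, "clean"),
    corrupted = purrr::map(frames, "corrupted"),
    mask = purrr::map(frames, "mask")
  )
}

#' Write synthetic frames to a directory
#'
#' Writes `<id>.png` (corrupted frame), `<id>_clean.png` and
#' `<id>_mask.png` per sample, plus `labels.csv`.
#'
#' @param samples Output of [generate_images()].
#' @param out_dir Destination directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_images <- function(samples, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  purrr::pwalk(samples, function(image_id, label, clean, corrupted, mask) {
    write_rgb(corrupted, file.path(out_dir, paste0(image_id, ".png")))
    write_rgb(clean, file.path(out_dir, paste0(image_id, "_clean.png")))
    png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)),
                  file.path(out_dir, paste0(image_id, "_mask.png")))
  })
  readr::write_csv(dplyr::select(samples, "image_id", "label"),
                   file.path(out_dir, "labels.csv"))
  invisible(out_dir)
}
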