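# Artifact detection in endoscopic frames.  Specular reflections from the
# light source are bright and desaturated (low S, high V); unlit regions are
# dark (low V).  Pixels whose HSV coordinates fall inside the configured
# valid ranges are tissue; the artifact mask is the complement.  An RGB
# per-channel threshold baseline is kept for comparison: it cannot separate
# highlights from bright-red ulcer and erosion tissue.

#' Valid-pixel HSV ranges for artifact detection
#'
#' The ranges define VALID tissue pixels; everything outside any range is an
#' artifact.  Defaults: hue `(0, 360)` (unconstrained), saturation
#' `(90, 255)` and value `(65, 236)` on the 8-bit scale, which flag
#' desaturated highlights (S < 90), blown-out highlights (V > 236) and
#' unlit regions (V < 65).  Endpoints are inclusive.
#'
#' @param h Length-2 numeric, hue range in degrees within `[0, 360]`.
#' @param s,v Length-2 numeric, saturation / value ranges within `[0, 255]`.
#' @return An `hsv_ranges` object.
#' @examples
#' hsv_ranges()
#' @export
hsv_ranges <- function(h = c(0, 360), s = c(90, 255), v = c(65, 236)) {
  chk <- function(r, name, hi) {
    if (length(r) != 2L || anyNA(r) || r[1] > r[2] || r[1] < 0 || r[2] > hi) {
      abort(sprintf("`%s` must be (lo, hi) with 0 <= lo <= hi <= %d.", name, hi))
    }
    as.numeric(r)
  }
  structure(
    list(h = chk(h, "h", 360), s = chk(s, "s", 255), v = chk(v, "v", 255)),
    class = "hsv_ranges"
  )
}

#' @export
print.hsv_ranges <- function(x, ...) {
  cat(sprintf("Valid HSV ranges: H (%g, %g) deg, S (%g, %g), V (%g, %g)\n",
              x$h[1], x$h[2], x$s[1], x$s[2], x$v[1], x$v[2]))
  invisible(x)
}

new_artifact_mask <- function(mask, provenance) {
  storage.mode(mask) <- "integer"
  structure(mask, class = c("artifact_mask", "matrix", "array"),
            provenance = provenance)
}

#' @export
print.artifact_mask <- function(x, ...) {
  cat(sprintf("Artifact mask %d x %d: %d artifact pixels (%.1f%%)\n",
              nrow(x), ncol(x), sum(x), 100 * mean(x)))
  invisible(x)
}

#' Detect reflection and dark-region artifacts via HSV thresholds
#'
#' Converts the frame to HSV and marks every pixel whose hue, saturation or
#' value falls outside the valid ranges.  With the default ranges the mask
#' captures specular reflections (low saturation and/or very high value) and
#' unlit dark regions (low value), while red lesion tissue — saturated and of
#' moderate value — stays valid.
#'
#' @param image Numeric array `height x width x 3`, 8-bit RGB.
#' @param ranges An [hsv_ranges()] object.
#' @return An `artifact_mask`: integer matrix, 1 = artifact, 0 = valid, with
#'   the generating ranges attached as the `provenance` attribute.
#' @export
hsv_artifact_mask <- function(image, ranges = hsv_ranges()) {
  check_rgb_image(image)
  stopifnot(inherits(ranges, "hsv_ranges"))
  hsv <- rgb_to_hsv255(image)
  valid <- hsv[, , 1] >= ranges$h[1] & hsv[, , 1] <= ranges$h[2] &
    hsv[, , 2] >= ranges$s[1] & hsv[, , 2] <= ranges$s[2] &
    hsv[, , 3] >= ranges$v[1] & hsv[, , 3] <= ranges$v[2]
  new_artifact_mask(!valid, ranges)
}

#' RGB per-channel threshold baseline for reflection detection
#'
#' Marks pixels with any channel outside its valid range (defaults
#' `(0, 210)` for each of R, G and B, so the mask is pixels with R, G or B
#' above 210).  This baseline catches white highlights but also flags
#' bright-red ulcer and erosion tissue whose red channel is high — the
#' failure mode that motivates the HSV detector.
#'
#' @param image Numeric array `height x width x 3`, 8-bit RGB.
#' @param r,g,b Length-2 valid ranges per channel on 0..255.
#' @return An `artifact_mask` (provenance records the channel ranges).
#' @export
rgb_artifact_mask <- function(image, r = c(0, 210), g = c(0, 210),
                              b = c(0, 210)) {
  check_rgb_image(image)
  rngs <- list(r = r, g = g, b = b)
  for (nm in names(rngs)) {
    rr <- rngs[[nm]]
    if (length(rr) != 2L || rr[1] > rr[2]) abort(sprintf("Bad `%s` range.", nm))
  }
  valid <- image[, , 1] >= r[1] & image[, , 1] <= r[2] &
    image[, , 2] >= g[1] & image[, , 2] <= g[2] &
    image[, , 3] >= b[1] & image[, , 3] <= b[2]
  new_artifact_mask(!valid, rngs)
}
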