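# Training-time augmentation: a single composed affine (rotation, zoom,
# shear, shifts, optional horizontal flip) applied by inverse mapping with
# bilinear interpolation, so the image is resampled exactly once.  Pixels
# mapped from outside the frame are filled by the configured border mode
# (default "reflect", mirror-symmetric).  Augmentation changes geometry
# only, never the severity label attached to a sample.

#' Augmentation recipe configuration
#'
#' Defaults follow a conventional endoscopy training recipe: full-circle
#' rotation, 15% zoom, 20% shifts in both directions, 15% shear, horizontal
#' flipping, and mirror ("reflect") border filling.  Parameters are drawn
#' uniformly per call: rotation angle from `[-rotation_range,
#' +rotation_range]` degrees, scale from `[1 - zoom_range, 1 + zoom_range]`,
#' shear factor from `[-shear_range, +shear_range]`, shifts from
#' `[-width_shift, +width_shift]` (resp. height) times the image dimension,
#' and a fair coin for the flip when enabled.
#'
#' @param rotation_range Degrees, in `[0, 360]`.
#' @param zoom_range,width_shift,height_shift,shear_range Fractions in
#'   `[0, 1)`.
#' @param horizontal_flip Logical.
#' @param fill_mode `"reflect"`, `"nearest"` or `"constant"`.
#' @param fill_value Constant used when `fill_mode = "constant"`.
#' @return An `augment_config` object.
#' @examples
#' augment_config()
#' augment_config(rotation_range = 0, zoom_range = 0, width_shift = 0,
#'                height_shift = 0, shear_range = 0, horizontal_flip = FALSE)
#' @export
augment_config <- function(rotation_range = 360, zoom_range = 0.15,
                           width_shift = 0.20, height_shift = 0.20,
                           shear_range = 0.15, horizontal_flip = TRUE,
                           fill_mode = c("reflect", "nearest", "constant"),
                           fill_value = 0) {
  fill_mode <- match.arg(fill_mode)
  fr <- c(zoom = zoom_range, width_shift = width_shift,
          height_shift = height_shift, shear = shear_range)
  if (any(fr < 0) || any(fr >= 1)) abort("Fractional ranges must lie in [0, 1).")
  if (rotation_range < 0 || rotation_range > 360) {
    abort("`rotation_range` must lie in [0, 360].")
  }
  structure(
    list(rotation_range = rotation_range, zoom_range = zoom_range,
         width_shift = width_shift, height_shift = height_shift,
         shear_range = shear_range, horizontal_flip = isTRUE(horizontal_flip),
         fill_mode = fill_mode, fill_value = fill_value),
    class = "augment_config"
  )
}

# mirror-symmetric coordinate folding onto [-0.5, n - 0.5)
reflect_coord <- function(t, n) {
  p <- (t + 0.5) %% (2 * n)
  p <- ifelse(p < 0, p + 2 * n, p)
  p <- ifelse(p >= n, 2 * n - p, p)
  pmin(p, n - 1e-9) - 0.5
}

bilinear_sample <- function(ch, xs, ys, fill_mode, fill_value) {
  h <- nrow(ch); w <- ncol(ch)
  oob <- xs < -0.5 | xs > w - 0.5 | ys < -0.5 | ys > h - 0.5
  if (fill_mode == "reflect") {
    xs <- reflect_coord(xs, w)
    ys <- reflect_coord(ys, h)
  } else {
    xs <- pmin(pmax(xs, 0), w - 1)
    ys <- pmin(pmax(ys, 0), h - 1)
  }
  x0 <- pmin(pmax(floor(xs), 0), w - 1)
  y0 <- pmin(pmax(floor(ys), 0), h - 1)
  x1 <- pmin(x0 + 1, w - 1)
  y1 <- pmin(y0 + 1, h - 1)
  fx <- xs - x0
  fy <- ys - y0
  v <- ch[cbind(y0 + 1, x0 + 1)] * (1 - fx) * (1 - fy) +
    ch[cbind(y0 + 1, x1 + 1)] * fx * (1 - fy) +
    ch[cbind(y1 + 1, x0 + 1)] * (1 - fx) * fy +
    ch[cbind(y1 + 1, x1 + 1)] * fx * fy
  if (fill_mode == "constant") v[oob] <- fill_value
  v
}

#' Apply one random draw of the augmentation recipe to an image
#'
#' Draws rotation, zoom, shear, shifts and the flip from the ranges in
#' `config` using R's random number stream (seed the session, or pass
#' `seed`, for reproducibility), composes them into a single affine about
#' the image centre, and resamples bilinearly.  Output dimensions and the
#' 0..255 value range always match the input.
#'
#' @param image Numeric array `height x width x 3` (or a matrix), 0..255.
#' @param config An [augment_config()].
#' @param seed Optional integer; if given, the draw is made under this seed
#'   and the caller's random stream is left untouched.
#' @return An array of the same dimensions and scale.
#' @export
augment_image <- function(image, config = augment_config(), seed = NULL) {
  stopifnot(inherits(config, "augment_config"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  is_mat <- is.matrix(image)
  if (is_mat) image <- array(image, dim = c(dim(image), 1))
  d <- dim(image)
  h <- d[1]; w <- d[2]

  theta <- runif(1, -config$rotation_range, config$rotation_range) * pi / 180
  scale <- runif(1, 1 - config$zoom_range, 1 + config$zoom_range)
  shear <- runif(1, -config$shear_range, config$shear_range)
  tx <- runif(1, -config$width_shift, config$width_shift) * w
  ty <- runif(1, -config$height_shift, config$height_shift) * h
  flip <- config$horizontal_flip && runif(1) < 0.5

  # forward map about the centre: flip, shear, zoom, rotate, then shift
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  shr <- matrix(c(1, 0, shear, 1), 2, 2)
  flp <- diag(c(if (flip) -1 else 1, 1))
  a <- rot %*% (scale * shr) %*% flp
  cx <- (w - 1) / 2; cy <- (h - 1) / 2

  grid <- expand.grid(x = 0:(w - 1), y = 0:(h - 1))
  # inverse mapping: source = A^{-1} ((out - centre - shift)) + centre
  ainv <- solve(a)
  dx <- grid$x - cx - tx
  dy <- grid$y - cy - ty
  xs <- ainv[1, 1] * dx + ainv[1, 2] * dy + cx
  ys <- ainv[2, 1] * dx + ainv[2, 2] * dy + cy

  out <- array(0, dim = d)
  for (c in seq_len(d[3])) {
    v <- bilinear_sample(image[, , c], xs, ys, config$fill_mode, config$fill_value)
    out[, , c] <- matrix(pmin(pmax(v, 0), 255), nrow = h, ncol = w, byrow = TRUE)
  }
  if (is_mat) out <- out[, , 1]
  out
}
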