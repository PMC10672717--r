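# Colour-space helpers.  Images are numeric arrays height x width x 3 on the
# 8-bit 0..255 scale.  Hue is handled in degrees [0, 360); saturation and
# value are rescaled to 0..255 so thresholds can be stated in 8-bit units.

check_rgb_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L) {
    abort("Expected a 3-channel RGB array (height x width x 3).")
  }
  if (anyNA(image) || min(image) < 0 || max(image) > 255) {
    abort("RGB values must lie in 0..255.")
  }
  invisible(image)
}

#' Convert an 8-bit RGB image to HSV
#'
#' Standard hexcone conversion with hue in degrees `[0, 360)` and saturation
#' and value rescaled to `0..255` (the scale on which masking thresholds are
#' stated).
#'
#' @param image Numeric array `height x width x 3` with values in 0..255.
#' @return Numeric array `height x width x 3`: hue, saturation, value.
#' @export
rgb_to_hsv255 <- function(image) {
  check_rgb_image(image)
  d <- dim(image)
  rgb <- rbind(
    as.vector(image[, , 1]), as.vector(image[, , 2]), as.vector(image[, , 3])
  )
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  out <- array(0, dim = d)
  out[, , 1] <- (hsv[1, ] * 360) %% 360
  out[, , 2] <- hsv[2, ] * 255
  out[, , 3] <- hsv[3, ] * 255
  out
}

#' Convert HSV (degrees / 0-255 / 0-255) to an 8-bit RGB image
#'
#' Inverse hexcone transform; output channels are rounded to integers on
#' 0..255.
#'
#' @param h,s,v Numeric arrays or vectors of equal length: hue in degrees,
#'   saturation and value in 0..255.
#' @param dim Output dimensions `c(height, width)`; defaults to `dim(h)`.
#' @return Numeric array `height x width x 3` of 8-bit RGB values.
#' @export
hsv255_to_rgb <- function(h, s, v, dim = NULL) {
  dim <- dim %||% base::dim(h)
  if (is.null(dim)) abort("`dim` needed when inputs are plain vectors.")
  h <- (as.vector(h) %% 360) / 60
  s <- as.vector(s) / 255
  v <- as.vector(v) / 255
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  out <- array(0, dim = c(dim[1], dim[2], 3))
  out[, , 1] <- round(r * 255)
  out[, , 2] <- round(g * 255)
  out[, , 3] <- round(b * 255)
  out
}

#' Read or write an 8-bit RGB PNG
#'
#' Thin wrappers over the png package that put images on the package's
#' 0..255 array convention (alpha channels are dropped on read).
#'
#' @param path File path.
#' @return `read_rgb()` returns a `height x width x 3` array on 0..255.
#' @export
read_rgb <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}

#' @rdname read_rgb
#' @param image Array on 0..255 (RGB) or a binary matrix (mask).
#' @export
write_rgb <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}
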