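# Hole filling.  The default backend is iterative diffusion: masked pixels
# are repeatedly replaced by the mean of their 4-neighbours (valid pixels
# held fixed) until the largest update falls below a tolerance — a Jacobi
# solve of the Laplace equation on the hole with the surrounding tissue as
# boundary.  By the maximum principle every filled value lies within the
# range of the surrounding valid pixels.  A nearest-valid-pixel backend is
# available as a fast alternative.

shift_up <- function(m) m[c(1L, seq_len(nrow(m) - 1L)), , drop = FALSE]
shift_down <- function(m) m[c(seq_len(nrow(m))[-1L], nrow(m)), , drop = FALSE]
shift_left <- function(m) m[, c(1L, seq_len(ncol(m) - 1L)), drop = FALSE]
shift_right <- function(m) m[, c(seq_len(ncol(m))[-1L], ncol(m)), drop = FALSE]

diffuse_channel <- function(ch, mask, tol, max_iter) {
  idx <- which(mask == 1L)
  ch[idx] <- mean(ch[-idx])
  for (iter in seq_len(max_iter)) {
    avg <- (shift_up(ch) + shift_down(ch) + shift_left(ch) + shift_right(ch)) / 4
    delta <- max(abs(avg[idx] - ch[idx]))
    ch[idx] <- avg[idx]
    if (delta < tol) break
  }
  ch
}

nearest_fill_channel <- function(ch, mask) {
  filled <- mask == 0L
  while (!all(filled)) {
    for (sh in list(shift_up, shift_down, shift_left, shift_right)) {
      src_val <- sh(ch)
      src_ok <- sh(filled)
      take <- !filled & src_ok
      if (any(take)) {
        ch[take] <- src_val[take]
        filled[take] <- TRUE
      }
    }
  }
  ch
}

#' Remove masked artifact pixels and fill them from surrounding tissue
#'
#' Masked pixels are zeroed out and refilled from their valid neighbourhood.
#' Unmasked pixels are returned bit-identical to the input.  `"diffusion"`
#' (default) solves a Laplace fill over each hole (neighbour averaging to a
#' convergence tolerance of `tol` intensity units, at most `max_iter`
#' sweeps); `"nearest"` copies the nearest valid pixel.  A frame more than
#' half covered by artifacts is refused rather than invented.
#'
#' @param image Numeric array `height x width x 3`, 8-bit RGB.
#' @param mask An [hsv_artifact_mask()]/[rgb_artifact_mask()] result or any
#'   binary matrix of matching size (1 = fill this pixel).
#' @param method `"diffusion"` or `"nearest"`.
#' @param tol,max_iter Diffusion stopping rule: stop when the largest update
#'   is below `tol` (intensity units on 0..255) or after `max_iter` sweeps.
#' @return An 8-bit RGB array of the same dimensions, rounded to integers on
#'   the filled pixels only.
#' @examples
#' img <- array(120, dim = c(8, 8, 3))
#' mask <- matrix(0L, 8, 8); mask[4:5, 4:5] <- 1L
#' filled <- apply_mask_and_inpaint(img, mask)
#' all(filled == 120)
#' @export
apply_mask_and_inpaint <- function(image, mask,
                                   method = c("diffusion", "nearest"),
                                   tol = 0.1, max_iter = 500L) {
  method <- match.arg(method)
  check_rgb_image(image)
  mask <- unclass(mask)
  if (!is.matrix(mask) || !all(dim(mask) == dim(image)[1:2])) {
    abort("`mask` must be a binary matrix matching the image dimensions.")
  }
  if (!all(mask %in% c(0L, 1L))) abort("`mask` must be strictly binary.")
  frac <- mean(mask)
  if (frac >= 0.5) {
    abort(sprintf(
      "Refusing to inpaint: %.0f%% of the frame is masked (>= 50%%); the fill would be dominated by invented data.",
      100 * frac
    ))
  }
  if (frac == 0) return(image)

  out <- image
  for (c in 1:3) {
    ch <- image[, , c]
    ch <- switch(method,
      diffusion = diffuse_channel(ch, mask, tol, max_iter),
      nearest = nearest_fill_channel(ch, mask)
    )
    idx <- which(mask == 1L)
    filled <- out[, , c]
    filled[idx] <- pmin(pmax(round(ch[idx]), 0), 255)
    out[, , c] <- filled
  }
  out
}

#' Clean a directory of endoscopic frames
#'
#' Reads every PNG in `in_dir`, masks artifacts with the given HSV ranges,
#' inpaints, and writes cleaned PNGs (and optionally the 1-bit masks) to
#' `out_dir`.
#'
#' @param in_dir,out_dir Input and output directories.
#' @param ranges An [hsv_ranges()] object.
#' @param method Inpainting backend, see [apply_mask_and_inpaint()].
#' @param save_masks Also write each mask as `<name>_mask.png`.
#' @return A tibble with one row per frame: `file`, `n_artifact_pixels`,
#'   `artifact_fraction`.
#' @export
clean_frames <- function(in_dir, out_dir, ranges = hsv_ranges(),
                         method = "diffusion", save_masks = FALSE) {
  files <- list.files(in_dir, pattern = "\\.png$", full.names = TRUE)
  if (!length(files)) abort(sprintf("No PNG files found in %s", in_dir))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  purrr::map_dfr(files, function(f) {
    img <- read_rgb(f)
    mask <- hsv_artifact_mask(img, ranges)
    cleaned <- apply_mask_and_inpaint(img, mask, method = method)
    write_rgb(cleaned, file.path(out_dir, basename(f)))
    if (save_masks) {
      png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)),
                    file.path(out_dir, sub("\\.png$", "_mask.png", basename(f))))
    }
    tibble(file = basename(f), n_artifact_pixels = sum(mask),
           artifact_fraction = mean(mask))
  })
}
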