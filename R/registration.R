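#' Estimate the translation between two images by Fourier phase correlation
#'
#' Sequentially acquired imaging rounds (e.g. RNA-FISH then DNA-FISH of the
#' same fields) drift by a few pixels; the translation is recovered from the
#' nuclear-stain images of each round. The normalized cross-power spectrum
#' \eqn{\overline{F(a)} F(b) / |\overline{F(a)} F(b)|} is inverse-transformed
#' and the argmax of the resulting correlation surface gives the integer
#' pixel shift that maps `image_a` onto `image_b`. Shifts above half the
#' axis length wrap to negative values, i.e. are reported in (-N/2, N/2].
#'
#' Only a whole-pixel translation is estimated (no rotation, scaling or
#' subpixel refinement); an optional Hann window (default off) can suppress
#' edge effects on non-periodic images.
#'
#' @param image_a,image_b numeric matrices of identical dimensions,
#'   non-constant.
#' @param field_id optional label carried into the result.
#' @param window apply a Hann window before the transform.
#' @return object of class `"registration_result"`: list with `shift`
#'   (`c(dx, dy)`, dx along columns/x and dy along rows/y), `peak_value`
#'   (normalized correlation peak in \[0, 1\]) and `field_id`.
#' @export
phase_correlation <- function(image_a, image_b, field_id = NA_character_,
                              window = FALSE) {
  stopifnot(is.matrix(image_a), is.matrix(image_b))
  if (!all(dim(image_a) == dim(image_b))) {
    stop("images must have identical dimensions", call. = FALSE)
  }
  if (sd(image_a) == 0 || sd(image_b) == 0) {
    stop("constant image: phase correlation is undefined", call. = FALSE)
  }
  if (window) {
    hr <- hann(nrow(image_a)); hc <- hann(ncol(image_a))
    w <- outer(hr, hc)
    image_a <- image_a * w
    image_b <- image_b * w
  }
  fa <- stats::fft(image_a)
  fb <- stats::fft(image_b)
  cross <- Conj(fa) * fb
  mag <- Mod(cross)
  cross <- cross / pmax(mag, .Machine$double.eps)
  corr <- Re(stats::fft(cross, inverse = TRUE)) / length(cross)
  i <- which.max(corr)
  nr <- nrow(corr); nc <- ncol(corr)
  dy <- (i - 1L) %% nr        # 0-based row offset
  dx <- (i - 1L) %/% nr       # 0-based column offset
  if (dy > nr / 2) dy <- dy - nr
  if (dx > nc / 2) dx <- dx - nc
  structure(list(shift = c(dx = as.integer(dx), dy = as.integer(dy)),
                 peak_value = min(max(corr[i], 0), 1),
                 field_id = field_id),
            class = "registration_result")
}

hann <- function(n) 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / n))

#' Apply a field translation to spot coordinates
#'
#' Propagates the per-field pixel shift estimated by [phase_correlation()]
#' to spot centroids, converting pixels to micrometres. All non-coordinate
#' columns are untouched.
#'
#' @param spots data.frame with `x_um` and `y_um` columns.
#' @param result a `registration_result`.
#' @param pixel_size_um micrometres per pixel (0.108 by default, the
#'   acquisition pixel size).
#' @return `spots` with translated coordinates.
#' @export
apply_translation <- function(spots, result, pixel_size_um = 0.108) {
  stopifnot(inherits(result, "registration_result"))
  check_cols(spots, c("x_um", "y_um"), "spots")
  check_pos(pixel_size_um, "pixel_size_um")
  spots$x_um <- spots$x_um + result$shift[["dx"]] * pixel_size_um
  spots$y_um <- spots$y_um + result$shift[["dy"]] * pixel_size_um
  spots
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("field %s: shift (dx = %d, dy = %d) px, peak %.3f\n",
              x$field_id, x$shift[["dx"]], x$shift[["dy"]], x$peak_value))
  invisible(x)
}
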