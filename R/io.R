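# Image I/O thin wrappers. Core operations take plain matrices; these
# helpers exist so TIFF stacks from the microscope can be fed in directly.

#' Read a single-channel TIFF image as a numeric matrix
#'
#' @param path file path.
#' @return numeric matrix (first channel if multi-channel).
#' @export
read_image_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("package 'tiff' is required to read TIFF files", call. = FALSE)
  }
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}

#' Write a numeric matrix as a 16-bit single-channel TIFF
#'
#' Intensities are rescaled to the 16-bit range by `max(image)`.
#'
#' @param image numeric matrix with non-negative values.
#' @param path destination path.
#' @export
write_image_tiff <- function(image, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("package 'tiff' is required to write TIFF files", call. = FALSE)
  }
  stopifnot(is.matrix(image), all(image >= 0))
  mx <- max(image)
  if (mx > 0) image <- image / mx
  tiff::writeTIFF(image, path, bits.per.sample = 16L)
  invisible(path)
}
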