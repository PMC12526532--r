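# Image input/output. Internally images are base-R arrays of dim
# (H, W, C) with values in [0, 1]; 8-bit files are converted at the
# boundary by EBImage.

#' Read an RGB image
#'
#' @param path PNG or JPEG file.
#' @return array (H, W, 3) with values in \[0, 1\].
#' @export
read_image <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3L] > 3L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  aperm(a, c(2L, 1L, 3L))
}

#' Write an RGB image
#'
#' @param image array (H, W, 3) in \[0, 1\].
#' @param path output PNG or JPEG file (decided by extension).
#' @export
write_image <- function(image, path) {
  stopifnot(length(dim(image)) == 3L)
  img <- EBImage::Image(aperm(pmin(pmax(image, 0), 1), c(2L, 1L, 3L)),
                        colormode = "Color")
  EBImage::writeImage(img, path)
  invisible(path)
}

check_image <- function(image, name = "image") {
  d <- dim(image)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop(sprintf("%s must be a (H, W) or (H, W, C) array", name),
         call. = FALSE)
  if (anyNA(image) || any(!is.finite(image)))
    stop(sprintf("%s contains non-finite values", name), call. = FALSE)
  if (min(image) < -1e-8 || max(image) > 1 + 1e-8)
    stop(sprintf("%s values must lie in [0, 1]", name), call. = FALSE)
  invisible(TRUE)
}

# BT.601 luma
luma <- function(image) {
  if (length(dim(image)) == 2L) return(image)
  0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L]
}
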