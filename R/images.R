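#' Image containers and file I/O
#'
#' Images are plain numeric matrices in row-major anatomical orientation:
#' `img[i, j]` is the pixel in row `i` (top to bottom) and column `j`
#' (left to right), with intensities in `[0, 1]`. RGB images are
#' `height x width x 3` arrays. Binary masks are logical matrices of the
#' same geometry, `TRUE` = foreground. 8-bit quantization happens only at
#' file I/O.
#'
#' @name image-containers
NULL

MIN_IMAGE_DIM <- 8L

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Validate a grayscale image
#'
#' Checks that `img` is a numeric matrix with values in `[0, 1]` and both
#' dimensions at least 8 pixels.
#'
#' @param img numeric matrix, intensities in `[0, 1]`.
#' @param min_dim minimum number of rows and columns accepted.
#' @return `img`, invisibly, after validation.
#' @export
validate_gray <- function(img, min_dim = MIN_IMAGE_DIM) {
  if (!is.matrix(img) || !is.numeric(img)) {
    abort("`img` must be a numeric matrix (rows x cols).", class = "cxr_type_error")
  }
  if (nrow(img) < min_dim || ncol(img) < min_dim) {
    abort(
      sprintf("image must be at least %dx%d pixels, got %dx%d",
              min_dim, min_dim, nrow(img), ncol(img)),
      class = "cxr_type_error"
    )
  }
  if (anyNA(img) || min(img) < 0 || max(img) > 1) {
    abort("grayscale intensities must lie in [0, 1] with no NA.",
          class = "cxr_type_error")
  }
  invisible(img)
}

validate_mask <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask) || anyNA(mask)) {
    abort("`mask` must be a logical matrix with no NA.", class = "cxr_type_error")
  }
  invisible(mask)
}

#' Read a radiograph from PNG/JPEG/TIFF
#'
#' Reads an image file and returns either a grayscale matrix or an RGB
#' array, scaled to `[0, 1]`. Multi-channel images with a single effective
#' channel are collapsed; an alpha channel, if present, is dropped.
#'
#' @param path path to a PNG, JPEG or TIFF file.
#' @param as one of `"auto"`, `"gray"`, `"rgb"`. `"gray"` converts colour
#'   input via [to_grayscale()].
#' @return numeric matrix (gray) or `H x W x 3` array (rgb).
#' @export
read_cxr_image <- function(path, as = c("auto", "gray", "rgb")) {
  as <- match.arg(as)
  if (!file.exists(path)) {
    abort(sprintf("no such image file: %s", path), class = "cxr_io_error")
  }
  x <- EBImage::readImage(path)
  d <- dim(x)
  a <- as.array(x)
  if (length(d) == 2L) {
    img <- t(a) # EBImage stores x,y; we use row,col
  } else {
    nch <- d[3]
    if (nch >= 3L) {
      img <- aperm(a[, , 1:3, drop = FALSE], c(2, 1, 3))
    } else {
      img <- t(a[, , 1])
    }
  }
  img <- clip01(img)
  if (as == "gray" && length(dim(img)) == 3L) img <- to_grayscale(img)
  if (as == "rgb" && length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  }
  img
}

#' Write an image or mask to disk
#'
#' Grayscale images are written as 8-bit using round-half-away-from-zero
#' quantization; masks are written as 0/255 PNG.
#'
#' @param img numeric matrix in `[0,1]`, RGB array, or logical mask.
#' @param path output path; format chosen from the extension
#'   (png/jpg/jpeg/tif/tiff).
#' @return `path`, invisibly.
#' @export
write_cxr_image <- function(img, path) {
  if (is.logical(img)) img <- matrix(as.numeric(img), nrow(img), ncol(img))
  # quantize to 8 bit, half away from zero, then back to [0,1] for EBImage
  q <- floor(img * 255 + 0.5) / 255
  if (length(dim(q)) == 3L) {
    x <- EBImage::Image(aperm(q, c(2, 1, 3)), colormode = "Color")
  } else {
    x <- EBImage::Image(t(q), colormode = "Grayscale")
  }
  EBImage::writeImage(x, path)
  invisible(path)
}
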