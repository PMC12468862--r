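#' Grayscale conversion by weighted channel average
#'
#' Collapses an RGB radiograph to a single luminance channel using a fixed
#' weight vector. The default weights are the ITU-R BT.601 luma
#' coefficients (0.299, 0.587, 0.114); any non-negative weights summing to
#' 1 may be supplied.
#'
#' @param img `H x W x 3` numeric array, channels in `[0, 1]`.
#' @param weights length-3 non-negative numeric, summing to 1.
#' @return grayscale matrix of the same height and width.
#' @export
to_grayscale <- function(img, weights = c(0.299, 0.587, 0.114)) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L) {
    abort("RGB input must have exactly 3 channels.", class = "cxr_channel_error")
  }
  if (length(weights) != 3L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8) {
    abort("`weights` must be 3 non-negative values summing to 1.",
          class = "cxr_param_error")
  }
  g <- img[, , 1] * weights[1] + img[, , 2] * weights[2] + img[, , 3] * weights[3]
  clip01(g)
}

#' Negative (intensity inversion) transform
#'
#' Maps every pixel `v` to `1 - v`, so dark lung fields become bright
#' foreground before thresholding. Involutive: `invert(invert(x)) == x`.
#'
#' @param img grayscale matrix in `[0, 1]`.
#' @return inverted matrix, same geometry.
#' @export
invert <- function(img) {
  validate_gray(img)
  1 - img
}

#' Parameters for (contrast-limited) adaptive histogram equalization
#'
#' @param tile_rows,tile_cols number of tiles along each axis (>= 1; each
#'   tile must be at least 4 px on a side for the target image).
#' @param clip_limit `NULL` for unclipped AHE, otherwise the maximum
#'   histogram mass a single bin may hold, as a fraction of the tile's
#'   pixel count in `(0, 1]`. `1` is equivalent to unclipped.
#' @param bins histogram resolution.
#' @return an `ahe_params` list.
#' @export
ahe_params <- function(tile_rows = 8L, tile_cols = 8L, clip_limit = NULL,
                       bins = 256L) {
  if (tile_rows < 1L || tile_cols < 1L) {
    abort("tile counts must be >= 1.", class = "cxr_param_error")
  }
  if (!is.null(clip_limit) && (clip_limit <= 0 || clip_limit > 1)) {
    abort("`clip_limit` must be in (0, 1] or NULL.", class = "cxr_param_error")
  }
  structure(
    list(tile_rows = as.integer(tile_rows), tile_cols = as.integer(tile_cols),
         clip_limit = clip_limit, bins = as.integer(bins)),
    class = "ahe_params"
  )
}

# per-tile mapping: clipped histogram -> midpoint CDF lookup (length bins).
# midpoint convention sends a constant tile to 0.5 instead of 1.
tile_mapping <- function(vals, bins, clip_limit) {
  h <- tabulate(pmin(bins, floor(vals * bins) + 1L), nbins = bins)
  n <- length(vals)
  if (!is.null(clip_limit) && clip_limit < 1) {
    cap <- clip_limit * n
    excess <- sum(pmax(h - cap, 0))
    h <- pmin(h, cap)
    h <- h + excess / bins
  }
  cdf <- cumsum(h) / sum(h)
  (cdf + c(0, cdf[-bins])) / 2
}

ahe_engine <- function(img, params) {
  validate_gray(img)
  tr <- params$tile_rows; tc <- params$tile_cols; bins <- params$bins
  H <- nrow(img); W <- ncol(img)
  if (tr > H / 4 || tc > W / 4) {
    abort("tile grid too fine for image: each tile must span >= 4 px.",
          class = "cxr_param_error")
  }
  row_br <- round(seq(0, H, length.out = tr + 1))
  col_br <- round(seq(0, W, length.out = tc + 1))
  maps <- vector("list", tr * tc)
  centers_r <- numeric(tr); centers_c <- numeric(tc)
  for (a in seq_len(tr)) {
    centers_r[a] <- (row_br[a] + row_br[a + 1] + 1) / 2
    for (b in seq_len(tc)) {
      if (a == 1) centers_c[b] <- (col_br[b] + col_br[b + 1] + 1) / 2
      tile <- img[(row_br[a] + 1):row_br[a + 1], (col_br[b] + 1):col_br[b + 1]]
      maps[[(a - 1) * tc + b]] <- tile_mapping(as.vector(tile), bins, params$clip_limit)
    }
  }
  bin_idx <- matrix(pmin(bins, floor(img * bins) + 1L), H, W)
  # bilinear interpolation between the four surrounding tile mappings:
  # r0/c0 index the tile whose center is at or above/left of the pixel,
  # wr/wc are the fractional distances toward the next tile center.
  r0 <- pmin(pmax(findInterval(seq_len(H), centers_r), 1L), tr)
  c0 <- pmin(pmax(findInterval(seq_len(W), centers_c), 1L), tc)
  r1 <- pmin(r0 + 1L, tr); c1 <- pmin(c0 + 1L, tc)
  wr <- numeric(H); wc <- numeric(W)
  sel <- r1 > r0
  wr[sel] <- (seq_len(H)[sel] - centers_r[r0[sel]]) /
    (centers_r[r1[sel]] - centers_r[r0[sel]])
  sel <- c1 > c0
  wc[sel] <- (seq_len(W)[sel] - centers_c[c0[sel]]) /
    (centers_c[c1[sel]] - centers_c[c0[sel]])
  wr <- pmin(1, pmax(0, wr)); wc <- pmin(1, pmax(0, wc))
  out <- matrix(0, H, W)
  for (a in seq_len(tr)) {
    rows <- which(r0 == a)
    if (length(rows) == 0L) next
    ra <- r1[rows][1]
    for (b in seq_len(tc)) {
      cols <- which(c0 == b)
      if (length(cols) == 0L) next
      cb <- c1[cols][1]
      bi <- bin_idx[rows, cols, drop = FALSE]
      m00 <- matrix(maps[[(a - 1) * tc + b]][bi], length(rows))
      m01 <- matrix(maps[[(a - 1) * tc + cb]][bi], length(rows))
      m10 <- matrix(maps[[(ra - 1) * tc + b]][bi], length(rows))
      m11 <- matrix(maps[[(ra - 1) * tc + cb]][bi], length(rows))
      WR <- matrix(wr[rows], length(rows), length(cols))
      WC <- matrix(wc[cols], length(rows), length(cols), byrow = TRUE)
      out[rows, cols] <- (1 - WR) * ((1 - WC) * m00 + WC * m01) +
        WR * ((1 - WC) * m10 + WC * m11)
    }
  }
  clip01(out)
}

#' Adaptive histogram equalization
#'
#' Tile-based histogram equalization with bilinear interpolation between
#' neighbouring tile mappings. Each tile's intensity histogram is turned
#' into a midpoint-CDF lookup, so a constant tile maps to a constant 0.5
#' and rank order within a tile is preserved up to histogram quantization.
#' With `clip_limit = NULL` (or 1) the equalization is unclipped AHE;
#' see [clahe()] for the contrast-limited variant.
#'
#' @param img grayscale matrix in `[0, 1]`.
#' @param params an [ahe_params()] object.
#' @return equalized matrix in `[0, 1]`, same geometry.
#' @export
adaptive_equalize <- function(img, params = ahe_params()) {
  ahe_engine(img, params)
}

#' Fixed-threshold binarization
#'
#' `mask[i, j] <- img[i, j] >= threshold`; ties go to foreground.
#'
#' @param img grayscale matrix in `[0, 1]`.
#' @param threshold scalar strictly inside `(0, 1)`.
#' @return logical mask, same geometry.
#' @export
binarize <- function(img, threshold = 0.5) {
  validate_gray(img)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    abort("`threshold` must be a scalar in (0, 1).", class = "cxr_param_error")
  }
  img >= threshold
}

#' Morphology parameters
#'
#' @param element_shape `"disk"`, `"square"` or `"cross"` structuring
#'   element.
#' @param element_radius radius in pixels (>= 1); the element spans
#'   `2 * radius + 1` pixels.
#' @param sequence ordered character vector of operations drawn from
#'   `"open"`, `"close"`, `"dilate"`, `"erode"`. The default
#'   close-then-open fills notch-scale holes first, then removes speckle.
#' @return a `morph_params` list.
#' @export
morph_params <- function(element_shape = c("disk", "square", "cross"),
                         element_radius = 3L,
                         sequence = c("close", "open")) {
  element_shape <- match.arg(element_shape)
  if (element_radius < 1L) {
    abort("`element_radius` must be >= 1.", class = "cxr_param_error")
  }
  if (length(sequence) == 0L ||
      !all(sequence %in% c("open", "close", "dilate", "erode"))) {
    abort("`sequence` must be a non-empty subset sequence of open/close/dilate/erode.",
          class = "cxr_param_error")
  }
  structure(
    list(element_shape = element_shape,
         element_radius = as.integer(element_radius),
         sequence = sequence),
    class = "morph_params"
  )
}

struct_element <- function(shape, radius) {
  size <- 2L * radius + 1L
  switch(shape,
    square = matrix(1, size, size),
    disk   = {
      d <- outer(seq_len(size) - radius - 1L, seq_len(size) - radius - 1L,
                 function(a, b) sqrt(a^2 + b^2))
      (d <= radius + 1e-9) * 1
    },
    cross  = {
      m <- matrix(0, size, size)
      m[radius + 1L, ] <- 1; m[, radius + 1L] <- 1
      m
    }
  )
}

# counting via FFT convolution with zero padding: pixels outside the image
# are background for dilation and erosion alike.
dilate_mask <- function(mask, kern) {
  cnt <- EBImage::filter2(matrix(as.numeric(mask), nrow(mask)), kern, boundary = 0)
  cnt > 0.5
}

erode_mask <- function(mask, kern) {
  cnt <- EBImage::filter2(matrix(as.numeric(mask), nrow(mask)), kern, boundary = 0)
  cnt > sum(kern) - 0.5
}

#' Morphological mask cleanup
#'
#' Applies the ordered operation sequence in `params` with the configured
#' structuring element. Opening is erosion followed by dilation (removes
#' specks smaller than the element); closing is dilation followed by
#' erosion (fills holes smaller than the element). Pixels outside the
#' image count as background in every primitive.
#'
#' @param mask logical matrix, `TRUE` = foreground.
#' @param params a [morph_params()] object.
#' @return cleaned logical mask, same geometry.
#' @export
morph_clean <- function(mask, params = morph_params()) {
  validate_mask(mask)
  size <- 2L * params$element_radius + 1L
  if (size > nrow(mask) || size > ncol(mask)) {
    abort("structuring element larger than the image.", class = "cxr_param_error")
  }
  kern <- struct_element(params$element_shape, params$element_radius)
  for (op in params$sequence) {
    mask <- switch(op,
      dilate = dilate_mask(mask, kern),
      erode  = erode_mask(mask, kern),
      open   = dilate_mask(erode_mask(mask, kern), kern),
      close  = erode_mask(dilate_mask(mask, kern), kern)
    )
  }
  mask
}

#' Full preprocessing chain: radiograph to binary lung mask
#'
#' Grayscale conversion (if RGB), negative transform, optional adaptive
#' equalization, fixed-threshold binarization, morphological cleanup.
#' After the negative transform the dark lung fields are bright, so the
#' thresholded foreground is lung plus extracorporeal air, which the
#' projection-profile cropper expects.
#'
#' By default the threshold is applied to the negative directly
#' (`use_ahe = FALSE`): tile equalization of near-constant regions (flat
#' abdomen or background) manufactures foreground speckle at any fixed
#' threshold, which corrupts the mask. Set `use_ahe = TRUE` to equalize
#' before thresholding.
#'
#' The default cleanup is a single opening (erosion then dilation, disk
#' radius 3): it removes threshold speckle while leaving foreground that
#' touches the frame border intact, because the closing primitive ends
#' in an erosion which — under the outside-is-background border policy —
#' strips an element-radius band along the frame and plants spurious
#' zero-minima in the projection profiles. Any [morph_params()] sequence
#' can be substituted.
#'
#' @param img grayscale matrix or RGB array.
#' @param threshold binarization threshold.
#' @param morph a [morph_params()] object, or `NULL` to skip cleanup.
#' @param use_ahe apply [adaptive_equalize()] before thresholding.
#' @param ahe an [ahe_params()] object used when `use_ahe = TRUE`.
#' @return logical lung mask with the source image's geometry.
#' @export
preprocess_mask <- function(img, threshold = 0.5,
                            morph = morph_params(sequence = "open"),
                            use_ahe = FALSE, ahe = ahe_params()) {
  if (length(dim(img)) == 3L) img <- to_grayscale(img)
  neg <- invert(img)
  if (use_ahe) neg <- adaptive_equalize(neg, ahe)
  mask <- binarize(neg, threshold)
  if (!is.null(morph)) mask <- morph_clean(mask, morph)
  mask
}
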