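#' Projection profiles of a binary mask
#'
#' `column_profile()` counts foreground pixels column by column;
#' `row_profile()` counts row by row, optionally restricted to a band of
#' columns (the mediastinal band when locating the upper lung margin).
#'
#' @param mask logical matrix, `TRUE` = foreground.
#' @param column_band optional integer vector of column indices to which
#'   the row sums are restricted; `NULL` uses the full width.
#' @return a `cxr_profile`: numeric vector of counts with an `axis`
#'   attribute (`"columns"` or `"rows"`).
#' @export
column_profile <- function(mask) {
  validate_mask(mask)
  structure(colSums(mask), axis = "columns", class = "cxr_profile")
}

#' @rdname column_profile
#' @export
row_profile <- function(mask, column_band = NULL) {
  validate_mask(mask)
  if (is.null(column_band)) {
    v <- rowSums(mask)
  } else {
    column_band <- as.integer(column_band)
    if (length(column_band) == 0L || min(column_band) < 1L ||
        max(column_band) > ncol(mask)) {
      abort("`column_band` must be a non-empty set of columns within the mask.",
            class = "cxr_param_error")
    }
    v <- rowSums(mask[, column_band, drop = FALSE])
  }
  structure(v, axis = "rows", class = "cxr_profile")
}

#' @export
print.cxr_profile <- function(x, ...) {
  cat(sprintf("<projection profile over %s, length %d, max %g>\n",
              attr(x, "axis"), length(x), max(x)))
  print(as.numeric(x), ...)
  invisible(x)
}

#' Segmentation parameters
#'
#' Tunables for the projection-profile cropper. The lateral boundaries
#' are profile minima searched in the outer `side_fraction` of columns;
#' the upper boundary is the first row whose (band-restricted) sum
#' exceeds `top_threshold` of the profile maximum; the lower boundary is
#' the profile minimum over the bottom `bottom_search` of rows.
#'
#' @param side_fraction fraction of the width searched at each side
#'   (default 1/5).
#' @param top_band `"columns"` to restrict the row profile to a central
#'   band of columns (default), `"rows"` to scan the full-width profile
#'   starting inside a central band of rows.
#' @param top_band_fraction width of the central band (default 1/3).
#' @param top_threshold fraction of the maximum row sum (default 0.10).
#' @param bottom_search fraction of image height searched from the bottom
#'   (default 0.5).
#' @param output_size length-2 integer, ROI output `(rows, cols)`.
#' @param single_lung `"none"`, `"left"` or `"right"`: optionally keep
#'   only one half of the cropped lung image, split at the vertical
#'   midline, before the lower-half step.
#' @param use_ahe passed to [preprocess_mask()].
#' @return a `seg_params` list.
#' @export
seg_params <- function(side_fraction = 0.2, top_band = c("columns", "rows"),
                       top_band_fraction = 1 / 3, top_threshold = 0.10,
                       bottom_search = 0.5, output_size = c(227L, 227L),
                       single_lung = c("none", "left", "right"),
                       use_ahe = FALSE) {
  top_band <- match.arg(top_band)
  single_lung <- match.arg(single_lung)
  for (f in c(side_fraction, top_band_fraction, top_threshold, bottom_search)) {
    if (f <= 0 || f >= 1) {
      abort("segmentation fractions must lie in (0, 1).", class = "cxr_param_error")
    }
  }
  structure(
    list(side_fraction = side_fraction, top_band = top_band,
         top_band_fraction = top_band_fraction, top_threshold = top_threshold,
         bottom_search = bottom_search,
         output_size = as.integer(output_size), single_lung = single_lung,
         use_ahe = use_ahe),
    class = "seg_params"
  )
}

#' Crop box in source coordinates
#'
#' Half-open pixel rectangle `[left, right) x [top, bottom)`, 0-based, in
#' source-image coordinates (rows top to bottom, columns left to right).
#'
#' @param left,right,top,bottom 0-based bounds, `left < right`,
#'   `top < bottom`.
#' @param source_height,source_width geometry of the image the box refers
#'   to (optional, for audit).
#' @return a `crop_box` list.
#' @export
crop_box <- function(left, right, top, bottom,
                     source_height = NA_integer_, source_width = NA_integer_) {
  if (left < 0 || top < 0 || left >= right || top >= bottom ||
      (!is.na(source_width) && right > source_width) ||
      (!is.na(source_height) && bottom > source_height)) {
    abort("invalid crop box: need 0 <= left < right <= width, 0 <= top < bottom <= height.",
          class = "cxr_param_error")
  }
  structure(
    list(left = as.integer(left), right = as.integer(right),
         top = as.integer(top), bottom = as.integer(bottom),
         source_height = as.integer(source_height),
         source_width = as.integer(source_width)),
    class = "crop_box"
  )
}

#' @export
print.crop_box <- function(x, ...) {
  cat(sprintf("<crop box [%d,%d) x [%d,%d) of %dx%d>\n",
              x$left, x$right, x$top, x$bottom,
              x$source_height, x$source_width))
  invisible(x)
}

seg_fail <- function(stage, msg) {
  abort(sprintf("segmentation failure at stage '%s': %s", stage, msg),
        class = "cxr_segmentation_failure", stage = stage)
}

#' Lateral lung-field boundaries from a column profile
#'
#' Finds the minimum of the profile in the leftmost and rightmost
#' `side_fraction` of columns; the chest wall (background after the
#' negative transform) gives a trough just lateral to each lung field.
#' Ties break toward the image edge. Returns a half-open 0-based pair
#' `(left, right_exclusive)`.
#'
#' @param profile a column `cxr_profile` (or plain numeric vector).
#' @param side_fraction search-window width as a fraction of the image
#'   width.
#' @return integer vector `c(left, right)` with `left < right`, half-open.
#' @export
find_lateral_bounds <- function(profile, side_fraction = 0.2) {
  v <- as.numeric(profile)
  W <- length(v)
  lw <- floor(W * side_fraction)           # left window [0, lw)
  rs <- ceiling(W * (1 - side_fraction))   # right window [rs, W)
  if (lw < 1L || rs >= W + 1L || rs < 1L || lw > W) {
    seg_fail("lateral", "profile too short for the side windows.")
  }
  if (rs > W - 1L) rs <- W - 1L
  left0 <- which.min(v[seq_len(lw)]) - 1L                 # ties -> smallest
  rwin <- v[(rs + 1L):W]
  right0 <- rs + (length(rwin) + 1L - which.min(rev(rwin))) - 1L  # ties -> largest
  c(left = left0, right = right0 + 1L)
}

#' Vertical lung-field boundaries from a row profile
#'
#' The upper boundary is the first row (from the top) whose profile value
#' exceeds `top_threshold` times the profile maximum; the lower boundary
#' is the profile minimum over the bottom `bottom_search` fraction of
#' rows, ties broken toward the bottom so the costophrenic angle stays in
#' frame. Returns 0-based row indices `(top, bottom)` with
#' `top < bottom`; the crop keeps rows `[top, bottom]`.
#'
#' @param row_prof a row `cxr_profile` (or plain numeric vector).
#' @param top_threshold fraction of the maximum row sum.
#' @param bottom_search fraction of the height searched from the bottom.
#' @return integer vector `c(top, bottom)` of 0-based row indices.
#' @export
find_vertical_bounds <- function(row_prof, top_threshold = 0.10,
                                 bottom_search = 0.5) {
  v <- as.numeric(row_prof)
  H <- length(v)
  mx <- max(v)
  if (mx <= 0) seg_fail("vertical", "profile is identically zero.")
  cut <- top_threshold * mx
  top_hits <- which(v > cut)
  if (length(top_hits) == 0L) {
    seg_fail("vertical", "no row exceeds the top threshold.")
  }
  top0 <- top_hits[1] - 1L
  lo_start <- H - floor(H * bottom_search) + 1L   # 1-based first row of window
  lo <- v[lo_start:H]
  bottom0 <- lo_start + (length(lo) + 1L - which.min(rev(lo))) - 2L  # ties -> bottom
  if (top0 >= bottom0) {
    seg_fail("vertical", sprintf("top (%d) not above bottom (%d).", top0, bottom0))
  }
  c(top = top0, bottom = bottom0)
}

#' Crop an image to a box
#'
#' Copies the half-open rectangle `[left, right) x [top, bottom)` out of
#' the source image, unchanged.
#'
#' @param img grayscale matrix.
#' @param box a [crop_box()].
#' @return the cropped matrix.
#' @export
crop_to_box <- function(img, box) {
  if (box$right > ncol(img) || box$bottom > nrow(img)) {
    abort("crop box extends outside the image.", class = "cxr_param_error")
  }
  img[(box$top + 1L):box$bottom, (box$left + 1L):box$right, drop = FALSE]
}

# plain bilinear resampling; EBImage's antialias option is left off
# because it filters image borders against zero padding and darkens them
resize_gray <- function(img, out_rows, out_cols) {
  out <- EBImage::resize(img, w = out_rows, h = out_cols, antialias = FALSE)
  clip01(matrix(as.numeric(out), out_rows, out_cols))
}

#' Keep the lower lung half and normalize size
#'
#' Retains rows `[floor(H/2), H)` of the cropped lung image — the band
#' from the heart down to the costophrenic angles — then resizes to
#' `output_size` with anti-aliased bilinear interpolation.
#'
#' @param img cropped lung-field image, height >= 2.
#' @param output_size length-2 integer `(rows, cols)`, default 227 x 227.
#' @return resized lower-half matrix.
#' @export
extract_lower_half_roi <- function(img, output_size = c(227L, 227L)) {
  H <- nrow(img)
  if (is.null(H) || H < 2L) {
    abort("image height must be >= 2 to split at the midline.",
          class = "cxr_param_error")
  }
  lower <- img[(floor(H / 2) + 1L):H, , drop = FALSE]
  resize_gray(lower, output_size[1], output_size[2])
}

#' Segment the heart-to-costophrenic-angle ROI
#'
#' Runs the full cropping chain: derives a binary lung mask from a
#' working copy of the radiograph ([preprocess_mask()]), locates lateral
#' boundaries from the column profile and vertical boundaries from the
#' row profile (restricted to the central `top_band_fraction` of columns
#' by default), crops the ORIGINAL grayscale image to the resulting box,
#' optionally keeps a single lung (vertical midline split), keeps the
#' lower half, and resizes to `params$output_size`.
#'
#' @param img grayscale matrix or RGB array.
#' @param params a [seg_params()] object.
#' @return list with `roi` (normalized matrix) and `box` (the
#'   source-coordinate [crop_box()] of the full lung field).
#' @export
segment <- function(img, params = seg_params()) {
  if (length(dim(img)) == 3L) img <- to_grayscale(img)
  validate_gray(img)
  if (diff(range(img)) < 1e-12) {
    seg_fail("mask", "image of identical pixels carries no lung-field structure.")
  }
  mask <- preprocess_mask(img, use_ahe = params$use_ahe)
  if (all(mask) || !any(mask)) {
    seg_fail("mask", "uniform mask carries no lung-field structure.")
  }
  lat <- find_lateral_bounds(column_profile(mask), params$side_fraction)
  W <- ncol(mask)
  band <- if (params$top_band == "columns") {
    half <- params$top_band_fraction / 2
    lo <- max(1L, floor(W * (0.5 - half)) + 1L)
    hi <- min(W, ceiling(W * (0.5 + half)))
    seq.int(lo, hi)
  } else NULL
  rp <- row_profile(mask, column_band = band)
  vert <- find_vertical_bounds(rp, params$top_threshold, params$bottom_search)
  box <- crop_box(lat[["left"]], lat[["right"]],
                  vert[["top"]], vert[["bottom"]] + 1L,
                  source_height = nrow(img), source_width = ncol(img))
  lung <- crop_to_box(img, box)
  if (params$single_lung != "none") {
    mid <- floor(ncol(lung) / 2)
    lung <- if (params$single_lung == "left") {
      lung[, seq_len(mid), drop = FALSE]
    } else {
      lung[, (mid + 1L):ncol(lung), drop = FALSE]
    }
  }
  roi <- extract_lower_half_roi(lung, params$output_size)
  list(roi = roi, box = box)
}

#' Intersection-over-union of two crop boxes
#'
#' @param a,b [crop_box()] objects.
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  iw <- max(0, min(a$right, b$right) - max(a$left, b$left))
  ih <- max(0, min(a$bottom, b$bottom) - max(a$top, b$top))
  inter <- iw * ih
  area <- function(x) (x$right - x$left) * (x$bottom - x$top)
  un <- area(a) + area(b) - inter
  if (un <= 0) return(0)
  inter / un
}

#' Serialize a crop box to JSON
#'
#' @param box a [crop_box()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_box_json <- function(box, path) {
  jsonlite::write_json(unclass(box), path, auto_unbox = TRUE)
  invisible(path)
}
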