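#' Histogram stretching
#'
#' Linearly maps the observed intensity range `[min, max]` onto the full
#' dynamic range (internally `[0, 1]`; the 8-bit 0-255 range only at file
#' export). Order-preserving and idempotent after the first application.
#' A constant image cannot be stretched and is returned unchanged with a
#' warning.
#'
#' @param img grayscale matrix in `[0, 1]`.
#' @return stretched matrix; on non-constant input its minimum is exactly
#'   0 and its maximum exactly 1.
#' @export
histogram_stretch <- function(img) {
  validate_gray(img)
  lo <- min(img); hi <- max(img)
  if (hi <= lo) {
    warn("constant image: histogram stretch is undefined, returning input unchanged.")
    return(img)
  }
  (img - lo) / (hi - lo)
}

#' Logarithmic intensity transform
#'
#' `out = log(1 + scale * in) / log(1 + scale)`: a monotone compressive
#' map that lifts dark intensities, normalized back to `[0, 1]`.
#'
#' @param img grayscale matrix in `[0, 1]`.
#' @param scale positive scaling constant.
#' @return transformed matrix in `[0, 1]`.
#' @export
log_transform <- function(img, scale = 1) {
  validate_gray(img)
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0) {
    abort("`scale` must be a positive scalar.", class = "cxr_param_error")
  }
  log1p(scale * img) / log1p(scale)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-based equalization as in [adaptive_equalize()], but each tile's
#' histogram is clipped at `clip_limit` (a fraction of the tile's pixel
#' count per bin) and the excess mass redistributed uniformly before the
#' CDF mapping, limiting noise amplification in flat regions.
#'
#' @param img grayscale matrix in `[0, 1]`.
#' @param params an [ahe_params()] with a non-`NULL` `clip_limit`.
#' @return equalized matrix in `[0, 1]`.
#' @export
clahe <- function(img, params = ahe_params(clip_limit = 0.02)) {
  if (is.null(params$clip_limit)) {
    abort("CLAHE requires a clip_limit; use adaptive_equalize() for unclipped AHE.",
          class = "cxr_param_error")
  }
  ahe_engine(img, params)
}

#' Sobel configuration
#'
#' Tunables for the Sobel gradient chain: optional Gaussian pre-smoothing
#' (`gaussian_sigma = 0` skips it), optional gradient-direction map,
#' optional binary thresholding of the magnitude, and an optional blend
#' `alpha * original + beta * magnitude`.
#'
#' @param gaussian_sigma standard deviation (px) of the pre-smoothing
#'   kernel; 0 disables smoothing.
#' @param compute_direction also return the gradient direction map.
#' @param edge_threshold `NULL`, or a threshold in `(0, 1)` applied to the
#'   max-normalized magnitude to binarize it.
#' @param combine_alpha,combine_beta non-negative blend weights for the
#'   original image and the gradient map; `alpha + beta > 0`.
#' @return a `sobel_config` list.
#' @export
sobel_config <- function(gaussian_sigma = 1.0, compute_direction = FALSE,
                         edge_threshold = NULL, combine_alpha = 0.5,
                         combine_beta = 0.5) {
  if (gaussian_sigma < 0 || combine_alpha < 0 || combine_beta < 0 ||
      combine_alpha + combine_beta <= 0) {
    abort("need sigma >= 0, alpha, beta >= 0 and alpha + beta > 0.",
          class = "cxr_param_error")
  }
  structure(
    list(gaussian_sigma = gaussian_sigma,
         compute_direction = isTRUE(compute_direction),
         edge_threshold = edge_threshold,
         combine_alpha = combine_alpha, combine_beta = combine_beta),
    class = "sobel_config"
  )
}

# the two 3x3 Sobel kernels, [row, col]; Gx responds to horizontal
# (left-right) intensity change, Gy to vertical.
sobel_kernels <- function() {
  gx <- matrix(c(-1, 0, 1,
                 -2, 0, 2,
                 -1, 0, 1), 3, 3, byrow = TRUE)
  list(gx = gx, gy = t(gx))
}

# correlation with edge replication. filter2's impulse response lays the
# kernel out as passed (convolution), so flip for correlation semantics.
correlate_replicate <- function(img, kern) {
  k <- kern[rev(seq_len(nrow(kern))), rev(seq_len(ncol(kern))), drop = FALSE]
  matrix(as.numeric(EBImage::filter2(img, k, boundary = "replicate")),
         nrow(img), ncol(img))
}

gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  size <- 2L * max(1L, ceiling(3 * sigma)) + 1L
  size <- min(size, 2L * (min(dim(img)) %/% 2) - 1L)
  kern <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
  correlate_replicate(img, kern)
}

#' Sobel gradient edge enhancement
#'
#' The gradient chain: optional Gaussian pre-smoothing; correlation with
#' the two 3x3 Sobel kernels (edge-replicated borders); gradient
#' magnitude `sqrt(Gx^2 + Gy^2)` normalized by its own maximum (a
#' constant image yields an exactly zero map); optional direction map
#' `atan2(Gy, Gx)`; optional binarization of the magnitude; optional
#' blend `alpha * original + beta * gradient_map`.
#'
#' @param img grayscale matrix, at least 3 x 3.
#' @param cfg a [sobel_config()].
#' @return enhanced matrix in `[0, 1]`. When `cfg$compute_direction` is
#'   `TRUE` the direction map is attached as attribute `"direction"`.
#' @export
sobel_gradient <- function(img, cfg = sobel_config()) {
  validate_gray(img, min_dim = 3L)
  if (nrow(img) < 3L || ncol(img) < 3L) {
    abort("image smaller than the 3x3 Sobel kernel.", class = "cxr_param_error")
  }
  sm <- gaussian_smooth(img, cfg$gaussian_sigma)
  k <- sobel_kernels()
  gx <- correlate_replicate(sm, k$gx)
  gy <- correlate_replicate(sm, k$gy)
  mag <- sqrt(gx^2 + gy^2)
  mx <- max(mag)
  gmap <- if (mx > 1e-9) mag / mx else mag * 0   # flat image: zero map
  if (!is.null(cfg$edge_threshold)) {
    gmap <- (gmap > cfg$edge_threshold) * 1
  }
  out <- cfg$combine_alpha * img + cfg$combine_beta * gmap
  out <- clip01(out / max(1, max(out)))   # renormalize only if blend exceeds 1
  if (cfg$compute_direction) attr(out, "direction") <- atan2(gy, gx)
  out
}

#' Unsharp-mask sharpening
#'
#' `out = clip(in + amount * (in - blur(in)))` with a Gaussian blur:
#' accentuates edges by adding back the high-pass residual.
#'
#' @param img grayscale matrix.
#' @param amount non-negative sharpening weight; 0 is the identity.
#' @param sigma blur standard deviation (px).
#' @return sharpened matrix in `[0, 1]`.
#' @export
sharpen <- function(img, amount = 1, sigma = 1) {
  validate_gray(img)
  if (amount < 0) abort("`amount` must be >= 0.", class = "cxr_param_error")
  if (amount == 0) return(img)
  clip01(img + amount * (img - gaussian_smooth(img, sigma)))
}

#' Canny edge detection
#'
#' The standard chain: Gaussian smoothing, Sobel gradients, non-maximum
#' suppression along the quantized gradient direction, and hysteresis
#' thresholding (weak-edge components are kept only when they touch a
#' strong edge). Thresholds are fractions of the maximum gradient
#' magnitude.
#'
#' @param img grayscale matrix, at least 3 x 3.
#' @param low,high hysteresis thresholds, `0 < low < high < 1`.
#' @param sigma smoothing standard deviation.
#' @return numeric 0/1 edge map (matrix), for pipeline uniformity.
#' @export
canny <- function(img, low = 0.1, high = 0.3, sigma = 1) {
  validate_gray(img, min_dim = 3L)
  if (!(low > 0 && high < 1 && low < high)) {
    abort("need 0 < low < high < 1.", class = "cxr_param_error")
  }
  sm <- gaussian_smooth(img, sigma)
  k <- sobel_kernels()
  gx <- correlate_replicate(sm, k$gx)
  gy <- correlate_replicate(sm, k$gy)
  mag <- sqrt(gx^2 + gy^2)
  mx <- max(mag)
  if (mx <= 1e-9) return(matrix(0, nrow(img), ncol(img)))   # flat image
  mag <- mag / mx
  H <- nrow(img); W <- ncol(img)
  ang <- atan2(gy, gx)                     # quantize to 4 directions
  sector <- (round(ang / (pi / 4)) %% 4)   # 0:E-W, 1:NE-SW, 2:N-S, 3:NW-SE
  pad <- matrix(0, H + 2L, W + 2L); pad[2:(H + 1L), 2:(W + 1L)] <- mag
  at <- function(dr, dc) pad[(2:(H + 1L)) + dr, (2:(W + 1L)) + dc]
  n1 <- matrix(0, H, W); n2 <- n1
  # neighbour offsets along the gradient for each sector
  offs <- list(`0` = c(0L, 1L), `1` = c(-1L, 1L), `2` = c(-1L, 0L), `3` = c(-1L, -1L))
  for (s in 0:3) {
    sel <- sector == s
    if (!any(sel)) next
    o <- offs[[as.character(s)]]
    n1[sel] <- at(o[1], o[2])[sel]
    n2[sel] <- at(-o[1], -o[2])[sel]
  }
  nms <- mag * (mag >= n1 & mag >= n2)
  strong <- nms > high
  weak <- nms > low
  if (!any(strong)) return(matrix(0, H, W))
  lab <- EBImage::bwlabel(t(weak))         # 8-connected components
  keep <- unique(lab[t(strong)])
  keep <- keep[keep > 0]
  edges <- t(matrix(lab %in% keep, nrow(lab), ncol(lab)))
  matrix(as.numeric(edges), H, W)
}

#' Enhancement configuration
#'
#' Selects the two-stage enhancement: a contrast stage
#' (`none`/`log`/`clahe`/`stretch`) followed by an edge stage
#' (`none`/`sobel`/`sobel_gradient`/`sharpen`/`canny`). The default
#' `(stretch, sobel_gradient)` is the selected pipeline: histogram
#' stretching makes the costophrenic angle discernible and the gradient
#' blend emphasizes tissue boundaries. `"sobel"` is the plain thresholded
#' edge map (threshold on, blend off); `"sobel_gradient"` is the
#' magnitude blend (threshold off, blend on).
#'
#' @param contrast_method one of `"none"`, `"log"`, `"clahe"`, `"stretch"`.
#' @param edge_method one of `"none"`, `"sobel"`, `"sobel_gradient"`,
#'   `"sharpen"`, `"canny"`.
#' @param sobel a [sobel_config()] for the gradient stages.
#' @param clahe_params [ahe_params()] for the CLAHE contrast stage.
#' @param log_scale scale for the log stage.
#' @param sharpen_amount weight for the sharpening stage.
#' @param canny_low,canny_high Canny hysteresis thresholds.
#' @param sobel_threshold step-5 threshold used by the plain `"sobel"`
#'   edge map.
#' @return an `enhance_config` list.
#' @export
enhance_config <- function(contrast_method = c("stretch", "none", "log", "clahe"),
                           edge_method = c("sobel_gradient", "none", "sobel",
                                           "sharpen", "canny"),
                           sobel = sobel_config(),
                           clahe_params = ahe_params(clip_limit = 0.02),
                           log_scale = 10, sharpen_amount = 1,
                           canny_low = 0.1, canny_high = 0.3,
                           sobel_threshold = 0.2) {
  structure(
    list(contrast_method = match.arg(contrast_method),
         edge_method = match.arg(edge_method),
         sobel = sobel, clahe_params = clahe_params, log_scale = log_scale,
         sharpen_amount = sharpen_amount,
         canny_low = canny_low, canny_high = canny_high,
         sobel_threshold = sobel_threshold),
    class = "enhance_config"
  )
}

#' Two-stage ROI enhancement
#'
#' Applies the configured contrast stage, then the configured edge stage.
#' With both stages `"none"` the input is returned bit-identical.
#'
#' @param img grayscale ROI matrix.
#' @param cfg an [enhance_config()].
#' @return enhanced matrix in `[0, 1]`.
#' @export
enhance <- function(img, cfg = enhance_config()) {
  out <- tryCatch(
    switch(cfg$contrast_method,
      none    = img,
      stretch = suppressWarnings(histogram_stretch(img)),
      log     = log_transform(img, cfg$log_scale),
      clahe   = clahe(img, cfg$clahe_params)
    ),
    error = function(e) {
      abort(sprintf("enhancement failed at contrast stage '%s': %s",
                    cfg$contrast_method, conditionMessage(e)),
            class = "cxr_enhance_error", parent = e)
    }
  )
  out <- tryCatch(
    switch(cfg$edge_method,
      none           = out,
      sobel_gradient = sobel_gradient(out, cfg$sobel),
      sobel          = {
        sc <- cfg$sobel
        sc$edge_threshold <- cfg$sobel_threshold
        sc$combine_alpha <- 0; sc$combine_beta <- 1
        sobel_gradient(out, sc)
      },
      sharpen        = sharpen(out, cfg$sharpen_amount),
      canny          = canny(out, cfg$canny_low, cfg$canny_high)
    ),
    error = function(e) {
      abort(sprintf("enhancement failed at edge stage '%s': %s",
                    cfg$edge_method, conditionMessage(e)),
            class = "cxr_enhance_error", parent = e)
    }
  )
  out
}
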