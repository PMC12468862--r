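#' Phantom configuration
#'
#' Parameters of the synthetic frontal chest radiograph generator. The
#' phantom emulates the gross intensity structure of a real CXR with
#' conventional polarity (air dark, tissue/fluid/bone bright): a dark
#' extracorporeal background, a bright soft-tissue body with a shoulder
#' band, two dark lung fields crossed by faint rib arcs, a bright
#' mediastinal band with the cardiac silhouette biased toward the
#' image-left lung, diaphragm domes falling laterally into sharp
#' costophrenic angles, and — when `effusion = TRUE` — a homogeneous
#' bright fluid opacity filling the costal recess up to `fill_level`
#' with a Gaussian-blurred meniscus that blunts the angle. Additive
#' Gaussian noise and a linear illumination tilt complete the image.
#'
#' @param image_size length-2 integer `(H, W)` in pixels.
#' @param effusion logical; render pleural fluid.
#' @param fill_level fraction of hemithorax height filled by fluid, in
#'   `[0, 1]`; must be 0 when `effusion = FALSE`.
#' @param side `"left"`, `"right"` or `"both"` (image coordinates).
#' @param heart_shift leftward shift of the cardiac silhouette center as
#'   a fraction of image width.
#' @param rib_count number of rib arcs per lung (>= 0).
#' @param noise_sd standard deviation of additive Gaussian intensity
#'   noise.
#' @param illumination_tilt linear illumination gradient in intensity per
#'   pixel, applied across columns.
#' @param exposure_gain,exposure_offset per-image exposure model
#'   `gain * (I - 0.5) + 0.5 + offset`, emulating acquisition-to-
#'   acquisition brightness/contrast variability; defaults are neutral.
#' @param seed integer seed; the phantom is bit-reproducible given the
#'   seed.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(image_size = c(256L, 256L), effusion = FALSE,
                           fill_level = if (effusion) 0.4 else 0,
                           side = c("right", "left", "both"),
                           heart_shift = 0.10, rib_count = 5L,
                           noise_sd = 0.03, illumination_tilt = 3e-4,
                           exposure_gain = 1, exposure_offset = 0,
                           seed = 1L) {
  side <- match.arg(side)
  if (!effusion && fill_level != 0) {
    abort("`fill_level` must be 0 when `effusion = FALSE`.",
          class = "cxr_param_error")
  }
  if (fill_level < 0 || fill_level > 1 || noise_sd < 0 || rib_count < 0) {
    abort("need fill_level in [0,1], noise_sd >= 0, rib_count >= 0.",
          class = "cxr_param_error")
  }
  if (abs(heart_shift) > 0.25) {
    abort("`heart_shift` would move the mediastinum off the lung fields.",
          class = "cxr_param_error")
  }
  if (exposure_gain <= 0) {
    abort("`exposure_gain` must be positive.", class = "cxr_param_error")
  }
  structure(
    list(image_size = as.integer(image_size), effusion = isTRUE(effusion),
         fill_level = fill_level, side = side, heart_shift = heart_shift,
         rib_count = as.integer(rib_count), noise_sd = noise_sd,
         illumination_tilt = illumination_tilt,
         exposure_gain = exposure_gain, exposure_offset = exposure_offset,
         seed = as.integer(seed)),
    class = "phantom_config"
  )
}

# run code under a given RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# fixed anatomical fractions of the phantom (of H or W). The body edge
# slants outward with depth, from body_top_edge at the shoulders to the
# lung's lateral edge (lat_edge) at the recess row: each chest-wall
# column then sees strictly fewer extracorporeal-air rows the closer it
# lies to the lung, so the lateral projection trough is unique and sits
# immediately lateral to the lung field.
phantom_anatomy <- function(H, W, heart_shift) {
  list(
    shoulder_rows = 0.05,     # bright band at the top
    lat_edge = 0.125,         # lateral lung edge (left; right mirrored)
    body_top_edge = 0.09,     # body edge at the shoulders
    medi_halfwidth = 0.10,    # mediastinal band half-width
    apex = 0.16,              # lung apex row
    apex_bulge = 0.05,        # extra drop of the lung top at its edges
    dome_top = 0.70,          # medial diaphragm row
    recess = 0.90,            # costophrenic recess row (lateral)
    heart_center = c(0.62, 0.50 - heart_shift),
    heart_radii = c(0.17, 0.14)  # (rows, cols) fractions of (H, W)
  )
}

render_phantom <- function(cfg) {
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  an <- phantom_anatomy(H, W, cfg$heart_shift)
  R <- matrix(seq_len(H), H, W)              # row index grid
  C <- matrix(seq_len(W), H, W, byrow = TRUE)
  rr <- R / H; cc <- C / W

  img <- matrix(0.06, H, W)                                   # air
  # body edge slants from body_top_edge (shoulders) to lat_edge (recess)
  slant <- pmin(1, pmax(0, (rr - an$shoulder_rows) / (an$recess - an$shoulder_rows)))
  edge <- an$body_top_edge + (an$lat_edge - an$body_top_edge) * slant
  body <- cc >= edge & cc <= 1 - edge & rr >= an$shoulder_rows
  img[body] <- 0.55                                           # soft tissue
  img[rr < an$shoulder_rows] <- 0.70                          # shoulder band

  # lung fields: per side, columns between the inner chest wall and the
  # mediastinum, rows between a rounded top and the diaphragm curve
  lat_l <- an$lat_edge; med_l <- 0.5 - an$medi_halfwidth
  med_r <- 0.5 + an$medi_halfwidth; lat_r <- 1 - an$lat_edge
  lung_side <- function(lat, med) {
    lo <- min(lat, med); hi <- max(lat, med)
    u <- (cc - lo) / (hi - lo)                     # 0..1 across the lung
    inside_c <- cc >= lo & cc <= hi
    mid <- (lo + hi) / 2; halfw <- (hi - lo) / 2
    top <- an$apex + an$apex_bulge * ((cc - mid) / halfw)^2
    # diaphragm falls from the medial dome to the lateral recess
    tow_lat <- if (lat < med) 1 - u else u         # 1 at the lateral edge
    dia <- an$dome_top + (an$recess - an$dome_top) * tow_lat^1.5
    inside_c & rr >= top & rr <= dia
  }
  left_lung <- lung_side(lat_l, med_l)
  right_lung <- lung_side(lat_r, med_r)
  img[left_lung | right_lung] <- 0.18

  # rib arcs: faint bright bands sweeping down-lateral across each lung
  if (cfg$rib_count > 0) {
    for (k in seq_len(cfg$rib_count)) {
      base <- an$apex + (k - 0.3) * (an$dome_top - an$apex) / cfg$rib_count
      curve <- base + 0.05 * sin(cc * pi * 2.2 + k)
      band <- abs(rr - curve) < 0.008
      sel <- band & (left_lung | right_lung)
      img[sel] <- img[sel] + 0.10
    }
  }

  # mediastinum and cardiac silhouette (drawn over the medial lung edges)
  medi <- cc > med_l & cc < med_r & rr >= 0.10
  img[medi & body] <- 0.72
  hc <- an$heart_center; hrad <- an$heart_radii
  heart <- ((rr - hc[1]) / hrad[1])^2 + ((cc - hc[2]) / hrad[2])^2 <= 1
  img[heart] <- 0.72

  aerated <- (left_lung | right_lung) & !heart & !medi
  # abdomen below the diaphragm, inside the body, brighter than lung
  dia_or_below <- body & !aerated & rr >= an$dome_top & !heart & !medi
  img[dia_or_below] <- pmax(img[dia_or_below], 0.62)

  # pleural fluid: fill each affected costal recess up to fill_level of
  # the hemithorax height, with a blurred meniscus
  hemi_h <- an$recess - an$apex
  fill_row <- NA_real_
  if (cfg$effusion && cfg$fill_level > 0) {
    fill_row <- an$recess - cfg$fill_level * hemi_h
    sides <- switch(cfg$side, left = "left", right = "right",
                    both = c("left", "right"))
    fluid <- matrix(FALSE, H, W)
    if ("left" %in% sides) fluid <- fluid | (left_lung & !heart & rr >= fill_row)
    if ("right" %in% sides) fluid <- fluid | (right_lung & !heart & rr >= fill_row)
    wgt <- gaussian_smooth(matrix(as.numeric(fluid), H, W), 2)
    img <- img * (1 - wgt) + 0.60 * wgt
  }

  img <- cfg$exposure_gain * (img - 0.5) + 0.5 + cfg$exposure_offset
  img <- img + cfg$illumination_tilt * (C - W / 2)
  if (cfg$noise_sd > 0) img <- img + rnorm(H * W, 0, cfg$noise_sd)
  img <- clip01(img)

  lungs <- left_lung | right_lung
  lung_rows <- range(which(rowSums(lungs) > 0))
  lung_cols <- range(which(colSums(lungs) > 0))
  truth <- list(
    lung_box = crop_box(lung_cols[1] - 1L, lung_cols[2], lung_rows[1] - 1L,
                        lung_rows[2], source_height = H, source_width = W),
    junction_left = c(row = round(an$recess * H) - 1, col = round(lat_l * W) - 1),
    junction_right = c(row = round(an$recess * H) - 1, col = round(lat_r * W) - 1),
    # narrow wedges hugging the costophrenic notch, mostly above the
    # diaphragm so their mean tracks lung air (or fluid), not abdomen
    recess_left = crop_box(round(lat_l * W), round((lat_l + 0.04) * W),
                           round((an$recess - 0.06) * H),
                           round((an$recess - 0.005) * H),
                           source_height = H, source_width = W),
    recess_right = crop_box(round((lat_r - 0.04) * W), round(lat_r * W),
                            round((an$recess - 0.06) * H),
                            round((an$recess - 0.005) * H),
                            source_height = H, source_width = W),
    fill_row = if (is.na(fill_row)) NA_integer_ else round(fill_row * H) - 1L
  )
  list(image = img, truth = truth)
}

#' Generate one synthetic radiograph
#'
#' Deterministic given `cfg$seed`: the same configuration always renders
#' a bit-identical image. Ground-truth geometry (lung-field box,
#' diaphragm-wall junction coordinates, recess regions and fluid
#' boundary row) is recorded alongside the image.
#'
#' @param cfg a [phantom_config()].
#' @return a `phantom_sample` list: `image` (grayscale matrix), `label`
#'   (`"normal"` or `"effusion"`), `truth` (geometry list), `config`.
#' @export
generate_phantom <- function(cfg = phantom_config()) {
  out <- with_seed(cfg$seed, render_phantom(cfg))
  structure(
    list(image = out$image,
         label = if (cfg$effusion) "effusion" else "normal",
         truth = out$truth, config = cfg),
    class = "phantom_sample"
  )
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom %s, %dx%d, fill %.2f, side %s, seed %d>\n",
              x$label, nrow(x$image), ncol(x$image), x$config$fill_level,
              x$config$side, x$config$seed))
  invisible(x)
}

sample_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 7919 + counter * 104729) %% 2147483647)
}

#' Generate a labelled phantom dataset
#'
#' Renders `n_per_class` normal and `n_per_class` effusion phantoms with
#' per-sample randomized parameters (fluid fill uniform in
#' `fill_range`, effusion side drawn at random, jittered heart position
#' and noise), reproducibly from one seed: per-sample seeds are derived
#' by counter from `seed`, never from global RNG state.
#'
#' @param n_per_class samples per class (>= 1).
#' @param base_cfg template [phantom_config()]; per-sample fields
#'   (`effusion`, `fill_level`, `side`, `seed`, jittered `heart_shift`)
#'   are overridden.
#' @param seed dataset seed.
#' @param out_dir directory for PNG files and `manifest.csv`; `NULL`
#'   keeps the images in memory (list-column `image`).
#' @param fill_range length-2 numeric, range of `fill_level` draws.
#' @return a tibble manifest: `filename`, `label`, per-sample parameters
#'   and flattened truth geometry; with `out_dir = NULL` also an `image`
#'   list-column of matrices.
#' @export
generate_dataset <- function(n_per_class, base_cfg = phantom_config(),
                             seed = 1L, out_dir = NULL,
                             fill_range = c(0.2, 0.7)) {
  if (n_per_class < 1L) {
    abort("`n_per_class` must be >= 1.", class = "cxr_param_error")
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output directory: %s", out_dir),
                   class = "cxr_io_error")
  }
  draws <- with_seed(seed, {
    n <- 2L * n_per_class
    tibble::tibble(
      idx = seq_len(n),
      label = rep(c("normal", "effusion"), each = n_per_class),
      fill = runif(n, fill_range[1], fill_range[2]),
      side = sample(c("left", "right"), n, replace = TRUE),
      heart_jitter = runif(n, -0.02, 0.02),
      gain = runif(n, 0.85, 1.15),
      offset = runif(n, -0.08, 0.08),
      tilt_mult = runif(n, -1.5, 1.5)
    )
  })
  rows <- purrr::pmap(draws, function(idx, label, fill, side, heart_jitter,
                                      gain, offset, tilt_mult) {
    cfg <- base_cfg
    cfg$effusion <- label == "effusion"
    cfg$fill_level <- if (cfg$effusion) fill else 0
    cfg$side <- if (cfg$effusion) side else base_cfg$side
    cfg$heart_shift <- base_cfg$heart_shift + heart_jitter
    cfg$exposure_gain <- base_cfg$exposure_gain * gain
    cfg$exposure_offset <- base_cfg$exposure_offset + offset
    cfg$illumination_tilt <- base_cfg$illumination_tilt * tilt_mult
    cfg$seed <- sample_seed(seed, idx)
    s <- generate_phantom(cfg)
    fn <- sprintf("phantom_%03d_%s.png", idx, label)
    tb <- s$truth$lung_box
    tibble::tibble(
      filename = fn, label = label, sample_seed = cfg$seed,
      fill_level = cfg$fill_level, side = cfg$side,
      noise_sd = cfg$noise_sd,
      box_left = tb$left, box_right = tb$right,
      box_top = tb$top, box_bottom = tb$bottom,
      junction_left_row = s$truth$junction_left[["row"]],
      junction_right_row = s$truth$junction_right[["row"]],
      fill_row = s$truth$fill_row,
      image = list(s$image), truth = list(s$truth)
    )
  })
  manifest <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    purrr::walk2(manifest$image, manifest$filename,
                 function(im, fn) write_cxr_image(im, file.path(out_dir, fn)))
    out <- dplyr::select(manifest, -"image", -"truth")
    utils::write.csv(out, file.path(out_dir, "manifest.csv"), row.names = FALSE)
    manifest$filename <- file.path(out_dir, manifest$filename)
    manifest <- dplyr::select(manifest, -"truth")
  }
  manifest
}
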