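test_that("projection profiles equal brute-force per-line counts", {
  expect_equal(as.numeric(column_profile(matrix(FALSE, 4, 4))), rep(0, 4))
  expect_equal(as.numeric(column_profile(matrix(TRUE, 5, 7))), rep(5, 7))

  m <- matrix(FALSE, 4, 4); m[2, 3] <- TRUE   # 0-based (1,2)
  expect_equal(as.numeric(column_profile(m)), c(0, 0, 1, 0))

  expect_equal(as.numeric(row_profile(matrix(TRUE, 4, 4))), rep(4, 4))
  expect_equal(as.numeric(row_profile(matrix(TRUE, 4, 6), column_band = 3:4)),
               rep(2, 4))

  set.seed(5)
  for (i in 1:25) {
    H <- sample(4:64, 1); W <- sample(4:64, 1)
    msk <- random_mask(H, W)
    expect_equal(as.numeric(column_profile(msk)), oracle_column_profile(msk))
    expect_equal(as.numeric(row_profile(msk)), oracle_row_profile(msk))
    # row profile equals transpose-then-column-profile
    expect_equal(as.numeric(row_profile(msk)),
                 as.numeric(column_profile(t(msk))))
    band <- sort(sample(seq_len(W), max(2, W %/% 3)))
    expect_equal(as.numeric(row_profile(msk, band)),
                 oracle_row_profile(msk, band))
  }
  expect_error(row_profile(matrix(TRUE, 4, 4), integer(0)),
               class = "cxr_param_error")
})

test_that("lateral boundary search matches the exhaustive argmin oracle", {
  v <- c(3, 0, 5, 6, 7, 7, 6, 5, 0, 4)
  expect_equal(unname(find_lateral_bounds(v, 0.2)), c(1L, 9L))

  # constant profile: ties resolve toward the image edges
  expect_equal(unname(find_lateral_bounds(rep(2, 10), 0.2)), c(0L, 10L))

  # strictly increasing: left window minimum at 0, right window at its start
  W <- 10
  expect_equal(unname(find_lateral_bounds(seq_len(W), 0.2)),
               c(0L, ceiling(W * 0.8) + 1L))

  set.seed(13)
  for (i in 1:1000) {
    W <- sample(6:80, 1)
    v <- sample(0:12, W, replace = TRUE)
    expect_equal(unname(find_lateral_bounds(v, 0.2)), oracle_lateral(v, 0.2))
  }
  expect_error(find_lateral_bounds(c(1, 2, 3), 0.1),
               class = "cxr_segmentation_failure")
})

test_that("vertical boundary search matches first-crossing/argmin oracle", {
  v <- c(0, 0, 6, 7, 8, 8, 2, 9)
  expect_equal(unname(find_vertical_bounds(v, 0.5)), c(2L, 6L))

  expect_error(find_vertical_bounds(rep(0, 8), 0.1),
               class = "cxr_segmentation_failure")

  # constant positive profile: top 0, bottom H-1 (ties toward the bottom)
  expect_equal(unname(find_vertical_bounds(rep(3, 9), 0.1)), c(0L, 8L))

  set.seed(17)
  kept <- 0
  for (i in 1:1000) {
    H <- sample(6:80, 1)
    v <- sample(0:12, H, replace = TRUE)
    ref <- suppressWarnings(tryCatch(oracle_vertical(v, 0.1),
                                     error = function(e) NULL))
    got <- tryCatch(unname(find_vertical_bounds(v, 0.1)),
                    error = function(e) NULL)
    if (is.null(ref) || ref[1] >= ref[2]) {
      expect_null(got)
    } else {
      expect_equal(got, ref)
      kept <- kept + 1
    }
  }
  expect_gt(kept, 500)   # the property suite mostly exercises the success path
})

test_that("crop boxes copy pixels unchanged and compose", {
  img <- random_gray(12, 10)
  full <- crop_box(0, 10, 0, 12, 12, 10)
  expect_identical(crop_to_box(img, full), img)

  one <- crop_box(3, 4, 5, 6)
  expect_equal(crop_to_box(img, one)[1, 1], img[6, 4])

  b1 <- crop_box(2, 9, 1, 11)
  b2 <- crop_box(1, 5, 2, 8)
  nested <- crop_to_box(crop_to_box(img, b1), b2)
  composed <- crop_box(b1$left + b2$left, b1$left + b2$right,
                       b1$top + b2$top, b1$top + b2$bottom)
  expect_identical(nested, crop_to_box(img, composed))

  expect_error(crop_box(5, 3, 0, 2), class = "cxr_param_error")
  expect_error(crop_to_box(img, crop_box(0, 11, 0, 12)),
               class = "cxr_param_error")
})

test_that("lower-half ROI keeps the bottom rows and resizes", {
  img <- random_gray(100, 80)
  roi <- extract_lower_half_roi(img)
  expect_identical(dim(roi), c(227L, 227L))

  const <- extract_lower_half_roi(matrix(0.3, 40, 30), c(64L, 64L))
  expect_equal(range(const), c(0.3, 0.3), tolerance = 1e-7)

  ab <- rbind(c(0.2, 0.2), c(0.8, 0.8))
  out <- extract_lower_half_roi(ab, c(8L, 8L))
  expect_true(all(abs(out - 0.8) < 1e-7))   # only the lower row survives

  expect_error(extract_lower_half_roi(matrix(0.1, 1, 5)),
               class = "cxr_param_error")
})

test_that("segmentation recovers phantom geometry and is flip-equivariant", {
  p <- generate_phantom(phantom_config(seed = 31, noise_sd = 0,
                                       illumination_tilt = 0))
  s <- segment(p$image)
  tb <- p$truth$lung_box
  expect_gte(box_iou(s$box, tb), 0.7)
  # lateral boundaries recovered to within 3 px of the lung edges
  expect_lte(abs(s$box$left - tb$left), 3)
  expect_lte(abs(s$box$right - tb$right), 3)
  expect_identical(dim(s$roi), c(227L, 227L))

  # flat image: no threshold crossing anywhere
  expect_error(segment(matrix(0.5, 64, 64)),
               class = "cxr_segmentation_failure")

  # horizontal mirror: box mirrors exactly, ROI mirrors up to resampling
  W <- ncol(p$image)
  sm <- segment(p$image[, W:1])
  expect_identical(sm$box$left, W - s$box$right)
  expect_identical(sm$box$right, W - s$box$left)
  expect_identical(sm$box$top, s$box$top)
  expect_identical(sm$box$bottom, s$box$bottom)
  expect_lt(max(abs(sm$roi[, ncol(sm$roi):1] - s$roi)), 0.05)

  # single-lung modes keep opposite halves of the crop
  sl <- segment(p$image, seg_params(single_lung = "left"))
  sr <- segment(p$image, seg_params(single_lung = "right"))
  expect_identical(sl$box, s$box)
  expect_false(isTRUE(all.equal(sl$roi, sr$roi)))

  # the crop never reads outside the source image
  expect_gte(s$box$left, 0)
  expect_gte(s$box$top, 0)
  expect_lte(s$box$right, W)
  expect_lte(s$box$bottom, nrow(p$image))
})
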