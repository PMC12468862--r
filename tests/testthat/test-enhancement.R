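test_that("histogram stretching maps the observed range onto [0, 1]", {
  toy <- matrix(c(0.2, 0.45, 0.7), 8, 9)
  out <- histogram_stretch(toy)
  expect_equal(sort(unique(as.vector(out))), c(0, 0.5, 1))

  full <- matrix(seq(0, 1, length.out = 64), 8, 8)
  expect_equal(histogram_stretch(full), full)

  set.seed(3)
  img <- random_gray(10, 10) * 0.4 + 0.3
  s1 <- histogram_stretch(img)
  expect_equal(min(s1), 0)
  expect_equal(max(s1), 1)
  expect_equal(histogram_stretch(s1), s1)                    # idempotent
  expect_true(all(diff(as.vector(s1)[order(as.vector(img))]) >= 0))

  expect_warning(out <- histogram_stretch(matrix(0.5, 8, 8)), "constant")
  expect_equal(out, matrix(0.5, 8, 8))
})

test_that("log transform is monotone and normalized", {
  expect_equal(log_transform(matrix(0, 8, 8)), matrix(0, 8, 8))
  two <- matrix(c(0, 1), 8, 8)
  expect_equal(sort(unique(as.vector(log_transform(two, 1)))), c(0, 1))
  img <- matrix(seq(0, 1, length.out = 64), 8, 8)
  out <- log_transform(img, 10)
  expect_true(all(diff(as.vector(out)) >= 0))
  expect_true(min(out) >= 0 && max(out) <= 1)
  expect_error(log_transform(img, -1), class = "cxr_param_error")
})

test_that("CLAHE clips tile histograms before the CDF mapping", {
  out <- clahe(matrix(0.5, 16, 16), ahe_params(2, 2, clip_limit = 0.02))
  expect_true(diff(range(out)) == 0)

  set.seed(8)
  img <- random_gray(16, 16)
  expect_equal(clahe(img, ahe_params(1, 1, clip_limit = 1)),
               adaptive_equalize(img, ahe_params(1, 1)), tolerance = 1e-12)

  # single-tile 8-level toy image against the hand clipped-HE oracle
  lv <- (0:7) / 8 + 0.01
  toy <- matrix(rep(lv, each = 8), 8, 8)
  got <- clahe(toy, ahe_params(1, 1, clip_limit = 0.05))
  expect_equal(as.vector(got), oracle_clipped_eq(as.vector(toy), 0.05),
               tolerance = 1e-12)

  expect_error(clahe(img, ahe_params(1, 1)), class = "cxr_param_error")
})

test_that("Sobel kernels and gradients match the printed operators", {
  k <- cxreffusion:::sobel_kernels()
  expect_identical(k$gx, matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3,
                                byrow = TRUE))
  expect_identical(k$gy, matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3,
                                byrow = TRUE))

  # a constant image has exactly zero gradient magnitude
  cfg <- sobel_config(gaussian_sigma = 0, combine_alpha = 0, combine_beta = 1)
  expect_equal(sobel_gradient(matrix(0.7, 9, 9), cfg), matrix(0, 9, 9))

  # vertical step edge: pure horizontal gradient, direction 0
  step <- cbind(matrix(0, 9, 5), matrix(1, 9, 4))
  cfg_dir <- sobel_config(gaussian_sigma = 0, compute_direction = TRUE,
                          combine_alpha = 0, combine_beta = 1)
  out <- sobel_gradient(step, cfg_dir)
  dir <- attr(out, "direction")
  gx <- oracle_correlate(step, k$gx)
  gy <- oracle_correlate(step, k$gy)
  expect_equal(max(abs(gy)), 0)
  expect_equal(dir[5, 5], 0)                      # interior on the edge
  expect_equal(matrix(as.numeric(out), 9, 9),
               sqrt(gx^2 + gy^2) / max(sqrt(gx^2 + gy^2)), tolerance = 1e-7)

  # horizontal ramp: constant interior gradient, checked against the
  # brute-force correlation oracle
  ramp <- matrix(rep(seq(0, 1, length.out = 12), each = 10), 10, 12)
  gxr <- oracle_correlate(ramp, k$gx)
  expect_lt(diff(range(gxr[3:8, 3:10])), 1e-12)
  got <- sobel_gradient(ramp, cfg)
  mag <- sqrt(gxr^2 + oracle_correlate(ramp, k$gy)^2)
  expect_equal(matrix(as.numeric(got), 10, 12), mag / max(mag),
               tolerance = 1e-7)

  # smoothing + blend stays inside [0, 1] on random images
  set.seed(23)
  for (i in 1:5) {
    r <- sobel_gradient(random_gray(16, 16), sobel_config())
    expect_true(min(r) >= 0 && max(r) <= 1)
  }
  expect_error(sobel_gradient(matrix(0.5, 2, 2)), class = "cxr_type_error")
})

test_that("unsharp masking overshoots at edges and fixes constants", {
  img <- random_gray(10, 10)
  expect_identical(sharpen(img, 0), img)
  expect_equal(sharpen(matrix(0.4, 10, 10), 2), matrix(0.4, 10, 10),
               tolerance = 1e-9)
  step <- cbind(matrix(0.2, 10, 6), matrix(0.7, 10, 6))
  sh <- sharpen(step, 1.5)
  expect_gt(max(sh), 0.7)          # overshoot above the bright plateau
  expect_lt(min(sh), 0.2)          # undershoot below the dark plateau
})

test_that("Canny produces thin hysteresis-linked edges", {
  expect_equal(canny(matrix(0.5, 16, 16)), matrix(0, 16, 16))

  step <- cbind(matrix(0.1, 16, 8), matrix(0.9, 16, 8))
  e <- canny(step, 0.2, 0.6)
  # a clean vertical step yields one thin vertical line: every interior
  # row crosses the edge in at most 2 adjacent columns
  interior <- e[4:13, ]
  expect_true(all(rowSums(interior) >= 1))
  expect_true(all(rowSums(interior) <= 2))
  edge_cols <- range(which(colSums(e) > 0))
  expect_lte(diff(edge_cols), 2)

  expect_error(canny(step, 0.6, 0.2), class = "cxr_param_error")
})

test_that("two-stage enhancement composes and flags stage errors", {
  img <- random_gray(12, 12)
  expect_identical(enhance(img, enhance_config("none", "none")), img)

  toy <- matrix(c(0.2, 0.45, 0.7), 9, 9)
  out <- enhance(toy, enhance_config("stretch", "none"))
  expect_equal(sort(unique(as.vector(out))), c(0, 0.5, 1))

  img64 <- random_gray(64, 64)   # large enough for the 8x8 CLAHE grid
  for (cm in c("none", "log", "clahe", "stretch")) {
    for (em in c("none", "sobel", "sobel_gradient", "sharpen", "canny")) {
      r <- enhance(img64, enhance_config(cm, em))
      expect_true(min(r) >= 0 && max(r) <= 1,
                  info = paste(cm, em))
    }
  }
  # stage errors carry the failing stage
  expect_error(enhance(random_gray(12, 12), enhance_config("clahe", "none")),
               class = "cxr_enhance_error")
})

test_that("gradient magnitude along the junction separates sharp from blunted angles", {
  pn <- generate_phantom(phantom_config(seed = 77, noise_sd = 0.01))
  pe <- generate_phantom(phantom_config(seed = 77, noise_sd = 0.01,
                                        effusion = TRUE, fill_level = 0.5,
                                        side = "right"))
  cfg <- sobel_config(gaussian_sigma = 1, combine_alpha = 0, combine_beta = 1)
  junction_mag <- function(p) {
    g <- sobel_gradient(histogram_stretch(p$image), cfg)
    rb <- p$truth$recess_right
    mean(crop_to_box(g, rb))
  }
  expect_gt(junction_mag(pn), junction_mag(pe))
})
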