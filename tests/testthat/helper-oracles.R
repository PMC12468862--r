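# Brute-force reference implementations used as independent oracles.
# All are written as direct loops over the defining formulas, never by
# calling the package's own code paths.

oracle_grayscale <- function(rgb, w = c(0.299, 0.587, 0.114)) {
  out <- matrix(0, dim(rgb)[1], dim(rgb)[2])
  for (i in seq_len(dim(rgb)[1])) for (j in seq_len(dim(rgb)[2])) {
    out[i, j] <- sum(w * rgb[i, j, ])
  }
  out
}

oracle_column_profile <- function(mask) {
  vapply(seq_len(ncol(mask)), function(j) sum(mask[, j]), numeric(1))
}

oracle_row_profile <- function(mask, band = seq_len(ncol(mask))) {
  vapply(seq_len(nrow(mask)), function(i) sum(mask[i, band]), numeric(1))
}

# exhaustive lateral search: argmin over each window, ties toward the edge
oracle_lateral <- function(v, f) {
  W <- length(v)
  lw <- floor(W * f); rs <- ceiling(W * (1 - f)); rs <- min(rs, W - 1)
  left_win <- v[1:lw]
  left <- min(which(left_win == min(left_win))) - 1L
  right_win <- v[(rs + 1):W]
  right <- rs + max(which(right_win == min(right_win))) - 1L
  c(left, right + 1L)
}

# exhaustive vertical search: first crossing from the top, argmin over
# the bottom window with ties toward the bottom
oracle_vertical <- function(v, thr, bottom_frac = 0.5) {
  H <- length(v)
  cut <- thr * max(v)
  top <- min(which(v > cut)) - 1L
  lo_start <- H - floor(H * bottom_frac) + 1L
  win <- v[lo_start:H]
  bottom <- lo_start + max(which(win == min(win))) - 2L
  c(top, bottom)
}

# set-arithmetic morphology with outside-is-background on both primitives
oracle_dilate <- function(mask, kern) {
  H <- nrow(mask); W <- ncol(mask); r <- (nrow(kern) - 1) / 2
  out <- matrix(FALSE, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    hit <- FALSE
    for (a in -r:r) for (b in -r:r) {
      if (kern[a + r + 1, b + r + 1] > 0) {
        ii <- i + a; jj <- j + b
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W && mask[ii, jj]) hit <- TRUE
      }
    }
    out[i, j] <- hit
  }
  out
}

oracle_erode <- function(mask, kern) {
  H <- nrow(mask); W <- ncol(mask); r <- (nrow(kern) - 1) / 2
  out <- matrix(FALSE, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    all_in <- TRUE
    for (a in -r:r) for (b in -r:r) {
      if (kern[a + r + 1, b + r + 1] > 0) {
        ii <- i + a; jj <- j + b
        if (!(ii >= 1 && ii <= H && jj >= 1 && jj <= W && mask[ii, jj])) {
          all_in <- FALSE
        }
      }
    }
    out[i, j] <- all_in
  }
  out
}

# direct correlation with edge replication
oracle_correlate <- function(img, kern) {
  H <- nrow(img); W <- ncol(img); r <- (nrow(kern) - 1) / 2
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (a in -r:r) for (b in -r:r) {
      ii <- min(max(i + a, 1), H); jj <- min(max(j + b, 1), W)
      acc <- acc + kern[a + r + 1, b + r + 1] * img[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

# classical histogram equalization with the midpoint-CDF convention
oracle_hist_eq <- function(vals, bins = 256) {
  h <- tabulate(pmin(bins, floor(vals * bins) + 1L), nbins = bins)
  cdf <- cumsum(h) / sum(h)
  m <- (cdf + c(0, cdf[-bins])) / 2
  m[pmin(bins, floor(vals * bins) + 1L)]
}

# clipped variant: cap each bin at clip * n, redistribute excess evenly
oracle_clipped_eq <- function(vals, clip, bins = 256) {
  n <- length(vals)
  h <- tabulate(pmin(bins, floor(vals * bins) + 1L), nbins = bins)
  cap <- clip * n
  excess <- sum(pmax(h - cap, 0))
  h <- pmin(h, cap) + excess / bins
  cdf <- cumsum(h) / sum(h)
  m <- (cdf + c(0, cdf[-bins])) / 2
  m[pmin(bins, floor(vals * bins) + 1L)]
}

oracle_confusion <- function(pred, truth, pos) {
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == pos && truth[i] == pos) tp <- tp + 1
    if (pred[i] == pos && truth[i] != pos) fp <- fp + 1
    if (pred[i] != pos && truth[i] == pos) fn <- fn + 1
    if (pred[i] != pos && truth[i] != pos) tn <- tn + 1
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# direct evaluation of the four standard metrics from one matrix
oracle_metrics <- function(tp, fp, fn, tn) {
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(accuracy = (tp + tn) / (tp + fp + fn + tn),
    precision = prec, recall = rec, f1 = f1)
}

random_mask <- function(H, W, p = 0.5) {
  matrix(runif(H * W) < p, H, W)
}

random_gray <- function(H, W) {
  matrix(runif(H * W), H, W)
}
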