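#' Round half up
#'
#' Decimal rounding with ties away from zero (base `round()` uses
#' banker's rounding), used when reconstructing report tables.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # small epsilon keeps exact decimal halves (e.g. 69.835) from falling
  # just below .5 in binary floating point
  sign(x) * floor(abs(x) * p + 0.5 + 1e-8) / p
}

#' Confusion counts for a binary classification
#'
#' Tallies true/false positives/negatives of `predicted` against `truth`
#' with an explicit positive class.
#'
#' @param predicted,truth equal-length label vectors over the same two
#'   classes.
#' @param positive the label counted as positive.
#' @return one-row tibble `tp, fp, fn, tn` of class `cxr_confusion`.
#' @export
confusion_counts <- function(predicted, truth, positive) {
  predicted <- as.character(predicted); truth <- as.character(truth)
  if (length(predicted) != length(truth) || length(truth) == 0L) {
    abort("`predicted` and `truth` must be equal-length, non-empty.",
          class = "cxr_input_error")
  }
  labs <- unique(c(predicted, truth))
  if (length(labs) > 2L || !positive %in% labs) {
    abort("labels must be binary and include the positive class.",
          class = "cxr_input_error")
  }
  p <- predicted == positive; t <- truth == positive
  out <- tibble::tibble(
    tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t), tn = sum(!p & !t)
  )
  class(out) <- c("cxr_confusion", class(out))
  out
}

safe_div <- function(num, den, what) {
  if (den == 0) {
    warn(sprintf("%s has a zero denominator; defining it as 0.", what))
    return(0)
  }
  num / den
}

metrics_one <- function(tp, fp, fn, tn) {
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  c(precision = precision, recall = recall, f1 = f1)
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' With `averaging = "per_positive_class"` the metrics are computed on
#' the given matrix directly: accuracy `(TP+TN)/N`, precision
#' `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1 the harmonic mean. With
#' `averaging = "macro"` (default) precision/recall/F1 are the unweighted
#' mean over both classes (the complementary class is the same matrix
#' with positives and negatives swapped); accuracy is global either way.
#' On exactly class-balanced truth labels macro recall equals accuracy.
#' Zero-denominator metrics are defined as 0 with a warning.
#'
#' @param cm a `cxr_confusion` (or any one-row data frame with columns
#'   `tp, fp, fn, tn`).
#' @param averaging `"macro"` or `"per_positive_class"`.
#' @return one-row tibble: `accuracy, precision, recall, f1, averaging`.
#' @export
classification_metrics <- function(cm, averaging = c("macro", "per_positive_class")) {
  averaging <- match.arg(averaging)
  if (is.null(cm) || nrow(cm) == 0L) {
    abort("empty confusion counts.", class = "cxr_input_error")
  }
  tp <- cm$tp[1]; fp <- cm$fp[1]; fn <- cm$fn[1]; tn <- cm$tn[1]
  n <- tp + fp + fn + tn
  if (n == 0) abort("no evaluated samples.", class = "cxr_input_error")
  accuracy <- (tp + tn) / n
  if (averaging == "per_positive_class") {
    m <- metrics_one(tp, fp, fn, tn)
  } else {
    m_pos <- metrics_one(tp, fp, fn, tn)
    m_neg <- metrics_one(tn, fn, fp, tp)   # swap positive/negative roles
    m <- (m_pos + m_neg) / 2
  }
  tibble::tibble(accuracy = accuracy, precision = m[["precision"]],
                 recall = m[["recall"]], f1 = m[["f1"]],
                 averaging = averaging)
}

#' Split specification
#'
#' @param train_fraction fraction of samples assigned to training,
#'   strictly in `(0, 1)`.
#' @param stratified draw the split per class (default).
#' @param seed RNG seed for the shuffle.
#' @return a `split_spec` list.
#' @export
split_spec <- function(train_fraction = 0.8, stratified = TRUE, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must be in (0, 1).", class = "cxr_param_error")
  }
  structure(list(train_fraction = train_fraction,
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "split_spec")
}

#' Stratified train/validation split
#'
#' Per class, `round(n * train_fraction)` samples (round to nearest, so
#' 461 at 0.8 gives 369 training and 92 validation) go to training and
#' the rest to validation; the partition is disjoint, exhaustive and
#' reproducible from `spec$seed`.
#'
#' @param manifest a data frame with a `label` column.
#' @param spec a [split_spec()].
#' @return list of tibbles `train` and `validation`.
#' @export
stratified_split <- function(manifest, spec = split_spec()) {
  if (!"label" %in% names(manifest)) {
    abort("`manifest` must have a `label` column.", class = "cxr_input_error")
  }
  counts <- table(manifest$label)
  if (any(counts < 2L)) {
    abort("every class needs at least 2 samples to split.",
          class = "cxr_input_error")
  }
  groups <- if (spec$stratified) split(seq_len(nrow(manifest)), manifest$label)
            else list(all = seq_len(nrow(manifest)))
  train_idx <- with_seed(spec$seed, {
    unlist(lapply(groups, function(ix) {
      n_tr <- floor(length(ix) * spec$train_fraction + 0.5)
      n_tr <- min(max(n_tr, 1L), length(ix) - 1L)
      sample(ix, n_tr)
    }), use.names = FALSE)
  })
  list(train = tibble::as_tibble(manifest[sort(train_idx), , drop = FALSE]),
       validation = tibble::as_tibble(
         manifest[setdiff(seq_len(nrow(manifest)), train_idx), , drop = FALSE]))
}

#' Stratified k-fold assignment
#'
#' @param labels class label vector.
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return integer fold index (1..k) per sample.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  if (k < 2L) abort("`k` must be >= 2.", class = "cxr_input_error")
  if (any(table(labels) < k)) {
    abort("every class needs at least k samples.", class = "cxr_input_error")
  }
  fold <- integer(length(labels))
  with_seed(seed, {
    for (lab in unique(labels)) {
      ix <- which(labels == lab)
      fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
    }
  })
  fold
}

#' Training configuration
#'
#' `learning_rate`, `batch_size` and `epochs` are the defaults for
#' gradient-trained deep backbones. The reference `tinycnn` backbone
#' (fixed convolutional filter bank + regularized logistic readout) has
#' a closed-form training path and uses `l2_lambda` instead; the
#' gradient hyperparameters are recorded but inert for it.
#'
#' @param learning_rate gradient-descent step size.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param backbone classifier backbone name; see
#'   [available_backbones()].
#' @param l2_lambda ridge penalty of the tinycnn readout.
#' @param seed training seed.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-5, batch_size = 32L,
                         epochs = 20L, backbone = "tinycnn",
                         l2_lambda = 0.01, seed = 1L) {
  if (learning_rate <= 0 || batch_size < 1L || epochs < 1L || l2_lambda < 0) {
    abort("hyperparameters must be positive.", class = "cxr_param_error")
  }
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), backbone = backbone,
                 l2_lambda = l2_lambda, seed = as.integer(seed)),
            class = "train_config")
}

REGISTERED_BACKBONES <- c("tinycnn", "efficientnet_b0", "mobilenet_v3",
                          "squeezenet", "darknet19", "alexnet")

#' Available classifier backbones
#'
#' The backbone interface is pluggable; this build ships the desk-scale
#' `tinycnn` reference backbone. Deep backbones are registered names
#' that require an external deep-learning runtime and raise a capability
#' error when requested.
#'
#' @return character vector of backbones usable in this installation.
#' @export
available_backbones <- function() "tinycnn"

check_backbone <- function(backbone) {
  if (!backbone %in% REGISTERED_BACKBONES) {
    abort(sprintf("unknown backbone '%s'; registered: %s", backbone,
                  paste(REGISTERED_BACKBONES, collapse = ", ")),
          class = "cxr_capability_error")
  }
  if (!backbone %in% available_backbones()) {
    abort(sprintf(
      "backbone '%s' needs a deep-learning runtime that is not installed; available: %s",
      backbone, paste(available_backbones(), collapse = ", ")),
      class = "cxr_capability_error")
  }
  invisible(backbone)
}

#' Pipeline configuration: segmentation + enhancement
#'
#' @param seg a [seg_params()].
#' @param enh an [enhance_config()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seg = seg_params(), enh = enhance_config()) {
  structure(list(seg = seg, enh = enh), class = "pipeline_config")
}

# segment + enhance one image; a segmentation failure falls back to the
# full-image box so batch evaluation never aborts (the fallback is flagged)
pipeline_roi <- function(img, pcfg) {
  res <- tryCatch(segment(img, pcfg$seg), cxr_segmentation_failure = function(e) NULL)
  fallback <- is.null(res)
  if (fallback) {
    box <- crop_box(0L, ncol(img), 0L, nrow(img),
                    source_height = nrow(img), source_width = ncol(img))
    lung <- img
    if (pcfg$seg$single_lung != "none") {
      mid <- floor(ncol(lung) / 2)
      lung <- if (pcfg$seg$single_lung == "left") lung[, seq_len(mid), drop = FALSE]
              else lung[, (mid + 1L):ncol(lung), drop = FALSE]
    }
    roi <- extract_lower_half_roi(lung, pcfg$seg$output_size)
    res <- list(roi = roi, box = box)
  }
  roi <- enhance(res$roi, pcfg$enh)
  list(roi = roi, box = res$box, fallback = fallback)
}

# tinycnn convolutional feature extractor: a fixed, seeded bank of
# zero-mean 5x5 filters + ReLU + 6x6 spatial average pooling, alongside
# a 6x6 average-pooled intensity map. 8*36 + 36 = 324 features.
TINYCNN_FILTER_SEED <- 490301L
TINYCNN_N_FILTERS <- 8L
TINYCNN_POOL <- 6L

tinycnn_filters <- function() {
  with_seed(TINYCNN_FILTER_SEED, {
    lapply(seq_len(TINYCNN_N_FILTERS), function(i) {
      f <- matrix(rnorm(25), 5, 5)
      f <- f - mean(f)
      f / sqrt(sum(f^2))
    })
  })
}

pool_grid <- function(x, g) {
  H <- nrow(x); W <- ncol(x)
  rb <- round(seq(0, H, length.out = g + 1))
  cb <- round(seq(0, W, length.out = g + 1))
  out <- matrix(0, g, g)
  for (a in seq_len(g)) for (b in seq_len(g)) {
    out[a, b] <- mean(x[(rb[a] + 1):rb[a + 1], (cb[b] + 1):cb[b + 1]])
  }
  as.vector(out)
}

tinycnn_features <- function(roi, filters) {
  feats <- unlist(lapply(filters, function(f) {
    r <- correlate_replicate(roi, f)
    pool_grid(pmax(r, 0), TINYCNN_POOL)
  }))
  c(feats, pool_grid(roi, TINYCNN_POOL))
}

manifest_images <- function(manifest) {
  if ("image" %in% names(manifest)) return(manifest$image)
  if (!"filename" %in% names(manifest)) {
    abort("manifest needs an `image` list-column or a `filename` column.",
          class = "cxr_input_error")
  }
  lapply(manifest$filename, read_cxr_image, as = "gray")
}

extract_feature_matrix <- function(manifest, pcfg, filters) {
  imgs <- manifest_images(manifest)
  t(vapply(imgs, function(im) {
    roi <- pipeline_roi(im, pcfg)$roi
    tinycnn_features(roi, filters)
  }, numeric(TINYCNN_N_FILTERS * TINYCNN_POOL^2 + TINYCNN_POOL^2)))
}

fit_head <- function(x, y, positive, lambda) {
  yy <- as.integer(y == positive)
  # desk-scale folds legitimately drop below glmnet's small-class
  # heuristic; the ridge penalty keeps the fit well-posed regardless
  suppressWarnings(
    glmnet::glmnet(x, yy, family = "binomial", alpha = 0,
                   lambda = lambda, standardize = TRUE)
  )
}

#' Train a classifier on a labelled set
#'
#' Runs every training image through the segmentation + enhancement
#' pipeline, extracts tinycnn convolutional features from the ROI and
#' fits the regularized logistic readout. Deterministic given the
#' configuration (the filter bank is a seeded constant and the readout
#' fit is deterministic).
#'
#' @param train manifest tibble (with `image` list-column or `filename`
#'   paths) including `label`.
#' @param pcfg a [pipeline_config()].
#' @param tcfg a [train_config()].
#' @param positive positive-class label (default `"effusion"`).
#' @return a `cxr_classifier` handle.
#' @export
train_classifier <- function(train, pcfg = pipeline_config(),
                             tcfg = train_config(), positive = "effusion") {
  check_backbone(tcfg$backbone)
  if (nrow(train) == 0L) abort("empty training set.", class = "cxr_input_error")
  filters <- tinycnn_filters()
  x <- extract_feature_matrix(train, pcfg, filters)
  fit <- fit_head(x, train$label, positive, tcfg$l2_lambda)
  structure(
    list(backbone = tcfg$backbone, filters = filters, fit = fit,
         positive = positive,
         negative = setdiff(unique(train$label), positive)[1],
         pipeline = pcfg, train_config = tcfg),
    class = "cxr_classifier"
  )
}

#' @export
print.cxr_classifier <- function(x, ...) {
  cat(sprintf("<%s classifier, positive class '%s'>\n", x$backbone, x$positive))
  invisible(x)
}

#' Predict labels for a manifest
#'
#' @param object a `cxr_classifier`.
#' @param newdata manifest tibble with images.
#' @param ... unused.
#' @return tibble with `prob` (positive-class probability) and
#'   `predicted` label per row.
#' @export
predict.cxr_classifier <- function(object, newdata, ...) {
  x <- extract_feature_matrix(newdata, object$pipeline, object$filters)
  p <- as.numeric(predict(object$fit, newx = x, type = "response"))
  tibble::tibble(
    prob = p,
    predicted = ifelse(p >= 0.5, object$positive, object$negative)
  )
}

#' Stratified k-fold cross-validation
#'
#' Partitions the manifest into k stratified folds; for each fold,
#' trains the readout on the other k-1 folds and evaluates on the held
#' fold. ROI features are extracted once per image (the pipeline is
#' deterministic and label-free) and reused across folds.
#'
#' @param manifest labelled manifest tibble with images.
#' @param k number of folds (default 5).
#' @param pcfg a [pipeline_config()].
#' @param tcfg a [train_config()].
#' @param seed fold-assignment seed.
#' @param positive positive-class label.
#' @param averaging metric averaging mode.
#' @return a `cxr_fold_report`: list with `folds` (per-fold metric
#'   tibble), `mean`, `sd`, `k`, `fold_assignment`.
#' @export
kfold_cross_validate <- function(manifest, k = 5L, pcfg = pipeline_config(),
                                 tcfg = train_config(), seed = 1L,
                                 positive = "effusion",
                                 averaging = c("macro", "per_positive_class")) {
  averaging <- match.arg(averaging)
  check_backbone(tcfg$backbone)
  fold <- stratified_folds(manifest$label, k, seed)
  filters <- tinycnn_filters()
  x <- extract_feature_matrix(manifest, pcfg, filters)
  negative <- setdiff(unique(manifest$label), positive)[1]
  per_fold <- purrr::map_dfr(seq_len(k), function(f) {
    tr <- fold != f; va <- !tr
    fit <- fit_head(x[tr, , drop = FALSE], manifest$label[tr], positive,
                    tcfg$l2_lambda)
    p <- as.numeric(predict(fit, newx = x[va, , drop = FALSE],
                            type = "response"))
    pred <- ifelse(p >= 0.5, positive, negative)
    cm <- confusion_counts(pred, manifest$label[va], positive)
    dplyr::mutate(classification_metrics(cm, averaging), fold = f,
                  n_validation = sum(va), .before = 1)
  })
  mets <- c("accuracy", "precision", "recall", "f1")
  structure(
    list(folds = per_fold,
         mean = vapply(mets, function(m) mean(per_fold[[m]]), numeric(1)),
         sd = vapply(mets, function(m) sd(per_fold[[m]]), numeric(1)),
         k = k, fold_assignment = fold, averaging = averaging),
    class = "cxr_fold_report"
  )
}

#' @export
print.cxr_fold_report <- function(x, ...) {
  cat(sprintf("<%d-fold cross-validation (%s averaging)>\n", x$k, x$averaging))
  for (m in names(x$mean)) {
    cat(sprintf("  %-9s %.2f%% +/- %.2f\n", m, 100 * x$mean[[m]],
                100 * x$sd[[m]]))
  }
  invisible(x)
}

#' Average-lung column reconstruction
#'
#' The single-lung summary column is the arithmetic mean of the left-
#' and right-lung columns, rounded half up to `digits` decimals on the
#' percent scale.
#'
#' @param left,right numeric metric vectors on the percent scale.
#' @param digits decimals kept.
#' @return numeric vector of column means.
#' @export
average_lung_metrics <- function(left, right, digits = 2) {
  round_half_up((left + right) / 2, digits)
}

#' Run a comparison experiment over a configuration grid
#'
#' One stratified k-fold cross-validation per grid cell. A cell is
#' either a [pipeline_config()] or one of the input-mode shortcuts
#' `"left_lung"`, `"right_lung"`, `"whole_lung"` (single-lung cropping
#' with default enhancement). When both `left_lung` and `right_lung`
#' are present, an `average_lungs` column (the half-up rounded column
#' mean) is appended. Per-cell failures are recorded and do not abort
#' the remaining cells.
#'
#' @param manifest labelled manifest with images.
#' @param grid named list of cells.
#' @param tcfg a [train_config()].
#' @param k folds per cell.
#' @param seed seed shared by every cell.
#' @param averaging metric averaging mode.
#' @return a `cxr_comparison`: list with `table` (long tibble: method,
#'   metric, mean, sd), `wide` (metrics x methods, percent, 2 decimals),
#'   `reports`, `errors`.
#' @export
run_comparison <- function(manifest, grid, tcfg = train_config(), k = 5L,
                           seed = 1L, averaging = "macro") {
  if (is.null(names(grid)) || any(names(grid) == "")) {
    abort("`grid` must be a fully named list.", class = "cxr_input_error")
  }
  cells <- lapply(grid, function(cell) {
    if (is.character(cell)) {
      switch(cell,
        left_lung  = pipeline_config(seg = seg_params(single_lung = "left")),
        right_lung = pipeline_config(seg = seg_params(single_lung = "right")),
        whole_lung = pipeline_config(),
        abort(sprintf("unknown input mode '%s'.", cell),
              class = "cxr_input_error"))
    } else if (inherits(cell, "enhance_config")) {
      pipeline_config(enh = cell)
    } else cell
  })
  reports <- list(); errors <- list()
  for (nm in names(cells)) {
    reports[[nm]] <- tryCatch(
      kfold_cross_validate(manifest, k = k, pcfg = cells[[nm]], tcfg = tcfg,
                           seed = seed, averaging = averaging),
      error = function(e) {
        errors[[nm]] <<- conditionMessage(e)
        NULL
      })
  }
  ok <- !vapply(reports, is.null, logical(1))
  long <- purrr::map_dfr(names(reports)[ok], function(nm) {
    r <- reports[[nm]]
    tibble::tibble(method = nm, metric = names(r$mean),
                   mean = unname(r$mean), sd = unname(r$sd))
  })
  wide <- tidyr::pivot_wider(
    dplyr::mutate(long, pct = round_half_up(100 * .data$mean, 2)),
    id_cols = "metric", names_from = "method", values_from = "pct")
  if (all(c("left_lung", "right_lung") %in% names(wide))) {
    wide <- dplyr::mutate(
      wide,
      average_lungs = average_lung_metrics(.data$left_lung, .data$right_lung),
      .after = "right_lung")
  }
  structure(list(table = long, wide = wide, reports = reports,
                 errors = errors, k = k, seed = seed),
            class = "cxr_comparison")
}

#' @export
print.cxr_comparison <- function(x, ...) {
  cat(sprintf("<comparison over %d methods, %d-fold CV, seed %d>\n",
              length(x$reports), x$k, x$seed))
  print(x$wide)
  if (length(x$errors)) {
    cat("failed cells:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a comparison table as CSV (metrics as rows, methods as columns)
#'
#' @param comparison a `cxr_comparison`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(comparison, path) {
  utils::write.csv(comparison$wide, path, row.names = FALSE)
  invisible(path)
}
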