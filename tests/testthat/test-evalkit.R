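test_that("confusion counts equal the exhaustive pairwise tally", {
  cm <- confusion_counts(c("+", "+", "-", "-"), c("+", "+", "-", "-"), "+")
  expect_equal(unlist(cm[1, ]), c(tp = 2L, fp = 0L, fn = 0L, tn = 2L))

  cm2 <- confusion_counts(c("+", "+"), c("+", "-"), "+")
  expect_equal(cm2$tp, 1); expect_equal(cm2$fp, 1)

  set.seed(29)
  for (i in 1:20) {
    pred <- sample(c("a", "b"), 50, replace = TRUE)
    truth <- sample(c("a", "b"), 50, replace = TRUE)
    got <- confusion_counts(pred, truth, "a")
    ref <- oracle_confusion(pred, truth, "a")
    expect_equal(unlist(got[1, ]), ref)
    expect_equal(sum(unlist(got[1, ])), 50)
  }
  expect_error(confusion_counts("a", c("a", "b"), "a"),
               class = "cxr_input_error")
  expect_error(confusion_counts(c("a", "b", "c"), c("a", "b", "c"), "a"),
               class = "cxr_input_error")
})

test_that("metric arithmetic follows the confusion-matrix definitions", {
  cm <- tibble::tibble(tp = 3, fp = 1, fn = 2, tn = 4)
  m <- classification_metrics(cm, "per_positive_class")
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 / 3, tolerance = 1e-12)

  perfect <- classification_metrics(tibble::tibble(tp = 5, fp = 0, fn = 0,
                                                   tn = 5))
  expect_true(all(unlist(perfect[1, 1:4]) == 1))

  # random-count property: per-positive metrics equal the arithmetic
  # oracle; macro recall equals accuracy on balanced truth labels
  set.seed(31)
  for (i in 1:1000) {
    cts <- sample(0:30, 4, replace = TRUE)
    if (sum(cts) == 0) next
    cm <- tibble::tibble(tp = cts[1], fp = cts[2], fn = cts[3], tn = cts[4])
    m <- suppressWarnings(classification_metrics(cm, "per_positive_class"))
    ref <- oracle_metrics(cts[1], cts[2], cts[3], cts[4])
    expect_equal(unlist(m[1, 1:4]), ref, tolerance = 1e-12)
  }
  for (i in 1:200) {
    npos <- sample(1:40, 1)
    tp <- sample(0:npos, 1); tn <- sample(0:npos, 1)
    cm <- tibble::tibble(tp = tp, fn = npos - tp, tn = tn, fp = npos - tn)
    m <- suppressWarnings(classification_metrics(cm, "macro"))
    expect_equal(m$recall, m$accuracy, tolerance = 1e-12)
  }

  expect_warning(z <- classification_metrics(
    tibble::tibble(tp = 0, fp = 0, fn = 3, tn = 4), "per_positive_class"),
    "zero denominator")
  expect_equal(z$precision, 0)
  expect_error(classification_metrics(tibble::tibble()),
               class = "cxr_input_error")
})

test_that("stratified splitting reproduces per-class rounding exactly", {
  man <- tibble::tibble(id = 1:922,
                        label = rep(c("normal", "effusion"), each = 461))
  sp <- stratified_split(man, split_spec(0.8, seed = 7))
  expect_equal(nrow(sp$train), 738)
  expect_equal(nrow(sp$validation), 184)
  expect_equal(as.integer(table(sp$train$label)), c(369L, 369L))
  expect_equal(as.integer(table(sp$validation$label)), c(92L, 92L))
  # disjoint and exhaustive
  expect_length(intersect(sp$train$id, sp$validation$id), 0)
  expect_setequal(c(sp$train$id, sp$validation$id), man$id)

  small <- tibble::tibble(id = 1:20, label = rep(c("a", "b"), each = 10))
  ss <- stratified_split(small, split_spec(0.8, seed = 1))
  expect_equal(as.integer(table(ss$train$label)), c(8L, 8L))
  expect_equal(as.integer(table(ss$validation$label)), c(2L, 2L))

  # per-class proportions deviate from the target by less than 1 sample
  set.seed(33)
  for (i in 1:20) {
    n1 <- sample(5:60, 1); n2 <- sample(5:60, 1)
    f <- runif(1, 0.5, 0.9)
    m <- tibble::tibble(label = rep(c("x", "y"), c(n1, n2)))
    s <- stratified_split(m, split_spec(f, seed = i))
    tr <- table(factor(s$train$label, c("x", "y")))
    expect_lt(abs(tr[["x"]] - n1 * f), 1)
    expect_lt(abs(tr[["y"]] - n2 * f), 1)
  }
  expect_error(stratified_split(tibble::tibble(label = c("a", "a", "b")),
                                split_spec()),
               class = "cxr_input_error")
})

test_that("k-fold assignment is a stratified disjoint cover", {
  labels <- rep(c("n", "e"), each = 25)
  fold <- stratified_folds(labels, 5, seed = 3)
  expect_equal(sort(unique(fold)), 1:5)
  # every sample in exactly one fold; strata balanced per fold
  expect_equal(length(fold), 50)
  for (f in 1:5) {
    expect_equal(sum(fold == f & labels == "n"), 5)
    expect_equal(sum(fold == f & labels == "e"), 5)
  }
  expect_identical(stratified_folds(labels, 5, seed = 3), fold)
  expect_error(stratified_folds(c("a", "b"), 5), class = "cxr_input_error")
})

test_that("average-lung column is the half-up rounded column mean", {
  expect_equal(round_half_up(69.835, 2), 69.84)
  expect_equal(round_half_up(81.245, 2), 81.25)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(average_lung_metrics(c(66.30, 79.87), c(73.37, 82.62)),
               c(69.84, 81.25))
})

test_that("the classifier fits the training set and is deterministic", {
  man <- generate_dataset(10, seed = 51)
  model <- train_classifier(man)
  pr1 <- predict(model, man)
  expect_gte(mean(pr1$predicted == man$label), 0.9)   # fit-to-train sanity
  model2 <- train_classifier(man)
  expect_identical(pr1, predict(model2, man))

  expect_error(train_classifier(man, tcfg = train_config(backbone = "alexnet")),
               class = "cxr_capability_error")
  expect_error(train_classifier(man, tcfg = train_config(backbone = "resnet")),
               class = "cxr_capability_error")
  err <- tryCatch(
    train_classifier(man, tcfg = train_config(backbone = "efficientnet_b0")),
    error = function(e) conditionMessage(e))
  expect_match(err, "tinycnn")   # capability errors list what is installed
})

test_that("cross-validation partitions cleanly and learns the phantoms", {
  man <- generate_dataset(15, seed = 61)
  rep <- kfold_cross_validate(man, k = 3, seed = 61)
  expect_equal(nrow(rep$folds), 3)
  expect_equal(sum(rep$folds$n_validation), 30)
  # each sample validated exactly once
  expect_equal(sort(unique(rep$fold_assignment)), 1:3)
  expect_equal(length(rep$fold_assignment), 30)
  expect_gte(rep$mean[["accuracy"]], 0.8)
  expect_true(rep$mean[["accuracy"]] >= min(rep$folds$accuracy) &&
              rep$mean[["accuracy"]] <= max(rep$folds$accuracy))
  # deterministic under the same seed
  rep2 <- kfold_cross_validate(man, k = 3, seed = 61)
  expect_identical(rep$folds, rep2$folds)

  td <- tidy(rep)
  expect_identical(td, rep$folds)
  gl <- glance(rep)
  expect_equal(gl$accuracy, rep$mean[["accuracy"]])

  expect_error(kfold_cross_validate(man, k = 40, seed = 1),
               class = "cxr_input_error")
})

test_that("comparison grids mirror single runs and build the average column", {
  man <- generate_dataset(10, seed = 71)
  cmp <- run_comparison(man, list(whole = pipeline_config()), k = 3, seed = 71)
  single <- kfold_cross_validate(man, k = 3, seed = 71)
  expect_equal(cmp$table$mean[cmp$table$metric == "accuracy"],
               unname(single$mean[["accuracy"]]))

  cmp2 <- run_comparison(man, list(left_lung = "left_lung",
                                   right_lung = "right_lung"),
                         k = 3, seed = 71)
  expect_true("average_lungs" %in% names(cmp2$wide))
  expect_equal(cmp2$wide$average_lungs,
               average_lung_metrics(cmp2$wide$left_lung,
                                    cmp2$wide$right_lung))
  # determinism of the whole table
  cmp3 <- run_comparison(man, list(left_lung = "left_lung",
                                   right_lung = "right_lung"),
                         k = 3, seed = 71)
  expect_identical(cmp2$table, cmp3$table)

  expect_error(run_comparison(man, list(pipeline_config())),
               class = "cxr_input_error")
})
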