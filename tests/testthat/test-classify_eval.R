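test_that("metric identities hold on random confusion matrices", {
  set.seed(11)
  for (i in 1:25) {
    cm <- new_confusion(TP = rpois(1, 20), FP = rpois(1, 8),
                        TN = rpois(1, 15), FN = rpois(1, 6))
    m <- classification_metrics(cm)
    if (!is.na(m$PPV)) expect_equal(m$FDR + m$PPV, 1)
    if (!is.na(m$SPC)) expect_equal(m$FPR + m$SPC, 1)
    expect_equal(m$ACC, (cm$TP + cm$TN) / (cm$P + cm$N))
    if (!is.na(m$F1) && !is.na(m$HM)) expect_equal(m$F1, m$HM)
    rates <- as.numeric(m[1, setdiff(names(m), "AUC")])
    expect_true(all(is.na(rates) | (rates >= 0 & rates <= 1)))
  }
})

test_that("a perfect classifier scores 1 on every indicator", {
  cm <- new_confusion(TP = 35, FP = 0, TN = 28, FN = 0)
  m <- classification_metrics(cm, scores = c(rep(1, 35), rep(0, 28)),
                              truth = rep(c("normal", "abnormal"), c(35, 28)))
  expect_equal(as.numeric(m[, c("TPR", "PPV", "F1", "HM", "SPC",
                                "NPV", "ACC", "AUC")]),
               rep(1, 8))
  expect_equal(m$FDR, 0); expect_equal(m$FPR, 0)
})

test_that("hand-evaluated confusion matrix reproduces the rate formulas", {
  m <- classification_metrics(new_confusion(TP = 3, FP = 1, TN = 3, FN = 1))
  expect_equal(m$TPR, 0.75); expect_equal(m$PPV, 0.75)
  expect_equal(m$ACC, 0.75); expect_equal(m$F1, 0.75)
  expect_equal(m$SPC, 0.75); expect_equal(m$NPV, 0.75)
  expect_equal(m$FDR, 0.25); expect_equal(m$FPR, 0.25)
  expect_true(is.na(m$AUC))  # undefined without scores, not silently 0

  # zero denominators are NA, never 0
  m0 <- classification_metrics(new_confusion(TP = 0, FP = 0, TN = 5, FN = 0))
  expect_true(is.na(m0$TPR)); expect_true(is.na(m0$PPV))

  expect_error(new_confusion(TP = -1, FP = 0, TN = 0, FN = 0), "negative")
})

test_that("AUC is the Mann-Whitney rank statistic with midrank ties", {
  truth <- rep(c("normal", "abnormal"), c(4, 4))
  m <- classification_metrics(new_confusion(4, 0, 4, 0),
                              scores = c(rep(1, 4), rep(0, 4)), truth = truth)
  expect_equal(m$AUC, 1)
  # all-tied scores: AUC 0.5
  m <- classification_metrics(new_confusion(4, 0, 4, 0),
                              scores = rep(0.3, 8), truth = truth)
  expect_equal(m$AUC, 0.5)
})

test_that("zsi is the Dice overlap with its edge cases", {
  a <- make_disk(30, 30, 14, 14, 8)
  expect_equal(zsi(a, a), 1)
  b <- matrix(0L, 30, 30); b[1:3, 1:3] <- 1L
  expect_equal(zsi(a, b), 0)

  # |A1| = |A2| = 100, overlap 60 -> 0.6
  a1 <- matrix(0L, 20, 20); a1[1:10, 1:10] <- 1L
  a2 <- matrix(0L, 20, 20); a2[1:10, 5:14] <- 1L
  expect_equal(zsi(a1, a2), 0.6)
  expect_equal(zsi(a2, a1), zsi(a1, a2))

  expect_error(zsi(a, matrix(0L, 10, 10)), "different shapes")
  expect_error(zsi(matrix(0L, 5, 5), matrix(0L, 5, 5)), "Undefined ZSI")
})

test_that("two-fold splits are stratified, balanced and seeded", {
  labels <- rep(c("normal", "abnormal"), c(35, 28))
  f <- split_two_fold(labels, seed = 3)
  expect_setequal(unique(f), 1:2)
  expect_equal(sort(as.vector(table(f))), c(31L, 32L))
  for (cl in c("normal", "abnormal"))
    expect_lte(abs(diff(table(f[labels == cl]))), 1)
  expect_identical(f, split_two_fold(labels, seed = 3))
  expect_false(identical(f, split_two_fold(labels, seed = 4)))

  f4 <- split_two_fold(c("a", "a", "b", "b"), seed = 0)
  expect_equal(as.vector(table(f4)), c(2L, 2L))
  expect_equal(as.vector(table(f4[1:2])), c(1L, 1L))  # one of each class per fold

  expect_error(split_two_fold(c("a", "b", "b")), "Stratification error")
})

test_that("every feature learner separates linearly separable data", {
  set.seed(21)
  n <- 30
  data <- tibble::tibble(
    label = rep(c("normal", "abnormal"), each = n),
    f1 = c(rnorm(n, 3, 0.5), rnorm(n, -3, 0.5)),
    f2 = rnorm(2 * n))
  for (kind in c("forest", "mlp", "bayes")) {
    folds <- split_two_fold(data$label, 1)
    pred <- train_predict(classifier_spec(kind, seed = 1),
                          data[folds == 1, ], data[folds == 2, ])
    expect_equal(mean(as.character(pred) == data$label[folds == 2]), 1,
                 info = kind)
    expect_length(attr(pred, "scores"), sum(folds == 2))
  }
})

test_that("forest importance ranks the label-defining feature first", {
  set.seed(22)
  n <- 40
  data <- tibble::tibble(
    label = ifelse(rnorm(n) > 0, "normal", "abnormal"),
    noise1 = rnorm(n), noise2 = rnorm(n))
  data$signal <- ifelse(data$label == "normal", 1, -1) + rnorm(n, 0, 0.1)
  pred <- train_predict(classifier_spec("forest", seed = 2), data, data)
  imp <- randomForest::importance(attr(pred, "fit"))
  expect_equal(rownames(imp)[which.max(imp[, "MeanDecreaseGini"])], "signal")
})

test_that("degenerate train/test sets are handled per contract", {
  data <- tibble::tibble(label = rep("normal", 5), f1 = rnorm(5))
  expect_error(train_predict(classifier_spec("forest"), data, data),
               "single class")
  ok <- tibble::tibble(label = rep(c("normal", "abnormal"), 3), f1 = rnorm(6))
  pred <- train_predict(classifier_spec("forest", seed = 0), ok, ok[0, ])
  expect_length(pred, 0)
  expect_length(attr(pred, "scores"), 0)
})

test_that("cross_validate tests every sample once and tidies", {
  set.seed(23)
  data <- tibble::tibble(
    id = sprintf("s%02d", 1:24),
    label = rep(c("normal", "abnormal"), each = 12),
    f1 = c(rnorm(12, 2), rnorm(12, -2)))
  cv <- cross_validate(data, classifier_spec("bayes", seed = 1), seed = 5)
  expect_s3_class(cv, "thermo_cv")
  expect_equal(sort(cv$predictions$id), sort(data$id))
  expect_equal(cv$cm$P + cv$cm$N, 24)
  expect_equal(cv$metrics$ACC, 1)

  td <- tidy(cv)
  expect_equal(nrow(td), 2)
  expect_equal(sum(td$TP + td$FP + td$TN + td$FN), 24)
  gl <- glance(cv)
  expect_equal(gl$kind, "bayes")
  expect_equal(gl$ACC, 1)

  # same seeds reproduce the same folds and predictions
  cv2 <- cross_validate(data, classifier_spec("bayes", seed = 1), seed = 5)
  expect_identical(cv$folds, cv2$folds)
  expect_equal(cv$predictions$score, cv2$predictions$score)
})

test_that("the conv net learns a hot-spot asymmetry quickly", {
  ds <- make_dataset(6, 6, seed = 13)
  dimg <- cnn_image_data(ds, function(s)
    segmented_input(s$image, s$left_mask, s$right_mask))
  folds <- split_two_fold(dimg$label, 1)
  pred <- train_predict(classifier_spec("cnn", seed = 1, side = 32L),
                        dimg[folds == 1, ], dimg[folds == 2, ])
  expect_gte(mean(as.character(pred) == dimg$label[folds == 2]), 5 / 6)
  # seeded training is reproducible
  pred2 <- train_predict(classifier_spec("cnn", seed = 1, side = 32L),
                         dimg[folds == 1, ], dimg[folds == 2, ])
  expect_equal(attr(pred, "scores"), attr(pred2, "scores"))
})
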