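# The default bucket under its shared contract: fit on labelled features,
# emit per-row a +/-1 label and a [0,1] posterior for the predicted class.

train_test <- function(sep = 10, n = 25, dims = 8, seed = 42) {
  fs <- synth_features(synth_feature_spec(n, dims = dims, class_separation = sep,
                                          seed = seed))[[1]]
  sp <- split_ids(fs$id, 0.8, seed = 3)
  list(train = fs[fs$id %in% sp$train, ], test = fs[fs$id %in% sp$test, ])
}

test_that("the default bucket matches the five configured rows", {
  bucket <- default_bucket()
  expect_length(bucket, 5)
  ids <- vapply(bucket, `[[`, character(1), "id")
  expect_equal(anyDuplicated(ids), 0L)
  fam <- vapply(bucket, `[[`, character(1), "family")
  expect_equal(sort(fam), sort(c("svm", "svm", "llp", "knn", "knn")))
  expect_equal(bucket[[1]]$params$kernel, "polynomial")
  expect_equal(bucket[[1]]$params$kernel_scale, "auto")
  expect_equal(bucket[[2]]$params$kernel, "gaussian")
  expect_equal(bucket[[3]]$params[c("C", "init", "maxiter")],
               list(C = 1, init = 0, maxiter = 1000))
  expect_equal(bucket[[4]]$params, list(k = 3, distance = "spearman"))
  expect_equal(bucket[[5]]$params, list(k = 4, distance = "correlation"))
})

test_that("every bucket member emits valid scores and separates easy fixtures", {
  tt <- train_test(sep = 10)
  for (spec in default_bucket()) {
    fit <- fit_classifier(tt$train, spec)
    pr <- predict(fit, tt$test)
    expect_equal(nrow(pr), nrow(tt$test))
    expect_true(all(pr$label %in% c(-1L, 1L)), label = spec$id)
    expect_true(all(pr$score >= 0 & pr$score <= 1), label = spec$id)
    expect_equal(mean(pr$label == tt$test$label), 1.0, label = spec$id)
  }
})

test_that("SVM training accuracy is perfect on linearly separable features", {
  tt <- train_test(sep = 10)
  fit <- fit_classifier(tt$train, default_bucket()[[1]])
  pr <- predict(fit, tt$train)
  expect_equal(mean(pr$label == tt$train$label), 1.0)
})

test_that("fit rejects degenerate training input", {
  tt <- train_test()
  one_class <- tt$train[tt$train$label == 1, ]
  expect_error(fit_classifier(one_class, default_bucket()[[2]]), "both classes")
  with_na <- tt$train
  with_na$f0[1] <- NA
  expect_error(fit_classifier(with_na, default_bucket()[[2]]), "missing")
})

test_that("prediction enforces the feature-width contract", {
  tt <- train_test(dims = 8)
  fit <- fit_classifier(tt$train, default_bucket()[[4]])
  narrower <- tt$test[, c("id", "label", paste0("f", 0:5))]
  expect_error(predict(fit, narrower), "width mismatch")
})

test_that("KNN scores are neighbour vote fractions", {
  # 4 obvious neighbours: 3 positive, 1 negative near the test point
  train <- tibble::tibble(
    id = paste0("t", 1:6), label = c(1L, 1L, 1L, -1L, -1L, -1L),
    f0 = c(0.9, 1.0, 1.1, 1.05, 5.0, 5.1), f1 = c(1.0, 0.9, 1.1, 0.95, 5.0, 4.9))
  test <- tibble::tibble(id = "q", label = 1L, f0 = 1.0, f1 = 1.0)
  fit <- fit_classifier(train, classifier_spec("knn", "k4", k = 4, distance = "correlation"))
  pr <- predict(fit, test)
  expect_equal(pr$label, 1L)
  expect_equal(pr$score, 0.75)
})

test_that("KNN clips k to the number of training rows with a warning", {
  train <- tibble::tibble(id = c("a", "b"), label = c(1L, -1L),
                          f0 = c(0, 5), f1 = c(0.2, 5.2), f2 = c(0, 4.8))
  expect_warning(
    fit <- fit_classifier(train, classifier_spec("knn", "k3", k = 3, distance = "correlation")),
    "clipping")
  pr <- predict(fit, train)
  expect_true(all(pr$score >= 0 & pr$score <= 1))
})

test_that("refits are deterministic", {
  tt <- train_test(sep = 2)
  for (spec in default_bucket()) {
    p1 <- predict(fit_classifier(tt$train, spec, seed = 5), tt$test)
    p2 <- predict(fit_classifier(tt$train, spec, seed = 5), tt$test)
    expect_identical(p1, p2, label = spec$id)
  }
})

test_that("flipping all training labels flips predictions and complements scores", {
  tt <- train_test(sep = 3, seed = 77)
  flipped <- tt$train
  flipped$label <- -flipped$label
  for (spec in default_bucket()) {
    pr <- predict(fit_classifier(tt$train, spec), tt$test)
    prf <- predict(fit_classifier(flipped, spec), tt$test)
    # the posterior of the positive class is complemented, so the predicted
    # label flips while the reported (predicted-class) score is unchanged;
    # exact 0.5 ties keep the -1 tie rule on both sides
    ties <- abs(pr$score - 0.5) < 1e-9
    expect_equal(prf$label[!ties], -pr$label[!ties], label = spec$id)
    expect_equal(prf$score, pr$score, tolerance = 1e-6, label = spec$id)
  }
})

test_that("one-class label propagation pulls every score above one half", {
  fs <- sep_features(n_per_class = 10, dims = 4, sep = 2, seed = 5)[[1]]
  train <- fs[fs$label == 1, ]
  test <- fs[fs$label == -1, ]
  pr <- llp_fit_predict(train, test)
  expect_true(all(pr$score > 0.5))
  expect_true(all(pr$label == 1L))
})

test_that("a perfectly symmetric propagation problem resolves to not-melanoma", {
  train <- tibble::tibble(id = c("p", "n"), label = c(1L, -1L),
                          f0 = c(1, -1), f1 = c(0, 0))
  test <- tibble::tibble(id = "q", label = 1L, f0 = 0, f1 = 0)
  pr <- llp_fit_predict(train, test)
  expect_equal(pr$score, 0.5)
  expect_equal(pr$label, -1L)
})

test_that("label propagation agrees with KNN on well-separated clusters", {
  tt <- train_test(sep = 10, n = 30, seed = 91)
  knn <- predict(fit_classifier(tt$train, classifier_spec("knn", "k3")), tt$test)
  llp <- llp_fit_predict(tt$train, tt$test)
  expect_gte(mean(knn$label == llp$label), 0.9)
})

test_that("non-positive propagation bandwidth errors", {
  tt <- train_test(n = 5)
  expect_error(llp_fit_predict(tt$train, tt$test, params = list(sigma = 0)), "positive")
})
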