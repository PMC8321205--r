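#' Construct a classifier specification
#'
#' @param family One of `"svm"`, `"llp"`, `"knn"`.
#' @param id Unique identifier for the spec.
#' @param ... Family parameters. SVM: `kernel` (`"polynomial"` or
#'   `"gaussian"`), `kernel_scale` (`"auto"` or a number), `cost`, `degree`.
#'   KNN: `k`, `distance` (`"spearman"` or `"correlation"`). LLP: `kernel`
#'   (`"rbf"`), `C` (regularisation), `init`, `maxiter`, `tol`, `sigma`.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(family = c("svm", "llp", "knn"), id, ...) {
  family <- match.arg(family)
  params <- list(...)
  defaults <- switch(family,
    svm = list(kernel = "gaussian", kernel_scale = "auto", cost = 1, degree = 3),
    knn = list(k = 3, distance = "spearman"),
    llp = list(kernel = "rbf", C = 1, init = 0, maxiter = 1000, tol = 1e-6, sigma = NULL)
  )
  for (nm in names(params)) defaults[[nm]] <- params[[nm]]
  structure(list(family = family, id = id, params = defaults), class = "classifier_spec")
}

#' The default five-member classifier bucket
#'
#' The set of probabilistic binary classifiers crossed with every feature
#' representation: a polynomial-kernel SVM and a Gaussian-kernel SVM (both
#' with automatic kernel scale), logistic label propagation on an rbf graph
#' (regularisation 1, init 0, at most 1000 iterations), and two KNNs
#' (3 neighbours / Spearman distance; 4 neighbours / correlation distance).
#'
#' @return A list of five [classifier_spec()] objects with unique ids.
#' @export
default_bucket <- function() {
  list(
    classifier_spec("svm", "svm_poly", kernel = "polynomial", kernel_scale = "auto"),
    classifier_spec("svm", "svm_gauss", kernel = "gaussian", kernel_scale = "auto"),
    classifier_spec("llp", "llp_rbf"),
    classifier_spec("knn", "knn3_spearman", k = 3, distance = "spearman"),
    classifier_spec("knn", "knn4_correlation", k = 4, distance = "correlation")
  )
}

#' Fit one bucket classifier on a feature table
#'
#' All members share one contract: fit on labelled features, then
#' [predict()] returns, per test row, a label in `{+1, -1}` and a posterior
#' score in `[0, 1]` for the predicted class. Exact 0.5 ties resolve to -1
#' (not-melanoma) unless `tie = "positive"`.
#'
#' @param train A feature table with both classes present and no missing
#'   feature values.
#' @param spec A [classifier_spec()].
#' @param seed Integer seed (used where the family has stochastic steps).
#' @return An `lf_fitted` model object.
#' @export
fit_classifier <- function(train, spec, seed = 1) {
  check_feature_tbl(train, "train")
  if (!inherits(spec, "classifier_spec")) abort("`spec` must be a classifier_spec.")
  x <- feature_matrix_of(train)
  if (anyNA(x)) abort("Training features contain missing values.")
  y <- as.integer(train$label)
  if (length(unique(y)) < 2L) abort("Training set must contain both classes.")

  fitted <- switch(spec$family,
    svm = fit_svm(x, y, spec$params, seed),
    knn = fit_knn(x, y, spec$params),
    llp = list(x = x, y = y, params = spec$params) # transductive: predict propagates
  )
  structure(list(spec = spec, model = fitted, n_features = ncol(x), seed = seed),
            class = "lf_fitted")
}

#' @export
print.lf_fitted <- function(x, ...) {
  cat(sprintf("<lf_fitted> %s (%s), %d features\n", x$spec$id, x$spec$family, x$n_features))
  invisible(x)
}

#' Predict labels and posterior scores
#'
#' @param object An `lf_fitted` model.
#' @param newdata A feature table with the same feature width as training.
#' @param ... Unused.
#' @return A tibble with columns `id`, `label` (+1/-1) and `score`
#'   (posterior probability of the predicted class, in `[0, 1]`).
#' @export
predict.lf_fitted <- function(object, newdata, ...) {
  check_feature_tbl(newdata, "newdata")
  x <- feature_matrix_of(newdata)
  if (ncol(x) != object$n_features) {
    abort(sprintf("Feature width mismatch: model has %d, data has %d.",
                  object$n_features, ncol(x)))
  }
  p_pos <- switch(object$spec$family,
    svm = predict_svm(object$model, x),
    knn = predict_knn(object$model, x),
    llp = llp_propagate(object$model$x, object$model$y, x, object$model$params)
  )
  posterior_to_prediction(newdata$id, p_pos)
}

# p_pos = P(label + 1 | x). Label = sign(p - 0.5), exact ties to -1; the
# reported score always refers to the predicted class.
posterior_to_prediction <- function(ids, p_pos, tie = "negative") {
  p_pos <- pmin(pmax(p_pos, 0), 1)
  lab <- ifelse(p_pos > 0.5, LABEL_POS, ifelse(p_pos < 0.5, LABEL_NEG,
                if (tie == "positive") LABEL_POS else LABEL_NEG))
  tibble(id = ids, label = as.integer(lab),
         score = ifelse(lab == LABEL_POS, p_pos, 1 - p_pos))
}

## ---- SVM (e1071 / libsvm) with logistic margin calibration -------------

# "Automatic" kernel scale: median pairwise Euclidean distance on (at most
# 256) training rows; deterministic by taking the first rows.
auto_kernel_scale <- function(x) {
  n <- min(nrow(x), 256L)
  d <- stats::dist(x[seq_len(n), , drop = FALSE])
  s <- stats::median(d[d > 0])
  if (!is.finite(s) || s <= 0) 1 else s
}

fit_svm <- function(x, y, params, seed) {
  scale <- if (identical(params$kernel_scale, "auto")) auto_kernel_scale(x) else params$kernel_scale
  yfac <- factor(y, levels = c(LABEL_POS, LABEL_NEG))
  fit <- if (params$kernel == "polynomial") {
    e1071::svm(x, yfac, scale = FALSE, kernel = "polynomial",
               degree = params$degree, gamma = 1 / scale^2, coef0 = 1,
               cost = params$cost)
  } else {
    e1071::svm(x, yfac, scale = FALSE, kernel = "radial",
               gamma = 1 / (2 * scale^2), cost = params$cost)
  }
  dv_train <- svm_decision(fit, x)
  # monotone margin -> [0,1] link (logistic), fitted on training margins
  calib <- suppressWarnings(
    stats::glm((y == LABEL_POS) ~ dv, family = stats::binomial(),
               data = data.frame(dv = dv_train))
  )
  list(fit = fit, calib = calib, kernel_scale = scale)
}

svm_decision <- function(fit, x) {
  pr <- stats::predict(fit, x, decision.values = TRUE)
  as.numeric(attr(pr, "decision.values")[, 1])
}

predict_svm <- function(model, x) {
  dv <- svm_decision(model$fit, x)
  as.numeric(stats::predict(model$calib, newdata = data.frame(dv = dv),
                            type = "response"))
}

## ---- KNN with rank / correlation distances -----------------------------

fit_knn <- function(x, y, params) {
  k <- params$k
  if (k > nrow(x)) {
    warn(sprintf("k = %d exceeds the %d training rows; clipping.", k, nrow(x)))
    k <- nrow(x)
  }
  list(x = x, y = y, k = as.integer(k), distance = params$distance)
}

# Distance between feature vectors = 1 - correlation coefficient
# (Spearman or Pearson across the feature dimensions).
knn_distances <- function(train_x, test_x, distance) {
  method <- if (distance == "spearman") "spearman" else "pearson"
  suppressWarnings(rho <- stats::cor(t(test_x), t(train_x), method = method))
  rho[!is.finite(rho)] <- 0 # constant vectors carry no correlation signal
  1 - rho # n_test x n_train
}

predict_knn <- function(model, x) {
  d <- knn_distances(model$x, x, model$distance)
  apply_rows(d, function(di) {
    nb <- order(di)[seq_len(model$k)] # stable: equal distances by index
    mean(model$y[nb] == LABEL_POS)    # vote fraction = posterior estimate
  })
}

apply_rows <- function(m, f) vapply(seq_len(nrow(m)), function(i) f(m[i, ]), numeric(1))

## ---- Logistic label propagation ----------------------------------------

# Semi-supervised propagation over an rbf-kernel graph of train+test points:
# symmetric-normalised affinities, f <- alpha*S*f + (1-alpha)*y with
# alpha = 1/(1+C), f initialised at `init`, run to |delta| < tol or maxiter.
# Propagated values are squashed through a logistic link to [0,1].
llp_propagate <- function(train_x, train_y, test_x, params) {
  if (nrow(test_x) == 0L) return(numeric(0))
  xs <- rbind(train_x, test_x)
  sigma <- params$sigma %||% auto_kernel_scale(xs)
  if (sigma <= 0) abort("LLP kernel bandwidth must be positive.")
  w <- exp(-as.matrix(stats::dist(xs))^2 / (2 * sigma^2))
  diag(w) <- 0
  deg <- pmax(rowSums(w), .Machine$double.eps)
  s <- w / sqrt(outer(deg, deg))
  yvec <- c(as.numeric(train_y), rep(0, nrow(test_x)))
  alpha <- 1 / (1 + params$C)
  f <- rep(as.numeric(params$init), length(yvec))
  for (it in seq_len(params$maxiter)) {
    f_new <- alpha * as.numeric(s %*% f) + (1 - alpha) * yvec
    if (max(abs(f_new - f)) < params$tol) { f <- f_new; break }
    f <- f_new
  }
  stats::plogis(2 * f[seq(nrow(train_x) + 1L, length(f))])
}

#' Fit-and-predict with logistic label propagation
#'
#' Transductive convenience wrapper: propagates the training labels over an
#' rbf-kernel graph built on train and test points together and returns the
#' test predictions under the common prediction contract.
#'
#' @param train,test Feature tables of equal width.
#' @param params LLP parameters (see [classifier_spec()]); defaults are
#'   regularisation `C = 1`, `init = 0`, `maxiter = 1000`, `tol = 1e-6`,
#'   median-heuristic bandwidth.
#' @return A prediction tibble (`id`, `label`, `score`).
#' @export
llp_fit_predict <- function(train, test, params = list()) {
  check_feature_tbl(train, "train")
  check_feature_tbl(test, "test")
  spec <- do.call(classifier_spec, c(list(family = "llp", id = "llp_rbf"), params))
  # propagation is well defined even from a one-class training set, so the
  # two-class requirement of fit_classifier() is not imposed here
  p_pos <- llp_propagate(feature_matrix_of(train), as.integer(train$label),
                         feature_matrix_of(test), spec$params)
  posterior_to_prediction(test$id, p_pos)
}
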