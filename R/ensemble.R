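#' Fit the full classifier-by-feature combination grid
#'
#' Crosses every classifier in the bucket (the set C, size n) with every
#' feature representation (the set F, size m) and fits each of the n*m
#' combinations on the training rows. The fitted grid is the object every
#' per-image decision and score is read from.
#'
#' @param features A feature table or list of feature tables (one per
#'   representation), all covering `train_ids`.
#' @param classifiers A list of [classifier_spec()]s, e.g. [default_bucket()].
#' @param train_ids Character vector of training image ids; duplicates are
#'   honoured (a balanced training bag may repeat rows).
#' @param seed Integer root seed; each grid cell gets a derived seed.
#' @return An `lf_grid` holding the n x m fitted models plus the feature
#'   tables (needed to look up test rows).
#' @export
fit_grid <- function(features, classifiers, train_ids, seed = 1) {
  if (is.data.frame(features)) features <- list(features)
  if (length(features) == 0L || length(classifiers) == 0L) {
    abort("Need at least one feature representation and one classifier.")
  }
  lapply(features, check_feature_tbl)
  for (f in features) {
    missing <- setdiff(train_ids, f$id)
    if (length(missing) > 0L) {
      abort(sprintf("Feature set '%s' is missing ids: %s",
                    attr(f, "extractor") %||% "?", paste(utils::head(missing, 3), collapse = ", ")))
    }
  }
  models <- vector("list", length(classifiers))
  for (i in seq_along(classifiers)) {
    models[[i]] <- vector("list", length(features))
    for (j in seq_along(features)) {
      train <- features[[j]][match(train_ids, features[[j]]$id), , drop = FALSE]
      models[[i]][[j]] <- fit_classifier(train, classifiers[[i]],
                                         seed = derive_seed(seed, i * 131L + j))
    }
  }
  structure(
    list(models = models, classifiers = classifiers, features = features,
         train_ids = train_ids,
         classifier_ids = vapply(classifiers, `[[`, character(1), "id"),
         feature_ids = vapply(seq_along(features), function(j) {
           attr(features[[j]], "extractor") %||% paste0("feature", j)
         }, character(1))),
    class = "lf_grid"
  )
}

#' @export
print.lf_grid <- function(x, ...) {
  cat(sprintf("<lf_grid> %d classifiers x %d feature sets = %d fitted models\n",
              length(x$classifiers), length(x$features),
              length(x$classifiers) * length(x$features)))
  invisible(x)
}

# Batch predictions for a set of test ids: returns n x m x n_ids arrays of
# decisions (+/-1) and scores ([0,1]). Each model predicts all its test rows
# in one call (the propagation classifier in particular is transductive).
grid_predictions <- function(grid, ids) {
  n <- length(grid$classifiers)
  m <- length(grid$features)
  D <- array(NA_integer_, dim = c(n, m, length(ids)),
             dimnames = list(grid$classifier_ids, grid$feature_ids, ids))
  S <- array(NA_real_, dim = dim(D), dimnames = dimnames(D))
  for (j in seq_len(m)) {
    f <- grid$features[[j]]
    rows <- match(ids, f$id)
    if (anyNA(rows)) abort(sprintf("Unknown id(s) in feature set '%s'.", grid$feature_ids[j]))
    test <- f[rows, , drop = FALSE]
    for (i in seq_len(n)) {
      pr <- predict(grid$models[[i]][[j]], test)
      D[i, j, ] <- pr$label
      S[i, j, ] <- pr$score
    }
  }
  list(D = D, S = S)
}

#' Decision and score matrices for one test image
#'
#' Entry (i, j) of the decision matrix D is the label the i-th classifier
#' trained on the j-th feature representation assigns to the image; the
#' aligned score matrix S holds the posterior probability attached to each
#' decision.
#'
#' @param grid An [fit_grid()] result.
#' @param image_id A single id present in every feature set (and not used
#'   for training).
#' @return A list with integer matrix `D` (entries +/-1) and numeric matrix
#'   `S` (entries in `[0, 1]`), both n x m with named rows/columns.
#' @export
score_image <- function(grid, image_id) {
  if (length(image_id) != 1L) abort("`image_id` must be a single id.")
  if (image_id %in% grid$train_ids) {
    warn(sprintf("Image '%s' was in the training ids; scores are in-sample.", image_id))
  }
  pr <- grid_predictions(grid, image_id)
  dn <- dimnames(pr$D)[1:2]
  list(D = matrix(pr$D[, , 1], nrow = dim(pr$D)[1], dimnames = dn),
       S = matrix(pr$S[, , 1], nrow = dim(pr$S)[1], dimnames = dn))
}

#' Mode of a column of binary decisions
#'
#' Returns the most frequent value of a +1/-1 decision column together with
#' the row indices where it occurs. When both decisions are equally frequent
#' the tie is resolved by the supporting evidence: the decision whose scores
#' have the larger mean wins; if that is also tied the result is -1
#' (not-melanoma), or +1 under `tie = "positive"` for conservative screening.
#'
#' @param column Vector of decisions in `{+1, -1}`.
#' @param scores Optional aligned score vector used for tie-breaking.
#' @param tie Final tie rule, `"negative"` (default) or `"positive"`.
#' @return List with `value` (+1 or -1) and `indices` (integer positions of
#'   the modal decision).
#' @export
discrete_mode <- function(column, scores = NULL, tie = c("negative", "positive")) {
  tie <- match.arg(tie)
  if (length(column) == 0L) abort("Empty decision column.")
  check_labels(column, "column")
  n_pos <- sum(column == LABEL_POS)
  n_neg <- sum(column == LABEL_NEG)
  value <- if (n_pos > n_neg) {
    LABEL_POS
  } else if (n_neg > n_pos) {
    LABEL_NEG
  } else if (!is.null(scores)) {
    mp <- mean(scores[column == LABEL_POS])
    mn <- mean(scores[column == LABEL_NEG])
    if (mp > mn) LABEL_POS else if (mn > mp) LABEL_NEG else
      if (tie == "positive") LABEL_POS else LABEL_NEG
  } else {
    if (tie == "positive") LABEL_POS else LABEL_NEG
  }
  list(value = value, indices = which(column == value))
}

#' Interpolated mode of grouped frequency data
#'
#' The classical grouped-data mode
#' `l + (f1 - f0) / (2*f1 - f0 - f2) * h`, where `l` is the lower limit of
#' the modal class, `h` the class-interval width, `f1` the modal class
#' frequency and `f0` / `f2` the frequencies of the neighbouring classes.
#' Provided for completeness; the decision-fusion path uses the discrete
#' mode, which is exact for binary decisions.
#'
#' @param l,h,f1,f0,f2 Grouped-distribution quantities; `h > 0` and
#'   `2*f1 - f0 - f2` must be nonzero.
#' @return The interpolated modal value.
#' @examples
#' grouped_mode(l = 10, h = 5, f1 = 20, f0 = 10, f2 = 15) # 13.33...
#' @export
grouped_mode <- function(l, h, f1, f0, f2) {
  if (h <= 0) abort("`h` must be positive.")
  denom <- 2 * f1 - f0 - f2
  if (denom == 0) abort("Grouped mode undefined: 2*f1 - f0 - f2 is zero.")
  l + (f1 - f0) / denom * h
}

#' Fuse a decision matrix and score matrix into a final prediction
#'
#' Per feature column j: the modal decision `dm[j]` of `D[, j]` and the
#' modal score `ds[j]`, the mean of the scores at the modal rows. The final
#' decision is the modal decision of the column with the maximum modal
#' score (`j* = argmax ds`; ties go to the lowest column index), reported
#' with that score as confidence: the fusion picks the feature
#' representation whose consensus is most confident for this image.
#'
#' @param D Integer matrix (n classifiers x m feature sets) of `{+1, -1}`.
#' @param S Aligned numeric matrix of scores in `[0, 1]`.
#' @param tie Column-tie rule passed to [discrete_mode()].
#' @return An `lf_fusion` list: `dm`, `ds`, `final_label`, `final_score`,
#'   `winning_feature`.
#' @export
fuse <- function(D, S, tie = c("negative", "positive")) {
  tie <- match.arg(tie)
  D <- as.matrix(D); S <- as.matrix(S)
  if (length(D) == 0L) abort("Empty decision matrix.")
  if (!all(dim(D) == dim(S))) abort("D and S must have identical shape.")
  check_labels(c(D), "D")
  if (any(S < 0 | S > 1)) abort("Scores must lie in [0, 1].")
  m <- ncol(D)
  dm <- integer(m); ds <- numeric(m)
  for (j in seq_len(m)) {
    md <- discrete_mode(D[, j], S[, j], tie = tie)
    dm[j] <- md$value
    ds[j] <- mean(S[md$indices, j])
  }
  jstar <- which.max(ds) # lowest index wins ties
  structure(
    list(dm = dm, ds = ds, final_label = dm[jstar], final_score = ds[jstar],
         winning_feature = jstar, feature_ids = colnames(D)),
    class = "lf_fusion"
  )
}

#' @export
print.lf_fusion <- function(x, ...) {
  cat(sprintf("<lf_fusion> label %+d @ %.3f (feature column %d)\n",
              x$final_label, x$final_score, x$winning_feature))
  invisible(x)
}

#' @rdname fuse
#' @param x An `lf_fusion` object.
#' @param ... Unused.
#' @method tidy lf_fusion
#' @export
tidy.lf_fusion <- function(x, ...) {
  tibble(
    feature = x$feature_ids %||% paste0("feature", seq_along(x$dm)),
    modal_decision = x$dm, modal_score = x$ds,
    winner = seq_along(x$dm) == x$winning_feature
  )
}
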