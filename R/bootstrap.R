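#' Bootstrap evaluation plan
#'
#' The evaluation protocol: per iteration a training bag of size
#' `round(train_frac * N)` is drawn (with replacement by default; images
#' never drawn form the test set), the training portion is balanced, the
#' full classifier-by-feature grid is fitted, every test image is fused, and
#' one metric report is emitted. Defaults are 10 iterations at an 80/20
#' train/test split.
#'
#' @param n_iterations Number of bootstrap iterations (>= 1).
#' @param train_frac Fraction of images in the training bag (0 < f < 1).
#' @param replace Draw the training bag with replacement (`TRUE`, bootstrap
#'   semantics) or as a plain split (`FALSE`).
#' @param seed Integer root seed; every split, balancing and classifier seed
#'   is derived from it.
#' @return A `boot_plan` list.
#' @export
boot_plan <- function(n_iterations = 10, train_frac = 0.8, replace = TRUE, seed = 1) {
  if (n_iterations < 1) abort("`n_iterations` must be at least 1.")
  if (train_frac <= 0 || train_frac >= 1) abort("`train_frac` must lie in (0, 1).")
  structure(list(n_iterations = as.integer(n_iterations), train_frac = train_frac,
                 replace = isTRUE(replace), seed = as.integer(seed)),
            class = "boot_plan")
}

#' Bootstrapped evaluation of the fusion ensemble on feature tables
#'
#' Runs the full protocol on precomputed feature representations: per
#' iteration, draw the train bag / test split over the shared ids, balance
#' the training bag by minority oversampling (round-robin duplication to
#' exact parity), fit the [fit_grid()] of `bucket` x `features`, fuse every
#' test image with [fuse()], and score the fused labels against truth.
#' Iterations whose test split misses a class are skipped with a warning.
#'
#' @param features A feature table or list of feature tables sharing
#'   `id`/`label`.
#' @param bucket List of [classifier_spec()]s; default the five-member
#'   bucket.
#' @param plan A [boot_plan()].
#' @param balance Balance the training bag to class parity (default `TRUE`).
#' @param tie Column-tie rule for [fuse()].
#' @return An `lf_boot` object; see [tidy.lf_boot()] / [glance.lf_boot()].
#' @examples
#' fs <- synth_features(synth_feature_spec(20, dims = c(6, 10), class_separation = 8))
#' res <- run_bootstrap(fs, plan = boot_plan(n_iterations = 2, seed = 7))
#' glance(res)$acc
#' @export
run_bootstrap <- function(features, bucket = default_bucket(),
                          plan = boot_plan(), balance = TRUE,
                          tie = c("negative", "positive")) {
  tie <- match.arg(tie)
  if (is.data.frame(features)) features <- list(features)
  lapply(features, check_feature_tbl)
  ids <- features[[1]]$id
  labels <- as.integer(features[[1]]$label)
  for (f in features[-1]) {
    if (!setequal(f$id, ids)) abort("All feature sets must cover the same ids.")
  }
  truth <- stats::setNames(labels, ids)

  iter_rows <- list()
  for (it in seq_len(plan$n_iterations)) {
    split <- draw_split(ids, plan, it)
    test_ids <- split$test
    if (length(unique(truth[test_ids])) < 2L) {
      warn(sprintf("Iteration %d: test split misses a class; skipped.", it))
      next
    }
    train_bag <- split$train
    if (balance) {
      train_bag <- oversample_to_parity(train_bag, truth, derive_seed(plan$seed, 7000L + it))
    }
    grid <- fit_grid(features, bucket, train_bag, seed = derive_seed(plan$seed, 9000L + it))
    pred <- fuse_all(grid, test_ids, tie)
    rep <- metrics(confusion(pred$label, truth[test_ids]))
    rep$iteration <- it
    rep$n_test <- length(test_ids)
    iter_rows[[length(iter_rows) + 1L]] <- rep
  }
  if (length(iter_rows) == 0L) abort("Every iteration was skipped; no report.")
  iterations <- dplyr::bind_rows(iter_rows)
  structure(
    list(iterations = iterations, aggregate = aggregate_metrics(iterations),
         plan = plan, n_classifiers = length(bucket), n_features = length(features)),
    class = "lf_boot"
  )
}

draw_split <- function(ids, plan, it) {
  b <- max(1L, round(plan$train_frac * length(ids)))
  withr::with_seed(derive_seed(plan$seed, it), {
    if (plan$replace) {
      train <- sample(ids, b, replace = TRUE)
      list(train = train, test = setdiff(ids, unique(train)))
    } else {
      train <- sample(ids, b)
      list(train = train, test = setdiff(ids, train))
    }
  })
}

# Round-robin duplication of minority ids until class counts match.
oversample_to_parity <- function(train_bag, truth, seed) {
  n_pos <- sum(truth[train_bag] == 1)
  n_neg <- sum(truth[train_bag] == -1)
  if (n_pos == n_neg || n_pos == 0L || n_neg == 0L) return(train_bag)
  minority <- if (n_pos < n_neg) 1L else -1L
  pool <- sort(unique(train_bag[truth[train_bag] == minority]))
  extra <- withr::with_seed(seed, {
    offset <- sample.int(length(pool), 1L) - 1L
    pool[((offset + seq_len(abs(n_pos - n_neg)) - 1L) %% length(pool)) + 1L]
  })
  c(train_bag, extra)
}

# Fuse every test image from one fitted grid; one row per image.
fuse_all <- function(grid, test_ids, tie = "negative") {
  pr <- grid_predictions(grid, test_ids)
  out <- lapply(seq_along(test_ids), function(k) {
    dn <- dimnames(pr$D)[1:2]
    fu <- fuse(matrix(pr$D[, , k], nrow = dim(pr$D)[1], dimnames = dn),
               matrix(pr$S[, , k], nrow = dim(pr$S)[1], dimnames = dn), tie = tie)
    tibble(id = test_ids[k], label = fu$final_label, score = fu$final_score,
           winning_feature = fu$winning_feature)
  })
  dplyr::bind_rows(out)
}

#' Bootstrapped evaluation straight from labelled images
#'
#' The image-level pipeline: per iteration the train/test image split is
#' drawn, the training portion is balanced by K-means colour augmentation
#' (never the test images), each configured extractor produces its feature
#' table, and the run proceeds as in [run_bootstrap()].
#'
#' @param images An image table.
#' @param extractors List of [backbone_spec()] / [toy_spec()] objects.
#' @param bucket List of [classifier_spec()]s.
#' @param plan A [boot_plan()].
#' @param k_colors Colour clusters for the balancing augmentation.
#' @param balance Balance the training images to parity (default `TRUE`).
#' @param tie Column-tie rule for [fuse()].
#' @param engine Optional extraction engine for backbone specs.
#' @return An `lf_boot` object.
#' @export
run_image_bootstrap <- function(images, extractors = list(toy_spec()),
                                bucket = default_bucket(), plan = boot_plan(),
                                k_colors = 5, balance = TRUE,
                                tie = c("negative", "positive"), engine = NULL) {
  tie <- match.arg(tie)
  check_image_tbl(images)
  truth <- stats::setNames(as.integer(images$label), images$id)

  iter_rows <- list()
  for (it in seq_len(plan$n_iterations)) {
    split <- draw_split(images$id, plan, it)
    test_ids <- split$test
    if (length(unique(truth[test_ids])) < 2L) {
      warn(sprintf("Iteration %d: test split misses a class; skipped.", it))
      next
    }
    train_imgs <- images[match(unique(split$train), images$id), , drop = FALSE]
    if (balance && length(unique(train_imgs$label)) == 2L) {
      bp <- plan_balance(train_imgs, k_colors = k_colors,
                         seed = derive_seed(plan$seed, 7000L + it))
      train_imgs <- apply_balance(train_imgs, bp)
    }
    test_imgs <- images[match(test_ids, images$id), , drop = FALSE]
    feats <- lapply(extractors, function(ex) {
      pool <- dplyr::bind_rows(train_imgs, test_imgs)
      if (inherits(ex, "backbone_spec")) pool <- resize_for_backbone(pool, ex)
      extract_features(pool, ex, engine = engine)
    })
    grid <- fit_grid(feats, bucket, train_imgs$id,
                     seed = derive_seed(plan$seed, 9000L + it))
    pred <- fuse_all(grid, test_ids, tie)
    rep <- metrics(confusion(pred$label, truth[test_ids]))
    rep$iteration <- it
    rep$n_test <- length(test_ids)
    iter_rows[[length(iter_rows) + 1L]] <- rep
  }
  if (length(iter_rows) == 0L) abort("Every iteration was skipped; no report.")
  iterations <- dplyr::bind_rows(iter_rows)
  structure(
    list(iterations = iterations, aggregate = aggregate_metrics(iterations),
         plan = plan, n_classifiers = length(bucket), n_features = length(extractors)),
    class = "lf_boot"
  )
}

#' @export
print.lf_boot <- function(x, ...) {
  cat(sprintf("<lf_boot> %d iteration(s), %d classifiers x %d feature sets\n",
              nrow(x$iterations), x$n_classifiers, x$n_features))
  agg <- x$aggregate
  cat(sprintf("  mean ACC %.3f  MCC %.3f  TPR %.3f  TNR %.3f\n",
              agg$acc, agg$mcc, agg$tpr, agg$tnr))
  invisible(x)
}

#' Per-iteration and aggregate views of a bootstrap run
#'
#' `tidy()` returns one row per bootstrap iteration with the eight metrics;
#' `glance()` returns the one-row aggregate (means, standard deviations,
#' iteration count).
#'
#' @param x An `lf_boot` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy lf_boot
#' @export
tidy.lf_boot <- function(x, ...) {
  dplyr::relocate(x$iterations, "iteration")
}

#' @rdname tidy.lf_boot
#' @method glance lf_boot
#' @export
glance.lf_boot <- function(x, ...) x$aggregate

#' Serialize a bootstrap report
#'
#' Writes the per-iteration rows and the aggregate (with the plan echoed)
#' as JSON, and optionally the iterations as CSV.
#'
#' @param x An `lf_boot` object.
#' @param path JSON output path.
#' @param csv Optional CSV path for the per-iteration rows.
#' @return `path`, invisibly.
#' @export
write_boot_report <- function(x, path, csv = NULL) {
  jsonlite::write_json(
    list(plan = unclass(x$plan), iterations = x$iterations, aggregate = x$aggregate),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(csv)) readr::write_csv(x$iterations, csv)
  invisible(path)
}
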