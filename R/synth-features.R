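#' Specify synthetic two-class feature clusters
#'
#' Specification for [synth_features()], which emulates the set of per-image
#' feature vectors that several independent extractors would produce: one
#' feature table per entry of `dims`, each drawn from two isotropic Gaussian
#' clusters (unit within-class standard deviation) whose means are
#' `class_separation` apart in Euclidean distance. Tables share ids and
#' labels; feature values are drawn independently per pseudo-extractor.
#'
#' @param n_per_class Images per class (each table has `2 * n_per_class` rows).
#' @param dims Integer vector of feature dimensionalities, one per
#'   pseudo-extractor; all positive, non-empty.
#' @param class_separation Distance between class means in units of the
#'   within-class standard deviation; `0` means no signal (chance-level
#'   downstream accuracy), `10` is effectively perfectly separable.
#' @param seed Integer seed; identical specs yield identical tables.
#' @return A `synth_feature_spec` list.
#' @export
synth_feature_spec <- function(n_per_class, dims, class_separation = 2, seed = 1) {
  if (length(dims) == 0L || any(dims <= 0)) abort("`dims` must be non-empty and all positive.")
  if (class_separation < 0) abort("`class_separation` must be non-negative.")
  if (n_per_class < 0) abort("`n_per_class` must be non-negative.")
  structure(
    list(n_per_class = as.integer(n_per_class), dims = as.integer(dims),
         class_separation = as.double(class_separation), seed = as.integer(seed)),
    class = "synth_feature_spec"
  )
}

#' Generate synthetic feature tables
#'
#' @param spec A [synth_feature_spec()].
#' @return A list of tibbles, one per entry of `spec$dims`. Each has columns
#'   `id`, `label` and `f0 ... f{d-1}`, plus an `extractor` attribute naming
#'   the pseudo-extractor.
#' @examples
#' fs <- synth_features(synth_feature_spec(10, dims = c(4, 8), class_separation = 3))
#' sapply(fs, function(f) length(feature_dims(f)))
#' @export
synth_features <- function(spec) {
  if (!inherits(spec, "synth_feature_spec")) spec <- do.call(synth_feature_spec, spec)
  n <- 2L * spec$n_per_class
  labels <- rep(c(LABEL_POS, LABEL_NEG), each = spec$n_per_class)
  ids <- sprintf("s_%03d", seq_len(n))
  # One RNG stream per pseudo-extractor. The mean difference alternates in
  # sign across dimensions (unit direction u_i = (-1)^(i+1)/sqrt(d)), so
  # ||mu_pos - mu_neg|| = class_separation at unit within-class sd and the
  # signal is a *pattern*, visible to correlation/rank distances as well as
  # to margin classifiers; a constant offset would be invisible to the
  # former.
  out <- lapply(seq_along(spec$dims), function(j) {
    d <- spec$dims[j]
    u <- rep_len(c(1, -1), d) / sqrt(d)
    x <- withr::with_seed(derive_seed(spec$seed, j), {
      matrix(stats::rnorm(n * d), n, d)
    })
    x <- x + outer(ifelse(labels == LABEL_POS, 1, -1) * spec$class_separation / 2, u)
    colnames(x) <- paste0("f", seq_len(d) - 1L)
    tbl <- dplyr::bind_cols(tibble(id = ids, label = labels), as_tibble(x))
    attr(tbl, "extractor") <- sprintf("synth%d_d%d", j, d)
    tbl
  })
  out
}

#' Feature dimensionality of a feature table
#' @param features A feature table (`id`, `label`, `f0...`).
#' @return Character vector of feature column names.
#' @export
feature_dims <- function(features) feature_cols(features)

#' Write / read a feature table as delimited text
#'
#' Plain CSV with header `id,label,f0..f{d-1}`.
#' @param features A feature table.
#' @param path File path.
#' @return `path` invisibly ([write_features()]); a tibble ([read_features()]).
#' @export
write_features <- function(features, path) {
  check_feature_tbl(features)
  readr::write_csv(features[c("id", "label", feature_cols(features))], path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  tbl$label <- as.integer(tbl$label)
  check_feature_tbl(tbl)
  as_tibble(tbl)
}
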