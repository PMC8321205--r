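#' Registry of supported pretrained backbones
#'
#' The four ImageNet-pretrained convolutional networks used for transfer
#' feature extraction, with the layer tapped for features and its width:
#' AlexNet (`fc7`, 4096), GoogLeNet (`pool5-7x7_s1`, 1024), ResNet-18
#' (`pool5`, 512) and ResNet-50 (`avg_pool`, 2048). These (name, tap layer,
#' dimension, input size) tuples define the feature-vector contract every
#' extractor must honour.
#'
#' @return A tibble with columns `name`, `input_size`, `tap_layer`,
#'   `feature_dim`, `pretrained`.
#' @export
backbone_registry <- function() {
  tibble(
    name        = c("alexnet", "googlenet", "resnet18", "resnet50"),
    input_size  = c(227L, 224L, 224L, 224L),
    tap_layer   = c("fc7", "pool5-7x7_s1", "pool5", "avg_pool"),
    feature_dim = c(4096L, 1024L, 512L, 2048L),
    pretrained  = TRUE
  )
}

#' Construct a backbone specification
#'
#' @param name A registry name (`"alexnet"`, `"googlenet"`, `"resnet18"`,
#'   `"resnet50"`) or a custom name if `input_size`, `tap_layer` and
#'   `feature_dim` are all supplied.
#' @param input_size,tap_layer,feature_dim Override / supply the declared
#'   input size (pixels, square), tapped layer and feature width.
#' @param finetune Optional [finetune_config()]; recorded in provenance and
#'   applied by extraction engines that support training.
#' @return A `backbone_spec` list.
#' @export
backbone_spec <- function(name, input_size = NULL, tap_layer = NULL,
                          feature_dim = NULL, finetune = NULL) {
  reg <- backbone_registry()
  if (name %in% reg$name) {
    row <- reg[reg$name == name, ]
    input_size <- input_size %||% row$input_size
    tap_layer <- tap_layer %||% row$tap_layer
    feature_dim <- feature_dim %||% row$feature_dim
  } else if (is.null(input_size) || is.null(tap_layer) || is.null(feature_dim)) {
    abort("Unknown backbone: supply input_size, tap_layer and feature_dim explicitly.")
  }
  if (feature_dim <= 0) abort("`feature_dim` must be positive.")
  structure(
    list(type = "backbone", name = name, input_size = as.integer(input_size),
         tap_layer = tap_layer, feature_dim = as.integer(feature_dim),
         pretrained = TRUE, finetune = finetune, head = NULL),
    class = "backbone_spec"
  )
}

#' Fine-tuning configuration
#'
#' Training settings used when a backbone head is re-trained on the lesion
#' task: mini-batch 5, at most 10 epochs, initial learning rate 3e-4,
#' stochastic gradient descent with momentum, 2 output classes. These are
#' carried on the spec and consumed by extraction engines that can train;
#' the built-in deterministic encoder is weight-free and records them as
#' provenance only.
#'
#' @param mini_batch,max_epochs Positive counts.
#' @param initial_lr Positive learning rate.
#' @param optimizer Optimizer label, default `"sgdm"`.
#' @param n_classes_out Must be 2 (melanoma / not-melanoma).
#' @param freeze_early If `TRUE`, early-layer learning rates are set to zero
#'   (weights frozen) to cut training time and overfitting on small data.
#' @return A `finetune_config` list.
#' @export
finetune_config <- function(mini_batch = 5, max_epochs = 10, initial_lr = 3e-4,
                            optimizer = "sgdm", n_classes_out = 2,
                            freeze_early = FALSE) {
  if (mini_batch <= 0 || max_epochs <= 0 || initial_lr <= 0) {
    abort("Fine-tune settings must all be positive.")
  }
  if (n_classes_out != 2) abort("The classification head must have 2 outputs.")
  structure(
    list(mini_batch = as.integer(mini_batch), max_epochs = as.integer(max_epochs),
         initial_lr = initial_lr, optimizer = optimizer,
         n_classes_out = 2L, freeze_early = isTRUE(freeze_early)),
    class = "finetune_config"
  )
}

#' Adapt a backbone's classification head to the two-class lesion task
#'
#' Replaces the final learnable layer with a 2-output head, raises the
#' learning-rate factor of the new layer relative to the transferred layers,
#' and optionally freezes early layers (learning-rate factor 0). Idempotent.
#'
#' @param backbone A [backbone_spec()].
#' @param new_layer_lr_factor Learning-rate multiplier of the new head.
#' @return The spec with a `head` field describing the adapted layers.
#' @export
adapt_head <- function(backbone, new_layer_lr_factor = 10) {
  if (!inherits(backbone, "backbone_spec")) abort("`backbone` must be a backbone_spec.")
  freeze <- isTRUE(backbone$finetune$freeze_early)
  backbone$head <- list(
    n_out = 2L,
    new_layer_lr_factor = new_layer_lr_factor,
    early_layer_lr_factor = if (freeze) 0 else 1
  )
  backbone
}

#' Toy feature extractor specification
#'
#' A weight-free deterministic extractor for offline use: per-channel colour
#' histograms plus first and second moments.
#'
#' @param bins Histogram bins per channel (>= 2); features have
#'   `3 * bins + 6` dimensions.
#' @return A `toy_spec` list usable wherever a backbone spec is.
#' @export
toy_spec <- function(bins = 8) {
  if (bins < 2) abort("`bins` must be at least 2.")
  structure(list(type = "toy", name = sprintf("toy%d", bins), bins = as.integer(bins),
                 feature_dim = 3L * as.integer(bins) + 6L),
            class = "toy_spec")
}

#' Extract toy colour features from images
#'
#' Per image: a `bins`-bin histogram of each RGB channel (proportions over
#' `[0, 1]`) concatenated with per-channel mean and variance - `3*bins + 6`
#' values, fully deterministic, no weights or downloads involved.
#'
#' @param images An image table.
#' @param bins Histogram bins per channel.
#' @return A feature table (`id`, `label`, `f0...`), rows in input order,
#'   with an `extractor` attribute.
#' @export
toy_extract <- function(images, bins = 8) {
  check_image_tbl(images)
  spec <- toy_spec(bins)
  feats <- t(vapply(images$pixels, toy_features_one, numeric(spec$feature_dim), bins = bins))
  colnames(feats) <- paste0("f", seq_len(ncol(feats)) - 1L)
  tbl <- dplyr::bind_cols(tibble(id = images$id, label = images$label), as_tibble(feats))
  attr(tbl, "extractor") <- spec$name
  tbl
}

toy_features_one <- function(px, bins) {
  breaks <- seq(0, 1, length.out = bins + 1L)
  per_channel <- lapply(1:3, function(ch) {
    v <- c(px[, , ch])
    h <- graphics::hist(pmin(pmax(v, 0), 1), breaks = breaks, plot = FALSE)$counts
    list(hist = h / length(v), mean = mean(v), var = stats::var(v))
  })
  c(unlist(lapply(per_channel, `[[`, "hist")),
    vapply(per_channel, `[[`, numeric(1), "mean"),
    vapply(per_channel, `[[`, numeric(1), "var"))
}

#' Extract per-image feature vectors with a configured extractor
#'
#' Runs the extractor over the images and returns one feature row per image,
#' in input order, with the extractor's declared dimensionality.
#'
#' For a backbone spec, images must already be at the declared input size
#' (use [resize_for_backbone()]); this function never resizes silently.
#' Extraction engines are pluggable via `engine`: a function
#' `function(images, backbone) -> numeric matrix` (rows = images, columns =
#' `feature_dim`), e.g. one wrapping real pretrained weights. When no engine
#' is supplied the built-in deterministic encoder is used and a warning is
#' emitted once per session: it computes rich colour-histogram statistics and
#' passes them through a fixed, backbone-seeded random projection with ReLU
#' to the declared width. It honours the dimension and determinism contracts
#' but carries no ImageNet knowledge.
#'
#' @param images An image table.
#' @param extractor A [backbone_spec()] or [toy_spec()].
#' @param engine Optional extraction function for backbone specs.
#' @return A feature table (`id`, `label`, `f0 ... f{d-1}`) with an
#'   `extractor` attribute naming the source.
#' @export
extract_features <- function(images, extractor, engine = NULL) {
  check_image_tbl(images)
  if (inherits(extractor, "toy_spec")) {
    return(toy_extract(images, extractor$bins))
  }
  if (!inherits(extractor, "backbone_spec")) abort("Unknown extractor type.")
  sizes_ok <- vapply(images$pixels, function(px) all(dim(px)[1:2] == extractor$input_size), logical(1))
  if (nrow(images) > 0 && !all(sizes_ok)) {
    abort(sprintf("Images must be %dx%d for backbone '%s'; resize_for_backbone() first.",
                  extractor$input_size, extractor$input_size, extractor$name))
  }
  if (is.null(engine)) {
    warn_fallback_once(extractor$name)
    feats <- builtin_encoder(images, extractor)
  } else {
    feats <- engine(images, extractor)
    if (!is.matrix(feats) || nrow(feats) != nrow(images) || ncol(feats) != extractor$feature_dim) {
      abort("Engine returned a matrix violating the (n_images x feature_dim) contract.")
    }
  }
  colnames(feats) <- paste0("f", seq_len(extractor$feature_dim) - 1L)
  tbl <- dplyr::bind_cols(tibble(id = images$id, label = images$label), as_tibble(feats))
  attr(tbl, "extractor") <- extractor$name
  tbl
}

the_fallback_warned <- new.env(parent = emptyenv())

warn_fallback_once <- function(name) {
  if (is.null(the_fallback_warned[[name]])) {
    the_fallback_warned[[name]] <- TRUE
    warn(sprintf(
      "No extraction engine supplied for backbone '%s'; using the deterministic weight-free encoder (histogram features + fixed random projection to %s's declared width).",
      name, name))
  }
}

# Deterministic weight-free encoder: 16-bin toy features -> fixed Gaussian
# projection (seeded from the backbone name) -> ReLU. The projection matrix
# is cached per (name, dim).
the_projection_cache <- new.env(parent = emptyenv())

builtin_encoder <- function(images, backbone) {
  base <- if (nrow(images) > 0) {
    t(vapply(images$pixels, toy_features_one, numeric(54), bins = 16))
  } else {
    matrix(numeric(0), 0, 54)
  }
  key <- sprintf("%s_%d", backbone$name, backbone$feature_dim)
  w <- the_projection_cache[[key]]
  if (is.null(w)) {
    seed <- as.integer(sum(utf8ToInt(backbone$name)) * 2654435 %% 2147483647)
    w <- withr::with_seed(seed, {
      matrix(stats::rnorm(54 * backbone$feature_dim, sd = 1 / sqrt(54)),
             54, backbone$feature_dim)
    })
    the_projection_cache[[key]] <- w
  }
  pmax(base %*% w, 0)
}
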