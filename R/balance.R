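#' Plan minority-class balancing
#'
#' Determines which class is under-represented and how many altered copies are
#' needed for exact parity. Copies are later produced by K-means colour
#' segmentation ([kmeans_color_augment()]) and added by [apply_balance()].
#'
#' @param images An image table (id, label, provenance, pixels).
#' @param k_colors Number of colour clusters for the augmentation (>= 2).
#'   Default 5: enough to keep lesion / skin / shadow structure while visibly
#'   posterising the image.
#' @param seed Integer root seed for the augmentation draws.
#' @return A `balance_plan` with `minority_label`, `n_to_add`, `k_colors`,
#'   `seed`.
#' @examples
#' imgs <- synth_images(synth_image_spec(3, 5, image_size = 24, seed = 1))
#' plan_balance(imgs)
#' @export
plan_balance <- function(images, k_colors = 5, seed = 1) {
  check_image_tbl(images)
  if (k_colors < 2) abort("`k_colors` must be at least 2.")
  n_pos <- sum(images$label == LABEL_POS)
  n_neg <- sum(images$label == LABEL_NEG)
  if (n_pos == 0L || n_neg == 0L) {
    abort("Balancing is undefined for a single-class dataset.")
  }
  structure(
    list(
      minority_label = if (n_pos <= n_neg) LABEL_POS else LABEL_NEG,
      n_to_add = abs(n_pos - n_neg),
      k_colors = as.integer(k_colors),
      seed = as.integer(seed)
    ),
    class = "balance_plan"
  )
}

#' @export
print.balance_plan <- function(x, ...) {
  cat(sprintf("<balance_plan> add %d K-means(k=%d) altered copies of class %+d\n",
              x$n_to_add, x$k_colors, x$minority_label))
  invisible(x)
}

#' Serialize / restore a balance plan as JSON
#' @param plan A [plan_balance()] result.
#' @param path File path.
#' @return `path` invisibly; [read_balance_plan()] returns the plan.
#' @export
write_balance_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_balance_plan
#' @export
read_balance_plan <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE), class = "balance_plan")
}

#' Alter one image by K-means colour segmentation
#'
#' Clusters the pixel RGB triples into `k_colors` groups (k-means++ seeding,
#' then Lloyd iterations) and replaces every pixel by its cluster centroid,
#' i.e. a posterised rendering of the image. The label is preserved and the
#' provenance becomes `"augmented"`. If the image has no more distinct
#' colours than `k_colors` the pixels are returned unchanged and the result
#' carries attribute `unchanged = TRUE`.
#'
#' @param image A one-row image table.
#' @param k_colors Number of colour clusters (>= 2).
#' @param seed Integer seed; same image + seed gives an identical output.
#' @return A one-row image table with provenance `"augmented"`.
#' @export
kmeans_color_augment <- function(image, k_colors = 5, seed = 1) {
  check_image_tbl(image)
  if (nrow(image) != 1L) abort("`image` must be a single-row image table.")
  if (k_colors < 2) abort("`k_colors` must be at least 2.")
  px <- image$pixels[[1]]
  h <- dim(px)[1]; w <- dim(px)[2]
  m <- pixels_to_rgb_matrix(px)
  out <- image
  out$provenance <- "augmented"
  if (nrow(unique(m)) <= k_colors) {
    attr(out, "unchanged") <- TRUE
    return(out)
  }
  seg <- withr::with_seed(seed, {
    centers <- kmeanspp_centers(m, k_colors)
    km <- suppressWarnings(
      stats::kmeans(m, centers = centers, iter.max = 50, algorithm = "Lloyd")
    )
    km$centers[km$cluster, , drop = FALSE]
  })
  out$pixels <- list(quantize8(rgb_matrix_to_pixels(seg, h, w)))
  out
}

# k-means++ seeding (D^2 weighting); stats::kmeans only offers random starts.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in 2:k) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- x[sample.int(n, 1L, prob = p), ]
    dj <- rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, dj)
  }
  # kmeans() requires distinct centers
  unique(centers)
}

#' Balance a dataset by augmenting the minority class
#'
#' Adds `plan$n_to_add` K-means colour-segmented copies of minority images,
#' sampled round-robin over the (id-sorted) minority class so source
#' diversity is maximal and deterministic. Originals are kept untouched;
#' added rows get ids `aug<i>_<source id>` and provenance `"augmented"`.
#'
#' @param images The image table the plan was computed from.
#' @param plan A [plan_balance()] result.
#' @return An image table with equal class counts.
#' @export
apply_balance <- function(images, plan) {
  check_image_tbl(images)
  if (!inherits(plan, "balance_plan")) abort("`plan` must come from plan_balance().")
  n_pos <- sum(images$label == LABEL_POS)
  n_neg <- sum(images$label == LABEL_NEG)
  if (abs(n_pos - n_neg) != plan$n_to_add) {
    abort("`plan` does not match this dataset (class gap differs).")
  }
  if (plan$n_to_add == 0L) return(images)
  minority <- images[images$label == plan$minority_label, , drop = FALSE]
  minority <- minority[order(minority$id), , drop = FALSE]
  added <- vector("list", plan$n_to_add)
  for (i in seq_len(plan$n_to_add)) {
    src <- minority[((i - 1L) %% nrow(minority)) + 1L, , drop = FALSE]
    aug <- kmeans_color_augment(src, plan$k_colors, seed = derive_seed(plan$seed, i))
    aug$id <- paste0("aug", i, "_", src$id)
    added[[i]] <- aug
  }
  dplyr::bind_rows(images, dplyr::bind_rows(added))
}

#' Resize an image set to a backbone's input size
#'
#' Bilinear resize (via EBImage) to the square input size the named network
#' expects; images already at the target size pass through pixel-identical.
#'
#' @param images An image table (one or more rows).
#' @param backbone A backbone spec (see [backbone_spec()]) or a bare integer
#'   size in pixels.
#' @return The image table with every `pixels` array at the target size.
#' @export
resize_for_backbone <- function(images, backbone) {
  check_image_tbl(images)
  size <- if (is.numeric(backbone)) as.integer(backbone) else backbone$input_size
  if (is.null(size) || size <= 0) abort("Backbone has no declared input size.")
  images$pixels <- lapply(images$pixels, function(px) {
    if (length(dim(px)) != 3L || dim(px)[3] != 3L) abort("Images must be RGB (h x w x 3).")
    if (all(dim(px)[1:2] == size)) return(px)
    img <- EBImage::Image(aperm(px, c(2, 1, 3)), colormode = "Color")
    res <- EBImage::resize(img, w = size, h = size, filter = "bilinear")
    quantize8(aperm(EBImage::imageData(res), c(2, 1, 3)))
  })
  images
}
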