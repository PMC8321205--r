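#' Specify a synthetic two-class lesion image set
#'
#' Builds the specification for [synth_images()]. The generator emulates a
#' small clinical photograph collection of pigmented skin lesions: every image
#' is a skin-toned background with a single central blob. "Melanoma" blobs
#' (label +1) are darker and have an irregular, radially perturbed boundary;
#' "benign" blobs (label -1) are lighter and nearly circular. This gives the
#' colour-segmentation balancer and the histogram feature extractor genuine
#' structure to act on while staying fully reproducible offline.
#'
#' @param n_melanoma,n_benign Number of images per class (non-negative).
#' @param image_size Side length of the square image in pixels (> 0).
#' @param lesion_contrast Number in `[0, 1]` scaling the luminance gap between
#'   the two lesion classes. At 0 the classes share one lesion tone and only
#'   the boundary-irregularity cue remains; the default 0.6 yields clearly
#'   separable colour statistics.
#' @param seed Integer seed; the same spec yields byte-identical images.
#' @return A `synth_image_spec` list.
#' @seealso [synth_images()]
#' @export
synth_image_spec <- function(n_melanoma, n_benign, image_size = 64,
                             lesion_contrast = 0.6, seed = 1) {
  if (n_melanoma < 0 || n_benign < 0) abort("Class counts must be non-negative.")
  if (image_size <= 0) abort("`image_size` must be a positive number of pixels.")
  if (lesion_contrast < 0 || lesion_contrast > 1) abort("`lesion_contrast` must lie in [0, 1].")
  structure(
    list(n_melanoma = as.integer(n_melanoma), n_benign = as.integer(n_benign),
         image_size = as.integer(image_size),
         lesion_contrast = as.double(lesion_contrast), seed = as.integer(seed)),
    class = "synth_image_spec"
  )
}

#' Generate synthetic labelled lesion images
#'
#' @param spec A [synth_image_spec()].
#' @return A tibble with one row per image and columns `id`, `label`
#'   (+1 melanoma / -1 not-melanoma), `provenance` (`"original"`) and
#'   `pixels` (list of `size x size x 3` arrays in `[0, 1]`, 8-bit quantised).
#'   Melanoma rows come first.
#' @examples
#' imgs <- synth_images(synth_image_spec(5, 5, image_size = 32, seed = 1))
#' dplyr::count(imgs, label)
#' @export
synth_images <- function(spec) {
  if (!inherits(spec, "synth_image_spec")) spec <- do.call(synth_image_spec, spec)
  n <- spec$n_melanoma + spec$n_benign
  withr::with_seed(spec$seed, {
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      melanoma <- i <= spec$n_melanoma
      px <- draw_lesion(spec$image_size, melanoma, spec$lesion_contrast)
      rows[[i]] <- tibble(
        id = if (melanoma) sprintf("mel_%03d", i) else sprintf("ben_%03d", i - spec$n_melanoma),
        label = if (melanoma) LABEL_POS else LABEL_NEG,
        provenance = "original",
        pixels = list(px)
      )
    }
  })
  dplyr::bind_rows(rows)
}

# One image: skin background + blob. Melanoma boundary is perturbed by a
# random low-order Fourier series (irregular border); benign is near-circular.
draw_lesion <- function(size, melanoma, contrast) {
  bg <- c(0.87, 0.72, 0.62) + stats::rnorm(3, 0, 0.015)
  cx <- stats::runif(1, 0.42, 0.58)
  cy <- stats::runif(1, 0.42, 0.58)
  r0 <- stats::runif(1, 0.16, 0.24)

  u <- (seq_len(size) - 0.5) / size
  dx <- outer(u, rep(1, size)) - cx       # rows = y, cols = x
  dy <- outer(rep(1, size), u) - cy
  dist <- sqrt(dx^2 + dy^2)
  theta <- atan2(dx, dy)

  base_col <- c(0.50, 0.34, 0.27) # shared lesion tone; contrast splits it
  if (melanoma) {
    k <- 2:5
    amp <- stats::runif(length(k), 0.05, 0.28)
    phase <- stats::runif(length(k), 0, 2 * pi)
    pert <- Reduce(`+`, lapply(seq_along(k), function(j) amp[j] * sin(k[j] * theta + phase[j])))
    radius <- r0 * (1 + 0.35 * pert)
    lesion_col <- base_col * (1 - 0.55 * contrast)
  } else {
    phase <- stats::runif(1, 0, 2 * pi)
    radius <- r0 * (1 + 0.04 * sin(2 * theta + phase))
    lesion_col <- pmin(base_col * (1 + 0.45 * contrast), 1)
  }

  inside <- dist < radius
  px <- array(0, dim = c(size, size, 3))
  for (ch in 1:3) {
    plane <- matrix(bg[ch], size, size)
    plane[inside] <- lesion_col[ch]
    px[, , ch] <- plane + stats::rnorm(size * size, 0, 0.02)
  }
  quantize8(px)
}

#' Write labelled images as PNG files
#'
#' Writes `<out>/melanoma/<id>.png` and `<out>/not_melanoma/<id>.png`.
#'
#' @param images An image table (see [synth_images()]).
#' @param out Output directory, created if absent.
#' @return `out`, invisibly.
#' @export
write_images <- function(images, out) {
  check_image_tbl(images)
  for (d in file.path(out, c("melanoma", "not_melanoma"))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  for (i in seq_len(nrow(images))) {
    cls <- if (images$label[i] == LABEL_POS) "melanoma" else "not_melanoma"
    png::writePNG(images$pixels[[i]], file.path(out, cls, paste0(images$id[i], ".png")))
  }
  invisible(out)
}

#' Read a labelled image directory tree
#'
#' Expects `<root>/<class>/*.png|jpg` with class directories `melanoma`
#' (label +1) and anything else (label -1). JPEG is accepted only when a
#' reader is available; the bundled reader handles PNG.
#'
#' @param root Directory containing one subdirectory per class.
#' @return An image table (id, label, provenance, pixels).
#' @export
read_images <- function(root) {
  classes <- list.dirs(root, recursive = FALSE)
  if (length(classes) == 0L) abort("No class subdirectories found.")
  rows <- list()
  for (d in classes) {
    lab <- if (basename(d) == "melanoma") LABEL_POS else LABEL_NEG
    for (f in list.files(d, pattern = "\\.png$", full.names = TRUE)) {
      px <- png::readPNG(f)
      if (length(dim(px)) == 2L) px <- array(rep(px, 3), dim = c(dim(px), 3))
      px <- px[, , 1:3, drop = FALSE]
      rows[[length(rows) + 1L]] <- tibble(
        id = sub("\\.png$", "", basename(f)), label = lab,
        provenance = "original", pixels = list(quantize8(px))
      )
    }
  }
  dplyr::bind_rows(rows)
}
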