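#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Labels are coded +1 (melanoma) / -1 (not-melanoma) throughout.
LABEL_POS <- 1L
LABEL_NEG <- -1L

check_labels <- function(labels, arg = "label") {
  if (!all(labels %in% c(-1L, 1L))) {
    abort(paste0("`", arg, "` must only contain +1 (melanoma) and -1 (not-melanoma)."))
  }
  invisible(as.integer(labels))
}

# Deterministic child seed from a root seed and a stream index.
# Kept strictly below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + as.double(stream) * 7919 + 1) %% 2147483647)
}

# Columns holding feature values in a feature table: f0, f1, ...
feature_cols <- function(tbl) {
  grep("^f[0-9]+$", names(tbl), value = TRUE)
}

feature_matrix_of <- function(tbl) {
  cols <- feature_cols(tbl)
  if (length(cols) == 0L) abort("No feature columns (f0, f1, ...) found.")
  m <- as.matrix(tbl[cols])
  storage.mode(m) <- "double"
  m
}

check_feature_tbl <- function(tbl, arg = "features") {
  if (!is.data.frame(tbl)) abort(paste0("`", arg, "` must be a data frame."))
  if (!all(c("id", "label") %in% names(tbl))) {
    abort(paste0("`", arg, "` must have `id` and `label` columns."))
  }
  check_labels(tbl$label)
  invisible(tbl)
}

# 8-bit quantisation of a [0,1] pixel array; all stored images satisfy this,
# which makes "number of distinct colours" a well-defined count.
quantize8 <- function(px) {
  round(pmin(pmax(px, 0), 1) * 255) / 255
}

n_distinct_colors <- function(pixels) {
  nrow(unique(pixels_to_rgb_matrix(pixels)))
}

pixels_to_rgb_matrix <- function(pixels) {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  cbind(c(pixels[, , 1]), c(pixels[, , 2]), c(pixels[, , 3]))
}

rgb_matrix_to_pixels <- function(m, h, w) {
  array(c(m[, 1], m[, 2], m[, 3]), dim = c(h, w, 3))
}

check_image_tbl <- function(images, arg = "images") {
  if (!is.data.frame(images) ||
      !all(c("id", "label", "provenance", "pixels") %in% names(images))) {
    abort(paste0("`", arg, "` must be an image table with columns id, label, provenance, pixels."))
  }
  check_labels(images$label)
  invisible(images)
}
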