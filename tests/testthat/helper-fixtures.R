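# Small fixtures shared across tests; everything is generated in code.

tiny_images <- function(n_mel = 3, n_ben = 4, size = 24, seed = 11, contrast = 0.6) {
  synth_images(synth_image_spec(n_mel, n_ben, image_size = size,
                                lesion_contrast = contrast, seed = seed))
}

sep_features <- function(n_per_class = 25, dims = c(8, 12), sep = 10, seed = 42) {
  synth_features(synth_feature_spec(n_per_class, dims = dims,
                                    class_separation = sep, seed = seed))
}

# 80/20 id split, deterministic
split_ids <- function(ids, frac = 0.8, seed = 1) {
  withr::with_seed(seed, {
    train <- sample(ids, round(frac * length(ids)))
    list(train = train, test = setdiff(ids, train))
  })
}

# Independent loop-based re-implementation of the fusion rule, used as a
# brute-force oracle: count votes per column, break ties by mean supporting
# score then towards -1, average modal scores, take the highest-scoring
# column (first on ties).
oracle_fuse <- function(D, S) {
  m <- ncol(D)
  dm <- numeric(m); ds <- numeric(m)
  for (j in 1:m) {
    pos <- 0; neg <- 0
    for (i in 1:nrow(D)) if (D[i, j] == 1) pos <- pos + 1 else neg <- neg + 1
    if (pos > neg) v <- 1
    else if (neg > pos) v <- -1
    else {
      sp <- mean(S[D[, j] == 1, j]); sn <- mean(S[D[, j] == -1, j])
      v <- if (sp > sn) 1 else -1
    }
    tot <- 0; cnt <- 0
    for (i in 1:nrow(D)) if (D[i, j] == v) { tot <- tot + S[i, j]; cnt <- cnt + 1 }
    dm[j] <- v; ds[j] <- tot / cnt
  }
  best <- 1
  for (j in 1:m) if (ds[j] > ds[best]) best <- j
  list(label = dm[best], score = ds[best], winner = best)
}

random_confusion <- function() {
  # all margins positive by construction
  counts <- as.list(sample(1:50, 4, replace = TRUE))
  names(counts) <- c("tp", "fp", "tn", "fn")
  structure(counts, class = "lf_confusion")
}
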