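# The decision-fusion core: combination grid, per-image decision/score
# matrices, column modes and the argmax-of-modal-scores rule.

grid_fixture <- function(n_per_class = 15, dims = c(5, 7, 4), sep = 8, seed = 55) {
  fs <- synth_features(synth_feature_spec(n_per_class, dims = dims,
                                          class_separation = sep, seed = seed))
  sp <- split_ids(fs[[1]]$id, 0.8, seed = 4)
  list(features = fs, train = sp$train, test = sp$test)
}

test_that("fit_grid fits the full classifier-by-feature cross product", {
  fx <- grid_fixture()
  grid <- fit_grid(fx$features, default_bucket(), fx$train)
  expect_s3_class(grid, "lf_grid")
  expect_length(grid$models, 5)
  expect_length(grid$models[[1]], 3)
  expect_equal(length(unlist(grid$models, recursive = FALSE)), 15)
  expect_error(fit_grid(fx$features, list(), fx$train), "at least one")
})

test_that("fit_grid rejects ids missing from a feature set", {
  fx <- grid_fixture()
  short <- fx$features
  short[[2]] <- short[[2]][-1, ]
  missing_id <- setdiff(fx$features[[2]]$id, short[[2]]$id)
  if (missing_id %in% fx$train) {
    expect_error(fit_grid(short, default_bucket()[4], fx$train), "missing ids")
  } else {
    expect_error(fit_grid(short, default_bucket()[4], c(fx$train, missing_id)), "missing ids")
  }
})

test_that("score_image matrices match per-model predictions element-wise", {
  fx <- grid_fixture(dims = c(5, 7))
  bucket <- default_bucket()[c(2, 4, 5)]
  grid <- fit_grid(fx$features, bucket, fx$train)
  id <- fx$test[1]
  ds <- score_image(grid, id)
  expect_equal(dim(ds$D), c(3L, 2L))
  expect_equal(dim(ds$S), c(3L, 2L))
  expect_true(all(ds$D %in% c(-1L, 1L)))
  expect_true(all(ds$S >= 0 & ds$S <= 1))
  for (i in 1:3) {
    for (j in 1:2) {
      f <- fx$features[[j]]
      pr <- predict(grid$models[[i]][[j]], f[f$id == id, ])
      expect_equal(ds$D[i, j], pr$label)
      expect_equal(ds$S[i, j], pr$score)
    }
  }
  expect_error(score_image(grid, "no_such_id"), "Unknown id")
})

test_that("discrete_mode returns the majority and its row indices", {
  expect_equal(discrete_mode(c(1, 1, -1)), list(value = 1L, indices = c(1L, 2L)))
  expect_equal(discrete_mode(c(-1, -1, -1)), list(value = -1L, indices = 1:3))
  # tie broken by mean supporting score
  expect_equal(discrete_mode(c(1, -1), scores = c(0.9, 0.6)),
               list(value = 1L, indices = 1L))
  expect_equal(discrete_mode(c(1, -1), scores = c(0.6, 0.9)),
               list(value = -1L, indices = 2L))
  # fully tied: defaults to not-melanoma, configurable to melanoma
  expect_equal(discrete_mode(c(1, -1), scores = c(0.7, 0.7))$value, -1L)
  expect_equal(discrete_mode(c(1, -1), scores = c(0.7, 0.7), tie = "positive")$value, 1L)
  expect_error(discrete_mode(integer(0)), "Empty")
})

test_that("grouped_mode evaluates the interpolation formula", {
  expect_equal(grouped_mode(l = 10, h = 5, f1 = 20, f0 = 10, f2 = 15), 40 / 3)
  # symmetric neighbours put the mode mid-interval
  expect_equal(grouped_mode(l = 2, h = 4, f1 = 9, f0 = 3, f2 = 3), 2 + 4 / 2)
  # f1 == f0 collapses to the lower limit
  expect_equal(grouped_mode(l = 7, h = 2, f1 = 5, f0 = 5, f2 = 1), 7)
  expect_error(grouped_mode(1, 0, 3, 1, 1), "positive")
  expect_error(grouped_mode(1, 2, 3, 3, 3), "undefined")
})

test_that("fuse reproduces the hand-worked example", {
  D <- matrix(c(1, 1, -1, -1, 1, -1), nrow = 3)
  S <- matrix(c(0.9, 0.8, 0.55, 0.6, 0.7, 0.95), nrow = 3)
  fu <- fuse(D, S)
  expect_equal(fu$dm, c(1L, -1L))
  expect_equal(fu$ds, c(0.85, 0.775))
  expect_equal(fu$final_label, 1L)
  expect_equal(fu$final_score, 0.85)
  expect_equal(fu$winning_feature, 1L)
})

test_that("fuse validates its inputs", {
  expect_error(fuse(matrix(integer(0), 0, 0), matrix(numeric(0), 0, 0)), "Empty")
  expect_error(fuse(matrix(1, 2, 2), matrix(0.5, 2, 3)), "identical shape")
  expect_error(fuse(matrix(2, 1, 1), matrix(0.5, 1, 1)), "only contain")
  expect_error(fuse(matrix(1, 1, 1), matrix(1.5, 1, 1)), "\\[0, 1\\]")
})

test_that("unanimous decisions win with the best column mean as confidence", {
  S <- matrix(c(0.6, 0.7, 0.95, 0.8), nrow = 2)
  fu <- fuse(matrix(1, 2, 2), S)
  expect_equal(fu$final_label, 1L)
  expect_equal(fu$final_score, max(colMeans(S)))
})

test_that("a 1x1 grid passes the single model's prediction through", {
  fu <- fuse(matrix(-1, 1, 1), matrix(0.81, 1, 1))
  expect_equal(fu$final_label, -1L)
  expect_equal(fu$final_score, 0.81)
  expect_equal(fu$winning_feature, 1L)
})

test_that("a strict majority for one class in every column decides the label", {
  withr::with_seed(8, {
    for (rep in 1:25) {
      n <- sample(3:5, 1); m <- sample(1:3, 1)
      v <- sample(c(-1L, 1L), 1)
      D <- matrix(v, n, m)
      # flip a strict minority per column
      for (j in seq_len(m)) {
        flip <- sample(n, sample.int(floor((n - 1) / 2) + 1, 1) - 1)
        D[flip, j] <- -v
      }
      S <- matrix(runif(n * m), n, m)
      expect_equal(fuse(D, S)$final_label, v)
    }
  })
})

test_that("fusing is equivariant under column permutation", {
  withr::with_seed(9, {
    for (rep in 1:20) {
      n <- sample(2:5, 1); m <- sample(2:4, 1)
      D <- matrix(sample(c(-1L, 1L), n * m, replace = TRUE), n, m)
      S <- matrix(round(runif(n * m), 3), n, m)
      perm <- sample(m)
      fu <- fuse(D, S)
      fup <- fuse(D[, perm, drop = FALSE], S[, perm, drop = FALSE])
      expect_equal(fup$dm, fu$dm[perm])
      expect_equal(fup$ds, fu$ds[perm])
      expect_equal(fup$final_label, fu$final_label)
      expect_equal(fup$final_score, fu$final_score)
    }
  })
})

test_that("modal scores are means of score subsets, hence within [min S, max S]", {
  withr::with_seed(10, {
    for (rep in 1:20) {
      n <- sample(1:5, 1); m <- sample(1:4, 1)
      D <- matrix(sample(c(-1L, 1L), n * m, replace = TRUE), n, m)
      S <- matrix(runif(n * m), n, m)
      fu <- fuse(D, S)
      expect_true(all(fu$ds >= min(S) - 1e-12 & fu$ds <= max(S) + 1e-12))
    }
  })
})

test_that("tidy() lays the fusion out one row per feature column", {
  fu <- fuse(matrix(c(1, -1, 1, 1), 2), matrix(c(0.9, 0.6, 0.7, 0.8), 2))
  td <- tidy(fu)
  expect_equal(nrow(td), 2)
  expect_equal(sum(td$winner), 1)
  expect_equal(td$modal_decision[td$winner], fu$final_label)
})
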