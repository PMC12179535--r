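# Unit tests of the MIL model surface on small seeded fixtures.

rand_tile <- function(n = 16, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::runif(n * n * 3), c(n, n, 3))
}

test_that("tile encoding is deterministic and permutation-equivariant", {
  m <- tiny_model("max")
  tiles <- lapply(1:4, function(i) rand_tile(8, seed = i))
  f1 <- encode_tiles(tiles, m)
  f2 <- encode_tiles(tiles, m)
  expect_identical(f1, f2)
  expect_equal(f1[1, ], f1[1, ])
  # identical tiles encode identically
  fd <- encode_tiles(list(tiles[[1]], tiles[[1]]), m)
  expect_equal(fd[1, ], fd[2, ], tolerance = 1e-12)
  # permuting the bag permutes the rows, same set of features
  fp <- encode_tiles(tiles[c(3, 1, 4, 2)], m)
  expect_equal(fp, f1[c(3, 1, 4, 2), ], tolerance = 1e-12)
})

test_that("a zero tile through a bias-free backbone encodes to zero", {
  m <- tiny_model("max")
  for (k in seq_along(m$params$conv)) m$params$conv[[k]]$b[] <- 0
  m$params$proj_b[] <- 0
  f <- encode_tiles(list(array(0, c(8, 8, 3))), m)
  expect_equal(max(abs(f)), 0)
})

test_that("bag aggregation obeys the pooling contracts", {
  # element-wise max on a toy pair
  f <- rbind(c(1, 0), c(0, 1))
  expect_equal(as.vector(aggregate_features(f, "max")), c(1, 1))
  # single-tile bags are identity under both poolings
  m <- tiny_model("attention")
  one <- matrix(stats::rnorm(16), 1)
  expect_equal(as.vector(aggregate_features(one, "max")), as.vector(one))
  expect_equal(as.vector(aggregate_features(one, "attention", m)),
               as.vector(one), tolerance = 1e-12)
  expect_error(aggregate_features(matrix(0, 0, 16), "max"), "empty")
  # attention weights lie on the simplex for many random bags
  set.seed(33)
  for (i in 1:1000) {
    ft <- matrix(stats::rnorm(5 * 16, sd = 2), 5)
    a <- attr(aggregate_features(ft, "attention", m), "attention")
    expect_true(all(a >= 0))
    expect_lt(abs(sum(a) - 1), 1e-6)
  }
})

test_that("the classification head matches hand-computed arithmetic", {
  # softmax(relu(f) W + b) on a worked 4-feature example:
  # relu(f) = (1, 2, 0.5, 0)
  # z1 = 0.2 - 0.2 + 0.2 + 0.3   = 0.5
  # z2 = -0.3 + 0.4 + 0.05 - 0.05 = 0.1
  # p1 = 1 / (1 + e^-0.4) = 0.5986877
  f <- c(1, 2, 0.5, -1)
  w <- cbind(c(0.2, -0.1, 0.4, 0.3), c(-0.3, 0.2, 0.1, 0.5))
  p <- classify_bag(f, w, c(0.3, -0.05))
  expect_equal(unname(p), c(0.5986877, 0.4013123), tolerance = 1e-6)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  # zero weights and bias give symmetric logits
  expect_equal(unname(classify_bag(f, matrix(0, 4, 2), c(0, 0))),
               c(0.5, 0.5))
})

test_that("bag predictions are invariant to tile order and duplication", {
  tiles <- lapply(1:6, function(i) rand_tile(8, seed = 10 + i))
  for (pooling in c("max", "attention")) {
    m <- tiny_model(pooling)
    p0 <- as.numeric(predict_sample(m, tiles))
    for (r in 1:5) {
      perm <- sample(length(tiles))
      expect_equal(as.numeric(predict_sample(m, tiles[perm])), p0,
                   tolerance = 1e-6)
    }
    # duplicating the whole bag changes nothing under either pooling
    expect_equal(as.numeric(predict_sample(m, c(tiles, tiles))), p0,
                 tolerance = 1e-9)
  }
  # max pooling is additionally invariant to duplicating single tiles
  m <- tiny_model("max")
  p0 <- as.numeric(predict_sample(m, tiles))
  expect_equal(as.numeric(predict_sample(m, c(tiles, tiles[3]))), p0,
               tolerance = 1e-12)
})

test_that("single-tile scoring is consistent with bag prediction", {
  m <- tiny_model("max")
  t1 <- rand_tile(8, seed = 5)
  expect_identical(score_tile(m, t1), as.numeric(predict_sample(m, list(t1))))
})

test_that("the VGG-19-like backbone honours the 512-feature contract", {
  m <- mil_model("vgg19_like", "max", seed = 2)
  expect_length(m$channels, 16L)
  expect_identical(m$channels[length(m$channels)], 512L)
  f <- encode_tiles(list(array(stats::runif(32 * 32 * 3), c(32, 32, 3))), m)
  expect_identical(dim(f), c(1L, 512L))
  expect_true(all(is.finite(f)))
  # five pooling stages: tiles must divide by 32
  expect_error(encode_tiles(list(array(0.5, c(48, 48, 3))), m),
               "divisible by 32")
})

test_that("incompatible tile sizes raise a divisibility error", {
  m <- mil_model("small_cnn", "max", seed = 1)
  expect_error(predict_sample(m, list(rand_tile(12))), "divisible by 8")
})

test_that("an empty tile list is unevaluable, not an error", {
  m <- tiny_model("max")
  expect_warning(p <- predict_sample(m, list()), "no tiles")
  expect_true(is.na(p))
})

test_that("training is reproducible and reports resampling", {
  cfg <- test_cfg(seed = 61, n = 2)
  cohort <- prepare_cohort(cfg)
  samples <- lapply(cohort$samples, function(s) {
    s$label <- s$class
    s
  })
  m0 <- mil_model("small_cnn", "max", seed = 5, bag_size = 20)
  expect_message(m1 <- mil_train(m0, samples, epochs = 2),
                 "fewer than 20 tiles")
  m2 <- suppressMessages(mil_train(m0, samples, epochs = 2))
  expect_identical(m1$params$cls_w, m2$params$cls_w)
  expect_identical(m1$history, m2$history)
  # on-the-fly augmentation changes the trajectory but stays reproducible
  ma <- suppressMessages(mil_train(m0, samples, epochs = 2,
                                   augment_fn = augment_tile))
  mb <- suppressMessages(mil_train(m0, samples, epochs = 2,
                                   augment_fn = augment_tile))
  expect_identical(ma$history, mb$history)
  expect_false(identical(ma$history$loss, m1$history$loss))
  expect_error(suppressMessages(mil_train(m0, samples[1:2], epochs = 1)),
               "2 samples of each class")
})

test_that("training on separable texture classes halves the loss and
           yields confident, class-pure tile scores", {
  cfg <- test_cfg(seed = 63, n = 4)
  cohort <- prepare_cohort(cfg)
  samples <- lapply(cohort$samples, function(s) { s$label <- s$class; s })
  m <- mil_model("small_cnn", "max", lr = 0.01, seed = 11)
  m <- suppressMessages(mil_train(m, samples, epochs = 150))
  l <- m$history$loss
  expect_lt(l[length(l)], 0.5 * l[1])
  # single-tile scores of the converged model are confident enough to pass
  # the 0.9 cutoff, and the retained tiles carry the planted class texture
  hc <- suppressWarnings(select_high_confidence(samples, m, cutoff = 0.9,
                                                per_sample = 8, seed = 3))
  retained <- rbind(hc$hypoxic, hc$normoxic)
  expect_gte(nrow(retained), 10)
  expect_gte(mean(retained$predicted == retained$true_class), 0.8)
  # activation maps of the trained model localise a planted lesion: a
  # hypoxic-texture patch inside an otherwise normoxic tile
  set.seed(31)
  lesion <- hypoxmorph:::render_tissue(32, 32, "normoxic", cfg, 0)
  lesion[9:24, 9:24, ] <- hypoxmorph:::render_tissue(16, 16, "hypoxic", cfg, 0)
  am <- activation_map(m, lesion, class = "hypoxic")
  expect_true(all(am >= 0 & am <= 1))
  inside <- mean(am[9:24, 9:24])
  outside <- (mean(am[1:8, ]) + mean(am[25:32, ]) +
              mean(am[9:24, c(1:8, 25:32)])) / 3
  expect_gt(inside, outside)
})

test_that("split metrics reduce to known values on constructed predictions", {
  pred <- data.frame(
    sample_id = paste0("s", 1:8),
    prob = c(0.9, 0.8, 0.85, 0.95, 0.1, 0.2, 0.15, 0.05),
    label = rep(c("hypoxic", "normoxic"), each = 4),
    stratum = c("high", "low", "high", "low", rep("normoxic", 4)))
  ms <- evaluate_split(pred)
  expect_equal(ms$auroc, c(1, 1, 1))
  expect_equal(ms$accuracy, c(1, 1, 1))
  expect_equal(ms$recall, c(1, 1, 1))
  # constant predictions rank nothing: chance AUROC
  pred$prob <- 0.5
  expect_equal(evaluate_split(pred)$auroc, c(0.5, 0.5, 0.5))
  # a 4-sample set agrees with the rank-sum (Mann-Whitney) relation
  pred4 <- data.frame(sample_id = paste0("s", 1:4),
                      prob = c(0.9, 0.4, 0.6, 0.1),
                      label = c("hypoxic", "hypoxic", "normoxic", "normoxic"),
                      stratum = c("high", "low", "normoxic", "normoxic"))
  expect_equal(evaluate_split(pred4)$auroc[1], 0.75)
  expect_equal(oracle_auroc(pred4$label, pred4$prob), 0.75)
})

test_that("metrics for an empty stratum are excluded from the average", {
  pred <- data.frame(sample_id = paste0("s", 1:4),
                     prob = c(0.9, 0.8, 0.2, 0.1),
                     label = c("hypoxic", "hypoxic", "normoxic", "normoxic"),
                     stratum = c("low", "low", "normoxic", "normoxic"))
  m1 <- evaluate_split(pred)
  expect_true(is.na(m1$auroc[m1$subset == "high"]))
  agg <- evaluate_splits(list(m1, m1))
  expect_identical(agg$n_splits_used[agg$subset == "high"], 0L)
  expect_identical(agg$n_splits_used[agg$subset == "low"], 2L)
})

test_that("activation maps are normalised and flat for uniform input", {
  m <- tiny_model("max")
  t1 <- rand_tile(16, seed = 2)
  am <- activation_map(m, t1)
  expect_identical(dim(am), c(16L, 16L))
  expect_true(all(am >= 0 & am <= 1))
  # a uniform tile gives a spatially constant response away from the
  # zero-padding border ring of the convolutions
  flat <- activation_map(m, array(0.5, c(16, 16, 3)))
  expect_lt(diff(range(flat[5:12, 5:12])), 0.1)
})
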