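test_that("activation maps obey count, shape and degenerate-range conventions", {
  em <- new_embedder(embed_config(image_size = 8, pool = 4,
                                  conv_channels = 5, d = 8), seed = 31)
  x <- with_seed(32, as_image(array(stats::runif(192, -1, 1), c(8, 8, 3))))
  maps <- activation_maps(em, x, "conv")
  expect_identical(dim(maps), c(8L, 8L, 5L))
  expect_true(all(maps >= 0 & maps <= 1))
  pooled <- activation_maps(em, x, "pool")
  expect_identical(dim(pooled), c(8L, 8L, 5L))

  # constant channels (zeroed conv weights) normalise to all-zero maps
  em0 <- em; em0$params$Wc[] <- 0; em0$params$bc[] <- 1
  maps0 <- activation_maps(em0, x, "conv")
  expect_identical(max(abs(maps0)), 0)
})

test_that("a single-channel layer reduces the heatmap to that channel's map", {
  em1 <- new_embedder(embed_config(image_size = 8, pool = 4,
                                   conv_channels = 1, d = 8), seed = 33)
  g <- with_seed(34, as_image(array(stats::runif(192, -1, 1), c(8, 8, 3))))
  cand <- with_seed(35, as_image(array(stats::runif(192, -1, 1), c(8, 8, 3))))
  hm <- similarity_scorecam(em1, g, cand, "conv")
  expect_identical(hm$weights, 1)
  expect_equal(hm$values, activation_maps(em1, cand, "conv")[, , 1])
})

test_that("the weighted heatmap matches an independently coded scalar loop", {
  for (case in 1:10) {
    em <- new_embedder(embed_config(image_size = 8, pool = 4,
                                    conv_channels = 4, d = 6),
                       seed = 40 + case)
    g <- with_seed(60 + case,
                   as_image(array(stats::runif(192, -1, 1), c(8, 8, 3))))
    cand <- with_seed(80 + case,
                      as_image(array(stats::runif(192, -1, 1), c(8, 8, 3))))
    hm <- similarity_scorecam(em, g, cand, "conv")

    # oracle: per-channel masking and scoring, one image at a time
    maps <- activation_maps(em, cand, "conv")
    eg <- embed(em, g)
    sc <- numeric(4)
    for (k in 1:4) {
      masked <- unclass(cand)
      for (ch in 1:3) masked[, , ch] <- masked[, , ch] * maps[, , k]
      ek <- embed(em, as_image(masked))
      sc[k] <- -sum((eg - ek)^2)
    }
    wk <- exp(sc - max(sc)); wk <- wk / sum(wk)
    acc <- matrix(0, 8, 8)
    for (k in 1:4) acc <- acc + wk[k] * maps[, , k]
    rng <- range(acc)
    oracle <- if (diff(rng) > 0) (acc - rng[1]) / diff(rng) else acc * 0
    expect_equal(hm$values, oracle, tolerance = 1e-12)
    expect_equal(unname(hm$weights), wk, tolerance = 1e-12)
    expect_equal(sum(hm$weights), 1)
  }
})

test_that("heatmaps are invariant to a uniform shift of all scores", {
  # softmax weights depend on score differences only; shifting the guide's
  # embedding origin or adding a constant leaves the map unchanged
  em <- new_embedder(embed_config(image_size = 8, pool = 4,
                                  conv_channels = 3, d = 6), seed = 51)
  g <- with_seed(52, as_image(array(stats::runif(192, -1, 1), c(8, 8, 3))))
  cand <- with_seed(53, as_image(array(stats::runif(192, -1, 1), c(8, 8, 3))))
  hm <- similarity_scorecam(em, g, cand, "conv")
  w2 <- exp((hm$scores + 5) - max(hm$scores + 5))
  expect_equal(unname(hm$weights), unname(w2 / sum(w2)), tolerance = 1e-12)
})

test_that("heatmaps localise the structure that drives embedding similarity", {
  # a toy matching task: one class carries a bright disk at a fixed
  # location on noise, the other does not; after triplet training the
  # heatmap between two disk images should concentrate on the disk
  set.seed(71)
  n <- 40; S <- 16L
  disk <- matrix(FALSE, S, S)
  disk[6:11, 6:11][outer(-2.5:2.5, -2.5:2.5,
                         function(a, b) a^2 + b^2) <= 9] <- TRUE
  mk <- function(has_disk) {
    img <- array(stats::rnorm(S * S * 3, -0.5, 0.2), c(S, S, 3))
    if (has_disk) for (ch in 1:3) img[, , ch][disk] <- 0.8
    pmin(pmax(img, -1), 1)
  }
  X <- do.call(rbind, lapply(seq_len(n), function(i)
    as.numeric(mk(i <= n / 2))))
  lab <- rep(condition_levels(), each = n / 2)
  em <- train_stage2(X, lab,
                     config = embed_config(image_size = S,
                                           conv_channels = 6, d = 8),
                     steps = 250, batch_size = 16, p_gen = 0, seed = 72)
  k <- sum(disk)
  ious <- vapply(3:8, function(j) {
    hm <- similarity_scorecam(em, array(X[1, ], c(S, S, 3)),
                              array(X[j, ], c(S, S, 3)), "conv")
    top <- hm$values >= sort(hm$values, decreasing = TRUE)[k]
    sum(top & disk) / sum(top | disk)
  }, numeric(1))
  expect_gt(mean(ious), 0.3)
})

test_that("overlay PNGs are written with valid dimensions", {
  em <- new_embedder(embed_config(image_size = 8, pool = 4, d = 6), seed = 71)
  g <- with_seed(72, as_image(array(stats::runif(192, -1, 1), c(8, 8, 3))))
  hm <- similarity_scorecam(em, g, g, "conv")
  f <- tempfile(fileext = ".png")
  write_heatmap_png(hm, g, f)
  u <- png::readPNG(f)
  expect_identical(dim(u)[1:2], c(8L, 8L))
})
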