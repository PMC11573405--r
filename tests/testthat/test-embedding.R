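test_that("embeddings are deterministic with the configured dimension", {
  em <- new_embedder(embed_config(image_size = 8, pool = 4, d = 24), seed = 2)
  x <- with_seed(3, as_image(array(stats::runif(192, -1, 1), c(8, 8, 3))))
  e1 <- embed(em, x); e2 <- embed(em, x)
  expect_identical(e1, e2)
  expect_length(e1, 24L)
  X <- with_seed(4, matrix(stats::runif(5 * 192, -1, 1), 5))
  expect_identical(dim(embed(em, X)), c(5L, 24L))
  expect_error(embed(em, matrix(0, 1, 100)), "geometry")
})

test_that("triplet loss matches its closed-form edge cases", {
  a <- matrix(c(1, 0), 1)
  n2 <- matrix(c(1 + sqrt(2), 0), 1)      # squared distance 2
  expect_equal(triplet_loss(a, a, n2, margin = 1), 0)
  # equal distances leave exactly the margin
  p <- matrix(c(2, 0), 1); n <- matrix(c(0, 0), 1)
  expect_equal(sum((a - p)^2), sum((a - n)^2))
  expect_equal(triplet_loss(a, p, n, margin = 1), 1)
  expect_error(triplet_loss(a[0, , drop = FALSE], p[0, , drop = FALSE],
                            n[0, , drop = FALSE]), "empty")
  expect_error(triplet_loss(a, p, n, margin = -1), "margin")
})

test_that("batched triplet loss equals an independently coded scalar loop", {
  for (case in 1:10) {
    set.seed(900 + case)
    nb <- sample(3:8, 1); d <- sample(2:6, 1)
    A <- matrix(rnorm(nb * d), nb); P <- matrix(rnorm(nb * d), nb)
    N <- matrix(rnorm(nb * d), nb)
    alpha <- runif(1, 0.2, 2)
    # brute-force oracle: plain scalar accumulation
    tot <- 0
    for (i in seq_len(nb)) {
      dap <- 0; dan <- 0
      for (j in seq_len(d)) {
        dap <- dap + (A[i, j] - P[i, j])^2
        dan <- dan + (A[i, j] - N[i, j])^2
      }
      h <- dap - dan + alpha
      tot <- tot + max(0, h)
    }
    expect_equal(triplet_loss(A, P, N, margin = alpha), tot / nb,
                 tolerance = 1e-12)
  }
})

test_that("triplet sampling respects sources, labels and p_gen", {
  real <- rep(c("infected", "uninfected"), c(6, 6))
  synth <- rep(c("infected", "uninfected"), c(5, 5))
  t0 <- sample_triplets(real, synth, p_gen = 0, rng_seed = 1, batch_size = 50)
  expect_true(all(t0$pair_source == "real"))
  t1 <- sample_triplets(real, synth, p_gen = 1, rng_seed = 2, batch_size = 50)
  expect_true(all(t1$pair_source == "synthetic"))
  for (tr in list(t0, t1)) {
    pool <- if (tr$pair_source[1] == "real") real else synth
    expect_true(all(pool[tr$pos] == tr$anchor_label))
    expect_true(all(pool[tr$neg] != tr$anchor_label))
    expect_true(all(real[tr$anchor] == tr$anchor_label))
  }
  # real-pool positives never reuse the anchor itself
  expect_true(all(t0$pos != t0$anchor))
  expect_error(sample_triplets(rep("infected", 4), synth, p_gen = 0.5),
               "both classes")
})

test_that("the synthetic-pair frequency is binomially consistent with p_gen", {
  real <- rep(c("infected", "uninfected"), 10)
  synth <- rep(c("infected", "uninfected"), 5)
  n <- 1e4
  tr <- sample_triplets(real, synth, p_gen = 0.2, rng_seed = 7, batch_size = n)
  frac <- mean(tr$pair_source == "synthetic")
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / n))
})

test_that("distance classification takes the argmin and breaks ties conservatively", {
  em <- new_embedder(embed_config(image_size = 8, pool = 4, d = 8), seed = 5)
  g <- with_seed(6, as_image(array(stats::runif(192, -1, 1), c(8, 8, 3))))
  other <- with_seed(7, as_image(array(stats::runif(192, -1, 1), c(8, 8, 3))))
  # synthesis identical to the guide for y1: distance exactly 0
  res <- classify_distance(g, list(uninfected = g, infected = other), em)
  expect_identical(res$predicted, "uninfected")
  expect_identical(unname(res$distances["uninfected"]), 0)
  expect_gt(res$margin, 0)
  res2 <- classify_distance(g, list(uninfected = other, infected = g), em)
  expect_identical(res2$predicted, "infected")
  # exact tie: both syntheses identical -> uninfected by convention
  tie <- classify_distance(g, list(uninfected = other, infected = other), em)
  expect_identical(tie$predicted, "uninfected")
  expect_identical(unname(tie$margin), 0)
  expect_error(classify_distance(g, list(uninfected = g), em), "missing")
})

test_that("triplet training separates the classes and keeps the best validation checkpoint", {
  world <- get_toy_world()
  em <- world$embedder
  held <- split_matrix(world$ds, c("val", "test"))
  E <- embed(em, held$x)
  dmat <- as.matrix(stats::dist(E))^2
  same <- outer(held$labels, held$labels, "==") & upper.tri(dmat)
  diff_ <- outer(held$labels, held$labels, "!=") & upper.tri(dmat)
  expect_lt(mean(dmat[same]), mean(dmat[diff_]))

  h <- em$history
  expect_true(!is.null(h$val_accuracy))
  expect_identical(h$best_accuracy, max(h$val_accuracy$accuracy))
  expect_true(h$best_step %in% h$val_accuracy$step)
})

test_that("stage-2 training drives the loss down on a separable toy task", {
  set.seed(21)
  n <- 20; D <- 8 * 8 * 3
  base <- matrix(runif(n * D, -0.2, 0.2), n)
  lab <- rep(condition_levels(), each = n / 2)
  base[lab == "infected", 1:150] <- base[lab == "infected", 1:150] + 1
  em <- train_stage2(base, lab, config = embed_config(image_size = 8, d = 8),
                     steps = 250, batch_size = 16, p_gen = 0, seed = 22)
  final <- mean(tail(em$history$loss$loss, 10))
  expect_lt(final, 0.05)
})
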