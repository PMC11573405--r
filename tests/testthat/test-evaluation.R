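test_that("confusion metrics match hand arithmetic", {
  m <- metrics_from_confusion(confusion_counts(tp = 3, fp = 1, tn = 5, fn = 1))
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 5 / 6)
  expect_equal(m$ppv, 0.75)
  expect_equal(m$f1, 0.75)
  expect_error(confusion_counts(tp = -1, fp = 0, tn = 1, fn = 0),
               "non-negative")
  expect_error(confusion_counts(tp = 0, fp = 0, tn = 0, fn = 0), "empty")
})

test_that("metrics agree with an independent scalar formula set on random counts", {
  for (case in 1:100) {
    set.seed(2000 + case)
    cts <- as.list(sample(0:40, 4, replace = TRUE))
    names(cts) <- c("tp", "fp", "tn", "fn")
    if (sum(unlist(cts)) == 0) next
    m <- suppressWarnings(metrics_from_confusion(
      confusion_counts(tp = cts$tp, fp = cts$fp, tn = cts$tn, fn = cts$fn)))
    tot <- cts$tp + cts$fp + cts$tn + cts$fn
    expect_identical(m$accuracy, (cts$tp + cts$tn) / tot)
    if (cts$tp + cts$fn > 0)
      expect_identical(m$sensitivity, cts$tp / (cts$tp + cts$fn))
    if (cts$tn + cts$fp > 0)
      expect_identical(m$specificity, cts$tn / (cts$tn + cts$fp))
    if (cts$tp + cts$fp > 0)
      expect_identical(m$ppv, cts$tp / (cts$tp + cts$fp))
    if (!is.na(m$ppv) && !is.na(m$sensitivity) && m$ppv + m$sensitivity > 0)
      expect_equal(m$f1, 2 * m$ppv * m$sensitivity / (m$ppv + m$sensitivity))
  }
})

test_that("undefined ratios propagate as NA with a warning, never as zero", {
  expect_warning(m <- metrics_from_confusion(
    confusion_counts(tp = 0, fp = 0, tn = 5, fn = 3)), "PPV")
  expect_true(is.na(m$ppv))
  expect_true(is.na(m$f1))
  expect_false(is.na(m$specificity))
})

test_that("counts reconstructed from published rates reproduce derived metrics", {
  cc <- confusion_from_rates(0.75, 0.80, 40, 60)
  m <- metrics_from_confusion(cc)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 0.80)
  expect_equal(m$accuracy, (0.75 * 40 + 0.8 * 60) / 100)
})

# A deterministic stub pipeline: zero-noise denoiser plus a linear embedding
# function, enough to exercise the evaluation bookkeeping cheaply.
stub_pipeline <- function(D = 16 * 16 * 3) {
  set.seed(77)
  Wemb <- matrix(rnorm(D * 6, sd = 1 / sqrt(D)), D, 6)
  condiff_pipeline(function(x, step, label) {
    shift <- if (is.null(label)) 0 else if (label == "infected") 0.05 else -0.05
    x * 0.5 + shift
  },
  function(X) X %*% Wemb,
  sampler_config(omega = 0.75, t0 = 0.6, n_steps = 5, seed = 41),
  make_schedule(100))
}

test_that("k-fold evaluation folds subjects disjointly and averages exactly", {
  ds <- generate_wound_dataset(wound_spec(n_subjects = 12, image_size = 16,
                                          seed = 14),
                               fractions = c(0.4, 0.3, 0.3))
  pipe <- stub_pipeline()
  kf <- kfold_evaluate(ds$images, ds$manifest, pipe, k = 2, seed = 15)
  # folds are subject-disjoint
  by_subj <- tapply(kf$predictions$fold, kf$predictions$subject_id,
                    function(f) length(unique(f)))
  expect_true(all(by_subj == 1L))
  expect_equal(unname(kf$mean["accuracy"]),
               mean(kf$folds$accuracy))
  # population (divide-by-k) standard deviation convention
  expect_equal(unname(kf$sd["accuracy"]),
               sqrt(mean((kf$folds$accuracy - mean(kf$folds$accuracy))^2)))
  expect_error(kfold_evaluate(ds$images, ds$manifest, pipe, k = 1), "k")
})

test_that("a single-t0 sweep equals a plain evaluation run", {
  ds <- generate_wound_dataset(wound_spec(n_subjects = 6, image_size = 16,
                                          seed = 16))
  pipe <- stub_pipeline()
  sw <- sweep_t0(ds$images, ds$manifest, pipe, t0_values = 0.6)
  direct <- metrics_from_results(
    condiff_predict_batch(ds$images, ds$manifest, pipe))
  expect_equal(sw$accuracy, direct$accuracy)
  expect_identical(nrow(sweep_t0(ds$images, ds$manifest, pipe,
                                 t0_values = c(0.5, 0.7, 0.9))), 3L)
})

test_that("the divergence curve is zero at omega 0 and non-negative always", {
  ds <- generate_wound_dataset(wound_spec(n_subjects = 6, image_size = 16,
                                          seed = 17))
  X <- do.call(rbind, lapply(ds$images, as.numeric))
  pipe <- stub_pipeline()
  pipe0 <- pipe; pipe0$cfg$omega <- 0
  curve0 <- divergence_vs_t0(X, pipe0, c(0.5, 0.7, 0.9))
  expect_identical(curve0$divergence, c(0, 0, 0))
  curve <- divergence_vs_t0(X, pipe, c(0.5, 0.7, 0.9))
  expect_true(all(curve$divergence >= 0))
})
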