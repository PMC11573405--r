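#' Confusion counts
#'
#' Tallies a two-class confusion table with "infected" as the positive
#' class. Counts may be fractional when reconstructed from published rates
#' rather than raw predictions.
#'
#' @param truth,predicted label vectors (values in [condition_levels()]).
#' @param tp,fp,tn,fn alternatively, the counts directly.
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(truth = NULL, predicted = NULL,
                             tp = NULL, fp = NULL, tn = NULL, fn = NULL) {
  if (!is.null(truth)) {
    pos <- condition_levels()[2]
    tp <- sum(truth == pos & predicted == pos)
    fp <- sum(truth != pos & predicted == pos)
    tn <- sum(truth != pos & predicted != pos)
    fn <- sum(truth == pos & predicted != pos)
  }
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("confusion counts must be finite and non-negative", call. = FALSE)
  if (sum(counts) <= 0) stop("empty confusion table", call. = FALSE)
  structure(as.list(counts), class = "confusion_counts")
}

#' Confusion counts from published per-class rates
#'
#' Reconstructs (possibly fractional) counts from sensitivity, specificity
#' and the class composition of the test set — the only way to audit a
#' published metrics row without the underlying predictions.
#'
#' @param sensitivity,specificity per-class rates in `[0, 1]`.
#' @param n_pos,n_neg positive ("infected") and negative class sizes.
#' @return [confusion_counts()].
#' @export
confusion_from_rates <- function(sensitivity, specificity, n_pos, n_neg) {
  confusion_counts(tp = sensitivity * n_pos, fn = (1 - sensitivity) * n_pos,
                   tn = specificity * n_neg, fp = (1 - specificity) * n_neg)
}

#' Derived classification metrics
#'
#' Computes accuracy, sensitivity (recall on infected), specificity,
#' positive predictive value, and F1 as the harmonic mean of PPV and
#' sensitivity. A ratio with zero denominator is reported as `NA` with a
#' warning, never silently coerced to 0.
#'
#' @param c a [confusion_counts()].
#' @return object of class `metrics_report`: named list with `accuracy`,
#'   `f1`, `sensitivity`, `specificity`, `ppv`, plus the counts.
#' @export
metrics_from_confusion <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  n <- c$tp + c$fp + c$tn + c$fn
  safe_div <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined (zero denominator)",
                            call. = FALSE); return(NA_real_) }
    num / den
  }
  sen <- safe_div(c$tp, c$tp + c$fn, "sensitivity")
  spec <- safe_div(c$tn, c$tn + c$fp, "specificity")
  ppv <- safe_div(c$tp, c$tp + c$fp, "PPV")
  f1 <- f1_from_rates(ppv, sen)
  structure(list(accuracy = (c$tp + c$tn) / n, f1 = f1, sensitivity = sen,
                 specificity = spec, ppv = ppv, counts = c, n = n),
            class = "metrics_report")
}

#' F1 from PPV and sensitivity
#'
#' @param ppv,sensitivity component rates.
#' @return harmonic mean `2 * ppv * sen / (ppv + sen)` (`NA` if undefined).
#' @export
f1_from_rates <- function(ppv, sensitivity) {
  if (is.na(ppv) || is.na(sensitivity) || (ppv + sensitivity) == 0)
    return(NA_real_)
  2 * ppv * sensitivity / (ppv + sensitivity)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.3f | F1 %.3f | sensitivity %.3f | specificity %.3f | PPV %.3f (n=%g)\n",
    x$accuracy, x$f1, x$sensitivity, x$specificity, x$ppv, x$n))
  invisible(x)
}

metrics_row <- function(m) {
  data.frame(accuracy = m$accuracy, f1 = m$f1, sensitivity = m$sensitivity,
             specificity = m$specificity, ppv = m$ppv)
}

#' Metrics from a prediction table
#'
#' @param results data frame with `label` (truth) and `predicted` columns,
#'   as produced by [condiff_predict_batch()].
#' @return [metrics_from_confusion()] report.
#' @export
metrics_from_results <- function(results) {
  metrics_from_confusion(confusion_counts(results$label, results$predicted))
}

#' Subject-wise k-fold evaluation
#'
#' Splits the evaluation manifest into `k` subject-disjoint folds
#' (stratified by label), scores the fixed trained pipeline on each fold,
#' and reports per-fold metrics plus their mean and population standard
#' deviation (divide-by-k). A fold missing one of the classes is skipped
#' with a warning. The trained models are reused across folds; only the
#' evaluation set is folded.
#'
#' @param images named list (or `n x D` matrix) of evaluation images.
#' @param manifest data frame with `image_id`, `subject_id`, `label`.
#' @param pipe a [condiff_pipeline()].
#' @param k number of folds.
#' @param seed fold-assignment seed.
#' @return list with `folds` (per-fold metric rows), `mean`, `sd`,
#'   and `predictions` (the pooled prediction table).
#' @export
kfold_evaluate <- function(images, manifest, pipe, k = 5L, seed = 1L) {
  if (k < 2L) stop("`k` must be >= 2", call. = FALSE)
  subj <- unique(manifest[, c("subject_id", "label")])
  fold_of <- integer(0)
  for (lab in unique(subj$label)) {
    ids <- with_seed(hash_seed(seed, paste0("fold", lab)),
                     sample(subj$subject_id[subj$label == lab]))
    f <- rep_len(seq_len(k), length(ids))
    fold_of[ids] <- f
  }
  manifest$fold <- fold_of[manifest$subject_id]
  preds <- condiff_predict_batch(images, manifest, pipe)
  preds$fold <- manifest$fold[match(preds$image_id, manifest$image_id)]
  rows <- list()
  for (f in seq_len(k)) {
    sub <- preds[preds$fold == f, , drop = FALSE]
    if (length(unique(sub$label)) < 2L) {
      warning("fold ", f, " lacks a class; skipped", call. = FALSE)
      next
    }
    m <- metrics_row(metrics_from_results(sub))
    m$fold <- f
    rows[[length(rows) + 1L]] <- m
  }
  folds <- do.call(rbind, rows)
  metric_cols <- c("accuracy", "f1", "sensitivity", "specificity", "ppv")
  mu <- colMeans(folds[metric_cols])
  sdev <- apply(folds[metric_cols], 2,
                function(v) sqrt(mean((v - mean(v))^2)))
  list(folds = folds, mean = mu, sd = sdev, predictions = preds)
}

#' Noise-strength sweep
#'
#' Re-scores the same evaluation images at several noise strengths `t0`
#' under a fixed guidance scale — a paired design: every row of the output
#' differs only in `t0` (identical images and per-image seeds).
#'
#' @param images,manifest evaluation set as in [kfold_evaluate()].
#' @param pipe a [condiff_pipeline()]; its sampler settings other than `t0`
#'   and `omega` are kept.
#' @param t0_values noise strengths to test, each in `(0, 1]`.
#' @param omega guidance scale used for all rows.
#' @return data frame of metric rows, one per `t0`.
#' @export
sweep_t0 <- function(images, manifest, pipe, t0_values, omega = pipe$cfg$omega) {
  rows <- lapply(t0_values, function(t0) {
    cfg <- pipe$cfg; cfg$t0 <- t0; cfg$omega <- omega
    p2 <- pipe; p2$cfg <- cfg
    res <- condiff_predict_batch(images, manifest, p2)
    out <- metrics_row(metrics_from_results(res))
    cbind(data.frame(t0 = t0, omega = omega), out)
  })
  do.call(rbind, rows)
}

#' Inter-condition synthesis divergence versus noise strength
#'
#' For each `t0`, synthesises both conditional reconstructions of every
#' guide and reports the mean pixel-space squared L2 distance
#' `||x0_hat(y1) - x0_hat(y2)||^2` (summed over pixels, averaged over
#' guides). At `omega = 0` the two syntheses coincide and the curve is
#' identically zero; larger `t0` gives the condition more room to act, so
#' the curve grows.
#'
#' @param guides `n x D` matrix (or list) of guide images.
#' @param pipe a [condiff_pipeline()].
#' @param t0_values noise strengths.
#' @param seed base seed for the shared perturbation draws.
#' @return data frame with columns `t0` and `divergence`.
#' @export
divergence_vs_t0 <- function(guides, pipe, t0_values, seed = 1L) {
  X <- as_image_matrix(guides)
  if (nrow(X) == 0L) stop("at least one guide required", call. = FALSE)
  # paired design: one shared noise realisation across all t0 values, so
  # rows differ only in the noise strength
  rows <- lapply(t0_values, function(t0) {
    cfg <- pipe$cfg; cfg$t0 <- t0
    syn <- synthesize_conditionals(X, pipe$denoiser, cfg, pipe$schedule,
                                   rng_seed = hash_seed(seed, "perturb"))
    d2 <- rowSums((syn$per_label[[1]] - syn$per_label[[2]])^2)
    data.frame(t0 = t0, divergence = mean(d2))
  })
  do.call(rbind, rows)
}
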