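#' Embedding network configuration
#'
#' The similarity embedding `f_phi` maps an image to a d-dimensional
#' Euclidean space. The backbone here is a small convolutional network —
#' one 3x3 convolution (stride 1, zero padding), ReLU, non-overlapping
#' average pooling, and a linear head — chosen so that desk-scale training
#' stays cheap while exposing genuine spatial activation maps for
#' Score-CAM. Any backbone exposing the same forward contract could be
#' substituted.
#'
#' @param image_size image side length.
#' @param channels input colour channels.
#' @param conv_channels number of convolutional feature channels.
#' @param pool average-pooling window (must divide `image_size`).
#' @param d embedding dimension.
#' @param normalize L2-normalise embeddings to the unit sphere (default
#'   `TRUE`). Normalisation keeps squared distances in `[0, 4]`, so the
#'   triplet margin stays an active constraint regardless of how separable
#'   the raw features are.
#' @return object of class `embed_config`.
#' @export
embed_config <- function(image_size = 32L, channels = 3L,
                         conv_channels = 8L, pool = 4L, d = 128L,
                         normalize = TRUE) {
  if (image_size %% pool != 0L)
    stop("`pool` must divide `image_size`", call. = FALSE)
  structure(list(image_size = as.integer(image_size),
                 channels = as.integer(channels),
                 conv_channels = as.integer(conv_channels),
                 pool = as.integer(pool), d = as.integer(d),
                 normalize = isTRUE(normalize)),
            class = "embed_config")
}

# Precompute the im2col gather indices, the zero-pad interior positions and
# the pooling group ids for a given geometry. Image vectors are column-major
# (row fastest, then column, then channel).
embed_geometry <- function(cf) {
  H <- cf$image_size; W <- cf$image_size; C <- cf$channels
  Hp <- H + 2L; Wp <- W + 2L
  pix_i <- rep(seq_len(H), times = W)
  pix_j <- rep(seq_len(W), each = H)
  offs <- expand.grid(di = -1:1, dj = -1:1)
  idx <- matrix(0L, H * W, 9L * C)
  for (ch in seq_len(C)) for (k in 1:9) {
    ii <- pix_i + offs$di[k] + 1L
    jj <- pix_j + offs$dj[k] + 1L
    idx[, (ch - 1L) * 9L + k] <- ii + (jj - 1L) * Hp + (ch - 1L) * Hp * Wp
  }
  i <- rep(seq_len(H), times = W * C)
  j <- rep(rep(seq_len(W), each = H), times = C)
  ch <- rep(seq_len(C), each = H * W)
  interior <- (i + 1L) + j * Hp + (ch - 1L) * Hp * Wp
  p <- cf$pool
  pool_id <- ((pix_i - 1L) %/% p) + ((pix_j - 1L) %/% p) * (H %/% p) + 1L
  list(H = H, W = W, C = C, D = H * W * C, Dpad = Hp * Wp * C,
       idx = idx, interior = interior, pool_id = pool_id,
       K = (H %/% p) * (W %/% p))
}

#' Initialise an embedding network
#'
#' @param config an [embed_config()].
#' @param seed initialisation seed.
#' @return object of class `embed_net`.
#' @export
new_embedder <- function(config = embed_config(), seed = 1L) {
  geom <- embed_geometry(config)
  Cc <- config$conv_channels
  params <- with_seed(seed, list(
    Wc = init_weight(9L * config$channels, Cc), bc = matrix(0, 1, Cc),
    Wf = init_weight(geom$K * Cc, config$d), bf = matrix(0, 1, config$d)))
  structure(list(config = config, geom = geom, params = params,
                 train_steps = 0L, history = NULL, seed = seed),
            class = "embed_net")
}

#' @export
print.embed_net <- function(x, ...) {
  cat(sprintf("<embed_net %dx%dx%d -> d=%d (%d conv channels), trained %d steps>\n",
              x$config$image_size, x$config$image_size, x$config$channels,
              x$config$d, x$config$conv_channels, x$train_steps))
  invisible(x)
}

# Batched forward pass over a flat n x D matrix. Returns embeddings (n x d)
# and, on request, the caches needed for backprop and Score-CAM.
embed_forward <- function(model, X, want_cache = FALSE) {
  g <- model$geom; p <- model$params
  pool <- model$config$pool
  n <- nrow(X); HW <- g$H * g$W; Cc <- model$config$conv_channels
  Xpad <- matrix(0, n, g$Dpad)
  Xpad[, g$interior] <- X
  colbig <- Xpad[, as.vector(g$idx), drop = FALSE]
  m <- matrix(aperm(array(colbig, c(n, HW, ncol(g$idx))), c(2, 1, 3)),
              n * HW, ncol(g$idx))
  pre <- add_bias(m %*% p$Wc, p$bc)          # (n*HW) x Cc, pixel fastest
  act <- relu(pre)
  groups <- rep(g$pool_id, times = n) + rep((seq_len(n) - 1L) * g$K, each = HW)
  pooled <- rowsum(act, groups) / pool^2      # (n*K) x Cc, cell fastest
  feat <- t(matrix(aperm(array(pooled, c(g$K, n, Cc)), c(1, 3, 2)),
                   g$K * Cc, n))              # n x (K*Cc)
  z <- add_bias(feat %*% p$Wf, p$bf)
  if (isTRUE(model$config$normalize)) {
    r <- sqrt(rowSums(z^2)) + 1e-12
    emb <- z / r
  } else {
    r <- NULL
    emb <- z
  }
  if (!want_cache) return(emb)
  list(emb = emb, m = m, pre = pre, act = act, feat = feat,
       groups = groups, n = n, r = r)
}

# Parameter gradients given d(loss)/d(emb).
embed_backward <- function(model, cache, demb) {
  g <- model$geom; p <- model$params
  pool <- model$config$pool
  n <- cache$n; HW <- g$H * g$W; Cc <- model$config$conv_channels
  if (!is.null(cache$r)) {
    # through the unit-sphere projection: dz = (de - e (e . de)) / r
    e <- cache$emb
    demb <- (demb - e * rowSums(demb * e)) / cache$r
  }
  dWf <- crossprod(cache$feat, demb)
  dbf <- matrix(colSums(demb), 1)
  dfeat <- tcrossprod(demb, p$Wf)                   # n x (K*Cc)
  dpool <- matrix(aperm(array(t(dfeat), c(g$K, Cc, n)), c(1, 3, 2)),
                  n * g$K, Cc)                # (n*K) x Cc
  rep_idx <- rep(g$pool_id, times = n) + rep((seq_len(n) - 1L) * g$K, each = HW)
  dact <- dpool[rep_idx, , drop = FALSE] / pool^2
  dact <- dact * (cache$pre > 0)
  list(Wc = crossprod(cache$m, dact), bc = matrix(colSums(dact), 1),
       Wf = dWf, bf = dbf)
}

#' Embed images in the similarity space
#'
#' Deterministic in evaluation: identical inputs give identical embeddings.
#'
#' @param model a trained `embed_net`.
#' @param x image array or flat `n x D` batch matrix.
#' @return numeric vector of length `d` (single image) or `n x d` matrix.
#' @export
embed <- function(model, x) {
  was_image <- !is.matrix(x)
  X <- if (was_image) as_flat_batch(x) else x
  if (ncol(X) != model$geom$D)
    stop("embedding input geometry mismatch: expected ", model$geom$D,
         " pixels", call. = FALSE)
  E <- embed_forward(model, X)
  if (was_image) as.numeric(E) else E
}

#' Triplet loss
#'
#' Mean over the batch of the hinge
#' `max(0, ||f(a) - f(p)||^2 - ||f(a) - f(n)||^2 + margin)`, pulling the
#' anchor towards its positive (same class) and away from its negative
#' (other class) by at least the margin in squared Euclidean distance.
#'
#' @param anchors,positives,negatives either embedding matrices (`n x d`,
#'   when `model` is `NULL`) or flat image batches embedded through `model`.
#' @param model optional `embed_net` applied to the three batches.
#' @param margin hinge margin `alpha >= 0` (default 1).
#' @return scalar loss.
#' @export
triplet_loss <- function(anchors, positives, negatives, model = NULL,
                         margin = 1) {
  if (margin < 0) stop("`margin` must be >= 0", call. = FALSE)
  if (!is.null(model)) {
    anchors <- embed_forward(model, anchors)
    positives <- embed_forward(model, positives)
    negatives <- embed_forward(model, negatives)
  }
  if (nrow(anchors) == 0L) stop("empty triplet batch", call. = FALSE)
  d_ap <- rowSums((anchors - positives)^2)
  d_an <- rowSums((anchors - negatives)^2)
  mean(pmax(0, d_ap - d_an + margin))
}

#' Sample a batch of training triplets
#'
#' Anchors are always drawn from the real set. With probability `p_gen` the
#' (positive, negative) pair of a triplet is drawn from the synthetic set,
#' otherwise from the real set. The positive shares the anchor's label, the
#' negative carries the other label.
#'
#' @param real_labels,synth_labels label vectors of the two pools.
#' @param p_gen probability that a pair is synthetic, in `[0, 1]`.
#' @param rng_seed sampling seed.
#' @param batch_size number of triplets.
#' @return data frame with columns `anchor`, `pos`, `neg` (indices into the
#'   respective pools), `pair_source` (`"real"`/`"synthetic"`) and
#'   `anchor_label`.
#' @export
sample_triplets <- function(real_labels, synth_labels = NULL, p_gen = 0.2,
                            rng_seed = 1L, batch_size = 32L) {
  if (p_gen < 0 || p_gen > 1) stop("`p_gen` must lie in [0, 1]", call. = FALSE)
  lev <- condition_levels()
  if (!all(lev %in% real_labels))
    stop("both classes must be present in the real set", call. = FALSE)
  if (p_gen > 0 && (is.null(synth_labels) || !all(lev %in% synth_labels)))
    stop("both classes must be present in the synthetic set when p_gen > 0",
         call. = FALSE)
  with_seed(rng_seed, {
    out <- vector("list", batch_size)
    for (b in seq_len(batch_size)) {
      a <- sample.int(length(real_labels), 1L)
      lab <- real_labels[a]
      other <- setdiff(lev, lab)
      synthetic <- stats::runif(1) < p_gen
      pool <- if (synthetic) synth_labels else real_labels
      pos_cand <- which(pool == lab)
      if (!synthetic) pos_cand <- setdiff(pos_cand, a)
      if (length(pos_cand) == 0L)
        stop("no positive candidate available for label ", lab, call. = FALSE)
      pos <- pos_cand[sample.int(length(pos_cand), 1L)]
      neg_cand <- which(pool == other)
      neg <- neg_cand[sample.int(length(neg_cand), 1L)]
      out[[b]] <- data.frame(anchor = a, pos = pos, neg = neg,
                             pair_source = if (synthetic) "synthetic" else "real",
                             anchor_label = lab)
    }
    do.call(rbind, out)
  })
}

#' Distance-based classification against conditional syntheses
#'
#' Implements the minimum-distance decision rule: the predicted label is
#' the one whose conditional synthesis lies closest to the guide in the
#' embedding space, under squared Euclidean distance. On an exact tie the
#' first class level ("uninfected") is predicted — the conservative choice
#' for specificity.
#'
#' @param x0 guide image.
#' @param synth a [synthesize_conditionals()] result (or a named list of
#'   per-label syntheses).
#' @param model a trained `embed_net` (or an embedding function on flat
#'   batch matrices).
#' @return object of class `condiff_classification`: list with `predicted`,
#'   `distances` (named squared L2 distances) and `margin`
#'   (`|d(y1) - d(y2)|`).
#' @export
classify_distance <- function(x0, synth, model) {
  per_label <- if (inherits(synth, "guided_synthesis")) synth$per_label else synth
  lev <- condition_levels()
  if (!all(lev %in% names(per_label)))
    stop("missing synthesis for label(s): ",
         paste(setdiff(lev, names(per_label)), collapse = ", "), call. = FALSE)
  emb_of <- function(x) {
    X <- as_flat_batch(x)
    if (is.function(model)) as.numeric(model(X)) else as.numeric(embed(model, X))
  }
  e0 <- emb_of(x0)
  d <- vapply(lev, function(lab) sum((e0 - emb_of(per_label[[lab]]))^2),
              numeric(1))
  predicted <- lev[which.min(d)]   # which.min takes the first on ties
  structure(list(predicted = predicted, distances = d,
                 margin = abs(d[1] - d[2])),
            class = "condiff_classification")
}

#' @export
print.condiff_classification <- function(x, ...) {
  cat(sprintf("<prediction: %s  (d_uninfected=%.4g, d_infected=%.4g, margin=%.4g)>\n",
              x$predicted, x$distances[1], x$distances[2], x$margin))
  invisible(x)
}

#' Stage-2 training of the embedding network
#'
#' Minimises the triplet loss with Adam over triplets sampled from the real
#' pool and (with probability `p_gen`) the synthetic pool of conditional
#' syntheses. When a validation set of guides with precomputed conditional
#' syntheses is supplied, distance-classification accuracy is evaluated
#' periodically and the best-on-validation weights are returned.
#'
#' @param real_x flat `n x D` matrix of real training images.
#' @param real_labels labels of `real_x`.
#' @param synth_x,synth_labels the synthetic pool (may be `NULL` when
#'   `p_gen = 0`).
#' @param config an [embed_config()].
#' @param steps,batch_size,lr optimisation settings.
#' @param margin triplet margin `alpha`.
#' @param p_gen synthetic-pair probability.
#' @param seed training seed.
#' @param validation optional list with `guides` (`m x D`), `synth_y1`,
#'   `synth_y2` (`m x D` conditional syntheses) and `labels` (length m).
#' @param val_every validation period in steps.
#' @return trained `embed_net`; `history` holds the loss curve and, when
#'   validated, `val_accuracy` and the selected step (`best_step`).
#' @export
train_stage2 <- function(real_x, real_labels, synth_x = NULL,
                         synth_labels = NULL, config = embed_config(),
                         steps = 400L, batch_size = 24L, lr = 1e-3,
                         margin = 1, p_gen = 0.2, seed = 1L,
                         validation = NULL, val_every = 50L) {
  model <- new_embedder(config, seed = seed)
  opt <- adam_new(model$params, lr = lr)
  curve <- list(); val_log <- list()
  best <- list(acc = -Inf, params = copy_params(model$params), step = 0L)
  for (s in seq_len(steps)) {
    tr <- sample_triplets(real_labels, synth_labels, p_gen = p_gen,
                          rng_seed = hash_seed(seed, paste0("trip", s)),
                          batch_size = batch_size)
    from_pool <- function(i, src)
      if (src == "synthetic") synth_x[i, , drop = FALSE] else real_x[i, , drop = FALSE]
    A <- real_x[tr$anchor, , drop = FALSE]
    P <- do.call(rbind, Map(from_pool, tr$pos, tr$pair_source))
    N <- do.call(rbind, Map(from_pool, tr$neg, tr$pair_source))
    nb <- nrow(A)
    fw <- embed_forward(model, rbind(A, P, N), want_cache = TRUE)
    ea <- fw$emb[seq_len(nb), , drop = FALSE]
    ep <- fw$emb[nb + seq_len(nb), , drop = FALSE]
    en <- fw$emb[2 * nb + seq_len(nb), , drop = FALSE]
    d_ap <- rowSums((ea - ep)^2); d_an <- rowSums((ea - en)^2)
    hinge <- d_ap - d_an + margin
    active <- as.numeric(hinge > 0)
    loss <- mean(pmax(0, hinge))
    if (!is.finite(loss)) stop("non-finite triplet loss at step ", s, call. = FALSE)
    da <- 2 * active * (en - ep) / nb
    dp <- 2 * active * (ep - ea) / nb
    dn <- 2 * active * (ea - en) / nb
    grads <- embed_backward(model, fw, rbind(da, dp, dn))
    st <- adam_step(opt, model$params, grads)
    opt <- st$opt; model$params <- st$params
    curve[[s]] <- data.frame(step = s, loss = loss)
    if (!is.null(validation) && (s %% val_every == 0L || s == steps)) {
      acc <- validate_embedder(model, validation)
      val_log[[length(val_log) + 1L]] <- data.frame(step = s, accuracy = acc)
      if (acc > best$acc)
        best <- list(acc = acc, params = copy_params(model$params), step = s)
    }
  }
  if (!is.null(validation)) {
    model$params <- best$params
    model$history <- list(loss = do.call(rbind, curve),
                          val_accuracy = do.call(rbind, val_log),
                          best_step = best$step, best_accuracy = best$acc)
  } else {
    model$history <- list(loss = do.call(rbind, curve))
  }
  model$train_steps <- as.integer(steps)
  model
}

# Distance-classification accuracy on precomputed validation syntheses.
validate_embedder <- function(model, validation) {
  e0 <- embed_forward(model, validation$guides)
  e1 <- embed_forward(model, validation$synth_y1)
  e2 <- embed_forward(model, validation$synth_y2)
  d1 <- rowSums((e0 - e1)^2); d2 <- rowSums((e0 - e2)^2)
  lev <- condition_levels()
  pred <- ifelse(d1 <= d2, lev[1], lev[2])
  mean(pred == validation$labels)
}
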