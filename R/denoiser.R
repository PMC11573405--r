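#' Conditional denoiser configuration
#'
#' Architecture and training-time options of the noise-prediction network
#' `eps_theta(x_t, t, y)`. The network is a fully connected net on the
#' flattened image concatenated with a sinusoidal step embedding and a
#' class-token one-hot (two class tokens plus the unconditional token used
#' by classifier-free guidance). The output head is zero-initialised so an
#' untrained model predicts zero noise.
#'
#' @param image_size image side length (images are square).
#' @param channels colour channels.
#' @param hidden width of the two hidden layers.
#' @param time_embed_dim sinusoidal step-embedding dimension (even).
#' @param n_classes number of condition classes (2).
#' @param p_uncond probability of replacing a label by the unconditional
#'   token during training, in `[0, 1)`; this is what makes guidance
#'   possible at sampling time.
#' @param tau2_floor lower bound on the prior variance of the shrinkage
#'   pathway. Keeps the prototype pull bounded at low noise even when
#'   training drives the learned variance towards the memorisation limit.
#' @return object of class `denoiser_config`.
#' @export
denoiser_config <- function(image_size = 32L, channels = 3L, hidden = 128L,
                            time_embed_dim = 32L, n_classes = 2L,
                            p_uncond = 0.1, tau2_floor = 0.05) {
  if (p_uncond < 0 || p_uncond >= 1)
    stop("`p_uncond` must lie in [0, 1)", call. = FALSE)
  if (time_embed_dim %% 2L != 0L)
    stop("`time_embed_dim` must be even", call. = FALSE)
  structure(list(image_size = as.integer(image_size),
                 channels = as.integer(channels),
                 hidden = as.integer(hidden),
                 time_embed_dim = as.integer(time_embed_dim),
                 n_classes = as.integer(n_classes),
                 p_uncond = p_uncond, tau2_floor = tau2_floor),
            class = "denoiser_config")
}

#' Initialise a conditional denoiser
#'
#' @param config a [denoiser_config()].
#' @param schedule the [make_schedule()] the model is trained against
#'   (its horizon scales the step embedding and is stored with the model).
#' @param seed initialisation seed.
#' @return object of class `cond_denoiser`.
#' @export
new_denoiser <- function(config = denoiser_config(),
                         schedule = make_schedule(), seed = 1L) {
  D <- config$image_size^2 * config$channels
  din <- D + config$time_embed_dim + config$n_classes + 1L
  H <- config$hidden
  params <- with_seed(seed, list(
    W1 = init_weight(din, H), b1 = matrix(0, 1, H),
    W2 = init_weight(H, H),   b2 = matrix(0, 1, H),
    W3 = init_weight(H, D, zero = TRUE), b3 = matrix(0, 1, D),
    g = matrix(0, 1, 1), lt = matrix(0, 1, 1),
    V = matrix(0, config$n_classes + 1L, D)))
  structure(list(config = config, params = params,
                 T_total = schedule$T_total,
                 alpha_bar = schedule$alpha_bar,
                 null_trained = config$p_uncond > 0,
                 loss_curve = NULL, train_steps = 0L, seed = seed),
            class = "cond_denoiser")
}

#' @export
print.cond_denoiser <- function(x, ...) {
  cat(sprintf("<cond_denoiser %dx%dx%d, hidden %d, trained %d steps>\n",
              x$config$image_size, x$config$image_size, x$config$channels,
              x$config$hidden, x$train_steps))
  invisible(x)
}

add_bias <- function(M, b) M + matrix(b, nrow(M), ncol(M), byrow = TRUE)

# One-hot rows over (unconditional, class 1, class 2, ...). `labels` is a
# character vector (NA or NULL entries = unconditional token).
label_onehot <- function(labels, n, n_classes) {
  oh <- matrix(0, n, n_classes + 1L)
  if (is.null(labels)) { oh[, 1L] <- 1; return(oh) }
  labels <- rep_len(labels, n)
  idx <- vapply(seq_len(n), function(i)
    if (is.na(labels[i])) 1L else label_index(labels[i]), integer(1))
  oh[cbind(seq_len(n), idx)] <- 1
  oh
}

# Batched forward pass on a flat n x D matrix. `step` is a scalar or
# length-n vector; `label` a scalar label, NULL, or length-n character with
# NA for the unconditional token. Returns n x D (plus a cache for backprop
# when requested).
#
# The prediction is the MLP output plus a Gaussian-posterior shrinkage
# pathway, zero-initialised so the untrained model predicts zero noise.
# Under a Gaussian prior N(mu_y, tau^2 I) on the clean image, the
# posterior mean given x_t is
#   (sqrt(ab) tau^2 x_t + (1 - ab) mu_y) / (ab tau^2 + 1 - ab)
# and substituting it into the noise estimate (x_t - sqrt(ab) x0_hat) /
# sqrt(1 - ab) gives
#   sqrt(1 - ab) / s * (x_t - sqrt(ab) mu_y),   s = ab tau^2 + 1 - ab.
# The pathway implements exactly that, with per-token prototype V
# (playing g * mu_y), gate g (init 0) and learnable log tau^2:
#   eps_path = sqrt(1 - ab) / s * (g x_t - sqrt(ab) V[y]).
# It provides the exact inversion in the memorisation limit (tau -> 0),
# the standard x_t skip at high noise, a mid-noise conditional pull, and
# a correctly vanishing prototype influence at low noise. The MLP handles
# the residual, condition- and step-dependent structure.
denoiser_forward <- function(model, x, step, label, want_cache = FALSE) {
  cf <- model$config
  D <- cf$image_size^2 * cf$channels
  if (!is.matrix(x) || ncol(x) != D)
    stop("denoiser input must be an n x ", D, " matrix", call. = FALSE)
  n <- nrow(x)
  step <- rep_len(step, n)
  abv <- ifelse(step == 0L, 1, model$alpha_bar[pmax(step, 1L)])
  temb <- time_embedding(step, cf$time_embed_dim, model$T_total)
  oh <- label_onehot(label, n, cf$n_classes)
  xin <- cbind(x, temb, oh)
  p <- model$params
  a1 <- add_bias(xin %*% p$W1, p$b1); h1 <- relu(a1)
  a2 <- add_bias(h1 %*% p$W2, p$b2); h2 <- relu(a2)
  lab_idx <- max.col(oh, ties.method = "first")
  tau2 <- (cf$tau2_floor) + exp(c(p$lt))
  sden <- abv * tau2 + (1 - abv)
  cpath <- sqrt(pmax(1 - abv, 1e-12)) / sden
  path <- cpath * (c(p$g) * x - sqrt(abv) * p$V[lab_idx, , drop = FALSE])
  out <- add_bias(h2 %*% p$W3, p$b3) + path
  if (want_cache) list(out = out, xin = xin, a1 = a1, h1 = h1,
                       a2 = a2, h2 = h2, lab_idx = lab_idx, x = x,
                       cpath = cpath, path = path, abv = abv,
                       sden = sden, tau2 = tau2)
  else out
}

# Gradient of a scalar loss wrt all parameters, given d(loss)/d(out).
denoiser_backward <- function(model, cache, dout) {
  p <- model$params
  dW3 <- crossprod(cache$h2, dout); db3 <- matrix(colSums(dout), 1)
  dh2 <- tcrossprod(dout, p$W3) * (cache$a2 > 0)
  dW2 <- crossprod(cache$h1, dh2); db2 <- matrix(colSums(dh2), 1)
  dh1 <- tcrossprod(dh2, p$W2) * (cache$a1 > 0)
  dW1 <- crossprod(cache$xin, dh1); db1 <- matrix(colSums(dh1), 1)
  dV <- p$V * 0
  dpr <- rowsum(-(cache$cpath * sqrt(cache$abv)) * dout, cache$lab_idx)
  dV[as.integer(rownames(dpr)), ] <- dpr
  dg <- sum(dout * (cache$cpath * cache$x))
  dlt <- sum(dout * (-cache$path) *
               (cache$abv * (cache$tau2 - model$config$tau2_floor) /
                  cache$sden))
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3,
       g = matrix(dg, 1, 1), lt = matrix(dlt, 1, 1), V = dV)
}

#' Predict the noise component of a noised image
#'
#' @param model a `cond_denoiser`.
#' @param x_t noised image (array) or flat batch matrix.
#' @param step diffusion step (scalar, or one per row for a batch).
#' @param label condition label, or `NULL` for the unconditional token.
#' @return noise estimate with the shape of `x_t`.
#' @export
predict_noise <- function(model, x_t, step, label = NULL) {
  was_image <- !is.matrix(x_t)
  x <- if (was_image) as_flat_batch(x_t) else x_t
  out <- denoiser_forward(model, x, step, label)
  if (was_image) flat_to_image(out, img_geometry(x_t)) else out
}

# Draw (step, noise, possibly-dropped label) for each example and assemble
# the noised batch. Per-example seeds make the loss invariant to batch
# order when example identities are kept fixed.
diffusion_batch <- function(x0, labels, schedule, rng_seed, p_uncond,
                            example_seeds = NULL) {
  n <- nrow(x0); D <- ncol(x0)
  if (is.null(example_seeds)) {
    draws <- with_seed(rng_seed, list(
      t = sample.int(schedule$T_total, n, replace = TRUE),
      e = matrix(stats::rnorm(n * D), n, D),
      u = stats::runif(n)))
    lab <- labels
    lab[draws$u < p_uncond] <- NA
    ab <- schedule$alpha_bar[draws$t]
    return(list(x_t = sqrt(ab) * x0 + sqrt(1 - ab) * draws$e,
                t_step = draws$t, eps = draws$e, labels = lab))
  }
  t_step <- integer(n); eps <- matrix(0, n, D); lab <- labels
  for (i in seq_len(n)) {
    draws <- with_seed(example_seeds[i], list(
      t = sample.int(schedule$T_total, 1L),
      e = stats::rnorm(D),
      u = stats::runif(1)))
    t_step[i] <- draws$t
    eps[i, ] <- draws$e
    if (draws$u < p_uncond) lab[i] <- NA
  }
  ab <- schedule$alpha_bar[t_step]
  x_t <- sqrt(ab) * x0 + sqrt(1 - ab) * eps
  list(x_t = x_t, t_step = t_step, eps = eps, labels = lab)
}

#' Denoising score-matching loss
#'
#' The conditional DDPM objective: steps are sampled uniformly, Gaussian
#' noise is added with the closed-form forward marginal, each label is
#' replaced by the unconditional token with probability `p_uncond`, and the
#' loss is the mean squared error between true and predicted noise
#' (mean per element, so the zero-prediction baseline sits at 1).
#'
#' @param model a `cond_denoiser`.
#' @param x0 flat `n x D` batch matrix (or list of images).
#' @param labels character vector of condition labels, one per row.
#' @param schedule a [make_schedule()].
#' @param rng_seed seed for steps/noise/label dropout.
#' @param example_seeds optional per-example seeds overriding the
#'   `rng_seed` derivation (ties randomness to example identity).
#' @return scalar loss.
#' @export
diffusion_loss <- function(model, x0, labels, schedule, rng_seed = 1L,
                           example_seeds = NULL) {
  x0 <- as_image_matrix(x0)
  if (nrow(x0) == 0L) stop("empty batch", call. = FALSE)
  b <- diffusion_batch(x0, labels, schedule, rng_seed,
                       model$config$p_uncond, example_seeds)
  out <- denoiser_forward(model, b$x_t, b$t_step, b$labels)
  mean((b$eps - out)^2)
}

# list of images -> n x D matrix
as_image_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.list(x)) return(do.call(rbind, lapply(x, function(im) as.numeric(im))))
  matrix(as.numeric(x), nrow = 1L)
}

#' Stage-1 training of the conditional denoiser
#'
#' Minimises the denoising objective with Adam over minibatches drawn from
#' the training images. Deterministic under `seed`.
#'
#' @param x0 training images: flat `n x D` matrix or list of image arrays.
#' @param labels condition label per image.
#' @param config a [denoiser_config()].
#' @param schedule a [make_schedule()].
#' @param steps optimisation steps.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param seed training seed.
#' @param checkpoint_path optional RDS path; the final model is saved there.
#' @param log_every record the running loss every this many steps.
#' @return trained `cond_denoiser` with a `loss_curve` data frame
#'   (columns `step`, `loss`).
#' @export
train_stage1 <- function(x0, labels, config = denoiser_config(),
                         schedule = make_schedule(), steps = 1000L,
                         batch_size = 32L, lr = 1e-3, seed = 1L,
                         checkpoint_path = NULL, log_every = 25L) {
  x0 <- as_image_matrix(x0)
  n <- nrow(x0)
  if (n == 0L) stop("empty training set", call. = FALSE)
  if (length(labels) != n) stop("one label per image required", call. = FALSE)
  model <- new_denoiser(config, schedule, seed = seed)
  # the analytic pathways are few parameters with clean gradients; a
  # higher group learning rate lets them converge within a short budget
  opt <- adam_new(model$params, lr = lr,
                  lr_mult = list(g = 10, lt = 25, V = 5))
  curve <- list()
  for (s in seq_len(steps)) {
    idx <- with_seed(hash_seed(seed, paste0("batch", s)),
                     sample.int(n, batch_size, replace = batch_size > n))
    b <- diffusion_batch(x0[idx, , drop = FALSE], labels[idx], schedule,
                         hash_seed(seed, paste0("noise", s)),
                         config$p_uncond)
    fw <- denoiser_forward(model, b$x_t, b$t_step, b$labels,
                           want_cache = TRUE)
    resid <- fw$out - b$eps
    loss <- mean(resid^2)
    if (!is.finite(loss))
      stop("non-finite diffusion loss at step ", s,
           "; try a lower learning rate", call. = FALSE)
    grads <- denoiser_backward(model, fw, 2 * resid / length(resid))
    st <- adam_step(opt, model$params, grads)
    opt <- st$opt; model$params <- st$params
    if (s %% log_every == 0L || s == steps)
      curve[[length(curve) + 1L]] <- data.frame(step = s, loss = loss)
  }
  model$loss_curve <- do.call(rbind, curve)
  model$train_steps <- as.integer(steps)
  if (!is.null(checkpoint_path)) save_model(model, checkpoint_path)
  model
}

#' Save / load model checkpoints
#'
#' Checkpoints are single-file RDS serialisations of the model object
#' (weights, configuration, training metadata); reloading reproduces
#' predictions bit-exactly.
#'
#' @param model a `cond_denoiser` or `embed_net`.
#' @param path file path.
#' @return `save_model` the path, `load_model` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
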