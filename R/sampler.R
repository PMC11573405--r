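#' Sampler configuration
#'
#' Bundles the guided-synthesis hyperparameters: guidance scale `omega`
#' mixing the unconditional and conditional noise estimates, noise strength
#' `t0` (fraction of the forward horizon applied to the guide), DDIM ladder
#' length `n_steps`, and DDIM stochasticity `eta` (0 = deterministic).
#'
#' @param omega guidance scale, `>= 0` (values above 1 extrapolate;
#'   a warning is emitted above 20).
#' @param t0 noise strength in `(0, 1]`.
#' @param n_steps number of reverse DDIM steps (>= 1).
#' @param eta DDIM stochasticity in `[0, 1]`.
#' @param seed base seed recorded with the configuration.
#' @param clip_denoised clip the running clean-image estimate to `[-1, 1]`
#'   at each DDIM step. Off by default: at high noise strengths the
#'   `1/sqrt(alpha_bar)` amplification pushes the estimate far outside the
#'   pixel range and per-rung clipping saturates away the conditional
#'   signal (the final synthesis is always clamped to `[-1, 1]`).
#' @return object of class `sampler_config`.
#' @export
sampler_config <- function(omega = 0.75, t0 = 0.8, n_steps = 30L,
                           eta = 0, seed = 1L, clip_denoised = FALSE) {
  if (t0 <= 0 || t0 > 1) stop("`t0` must lie in (0, 1]", call. = FALSE)
  if (n_steps < 1) stop("`n_steps` must be >= 1", call. = FALSE)
  if (eta < 0 || eta > 1) stop("`eta` must lie in [0, 1]", call. = FALSE)
  if (omega < 0) warning("omega < 0 extrapolates away from the condition")
  if (omega > 20) warning("omega > 20: extreme guidance scale")
  structure(list(omega = omega, t0 = t0, n_steps = as.integer(n_steps),
                 eta = eta, seed = as.integer(seed),
                 clip_denoised = isTRUE(clip_denoised)),
            class = "sampler_config")
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Perturb a guide image with forward-process noise
#'
#' Realises the partial noising of a guide image before conditional
#' resynthesis: the continuous noise strength `t0` is mapped to the discrete
#' step `s = round(t0 * T_total)` (half away from zero) and one draw of
#' `q(x_s | x0)` is taken. In the variance-preserving convention used here
#' this corresponds to additive noise of magnitude
#' `sigma(t0) = sqrt(1 - alpha_bar_s) / sqrt(alpha_bar_s)` relative to the
#' (rescaled) guide.
#'
#' @param x0 guide image (array) or flat batch matrix.
#' @param cfg a [sampler_config()].
#' @param schedule a [make_schedule()].
#' @param rng_seed integer seed for the noise draw.
#' @return list with `perturbed` (same shape as `x0`) and `step` (the
#'   discrete start step `s`).
#' @export
perturb_guide <- function(x0, cfg, schedule, rng_seed = cfg$seed) {
  if (cfg$t0 <= 0 || cfg$t0 > 1) stop("`t0` must lie in (0, 1]", call. = FALSE)
  s <- as.integer(round_half_away(cfg$t0 * schedule$T_total))
  s <- max(1L, min(s, schedule$T_total))
  z <- with_seed(rng_seed, array(stats::rnorm(length(x0)), dim(x0)))
  list(perturbed = forward_marginal(x0, s, schedule, z), step = s)
}

#' Classifier-free guidance combination
#'
#' Mixes the unconditional and conditional noise predictions:
#' `(1 - omega) * eps_uncond + omega * eps_cond`. At `omega = 0` the
#' condition is ignored; at `omega = 1` the estimate is purely conditional;
#' larger values extrapolate towards the condition.
#'
#' @param eps_uncond,eps_cond noise estimates of identical geometry.
#' @param omega guidance scale.
#' @return combined estimate, same shape.
#' @export
cfg_combine <- function(eps_uncond, eps_cond, omega) {
  stopifnot_same_geometry(eps_uncond, eps_cond)
  (1 - omega) * eps_uncond + omega * eps_cond
}

#' One DDIM update
#'
#' Given the current state `x_t` at `step_from` and a noise estimate
#' `eps_hat`, forms the clean-image estimate
#' `x0_hat = (x_t - sqrt(1 - ab_from) * eps_hat) / sqrt(ab_from)`
#' (optionally clipped to `[-1, 1]`) and jumps to `step_to` via
#' `sqrt(ab_to) * x0_hat + sqrt(1 - ab_to - sigma^2) * eps_hat + sigma * z`
#' with `sigma = eta * sqrt((1 - ab_to) / (1 - ab_from)) *
#' sqrt(1 - ab_from / ab_to)`. With `eta = 0` the update is deterministic.
#'
#' @param x_t current state (array or flat batch matrix).
#' @param eps_hat noise estimate, same shape.
#' @param step_from,step_to source and target steps, `step_to < step_from`;
#'   `step_to = 0` lands on the clean-image boundary.
#' @param schedule a [make_schedule()].
#' @param eta stochasticity in `[0, 1]`.
#' @param noise standard-normal draw, required when `eta > 0`.
#' @param clip_denoised clip `x0_hat` to `[-1, 1]` before re-noising.
#' @return state at `step_to`, same shape as `x_t`.
#' @export
ddim_step <- function(x_t, eps_hat, step_from, step_to, schedule,
                      eta = 0, noise = NULL, clip_denoised = FALSE) {
  if (step_to >= step_from)
    stop("`step_to` must be strictly below `step_from`", call. = FALSE)
  ab_from <- alpha_bar_at(schedule, step_from)
  ab_to <- alpha_bar_at(schedule, step_to)
  x0_hat <- (x_t - sqrt(1 - ab_from) * eps_hat) / sqrt(ab_from)
  if (clip_denoised) x0_hat <- pmin(pmax(x0_hat, -1), 1)
  sigma <- 0
  if (eta > 0 && ab_from < 1) {
    sigma <- eta * sqrt((1 - ab_to) / (1 - ab_from)) * sqrt(1 - ab_from / ab_to)
    if (is.null(noise)) stop("`noise` required when eta > 0", call. = FALSE)
  }
  dir_coef <- sqrt(pmax(1 - ab_to - sigma^2, 0))
  y <- sqrt(ab_to) * x0_hat + dir_coef * eps_hat
  if (sigma > 0) y <- y + sigma * noise
  attributes(y) <- attributes(x_t)
  y
}

# Decreasing ladder of DDIM steps from start_step down to 0, at most
# n_steps transitions, evenly spaced.
ddim_ladder <- function(start_step, n_steps) {
  steps <- unique(as.integer(round(seq(start_step, 0, length.out = n_steps + 1))))
  if (steps[1] != start_step) steps <- c(start_step, steps)
  steps
}

# Normalise a denoiser (object or plain function) to the batch contract
# f(x: n x D matrix, step: int, label: character or NULL) -> n x D matrix.
as_denoiser_fun <- function(denoiser) {
  if (is.function(denoiser)) return(denoiser)
  if (inherits(denoiser, "cond_denoiser"))
    return(function(x, step, label) denoiser_forward(denoiser, x, step, label))
  stop("`denoiser` must be a function or a cond_denoiser", call. = FALSE)
}

#' Classifier-free-guided DDIM sampling from a perturbed guide
#'
#' Walks a decreasing step ladder from `start_step` to 0. At each rung the
#' denoiser is evaluated twice — once with the condition label, once with
#' the unconditional token (`NULL`) — the two estimates are mixed with
#' [cfg_combine()], and the state advances with [ddim_step()]. The final
#' state is the conditional synthesis `x0_hat^(label)`, clipped to
#' `[-1, 1]`.
#'
#' @param perturbed noised guide, image array or flat `n x D` batch matrix.
#' @param start_step discrete step of `perturbed` (from [perturb_guide()]).
#' @param label condition label (one of [condition_levels()]).
#' @param denoiser a trained `cond_denoiser` or a function
#'   `(x, step, label-or-NULL) -> noise estimate` on flat batch matrices.
#' @param cfg a [sampler_config()].
#' @param schedule a [make_schedule()].
#' @param rng_seed seed for the `eta > 0` noise draws.
#' @return synthesis with the shape of `perturbed`.
#' @export
cfg_ddim_sample <- function(perturbed, start_step, label, denoiser, cfg,
                            schedule, rng_seed = cfg$seed) {
  if (start_step > schedule$T_total)
    stop("start_step exceeds the schedule horizon", call. = FALSE)
  if (inherits(denoiser, "cond_denoiser") && !denoiser$null_trained &&
      cfg$omega != 1)
    warning("unconditional token was never trained (p_uncond = 0); ",
            "guidance with omega != 1 is unreliable", call. = FALSE)
  f <- as_denoiser_fun(denoiser)
  was_image <- !is.matrix(perturbed)
  x <- if (was_image) as_flat_batch(perturbed) else perturbed
  steps <- ddim_ladder(start_step, cfg$n_steps)
  for (i in seq_len(length(steps) - 1L)) {
    eps_c <- f(x, steps[i], label)
    eps_u <- f(x, steps[i], NULL)
    if (!identical(dim(eps_c), dim(x)) || !identical(dim(eps_u), dim(x)))
      stop("denoiser output geometry does not match its input", call. = FALSE)
    eps_hat <- cfg_combine(eps_u, eps_c, cfg$omega)
    z <- NULL
    if (cfg$eta > 0)
      z <- with_seed(rng_seed + i, matrix(stats::rnorm(length(x)), nrow(x)))
    x <- ddim_step(x, eps_hat, steps[i], steps[i + 1L], schedule,
                   eta = cfg$eta, noise = z, clip_denoised = cfg$clip_denoised)
  }
  x <- pmin(pmax(x, -1), 1)
  if (was_image) flat_to_image(x, img_geometry(perturbed)) else x
}

#' Guided conditional synthesis for every class
#'
#' The inference-time generator: the guide is perturbed once (a single noise
#' realisation shared by both conditions, so the only difference between the
#' class syntheses is the condition itself) and then denoised with
#' [cfg_ddim_sample()] once per class label.
#'
#' @inheritParams cfg_ddim_sample
#' @param x0 guide image (array) or flat batch matrix.
#' @param labels class labels to synthesise (default both levels).
#' @return object of class `guided_synthesis`: list with `guide`,
#'   `perturbed`, `start_step` and `per_label` (named list of syntheses).
#' @export
synthesize_conditionals <- function(x0, denoiser, cfg, schedule,
                                    rng_seed = cfg$seed,
                                    labels = condition_levels()) {
  p <- perturb_guide(x0, cfg, schedule, rng_seed = rng_seed)
  per_label <- lapply(labels, function(lab)
    cfg_ddim_sample(p$perturbed, p$step, lab, denoiser, cfg, schedule,
                    rng_seed = rng_seed))
  names(per_label) <- labels
  structure(list(guide = x0, perturbed = p$perturbed, start_step = p$step,
                 per_label = per_label, cfg = cfg),
            class = "guided_synthesis")
}

#' @export
print.guided_synthesis <- function(x, ...) {
  cat(sprintf("<guided_synthesis: start_step %d, labels: %s>\n",
              x$start_step, paste(names(x$per_label), collapse = ", ")))
  invisible(x)
}
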