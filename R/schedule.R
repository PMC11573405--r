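#' Discrete diffusion noise schedule
#'
#' Builds the per-step variances `beta[t]` and cumulative signal fractions
#' `alpha_bar[t] = prod(1 - beta[1:t])` of a variance-preserving diffusion
#' process with `T_total` forward steps. By convention `alpha_bar` at step 0
#' equals 1 (no noise); [alpha_bar_at()] implements that boundary.
#'
#' @param T_total number of forward diffusion steps (default 1000).
#' @param kind schedule family; currently `"linear"` (beta interpolated
#'   linearly between `beta_min` and `beta_max`).
#' @param beta_min,beta_max endpoints of the beta ramp, in (0, 1).
#' @return object of class `noise_schedule` with fields `T_total`, `beta`,
#'   `alpha_bar`.
#' @export
make_schedule <- function(T_total = 1000L, kind = c("linear"),
                          beta_min = 1e-4, beta_max = 0.02) {
  kind <- match.arg(kind)
  T_total <- as.integer(T_total)
  if (is.na(T_total) || T_total < 1L)
    stop("`T_total` must be a positive integer", call. = FALSE)
  if (!(beta_min > 0 && beta_min <= beta_max && beta_max < 1))
    stop("need 0 < beta_min <= beta_max < 1", call. = FALSE)
  beta <- if (T_total == 1L) beta_min else
    seq(beta_min, beta_max, length.out = T_total)
  alpha_bar <- cumprod(1 - beta)
  structure(list(T_total = T_total, beta = beta, alpha_bar = alpha_bar,
                 kind = kind, beta_min = beta_min, beta_max = beta_max),
            class = "noise_schedule")
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat(sprintf("<noise_schedule %s, T=%d, beta [%g, %g], final alpha_bar %.3g>\n",
              x$kind, x$T_total, x$beta_min, x$beta_max,
              x$alpha_bar[x$T_total]))
  invisible(x)
}

#' Cumulative signal fraction at a step
#'
#' @param schedule a [make_schedule()] object.
#' @param step integer in `0..T_total`; step 0 returns 1 (clean-image
#'   boundary).
#' @return `alpha_bar` at `step`.
#' @export
alpha_bar_at <- function(schedule, step) {
  step <- as.integer(step)
  if (any(is.na(step)) || any(step < 0L) || any(step > schedule$T_total))
    stop("step out of range 0..", schedule$T_total, call. = FALSE)
  ifelse(step == 0L, 1, schedule$alpha_bar[pmax(step, 1L)])
}

#' Closed-form forward marginal
#'
#' One draw from `q(x_step | x0)` of the variance-preserving forward
#' process: `sqrt(alpha_bar) * x0 + sqrt(1 - alpha_bar) * noise`. The noise
#' is injected by the caller so that all randomness is seedable.
#'
#' @param x0 clean image (array) or flat batch matrix.
#' @param step forward step in `0..T_total` (0 returns `x0` exactly).
#' @param schedule a [make_schedule()] object.
#' @param noise standard-normal array/matrix with the geometry of `x0`.
#' @return noised image, same shape and attributes as `x0`.
#' @export
forward_marginal <- function(x0, step, schedule, noise) {
  if (!identical(dim(x0), dim(noise)))
    stop("noise geometry does not match x0", call. = FALSE)
  ab <- alpha_bar_at(schedule, step)
  y <- sqrt(ab) * x0 + sqrt(1 - ab) * noise
  attributes(y) <- attributes(x0)
  y
}
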