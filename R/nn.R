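# Small neural-network primitives shared by the denoiser and embedding
# networks: seeded RNG scoping, sinusoidal step embeddings, parameter
# initialisation and an Adam optimiser over flat parameter lists.

# Evaluate `expr` under `set.seed(seed)` and restore the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Deterministic 31-bit hash of a string, for deriving per-image seeds from
# (global seed, image id) so batch order never changes a prediction.
hash_seed <- function(seed, key) {
  h <- as.numeric(seed) %% 2147483647
  for (b in utf8ToInt(as.character(key))) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

# Sinusoidal embedding of a diffusion step, dim `d` (even): the standard
# transformer-style frequency fan over log-spaced wavelengths.
time_embedding <- function(step, d, T_total) {
  half <- d %/% 2L
  freq <- exp(-log(10000) * (seq_len(half) - 1L) / max(half - 1L, 1L))
  ang <- outer(step / T_total * 1000, freq)
  cbind(sin(ang), cos(ang))
}

# He-uniform initialisation for a fan_in x fan_out weight matrix.
init_weight <- function(fan_in, fan_out, zero = FALSE) {
  if (zero) return(matrix(0, fan_in, fan_out))
  lim <- sqrt(6 / fan_in)
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

relu <- function(x) x * (x > 0)

# --- Adam over a named list of parameter matrices -------------------------
#
# The moment buffers and the parameter matrices are mutated in place by the
# compiled kernel, so the optimiser state and the parameter list must be
# owned exclusively by the training loop (snapshots taken with
# copy_params()).

adam_new <- function(params, lr = 2e-4, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, lr_mult = NULL) {
  mult <- rep(1, length(params)); names(mult) <- names(params)
  for (nm in names(lr_mult)) mult[nm] <- lr_mult[[nm]]
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       mult = mult,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  corr1 <- 1 - opt$beta1^opt$t
  corr2 <- 1 - opt$beta2^opt$t
  for (nm in names(params))
    adam_update_inplace(params[[nm]], opt$m[[nm]], opt$v[[nm]], grads[[nm]],
                        opt$lr * opt$mult[[nm]], opt$beta1, opt$beta2,
                        opt$eps, corr1, corr2)
  list(opt = opt, params = params)
}

# Deep copy of a parameter list (in-place updates would otherwise reach
# into stored snapshots).
copy_params <- function(params) lapply(params, function(p) p + 0)
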