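#' Assemble a trained classification pipeline
#'
#' Binds the Stage-1 denoiser, the Stage-2 embedding network, the sampler
#' configuration and the noise schedule into a single predictor object.
#'
#' @param denoiser a trained `cond_denoiser` (or a denoising function with
#'   the batch contract).
#' @param embedder a trained `embed_net`.
#' @param cfg a [sampler_config()].
#' @param schedule a [make_schedule()]; must match the denoiser's horizon.
#' @return object of class `condiff_pipeline`.
#' @export
condiff_pipeline <- function(denoiser, embedder, cfg = sampler_config(),
                             schedule = make_schedule()) {
  if (inherits(denoiser, "cond_denoiser") &&
      denoiser$T_total != schedule$T_total)
    stop("denoiser was trained against a different schedule horizon",
         call. = FALSE)
  structure(list(denoiser = denoiser, embedder = embedder, cfg = cfg,
                 schedule = schedule),
            class = "condiff_pipeline")
}

#' @export
print.condiff_pipeline <- function(x, ...) {
  cat(sprintf("<condiff_pipeline: omega=%g, t0=%g, %d DDIM steps, T=%d>\n",
              x$cfg$omega, x$cfg$t0, x$cfg$n_steps, x$schedule$T_total))
  invisible(x)
}

#' Classify one image
#'
#' End-to-end inference: the guide is partially noised (one shared
#' realisation for both conditions), resynthesised under each class with
#' classifier-free-guided DDIM sampling, and assigned the label whose
#' synthesis lies closest in embedding space. The per-image noise seed is
#' derived from the pipeline seed and `image_id`, so predictions are
#' independent of batch composition and order.
#'
#' @param x0 guide image.
#' @param pipe a [condiff_pipeline()].
#' @param image_id identifier entering the per-image seed derivation.
#' @return `condiff_classification` with added `provenance` (seed, omega,
#'   t0, n_steps).
#' @export
condiff_predict <- function(x0, pipe, image_id = "image") {
  seed_i <- hash_seed(pipe$cfg$seed, image_id)
  syn <- synthesize_conditionals(x0, pipe$denoiser, pipe$cfg, pipe$schedule,
                                 rng_seed = seed_i)
  res <- classify_distance(x0, syn, pipe$embedder)
  res$provenance <- list(image_id = image_id, seed = seed_i,
                         omega = pipe$cfg$omega, t0 = pipe$cfg$t0,
                         n_steps = pipe$cfg$n_steps)
  res$synthesis <- syn
  res
}

#' Classify a manifest of images
#'
#' Batched view of [condiff_predict()]: guides are stacked and the reverse
#' ladder is run once per condition for the whole batch. Per-image seeds
#' make the results identical to per-image calls (`eta = 0`). Rows whose
#' image cannot be resolved are skipped with a warning.
#'
#' @param images named list of image arrays (names matching
#'   `manifest$image_id`), or `NULL` to read `manifest$image_path` PNGs.
#' @param manifest data frame with `image_id`, `label`, `subject_id` (and
#'   `image_path` when `images` is `NULL`).
#' @param pipe a [condiff_pipeline()].
#' @return data frame: `image_id`, `subject_id`, `label`, `predicted`,
#'   `d_uninfected`, `d_infected`, `margin`, `seed`.
#' @export
condiff_predict_batch <- function(images, manifest, pipe) {
  if (nrow(manifest) == 0L) {
    warning("empty manifest: no predictions", call. = FALSE)
    return(data.frame(image_id = character(), subject_id = character(),
                      label = character(), predicted = character(),
                      d_uninfected = numeric(), d_infected = numeric(),
                      margin = numeric(), seed = integer()))
  }
  rows <- seq_len(nrow(manifest))
  fetch <- function(i) {
    id <- manifest$image_id[i]
    if (!is.null(images)) {
      if (!is.null(images[[id]])) return(images[[id]])
      return(NULL)
    }
    tryCatch(read_image_png(manifest$image_path[i]), error = function(e) NULL)
  }
  imgs <- lapply(rows, fetch)
  ok <- !vapply(imgs, is.null, logical(1))
  if (any(!ok))
    warning(sum(!ok), " image(s) could not be read; skipped", call. = FALSE)
  manifest <- manifest[ok, , drop = FALSE]
  imgs <- imgs[ok]
  if (nrow(manifest) == 0L)
    return(condiff_predict_batch(images, manifest[0, , drop = FALSE], pipe))
  X <- do.call(rbind, lapply(imgs, function(im) as.numeric(im)))
  D <- ncol(X)
  seeds <- vapply(manifest$image_id, function(id)
    hash_seed(pipe$cfg$seed, id), integer(1))
  Z <- do.call(rbind, lapply(seeds, function(s)
    with_seed(s, stats::rnorm(D))))
  s0 <- as.integer(round_half_away(pipe$cfg$t0 * pipe$schedule$T_total))
  s0 <- max(1L, min(s0, pipe$schedule$T_total))
  Xt <- forward_marginal(X, s0, pipe$schedule, Z)
  lev <- condition_levels()
  synths <- lapply(lev, function(lab)
    cfg_ddim_sample(Xt, s0, lab, pipe$denoiser, pipe$cfg, pipe$schedule))
  e0 <- embed_forward_of(pipe$embedder, X)
  d1 <- rowSums((e0 - embed_forward_of(pipe$embedder, synths[[1]]))^2)
  d2 <- rowSums((e0 - embed_forward_of(pipe$embedder, synths[[2]]))^2)
  predicted <- ifelse(d1 <= d2, lev[1], lev[2])
  data.frame(image_id = manifest$image_id, subject_id = manifest$subject_id,
             label = manifest$label, predicted = predicted,
             d_uninfected = d1, d_infected = d2, margin = abs(d1 - d2),
             seed = seeds, row.names = NULL)
}

embed_forward_of <- function(embedder, X) {
  if (inherits(embedder, "embed_net")) embed_forward(embedder, X)
  else embedder(X)
}

#' Two-stage end-to-end training
#'
#' Runs the full training recipe on a labelled dataset: Stage 1 trains the
#' conditional denoiser on the training split; the trained generator then
#' synthesises the conditional dataset `D_s` from the training guides (at
#' the pipeline's omega / t0 / ladder length); Stage 2 trains the embedding
#' network on triplets whose (positive, negative) pair is synthetic with
#' probability `p_gen`, selecting the checkpoint with the best
#' distance-classification accuracy on the validation split.
#'
#' @param dataset a [generate_wound_dataset()]-shaped list (`images`,
#'   `manifest` with `split` column).
#' @param cfg a [sampler_config()] (omega, t0, ladder length, seed).
#' @param schedule a [make_schedule()].
#' @param denoiser_cfg,embed_cfg architecture configurations; image size is
#'   aligned to the dataset automatically.
#' @param stage1_steps,stage1_batch,stage2_steps optimisation budgets.
#' @param p_gen synthetic-pair probability for Stage 2.
#' @param margin triplet margin.
#' @param seed master training seed.
#' @return a fitted [condiff_pipeline()]; the synthetic pool and training
#'   histories are attached as `attr(fit, "artifacts")`.
#' @export
condiff_fit <- function(dataset, cfg = sampler_config(),
                        schedule = make_schedule(),
                        denoiser_cfg = NULL, embed_cfg = NULL,
                        stage1_steps = 2500L, stage1_batch = 48L,
                        stage2_steps = 500L, p_gen = 0.2, margin = 1,
                        seed = 1L) {
  man <- dataset$manifest
  size <- dim(dataset$images[[1]])[1]
  if (is.null(denoiser_cfg)) denoiser_cfg <- denoiser_config(image_size = size)
  if (is.null(embed_cfg))
    embed_cfg <- embed_config(image_size = size, conv_channels = 12L, d = 32L)
  pick <- function(split) {
    ids <- man$image_id[man$split == split]
    list(x = do.call(rbind, lapply(dataset$images[ids], as.numeric)),
         labels = man$label[match(ids, man$image_id)], ids = ids)
  }
  tr <- pick("train"); va <- pick("val")
  denoiser <- train_stage1(tr$x, tr$labels, denoiser_cfg, schedule,
                           steps = stage1_steps, batch_size = stage1_batch,
                           seed = hash_seed(seed, "stage1"))
  # synthetic pool D_s: both conditional syntheses of every training guide
  syn_tr <- synthesize_conditionals(tr$x, denoiser, cfg, schedule,
                                    rng_seed = hash_seed(seed, "Ds"))
  synth_x <- rbind(syn_tr$per_label[[1]], syn_tr$per_label[[2]])
  synth_labels <- rep(names(syn_tr$per_label), each = nrow(tr$x))
  syn_va <- synthesize_conditionals(va$x, denoiser, cfg, schedule,
                                    rng_seed = hash_seed(seed, "val"))
  validation <- list(guides = va$x,
                     synth_y1 = syn_va$per_label[["uninfected"]],
                     synth_y2 = syn_va$per_label[["infected"]],
                     labels = va$labels)
  embedder <- train_stage2(tr$x, tr$labels, synth_x, synth_labels,
                           config = embed_cfg, steps = stage2_steps,
                           margin = margin, p_gen = p_gen,
                           seed = hash_seed(seed, "stage2"),
                           validation = validation)
  fit <- condiff_pipeline(denoiser, embedder, cfg, schedule)
  attr(fit, "artifacts") <- list(
    synth_labels = synth_labels,
    stage1_loss = denoiser$loss_curve,
    stage2_history = embedder$history)
  fit
}
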