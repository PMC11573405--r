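# Trained toy models are expensive to build, so they are created once per
# test session (cached in tempdir RDS files) and shared across test files.

toy_schedule <- function() make_schedule(1000)

cache_rds <- function(key, builder) {
  f <- file.path(tempdir(), paste0("condiff-cache-", key, ".rds"))
  if (file.exists(f)) return(readRDS(f))
  obj <- builder()
  saveRDS(obj, f)
  obj
}

# A small 16x16 study: generated dataset, trained stage-1 denoiser and
# trained stage-2 embedder, used by sampler/denoiser/pipeline tests.
get_toy_world <- function() {
  cache_rds("toy-world", function() {
    ds <- generate_wound_dataset(
      wound_spec(n_subjects = 24, image_size = 16, delta = 1, seed = 71))
    sch <- toy_schedule()
    cfg <- sampler_config(omega = 0.75, t0 = 0.8, n_steps = 30, seed = 73)
    fit <- condiff_fit(ds, cfg = cfg, schedule = sch,
                       denoiser_cfg = denoiser_config(image_size = 16,
                                                      hidden = 96),
                       embed_cfg = embed_config(image_size = 16, d = 16),
                       stage1_steps = 600L, stage2_steps = 150L, seed = 72)
    list(ds = ds, schedule = sch, cfg = cfg, fit = fit,
         denoiser = fit$denoiser, embedder = fit$embedder)
  })
}

# Flat matrix of all images in a split.
split_matrix <- function(ds, splits) {
  ids <- ds$manifest$image_id[ds$manifest$split %in% splits]
  list(x = do.call(rbind, lapply(ds$images[ids], as.numeric)),
       labels = ds$manifest$label[match(ids, ds$manifest$image_id)],
       ids = ids,
       manifest = ds$manifest[ds$manifest$image_id %in% ids, , drop = FALSE])
}

# The full desk-scale study used by the end-to-end acceptance checks:
# 60 subjects at 32x32, omega = 0.75, t0 = 0.8, 30 DDIM steps, p_gen = 0.2.
get_desk_study <- function(delta = 1, seed = 401L) {
  cache_rds(paste0("desk-", delta, "-", seed), function() {
    ds <- generate_wound_dataset(
      wound_spec(n_subjects = 60, image_size = 32, delta = delta,
                 seed = seed))
    cfg <- sampler_config(omega = 0.75, t0 = 0.8, n_steps = 30,
                          seed = seed + 1L)
    fit <- condiff_fit(ds, cfg = cfg, seed = seed + 2L)
    ev <- ds$manifest[ds$manifest$split %in% c("val", "test"), , drop = FALSE]
    kf <- suppressWarnings(  # delta = 0 folds can have undefined PPV
      kfold_evaluate(ds$images, ev, fit, k = 5, seed = seed + 3L))
    list(ds = ds, fit = fit, kfold = kf,
         accuracy = mean(kf$predictions$predicted == kf$predictions$label),
         n_eval = nrow(kf$predictions))
  })
}
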