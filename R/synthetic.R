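#' Synthetic two-class wound-image generator
#'
#' Generates a stylised stand-in for a clinical wound-infection photograph
#' dataset: per subject, a skin-toned background with a smooth low-frequency
#' texture field and an elliptical lesion, photographed at three
#' magnifications (center-crop ratios 1.0 / 0.8 / 0.6, resized back — the
#' "natural augmentation" that makes sample-wise splitting leak). The two
#' classes differ only by a class signature of amplitude `delta` on the
#' lesion: infected lesions get a red-shifted rim and a darkened core.
#' `delta = 0` makes the classes distributionally identical (null control);
#' intra-class variation comes from per-subject geometry, colour jitter and
#' pixel noise, giving the high inter-class similarity / intra-class
#' variation regime that makes the task non-trivial.
#'
#' @param n_subjects number of subjects (one label and one wound per
#'   subject).
#' @param image_size output image side (default 32).
#' @param delta class-signal amplitude, `>= 0`, on the `[-1, 1]` pixel
#'   scale. The default (2) is calibrated so that the classes are plainly
#'   separable (a three-statistic linear probe exceeds 0.95 accuracy);
#'   `delta = 0` gives distributionally identical classes.
#' @param class_balance fraction of infected subjects.
#' @param texture_amp amplitude of the low-frequency skin texture.
#' @param pixel_noise i.i.d. pixel noise s.d.
#' @param magnifications center-crop ratios of the three captures.
#' @param seed generator seed (byte-level deterministic).
#' @return object of class `wound_spec`.
#' @export
wound_spec <- function(n_subjects = 60L, image_size = 32L, delta = 2,
                       class_balance = 0.5, texture_amp = 0.15,
                       pixel_noise = 0.05,
                       magnifications = c(1.0, 0.8, 0.6), seed = 1L) {
  if (delta < 0) stop("`delta` must be >= 0", call. = FALSE)
  if (length(magnifications) != 3L)
    stop("three magnifications expected", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 image_size = as.integer(image_size), delta = delta,
                 class_balance = class_balance, texture_amp = texture_amp,
                 pixel_noise = pixel_noise,
                 magnifications = magnifications, seed = as.integer(seed)),
            class = "wound_spec")
}

# Smooth low-frequency noise field: coarse Gaussian grid, bilinear upsample.
low_freq_field <- function(size, grid = 4L, amp = 1) {
  g <- matrix(stats::rnorm(grid * grid), grid, grid)
  amp * resize_bilinear(g, size, size)
}

# Render one capture of one subject's wound. All randomness comes from the
# caller's RNG state.
render_wound <- function(spec, label, mag) {
  S <- spec$image_size
  # render at base scale, then crop + resize to emulate magnification
  base_color <- c(0.35, 0.05, -0.15) + stats::rnorm(3, 0, 0.05)
  cx <- S / 2 + stats::rnorm(1, 0, S * 0.06)
  cy <- S / 2 + stats::rnorm(1, 0, S * 0.06)
  rx <- S * stats::runif(1, 0.22, 0.30)
  ry <- S * stats::runif(1, 0.22, 0.30)
  theta <- stats::runif(1, 0, pi)
  img <- array(0, c(S, S, 3))
  xg <- matrix(seq_len(S), S, S, byrow = TRUE)   # column coordinate
  yg <- matrix(seq_len(S), S, S)                 # row coordinate
  xr <- (xg - cx) * cos(theta) + (yg - cy) * sin(theta)
  yr <- -(xg - cx) * sin(theta) + (yg - cy) * cos(theta)
  r <- sqrt((xr / rx)^2 + (yr / ry)^2)           # 1 on the lesion boundary
  inside <- r <= 1
  rim <- r > 0.62 & r <= 1
  core <- r <= 0.45
  lesion_color <- c(0.10, -0.35, -0.45) + stats::rnorm(3, 0, 0.05)
  d <- spec$delta
  jit <- stats::rnorm(1, 1, 0.1)                 # intra-class signal jitter
  for (ch in 1:3) {
    plane <- base_color[ch] + low_freq_field(S, amp = spec$texture_amp)
    plane[inside] <- lesion_color[ch] + plane[inside] * 0.3
    if (label == "infected") {
      sig_rim <- c(0.9, -0.5, -0.5)[ch]          # red-shifted rim
      plane[rim] <- plane[rim] + d * jit * sig_rim * 0.5
      plane[core] <- plane[core] - d * jit * 0.45 # darkened (necrotic) core
    }
    img[, , ch] <- plane
  }
  img <- img + array(stats::rnorm(S * S * 3, 0, spec$pixel_noise), dim(img))
  if (mag < 1) {
    half <- floor(S * mag / 2)
    lo <- max(1L, as.integer(round(S / 2 - half)))
    hi <- min(S, as.integer(lo + 2L * half - 1L))
    img <- resize_bilinear(img[lo:hi, lo:hi, , drop = FALSE], S, S)
  }
  clip_image(as_image(img))
}

#' Generate a synthetic wound dataset
#'
#' Produces one wound per subject at three magnifications, assigns a
#' subject-wise 70/15/15 train/validation/test split, and returns images
#' in memory together with a manifest. With `single_magnification = TRUE`
#' (the leak-free protocol) only the x2-magnification capture of each
#' subject is emitted.
#'
#' @param spec a [wound_spec()].
#' @param single_magnification emit only the middle magnification.
#' @param fractions train/validation/test subject fractions (sum to 1).
#' @return list with `images` (named list of image arrays) and `manifest`
#'   (data frame: `image_id`, `label`, `subject_id`, `magnification`,
#'   `split`).
#' @export
generate_wound_dataset <- function(spec = wound_spec(),
                                   single_magnification = TRUE,
                                   fractions = c(0.70, 0.15, 0.15)) {
  n <- spec$n_subjects
  n_inf <- round(n * spec$class_balance)
  labels <- with_seed(hash_seed(spec$seed, "labels"),
                      sample(rep(c("infected", "uninfected"),
                                 c(n_inf, n - n_inf))))
  mags <- if (single_magnification) 2L else 1:3
  images <- list(); rows <- list()
  for (s in seq_len(n)) {
    sid <- sprintf("subj%03d", s)
    for (m in mags) {
      id <- sprintf("%s_mag%d", sid, m)
      images[[id]] <- with_seed(
        hash_seed(spec$seed, id),
        render_wound(spec, labels[s], spec$magnifications[m]))
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = id, label = labels[s], subject_id = sid,
        magnification = m, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  manifest <- subjectwise_split(manifest, fractions,
                                seed = hash_seed(spec$seed, "split"))
  list(images = images, manifest = manifest, spec = spec)
}

#' Subject-wise train/validation/test split
#'
#' Assigns every subject — and therefore all of its magnification captures —
#' to exactly one split, stratified by class label. Within each class,
#' subject counts per split follow the largest-remainder rule on the
#' requested fractions, so the realised sizes are deterministic.
#'
#' @param manifest data frame with columns `subject_id` and `label`.
#' @param fractions length-3 numeric summing to 1 (train, val, test).
#' @param seed shuffling seed.
#' @return the manifest with a `split` column added/replaced.
#' @export
subjectwise_split <- function(manifest, fractions = c(0.70, 0.15, 0.15),
                              seed = 1L) {
  if (nrow(manifest) == 0L) stop("empty manifest", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("`fractions` must sum to 1", call. = FALSE)
  split_names <- c("train", "val", "test")
  subj <- unique(manifest[, c("subject_id", "label")])
  assign <- character(0); names(assign) <- character(0)
  for (lab in unique(subj$label)) {
    ids <- subj$subject_id[subj$label == lab]
    ids <- with_seed(hash_seed(seed, lab), sample(ids))
    k <- length(ids)
    base <- floor(fractions * k)
    rem <- fractions * k - base
    extra <- k - sum(base)
    if (extra > 0) {
      take <- order(rem, decreasing = TRUE)[seq_len(extra)]
      base[take] <- base[take] + 1L
    }
    if (any(base == 0L) && k >= 3L) {  # guarantee non-empty splits
      for (i in which(base == 0L)) {
        donor <- which.max(base); base[donor] <- base[donor] - 1L
        base[i] <- 1L
      }
    }
    sp <- rep(split_names, base)
    assign[ids] <- sp
  }
  manifest$split <- unname(assign[manifest$subject_id])
  manifest
}

#' Sample-wise split (leakage hazard, for audits)
#'
#' Splits individual images at random, ignoring subjects — the protocol
#' that leaks information when the same wound appears at several
#' magnifications. Provided as a negative control for
#' [audit_subject_leakage()].
#'
#' @inheritParams subjectwise_split
#' @return manifest with a `split` column.
#' @export
samplewise_split <- function(manifest, fractions = c(0.70, 0.15, 0.15),
                             seed = 1L) {
  if (nrow(manifest) == 0L) stop("empty manifest", call. = FALSE)
  n <- nrow(manifest)
  counts <- floor(fractions * n)
  counts[1] <- counts[1] + n - sum(counts)
  sp <- with_seed(seed, sample(rep(c("train", "val", "test"), counts)))
  manifest$split <- sp
  manifest
}

#' Audit a split manifest for subject leakage
#'
#' @param manifest data frame with `subject_id` and `split` columns.
#' @return list with `ok` (logical) and `leaking_subjects` (character
#'   vector of subjects present in more than one split).
#' @export
audit_subject_leakage <- function(manifest) {
  tab <- tapply(manifest$split, manifest$subject_id,
                function(s) length(unique(s)))
  leaking <- names(tab)[tab > 1]
  list(ok = length(leaking) == 0L, leaking_subjects = leaking)
}

#' Write a generated dataset to disk
#'
#' Writes each image as an 8-bit PNG and the manifest as CSV (with an
#' `image_path` column), mirroring the schema a real labelled wound dataset
#' would use.
#'
#' @param dataset a [generate_wound_dataset()] result.
#' @param dir output directory (created if needed).
#' @return path of the manifest CSV.
#' @export
write_wound_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(dataset$images), function(id) {
    p <- file.path(dir, paste0(id, ".png"))
    write_image_png(dataset$images[[id]], p)
    p
  }, character(1))
  man <- dataset$manifest
  man$image_path <- unname(paths[man$image_id])
  csv <- file.path(dir, "manifest.csv")
  utils::write.csv(man, csv, row.names = FALSE)
  csv
}

#' Read a dataset written by [write_wound_dataset()]
#'
#' @param manifest_csv path to the manifest CSV.
#' @return list with `images` and `manifest` as in
#'   [generate_wound_dataset()].
#' @export
read_wound_dataset <- function(manifest_csv) {
  man <- utils::read.csv(manifest_csv, stringsAsFactors = FALSE)
  images <- lapply(seq_len(nrow(man)), function(i)
    read_image_png(man$image_path[i], label = man$label[i],
                   subject_id = man$subject_id[i]))
  names(images) <- man$image_id
  list(images = images, manifest = man)
}
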