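#' Activation maps of the embedding backbone
#'
#' Per-channel spatial activations at a named layer of the embedding
#' network, upsampled to input resolution and min-max normalised to
#' `[0, 1]` channel by channel. A constant (degenerate-range) channel
#' normalises to all zeros.
#'
#' @param model a trained `embed_net`.
#' @param x image array (or flat length-D vector).
#' @param layer `"conv"` (post-ReLU convolution output, full resolution) or
#'   `"pool"` (pooled stage, bilinearly upsampled).
#' @return `H x W x K` array of normalised maps, `K` = channel count.
#' @export
activation_maps <- function(model, x, layer = c("conv", "pool")) {
  layer <- match.arg(layer)
  g <- model$geom
  X <- as_flat_batch(x)
  if (ncol(X) != g$D) stop("input geometry mismatch", call. = FALSE)
  fw <- embed_forward(model, X, want_cache = TRUE)
  Cc <- model$config$conv_channels
  H <- g$H; W <- g$W
  maps <- array(0, c(H, W, Cc))
  if (layer == "conv") {
    for (k in seq_len(Cc)) maps[, , k] <- matrix(fw$act[, k], H, W)
  } else {
    hp <- H %/% model$config$pool
    pooled <- rowsum(fw$act, fw$groups) / model$config$pool^2
    for (k in seq_len(Cc))
      maps[, , k] <- resize_bilinear(matrix(pooled[, k], hp), H, W)
  }
  for (k in seq_len(Cc)) maps[, , k] <- normalize01(maps[, , k])
  maps
}

# min-max normalise to [0, 1]; a constant map stays all-zero.
normalize01 <- function(m) {
  rng <- range(m)
  if (rng[2] - rng[1] <= 0) return(m * 0)
  (m - rng[1]) / (rng[2] - rng[1])
}

#' Similarity Score-CAM between a guide and a candidate synthesis
#'
#' A gradient-free saliency map showing which regions of `candidate` the
#' embedding model treats as similar to `guide`. Each activation channel of
#' the candidate produces a masked input `candidate * M_k`; its score is
#' the negative squared embedding distance to the guide,
#' `s_k = -||f(guide) - f(candidate * M_k)||^2`; the heatmap is the
#' softmax(s)-weighted sum of the maps, min-max normalised. (Classic
#' Score-CAM scores class logits; here the "class score" is similarity to
#' the guide, matching the distance-based decision rule.)
#'
#' @param model a trained `embed_net`.
#' @param guide,candidate image arrays of the model's geometry.
#' @param layer activation layer tag (see [activation_maps()]).
#' @return object of class `scorecam_heatmap`: list with `values`
#'   (`H x W` in `[0, 1]`), `weights` (softmax weights), `scores`, `layer`.
#' @export
similarity_scorecam <- function(model, guide, candidate,
                                layer = c("conv", "pool")) {
  layer <- match.arg(layer)
  g <- model$geom
  stopifnot_same_geometry(array(0, c(g$H, g$W, g$C)), candidate)
  maps <- activation_maps(model, candidate, layer)
  K <- dim(maps)[3]
  cand <- as.numeric(candidate)
  masked <- do.call(rbind, lapply(seq_len(K), function(k)
    cand * as.numeric(maps[, , k][rep(seq_len(g$H * g$W), g$C)])))
  # each mask multiplies every colour channel by the same spatial map
  e_guide <- embed(model, as_flat_batch(guide))
  e_masked <- embed_forward(model, masked)
  scores <- -rowSums(sweep(e_masked, 2, e_guide)^2)
  w <- exp(scores - max(scores)); w <- w / sum(w)
  heat <- matrix(0, g$H, g$W)
  for (k in seq_len(K)) heat <- heat + w[k] * maps[, , k]
  structure(list(values = normalize01(heat), weights = w, scores = scores,
                 layer = layer),
            class = "scorecam_heatmap")
}

#' @export
print.scorecam_heatmap <- function(x, ...) {
  cat(sprintf("<scorecam_heatmap %dx%d, layer '%s', %d channels>\n",
              nrow(x$values), ncol(x$values), x$layer, length(x$weights)))
  invisible(x)
}

#' Write a heatmap overlay PNG
#'
#' Renders the heatmap with a jet-style colour ramp, alpha-blended at 0.5
#' over the underlying image.
#'
#' @param heatmap a [similarity_scorecam()] result (or `H x W` matrix in
#'   `[0, 1]`).
#' @param image underlying image array in `[-1, 1]`.
#' @param path output PNG path.
#' @param alpha blend weight of the heatmap.
#' @return the path, invisibly.
#' @export
write_heatmap_png <- function(heatmap, image, path, alpha = 0.5) {
  hm <- if (inherits(heatmap, "scorecam_heatmap")) heatmap$values else heatmap
  ramp <- grDevices::colorRamp(c("navy", "blue", "cyan", "yellow", "red"))
  rgbmap <- ramp(as.numeric(hm)) / 255
  H <- nrow(hm); W <- ncol(hm)
  base <- (clip_image(image) + 1) / 2
  out <- array(0, c(H, W, 3))
  for (ch in 1:3)
    out[, , ch] <- (1 - alpha) * base[, , ch] + alpha * matrix(rgbmap[, ch], H, W)
  attributes(out) <- list(dim = dim(out))
  png::writePNG(pmin(pmax(out, 0), 1), path)
  invisible(path)
}
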