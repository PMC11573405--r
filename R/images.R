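#' Image tensors
#'
#' Images are plain numeric arrays of dimension `H x W x C` with pixel values
#' on the symmetric scale `[-1, 1]` used throughout the diffusion model.
#' 8-bit PNG values in `[0, 1]` are mapped linearly: `x = 2 * u - 1`.
#'
#' @param pixels numeric array `H x W x C` (or `H x W`, promoted to one
#'   channel), finite, typically in `[-1, 1]`.
#' @param label optional condition label (see [condition_levels()]).
#' @param subject_id optional subject identifier.
#' @return numeric array of class `condiff_image`.
#' @export
as_image <- function(pixels, label = NULL, subject_id = NULL) {
  if (is.matrix(pixels)) dim(pixels) <- c(dim(pixels), 1L)
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    stop("`pixels` must be an H x W x C array", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("image contains non-finite values", call. = FALSE)
  storage.mode(pixels) <- "double"
  structure(pixels,
            label = label, subject_id = subject_id,
            class = c("condiff_image", "array"))
}

#' @export
print.condiff_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<condiff_image %dx%dx%d, range [%.3f, %.3f]%s>\n",
              d[1], d[2], d[3], min(x), max(x),
              if (!is.null(attr(x, "label"))) paste0(", label=", attr(x, "label")) else ""))
  invisible(x)
}

img_geometry <- function(x) dim(x)[1:3]

stopifnot_same_geometry <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("image geometry mismatch: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"), call. = FALSE)
  invisible(TRUE)
}

#' Clip pixel values to the model range
#' @param x image array.
#' @param lo,hi clipping bounds (default `[-1, 1]`).
#' @return clipped array, attributes preserved.
#' @export
clip_image <- function(x, lo = -1, hi = 1) {
  y <- pmin(pmax(x, lo), hi)
  attributes(y) <- attributes(x)
  y
}

#' Read / write 8-bit PNG images
#'
#' PNG intensities in `[0, 1]` are mapped linearly to the internal `[-1, 1]`
#' scale on read and back (with clipping) on write. Alpha channels are
#' dropped; greyscale files are promoted to one channel.
#'
#' @param path file path.
#' @param label,subject_id optional metadata attached to the returned image.
#' @return [as_image()] array.
#' @export
read_image_png <- function(path, label = NULL, subject_id = NULL) {
  u <- png::readPNG(path)
  if (is.matrix(u)) dim(u) <- c(dim(u), 1L)
  if (dim(u)[3] == 4L) u <- u[, , 1:3, drop = FALSE]
  as_image(2 * u - 1, label = label, subject_id = subject_id)
}

#' @rdname read_image_png
#' @param x image array in `[-1, 1]`.
#' @export
write_image_png <- function(x, path) {
  u <- (clip_image(x) + 1) / 2
  attributes(u) <- list(dim = dim(x))
  png::writePNG(u, path)
  invisible(path)
}

#' Bilinear resize
#'
#' Used by the synthetic generator (magnification crops) and Score-CAM
#' (upsampling activation maps to input resolution).
#'
#' @param x `H x W x C` array or `H x W` matrix.
#' @param out_h,out_w output size.
#' @return resized array (matrix in, matrix out).
#' @export
resize_bilinear <- function(x, out_h, out_w) {
  was_matrix <- is.matrix(x)
  if (was_matrix) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  # sample at pixel centres; clamp to the source grid
  src_r <- (seq_len(out_h) - 0.5) * d[1] / out_h + 0.5 - 1e-9
  src_c <- (seq_len(out_w) - 0.5) * d[2] / out_w + 0.5 - 1e-9
  r0 <- pmin(pmax(floor(src_r), 1L), d[1]); r1 <- pmin(r0 + 1L, d[1])
  c0 <- pmin(pmax(floor(src_c), 1L), d[2]); c1 <- pmin(c0 + 1L, d[2])
  fr <- pmin(pmax(src_r - r0, 0), 1); fc <- pmin(pmax(src_c - c0, 0), 1)
  out <- array(0, c(out_h, out_w, d[3]))
  for (ch in seq_len(d[3])) {
    p <- x[, , ch]
    a <- p[r0, c0, drop = FALSE]; b <- p[r0, c1, drop = FALSE]
    cc <- p[r1, c0, drop = FALSE]; dd <- p[r1, c1, drop = FALSE]
    wr <- matrix(fr, out_h, out_w); wc <- matrix(fc, out_h, out_w, byrow = TRUE)
    out[, , ch] <- (1 - wr) * ((1 - wc) * a + wc * b) + wr * ((1 - wc) * cc + wc * dd)
  }
  if (was_matrix) dim(out) <- dim(out)[1:2]
  out
}

#' Condition labels
#'
#' The two wound states, ordered so that the first level is the negative
#' class ("uninfected") and the second the positive class ("infected").
#' `NULL` is reserved for the unconditional branch of classifier-free
#' guidance and never appears in data manifests.
#'
#' @return character vector of the two class labels.
#' @export
condition_levels <- function() c("uninfected", "infected")

# Map a label (or NULL) to the 1-based embedding row: 1 = unconditional
# token, 2 = uninfected, 3 = infected.
label_index <- function(label) {
  if (is.null(label)) return(1L)
  i <- match(label, condition_levels())
  if (is.na(i)) stop("unknown condition label: ", label, call. = FALSE)
  i + 1L
}

# Flatten one image (or verify a batch matrix) to an n x D matrix.
as_flat_batch <- function(x) {
  if (is.matrix(x) && is.null(attr(x, "label"))) return(x)
  matrix(as.numeric(x), nrow = 1L)
}

flat_to_image <- function(v, geom, label = NULL, subject_id = NULL) {
  as_image(array(as.numeric(v), geom), label = label, subject_id = subject_id)
}
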