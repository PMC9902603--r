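# Grad-CAM saliency over the classifier: gradient-weighted class activation
# mapping at any convolutional activation of the frozen backbone.

#' Compute a Grad-CAM saliency map
#'
#' For a target class c and a convolutional activation A (channels k), the
#' map is `ReLU(sum_k alpha_k A_k)` where `alpha_k` is the spatial mean of
#' the gradient of the pre-softmax class score with respect to `A_k`. The
#' gradient flows from the linear head through global average pooling and
#' backwards through any layers between the network output and the target
#' activation. The map is normalized by its maximum (when positive) and
#' bilinearly upsampled to the input resolution.
#'
#' @param model a trained [train_head()] model.
#' @param image a preprocessed array (output of [preprocess_pipeline()]) or
#'   a raw labeled image, which is preprocessed with the model's stored
#'   configuration first.
#' @param target_class `"A"`, `"B"` or `"C"` (or index 1..3).
#' @param layer_id id of a backbone activation (e.g. `"conv1"`); default is
#'   the final convolutional activation.
#' @return object of class `saliency_map`: `values` (feature-resolution
#'   map in `[0, 1]`), `upsampled` (input-resolution map), `target_class`,
#'   `layer_id`, `alpha` (the channel weights).
#' @export
#' @examples
#' \donttest{
#' cfg <- synth_config()
#' ds <- generate_dataset(c(A = 8, B = 8, C = 8), cfg, seed = 1)
#' bb <- build_backbone("small_scratch", seed = 1)
#' m <- train_head(bb, ds[c(1:6, 9:14, 17:22)], ds[c(7:8, 15:16, 23:24)],
#'                 hyper = head_hyperparams(epochs = 5), seed = 1)
#' sal <- grad_cam(m, ds[[17]], "C")
#' range(sal$values)
#' }
grad_cam <- function(model, image, target_class, layer_id = NULL) {
  stopifnot(inherits(model, "chromo_model"))
  if (is.numeric(target_class)) {
    if (target_class < 1 || target_class > 3) {
      stop("class index out of range (must be 1..3)")
    }
    target_class <- model$label_order[target_class]
  }
  target_class <- match.arg(target_class, model$label_order)
  ci <- match(target_class, model$label_order)

  x <- if (is.list(image)) {
    preprocess_pipeline(image, config = model$preprocess)
  } else image
  bb <- model$backbone
  ids <- vapply(bb$layers, `[[`, "", "id")
  types <- vapply(bb$layers, `[[`, "", "type")
  conv_ids <- ids[!types %in% c("maxpool", "polar")]
  layer_id <- layer_id %||% conv_ids[length(conv_ids)]
  if (!layer_id %in% conv_ids) {
    stop(sprintf("layer_id '%s' is not a convolutional activation (one of %s)",
                 layer_id, paste(conv_ids, collapse = ", ")))
  }
  fw <- backbone_forward(bb, x, record = TRUE)
  A <- fw$activations[[layer_id]]

  # Gradient of the class score at the network output: the head is linear
  # in the feature-standardized global average pool, so
  # d score / d F_k(i, j) = W[c, k] / (scale_k * h * w).
  fd <- dim(fw$y)
  g <- model$head$W[ci, ] / (model$head$scale * fd[1] * fd[2])
  dy <- array(rep(g, each = fd[1] * fd[2]), fd)

  # Backpropagate to the target activation through any later layers.
  pos <- match(layer_id, ids)
  if (pos < length(bb$layers)) {
    for (li in rev(seq(pos + 1L, length(bb$layers)))) {
      dy <- op_backward(bb$layers[[li]], dy, fw$caches[[ids[li]]])
    }
  }

  alpha <- apply(dy, 3L, mean)
  da <- dim(A)
  map <- matrix(0, da[1], da[2])
  for (k in seq_len(da[3])) map <- map + alpha[k] * A[, , k]
  map <- pmax(map, 0)
  mx <- max(map)
  if (mx > 0) map <- map / mx
  polar_cache <- if ("polar" %in% types) fw$caches[[ids[types == "polar"][1]]]
  up <- if (is.null(polar_cache)) {
    resize_single(map, dim(x)[1])
  } else {
    # feature grid lives in (radius, angle) coordinates: render it back
    # around the stem's centroid
    polar_map_to_cartesian(map, polar_cache$center, polar_cache$rmax,
                           polar_cache$input_size)
  }
  structure(list(values = map, upsampled = up, target_class = target_class,
                 layer_id = layer_id, alpha = alpha),
            class = "saliency_map")
}

# Render a (radius x angle) saliency map into image coordinates by inverse
# polar lookup with bilinear interpolation (circular in the angle axis).
polar_map_to_cartesian <- function(map, center, rmax, input_size) {
  nr <- nrow(map); np <- ncol(map)
  H <- input_size[1]; Wd <- input_size[2]
  px <- matrix(rep(seq_len(Wd), each = H), H, Wd)
  py <- matrix(rep(seq_len(H), times = Wd), H, Wd)
  dx <- px - center[1]
  dy <- py - center[2]
  r <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx) %% (2 * pi)
  ri <- clip(r / rmax * nr + 0.5, 1, nr)
  aj <- ang / (2 * pi) * np + 0.5
  i0 <- floor(ri); i1 <- pmin(i0 + 1, nr); fi <- ri - i0
  j0 <- floor(aj); fj <- aj - j0
  wrap <- function(j) ((j - 1) %% np) + 1
  out <- map[cbind(c(i0), c(wrap(j0)))] * (1 - fi) * (1 - fj) +
         map[cbind(c(i0), c(wrap(j0 + 1)))] * (1 - fi) * fj +
         map[cbind(c(i1), c(wrap(j0)))] * fi * (1 - fj) +
         map[cbind(c(i1), c(wrap(j0 + 1)))] * fi * fj
  out[r > rmax] <- 0
  matrix(out, H, Wd)
}

# Bilinear upsampling of a single-channel map without the [0,255] clipping
# used for images.
resize_single <- function(m, output_size) {
  Wr <- resample_weights(nrow(m), output_size, "bilinear")
  Wc <- resample_weights(ncol(m), output_size, "bilinear")
  Wr %*% m %*% t(Wc)
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("<saliency_map> class %s at layer %s, %dx%d (up %dx%d), max %.3f\n",
              x$target_class, x$layer_id, nrow(x$values), ncol(x$values),
              nrow(x$upsampled), ncol(x$upsampled), max(x$values)))
  invisible(x)
}

#' Overlay a saliency map on its source image
#'
#' Blends a colormapped heat map over the image with per-pixel opacity
#' proportional to saliency. The blending alpha and the original pixels are
#' stored as attributes (`"alpha"`, `"original"`), so the input is exactly
#' recoverable; a zero map returns the image unchanged.
#'
#' @param image raw H x W x 3 image (8-bit intensities).
#' @param saliency a [grad_cam()] result with matching upsampled size.
#' @param colormap name of a built-in ramp (`"jet"` or `"inferno"`).
#' @param opacity maximal blend weight in `[0, 1]`.
#' @return blended H x W x 3 array with attributes `alpha` and `original`.
#' @export
overlay <- function(image, saliency, colormap = c("jet", "inferno"),
                    opacity = 0.5) {
  colormap <- match.arg(colormap)
  x <- as_pixels(image)
  s <- saliency$upsampled
  if (!all(dim(s) == dim(x)[1:2])) {
    stop(sprintf("saliency map is %dx%d but image is %dx%d",
                 nrow(s), ncol(s), dim(x)[1], dim(x)[2]))
  }
  ramp <- switch(colormap,
    jet = grDevices::colorRamp(c("navy", "blue", "cyan", "yellow",
                                 "red", "darkred")),
    inferno = grDevices::colorRamp(grDevices::hcl.colors(16, "Inferno")))
  heat <- ramp(clip(as.vector(s), 0, 1))
  a <- opacity * clip(s, 0, 1)
  out <- x
  for (ch in 1:3) {
    hm <- matrix(heat[, ch], nrow(s), ncol(s))
    out[, , ch] <- x[, , ch] * (1 - a) + hm * a
  }
  attr(out, "alpha") <- a
  attr(out, "original") <- x
  out
}
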