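# Frozen convolutional feature extractors. Three reduced-depth families are
# provided, mirroring the two reference transfer-learning architectures'
# motifs at desk scale plus a from-scratch design:
#   - fire_module:    squeeze 1x1 -> parallel expand 1x1 / 3x3, concatenated
#   - residual_block: 3x3 conv pair with an identity shortcut
#   - small_scratch:  polar-resampling stem followed by circular
#                     convolutions; with global average pooling the feature
#                     vector is approximately invariant to chromosome
#                     rotation and translation, which dominates nuisance
#                     variation in cropped single-chromosome images
# Backbone weights are drawn once from a seeded He-normal initialization and
# then frozen; only the classification head is ever trained. Hooks accept
# externally supplied weights for users who have pretrained parameters.

#' Build a frozen feature-extractor backbone
#'
#' @param family `"small_scratch"`, `"fire_module"` or `"residual_block"`.
#' @param seed seed for the (frozen) weight initialization.
#' @param input_size expected square input side, pixels.
#' @param weights optional externally supplied layer list (a pretrained
#'   plug-in); must match the family's layer structure. When given,
#'   `pretrained` is recorded as `TRUE`.
#' @return object of class `chromo_backbone` with fields `family`, `layers`,
#'   `feature_shape` (height, width, channels of the final activation),
#'   `frozen` (always `TRUE`) and `pretrained`.
#' @export
#' @examples
#' bb <- build_backbone("small_scratch", seed = 1)
#' bb$feature_shape
build_backbone <- function(family = c("small_scratch", "fire_module",
                                      "residual_block"),
                           seed = 42L, input_size = 224L, weights = NULL) {
  family <- match.arg(family)
  layers <- with_seed(seed, {
    switch(family,
      small_scratch = list(
        layer_polar("polar"),
        layer_conv("conv1", 5L, 5L, 3L, 32L, stride = 1L, pad = 2L,
                   circular = TRUE),
        layer_pool("pool1"),
        layer_conv("conv2", 3L, 3L, 32L, 64L, stride = 1L, pad = 1L,
                   circular = TRUE),
        layer_pool("pool2")
      ),
      fire_module = list(
        layer_conv("conv1", 7L, 7L, 3L, 16L, stride = 4L, pad = 3L),
        layer_pool("pool1"),
        layer_fire("fire1", 16L, squeeze = 8L, expand = 16L),
        layer_pool("pool2")
      ),
      residual_block = list(
        layer_conv("conv1", 7L, 7L, 3L, 16L, stride = 4L, pad = 3L),
        layer_pool("pool1"),
        layer_resblock("res1", 16L),
        layer_pool("pool2"),
        layer_conv("conv2", 1L, 1L, 16L, 32L, stride = 1L, pad = 0L)
      ))
  })
  pretrained <- FALSE
  if (!is.null(weights)) {
    if (length(weights) != length(layers) ||
        !identical(vapply(weights, `[[`, "", "type"),
                   vapply(layers, `[[`, "", "type"))) {
      stop("supplied weights do not match the '", family, "' layer structure")
    }
    layers <- weights
    pretrained <- TRUE
  }
  bb <- structure(list(family = family, layers = layers,
                       input_size = as.integer(input_size),
                       frozen = TRUE, pretrained = pretrained,
                       seed = as.integer(seed)),
                  class = "chromo_backbone")
  bb$feature_shape <- dim(backbone_forward(bb, array(0, c(input_size, input_size, 3)))$y)
  bb
}

#' @export
print.chromo_backbone <- function(x, ...) {
  cat(sprintf("<chromo_backbone> family %s, %d layers, feature %s, %s\n",
              x$family, length(x$layers),
              paste(x$feature_shape, collapse = "x"),
              if (x$pretrained) "pretrained weights" else
                sprintf("frozen seeded weights (seed %d)", x$seed)))
  invisible(x)
}

# Full forward pass; optionally records every layer's activation and cache
# (needed for Grad-CAM backprop).
backbone_forward <- function(backbone, x, record = FALSE) {
  acts <- list()
  caches <- list()
  for (op in backbone$layers) {
    out <- op_forward(op, x)
    x <- out$y
    if (record) {
      acts[[op$id]] <- x
      caches[[op$id]] <- out$cache
    }
  }
  list(y = x, activations = acts, caches = caches)
}

#' Extract the frozen convolutional features for one preprocessed image
#'
#' Deterministic for fixed backbone weights: the backbone is never updated
#' by head training, so features computed before and after training are
#' bitwise identical.
#'
#' @param backbone a [build_backbone()] object.
#' @param preprocessed_image output of [preprocess_pipeline()] (a
#'   `input_size` x `input_size` x 3 array).
#' @return the final convolutional activation, an h x w x channels array of
#'   shape `backbone$feature_shape`.
#' @export
extract_features <- function(backbone, preprocessed_image) {
  stopifnot(inherits(backbone, "chromo_backbone"))
  x <- preprocessed_image
  if (is.list(x)) stop("extract_features expects a preprocessed pixel array; ",
                       "run preprocess_pipeline() first")
  d <- dim(x)
  if (length(d) != 3L || d[1] != backbone$input_size ||
      d[2] != backbone$input_size || d[3] != 3L) {
    stop(sprintf("input must be %dx%dx3, got %s", backbone$input_size,
                 backbone$input_size, paste(d, collapse = "x")))
  }
  backbone_forward(backbone, x)$y
}

# Pooled feature vector for a raw labeled image (preprocess + extract + GAP).
pooled_features <- function(backbone, image, preprocess = preprocess_config(),
                            mask = NULL) {
  x <- preprocess_pipeline(image, mask = mask, config = preprocess)
  global_average_pool(extract_features(backbone, x))
}

# Feature matrix (n x d) for a list of labeled images. This is the shared
# workhorse of the evaluation protocol: with a frozen backbone the features
# of an image never change, so they are computed once per dataset.
feature_matrix <- function(backbone, images, preprocess = preprocess_config(),
                           progress = FALSE) {
  n <- length(images)
  d <- backbone$feature_shape[3]
  X <- matrix(0, n, d)
  for (i in seq_len(n)) {
    X[i, ] <- pooled_features(backbone, images[[i]], preprocess)
    if (progress && i %% 50L == 0L) message("  features ", i, "/", n)
  }
  X
}
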