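# Image preprocessing chain: white-out of bystander objects, resize to the
# model input size, linear contrast/brightness, gamma correction, and
# per-channel shade standardization.

#' Preprocessing configuration
#'
#' Holds every constant of the preprocessing chain. Defaults follow the
#' standard recipe for Giemsa chromosome crops: contrast `alpha = 3.0`,
#' brightness `beta = 80.0`, `gamma = 3.0`, then each RGB channel is
#' standardized to mean 64 and standard deviation 16 to remove per-image
#' staining-shade differences. The stage order is recorded in the config and
#' can be permuted for experiments; the default applies white-out before
#' resizing so interpolation cannot bleed removed objects back in.
#'
#' @param alpha contrast multiplier (> 0, dimensionless).
#' @param beta brightness offset, 8-bit intensity units.
#' @param gamma gamma exponent (> 0, dimensionless).
#' @param target_mean,target_sd per-channel statistics after
#'   standardization, 8-bit intensity units.
#' @param output_size model input side, pixels (square).
#' @param white_value RGB triple written into masked-out pixels.
#' @param resize_method interpolation used by the resize stage.
#' @param stage_order character vector permuting the five stages.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(alpha = 3.0, beta = 80.0, gamma = 3.0,
                              target_mean = 64, target_sd = 16,
                              output_size = 224,
                              white_value = c(255, 255, 255),
                              resize_method = c("bilinear", "nearest", "area"),
                              stage_order = c("whiteout", "resize",
                                              "contrast_brightness",
                                              "gamma_correct", "standardize")) {
  resize_method <- match.arg(resize_method)
  stopifnot(alpha > 0, gamma > 0, target_sd > 0, output_size >= 8)
  if (!setequal(stage_order, c("whiteout", "resize", "contrast_brightness",
                               "gamma_correct", "standardize"))) {
    stop("stage_order must be a permutation of the five pipeline stages")
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 target_mean = target_mean, target_sd = target_sd,
                 output_size = as.integer(output_size),
                 white_value = white_value, resize_method = resize_method,
                 stage_order = stage_order),
            class = "preprocess_config")
}

#' Replace masked pixels with white
#'
#' Bystander objects (other chromosomes, debris) marked in `mask` are
#' overwritten with white `(255, 255, 255)`, the background convention of a
#' bright-field crop; unmasked pixels pass through unchanged.
#'
#' @param image labeled image or H x W x 3 array.
#' @param mask H x W logical matrix, `TRUE` where pixels are to be removed.
#' @param white_value RGB triple to write.
#' @return numeric H x W x 3 array.
#' @export
whiteout <- function(image, mask, white_value = c(255, 255, 255)) {
  x <- as_pixels(image)
  if (is.null(mask)) return(x)
  mask <- as.matrix(mask)
  if (!all(dim(mask) == dim(x)[1:2])) {
    stop(sprintf("mask is %dx%d but image is %dx%d",
                 nrow(mask), ncol(mask), dim(x)[1], dim(x)[2]))
  }
  m <- which(mask)
  if (length(m)) {
    npix <- prod(dim(x)[1:2])
    for (ch in 1:3) x[m + (ch - 1L) * npix] <- white_value[ch]
  }
  x
}

# Separable resampling weights mapping n_in source pixels onto n_out output
# pixels. Rows sum to 1. "area" integrates the source over each output
# pixel's footprint (exact box average); "bilinear" samples at output pixel
# centres with the half-pixel alignment convention; "nearest" picks the
# covering source pixel (identity when n_in == n_out).
resample_weights <- function(n_in, n_out, method) {
  W <- matrix(0, n_out, n_in)
  s <- n_in / n_out
  if (method == "area") {
    for (i in seq_len(n_out)) {
      lo <- (i - 1) * s
      hi <- i * s
      j0 <- floor(lo) + 1L
      j1 <- min(ceiling(hi), n_in)
      for (j in j0:j1) {
        ov <- min(hi, j) - max(lo, j - 1)
        if (ov > 0) W[i, j] <- ov / s
      }
    }
  } else if (method == "bilinear") {
    src <- (seq_len(n_out) - 0.5) * s + 0.5  # source coordinate of centre
    for (i in seq_len(n_out)) {
      j <- clip(src[i], 1, n_in)
      j0 <- floor(j)
      f <- j - j0
      j1 <- min(j0 + 1L, n_in)
      W[i, j0] <- W[i, j0] + (1 - f)
      W[i, j1] <- W[i, j1] + f
    }
  } else {  # nearest
    j <- clip(ceiling((seq_len(n_out) - 0.5) * s), 1, n_in)
    W[cbind(seq_len(n_out), j)] <- 1
  }
  W
}

#' Resize an image to a square target size
#'
#' Separable resampling with a choice of bilinear interpolation (default),
#' nearest neighbour, or exact area averaging (a box filter, appropriate for
#' strong downscaling). Values are clipped to `[0, 255]`.
#'
#' @param image labeled image, H x W x 3 array, or a plain matrix (one
#'   channel, returned as a matrix).
#' @param output_size target side, pixels.
#' @param method `"bilinear"`, `"nearest"` or `"area"`.
#' @return resized array (or matrix) of side `output_size`.
#' @export
resize_image <- function(image, output_size,
                         method = c("bilinear", "nearest", "area")) {
  method <- match.arg(method)
  single <- is.matrix(image)
  x <- if (single) array(image, c(dim(image), 1L)) else as_pixels(image)
  d <- dim(x)
  if (d[1] < 1 || d[2] < 1) stop("cannot resize an empty image")
  if (output_size < 1) stop("output_size must be positive")
  Wr <- resample_weights(d[1], output_size, method)
  Wc <- resample_weights(d[2], output_size, method)
  out <- array(0, c(output_size, output_size, d[3]))
  for (ch in seq_len(d[3])) {
    out[, , ch] <- Wr %*% x[, , ch] %*% t(Wc)
  }
  out <- clip(out, 0, 255)
  if (single) out[, , 1] else out
}

#' Linear contrast and brightness adjustment
#'
#' `dst = alpha * src + beta`, applied per channel and clipped to
#' `[0, 255]`.
#'
#' @param image labeled image or pixel array.
#' @param alpha contrast multiplier (> 0).
#' @param beta brightness offset.
#' @return adjusted array.
#' @export
contrast_brightness <- function(image, alpha = 3.0, beta = 80.0) {
  stopifnot(alpha > 0)
  clip(alpha * as_pixels(image) + beta, 0, 255)
}

#' Gamma correction
#'
#' `y = (x / 255)^gamma * 255` per channel. The endpoints 0 and 255 are
#' fixed points for every exponent, and the map is monotone for `gamma > 0`.
#'
#' @param image labeled image or pixel array.
#' @param gamma exponent (> 0).
#' @return corrected array (real-valued; no quantization).
#' @export
gamma_correct <- function(image, gamma = 3.0) {
  stopifnot(gamma > 0)
  x <- as_pixels(image)
  (x / 255)^gamma * 255
}

#' Standardize each RGB channel to a fixed mean and standard deviation
#'
#' Affine per-channel rescaling so the sample mean and standard deviation of
#' every channel equal `target_mean` and `target_sd`. This removes the
#' per-image staining-shade differences. Output is real-valued and is
#' deliberately not clipped: clipping would destroy the fixed statistics
#' this stage exists to guarantee.
#'
#' @param image labeled image or pixel array.
#' @param target_mean,target_sd target sample statistics.
#' @return standardized array (real-valued, may exceed `[0, 255]`).
#' @export
standardize_channels <- function(image, target_mean = 64, target_sd = 16) {
  stopifnot(target_sd > 0)
  x <- as_pixels(image)
  for (ch in 1:3) {
    v <- x[, , ch]
    s <- stats::sd(v)
    if (!is.finite(s) || s < 1e-9) {
      stop(sprintf("channel %s is constant (zero standard deviation); %s",
                   c("R", "G", "B")[ch],
                   "shade standardization is undefined"), call. = FALSE)
    }
    x[, , ch] <- (v - mean(v)) / s * target_sd + target_mean
  }
  x
}

#' Run the full preprocessing chain
#'
#' Applies, in the configured order (default: white-out, resize, contrast/
#' brightness, gamma, standardization), every stage of the preprocessing
#' chain and returns the model-ready tensor.
#'
#' @param image labeled image or H x W x 3 array of 8-bit intensities.
#' @param mask optional H x W logical matrix of pixels to white out (at the
#'   input resolution when white-out precedes resizing).
#' @param config a [preprocess_config()].
#' @return numeric `output_size` x `output_size` x 3 array, each channel
#'   with mean `target_mean` and standard deviation `target_sd`.
#' @export
#' @examples
#' img <- generate_chromosome("A", synth_config(), seed = 3)
#' x <- preprocess_pipeline(img)
#' round(c(mean(x[, , 1]), sd(x[, , 1])), 2)
preprocess_pipeline <- function(image, mask = NULL,
                                config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  x <- as_pixels(image)
  for (stage in config$stage_order) {
    x <- switch(stage,
      whiteout = whiteout(x, mask, config$white_value),
      resize = resize_image(x, config$output_size, config$resize_method),
      contrast_brightness = contrast_brightness(x, config$alpha, config$beta),
      gamma_correct = gamma_correct(x, config$gamma),
      standardize = standardize_channels(x, config$target_mean, config$target_sd)
    )
  }
  x
}
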