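# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded package operations never
#' disturb the caller's random stream. A `NULL` seed evaluates the expression
#' under the current stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible sub-seed from a base seed and index coordinates
#'
#' Polynomial hash over the base seed and the integer coordinates (for
#' example selection index and repeat index), reduced modulo 2^31 - 1.
#' Documented so that any trial of the repeated-trial protocol can be rerun
#' in isolation.
#'
#' @param base integer base seed.
#' @param ... integer coordinates identifying the sub-stream.
#' @return a single integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, 2, 3)
derive_seed <- function(base, ...) {
  parts <- c(as.numeric(base), as.numeric(c(...)))
  if (anyNA(parts)) stop("derive_seed: seed coordinates must be non-missing")
  h <- 0
  for (p in parts) {
    h <- (h * 7919 + (p %% 1000003) + 17) %% 2147483647
  }
  as.integer(h)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
}

TYPE_LEVELS <- c("A", "B", "C")

as_label_factor <- function(labels) {
  labels <- as.character(labels)
  bad <- !labels %in% TYPE_LEVELS
  if (any(bad)) {
    stop(sprintf("invalid label(s): %s (must be one of %s)",
                 paste(unique(labels[bad]), collapse = ", "),
                 paste(TYPE_LEVELS, collapse = ", ")))
  }
  factor(labels, levels = TYPE_LEVELS)
}

# Extract the pixel array from a labeled image or pass a bare array through.
as_pixels <- function(image) {
  if (is.list(image) && !is.null(image$pixels)) image <- image$pixels
  if (is.matrix(image)) image <- array(rep(image, 3L), c(dim(image), 3L))
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("expected an H x W x 3 pixel array (or a labeled image containing one)")
  }
  storage.mode(image) <- "double"
  image
}

labels_of <- function(images) {
  vapply(images, function(im) im$label, character(1))
}

cells_of <- function(images) {
  vapply(images, function(im) im$cell_id, character(1))
}
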