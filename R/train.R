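# Trainable 3-way classification head over frozen pooled features:
# multinomial logistic regression fitted by seeded mini-batch stochastic
# gradient descent, with per-epoch validation and selection of the
# best-validating epoch checkpoint.

#' Head training hyperparameters
#'
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param learning_rate fixed SGD step size (on standardized features).
#' @param init_sd standard deviation of the seeded head initialization.
#' @return a plain list.
#' @export
head_hyperparams <- function(epochs = 30L, batch_size = 32L,
                             learning_rate = 0.1, init_sd = 0.01) {
  list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       learning_rate = learning_rate, init_sd = init_sd)
}

softmax_rows <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

# Fit the softmax head on a precomputed feature matrix. Features are
# standardized with training-set statistics (stored in the head); the model
# checkpoint kept is the epoch with the highest validation concordance
# (earliest epoch on ties).
fit_head <- function(X, y, Xval, yval, hyper, seed) {
  y <- as_label_factor(y)
  yval <- as_label_factor(yval)
  d <- ncol(X)
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[!is.finite(scale) | scale < 1e-9] <- 1
  Z <- sweep(sweep(X, 2L, center), 2L, scale, `/`)
  Zval <- sweep(sweep(Xval, 2L, center), 2L, scale, `/`)
  Yk <- as.integer(y)
  n <- nrow(Z)
  Yhot <- matrix(0, n, 3L)
  Yhot[cbind(seq_len(n), Yk)] <- 1
  with_seed(seed, {
    W <- matrix(stats::rnorm(3L * d, 0, hyper$init_sd), 3L, d)
    b <- stats::rnorm(3L, 0, hyper$init_sd)
    tlog <- data.frame(epoch = integer(), loss = numeric(),
                       val_concordance = numeric())
    best <- list(W = W, b = b, val = -Inf, epoch = 0L)
    for (ep in seq_len(hyper$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = hyper$batch_size)) {
        idx <- ord[start:min(start + hyper$batch_size - 1L, n)]
        Zb <- Z[idx, , drop = FALSE]
        P <- softmax_rows(Zb %*% t(W) +
                            matrix(b, length(idx), 3L, byrow = TRUE))
        G <- P - Yhot[idx, , drop = FALSE]
        W <- W - hyper$learning_rate * (t(G) %*% Zb) / length(idx)
        b <- b - hyper$learning_rate * colMeans(G)
      }
      P <- softmax_rows(Z %*% t(W) + matrix(b, n, 3L, byrow = TRUE))
      loss <- -mean(log(pmax(P[cbind(seq_len(n), Yk)], 1e-12)))
      pv <- TYPE_LEVELS[max.col(Zval %*% t(W) +
                                  matrix(b, nrow(Zval), 3L, byrow = TRUE),
                                ties.method = "first")]
      val <- concordance_rate(as.character(yval), pv)
      tlog <- rbind(tlog, data.frame(epoch = ep, loss = loss,
                                     val_concordance = val))
      if (val > best$val) best <- list(W = W, b = b, val = val, epoch = ep)
    }
    list(W = best$W, b = best$b, center = center, scale = scale,
         best_epoch = best$epoch, training_log = tlog)
  })
}

images_or_features <- function(x) {
  if (is.list(x) && !is.null(x$X) && !is.null(x$labels)) return(x)
  NULL
}

#' Train the classification head on a frozen backbone
#'
#' Extracts pooled features for the training and validation images with the
#' frozen backbone, then fits a 3-way softmax head by seeded mini-batch SGD.
#' The returned model is the per-epoch checkpoint with the highest
#' validation concordance. Backbone weights are untouched (the transfer
#' contract): features extracted before and after training are identical.
#'
#' Both sets may alternatively be precomputed feature sets
#' (`list(X = <n x d matrix>, labels = <character>)`), the fast path used by
#' the repeated-trial protocol where the same frozen features are reused
#' across many trials.
#'
#' @param backbone a [build_backbone()] object.
#' @param train_set,validation_set disjoint lists of labeled images (or
#'   feature sets). All three labels must be present in `train_set`;
#'   `validation_set` must be non-empty.
#' @param hyper a [head_hyperparams()] list.
#' @param preprocess the [preprocess_config()] the model will expect; it is
#'   stored in the model and re-applied automatically at prediction time.
#' @param seed seed for head initialization and batch shuffling.
#' @return object of class `chromo_model`: `backbone`, `head` (weights,
#'   bias, feature standardization), `label_order`, `preprocess`,
#'   `training_log`, `best_epoch`.
#' @export
train_head <- function(backbone, train_set, validation_set,
                       hyper = head_hyperparams(),
                       preprocess = preprocess_config(), seed = 0L) {
  stopifnot(inherits(backbone, "chromo_backbone"))
  ftr <- images_or_features(train_set)
  fva <- images_or_features(validation_set)
  if (is.null(ftr)) {
    if (length(train_set) == 0L) stop("train_set is empty")
    tr_labels <- labels_of(train_set)
  } else tr_labels <- ftr$labels
  if (is.null(fva)) {
    if (length(validation_set) == 0L) {
      stop("validation_set must be non-empty (used for model selection)")
    }
    va_labels <- labels_of(validation_set)
  } else {
    if (length(fva$labels) == 0L) {
      stop("validation_set must be non-empty (used for model selection)")
    }
    va_labels <- fva$labels
  }
  missing_lab <- setdiff(TYPE_LEVELS, unique(tr_labels))
  if (length(missing_lab)) {
    stop("train_set lacks label(s): ", paste(missing_lab, collapse = ", "))
  }
  if (is.null(ftr) && is.null(fva)) {
    tr_uid <- unlist(lapply(train_set, `[[`, "uid"))
    va_uid <- unlist(lapply(validation_set, `[[`, "uid"))
    if (length(intersect(tr_uid, va_uid))) {
      stop("train_set and validation_set share images")
    }
  }
  X <- if (is.null(ftr)) feature_matrix(backbone, train_set, preprocess) else ftr$X
  Xv <- if (is.null(fva)) feature_matrix(backbone, validation_set, preprocess) else fva$X
  fit <- fit_head(X, tr_labels, Xv, va_labels, hyper, seed)
  structure(list(backbone = backbone,
                 head = fit[c("W", "b", "center", "scale")],
                 label_order = TYPE_LEVELS,
                 preprocess = preprocess,
                 training_log = fit$training_log,
                 best_epoch = fit$best_epoch,
                 hyper = hyper, seed = as.integer(seed)),
            class = "chromo_model")
}

#' @export
print.chromo_model <- function(x, ...) {
  cat(sprintf(paste0("<chromo_model> %s backbone, 3-way head ",
                     "(best epoch %d, validation concordance %.1f%%)\n"),
              x$backbone$family, x$best_epoch,
              max(x$training_log$val_concordance)))
  invisible(x)
}

# Class scores for a pooled feature vector (pre-softmax).
head_scores <- function(model, f) {
  z <- (f - model$head$center) / model$head$scale
  drop(model$head$W %*% z + model$head$b)
}

#' Predict the morphology type of a raw image
#'
#' The raw image is preprocessed with the model's stored configuration,
#' passed through the frozen backbone, pooled, and scored by the head. The
#' predicted label is the argmax of the three class scores; exact ties break
#' to the lowest label index (A before B before C).
#'
#' @param object a trained [train_head()] model.
#' @param image labeled image or H x W x 3 array of 8-bit intensities.
#' @param mask optional white-out mask (input resolution).
#' @param ... unused.
#' @return list with `label` and `scores` (named pre-softmax 3-vector).
#' @export
predict.chromo_model <- function(object, image, mask = NULL, ...) {
  f <- pooled_features(object$backbone, image, object$preprocess, mask)
  s <- head_scores(object, f)
  names(s) <- object$label_order
  k <- which(s == max(s))[1L]  # tie-break: lowest label index
  list(label = object$label_order[k], scores = s)
}
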