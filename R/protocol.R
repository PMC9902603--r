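# Dataset-splitting and repeated-trial evaluation protocol.
#
# The dataset is divided into a fixed test set, and a pool from which
# validation and training images are drawn; validation/training selection is
# repeated n_selections times and each selection is trained n_repeats times,
# so a reported score is the average over n_selections x n_repeats trials.

#' Splitting and repeated-trial specification
#'
#' Defaults mirror the full-scale protocol: a 654-image test set selected at
#' cell level, 400 validation images, a balanced training subset of 231
#' images per label, and 3 selections x 10 training cycles = 30 trials.
#'
#' @param test_size images in the test set. With `test_unit = "cell"` whole
#'   cells are taken in random order until the image count first reaches
#'   `test_size` (the result can exceed the request by at most one cell,
#'   since a cell is never split across test and pool); with
#'   `test_unit = "image"` the count is exact.
#' @param test_unit `"cell"` (no cell contributes to both sides) or
#'   `"image"`.
#' @param validation_size images selected (image-level) for validation.
#' @param training_size images selected for training data, or `NULL` for
#'   the whole pool remainder (the full-scale protocol uses 1,275 of the
#'   1,311 images remaining after validation selection).
#' @param n_per_label_train balanced training-subset size per label.
#' @param n_selections independent validation/training selections.
#' @param n_repeats training cycles per selection.
#' @param seed default base seed.
#' @return object of class `split_spec`.
#' @export
split_spec <- function(test_size = 654L, test_unit = c("cell", "image"),
                       validation_size = 400L, training_size = NULL,
                       n_per_label_train = 231L,
                       n_selections = 3L, n_repeats = 10L, seed = NULL) {
  test_unit <- match.arg(test_unit)
  stopifnot(is_count(test_size), is_count(validation_size),
            is.null(training_size) || is_count(training_size),
            is_count(n_per_label_train),
            is_count(n_selections), n_selections >= 1,
            is_count(n_repeats), n_repeats >= 1)
  structure(list(test_size = as.integer(test_size), test_unit = test_unit,
                 validation_size = as.integer(validation_size),
                 training_size = if (!is.null(training_size))
                   as.integer(training_size),
                 n_per_label_train = as.integer(n_per_label_train),
                 n_selections = as.integer(n_selections),
                 n_repeats = as.integer(n_repeats), seed = seed),
            class = "split_spec")
}

#' Split a dataset into test set and pool
#'
#' @param dataset list of labeled images.
#' @param spec a [split_spec()].
#' @param seed selection seed (defaults to `spec$seed`).
#' @return list with `test` and `pool` (disjoint, exhaustive).
#' @export
split_dataset <- function(dataset, spec, seed = NULL) {
  stopifnot(inherits(spec, "split_spec"))
  n <- length(dataset)
  if (spec$test_size > n) {
    stop(sprintf("test_size %d exceeds dataset size %d", spec$test_size, n))
  }
  seed <- seed %||% spec$seed
  idx <- with_seed(seed, {
    if (spec$test_unit == "image") {
      sample.int(n, spec$test_size)
    } else {
      cells <- cells_of(dataset)
      if (any(!nzchar(cells))) stop("cell-level split requires cell_ids")
      ord <- sample(unique(cells))
      sizes <- cumsum(vapply(ord, function(cl) sum(cells == cl), numeric(1)))
      k <- if (spec$test_size == 0L) 0L else which(sizes >= spec$test_size)[1L]
      if (is.na(k)) k <- length(ord)
      which(cells %in% ord[seq_len(k)])
    }
  })
  list(test = dataset[idx],
       pool = if (length(idx)) dataset[-idx] else dataset)
}

#' Add extra images to the pool
#'
#' Mirrors rebalancing of a skewed pool (e.g. adding extra type C images,
#' the rarest class in wild-type cells, before training). Added images are
#' flagged with `augmented = TRUE` so provenance is preserved.
#'
#' @param pool list of labeled images.
#' @param extra_images list of labeled images to append.
#' @return the enlarged pool.
#' @export
augment_pool <- function(pool, extra_images) {
  if (length(extra_images) == 0L) return(pool)
  as_label_factor(labels_of(extra_images))  # validates labels
  extra_images <- lapply(extra_images, function(im) {
    im$augmented <- TRUE
    im
  })
  c(pool, extra_images)
}

#' Select validation and training sets from the pool
#'
#' Image-level random selection of `validation_size` images for validation.
#' By default the whole remainder becomes training data; when
#' `training_size` is given, that many images are randomly selected from
#' the remainder instead and the rest of the pool goes unused in the trial
#' (the full-scale protocol draws 400 validation and 1,275 training images
#' from a pool of 1,711, leaving 36 aside).
#'
#' @param pool list of labeled images.
#' @param validation_size images for validation.
#' @param training_size optional number of training images; `NULL` takes
#'   the whole remainder.
#' @param seed selection seed.
#' @return list with `validation` and `training` (always disjoint).
#' @export
select_validation_and_training <- function(pool, validation_size,
                                           training_size = NULL,
                                           seed = NULL) {
  n <- length(pool)
  if (validation_size >= n) {
    stop(sprintf("validation_size %d must be below pool size %d",
                 validation_size, n))
  }
  with_seed(seed, {
    idx <- sample.int(n, validation_size)
    rest <- if (validation_size) setdiff(seq_len(n), idx) else seq_len(n)
    if (!is.null(training_size)) {
      if (training_size > length(rest)) {
        stop(sprintf("training_size %d exceeds remaining pool %d",
                     training_size, length(rest)))
      }
      rest <- sample(rest, training_size)
    }
    list(validation = pool[idx], training = pool[rest])
  })
}

#' Draw a balanced training subset
#'
#' @param training list of labeled images.
#' @param n_per_label images per label.
#' @param seed selection seed.
#' @return list of `3 * n_per_label` images, exactly `n_per_label` per type.
#' @export
balanced_subset <- function(training, n_per_label, seed = NULL) {
  labs <- labels_of(training)
  with_seed(seed, {
    idx <- unlist(lapply(TYPE_LEVELS, function(lv) {
      have <- which(labs == lv)
      if (length(have) < n_per_label) {
        stop(sprintf("only %d type %s images available, need %d",
                     length(have), lv, n_per_label), call. = FALSE)
      }
      sample(have, n_per_label)
    }))
    training[idx]
  })
}

#' Concordance rate between two label assignments
#'
#' Percentage of positions where the two assignments agree — used both for
#' annotator-vs-annotator and annotator-vs-model (EA vs PA) comparisons.
#'
#' @param ea_labels,pa_labels equal-length label vectors.
#' @return percent in `[0, 100]`.
#' @export
#' @examples
#' concordance_rate(c("A", "A", "B"), c("A", "B", "B"))
concordance_rate <- function(ea_labels, pa_labels) {
  if (length(ea_labels) != length(pa_labels)) {
    stop(sprintf("label vectors differ in length (%d vs %d)",
                 length(ea_labels), length(pa_labels)))
  }
  if (length(ea_labels) == 0L) stop("label vectors are empty")
  100 * mean(as.character(ea_labels) == as.character(pa_labels))
}

#' Per-type distribution of a label vector
#'
#' @param labels non-empty vector of labels in `{A, B, C}`.
#' @return named numeric: percent per type, summing to 100.
#' @export
type_distribution <- function(labels) {
  if (length(labels) == 0L) stop("cannot compute a distribution of no labels")
  f <- as_label_factor(labels)
  stats::setNames(100 * as.numeric(table(f)) / length(f), TYPE_LEVELS)
}

#' Confusion matrix of example answers versus predicted answers
#'
#' @param ea_labels,pa_labels equal-length label vectors; EA indexes rows,
#'   PA columns.
#' @return 3 x 3 count matrix.
#' @export
confusion_matrix <- function(ea_labels, pa_labels) {
  if (length(ea_labels) != length(pa_labels)) {
    stop("label vectors differ in length")
  }
  m <- table(EA = as_label_factor(ea_labels), PA = as_label_factor(pa_labels))
  matrix(as.numeric(m), 3L, 3L, dimnames = list(EA = TYPE_LEVELS,
                                                PA = TYPE_LEVELS))
}

default_model_config <- function() {
  list(backbone = "small_scratch", backbone_seed = 42L,
       preprocess = preprocess_config(), hyper = head_hyperparams())
}

resolve_backbone <- function(model_config, input_size) {
  if (inherits(model_config$backbone, "chromo_backbone")) {
    model_config$backbone
  } else {
    build_backbone(model_config$backbone %||% "small_scratch",
                   seed = model_config$backbone_seed %||% 42L,
                   input_size = input_size)
  }
}

#' Run the repeated-trial evaluation protocol
#'
#' Fixes a test set, then runs `n_selections` independent validation/
#' training selections, each trained `n_repeats` times with derived
#' sub-seeds, and averages concordance, confusion matrix and type
#' distributions over all trials. Because the backbone is frozen, pooled
#' features for the whole dataset are computed once and shared by every
#' trial.
#'
#' @param dataset list of labeled images.
#' @param spec a [split_spec()].
#' @param model_config list: `backbone` (family name or a built backbone),
#'   `backbone_seed`, `preprocess`, `hyper`.
#' @param base_seed integer; trial seeds are derived from it with
#'   [derive_seed()].
#' @param features optional precomputed feature matrix for `dataset`
#'   (rows in dataset order), for reuse across protocol runs.
#' @return object of class `evaluation_report`: averaged `concordance`,
#'   `confusion` (EA rows, PA columns), `distribution` (`EA`, `PA`),
#'   `n_trials`, and `per_trial` (list of unaveraged trial results).
#' @export
run_protocol <- function(dataset, spec = split_spec(),
                         model_config = default_model_config(),
                         base_seed = 0L, features = NULL) {
  stopifnot(inherits(spec, "split_spec"))
  pp <- model_config$preprocess %||% preprocess_config()
  backbone <- resolve_backbone(model_config, pp$output_size)
  hyper <- model_config$hyper %||% head_hyperparams()

  if (is.null(features)) {
    features <- feature_matrix(backbone, dataset, pp)
  }
  labs <- labels_of(dataset)
  n <- length(dataset)

  sp <- split_dataset(dataset, spec, seed = derive_seed(base_seed, 0L, 0L))
  # recover indices of the split (by uid when present, else by identity)
  test_idx <- match_images(sp$test, dataset)
  pool_idx <- setdiff(seq_len(n), test_idx)

  ea <- labs[test_idx]
  dist_ea <- type_distribution(ea)
  Xtest <- features[test_idx, , drop = FALSE]

  trials <- list()
  for (sel in seq_len(spec$n_selections)) {
    sel_seed <- derive_seed(base_seed, sel, 0L)
    vt <- with_seed(sel_seed, {
      vi <- sample(pool_idx, spec$validation_size)
      ti <- setdiff(pool_idx, vi)
      if (!is.null(spec$training_size)) ti <- sample(ti, spec$training_size)
      list(val = vi, train = ti)
    })
    for (rep in seq_len(spec$n_repeats)) {
      trial_seed <- derive_seed(base_seed, sel, rep)
      bal <- with_seed(trial_seed, {
        unlist(lapply(TYPE_LEVELS, function(lv) {
          have <- vt$train[labs[vt$train] == lv]
          if (length(have) < spec$n_per_label_train) {
            stop(sprintf("only %d type %s images in training data, need %d",
                         length(have), lv, spec$n_per_label_train),
                 call. = FALSE)
          }
          sample(have, spec$n_per_label_train)
        }))
      })
      model <- train_head(backbone,
                          list(X = features[bal, , drop = FALSE],
                               labels = labs[bal]),
                          list(X = features[vt$val, , drop = FALSE],
                               labels = labs[vt$val]),
                          hyper = hyper, preprocess = pp, seed = trial_seed)
      Z <- sweep(sweep(Xtest, 2L, model$head$center),
                 2L, model$head$scale, `/`)
      S <- sweep(Z %*% t(model$head$W), 2L, model$head$b, `+`)
      pa <- TYPE_LEVELS[max.col(S, ties.method = "first")]
      trials[[length(trials) + 1L]] <- list(
        selection = sel, repeat_index = rep, seed = trial_seed,
        concordance = concordance_rate(ea, pa),
        confusion = confusion_matrix(ea, pa),
        distribution = list(EA = dist_ea, PA = type_distribution(pa)))
    }
  }
  structure(list(
    concordance = mean(vapply(trials, `[[`, numeric(1), "concordance")),
    confusion = Reduce(`+`, lapply(trials, `[[`, "confusion")) / length(trials),
    distribution = list(
      EA = dist_ea,
      PA = colMeans(do.call(rbind, lapply(trials,
                                          function(t) t$distribution$PA)))),
    n_trials = length(trials),
    n_test = length(test_idx),
    per_trial = trials,
    spec = spec, base_seed = base_seed),
    class = "evaluation_report")
}

# Match a list of images back to their positions in the full dataset.
match_images <- function(subset, dataset) {
  uid <- unlist(lapply(dataset, function(im) im$uid %||% NA_character_))
  su <- unlist(lapply(subset, function(im) im$uid %||% NA_character_))
  if (!anyNA(uid) && !anyNA(su) && !anyDuplicated(uid)) {
    return(match(su, uid))
  }
  vapply(subset, function(im) {
    for (i in seq_along(dataset)) if (identical(dataset[[i]], im)) return(i)
    stop("subset image not found in dataset")
  }, integer(1))
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d trials, test n = %d\n",
              x$n_trials, x$n_test))
  cat(sprintf("  concordance (EA vs PA): %.1f%%\n", x$concordance))
  cat("  type distribution (%):\n")
  m <- rbind(EA = x$distribution$EA, PA = x$distribution$PA)
  print(round(m, 1))
  cat("  mean confusion matrix (EA rows, PA columns):\n")
  print(round(x$confusion, 1))
  invisible(x)
}

#' Concordance as a function of training-set size
#'
#' Runs the full repeated-trial protocol once per requested balanced
#' training size and reports the averaged concordance for each, reproducing
#' the learning-curve analysis. Duplicate sizes are evaluated independently
#' (per-entry derived seeds).
#'
#' @param dataset list of labeled images.
#' @param spec a [split_spec()]; its `n_per_label_train` is overridden by
#'   each entry of `sizes`.
#' @param sizes integer vector of per-label training sizes.
#' @param model_config as in [run_protocol()].
#' @param seed base seed.
#' @return data.frame with `n_per_label`, `concordance`, and the per-size
#'   reports as attribute `"reports"`.
#' @export
training_size_sweep <- function(dataset, spec = split_spec(), sizes,
                                model_config = default_model_config(),
                                seed = 0L) {
  pp <- model_config$preprocess %||% preprocess_config()
  backbone <- resolve_backbone(model_config, pp$output_size)
  model_config$backbone <- backbone
  features <- feature_matrix(backbone, dataset, pp)
  reports <- vector("list", length(sizes))
  conc <- numeric(length(sizes))
  for (i in seq_along(sizes)) {
    sp <- spec
    sp$n_per_label_train <- as.integer(sizes[i])
    reports[[i]] <- run_protocol(dataset, sp, model_config,
                                 base_seed = derive_seed(seed, i),
                                 features = features)
    conc[i] <- reports[[i]]$concordance
  }
  out <- data.frame(n_per_label = as.integer(sizes), concordance = conc)
  attr(out, "reports") <- reports
  out
}
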