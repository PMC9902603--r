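# Genotype contrast: compare the type distributions of two samples (e.g.
# wild type vs. a cohesion-regulator knockout) from manual labels or model
# predictions. A cohesion defect appears as a shift of mass from type A
# toward types B and C.

#' Contrast chromosome-type distributions between two genotypes
#'
#' @param labels_ref,labels_mut non-empty label vectors for the reference
#'   (e.g. wild type) and mutant samples.
#' @param names character pair naming the genotypes.
#' @return object of class `genotype_contrast`: per-genotype
#'   `distributions` (percent), `deltas` (mutant minus reference,
#'   percentage points, summing to 0), the raw 2 x 3 `counts` table, and a
#'   chi-squared independence test on that table (`test_statistic`,
#'   `p_value`) as supplementary output.
#' @export
#' @examples
#' contrast_genotypes(rep(c("A", "B", "C"), c(64, 31, 5)),
#'                    rep(c("A", "B", "C"), c(26, 52, 22)),
#'                    names = c("WT", "CTF18-KO"))
contrast_genotypes <- function(labels_ref, labels_mut,
                               names = c("reference", "mutant")) {
  if (length(labels_ref) == 0L || length(labels_mut) == 0L) {
    stop("both label vectors must be non-empty")
  }
  dist_ref <- type_distribution(labels_ref)
  dist_mut <- type_distribution(labels_mut)
  counts <- rbind(as.numeric(table(as_label_factor(labels_ref))),
                  as.numeric(table(as_label_factor(labels_mut))))
  dimnames(counts) <- list(genotype = names, type = TYPE_LEVELS)
  # types absent from both samples carry no information and would make the
  # chi-squared statistic undefined
  informative <- colSums(counts) > 0
  test <- if (sum(informative) >= 2) {
    suppressWarnings(stats::chisq.test(counts[, informative, drop = FALSE]))
  } else {
    list(statistic = NA_real_, p.value = NA_real_)
  }
  structure(list(genotype_names = names,
                 distributions = rbind(stats::setNames(dist_ref, TYPE_LEVELS),
                                       dist_mut),
                 deltas = dist_mut - dist_ref,
                 counts = counts,
                 test_statistic = unname(test$statistic),
                 p_value = unname(test$p.value)),
            class = "genotype_contrast")
}

#' @export
print.genotype_contrast <- function(x, ...) {
  cat(sprintf("<genotype_contrast> %s vs %s\n",
              x$genotype_names[1], x$genotype_names[2]))
  m <- x$distributions
  rownames(m) <- x$genotype_names
  print(round(m, 1))
  cat("  delta (mutant - reference, percentage points):\n  ")
  cat(paste(sprintf("%s %+0.1f", TYPE_LEVELS, x$deltas), collapse = "  "), "\n")
  cat(sprintf("  chi-squared independence test: X2 = %.2f, p = %.3g\n",
              x$test_statistic, x$p_value))
  cat("  (the test is supplementary output, not part of the protocol)\n")
  invisible(x)
}

#' Classify every image listed in a manifest
#'
#' Reads each image (PNG) named in a manifest, predicts its type with a
#' trained model, and returns the predictions in manifest order.
#'
#' @param model a trained [train_head()] model.
#' @param manifest a manifest data frame (see [read_manifest()]), a path to
#'   a manifest CSV, or a list of labeled images (in-memory shortcut).
#' @return data.frame with columns `path` (when available), `label` (the
#'   manifest label, `NA` if absent), `pred`, `genotype`.
#' @export
classify_sample <- function(model, manifest) {
  stopifnot(inherits(model, "chromo_model"))
  if (is.character(manifest) && length(manifest) == 1L) {
    manifest <- read_manifest(manifest)
  }
  if (is.list(manifest) && !is.data.frame(manifest) &&
      (length(manifest) == 0L || inherits(manifest[[1]], "labeled_image"))) {
    preds <- vapply(manifest, function(im) predict(model, im)$label, "")
    return(data.frame(path = rep(NA_character_, length(manifest)),
                      label = unlist(lapply(manifest, `[[`, "label")) %||%
                        character(0),
                      pred = preds,
                      genotype = unlist(lapply(manifest, `[[`,
                                               "genotype")) %||%
                        character(0)))
  }
  stopifnot(is.data.frame(manifest))
  n <- nrow(manifest)
  preds <- character(n)
  for (i in seq_len(n)) {
    img <- read_image(manifest$path[i])
    preds[i] <- predict(model, img)$label
  }
  data.frame(path = manifest$path,
             label = if ("label" %in% names(manifest)) manifest$label
                     else rep(NA_character_, n),
             pred = preds,
             genotype = if ("genotype" %in% names(manifest))
               manifest$genotype else rep(NA_character_, n))
}
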