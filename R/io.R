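# Manifests, image files, run configuration and model checkpoints.
#
# Interchange formats are deliberately plain: PNG images, UTF-8 comma-
# delimited manifests with header `path,label,cell_id,genotype`, JSON
# reports, and flat key=value run-configuration files.

MANIFEST_COLS <- c("path", "label", "cell_id", "genotype")

#' Read and validate an image manifest
#'
#' A manifest is a UTF-8 CSV with header and at least a `path` column;
#' `label` (one of A, B, C), `cell_id` and `genotype` are optional (a
#' prediction-only manifest has no labels). Paths must be unique.
#' Validation errors cite the offending data row.
#'
#' @param path manifest file.
#' @param check_files also require every referenced image file to exist.
#' @return data.frame of class `chromo_manifest`.
#' @export
read_manifest <- function(path, check_files = FALSE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, colClasses = "character",
                        fileEncoding = "UTF-8")
  if (!"path" %in% names(df)) stop("manifest must have a 'path' column")
  for (i in seq_len(nrow(df))) {
    if (!nzchar(df$path[i])) stop(sprintf("row %d: empty path", i))
    if ("label" %in% names(df) && nzchar(df$label[i]) &&
        !df$label[i] %in% TYPE_LEVELS) {
      stop(sprintf("row %d: invalid label '%s' (must be A, B or C)",
                   i, df$label[i]))
    }
    if (check_files && !file.exists(df$path[i])) {
      stop(sprintf("row %d: image file not found: %s", i, df$path[i]))
    }
  }
  dup <- which(duplicated(df$path))
  if (length(dup)) {
    stop(sprintf("row %d: duplicate path '%s'", dup[1], df$path[dup[1]]))
  }
  class(df) <- c("chromo_manifest", "data.frame")
  df
}

#' Write a manifest in canonical form
#'
#' Canonical column order `path,label,cell_id,genotype` (columns absent
#' from the input are filled with empty strings), no quoting, UTF-8. A
#' written manifest re-read with [read_manifest()] and re-written is
#' byte-identical.
#'
#' @param manifest data.frame with at least a `path` column.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  df <- as.data.frame(manifest)
  for (col in MANIFEST_COLS) if (!col %in% names(df)) df[[col]] <- ""
  df <- df[MANIFEST_COLS]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an image file as an 8-bit pixel array
#'
#' PNG input; grayscale images are replicated to three channels, an alpha
#' channel is dropped.
#'
#' @param path PNG file.
#' @return H x W x 3 array of intensities in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  if (!grepl("\\.png$", path, ignore.case = TRUE)) {
    stop("only PNG images are supported; got: ", path)
  }
  x <- png::readPNG(path)
  if (is.matrix(x)) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  if (dim(x)[3] == 1L) x <- array(rep(x, 3L), c(dim(x)[1:2], 3L))
  round(x * 255)
}

#' Write an 8-bit pixel array (or labeled image) as PNG
#'
#' @param image labeled image or H x W x 3 array in `[0, 255]`. Real-valued
#'   arrays (e.g. standardized pipeline output) are clipped for display.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  x <- clip(as_pixels(image), 0, 255)
  png::writePNG(x / 255, path)
  invisible(path)
}

#' Write a synthetic dataset to disk
#'
#' Writes one PNG per image plus a `manifest.csv` with header
#' `path,label,cell_id,genotype`.
#'
#' @param images list of labeled images.
#' @param dir output directory (created if needed).
#' @param manifest manifest file name within `dir`.
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(images, dir, manifest = "manifest.csv") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(images)
  paths <- character(n)
  for (i in seq_len(n)) {
    im <- images[[i]]
    paths[i] <- file.path(dir, sprintf("%s_%s_%05d.png",
                                       im$genotype, im$label, i))
    write_image(im, paths[i])
  }
  mf <- data.frame(path = paths,
                   label = vapply(images, `[[`, "", "label"),
                   cell_id = vapply(images, `[[`, "", "cell_id"),
                   genotype = vapply(images, `[[`, "", "genotype"))
  write_manifest(mf, file.path(dir, manifest))
  invisible(file.path(dir, manifest))
}

#' Load a manifest's images into memory as labeled images
#'
#' @param manifest manifest data.frame or path.
#' @return list of labeled images (geometry absent for file-backed images).
#' @export
load_dataset <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  lapply(seq_len(nrow(manifest)), function(i) {
    structure(list(pixels = read_image(manifest$path[i]),
                   label = if ("label" %in% names(manifest) &&
                               nzchar(manifest$label[i]))
                     manifest$label[i] else NA_character_,
                   cell_id = if ("cell_id" %in% names(manifest))
                     manifest$cell_id[i] else sprintf("cell%05d", i),
                   genotype = if ("genotype" %in% names(manifest))
                     manifest$genotype[i] else "",
                   uid = manifest$path[i], geometry = NULL),
              class = "labeled_image")
  })
}

# ---- flat key=value run configuration --------------------------------------

flatten_config <- function(x, prefix = "") {
  out <- character(0)
  for (nm in names(x)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    v <- x[[nm]]
    if (is.list(v) && !is.null(names(v))) {
      out <- c(out, flatten_config(v, key))
    } else if (is.null(v)) {
      out <- c(out, paste0(key, "="))
    } else {
      out <- c(out, paste0(key, "=", paste(v, collapse = ",")))
    }
  }
  out
}

#' Write a resolved run configuration as a flat key=value file
#'
#' Nested names are joined with dots; vector values are comma-separated.
#' Every pipeline run writes its resolved configuration (including seeds)
#' next to its outputs so any result file can be regenerated.
#'
#' @param config named (possibly nested) list.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  writeLines(flatten_config(unclass_rec(config)), path)
  invisible(path)
}

unclass_rec <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    x[] <- lapply(x, unclass_rec)
  }
  x
}

#' Read a flat key=value configuration file
#'
#' @param path file written by [write_run_config()].
#' @return named list of character values (dotted keys preserved).
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  stats::setNames(lapply(kv, `[[`, 2L), vapply(kv, `[[`, "", 1L))
}

# ---- model checkpoints ------------------------------------------------------

CHECKPOINT_FORMAT <- "chromotype-checkpoint-1"

#' Save a trained model checkpoint
#'
#' The container holds the backbone family and weights, head weights, label
#' order, preprocessing configuration, training log and seed, under a
#' version tag.
#'
#' @param model a [train_head()] model.
#' @param path output file (RDS container).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "chromo_model"))
  saveRDS(list(format = CHECKPOINT_FORMAT, model = model), path)
  invisible(path)
}

#' Load a trained model checkpoint
#'
#' @param path file written by [save_model()].
#' @return the `chromo_model`.
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, CHECKPOINT_FORMAT)) {
    stop("not a chromotype checkpoint (or unsupported version): ", path)
  }
  x$model
}
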