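# Shared fixtures. Most unit tests run on 96-px images with proportionally
# scaled geometry: the generator, pipeline and polar-stem backbone are all
# size-agnostic, and the small scale keeps the suite fast. Fixtures are
# memoized so expensive objects are built once per run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

small_cfg <- function() chromotype:::scale_synth_config(96)

small_pp <- function() preprocess_config(output_size = 96)

# 20 images per type at 96 px, fixed seed
small_dataset <- function() {
  memo("small_dataset",
       generate_dataset(c(A = 20, B = 20, C = 20), small_cfg(), seed = 42))
}

small_backbone <- function() {
  memo("small_backbone",
       build_backbone("small_scratch", seed = 7, input_size = 96))
}

# model trained on 16/type, validated on 4/type of the small dataset
small_model <- function() {
  memo("small_model", {
    ds <- small_dataset()
    labs <- vapply(ds, `[[`, "", "label")
    tr <- unlist(lapply(c("A", "B", "C"),
                        function(l) which(labs == l)[1:16]))
    va <- setdiff(seq_along(ds), tr)
    train_head(small_backbone(), ds[tr], ds[va],
               hyper = head_hyperparams(epochs = 15),
               preprocess = small_pp(), seed = 3)
  })
}

# Count the dark connected components of an image (independent oracle:
# EBImage's labelling, not any package code). Chromatin is well below the
# threshold, background well above.
count_dark_components <- function(image, threshold = 150) {
  px <- if (is.list(image)) image$pixels else image
  gray <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
  max(EBImage::bwlabel(gray < threshold))
}

# Lightweight label/cell stand-ins for split arithmetic (no pixels needed).
stub_dataset <- function(counts, n_cells = 150, prefix = "stub") {
  labels <- rep(names(counts), times = counts)
  n <- length(labels)
  lapply(seq_len(n), function(i) {
    structure(list(label = labels[i],
                   cell_id = sprintf("%s_cell%03d", prefix,
                                     ((i - 1) %% n_cells) + 1),
                   genotype = prefix, uid = sprintf("%s_%05d", prefix, i)),
              class = "labeled_image")
  })
}
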