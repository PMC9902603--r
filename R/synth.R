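# Synthetic single-chromosome image generator.
#
# Emulates Giemsa-stained metaphase chromosomes cropped to a single object:
# two elongated chromatid bodies, dark on a light background, whose arm
# opening angle and centromere separation realize the three cohesion
# morphology types (A: tight, B: arms splayed but joined at the centromere,
# C: sister chromatids fully separated).

#' Configuration for the synthetic chromosome generator
#'
#' Geometry is sampled per image. Each chromatid is a bent rod: two arms of
#' combined tip-to-tip length `chromatid_length_range` meeting at the
#' centromere, tilted away from the chromosome axis by a half-opening angle
#' drawn from `arm_angle_by_type`. The two sister chromatids are mirror
#' images; for types A and B their bodies touch (centromere gap 0), for type
#' C they are displaced so the closest edges are `centromere_gap_by_type$C`
#' pixels apart. The angle ranges for A and B must be disjoint so every
#' label is geometrically realizable and recoverable from the draw.
#'
#' @param image_size side of the square output image, pixels.
#' @param chromatid_length_range tip-to-tip chromatid length range, pixels.
#' @param chromatid_width_range chromatid thickness range, pixels.
#' @param arm_angle_by_type named list of degree ranges for the half-opening
#'   angle of the arms; `A` near 0 (arms appressed), `B` clearly positive,
#'   `C` unconstrained by the label (bodies are disjoint anyway).
#' @param centromere_gap_by_type named list: scalar 0 for `A` and `B`, a
#'   strictly positive pixel range for `C` (edge-to-edge distance).
#' @param stain_mean_range,stain_sd_range per-image Giemsa shade variation,
#'   8-bit intensity units (mean chromatin darkness and within-body texture).
#' @param noise_sd additive Gaussian sensor noise, 8-bit intensity units.
#' @param fragment_probability chance of one small "photobombing" chromatin
#'   fragment near the image border.
#' @param rotation_range whole-chromosome rotation, degrees.
#' @param background background intensity (near-white bright field).
#' @param center_jitter maximal displacement of the chromosome centre from
#'   the image centre, pixels.
#' @param arm_ratio_range fraction of length allotted to the upper arm
#'   (centromere position; 0.5 = metacentric).
#' @param images_per_cell target number of images grouped under one
#'   synthetic cell id by [generate_dataset()].
#' @param seed default seed used when an operation is not given one.
#' @return an object of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config()
#' img <- generate_chromosome("B", cfg, seed = 1)
#' dim(img$pixels)
synth_config <- function(image_size = 224,
                         chromatid_length_range = c(80, 124),
                         chromatid_width_range = c(10, 16),
                         arm_angle_by_type = list(A = c(0, 6),
                                                  B = c(18, 40),
                                                  C = c(4, 20)),
                         centromere_gap_by_type = list(A = 0, B = 0,
                                                       C = c(12, 26)),
                         stain_mean_range = c(15, 50),
                         stain_sd_range = c(4, 12),
                         noise_sd = 5,
                         fragment_probability = 0.1,
                         rotation_range = c(0, 360),
                         background = 244,
                         center_jitter = 5,
                         arm_ratio_range = c(0.38, 0.62),
                         images_per_cell = 14,
                         seed = NULL) {
  cfg <- structure(list(
    image_size = as.integer(image_size),
    chromatid_length_range = as.numeric(chromatid_length_range),
    chromatid_width_range = as.numeric(chromatid_width_range),
    arm_angle_by_type = arm_angle_by_type,
    centromere_gap_by_type = centromere_gap_by_type,
    stain_mean_range = as.numeric(stain_mean_range),
    stain_sd_range = as.numeric(stain_sd_range),
    noise_sd = as.numeric(noise_sd),
    fragment_probability = as.numeric(fragment_probability),
    rotation_range = as.numeric(rotation_range),
    background = as.numeric(background),
    center_jitter = as.numeric(center_jitter),
    arm_ratio_range = as.numeric(arm_ratio_range),
    images_per_cell = as.integer(images_per_cell),
    seed = seed
  ), class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

range2 <- function(x) if (length(x) == 1L) c(x, x) else as.numeric(x[1:2])

validate_synth_config <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$image_size < 32) stop("image_size must be at least 32 pixels")
  aa <- cfg$arm_angle_by_type
  if (max(range2(aa$A)) >= min(range2(aa$B))) {
    stop("arm_angle_by_type ranges for A and B must be disjoint with A below B")
  }
  gp <- cfg$centromere_gap_by_type
  if (any(range2(gp$A) != 0) || any(range2(gp$B) != 0)) {
    stop("centromere_gap_by_type must be 0 for types A and B")
  }
  if (min(range2(gp$C)) <= 0) {
    stop("centromere_gap_by_type$C must be strictly positive")
  }
  # Worst-case extent check: the farthest arm tip over all types must stay
  # inside the image for every admissible draw (rotation can point it
  # anywhere, so the bound is radial).
  w <- max(cfg$chromatid_width_range)
  len <- max(cfg$chromatid_length_range) * max(cfg$arm_ratio_range)
  r_max <- 0
  for (ty in TYPE_LEVELS) {
    th <- max(range2(aa[[ty]])) * pi / 180
    dx <- if (ty == "C") (w + max(range2(gp$C))) / 2 else 0.35 * w
    r <- sqrt((dx + len * sin(th))^2 + (len * cos(th))^2)
    r_max <- max(r_max, r)
  }
  r_max <- r_max + w / 2 + cfg$center_jitter + 2
  if (r_max > cfg$image_size / 2 - 2) {
    stop(sprintf(paste0("geometry cannot fit: worst-case chromosome radius ",
                        "%.1f px exceeds image half-size %.1f px"),
                 r_max, cfg$image_size / 2 - 2), call. = FALSE)
  }
  invisible(cfg)
}

# Sample the geometric parameters for one chromosome of a given type.
sample_geometry <- function(label, cfg) {
  len <- stats::runif(1, cfg$chromatid_length_range[1], cfg$chromatid_length_range[2])
  w <- stats::runif(1, cfg$chromatid_width_range[1], cfg$chromatid_width_range[2])
  ar <- stats::runif(1, cfg$arm_ratio_range[1], cfg$arm_ratio_range[2])
  ang <- range2(cfg$arm_angle_by_type[[label]])
  theta <- stats::runif(1, ang[1], ang[2])
  gapr <- range2(cfg$centromere_gap_by_type[[label]])
  gap <- if (label == "C") stats::runif(1, gapr[1], gapr[2]) else 0
  rot <- stats::runif(1, cfg$rotation_range[1], cfg$rotation_range[2])
  jit <- stats::runif(2, -cfg$center_jitter, cfg$center_jitter)
  list(label = label, length = len, width = w, arm_ratio = ar,
       theta_deg = theta, gap = gap, rotation_deg = rot,
       center = (cfg$image_size + 1) / 2 + jit,
       stain_mean = stats::runif(1, cfg$stain_mean_range[1], cfg$stain_mean_range[2]),
       stain_sd = stats::runif(1, cfg$stain_sd_range[1], cfg$stain_sd_range[2]))
}

# Segment endpoints (4 segments: two arms per chromatid) for a geometry
# draw, in (x = column, y = row) image coordinates.
geometry_segments <- function(geom, cfg) {
  th <- geom$theta_deg * pi / 180
  dx <- if (geom$gap > 0) (geom$width + geom$gap) / 2 else 0.35 * geom$width
  lu <- geom$length * geom$arm_ratio
  ld <- geom$length * (1 - geom$arm_ratio)
  segs <- list()
  for (s in c(-1, 1)) {
    p0 <- c(s * dx, 0)
    up <- p0 + lu * c(s * sin(th), -cos(th))
    dn <- p0 + ld * c(s * sin(th), cos(th))
    segs[[length(segs) + 1L]] <- rbind(p0, up)
    segs[[length(segs) + 1L]] <- rbind(p0, dn)
  }
  phi <- geom$rotation_deg * pi / 180
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  lapply(segs, function(seg) {
    out <- seg %*% t(R)
    out[, 1] <- out[, 1] + geom$center[1]
    out[, 2] <- out[, 2] + geom$center[2]
    out
  })
}

# Minimal distance from every pixel centre to a segment, vectorized over the
# full image grid.
dist_to_segment <- function(px, py, seg) {
  a <- seg[1, ]; b <- seg[2, ]
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 < 1e-12) return(sqrt((px - a[1])^2 + (py - a[2])^2))
  t <- ((px - a[1]) * ab[1] + (py - a[2]) * ab[2]) / len2
  t <- clip(t, 0, 1)
  sqrt((px - (a[1] + t * ab[1]))^2 + (py - (a[2] + t * ab[2]))^2)
}

sample_fragment <- function(geom, segs, cfg) {
  n <- cfg$image_size
  for (try in 1:20) {
    ax <- stats::runif(1, 4, 9)
    bx <- stats::runif(1, 4, 9)
    side <- sample.int(4L, 1L)
    depth <- stats::runif(1, 12, 24)
    along <- stats::runif(1, 16, n - 16)
    ctr <- switch(side,
                  c(along, depth), c(along, n - depth),
                  c(depth, along), c(n - depth, along))
    clearance <- geom$width / 2 + max(ax, bx) + 4
    dmin <- min(vapply(segs, function(s) {
      dist_to_segment(ctr[1], ctr[2], s)
    }, numeric(1)))
    if (dmin > clearance &&
        all(ctr > max(ax, bx) + 2) && all(ctr < n - max(ax, bx) - 1)) {
      return(list(center = ctr, a = ax, b = bx,
                  angle = stats::runif(1, 0, pi)))
    }
  }
  NULL
}

fragment_coverage <- function(frag, px, py) {
  dx <- px - frag$center[1]
  dy <- py - frag$center[2]
  ca <- cos(frag$angle); sa <- sin(frag$angle)
  u <- dx * ca + dy * sa
  v <- -dx * sa + dy * ca
  q <- (u / frag$a)^2 + (v / frag$b)^2
  clip((1 - q) * min(frag$a, frag$b) / 2 + 0.5, 0, 1)
}

# Channel tint of Giemsa chromatin (purple: green channel darkest).
STAIN_TINT <- c(1.05, 0.88, 1.12)

#' Generate one synthetic labeled chromosome image
#'
#' Draws geometry for the requested morphology type, rasterizes the two
#' chromatid bodies with anti-aliasing (soft 1-px edge), applies per-image
#' stain shade, texture and sensor noise, and quantizes to 8 bits. Dark
#' chromatin on a light background, matching bright-field Giemsa convention.
#'
#' @param label `"A"`, `"B"` or `"C"`.
#' @param config a [synth_config()].
#' @param seed optional integer; when `NULL` the current RNG stream is used.
#' @param cell_id,genotype provenance tags stored on the image.
#' @return a labeled image: list with `pixels` (H x W x 3 integer array in
#'   `[0, 255]`), `label`, `cell_id`, `genotype` and `geometry` (the draw
#'   that produced it, including the rasterized segment endpoints and the
#'   per-chromatid bounding boxes).
#' @export
generate_chromosome <- function(label, config = synth_config(), seed = NULL,
                                cell_id = "synthetic_cell", genotype = "synthetic") {
  label <- match.arg(label, TYPE_LEVELS)
  validate_synth_config(config)
  if (!nzchar(cell_id)) stop("cell_id must be non-empty")
  with_seed(seed, {
    geom <- sample_geometry(label, config)
    segs <- geometry_segments(geom, config)
    n <- config$image_size
    # sampled-draw fit check (the config validator bounds the worst case,
    # but a hand-edited config can still produce an overflowing draw)
    pts <- do.call(rbind, segs)
    half_w <- geom$width / 2 + 1.5
    if (any(pts < half_w + 0.5) || any(pts > n - half_w + 0.5)) {
      stop("sampled geometry does not fit inside the image bounds",
           call. = FALSE)
    }
    px <- matrix(rep(seq_len(n), each = n), n, n)   # column index
    py <- matrix(rep(seq_len(n), times = n), n, n)  # row index
    d1 <- pmin(dist_to_segment(px, py, segs[[1]]),
               dist_to_segment(px, py, segs[[2]]))
    d2 <- pmin(dist_to_segment(px, py, segs[[3]]),
               dist_to_segment(px, py, segs[[4]]))
    cov <- pmax(clip(geom$width / 2 + 0.5 - d1, 0, 1),
                clip(geom$width / 2 + 0.5 - d2, 0, 1))
    frag <- NULL
    if (stats::runif(1) < config$fragment_probability) {
      frag <- sample_fragment(geom, segs, config)
      if (!is.null(frag)) cov <- pmax(cov, fragment_coverage(frag, px, py))
    }
    texture <- matrix(stats::rnorm(n * n, 0, geom$stain_sd), n, n)
    pix <- array(0, c(n, n, 3L))
    for (ch in 1:3) {
      stain <- clip(geom$stain_mean * STAIN_TINT[ch] + texture, 0, 255)
      plane <- config$background * (1 - cov) + stain * cov
      plane <- plane + stats::rnorm(n * n, 0, config$noise_sd)
      pix[, , ch] <- clip(round(plane), 0, 255)
    }
    storage.mode(pix) <- "integer"
    geom$segments <- segs
    geom$fragment <- frag
    geom$bboxes <- lapply(list(segs[1:2], segs[3:4]), function(ss) {
      p <- do.call(rbind, ss)
      c(xmin = min(p[, 1]) - half_w, xmax = max(p[, 1]) + half_w,
        ymin = min(p[, 2]) - half_w, ymax = max(p[, 2]) + half_w)
    })
    structure(list(pixels = pix, label = label, cell_id = cell_id,
                   genotype = genotype, geometry = geom),
              class = "labeled_image")
  })
}

#' @export
print.labeled_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<labeled_image> %dx%dx%d  type %s  cell %s  genotype %s\n",
              d[1], d[2], d[3], x$label, x$cell_id, x$genotype))
  invisible(x)
}

#' Rule-based morphology call from generator ground truth
#'
#' Applies the geometric definition of the three types to a stored geometry
#' draw: a positive centromere gap is type C; otherwise the arm half-opening
#' angle decides between A and B at the midpoint of the (disjoint)
#' configured ranges. For generator output this recovers the stored label
#' exactly, which is the label-geometry consistency invariant.
#'
#' @param geometry the `geometry` element of a generated image.
#' @param config the [synth_config()] used to generate it.
#' @return `"A"`, `"B"` or `"C"`.
#' @export
classify_geometry <- function(geometry, config) {
  if (geometry$gap > 0) return("C")
  boundary <- (max(range2(config$arm_angle_by_type$A)) +
               min(range2(config$arm_angle_by_type$B))) / 2
  if (geometry$theta_deg > boundary) "B" else "A"
}

#' Generate a labeled synthetic dataset
#'
#' Produces the requested number of images per type and groups them under
#' synthetic cell ids round-robin, targeting `config$images_per_cell`
#' images per cell (mirroring real spreads, where one metaphase cell yields
#' a handful of scorable chromosomes of mixed types).
#'
#' @param counts named vector or list, images per label, e.g.
#'   `c(A = 231, B = 231, C = 231)`; missing names count 0.
#' @param config a [synth_config()].
#' @param genotype genotype tag stamped on every image.
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of `(counts, config, genotype, seed)`.
#' @return list of labeled images, in label order A, B, C.
#' @export
#' @examples
#' ds <- generate_dataset(c(A = 2, B = 2, C = 2), synth_config(), seed = 7)
#' table(vapply(ds, `[[`, "", "label"))
generate_dataset <- function(counts, config = synth_config(),
                             genotype = "synthetic", seed = NULL) {
  counts <- unlist(counts)
  if (!all(names(counts) %in% TYPE_LEVELS)) {
    stop("counts must be named with labels A, B, C")
  }
  full <- stats::setNames(numeric(3), TYPE_LEVELS)
  full[names(counts)] <- counts
  if (any(full < 0) || any(full != floor(full))) {
    stop("counts must be non-negative integers")
  }
  labels <- rep(TYPE_LEVELS, times = full)
  n <- length(labels)
  if (n == 0L) return(list())
  ncells <- max(1L, ceiling(n / config$images_per_cell))
  cell_ids <- sprintf("%s_cell%03d", genotype, ((seq_len(n) - 1L) %% ncells) + 1L)
  seed <- seed %||% config$seed
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      im <- generate_chromosome(labels[i], config, seed = NULL,
                                cell_id = cell_ids[i], genotype = genotype)
      im$uid <- sprintf("%s_%05d", genotype, i)
      im
    })
  })
}

#' Generate paired datasets for two genotypes with given type distributions
#'
#' Samples per-image labels from the requested multinomial for each genotype
#' and renders them, e.g. a wild-type-like sample versus a cohesion-mutant
#' sample with types B and C enriched.
#'
#' @param wt_distribution,mutant_distribution length-3 probability vectors
#'   over types (A, B, C); each must sum to 1 within `1e-6`.
#' @param n_per_genotype images per genotype.
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @param genotype_names character pair naming the two samples.
#' @return named list of two image lists (`reference`, `mutant`).
#' @export
generate_genotype_pair <- function(wt_distribution, mutant_distribution,
                                   n_per_genotype, config = synth_config(),
                                   seed = NULL,
                                   genotype_names = c("WT", "mutant")) {
  check_dist <- function(p, what) {
    # 0.005 tolerance admits distributions quoted as rounded percentages
    if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 5e-3) {
      stop(sprintf("%s must be 3 non-negative proportions summing to 1", what))
    }
    p / sum(p)
  }
  wt_distribution <- check_dist(wt_distribution, "wt_distribution")
  mutant_distribution <- check_dist(mutant_distribution, "mutant_distribution")
  if (!is_count(n_per_genotype) || n_per_genotype < 1) {
    stop("n_per_genotype must be a positive integer")
  }
  with_seed(seed, {
    out <- list()
    dists <- list(wt_distribution, mutant_distribution)
    for (g in 1:2) {
      cnt <- stats::rmultinom(1, n_per_genotype, dists[[g]])[, 1]
      names(cnt) <- TYPE_LEVELS
      out[[c("reference", "mutant")[g]]] <-
        generate_dataset(cnt, config, genotype = genotype_names[g], seed = NULL)
    }
    out
  })
}
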