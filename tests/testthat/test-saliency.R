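# Grad-CAM: exact agreement with a hand-derived chain-rule oracle on a toy
# network, numerical gradient checks of the layer backward passes,
# normalization contracts, and localization on synthetic type C images.

# A toy model: one 1x1 linear conv (3 -> 2 channels) on a 2x2 input,
# global average pooling, and a known linear head with identity feature
# scaling. Every quantity is small enough to compute by hand.
toy_model <- function(Wc, head_W) {
  conv <- chromotype:::layer_conv("conv1", 1L, 1L, 3L, 2L,
                                  activation = "linear")
  conv$W <- Wc
  conv$b <- c(0, 0)
  bb <- structure(list(family = "small_scratch", layers = list(conv),
                       input_size = 2L, frozen = TRUE, pretrained = TRUE,
                       seed = 0L, feature_shape = c(2L, 2L, 2L)),
                  class = "chromo_backbone")
  structure(list(backbone = bb,
                 head = list(W = head_W, b = c(0, 0, 0),
                             center = c(0, 0), scale = c(1, 1)),
                 label_order = c("A", "B", "C"),
                 preprocess = preprocess_config(output_size = 8),
                 training_log = NULL, best_epoch = 1L),
            class = "chromo_model")
}

test_that("grad_cam equals the hand-derived chain rule on the toy network", {
  Wc <- array(0, c(1, 1, 3, 2))
  Wc[1, 1, , 1] <- c(1, 0, 0)    # channel 1 = red plane
  Wc[1, 1, , 2] <- c(0, 1, -1)   # channel 2 = green - blue
  head_W <- rbind(c(2, -1), c(0, 0), c(-1, 3))
  model <- toy_model(Wc, head_W)
  x <- array(0, c(2, 2, 3))
  x[, , 1] <- rbind(c(1, 2), c(3, 4))
  x[, , 2] <- rbind(c(5, -6), c(7, 8))
  x[, , 3] <- rbind(c(1, 1), c(2, 2))
  # forward by hand: A_1 = x_red, A_2 = x_green - x_blue
  A1 <- x[, , 1]
  A2 <- x[, , 2] - x[, , 3]
  # class A score = 2 * mean(A1) - 1 * mean(A2); alpha_k = W[1, k] / 4
  expected <- pmax(2 / 4 * A1 + (-1) / 4 * A2, 0)
  expected <- expected / max(expected)
  sal <- grad_cam(model, x, "A")
  expect_equal(sal$values, expected, tolerance = 1e-12)
  expect_equal(sal$alpha, c(2 / 4, -1 / 4), tolerance = 1e-12)
  # class C weights (-1, 3)
  expected_c <- pmax(-1 / 4 * A1 + 3 / 4 * A2, 0)
  expected_c <- expected_c / max(expected_c)
  expect_equal(grad_cam(model, x, "C")$values, expected_c, tolerance = 1e-12)
  # a class whose head row is all zero gives an identically zero map
  expect_true(all(grad_cam(model, x, "B")$values == 0))
})

test_that("layer backward passes agree with finite differences", {
  # scalar objective: weighted sum of the stack's output
  set.seed(4)
  check_grad <- function(layers, in_dim, tol = 1e-6) {
    x <- array(rnorm(prod(in_dim)), in_dim)
    fwd <- function(x) {
      caches <- list()
      for (i in seq_along(layers)) {
        out <- chromotype:::op_forward(layers[[i]], x)
        x <- out$y
        caches[[i]] <- out$cache
      }
      list(y = x, caches = caches)
    }
    f0 <- fwd(x)
    wts <- array(rnorm(length(f0$y)), dim(f0$y))
    dy <- wts
    for (i in rev(seq_along(layers))) {
      dy <- chromotype:::op_backward(layers[[i]], dy, f0$caches[[i]])
    }
    eps <- 1e-5
    idx <- sample(length(x), 12)
    for (ii in idx) {
      xp <- x; xp[ii] <- xp[ii] + eps
      xm <- x; xm[ii] <- xm[ii] - eps
      num <- (sum(wts * fwd(xp)$y) - sum(wts * fwd(xm)$y)) / (2 * eps)
      expect_equal(dy[ii], num, tolerance = tol)
    }
  }
  w <- chromotype:::with_seed
  w(1, check_grad(list(chromotype:::layer_conv("c", 3, 3, 2, 3,
                                               stride = 2, pad = 1)),
                  c(8, 8, 2)))
  w(2, check_grad(list(chromotype:::layer_conv("c", 3, 3, 2, 2, pad = 1,
                                               circular = TRUE),
                       chromotype:::layer_pool("p")),
                  c(6, 8, 2)))
  w(3, check_grad(list(chromotype:::layer_fire("f", 3, 2, 4)), c(6, 6, 3)))
  w(4, check_grad(list(chromotype:::layer_resblock("r", 3)), c(6, 6, 3)))
})

test_that("maps are normalized, non-negative, and sized to the input", {
  model <- small_model()
  for (lab in c("A", "B", "C")) {
    img <- generate_chromosome(lab, small_cfg(), seed = 60 + match(lab, LETTERS))
    sal <- grad_cam(model, img, lab)
    expect_true(all(sal$values >= 0 & sal$values <= 1))
    expect_true(max(sal$values) %in% c(0, 1))
    expect_equal(dim(sal$upsampled), c(96, 96))
    expect_true(all(sal$upsampled >= 0 & sal$upsampled <= 1 + 1e-9))
  }
  # earlier conv layer is a legal target; pool layers are not
  img <- generate_chromosome("B", small_cfg(), seed = 3)
  sal1 <- grad_cam(model, img, "B", layer_id = "conv1")
  expect_equal(dim(sal1$values), c(32, 64))  # polar stem resolution
  expect_error(grad_cam(model, img, "B", layer_id = "pool1"),
               "not a convolutional activation")
  expect_error(grad_cam(model, img, 7), "out of range")
})

test_that("type C saliency concentrates on the chromatid bodies", {
  model <- small_model()
  hits <- 0; n <- 15
  for (seed in seq_len(n)) {
    img <- generate_chromosome("C", small_cfg(), seed = 300 + seed)
    sal <- grad_cam(model, img, "C")
    m <- sal$upsampled
    tot <- sum(m)
    expect_gt(tot, 0)
    px <- matrix(rep(1:96, each = 96), 96, 96)
    py <- matrix(rep(1:96, times = 96), 96, 96)
    cx <- sum(m * px) / tot
    cy <- sum(m * py) / tot
    boxes <- img$geometry$bboxes
    xmin <- min(vapply(boxes, `[[`, 0, "xmin"))
    xmax <- max(vapply(boxes, `[[`, 0, "xmax"))
    ymin <- min(vapply(boxes, `[[`, 0, "ymin"))
    ymax <- max(vapply(boxes, `[[`, 0, "ymax"))
    if (cx >= xmin && cx <= xmax && cy >= ymin && cy <= ymax) hits <- hits + 1
  }
  expect_gte(hits / n, 0.8)
})

test_that("overlay blends reversibly and a zero map is the identity", {
  model <- small_model()
  img <- generate_chromosome("A", small_cfg(), seed = 90)
  sal <- grad_cam(model, img, "A")
  zero <- sal
  zero$upsampled <- matrix(0, 96, 96)
  out0 <- overlay(img, zero)
  expect_equal(unclass(out0), chromotype:::as_pixels(img$pixels),
               ignore_attr = TRUE)
  out1 <- overlay(img, sal)
  out2 <- overlay(img, sal)
  expect_identical(out1, out2)
  expect_equal(attr(out1, "original"), chromotype:::as_pixels(img$pixels))
  expect_equal(dim(attr(out1, "alpha")), c(96, 96))
  bad <- sal
  bad$upsampled <- matrix(0, 10, 10)
  expect_error(overlay(img, bad), "96x96")
})
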