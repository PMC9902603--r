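# Frozen backbones and head training: convolution arithmetic against a
# naive oracle, the transfer (freezing) contract, head capacity on
# separable features, and seeded reproducibility.

naive_conv <- function(x, W, b, stride, pad, circular = FALSE) {
  d <- dim(x); dW <- dim(W)
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  if (circular && pad > 0) {
    xp[pad + seq_len(d[1]), seq_len(pad), ] <-
      x[, d[2] - pad + seq_len(pad), , drop = FALSE]
    xp[pad + seq_len(d[1]), d[2] + pad + seq_len(pad), ] <-
      x[, seq_len(pad), , drop = FALSE]
  }
  oh <- (dim(xp)[1] - dW[1]) %/% stride + 1
  ow <- (dim(xp)[2] - dW[2]) %/% stride + 1
  out <- array(0, c(oh, ow, dW[4]))
  for (i in 1:oh) for (j in 1:ow) for (k in 1:dW[4]) {
    acc <- b[k]
    for (di in 1:dW[1]) for (dj in 1:dW[2]) for (c in 1:dW[3]) {
      acc <- acc + xp[(i - 1) * stride + di, (j - 1) * stride + dj, c] *
        W[di, dj, c, k]
    }
    out[i, j, k] <- acc
  }
  out
}

test_that("im2col convolution agrees with the naive triple loop", {
  set.seed(1)
  x <- array(rnorm(10 * 12 * 3), c(10, 12, 3))
  W <- array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4))
  b <- rnorm(4)
  for (stride in 1:2) for (pad in 0:1) {
    expect_equal(chromotype:::conv2d_forward(x, W, b, stride, pad),
                 naive_conv(x, W, b, stride, pad), tolerance = 1e-10)
  }
  expect_equal(chromotype:::conv2d_forward(x, W, b, 1L, 1L, circular = TRUE),
               naive_conv(x, W, b, 1, 1, circular = TRUE), tolerance = 1e-10)
})

test_that("all three families build and produce their declared shape", {
  for (fam in c("small_scratch", "fire_module", "residual_block")) {
    bb <- build_backbone(fam, seed = 5, input_size = 96)
    img <- generate_chromosome("B", small_cfg(), seed = 1)
    f <- extract_features(bb, preprocess_pipeline(img, config = small_pp()))
    expect_equal(dim(f), bb$feature_shape)
    f2 <- extract_features(bb, preprocess_pipeline(img, config = small_pp()))
    expect_identical(f, f2)  # frozen determinism
  }
  expect_error(extract_features(small_backbone(), array(0, c(10, 10, 3))),
               "96x96x3")
})

test_that("a zero input yields zero features (bias-free, non-negative stack)", {
  f <- extract_features(small_backbone(), array(0, c(96, 96, 3)))
  expect_true(all(f == 0))
})

test_that("head training never touches backbone weights and features stay bitwise stable", {
  bb <- small_backbone()
  before <- serialize(bb$layers, NULL)
  ds <- small_dataset()
  img <- preprocess_pipeline(ds[[1]], config = small_pp())
  feat_before <- extract_features(bb, img)
  model <- small_model()
  expect_identical(serialize(model$backbone$layers, NULL), before)
  expect_identical(extract_features(model$backbone, img), feat_before)
})

test_that("the head reaches 100% training concordance on separable features", {
  # three well-separated Gaussian blobs in feature space
  set.seed(9)
  n <- 40; d <- 6
  centers <- rbind(c(8, 0, 0, 0, 0, 0), c(0, 8, 0, 0, 0, 0),
                   c(0, 0, 8, 0, 0, 0))
  X <- do.call(rbind, lapply(1:3, function(k) {
    matrix(rnorm(n * d), n, d) + matrix(centers[k, ], n, d, byrow = TRUE)
  }))
  y <- rep(c("A", "B", "C"), each = n)
  # independent separability oracle: one-vs-rest perceptron must converge
  for (k in 1:3) {
    t <- ifelse(y == c("A", "B", "C")[k], 1, -1)
    w <- numeric(d + 1); converged <- FALSE
    Xa <- cbind(1, X)
    for (epoch in 1:200) {
      miss <- which(t * (Xa %*% w) <= 0)
      if (!length(miss)) { converged <- TRUE; break }
      i <- miss[1]
      w <- w + t[i] * Xa[i, ]
    }
    expect_true(converged)
  }
  model <- train_head(small_backbone(),
                      list(X = X, labels = y),
                      list(X = X[seq(1, 120, 4), ], labels = y[seq(1, 120, 4)]),
                      hyper = head_hyperparams(epochs = 20), seed = 1)
  Z <- sweep(sweep(X, 2, model$head$center), 2, model$head$scale, `/`)
  S <- sweep(Z %*% t(model$head$W), 2, model$head$b, `+`)
  pred <- c("A", "B", "C")[max.col(S, ties.method = "first")]
  expect_equal(100 * mean(pred == y), 100)
})

test_that("training is reproducible for a fixed seed and data", {
  ds <- small_dataset()
  labs <- vapply(ds, `[[`, "", "label")
  tr <- unlist(lapply(c("A", "B", "C"), function(l) which(labs == l)[1:6]))
  va <- unlist(lapply(c("A", "B", "C"), function(l) which(labs == l)[7:8]))
  h <- head_hyperparams(epochs = 5)
  m1 <- train_head(small_backbone(), ds[tr], ds[va], h,
                   preprocess = small_pp(), seed = 123)
  m2 <- train_head(small_backbone(), ds[tr], ds[va], h,
                   preprocess = small_pp(), seed = 123)
  expect_identical(m1$head, m2$head)
  expect_identical(m1$training_log, m2$training_log)
})

test_that("train_head validates its inputs", {
  ds <- small_dataset()
  labs <- vapply(ds, `[[`, "", "label")
  only_ab <- ds[labs != "C"]
  expect_error(train_head(small_backbone(), only_ab[1:10], only_ab[11:12],
                          preprocess = small_pp()),
               "lacks label")
  expect_error(train_head(small_backbone(), ds[1:50], list(),
                          preprocess = small_pp()),
               "non-empty")
  expect_error(train_head(small_backbone(), ds[1:50], ds[1:3],
                          preprocess = small_pp()),
               "share images")
})

test_that("prediction returns finite scores and breaks exact ties toward A", {
  model <- small_model()
  img <- generate_chromosome("B", small_cfg(), seed = 200)
  p <- predict(model, img)
  expect_length(p$scores, 3)
  expect_true(all(is.finite(p$scores)))
  expect_named(p$scores, c("A", "B", "C"))
  expect_true(p$label %in% c("A", "B", "C"))
  # force an exact three-way tie through a zero head
  tied <- model
  tied$head$W[] <- 0
  tied$head$b[] <- 0
  expect_equal(predict(tied, img)$label, "A")
})

test_that("externally supplied weights are accepted but must match the family", {
  bb <- build_backbone("small_scratch", seed = 1, input_size = 96)
  bb2 <- build_backbone("small_scratch", seed = 2, input_size = 96,
                        weights = bb$layers)
  expect_true(bb2$pretrained)
  img <- preprocess_pipeline(generate_chromosome("A", small_cfg(), seed = 1),
                             config = small_pp())
  expect_identical(extract_features(bb2, img), extract_features(bb, img))
  expect_error(build_backbone("fire_module", weights = bb$layers,
                              input_size = 96),
               "layer structure")
})
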