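# Convolutional network primitives: im2col convolution, ReLU, 2x2 max
# pooling, and composite fire / residual blocks, each with a forward pass
# (with cache) and a backward pass for input gradients. BLAS matrix products
# do the heavy lifting; forward passes are exactly deterministic for fixed
# weights, which is what the frozen-backbone transfer contract requires.

pad_array <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  xp
}

# Zero padding in rows, circular (wrap-around) padding in columns — used on
# polar grids where the column axis is the angle and wraps at 2*pi.
pad_array_circular <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  xp[pad + seq_len(d[1]), seq_len(pad), ] <-
    x[, d[2] - pad + seq_len(pad), , drop = FALSE]
  xp[pad + seq_len(d[1]), d[2] + pad + seq_len(pad), ] <-
    x[, seq_len(pad), , drop = FALSE]
  xp
}

# Fold the gradient of a circularly padded array back onto the unpadded one.
unpad_circular <- function(dxp, pad, in_dim) {
  if (pad == 0) return(dxp)
  dx <- dxp[pad + seq_len(in_dim[1]), pad + seq_len(in_dim[2]), ,
            drop = FALSE]
  dx[, in_dim[2] - pad + seq_len(pad), ] <-
    dx[, in_dim[2] - pad + seq_len(pad), , drop = FALSE] +
    dxp[pad + seq_len(in_dim[1]), seq_len(pad), , drop = FALSE]
  dx[, seq_len(pad), ] <- dx[, seq_len(pad), , drop = FALSE] +
    dxp[pad + seq_len(in_dim[1]), in_dim[2] + pad + seq_len(pad), ,
        drop = FALSE]
  dx
}

# Unfold kernel-sized patches into the rows of a matrix. Column order
# matches R's flattening of a [kh, kw, cin, cout] weight array, so the
# convolution is a single matrix product.
im2col <- function(x, kh, kw, stride) {
  d <- dim(x)
  oh <- (d[1] - kh) %/% stride + 1L
  ow <- (d[2] - kw) %/% stride + 1L
  rows <- seq(1L, by = stride, length.out = oh)
  cols <- seq(1L, by = stride, length.out = ow)
  P <- matrix(0, oh * ow, kh * kw * d[3])
  k <- 0L
  for (ch in seq_len(d[3])) {
    for (dj in seq_len(kw)) {
      for (di in seq_len(kh)) {
        k <- k + 1L
        P[, k] <- x[rows + di - 1L, cols + dj - 1L, ch]
      }
    }
  }
  list(P = P, oh = oh, ow = ow, rows = rows, cols = cols)
}

conv2d_forward <- function(x, W, b, stride = 1L, pad = 0L,
                           circular = FALSE) {
  dW <- dim(W)
  xp <- if (circular) pad_array_circular(x, pad) else pad_array(x, pad)
  u <- im2col(xp, dW[1], dW[2], stride)
  Y <- u$P %*% matrix(W, ncol = dW[4])
  Y <- sweep(Y, 2L, b, `+`)
  array(Y, c(u$oh, u$ow, dW[4]))
}

# Gradient of a convolution with respect to its input (col2im scatter-add).
conv2d_backward <- function(dy, W, stride, pad, in_dim, circular = FALSE) {
  dW <- dim(W)
  dYm <- matrix(dy, ncol = dW[4])
  dP <- dYm %*% t(matrix(W, ncol = dW[4]))
  ph <- in_dim[1] + 2L * pad
  pw <- in_dim[2] + 2L * pad
  oh <- (ph - dW[1]) %/% stride + 1L
  ow <- (pw - dW[2]) %/% stride + 1L
  rows <- seq(1L, by = stride, length.out = oh)
  cols <- seq(1L, by = stride, length.out = ow)
  dxp <- array(0, c(ph, pw, in_dim[3]))
  k <- 0L
  for (ch in seq_len(in_dim[3])) {
    for (dj in seq_len(dW[2])) {
      for (di in seq_len(dW[1])) {
        k <- k + 1L
        dxp[rows + di - 1L, cols + dj - 1L, ch] <-
          dxp[rows + di - 1L, cols + dj - 1L, ch] + matrix(dP[, k], oh, ow)
      }
    }
  }
  if (pad == 0L) {
    dxp
  } else if (circular) {
    unpad_circular(dxp, pad, in_dim)
  } else {
    dxp[pad + seq_len(in_dim[1]), pad + seq_len(in_dim[2]), , drop = FALSE]
  }
}

relu <- function(x) pmax(x, 0)

maxpool_forward <- function(x) {
  d <- dim(x)
  h <- (d[1] %/% 2L) * 2L
  w <- (d[2] %/% 2L) * 2L
  s <- list(x[seq(1L, h, 2L), seq(1L, w, 2L), , drop = FALSE],
            x[seq(2L, h, 2L), seq(1L, w, 2L), , drop = FALSE],
            x[seq(1L, h, 2L), seq(2L, w, 2L), , drop = FALSE],
            x[seq(2L, h, 2L), seq(2L, w, 2L), , drop = FALSE])
  y <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  # first-match argmax routing for the backward pass
  am <- array(1L, dim(y))
  taken <- s[[1]] == y
  for (k in 2:4) {
    hit <- (s[[k]] == y) & !taken
    am[hit] <- k
    taken <- taken | hit
  }
  list(y = y, cache = list(am = am, in_dim = d, h = h, w = w))
}

maxpool_backward <- function(dy, cache) {
  d <- cache$in_dim
  dx <- array(0, d)
  offs <- list(c(1L, 1L), c(2L, 1L), c(1L, 2L), c(2L, 2L))
  for (k in 1:4) {
    o <- offs[[k]]
    sel <- cache$am == k
    block <- array(0, dim(dy))
    block[sel] <- dy[sel]
    dx[seq(o[1], cache$h, 2L), seq(o[2], cache$w, 2L), ] <- block
  }
  dx
}

he_weights <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

# ---- layer constructors -----------------------------------------------------

layer_conv <- function(id, kh, kw, cin, cout, stride = 1L, pad = 0L,
                       activation = "relu", circular = FALSE) {
  list(id = id, type = "conv", W = he_weights(kh, kw, cin, cout),
       b = numeric(cout), stride = as.integer(stride), pad = as.integer(pad),
       activation = activation, circular = circular)
}

layer_pool <- function(id) list(id = id, type = "maxpool")

# Polar resampling stem: bilinearly samples the image on an (n_r x n_phi)
# radius-by-angle grid centred on the chromatin centroid (darkness-weighted
# centre of mass). Image rotation becomes a circular shift along the angle
# axis, which subsequent circular convolutions plus global average pooling
# cancel — the stack becomes approximately rotation invariant, and object
# translation is absorbed by the centroid. Parameter-free and deterministic.
layer_polar <- function(id, n_r = 32L, n_phi = 64L, r_frac = 0.45) {
  list(id = id, type = "polar", n_r = as.integer(n_r),
       n_phi = as.integer(n_phi), r_frac = r_frac)
}

polar_forward <- function(op, x) {
  d <- dim(x)
  H <- d[1]
  gray <- (x[, , 1] + x[, , 2] + x[, , 3]) / 3
  dark <- pmax(mean(gray) - gray, 0)
  tot <- sum(dark)
  if (tot > 0) {
    cx <- sum(dark * matrix(rep(seq_len(d[2]), each = H), H, d[2])) / tot
    cy <- sum(dark * matrix(rep(seq_len(H), times = d[2]), H, d[2])) / tot
  } else {
    cx <- (d[2] + 1) / 2
    cy <- (H + 1) / 2
  }
  rmax <- op$r_frac * H
  r <- (seq_len(op$n_r) - 0.5) / op$n_r * rmax
  phi <- (seq_len(op$n_phi) - 1) / op$n_phi * 2 * pi
  xs <- clip(outer(r, phi, function(r, p) cx + r * cos(p)), 1, d[2])
  ys <- clip(outer(r, phi, function(r, p) cy + r * sin(p)), 1, H)
  x0 <- floor(xs); y0 <- floor(ys)
  x1 <- pmin(x0 + 1, d[2]); y1 <- pmin(y0 + 1, H)
  fx <- xs - x0; fy <- ys - y0
  out <- array(0, c(op$n_r, op$n_phi, d[3]))
  for (ch in seq_len(d[3])) {
    g <- x[, , ch]
    out[, , ch] <-
      g[cbind(c(y0), c(x0))] * (1 - fx) * (1 - fy) +
      g[cbind(c(y0), c(x1))] * fx * (1 - fy) +
      g[cbind(c(y1), c(x0))] * (1 - fx) * fy +
      g[cbind(c(y1), c(x1))] * fx * fy
  }
  list(y = out, cache = list(center = c(cx, cy), rmax = rmax,
                             input_size = c(H, d[2])))
}

layer_fire <- function(id, cin, squeeze, expand) {
  list(id = id, type = "fire",
       Ws = he_weights(1L, 1L, cin, squeeze), bs = numeric(squeeze),
       We1 = he_weights(1L, 1L, squeeze, expand), be1 = numeric(expand),
       We3 = he_weights(3L, 3L, squeeze, expand), be3 = numeric(expand))
}

layer_resblock <- function(id, cin) {
  list(id = id, type = "resblock",
       W1 = he_weights(3L, 3L, cin, cin), b1 = numeric(cin),
       W2 = he_weights(3L, 3L, cin, cin), b2 = numeric(cin))
}

# ---- forward / backward through one layer ----------------------------------

op_forward <- function(op, x) {
  switch(op$type,
    conv = {
      z <- conv2d_forward(x, op$W, op$b, op$stride, op$pad,
                          circular = isTRUE(op$circular))
      y <- if (op$activation == "relu") relu(z) else z
      list(y = y, cache = list(in_dim = dim(x), z = z))
    },
    polar = polar_forward(op, x),
    maxpool = maxpool_forward(x),
    fire = {
      zs <- conv2d_forward(x, op$Ws, op$bs, 1L, 0L)
      as_ <- relu(zs)
      z1 <- conv2d_forward(as_, op$We1, op$be1, 1L, 0L)
      z3 <- conv2d_forward(as_, op$We3, op$be3, 1L, 1L)
      d1 <- dim(z1)
      z <- array(c(z1, z3), c(d1[1], d1[2], 2L * d1[3]))
      list(y = relu(z),
           cache = list(in_dim = dim(x), zs = zs, as_dim = dim(as_),
                        as_ = as_, z = z, nexp = d1[3]))
    },
    resblock = {
      z1 <- conv2d_forward(x, op$W1, op$b1, 1L, 1L)
      a1 <- relu(z1)
      z2 <- conv2d_forward(a1, op$W2, op$b2, 1L, 1L)
      z <- z2 + x
      list(y = relu(z), cache = list(in_dim = dim(x), z1 = z1, z = z))
    },
    stop("unknown layer type: ", op$type))
}

op_backward <- function(op, dy, cache) {
  switch(op$type,
    conv = {
      dz <- if (op$activation == "relu") dy * (cache$z > 0) else dy
      conv2d_backward(dz, op$W, op$stride, op$pad, cache$in_dim,
                      circular = isTRUE(op$circular))
    },
    maxpool = maxpool_backward(dy, cache),
    fire = {
      dz <- dy * (cache$z > 0)
      ne <- cache$nexp
      dz1 <- dz[, , seq_len(ne), drop = FALSE]
      dz3 <- dz[, , ne + seq_len(ne), drop = FALSE]
      das <- conv2d_backward(dz1, op$We1, 1L, 0L, cache$as_dim) +
             conv2d_backward(dz3, op$We3, 1L, 1L, cache$as_dim)
      dzs <- das * (cache$zs > 0)
      conv2d_backward(dzs, op$Ws, 1L, 0L, cache$in_dim)
    },
    resblock = {
      dz <- dy * (cache$z > 0)
      da1 <- conv2d_backward(dz, op$W2, 1L, 1L, cache$in_dim)
      dz1 <- da1 * (cache$z1 > 0)
      conv2d_backward(dz1, op$W1, 1L, 1L, cache$in_dim) + dz
    },
    stop("unknown layer type: ", op$type))
}

global_average_pool <- function(a) {
  apply(a, 3L, mean)
}
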