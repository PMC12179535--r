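# Minimal convolutional network engine used by the MIL model.
#
# Tensors are stored as 4-d arrays with dimensions (H, W, N, C): spatial rows,
# spatial columns, instances in the bag, channels. R is column-major, so
# matrix(x, ncol = C) flattens (H, W, N) into rows with channels as columns,
# which lets every layer reduce to a handful of BLAS matrix products.
# Each layer returns list(out, cache); the matching backward consumes the
# cache and returns gradients for input and parameters.

nn_he_init <- function(fan_in, dims) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

# im2col: unfold 3x3 same-padding neighbourhoods of x (H, W, N, C) into a
# (H*W*N) x (9*C) matrix so convolution becomes a single BLAS product.
im2col3 <- function(x) {
  d <- dim(x); h <- d[1]; wd <- d[2]; n <- d[3]; cc <- d[4]
  hp <- h + 2L; wp <- wd + 2L
  xp <- matrix(0, hp * wp, n * cc)
  inner <- as.vector(outer(2:(h + 1L), (2:(wd + 1L) - 1L) * hp, "+"))
  xp[inner, ] <- x
  cols <- matrix(0, h * wd * n, 9 * cc)
  k <- 0L
  for (ddx in 0:2) {
    for (ddy in 0:2) {
      idx <- as.vector(outer((1L + ddy):(h + ddy),
                             ((1L + ddx):(wd + ddx) - 1L) * hp, "+"))
      cols[, k * cc + seq_len(cc)] <- matrix(xp[idx, ], ncol = cc)
      k <- k + 1L
    }
  }
  cols
}

# Weight array (3, 3, Cin, Cout) flattened to match im2col3 column order
# (offset-major over dx then dy, channel-minor).
wmat3 <- function(w) {
  cin <- dim(w)[3]; cout <- dim(w)[4]
  m <- matrix(0, 9 * cin, cout)
  k <- 0L
  for (ddx in 0:2) {
    for (ddy in 0:2) {
      m[k * cin + seq_len(cin), ] <- w[ddy + 1, ddx + 1, , ]
      k <- k + 1L
    }
  }
  m
}

# 3x3 same-padding convolution. W: (3, 3, Cin, Cout), b: length Cout.
conv_forward <- function(x, w, b) {
  d <- dim(x)
  cout <- dim(w)[4]
  cols <- im2col3(x)
  ymat <- cols %*% wmat3(w)
  ymat <- sweep(ymat, 2, b, "+")
  list(out = array(ymat, c(d[1], d[2], d[3], cout)),
       cache = list(cols = cols, w = w, dims = d))
}

# Gradient wrt the input equals a same-padding convolution of the output
# gradient with the spatially flipped, channel-transposed kernel.
conv_backward <- function(dy, cache, need_dx = TRUE) {
  d <- cache$dims; cin <- d[4]
  w <- cache$w
  cout <- dim(w)[4]
  dymat <- matrix(dy, ncol = cout)
  dwmat <- crossprod(cache$cols, dymat)
  dw <- array(0, dim(w))
  k <- 0L
  for (ddx in 0:2) {
    for (ddy in 0:2) {
      dw[ddy + 1, ddx + 1, , ] <- dwmat[k * cin + seq_len(cin), ]
      k <- k + 1L
    }
  }
  dx <- NULL
  if (need_dx) {
    wflip <- array(0, c(3, 3, cout, cin))
    for (ddy in 1:3) for (ddx in 1:3)
      wflip[4 - ddy, 4 - ddx, , ] <- t(matrix(w[ddy, ddx, , ], cin, cout))
    dycols <- im2col3(array(dy, c(d[1], d[2], d[3], cout)))
    dx <- array(dycols %*% wmat3(wflip), c(d[1], d[2], d[3], cin))
  }
  list(dx = dx, dw = dw, db = colSums(dymat))
}

relu_forward <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}

relu_backward <- function(dy, mask) dy * mask

# 2x2 max pooling, stride 2. Requires even H and W; ties resolved in the
# fixed order top-left, top-right, bottom-left, bottom-right.
maxpool_forward <- function(x) {
  d <- dim(x); h <- d[1]; w <- d[2]
  stopifnot(h %% 2 == 0, w %% 2 == 0)
  ri <- seq(1L, h, 2L); ci <- seq(1L, w, 2L)
  v00 <- x[ri, ci, , , drop = FALSE]; v01 <- x[ri, ci + 1L, , , drop = FALSE]
  v10 <- x[ri + 1L, ci, , , drop = FALSE]; v11 <- x[ri + 1L, ci + 1L, , , drop = FALSE]
  a <- pmax(v00, v01); b <- pmax(v10, v11)
  out <- pmax(a, b)
  list(out = out,
       cache = list(top = a >= b, left_top = v00 >= v01, left_bot = v10 >= v11,
                    dims = d))
}

maxpool_backward <- function(dy, cache) {
  d <- cache$dims; h <- d[1]; w <- d[2]
  ri <- seq(1L, h, 2L); ci <- seq(1L, w, 2L)
  da <- dy * cache$top
  db <- dy * !cache$top
  dx <- array(0, d)
  dx[ri, ci, , ]           <- da * cache$left_top
  dx[ri, ci + 1L, , ]      <- da * !cache$left_top
  dx[ri + 1L, ci, , ]      <- db * cache$left_bot
  dx[ri + 1L, ci + 1L, , ] <- db * !cache$left_bot
  dx
}

# Global average pooling over the spatial dimensions: (H, W, N, C) -> (N, C).
gap_forward <- function(x) {
  d <- dim(x)
  m <- matrix(x, nrow = d[1] * d[2])
  list(out = matrix(colMeans(m), nrow = d[3], ncol = d[4]), cache = d)
}

gap_backward <- function(dy, d) {
  array(rep(as.vector(dy) / (d[1] * d[2]), each = d[1] * d[2]), d)
}

dense_forward <- function(x, w, b) {
  list(out = sweep(x %*% w, 2, b, "+"), cache = list(x = x, w = w))
}

dense_backward <- function(dy, cache) {
  list(dx = tcrossprod(dy, cache$w),
       dw = crossprod(cache$x, dy),
       db = colSums(dy))
}

softmax_vec <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}
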