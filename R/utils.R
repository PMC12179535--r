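# Shared image helpers.

#' Convert an RGB array to grayscale
#'
#' Standard luminance weighting (0.2125 R + 0.7154 G + 0.0721 B).
#'
#' @param img `(H, W, 3)` array in `[0, 1]`, or an `(H, W)` matrix (returned
#'   unchanged).
#' @return `(H, W)` matrix in `[0, 1]`.
#' @export
rgb_to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  stopifnot(length(dim(img)) == 3, dim(img)[3] >= 3)
  0.2125 * img[, , 1] + 0.7154 * img[, , 2] + 0.0721 * img[, , 3]
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Vectorised HSV -> RGB on numeric vectors (h in [0,1), s, v in [0,1]).
hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 1) * 6
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- g <- b <- numeric(length(h))
  for (k in 0:5) {
    m <- i == k
    if (!any(m)) next
    rgb <- switch(as.character(k),
      "0" = list(v, t, p), "1" = list(q, v, p), "2" = list(p, v, t),
      "3" = list(p, q, v), "4" = list(t, p, v), "5" = list(v, p, q))
    r[m] <- rgb[[1]][m]; g[m] <- rgb[[2]][m]; b[m] <- rgb[[3]][m]
  }
  list(r = r, g = g, b = b)
}

# Smoothed standard-normal random field: white noise blurred with an
# isotropic Gaussian of the given sigma, rescaled to zero mean, unit sd, so
# that the correlation length varies with sigma but the contrast does not.
smooth_field <- function(h, w, sigma) {
  z <- matrix(stats::rnorm(h * w), h, w)
  if (sigma > 0) {
    z <- EBImage::gblur(z, sigma = sigma)
  }
  (z - mean(z)) / stats::sd(z)
}

# Rasterise an ellipse: pixel centres inside the ellipse centred at integer
# (cy, cx) with semi-axes (a, b) and orientation theta. Returns the mask as
# index pairs relative to the enclosing image of size (h, w).
ellipse_pixels <- function(cy, cx, a, b, theta, h, w) {
  r <- ceiling(a) + 1L
  ys <- max(1L, cy - r):min(h, cy + r)
  xs <- max(1L, cx - r):min(w, cx + r)
  g <- expand.grid(y = ys, x = xs)
  dy <- g$y - cy; dx <- g$x - cx
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy
  keep <- (u / a)^2 + (v / b)^2 <= 1
  cbind(y = g$y[keep], x = g$x[keep])
}
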