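# Independent brute-force oracles and small fixture builders.

# GLCM by explicit pair enumeration (O(H*W) double loop), one direction.
oracle_glcm <- function(img, distance = 1L, angle = 0, n_levels = 256L) {
  off <- switch(as.character(angle),
                "0" = c(0L, distance), "45" = c(-distance, distance),
                "90" = c(-distance, 0L), "135" = c(-distance, -distance))
  counts <- matrix(0, n_levels, n_levels)
  h <- nrow(img); w <- ncol(img)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w)
        counts[img[r, c] + 1L, img[r2, c2] + 1L] <-
          counts[img[r, c] + 1L, img[r2, c2] + 1L] + 1
    }
  }
  counts / sum(counts)
}

# Texture features by direct double sums over the matrix entries.
oracle_texture <- function(p) {
  n <- nrow(p)
  homog <- 0; energy <- 0
  for (i in 1:n) for (j in 1:n) {
    homog <- homog + p[i, j] / (1 + (i - j)^2)
    energy <- energy + p[i, j]^2
  }
  mu_i <- 0; mu_j <- 0
  for (i in 1:n) for (j in 1:n) {
    mu_i <- mu_i + (i - 1) * p[i, j]
    mu_j <- mu_j + (j - 1) * p[i, j]
  }
  v_i <- 0; v_j <- 0
  for (i in 1:n) for (j in 1:n) {
    v_i <- v_i + (i - 1 - mu_i)^2 * p[i, j]
    v_j <- v_j + (j - 1 - mu_j)^2 * p[i, j]
  }
  corr <- 0
  for (i in 1:n) for (j in 1:n)
    corr <- corr + (i - 1 - mu_i) * (j - 1 - mu_j) * p[i, j]
  corr <- corr / sqrt(v_i * v_j)
  list(homogeneity = homog, energy = energy, correlation = corr)
}

# Otsu threshold by exhaustive per-cut scan maximising the between-class
# variance of the 256-bin histogram (low class = bins 1..k, high class =
# bins k..levels; threshold reported as the optimal bin's midpoint,
# averaging the first and last cut under ties).
oracle_otsu <- function(gray, levels = 256L) {
  h <- hist(as.vector(gray), breaks = seq(0, 1, length.out = levels + 1),
            plot = FALSE)
  counts <- h$counts; mids <- h$mids
  v <- rep(NA_real_, levels)
  for (k in seq_len(levels)) {
    lo <- 1:k; hi <- k:levels
    w1 <- sum(counts[lo]); w2 <- sum(counts[hi])
    if (w1 == 0 || w2 == 0) next
    m1 <- sum(counts[lo] * mids[lo]) / w1
    m2 <- sum(counts[hi] * mids[hi]) / w2
    v[k] <- w1 * w2 * (m2 - m1)^2
  }
  best <- which(v == max(v, na.rm = TRUE))
  (mids[best[1]] + mids[best[length(best)]]) / 2
}

# AUROC through the rank-sum (Mann-Whitney U) relation.
oracle_auroc <- function(labels, scores, positive = "hypoxic") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  r <- rank(c(pos, neg))
  u <- sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2
  u / (length(pos) * length(neg))
}

# Rasterise an ellipse mask (pixel-centre test, integer centre).
make_ellipse_mask <- function(n, a, b, theta = 0, cy = NULL, cx = NULL) {
  if (is.null(cy)) cy <- ceiling(n / 2)
  if (is.null(cx)) cx <- ceiling(n / 2)
  g <- expand.grid(y = 1:n, x = 1:n)
  dy <- g$y - cy; dx <- g$x - cx
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy
  matrix((u / a)^2 + (v / b)^2 <= 1, n, n)
}

# Tiny MIL model (two truncated conv blocks, narrow feature dim) for fast
# unit tests; weights seeded.
tiny_model <- function(pooling = "max", seed = 7, in_channels = 3L,
                       feature_dim = 16L) {
  m <- mil_model("small_cnn", pooling, seed = seed,
                 in_channels = in_channels, feature_dim = feature_dim,
                 att_dim = 4L)
  set.seed(seed)
  m$channels <- c(3L, 4L)
  m$pool_after <- c(1L, 2L)
  m$params$conv <- list(
    list(w = hypoxmorph:::nn_he_init(9 * in_channels, c(3, 3, in_channels, 3)),
         b = rep(0, 3)),
    list(w = hypoxmorph:::nn_he_init(9 * 3, c(3, 3, 3, 4)), b = rep(0, 4)))
  m$params$proj_w <- hypoxmorph:::nn_he_init(4, c(4, feature_dim))
  m$params$proj_b <- rep(0, feature_dim)
  if (pooling == "attention") {
    m$params$att_v <- hypoxmorph:::nn_he_init(feature_dim, c(feature_dim, 4))
    m$params$att_u <- hypoxmorph:::nn_he_init(feature_dim, c(feature_dim, 4))
    m$params$att_w <- hypoxmorph:::nn_he_init(4, c(4, 1))
  }
  m$params$cls_w <- hypoxmorph:::nn_he_init(feature_dim, c(feature_dim, 2))
  m$params$cls_b <- c(0.1, 0.1)
  m
}

# Small synthetic cohort configuration used across tests.
test_cfg <- function(seed = 3, n = 3, slide = 128, tile = 32, ...) {
  synth_config(seed = seed, n_samples_per_class = n,
               slide_size_px = c(slide, slide), tile_size_px = tile, ...)
}
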