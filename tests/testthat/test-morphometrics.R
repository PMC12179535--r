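test_that("co-occurrence matrices match hand-enumerable cases", {
  # 2x2 image, distance 1, angle 0: the two horizontal pairs (0,0), (1,1)
  img <- rbind(c(0L, 0L), c(1L, 1L))
  p <- glcm(img, 1, 0, n_levels = 2)
  expect_equal(p, rbind(c(0.5, 0), c(0, 0.5)))
  # constant image: all mass in one diagonal cell
  pc <- glcm(matrix(3L, 4, 4), 1, 0, n_levels = 8)
  expect_equal(pc[4, 4], 1)
  expect_equal(sum(pc), 1)
  # angle 90 steps upward: the lower row (1) pairs with the upper row (0)
  p90 <- glcm(img, 1, 90, n_levels = 2)
  expect_equal(p90, rbind(c(0, 0), c(1, 0)))
})

test_that("glcm rejects invalid input and undersized images", {
  expect_error(glcm(matrix(c(0L, 256L), 1, 2), n_levels = 256), "integers in")
  expect_error(glcm(matrix(0.5, 2, 2)), "integers in")
  expect_error(glcm(matrix(0L, 1, 1), 1, 0), "smaller than the pair offset")
  expect_error(glcm(matrix(0L, 2, 2), 1, 30), "angle")
})

test_that("glcm equals brute-force pair enumeration on random images", {
  set.seed(14)
  for (i in 1:5) {
    img <- matrix(sample(0:15, 64, replace = TRUE), 8, 8)
    for (ang in c(0, 45, 90, 135)) {
      expect_equal(glcm(img, 1, ang, n_levels = 16),
                   oracle_glcm(img, 1, ang, n_levels = 16))
      expect_equal(sum(glcm(img, 1, ang, n_levels = 16)), 1)
    }
  }
})

test_that("texture features follow the printed formulas", {
  # constant image: homogeneity and energy 1, correlation undefined
  f <- glcm_features(glcm(matrix(7L, 8, 8), 1, 0, n_levels = 16))
  expect_equal(f$homogeneity, 1)
  expect_equal(f$energy, 1)
  expect_true(is.na(f$correlation))
  expect_false(f$correlation_defined)
  # 0/255 checkerboard at distance 1, angle 0: all mass off-diagonal at
  # |i-j| = 255, so homogeneity = 1/(1+255^2) and energy = 2 * 0.5^2
  ck <- matrix(0L, 8, 8)
  ck[(row(ck) + col(ck)) %% 2 == 0] <- 255L
  fck <- glcm_features(glcm(ck, 1, 0, n_levels = 256))
  expect_equal(fck$homogeneity, 1 / (1 + 255^2))
  expect_equal(fck$energy, 0.5)
  expect_equal(fck$correlation, -1)
})

test_that("features agree with brute-force double sums to 1e-10", {
  set.seed(15)
  for (i in 1:5) {
    img <- matrix(sample(0:31, 16 * 16, replace = TRUE), 16, 16)
    p <- glcm(img, 1, 45, n_levels = 32)
    f <- glcm_features(p)
    o <- oracle_texture(p)
    expect_equal(f$homogeneity, o$homogeneity, tolerance = 1e-10)
    expect_equal(f$energy, o$energy, tolerance = 1e-10)
    expect_equal(f$correlation, o$correlation, tolerance = 1e-10)
  }
})

test_that("four-angle averaged features are 90-degree rotation invariant", {
  set.seed(16)
  img <- matrix(sample(0:255, 32 * 32, replace = TRUE), 32, 32)
  f0 <- texture_features(img)
  rot <- t(img)[ncol(img):1, ]
  f90 <- texture_features(rot)
  for (nm in c("homogeneity", "energy", "correlation", "contrast"))
    expect_equal(f0[[nm]], f90[[nm]], tolerance = 1e-12)
})

test_that("energy and homogeneity attain 1 only in the degenerate cases", {
  set.seed(17)
  for (i in 1:10) {
    img <- matrix(sample(0:7, 36, replace = TRUE), 6, 6)
    f <- glcm_features(glcm(img, 1, 0, n_levels = 8))
    expect_lte(f$energy, 1)
    expect_lte(f$homogeneity, 1)
    if (length(unique(as.vector(img))) > 1) {
      expect_lt(f$energy, 1)
    }
  }
})

test_that("shape descriptors reproduce analytic geometry", {
  # analytic circle: circularity exactly 1 for any radius
  for (r in c(1, 5, 100))
    expect_equal(circularity_measure(pi * r^2, 2 * pi * r), 1)
  # equal axes: eccentricity exactly 0
  for (a in c(1, 3, 10))
    expect_identical(eccentricity_axes(a, a), 0)
  # elongated limit approaches 1 from below, monotonically
  e <- eccentricity_axes(1, c(0.1, 0.01, 0.001))
  expect_true(all(diff(e) > 0))
  expect_true(all(e < 1))
})

test_that("rasterised shapes measure close to their planted geometry", {
  # axis-aligned filled rectangle: extent and solidity exactly 1
  rect <- matrix(FALSE, 20, 20); rect[5:15, 3:12] <- TRUE
  d <- shape_descriptors(rect)
  expect_equal(d$extent, 1)
  expect_equal(d$solidity, 1)
  expect_equal(d$area, 11 * 10)
  # ellipses across axis ratios 1..4: moment eccentricity within 0.05
  for (ratio in c(1, 2, 3, 4)) {
    for (th in c(0, 0.4, 1.1)) {
      m <- make_ellipse_mask(64, 12, 12 / ratio, theta = th)
      d <- shape_descriptors(m)
      expect_lt(abs(d$eccentricity - eccentricity_axes(12, 12 / ratio)), 0.05)
    }
  }
  # rasterised disks: circularity near 1, eccentricity exactly 0
  dk <- shape_descriptors(make_ellipse_mask(32, 9, 9))
  expect_lt(abs(dk$circularity - 1), 0.12)
  expect_identical(dk$eccentricity, 0)
  expect_equal(dk$equivalent_diameter, sqrt(4 * dk$area / pi))
})

test_that("descriptors are translation invariant and scale correctly", {
  base <- make_ellipse_mask(96, 22, 13, theta = 0.3, cy = 40, cx = 40)
  shifted <- make_ellipse_mask(96, 22, 13, theta = 0.3, cy = 52, cx = 45)
  d1 <- shape_descriptors(base); d2 <- shape_descriptors(shifted)
  expect_equal(d1$area, d2$area)
  expect_equal(d1$perimeter, d2$perimeter)
  expect_equal(d1$eccentricity, d2$eccentricity)
  # scaling the shape by an integer factor: area scales as s^2 (within
  # rasterisation tolerance), perimeter as s (within 5%)
  s <- 2L
  du <- shape_descriptors(make_ellipse_mask(96 * s, 22 * s, 13 * s,
                                            theta = 0.3, cy = 80, cx = 80))
  expect_equal(du$area / (s^2 * d1$area), 1, tolerance = 0.02)
  expect_lt(abs(du$perimeter / (s * d1$perimeter) - 1), 0.05)
})

test_that("invalid masks are rejected with informative errors", {
  expect_error(shape_descriptors(matrix(FALSE, 4, 4)), "empty")
  small <- matrix(FALSE, 4, 4); small[2, 2:3] <- TRUE
  expect_error(shape_descriptors(small), "at least 8")
  two <- matrix(FALSE, 12, 12); two[2:5, 2:5] <- TRUE; two[8:11, 8:11] <- TRUE
  expect_error(shape_descriptors(two), "2 connected components")
})

test_that("high-confidence selection respects the cutoff semantics", {
  m <- tiny_model("max")
  set.seed(4)
  samples <- lapply(1:3, function(i) list(
    sample_id = paste0("s", i), class = "normoxic",
    tiles = lapply(1:6, function(j) array(stats::runif(8 * 8 * 3), c(8, 8, 3)))))
  # cutoff 1 retains nothing (probability cannot exceed 1); one warning
  # per empty class
  w <- capture_warnings(hc1 <- select_high_confidence(samples, m, cutoff = 1,
                                                      per_sample = 4))
  expect_length(w, 2)
  expect_match(w, "no tiles retained", all = TRUE)
  expect_identical(nrow(hc1$hypoxic) + nrow(hc1$normoxic), 0L)
  # cutoff 0 retains every sampled tile
  hc0 <- suppressWarnings(select_high_confidence(samples, m, cutoff = 0,
                                                 per_sample = 4))
  expect_identical(nrow(hc0$hypoxic) + nrow(hc0$normoxic), 12L)
})
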