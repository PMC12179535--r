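#' Gray-level co-occurrence matrix
#'
#' Counts pairs of gray levels at the given pixel offset, in one direction
#' only, and normalises the counts to sum to 1. Offsets follow the usual
#' image convention: at distance `d`, angle 0 pairs each pixel with the
#' pixel `d` columns to its right; 45, 90 and 135 degrees step up-right,
#' up, and up-left respectively.
#'
#' @param img integer-valued matrix with values in `[0, n_levels)`.
#' @param distance pixel offset distance (default 1).
#' @param angle one of 0, 45, 90, 135 (degrees).
#' @param n_levels number of gray levels (default 256).
#' @return `n_levels` x `n_levels` matrix `P` with nonnegative entries
#'   summing to 1; `P[i+1, j+1]` is the relative frequency of the level
#'   pair `(i, j)`.
#' @export
glcm <- function(img, distance = 1L, angle = 0, n_levels = 256L) {
  stopifnot(is.matrix(img), distance >= 1)
  if (any(img < 0) || any(img >= n_levels) || any(img != round(img)))
    stop("img must contain integers in [0, ", n_levels, ")", call. = FALSE)
  d <- as.integer(distance)
  off <- switch(as.character(angle),
                "0"   = c(0L, d),
                "45"  = c(-d, d),
                "90"  = c(-d, 0L),
                "135" = c(-d, -d),
                stop("angle must be one of 0, 45, 90, 135", call. = FALSE))
  h <- nrow(img); w <- ncol(img)
  rows <- seq_len(h - abs(off[1]))
  cols <- seq_len(w - abs(off[2]))
  if (length(rows) == 0 || length(cols) == 0)
    stop("image (", h, "x", w, ") is smaller than the pair offset",
         call. = FALSE)
  if (off[1] < 0) { from_r <- rows - off[1]; to_r <- rows } else
                  { from_r <- rows;          to_r <- rows + off[1] }
  if (off[2] < 0) { from_c <- cols - off[2]; to_c <- cols } else
                  { from_c <- cols;          to_c <- cols + off[2] }
  i <- img[from_r, from_c]
  j <- img[to_r, to_c]
  counts <- tabulate(i * n_levels + j + 1L, nbins = n_levels^2)
  matrix(counts / sum(counts), n_levels, n_levels, byrow = TRUE)
}

#' Texture features of a normalised co-occurrence matrix
#'
#' Homogeneity `sum P(i,j) / (1 + (i-j)^2)`, energy `sum P(i,j)^2` and
#' correlation `sum (i - mu_i)(j - mu_j) P(i,j) / (sigma_i sigma_j)`, plus
#' contrast and dissimilarity as extras. Correlation is undefined when a
#' marginal variance is zero (constant image); it is returned as `NA` with
#' `correlation_defined = FALSE` so callers can exclude it from group
#' statistics.
#'
#' @param p normalised GLCM from [glcm()].
#' @return one-row data frame of features.
#' @export
glcm_features <- function(p) {
  n <- nrow(p)
  idx <- seq_len(n) - 1
  di <- outer(idx, idx, "-")
  homog <- sum(p / (1 + di^2))
  energy <- sum(p^2)
  contrast <- sum(p * di^2)
  dissim <- sum(p * abs(di))
  pi_ <- rowSums(p); pj <- colSums(p)
  mu_i <- sum(idx * pi_); mu_j <- sum(idx * pj)
  var_i <- sum((idx - mu_i)^2 * pi_); var_j <- sum((idx - mu_j)^2 * pj)
  if (var_i < 1e-12 || var_j < 1e-12) {
    corr <- NA_real_; def <- FALSE
  } else {
    corr <- sum(outer(idx - mu_i, idx - mu_j) * p) / sqrt(var_i * var_j)
    def <- TRUE
  }
  data.frame(homogeneity = homog, energy = energy, correlation = corr,
             contrast = contrast, dissimilarity = dissim,
             correlation_defined = def)
}

#' Four-angle averaged texture features of a grayscale tile
#'
#' Computes the GLCM at distance `distance` for angles 0, 45, 90 and 135
#' degrees and averages the features over the four angles, the standard
#' rotation-insensitive protocol.
#'
#' @param gray numeric matrix in `[0, 1]` (quantised to `n_levels` levels)
#'   or an integer matrix already in `[0, n_levels)`.
#' @param distance pair distance (default 1).
#' @param n_levels gray levels (default 256).
#' @return one-row data frame as in [glcm_features()];
#'   `correlation_defined` is `FALSE` if any angle's correlation was
#'   undefined.
#' @export
texture_features <- function(gray, distance = 1L, n_levels = 256L) {
  img <- if (all(gray == round(gray)) && max(gray) > 1) gray
         else round(clamp01(gray) * (n_levels - 1))
  feats <- lapply(c(0, 45, 90, 135), function(a)
    glcm_features(glcm(img, distance, a, n_levels)))
  f <- do.call(rbind, feats)
  out <- data.frame(homogeneity = mean(f$homogeneity),
                    energy = mean(f$energy),
                    correlation = mean(f$correlation),
                    contrast = mean(f$contrast),
                    dissimilarity = mean(f$dissimilarity),
                    correlation_defined = all(f$correlation_defined))
  out
}

#' Eccentricity from axis lengths
#'
#' `sqrt(1 - b^2 / a^2)` for major axis `a` and minor axis `b`: 0 for a
#' round object (`b = a`), approaching 1 in the elongated limit.
#'
#' @param major,minor axis lengths, `major >= minor > 0`.
#' @return eccentricity in `[0, 1)`.
#' @export
eccentricity_axes <- function(major, minor) {
  stopifnot(all(major >= minor), all(minor > 0))
  sqrt(1 - minor^2 / major^2)
}

#' Circularity from area and perimeter
#'
#' `4 * pi * Area / Perimeter^2`: exactly 1 for a perfect circle, falling
#' towards 0 for highly non-circular shapes.
#'
#' @param area object area.
#' @param perimeter object perimeter.
#' @return circularity.
#' @export
circularity_measure <- function(area, perimeter) {
  4 * pi * area / perimeter^2
}

# Moore-neighbour boundary trace of a single-component mask; returns the
# perimeter as the weighted chain length with the Vossepoel-Smeulders step
# weights (0.948 axial, 1.340 diagonal). The chain runs through pixel
# centres, half a pixel inside the true object boundary, so callers add a
# pi dilation correction (perimeter of a half-pixel outward offset of a
# convex contour); with it, rasterised disks measure close to their true
# circumference.
trace_perimeter <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  m <- matrix(FALSE, h + 2, w + 2)
  m[2:(h + 1), 2:(w + 1)] <- mask
  start <- which(m, arr.ind = TRUE)[1, ]            # first TRUE in scan order
  # neighbour ring, clockwise from west
  dy <- c(0, -1, -1, -1, 0, 1, 1, 1)
  dx <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  wgt <- ifelse(dy != 0 & dx != 0, 1.340, 0.948)
  if (sum(m) == 1) return(4 * 0.948)                # lone pixel
  per <- 0
  cur <- start; back <- 1                            # came from the west
  first_move <- NULL
  repeat {
    found <- FALSE
    for (k in 0:7) {
      dir <- (back + k) %% 8 + 1
      ny <- cur[1] + dy[dir]; nx <- cur[2] + dx[dir]
      if (m[ny, nx]) {
        per <- per + wgt[dir]
        prev <- cur
        cur <- c(ny, nx)
        # backtrack direction: neighbour index of prev as seen from cur
        back <- (dir + 3) %% 8 + 1
        back <- back %% 8                            # start search after backtrack
        if (is.null(first_move)) {
          first_move <- dir
          start_cell <- prev
        } else if (all(cur == c(start_cell[1] + dy[first_move],
                                start_cell[2] + dx[first_move])) &&
                   all(prev == start_cell)) {
          return(per - wgt[dir])                     # closed the contour
        }
        found <- TRUE
        break
      }
    }
    if (!found) return(per)                          # isolated after all
    if (all(cur == start) && !is.null(first_move)) {
      # next step from start repeats the first move -> contour closed
      for (k in 0:7) {
        dir <- (back + k) %% 8 + 1
        ny <- cur[1] + dy[dir]; nx <- cur[2] + dx[dir]
        if (m[ny, nx]) {
          if (dir == first_move) return(per)
          break
        }
      }
    }
  }
}

#' Binary shape descriptors of a single cell mask
#'
#' Measures the classic region properties of one connected binary mask:
#' pixel area, boundary-traced perimeter (weighted chain code), equivalent
#' (area-derived) diameter, axis lengths and eccentricity from the
#' normalised second central moments, circularity `4 pi A / P^2`, extent
#' (area over bounding-box area) and solidity (area over rasterised
#' convex-hull area).
#'
#' @param mask logical (or 0/1) matrix containing exactly one 8-connected
#'   component of at least 8 pixels.
#' @return one-row data frame of descriptors.
#' @export
shape_descriptors <- function(mask) {
  mask <- mask > 0
  a_px <- sum(mask)
  if (a_px == 0) stop("empty mask", call. = FALSE)
  if (a_px < 8) stop("mask has ", a_px, " pixels; at least 8 required",
                     call. = FALSE)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  if (max(lab) > 1)
    stop("mask has ", max(lab), " connected components; exactly 1 required",
         call. = FALSE)
  idx <- which(mask, arr.ind = TRUE)
  y <- idx[, 1]; x <- idx[, 2]
  mu20 <- mean((y - mean(y))^2); mu02 <- mean((x - mean(x))^2)
  mu11 <- mean((y - mean(y)) * (x - mean(x)))
  ev <- eigen(matrix(c(mu20, mu11, mu11, mu02), 2), symmetric = TRUE)$values
  major <- 4 * sqrt(max(ev[1], 0))
  minor <- 4 * sqrt(max(ev[2], 0))
  ecc <- if (major > 0) sqrt(1 - min(ev[2] / ev[1], 1)) else 0
  per <- trace_perimeter(mask) + pi   # half-pixel boundary offset correction
  bbox_a <- (diff(range(y)) + 1) * (diff(range(x)) + 1)
  hull_a <- convex_hull_area(idx)
  data.frame(area = a_px,
             perimeter = per,
             equivalent_diameter = sqrt(4 * a_px / pi),
             major_axis = major,
             minor_axis = minor,
             eccentricity = ecc,
             circularity = circularity_measure(a_px, per),
             extent = a_px / bbox_a,
             solidity = a_px / hull_a)
}

# Rasterised convex-hull area of a pixel set: hull of the pixel centres,
# counted as the number of lattice points inside or on the hull polygon.
convex_hull_area <- function(idx) {
  if (nrow(idx) <= 2) return(nrow(idx))
  hull <- grDevices::chull(idx[, 2], idx[, 1])
  hx <- idx[hull, 2]; hy <- idx[hull, 1]
  g <- expand.grid(y = min(idx[, 1]):max(idx[, 1]),
                   x = min(idx[, 2]):max(idx[, 2]))
  inside <- pracma::inpolygon(g$x, g$y, hx, hy, boundary = TRUE)
  sum(inside)
}

#' Measure shape descriptors for every annotated cell
#'
#' @param annotated output of [generate_annotated_tiles()], or any list of
#'   tiles carrying `annotations` with `mask`, `cell_type` and optionally
#'   planted axes.
#' @return data frame of per-cell descriptors with `tile_id`, `class` and
#'   `cell_type` attached (and planted axis columns when available).
#' @export
measure_cells <- function(annotated) {
  rows <- list()
  for (tl in annotated) {
    for (a in tl$annotations) {
      d <- shape_descriptors(a$mask)
      d$tile_id <- tl$tile_id
      d$class <- tl$class
      d$cell_type <- a$cell_type
      d$cell_id <- a$cell_id
      if (!is.null(a$major)) {
        d$planted_major <- a$major
        d$planted_minor <- a$minor
        d$planted_eccentricity <- eccentricity_axes(a$major, a$minor)
      }
      rows[[length(rows) + 1L]] <- d
    }
  }
  do.call(rbind, rows)
}

#' Select high-confidence tiles by single-tile model score
#'
#' Randomly samples `per_sample` tiles per sample, scores each as a bag of
#' one instance, and keeps only tiles classified with probability above
#' `cutoff` for either class, partitioned by predicted class.
#'
#' @param samples list of samples, each with `sample_id`, `tiles` (list of
#'   tile pixel arrays) and optionally `class` (ground truth, carried
#'   through).
#' @param model a trained [mil_model()].
#' @param cutoff confidence cutoff (default 0.9, strict).
#' @param per_sample tiles sampled per sample (default 10).
#' @param seed seed for the per-sample tile draw.
#' @return list with data frames `hypoxic` and `normoxic` (columns
#'   `sample_id`, `tile_index`, `prob_hypoxic`, `true_class`) and matching
#'   tile lists `hypoxic_tiles`, `normoxic_tiles`. A class with no retained
#'   tiles yields an empty data frame with a warning.
#' @export
select_high_confidence <- function(samples, model, cutoff = 0.9,
                                   per_sample = 10L, seed = 1L) {
  set.seed(seed)
  rows <- list(); tiles_kept <- list()
  for (s in samples) {
    n <- length(s$tiles)
    if (n == 0) next
    take <- sample.int(n, min(per_sample, n))
    for (i in take) {
      pr <- score_tile(model, s$tiles[[i]])
      pred <- if (pr > cutoff) "hypoxic"
              else if (1 - pr > cutoff) "normoxic" else NA_character_
      if (is.na(pred)) next
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s$sample_id, tile_index = i, prob_hypoxic = pr,
        predicted = pred,
        true_class = if (is.null(s$class)) NA_character_ else s$class)
      tiles_kept[[length(rows)]] <- s$tiles[[i]]
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(), tile_index = integer(),
               prob_hypoxic = numeric(), predicted = character(),
               true_class = character())
  out <- list()
  for (cl in c("hypoxic", "normoxic")) {
    sel <- which(df$predicted == cl)
    if (length(sel) == 0)
      warning("no tiles retained at cutoff ", cutoff, " for class ", cl,
              "; downstream comparison will be skipped")
    out[[cl]] <- df[sel, , drop = FALSE]
    out[[paste0(cl, "_tiles")]] <- tiles_kept[sel]
  }
  out
}
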