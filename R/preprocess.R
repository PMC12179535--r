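#' Cut a slide into non-overlapping grid tiles
#'
#' The slide is partitioned into `tile_size` x `tile_size` tiles aligned to
#' the top-left corner; partial tiles at the right and bottom edges are
#' dropped, so the tile count is `floor(H/ts) * floor(W/ts)`.
#'
#' @param slide a slide record from [generate_slides()] or a plain
#'   `(H, W, 3)` array.
#' @param tile_size tile edge in pixels.
#' @return list of tiles, each with `tile_id`, `slide_id`, `origin`
#'   (0-based `(row, col)` pixel offset), and `pixels`. Empty (with a
#'   warning) when the slide is smaller than one tile.
#' @export
tile_slide <- function(slide, tile_size = 256L) {
  img <- if (is.list(slide)) slide$image else slide
  sid <- if (is.list(slide)) slide$sample_id else "slide"
  ts <- as.integer(tile_size)
  h <- dim(img)[1]; w <- dim(img)[2]
  nr <- h %/% ts; nc <- w %/% ts
  if (nr == 0 || nc == 0) {
    warning("slide ", sid, " (", h, "x", w, ") is smaller than one ",
            ts, "x", ts, " tile; no tiles produced")
    return(list())
  }
  out <- vector("list", nr * nc)
  k <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      k <- k + 1L
      r0 <- (i - 1L) * ts; c0 <- (j - 1L) * ts
      out[[k]] <- list(tile_id = sprintf("%s_r%02d_c%02d", sid, i - 1L, j - 1L),
                       slide_id = sid,
                       origin = c(row = r0, col = c0),
                       pixels = img[r0 + seq_len(ts), c0 + seq_len(ts), ,
                                    drop = FALSE])
    }
  }
  out
}

#' Otsu threshold of a grayscale image
#'
#' Exhaustive scan of the 256-bin histogram for the cut maximising the
#' between-class variance, computed on the image's own histogram.
#'
#' @param gray numeric matrix in `[0, 1]`.
#' @param levels number of gray levels (default 256).
#' @return threshold on the `[0, 1]` scale.
#' @export
otsu_threshold <- function(gray, levels = 256L) {
  EBImage::otsu(EBImage::Image(gray), range = c(0, 1), levels = levels)
}

#' Segment tissue from background within one tile
#'
#' The tile is converted to grayscale and thresholded by Otsu's method on
#' its own histogram; stained tissue is darker than the near-white slide
#' background, so pixels strictly below the threshold count as tissue. The
#' tissue fraction is the share of tissue pixels in the tile.
#'
#' @param tile a tile from [tile_slide()] or a plain RGB array / gray matrix.
#' @return list with `mask` (logical matrix), `tissue_fraction`,
#'   `threshold`, and `flagged` (`TRUE` for constant-intensity tiles, whose
#'   fraction is reported as 0).
#' @export
tissue_mask <- function(tile) {
  px <- if (is.list(tile)) tile$pixels else tile
  gray <- rgb_to_gray(px)
  if (diff(range(gray)) < 1e-8) {
    return(list(mask = matrix(FALSE, nrow(gray), ncol(gray)),
                tissue_fraction = 0, threshold = NA_real_, flagged = TRUE))
  }
  thr <- otsu_threshold(gray)
  mask <- gray < thr
  list(mask = mask, tissue_fraction = mean(mask), threshold = thr,
       flagged = FALSE)
}

#' Attach tissue fractions to a list of tiles
#'
#' @param tiles list of tiles from [tile_slide()].
#' @return the same list with `tissue_fraction` (and `flagged`) filled in.
#' @export
compute_tissue_fractions <- function(tiles) {
  lapply(tiles, function(t) {
    tm <- tissue_mask(t)
    t$tissue_fraction <- tm$tissue_fraction
    t$flagged <- tm$flagged
    t
  })
}

#' Keep tiles with more than the minimum tissue content
#'
#' Retains exactly the tiles whose `tissue_fraction` strictly exceeds
#' `min_fraction` (tiles with 50% or less tissue are discarded under the
#' default), preserving input order.
#'
#' @param tiles list of tiles with `tissue_fraction` populated.
#' @param min_fraction threshold in `[0, 1]` (default 0.5).
#' @return the retained sub-list.
#' @export
filter_tiles <- function(tiles, min_fraction = 0.5) {
  fr <- vapply(tiles, function(t) {
    if (is.null(t$tissue_fraction))
      stop("tissue_fraction not populated; run compute_tissue_fractions() first",
           call. = FALSE)
    t$tissue_fraction
  }, 0)
  tiles[fr > min_fraction]
}

#' Training-time tile augmentation
#'
#' Applies, each with independent probability `p`: rotation by a random
#' multiple of 90 degrees, horizontal flip, vertical flip, hue shift
#' (uniform in +/-0.05 fractional hue), gamma correction (uniform in
#' [0.8, 1.25]) and additive Gaussian noise (sd 5 gray levels). The result
#' is clipped to `[0, 1]`; the tile's label is untouched. Draws come from
#' the current RNG state, so a fixed seed reproduces the augmentation.
#'
#' @param tile `(H, W, 3)` array in `[0, 1]` (or a tile record, in which
#'   case `pixels` is augmented in place).
#' @param p probability of applying each augmentation (0 gives the
#'   identity).
#' @return augmented tile of the same form.
#' @export
augment_tile <- function(tile, p = 0.5) {
  rec <- is.list(tile)
  img <- if (rec) tile$pixels else tile
  if (stats::runif(1) < p) {                       # rotation by k * 90
    k <- sample(1:3, 1)
    for (i in seq_len(k)) {
      img <- aperm(img, c(2, 1, 3))                # transpose ...
      img <- img[dim(img)[1]:1, , , drop = FALSE]  # ... then reverse rows
    }
  }
  if (stats::runif(1) < p) img <- img[, dim(img)[2]:1, , drop = FALSE]
  if (stats::runif(1) < p) img <- img[dim(img)[1]:1, , , drop = FALSE]
  if (stats::runif(1) < p) {                       # hue shift
    d <- dim(img)
    hsv <- grDevices::rgb2hsv(rbind(as.vector(img[, , 1]),
                                    as.vector(img[, , 2]),
                                    as.vector(img[, , 3])), maxColorValue = 1)
    rgb <- hsv_to_rgb(hsv[1, ] + stats::runif(1, -0.05, 0.05),
                      hsv[2, ], hsv[3, ])
    img <- array(c(rgb$r, rgb$g, rgb$b), d)
  }
  if (stats::runif(1) < p) {                       # gamma
    img <- clamp01(img)^stats::runif(1, 0.8, 1.25)
  }
  if (stats::runif(1) < p) {                       # additive Gaussian noise
    img <- img + array(stats::rnorm(length(img), 0, 5 / 255), dim(img))
  }
  img <- clamp01(img)
  if (rec) { tile$pixels <- img; tile } else img
}

#' Preprocess one slide end to end
#'
#' Tiles the slide, computes per-tile Otsu tissue fractions and applies the
#' tissue-content filter.
#'
#' @param slide slide record or RGB array.
#' @param tile_size tile edge (pixels).
#' @param min_fraction minimum tissue fraction (strict; default 0.5).
#' @return list with `tiles` (retained tiles), `n_total` and `n_kept`.
#' @export
preprocess_slide <- function(slide, tile_size = 256L, min_fraction = 0.5) {
  tiles <- compute_tissue_fractions(tile_slide(slide, tile_size))
  kept <- filter_tiles(tiles, min_fraction)
  list(tiles = kept, n_total = length(tiles), n_kept = length(kept))
}
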