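#' Configuration for the synthetic histology cohort generator
#'
#' Bundles every knob of the synthetic-data module: seeded generation of
#' H&E-like slide images for two oxygenation classes, a matched expression
#' matrix with a planted hypoxia-signature shift, and annotated tiles with
#' per-cell nucleus masks. All outputs are pure functions of this
#' configuration; regenerating with the same configuration reproduces them
#' bit for bit.
#'
#' Tissue is rendered as smoothed pink noise (an H&E-like hue) whose Gaussian
#' correlation length is set by `texture_granularity`, so one scalar per
#' class controls the co-occurrence texture statistics measured downstream.
#' Brighter stromal gaps (about a quarter of the tissue area) keep the
#' grayscale histogram of pure-tissue tiles bimodal, which is what per-tile
#' Otsu segmentation of stained tissue relies on. Nuclei are rendered as
#' dark ellipses stamped at integer pixel centres; integer centres make
#' rasterised circles exactly 4-fold symmetric, so a planted axis ratio of 1
#' measures a moment eccentricity of exactly 0.
#'
#' @param seed integer; fully determines all generated outputs.
#' @param n_samples_per_class samples per oxygenation class (default 40).
#' @param slide_size_px integer pair `(H, W)` of each slide (default
#'   1024 x 1024).
#' @param tile_size_px tile edge in pixels (default 256).
#' @param background_level background gray value in `[0, 255]`, near white.
#' @param texture_granularity named positive pair: Gaussian blur sigma (px)
#'   of the tissue texture per class.
#' @param nucleus_axes per-class, per-cell-type `(major, minor)` full axis
#'   lengths in pixels: a nested list
#'   `list(normoxic = list(epithelial = , macrophage = ), hypoxic = ...)`.
#' @param axis_jitter fractional s.d. of the per-cell size jitter; one
#'   factor scales both axes, so planted axis ratios are preserved.
#' @param nucleus_density expected nuclei per tissue pixel.
#' @param signature_genes character vector of hypoxia signature gene ids.
#' @param n_background_genes genes with no class effect (default 200).
#' @param signature_shift log-scale expression up-shift of signature genes
#'   in hypoxic samples (default 2.5, i.e. 5 within-class log-sd units).
#' @param intensity_range range of the per-sample hypoxia intensity factor
#'   scaling `signature_shift` in hypoxic samples; the default
#'   `c(0.35, 1)` yields a continuum of positive scores (both strata
#'   populated) while keeping the weak labels reliable. `c(1, 1)` plants
#'   the full shift in every hypoxic sample.
#' @param expression_sdlog within-class log-normal s.d. per gene.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_samples_per_class = 40L,
                         slide_size_px = c(1024L, 1024L),
                         tile_size_px = 256L,
                         background_level = 242,
                         texture_granularity = c(normoxic = 2.5, hypoxic = 1.0),
                         nucleus_axes = list(
                           normoxic = list(epithelial = c(9, 9),
                                           macrophage = c(12, 7)),
                           hypoxic  = list(epithelial = c(16, 8),
                                           macrophage = c(10, 9))),
                         axis_jitter = 0.08,
                         nucleus_density = 0.0012,
                         signature_genes = sprintf("SIG%02d", 1:52),
                         n_background_genes = 200L,
                         signature_shift = 2.5,
                         intensity_range = c(0.35, 1),
                         expression_sdlog = 0.5) {
  slide_size_px <- as.integer(rep(slide_size_px, length.out = 2))
  tile_size_px <- as.integer(tile_size_px)
  if (any(slide_size_px < tile_size_px))
    stop("degenerate configuration: slide (", paste(slide_size_px, collapse = "x"),
         ") is smaller than one tile (", tile_size_px, ")", call. = FALSE)
  if (anyDuplicated(signature_genes))
    stop("duplicate gene identifiers in signature_genes", call. = FALSE)
  stopifnot(n_samples_per_class >= 1, background_level >= 0,
            background_level <= 255, all(texture_granularity > 0),
            n_background_genes >= 0, signature_shift >= 0,
            expression_sdlog > 0, length(intensity_range) == 2,
            intensity_range[1] <= intensity_range[2],
            intensity_range[1] > 0, intensity_range[2] <= 1)
  for (cl in names(nucleus_axes)) {
    for (ty in names(nucleus_axes[[cl]])) {
      ax <- nucleus_axes[[cl]][[ty]]
      if (length(ax) != 2 || ax[1] < ax[2] || ax[2] <= 0)
        stop("nucleus_axes$", cl, "$", ty,
             " must be (major, minor) with major >= minor > 0", call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed),
                 n_samples_per_class = as.integer(n_samples_per_class),
                 slide_size_px = slide_size_px,
                 tile_size_px = tile_size_px,
                 background_level = background_level,
                 texture_granularity = texture_granularity,
                 nucleus_axes = nucleus_axes,
                 axis_jitter = axis_jitter,
                 nucleus_density = nucleus_density,
                 signature_genes = signature_genes,
                 n_background_genes = as.integer(n_background_genes),
                 signature_shift = signature_shift,
                 intensity_range = intensity_range,
                 expression_sdlog = expression_sdlog),
            class = "synth_config")
}

# H&E-like colours (RGB in [0, 1])
.he_tissue  <- c(0.80, 0.55, 0.70)   # eosin-stained cytoplasm/stroma
.he_gap     <- c(0.93, 0.86, 0.91)   # pale stromal gap / lumen
.he_nucleus <- c(0.34, 0.22, 0.47)   # hematoxylin-stained nucleus

# Paint one class's tissue texture into the rectangle (h, w): a pink base
# modulated by a smoothed noise field, pale gaps where a second smoothed
# field exceeds its upper quartile, and dark nuclear ellipses.
render_tissue <- function(h, w, class, cfg, tissue_px = NULL) {
  gran <- cfg$texture_granularity[[class]]
  img <- array(0, c(h, w, 3))
  f1 <- smooth_field(h, w, gran)
  f2 <- smooth_field(h, w, gran * 1.5)
  gap <- f2 > stats::quantile(f2, 0.73)
  for (ch in 1:3) {
    base <- .he_tissue[ch] + 0.10 * f1
    base[gap] <- .he_gap[ch] + 0.04 * f1[gap]
    img[, , ch] <- base
  }
  # nuclei: dark ellipses with class/type-specific axes, integer centres
  n_px <- if (is.null(tissue_px)) h * w else tissue_px
  n_nuc <- round(cfg$nucleus_density * n_px)
  if (n_nuc > 0) {
    types <- sample(c("epithelial", "macrophage"), n_nuc, replace = TRUE,
                    prob = c(0.8, 0.2))
    for (i in seq_len(n_nuc)) {
      ax <- cfg$nucleus_axes[[class]][[types[i]]] / 2   # semi-axes
      sfac <- max(0.5, stats::rnorm(1, 1, cfg$axis_jitter))
      px <- ellipse_pixels(sample.int(h, 1), sample.int(w, 1),
                           ax[1] * sfac, ax[2] * sfac,
                           stats::runif(1, 0, pi), h, w)
      if (nrow(px) == 0) next
      shade <- 1 + stats::rnorm(1, 0, 0.06)
      for (ch in 1:3)
        img[cbind(px, ch)] <- .he_nucleus[ch] * shade + stats::rnorm(nrow(px), 0, 0.015)
    }
  }
  clamp01(img)
}

#' Generate a two-class cohort of synthetic slide images
#'
#' Each slide mixes a near-white background with one elliptical tissue
#' region (about 55% of the slide area, so at least 30% stays background)
#' whose texture correlation length is the class's `texture_granularity`.
#' The oxygenation class is stored as ground truth next to the image; the
#' classifier only ever sees it through the expression-derived weak label.
#'
#' @param cfg a [synth_config()].
#' @return list of slide records: `sample_id`, `image` (`(H, W, 3)` array in
#'   `[0, 1]`), `class` (ground truth), `tissue_mask_true` (logical matrix).
#' @export
generate_slides <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  h <- cfg$slide_size_px[1]; w <- cfg$slide_size_px[2]
  classes <- rep(c("normoxic", "hypoxic"), each = cfg$n_samples_per_class)
  lapply(seq_along(classes), function(i) {
    cl <- classes[i]
    bg <- cfg$background_level / 255
    img <- array(stats::rnorm(h * w * 3, bg, 0.006), c(h, w, 3))
    # elliptical tissue region, jittered centre and axes (~55% of area)
    cy <- h / 2 + stats::runif(1, -0.04, 0.04) * h
    cx <- w / 2 + stats::runif(1, -0.04, 0.04) * w
    ay <- h * stats::runif(1, 0.40, 0.44)
    ax <- w * stats::runif(1, 0.40, 0.44)
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    inside <- ((yy - cy) / ay)^2 + ((xx - cx) / ax)^2 <= 1
    tis <- render_tissue(h, w, cl, cfg, tissue_px = sum(inside))
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[inside] <- tis[, , ch][inside]
      img[, , ch] <- pl
    }
    list(sample_id = sprintf("S%03d", i), image = clamp01(img), class = cl,
         tissue_mask_true = inside)
  })
}

#' Generate a genes x samples expression matrix with a planted hypoxia shift
#'
#' Per-gene log-normal expression; signature genes are shifted upward in
#' hypoxic samples, background genes are exchangeable between classes. Each
#' hypoxic sample draws a hypoxia intensity uniform on `[0.15, 1]` that
#' scales `signature_shift`, so the downstream metagene score forms a
#' continuum over the positive range (populating both the low and the high
#' hypoxia stratum) rather than saturating at the maximum score.
#'
#' @param cfg a [synth_config()].
#' @return list with `matrix` (genes x samples, nonnegative, dimnames set)
#'   and `truth` (data frame `sample_id`, `class`, `intensity`).
#' @export
generate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  genes <- c(cfg$signature_genes,
             if (cfg$n_background_genes > 0)
               sprintf("BG%04d", seq_len(cfg$n_background_genes)))
  if (anyDuplicated(genes))
    stop("duplicate gene identifiers", call. = FALSE)
  set.seed(cfg$seed + 1L)
  n <- 2L * cfg$n_samples_per_class
  classes <- rep(c("normoxic", "hypoxic"), each = cfg$n_samples_per_class)
  sample_ids <- sprintf("S%03d", seq_len(n))
  mu <- stats::runif(length(genes), log(50), log(500))
  lx <- matrix(stats::rnorm(length(genes) * n, mean = mu,
                            sd = cfg$expression_sdlog),
               nrow = length(genes), ncol = n)
  sig_rows <- seq_along(cfg$signature_genes)
  intensity <- ifelse(classes == "hypoxic",
                      stats::runif(n, cfg$intensity_range[1],
                                   cfg$intensity_range[2]), 0)
  lx[sig_rows, ] <- lx[sig_rows, ] +
    rep(cfg$signature_shift * intensity, each = length(sig_rows))
  m <- exp(lx)
  dimnames(m) <- list(genes, sample_ids)
  list(matrix = m,
       truth = data.frame(sample_id = sample_ids, class = classes,
                          intensity = intensity, stringsAsFactors = FALSE))
}

#' Generate annotated tiles with per-cell nucleus masks
#'
#' Emulates externally annotated histology patches: each tile carries the
#' class's tissue texture plus non-overlapping elliptical nuclei whose
#' painted binary masks, cell types and planted axis lengths are returned as
#' annotations. Cells that cannot be placed without overlap after bounded
#' retries are skipped (the tile is emitted with fewer cells).
#'
#' @param cfg a [synth_config()].
#' @param n_tiles_per_class tiles to generate for each class.
#' @param cells_per_tile requested cells per tile.
#' @param cell_types types to draw from (equal probability).
#' @param tile_size tile edge in pixels (defaults to `cfg$tile_size_px`).
#' @return list of tiles: `tile_id`, `class`, `image`, and `annotations` --
#'   a list of `cell_id`, `cell_type`, `mask` (logical matrix), and the
#'   planted `major`, `minor` axis lengths in pixels.
#' @export
generate_annotated_tiles <- function(cfg, n_tiles_per_class = 10L,
                                     cells_per_tile = 8L,
                                     cell_types = c("epithelial", "macrophage"),
                                     tile_size = cfg$tile_size_px) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 2L)
  ts <- as.integer(tile_size)
  classes <- rep(c("normoxic", "hypoxic"), each = n_tiles_per_class)
  out <- vector("list", length(classes))
  for (t in seq_along(classes)) {
    cl <- classes[t]
    img <- render_tissue(ts, ts, cl, cfg, tissue_px = 0)  # no auto nuclei
    occupied <- matrix(FALSE, ts, ts)
    anns <- list()
    cid <- 0L
    n_request <- cells_per_tile
    for (i in seq_len(n_request)) {
      ty <- sample(cell_types, 1)
      ax <- cfg$nucleus_axes[[cl]][[ty]]
      sfac <- max(0.5, stats::rnorm(1, 1, cfg$axis_jitter))
      major <- ax[1] * sfac; minor <- ax[2] * sfac
      placed <- FALSE
      for (try in 1:25) {
        margin <- ceiling(major / 2) + 2L
        if (2L * margin >= ts) break
        cy <- sample(margin:(ts - margin), 1)
        cx <- sample(margin:(ts - margin), 1)
        px <- ellipse_pixels(cy, cx, major / 2, minor / 2,
                             stats::runif(1, 0, pi), ts, ts)
        if (nrow(px) < 8 || any(occupied[px])) next
        occupied[px] <- TRUE
        mask <- matrix(FALSE, ts, ts)
        mask[px] <- TRUE
        shade <- 1 + stats::rnorm(1, 0, 0.06)
        for (ch in 1:3)
          img[cbind(px, ch)] <- .he_nucleus[ch] * shade +
            stats::rnorm(nrow(px), 0, 0.015)
        cid <- cid + 1L
        anns[[cid]] <- list(cell_id = cid, cell_type = ty, mask = mask,
                            major = major, minor = minor)
        placed <- TRUE
        break
      }
      if (!placed && n_request > 0)
        message("tile ", t, ": cell ", i, " could not be placed without ",
                "overlap; emitted with fewer cells")
    }
    out[[t]] <- list(tile_id = sprintf("T%03d", t), class = cl,
                     image = clamp01(img), annotations = anns)
  }
  out
}

#' Write a synthetic cohort bundle to disk
#'
#' Slides as PNG, annotated tiles as PNG with 16-bit labelled TIFF masks and
#' a CSV cell index, expression as TSV (genes in rows), ground truth as CSV,
#' plus a JSON manifest tying everything to the generating configuration.
#'
#' @param dir output directory (created if missing).
#' @param slides output of [generate_slides()] (optional).
#' @param expression output of [generate_expression()] (optional).
#' @param annotated output of [generate_annotated_tiles()] (optional).
#' @param cfg the [synth_config()] used.
#' @return `dir`, invisibly.
#' @export
write_synth_bundle <- function(dir, cfg, slides = NULL, expression = NULL,
                               annotated = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed, files = list())
  if (!is.null(slides)) {
    dir.create(file.path(dir, "slides"), showWarnings = FALSE)
    truth <- data.frame(sample_id = vapply(slides, `[[`, "", "sample_id"),
                        class = vapply(slides, `[[`, "", "class"))
    for (s in slides)
      png::writePNG(s$image, file.path(dir, "slides",
                                       paste0(s$sample_id, ".png")))
    utils::write.csv(truth, file.path(dir, "slide_truth.csv"),
                     row.names = FALSE)
    manifest$files$slides <- file.path("slides",
                                       paste0(truth$sample_id, ".png"))
    manifest$files$slide_truth <- "slide_truth.csv"
  }
  if (!is.null(expression)) {
    m <- expression$matrix
    utils::write.table(data.frame(gene = rownames(m), m, check.names = FALSE),
                       file.path(dir, "expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.csv(expression$truth,
                     file.path(dir, "expression_truth.csv"), row.names = FALSE)
    manifest$files$expression <- "expression.tsv"
  }
  if (!is.null(annotated)) {
    dir.create(file.path(dir, "tiles"), showWarnings = FALSE)
    idx <- list()
    for (tl in annotated) {
      png::writePNG(tl$image, file.path(dir, "tiles",
                                        paste0(tl$tile_id, ".png")))
      lab <- matrix(0L, nrow(tl$image), ncol(tl$image))
      for (a in tl$annotations) lab[a$mask] <- a$cell_id
      tiff::writeTIFF(lab / 65535,
                      file.path(dir, "tiles", paste0(tl$tile_id, "_mask.tif")),
                      bits.per.sample = 16L)
      for (a in tl$annotations) {
        bb <- which(a$mask, arr.ind = TRUE)
        idx[[length(idx) + 1L]] <- data.frame(
          tile_id = tl$tile_id, cell_id = a$cell_id, cell_type = a$cell_type,
          class = tl$class, ymin = min(bb[, 1]), ymax = max(bb[, 1]),
          xmin = min(bb[, 2]), xmax = max(bb[, 2]))
      }
    }
    utils::write.csv(do.call(rbind, idx), file.path(dir, "cell_index.csv"),
                     row.names = FALSE)
    manifest$files$tiles <- "tiles"
    manifest$files$cell_index <- "cell_index.csv"
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read back a labelled mask written by [write_synth_bundle()]
#'
#' @param path a 16-bit labelled TIFF mask file.
#' @return integer label matrix.
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path)
  lab <- round(m * 65535)
  storage.mode(lab) <- "integer"
  lab
}
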