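#' Generate, preprocess and score a synthetic cohort
#'
#' Runs the data-dependent stages shared by every pipeline variant:
#' generates the slides and expression matrix, tiles and tissue-filters
#' every slide, and computes the median-split hypoxia scores. The result
#' can be passed to [run_pipeline()] so repeated runs (different model
#' settings, permutation nulls) reuse it.
#'
#' @param cfg a [synth_config()].
#' @param tile_px tile edge for preprocessing (defaults to
#'   `cfg$tile_size_px`).
#' @param verbose print stage progress.
#' @return list with `samples` (per-sample filtered tile pixel lists with
#'   ground-truth class) and `scores` (from [buffa_score()]).
#' @export
prepare_cohort <- function(cfg, tile_px = cfg$tile_size_px, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  say("generating slides and expression")
  slides <- generate_slides(cfg)
  expr <- generate_expression(cfg)
  scores <- buffa_score(expr$matrix, cfg$signature_genes)
  say("preprocessing ", length(slides), " slides")
  samples <- lapply(slides, function(s) {
    pp <- preprocess_slide(s, tile_size = tile_px)
    list(sample_id = s$sample_id, class = s$class,
         tiles = lapply(pp$tiles, `[[`, "pixels"),
         n_total = pp$n_total, n_kept = pp$n_kept)
  })
  names(samples) <- vapply(samples, `[[`, "", "sample_id")
  list(samples = samples, scores = scores, truth = expr$truth)
}

#' Compare a morphometric feature between hypoxic and normoxic groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test by default, with Welch's
#' t test available behind `test = "welch"`. Significance stars follow the
#' figure-legend convention: `***` for p < 0.001 and `****` for p < 0.0001;
#' no multiple-testing correction is applied (per-feature raw p values).
#'
#' @param values_hypoxic,values_normoxic numeric vectors (NAs dropped).
#' @param feature feature name carried into the output.
#' @param test `"wilcoxon"` (default) or `"welch"`.
#' @param min_n minimum group size; below it the comparison is skipped with
#'   a warning and `NULL` is returned.
#' @return one-row data frame: feature, group sizes, means, medians, test
#'   statistic, p value and stars.
#' @export
compare_groups <- function(values_hypoxic, values_normoxic,
                           feature = "feature",
                           test = c("wilcoxon", "welch"), min_n = 3L) {
  test <- match.arg(test)
  vh <- values_hypoxic[!is.na(values_hypoxic)]
  vn <- values_normoxic[!is.na(values_normoxic)]
  if (length(vh) < min_n || length(vn) < min_n) {
    warning("comparison of '", feature, "' skipped: group sizes ",
            length(vh), " and ", length(vn), " below minimum ", min_n)
    return(NULL)
  }
  ht <- if (test == "wilcoxon")
    stats::wilcox.test(vh, vn, exact = FALSE, correct = TRUE)
  else
    stats::t.test(vh, vn)
  if (is.nan(ht$p.value)) ht$p.value <- NA_real_  # both groups constant
  data.frame(feature = feature,
             n_hypoxic = length(vh), n_normoxic = length(vn),
             mean_hypoxic = mean(vh), mean_normoxic = mean(vn),
             median_hypoxic = stats::median(vh),
             median_normoxic = stats::median(vn),
             statistic = unname(ht$statistic),
             p_value = ht$p.value,
             stars = p_stars(ht$p.value),
             test = test,
             stringsAsFactors = FALSE)
}

#' Significance stars for a p value
#'
#' `****` if p < 0.0001, `***` if p < 0.001, otherwise none -- the
#' convention used in the figure legends this package's comparison tables
#' mirror.
#'
#' @param p p value(s) in `[0, 1]`.
#' @return character vector of stars.
#' @export
p_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 1e-4, "****", ifelse(p < 1e-3, "***", "")))
}

#' Box-plot summary of two groups
#'
#' Quartiles and whiskers at 1.5 IQR for each group, the numbers a box plot
#' of the comparison would draw.
#'
#' @param values_hypoxic,values_normoxic numeric vectors.
#' @param feature feature name.
#' @return data frame with one row per group.
#' @export
boxplot_summary <- function(values_hypoxic, values_normoxic,
                            feature = "feature") {
  one <- function(v, g) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE)
    iqr <- q[3] - q[1]
    lo <- min(v[v >= q[1] - 1.5 * iqr], na.rm = TRUE)
    hi <- max(v[v <= q[3] + 1.5 * iqr], na.rm = TRUE)
    data.frame(feature = feature, group = g, n = sum(!is.na(v)),
               whisker_low = lo, q1 = unname(q[1]), median = unname(q[2]),
               q3 = unname(q[3]), whisker_high = hi)
  }
  rbind(one(values_hypoxic, "hypoxic"), one(values_normoxic, "normoxic"))
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Composes every stage end to end on generated data: synthetic slides and
#' expression; per-tile preprocessing (tiling, Otsu tissue segmentation,
#' tissue-content filter); median-split weak labels and strata; repeated
#' stratified train/test splits; MIL training and per-stratum evaluation;
#' high-confidence single-tile selection with GLCM texture comparison; and
#' cell shape morphometry on annotated tiles. Everything is a deterministic
#' function of `cfg`, `seed` and the model settings.
#'
#' @param cfg a [synth_config()]; its seed drives data generation.
#' @param seed seed for splits, training and tile sampling.
#' @param pooling bag pooling for the model (`"max"` default).
#' @param epochs training epochs per split.
#' @param lr learning rate (default 0.01; desk-scale cohorts see far fewer
#'   SGD steps than a full-size training run, so the pipeline default is
#'   larger than the [mil_model()] default of 0.0003).
#' @param n_splits number of train/test splits (default 3).
#' @param tile_px tile edge used for preprocessing (defaults to
#'   `cfg$tile_size_px`).
#' @param shuffle_labels permute the weak labels before training (the
#'   permutation null; predictions are then evaluated against the permuted
#'   labels).
#' @param n_annotated_per_class annotated tiles per class for the shape
#'   analysis (0 skips it).
#' @param cohort optionally, a precomputed [prepare_cohort()] result, so
#'   repeated pipeline runs (e.g. the permutation null) reuse the generated
#'   and preprocessed slides.
#' @param verbose print stage progress.
#' @return a report bundle: scores, split metrics and their average,
#'   per-split predictions, trained models, texture and shape comparison
#'   tables, and a manifest of seeds and settings.
#' @export
run_pipeline <- function(cfg, seed = 1L, pooling = "max", epochs = 15L,
                         lr = 0.01, n_splits = 3L, tile_px = cfg$tile_size_px,
                         shuffle_labels = FALSE,
                         n_annotated_per_class = 10L, cohort = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  if (is.null(cohort)) cohort <- prepare_cohort(cfg, tile_px, verbose = verbose)
  samples <- cohort$samples
  scores <- cohort$scores
  if (shuffle_labels) {
    set.seed(seed + 7L)
    perm <- sample.int(nrow(scores))
    scores$label <- scores$label[perm]
    scores$stratum <- scores$stratum[perm]
    scores$score <- scores$score[perm]
  }
  splits <- stratify_cohort(scores, n_splits = n_splits, seed = seed)
  lab_of <- stats::setNames(scores$label, scores$sample_id)
  str_of <- stats::setNames(scores$stratum, scores$sample_id)
  split_metrics <- list(); predictions <- list(); models <- list()
  for (k in seq_along(splits)) {
    say("split ", k, ": training")
    tr <- splits[[k]]$train
    te <- splits[[k]]$test
    train_samples <- lapply(tr, function(id) {
      s <- samples[[id]]; s$label <- unname(lab_of[id]); s
    })
    model <- mil_model("small_cnn", pooling, lr = lr, epochs = epochs,
                       seed = seed + k)
    model <- suppressMessages(mil_train(model, train_samples))
    say("split ", k, ": evaluating ", length(te), " test samples")
    prob <- vapply(te, function(id)
      as.numeric(predict_sample(model, samples[[id]]$tiles)), 0)
    pred <- data.frame(sample_id = te, prob = prob,
                       label = unname(lab_of[te]),
                       stratum = unname(str_of[te]),
                       split = k, row.names = NULL)
    predictions[[k]] <- pred
    split_metrics[[k]] <- evaluate_split(pred)
    models[[k]] <- model
  }
  metrics <- evaluate_splits(split_metrics)
  # texture analysis on high-confidence single tiles (last split's model)
  say("texture analysis")
  hc <- suppressWarnings(
    select_high_confidence(samples, models[[n_splits]], cutoff = 0.9,
                           per_sample = 10L, seed = seed + 100L))
  texture <- NULL; texture_tiles <- NULL
  if (nrow(hc$hypoxic) > 0 && nrow(hc$normoxic) > 0) {
    tf <- function(tiles) do.call(rbind, lapply(tiles, function(t)
      texture_features(rgb_to_gray(t))))
    fh <- tf(hc$hypoxic_tiles); fn <- tf(hc$normoxic_tiles)
    texture <- do.call(rbind, lapply(
      c("homogeneity", "energy", "correlation"), function(f)
        compare_groups(fh[[f]][fh$correlation_defined | f != "correlation"],
                       fn[[f]][fn$correlation_defined | f != "correlation"],
                       feature = f)))
    texture_tiles <- list(hypoxic = fh, normoxic = fn)
  }
  # cell shape analysis on annotated tiles
  shape <- NULL; cells <- NULL
  if (n_annotated_per_class > 0) {
    say("shape analysis")
    ann <- generate_annotated_tiles(cfg, n_tiles_per_class = n_annotated_per_class,
                                    cells_per_tile = 8L,
                                    tile_size = max(96L, cfg$tile_size_px))
    cells <- measure_cells(ann)
    shape_rows <- list()
    for (ty in unique(cells$cell_type)) {
      d <- cells[cells$cell_type == ty, ]
      for (f in c("area", "eccentricity", "circularity", "solidity", "extent")) {
        cmp <- compare_groups(d[[f]][d$class == "hypoxic"],
                              d[[f]][d$class == "normoxic"], feature = f)
        if (!is.null(cmp)) {
          cmp$cell_type <- ty
          shape_rows[[length(shape_rows) + 1L]] <- cmp
        }
      }
    }
    shape <- do.call(rbind, shape_rows)
  }
  list(scores = scores, splits = splits, predictions = predictions,
       models = models,
       split_metrics = split_metrics, metrics = metrics,
       texture_comparisons = texture, texture_features = texture_tiles,
       shape_comparisons = shape, cells = cells,
       tiles_per_sample = vapply(samples, `[[`, 0L, "n_kept"),
       manifest = list(seed = as.integer(seed), generator_seed = cfg$seed,
                       pooling = pooling, epochs = as.integer(epochs),
                       lr = lr,
                       n_splits = as.integer(n_splits),
                       tile_px = as.integer(tile_px),
                       shuffle_labels = shuffle_labels,
                       n_samples = 2L * cfg$n_samples_per_class,
                       timestamp = format(Sys.time(), tz = "UTC")))
}
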