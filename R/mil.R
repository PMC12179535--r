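#' Multiple-instance hypoxia classifier
#'
#' Builds the weakly supervised MIL model: a convolutional tile encoder whose
#' feature maps are reduced to a 512-long vector per tile by global average
#' pooling (plus a linear channel projection when the backbone's last block is
#' not 512 channels wide), a bag-level pooling step (element-wise max, or a
#' gated attention mechanism producing a learned convex combination of tile
#' features), and a dense softmax head. Bags of tiles inherit the sample-level
#' weak label derived from the hypoxia signature score, so no tile-level
#' annotation is ever used.
#'
#' The \code{small_cnn} backbone (three conv/ReLU/max-pool blocks, 8/16/32
#' channels) is sized for CPU-scale experiments on synthetic cohorts; the
#' \code{vgg19_like} backbone reproduces the VGG-19 convolutional stack
#' (randomly initialised -- no pretrained weights are bundled).
#'
#' @param backbone `"small_cnn"` or `"vgg19_like"`.
#' @param pooling `"max"` or `"attention"`.
#' @param lr learning rate for plain stochastic gradient descent (default
#'   0.0003).
#' @param epochs number of training epochs (default 100).
#' @param bag_size tiles per training bag (default 20); bags are re-drawn per
#'   sample at every epoch, with replacement when a sample has fewer tiles.
#' @param seed integer seed controlling weight initialisation.
#' @param in_channels input image channels (3 for RGB).
#' @param feature_dim tile feature length after projection (default 512).
#' @param att_dim hidden width of the gated attention scorer.
#' @return an object of class `mil_model` holding the configuration and the
#'   parameter list.
#' @export
mil_model <- function(backbone = c("small_cnn", "vgg19_like"),
                      pooling = c("max", "attention"),
                      lr = 3e-4, epochs = 100L, bag_size = 20L, seed = 1L,
                      in_channels = 3L, feature_dim = 512L, att_dim = 64L) {
  backbone <- match.arg(backbone)
  pooling <- match.arg(pooling)
  stopifnot(lr > 0, bag_size >= 1L, epochs >= 1L)
  channels <- switch(backbone,
    small_cnn  = c(8L, 16L, 32L),
    vgg19_like = c(64L, 64L, 128L, 128L, 256L, 256L, 256L, 256L,
                   512L, 512L, 512L, 512L, 512L, 512L, 512L, 512L))
  # pool after these conv layers (1-based index into `channels`)
  pool_after <- switch(backbone,
    small_cnn  = c(1L, 2L, 3L),
    vgg19_like = c(2L, 4L, 8L, 12L, 16L))
  set.seed(seed)
  params <- list(conv = vector("list", length(channels)))
  cin <- in_channels
  for (k in seq_along(channels)) {
    cout <- channels[k]
    params$conv[[k]] <- list(w = nn_he_init(9 * cin, c(3, 3, cin, cout)),
                             b = rep(0, cout))
    cin <- cout
  }
  params$proj_w <- nn_he_init(cin, c(cin, feature_dim))
  params$proj_b <- rep(0, feature_dim)
  if (pooling == "attention") {
    params$att_v <- nn_he_init(feature_dim, c(feature_dim, att_dim))
    params$att_u <- nn_he_init(feature_dim, c(feature_dim, att_dim))
    params$att_w <- nn_he_init(att_dim, c(att_dim, 1))
  }
  params$cls_w <- nn_he_init(feature_dim, c(feature_dim, 2))
  params$cls_b <- c(0, 0)
  structure(list(backbone = backbone, pooling = pooling, lr = lr,
                 epochs = as.integer(epochs), bag_size = as.integer(bag_size),
                 seed = as.integer(seed), in_channels = as.integer(in_channels),
                 feature_dim = as.integer(feature_dim),
                 att_dim = as.integer(att_dim),
                 channels = channels, pool_after = pool_after,
                 classes = c("normoxic", "hypoxic"),
                 params = params, history = NULL),
            class = "mil_model")
}

#' @export
print.mil_model <- function(x, ...) {
  n_par <- sum(vapply(rapply(x$params, length, how = "unlist"), sum, 0))
  cat("MIL hypoxia classifier\n",
      "  backbone: ", x$backbone, " (", length(x$channels), " conv layers)\n",
      "  pooling:  ", x$pooling, "\n",
      "  bag size: ", x$bag_size, ", lr ", x$lr, ", ", x$epochs, " epochs\n",
      "  parameters: ", format(n_par, big.mark = ","), "\n", sep = "")
  if (!is.null(x$history))
    cat("  trained; final epoch loss ",
        signif(utils::tail(x$history$loss, 1), 4), "\n", sep = "")
  invisible(x)
}

# Stack a list of (H, W, C) tiles into the engine layout (H, W, N, C).
stack_tiles <- function(tiles) {
  if (is.array(tiles) && length(dim(tiles)) == 4) return(tiles)
  if (is.array(tiles) && length(dim(tiles)) == 3) tiles <- list(tiles)
  d <- dim(tiles[[1]])
  x <- array(0, c(d[1], d[2], length(tiles), d[3]))
  for (i in seq_along(tiles)) x[, , i, ] <- tiles[[i]]
  x
}

check_divisible <- function(model, h, w) {
  div <- 2L^length(model$pool_after)
  if (h %% div != 0 || w %% div != 0)
    stop("tile size ", h, "x", w, " incompatible with the '", model$backbone,
         "' backbone: both dimensions must be divisible by ", div,
         " (one factor of 2 per pooling stage)", call. = FALSE)
}

# Backbone forward: returns GAP output (N x C_last) and, when cache = TRUE,
# the per-layer caches needed for backprop / activation maps.
backbone_forward <- function(model, x, cache = FALSE) {
  check_divisible(model, dim(x)[1], dim(x)[2])
  caches <- if (cache) list() else NULL
  for (k in seq_along(model$channels)) {
    cv <- conv_forward(x, model$params$conv[[k]]$w, model$params$conv[[k]]$b)
    rl <- relu_forward(cv$out)
    x <- rl$out
    step <- list(conv = if (cache) cv$cache, relu = if (cache) rl$cache,
                 pooled = FALSE)
    if (k %in% model$pool_after) {
      mp <- maxpool_forward(x)
      x <- mp$out
      step$pool <- if (cache) mp$cache
      step$pooled <- TRUE
    }
    if (cache) caches[[k]] <- step
  }
  gp <- gap_forward(x)
  list(gap = gp$out, final_maps = x, gap_cache = gp$cache, layer_caches = caches)
}

backbone_backward <- function(model, dgap, fwd) {
  dx <- gap_backward(dgap, fwd$gap_cache)
  grads <- vector("list", length(model$channels))
  for (k in rev(seq_along(model$channels))) {
    step <- fwd$layer_caches[[k]]
    if (step$pooled) dx <- maxpool_backward(dx, step$pool)
    dx <- relu_backward(dx, step$relu)
    cb <- conv_backward(dx, step$conv, need_dx = k > 1L)
    grads[[k]] <- list(dw = cb$dw, db = cb$db)
    dx <- cb$dx
  }
  list(conv = grads, dx = dx)
}

#' Encode the tiles of a bag into 512-long feature vectors
#'
#' Each tile is passed through the convolutional backbone, its feature maps
#' are averaged spatially (global average pooling) and linearly projected to
#' `feature_dim` channels.
#'
#' @param tiles a list of `(H, W, C)` arrays in `[0, 1]`, or a single such
#'   array, or a pre-stacked `(H, W, N, C)` array.
#' @param model a [mil_model()].
#' @return a numeric matrix, one row per tile, `feature_dim` columns.
#' @export
encode_tiles <- function(tiles, model) {
  x <- stack_tiles(tiles)
  bb <- backbone_forward(model, x)
  dense_forward(bb$gap, model$params$proj_w, model$params$proj_b)$out
}

#' Aggregate tile features into one bag-level feature vector
#'
#' Max pooling takes the element-wise maximum over tiles. Attention pooling
#' computes gated attention scores (tanh and sigmoid branches combined, then
#' softmax over tiles) and returns the attention-weighted sum; the weights are
#' nonnegative, sum to one, and are attached as attribute `"attention"`.
#'
#' @param features matrix of tile features (tiles in rows).
#' @param pooling `"max"` or `"attention"`.
#' @param model required for attention pooling (holds the scorer weights).
#' @return numeric vector of length `ncol(features)`.
#' @export
aggregate_features <- function(features, pooling = c("max", "attention"),
                               model = NULL) {
  pooling <- match.arg(pooling)
  if (!is.matrix(features)) features <- matrix(features, nrow = 1)
  if (nrow(features) == 0) stop("cannot aggregate an empty bag", call. = FALSE)
  if (pooling == "max") {
    out <- apply(features, 2, max)
    attr(out, "argmax") <- max.col(t(features), ties.method = "first")
    return(out)
  }
  stopifnot(!is.null(model))
  p <- model$params
  hid <- tanh(features %*% p$att_v)
  gate <- 1 / (1 + exp(-(features %*% p$att_u)))
  s <- (hid * gate) %*% p$att_w
  a <- softmax_vec(as.vector(s))
  out <- as.vector(crossprod(features, a))
  attr(out, "attention") <- a
  attr(out, "att_cache") <- list(hid = hid, gate = gate, features = features)
  out
}

#' Classify a bag feature vector
#'
#' The dense head of the model: the pooled bag feature is rectified, passed
#' through a dense layer, and turned into two class probabilities by a
#' softmax. (Rectifying the pooled feature rather than the logits keeps the
#' softmax input affine, so gradient descent has no flat region; a
#' rectifier after the dense layer can clamp both logits at zero, where the
#' head emits (0.5, 0.5) with zero gradient and training stalls -- see the
#' methods vignette.) Exposed separately so the forward pass can be checked
#' by hand.
#'
#' @param bag_feature numeric vector (length `feature_dim`).
#' @param w dense weights (`feature_dim` x 2).
#' @param b dense bias (length 2).
#' @return numeric vector of two probabilities (normoxic, hypoxic), summing
#'   to 1.
#' @export
classify_bag <- function(bag_feature, w, b) {
  z <- as.vector(pmax(bag_feature, 0) %*% w) + b
  p <- softmax_vec(z)
  names(p) <- c("normoxic", "hypoxic")
  p
}

# Full forward pass over one bag. y (1 = normoxic, 2 = hypoxic) may be NA for
# inference. Returns probabilities plus every cache needed for one SGD step.
mil_forward <- function(model, x, cache = FALSE) {
  bb <- backbone_forward(model, x, cache = cache)
  pj <- dense_forward(bb$gap, model$params$proj_w, model$params$proj_b)
  feats <- pj$out
  bagfeat <- aggregate_features(feats, model$pooling, model)
  bagrelu <- pmax(as.vector(bagfeat), 0)
  z <- as.vector(bagrelu %*% model$params$cls_w) + model$params$cls_b
  p <- softmax_vec(z)
  names(p) <- model$classes
  list(p = p, z = z, bagrelu = bagrelu, bagfeat = bagfeat, feats = feats,
       attention = attr(bagfeat, "attention"),
       bb = if (cache) bb, proj_cache = if (cache) pj$cache)
}

# Gradients of the cross-entropy loss wrt all parameters for one bag.
mil_backward <- function(model, fwd, y) {
  p <- fwd$p
  dz <- p; dz[y] <- dz[y] - 1
  g <- list(cls_w = outer(fwd$bagrelu, dz), cls_b = dz)
  dbag <- as.vector(model$params$cls_w %*% dz) * (as.vector(fwd$bagfeat) > 0)
  feats <- fwd$feats
  n <- nrow(feats)
  if (model$pooling == "max") {
    dfeats <- matrix(0, n, ncol(feats))
    am <- attr(fwd$bagfeat, "argmax")
    dfeats[cbind(am, seq_along(am))] <- dbag
  } else {
    ac <- attr(fwd$bagfeat, "att_cache")
    a <- as.vector(attr(fwd$bagfeat, "attention"))
    p_ <- model$params
    dfeats <- a %o% dbag
    da <- as.vector(feats %*% dbag)
    ds <- a * (da - sum(a * da))
    hg <- ac$hid * ac$gate
    g$att_w <- crossprod(hg, ds)
    dhg <- ds %o% as.vector(p_$att_w)
    dpre_h <- dhg * ac$gate * (1 - ac$hid^2)
    dpre_g <- dhg * ac$hid * ac$gate * (1 - ac$gate)
    g$att_v <- crossprod(feats, dpre_h)
    g$att_u <- crossprod(feats, dpre_g)
    dfeats <- dfeats + tcrossprod(dpre_h, p_$att_v) + tcrossprod(dpre_g, p_$att_u)
  }
  pb <- dense_backward(dfeats, fwd$proj_cache)
  g$proj_w <- pb$dw; g$proj_b <- pb$db
  bbg <- backbone_backward(model, pb$dx, fwd$bb)
  g$conv <- bbg$conv
  g
}

sgd_update <- function(model, g) {
  lr <- model$lr
  p <- model$params
  for (k in seq_along(p$conv)) {
    p$conv[[k]]$w <- p$conv[[k]]$w - lr * g$conv[[k]]$dw
    p$conv[[k]]$b <- p$conv[[k]]$b - lr * g$conv[[k]]$db
  }
  for (nm in c("proj_w", "proj_b", "att_v", "att_u", "att_w",
               "cls_w", "cls_b")) {
    if (!is.null(g[[nm]])) p[[nm]] <- p[[nm]] - lr * g[[nm]]
  }
  model$params <- p
  model
}

#' Train the MIL model on weakly labelled samples
#'
#' One SGD step per bag, cross-entropy loss. At every epoch a fresh bag of
#' `bag_size` tiles is drawn per sample (with replacement when the sample has
#' fewer tiles than the bag size) and the sample order is reshuffled, so the
#' model never sees a fixed tile composition.
#'
#' @param model a [mil_model()].
#' @param samples list of samples; each is a list with `tiles` (list of
#'   `(H, W, C)` arrays) and `label` (`"hypoxic"` or `"normoxic"`).
#' @param epochs overrides the model's configured epoch count when given.
#' @param augment_fn optional function applied to every tile as it is drawn
#'   into a bag (e.g. [augment_tile()]), for on-the-fly training
#'   augmentation; `NULL` disables it.
#' @param verbose print the epoch loss every few epochs.
#' @return the trained model, with `history` (data frame of per-epoch mean
#'   loss) attached.
#' @export
mil_train <- function(model, samples, epochs = NULL, augment_fn = NULL,
                      verbose = FALSE) {
  epochs <- if (is.null(epochs)) model$epochs else as.integer(epochs)
  labs <- vapply(samples, function(s) s$label, "")
  if (length(unique(labs)) < 2 || min(table(labs)) < 2)
    stop("training requires at least 2 samples of each class", call. = FALSE)
  y <- match(labs, model$classes)
  if (anyNA(y)) stop("labels must be 'normoxic' or 'hypoxic'", call. = FALSE)
  n_short <- sum(vapply(samples, function(s) length(s$tiles), 0L) < model$bag_size)
  if (n_short > 0)
    message(n_short, " sample(s) have fewer than ", model$bag_size,
            " tiles; bags for these are drawn with replacement")
  set.seed(model$seed)
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(samples))
    ep_loss <- 0
    for (i in ord) {
      tl <- samples[[i]]$tiles
      idx <- sample.int(length(tl), model$bag_size,
                        replace = length(tl) < model$bag_size)
      bag <- tl[idx]
      if (!is.null(augment_fn)) bag <- lapply(bag, augment_fn)
      x <- stack_tiles(bag)
      fwd <- mil_forward(model, x, cache = TRUE)
      loss <- -log(fwd$p[y[i]] + 1e-12)
      if (!is.finite(loss))
        stop("non-finite loss at epoch ", ep, ", sample ",
             samples[[i]]$sample_id, "; probabilities: ",
             paste(signif(fwd$p, 4), collapse = ", "), call. = FALSE)
      g <- mil_backward(model, fwd, y[i])
      model <- sgd_update(model, g)
      ep_loss <- ep_loss + loss
    }
    losses[ep] <- ep_loss / length(samples)
    if (verbose && (ep %% 5 == 0 || ep == 1))
      message("epoch ", ep, "  loss ", signif(losses[ep], 4))
  }
  model$history <- data.frame(epoch = seq_len(epochs), loss = losses)
  model
}

#' Predict the hypoxia probability of one sample
#'
#' All (tissue-filtered) tiles of the sample form a single inference bag.
#'
#' @param model a trained [mil_model()].
#' @param tiles list of `(H, W, C)` tile arrays; may be the `pixels` of
#'   [tile_slide()] output.
#' @return the probability that the sample is hypoxic; `NA` (with a warning)
#'   when no tiles are left after filtering. Attention weights, when the
#'   model uses attention pooling, are attached as attribute `"attention"`.
#' @export
predict_sample <- function(model, tiles) {
  if (length(tiles) == 0) {
    warning("sample has no tiles after filtering; marked unevaluable")
    return(NA_real_)
  }
  fwd <- mil_forward(model, stack_tiles(tiles))
  out <- unname(fwd$p["hypoxic"])
  if (!is.null(fwd$attention)) attr(out, "attention") <- as.vector(fwd$attention)
  out
}

#' Score a single tile as a bag of one instance
#'
#' @param model a trained [mil_model()].
#' @param tile one `(H, W, C)` array.
#' @return probability that the tile is hypoxic.
#' @export
score_tile <- function(model, tile) {
  as.numeric(predict_sample(model, list(tile)))
}

#' Class activation map for one tile
#'
#' Gradient-weighted activation mapping on the last convolutional block: the
#' gradient of the chosen class score with respect to the final feature maps
#' is averaged spatially to weight each map, the weighted sum is rectified,
#' normalised to `[0, 1]` and upsampled (nearest neighbour) to the tile size.
#'
#' @param model a trained [mil_model()].
#' @param tile one `(H, W, C)` array.
#' @param class `"hypoxic"` or `"normoxic"`.
#' @return an `(H, W)` matrix in `[0, 1]`.
#' @export
activation_map <- function(model, tile, class = "hypoxic") {
  cls <- match(match.arg(class, model$classes), model$classes)
  x <- stack_tiles(list(tile))
  fwd <- mil_forward(model, x, cache = TRUE)
  # gradient of the class logit wrt the tile feature; for a bag of one
  # instance both poolings pass the gradient straight through
  dz <- c(0, 0); dz[cls] <- 1
  dbag <- as.vector(model$params$cls_w %*% dz) * (as.vector(fwd$bagfeat) > 0)
  dfeats <- matrix(dbag, nrow = 1)
  dgap <- dense_backward(dfeats, fwd$proj_cache)$dx
  maps <- fwd$bb$final_maps            # (h, w, 1, C)
  d <- dim(maps)
  alpha <- as.vector(dgap)             # one weight per channel
  cam <- matrix(0, d[1], d[2])
  for (c in seq_len(d[4])) cam <- cam + alpha[c] * maps[, , 1, c]
  cam <- pmax(cam, 0)
  rng <- range(cam)
  if (diff(rng) > 1e-12) cam <- (cam - rng[1]) / diff(rng) else cam[] <- 0
  # nearest-neighbour upsampling to the tile size
  th <- dim(tile)[1]; tw <- dim(tile)[2]
  cam[ceiling(seq_len(th) / (th / d[1])), ceiling(seq_len(tw) / (tw / d[2]))]
}

#' Per-stratum classification metrics for one test split
#'
#' AUROC (trapezoidal / rank convention), accuracy, precision and recall for
#' hypoxic-vs-normoxic, computed for the whole test set and restricted to the
#' low (0 < score <= 20) and high (score > 20) hypoxia strata, each versus
#' all normoxic test samples.
#'
#' @param pred data frame with columns `sample_id`, `prob` (predicted
#'   hypoxia probability), `label` (`"hypoxic"`/`"normoxic"`) and `stratum`
#'   (`"normoxic"`/`"low"`/`"high"`).
#' @param threshold probability cut for the binary metrics (default 0.5).
#' @return data frame with one row per stratum subset (`all`, `low`, `high`)
#'   and columns `auroc`, `accuracy`, `precision`, `recall`, `n_pos`, `n_neg`.
#'   Metrics that are undefined for a subset (one class absent) are `NA`.
#' @export
evaluate_split <- function(pred, threshold = 0.5) {
  pred <- pred[!is.na(pred$prob), , drop = FALSE]
  subset_metrics <- function(d) {
    pos <- d$label == "hypoxic"
    if (sum(pos) == 0 || sum(!pos) == 0)
      return(data.frame(auroc = NA_real_, accuracy = NA_real_,
                        precision = NA_real_, recall = NA_real_,
                        n_pos = sum(pos), n_neg = sum(!pos)))
    au <- as.numeric(pROC::auc(pROC::roc(
      response = factor(d$label, levels = c("normoxic", "hypoxic")),
      predictor = d$prob, quiet = TRUE, direction = "<")))
    hat <- d$prob > threshold
    tp <- sum(hat & pos); fp <- sum(hat & !pos); fn <- sum(!hat & pos)
    data.frame(auroc = au,
               accuracy = mean(hat == pos),
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = tp / (tp + fn),
               n_pos = sum(pos), n_neg = sum(!pos))
  }
  norm <- pred[pred$stratum == "normoxic", , drop = FALSE]
  out <- rbind(
    cbind(subset = "all", subset_metrics(pred)),
    cbind(subset = "low",
          subset_metrics(rbind(pred[pred$stratum == "low", , drop = FALSE], norm))),
    cbind(subset = "high",
          subset_metrics(rbind(pred[pred$stratum == "high", , drop = FALSE], norm))))
  rownames(out) <- NULL
  out
}

#' Average split metrics over repeated train/test splits
#'
#' @param split_metrics list of data frames from [evaluate_split()].
#' @return data frame of per-subset means and standard deviations; splits in
#'   which a metric was undefined are excluded from that metric's average.
#' @export
evaluate_splits <- function(split_metrics) {
  all <- do.call(rbind, split_metrics)
  agg <- function(sub) {
    d <- all[all$subset == sub, , drop = FALSE]
    data.frame(subset = sub,
               auroc_mean = mean(d$auroc, na.rm = TRUE),
               auroc_sd = stats::sd(d$auroc, na.rm = TRUE),
               accuracy_mean = mean(d$accuracy, na.rm = TRUE),
               precision_mean = mean(d$precision, na.rm = TRUE),
               recall_mean = mean(d$recall, na.rm = TRUE),
               n_splits_used = sum(!is.na(d$auroc)))
  }
  out <- do.call(rbind, lapply(c("all", "low", "high"), agg))
  rownames(out) <- NULL
  out
}
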