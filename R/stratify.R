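#' Median-split hypoxia metagene score and weak labels
#'
#' For each sample, every signature gene contributes +1 when the sample's
#' expression of that gene is strictly above the cohort median for the gene
#' and -1 otherwise (ties at the median count as not above). The summed
#' score therefore lies in `[-G, +G]` for `G` signature genes and has the
#' parity of `G`. Samples with a positive score are labelled hypoxic, the
#' rest normoxic; scores above 20 form the high-hypoxia stratum and scores
#' in (0, 20] the low stratum, mirroring the strata used for per-stratum
#' evaluation.
#'
#' @param expr numeric genes x samples matrix with gene ids as row names and
#'   sample ids as column names.
#' @param signature character vector of signature gene ids; all must be
#'   present in `expr`.
#' @return data frame with `sample_id`, `score`, `label`
#'   (`"hypoxic"`/`"normoxic"`) and `stratum` (`"normoxic"`/`"low"`/`"high"`).
#' @export
buffa_score <- function(expr, signature) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  if (ncol(expr) < 2)
    stop("at least 2 samples are required: the cohort median split is ",
         "undefined for a single sample", call. = FALSE)
  missing <- setdiff(signature, rownames(expr))
  if (length(missing) > 0)
    stop("signature gene(s) missing from the expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  sub <- expr[signature, , drop = FALSE]
  med <- apply(sub, 1, stats::median)
  score <- colSums(ifelse(sub > med, 1L, -1L))
  data.frame(sample_id = colnames(expr),
             score = as.integer(score),
             label = ifelse(score > 0, "hypoxic", "normoxic"),
             stratum = ifelse(score > 20, "high",
                              ifelse(score > 0, "low", "normoxic")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Repeated stratified train/test splits of a scored cohort
#'
#' Draws `n_splits` independent random splits of the cohort into training
#' (`train_frac`, default 3/4) and test sets, stratified by the binary weak
#' label so that both classes appear on both sides of every split. Per-label
#' training counts are apportioned by largest remainder so the overall
#' training size is exactly `round(train_frac * n)`.
#'
#' @param scores data frame from [buffa_score()].
#' @param n_splits number of independent splits (default 3).
#' @param train_frac training fraction (default 0.75).
#' @param seed integer seed; the same seed reproduces the same splits.
#' @param max_retries redraws allowed before giving up when a class ends up
#'   absent from either side.
#' @return list of length `n_splits`; each element has `train` and `test`
#'   character vectors of sample ids.
#' @export
stratify_cohort <- function(scores, n_splits = 3L, train_frac = 0.75,
                            seed = 1L, max_retries = 20L) {
  stopifnot(nrow(scores) >= 8)
  set.seed(seed)
  labs <- split(scores$sample_id, scores$label)
  n <- nrow(scores)
  n_train_total <- round(train_frac * n)
  # largest-remainder apportionment of training slots across labels
  raw <- vapply(labs, length, 0L) * train_frac
  base <- floor(raw)
  rem <- n_train_total - sum(base)
  extra <- order(raw - base, decreasing = TRUE)[seq_len(max(0, rem))]
  n_train <- base
  n_train[extra] <- n_train[extra] + 1L
  lapply(seq_len(n_splits), function(s) {
    for (try in seq_len(max_retries)) {
      train <- unlist(lapply(seq_along(labs), function(l) {
        sample(labs[[l]], n_train[l])
      }), use.names = FALSE)
      test <- setdiff(scores$sample_id, train)
      lab_of <- scores$label[match(c(train, test), scores$sample_id)]
      ok <- length(unique(scores$label[match(train, scores$sample_id)])) ==
              length(labs) &&
            length(unique(scores$label[match(test, scores$sample_id)])) ==
              length(labs)
      if (ok) return(list(train = sort(train), test = sort(test)))
    }
    stop("could not draw a split with both classes on both sides after ",
         max_retries, " retries", call. = FALSE)
  })
}
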