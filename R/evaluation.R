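#' Precision, recall and precision-weighted F-beta
#'
#' `P = tp/(tp+fp)`, `R = tp/(tp+fn)` (0 on empty denominators), and
#' `F_beta = (1 + beta^2) P R / (beta^2 R + P)`. Note the convention:
#' beta > 1 up-weights *precision*, so the default beta = 2 favors
#' accurate models over high-recall ones. This is the mirror image of
#' the recall-weighted F-beta common elsewhere; see the methods
#' vignette.
#'
#' @param tp,fp,fn Non-negative counts.
#' @param beta Precision weight (default 2).
#' @return List `precision`, `recall`, `f_beta`.
#' @export
precision_recall_fbeta <- function(tp, fp, fn, beta = 2) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, beta > 0)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) (1 + beta^2) * p * r / (beta^2 * r + p) else 0
  list(precision = p, recall = r, f_beta = f)
}

#' Upper-tail hypergeometric enrichment of predictions in new annotations
#'
#' `P(X >= overlap)` drawing `pred_set_size` genes from a universe with
#' `new_annot_size` marked successes.
#'
#' @param pred_genes Predicted gene IDs.
#' @param new_annot_genes Newly annotated gene IDs.
#' @param universe All testable gene IDs (both sets are intersected with
#'   it).
#' @param term Optional term label carried into the result.
#' @return One-row data frame `term`, `overlap`, `pred_set_size`,
#'   `new_annot_size`, `universe_size`, `p_value`.
#' @export
hypergeom_enrichment <- function(pred_genes, new_annot_genes, universe,
                                 term = NA_character_) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  pred <- intersect(unique(pred_genes), universe)
  new_ann <- intersect(unique(new_annot_genes), universe)
  ov <- length(intersect(pred, new_ann))
  p <- stats::phyper(ov - 1, length(new_ann),
                     length(universe) - length(new_ann),
                     length(pred), lower.tail = FALSE)
  data.frame(term = term, overlap = ov,
             pred_set_size = length(pred),
             new_annot_size = length(new_ann),
             universe_size = length(universe),
             p_value = p, stringsAsFactors = FALSE)
}

stratified_folds <- function(ids, k) {
  # random fold labels balanced within the class; caller seeds the RNG
  sample(rep(seq_len(k), length.out = length(ids)))
}

dls_predict_genes <- function(dataset, training, params, genes,
                              bandwidth_spec, fnd = FALSE, max_iter = 3L) {
  if (fnd) {
    training <- run_fnd(dataset, training, params,
                        max_iter = max_iter,
                        bandwidth_spec = bandwidth_spec)$training
  }
  model <- dls_train(dataset, training, params)
  if (!length(valid_signatures(model))) return(character())
  model <- fit_densities(model, dataset, bandwidth_spec)
  pred <- predict_all(model, dataset, params$conf_threshold, genes = genes)
  unique(pred$gene)
}

#' Guilt-by-association co-expression-network baseline
#'
#' Links gene pairs whose |cosine| over *all* features reaches
#' `corr_threshold`, then flags a gene as positive when its neighborhood
#' is enriched for training positives (upper-tail hypergeometric,
#' Bonferroni-corrected over the number of tested genes, corrected
#' p <= `p_threshold`).
#'
#' @param dataset An [expression_dataset()].
#' @param training A [training_set()].
#' @param corr_threshold Correlation threshold in (0, 1); default 0.6.
#' @param p_threshold Corrected p-value threshold in (0, 1); default 0.1.
#' @param genes Genes to test (default: all genes in the dataset).
#' @return Character vector of predicted-positive gene IDs.
#' @export
cn_baseline_predict <- function(dataset, training, corr_threshold = 0.6,
                                p_threshold = 0.1, genes = NULL) {
  stopifnot(corr_threshold > 0, corr_threshold < 1,
            p_threshold > 0, p_threshold < 1)
  if (is.null(genes)) genes <- dataset$gene_ids
  X <- dataset$X_LR
  nrm <- sqrt(rowSums(X^2))
  pos <- training$positives
  n_tests <- length(genes)
  predicted <- character()
  for (g in genes) {
    co <- abs(as.vector(X %*% X[g, ]))
    denom <- nrm * nrm[g]
    co <- ifelse(denom > 0, co / denom, 0)
    names(co) <- rownames(X)
    nb <- setdiff(names(co)[co >= corr_threshold], g)
    if (!length(nb)) next
    others <- setdiff(rownames(X), g)
    n_pos <- sum(others %in% pos)
    ov <- sum(nb %in% pos)
    p <- stats::phyper(ov - 1, n_pos, length(others) - n_pos, length(nb),
                       lower.tail = FALSE)
    if (min(1, p * n_tests) <= p_threshold)
      predicted <- c(predicted, g)
  }
  predicted
}

#' Repeated stratified k-fold cross-validation
#'
#' Positives and negatives are partitioned into k folds separately; per
#' fold the remaining folds train the chosen method and the held-out
#' genes are scored, with tp/fp/fn accumulated over folds. Metrics are
#' computed per repeat (each repeat uses an independent seeded
#' partition) and averaged.
#'
#' @param dataset An [expression_dataset()].
#' @param training A [training_set()].
#' @param method One of `"dls"`, `"fnd-dls"`, `"cn"`.
#' @param k Number of folds (>= 2; both classes must have >= k members).
#' @param repeats Number of independent partitions.
#' @param seed Integer seed.
#' @param params A [dls_params()] (DLS methods).
#' @param bandwidth_spec Passed to [fit_densities()].
#' @param beta F-beta weight.
#' @param corr_threshold,p_threshold CN-baseline thresholds.
#' @return An `EvalReport`: list with `per_repeat` (data frame of counts
#'   and metrics), averaged `precision`, `recall`, `f_beta`, and the
#'   run's settings.
#' @export
cross_validate <- function(dataset, training, method = "dls", k = 10L,
                           repeats = 3L, seed = 1L,
                           params = dls_params(),
                           bandwidth_spec = "silverman", beta = 2,
                           corr_threshold = 0.6, p_threshold = 0.1) {
  method <- match.arg(method, c("dls", "fnd-dls", "cn"))
  training <- attach_training(training, dataset)
  if (length(training$positives) < k || length(training$negatives) < k)
    stop("a class has fewer members than k = ", k,
         "; use a smaller k")
  rows <- list()
  for (rep_i in seq_len(repeats)) {
    set.seed(seed + rep_i - 1L)
    fp_pos <- stratified_folds(training$positives, k)
    fp_neg <- stratified_folds(training$negatives, k)
    tp <- fp <- fn <- 0L
    for (fold in seq_len(k)) {
      test_pos <- training$positives[fp_pos == fold]
      test_neg <- training$negatives[fp_neg == fold]
      tr <- training_set(training$positives[fp_pos != fold],
                         training$negatives[fp_neg != fold],
                         training$process_term)
      held <- c(test_pos, test_neg)
      hit <- if (method == "cn")
        cn_baseline_predict(dataset, tr, corr_threshold, p_threshold,
                            genes = held)
      else
        dls_predict_genes(dataset, tr, params, held, bandwidth_spec,
                          fnd = (method == "fnd-dls"))
      tp <- tp + sum(test_pos %in% hit)
      fp <- fp + sum(test_neg %in% hit)
      fn <- fn + sum(!test_pos %in% hit)
    }
    m <- precision_recall_fbeta(tp, fp, fn, beta)
    rows[[rep_i]] <- data.frame(repeat_i = rep_i, tp = tp, fp = fp,
                                fn = fn, precision = m$precision,
                                recall = m$recall, f_beta = m$f_beta)
  }
  per_repeat <- do.call(rbind, rows)
  structure(list(per_repeat = per_repeat,
                 precision = mean(per_repeat$precision),
                 recall = mean(per_repeat$recall),
                 f_beta = mean(per_repeat$f_beta),
                 method = method, folds = as.integer(k),
                 repeats = as.integer(repeats), beta = beta,
                 seed = as.integer(seed)),
            class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf(
    "EvalReport [%s, %d-fold x %d]: P = %.3f, R = %.3f, F%g = %.3f\n",
    x$method, x$folds, x$repeats, x$precision, x$recall, x$beta,
    x$f_beta))
  invisible(x)
}

#' Summarize which runs are "useful" and pairwise wins
#'
#' A run is useful when its precision exceeds `precision_floor`
#' (default 1/3: at least one of three predictions correct). The wins
#' matrix counts, for each ordered method pair, the runs where the row
#' method's F-beta strictly exceeds the column method's.
#'
#' @param reports Data frame with columns `method`, `run`, `precision`,
#'   `f_beta` (one row per method x run).
#' @param precision_floor Usefulness threshold in (0, 1).
#' @return List `useful` (named count per method) and `wins` (matrix).
#' @export
usefulness_summary <- function(reports, precision_floor = 1/3) {
  stopifnot(precision_floor > 0, precision_floor < 1)
  methods <- unique(reports$method)
  useful <- vapply(methods, function(m)
    sum(reports$precision[reports$method == m] > precision_floor), 0L)
  wins <- matrix(0L, length(methods), length(methods),
                 dimnames = list(methods, methods))
  for (a in methods) for (b in setdiff(methods, a)) {
    fa <- reports$f_beta[reports$method == a][order(
      reports$run[reports$method == a])]
    fb <- reports$f_beta[reports$method == b][order(
      reports$run[reports$method == b])]
    n <- min(length(fa), length(fb))
    wins[a, b] <- sum(fa[seq_len(n)] > fb[seq_len(n)])
  }
  list(useful = useful, wins = wins)
}
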