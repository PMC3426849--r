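#' Gaussian kernel density estimate at a point
#'
#' `(1 / (n sigma sqrt(2 pi))) * sum_i exp(-(x - x_i)^2 / (2 sigma^2))`,
#' floored at 1e-12 so likelihood ratios never hit 0/0.
#'
#' @param samples Numeric vector of at least two observations.
#' @param bandwidth Kernel bandwidth sigma > 0.
#' @param x Evaluation point(s); vectorized.
#' @return Density value(s), >= 1e-12.
#' @export
kde_density <- function(samples, bandwidth, x) {
  if (length(samples) < 2)
    stop("need >= 2 samples for a density estimate; ",
         "consider a fixed bandwidth on pooled classes")
  stopifnot(bandwidth > 0)
  n <- length(samples)
  vapply(x, function(xi)
    max(1e-12, sum(exp(-(xi - samples)^2 / (2 * bandwidth^2))) /
          (n * bandwidth * sqrt(2 * pi))), 0)
}

#' Silverman's rule-of-thumb bandwidth
#'
#' `1.06 * sd(x) * n^(-1/5)`, with a fixed floor of `min_bw` for
#' degenerate (all-identical) samples.
#'
#' @param samples Numeric vector.
#' @param min_bw Lower bound on the returned bandwidth.
#' @return A bandwidth > 0.
#' @export
silverman_bw <- function(samples, min_bw = 0.01) {
  s <- stats::sd(samples)
  if (!is.finite(s) || s == 0) {
    message("degenerate samples; bandwidth floored at ", min_bw)
    return(min_bw)
  }
  max(min_bw, 1.06 * s * length(samples)^(-1/5))
}

#' Posterior probability of class membership from a co-expression level
#'
#' Bayes rule with class-conditional kernel densities:
#' `P(h|e) = pi f+(L) / (pi f+(L) + (1 - pi) f-(L))` where `pi` is the
#' positive prior and `f+`, `f-` the KDEs of co-expression against this
#' signature among training positives and negatives.
#'
#' @param L Co-expression level(s) in [0, 1].
#' @param density_model A per-signature density model as built by
#'   [fit_densities()]: list with `pos_samples`, `neg_samples`, `bw_pos`,
#'   `bw_neg`, `prior_pos`.
#' @return Posterior value(s) in (0, 1).
#' @export
posterior <- function(L, density_model) {
  dm <- density_model
  fp <- kde_density(dm$pos_samples, dm$bw_pos, L)
  fn <- kde_density(dm$neg_samples, dm$bw_neg, L)
  pi0 <- dm$prior_pos
  pi0 * fp / (pi0 * fp + (1 - pi0) * fn)
}

signature_coexpr <- function(sig, genes, dataset) {
  abs_cosine_rows(dataset$X_LR[sig$gene, ],
                  dataset$X_LR[genes, , drop = FALSE], sig$features)
}

#' Fit per-signature class-conditional co-expression densities
#'
#' For every valid signature, the co-expression of each training positive
#' (excluding the signature's own gene) and each training negative
#' against the signature is collected, and Gaussian KDEs are fitted per
#' class. The positive prior is the class proportion in the training set.
#'
#' @param model A `SignatureModel` from [dls_train()].
#' @param dataset An [expression_dataset()].
#' @param bandwidth_spec Either a single number (fixed sigma for all
#'   models), the string `"silverman"` (per-sample-set rule of thumb, the
#'   default), or a list `list(method = "grid", grid = c(...))` selecting
#'   the sigma maximizing resubstitution F-beta on the training genes.
#' @param beta F-beta weight used by the grid search.
#' @return The model with its `densities` slot filled.
#' @export
fit_densities <- function(model, dataset, bandwidth_spec = "silverman",
                          beta = 2) {
  vs <- valid_signatures(model)
  if (!length(vs)) {
    warning("no valid signatures; nothing to fit")
    model$densities <- list()
    return(model)
  }
  training <- model$training
  build <- function(bw_fun) {
    lapply(vs, function(sig) {
      pos <- setdiff(training$positives, sig$gene)
      ps <- signature_coexpr(sig, pos, dataset)
      ns <- signature_coexpr(sig, training$negatives, dataset)
      list(signature_gene = sig$gene,
           pos_samples = ps, neg_samples = ns,
           bw_pos = bw_fun(ps), bw_neg = bw_fun(ns),
           prior_pos = model$prior_pos)
    })
  }
  if (is.numeric(bandwidth_spec)) {
    stopifnot(bandwidth_spec > 0)
    model$densities <- build(function(s) bandwidth_spec)
  } else if (identical(bandwidth_spec, "silverman")) {
    model$densities <- build(silverman_bw)
  } else if (is.list(bandwidth_spec) &&
             identical(bandwidth_spec$method, "grid")) {
    grid <- bandwidth_spec$grid
    if (is.null(grid)) grid <- c(0.01, 0.02, 0.05, 0.1, 0.2)
    best <- NULL
    for (bw in grid) {
      cand <- model
      cand$densities <- build(function(s) bw)
      pred <- predict_all(cand, dataset, model$params$conf_threshold)
      hit <- unique(pred$gene)
      tp <- sum(training$positives %in% hit)
      fp <- sum(training$negatives %in% hit)
      fn <- length(training$positives) - tp
      f <- precision_recall_fbeta(tp, fp, fn, beta)$f_beta
      if (is.null(best) || f > best$f) best <- list(f = f, bw = bw)
    }
    model$densities <- build(function(s) best$bw)
  } else stop("unknown bandwidth_spec")
  names(model$densities) <-
    vapply(model$densities, `[[`, "", "signature_gene")
  model
}

#' Genome-wide prediction from all valid signatures
#'
#' Every gene other than the signature's own (training genes included) is
#' scored against every valid signature: the co-expression level L on the
#' signature's features is converted to a posterior via [posterior()],
#' and a prediction is emitted when it exceeds `conf_threshold`. Because
#' each signature carries its own density model, the same confidence
#' cutoff translates into a different minimum co-expression per
#' signature (the adaptive-threshold property).
#'
#' @param model A `SignatureModel` with fitted densities.
#' @param dataset An [expression_dataset()].
#' @param conf_threshold Required posterior confidence (default from the
#'   model's params).
#' @param genes Optional subset of gene IDs to score (default: all).
#' @return Data frame with `gene`, `signature_gene`, `L`, `confidence`.
#' @export
predict_all <- function(model, dataset,
                        conf_threshold = model$params$conf_threshold,
                        genes = NULL) {
  empty <- data.frame(gene = character(), signature_gene = character(),
                      L = numeric(), confidence = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(model$densities) || !length(model$densities)) {
    warning("model has no fitted valid signatures")
    return(empty)
  }
  if (is.null(genes)) genes <- dataset$gene_ids
  vs <- valid_signatures(model)
  out <- list()
  for (sig in vs) {
    dm <- model$densities[[sig$gene]]
    g <- setdiff(genes, sig$gene)
    if (!length(g)) next
    L <- signature_coexpr(sig, g, dataset)
    conf <- posterior(L, dm)
    keep <- conf > conf_threshold
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(
        gene = g[keep], signature_gene = sig$gene,
        L = L[keep], confidence = conf[keep],
        stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$signature_gene, res$gene), , drop = FALSE]
}
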