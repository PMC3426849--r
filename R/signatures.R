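#' Absolute cosine co-expression on a feature subset
#'
#' The co-expression of two log-ratio patterns restricted to a feature
#' subset F: `|x_F . y_F| / (||x_F|| * ||y_F||)`. The absolute value
#' captures positive and negative correlation alike; unlike the Pearson
#' coefficient, the cosine is not re-centred, so a pattern that does not
#' change (all-zero log-ratios) is orthogonal to everything. A restricted
#' vector of zero norm yields 0.
#'
#' @param x,y Numeric log-ratio vectors of equal length.
#' @param features Integer indices of the subset F (nonempty).
#' @return A value in [0, 1].
#' @export
abs_cosine <- function(x, y, features = seq_along(x)) {
  if (!length(features)) stop("empty feature set")
  xf <- x[features]; yf <- y[features]
  nx <- sqrt(sum(xf^2)); ny <- sqrt(sum(yf^2))
  if (nx == 0 || ny == 0) return(0)
  min(1, abs(sum(xf * yf)) / (nx * ny))
}

# Vectorized |cosine| of one gene against every row of a matrix,
# restricted to `features`. Zero-norm rows (either side) give 0.
abs_cosine_rows <- function(x, mat, features) {
  xf <- x[features]
  nx <- sqrt(sum(xf^2))
  mf <- mat[, features, drop = FALSE]
  nm <- sqrt(rowSums(mf^2))
  num <- abs(as.vector(mf %*% xf))
  out <- numeric(nrow(mat))
  ok <- nm > 0 & nx > 0
  out[ok] <- pmin(1, num[ok] / (nm[ok] * nx))
  out
}

#' Logistic soft threshold separating strong from weak co-expression
#'
#' `1 / (1 + exp(-steepness * (c - midpoint)))`. With the default shape
#' (midpoint 0.75, steepness 30) the output is near 0 for co-expression
#' below 0.6 and above 0.5 for co-expression above 0.8, replacing a hard
#' correlation cutoff with a continuous one.
#'
#' @param c Co-expression value(s) in [0, 1]; vectorized.
#' @param midpoint Input at which the output is exactly 0.5.
#' @param steepness Slope scale of the logistic.
#' @return Value(s) in [0, 1], monotone increasing in `c`.
#' @export
soft_threshold <- function(c, midpoint = 0.75, steepness = 30) {
  1 / (1 + exp(-steepness * (c - midpoint)))
}

#' Soft counts of strongly co-expressed training partners
#'
#' For a gene and feature subset, `c_pos` sums the soft-thresholded
#' |cosine| against every other positive gene and `c_neg` against every
#' negative (minus any bootstrap-discarded negatives). These are the two
#' components of the expression signature score.
#'
#' @param gene Gene ID (must be a row of the dataset).
#' @param features Integer feature indices (nonempty).
#' @param dataset An [expression_dataset()].
#' @param training A [training_set()].
#' @param params A [dls_params()].
#' @param exclude_negatives Gene IDs to leave out of the negative sum.
#' @return Named list `c_pos`, `c_neg`.
#' @export
coexpr_components <- function(gene, features, dataset, training,
                              params = dls_params(),
                              exclude_negatives = character()) {
  x <- dataset$X_LR[gene, ]
  pos <- setdiff(training$positives, gene)
  neg <- setdiff(training$negatives, exclude_negatives)
  if (!length(pos)) {
    warning("positive class has no partners for ", gene)
    c_pos <- 0
  } else {
    c_pos <- sum(soft_threshold(
      abs_cosine_rows(x, dataset$X_LR[pos, , drop = FALSE], features),
      params$sigmoid_midpoint, params$sigmoid_steepness))
  }
  c_neg <- if (!length(neg)) 0 else
    sum(soft_threshold(
      abs_cosine_rows(x, dataset$X_LR[neg, , drop = FALSE], features),
      params$sigmoid_midpoint, params$sigmoid_steepness))
  list(c_pos = c_pos, c_neg = c_neg)
}

# Signature-size penalty: linear ramp reaching 1/2 at alpha_halfsize and
# saturating exactly at 1 for subsets of 2*alpha_halfsize features or
# more. The hard saturation matters: a penalty whose marginal gain never
# reaches zero would make any pure-noise feature addition score-improving
# on clean data, and the greedy search would absorb the whole feature
# space (see the methods vignette).
alpha_penalty <- function(n_features, alpha_halfsize) {
  pmin(1, n_features / (2 * alpha_halfsize))
}

ess_from_components <- function(c_pos, c_neg, n_features, params) {
  eps <- 1e-12
  alpha_penalty(n_features, params$alpha_halfsize) *
    c_pos / (c_pos + params$beta * c_neg + eps)
}

#' Expression Signature Score of a gene on a feature subset
#'
#' `ESS = alpha(|F|) * c_pos / (c_pos + beta * c_neg + eps)`: the ratio
#' rewards subsets on which the gene is strongly co-expressed with the
#' positive class and weakly with the negative class, `beta` tunes the
#' discrimination pressure, and the saturating size penalty `alpha`
#' discourages trivially small subsets. Bounded in [0, 1].
#'
#' @inheritParams coexpr_components
#' @return The score in [0, 1].
#' @export
ess <- function(gene, features, dataset, training, params = dls_params(),
                exclude_negatives = character()) {
  comp <- coexpr_components(gene, features, dataset, training, params,
                            exclude_negatives)
  ess_from_components(comp$c_pos, comp$c_neg, length(features), params)
}

#' Negatives to discard for one bootstrap iteration
#'
#' A negative is temporarily discarded (treated as a potential false
#' negative) when its |cosine| with the gene on the current features is
#' at least `boot_min_coexpr` and it ranks within the top `boot_top_k`
#' most co-expressed negatives (descending co-expression, ties broken by
#' gene ID).
#'
#' @inheritParams coexpr_components
#' @return Character vector of negative gene IDs (possibly empty).
#' @export
bootstrap_discard <- function(gene, features, dataset, training,
                              params = dls_params()) {
  neg <- training$negatives
  if (!length(neg) || !length(features)) return(character())
  co <- abs_cosine_rows(dataset$X_LR[gene, ],
                        dataset$X_LR[neg, , drop = FALSE], features)
  ord <- order(-co, neg)
  k <- resolve_boot_top_k(params, length(neg))
  top <- neg[ord[seq_len(min(k, length(neg)))]]
  eligible <- neg[co >= params$boot_min_coexpr]
  sort(intersect(top, eligible))
}

#' Greedy discriminative feature selection for one positive gene (signFS)
#'
#' Seeds the feature set with the comparisons where the gene changes
#' significantly (FDR below `fdr_init`), then repeatedly applies the best
#' single-feature addition or removal that strictly increases the ESS.
#' Candidate additions are limited to the `candidate_frac` (default 20%)
#' of all features with the lowest FDR for this gene not already
#' selected, steering the search toward significant changes. Ties are
#' broken by the lowest feature index. With the bootstrap option, likely
#' false-negative training genes are re-identified from the current
#' feature set at the start of each iteration and ignored in that
#' iteration's scores.
#'
#' @param gene A positive gene ID.
#' @inheritParams coexpr_components
#' @return An `ExpressionSignature`: list with `gene`, integer `features`,
#'   `feature_ids`, `ess`, `c_pos`, `c_neg`, `valid`,
#'   `discarded_negatives` (union over iterations) and the monotone
#'   improving `trace` of scores.
#' @export
signfs <- function(gene, dataset, training, params = dls_params()) {
  if (!gene %in% training$positives)
    stop(gene, " is not in the positive class")
  M <- ncol(dataset$X_LR)
  fdr <- dataset$X_FDR[gene, ]
  F_cur <- which(fdr < params$fdr_init)
  make_sig <- function(features, score, comp, discarded, trace) {
    structure(list(gene = gene, features = features,
                   feature_ids = colnames(dataset$X_LR)[features],
                   ess = score, c_pos = comp$c_pos, c_neg = comp$c_neg,
                   valid = score > params$tau_valid,
                   discarded_negatives = discarded, trace = trace),
              class = "ExpressionSignature")
  }
  if (!length(F_cur)) {
    message("signFS: no significant seed features for ", gene)
    return(make_sig(integer(), 0, list(c_pos = 0, c_neg = 0),
                    character(), numeric()))
  }
  n_cand <- ceiling(params$candidate_frac * M)
  discarded_all <- character()
  excl <- character()
  score_of <- function(features) {
    comp <- coexpr_components(gene, features, dataset, training, params,
                              exclude_negatives = excl)
    list(score = ess_from_components(comp$c_pos, comp$c_neg,
                                     length(features), params),
         comp = comp)
  }
  cur <- score_of(F_cur)
  trace <- cur$score
  for (it in seq_len(params$max_iters)) {
    if (params$bootstrap) {
      excl <- bootstrap_discard(gene, F_cur, dataset, training, params)
      discarded_all <- union(discarded_all, excl)
      cur <- score_of(F_cur)  # re-score under this iteration's discards
    }
    # additions must themselves be significant changes for this gene:
    # the rank-based 20% pool alone admits insignificant features when M
    # is small, letting a noise gene assemble a vacuous subspace whose
    # scale-free ESS ratio overfits the nearest positive neighbor
    not_sel <- setdiff(which(fdr < params$fdr_init), F_cur)
    add_pool <- not_sel[order(fdr[not_sel], not_sel)]
    add_pool <- add_pool[seq_len(min(n_cand, length(add_pool)))]
    moves <- rbind(
      if (length(add_pool))
        data.frame(type = "add", feature = add_pool),
      if (length(F_cur) > 1L)
        data.frame(type = "remove", feature = F_cur))
    if (is.null(moves) || !nrow(moves)) break
    best <- NULL
    for (m in seq_len(nrow(moves))) {
      f <- moves$feature[m]
      Fm <- if (moves$type[m] == "add") sort(c(F_cur, f))
            else setdiff(F_cur, f)
      sc <- score_of(Fm)
      if (sc$score > cur$score + params$min_improve &&
          (is.null(best) || sc$score > best$score + 1e-12 ||
           (abs(sc$score - best$score) <= 1e-12 && f < best$feature))) {
        best <- list(score = sc$score, comp = sc$comp, features = Fm,
                     feature = f)
      }
    }
    if (is.null(best)) break
    F_cur <- best$features
    cur <- list(score = best$score, comp = best$comp)
    trace <- c(trace, cur$score)
  }
  # final score without any temporary discards
  final <- {
    comp <- coexpr_components(gene, F_cur, dataset, training, params)
    list(score = ess_from_components(comp$c_pos, comp$c_neg,
                                     length(F_cur), params), comp = comp)
  }
  make_sig(F_cur, final$score, final$comp, discarded_all, trace)
}

#' @export
print.ExpressionSignature <- function(x, ...) {
  cat(sprintf("ExpressionSignature %s: ESS %.3f (%svalid), %d features\n",
              x$gene, x$ess, if (x$valid) "" else "not ",
              length(x$features)))
  invisible(x)
}

#' Train a signature model: one signFS search per positive gene
#'
#' Runs [signfs()] independently for every gene in the positive class
#' (the searches do not interact, so the result is order-invariant) and
#' keeps the validity flags `ess > tau_valid`.
#'
#' @inheritParams coexpr_components
#' @return A `SignatureModel`: list with `signatures` (named by gene),
#'   `params`, `training`, `prior_pos`, and a `densities` slot filled by
#'   [fit_densities()].
#' @export
dls_train <- function(dataset, training, params = dls_params()) {
  training <- attach_training(training, dataset)
  sigs <- lapply(training$positives, signfs, dataset = dataset,
                 training = training, params = params)
  names(sigs) <- training$positives
  if (!any(vapply(sigs, `[[`, TRUE, "valid")))
    warning("no valid signatures found")
  structure(list(signatures = sigs, params = params, training = training,
                 prior_pos = length(training$positives) /
                   (length(training$positives) + length(training$negatives)),
                 densities = NULL),
            class = "SignatureModel")
}

#' @export
print.SignatureModel <- function(x, ...) {
  nv <- sum(vapply(x$signatures, `[[`, TRUE, "valid"))
  cat(sprintf(
    "SignatureModel: %d signatures (%d valid), prior P(+) = %.3f%s\n",
    length(x$signatures), nv, x$prior_pos,
    if (is.null(x$densities)) ", densities not fitted" else ""))
  invisible(x)
}

valid_signatures <- function(model) {
  Filter(function(s) isTRUE(s$valid), model$signatures)
}

#' Write / read a signature table
#'
#' Tab-delimited with columns gene, ess, c_pos, c_neg, valid and
#' semicolon-joined feature IDs; parameters go to a JSON sidecar.
#'
#' @param model A `SignatureModel`.
#' @param prefix Output path prefix (`<prefix>_signatures.tsv`,
#'   `<prefix>_params.json`).
#' @return The prefix, invisibly.
#' @export
write_signatures <- function(model, prefix) {
  df <- do.call(rbind, lapply(model$signatures, function(s)
    data.frame(gene = s$gene, ess = s$ess, c_pos = s$c_pos,
               c_neg = s$c_neg, valid = s$valid,
               feature_ids = paste(s$feature_ids, collapse = ";"),
               stringsAsFactors = FALSE)))
  utils::write.table(df, paste0(prefix, "_signatures.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(model$params[!vapply(model$params, is.null, TRUE)],
                       paste0(prefix, "_params.json"), auto_unbox = TRUE)
  invisible(prefix)
}
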