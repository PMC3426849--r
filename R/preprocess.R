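#' A replicated multi-condition expression experiment
#'
#' Raw intensities for one experimental set: a genes-by-samples matrix plus
#' a sample-to-condition map. Zero intensities are tolerated here and
#' offset (by the smallest positive value in the experiment, added to all
#' cells) before any log-ratio is taken; negative intensities are an error.
#'
#' @param experiment_id Opaque identifier string.
#' @param intensities Non-negative numeric matrix, genes x samples, with
#'   gene rownames and sample colnames.
#' @param sample_condition Named character vector mapping every sample
#'   (names) to its condition label.
#' @return A `RawExperimentSet` object.
#' @export
raw_experiment <- function(experiment_id, intensities, sample_condition) {
  stopifnot(is.matrix(intensities), !is.null(rownames(intensities)),
            !is.null(colnames(intensities)))
  if (anyNA(intensities) || any(!is.finite(intensities)))
    stop("intensities must be finite")
  if (any(intensities < 0))
    stop("intensities must be non-negative")
  if (!setequal(names(sample_condition), colnames(intensities)))
    stop("sample_condition must name exactly the samples of the matrix")
  sample_condition <- sample_condition[colnames(intensities)]
  structure(list(experiment_id = as.character(experiment_id),
                 intensities = intensities,
                 sample_condition = sample_condition,
                 conditions = unique(unname(sample_condition)),
                 gene_ids = rownames(intensities)),
            class = "RawExperimentSet")
}

# Offset an experiment's intensity matrix so every cell is strictly
# positive: add the smallest positive value if zeros are present.
offset_intensities <- function(exp) {
  x <- exp$intensities
  if (any(x == 0)) {
    eps <- min(x[x > 0])
    message(sprintf("experiment %s: zero intensities offset by %g",
                    exp$experiment_id, eps))
    x <- x + eps
  }
  x
}

condition_columns <- function(exp, condition) {
  cols <- names(exp$sample_condition)[exp$sample_condition == condition]
  if (!length(cols))
    stop(sprintf("condition '%s' absent from experiment %s",
                 condition, exp$experiment_id))
  cols
}

#' Rank-product differential expression for one condition pair
#'
#' For each gene, the rank product is the geometric mean of its
#' fold-change ranks across all control-replicate x test-replicate
#' pairings; small rank products for up- (or down-) regulation mark
#' consistently changed genes. Significance is the expected number of
#' false positives at the gene's rank-product value under a null of
#' shuffled group labels, divided by the gene's rank -- the standard
#' percentage-of-false-prediction estimate, clamped to [0, 1]. Up- and
#' down-regulation are analysed one-sidedly and merged per gene by the
#' sign of its log-ratio.
#'
#' Label reassignments are enumerated exhaustively when
#' `choose(n_samples, n_control) <= 10000` (making small cases exact);
#' otherwise `n_perm` random reassignments are drawn.
#'
#' @param control,test Strictly positive intensity matrices (genes x
#'   replicates) sharing rownames.
#' @param n_perm Number of sampled label permutations when exhaustive
#'   enumeration is infeasible.
#' @param seed Integer seed for the sampled permutations.
#' @return A data frame with `gene_id`, `log_ratio` (log2 of mean test
#'   over mean control), `fdr`, and the one-sided `rp_up` / `rp_down`
#'   statistics.
#' @export
rank_products <- function(control, test, n_perm = 100L, seed = 1L) {
  if (!identical(rownames(control), rownames(test))) {
    bad <- union(setdiff(rownames(control), rownames(test)),
                 setdiff(rownames(test), rownames(control)))
    stop("control/test gene rows differ: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (any(control <= 0) || any(test <= 0))
    stop("intensities must be strictly positive (offset zeros upstream)")
  kc <- ncol(control); kt <- ncol(test)
  stopifnot(kc >= 1, kt >= 1)
  n <- nrow(control)

  log_ratio <- log2(rowMeans(test) / rowMeans(control))

  rp_pair <- function(ctl, tst) {
    # geometric mean of per-pairing fold-change ranks, both directions
    lr_up <- matrix(0, n, ncol(ctl) * ncol(tst))
    k <- 0L
    for (i in seq_len(ncol(ctl))) for (j in seq_len(ncol(tst))) {
      k <- k + 1L
      lr_up[, k] <- log2(tst[, j] / ctl[, i])
    }
    up <- exp(rowMeans(log(apply(-lr_up, 2, rank, ties.method = "average"))))
    dn <- exp(rowMeans(log(apply(lr_up, 2, rank, ties.method = "average"))))
    list(up = up, down = dn)
  }

  obs <- rp_pair(control, test)

  pooled <- cbind(control, test)
  ntot <- kc + kt
  n_exhaustive <- choose(ntot, kc)
  if (n_exhaustive <= 10000) {
    assigns <- utils::combn(ntot, kc, simplify = FALSE)
  } else {
    set.seed(seed)
    assigns <- replicate(n_perm, sort(sample.int(ntot, kc)),
                         simplify = FALSE)
  }
  null_up <- null_dn <- vector("list", length(assigns))
  for (a in seq_along(assigns)) {
    idx <- assigns[[a]]
    rp <- rp_pair(pooled[, idx, drop = FALSE],
                  pooled[, -idx, drop = FALSE])
    null_up[[a]] <- rp$up
    null_dn[[a]] <- rp$down
  }
  null_up <- sort(unlist(null_up))
  null_dn <- sort(unlist(null_dn))
  nperm_eff <- length(assigns)

  pfp <- function(rp_obs, null_sorted) {
    e <- findInterval(rp_obs, null_sorted) / nperm_eff
    r <- rank(rp_obs, ties.method = "max")
    pmin(1, e / r)
  }
  fdr_up <- pfp(obs$up, null_up)
  fdr_dn <- pfp(obs$down, null_dn)
  fdr <- ifelse(log_ratio > 0, fdr_up,
                ifelse(log_ratio < 0, fdr_dn, pmin(fdr_up, fdr_dn)))

  data.frame(gene_id = rownames(control), log_ratio = log_ratio,
             fdr = fdr, rp_up = obs$up, rp_down = obs$down,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Plain log2 ratio of replicate means for a condition pair; used for the
# redundancy filter, where the full rank-product machinery is unnecessary.
pair_log_ratio <- function(exp, control, test, intensities = NULL) {
  x <- if (is.null(intensities)) offset_intensities(exp) else intensities
  cc <- condition_columns(exp, control)
  tc <- condition_columns(exp, test)
  log2(rowMeans(x[, tc, drop = FALSE]) / rowMeans(x[, cc, drop = FALSE]))
}

#' Enumerate condition pairs with greedy redundancy filtering
#'
#' All unordered condition pairs of each experiment are enumerated (the
#' lexicographically smaller label is taken as control), visited in sorted
#' order, and a pair is kept only if the absolute Pearson correlation of
#' its log-ratio profile with every already-kept feature of the same
#' experiment is at most `max_redundancy`. With `max_redundancy = 1` the
#' filter is disabled.
#'
#' @param experiments List of [raw_experiment()] objects.
#' @param max_redundancy Correlation ceiling in (0, 1].
#' @return Data frame of condition pairs (`feature_id`, `experiment`,
#'   `control`, `test`).
#' @export
generate_pairs_auto <- function(experiments, max_redundancy = 0.9) {
  stopifnot(max_redundancy > 0, max_redundancy <= 1)
  out <- list()
  for (exp in experiments) {
    conds <- sort(exp$conditions)
    if (length(conds) < 2) {
      warning(sprintf("experiment %s has <2 conditions; skipped",
                      exp$experiment_id))
      next
    }
    x <- offset_intensities(exp)
    kept_lr <- NULL
    for (i in seq_len(length(conds) - 1)) for (j in (i + 1):length(conds)) {
      ctl <- conds[i]; tst <- conds[j]
      lr <- pair_log_ratio(exp, ctl, tst, intensities = x)
      redundant <- FALSE
      if (!is.null(kept_lr) && max_redundancy < 1) {
        cors <- suppressWarnings(abs(stats::cor(lr, kept_lr)))
        cors[is.na(cors)] <- 0
        redundant <- any(cors > max_redundancy)
      }
      if (!redundant) {
        kept_lr <- cbind(kept_lr, lr)
        out[[length(out) + 1L]] <- data.frame(
          feature_id = sprintf("%s:%s_vs_%s", exp$experiment_id, ctl, tst),
          experiment = exp$experiment_id, control = ctl, test = tst,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(feature_id = character(), experiment = character(),
                      control = character(), test = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Assemble the paired log-ratio / FDR dataset from raw experiments
#'
#' Runs [rank_products()] for every condition pair and stacks the results
#' into an [expression_dataset()]. Experiments with differing gene
#' universes are intersected (with a message).
#'
#' @param experiments List of [raw_experiment()] objects.
#' @param pairs Condition-pair data frame, e.g. from
#'   [generate_pairs_auto()].
#' @param n_perm,seed Passed to [rank_products()]; each pair uses a
#'   distinct derived seed.
#' @return An `ExpressionDataset`.
#' @export
assemble_dataset <- function(experiments, pairs, n_perm = 100L, seed = 1L) {
  if (is.null(pairs) || nrow(pairs) == 0L) stop("empty pair list")
  names(experiments) <- vapply(experiments, `[[`, "", "experiment_id")
  missing <- setdiff(pairs$experiment, names(experiments))
  if (length(missing))
    stop("pairs reference unknown experiments: ",
         paste(missing, collapse = ", "))
  genes <- Reduce(intersect, lapply(experiments, `[[`, "gene_ids"))
  if (!all(vapply(experiments, function(e)
    length(e$gene_ids) == length(genes), TRUE)))
    message("experiments differ in gene universe; intersection of ",
            length(genes), " genes used")
  X_LR <- X_FDR <- matrix(NA_real_, length(genes), nrow(pairs),
                          dimnames = list(genes, pairs$feature_id))
  for (j in seq_len(nrow(pairs))) {
    exp <- experiments[[pairs$experiment[j]]]
    x <- offset_intensities(exp)[genes, , drop = FALSE]
    rp <- rank_products(x[, condition_columns(exp, pairs$control[j]),
                          drop = FALSE],
                        x[, condition_columns(exp, pairs$test[j]),
                          drop = FALSE],
                        n_perm = n_perm, seed = seed + j)
    X_LR[, j] <- rp$log_ratio
    X_FDR[, j] <- rp$fdr
  }
  expression_dataset(X_LR, X_FDR, pairs)
}

#' Read one raw experiment from tab-delimited files
#'
#' @param intensity_path Wide table: first column gene IDs, remaining
#'   columns one per sample (header row = sample IDs).
#' @param condition_path Two-column table (`sample`, `condition`).
#' @param experiment_id Identifier; defaults to the intensity file stem.
#' @return A `RawExperimentSet`.
#' @export
read_experiment <- function(intensity_path, condition_path,
                            experiment_id = NULL) {
  if (is.null(experiment_id))
    experiment_id <- sub("\\.[^.]*$", "", basename(intensity_path))
  m <- read_tsv_matrix(intensity_path)
  sc <- utils::read.table(condition_path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  raw_experiment(experiment_id, m,
                 stats::setNames(sc[[2]], sc[[1]]))
}
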