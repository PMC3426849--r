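#' Specification of a synthetic planted-signature dataset
#'
#' Describes the world the generator emits: groups of positive genes
#' sharing a template expression pattern on a disjoint subspace of
#' features, optional planted false negatives (positive pattern, negative
#' label), background Gaussian noise everywhere else, and an FDR matrix
#' marking the planted cells as significant with a controllable
#' mislabeling rate. Defaults (200 genes x 60 features, 40 positives in
#' two 20-feature groups, pattern strength 2 -- i.e. planted log2-ratios
#' of roughly 4-fold changes -- background noise 0.2, 5% spurious
#' significance in the FDR matrix) are documented in the methods
#' vignette.
#'
#' @param n_genes,n_features Matrix dimensions.
#' @param n_positives Size of the positive class.
#' @param n_groups Number of co-regulated groups the positives split into.
#' @param features_per_group Planted subspace size per group (disjoint
#'   blocks).
#' @param strength Template scale: planted cells are
#'   `strength * N(0,1)` template values plus noise.
#' @param noise_sd Background noise standard deviation.
#' @param n_planted_fns Negatives that receive a group's pattern.
#' @param fdr_mislabel Probability that a background cell draws a
#'   spuriously significant FDR, stressing the candidate rule of the
#'   signature search with false seed features.
#' @param seed Integer seed; the generator is fully reproducible.
#' @return A `SyntheticSpec` list.
#' @export
synth_spec <- function(n_genes = 200L, n_features = 60L,
                       n_positives = 40L, n_groups = 2L,
                       features_per_group = 20L, strength = 2,
                       noise_sd = 0.2, n_planted_fns = 0L,
                       fdr_mislabel = 0.05, seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes),
               n_features = as.integer(n_features),
               n_positives = as.integer(n_positives),
               n_groups = as.integer(n_groups),
               features_per_group = as.integer(features_per_group),
               strength = strength, noise_sd = noise_sd,
               n_planted_fns = as.integer(n_planted_fns),
               fdr_mislabel = fdr_mislabel, seed = as.integer(seed))
  if (spec$n_groups * spec$features_per_group > spec$n_features)
    stop("planted feature blocks exceed the feature range")
  if (spec$n_positives >= spec$n_genes)
    stop("need at least one negative gene")
  if (spec$n_planted_fns > spec$n_genes - spec$n_positives)
    stop("more planted false negatives than negatives")
  if (spec$n_positives < spec$n_groups)
    stop("fewer positives than groups")
  if (spec$fdr_mislabel < 0 || spec$fdr_mislabel > 1)
    stop("fdr_mislabel must be in [0, 1]")
  structure(spec, class = "SyntheticSpec")
}

#' Generate a synthetic dataset with planted ground truth
#'
#' Positives in group g share template `strength * N(0,1)` values on
#' that group's feature block, observed with `N(0, noise_sd)` noise;
#' every other cell is pure `N(0, noise_sd)` noise. Planted false
#' negatives carry a group's pattern (groups assigned round-robin) but a
#' negative label. The FDR matrix draws planted cells from
#' `U(0, 0.08)` and background cells from `U(0.15, 1)`, except that a
#' background cell is spuriously significant (drawn from the planted
#' regime) with probability `fdr_mislabel`.
#'
#' @param spec A [synth_spec()].
#' @return List with `dataset` (an [expression_dataset()]), `training`
#'   (a [training_set()]; negatives are all non-positive genes), and
#'   `truth` (a `GroundTruth`: `true_positive_genes`,
#'   `planted_features_per_gene`, `planted_fn_genes`, `group_of`).
#' @export
generate_synthetic <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  genes <- sprintf("g%04d", seq_len(spec$n_genes))
  feats <- sprintf("synth:c00_vs_c%02d", seq_len(spec$n_features))
  positives <- genes[seq_len(spec$n_positives)]
  negatives <- setdiff(genes, positives)

  group_of <- stats::setNames(rep(NA_integer_, spec$n_genes), genes)
  group_of[positives] <-
    rep(seq_len(spec$n_groups), length.out = spec$n_positives)
  fn_genes <- character()
  if (spec$n_planted_fns > 0) {
    fn_genes <- negatives[seq_len(spec$n_planted_fns)]
    group_of[fn_genes] <-
      rep(seq_len(spec$n_groups), length.out = spec$n_planted_fns)
  }
  block <- function(g)
    ((g - 1L) * spec$features_per_group + 1L):(g * spec$features_per_group)

  X_LR <- matrix(stats::rnorm(spec$n_genes * spec$n_features,
                              sd = spec$noise_sd),
                 spec$n_genes, spec$n_features,
                 dimnames = list(genes, feats))
  templates <- lapply(seq_len(spec$n_groups), function(g)
    spec$strength * stats::rnorm(spec$features_per_group))
  planted <- matrix(FALSE, spec$n_genes, spec$n_features,
                    dimnames = list(genes, feats))
  for (g in genes[!is.na(group_of)]) {
    b <- block(group_of[[g]])
    X_LR[g, b] <- templates[[group_of[[g]]]] +
      stats::rnorm(spec$features_per_group, sd = spec$noise_sd)
    planted[g, b] <- TRUE
  }

  n_cells <- spec$n_genes * spec$n_features
  low <- stats::runif(n_cells, 0, 0.08)
  high <- stats::runif(n_cells, 0.15, 1)
  spurious <- stats::runif(n_cells) < spec$fdr_mislabel
  sig <- as.vector(planted) | spurious
  X_FDR <- matrix(ifelse(sig, low, high), spec$n_genes, spec$n_features,
                  dimnames = list(genes, feats))

  features <- data.frame(feature_id = feats, experiment = "synth",
                         control = "c00",
                         test = sprintf("c%02d", seq_len(spec$n_features)),
                         stringsAsFactors = FALSE)
  planted_features <- lapply(stats::setNames(genes, genes), function(g)
    if (is.na(group_of[[g]])) integer() else block(group_of[[g]]))

  list(dataset = expression_dataset(X_LR, X_FDR, features),
       training = training_set(positives, negatives,
                               process_term = "SYNTH:0000001"),
       truth = structure(list(true_positive_genes =
                                c(positives, fn_genes),
                              planted_features_per_gene = planted_features,
                              planted_fn_genes = fn_genes,
                              group_of = group_of),
                         class = "GroundTruth"))
}

#' Generate a random rooted ontology DAG with annotations
#'
#' Terms are layered to `depth`; each non-root term gets one or two
#' parents drawn from the previous layer, so every term reaches the
#' single root and the graph is acyclic by construction. Each gene is
#' directly annotated to each non-root term independently with
#' probability `annotation_density`.
#'
#' @param n_terms Total number of terms including the root.
#' @param depth Number of layers below the root (`depth = 1` gives a
#'   star).
#' @param n_genes Number of genes to annotate (IDs `g0001`...).
#' @param annotation_density Per-(gene, term) annotation probability.
#' @param seed Integer seed.
#' @return List with `dag` (an [ontology_dag()]) and `annotations` (a
#'   propagated [annotation_set()]).
#' @export
generate_ontology <- function(n_terms = 20L, depth = 3L, n_genes = 50L,
                              annotation_density = 0.05, seed = 1L) {
  stopifnot(n_terms >= depth + 1, depth >= 1)
  set.seed(seed)
  terms <- c("T:root", sprintf("T:%04d", seq_len(n_terms - 1L)))
  layer <- c(0L, rep(seq_len(depth), length.out = n_terms - 1L))
  layer <- sort(layer)  # contiguous layers, root first
  edges <- list()
  for (i in which(layer > 0)) {
    prev <- which(layer == layer[i] - 1L)
    k <- min(length(prev), sample(1:2, 1))
    for (p in sample(prev, k))
      edges[[length(edges) + 1L]] <- c(terms[i], terms[p])
  }
  dag <- ontology_dag(terms, do.call(rbind, edges))
  genes <- sprintf("g%04d", seq_len(n_genes))
  hit <- which(matrix(stats::runif(n_genes * (n_terms - 1L)),
                      n_genes) < annotation_density, arr.ind = TRUE)
  df <- data.frame(gene_id = genes[hit[, 1]],
                   term_id = terms[-1][hit[, 2]],
                   evidence = "EXP", stringsAsFactors = FALSE)
  if (!nrow(df))  # guarantee at least one annotation
    df <- data.frame(gene_id = genes[1], term_id = terms[2],
                     evidence = "EXP", stringsAsFactors = FALSE)
  list(dag = dag, annotations = propagate(dag, annotation_set(df)))
}
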