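# Small in-code fixtures shared across test files.

make_dataset <- function(X, fdr = NULL) {
  if (is.null(rownames(X)))
    rownames(X) <- sprintf("g%02d", seq_len(nrow(X)))
  if (is.null(colnames(X)))
    colnames(X) <- sprintf("f%02d", seq_len(ncol(X)))
  if (is.null(fdr)) {
    fdr <- matrix(0.5, nrow(X), ncol(X), dimnames = dimnames(X))
  } else dimnames(fdr) <- dimnames(X)
  expression_dataset(X, fdr)
}

# deterministic toy: 2 positives sharing a pattern on features 1:3,
# negatives co-expressed with the query gene on features 4:5
toy_discriminative <- function() {
  X <- rbind(
    gA = c(2, -1, 3, 1, 1),
    gB = c(2, -1, 3, 0, 0),
    gC = c(2, -1, 3, -1, 2),
    n1 = c(0, 0, 0, 1, 1),
    n2 = c(0, 0, 0, 2, 2),
    n3 = c(0.1, 0.2, -0.1, 1, 1))
  colnames(X) <- sprintf("f%02d", 1:5)
  fdr <- matrix(1, nrow(X), ncol(X), dimnames = dimnames(X))
  fdr[c("gA", "gB", "gC"), 1:3] <- 0.01
  list(dataset = expression_dataset(X, fdr),
       training = training_set(c("gA", "gB", "gC"), c("n1", "n2", "n3")))
}

# raw 3-condition experiment where condition c is 2*b elementwise
make_proportional_experiment <- function() {
  set.seed(99)
  a <- matrix(rlnorm(10, 4, 0.5), 5, 2)
  b <- matrix(rlnorm(10, 4, 0.5), 5, 2)
  x <- cbind(a, b, 2 * b)
  rownames(x) <- paste0("g", 1:5)
  colnames(x) <- paste0("s", 1:6)
  raw_experiment("e1", x,
                 setNames(rep(c("a", "b", "c"), each = 2),
                          colnames(x)))
}

small_synth <- function(...) {
  generate_synthetic(synth_spec(n_genes = 60L, n_features = 30L,
                                n_positives = 16L, n_groups = 2L,
                                features_per_group = 10L, ...))
}
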