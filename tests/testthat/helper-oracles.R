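# Independent brute-force oracles. These deliberately avoid the package's
# vectorized code paths: plain double loops and explicit enumeration.

oracle_abs_cosine <- function(x, y, f) {
  x <- unname(x); y <- unname(y)
  num <- 0; sx <- 0; sy <- 0
  for (i in f) {
    num <- num + x[i] * y[i]
    sx <- sx + x[i]^2
    sy <- sy + y[i]^2
  }
  if (sx == 0 || sy == 0) return(0)
  abs(num) / (sqrt(sx) * sqrt(sy))
}

oracle_sigmoid <- function(c, mid = 0.75, steep = 30) {
  1 / (1 + exp(-steep * (c - mid)))
}

# two-loop soft-neighbor counts, the spec's dual route for
# coexpr_components
oracle_coexpr <- function(gene, features, X, positives, negatives,
                          mid = 0.75, steep = 30) {
  cp <- 0
  for (g in positives) if (g != gene)
    cp <- cp + oracle_sigmoid(
      oracle_abs_cosine(X[gene, ], X[g, ], features), mid, steep)
  cn <- 0
  for (g in negatives)
    cn <- cn + oracle_sigmoid(
      oracle_abs_cosine(X[gene, ], X[g, ], features), mid, steep)
  list(c_pos = cp, c_neg = cn)
}

# exhaustive upper-tail hypergeometric by enumerating all draws
oracle_hypergeom_tail <- function(overlap, n_success, n_universe, n_draw) {
  sets <- utils::combn(n_universe, n_draw, simplify = FALSE)
  hits <- vapply(sets, function(s) sum(s <= n_success) >= overlap, TRUE)
  mean(hits)
}

# exhaustive rank-product FDR oracle for one direction (up-regulation):
# enumerate every reassignment of group labels, pool the null rank
# products, and compute expected-false-positives / rank
oracle_rp_up <- function(ctl, tst) {
  ranks <- NULL
  for (i in seq_len(ncol(ctl))) for (j in seq_len(ncol(tst))) {
    fc <- tst[, j] / ctl[, i]
    ranks <- cbind(ranks, rank(-fc, ties.method = "average"))
  }
  apply(ranks, 1, function(r) prod(r)^(1 / length(r)))
}

oracle_rp_fdr_up <- function(ctl, tst) {
  obs <- oracle_rp_up(ctl, tst)
  pooled <- cbind(ctl, tst)
  kc <- ncol(ctl)
  combos <- utils::combn(ncol(pooled), kc, simplify = FALSE)
  null_vals <- unlist(lapply(combos, function(idx)
    oracle_rp_up(pooled[, idx, drop = FALSE],
                 pooled[, -idx, drop = FALSE])))
  sapply(seq_along(obs), function(g) {
    e <- sum(null_vals <= obs[g]) / length(combos)
    r <- sum(obs <= obs[g])
    min(1, e / r)
  })
}
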