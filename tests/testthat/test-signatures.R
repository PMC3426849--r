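test_that("absolute cosine matches hand values and its invariances", {
  expect_equal(abs_cosine(c(1, 2), c(2, 4), 1:2), 1)       # collinear
  expect_equal(abs_cosine(c(1, 0), c(0, 1), 1:2), 0)       # orthogonal
  expect_equal(abs_cosine(c(1, 1), c(1, -1), 1:2), 0)
  expect_equal(abs_cosine(c(3, 4), c(4, 3), 1:2), 24 / 25)
  expect_equal(abs_cosine(c(0, 0), c(1, 1), 1:2), 0)       # zero norm
  expect_error(abs_cosine(c(1, 2), c(1, 2), integer()), "empty")

  set.seed(10)
  for (i in 1:20) {
    x <- rnorm(6); y <- rnorm(6); f <- sample(6, sample(2:6, 1))
    expect_equal(abs_cosine(x, y, f), abs_cosine(y, x, f))
    expect_equal(abs_cosine(3.7 * x, y, f), abs_cosine(x, y, f))
    expect_equal(abs_cosine(-2 * x, y, f), abs_cosine(x, y, f))
    expect_equal(abs_cosine(x, y, f), oracle_abs_cosine(x, y, f))
  }
  expect_equal(abs_cosine(c(2, 4, 1), c(-1, -2, 9), 1:2), 1)  # collinear on F
})

test_that("soft threshold satisfies the published shape constraints", {
  expect_gt(soft_threshold(0.8), 0.5)
  expect_lte(soft_threshold(0.6), 0.05)
  expect_equal(soft_threshold(0.6), 1 / (1 + exp(30 * 0.15)))
  expect_equal(soft_threshold(0.75), 0.5)  # logistic symmetry at midpoint
  grid <- seq(0, 1, 0.01)
  expect_true(all(diff(soft_threshold(grid)) > 0))
  expect_true(all(soft_threshold(grid) >= 0 & soft_threshold(grid) <= 1))
})

test_that("coexpr components equal the brute-force double loop", {
  # limiting case: identical to positives, orthogonal-ish to negatives
  X <- rbind(g1 = c(1, 2, 3), g2 = c(1, 2, 3), g3 = c(1, 2, 3),
             g4 = c(1, 2, 3), n1 = c(3, 0, -1), n2 = c(-2, 3, -1))
  ds <- make_dataset(X)
  tr <- training_set(paste0("g", 1:4), c("n1", "n2"))
  comp <- coexpr_components("g1", 1:3, ds, tr)
  expect_equal(comp$c_pos, 3 * soft_threshold(1), tolerance = 1e-9)
  expect_lt(comp$c_neg, 0.01)

  tr0 <- training_set(paste0("g", 1:4), character())
  expect_equal(coexpr_components("g1", 1:3, ds, tr0)$c_neg, 0)

  expect_warning(
    solo <- coexpr_components("g1", 1:3, ds,
                              training_set("g1", c("n1", "n2"))),
    "partners")
  expect_equal(solo$c_pos, 0)

  # randomized instances vs the independent oracle
  set.seed(11)
  for (i in 1:10) {
    n <- sample(6:20, 1); m <- sample(4:10, 1)
    X <- matrix(rnorm(n * m), n, m,
                dimnames = list(sprintf("g%02d", 1:n), NULL))
    colnames(X) <- sprintf("f%02d", 1:m)
    ds <- make_dataset(X)
    pos <- rownames(X)[1:ceiling(n / 3)]
    neg <- setdiff(rownames(X), pos)
    f <- sort(sample(m, sample(2:m, 1)))
    got <- coexpr_components(pos[1], f, ds, training_set(pos, neg))
    want <- oracle_coexpr(pos[1], f, X, pos, neg)
    expect_equal(got$c_pos, want$c_pos, tolerance = 1e-9)
    expect_equal(got$c_neg, want$c_neg, tolerance = 1e-9)
  }
})

test_that("ESS has the stated algebra, bounds and beta monotonicity", {
  toy <- toy_discriminative()
  p <- dls_params()
  # plug-in check of the composition at |F| = alpha_halfsize
  comp <- list(c_pos = 2, c_neg = 2)
  expect_equal(dlsnet:::ess_from_components(2, 2, p$alpha_halfsize, p),
               0.5 * 0.5, tolerance = 1e-9)
  # c_pos = 0 -> 0; large clean subsets -> 1
  expect_equal(dlsnet:::ess_from_components(0, 5, 10, p), 0)
  expect_equal(dlsnet:::ess_from_components(3, 0, 2 * p$alpha_halfsize, p),
               1, tolerance = 1e-6)

  # beta = 0 ignores negatives entirely
  p0 <- dls_params(beta = 0)
  e_no_neg <- ess("gA", 1:3, toy$dataset,
                  training_set(c("gA", "gB", "gC"), character()), p0)
  e_with <- ess("gA", 1:3, toy$dataset, toy$training, p0)
  expect_equal(e_with, e_no_neg, tolerance = 1e-9)

  # increasing beta never increases ESS at fixed F; ESS stays in [0, 1]
  set.seed(12)
  for (i in 1:8) {
    f <- sort(sample(5, sample(2:5, 1)))
    vals <- sapply(c(0, 0.5, 1, 2, 5), function(b)
      ess("gA", f, toy$dataset, toy$training, dls_params(beta = b)))
    expect_true(all(diff(vals) <= 1e-12))
    expect_true(all(vals >= 0 & vals <= 1))
  }
  # alpha penalty is (weakly) monotone in subset size
  a <- dlsnet:::alpha_penalty(1:30, 5)
  expect_true(all(diff(a) >= 0))
})

test_that("signFS improves monotonically and is bounded by the exhaustive optimum", {
  set.seed(13)
  syn <- small_synth(seed = 13)
  m <- ncol(syn$dataset$X_LR)
  # restrict to a 10-feature view so 2^10 - 1 subsets are enumerable
  keep <- c(1:6, 11:14)  # 6 of group 1's block, 4 of group 2's
  ds <- expression_dataset(syn$dataset$X_LR[, keep],
                           syn$dataset$X_FDR[, keep])
  tr <- syn$training
  p <- dls_params(candidate_frac = 1, fdr_init = 0.1)
  g <- tr$positives[1]
  sig <- signfs(g, ds, tr, p)
  expect_true(all(diff(sig$trace) > 0))

  f0 <- which(ds$X_FDR[g, ] < p$fdr_init)
  expect_gte(sig$ess, ess(g, f0, ds, tr, p))

  subsets <- unlist(lapply(1:10, function(k)
    utils::combn(10, k, simplify = FALSE)), recursive = FALSE)
  best <- max(vapply(subsets, function(f) ess(g, f, ds, tr, p), 0))
  expect_lte(sig$ess, best + 1e-12)
})

test_that("signFS removes an anti-discriminative feature", {
  # feature 3 is where the gene co-expresses with every negative; on
  # features 1:2 the negatives sit along (1,2), orthogonal to the
  # positives' (2,-1) pattern (|cosine| is scale-invariant, so the
  # negative profiles must be orthogonal, not merely small)
  X <- rbind(gA = c(2, -1, 5), gB = c(2, -1, -0.2), gC = c(2, -1, 0.3),
             n1 = c(0.01, 0.02, 5), n2 = c(0.02, 0.04, 5),
             n3 = c(-0.01, -0.02, 5), n4 = c(0.015, 0.03, 5))
  ds <- make_dataset(X, matrix(0.01, nrow(X), ncol(X)))
  tr <- training_set(c("gA", "gB", "gC"), paste0("n", 1:4))
  p <- dls_params(candidate_frac = 1, fdr_init = 1, alpha_halfsize = 1)
  sig <- signfs("gA", ds, tr, p)
  expect_false(3L %in% sig$features)
  expect_true(all(c(1L, 2L) %in% sig$features))
  # and the greedy result matches the best of all 7 subsets
  subsets <- unlist(lapply(1:3, function(k)
    utils::combn(3, k, simplify = FALSE)), recursive = FALSE)
  scores <- vapply(subsets, function(f) ess("gA", f, ds, tr, p), 0)
  expect_equal(sig$ess, max(scores), tolerance = 1e-9)
})

test_that("signFS recovers planted feature subspaces", {
  # subspaces must be wide enough that chance co-expression of noise
  # genes rarely clears the sigmoid's weak zone (see methods vignette)
  syn <- generate_synthetic(synth_spec(n_genes = 100, n_features = 60,
                                       n_positives = 20,
                                       features_per_group = 20,
                                       noise_sd = 0.2, seed = 2))
  jac <- vapply(syn$training$positives, function(g) {
    s <- signfs(g, syn$dataset, syn$training)
    pl <- syn$truth$planted_features_per_gene[[g]]
    length(intersect(s$features, pl)) / length(union(s$features, pl))
  }, 0)
  expect_gte(mean(jac >= 0.8), 0.9)
})

test_that("empty seed set yields an invalid empty signature, not an error", {
  toy <- toy_discriminative()
  ds <- toy$dataset
  ds$X_FDR[] <- 1
  expect_message(sig <- signfs("gA", ds, toy$training), "no significant")
  expect_length(sig$features, 0)
  expect_equal(sig$ess, 0)
  expect_false(sig$valid)
})

test_that("bootstrap discard applies both the floor and the top-k rank rule", {
  toy <- toy_discriminative()
  p <- dls_params(bootstrap = TRUE, boot_min_coexpr = 0.8, boot_top_k = 3)
  # no negative reaches the floor on the discriminative features
  expect_length(bootstrap_discard("gA", 1:3, toy$dataset, toy$training, p),
                0)
  # 5 negatives above the floor, top_k = 3 -> exactly the top 3
  X <- rbind(gA = c(1, 2, 3), gB = c(1, 2, 3.2),
             n1 = 1.00 * c(1, 2, 3), n2 = 0.99 * c(1, 2, 3) + c(0, 0.01, 0),
             n3 = c(1, 2, 3.1), n4 = c(1, 2.1, 3), n5 = c(1.1, 2, 3),
             n6 = c(3, -1, 0))
  ds <- make_dataset(X)
  tr <- training_set(c("gA", "gB"), paste0("n", 1:6))
  co <- sapply(paste0("n", 1:6), function(n)
    abs_cosine(X["gA", ], X[n, ], 1:3))
  top3 <- names(sort(co, decreasing = TRUE))[1:3]
  got <- bootstrap_discard("gA", 1:3, ds, tr, p)
  expect_setequal(got, top3)
  expect_true(all(co[got] >= 0.8))
})

test_that("training is deterministic and collapses under label shuffling", {
  syn <- small_synth(seed = 3)
  model <- dls_train(syn$dataset, syn$training)
  expect_s3_class(model, "SignatureModel")
  nv <- sum(vapply(model$signatures, `[[`, TRUE, "valid"))
  expect_gte(nv, length(syn$training$positives) - 1)

  # a duplicate of a positive gene (identical data, new ID) gets an
  # identical signature
  ds2 <- syn$dataset
  X2 <- rbind(ds2$X_LR, dup = ds2$X_LR[syn$training$positives[1], ])
  F2 <- rbind(ds2$X_FDR, dup = ds2$X_FDR[syn$training$positives[1], ])
  rownames(X2)[nrow(X2)] <- rownames(F2)[nrow(F2)] <- "gdup"
  ds2 <- expression_dataset(X2, F2, syn$dataset$features)
  tr2 <- training_set(c(syn$training$positives, "gdup"),
                      syn$training$negatives)
  m2 <- dls_train(ds2, tr2)
  s_orig <- m2$signatures[[syn$training$positives[1]]]
  s_dup <- m2$signatures[["gdup"]]
  expect_identical(s_dup$features, s_orig$features)
  expect_equal(s_dup$ess, s_orig$ess, tolerance = 1e-9)

  # label-permutation null: valid signatures collapse
  set.seed(30)
  shuffled <- sample(syn$dataset$gene_ids)
  tr_null <- training_set(shuffled[1:16], shuffled[17:60])
  m_null <- suppressWarnings(dls_train(syn$dataset, tr_null))
  nv_null <- sum(vapply(m_null$signatures, `[[`, TRUE, "valid"))
  expect_lte(nv_null, 2)
})
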