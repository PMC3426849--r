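#' Parameters controlling signature search, classification and FND
#'
#' Collects every tunable of the DLS pipeline in one validated object.
#' Defaults follow the method's published constraints where those are stated
#' (FDR seeding cutoff 0.1, 20% candidate rule, negative-term fraction 5%)
#' and this package's documented completions elsewhere (see the methods
#' vignette).
#'
#' @param beta Non-negative weight on negative co-expression in the ESS
#'   denominator. `beta = 0` ignores negatives entirely.
#' @param tau_valid Validity threshold on the ESS; a signature is used for
#'   prediction only if its ESS strictly exceeds this. Must be in (0, 1).
#' @param fdr_init FDR cutoff seeding the initial feature set of signFS.
#' @param candidate_frac Fraction of all features (lowest FDR first, not yet
#'   selected) eligible for addition at each signFS iteration.
#' @param sigmoid_midpoint,sigmoid_steepness Shape of the logistic soft
#'   threshold separating strong from weak co-expression.
#' @param alpha_halfsize Feature count at which the signature-size penalty
#'   reaches 1/2; `alpha(n) = n / (n + alpha_halfsize)`.
#' @param max_iters Cap on signFS iterations.
#' @param min_improve Convergence tolerance of the greedy search: a move
#'   is applied only if it improves the ESS by more than this. The ESS
#'   lives on [0, 1], so the default 1e-3 treats sub-0.1% gains --
#'   typically chance-co-expression dilution, not signal -- as noise.
#' @param bootstrap Logical; temporarily discard likely false-negative
#'   training genes at each signFS iteration.
#' @param boot_min_coexpr Minimum |cosine| for a negative to be discarded.
#' @param boot_top_k Discard at most this many negatives per iteration;
#'   `NULL` means `max(1, ceiling(0.01 * |C-|))`, resolved at run time.
#' @param conf_threshold Posterior confidence required for a prediction.
#' @param seed Integer seed for any randomized components (the core training
#'   loop is deterministic).
#' @return An object of class `dls_params` (a validated list).
#' @examples
#' p <- dls_params(beta = 2)
#' p$tau_valid
#' @export
dls_params <- function(beta = 1,
                       tau_valid = 0.5,
                       fdr_init = 0.1,
                       candidate_frac = 0.2,
                       sigmoid_midpoint = 0.75,
                       sigmoid_steepness = 30,
                       alpha_halfsize = 5,
                       max_iters = 100L,
                       min_improve = 1e-3,
                       bootstrap = FALSE,
                       boot_min_coexpr = 0.8,
                       boot_top_k = NULL,
                       conf_threshold = 0.9,
                       seed = 1L) {
  stopifnot(beta >= 0,
            tau_valid > 0, tau_valid < 1,
            fdr_init >= 0, fdr_init <= 1,
            candidate_frac > 0, candidate_frac <= 1,
            sigmoid_steepness > 0,
            alpha_halfsize > 0,
            max_iters >= 1,
            min_improve >= 0,
            is.logical(bootstrap),
            boot_min_coexpr >= 0, boot_min_coexpr <= 1,
            is.null(boot_top_k) || boot_top_k >= 1,
            conf_threshold >= 0, conf_threshold <= 1)
  structure(list(beta = beta, tau_valid = tau_valid, fdr_init = fdr_init,
                 candidate_frac = candidate_frac,
                 sigmoid_midpoint = sigmoid_midpoint,
                 sigmoid_steepness = sigmoid_steepness,
                 alpha_halfsize = alpha_halfsize,
                 max_iters = as.integer(max_iters),
                 min_improve = min_improve,
                 bootstrap = bootstrap,
                 boot_min_coexpr = boot_min_coexpr,
                 boot_top_k = boot_top_k,
                 conf_threshold = conf_threshold,
                 seed = as.integer(seed)),
            class = "dls_params")
}

#' @export
print.dls_params <- function(x, ...) {
  cat("DLS parameters:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-18s %s\n", nm, if (is.null(v)) "<auto>" else format(v)))
  }
  invisible(x)
}

resolve_boot_top_k <- function(params, n_neg) {
  if (is.null(params$boot_top_k)) max(1L, ceiling(0.01 * n_neg))
  else as.integer(params$boot_top_k)
}
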