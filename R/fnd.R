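#' One iteration of False-Negatives Discovery
#'
#' Three steps narrow the candidate list Theta (a subset of the original
#' negative class): (1) a model is trained with the bootstrap option and
#' Theta is bounded to the negatives discarded by at least one valid
#' signature; (2) the trained signatures classify the genes in Theta and
#' those not predicted positive are filtered out; (3) a signature is
#' searched for each remaining candidate (bootstrap off, the candidate
#' temporarily treated as positive), and the candidate is confirmed as a
#' false negative iff its ESS exceeds `tau_valid` and its positive
#' co-expression component is at least the mean c_pos of the iteration's
#' valid positive-class signatures -- i.e. it is discriminatively
#' connected and at least as connected as an average positive gene.
#' Confirmed genes move from the negative to the positive class.
#'
#' @param state An `FNDState` from [fnd_init()].
#' @param dataset An [expression_dataset()].
#' @param params A [dls_params()].
#' @param bandwidth_spec Passed to [fit_densities()] for step 2.
#' @param ablate_bootstrap Train step 1 without the bootstrap option (an
#'   ablation control; no negatives are ever flagged, so no false
#'   negatives can be discovered).
#' @return The updated state (fields `training`, `candidates`,
#'   `confirmed`, `iteration`, `history`).
#' @export
fnd_iteration <- function(state, dataset, params = dls_params(),
                          bandwidth_spec = "silverman",
                          ablate_bootstrap = FALSE) {
  training <- state$training
  if (length(training$positives) < 2)
    stop("FND needs >= 2 positive genes")
  params_boot <- params; params_boot$bootstrap <- !ablate_bootstrap
  model <- dls_train(dataset, training, params_boot)
  vs <- valid_signatures(model)
  detected <- sort(unique(unlist(lapply(vs, `[[`, "discarded_negatives"))))
  theta1 <- intersect(state$candidates, detected)

  theta2 <- character()
  if (length(theta1) && length(vs)) {
    # candidates are "temporarily discarded": keep them out of the
    # negative KDE samples, or their own co-expression mass would cap
    # their posteriors
    model_flt <- model
    model_flt$training <- training_set(training$positives,
                                       setdiff(training$negatives, theta1),
                                       training$process_term)
    model_flt <- fit_densities(model_flt, dataset, bandwidth_spec)
    pred <- predict_all(model_flt, dataset, params$conf_threshold,
                        genes = theta1)
    theta2 <- intersect(theta1, unique(pred$gene))
  }

  mean_cpos <- if (length(vs))
    mean(vapply(vs, `[[`, 0, "c_pos")) else Inf
  params_plain <- params; params_plain$bootstrap <- FALSE
  confirmed_now <- character()
  for (g in theta2) {
    tr_g <- training_set(c(training$positives, g),
                         setdiff(training$negatives, g),
                         training$process_term)
    sig <- signfs(g, dataset, tr_g, params_plain)
    if (sig$ess > params$tau_valid && sig$c_pos >= mean_cpos)
      confirmed_now <- c(confirmed_now, g)
  }

  state$iteration <- state$iteration + 1L
  state$history[[state$iteration]] <-
    list(theta_after_bootstrap = theta1,
         theta_after_classify = theta2,
         confirmed = confirmed_now,
         mean_cpos = mean_cpos,
         n_valid_signatures = length(vs))
  state$confirmed <- c(state$confirmed, confirmed_now)
  state$candidates <- setdiff(state$candidates, confirmed_now)
  state$training <- training_set(
    c(training$positives, confirmed_now),
    setdiff(training$negatives, confirmed_now),
    training$process_term, training$negative_terms)
  state
}

#' Initial FND state: every negative is a candidate
#'
#' @param training A [training_set()].
#' @return An `FNDState`.
#' @export
fnd_init <- function(training) {
  structure(list(iteration = 0L, training = training,
                 candidates = training$negatives,
                 confirmed = character(), history = list()),
            class = "FNDState")
}

#' Run False-Negatives Discovery to fixpoint
#'
#' Iterates [fnd_iteration()] until an iteration confirms no new false
#' negatives or `max_iter` is reached. By default confirmed genes end in
#' the positive class of the refined training set (the FND-DLS
#' configuration); with `promote = FALSE` they are only removed from the
#' negatives.
#'
#' @inheritParams fnd_iteration
#' @param training A [training_set()].
#' @param max_iter Maximum number of iterations (>= 1).
#' @param ablate_bootstrap Disable the bootstrap in step 1 (ablation).
#' @param promote Move confirmed FNs into the positive class.
#' @return List with `state` (the `FNDState`) and `training` (the
#'   refined `TrainingSet`).
#' @export
run_fnd <- function(dataset, training, params = dls_params(),
                    max_iter = 10L, bandwidth_spec = "silverman",
                    promote = TRUE, ablate_bootstrap = FALSE) {
  stopifnot(max_iter >= 1)
  training <- attach_training(training, dataset)
  state <- fnd_init(training)
  for (i in seq_len(max_iter)) {
    state <- fnd_iteration(state, dataset, params, bandwidth_spec,
                           ablate_bootstrap)
    if (!length(state$history[[state$iteration]]$confirmed)) break
  }
  refined <- if (promote) state$training else
    training_set(training$positives,
                 setdiff(training$negatives, state$confirmed),
                 training$process_term, training$negative_terms)
  list(state = state, training = refined)
}

#' @export
print.FNDState <- function(x, ...) {
  cat(sprintf("FNDState: %d iteration(s), %d confirmed false negative(s)\n",
              x$iteration, length(x$confirmed)))
  invisible(x)
}
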