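#' Assign whole sessions to cross-validation folds
#'
#' Sessions are never split: each fold holds entire sessions. The assignment
#' is a seeded uniform shuffle; 5 folds is the protocol default.
#'
#' @param data a [session_set()].
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return named integer vector mapping session id to fold in 1..k.
#' @export
session_kfold_split <- function(data, k = 5L, seed = 1L) {
  ids <- names(data$sessions)
  if (k > length(ids)) stop("k = ", k, " exceeds the number of sessions (", length(ids), ")")
  set.seed(seed)
  folds <- sample(rep(seq_len(k), length.out = length(ids)))
  setNames(folds, ids)
}

#' Log-likelihood of a baseline Bernoulli model
#'
#' The baseline is a single Bernoulli rate for P(choice = right), fitted as
#' the training-set frequency (or fixed at 0.5 via `rate`), applied to the
#' test choices.
#'
#' @param train_designs,test_designs `glmhmm_designs` lists (only `y` is used).
#' @param rate optional fixed rate; default `NULL` fits the train MLE.
#' @return scalar baseline log-likelihood of the test choices.
#' @export
baseline_loglik <- function(train_designs, test_designs, rate = NULL) {
  if (is.null(rate)) {
    y_train <- unlist(lapply(train_designs, `[[`, "y"))
    rate <- mean(y_train)
  }
  rate <- min(max(rate, 1e-12), 1 - 1e-12)
  y <- unlist(lapply(test_designs, `[[`, "y"))
  sum(y * log(rate) + (1 - y) * log(1 - rate))
}

#' Bits per trial
#'
#' `(L_t - L_0) / (T_t * log(2))`: the held-out log-likelihood improvement
#' over the baseline, per trial, in base-2 units.
#'
#' @param test_ll held-out log-likelihood `L_t` (natural log).
#' @param baseline_ll baseline log-likelihood `L_0`.
#' @param n_trials number of held-out trials `T_t`.
#' @return scalar bits per trial.
#' @export
bits_per_trial <- function(test_ll, baseline_ll, n_trials) {
  stopifnot(n_trials > 0)
  (test_ll - baseline_ll) / (n_trials * log(2))
}

#' Likelihood-ratio factor implied by a bits-per-trial difference
#'
#' Returns `2^(bpt * n_trials)`, the factor by which the data are more
#' probable under the better model. A 0.015 bits-per-trial advantage over 400
#' trials is a factor of 2^6 = 64; over 4000 trials, 2^60 ~ 1.15e18.
#'
#' @param bpt bits-per-trial difference.
#' @param n_trials number of trials.
#' @return scalar likelihood ratio.
#' @export
likelihood_ratio_factor <- function(bpt, n_trials) {
  stopifnot(n_trials >= 0)
  2^(bpt * n_trials)
}

#' Held-out log-likelihood of fitted parameters
#'
#' A single forward pass over held-out sessions with training-fitted
#' parameters and the training-fitted contrast normalizer.
#'
#' @param params a [glmhmm_params()].
#' @param test_designs a `glmhmm_designs` list for the held-out sessions.
#' @return list with `ll` (sum of session marginal log-likelihoods) and `n`
#'   (trial count).
#' @export
test_loglik <- function(params, test_designs) {
  ll <- sum(vapply(test_designs, function(d) {
    forward_backward(d$X_ob, d$X_tr, d$y, params)$logZ
  }, numeric(1)))
  list(ll = ll, n = sum(vapply(test_designs, `[[`, numeric(1), "T")))
}

# build designs for a subset of sessions reusing a training normalizer
subset_designs <- function(data, ids, config, contrast_sd) {
  sub <- session_set(do.call(rbind, data$sessions[ids]))
  sub$contrast_sd <- contrast_sd
  build_designs(sub, config)
}

#' Session-level cross-validation of a GLM-HMM
#'
#' For each fold: fit on the training sessions (contrast normalizer fitted on
#' train only), score the held-out sessions with a single forward pass, and
#' report bits per trial against the train-fitted Bernoulli baseline.
#'
#' @param data a [session_set()].
#' @param K number of states.
#' @param prior a [prior_config()].
#' @param config a [feature_config()].
#' @param k number of folds (default 5).
#' @param seed fold-assignment and restart seed.
#' @param n_restarts EM restarts per fold.
#' @param ablate_transitions fit the static-transition ablation.
#' @param baseline_rate optional fixed baseline rate (default train MLE).
#' @param folds optional precomputed [session_kfold_split()] assignment, so
#'   two model variants can share identical folds.
#' @param ... passed to [em_fit()].
#' @return data.frame of class `glmhmm_cv` with one row per fold: `fold`,
#'   `test_ll`, `baseline_ll`, `n_test`, `bpt`, `model_tag`; fitted fold
#'   models in `attr(, "fits")`.
#' @export
cv_glmhmm <- function(data, K, prior = prior_config(), config = feature_config(),
                      k = 5L, seed = 1L, n_restarts = 3L,
                      ablate_transitions = FALSE, baseline_rate = NULL,
                      folds = NULL, ...) {
  stopifnot(inherits(data, "session_set"))
  if (is.null(folds)) folds <- session_kfold_split(data, k, seed)
  k <- max(folds)
  rows <- vector("list", k)
  fits <- vector("list", k)
  for (f in seq_len(k)) {
    test_ids <- names(folds)[folds == f]
    train_ids <- names(folds)[folds != f]
    train <- session_set(do.call(rbind, data$sessions[train_ids]))
    train <- normalize_contrast(train, config)
    d_train <- build_designs(train, config)
    d_test <- subset_designs(data, test_ids, config, train$contrast_sd)
    fit <- fit_with_restarts(d_train, K, prior, n_restarts = n_restarts,
                             base_seed = seed * 1000L + f,
                             ablate_transitions = ablate_transitions, ...)
    sc <- test_loglik(fit$params, d_test)
    l0 <- baseline_loglik(d_train, d_test, rate = baseline_rate)
    rows[[f]] <- data.frame(
      fold = f, test_ll = sc$ll, baseline_ll = l0, n_test = sc$n,
      bpt = bits_per_trial(sc$ll, l0, sc$n),
      model_tag = if (ablate_transitions) "static-transitions"
                  else if (K == 1L) "1-state" else "with-GLM-T",
      stringsAsFactors = FALSE)
    fits[[f]] <- fit
  }
  out <- do.call(rbind, rows)
  class(out) <- c("glmhmm_cv", "data.frame")
  attr(out, "fits") <- fits
  attr(out, "folds") <- folds
  out
}

#' Compare models with and without input-driven transitions
#'
#' Fits the full GLM-HMM and the static-transition ablation (`W_tr` fixed at
#' zero, baseline logits `B` free) on identical folds and seeds, so the
#' difference in held-out bits per trial is attributable to the transition
#' model alone. Also returns, per trial, the MAP-state posterior probability
#' under each model (the confidence scatter), and a percentile bootstrap over
#' folds for the bits-per-trial difference.
#'
#' @inheritParams cv_glmhmm
#' @param n_boot bootstrap resamples over folds (default 2000).
#' @param map_scatter if `TRUE` (default), additionally fit both models on the
#'   pooled data and return per-trial MAP-state posterior probabilities under
#'   each (the confidence scatter); disable to skip the two extra fits.
#' @return list with `cv_full`, `cv_static` (fold tables), `delta_bpt`
#'   (mean fold difference), `delta_se` (SE over folds), `ci68`, `ci95`
#'   (bootstrap percentile intervals), and, with `map_scatter`,
#'   `map_prob_scatter` (data.frame with per-trial MAP posterior probabilities
#'   under both models) plus the two pooled fits.
#' @export
compare_transition_models <- function(data, K, prior = prior_config(),
                                      config = feature_config(), k = 5L,
                                      seed = 1L, n_restarts = 3L,
                                      n_boot = 2000L, map_scatter = TRUE,
                                      ...) {
  folds <- session_kfold_split(data, k, seed)
  cv_full <- cv_glmhmm(data, K, prior, config, seed = seed,
                       n_restarts = n_restarts, folds = folds, ...)
  cv_static <- cv_glmhmm(data, K, prior, config, seed = seed,
                         n_restarts = n_restarts, folds = folds,
                         ablate_transitions = TRUE, ...)
  d <- cv_full$bpt - cv_static$bpt
  set.seed(seed)
  boot <- replicate(n_boot, mean(sample(d, length(d), replace = TRUE)))
  out <- list(cv_full = cv_full, cv_static = cv_static,
              delta_bpt = mean(d), delta_se = sd(d) / sqrt(length(d)),
              ci68 = quantile(boot, c(0.16, 0.84), names = FALSE),
              ci95 = quantile(boot, c(0.025, 0.975), names = FALSE))
  if (map_scatter) {
    # per-trial MAP-state posterior confidence under each model (pooled fits)
    full_fit <- glmhmm(data, K, prior, config, n_restarts = n_restarts,
                       seed = seed, ...)
    static_fit <- glmhmm(data, K, prior, config, n_restarts = n_restarts,
                         seed = seed, ablate_transitions = TRUE, ...)
    out$map_prob_scatter <- data.frame(
      p_full = unlist(lapply(full_fit$posteriors,
                             function(b) apply(b$phi, 1, max))),
      p_static = unlist(lapply(static_fit$posteriors,
                               function(b) apply(b$phi, 1, max))))
    out$full_fit <- full_fit
    out$static_fit <- static_fit
  }
  out
}
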