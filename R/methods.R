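#' @export
print.glmhmm <- function(x, ...) {
  cat("Input-driven GLM-HMM fit\n")
  cat("  states (K):        ", x$K, if (x$ablated) " [static transitions]" else "", "\n", sep = "")
  cat("  sessions / trials:  ", length(x$data$sessions), " / ", n_trials(x$data), "\n", sep = "")
  cat("  log-posterior:      ", format(x$logpost, digits = 8), "\n", sep = "")
  cat("  EM iterations:      ", x$n_iters,
      " (", if (x$converged) paste0("converged: ", x$reason) else "not converged", ")\n", sep = "")
  if (!is.na(x$restart_index)) {
    cat("  best restart:       ", x$restart_index, "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.glmhmm <- function(object, ...) {
  p <- object$params
  ob <- p$W_ob
  colnames(ob) <- object$feature_config$obs_covariates
  tr <- p$W_tr
  colnames(tr) <- object$feature_config$tr_covariates
  rownames(ob) <- rownames(tr) <- paste0("state_", seq_len(p$K))
  A_bar <- Reduce(`+`, lapply(object$designs, function(d) {
    A <- transition_tensor(d$X_tr, p)
    apply(A, c(2, 3), mean) * d$T
  })) / n_trials(object$data)
  occ <- table(factor(unlist(object$map_labels), levels = seq_len(p$K)))
  out <- list(K = p$K, pi = p$pi, W_ob = ob, W_tr = tr, B = p$B,
              transition_matrix = A_bar,
              dwell = expected_dwell_times(A_bar),
              occupancy = as.numeric(occ) / sum(occ),
              logpost = object$logpost, n_iters = object$n_iters,
              converged = object$converged)
  class(out) <- "summary.glmhmm"
  out
}

#' @export
print.summary.glmhmm <- function(x, ...) {
  cat("Input-driven GLM-HMM (K =", x$K, ")\n\n")
  cat("Observation weights (per-state Bernoulli GLM):\n")
  print(round(x$W_ob, 3))
  cat("\nTransition filters (per destination state):\n")
  print(round(x$W_tr, 3))
  cat("\nBaseline transition logits B:\n")
  print(round(x$B, 3))
  cat("\nCovariate-averaged transition matrix:\n")
  print(round(x$transition_matrix, 3))
  cat("\nExpected dwell (trials):",
      paste(format(x$dwell, digits = 3), collapse = " "), "\n")
  cat("Fractional occupancy (MAP):",
      paste(format(x$occupancy, digits = 3), collapse = " "), "\n")
  cat("Initial distribution pi:",
      paste(format(x$pi, digits = 3), collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.glmhmm <- function(object, ...) {
  p <- object$params
  list(pi = p$pi, W_ob = p$W_ob, W_tr = p$W_tr, B = p$B)
}

#' @export
logLik.glmhmm <- function(object, ...) {
  ll <- sum(vapply(object$posteriors, `[[`, numeric(1), "logZ"))
  p <- object$params
  df <- (p$K - 1) + length(p$W_ob) + length(p$W_tr) + length(p$B)
  structure(ll, df = df, nobs = n_trials(object$data), class = "logLik")
}

#' Predictions from a fitted GLM-HMM
#'
#' @param object a fitted [glmhmm()] object.
#' @param newdata optional [session_set()] or data.frame of trials; defaults
#'   to the training data. The training contrast normalizer is reused.
#' @param type `"state"` for per-trial posterior state probabilities (list of
#'   T x K matrices), `"map"` for MAP state labels, or `"response"` for the
#'   posterior-weighted probability of a rightward choice per trial.
#' @param ... unused.
#' @return see `type`.
#' @export
predict.glmhmm <- function(object, newdata = NULL,
                           type = c("state", "map", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    designs <- object$designs
    bundles <- object$posteriors
  } else {
    if (is.data.frame(newdata)) newdata <- session_set(newdata)
    newdata$contrast_sd <- object$contrast_sd
    designs <- build_designs(newdata, object$feature_config)
    bundles <- lapply(designs, function(d) {
      forward_backward(d$X_ob, d$X_tr, d$y, object$params)
    })
  }
  switch(type,
    state = lapply(bundles, `[[`, "phi"),
    map = lapply(bundles, map_states),
    response = Map(function(d, b) {
      P <- plogis(d$X_ob %*% t(object$params$W_ob))
      rowSums(b$phi * P)
    }, designs, bundles)
  )
}

#' @export
residuals.glmhmm <- function(object, ...) {
  pr <- predict(object, type = "response")
  Map(function(d, p) d$y - p, object$designs, pr)
}

#' Simulate choices from a fitted GLM-HMM
#'
#' Re-simulates latent states and choices on the fitted model's own task
#' (stimulus sequences and block structure taken from the training data),
#' recursively updating the history covariates from the simulated trials.
#'
#' @param object a fitted [glmhmm()] object.
#' @param nsim number of simulated datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return a list of `nsim` results from [simulate_agent()].
#' @export
simulate.glmhmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, nsim)
  lapply(seq_len(nsim), function(i) {
    simulate_agent(object$data, object$params, object$feature_config,
                   seed = seeds[i], contrast_sd = object$contrast_sd)
  })
}

#' Plot a fitted GLM-HMM
#'
#' Two base-graphics panels: per-state psychometric curves and the EM
#' log-posterior trace.
#'
#' @param x a fitted [glmhmm()] object.
#' @param which `"psychometric"`, `"trace"`, or both (default).
#' @param ... unused.
#' @export
plot.glmhmm <- function(x, which = c("psychometric", "trace"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  if ("psychometric" %in% which) {
    pc <- psychometric_curves(x)
    grid <- pc$contrast_grid
    graphics::matplot(grid * 100, pc$state_curves, type = "l", lty = 1,
                      xlab = "signed contrast (%)", ylab = "P(choice = right)",
                      ylim = c(0, 1), main = "State psychometric curves")
    graphics::lines(grid * 100, pc$mixture_curve, lwd = 2, col = "black")
    graphics::abline(h = 0.5, v = 0, col = "grey", lty = 3)
  }
  if ("trace" %in% which) {
    graphics::plot(x$logpost_trace, type = "b", pch = 16, cex = 0.6,
                   xlab = "EM iteration", ylab = "log-posterior",
                   main = "EM trace")
  }
  invisible(x)
}
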