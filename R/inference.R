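#' Forward-backward inference for one session
#'
#' Exact E-step quantities via scaled (normalized-message) forward and backward
#' recursions. The forward recursion is seeded with `pi_k * p(y_1 | z_1 = k)`
#' and propagated through the per-trial transition matrices; per-trial
#' rescaling constants are accumulated so the marginal log-likelihood `logZ`
#' is exact.
#'
#' @param X_ob observation design matrix T x D_ob.
#' @param X_tr transition design matrix T x D_tr.
#' @param choices binary 0/1 vector of length T.
#' @param params a [glmhmm_params()].
#' @return object of class `posterior_bundle`: list with
#'   \describe{
#'     \item{phi}{T x K single posterior state probabilities (rows sum to 1).}
#'     \item{mu}{(T-1) x K x K joint posteriors of consecutive states; each
#'       trial slice sums to 1.}
#'     \item{logZ}{marginal log-likelihood of the session's choices.}
#'     \item{alpha_hat, beta_hat}{scaled forward/backward messages.}
#'     \item{log_scale}{per-trial log rescaling constants (sum = logZ).}
#'   }
#' @export
forward_backward <- function(X_ob, X_tr, choices, params) {
  X_ob <- as.matrix(X_ob)
  T_ <- nrow(X_ob)
  stopifnot(T_ >= 1L, length(choices) == T_)
  logB <- bernoulli_loglik_matrix(X_ob, as.numeric(choices), params$W_ob)
  A <- transition_tensor(X_tr, params)
  out <- .fb_core(logB, as.numeric(A), params$pi)
  K <- params$K
  if (T_ > 1L) {
    out$mu <- array(out$mu, dim = c(T_ - 1L, K, K))
  } else {
    out$mu <- array(numeric(0), dim = c(0L, K, K))
  }
  structure(out, class = "posterior_bundle")
}

#' @export
print.posterior_bundle <- function(x, ...) {
  cat("posterior_bundle: T =", nrow(x$phi), "| K =", ncol(x$phi),
      "| logZ =", format(x$logZ, digits = 6), "\n")
  invisible(x)
}

#' Expected complete-data log-likelihood
#'
#' The EM surrogate objective for one session:
#' `sum_t sum_jk mu[t,j,k] log A_t[j,k] + sum_tk phi[t,k] log p(y_t | k) +
#' sum_k phi[1,k] log pi_k`, with per-trial transition matrices from
#' [transition_tensor()]. Always bounded above by the bundle's `logZ`
#' (equality at K = 1).
#'
#' @param bundle a `posterior_bundle` computed for the same data/params.
#' @inheritParams forward_backward
#' @return scalar expected complete-data log-likelihood.
#' @export
expected_complete_loglik <- function(bundle, X_ob, X_tr, choices, params) {
  T_ <- nrow(bundle$phi)
  logB <- bernoulli_loglik_matrix(as.matrix(X_ob), as.numeric(choices), params$W_ob)
  out <- sum(bundle$phi * logB) +
    sum(bundle$phi[1, ] * log(pmax(params$pi, 1e-300)))
  if (T_ > 1L) {
    logA <- log_transition_tensor(X_tr, params)
    out <- out + sum(bundle$mu * logA[-1, , , drop = FALSE])
  }
  out
}

#' Maximum-posterior state labels
#'
#' Per-trial argmax of the single posterior state probabilities; exact ties are
#' broken toward the lowest state index, deterministically.
#'
#' @param bundle a `posterior_bundle`.
#' @return integer vector of state labels in 1..K.
#' @export
map_states <- function(bundle) {
  apply(bundle$phi, 1L, which.max)
}
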