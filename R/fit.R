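# ---- weight vector packing ----------------------------------------------

pack_weights <- function(W_ob, W_tr, B, ablate = FALSE) {
  if (ablate) c(as.vector(W_ob), as.vector(B))
  else c(as.vector(W_ob), as.vector(W_tr), as.vector(B))
}

unpack_weights <- function(theta, K, D_ob, D_tr, ablate = FALSE, W_tr0 = NULL) {
  n_ob <- K * D_ob
  W_ob <- matrix(theta[seq_len(n_ob)], K, D_ob)
  if (ablate) {
    W_tr <- W_tr0
    B <- matrix(theta[n_ob + seq_len(K * K)], K, K)
  } else {
    W_tr <- matrix(theta[n_ob + seq_len(K * D_tr)], K, D_tr)
    B <- matrix(theta[n_ob + K * D_tr + seq_len(K * K)], K, K)
  }
  list(W_ob = W_ob, W_tr = W_tr, B = B)
}

# ---- M-step objective ----------------------------------------------------

# Pool the per-session E-step posteriors into flat matrices: the expected
# complete log-likelihood is additive over trials, so the M-step never needs
# session boundaries (transition terms drop each session's first trial).
pool_estats <- function(designs, bundles, K) {
  keep <- vapply(designs, function(d) d$T > 1L, logical(1))
  mu_by_origin <- lapply(seq_len(K), function(i) {
    do.call(rbind, lapply(bundles[keep], function(b) {
      m <- b$mu[, i, , drop = FALSE]
      dim(m) <- c(dim(b$mu)[1L], K)
      m
    }))
  })
  list(
    X_ob = do.call(rbind, lapply(designs, `[[`, "X_ob")),
    y = unlist(lapply(designs, `[[`, "y"), use.names = FALSE),
    phi = do.call(rbind, lapply(bundles, `[[`, "phi")),
    X2 = do.call(rbind, lapply(designs[keep], function(d) {
      d$X_tr[-1L, , drop = FALSE]
    })),
    mu = mu_by_origin
  )
}

# Negative (expected complete log-likelihood + Gaussian log-prior kernel) and
# its analytic gradient over flattened {W_ob, W_tr, B}. Normalizing constants
# of the priors are omitted here (they do not move the argmax); the EM trace
# uses log_posterior, which keeps them.
mstep_eval <- function(theta, st, K, D_ob, D_tr, prior,
                       ablate = FALSE, W_tr0 = NULL) {
  w <- unpack_weights(theta, K, D_ob, D_tr, ablate, W_tr0)
  eta <- st$X_ob %*% t(w$W_ob)
  val <- sum(st$phi * (st$y * eta - log1pexp(eta)))
  G_ob <- t(st$phi * (st$y - plogis(eta))) %*% st$X_ob
  G_tr <- matrix(0, K, D_tr)
  G_B <- matrix(0, K, K)
  if (!is.null(st$X2) && nrow(st$X2) > 0L) {
    S <- st$X2 %*% t(w$W_tr)                 # destination scores
    Gtot <- matrix(0, nrow(S), K)
    for (i in seq_len(K)) {
      L <- sweep(S, 2L, w$B[i, ], "+")
      m <- row_max(L)
      lse <- m + log(rowSums(exp(L - m)))
      mu_i <- st$mu[[i]]
      ri <- rowSums(mu_i)
      val <- val + sum(mu_i * L) - sum(ri * lse)
      Gi <- mu_i - ri * exp(L - lse)
      G_B[i, ] <- colSums(Gi)
      Gtot <- Gtot + Gi
    }
    G_tr <- t(Gtot) %*% st$X2
  }
  val <- val - 0.5 * prior$lambda_ob * sum(w$W_ob^2) -
    0.5 * prior$lambda_tr * (sum(w$W_tr^2) + sum(w$B^2))
  G_ob <- G_ob - prior$lambda_ob * w$W_ob
  G_tr <- G_tr - prior$lambda_tr * w$W_tr
  G_B <- G_B - prior$lambda_tr * w$B
  list(value = -val, grad = -pack_weights(G_ob, G_tr, G_B, ablate))
}

# optim-compatible fn/gr pair sharing one evaluation per theta
mstep_fngr <- function(st, K, D_ob, D_tr, prior, ablate, W_tr0) {
  cache <- new.env(parent = emptyenv())
  cache$theta <- NULL
  ensure <- function(theta) {
    if (is.null(cache$theta) || !identical(theta, cache$theta)) {
      cache$res <- mstep_eval(theta, st, K, D_ob, D_tr, prior, ablate, W_tr0)
      cache$theta <- theta
    }
    cache$res
  }
  list(fn = function(theta) ensure(theta)$value,
       gr = function(theta) ensure(theta)$grad)
}

# penalized one-state Bernoulli GLM on pooled trials (used for initialization
# and as the K = 1 reduction)
fit_pooled_glm <- function(designs, prior) {
  X <- do.call(rbind, lapply(designs, `[[`, "X_ob"))
  y <- unlist(lapply(designs, `[[`, "y"))
  negll <- function(w) {
    eta <- drop(X %*% w)
    -(sum(y * eta - log1pexp(eta)) - 0.5 * prior$lambda_ob * sum(w^2))
  }
  neggr <- function(w) {
    eta <- drop(X %*% w)
    -(drop(t(X) %*% (y - plogis(eta))) - prior$lambda_ob * w)
  }
  opt <- optim(numeric(ncol(X)), negll, neggr, method = "L-BFGS-B",
               control = list(maxit = 500, factr = 1e4))
  if (opt$convergence != 0 && opt$convergence != 52) {
    stop("one-state GLM fit failed: ", opt$message)
  }
  opt$par
}

#' Initialize GLM-HMM parameters
#'
#' Observation weights start from a penalized one-state Bernoulli GLM fitted to
#' the pooled trials, with independent Gaussian noise (scale `noise_scale`)
#' added per state to break symmetry. Transition filters start at zero (no
#' initial knowledge of input-driven transitions), baseline logits at zero
#' except a common positive diagonal offset (a sticky start), and the initial
#' state distribution uniform.
#'
#' @param designs a `glmhmm_designs` object from [build_designs()].
#' @param K number of states.
#' @param seed integer seed for the initialization noise (`NULL` = leave RNG
#'   state alone).
#' @param noise_scale standard deviation of the initialization noise
#'   (default 0.2).
#' @param prior a [prior_config()] (regularizes the one-state GLM).
#' @param diag_offset positive baseline self-transition logit (default 1.5).
#' @return a [glmhmm_params()].
#' @export
initialize_params <- function(designs, K, seed = NULL, noise_scale = 0.2,
                              prior = prior_config(), diag_offset = 1.5) {
  stopifnot(K >= 1L)
  if (!is.null(seed)) set.seed(seed)
  w0 <- fit_pooled_glm(designs, prior)
  D_ob <- length(w0)
  D_tr <- ncol(designs[[1L]]$X_tr)
  W_ob <- matrix(rep(w0, each = K), K, D_ob)
  if (K > 1L && noise_scale > 0) {
    W_ob <- W_ob + matrix(rnorm(K * D_ob, sd = noise_scale), K, D_ob)
  }
  glmhmm_params(pi = rep(1 / K, K),
                W_ob = W_ob,
                W_tr = matrix(0, K, D_tr),
                B = diag(diag_offset, K))
}

#' Fit a GLM-HMM by expectation-maximization from a given start
#'
#' Alternates an exact E-step ([forward_backward()] over all sessions) with an
#' M-step that maximizes the expected complete-data log-likelihood plus the
#' Gaussian log-prior jointly over \{`W_ob`, `W_tr`, `B`\} by L-BFGS-B with
#' analytic gradients, and updates `pi` by its closed-form
#' Dirichlet-regularized update from the first-trial posteriors. Stops when the
#' log-posterior improves by less than `tol`, when the M-step no longer moves
#' the weights, or at `max_iters`. A decrease of the log-posterior beyond
#' numerical tolerance (1e-6) is a hard error, as it signals a gradient bug.
#'
#' @param designs a `glmhmm_designs` object.
#' @param init starting [glmhmm_params()].
#' @param prior a [prior_config()].
#' @param max_iters maximum EM iterations (default 300).
#' @param tol convergence tolerance on the log-posterior (default 1e-4).
#' @param ablate_transitions if `TRUE`, `W_tr` is held at zero and only `B` is
#'   free: the static-transition (no input modulation) ablation.
#' @param mstep_control `control` list for the M-step [stats::optim()] call
#'   (default `list(maxit = 100, factr = 1e6)`); lower `factr` for
#'   tight-convergence checks.
#' @return list of class `glmhmm_em` with elements `params`, `logpost`,
#'   `logpost_trace`, `converged`, `reason`, `n_iters`.
#' @export
em_fit <- function(designs, init, prior = prior_config(), max_iters = 300L,
                   tol = 1e-4, ablate_transitions = FALSE,
                   mstep_control = list(maxit = 100, factr = 1e6)) {
  params <- init
  K <- params$K
  D_ob <- ncol(params$W_ob)
  D_tr <- ncol(params$W_tr)
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  reason <- "max_iters"
  for (it in seq_len(max_iters)) {
    bundles <- lapply(designs, function(d) {
      forward_backward(d$X_ob, d$X_tr, d$y, params)
    })
    lp <- sum(vapply(bundles, `[[`, numeric(1), "logZ")) +
      log_prior(params, prior)
    trace <- c(trace, lp)
    if (lp < prev - 1e-6) {
      stop(sprintf(
        "log-posterior decreased at EM iteration %d (%.8g -> %.8g); gradient bug",
        it, prev, lp))
    }
    if (it > 1L && lp - prev < tol) {
      converged <- TRUE
      reason <- "logposterior_tol"
      break
    }
    prev <- lp
    # pi update: Dirichlet-regularized closed form, floored at 0
    phi1 <- colSums(do.call(rbind, lapply(bundles, function(b) b$phi[1L, ])))
    pi_new <- pmax(phi1 + prior$gamma_pi - 1, 0)
    if (sum(pi_new) <= 0) pi_new <- rep(1, K)
    params$pi <- pi_new / sum(pi_new)
    # weight update
    theta0 <- pack_weights(params$W_ob, params$W_tr, params$B,
                           ablate_transitions)
    st <- pool_estats(designs, bundles, K)
    fg <- mstep_fngr(st, K, D_ob, D_tr, prior, ablate_transitions,
                     params$W_tr)
    opt <- optim(theta0, fn = fg$fn, gr = fg$gr,
                 method = "L-BFGS-B", control = mstep_control)
    w <- unpack_weights(opt$par, K, D_ob, D_tr, ablate_transitions, params$W_tr)
    moved <- max(abs(opt$par - theta0))
    params$W_ob <- w$W_ob
    params$W_tr <- w$W_tr
    params$B <- w$B
    if (moved < 1e-8) {
      converged <- TRUE
      reason <- "mstep_stationary"
      break
    }
  }
  list(params = params, logpost = trace[length(trace)], logpost_trace = trace,
       converged = converged, reason = reason, n_iters = length(trace))
}

#' Fit with multiple random restarts
#'
#' Runs [initialize_params()] + [em_fit()] once per seed and returns the fit
#' with the highest final training log-posterior. Fifty initializations is the
#' protocol default.
#'
#' @inheritParams em_fit
#' @param K number of states.
#' @param n_restarts number of restarts (default 50).
#' @param seeds integer seeds, one per restart (default `base_seed + 1:n`).
#' @param base_seed offset for default seeds.
#' @param noise_scale initialization noise scale.
#' @param ... passed to [em_fit()].
#' @return the best `glmhmm_em` result, with `restart_index`, `seed` and
#'   `restart_traces` (all restarts' traces) attached.
#' @export
fit_with_restarts <- function(designs, K, prior = prior_config(),
                              n_restarts = 50L, seeds = NULL, base_seed = 0L,
                              noise_scale = 0.2, ...) {
  stopifnot(n_restarts >= 1L)
  if (is.null(seeds)) seeds <- base_seed + seq_len(n_restarts)
  stopifnot(length(seeds) == n_restarts)
  best <- NULL
  traces <- vector("list", n_restarts)
  errors <- character(0)
  for (r in seq_len(n_restarts)) {
    fit <- tryCatch({
      init <- initialize_params(designs, K, seed = seeds[r],
                                noise_scale = noise_scale, prior = prior)
      em_fit(designs, init, prior, ...)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      errors <- c(errors, conditionMessage(fit))
      next
    }
    traces[[r]] <- fit$logpost_trace
    if (is.null(best) || fit$logpost > best$logpost) {
      best <- fit
      best$restart_index <- r
      best$seed <- seeds[r]
    }
  }
  if (is.null(best)) {
    stop("all ", n_restarts, " restarts failed; first error: ", errors[1L])
  }
  best$restart_traces <- traces
  best
}

#' Grid search over the prior width
#'
#' Fits the model once per candidate `sigma` (shared between `sigma_ob` and
#' `sigma_tr` unless `sigma_tr_grid` is given) on the training sessions and
#' scores held-out validation sessions in bits per trial. The default grid is
#' \{0.25, 0.5, 1, 2, 4, 8, 16\}; the shipped default prior width of 4 is the
#' value this selection produced in the underlying study and is not recomputed
#' at fit time.
#'
#' @param data a [session_set()].
#' @param K number of states.
#' @param grid numeric vector of candidate sigma values.
#' @param val_sessions character vector of session ids held out for
#'   validation; default: a seeded 20% draw.
#' @param config a [feature_config()].
#' @param seed seed for the default validation draw and restarts.
#' @param n_restarts restarts per candidate (default 3 to keep the search
#'   affordable; raise for final fits).
#' @param ... passed to [em_fit()].
#' @return list with `best_sigma` and `table` (sigma, validation bits per
#'   trial).
#' @export
grid_search_sigma <- function(data, K, grid = c(0.25, 0.5, 1, 2, 4, 8, 16),
                              val_sessions = NULL, config = feature_config(),
                              seed = 1L, n_restarts = 3L, ...) {
  if (length(grid) == 0L) stop("empty sigma grid")
  ids <- names(data$sessions)
  if (is.null(val_sessions)) {
    set.seed(seed)
    n_val <- max(1L, round(0.2 * length(ids)))
    val_sessions <- sample(ids, n_val)
  }
  train_ids <- setdiff(ids, val_sessions)
  if (length(train_ids) == 0L) stop("no training sessions left")
  train <- session_set(do.call(rbind, data$sessions[train_ids]))
  val <- session_set(do.call(rbind, data$sessions[val_sessions]))
  train <- normalize_contrast(train, config)
  val$contrast_sd <- train$contrast_sd
  d_train <- build_designs(train, config)
  d_val <- build_designs(val, config)
  bpt <- vapply(grid, function(sg) {
    pr <- prior_config(sigma_ob = sg, sigma_tr = sg)
    fit <- fit_with_restarts(d_train, K, pr, n_restarts = n_restarts,
                             base_seed = seed, ...)
    ll <- sum(vapply(d_val, function(d) {
      forward_backward(d$X_ob, d$X_tr, d$y, fit$params)$logZ
    }, numeric(1)))
    l0 <- baseline_loglik(d_train, d_val)
    bits_per_trial(ll, l0, sum(vapply(d_val, `[[`, numeric(1), "T")))
  }, numeric(1))
  tab <- data.frame(sigma = grid, val_bpt = bpt)
  list(best_sigma = grid[which.max(bpt)], table = tab)
}

# gradient of the log-posterior w.r.t. flattened weights at arbitrary params;
# by Fisher's identity this equals the E-step surrogate gradient evaluated
# with posteriors recomputed at the same params
logpost_grad <- function(theta, designs, K, D_ob, D_tr, prior, pi) {
  w <- unpack_weights(theta, K, D_ob, D_tr)
  params <- glmhmm_params(pi, w$W_ob, w$W_tr, w$B)
  bundles <- lapply(designs, function(d) {
    forward_backward(d$X_ob, d$X_tr, d$y, params)
  })
  st <- pool_estats(designs, bundles, K)
  -mstep_eval(theta, st, K, D_ob, D_tr, prior)$grad
}

#' Posterior standard deviations of the weights
#'
#' Numerical Hessian of the negative log-posterior at the optimum over the
#' flattened \{`W_ob`, `W_tr`, `B`\}, computed by central differences of the
#' exact (Fisher-identity) gradient of the marginal log-posterior. Standard
#' deviations are the square roots of the inverse-Hessian diagonal. A
#' non-positive-definite Hessian raises a diagnostic error listing the
#' near-null directions (expected if the priors are disabled, by softmax shift
#' invariance) rather than being silently pseudo-inverted.
#'
#' @param fit a fitted [glmhmm()] object or `glmhmm_em` result.
#' @param designs the `glmhmm_designs` the model was fitted to (taken from the
#'   fit when present).
#' @param h finite-difference step (default 1e-5).
#' @return list with `sd` (named per-weight standard deviations), `hessian`.
#' @export
posterior_sd_weights <- function(fit, designs = NULL, h = 1e-5) {
  params <- fit$params
  if (is.null(designs)) designs <- fit$designs
  stopifnot(!is.null(designs))
  K <- params$K
  D_ob <- ncol(params$W_ob)
  D_tr <- ncol(params$W_tr)
  theta <- pack_weights(params$W_ob, params$W_tr, params$B)
  n <- length(theta)
  Hn <- matrix(0, n, n)
  prior <- if (!is.null(fit$prior)) fit$prior else prior_config()
  for (i in seq_len(n)) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    gp <- logpost_grad(tp, designs, K, D_ob, D_tr, prior, params$pi)
    gm <- logpost_grad(tm, designs, K, D_ob, D_tr, prior, params$pi)
    Hn[, i] <- -(gp - gm) / (2 * h)   # negative log-posterior curvature
  }
  Hn <- (Hn + t(Hn)) / 2
  ev <- eigen(Hn, symmetric = TRUE)
  if (any(ev$values <= 0)) {
    bad <- which(ev$values <= max(ev$values) * 1e-10)
    stop("Hessian of the negative log-posterior is not positive definite; ",
         length(bad), " null direction(s) with eigenvalues: ",
         paste(format(ev$values[bad], digits = 3), collapse = ", "))
  }
  sds <- sqrt(diag(solve(Hn)))
  nm <- c(paste0("W_ob[", rep(seq_len(K), times = D_ob), ",",
                 rep(seq_len(D_ob), each = K), "]"),
          paste0("W_tr[", rep(seq_len(K), times = D_tr), ",",
                 rep(seq_len(D_tr), each = K), "]"),
          paste0("B[", rep(seq_len(K), times = K), ",",
                 rep(seq_len(K), each = K), "]"))
  list(sd = setNames(sds, nm), hessian = Hn)
}

#' Fit an input-driven GLM-HMM to trial-level choice data
#'
#' The main model-fitting entry point. Builds observation and transition
#' design matrices from the sessions (normalizing contrast on these data
#' unless a normalizer is already attached), then fits a K-state hidden Markov
#' model whose choice emissions are per-state Bernoulli GLMs and whose
#' transitions are a multinomial GLM over exponentially filtered trial-history
#' covariates, by MAP expectation-maximization with multiple restarts.
#'
#' @param data a [session_set()] or a data.frame of trials (see
#'   [session_set()] for the required columns).
#' @param K number of latent states (>= 1).
#' @param prior a [prior_config()].
#' @param config a [feature_config()].
#' @param n_restarts number of EM restarts (default 50, the protocol value;
#'   reduce for exploratory fits).
#' @param seed base seed for initialization noise.
#' @param warm_start optional [glmhmm_params()] to start from, in which case a
#'   single EM run is performed (the pooled-then-individual protocol: fit
#'   pooled data first, then warm-start per-group fits from the pooled
#'   optimum).
#' @param ablate_transitions fit the static-transition ablation (`W_tr` pinned
#'   at zero, `B` free).
#' @param max_iters,tol EM stopping controls.
#' @param noise_scale initialization noise scale.
#' @return an object of class `glmhmm` with components `params`, `prior`,
#'   `feature_config`, `logpost`, `logpost_trace`, `converged`, `posteriors`
#'   (per-session `posterior_bundle`s at the optimum), `map_labels`, `data`,
#'   `designs` and bookkeeping fields. Methods: `print`, `summary`, `coef`,
#'   `logLik`, `predict`, `simulate`, `residuals`, `plot`.
#' @examples
#' sim <- simulate_benchmark_dataset(n_sessions = 4, trials_per_session = 150,
#'                                   input_driven = TRUE, seed = 1)
#' fit <- glmhmm(sim$data, K = 2, n_restarts = 2, max_iters = 50)
#' fit
#' coef(fit)$W_ob
#' @export
glmhmm <- function(data, K, prior = prior_config(), config = feature_config(),
                   n_restarts = 50L, seed = 1L, warm_start = NULL,
                   ablate_transitions = FALSE, max_iters = 300L, tol = 1e-4,
                   noise_scale = 0.2) {
  if (is.data.frame(data)) data <- session_set(data)
  stopifnot(inherits(data, "session_set"), K >= 1L)
  if (is.null(data$contrast_sd)) data <- normalize_contrast(data, config)
  designs <- build_designs(data, config)
  if (!is.null(warm_start)) {
    fit <- em_fit(designs, warm_start, prior, max_iters = max_iters, tol = tol,
                  ablate_transitions = ablate_transitions)
    fit$restart_index <- NA_integer_
    fit$seed <- NA_integer_
  } else {
    fit <- fit_with_restarts(designs, K, prior, n_restarts = n_restarts,
                             base_seed = seed, noise_scale = noise_scale,
                             max_iters = max_iters, tol = tol,
                             ablate_transitions = ablate_transitions)
  }
  bundles <- lapply(designs, function(d) {
    forward_backward(d$X_ob, d$X_tr, d$y, fit$params)
  })
  structure(list(
    params = fit$params, K = K, prior = prior, feature_config = config,
    logpost = fit$logpost, logpost_trace = fit$logpost_trace,
    converged = fit$converged, reason = fit$reason, n_iters = fit$n_iters,
    restart_index = fit$restart_index, seed = fit$seed,
    ablated = ablate_transitions,
    posteriors = bundles,
    map_labels = lapply(bundles, map_states),
    data = data, designs = designs,
    contrast_sd = attr(designs, "contrast_sd"),
    call = match.call()
  ), class = "glmhmm")
}
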