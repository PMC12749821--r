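#' Task configuration for the block-structured 2AFC simulator
#'
#' Emulates the structure of the standard mouse visual two-alternative
#' forced-choice task with stimulus-prior blocks: each session opens with
#' `n_unbiased` trials in which the stimulus side is equiprobable, followed by
#' alternating bias blocks in which the right-side stimulus probability is 0.8
#' or 0.2. Block lengths follow a shifted, truncated geometric law: after
#' `block_min` trials a constant per-trial switch hazard applies, truncated at
#' `block_max`; the hazard is solved numerically so the mean block length
#' equals `block_mean_target`.
#'
#' @param n_unbiased unbiased opening trials per session (default 90).
#' @param p_right_blocks the two biased right-stimulus probabilities
#'   (default c(0.8, 0.2)).
#' @param block_min,block_max block length bounds in trials (defaults 20, 100).
#' @param block_mean_target mean block length in trials (default 50).
#' @param contrast_set contrast magnitudes as fractions
#'   (default \{0, 0.0625, 0.125, 0.25, 0.5, 1\}).
#' @param n_sessions number of sessions to generate (default 20).
#' @param trials_per_session trials per session; a scalar, or a length-2 range
#'   sampled uniformly per session (default 500).
#' @return object of class `task_config` (includes the solved switch hazard).
#' @export
task_config <- function(n_unbiased = 90L, p_right_blocks = c(0.8, 0.2),
                        block_min = 20L, block_max = 100L,
                        block_mean_target = 50,
                        contrast_set = c(0, 0.0625, 0.125, 0.25, 0.5, 1),
                        n_sessions = 20L, trials_per_session = 500L) {
  stopifnot(length(p_right_blocks) == 2L, length(contrast_set) >= 1L)
  if (!(block_min <= block_mean_target && block_mean_target <= block_max)) {
    stop("block_mean_target must lie in [block_min, block_max]")
  }
  m <- block_max - block_min
  target_excess <- block_mean_target - block_min
  # E[min(G, m)] for G ~ Geom(p) on {0, 1, ...} is (1-p)(1-(1-p)^m)/p
  trunc_mean <- function(p) (1 - p) * (1 - (1 - p)^m) / p
  if (target_excess <= 0) {
    hazard <- 1
  } else if (target_excess >= m * (1 - 1e-9)) {
    stop("infeasible block_mean_target for the given block_min/block_max")
  } else {
    hazard <- uniroot(function(p) trunc_mean(p) - target_excess,
                      c(1e-8, 1 - 1e-8), tol = 1e-12)$root
  }
  structure(list(n_unbiased = as.integer(n_unbiased),
                 p_right_blocks = p_right_blocks,
                 block_min = as.integer(block_min),
                 block_max = as.integer(block_max),
                 block_mean_target = block_mean_target,
                 hazard = hazard,
                 contrast_set = contrast_set,
                 n_sessions = as.integer(n_sessions),
                 trials_per_session = trials_per_session),
            class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat("task_config:", x$n_sessions, "session(s) x",
      paste(x$trials_per_session, collapse = "-"), "trials |",
      x$n_unbiased, "unbiased then blocks", x$block_min, "-", x$block_max,
      "(mean", x$block_mean_target, ")\n")
  invisible(x)
}

# one block length: shifted, truncated geometric
sample_block_length <- function(config) {
  config$block_min + min(rgeom(1L, config$hazard),
                         config$block_max - config$block_min)
}

#' Generate task structure: blocks and stimuli, no choices
#'
#' Per session: `n_unbiased` trials with right-stimulus probability 0.5, then
#' alternating 0.8/0.2 bias blocks (first biased side random) with shifted
#' truncated-geometric lengths. Stimulus side is Bernoulli(block p_right);
#' contrast magnitude is uniform over `contrast_set`; `signed_contrast` =
#' side x magnitude.
#'
#' @param config a [task_config()].
#' @param seed integer seed.
#' @return a [session_set()] (built without choice validation) whose trials
#'   have `signed_contrast` and `block_p_right` but `NA` choices and rewards.
#' @export
generate_task <- function(config = task_config(), seed = 1L) {
  set.seed(seed)
  sessions <- vector("list", config$n_sessions)
  for (s in seq_len(config$n_sessions)) {
    T_ <- if (length(config$trials_per_session) == 2L) {
      sample(config$trials_per_session[1L]:config$trials_per_session[2L], 1L)
    } else as.integer(config$trials_per_session)
    p_right <- numeric(0)
    p_right <- rep(0.5, min(config$n_unbiased, T_))
    cur <- sample(config$p_right_blocks, 1L)
    while (length(p_right) < T_) {
      len <- sample_block_length(config)
      p_right <- c(p_right, rep(cur, len))
      cur <- config$p_right_blocks[config$p_right_blocks != cur][1L]
    }
    p_right <- p_right[seq_len(T_)]
    side <- rbinom(T_, 1L, p_right)            # 1 = right
    mag <- sample(config$contrast_set, T_, replace = TRUE)
    sessions[[s]] <- data.frame(
      session_id = sprintf("sim%03d", s),
      trial_index = seq_len(T_) - 1L,
      signed_contrast = ifelse(side == 1L, mag, -mag),
      choice = NA_real_,
      reward = NA_real_,
      block_p_right = p_right,
      stringsAsFactors = FALSE)
  }
  out <- session_set(do.call(rbind, sessions), validate = FALSE)
  out
}

#' Simulate a GLM-HMM agent on a task
#'
#' Trial loop per session: the transition covariates (exponentially filtered
#' choice, rewarded-side and reward series plus warm-up bases) are updated
#' recursively from the simulated history; the latent state is sampled from
#' the initial distribution on trial 1 and from the per-trial transition row
#' afterwards; the choice is Bernoulli under the state's observation GLM; the
#' reward is +1 iff the choice matches the rewarded side (for zero-contrast
#' trials the rewarded side is drawn from the block's p_right).
#'
#' @param task a [session_set()] with stimuli (e.g. from [generate_task()]);
#'   any existing choices are ignored and regenerated.
#' @param params a [glmhmm_params()] (the ground-truth generator).
#' @param config a [feature_config()].
#' @param seed integer seed; fixed seeds give bit-identical datasets.
#' @param contrast_sd stimulus normalizer; default: population SD of the
#'   task's signed contrasts.
#' @param response_time_by_state optional list with `mean` (length-K vector of
#'   per-state response-time means, seconds) and `sd`; when given, a lognormal
#'   `response_time` column is added per trial from the sampled state.
#' @return list of class `glmhmm_sim` with `data` (a complete [session_set()]
#'   passing [validate_sessions()]), `states` (per-session ground-truth latent
#'   state sequences), `params`, and `contrast_sd`.
#' @export
simulate_agent <- function(task, params, config = feature_config(), seed = 1L,
                           contrast_sd = NULL,
                           response_time_by_state = NULL) {
  stopifnot(inherits(task, "session_set"), inherits(params, "glmhmm_params"))
  K <- params$K
  if (ncol(params$W_tr) != 3L + config$n_bases) {
    stop("shape mismatch: W_tr has ", ncol(params$W_tr),
         " columns but the feature config implies ", 3L + config$n_bases)
  }
  set.seed(seed)
  if (is.null(contrast_sd)) {
    x <- as.data.frame(task)$signed_contrast
    contrast_sd <- sqrt(mean((x - mean(x))^2))
  }
  decay <- exp(-1 / config$tau)
  sessions <- vector("list", length(task$sessions))
  states <- vector("list", length(task$sessions))
  names(sessions) <- names(states) <- names(task$sessions)
  for (sid in names(task$sessions)) {
    s <- task$sessions[[sid]]
    T_ <- nrow(s)
    basis <- warmup_bases(T_, config)
    block_p <- if ("block_p_right" %in% names(s)) s$block_p_right else rep(0.5, T_)
    z <- integer(T_); y <- numeric(T_); rew <- numeric(T_)
    f <- c(0, 0, 0)                      # filtered choice, side, reward
    ch_prev <- 0; side_prev <- 0; rew_prev <- 0
    for (t in seq_len(T_)) {
      if (t > 1L) {
        f <- decay * f + c(ch_prev, side_prev, rew_prev)
      }
      x_tr <- c(f, basis[t, ])
      if (t == 1L) {
        z[t] <- sample.int(K, 1L, prob = params$pi)
      } else {
        logits <- params$B[z[t - 1L], ] + drop(params$W_tr %*% x_tr)
        pr <- exp(logits - max(logits))
        z[t] <- sample.int(K, 1L, prob = pr / sum(pr))
      }
      x_ob <- c(s$signed_contrast[t] / contrast_sd, ch_prev, side_prev, 1)
      p_right <- plogis(sum(params$W_ob[z[t], ] * x_ob))
      y[t] <- rbinom(1L, 1L, p_right)
      correct_side <- if (s$signed_contrast[t] > 0) 1L
                      else if (s$signed_contrast[t] < 0) 0L
                      else rbinom(1L, 1L, block_p[t])
      rew[t] <- if (y[t] == correct_side) 1 else -1
      ch_prev <- 2 * y[t] - 1
      side_prev <- ch_prev * rew[t]
      rew_prev <- rew[t]
    }
    s$choice <- y
    s$reward <- rew
    if (!is.null(response_time_by_state)) {
      mu <- response_time_by_state$mean[z]
      sdl <- if (!is.null(response_time_by_state$sd)) response_time_by_state$sd else 0.3
      s$response_time <- exp(rnorm(T_, log(mu), sdl))
    }
    sessions[[sid]] <- s
    states[[sid]] <- z
  }
  data <- session_set(do.call(rbind, sessions))
  data$contrast_sd <- contrast_sd
  structure(list(data = data, states = states, params = params,
                 contrast_sd = contrast_sd),
            class = "glmhmm_sim")
}

#' @export
print.glmhmm_sim <- function(x, ...) {
  cat("glmhmm_sim: ground-truth K =", x$params$K, "\n")
  print(x$data)
  invisible(x)
}

#' Synthetic ground-truth parameter templates
#'
#' Documented generator parameter sets for 2- and 4-state agents, used by the
#' simulator and tests. These are synthetic templates with the qualitative
#' structure reported for mice in this task -- engaged states with large
#' stimulus weight and small bias, disengaged states with small stimulus
#' weight and large side bias; transition side-filters signed by the
#' destination's side bias and the reward filter positive into disengaged
#' states -- not fitted values from any real dataset.
#'
#' @param K 2 or 4.
#' @param input_driven if `FALSE`, the transition filters are zeroed (static
#'   transitions; baseline logits only).
#' @param n_bases warm-up basis count (default 3).
#' @return a [glmhmm_params()].
#' @export
example_glmhmm_params <- function(K = c(2L, 4L), input_driven = TRUE,
                                  n_bases = 3L) {
  K <- as.integer(K[1L])
  basis_cols <- function(v) matrix(rep(v, n_bases), ncol = n_bases)
  if (K == 2L) {
    # state 1: engaged; state 2: disengaged, right-biased
    W_ob <- rbind(c(3.0, 0.2, 0.1, 0.0),
                  c(0.5, 1.0, 0.3, 1.5))
    W_tr <- cbind(rbind(c(-0.25, -0.15, -0.4),
                        c( 0.25,  0.15,  0.4)),
                  rbind(basis_cols(-0.4)[1, ], basis_cols(0.4)[1, ]))
    B <- matrix(0, 2, 2); diag(B) <- 2.5
    pi <- c(0.6, 0.4)
  } else if (K == 4L) {
    # 1: engaged-L, 2: engaged-R, 3: disengaged-L, 4: disengaged-R
    W_ob <- rbind(c(3.0, 0.2, 0.1, -0.5),
                  c(3.0, 0.2, 0.1,  0.5),
                  c(0.5, 0.8, 0.3, -2.5),
                  c(0.5, 0.8, 0.3,  2.5))
    W_tr <- cbind(rbind(c(-0.2, -0.15, -0.3),
                        c( 0.2,  0.15, -0.3),
                        c(-0.2, -0.15,  0.3),
                        c( 0.2,  0.15,  0.3)),
                  rbind(basis_cols(-0.3)[1, ], basis_cols(-0.3)[1, ],
                        basis_cols(0.3)[1, ], basis_cols(0.3)[1, ]))
    B <- matrix(0, 4, 4); diag(B) <- 3
    pi <- rep(0.25, 4)
  } else {
    stop("templates are shipped for K = 2 and K = 4")
  }
  if (!input_driven) W_tr[] <- 0
  glmhmm_params(pi, W_ob, W_tr, B)
}

#' Generate one complete synthetic dataset
#'
#' Convenience wrapper: [generate_task()] then [simulate_agent()] with an
#' [example_glmhmm_params()] template.
#'
#' @param K ground-truth states (2 or 4).
#' @param n_sessions,trials_per_session task size.
#' @param input_driven whether transitions are input-driven.
#' @param seed integer seed.
#' @param config a [feature_config()].
#' @return a `glmhmm_sim` (see [simulate_agent()]).
#' @export
simulate_benchmark_dataset <- function(K = 2L, n_sessions = 20L,
                                       trials_per_session = 500L,
                                       input_driven = TRUE, seed = 1L,
                                       config = feature_config()) {
  tc <- task_config(n_sessions = n_sessions,
                    trials_per_session = trials_per_session)
  task <- generate_task(tc, seed = seed)
  simulate_agent(task, example_glmhmm_params(K, input_driven = input_driven,
                                             n_bases = config$n_bases),
                 config, seed = seed + 1L)
}

#' Benchmark pair: static vs input-driven transition generators
#'
#' Dataset A is generated with zero transition filters (static transitions);
#' dataset B with the template's nonzero filters (side filters signed by the
#' destination's side bias, reward filter positive into disengaged states).
#' Both come with ground truth for [compare_transition_models()].
#'
#' @param K ground-truth states (2 or 4).
#' @param n_sessions,trials_per_session task size per dataset.
#' @param seed integer seed.
#' @param config a [feature_config()].
#' @return list with elements `static` and `input_driven`, each a
#'   `glmhmm_sim`.
#' @export
make_benchmark_pair <- function(K = 4L, n_sessions = 20L,
                                trials_per_session = 500L, seed = 1L,
                                config = feature_config()) {
  list(
    static = simulate_benchmark_dataset(K, n_sessions, trials_per_session,
                                        input_driven = FALSE, seed = seed,
                                        config = config),
    input_driven = simulate_benchmark_dataset(K, n_sessions,
                                              trials_per_session,
                                              input_driven = TRUE,
                                              seed = seed + 1000L,
                                              config = config)
  )
}
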