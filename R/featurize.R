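#' Feature configuration for design matrices
#'
#' Controls how per-session observation and transition design matrices are
#' built: the exponential-filter time constant, the warm-up temporal basis, the
#' contrast normalizer and the covariate sets.
#'
#' The observation covariates are, in order: the normalized signed stimulus
#' contrast, the previous choice (sign-coded -1/+1), the previously rewarded
#' side (`prev_choice * prev_reward`, the -1/+1 code for "stay after reward,
#' switch after failure") and a constant bias of 1. The transition covariates
#' are exponentially filtered versions of the -1/+1 choice, rewarded-side and
#' reward series (all sharing one time constant `tau`) followed by `n_bases`
#' warm-up basis columns supported on the first `warmup_span` trials of each
#' session.
#'
#' @param tau positive time constant of the causal exponential filter, in
#'   trials. Default 4, the value selected by held-out log-likelihood in the
#'   underlying analysis.
#' @param n_bases number of warm-up basis functions (default 3).
#' @param warmup_span number of initial trials spanned by the warm-up basis
#'   (default 100).
#' @param contrast_sd either a positive numeric normalizer for signed contrast
#'   or `"fit"` to estimate it from data via [normalize_contrast()].
#' @return an object of class `feature_config`.
#' @export
feature_config <- function(tau = 4, n_bases = 3L, warmup_span = 100L,
                           contrast_sd = "fit") {
  if (!is.numeric(tau) || tau <= 0) stop("tau must be a positive real")
  n_bases <- as.integer(n_bases)
  warmup_span <- as.integer(warmup_span)
  stopifnot(n_bases >= 1L, warmup_span >= n_bases)
  if (!(identical(contrast_sd, "fit") ||
        (is.numeric(contrast_sd) && contrast_sd > 0))) {
    stop("contrast_sd must be a positive number or \"fit\"")
  }
  structure(list(
    tau = tau, n_bases = n_bases, warmup_span = warmup_span,
    contrast_sd = contrast_sd,
    obs_covariates = c("stimulus", "prev_choice", "prev_stim_side", "bias"),
    tr_covariates = c("filt_prev_choice", "filt_prev_stim_side",
                      "filt_prev_reward", paste0("basis_", seq_len(n_bases)))
  ), class = "feature_config")
}

#' @export
print.feature_config <- function(x, ...) {
  cat("feature_config: tau =", x$tau, "| bases =", x$n_bases,
      "over", x$warmup_span, "trials | contrast_sd =",
      if (identical(x$contrast_sd, "fit")) "fit" else format(x$contrast_sd, digits = 4),
      "\n")
  invisible(x)
}

#' Fit or apply the contrast normalizer
#'
#' The stimulus covariate is the signed contrast divided by a scale constant.
#' With `contrast_sd = "fit"` the constant is the population standard deviation
#' of the signed contrasts pooled across sessions, and it is stored on the
#' returned session set so held-out sessions reuse the training-set constant.
#'
#' @param data a [session_set()].
#' @param config a [feature_config()].
#' @return the session set with `contrast_sd` set to the (fitted or supplied)
#'   normalizer.
#' @export
normalize_contrast <- function(data, config = feature_config()) {
  stopifnot(inherits(data, "session_set"), inherits(config, "feature_config"))
  if (identical(config$contrast_sd, "fit")) {
    x <- as.data.frame(data)$signed_contrast
    # population SD (divide by n): a scale constant, not a sample estimate
    s <- sqrt(mean((x - mean(x))^2))
    if (!is.finite(s) || s <= 0) {
      stop("degenerate input: zero contrast variance, cannot fit normalizer")
    }
    data$contrast_sd <- s
  } else {
    data$contrast_sd <- config$contrast_sd
  }
  data
}

#' Causal exponential filter over a trial series
#'
#' First-order recursive filter with decay `exp(-1/tau)` and a strict one-trial
#' lag: `f[1] = 0`, `f[t] = exp(-1/tau) * f[t-1] + s[t-1]`. The output at trial
#' t therefore uses only trials before t; filter state never crosses session
#' boundaries (apply per session).
#'
#' @param series numeric input series of length T.
#' @param tau positive time constant in trials.
#' @return filtered series of length T.
#' @export
exponential_filter <- function(series, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0) {
    stop("tau must be a positive real")
  }
  T_ <- length(series)
  stopifnot(T_ >= 1L)
  d <- exp(-1 / tau)
  f <- numeric(T_)
  if (T_ >= 2L) {
    for (t in 2:T_) f[t] <- d * f[t - 1L] + series[t - 1L]
  }
  f
}

#' Warm-up temporal basis
#'
#' `n_bases` non-overlapping raised-cosine bumps tiling trials 1..`warmup_span`,
#' each peak-normalized to 1 and exactly zero after `warmup_span`. The columns
#' are linearly independent by construction (disjoint supports).
#'
#' @param T_ session length in trials.
#' @param config a [feature_config()] (uses `n_bases`, `warmup_span`).
#' @return numeric matrix `T_ x n_bases`.
#' @export
warmup_bases <- function(T_, config = feature_config()) {
  stopifnot(T_ >= 1L)
  n <- config$n_bases
  span <- config$warmup_span
  B <- matrix(0, nrow = T_, ncol = n,
              dimnames = list(NULL, paste0("basis_", seq_len(n))))
  edges <- round(seq(0L, span, length.out = n + 1L))
  t_all <- seq_len(min(T_, span))
  for (j in seq_len(n)) {
    lo <- edges[j] + 1L
    hi <- edges[j + 1L]
    idx <- t_all[t_all >= lo & t_all <= hi]
    if (length(idx) > 0L) {
      center <- (lo + hi) / 2
      width <- hi - lo + 1L
      B[idx, j] <- 0.5 * (1 + cos(2 * pi * (idx - center) / width))
    }
  }
  # peak-normalize on the full-span support
  full <- seq_len(span)
  for (j in seq_len(n)) {
    lo <- edges[j] + 1L; hi <- edges[j + 1L]
    center <- (lo + hi) / 2; width <- hi - lo + 1L
    peak <- max(0.5 * (1 + cos(2 * pi * (full[full >= lo & full <= hi] - center) / width)))
    if (peak > 0) B[, j] <- B[, j] / peak
  }
  B
}

sign_code_choice <- function(choice) 2 * choice - 1   # 0/1 -> -1/+1

# per-session history series used by both design builders and the simulator:
# prev_choice, prev_stim_side (= prev_choice * prev_reward), prev_reward,
# each padded with 0 at t = 1 (the neutral point of a +/-1 code)
history_series <- function(choice, reward) {
  T_ <- length(choice)
  ch <- sign_code_choice(choice)
  side <- ch * reward
  list(
    prev_choice = c(0, ch[-T_])[seq_len(T_)],
    prev_stim_side = c(0, side[-T_])[seq_len(T_)],
    prev_reward = c(0, reward[-T_])[seq_len(T_)]
  )
}

#' Observation design matrix for one session
#'
#' Columns in order: `stimulus` (signed contrast / normalizer), `prev_choice`
#' in \{-1, +1\} (0-padded at the first trial), `prev_stim_side` =
#' `prev_choice * prev_reward` (the previously rewarded side) and `bias` = 1.
#'
#' @param session per-session data.frame (one element of
#'   `session_set$sessions`).
#' @param config a [feature_config()].
#' @param contrast_sd numeric normalizer (from [normalize_contrast()]).
#' @return numeric matrix `T x 4` with column names.
#' @export
build_observation_design <- function(session, config = feature_config(),
                                     contrast_sd = NULL) {
  if (is.null(contrast_sd)) {
    if (!is.numeric(config$contrast_sd)) {
      stop("contrast_sd must be supplied or fixed in the config; ",
           "run normalize_contrast() first")
    }
    contrast_sd <- config$contrast_sd
  }
  T_ <- nrow(session)
  h <- history_series(session$choice, session$reward)
  X <- cbind(
    stimulus = session$signed_contrast / contrast_sd,
    prev_choice = h$prev_choice,
    prev_stim_side = h$prev_stim_side,
    bias = rep(1, T_)
  )
  X
}

#' Transition design matrix for one session
#'
#' Columns in order: exponential-filtered versions of the -1/+1 previous-choice,
#' previously-rewarded-side and reward series (shared time constant `tau`),
#' followed by the warm-up basis columns. Row t contains only information
#' available before trial t; all filters reset at session boundaries.
#'
#' @inheritParams build_observation_design
#' @return numeric matrix `T x (3 + n_bases)` with column names.
#' @export
build_transition_design <- function(session, config = feature_config()) {
  T_ <- nrow(session)
  ch <- sign_code_choice(session$choice)
  side <- ch * session$reward
  X <- cbind(
    filt_prev_choice = exponential_filter(ch, config$tau),
    filt_prev_stim_side = exponential_filter(side, config$tau),
    filt_prev_reward = exponential_filter(session$reward, config$tau),
    warmup_bases(T_, config)
  )
  X
}

#' Build all per-session design matrices
#'
#' @param data a [session_set()] whose `contrast_sd` has been set (see
#'   [normalize_contrast()]), or a config with numeric `contrast_sd`.
#' @param config a [feature_config()].
#' @return list of class `glmhmm_designs`: per session, a list with `X_ob`,
#'   `X_tr`, `y` (choices) and `T`; attributes record column names and the
#'   normalizer used.
#' @export
build_designs <- function(data, config = feature_config()) {
  stopifnot(inherits(data, "session_set"))
  contrast_sd <- data$contrast_sd
  if (is.null(contrast_sd)) {
    if (is.numeric(config$contrast_sd)) {
      contrast_sd <- config$contrast_sd
    } else {
      data <- normalize_contrast(data, config)
      contrast_sd <- data$contrast_sd
    }
  }
  out <- lapply(data$sessions, function(s) {
    list(
      X_ob = build_observation_design(s, config, contrast_sd),
      X_tr = build_transition_design(s, config),
      y = as.numeric(s$choice),
      T = nrow(s)
    )
  })
  structure(out, class = "glmhmm_designs",
            contrast_sd = contrast_sd,
            obs_covariates = config$obs_covariates,
            tr_covariates = config$tr_covariates,
            config = config)
}
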