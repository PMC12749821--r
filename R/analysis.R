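#' Per-state and model-average psychometric curves
#'
#' For each state, the probability of a rightward choice over a signed
#' contrast grid with history covariates at their neutral value (0) and bias
#' fixed at 1. The model-average curve weights the per-state curves by
#' one-step-ahead predictive state probabilities along the fitted data
#' (`pred_t = phi_{t-1} %*% A_t`, averaged over trials), i.e. the mixture a
#' trial faces given the latent state of the preceding trial. An empirical
#' overlay with Wilson binomial confidence intervals can be computed from the
#' trial table.
#'
#' @param object a fitted [glmhmm()] object, or a [glmhmm_params()] (in which
#'   case `contrast_sd` and optionally `state_weights` must be supplied).
#' @param contrast_grid signed contrasts (fractions) to evaluate
#'   (default `seq(-1, 1, length.out = 41)`).
#' @param contrast_sd stimulus normalizer (taken from the fit when available).
#' @param state_weights optional mixture weights; default: average predictive
#'   state probabilities for a fit, uniform for bare params.
#' @param empirical_from optional [session_set()] for the empirical overlay.
#' @return list of class `glmhmm_psychometric`: `contrast_grid`,
#'   `state_curves` (grid x K), `mixture_curve`, `state_weights` and
#'   optionally `empirical` (data.frame contrast, p_right, lo, hi, n).
#' @export
psychometric_curves <- function(object, contrast_grid = seq(-1, 1, length.out = 41),
                                contrast_sd = NULL, state_weights = NULL,
                                empirical_from = NULL) {
  if (inherits(object, "glmhmm")) {
    params <- object$params
    if (is.null(contrast_sd)) contrast_sd <- object$contrast_sd
    if (is.null(state_weights)) {
      # average one-step-ahead predictive state probabilities
      acc <- numeric(params$K); n <- 0
      for (i in seq_along(object$designs)) {
        d <- object$designs[[i]]
        phi <- object$posteriors[[i]]$phi
        A <- transition_tensor(d$X_tr, params)
        acc <- acc + params$pi
        if (d$T > 1L) {
          for (t in 2:d$T) acc <- acc + drop(phi[t - 1L, ] %*% A[t, , ])
        }
        n <- n + d$T
      }
      state_weights <- acc / n
    }
  } else {
    params <- object
    if (is.null(contrast_sd)) stop("contrast_sd required with bare parameters")
    if (is.null(state_weights)) state_weights <- rep(1 / params$K, params$K)
  }
  K <- params$K
  X <- cbind(contrast_grid / contrast_sd, 0, 0, 1)
  state_curves <- plogis(X %*% t(params$W_ob))
  colnames(state_curves) <- paste0("state_", seq_len(K))
  mixture <- drop(state_curves %*% state_weights)
  out <- list(contrast_grid = contrast_grid, state_curves = state_curves,
              mixture_curve = mixture, state_weights = state_weights)
  if (!is.null(empirical_from)) {
    df <- as.data.frame(empirical_from)
    agg <- split(df$choice, df$signed_contrast)
    xs <- as.numeric(names(agg))
    n <- vapply(agg, length, integer(1))
    k <- vapply(agg, sum, numeric(1))
    p <- k / n
    z <- 1.96
    den <- 1 + z^2 / n
    ctr <- (p + z^2 / (2 * n)) / den
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    out$empirical <- data.frame(contrast = xs, p_right = p,
                                lo = pmax(0, ctr - hw), hi = pmin(1, ctr + hw),
                                n = n)
  }
  class(out) <- "glmhmm_psychometric"
  out
}

#' Expected dwell times from a transition matrix
#'
#' Geometric mean holding time per state, `1 / (1 - A[k, k])`, evaluated on
#' the covariate-averaged transition matrix. A self-transition probability of
#' exactly 1 yields `Inf` (flagged, not an error).
#'
#' @param A_bar row-stochastic K x K matrix.
#' @return numeric vector of expected dwell times (trials); infinite entries
#'   flagged via the `"infinite"` attribute.
#' @export
expected_dwell_times <- function(A_bar) {
  A_bar <- as.matrix(A_bar)
  if (max(abs(rowSums(A_bar) - 1)) > 1e-8) stop("A_bar rows must sum to 1")
  p_stay <- diag(A_bar)
  dwell <- ifelse(p_stay >= 1, Inf, 1 / (1 - p_stay))
  attr(dwell, "infinite") <- which(!is.finite(dwell))
  dwell
}

#' Baseline transition bias and covariate-averaged transition matrix
#'
#' The bias matrix is the row-softmax of the baseline logits `B` alone (the
#' model's default transition expectations prior to input modulation); the
#' averaged matrix is the mean over all trials of the per-trial transition
#' matrices. Both are row-stochastic.
#'
#' @param fit a fitted [glmhmm()] object.
#' @return list with `bias_matrix` and `averaged_matrix`.
#' @export
transition_bias_and_matrix <- function(fit) {
  p <- fit$params
  bias <- softmax_rows(p$B)
  total <- n_trials(fit$data)
  avg <- Reduce(`+`, lapply(fit$designs, function(d) {
    apply(transition_tensor(d$X_tr, p), c(2, 3), sum)
  })) / total
  list(bias_matrix = bias, averaged_matrix = avg)
}

#' Classify states as engaged/disengaged and by side preference
#'
#' Engaged states have stimulus-weight magnitude at or above the across-state
#' median; side preference is the sign of the bias weight. A helper for
#' supplying block-congruence mappings to [state_summaries()].
#'
#' @param params a [glmhmm_params()] (or fitted [glmhmm()] object).
#' @param stim_col,bias_col columns of `W_ob` holding the stimulus and bias
#'   weights (defaults 1 and 4).
#' @return data.frame with per-state `engaged` (logical) and `side`
#'   (-1 left / +1 right / 0 neutral).
#' @export
classify_states <- function(params, stim_col = 1L, bias_col = 4L) {
  if (inherits(params, "glmhmm")) params <- params$params
  w_stim <- abs(params$W_ob[, stim_col])
  engaged <- w_stim >= median(w_stim)
  side <- sign(params$W_ob[, bias_col])
  data.frame(state = seq_len(params$K), engaged = engaged, side = side)
}

#' Summaries of inferred state usage
#'
#' Computes fractional occupancy of MAP-labeled states (overall and within
#' each block type), the number of label switches per session, the latency
#' from each bias-block onset to the first trial labeled with a
#' block-congruent state, and the session-normalized posterior time course
#' (each session's posteriors linearly interpolated to a 100-point grid, then
#' averaged).
#'
#' @param fit a fitted [glmhmm()] object (block labels are taken from the
#'   data's `block_p_right` column when present).
#' @param congruent named list mapping block type (`"0.8"`, `"0.2"`) to the
#'   integer set of congruent states; default derives it from
#'   [classify_states()] (right-side states for 0.8 blocks, left for 0.2).
#' @param grid_points time-course grid size (default 100).
#' @return list of class `glmhmm_state_summary`: `occupancy` (overall),
#'   `occupancy_by_block` (matrix block type x state, or `NULL` with a warning
#'   when block labels are missing), `state_changes` (per session),
#'   `first_transition_latency` (per bias block, trials; `NA` when the block
#'   never reaches a congruent state), `timecourse` (grid_points x K).
#' @export
state_summaries <- function(fit, congruent = NULL, grid_points = 100L) {
  K <- fit$params$K
  labels <- fit$map_labels
  occ <- table(factor(unlist(labels), levels = seq_len(K)))
  occ <- as.numeric(occ) / sum(occ)
  changes <- vapply(labels, function(l) sum(diff(l) != 0), numeric(1))
  has_blocks <- all(vapply(fit$data$sessions, function(s)
    "block_p_right" %in% names(s), logical(1)))
  occ_block <- NULL
  latency <- NULL
  if (has_blocks) {
    blocks <- lapply(fit$data$sessions, `[[`, "block_p_right")
    lab_all <- unlist(labels)
    blk_all <- unlist(blocks)
    types <- sort(unique(blk_all))
    occ_block <- t(vapply(types, function(b) {
      tab <- table(factor(lab_all[blk_all == b], levels = seq_len(K)))
      as.numeric(tab) / max(1, sum(tab))
    }, numeric(K)))
    rownames(occ_block) <- as.character(types)
    if (is.null(congruent)) {
      cls <- classify_states(fit$params)
      congruent <- list("0.8" = cls$state[cls$side > 0],
                        "0.2" = cls$state[cls$side < 0])
    }
    lat <- list()
    for (i in seq_along(labels)) {
      b <- blocks[[i]]; l <- labels[[i]]
      onsets <- c(1L, which(b[-1] != b[-length(b)]) + 1L)
      for (o in onsets) {
        btype <- as.character(b[o])
        if (!btype %in% names(congruent)) next   # unbiased opening block
        target <- congruent[[btype]]
        end <- if (any(b[o:length(b)] != b[o])) {
          o + which(b[o:length(b)] != b[o])[1L] - 2L
        } else length(b)
        hit <- which(l[o:end] %in% target)
        lat[[length(lat) + 1L]] <- data.frame(
          session = names(labels)[i], block_type = btype,
          latency = if (length(hit)) hit[1L] - 1L else NA_integer_)
      }
    }
    latency <- if (length(lat)) do.call(rbind, lat) else NULL
  } else {
    warning("no block_p_right column: occupancy by block and latency skipped")
  }
  grid <- seq(0, 1, length.out = grid_points)
  tc <- matrix(0, grid_points, K)
  for (b in fit$posteriors) {
    T_ <- nrow(b$phi)
    xin <- if (T_ > 1L) seq(0, 1, length.out = T_) else c(0, 1)
    for (k in seq_len(K)) {
      yin <- if (T_ > 1L) b$phi[, k] else rep(b$phi[1, k], 2L)
      tc[, k] <- tc[, k] + approx(xin, yin, xout = grid)$y
    }
  }
  tc <- tc / length(fit$posteriors)
  structure(list(occupancy = occ, occupancy_by_block = occ_block,
                 state_changes = changes,
                 first_transition_latency = latency,
                 timecourse = tc),
            class = "glmhmm_state_summary")
}

#' Response-time separation between disengaged and engaged states
#'
#' Difference in the 90th percentile response time (disengaged minus engaged)
#' over MAP-labeled trials, with a percentile bootstrap confidence interval
#' over trials. Quantiles use the linear-interpolation convention
#' (`stats::quantile` type 7).
#'
#' @param data a [session_set()] with a `response_time` column.
#' @param labels per-session list of MAP state labels (e.g.
#'   `fit$map_labels`).
#' @param engaged_states integer set of engaged states; all others count as
#'   disengaged.
#' @param n_boot bootstrap resamples (default 5000).
#' @param seed bootstrap seed.
#' @param prob quantile level (default 0.9).
#' @return list with `delta_t90`, `ci95`, `n_engaged`, `n_disengaged`.
#' @export
rt_engagement_separation <- function(data, labels, engaged_states,
                                     n_boot = 5000L, seed = 1L, prob = 0.9) {
  df <- as.data.frame(data)
  if (!"response_time" %in% names(df)) {
    stop("feature unavailable: no response_time column in the data")
  }
  lab <- unlist(labels)
  stopifnot(length(lab) == nrow(df))
  rt_e <- df$response_time[lab %in% engaged_states]
  rt_d <- df$response_time[!(lab %in% engaged_states)]
  if (length(rt_e) == 0L || length(rt_d) == 0L) {
    stop("need trials in both engaged and disengaged label sets")
  }
  delta <- quantile(rt_d, prob, names = FALSE) - quantile(rt_e, prob, names = FALSE)
  set.seed(seed)
  boot <- replicate(n_boot, {
    quantile(sample(rt_d, length(rt_d), replace = TRUE), prob, names = FALSE) -
      quantile(sample(rt_e, length(rt_e), replace = TRUE), prob, names = FALSE)
  })
  list(delta_t90 = delta,
       ci95 = quantile(boot, c(0.025, 0.975), names = FALSE),
       n_engaged = length(rt_e), n_disengaged = length(rt_d))
}
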