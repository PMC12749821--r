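# a tiny fitted object for analysis tests, built by a real (short) fit
fit_small <- local({
  f <- NULL
  function() {
    if (is.null(f)) {
      sim <- simulate_benchmark_dataset(K = 2, n_sessions = 4,
                                        trials_per_session = 150, seed = 17)
      f <<- glmhmm(sim$data, K = 2, n_restarts = 1, max_iters = 40,
                   tol = 1e-3)
    }
    f
  }
})

test_that("psychometric curves: flat bias-only state, monotone engaged state", {
  p <- glmhmm_params(
    pi = c(0.5, 0.5),
    W_ob = rbind(c(0, 0, 0, 0.8),    # no stimulus sensitivity, bias only
                 c(4, 0, 0, 0)),     # stimulus-driven, unbiased
    W_tr = matrix(0, 2, 6), B = diag(2))
  pc <- psychometric_curves(p, contrast_sd = 0.5)
  expect_true(all(abs(pc$state_curves[, 1] - plogis(0.8)) < 1e-12))
  expect_equal(unname(pc$state_curves[21, 2]), 0.5)          # zero contrast -> 0.5
  expect_true(all(diff(pc$state_curves[, 2]) > 0))   # monotone increasing
  # mixture lies in the pointwise convex hull of the state curves
  lo <- pmin(pc$state_curves[, 1], pc$state_curves[, 2])
  hi <- pmax(pc$state_curves[, 1], pc$state_curves[, 2])
  expect_true(all(pc$mixture_curve >= lo - 1e-12 & pc$mixture_curve <= hi + 1e-12))
})

test_that("psychometric curves from a fit include a sane empirical overlay", {
  fit <- fit_small()
  pc <- psychometric_curves(fit, empirical_from = fit$data)
  expect_equal(sum(pc$state_weights), 1, tolerance = 1e-8)
  emp <- pc$empirical
  expect_true(all(emp$lo <= emp$p_right + 1e-12 & emp$p_right <= emp$hi + 1e-12))
  expect_equal(sum(emp$n), n_trials(fit$data))
})

test_that("expected dwell times follow the geometric holding-time law", {
  A <- rbind(c(0.9, 0.1), c(0.4, 0.6))
  expect_equal(unname(expected_dwell_times(A)), c(10, 2.5), ignore_attr = TRUE)
  A0 <- rbind(c(0, 1), c(1, 0))
  expect_equal(unname(expected_dwell_times(A0)), c(1, 1), ignore_attr = TRUE)
  dI <- expected_dwell_times(diag(2))
  expect_true(all(is.infinite(dI)))
  expect_equal(attr(dI, "infinite"), 1:2)
  expect_error(expected_dwell_times(rbind(c(0.5, 0.2), c(0.1, 0.9))), "sum")
})

test_that("transition bias and averaged matrix are row-stochastic and consistent", {
  fit <- fit_small()
  tb <- transition_bias_and_matrix(fit)
  expect_lt(max(abs(rowSums(tb$bias_matrix) - 1)), 1e-10)
  expect_lt(max(abs(rowSums(tb$averaged_matrix) - 1)), 1e-10)
  # zero parameters: both uniform
  p0 <- glmhmm_params(c(0.5, 0.5), matrix(0, 2, 4), matrix(0, 2, 6),
                      matrix(0, 2, 2))
  fit0 <- fit_small()
  fit0$params <- p0
  tb0 <- transition_bias_and_matrix(fit0)
  expect_equal(tb0$bias_matrix, matrix(0.5, 2, 2))
  expect_equal(tb0$averaged_matrix, matrix(0.5, 2, 2), tolerance = 1e-12)
})

test_that("state summaries: occupancy, switches, latency, time course", {
  fit <- fit_small()
  # overwrite labels with a known pattern to pin the definitions
  T_s <- vapply(fit$data$sessions, nrow, integer(1))
  fit2 <- fit
  fit2$map_labels <- lapply(T_s, function(n) rep(c(1L, 2L), length.out = n))
  s2 <- state_summaries(fit2, congruent = list("0.8" = 2L, "0.2" = 1L))
  expect_equal(unname(s2$state_changes), unname(T_s - 1))       # alternating labels
  fit3 <- fit
  fit3$map_labels <- lapply(T_s, function(n) rep(1L, n))
  s3 <- state_summaries(fit3, congruent = list("0.8" = 1L, "0.2" = 1L))
  expect_equal(s3$occupancy, c(1, 0))
  expect_equal(unname(s3$state_changes), rep(0, length(T_s)))
  expect_true(all(s3$first_transition_latency$latency == 0))
  # real fit: occupancies sum to 1, time course rows are distributions
  s <- state_summaries(fit)
  expect_equal(sum(s$occupancy), 1)
  expect_equal(dim(s$timecourse), c(100L, 2L))
  expect_lt(max(abs(rowSums(s$timecourse) - 1)), 1e-6)
  expect_lt(max(abs(rowSums(s$occupancy_by_block) - 1)), 1e-12)
})

test_that("occupancy is invariant to session order", {
  fit <- fit_small()
  rev_fit <- fit
  rev_fit$map_labels <- rev(fit$map_labels)
  rev_fit$posteriors <- rev(fit$posteriors)
  rev_fit$data$sessions <- rev(fit$data$sessions)
  expect_equal(state_summaries(rev_fit)$occupancy,
               state_summaries(fit)$occupancy)
})

test_that("state classifier separates engaged from biased states by weights", {
  p <- example_glmhmm_params(4)
  cls <- classify_states(p)
  expect_equal(cls$engaged, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(cls$side, c(-1, 1, -1, 1))
})

test_that("response-time separation recovers a constructed shift", {
  sim <- simulate_benchmark_dataset(K = 2, n_sessions = 3,
                                    trials_per_session = 200, seed = 23)
  lab <- lapply(sim$states, identity)
  df <- as.data.frame(sim$data)
  z <- unlist(lab)
  set.seed(1)
  # identical distributions: delta ~ 0, CI covers 0
  df$response_time <- runif(nrow(df), 0.5, 1.5)
  d0 <- rt_engagement_separation(session_set(df), lab, engaged_states = 1L,
                                 n_boot = 500, seed = 2)
  expect_true(d0$ci95[1] <= 0 && 0 <= d0$ci95[2])
  # disengaged trials shifted +1 s: delta ~ 1
  df$response_time <- runif(nrow(df), 0.5, 1.5) + ifelse(z == 2, 1, 0)
  d1 <- rt_engagement_separation(session_set(df), lab, engaged_states = 1L,
                                 n_boot = 500, seed = 2)
  expect_equal(d1$delta_t90, 1, tolerance = 0.15)
  # deterministic under a fixed bootstrap seed
  d1b <- rt_engagement_separation(session_set(df), lab, engaged_states = 1L,
                                  n_boot = 500, seed = 2)
  expect_identical(d1$ci95, d1b$ci95)
  df$response_time <- NULL
  expect_error(rt_engagement_separation(session_set(df), lab, 1L),
               "response_time")
})
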