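test_that("block lengths honor the bounds and the unbiased opening", {
  tc <- task_config(n_sessions = 8, trials_per_session = 400)
  task <- generate_task(tc, seed = 21)
  for (s in task$sessions) {
    expect_equal(s$block_p_right[1:90], rep(0.5, 90))
    # runs after the opening stay within the configured bounds, except a
    # possibly truncated final block
    r <- rle(s$block_p_right[-(1:90)])
    lens <- r$lengths
    if (length(lens) > 1) {
      expect_true(all(lens[-length(lens)] >= tc$block_min))
      expect_true(all(lens <= tc$block_max))
    }
    expect_true(all(r$values %in% c(0.8, 0.2)))
    # alternation: consecutive blocks differ
    if (length(r$values) > 1) expect_true(all(diff(r$values) != 0))
  }
  # stimulus magnitude from the contrast set, side sign consistent
  df <- as.data.frame(task)
  expect_true(all(abs(df$signed_contrast) %in% tc$contrast_set))
})

test_that("the truncated-geometric hazard hits the target mean length", {
  tc <- task_config()
  set.seed(77)
  lens <- replicate(4000, glmhmm:::sample_block_length(tc))
  expect_true(all(lens >= 20 & lens <= 100))
  expect_lt(abs(mean(lens) - 50), 1)
  # infeasible target rejected
  expect_error(task_config(block_mean_target = 15), "block_mean_target")
})

test_that("simulation is reproducible and records a valid trial table", {
  s1 <- simulate_benchmark_dataset(K = 2, n_sessions = 3,
                                   trials_per_session = 100, seed = 31)
  s2 <- simulate_benchmark_dataset(K = 2, n_sessions = 3,
                                   trials_per_session = 100, seed = 31)
  expect_identical(as.data.frame(s1$data), as.data.frame(s2$data))
  expect_identical(s1$states, s2$states)
  expect_equal(nrow(validate_sessions(s1$data)), 0L)
})

test_that("the recorded history covariates match the design builders", {
  # the agent's recursively updated filters must agree exactly with the
  # design matrices rebuilt from its own trial table
  sim <- simulate_benchmark_dataset(K = 2, n_sessions = 2,
                                    trials_per_session = 80, seed = 41)
  d <- build_designs(sim$data)
  cfg <- feature_config()
  for (i in seq_along(d)) {
    s <- sim$data$sessions[[i]]
    expect_equal(d[[i]]$X_tr, build_transition_design(s, cfg))
  }
  # re-simulating with the generating params on the same task and seed,
  # covariate recursion produces identical choices (self-consistency)
  task <- generate_task(task_config(n_sessions = 2, trials_per_session = 80),
                        seed = 41)
  again <- simulate_agent(task, sim$params, cfg, seed = 42,
                          contrast_sd = sim$contrast_sd)
  expect_identical(as.data.frame(again$data), as.data.frame(sim$data))
})

test_that("agent behavior follows the generator: saturation and dwell law", {
  cfg <- feature_config()
  task <- generate_task(task_config(n_sessions = 4,
                                    trials_per_session = 300), seed = 51)
  # near-infinite stimulus weight: accuracy approaches 1 on nonzero contrast
  p_acc <- example_glmhmm_params(2)
  p_acc$W_ob[, 1] <- 50
  p_acc$W_ob[, 2:4] <- 0
  res <- simulate_agent(task, p_acc, cfg, seed = 1)
  df <- as.data.frame(res$data)
  nz <- df$signed_contrast != 0
  expect_gt(mean(df$reward[nz] == 1), 0.99)

  # static sticky transitions: dwell times follow Geometric(1 - A_kk)
  p_dw <- example_glmhmm_params(2, input_driven = FALSE)
  p_dw$B <- matrix(0, 2, 2); diag(p_dw$B) <- log(9)   # A_kk = 0.9
  res2 <- simulate_agent(task, p_dw, cfg, seed = 2)
  runs <- unlist(lapply(res2$states, function(z) rle(z)$lengths))
  expect_equal(mean(runs), 10, tolerance = 0.2)       # 1/(1 - 0.9)

  # one-hot initial distribution pins the first state
  p_pi <- example_glmhmm_params(2)
  p_pi$pi <- c(1, 0)
  res3 <- simulate_agent(task, p_pi, cfg, seed = 3)
  expect_true(all(vapply(res3$states, `[`, integer(1), 1) == 1L))
})

test_that("benchmark pair: static arm is input-independent, driven arm is not", {
  pair <- make_benchmark_pair(K = 2, n_sessions = 6, trials_per_session = 200,
                              seed = 61)
  expect_true(all(pair$static$params$W_tr == 0))
  expect_false(all(pair$input_driven$params$W_tr == 0))
  # in the input-driven arm, transitions into the disengaged state (2) become
  # more likely as filtered reward grows (positive reward filter)
  sim <- pair$input_driven
  d <- build_designs(sim$data)
  frew <- unlist(lapply(d, function(x) x$X_tr[, "filt_prev_reward"]))
  z <- unlist(sim$states)
  trans_in <- c(FALSE, z[-1] == 2 & z[-length(z)] != 2)
  keep <- unlist(lapply(d, function(x) c(FALSE, rep(TRUE, x$T - 1))))
  hi <- frew > median(frew)
  p_hi <- mean(trans_in[keep & hi])
  p_lo <- mean(trans_in[keep & !hi])
  expect_gt(p_hi, p_lo)
})
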