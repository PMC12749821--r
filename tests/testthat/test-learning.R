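small_sim <- function(seed = 1, n_sessions = 4, trials = 120) {
  simulate_benchmark_dataset(K = 2, n_sessions = n_sessions,
                             trials_per_session = trials, seed = seed)
}

test_that("initialization is deterministic and reduces correctly", {
  sim <- small_sim()
  d <- build_designs(sim$data)
  i1 <- initialize_params(d, K = 3, seed = 7)
  i2 <- initialize_params(d, K = 3, seed = 7)
  expect_identical(i1, i2)
  # zero noise: all observation rows equal the pooled GLM fit
  i0 <- initialize_params(d, K = 3, seed = 7, noise_scale = 0)
  expect_equal(i0$W_ob[1, ], i0$W_ob[2, ])
  expect_equal(i0$W_ob[2, ], i0$W_ob[3, ])
  expect_true(all(i0$W_tr == 0))
  expect_equal(i0$pi, rep(1 / 3, 3))
  # K = 1 equals the plain penalized GLM fit
  ik <- initialize_params(d, K = 1, seed = 7)
  expect_equal(unname(ik$W_ob[1, ]), unname(i0$W_ob[1, ]))
})

test_that("M-step gradient matches finite differences", {
  sim <- small_sim(seed = 5, n_sessions = 2, trials = 40)
  d <- build_designs(sim$data)
  K <- 2
  init <- initialize_params(d, K, seed = 1)
  bundles <- lapply(d, function(x) forward_backward(x$X_ob, x$X_tr, x$y, init))
  st <- glmhmm:::pool_estats(d, bundles, K)
  D_ob <- ncol(init$W_ob); D_tr <- ncol(init$W_tr)
  pr <- prior_config()
  set.seed(9)
  theta <- rnorm(K * D_ob + K * D_tr + K * K, sd = 0.5)
  ev <- glmhmm:::mstep_eval(theta, st, K, D_ob, D_tr, pr)
  h <- 1e-6
  for (i in sample(length(theta), 8)) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    fd <- (glmhmm:::mstep_eval(tp, st, K, D_ob, D_tr, pr)$value -
             glmhmm:::mstep_eval(tm, st, K, D_ob, D_tr, pr)$value) / (2 * h)
    expect_equal(ev$grad[i], fd, tolerance = 1e-4)
  }
})

test_that("EM trace is monotone and K = 1 matches the direct GLM optimum", {
  sim <- small_sim(seed = 3)
  d <- build_designs(sim$data)
  pr <- prior_config()
  fit <- em_fit(d, initialize_params(d, 2, seed = 2), pr, max_iters = 60)
  expect_true(all(diff(fit$logpost_trace) > -1e-6))
  # K = 1: EM and a direct penalized logistic fit agree
  fit1 <- em_fit(d, initialize_params(d, 1, seed = 2), pr, max_iters = 20)
  X <- do.call(rbind, lapply(d, `[[`, "X_ob"))
  y <- unlist(lapply(d, `[[`, "y"))
  # independently coded objective and gradient
  negll <- function(w) {
    eta <- drop(X %*% w)
    -sum(y * eta - log(1 + exp(eta))) + sum(w^2) / (2 * pr$sigma_ob^2)
  }
  gr <- function(w) {
    eta <- drop(X %*% w)
    -drop(t(X) %*% (y - 1 / (1 + exp(-eta)))) + w / pr$sigma_ob^2
  }
  opt <- optim(numeric(ncol(X)), negll, gr, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  expect_equal(unname(fit1$params$W_ob[1, ]), opt$par, tolerance = 1e-5)
})

test_that("restarts return the best run and beat any single run", {
  sim <- small_sim(seed = 8, n_sessions = 3, trials = 80)
  d <- build_designs(sim$data)
  pr <- prior_config()
  best <- fit_with_restarts(d, 2, pr, n_restarts = 3, max_iters = 40)
  singles <- vapply(1:3, function(s) {
    em_fit(d, initialize_params(d, 2, seed = s, prior = pr), pr,
           max_iters = 40)$logpost
  }, numeric(1))
  expect_gte(best$logpost + 1e-9, max(singles))
  expect_equal(best$logpost, singles[best$restart_index])
})

test_that("sigma grid search returns the only candidate on a singleton grid", {
  sim <- small_sim(seed = 12, n_sessions = 5, trials = 80)
  res <- grid_search_sigma(sim$data, K = 2, grid = 4,
                           val_sessions = names(sim$data$sessions)[5],
                           n_restarts = 1, max_iters = 30)
  expect_equal(res$best_sigma, 4)
  expect_equal(nrow(res$table), 1L)
  expect_true(is.finite(res$table$val_bpt))
  expect_error(grid_search_sigma(sim$data, 2, grid = numeric(0)), "empty")
})

test_that("posterior weight SDs match logistic-regression asymptotics at K = 1", {
  set.seed(44)
  n <- 4000
  X <- cbind(rnorm(n), 1)
  w_true <- c(1.5, -0.3)
  y <- rbinom(n, 1, plogis(drop(X %*% w_true)))
  df <- data.frame(session_id = "s", trial_index = seq_len(n) - 1,
                   signed_contrast = pmin(pmax(X[, 1] / 4, -1), 1),
                   choice = y, reward = sample(c(-1, 1), n, TRUE))
  ss <- session_set(df)
  ss$contrast_sd <- 0.25          # so the stimulus column reproduces X[, 1]
  d <- build_designs(ss)
  pr <- prior_config(sigma_ob = 50, sigma_tr = 4)   # near-flat on W_ob
  fit <- em_fit(d, initialize_params(d, 1, seed = 1, prior = pr), pr,
                max_iters = 10)
  fit$prior <- pr
  sds <- posterior_sd_weights(fit, d)
  # analytic Fisher information for the logistic model
  p_hat <- plogis(drop(d[[1]]$X_ob %*% fit$params$W_ob[1, ]))
  Fi <- t(d[[1]]$X_ob) %*% (d[[1]]$X_ob * (p_hat * (1 - p_hat)))
  analytic <- sqrt(diag(solve(Fi)))
  got <- sds$sd[grepl("^W_ob", names(sds$sd))]
  # stimulus and bias weight SDs (columns 1 and 4 of the design)
  expect_equal(unname(got[1]), unname(analytic[1]), tolerance = 0.1)
  expect_equal(unname(got[4]), unname(analytic[4]), tolerance = 0.1)
})
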