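test_that("emission probability matches hand arithmetic and saturates safely", {
  x <- c(1, 2, -1)
  expect_equal(emission_prob(x, c(0, 0, 0)), 0.5)
  # x . w = ln 3 -> p = 1/(1 + 1/3) = 0.75
  expect_equal(emission_prob(c(1, 0, 0), c(log(3), 5, -2)), 0.75)
  # huge logits saturate without overflow
  expect_equal(emission_prob(c(1e4, 0, 0), c(1, 0, 0)), 1)
  expect_equal(emission_prob(c(-1e4, 0, 0), c(1, 0, 0)), 0)
  # log-odds antisymmetry: p(x) + p(-x) = 1
  w <- c(0.7, -1.2, 0.4)
  expect_equal(emission_prob(x, w) + emission_prob(-x, w), 1)
  expect_error(emission_prob(c(1, 2), c(1, 2, 3)), "shape")
})

test_that("transition tensor limits: uniform, static, shift-invariant", {
  set.seed(42)
  K <- 3
  X_tr <- matrix(rnorm(20 * 4), 20)
  p0 <- glmhmm_params(rep(1 / K, K), matrix(0, K, 2),
                      matrix(0, K, 4), matrix(0, K, K))
  A <- transition_tensor(X_tr, p0)
  expect_equal(A, array(1 / K, dim = c(20, K, K)))
  # zero filters + arbitrary B: constant over trials, rows = softmax(B rows)
  B <- matrix(rnorm(K * K), K)
  pB <- glmhmm_params(rep(1 / K, K), matrix(0, K, 2), matrix(0, K, 4), B)
  AB <- transition_tensor(X_tr, pB)
  sm <- exp(B) / rowSums(exp(B))
  for (t in c(1, 10, 20)) expect_equal(AB[t, , ], sm, tolerance = 1e-12)
  # adding a constant to row i of B leaves row i unchanged
  B2 <- B; B2[2, ] <- B2[2, ] + 3.7
  AB2 <- transition_tensor(X_tr, glmhmm_params(rep(1 / K, K),
                                               matrix(0, K, 2),
                                               matrix(0, K, 4), B2))
  expect_equal(AB2[5, 2, ], AB[5, 2, ], tolerance = 1e-12)
})

test_that("transition rows sum to one for random inputs", {
  for (seed in 1:5) {
    inst <- random_instance(T_ = 15, K = 3, D_tr = 4, seed = seed)
    A <- transition_tensor(inst$X_tr, inst$params)
    expect_lt(max(abs(apply(A, c(1, 2), sum) - 1)), 1e-12)
  }
})

test_that("log-prior: uniform Dirichlet, Gaussian mode, sigma monotonicity", {
  K <- 3
  mk <- function(pi) glmhmm_params(pi, matrix(0.5, K, 2),
                                   matrix(0.2, K, 3), diag(K))
  pr <- prior_config(gamma_pi = 1)
  # gamma_pi = 1: the pi term does not depend on pi
  expect_equal(log_prior(mk(c(0.7, 0.2, 0.1)), pr),
               log_prior(mk(rep(1 / 3, 3)), pr))
  # all-zero weights maximize the Gaussian part
  z <- glmhmm_params(rep(1 / 3, 3), matrix(0, K, 2), matrix(0, K, 3),
                     matrix(0, K, K))
  expect_gt(log_prior(z, pr), log_prior(mk(rep(1 / 3, 3)), pr))
  # tightening sigma well below the weight scale penalizes nonzero weights
  nz <- glmhmm_params(rep(1 / 3, 3), matrix(2, K, 2),
                      matrix(2, K, 3), matrix(2, K, K))
  pr_tight <- prior_config(sigma_ob = 0.25, sigma_tr = 0.25)
  expect_lt(log_prior(nz, pr_tight), log_prior(nz, pr))
})

test_that("log-posterior: additivity and the wide-prior likelihood limit", {
  sim <- simulate_benchmark_dataset(K = 2, n_sessions = 1,
                                    trials_per_session = 50, seed = 2)
  d1 <- build_designs(sim$data)
  # duplicate the session: exactly twice the likelihood term
  df <- as.data.frame(sim$data)
  df2 <- df; df2$session_id <- "copy"
  both <- session_set(rbind(df, df2))
  both$contrast_sd <- sim$data$contrast_sd
  d2 <- build_designs(both)
  p <- example_glmhmm_params(2)
  pr <- prior_config()
  ll1 <- log_posterior(d1, p, pr) - log_prior(p, pr)
  ll2 <- log_posterior(d2, p, pr) - log_prior(p, pr)
  expect_equal(ll2, 2 * ll1, tolerance = 1e-10)
  # sigma -> infinity: log-posterior approaches the pure log-likelihood
  # (up to the pi term, constant at gamma_pi = 1)
  pr_wide <- prior_config(sigma_ob = 1e8, sigma_tr = 1e8)
  const <- lgamma(p$K * 1)                     # Dirichlet normalizer
  gauss_const <- -0.5 * log(2 * pi * 1e16) *
    (length(p$W_ob) + length(p$W_tr) + length(p$B))
  expect_equal(log_posterior(d1, p, pr_wide) - const - gauss_const, ll1,
               tolerance = 1e-6)
})

test_that("shift degeneracy: likelihood invariant, posterior strictly lower", {
  inst <- random_instance(T_ = 20, K = 3, D_ob = 3, D_tr = 3, seed = 8)
  p <- inst$params
  # center each filter column across destinations so any common shift moves
  # the weights away from the prior mean
  p$W_tr <- sweep(p$W_tr, 2, colMeans(p$W_tr))
  delta <- 0.9
  p_shift <- glmhmm_params(p$pi, p$W_ob, p$W_tr + delta, p$B)
  ll <- forward_backward(inst$X_ob, inst$X_tr, inst$y, p)$logZ
  ll_shift <- forward_backward(inst$X_ob, inst$X_tr, inst$y, p_shift)$logZ
  expect_equal(ll, ll_shift, tolerance = 1e-9)
  pr <- prior_config()
  expect_lt(log_prior(p_shift, pr), log_prior(p, pr))
})
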