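# Independent oracles used across the suite. These deliberately avoid the
# package's recursions: likelihoods and posteriors are computed by exhaustive
# enumeration over all K^T latent paths, and the static-HMM check uses a
# plainly-written textbook forward-backward.

# joint probability of one latent path under per-trial transition matrices
path_logprob <- function(path, logB, A, pi) {
  lp <- log(pi[path[1]]) + logB[1, path[1]]
  T_ <- nrow(logB)
  if (T_ > 1) {
    for (t in 2:T_) {
      lp <- lp + log(A[t, path[t - 1], path[t]]) + logB[t, path[t]]
    }
  }
  lp
}

# enumerate all paths: marginal log-likelihood, phi, mu
enum_posteriors <- function(logB, A, pi) {
  T_ <- nrow(logB)
  K <- ncol(logB)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  lps <- apply(paths, 1, path_logprob, logB = logB, A = A, pi = pi)
  m <- max(lps)
  w <- exp(lps - m)
  logZ <- m + log(sum(w))
  w <- w / sum(w)
  phi <- matrix(0, T_, K)
  for (t in seq_len(T_)) {
    for (k in seq_len(K)) phi[t, k] <- sum(w[paths[, t] == k])
  }
  mu <- array(0, dim = c(max(T_ - 1, 0), K, K))
  if (T_ > 1) {
    for (t in seq_len(T_ - 1)) {
      for (j in seq_len(K)) {
        for (k in seq_len(K)) {
          mu[t, j, k] <- sum(w[paths[, t] == j & paths[, t + 1] == k])
        }
      }
    }
  }
  list(logZ = logZ, phi = phi, mu = mu)
}

# expected complete-data log-likelihood by direct E_{z|Y}[log p(Y, z)]
enum_ecll <- function(logB, A, pi) {
  T_ <- nrow(logB)
  K <- ncol(logB)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  lps <- apply(paths, 1, path_logprob, logB = logB, A = A, pi = pi)
  m <- max(lps)
  w <- exp(lps - m)
  w <- w / sum(w)
  sum(w * lps)
}

# textbook scaled forward-backward for a STATIC transition matrix
static_hmm_fb <- function(P_emis, A_static, pi) {
  T_ <- nrow(P_emis)
  K <- ncol(P_emis)
  a <- matrix(0, T_, K)
  cvec <- numeric(T_)
  a[1, ] <- pi * P_emis[1, ]
  cvec[1] <- sum(a[1, ])
  a[1, ] <- a[1, ] / cvec[1]
  if (T_ > 1) {
    for (t in 2:T_) {
      a[t, ] <- (a[t - 1, ] %*% A_static) * P_emis[t, ]
      cvec[t] <- sum(a[t, ])
      a[t, ] <- a[t, ] / cvec[t]
    }
  }
  b <- matrix(1, T_, K)
  if (T_ > 1) {
    for (t in (T_ - 1):1) {
      b[t, ] <- A_static %*% (P_emis[t + 1, ] * b[t + 1, ]) / cvec[t + 1]
    }
  }
  phi <- a * b
  phi <- phi / rowSums(phi)
  list(logZ = sum(log(cvec)), phi = phi)
}

# random small problem instance (designs + params) for oracle checks
random_instance <- function(T_ = 6, K = 2, D_ob = 3, D_tr = 2, seed = 1) {
  set.seed(seed)
  X_ob <- cbind(matrix(rnorm(T_ * (D_ob - 1)), T_), 1)
  X_tr <- matrix(rnorm(T_ * D_tr), T_)
  y <- rbinom(T_, 1, 0.5)
  params <- glmhmm_params(
    pi = as.numeric(prop.table(runif(K) + 0.1)),
    W_ob = matrix(rnorm(K * D_ob), K),
    W_tr = matrix(rnorm(K * D_tr, sd = 0.7), K),
    B = matrix(rnorm(K * K), K)
  )
  list(X_ob = X_ob, X_tr = X_tr, y = y, params = params)
}

# log emission matrix for an instance (independent small reimplementation)
inst_logB <- function(inst) {
  eta <- inst$X_ob %*% t(inst$params$W_ob)
  inst$y * eta - log(1 + exp(eta))
}

# small clean trial table used by I/O tests
toy_trials <- function(n = 6, sessions = c("a", "b")) {
  do.call(rbind, lapply(sessions, function(s) {
    data.frame(session_id = s, trial_index = seq_len(n) - 1L,
               signed_contrast = rep(c(-0.25, 0, 0.5), length.out = n),
               choice = rep(c(0, 1), length.out = n),
               reward = rep(c(1, -1), length.out = n),
               stringsAsFactors = FALSE)
  }))
}
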