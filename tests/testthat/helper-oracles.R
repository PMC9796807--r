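# Independent oracles used across the test files. All are deliberately naive
# (exhaustive path enumeration, finite differences) so they share no code with
# the implementation under test.

# exhaustive path-sum likelihood: L = sum over all state paths of
# delta_{s1} p_{s1}(x1) prod_t Gamma_{s_{t-1} s_t} p_{s_t}(x_t);
# a missing observation contributes no emission factor (identity rule)
oracle_nll <- function(x, params) {
  m <- params$m
  T_ <- length(x)
  paths <- as.matrix(expand.grid(rep(list(seq_len(m)), T_)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    pr <- params$delta[s[1L]]
    if (!is.na(x[1L])) pr <- pr * dpois(x[1L], params$lambda[s[1L]])
    if (T_ > 1L)
      for (t in 2:T_) {
        pr <- pr * params$Gamma[s[t - 1L], s[t]]
        if (!is.na(x[t])) pr <- pr * dpois(x[t], params$lambda[s[t]])
      }
    tot <- tot + pr
  }
  -log(tot)
}

# exhaustive smoothing probabilities P(C_t = i | x): accumulate joint path
# probabilities per (t, state) and normalize by the total likelihood
oracle_posterior <- function(x, params) {
  m <- params$m
  T_ <- length(x)
  paths <- as.matrix(expand.grid(rep(list(seq_len(m)), T_)))
  post <- matrix(0, T_, m)
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    pr <- params$delta[s[1L]]
    if (!is.na(x[1L])) pr <- pr * dpois(x[1L], params$lambda[s[1L]])
    if (T_ > 1L)
      for (t in 2:T_) {
        pr <- pr * params$Gamma[s[t - 1L], s[t]]
        if (!is.na(x[t])) pr <- pr * dpois(x[t], params$lambda[s[t]])
      }
    tot <- tot + pr
    for (t in seq_len(T_)) post[t, s[t]] <- post[t, s[t]] + pr
  }
  post / tot
}

# probability of the single most probable path (for comparing against the
# Viterbi path by value, which is immune to tie-breaking conventions)
oracle_max_path_prob <- function(x, params) {
  m <- params$m
  T_ <- length(x)
  paths <- as.matrix(expand.grid(rep(list(seq_len(m)), T_)))
  best <- -Inf
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    pr <- params$delta[s[1L]]
    if (!is.na(x[1L])) pr <- pr * dpois(x[1L], params$lambda[s[1L]])
    if (T_ > 1L)
      for (t in 2:T_) {
        pr <- pr * params$Gamma[s[t - 1L], s[t]]
        if (!is.na(x[t])) pr <- pr * dpois(x[t], params$lambda[s[t]])
      }
    if (pr > best) best <- pr
  }
  best
}

# joint probability of one specific path
oracle_path_prob <- function(x, params, s) {
  pr <- params$delta[s[1L]]
  if (!is.na(x[1L])) pr <- pr * dpois(x[1L], params$lambda[s[1L]])
  if (length(x) > 1L)
    for (t in 2:length(x)) {
      pr <- pr * params$Gamma[s[t - 1L], s[t]]
      if (!is.na(x[t])) pr <- pr * dpois(x[t], params$lambda[s[t]])
    }
  pr
}

# random strictly positive parameter sets for property tests
random_params <- function(m, seed, init = "stationary") {
  set.seed(seed)
  G <- matrix(rgamma(m * m, shape = 2) + 0.05, m, m)
  G <- G / rowSums(G)
  lambda <- sort(runif(m, 0.3, 9))
  pohmm_params(G, lambda, init = init)
}

# central finite differences of a scalar function (gradient)
fd_grad <- function(f, w, h = 1e-5) {
  vapply(seq_along(w), function(i) {
    e <- numeric(length(w)); e[i] <- h
    (f(w + e) - f(w - e)) / (2 * h)
  }, numeric(1))
}

# central finite differences of a gradient function (Hessian)
fd_hess <- function(g, w, h = 1e-5) {
  K <- length(w)
  H <- matrix(NA_real_, K, K)
  for (i in seq_len(K)) {
    e <- numeric(K); e[i] <- h
    H[i, ] <- (g(w + e) - g(w - e)) / (2 * h)
  }
  (H + t(H)) / 2
}
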