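# Likelihood machinery: conditional density matrix, stationary distribution,
# scaled forward/backward recursions. The heavy per-iteration evaluation of
# the nll and its derivatives lives in src/hmm_core.cpp; the R versions here
# serve validation, decoding and one-off computations.

#' Diagonal matrix of Poisson conditional densities
#'
#' Returns `P(x) = diag(p_1(x), ..., p_m(x))` with
#' `p_i(x) = exp(-lambda_i) lambda_i^x / x!`. For a missing observation
#' (`NA`) the identity matrix is returned, which integrates the observation
#' out of the likelihood.
#'
#' @param x a single count, or `NA` for missing.
#' @param lambda vector of positive conditional means.
#' @return `length(lambda)` x `length(lambda)` diagonal matrix.
#' @export
emission_matrix <- function(x, lambda) {
  if (any(lambda <= 0)) stop("lambda must be strictly positive")
  m <- length(lambda)
  if (is.na(x)) return(diag(1, m))
  if (x < 0 || x != round(x))
    stop("invalid observation: counts must be non-negative integers")
  diag(dpois(x, lambda), m)
}

#' Stationary distribution of a transition probability matrix
#'
#' Solves `delta (I - Gamma + U) = 1` (U the all-ones matrix), the augmented
#' linear system equivalent to `delta Gamma = delta`, `sum(delta) = 1`. A
#' linear solve is used rather than eigen-decomposition for determinism and
#' differentiability.
#'
#' @param Gamma row-stochastic matrix.
#' @return probability vector `delta` with `delta %*% Gamma == delta`.
#' @export
#' @examples
#' stationary_dist(matrix(c(0.9, 0.1, 0.1, 0.9), 2))
stationary_dist <- function(Gamma) {
  Gamma <- as.matrix(Gamma)
  m <- nrow(Gamma)
  if (any(abs(rowSums(Gamma) - 1) > 1e-8))
    stop("Gamma must be row-stochastic")
  M <- diag(m) - Gamma + matrix(1, m, m)
  d <- tryCatch(solve(t(M), rep(1, m)),
                error = function(e)
                  stop("degenerate Markov chain: stationary distribution is not unique"))
  as.numeric(d)
}

# internal: log Poisson emission probabilities, identity rule for missing
log_emission_probs <- function(x, lambda) {
  m <- length(lambda)
  lp <- matrix(0, length(x), m)
  ok <- !is.na(x)
  for (i in seq_len(m))
    lp[ok, i] <- dpois(x[ok], lambda[i], log = TRUE)
  lp
}

# internal: map an init spec to the C++ encoding
init_mode_code <- function(init) {
  if (is.numeric(init)) 2L
  else if (identical(init, "estimated")) 1L
  else 0L
}

# internal: call the compiled core on a full working vector
nll_core <- function(x, w, m, init = "stationary", order = 0L) {
  init_fixed <- if (is.numeric(init)) init else numeric(m)
  .hmm_nll_cpp(as.integer(x), as.numeric(w), as.integer(m),
               init_mode_code(init), init_fixed, as.integer(order))
}

#' Negative log-likelihood of a Poisson HMM
#'
#' Evaluates `-log L(theta)` with
#' `L(theta) = delta P(x_1) Gamma P(x_2) ... Gamma P(x_T) 1'` using the
#' scaled forward recursion (per-step renormalization), so no intermediate
#' quantity underflows even for very long series.
#'
#' @param x count series (`NA` = missing).
#' @param params a [pohmm_params()] object.
#' @return the negative log-likelihood (nats).
#' @export
pohmm_nll <- function(x, params) {
  stopifnot(inherits(params, "pohmm_params"))
  x <- as_count_series(x)
  init <- if (is.numeric(params$init)) params$init
          else if (identical(params$init, "estimated")) params$delta
          else "stationary"
  w <- natural_to_working(
    pohmm_params(params$Gamma, params$lambda, init = "stationary"))
  nll_core(x, w, params$m, init = init, order = 0L)$value
}

#' Scaled forward and backward recursions
#'
#' Computes the logarithms of the scaled forward quantities
#' `alpha_t = delta P(x_1) prod_{s<=t} Gamma P(x_s)` and backward quantities
#' `beta_t`, stored as `log_alpha` and `log_beta` (T x m). Both directions
#' reproduce the same log-likelihood; the forward value is returned.
#'
#' @inheritParams pohmm_nll
#' @return list with `log_alpha`, `log_beta`, `log_likelihood` and
#'   `log_likelihood_backward`.
#' @export
forward_backward <- function(x, params) {
  stopifnot(inherits(params, "pohmm_params"))
  x <- as_count_series(x)
  T_ <- length(x)
  m <- params$m
  lp <- log_emission_probs(x, params$lambda)
  G <- params$Gamma
  delta <- params$delta

  la <- matrix(NA_real_, T_, m)
  foo <- delta * exp(lp[1L, ])
  sumfoo <- sum(foo)
  lscale <- log(sumfoo)
  foo <- foo / sumfoo
  la[1L, ] <- lscale + log(foo)
  if (T_ > 1L)
    for (t in 2:T_) {
      foo <- as.numeric(foo %*% G) * exp(lp[t, ])
      sumfoo <- sum(foo)
      lscale <- lscale + log(sumfoo)
      foo <- foo / sumfoo
      la[t, ] <- lscale + log(foo)
    }
  ll <- lscale

  lb <- matrix(0, T_, m)
  if (T_ > 1L) {
    foo <- rep(1 / m, m)
    lscale <- log(m)
    for (t in (T_ - 1L):1L) {
      foo <- as.numeric(G %*% (exp(lp[t + 1L, ]) * foo))
      lb[t, ] <- log(foo) + lscale
      sumfoo <- sum(foo)
      foo <- foo / sumfoo
      lscale <- lscale + log(sumfoo)
    }
  }
  # backward-derived log-likelihood: log sum_i delta_i p_i(x1) beta_1(i)
  v <- log(delta) + lp[1L, ] + lb[1L, ]
  llb <- max(v) + log(sum(exp(v - max(v))))
  list(log_alpha = la, log_beta = lb,
       log_likelihood = ll, log_likelihood_backward = llb)
}
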