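# Posterior state inference and forecasting.

# accept either a fitted model or explicit parameters + data
resolve_params <- function(object, x) {
  if (inherits(object, "pohmm")) {
    list(params = object$params, x = if (is.null(x)) object$x else as_count_series(x))
  } else if (inherits(object, "pohmm_params")) {
    if (is.null(x)) stop("x is required when decoding from raw parameters")
    list(params = object, x = as_count_series(x))
  } else stop("object must be a 'pohmm' fit or 'pohmm_params'")
}

#' Smoothing probabilities
#'
#' Posterior probabilities `P(C_t = i | x_1, ..., x_T)` computed from the
#' scaled forward and backward quantities in log space as
#' `alpha_t(i) beta_t(i) / L(theta)`; each row is renormalized to sum to 1.
#'
#' @param object a fitted [pohmm()] model or a [pohmm_params()] object.
#' @param x count series; defaults to the fitted data.
#' @return T x m matrix of smoothing probabilities.
#' @export
posterior_probs <- function(object, x = NULL) {
  rp <- resolve_params(object, x)
  fb <- forward_backward(rp$x, rp$params)
  lsp <- fb$log_alpha + fb$log_beta - fb$log_likelihood
  sp <- exp(lsp)
  sp / rowSums(sp)
}

#' Local decoding
#'
#' The most probable state at each time taken marginally, i.e. the argmax of
#' the smoothing probabilities (ties broken toward the lower state index,
#' which is what `which.max` does).
#'
#' @inheritParams posterior_probs
#' @return integer vector of length T.
#' @export
local_decode <- function(object, x = NULL) {
  sp <- posterior_probs(object, x)
  apply(sp, 1L, which.max)
}

#' Viterbi decoding
#'
#' The jointly most probable hidden-state sequence given the observations,
#' computed by the Viterbi dynamic program in log space. Ties are broken
#' toward the lower state index.
#'
#' @inheritParams posterior_probs
#' @return integer vector of length T.
#' @export
viterbi <- function(object, x = NULL) {
  rp <- resolve_params(object, x)
  p <- rp$params
  xx <- rp$x
  T_ <- length(xx)
  m <- p$m
  lp <- log_emission_probs(xx, p$lambda)
  lG <- log(p$Gamma)
  xi <- matrix(NA_real_, T_, m)
  bp <- matrix(NA_integer_, T_, m)
  xi[1L, ] <- log(p$delta) + lp[1L, ]
  if (T_ > 1L)
    for (t in 2:T_)
      for (j in seq_len(m)) {
        cand <- xi[t - 1L, ] + lG[, j]
        bp[t, j] <- which.max(cand)
        xi[t, j] <- cand[bp[t, j]] + lp[t, j]
      }
  path <- integer(T_)
  path[T_] <- which.max(xi[T_, ])
  if (T_ > 1L)
    for (t in (T_ - 1L):1L) path[t] <- bp[t + 1L, path[t + 1L]]
  path
}

#' h-step-ahead forecast distribution
#'
#' Computes `P(X_{T+h} = x | x_1, ..., x_T) = phi_T Gamma^h P(x) 1'` where
#' `phi_T = alpha_T / alpha_T 1'` is the filtering distribution at the end of
#' the series. `Gamma^h` is computed by repeated squaring.
#'
#' @inheritParams posterior_probs
#' @param h forecast horizon (>= 1).
#' @param xvals count values at which to evaluate the forecast pmf; defaults
#'   to `0:qpois(1 - 1e-10, max(lambda))`.
#' @return data.frame with columns `x` and `prob`.
#' @export
forecast <- function(object, h = 1L, xvals = NULL, x = NULL) {
  stopifnot(h >= 1L)
  rp <- resolve_params(object, x)
  p <- rp$params
  fb <- forward_backward(rp$x, rp$params)
  laT <- fb$log_alpha[length(rp$x), ]
  phi <- exp(laT - max(laT))
  phi <- phi / sum(phi)
  Gh <- matpow(p$Gamma, h)
  w <- as.numeric(phi %*% Gh)
  if (is.null(xvals)) xvals <- 0:qpois(1 - 1e-10, max(p$lambda))
  prob <- vapply(xvals, function(v) sum(w * dpois(v, p$lambda)), numeric(1))
  data.frame(x = xvals, prob = prob)
}

# matrix power by repeated squaring
matpow <- function(A, n) {
  out <- diag(nrow(A))
  P <- A
  while (n > 0) {
    if (n %% 2 == 1) out <- out %*% P
    P <- P %*% P
    n <- n %/% 2
  }
  out
}

#' Full decoding table
#'
#' One row per time point: the observation, the smoothing probabilities, the
#' locally and globally (Viterbi) decoded states, and the conditional mean of
#' the locally decoded state (the quantity plotted over the data in the
#' package's figures).
#'
#' @inheritParams posterior_probs
#' @return data.frame with columns `time`, `obs`, `smooth_1..m`, `local`,
#'   `viterbi`, `cond_mean`.
#' @export
decode_table <- function(object, x = NULL) {
  rp <- resolve_params(object, x)
  sp <- posterior_probs(object, x)
  loc <- apply(sp, 1L, which.max)
  vit <- viterbi(object, x)
  out <- data.frame(time = seq_along(rp$x), obs = rp$x)
  for (i in seq_len(rp$params$m)) out[[paste0("smooth_", i)]] <- sp[, i]
  out$local <- loc
  out$viterbi <- vit
  out$cond_mean <- rp$params$lambda[loc]
  out
}
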