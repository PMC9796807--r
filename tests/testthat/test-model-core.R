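# Likelihood machinery against independent oracles.

test_that("emission matrix is diagonal Poisson, identity for missing", {
  lam <- c(1, 5)
  E <- emission_matrix(3, lam)
  expect_equal(E, diag(dpois(3, lam)))
  expect_equal(emission_matrix(NA, lam), diag(1, 2))
  expect_error(emission_matrix(3, c(0, 5)), "strictly positive")
  expect_error(emission_matrix(-1, lam), "non-negative")
})

test_that("stationary_dist solves delta Gamma = delta, sum(delta) = 1", {
  for (m in 2:4) {
    p <- random_params(m, seed = 300 + m)
    d <- stationary_dist(p$Gamma)
    expect_equal(as.numeric(d %*% p$Gamma), d, tolerance = 1e-12)
    expect_equal(sum(d), 1, tolerance = 1e-12)
    # agreement with the eigen-decomposition route
    ev <- eigen(t(p$Gamma))
    k <- which.min(abs(ev$values - 1))
    d2 <- Re(ev$vectors[, k]); d2 <- d2 / sum(d2)
    expect_equal(d, d2, tolerance = 1e-10)
  }
  expect_error(stationary_dist(matrix(c(0.9, 0.2, 0.2, 0.8), 2)),
               "row-stochastic")
})

test_that("nll matches the exhaustive path-sum oracle (T <= 8, m <= 3)", {
  cases <- expand.grid(m = 2:3, T_ = c(1, 2, 5, 8))
  for (r in seq_len(nrow(cases))) {
    m <- cases$m[r]; T_ <- cases$T_[r]
    p <- random_params(m, seed = 1000 + r)
    x <- simulate_pohmm(p, T_, seed = 2000 + r)$x
    expect_equal(pohmm_nll(x, p), oracle_nll(x, p), tolerance = 1e-8)
  }
})

test_that("missing observations contribute an identity emission factor", {
  p <- random_params(2, seed = 5)
  x <- c(3L, NA, 1L, NA, 4L)
  expect_equal(pohmm_nll(x, p), oracle_nll(x, p), tolerance = 1e-8)
  # marginalization check: identity rule equals summing the likelihood
  # over all values of the missing observation
  x_at <- function(v) { y <- x; y[2L] <- v; y }
  lik_sum <- sum(vapply(0:200, function(v) exp(-pohmm_nll(x_at(v), p)),
                        numeric(1)))
  expect_equal(exp(-pohmm_nll(x, p)), lik_sum, tolerance = 1e-10)
})

test_that("an all-missing series has likelihood 1", {
  p <- random_params(2, seed = 6)
  expect_equal(pohmm_nll(c(NA_integer_, NA_integer_, NA_integer_), p), 0,
               tolerance = 1e-12)
})

test_that("fixed and estimated initial distributions enter the likelihood", {
  pS <- random_params(2, seed = 8)
  x <- simulate_pohmm(pS, 6, seed = 9)$x
  pF <- pohmm_params(pS$Gamma, pS$lambda, init = c(0.9, 0.1))
  expect_equal(pohmm_nll(x, pF), oracle_nll(x, pF), tolerance = 1e-8)
  expect_false(isTRUE(all.equal(pohmm_nll(x, pF), pohmm_nll(x, pS))))
})

test_that("scaling prevents underflow on long series", {
  p <- random_params(2, seed = 10)
  x <- simulate_pohmm(p, 5000, seed = 11)$x
  v <- pohmm_nll(x, p)
  expect_true(is.finite(v))
  expect_gt(v, 1000)  # raw likelihood would underflow: exp(-v) == 0
  expect_equal(exp(-v), 0)
})

test_that("forward and backward recursions agree on the log-likelihood", {
  for (m in 2:3) {
    p <- random_params(m, seed = 20 + m)
    x <- simulate_pohmm(p, 60, seed = 30 + m)$x
    x[c(7, 20)] <- NA
    fb <- forward_backward(x, p)
    expect_equal(fb$log_likelihood, fb$log_likelihood_backward,
                 tolerance = 1e-10)
    expect_equal(fb$log_likelihood, -pohmm_nll(x, p), tolerance = 1e-10)
    # last forward row sums (in exp space) to the likelihood
    la <- fb$log_alpha[length(x), ]
    expect_equal(max(la) + log(sum(exp(la - max(la)))), fb$log_likelihood,
                 tolerance = 1e-10)
  }
})

test_that("analytic gradient and Hessian match finite differences", {
  for (spec in list(list(m = 2, init = "stationary"),
                    list(m = 3, init = "stationary"),
                    list(m = 2, init = "estimated"),
                    list(m = 2, init = c(0.3, 0.7)))) {
    m <- spec$m
    base <- random_params(m, seed = 50 + m)
    x <- simulate_pohmm(base, 40, seed = 60 + m)$x
    x[5] <- NA
    p <- if (identical(spec$init, "estimated")) {
      tmp <- pohmm_params(base$Gamma, base$lambda, init = "estimated")
      tmp$delta <- rep(1 / m, m)
      tmp
    } else pohmm_params(base$Gamma, base$lambda,
                        init = if (is.numeric(spec$init)) spec$init
                               else "stationary")
    w <- as.numeric(natural_to_working(p))
    r <- pohmm_nll_derivs(x, w, m, init = spec$init, order = 2L)
    fval <- function(wv) pohmm_nll_derivs(x, wv, m, init = spec$init,
                                          order = 0L)$value
    gval <- function(wv) as.numeric(
      pohmm_nll_derivs(x, wv, m, init = spec$init, order = 1L)$gradient)
    expect_equal(as.numeric(r$gradient), fd_grad(fval, w), tolerance = 1e-5)
    expect_equal(unname(r$hessian), fd_hess(gval, w), tolerance = 1e-5)
  }
})
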