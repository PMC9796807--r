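# Maximum likelihood fitting of Poisson HMMs by unconstrained quasi-Newton
# optimization of the working-parameter nll, with the exact gradient (and
# optionally exact Hessian) computed by the compiled core. Nested models are
# expressed through a constraint map over working-parameter positions.

# ---- constraint maps --------------------------------------------------------

# labels: one per working position; "FIXED" holds the position at its start
# value; identical non-FIXED labels force equality; distinct labels are free.
build_map <- function(labels, K, names = NULL) {
  if (is.null(labels))
    labels <- if (is.null(names)) as.character(seq_len(K)) else names
  labels <- as.character(labels)
  if (length(labels) != K)
    stop("constraint map has length ", length(labels), ", expected ", K)
  fixed <- labels == "FIXED"
  free_labels <- unique(labels[!fixed])
  k <- length(free_labels)
  A <- matrix(0, K, k, dimnames = list(names, free_labels))
  for (pos in which(!fixed))
    A[pos, match(labels[pos], free_labels)] <- 1
  list(labels = labels, fixed = fixed, free_labels = free_labels, A = A, k = k)
}

expand_working <- function(z, mp, w_fixed) {
  w <- as.numeric(mp$A %*% z)
  w[mp$fixed] <- w_fixed[mp$fixed]
  w
}

reduce_start <- function(w, mp) {
  # start value of each free label = value at its first occurrence
  vapply(mp$free_labels,
         function(lb) w[which(mp$labels == lb)[1L]], numeric(1))
}

# ---- objective with exact derivatives ---------------------------------------

#' Negative log-likelihood with exact derivatives over free coordinates
#'
#' Evaluates the working-parameter nll together with its gradient and Hessian
#' computed by analytic forward-mode propagation through the scaled forward
#' recursion (no finite differences). Fixed and equality constraints from the
#' map are respected by construction: derivatives are reported in the reduced
#' coordinate space of the free labels.
#'
#' @param x count series (`NA` = missing).
#' @param w full working-parameter vector (layout of [natural_to_working()]).
#' @param m number of states.
#' @param map optional character vector of constraint labels, one per working
#'   position (`"FIXED"` = held at its value in `w`; repeated labels =
#'   equality).
#' @param init `"stationary"`, `"estimated"`, or a fixed probability vector.
#' @param order 0 = value only, 1 = + gradient, 2 = + Hessian.
#' @return list with `value`, and (per `order`) `gradient` and `hessian` over
#'   the free coordinates.
#' @export
pohmm_nll_derivs <- function(x, w, m, map = NULL, init = "stationary",
                             order = 2L) {
  x <- as_count_series(x)
  free_init <- identical(init, "estimated") && m > 1L
  K <- working_length(m, free_init)
  if (length(w) != K) stop("working vector has length ", length(w),
                           ", expected ", K)
  mp <- build_map(map, K, working_names(m, free_init))
  res <- nll_core(x, w, m, init = init, order = order)
  if (!is.finite(res$value))
    stop("nll evaluation is not finite at the supplied working parameters")
  out <- list(value = res$value)
  if (order >= 1L)
    out$gradient <- setNames(as.numeric(crossprod(mp$A, res$grad)),
                             mp$free_labels)
  if (order >= 2L)
    out$hessian <- crossprod(mp$A, res$hess %*% mp$A)
  out
}

# ---- starting values --------------------------------------------------------

# lambda: quantiles of the positive counts at levels (i - 0.5)/m, nudged to be
# strictly increasing; Gamma: 0.8 persistence, off-diagonal mass uniform.
default_start <- function(x, m, init = "stationary") {
  xs <- x[!is.na(x)]
  xp <- xs[xs > 0]
  if (length(xp) == 0L) xp <- xs + 0.5
  lam <- as.numeric(quantile(xp, probs = (seq_len(m) - 0.5) / m, names = FALSE))
  lam <- pmax(lam, 0.05)
  if (m > 1L)
    for (i in 2:m)
      if (lam[i] <= lam[i - 1L]) lam[i] <- lam[i - 1L] * 1.25 + 0.1
  Gamma <- if (m == 1L) matrix(1, 1, 1)
           else matrix(0.2 / (m - 1L), m, m) + diag(0.8 - 0.2 / (m - 1L), m)
  pohmm_params(Gamma, lam, init = init)
}

# ---- the fitting function ---------------------------------------------------

#' Fit a Poisson hidden Markov model by maximum likelihood
#'
#' Minimizes the negative log-likelihood over the unconstrained working
#' parameters with [stats::nlminb()], supplying the exact analytic gradient
#' (and, for `method = "newton"`, the exact Hessian). After the optimizer
#' stops, a few guarded Newton steps polish the solution so the reported
#' optimum has an essentially vanishing gradient. The Hessian over the free
#' coordinates is evaluated at the optimum for later delta-method inference.
#'
#' @param x count series (`NA` = missing observation).
#' @param m number of hidden states (>= 1).
#' @param start optional [pohmm_params()] starting values; default: conditional
#'   means at the (i - 0.5)/m quantiles of the positive counts and a
#'   persistence-0.8 transition matrix.
#' @param init initial state distribution: `"stationary"` (default, tied to
#'   the transition matrix), `"estimated"` (adds m - 1 free logits), or a
#'   fixed probability vector.
#' @param map optional constraint labels over working positions (see
#'   [pohmm_nll_derivs()]). Constraints act on the working scale; e.g. fixing
#'   `lambda1 = 1` means fixing `eta1 = log(1) = 0` via
#'   `map = c("FIXED", ...)` with `start` carrying `lambda1 = 1`.
#' @param method `"gradient"` (quasi-Newton with exact gradient, default) or
#'   `"newton"` (also passes the exact Hessian to the optimizer).
#' @param control list overriding optimizer settings: `rel.tol` (1e-10),
#'   `iter.max` (1000), `eval.max` (2000), `polish` (TRUE).
#' @return object of class `"pohmm"`; see [summary.pohmm()], [confint.pohmm()],
#'   [posterior_probs()], [viterbi()], [predict.pohmm()], [simulate.pohmm()].
#' @export
#' @examples
#' fit <- pohmm(tyt_arousal(), m = 2)
#' fit
#' AIC(fit); BIC(fit)
pohmm <- function(x, m = 2L, start = NULL, init = "stationary", map = NULL,
                  method = c("gradient", "newton"), control = list()) {
  cl <- match.call()
  method <- match.arg(method)
  x <- as_count_series(x)
  if (all(is.na(x))) stop("cannot fit: all observations are missing")
  if (m < 1L) stop("m must be >= 1")
  ctrl <- list(rel.tol = 1e-10, iter.max = 1000L, eval.max = 2000L,
               polish = TRUE)
  ctrl[names(control)] <- control

  if (is.null(start)) start <- default_start(x, m, init = init)
  stopifnot(inherits(start, "pohmm_params"), start$m == m)
  if (!identical(start$init, init)) {
    start <- pohmm_params(start$Gamma, start$lambda, init = init)
  }
  free_init <- identical(init, "estimated") && m > 1L
  w0 <- natural_to_working(start)
  K <- length(w0)
  mp <- build_map(map, K, working_names(m, free_init))
  if (mp$k == 0L && any(!mp$fixed)) stop("constraint map leaves no free parameter")
  init_arg <- if (is.numeric(init)) init else init

  # cached evaluation: nlminb asks for value and gradient separately
  cache <- new.env(parent = emptyenv())
  evaluate <- function(z, order) {
    if (!is.null(cache$z) && identical(cache$z, z) && cache$order >= order)
      return(cache$res)
    w <- expand_working(z, mp, w0)
    res <- nll_core(x, w, m, init = init_arg, order = order)
    cache$z <- z; cache$order <- order; cache$res <- res
    res
  }
  fn <- function(z) evaluate(z, 1L)$value
  gr <- function(z) as.numeric(crossprod(mp$A, evaluate(z, 1L)$grad))
  he <- function(z) crossprod(mp$A, evaluate(z, 2L)$hess %*% mp$A)

  z0 <- reduce_start(w0, mp)
  iterations <- 0L
  if (mp$k > 0L) {
    if (!is.finite(fn(z0)))
      stop("negative log-likelihood is not finite at the starting values")
    opt <- if (method == "newton")
      nlminb(z0, fn, gradient = gr, hessian = he,
             control = list(rel.tol = ctrl$rel.tol, iter.max = ctrl$iter.max,
                            eval.max = ctrl$eval.max))
    else
      nlminb(z0, fn, gradient = gr,
             control = list(rel.tol = ctrl$rel.tol, iter.max = ctrl$iter.max,
                            eval.max = ctrl$eval.max))
    z <- opt$par
    value <- opt$objective
    iterations <- opt$iterations
    conv_ok <- opt$convergence == 0L
    message <- opt$message
    # guarded Newton polish: accept steps that do not increase the nll
    if (isTRUE(ctrl$polish)) {
      for (s in seq_len(10L)) {
        r2 <- nll_core(x, expand_working(z, mp, w0), m, init = init_arg,
                       order = 2L)
        g <- as.numeric(crossprod(mp$A, r2$grad))
        if (!all(is.finite(g)) || max(abs(g)) < 1e-11) break
        H <- crossprod(mp$A, r2$hess %*% mp$A)
        step <- tryCatch(solve(H, g), error = function(e) NULL)
        if (is.null(step) || !all(is.finite(step))) break
        accepted <- FALSE
        for (damp in c(1, 0.5, 0.25)) {
          znew <- z - damp * step
          vnew <- tryCatch(nll_core(x, expand_working(znew, mp, w0), m,
                                    init = init_arg, order = 0L)$value,
                           error = function(e) Inf)
          if (is.finite(vnew) && vnew <= value + 1e-12) {
            z <- znew; value <- vnew; accepted <- TRUE; break
          }
        }
        iterations <- iterations + 1L
        if (!accepted) break
      }
    }
  } else {
    z <- numeric(0)
    value <- fn0 <- nll_core(x, w0, m, init = init_arg, order = 0L)$value
    conv_ok <- TRUE
    message <- "fully fixed model: nothing to optimize"
  }

  w_hat <- expand_working(z, mp, w0)
  names(w_hat) <- working_names(m, free_init)
  res <- nll_core(x, w_hat, m, init = init_arg, order = 2L)
  grad_free <- setNames(as.numeric(crossprod(mp$A, res$grad)), mp$free_labels)
  hess_free <- crossprod(mp$A, res$hess %*% mp$A)
  dimnames(hess_free) <- list(mp$free_labels, mp$free_labels)
  grad_norm <- if (mp$k) max(abs(grad_free)) else 0
  params <- working_to_natural(w_hat, m, init = init_arg)

  structure(list(
    call = cl, x = x, m = m, T = length(x), n_obs = sum(!is.na(x)),
    init = init, map = mp$labels, free_labels = mp$free_labels,
    map_internal = mp, start_working = w0, working = w_hat,
    params = params, nll = res$value, df = mp$k,
    iterations = iterations,
    converged = conv_ok || grad_norm < 1e-6,
    message = message, gradient = grad_free, grad_norm = grad_norm,
    hessian = hess_free, method = method, control = ctrl
  ), class = "pohmm")
}

# ---- information criteria ---------------------------------------------------

#' @export
logLik.pohmm <- function(object, ...) {
  structure(-object$nll, df = object$df, nobs = object$T,
            class = "logLik")
}

#' @export
nobs.pohmm <- function(object, ...) object$T

#' Akaike and Bayesian information criteria of a fitted Poisson HMM
#'
#' `aic = 2 nll + 2 k`, `bic = 2 nll + k log(T)` with `k` the number of free
#' working parameters and `T` the series length.
#'
#' @param fit a fitted [pohmm()] model.
#' @return named vector `c(aic, bic)`.
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "pohmm"))
  c(aic = 2 * fit$nll + 2 * fit$df,
    bic = 2 * fit$nll + fit$df * log(fit$T))
}
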