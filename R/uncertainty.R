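# Standard errors and confidence intervals: delta-method Wald intervals from
# the exact working-parameter Hessian, profile-likelihood intervals by
# re-optimizing nuisance parameters along a target coordinate, and parametric
# percentile-bootstrap intervals.

# pseudo-inverse fallback for singular Hessians (flagged unreliable)
pinv <- function(A, tol = 1e-12) {
  s <- svd(A)
  pos <- s$d > tol * max(s$d)
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Delta-method covariance of the natural and derived parameters
#'
#' Propagates the inverse Hessian of the working-parameter nll through the
#' exact Jacobian of the extended map working -> (Gamma, lambda, delta):
#' `Sigma = J H^{-1} J'`. Columns of the Jacobian corresponding to fixed
#' working coordinates are zero, so fixed parameters get standard error 0.
#'
#' @param fit a converged [pohmm()] fit.
#' @return list of class `"pohmm_se"` with elements `estimate`, `se` (named
#'   vectors over gamma/lambda/delta), `cov` (the full covariance matrix) and
#'   `reliable` (FALSE when the Hessian was singular and a pseudo-inverse was
#'   used).
#' @export
delta_method_cov <- function(fit) {
  stopifnot(inherits(fit, "pohmm"))
  J <- jacobian_gext(fit$working, fit$m, fit$init)
  A <- fit$map_internal$A
  Jf <- J %*% A
  reliable <- TRUE
  if (fit$df == 0L) {
    Sigma <- matrix(0, nrow(J), nrow(J), dimnames = list(rownames(J), rownames(J)))
  } else {
    Hinv <- tryCatch(solve(fit$hessian), error = function(e) NULL)
    if (is.null(Hinv) || any(!is.finite(Hinv))) {
      warning("singular Hessian: covariance computed from a pseudo-inverse; ",
              "standard errors are unreliable")
      reliable <- FALSE
      Hinv <- pinv(fit$hessian)
    }
    Sigma <- Jf %*% Hinv %*% t(Jf)
    Sigma <- (Sigma + t(Sigma)) / 2
    dimnames(Sigma) <- list(rownames(J), rownames(J))
  }
  est <- natural_estimates(fit$params)
  se <- sqrt(pmax(diag(Sigma), 0))[names(est)]
  structure(list(estimate = est, se = se, cov = Sigma, reliable = reliable),
            class = "pohmm_se")
}

#' @export
vcov.pohmm <- function(object, ...) delta_method_cov(object)$cov

# ---- Wald -------------------------------------------------------------------

wald_ci_matrix <- function(se_report, level) {
  z <- if (level >= 1) Inf else qnorm(1 - (1 - level) / 2)
  est <- se_report$estimate
  se <- se_report$se
  lo <- est - z * se
  up <- est + z * se
  lo[se == 0] <- est[se == 0]
  up[se == 0] <- est[se == 0]
  cbind(lower = lo, upper = up)
}

# ---- profile likelihood -----------------------------------------------------

# refit with working position `pos` held at value `v`; warm start from z_start
refit_fixed_at <- function(fit, pos, v, z_start = NULL) {
  labels <- fit$map_internal$labels
  labels[pos] <- "FIXED"
  mp <- build_map(labels, length(fit$working), names(fit$working))
  w0 <- fit$working
  w0[pos] <- v
  init_arg <- fit$init
  x <- fit$x
  m <- fit$m
  fn <- function(z) nll_core(x, expand_working(z, mp, w0), m,
                             init = init_arg, order = 0L)$value
  gr <- function(z) as.numeric(crossprod(
    mp$A, nll_core(x, expand_working(z, mp, w0), m,
                   init = init_arg, order = 1L)$grad))
  if (is.null(z_start)) z_start <- reduce_start(fit$working, mp)
  if (mp$k == 0L)
    return(list(value = fn(numeric(0)), z = numeric(0),
                w = expand_working(numeric(0), mp, w0)))
  opt <- nlminb(z_start, fn, gradient = gr,
                control = list(rel.tol = 1e-10, iter.max = 500L))
  list(value = opt$objective, z = opt$par,
       w = expand_working(opt$par, mp, w0))
}

# profile-likelihood interval for one free working coordinate.
# Root finding: step-out bracketing up to max_se Wald SEs from the MLE, then
# bisection of R_p(v) - crit to tolerance rp_tol. Returns working-scale
# bounds (NA where the root could not be bracketed) plus the constrained
# working vectors at the bounds and an evaluation trace.
profile_ci_working <- function(fit, pos, level, rp_tol = 1e-4, max_se = 8) {
  lb <- fit$map_internal$labels[pos]
  if (lb == "FIXED") stop("cannot profile a fixed working coordinate")
  if (sum(fit$map_internal$labels == lb) > 1L)
    stop("cannot profile a coordinate under an equality constraint")
  crit <- qchisq(level, df = 1)
  Hinv <- tryCatch(solve(fit$hessian), error = function(e) pinv(fit$hessian))
  se_w <- sqrt(max(Hinv[lb, lb], 1e-12))
  w_hat <- fit$working[pos]
  trace <- data.frame(value = w_hat, profile_nll = fit$nll, ratio = 0)

  rp_at <- local({
    z_last <- NULL
    function(v) {
      r <- refit_fixed_at(fit, pos, v, z_start = z_last)
      z_last <<- r$z
      rp <- max(2 * (r$value - fit$nll), 0)
      trace <<- rbind(trace, data.frame(value = v, profile_nll = r$value,
                                        ratio = rp))
      list(rp = rp, w = r$w)
    }
  })

  solve_side <- function(sign) {
    prev_v <- w_hat
    prev_rp <- 0
    hit <- NULL
    for (j in seq_len(max_se)) {
      v <- w_hat + sign * j * se_w
      r <- rp_at(v)
      if (r$rp >= crit) { hit <- list(v = v, rp = r$rp, w = r$w); break }
      prev_v <- v
      prev_rp <- r$rp
    }
    if (is.null(hit)) return(list(bound = NA_real_, w = NULL))
    a <- prev_v; b <- hit$v
    w_at <- hit$w
    for (it in seq_len(200L)) {
      mid <- (a + b) / 2
      r <- rp_at(mid)
      if (abs(r$rp - crit) < rp_tol || abs(b - a) < 1e-12) {
        return(list(bound = mid, w = r$w))
      }
      if (r$rp < crit) a <- mid else { b <- mid; w_at <- r$w }
    }
    list(bound = (a + b) / 2, w = w_at)
  }

  lo <- solve_side(-1)
  up <- solve_side(+1)
  list(lower = lo$bound, upper = up$bound,
       w_lower = lo$w, w_upper = up$w,
       critical = crit, se_working = se_w, trace = trace)
}

#' Profile-likelihood trace of one working parameter
#'
#' Re-optimizes all nuisance parameters at a sequence of fixed values of the
#' target working coordinate and records the profile nll and the likelihood
#' ratio `R_p = 2 (nll_profile - nll_hat)`. The 95% interval boundary is where
#' `R_p` crosses the `qchisq(level, 1)` critical value (3.841 at level 0.95).
#'
#' @param fitted a converged [pohmm()] fit.
#' @param parm working-parameter name (e.g. `"eta2"`, `"tau12"`) or position.
#' @param level confidence level used for the reported interval.
#' @param ... unused.
#' @return list of class `"pohmm_profile"` with the trace data.frame,
#'   working-scale interval, and the critical value.
#' @export
profile.pohmm <- function(fitted, parm, level = 0.95, ...) {
  pos <- if (is.character(parm)) match(parm, names(fitted$working)) else as.integer(parm)
  if (is.na(pos) || pos < 1L || pos > length(fitted$working))
    stop("unknown working parameter: ", parm)
  r <- profile_ci_working(fitted, pos, level)
  tr <- r$trace[order(r$trace$value), ]
  rownames(tr) <- NULL
  structure(list(parm = names(fitted$working)[pos], trace = tr,
                 lower = r$lower, upper = r$upper, level = level,
                 critical = r$critical),
            class = "pohmm_profile")
}

#' @export
print.pohmm_profile <- function(x, ...) {
  cat("Profile likelihood of", x$parm, "(", nrow(x$trace), "evaluations )\n")
  cat(sprintf("%g%% interval on the working scale: [%.6g, %.6g] (critical value %.3f)\n",
              100 * x$level, x$lower, x$upper, x$critical))
  invisible(x)
}

# profile CI for a natural parameter name; returns c(lower, upper) or NAs
profile_ci_natural <- function(fit, pname, level) {
  m <- fit$m
  if (grepl("^lambda", pname)) {
    i <- as.integer(sub("lambda", "", pname))
    r <- profile_ci_working(fit, i, level)
    return(c(exp(r$lower), exp(r$upper)))
  }
  if (grepl("^gamma", pname)) {
    idx <- sub("gamma", "", pname)
    i <- as.integer(substr(idx, 1L, nchar(idx) / 2))
    j <- as.integer(substr(idx, nchar(idx) / 2 + 1L, nchar(idx)))
    if (i == j) {
      if (m == 2L) {
        # two-state row constraint: gamma_ii = 1 - gamma_ij
        other <- if (i == 1L) 2L else 1L
        ci <- profile_ci_natural(fit, paste0("gamma", i, other), level)
        return(c(1 - ci[2L], 1 - ci[1L]))
      }
      return(c(NA_real_, NA_real_))  # unavailable for m > 2
    }
    pos <- tau_position(m, i, j)
    r <- profile_ci_working(fit, pos, level)
    # map each working bound through the full row transform, holding the other
    # taus in the row at their re-optimized values at that bound
    bound_to_gamma <- function(w) {
      if (is.null(w)) return(NA_real_)
      working_to_natural(w, m, init = fit$init)$Gamma[i, j]
    }
    lo <- if (is.na(r$lower)) NA_real_ else bound_to_gamma(r$w_lower)
    up <- if (is.na(r$upper)) NA_real_ else bound_to_gamma(r$w_upper)
    if (!is.na(lo) && !is.na(up) && lo > up) { tmp <- lo; lo <- up; up <- tmp }
    return(c(lo, up))
  }
  c(NA_real_, NA_real_)  # delta: no profile interval exists
}

# ---- parametric bootstrap ---------------------------------------------------

#' Parametric bootstrap replicates of a fitted Poisson HMM
#'
#' Simulates `B` series from the fitted model (stationary start), refits each
#' starting from the fitted parameters (the standard warm-start policy for a
#' parametric HMM bootstrap), resolves label switching by sorting states by
#' ascending fitted lambda, and returns the matrix of natural parameter
#' estimates. A sample is discarded and replaced by a fresh simulation when
#' (a) its state path does not visit every state, (b) the refit optimizer
#' fails to converge, or (c) the refit's working-parameter Hessian is not
#' numerically positive definite (the optimum sits on a boundary or ridge, so
#' the fit did not converge properly to an interior maximum). Replacements
#' are counted by cause and capped by a budget.
#'
#' @param fit a converged [pohmm()] fit.
#' @param B number of bootstrap resamples (>= 2).
#' @param seed master seed; resample `b` uses a child seed.
#' @param budget replacement budget (default `10 * B`).
#' @return list of class `"pohmm_boot"`: `estimates` (B x n_params matrix),
#'   `replaced` counts, `B`, `seed`.
#' @export
pohmm_bootstrap <- function(fit, B = 1000L, seed = 1L, budget = 10L * B) {
  stopifnot(inherits(fit, "pohmm"), B >= 2L)
  tmpl <- natural_estimates(fit$params)
  est <- matrix(NA_real_, B, length(tmpl),
                dimnames = list(NULL, names(tmpl)))
  constrained <- any(fit$map_internal$fixed) ||
    length(fit$free_labels) < length(fit$working)
  replaced <- c(invalid_path = 0L, fit_failure = 0L, improper_optimum = 0L)
  attempts <- 0L
  b <- 1L
  while (b <= B) {
    if (attempts - (b - 1L) > budget)
      stop("bootstrap replacement budget exhausted after ", attempts,
           " attempts (", replaced["invalid_path"], " invalid paths, ",
           replaced["fit_failure"], " fit failures, ",
           replaced["improper_optimum"], " improper optima)")
    attempts <- attempts + 1L
    sim <- simulate_pohmm(fit$params, fit$T, seed = child_seed(seed, attempts))
    if (!sample_is_valid(sim$states, fit$m)) {
      replaced["invalid_path"] <- replaced["invalid_path"] + 1L
      next
    }
    refit <- tryCatch(
      pohmm(sim$x, m = fit$m, start = fit$params, init = fit$init,
            map = if (constrained) fit$map else NULL),
      error = function(e) NULL)
    if (is.null(refit) || !refit$converged) {
      replaced["fit_failure"] <- replaced["fit_failure"] + 1L
      next
    }
    if (refit$df > 0L) {
      ev <- eigen(refit$hessian, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) <= 0 || min(ev) < 1e-8 * max(abs(ev))) {
        replaced["improper_optimum"] <- replaced["improper_optimum"] + 1L
        next
      }
    }
    p <- refit$params
    if (!constrained) p <- permute_params(p, state_order(p))
    est[b, ] <- natural_estimates(p)
    b <- b + 1L
  }
  structure(list(estimates = est, replaced = replaced, B = B, seed = seed,
                 attempts = attempts),
            class = "pohmm_boot")
}

# ---- unified confint --------------------------------------------------------

#' Confidence intervals for a fitted Poisson HMM
#'
#' Three methods are available: `"wald"` (delta-method standard errors from
#' the exact working-parameter Hessian, symmetric on the natural scale, not
#' clipped to parameter bounds), `"profile"` (likelihood-ratio inversion
#' against the chi-squared(1) critical value, transformed monotonically to
#' the natural scale; not defined for the stationary distribution delta, and
#' for diagonal transition probabilities only via the two-state row
#' constraint), and `"bootstrap"` (parametric percentile bootstrap).
#'
#' @param object a converged [pohmm()] fit.
#' @param parm natural parameter names (e.g. `"lambda2"`, `"gamma21"`,
#'   `"delta1"`); default all.
#' @param level confidence level.
#' @param method one of `"wald"`, `"profile"`, `"bootstrap"`.
#' @param B bootstrap resamples (method `"bootstrap"`).
#' @param seed bootstrap seed (method `"bootstrap"`).
#' @param boot optional precomputed [pohmm_bootstrap()] result to reuse.
#' @param ... unused.
#' @return matrix with one row per parameter and columns `lower`, `upper`;
#'   `NA` marks intervals the method cannot provide.
#' @export
confint.pohmm <- function(object, parm = NULL, level = 0.95,
                          method = c("wald", "profile", "bootstrap"),
                          B = 1000L, seed = 1L, boot = NULL, ...) {
  method <- match.arg(method)
  all_parm <- names(natural_estimates(object$params))
  if (is.null(parm)) parm <- all_parm
  bad <- setdiff(parm, all_parm)
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))

  out <- matrix(NA_real_, length(parm), 2L,
                dimnames = list(parm, c("lower", "upper")))
  if (method == "wald") {
    ci <- wald_ci_matrix(delta_method_cov(object), level)
    out[, ] <- ci[parm, , drop = FALSE]
  } else if (method == "profile") {
    for (pn in parm)
      out[pn, ] <- profile_ci_natural(object, pn, level)
  } else {
    if (is.null(boot)) boot <- pohmm_bootstrap(object, B = B, seed = seed)
    a <- (1 - level) / 2
    for (pn in parm)
      out[pn, ] <- quantile(boot$estimates[, pn], c(a, 1 - a), names = FALSE)
  }
  attr(out, "level") <- level
  attr(out, "method") <- method
  out
}

#' Serialize estimates and all three interval types to a CSV table
#'
#' Produces one row per natural parameter with columns `parameter`,
#' `estimate`, `wald_l`, `wald_u`, `profile_l`, `profile_u`, `boot_l`,
#' `boot_u` (profile columns are empty for delta).
#'
#' @param fit a converged [pohmm()] fit.
#' @param path output CSV path.
#' @param level confidence level.
#' @param B,seed bootstrap settings.
#' @param methods which interval types to include.
#' @return the data.frame written, invisibly.
#' @export
write_ci_csv <- function(fit, path, level = 0.95, B = 1000L, seed = 1L,
                         methods = c("wald", "profile", "bootstrap")) {
  est <- natural_estimates(fit$params)
  df <- data.frame(parameter = names(est), estimate = as.numeric(est))
  short <- c(wald = "wald", profile = "profile", bootstrap = "boot")
  for (mt in methods) {
    ci <- confint(fit, level = level, method = mt, B = B, seed = seed)
    df[[paste0(short[[mt]], "_l")]] <- ci[, "lower"]
    df[[paste0(short[[mt]], "_u")]] <- ci[, "upper"]
  }
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
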