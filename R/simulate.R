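# Seeded simulation from a Poisson HMM and the Monte Carlo coverage harness.

# deterministic child seed for replicate r of a master seed; keeps replacement
# draws on a distinct part of the stream from retained draws
child_seed <- function(seed, r) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(r) * 69621
  as.integer(s %% 2147483646) + 1L
}

#' Simulate a Poisson HMM
#'
#' Draws the initial state from the model's initial distribution (stationary
#' by default), subsequent states from the transition matrix, and counts from
#' the state-conditional Poisson distributions. Fully reproducible under
#' `seed`.
#'
#' @param params a [pohmm_params()] object.
#' @param n series length.
#' @param seed optional integer seed (set via [set.seed()] when given).
#' @return list with integer vectors `x` (counts) and `states`.
#' @export
simulate_pohmm <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "pohmm_params"), n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  m <- params$m
  states <- integer(n)
  u <- runif(n)
  cum0 <- cumsum(params$delta)
  cum <- t(apply(params$Gamma, 1L, cumsum))
  states[1L] <- 1L + sum(u[1L] > cum0[-m])
  if (n > 1L)
    for (t in 2:n)
      states[t] <- 1L + sum(u[t] > cum[states[t - 1L], -m])
  x <- rpois(n, params$lambda[states])
  list(x = as.integer(x), states = states)
}

#' @export
simulate.pohmm <- function(object, nsim = 1L, seed = NULL, n = object$T, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- replicate(nsim, simulate_pohmm(object$params, n)$x, simplify = FALSE)
  if (nsim == 1L) out[[1L]] else out
}

#' Sample-validity rule for simulated state sequences
#'
#' A simulated sequence is valid only if its hidden-state path sojourns in
#' every state of the model at least once; otherwise refits are prone to
#' non-convergence and the model is not identifiable from the sample.
#'
#' @param states integer state path over states `1..m`.
#' @param m number of states of the generating model.
#' @return logical flag.
#' @export
sample_is_valid <- function(states, m) {
  all(tabulate(states, nbins = m) > 0L)
}

# natural parameter vector (gamma row-major, lambda, delta) with names
natural_estimates <- function(params) {
  m <- params$m
  setNames(c(as.vector(t(params$Gamma)), params$lambda, params$delta),
           c(paste0("gamma", rep(seq_len(m), each = m), rep(seq_len(m), m)),
             paste0("lambda", seq_len(m)),
             paste0("delta", seq_len(m))))
}

# permutation that sorts states by ascending lambda; exact ties broken by
# descending delta
state_order <- function(params) {
  order(params$lambda, -params$delta)
}

permute_params <- function(params, perm) {
  if (identical(perm, seq_len(params$m))) return(params)
  init <- if (is.numeric(params$init)) params$init[perm] else params$init
  out <- pohmm_params(params$Gamma[perm, perm, drop = FALSE],
                      params$lambda[perm], init = init)
  out$delta <- params$delta[perm]
  out
}

# relabel a fitted model so states are sorted by ascending lambda; rebuilds
# the working vector and re-evaluates gradient/Hessian at the permuted point
# (an exact symmetry of the likelihood). Only defined for unconstrained fits.
relabel_fit <- function(fit, perm = state_order(fit$params)) {
  m <- fit$m
  if (identical(perm, seq_len(m))) return(fit)
  if (any(fit$map_internal$fixed) ||
      length(fit$free_labels) != length(fit$working))
    stop("state relabeling is only supported for unconstrained fits")
  params2 <- permute_params(fit$params, perm)
  free_init <- identical(fit$init, "estimated") && m > 1L
  init_arg <- if (is.numeric(fit$init)) fit$init[perm] else fit$init
  p_for_w <- if (free_init) {
    tmp <- pohmm_params(params2$Gamma, params2$lambda, init = "estimated")
    tmp$delta <- params2$delta
    tmp
  } else pohmm_params(params2$Gamma, params2$lambda, init = "stationary")
  w2 <- natural_to_working(p_for_w)
  res <- nll_core(fit$x, w2, m, init = init_arg, order = 2L)
  mp <- build_map(NULL, length(w2), names(w2))
  fit$working <- setNames(w2, working_names(m, free_init))
  fit$params <- params2
  fit$init <- init_arg
  fit$map <- mp$labels
  fit$free_labels <- mp$free_labels
  fit$map_internal <- mp
  fit$gradient <- setNames(as.numeric(res$grad), mp$free_labels)
  fit$grad_norm <- max(abs(res$grad))
  fit$hessian <- res$hess
  dimnames(fit$hessian) <- list(mp$free_labels, mp$free_labels)
  fit$nll <- res$value
  fit
}

#' Monte Carlo coverage study
#'
#' Repeatedly simulates series from a known model, refits, computes the
#' requested confidence intervals, and reports the fraction of replicates
#' whose interval contains the true parameter value. Replicates whose state
#' path does not visit every state, whose fit fails to converge (including
#' fits whose working-parameter Hessian is not numerically positive definite,
#' i.e. the optimum is on a boundary or ridge), or (when profile intervals are
#' requested) whose profile bounds cannot be bracketed are discarded and
#' replaced by freshly simulated ones, with the causes counted. Estimated states are aligned to the truth by ascending fitted
#' lambda before coverage is assessed.
#'
#' @param truth a [pohmm_params()] object (states are canonicalized to
#'   ascending lambda).
#' @param n series length of each replicate.
#' @param M number of retained replicates.
#' @param level nominal confidence level; `level = 1` yields infinite Wald
#'   intervals and coverage 1.
#' @param methods subset of `c("wald", "profile", "bootstrap")`.
#' @param seed master seed; replicate `r` uses a child seed derived from
#'   `(seed, r)`.
#' @param validity_filter apply the all-states-visited rule of
#'   [sample_is_valid()].
#' @param budget maximum number of replacement simulations (default `10 * M`).
#' @param B bootstrap resamples per replicate when `"bootstrap"` is requested.
#' @return object of class `"pohmm_coverage"`: coverage matrix
#'   (parameters x methods), replacement counts by cause, and bookkeeping.
#' @export
coverage_study <- function(truth, n, M = 1000L, level = 0.95,
                           methods = "wald", seed = 1L,
                           validity_filter = TRUE, budget = 10L * M,
                           B = 200L) {
  stopifnot(inherits(truth, "pohmm_params"), M >= 1L, budget >= M)
  methods <- match.arg(methods, c("wald", "profile", "bootstrap"),
                       several.ok = TRUE)
  truth <- permute_params(truth, state_order(truth))
  tv <- natural_estimates(truth)
  m <- truth$m
  hits <- array(0L, dim = c(length(tv), length(methods)),
                dimnames = list(names(tv), methods))
  avail <- array(0L, dim = dim(hits), dimnames = dimnames(hits))
  replaced <- c(invalid_path = 0L, fit_failure = 0L, profile_failure = 0L)
  attempts <- 0L
  retained <- 0L
  partial <- FALSE

  while (retained < M) {
    if (attempts - retained > budget) { partial <- TRUE; break }
    attempts <- attempts + 1L
    sim <- simulate_pohmm(truth, n, seed = child_seed(seed, attempts))
    if (validity_filter && !sample_is_valid(sim$states, m)) {
      replaced["invalid_path"] <- replaced["invalid_path"] + 1L
      next
    }
    fit <- tryCatch(pohmm(sim$x, m = m), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      replaced["fit_failure"] <- replaced["fit_failure"] + 1L
      next
    }
    ev <- eigen(fit$hessian, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0 || min(ev) < 1e-8 * max(abs(ev))) {
      replaced["fit_failure"] <- replaced["fit_failure"] + 1L
      next
    }
    fit <- relabel_fit(fit)
    cis <- list()
    bad <- FALSE
    for (mt in methods) {
      ci <- tryCatch(
        confint(fit, level = level, method = mt, B = B,
                seed = child_seed(seed, attempts + 500000L)),
        error = function(e) NULL)
      if (is.null(ci)) { bad <- TRUE; break }
      if (mt == "profile") {
        # profile bounds exist only for lambda and gamma rows; a bracketing
        # failure on an available parameter triggers replacement
        pr <- rownames(ci)[!startsWith(rownames(ci), "delta")]
        if (m > 2L) pr <- pr[!pr %in% paste0("gamma", seq_len(m), seq_len(m))]
        if (any(is.na(ci[pr, ]))) { bad <- TRUE; break }
      }
      cis[[mt]] <- ci
    }
    if (bad) {
      replaced["profile_failure"] <- replaced["profile_failure"] + 1L
      next
    }
    retained <- retained + 1L
    for (mt in methods) {
      ci <- cis[[mt]]
      for (pn in names(tv)) {
        lo <- ci[pn, 1L]; up <- ci[pn, 2L]
        if (is.na(lo) || is.na(up)) next
        avail[pn, mt] <- avail[pn, mt] + 1L
        if (tv[pn] >= lo && tv[pn] <= up)
          hits[pn, mt] <- hits[pn, mt] + 1L
      }
    }
  }

  coverage <- hits / pmax(avail, 1L)
  coverage[avail == 0L] <- NA_real_
  structure(list(coverage = coverage, truth = tv, M = retained,
                 requested_M = M, n = n, level = level, methods = methods,
                 replaced = replaced, attempts = attempts,
                 partial = partial, seed = seed),
            class = "pohmm_coverage")
}

#' @export
print.pohmm_coverage <- function(x, digits = 3, ...) {
  cat("Monte Carlo coverage study:", x$M, "replicates of length", x$n,
      "at level", x$level, "\n")
  if (x$partial)
    cat("WARNING: replacement budget exhausted; results are partial (",
        x$M, "of", x$requested_M, "replicates )\n")
  print(round(x$coverage, digits))
  cat("replaced replicates:",
      paste(names(x$replaced), x$replaced, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a coverage study to CSV
#'
#' One row per parameter with the true value and per-method empirical
#' coverage.
#'
#' @param result a [coverage_study()] result.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_coverage_csv <- function(result, path) {
  df <- data.frame(parameter = rownames(result$coverage),
                   truth = as.numeric(result$truth))
  for (mt in colnames(result$coverage))
    df[[paste0("coverage_", mt)]] <- result$coverage[, mt]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
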