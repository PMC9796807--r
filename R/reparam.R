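# Natural <-> working reparameterization.
#
# Working-parameter layout (fixed package-wide, mirrored by the C++ core):
#   eta_i = log(lambda_i)                        positions 1..m
#   tau_ij = log(gamma_ij / gamma_ii), i != j    positions m+1..m+m(m-1),
#            row-major, diagonal skipped
#   nu_2..nu_m initial-distribution logits       appended only when the
#            initial distribution is freely estimated

#' Construct and validate natural Poisson-HMM parameters
#'
#' @param Gamma m x m row-stochastic transition probability matrix.
#' @param lambda m strictly positive Poisson conditional means.
#' @param init initial state distribution: `"stationary"` (default, derived
#'   from `Gamma`), `"estimated"` (freely estimated during fitting), or an
#'   explicit probability vector of length m held fixed.
#' @return object of class `"pohmm_params"`: a list with elements `m`,
#'   `Gamma`, `lambda`, `delta` (the initial distribution actually used) and
#'   `init`.
#' @export
#' @examples
#' pohmm_params(matrix(c(0.95, 0.15, 0.05, 0.85), 2), lambda = c(1, 7))
pohmm_params <- function(Gamma, lambda, init = "stationary") {
  Gamma <- as.matrix(Gamma)
  m <- length(lambda)
  if (!is.numeric(lambda) || any(!is.finite(lambda)) || any(lambda <= 0))
    stop("lambda must be strictly positive and finite")
  if (nrow(Gamma) != m || ncol(Gamma) != m)
    stop("Gamma must be ", m, " x ", m)
  if (any(Gamma < 0) || any(Gamma > 1) ||
      any(abs(rowSums(Gamma) - 1) > 1e-10))
    stop("Gamma rows must be probabilities summing to 1 (tolerance 1e-10)")
  if (is.numeric(init)) {
    if (length(init) != m || any(init < 0) || any(init > 1) ||
        abs(sum(init) - 1) > 1e-10)
      stop("explicit initial distribution must be a probability vector of length m")
    delta <- init
  } else {
    init <- match.arg(init, c("stationary", "estimated"))
    delta <- stationary_dist(Gamma)
  }
  structure(list(m = m, Gamma = unname(Gamma), lambda = unname(lambda),
                 delta = unname(delta), init = init),
            class = "pohmm_params")
}

#' @export
print.pohmm_params <- function(x, digits = 4, ...) {
  cat("Poisson HMM parameters (m =", x$m, ")\n")
  cat("lambda:", format(x$lambda, digits = digits), "\n")
  cat("Gamma:\n")
  print(round(x$Gamma, digits))
  cat("initial distribution (", if (is.numeric(x$init)) "fixed" else x$init,
      "):", format(x$delta, digits = digits), "\n")
  invisible(x)
}

# number of working parameters
working_length <- function(m, free_init = FALSE) {
  m + m * (m - 1L) + if (free_init) m - 1L else 0L
}

working_names <- function(m, free_init = FALSE) {
  nm <- paste0("eta", seq_len(m))
  for (i in seq_len(m))
    for (j in seq_len(m))
      if (i != j) nm <- c(nm, paste0("tau", i, j))
  if (free_init && m > 1L) nm <- c(nm, paste0("nu", 2:m))
  nm
}

# index of tau_{ij} within the full working vector (1-based)
tau_position <- function(m, i, j) {
  stopifnot(i != j)
  m + (i - 1L) * (m - 1L) + if (j > i) j - 1L else j
}

#' Map natural parameters to the unconstrained working scale
#'
#' `eta_i = log(lambda_i)`; `tau_ij = log(gamma_ij / gamma_ii)` for `i != j`
#' (multinomial logit with the diagonal as reference category); when the
#' initial distribution is freely estimated, logits
#' `nu_i = log(delta_i / delta_1)` are appended.
#'
#' @param params a [pohmm_params()] object.
#' @return named numeric working-parameter vector.
#' @export
natural_to_working <- function(params) {
  stopifnot(inherits(params, "pohmm_params"))
  m <- params$m
  if (any(diag(params$Gamma) <= 0))
    stop("transform undefined: a diagonal entry of Gamma is zero")
  w <- log(params$lambda)
  for (i in seq_len(m))
    for (j in seq_len(m))
      if (i != j) w <- c(w, log(params$Gamma[i, j] / params$Gamma[i, i]))
  if (identical(params$init, "estimated") && m > 1L) {
    if (any(params$delta <= 0))
      stop("transform undefined: a zero entry in the initial distribution")
    w <- c(w, log(params$delta[-1L] / params$delta[1L]))
  }
  setNames(w, working_names(m, identical(params$init, "estimated") && m > 1L))
}

#' Map working parameters back to natural parameters
#'
#' Inverse of [natural_to_working()]: `lambda = exp(eta)`,
#' `gamma_ij = exp(tau_ij) / (1 + sum_k exp(tau_ik))` with
#' `gamma_ii = 1 / (1 + sum_k exp(tau_ik))`.
#'
#' @param w working-parameter vector.
#' @param m number of states.
#' @param init `"stationary"`, `"estimated"`, or a fixed probability vector;
#'   must match the layout `w` was produced under.
#' @return a [pohmm_params()] object.
#' @export
working_to_natural <- function(w, m, init = "stationary") {
  free_init <- identical(init, "estimated") && m > 1L
  K <- working_length(m, free_init)
  if (length(w) != K)
    stop("working vector has length ", length(w), ", expected ", K)
  if (any(!is.finite(w))) stop("working parameters must be finite")
  lambda <- exp(w[seq_len(m)])
  Gamma <- diag(1, m)
  for (i in seq_len(m)) {
    e <- rep(1, m)
    for (j in seq_len(m))
      if (i != j) e[j] <- exp(w[tau_position(m, i, j)])
    Gamma[i, ] <- e / sum(e)
  }
  if (free_init) {
    e <- c(1, unname(exp(w[(m + m * (m - 1L) + 1L):K])))
    delta <- e / sum(e)
    out <- pohmm_params(Gamma, lambda, init = "estimated")
    out$delta <- delta
    return(out)
  }
  pohmm_params(Gamma, lambda, init = init)
}

# Analytic Jacobian of the extended map g_ext: working -> (Gamma row-major,
# lambda, delta). Rows ordered gamma11..gamma1m, gamma21.., lambda1..m,
# delta1..m; columns follow the working layout. Used by the delta method.
jacobian_gext <- function(w, m, init = "stationary") {
  free_init <- identical(init, "estimated") && m > 1L
  K <- working_length(m, free_init)
  p <- working_to_natural(w, m, init)
  G <- p$Gamma
  n_nat <- m * m + 2L * m
  J <- matrix(0, n_nat, K,
              dimnames = list(c(paste0("gamma", rep(seq_len(m), each = m),
                                       rep(seq_len(m), m)),
                                paste0("lambda", seq_len(m)),
                                paste0("delta", seq_len(m))),
                              working_names(m, free_init)))
  # Gamma block: softmax rows with diagonal reference
  dG <- vector("list", K)  # per-column derivative of Gamma
  for (a in seq_len(K)) dG[[a]] <- matrix(0, m, m)
  for (i in seq_len(m))
    for (j in seq_len(m))
      if (i != j) {
        a <- tau_position(m, i, j)
        dG[[a]][i, ] <- -G[i, j] * G[i, ]
        dG[[a]][i, j] <- dG[[a]][i, j] + G[i, j]
      }
  for (a in seq_len(K))
    J[seq_len(m * m), a] <- as.vector(t(dG[[a]]))
  # lambda block
  for (i in seq_len(m))
    J[m * m + i, i] <- p$lambda[i]
  # delta block
  drow <- m * m + m
  if (identical(p$init, "stationary")) {
    M <- diag(m) - G + matrix(1, m, m)
    Minv <- solve(M)
    for (a in seq_len(K)) {
      dd <- p$delta %*% dG[[a]] %*% Minv
      J[drow + seq_len(m), a] <- dd
    }
  } else if (free_init) {
    d <- p$delta
    for (i in 2:m) {
      a <- m + m * (m - 1L) + (i - 1L)
      dd <- -d[i] * d
      dd[i] <- dd[i] + d[i]
      J[drow + seq_len(m), a] <- dd
    }
  } # fixed init: zero block
  J
}
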