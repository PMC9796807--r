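# S3 methods for fitted models.

#' @export
print.pohmm <- function(x, digits = 4, ...) {
  cat("Poisson hidden Markov model (m =", x$m, "states ),",
      x$T, "observations\n")
  cat("nll:", format(x$nll, digits = 12),
      "  AIC:", format(2 * x$nll + 2 * x$df, digits = 10),
      "  BIC:", format(2 * x$nll + x$df * log(x$T), digits = 10), "\n")
  cat("converged:", x$converged,
      " (", x$iterations, "iterations, max |gradient|",
      format(x$grad_norm, digits = 3), ")\n")
  cat("lambda:", format(x$params$lambda, digits = digits), "\n")
  cat("Gamma:\n")
  print(round(x$params$Gamma, digits))
  cat("delta:", format(x$params$delta, digits = digits), "\n")
  invisible(x)
}

#' @export
coef.pohmm <- function(object, type = c("natural", "working"), ...) {
  type <- match.arg(type)
  if (type == "working") object$working else natural_estimates(object$params)
}

#' Summary of a fitted Poisson HMM
#'
#' Parameter estimates with delta-method standard errors for all transition
#' probabilities, conditional means, and the derived stationary distribution.
#'
#' @param object a [pohmm()] fit.
#' @param ... unused.
#' @return object of class `"summary.pohmm"`.
#' @export
summary.pohmm <- function(object, ...) {
  sr <- delta_method_cov(object)
  tab <- cbind(Estimate = sr$estimate, `Std. Error` = sr$se)
  structure(list(fit = object, coefficients = tab, reliable = sr$reliable),
            class = "summary.pohmm")
}

#' @export
print.summary.pohmm <- function(x, digits = 6, ...) {
  print(x$fit)
  cat("\nEstimates and delta-method standard errors:\n")
  print(round(x$coefficients, digits))
  if (!x$reliable)
    cat("NOTE: Hessian was singular; standard errors are unreliable.\n")
  invisible(x)
}

#' @export
predict.pohmm <- function(object, h = 1L, xvals = NULL, ...) {
  forecast(object, h = h, xvals = xvals)
}

#' @export
residuals.pohmm <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  sp <- posterior_probs(object)
  lam <- object$params$lambda
  mu <- as.numeric(sp %*% lam)
  r <- object$x - mu
  if (type == "response") return(r)
  v <- as.numeric(sp %*% (lam + lam^2)) - mu^2
  r / sqrt(v)
}

#' @export
plot.pohmm <- function(x, ...) {
  dt <- decode_table(x)
  plot(dt$time, dt$obs, type = "p", pch = 20,
       xlab = "time", ylab = "count",
       main = paste0("Observed counts and decoded conditional mean (m = ",
                     x$m, ")"), ...)
  lines(dt$time, dt$cond_mean, type = "s", lwd = 2)
  invisible(dt)
}

#' Write a fitted model to JSON at full precision
#'
#' The JSON carries the natural parameters, working parameters, nll, and fit
#' diagnostics at full serialization precision (`digits = NA`, about 15
#' significant digits); [read_pohmm_json()] restores the parameter object.
#'
#' @param fit a [pohmm()] fit.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_pohmm_json <- function(fit, path) {
  obj <- list(
    m = fit$m, T = fit$T,
    lambda = fit$params$lambda,
    Gamma = fit$params$Gamma,
    delta = fit$params$delta,
    init = if (is.numeric(fit$init)) fit$init else fit$init,
    working = as.list(fit$working),
    map = fit$map,
    nll = fit$nll,
    aic = 2 * fit$nll + 2 * fit$df,
    bic = 2 * fit$nll + fit$df * log(fit$T),
    df = fit$df,
    iterations = fit$iterations,
    converged = fit$converged,
    grad_norm = fit$grad_norm,
    package_version = as.character(packageVersion("pohmm"))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore natural parameters from a JSON file written by [write_pohmm_json()]
#'
#' @param path JSON path.
#' @return a [pohmm_params()] object.
#' @export
read_pohmm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  init <- if (is.numeric(obj$init)) obj$init else obj$init
  p <- pohmm_params(matrix(obj$Gamma, obj$m, obj$m), obj$lambda,
                    init = if (identical(init, "estimated")) "estimated"
                           else if (is.numeric(init)) init else "stationary")
  p$delta <- obj$delta
  p
}
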