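# Delta-method, profile-likelihood and bootstrap inference.

fit_tyt <- pohmm(tyt_arousal(), m = 2)

test_that("delta-method covariance is symmetric PSD with coherent names", {
  sr <- delta_method_cov(fit_tyt)
  expect_true(sr$reliable)
  expect_equal(sr$cov, t(sr$cov), tolerance = 1e-12)
  expect_true(all(eigen(sr$cov, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-10))
  expect_named(sr$estimate, c("gamma11", "gamma12", "gamma21", "gamma22",
                              "lambda1", "lambda2", "delta1", "delta2"))
  expect_equal(unname(sr$estimate["lambda2"]), fit_tyt$params$lambda[2])
  # within a 2-state row, gamma_i1 and gamma_i2 have identical SEs
  expect_equal(sr$se[["gamma11"]], sr$se[["gamma12"]], tolerance = 1e-12)
  expect_equal(vcov(fit_tyt), sr$cov)
})

test_that("Wald intervals contain the MLE and behave at level boundaries", {
  ci <- confint(fit_tyt, method = "wald", level = 0.95)
  est <- coef(fit_tyt)
  expect_true(all(ci[, "lower"] <= est & est <= ci[, "upper"]))
  ci50 <- confint(fit_tyt, method = "wald", level = 0.5)
  expect_true(all(ci50[, "upper"] - ci50[, "lower"] <
                  ci[, "upper"] - ci[, "lower"]))
  ci1 <- confint(fit_tyt, method = "wald", level = 1)
  expect_true(all(is.infinite(ci1[, "lower"]) | is.infinite(ci1[, "upper"])))
})

test_that("SE of a FIXED parameter is exactly zero; its Wald CI is a point", {
  s <- pohmm_params(matrix(c(0.9, 0.1, 0.1, 0.9), 2), c(1, 5))
  fit <- pohmm(tyt_arousal(), m = 2, start = s,
               map = c("FIXED", "eta2", "tau12", "tau21"))
  sr <- delta_method_cov(fit)
  expect_identical(unname(sr$se["lambda1"]), 0)
  ci <- confint(fit, parm = "lambda1", method = "wald")
  expect_equal(ci[1, "lower"], ci[1, "upper"])
  expect_equal(unname(ci[1, "lower"]), 1)
})

test_that("profile machinery uses the chi-squared(1) critical value 3.841", {
  pr <- profile(fit_tyt, "eta2")
  expect_equal(pr$critical, qchisq(0.95, 1), tolerance = 1e-12)
  expect_equal(round(pr$critical, 3), 3.841)
  # the likelihood ratio at the bounds equals the critical value
  w_mle <- fit_tyt$working[["eta2"]]
  expect_lt(pr$lower, w_mle)
  expect_gt(pr$upper, w_mle)
  tr <- pr$trace
  at_lo <- tr$ratio[which.min(abs(tr$value - pr$lower))]
  expect_equal(at_lo, pr$critical, tolerance = 1e-3)
})

test_that("profile CIs transform monotonically to the natural scale", {
  ci <- confint(fit_tyt, parm = c("lambda1", "lambda2"), method = "profile")
  pr2 <- profile(fit_tyt, "eta2")
  expect_equal(unname(ci["lambda2", ]),
               unname(exp(c(pr2$lower, pr2$upper))), tolerance = 1e-10)
  est <- coef(fit_tyt)
  expect_true(all(ci[, "lower"] < est[rownames(ci)]))
  expect_true(all(ci[, "upper"] > est[rownames(ci)]))
})

test_that("two-state diagonal gamma profile uses the row complement", {
  ci_off <- confint(fit_tyt, parm = "gamma12", method = "profile")
  ci_diag <- confint(fit_tyt, parm = "gamma11", method = "profile")
  expect_equal(unname(ci_diag[1, ]),
               unname(c(1 - ci_off[1, "upper"], 1 - ci_off[1, "lower"])),
               tolerance = 1e-10)
})

test_that("profile CIs are unavailable for delta and flagged as NA", {
  ci <- confint(fit_tyt, parm = c("delta1", "delta2"), method = "profile")
  expect_true(all(is.na(ci)))
})

test_that("profiling a constrained coordinate is refused", {
  s <- pohmm_params(matrix(c(0.9, 0.1, 0.1, 0.9), 2), c(1, 5))
  fit <- pohmm(tyt_arousal(), m = 2, start = s,
               map = c("FIXED", "eta2", "tau12", "tau21"))
  expect_error(profile(fit, "eta1"), "fixed")
  fit2 <- pohmm(tyt_arousal(), m = 2, map = c("eta1", "eta2", "s", "s"))
  expect_error(profile(fit2, "tau12"), "equality")
})

test_that("bootstrap replicates are reproducible and bookkept", {
  b1 <- pohmm_bootstrap(fit_tyt, B = 25, seed = 77)
  b2 <- pohmm_bootstrap(fit_tyt, B = 25, seed = 77)
  expect_identical(b1$estimates, b2$estimates)
  expect_identical(b1$attempts, b2$attempts)
  expect_false(any(is.na(b1$estimates)))
  # every replacement cause is counted and attempts reconcile
  expect_named(b1$replaced,
               c("invalid_path", "fit_failure", "improper_optimum"))
  expect_equal(b1$attempts, b1$B + sum(b1$replaced))
  b3 <- pohmm_bootstrap(fit_tyt, B = 25, seed = 78)
  expect_false(identical(b1$estimates, b3$estimates))
})

test_that("bootstrap estimates are relabeled to ascending lambda", {
  b <- pohmm_bootstrap(fit_tyt, B = 25, seed = 5)
  expect_true(all(b$estimates[, "lambda1"] <= b$estimates[, "lambda2"]))
  rows <- b$estimates[, c("gamma11", "gamma12")]
  expect_equal(unname(rowSums(rows)), rep(1, 25), tolerance = 1e-10)
})

test_that("the replacement budget aborts degenerate resampling", {
  expect_error(pohmm_bootstrap(fit_tyt, B = 10, seed = 1, budget = 0),
               "budget exhausted")
})

test_that("percentile bootstrap intervals come from the resample quantiles", {
  b <- pohmm_bootstrap(fit_tyt, B = 40, seed = 3)
  ci <- confint(fit_tyt, parm = "lambda2", method = "bootstrap", boot = b)
  expect_equal(unname(ci[1, ]),
               unname(quantile(b$estimates[, "lambda2"], c(0.025, 0.975))),
               tolerance = 1e-12)
})

test_that("write_ci_csv emits the documented table", {
  f <- tempfile(fileext = ".csv")
  df <- write_ci_csv(fit_tyt, f, B = 20, seed = 2)
  expect_true(file.exists(f))
  got <- read.csv(f)
  expect_identical(names(got),
                   c("parameter", "estimate", "wald_l", "wald_u",
                     "profile_l", "profile_u", "boot_l", "boot_u"))
  expect_equal(nrow(got), 8L)
  expect_true(all(is.na(got$profile_l[got$parameter %in%
                                        c("delta1", "delta2")])))
})

test_that("unknown parameter names are rejected", {
  expect_error(confint(fit_tyt, parm = "lambda9"), "unknown parameter")
})
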