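# Seeded simulation, label alignment, and the coverage harness.

truth2 <- pohmm_params(matrix(c(0.95, 0.05, 0.15, 0.85), 2, byrow = TRUE),
                       c(1, 7))

test_that("simulation is reproducible under a seed and respects the model", {
  s1 <- simulate_pohmm(truth2, 200, seed = 9)
  s2 <- simulate_pohmm(truth2, 200, seed = 9)
  expect_identical(s1, s2)
  s3 <- simulate_pohmm(truth2, 200, seed = 10)
  expect_false(identical(s1$x, s3$x))
  expect_true(all(s1$states %in% 1:2))
  expect_length(s1$x, 200L)
})

test_that("long-run simulation frequencies match the generating model", {
  sim <- simulate_pohmm(truth2, 20000, seed = 123)
  # empirical transition frequencies within 0.01 of Gamma
  trans <- table(factor(sim$states[-20000], levels = 1:2),
                 factor(sim$states[-1], levels = 1:2))
  emp <- trans / rowSums(trans)
  expect_true(max(abs(emp - truth2$Gamma)) < 0.01)
  # state-wise sample means within 0.1 of lambda
  for (i in 1:2)
    expect_lt(abs(mean(sim$x[sim$states == i]) - truth2$lambda[i]), 0.1)
  # occupancy near the stationary distribution
  expect_lt(abs(mean(sim$states == 1) - truth2$delta[1]), 0.02)
})

test_that("child seeds are deterministic and distinct across replicates", {
  a <- vapply(1:500, function(r) pohmm:::child_seed(1, r), integer(1))
  b <- vapply(1:500, function(r) pohmm:::child_seed(1, r), integer(1))
  expect_identical(a, b)
  expect_equal(anyDuplicated(a), 0L)
  expect_false(identical(a, vapply(1:500, function(r) pohmm:::child_seed(2, r),
                                   integer(1))))
})

test_that("sample validity requires every state to be visited", {
  expect_true(sample_is_valid(c(1L, 2L, 1L), 2))
  expect_false(sample_is_valid(c(1L, 1L, 1L), 2))
  expect_false(sample_is_valid(c(1L, 2L), 3))
})

test_that("simulate method draws from the fitted model", {
  fit <- pohmm(tyt_arousal(), m = 2)
  y1 <- simulate(fit, seed = 4)
  y2 <- simulate(fit, seed = 4)
  expect_identical(y1, y2)
  expect_length(y1, fit$T)
  ys <- simulate(fit, nsim = 3, seed = 5, n = 50)
  expect_length(ys, 3L)
  expect_true(all(lengths(ys) == 50L))
})

test_that("state relabeling is an exact symmetry of the likelihood", {
  sim <- simulate_pohmm(truth2, 400, seed = 21)
  fit <- pohmm(sim$x, m = 2,
               start = pohmm_params(matrix(c(0.8, 0.2, 0.2, 0.8), 2),
                                    c(8, 1.2)))
  perm <- pohmm:::state_order(fit$params)
  fit2 <- pohmm:::relabel_fit(fit)
  expect_equal(fit2$nll, fit$nll, tolerance = 1e-10)
  expect_true(all(diff(fit2$params$lambda) > 0))
  expect_equal(fit2$params$Gamma, fit$params$Gamma[perm, perm],
               tolerance = 1e-12)
  expect_lt(fit2$grad_norm, 1e-8)
})

test_that("parameter recovery: each seeded estimate within 3 sampling SEs", {
  # per-replicate recovery oracle: on each seeded T = 2000 draw, every
  # estimate lies within 3 of its (Monte Carlo sampling) standard errors of
  # the truth, with the delta-method SE standing in for the sampling SE.
  # (An oracle on the *average* over replicates is not used: the MLE of
  # near-boundary transition probabilities carries a genuine small O(1/T)
  # bias, so a sufficiently precise average fails any consistent estimator.)
  tv <- pohmm:::natural_estimates(truth2)
  for (seed in 1:3) {
    sim <- simulate_pohmm(truth2, 2000, seed = pohmm:::child_seed(seed, 1))
    expect_true(sample_is_valid(sim$states, 2))
    fit <- pohmm:::relabel_fit(pohmm(sim$x, m = 2))
    sr <- delta_method_cov(fit)
    z <- (sr$estimate - tv) / sr$se
    expect_true(all(abs(z) <= 3),
                info = paste0("seed ", seed, ": worst |z| = ",
                              round(max(abs(z)), 2)))
  }
})

test_that("estimation uncertainty shrinks with the series length", {
  sim_s <- simulate_pohmm(truth2, 500, seed = pohmm:::child_seed(7, 1))
  sim_l <- simulate_pohmm(truth2, 4000, seed = pohmm:::child_seed(7, 2))
  se_s <- delta_method_cov(pohmm:::relabel_fit(pohmm(sim_s$x, m = 2)))$se
  se_l <- delta_method_cov(pohmm:::relabel_fit(pohmm(sim_l$x, m = 2)))$se
  # SEs scale roughly as 1/sqrt(T); with one draw per length the observed
  # per-parameter ratios fluctuate around sqrt(8) = 2.8, so require a
  # conservative uniform shrink factor
  expect_true(all(se_l < se_s / 1.5))
  expect_gt(median(se_s / se_l), 2)
})

test_that("coverage_study covers near the nominal level and bookkeeps", {
  cs <- coverage_study(truth2, n = 500, M = 60, level = 0.90,
                       methods = "wald", seed = 31)
  expect_s3_class(cs, "pohmm_coverage")
  expect_equal(cs$M, 60L)
  expect_false(cs$partial)
  expect_equal(cs$attempts, cs$M + sum(cs$replaced))
  cov_l1 <- cs$coverage["lambda1", "wald"]
  # binomial(60, 0.9) 4-sigma band
  expect_gt(cov_l1, 0.9 - 4 * sqrt(0.9 * 0.1 / 60))
  expect_lte(cov_l1, 1)
})

test_that("coverage_study is reproducible under its seed", {
  c1 <- coverage_study(truth2, n = 300, M = 10, methods = "wald", seed = 8)
  c2 <- coverage_study(truth2, n = 300, M = 10, methods = "wald", seed = 8)
  expect_identical(c1$coverage, c2$coverage)
  expect_identical(c1$replaced, c2$replaced)
})

test_that("level = 1 yields infinite Wald intervals and full coverage", {
  cs <- coverage_study(truth2, n = 200, M = 5, level = 1, methods = "wald",
                       seed = 2)
  expect_true(all(cs$coverage[, "wald"] == 1))
})

test_that("coverage CSV round-trips the coverage matrix", {
  cs <- coverage_study(truth2, n = 200, M = 8, methods = "wald", seed = 3)
  f <- tempfile(fileext = ".csv")
  write_coverage_csv(cs, f)
  got <- read.csv(f)
  expect_identical(got$parameter, rownames(cs$coverage))
  expect_equal(got$coverage_wald, unname(cs$coverage[, "wald"]))
  expect_equal(got$truth, unname(as.numeric(cs$truth)))
})
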