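p <- deb_params()
g <- small_grid(60)

test_that("a constant sequence recovers the kernel's dominant eigenvalue", {
  # the fine grid: structure mixing is slow when growth steps undercut
  # coarse bins, so the transient dies off fastest at 200 bins
  g200 <- size_grid(p)
  K <- build_kernel(0.45, g200, p)
  ll <- lambda_s_sequence(rep(0.45, 2500), p, g200, burn_in = 500)
  expect_equal(as.numeric(ll), log(lambda1(K)), tolerance = 1e-4)
})

test_that("a degenerate Markov chain equals the constant environment", {
  env <- markov_environment(0.5, 0.5, EY_good = 0.45, EY_bad = 0.449999)
  ll <- stochastic_lambda(env, p, g, length = 1500, burn_in = 300, seed = 1)
  expect_equal(as.numeric(ll), log(lambda1(build_kernel(0.45, g, p))),
               tolerance = 1e-3)
})

test_that("log lambda_s is stable across environment seeds", {
  env <- markov_environment(0.5, 0.5)
  lls <- vapply(1:10, function(s)
    as.numeric(stochastic_lambda(env, p, g, seed = s)), numeric(1))
  expect_lt(stats::sd(lls), 0.01)
})

test_that("harvesting lowers log lambda_s under a common environment sequence", {
  for (pq in list(c(0.2, 0.6), c(0.5, 0.5), c(0.8, 0.2))) {
    env <- markov_environment(pq[1], pq[2])
    seq_EY <- sample_markov_sequence(env, 1500, seed = 21)
    l0 <- lambda_s_sequence(seq_EY, p, g, rule = NULL, burn_in = 300)
    l1 <- lambda_s_sequence(seq_EY, p, g, rule = harvest_rule(),
                            burn_in = 300)
    expect_lte(as.numeric(l1), as.numeric(l0))
  }
})

test_that("the stochastic grid annotates rho and f and respects limits", {
  sg <- stochastic_grid(c(0.2, 0.8), c(0.2, 0.8), p, g,
                        length = 1200, burn_in = 200, seed = 2)
  expect_equal(sg$rho, 1 - sg$p - sg$q)
  expect_equal(sg$f, sg$q / (sg$p + sg$q))
  # f -> 1 and f -> 0 approach the two constant-environment growth rates
  good <- log(lambda1(build_kernel(0.60, g, p)))
  bad <- log(lambda1(build_kernel(0.15, g, p)))
  nearly_good <- stochastic_lambda(markov_environment(0.01, 0.99), p, g,
                                   length = 2000, burn_in = 400, seed = 3)
  nearly_bad <- stochastic_lambda(markov_environment(0.99, 0.01), p, g,
                                  length = 2000, burn_in = 400, seed = 4)
  expect_equal(as.numeric(nearly_good), good, tolerance = 0.01)
  expect_equal(as.numeric(nearly_bad), bad, tolerance = 0.01)
})

test_that("elasticities: inert parameters give zero, mortality is negative", {
  env <- markov_environment(0.3, 0.5)
  # sigma_Lb = 0 never enters the kernel: exactly zero elasticity
  e0 <- elasticity(env, p, g, parameters = "sigma_Lb",
                   length = 800, burn_in = 100, seed = 5)
  expect_identical(e0$elasticity, 0)
  # higher mortality always lowers the growth rate
  for (pp in c(0.2, 0.5, 0.8)) for (qq in c(0.2, 0.5, 0.8)) {
    env <- markov_environment(pp, qq)
    em <- elasticity(env, p, g, parameters = "mu",
                     length = 1200, burn_in = 200, seed = 6)
    expect_lt(em$elasticity, 0)
  }
})

test_that("elasticities are near-linear: opposite perturbations agree", {
  g200 <- size_grid(p) # the fine study grid: coarse bins distort responses
  env <- markov_environment(0.4, 0.4)
  ef <- elasticity(env, p, g200, delta = 0.01, length = 2000, burn_in = 400,
                   seed = 7)
  eb <- elasticity(env, p, g200, delta = -0.01, length = 2000, burn_in = 400,
                   seed = 7)
  # L_b is excluded: with a point offspring size it enters the kernel only
  # through the discrete natal-bin assignment, so its perturbation response
  # is a staircase in the grid, not a smooth derivative
  keep <- abs(ef$elasticity) > 1e-4 & ef$parameter != "L_b"
  expect_true(all(sign(ef$elasticity[keep]) == sign(eb$elasticity[keep])))
  rel <- abs(ef$elasticity[keep] - eb$elasticity[keep]) /
    pmax(abs(ef$elasticity[keep]), abs(eb$elasticity[keep]))
  expect_true(all(rel < 0.25))
})

test_that("elasticities are reproducible under a fixed seed", {
  env <- markov_environment(0.3, 0.6)
  e1 <- elasticity(env, p, g, length = 800, burn_in = 100, seed = 9)
  e2 <- elasticity(env, p, g, length = 800, burn_in = 100, seed = 9)
  expect_identical(e1$elasticity, e2$elasticity)
})

test_that("the cross-level sweep runs per cell, colour and harvest option", {
  sw <- crosslevel_sweep(EY_low_values = c(0.20, 0.30),
                         EY_high_values = c(0.40, 0.55),
                         colours = c("blue", "red"), params = p, grid = g,
                         seed = 10)
  expect_equal(nrow(sw), 2 * 2 * 2 * 2)
  expect_false(any(sw$extinct))
  # harvested log lambda_s never exceeds the unharvested one, cellwise
  wide <- merge(sw[!sw$harvest, ], sw[sw$harvest, ],
                by = c("EY_low", "EY_high", "colour"))
  expect_true(all(wide$log_lambda_s.y <= wide$log_lambda_s.x))
  # continuity smoke test: a narrow EY gap gives near-identical cells
  sw2 <- crosslevel_sweep(EY_low_values = c(0.399, 0.3995),
                          EY_high_values = c(0.4, 0.4005),
                          colours = "white", harvest = FALSE,
                          params = p, grid = g, seed = 10)
  expect_lt(diff(range(sw2$log_lambda_s)), 0.005)
})

test_that("stratified BCa intervals behave at the edges", {
  # identical values collapse to a flagged point interval
  ci <- bootstrap_bca(rep(2.5, 12), strata = gl(3, 4), seed = 1)
  expect_true(ci$degenerate)
  expect_equal(c(ci$lower, ci$estimate, ci$upper), rep(2.5, 3))

  # a single stratum reduces to the ordinary BCa interval
  set.seed(2)
  x <- rnorm(40)
  c1 <- bootstrap_bca(x, seed = 3)
  c2 <- bootstrap_bca(x, strata = rep(1L, 40), seed = 3)
  expect_equal(c1$lower, c2$lower)
  expect_equal(c1$upper, c2$upper)
  expect_true(c1$lower <= c1$estimate && c1$estimate <= c1$upper)

  expect_error(bootstrap_bca(rnorm(5), strata = c(1, 1, 1, 1, 2)),
               "at least 2")
})

test_that("BCa intervals for a normal mean reach nominal coverage", {
  set.seed(42)
  cov <- mean(replicate(500, {
    x <- rnorm(100)
    ci <- bootstrap_bca(x, n_resamples = 1000)
    ci$lower <= 0 && 0 <= ci$upper
  }))
  expect_equal(cov, 0.95, tolerance = 0.032)
})

test_that("overlap verdicts follow closed-interval conventions", {
  obs <- list(lower = 1, upper = 3)
  expect_true(overlap_test(obs, 2))
  expect_true(overlap_test(obs, 3))        # touching endpoint: consistent
  expect_false(overlap_test(obs, 3.01))
  expect_true(overlap_test(obs, list(lower = 3, upper = 5)))
  expect_false(overlap_test(obs, list(lower = 4, upper = 5)))
})
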