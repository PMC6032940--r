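p <- deb_params()
g <- small_grid(60)

test_that("daily projection is the linear kernel map", {
  K <- build_kernel(0.4, g, p)
  z <- population_state(numeric(60), g)
  expect_equal(project_one_day(z, K)$abundance, numeric(60))

  s1 <- population_state(runif(60), g)
  out1 <- project_one_day(s1, K)
  out2 <- project_one_day(population_state(2 * s1$abundance, g), K)
  expect_equal(out2$abundance, 2 * out1$abundance)
  expect_equal(out1$day, 1L)

  other <- small_grid(50)
  expect_error(project_one_day(population_state(numeric(50), other), K),
               "grids")
})

test_that("harvest removes the stated fraction above the relative threshold", {
  # two equally occupied adult bins at 0.6 and 0.9 mm: mean 0.75, threshold
  # 0.7676, so only the 0.9 mm bin is halved
  ab <- numeric(60)
  i6 <- which.min(abs(g$midpoints - 0.6))
  i9 <- which.min(abs(g$midpoints - 0.9))
  ab[c(i6, i9)] <- 10
  st <- population_state(ab, g)
  out <- apply_harvest(st, harvest_rule(), EY = 1, params = p)
  expect_equal(out$abundance[i6], 10)
  expect_equal(out$abundance[i9], 5)
  expect_equal(sum(out$abundance > 0), 2L)

  # a single occupied adult bin can never exceed 1.0235 x its own mean
  ab1 <- numeric(60); ab1[i9] <- 10
  st1 <- population_state(ab1, g)
  expect_equal(apply_harvest(st1, harvest_rule(), 1, p)$abundance, ab1)

  # zero fraction and disabled rules are no-ops
  expect_equal(apply_harvest(st, harvest_rule(fraction = 0), 1, p)$abundance,
               ab)
  expect_equal(apply_harvest(st, harvest_rule(enabled = FALSE), 1, p)$abundance,
               ab)

  # juveniles-only population: no adults, nothing harvested
  abj <- numeric(60); abj[which.min(abs(g$midpoints - 0.2))] <- 5
  expect_equal(apply_harvest(population_state(abj, g),
                             harvest_rule(), 1, p)$abundance, abj)
})

test_that("stage counts partition the population", {
  ab <- runif(60)
  st <- population_state(ab, g)
  cs <- stage_counts(st, 0.45, p)
  expect_equal(cs$eggs + cs$juveniles + cs$adults, cs$total)
  expect_equal(cs$total, sum(ab))

  # all mass at the birth length counts as eggs under a high feeding level
  abe <- numeric(60); abe[which.min(abs(g$midpoints - p$L_b))] <- 7
  cse <- stage_counts(population_state(abe, g), 0.45, p)
  expect_equal(cse$eggs, 7)
  # all mass at L_m under EY = 1 counts as adults
  aba <- numeric(60); aba[60] <- 3
  csa <- stage_counts(population_state(aba, g), 1, p)
  expect_equal(csa$adults, 3)

  expect_error(stage_counts(st, 0.45, p, egg_cutoff = 0.6), "EY = 1")
  # production mode reports the day's egg output instead of newborn mass
  csp <- stage_counts(st, 0.45, p, egg_mode = "production")
  expect_equal(csp$eggs, sum(fecundity(g$midpoints, 0.45, p) * ab))
  expect_equal(csp$juveniles + csp$adults, csp$total)
})

test_that("log growth rate telescopes and rejects extinction", {
  expect_equal(log_stochastic_growth_rate(rep(5, 10)), 0)
  expect_equal(log_stochastic_growth_rate(2^(0:10)), log(2))
  tot <- exp(cumsum(rnorm(50, 0.01, 0.2)))
  expect_equal(log_stochastic_growth_rate(tot),
               log(tot[50] / tot[1]) / 49)
  expect_error(log_stochastic_growth_rate(c(3, 0, 2)), "extinct")
  expect_error(log_stochastic_growth_rate(5), "length")
})

test_that("the simulated experiment has the protocol's shape", {
  w <- make_white_series(seed = 1)
  sim <- run_experiment_simulation(w, EY_low = 0.25, EY_high = 0.45,
                                   grid = g)
  expect_equal(nrow(sim$censuses), 37L)
  expect_equal(sim$censuses$day, seq(4L, 148L, by = 4L))
  expect_equal(sim$tau, 148L)
  expect_length(sim$daily_totals, 149L)
  expect_equal(sim$log_lambda_s,
               log(sim$daily_totals[149] / sim$daily_totals[1]) / 148)
  with(sim$censuses,
       expect_equal(eggs + juveniles + adults, total))
})

test_that("harvesting never increases abundance along the trajectory", {
  w <- make_white_series(seed = 2)
  s0 <- run_experiment_simulation(w, EY_low = 0.2, EY_high = 0.5, grid = g)
  s1 <- run_experiment_simulation(w, EY_low = 0.2, EY_high = 0.5, grid = g,
                                  rule = harvest_rule())
  expect_true(all(s1$daily_totals <= s0$daily_totals + 1e-12))
  expect_lte(s1$log_lambda_s, s0$log_lambda_s)
})

test_that("identical low and high feeding levels collapse to the constant run", {
  w <- make_white_series(seed = 3)
  sa <- run_experiment_simulation(w, EY_low = 0.4, EY_high = 0.4, grid = g)
  sb <- run_experiment_simulation(constant_series(), EY_low = 0.35,
                                  EY_high = 0.45, EY_mid = 0.4, grid = g)
  expect_equal(sa$daily_totals, sb$daily_totals)
  expect_equal(sa$log_lambda_s, sb$log_lambda_s)
})

test_that("log lambda_s is invariant to the scale of the founder population", {
  w <- make_white_series(seed = 4)
  s1 <- run_experiment_simulation(w, EY_low = 0.25, EY_high = 0.45, grid = g,
                                  n_founders = 20)
  s2 <- run_experiment_simulation(w, EY_low = 0.25, EY_high = 0.45, grid = g,
                                  n_founders = 2000)
  expect_equal(s1$log_lambda_s, s2$log_lambda_s, tolerance = 1e-12)
})

test_that("census tables export and read back", {
  w <- make_white_series(seed = 5)
  sim <- run_experiment_simulation(w, EY_low = 0.25, EY_high = 0.45, grid = g)
  f <- tempfile(fileext = ".tsv")
  write_simulation(sim, f)
  back <- utils::read.table(f, header = TRUE, sep = "\t", skip = 1L)
  expect_equal(nrow(back), 37L)
  expect_equal(back$day, sim$censuses$day)
  expect_equal(back$total, sim$censuses$total, tolerance = 1e-8)
})
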