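p <- deb_params()

test_that("derived rates match hand-computed values", {
  expect_equal(ultimate_length(1, p), 1.008)
  expect_equal(ultimate_length(0.36, p), 0.36288)
  expect_error(ultimate_length(0, p), "EY")
  expect_error(ultimate_length(1.2, p), "EY")

  expect_equal(maturation_length(1, p), 0.543312)
  expect_equal(maturation_length(0.60, p), 0.3259872)
  p0 <- deb_params(lp_coeff = 0) # degenerate: everyone mature at birth
  expect_equal(maturation_length(0.5, p0), 0)

  expect_equal(vb_growth_rate(1, p), 1 / (151.0 - 137.8 * 1.008))
  expect_equal(vb_growth_rate(1, p), 0.0826610, tolerance = 1e-5)
  expect_equal(vb_growth_rate(1e-9, p), 1 / 151.0, tolerance = 1e-6)
  expect_gt(vb_growth_rate(0.8, p), vb_growth_rate(0.4, p))
  # with validated parameters the growth-rate denominator stays positive
  # for every admissible feeding level; the guard is for raw inputs only
  expect_silent(vb_growth_rate(1, deb_params(rb_c0 = 151, rb_c1 = 149)))
})

test_that("survival has a mortality plateau and a starvation cliff", {
  expect_equal(survival_prob(0.5, 0.5, p), exp(-0.03))
  # bound at EY = 0.08 is 1.008 * 0.08 / 0.083 = 0.9715 < 1.0: starvation
  expect_identical(survival_prob(1.0, 0.08, p), 0)
  expect_equal(survival_prob(0.5, 0.9, deb_params(mu = 0)), 1)
})

test_that("growth follows the von Bertalanffy mean and fixed point", {
  expect_equal(growth_mean(0.166, 1, p), 0.232801, tolerance = 1e-5)
  # the asymptote Linf = L_m * EY is an exact fixed point
  for (ey in seq(0.05, 1, length.out = 20)) {
    Linf <- ultimate_length(ey, p)
    expect_equal(growth_mean(Linf, ey, p), Linf)
  }
  expect_lt(growth_mean(1.008, 0.5, p), 1.008) # shrinking above asymptote

  expect_equal(growth_sd(1, p), 0.023991, tolerance = 1e-4)
  expect_equal(growth_sd(0.5, deb_params(sigma_Y = 0)), 0)
  expect_gt(growth_sd(0.8, p), growth_sd(0.4, p))
})

test_that("growth density is a Gaussian in the next-day length", {
  m <- growth_mean(0.3, 0.5, p)
  s <- growth_sd(0.5, p)
  expect_equal(growth_density(m, 0.3, 0.5, p), 1 / (sqrt(2 * pi) * s))
  expect_equal(growth_density(m + 0.01, 0.3, 0.5, p),
               growth_density(m - 0.01, 0.3, 0.5, p))
  Lgrid <- seq(m - 8 * s, m + 8 * s, length.out = 4001)
  expect_equal(sum(growth_density(Lgrid, 0.3, 0.5, p)) * diff(Lgrid[1:2]), 1,
               tolerance = 1e-6)
  expect_error(growth_density(0.3, 0.3, 0.5, deb_params(sigma_Y = 0)),
               "single-bin")
})

test_that("fecundity is gated by maturity and starvation", {
  expect_equal(fecundity(1.008, 1, p), 16)
  expect_identical(fecundity(0.30, 0.60, p), 0) # below L_p = 0.32599
  expect_equal(fecundity(0.50, 0.60, p), 2.362055, tolerance = 1e-6)
  # above the starvation bound fecundity is zero alongside survival
  expect_identical(fecundity(1.0, 0.08, p), 0)
})

test_that("offspring column is a unit mass at the birth length", {
  g <- small_grid(50)
  col <- offspring_column(0.9, 1, g, p) # mature parent
  expect_equal(sum(col), 1)
  expect_equal(sum(col > 0), 1L)
  expect_lt(abs(g$midpoints[which(col > 0)] - p$L_b), g$bin_width / 2 + 1e-12)

  expect_equal(offspring_column(0.2, 1, g, p), numeric(50)) # immature

  psd <- deb_params(sigma_Lb = 0.01)
  col2 <- offspring_column(0.9, 1, g, psd)
  expect_equal(sum(col2), 1)
  expect_gt(sum(col2 > 1e-8), 3L)
})

test_that("size grid invariants hold", {
  g <- size_grid(p, n_bins = 200)
  expect_equal(length(g$midpoints), 200L)
  expect_true(all(diff(g$midpoints) > 0))
  expect_equal(g$bin_width, (g$upper - g$lower) / 200)
  expect_equal(g$lower, 0.9 * p$L_b)
  expect_equal(g$upper, p$L_m)
  expect_error(size_grid(p, lower = 0.5, upper = 0.4))
  expect_error(size_grid(p, lower = 0.2), "birth length")
})

test_that("kernel parts add up, stay non-negative and bound survival mass", {
  g <- small_grid(80)
  for (ey in c(0.15, 0.36, 0.60)) {
    K <- build_kernel(ey, g, p)
    expect_equal(K$matrix, K$survival_part + K$fecundity_part)
    expect_true(all(K$matrix >= 0))
    # growth redistributes mass, never creates it
    expect_true(all(colSums(K$survival_part) <= exp(-p$mu) + 1e-9))
  }
})

test_that("interior growth columns conserve mass to 0.1%", {
  # the bin-integrated transition makes this hold for any bin width and
  # feeding level, including where the growth s.d. undercuts the bin size
  for (n_bins in c(60, 200)) for (ey in c(0.12, 0.45)) {
    g <- size_grid(p, n_bins = n_bins)
    K <- build_kernel(ey, g, p)
    gm <- growth_mean(g$midpoints, ey, p)
    gs <- growth_sd(ey, p)
    interior <- gm - 4 * gs > g$lower & gm + 4 * gs < g$upper &
      survival_prob(g$midpoints, ey, p) > 0
    sums <- colSums(K$survival_part)[interior] / exp(-p$mu)
    expect_true(all(sums >= 0.999 & sums <= 1.001))
  }
})

test_that("doubling R_m doubles fecundity and leaves survival untouched", {
  g <- small_grid(40)
  K1 <- build_kernel(0.5, g, p)
  K2 <- build_kernel(0.5, g, deb_params(R_m = 32))
  expect_equal(K2$fecundity_part, 2 * K1$fecundity_part)
  expect_equal(K2$survival_part, K1$survival_part)
})

test_that("kernel matches an independent direct-quadrature evaluation", {
  g <- size_grid(p, n_bins = 10)
  for (w in c(FALSE, TRUE)) {
    K <- build_kernel(0.42, g, p, survivor_weighted_fecundity = w)
    expect_equal(K$matrix, oracle_kernel(0.42, g, p, weighted = w),
                 tolerance = 1e-10)
  }
})

test_that("no reproduction and overwhelming mortality empty the kernel", {
  g <- small_grid(30)
  K <- build_kernel(0.5, g, deb_params(R_m = 0, mu = 50))
  expect_lt(max(K$matrix), 1e-20)
})

test_that("dominant eigenvalue increases with feeding level while newborns mature at birth", {
  # below EY ~ 0.3055 the plastic maturation length sits below the birth
  # length; in that regime more food monotonically raises growth rate
  g <- size_grid(p, n_bins = 200)
  ey <- seq(0.10, 0.30, length.out = 11)
  lam <- vapply(ey, function(e) power_lambda(build_kernel(e, g, p)$matrix),
                numeric(1))
  expect_true(all(diff(lam) > 0))
  # power-iteration oracle agrees with the eigen() route
  K <- build_kernel(0.36, g, p)
  expect_equal(lambda1(K), power_lambda(K$matrix), tolerance = 1e-8)
})

test_that("sigma_Y = 0 gives an exact deterministic-growth kernel", {
  g <- small_grid(50)
  K <- build_kernel(0.5, g, deb_params(sigma_Y = 0))
  cs <- colSums(K$survival_part)
  expect_true(all(cs %in% c(0, exp(-p$mu))))
})

test_that("kernel export round-trips through delimited text", {
  g <- small_grid(20)
  K <- build_kernel(0.37, g, p)
  f <- tempfile(fileext = ".tsv")
  write_kernel(K, f)
  back <- read_kernel(f)
  expect_equal(back$matrix, K$matrix, tolerance = 1e-12)
  expect_equal(back$EY, 0.37)
  expect_equal(back$n_bins, 20L)
  expect_equal(back$lower, g$lower)
})
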