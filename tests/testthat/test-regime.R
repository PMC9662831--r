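test_that("phi is 1 at regular positions and 0 at poles and midpoints", {
  L <- 2.53
  expect_equal(phi_regular(L / 2, L, 1), 1)
  expect_equal(phi_regular(0, L, 1), 0)
  expect_equal(phi_regular(L, L, 1), 0)
  expect_equal(phi_regular(L / 4, L, 2), 1)
  expect_equal(phi_regular(3 * L / 4, L, 2), 1)
  expect_equal(phi_regular(L / 2, L, 2), 0)
  expect_error(phi_regular(-0.1, L, 1), "within")
})

test_that("phi is periodic with period L/n and symmetric about regular positions", {
  L <- 3
  for (n in 1:3) {
    x <- seq(0.01, L / n - 0.01, by = 0.07)
    x2 <- x + L / n * (n - 1)
    expect_equal(phi_regular(x, L, n), phi_regular(x2[x2 <= L], L, n)[seq_along(x[x2 <= L])],
                 tolerance = 1e-12)
    centre <- L / (2 * n)
    d <- seq(0, centre - 0.01, by = 0.05)
    expect_equal(phi_regular(centre + d, L, n), phi_regular(centre - d, L, n),
                 tolerance = 1e-12)
  }
})

test_that("psi normalises the position spread to a uniform of width L/n", {
  L <- 2.4
  expect_equal(psi_mobility(0, L, 1), 0)
  expect_equal(psi_mobility(L / sqrt(12), L, 1), 1)
  expect_equal(psi_mobility(L / sqrt(12), L, 2), 2)
  # uniform samples over width L/n give psi ~ 1
  set.seed(10)
  x <- runif(5e4, 0, L / 2)
  expect_rel(psi_mobility(sd(x), L, 2), 1, 0.02)
})

test_that("chi is ~1 for periodic signals and 0 for monotone decay", {
  t <- 0:199
  expect_gt(chi_oscillation(sin(2 * pi * t / 10)), 0.9)
  tri <- (2 / pi) * asin(sin(2 * pi * t / 10))
  expect_gt(chi_oscillation(tri), 0.9)
  # a slowly decaying positive-autocorrelation series: no negative minimum
  expect_equal(chi_oscillation(exp(-(0:50) / 50)), 0)
})

test_that("chi stays small for white noise", {
  chis <- vapply(1:100, function(s) {
    set.seed(s)
    chi_oscillation(rnorm(500))
  }, 0)
  expect_gte(mean(chis < 0.3), 0.95)
})

test_that("chi is invariant under affine transforms of the series", {
  set.seed(4)
  x <- sin(2 * pi * (0:149) / 12) + rnorm(150, 0, 0.3)
  c0 <- chi_oscillation(x)
  expect_equal(chi_oscillation(3.7 * x - 12), c0, tolerance = 1e-12)
  expect_equal(chi_oscillation(-x), c0, tolerance = 1e-12)
})

test_that("regime scores combine descriptors as (1-psi)*phi etc.", {
  # confined at the regular position: regular positioning dominates
  set.seed(1)
  L <- 2.53
  x <- rnorm(300, 0, 0.05)                 # mid-relative
  d <- regime_descriptors(x, n = 1, L = L)
  expect_gt(d$phi, 0.9)
  expect_lt(d$psi, 0.3)
  expect_equal(d$score_regular, (1 - min(d$psi, 1)) * d$phi, tolerance = 1e-12)
  expect_equal(d$score_static, (1 - min(d$psi, 1)) * (1 - d$phi),
               tolerance = 1e-12)
  expect_identical(d$regime, "regular")
  # confined off-target: static dominates
  d2 <- regime_descriptors(rnorm(300, -1.0, 0.05), n = 1, L = L)
  expect_identical(d2$regime, "static")
  expect_gt(d2$score_static, 0.6)
  # sweeping triangle wave: oscillation dominates
  tri <- gen_triangle(synthetic_spec(kind = "triangle", amplitude = 1.1,
                                     period = 600, noise_sd = 0.02,
                                     dt_sample = 30, n_steps = 300,
                                     seed = 2, cell_length = 2.53))
  d3 <- regime_descriptors(tri, n = 1)
  expect_identical(d3$regime, "oscillation")
  expect_gt(d3$chi, 0.5)
  # mobile and aperiodic: a uniform sweep has psi = 1 and a monotone
  # autocorrelation decay (chi = 0), so every score vanishes -> diffusive
  d4 <- regime_descriptors(seq(-1.26, 1.26, length.out = 400), n = 1,
                           L = 2.53)
  expect_identical(d4$regime, "diffusive")
  expect_lt(max(d4$score_regular, d4$score_static, d4$score_osc), 0.1)
})

test_that("scores stay in [0,1] with psi clamped, and colours blend by score", {
  d <- regime_descriptors(runif(400, -1.26, 1.26), n = 2, L = 2.53)
  expect_gte(d$score_regular, 0)
  expect_lte(d$score_regular + d$score_static, 1)
  expect_equal(regime_colour(c(1, 0, 0)), c(255L, 193L, 7L))
  expect_equal(regime_colour(c(0, 1, 0)), c(30L, 136L, 229L))
  expect_equal(regime_colour(c(0, 0, 1)), c(216L, 27L, 96L))
  expect_equal(regime_colour(c(0, 0, 0)), c(0L, 0L, 0L))
})

test_that("ensemble-averaged descriptors damp single-track chi noise", {
  trs <- lapply(1:5, function(s)
    gen_triangle(synthetic_spec(kind = "triangle", amplitude = 1.1,
                                period = 600, noise_sd = 0.05,
                                dt_sample = 30, n_steps = 200, seed = s,
                                cell_length = 2.53)))
  d <- regime_descriptors(trs, n = 1)
  expect_identical(d$regime, "oscillation")
  # averaged descriptors equal the mean of the per-track ones
  per <- sapply(trs, function(tr) regime_descriptors(tr, n = 1)$chi)
  expect_equal(d$chi, mean(per), tolerance = 1e-12)
})
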