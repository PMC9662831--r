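test_that("stepwise velocities pair each step with its mean-relative start", {
  pr <- stepwise_velocities(c(0, 1, 0), dt_min = 1)
  expect_equal(pr$x_rel, c(-1 / 3, 2 / 3))
  expect_equal(pr$v, c(1, -1))
  # constant trajectory: all zeros
  pr0 <- stepwise_velocities(rep(2.2, 10), dt_min = 1)
  expect_true(all(pr0$x_rel == 0) && all(pr0$v == 0))
})

test_that("an exactly linear restoring field is fitted exactly", {
  # one point per display bin so within-bin velocity spread is exactly zero
  x <- seq(-0.475, 0.475, by = 0.05)
  pairs <- data.frame(x_rel = x, v = -0.4 * x)
  prof <- fit_velocity_profile(pairs, bin_width = 0.05)
  expect_equal(prof$m, -0.4, tolerance = 1e-10)
  expect_true(all(prof$profile$sd_v < 1e-12))
  expect_error(fit_velocity_profile(data.frame(x_rel = rep(0, 5), v = 1:5)),
               "single.*bin|bin")
})

test_that("the central fit region holds at least 68.27% of points", {
  set.seed(42)
  pairs <- data.frame(x_rel = rnorm(5000, 0, 0.2))
  pairs$v <- -0.3 * pairs$x_rel + rnorm(5000, 0, 0.1)
  prof <- fit_velocity_profile(pairs)
  frac <- mean(pairs$x_rel >= prof$fit_region[1] &
                 pairs$x_rel <= prof$fit_region[2])
  expect_gte(frac, 0.6827)
  # and it is the smallest such symmetric region (quantile construction)
  expect_equal(prof$fit_region[2],
               as.numeric(quantile(abs(pairs$x_rel), 0.6827, type = 1)))
})

test_that("ou_estimates inverts the discrete-sampling closed forms", {
  # slope corresponding to tau = 2 min at 1 min sampling
  m <- (exp(-1 / 2) - 1) / 1
  est <- ou_estimates(m, var_v = 0.02, dt_min = 1)
  expect_equal(est$tau_min, 2, tolerance = 1e-12)
  # D recovers the generating value: var_v = D*tau/dt^2*(1 - exp(-2 dt/tau))
  D0 <- 3e-4 * 60  # um^2/min
  tau0 <- 2
  vv <- D0 * tau0 * (1 - exp(-2 / tau0)) / 1
  est2 <- ou_estimates((exp(-1 / tau0) - 1), vv, 1)
  expect_equal(est2$D_um2_s, D0 / 60, tolerance = 1e-12)
  expect_equal(est2$k_over_kBT, 1 / (D0 * tau0), tolerance = 1e-12)
  # out-of-range slopes have no finite positive tau
  expect_error(ou_estimates(0.1, 1, 1), "m")
  expect_error(ou_estimates(-1.5, 1, 1), "m")
})

test_that("the m -> 0- limit approaches pure diffusion D = var_v * dt / 2", {
  est <- ou_estimates(-1e-8, var_v = 0.04, dt_min = 1)
  expect_gt(est$tau_min, 1e6)
  expect_equal(est$D_um2_s * 60, 0.04 * 1 / 2, tolerance = 1e-4)
})

test_that("the spring transition density is a normalised Gaussian with the right limits", {
  D <- 2.27e-4; tau <- 120
  for (dt_s in c(5, 60, 600)) {
    dens <- function(x) ou_transition_density(x, dt_s, x0 = 0.3, D = D, tau = tau)
    expect_equal(integrate(dens, -Inf, Inf)$value, 1, tolerance = 1e-6)
  }
  # long-time limit: stationary, mean 0, variance D*tau
  xs <- seq(-1, 1, by = 0.001)
  d_inf <- ou_transition_density(xs, 1e9, x0 = 0.3, D = D, tau = tau)
  expect_equal(d_inf, dnorm(xs, 0, sqrt(D * tau)), tolerance = 1e-9)
  # short-time limit concentrates at x0
  expect_gt(ou_transition_density(0.3, 1e-9, 0.3, D, tau), 1e3)
})

test_that("model autocorrelations are normalised and negative at lag dt for velocity", {
  ac0 <- autocorr_models(0, dt_sample = 1, tau = 2)
  expect_equal(ac0$position, 1)
  expect_equal(ac0$velocity, 1)
  expect_equal(autocorr_models(2, 1, 2)$position, exp(-1))
  # velocity autocorrelation at one sampling lag: -(1-a)^2 / (2 - 2a) < 0
  for (tau in c(0.3, 1, 5, 50)) for (dt in c(0.5, 1, 3)) {
    a <- exp(-dt / tau)
    v <- autocorr_models(dt, dt, tau)$velocity
    expect_equal(v, -(1 - a)^2 / (2 - 2 * a))
    expect_lt(v, 0)
  }
})

test_that("empirical autocorrelation is 1 at lag 0 and tracks a sampled cosine", {
  set.seed(7)
  y <- rnorm(100)
  ac <- empirical_autocorr(y, 10)
  expect_identical(unname(ac[1]), 1)
  t <- 0:399
  cosser <- cos(2 * pi * t / 50)
  ac_cos <- empirical_autocorr(cosser, 100)
  # the biased (1/n) estimator tapers the cosine by (1 - lag/n)
  expect_equal(unname(ac_cos[1 + c(25, 50)]),
               (1 - c(25, 50) / 400) * c(-1, 1), tolerance = 0.05)
  expect_error(empirical_autocorr(rep(1, 50), 10), "constant")
  expect_error(empirical_autocorr(1:10, 10), "max_lag")
})

test_that("OU parameter recovery from synthetic tracks is within 10%", {
  # the fitted experimental magnitudes: D ~ 2.27e-4 um^2/s, tau ~ 2 min
  spec <- synthetic_spec(kind = "ou", D = 2.27e-4, tau = 120, dt_sample = 60,
                         n_steps = 1e5, seed = 41)
  tr <- gen_ou(spec)
  fit <- spring_fit(tr)
  expect_rel(fit$estimates$tau_min, 2, 0.10)
  expect_rel(fit$estimates$D_um2_s, 2.27e-4, 0.10)
  # velocity spread does not depend on position for spring-like motion:
  # regressing squared residuals on position gives a slope ~ 0
  r2 <- residuals(fit)^2
  sl <- summary(lm(r2 ~ fit$pairs$x_rel))$coefficients[2, ]
  expect_gt(sl["Pr(>|t|)"], 0.01)
})

test_that("MSD closed forms hold for diffusion and the over-damped spring", {
  # pure diffusion: MSD(t) = 2 D t
  spec_d <- synthetic_spec(kind = "diffusion", D = 2.01e-4, dt_sample = 1,
                           n_steps = 2e5, seed = 5, cell_length = 40)
  tr_d <- gen_diffusion(spec_d)
  lags <- c(1, 2, 4)
  m <- msd(tr_d, lags)
  expect_rel(unname(m["1"]), 2 * 2.01e-4 * 1, 0.10)
  fitD <- unname(lm(m ~ lags)$coefficients[2]) / 2
  expect_rel(fitD, 2.01e-4, 0.10)
  # stationary spring: MSD(t) = 2 D tau (1 - exp(-t/tau)), plateau 2 D tau
  spec_o <- synthetic_spec(kind = "ou", D = 2.27e-4, tau = 120,
                           dt_sample = 30, n_steps = 1e5, seed = 6)
  tr_o <- gen_ou(spec_o)
  m_o <- msd(tr_o, c(30, 120, 1200))
  th <- 2 * 2.27e-4 * 120 * (1 - exp(-c(30, 120, 1200) / 120))
  expect_rel(unname(m_o["30"]), th[1], 0.10)
  expect_rel(unname(m_o["120"]), th[2], 0.10)
  expect_rel(unname(m_o["1200"]), th[3], 0.10)
  expect_error(msd(tr_o, 45), "multiple")
  expect_error(msd(tr_o, 30 * 1e5), "span")
})

test_that("characteristic force converts the spring constant to pN", {
  expect_equal(characteristic_force(0), 0)
  # k/kBT = 36.8 um^-2 at 30 C
  expect_equal(characteristic_force(36.8, 303.15), 0.0254, tolerance = 2e-3)
  expect_equal(characteristic_force(2 * 10) / characteristic_force(10),
               sqrt(2), tolerance = 1e-12)
})

test_that("spring_fit methods are coherent", {
  tr <- gen_ou(synthetic_spec(kind = "ou", n_steps = 3000, seed = 9))
  fit <- spring_fit(tr)
  co <- coef(fit)
  expect_named(co, c("m", "var_v", "tau_min", "D_um2_s", "k_over_kBT"))
  expect_equal(unname(co["k_over_kBT"]),
               1 / (unname(co["D_um2_s"]) * 60 * unname(co["tau_min"])),
               tolerance = 1e-10)
  expect_equal(predict(fit, 0), fit$profile$intercept)
  sims <- simulate(fit, nsim = 2, seed = 3, n_steps = 50)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "par_trajectory")
})
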