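test_that("dimer number is conserved through state changes", {
  p <- small_params("fig4", nA = 40, dt = 0.001)
  st <- init_state(p, seed = 3)
  for (i in 1:20) {
    st <- par_step(st, p, n = 50)
    expect_equal(length(st$state), 40)
    expect_equal(sum(st$state %in% 0:2), 40)
    # tethered <=> partner set
    expect_true(all((st$state == 2) == (st$partner >= 0)))
    # all positions of nucleoid-associated dimers inside the rectangle
    on <- st$state != 0
    expect_true(all(st$x[on] >= 0 & st$x[on] <= p$L))
    expect_true(all(st$y[on] >= 0 & st$y[on] <= p$W))
    expect_true(all(st$hx[on] >= 0 & st$hx[on] <= p$L))
  }
  # counters are non-decreasing and populated
  expect_true(all(st$counters >= 0))
  expect_gt(st$counters[["associations"]], 0)
})

test_that("identical seeds give bit-identical trajectories", {
  p <- small_params("fig4", nA = 30)
  a <- par_run(p, duration = 120, burn_in = 60, sampling_interval = 60,
               seed = 9)
  b <- par_run(p, duration = 120, burn_in = 60, sampling_interval = 60,
               seed = 9)
  expect_identical(a$positions, b$positions)
  expect_identical(a$tether_counts, b$tether_counts)
  expect_identical(a$counters, b$counters)
  c <- par_run(p, duration = 120, burn_in = 60, sampling_interval = 60,
               seed = 10)
  expect_false(identical(a$positions, c$positions))
})

test_that("plasmids start at the regular positions unless overridden", {
  p1 <- small_params("fig4", nA = 10)
  expect_equal(init_state(p1, 1)$px, p1$L / 2)
  p2 <- small_params("fig5A", nA = 10)
  expect_equal(init_state(p2, 1)$px, c(p2$L / 4, 3 * p2$L / 4))
  # same-point override is allowed (no excluded volume)
  st <- init_state(p2, 1, plasmid_positions = list(c(0.3, p2$W / 2),
                                                   c(0.3, p2$W / 2)))
  expect_equal(st$px, c(0.3, 0.3))
  expect_error(init_state(p1, 1, plasmid_positions = list(c(p1$L + 1, 0.2))),
               "outside")
})

test_that("with no ParA the plasmid diffuses freely at Dp", {
  p <- par_params(kh = 0.5642, Dh = 0.056760, nA = 0, np = 1, L = 10, W = 1)
  tr <- par_run(p, duration = 1500, burn_in = 0, sampling_interval = 1,
                seed = 21)
  m <- msd(tr, c(1, 2, 4))
  # MSD(t) = 2 Dp t along the long axis, far from confinement (L = 10)
  expect_rel(unname(m["1"]), 2 * p$Dp, 0.15)
  expect_rel(unname(m["4"]), 8 * p$Dp, 0.15)
})

test_that("a lone dimer's stationary fluctuation variance is sigma_x^2", {
  p <- par_params(kh = 0, Dh = 0, ka = 0, kd = 0, nA = 1, np = 0)
  st <- single_dimer_state(p)
  # 2000 s of dynamics (correlation time sigma_x^2/DA = 1 s) for a ~4%
  # standard error on the variance estimate
  res <- hoprelay:::cpp_run(hoprelay:::.state_to_cpp(st), p, 2e6, 200L,
                            TRUE, 1L)
  xs <- vapply(res$dimer_x, `[`, 0, 1)
  expect_rel(var(xs), p$sigma_x^2, 0.10)
  expect_lt(abs(mean(xs) - p$L / 2), 0.01)
})

test_that("without a plasmid the bound fraction approaches ka/(ka+kd)", {
  p <- par_params(kh = 0.5642, Dh = 0.056760, nA = 200, np = 0)
  tr <- par_run(p, duration = 240, burn_in = 60, sampling_interval = 1,
                seed = 31)
  expect_equal(mean(tr$bound_counts) / 200, 0.19 / 0.20, tolerance = 0.02)
})

test_that("replication duplicates the position but not the tethers", {
  p <- small_params("fig4", nA = 40)
  st <- init_state(p, seed = 7)
  st <- par_step(st, p, n = 5000)   # 5 s: tethers have formed
  nteth <- sum(st$state == 2)
  expect_gt(nteth, 0)
  st2 <- replicate_plasmid(st, 1)
  expect_length(st2$px, 2)
  expect_equal(st2$px[2], st2$px[1])
  expect_equal(st2$py[2], st2$py[1])
  expect_true(all(st2$partner[st2$state == 2] == 0))   # all stay with parent
  expect_error(replicate_plasmid(st, 5), "unknown")
})

test_that("par_run stitches a replication event into a two-plasmid trajectory", {
  p <- small_params("fig5E", nA = 30)
  tr <- par_run(p, duration = 600, burn_in = 60, sampling_interval = 60,
                seed = 13, replicate_at = 300)
  expect_equal(ncol(tr$positions), 2)
  expect_equal(nrow(tr$positions), 11)
  pre <- tr$times < 300
  expect_true(all(is.na(tr$positions[pre, 2])))
  expect_true(all(!is.na(tr$positions[!pre, 2])))
  # both plasmids at the same position at the replication sample
  i <- which(tr$times == 300)
  expect_equal(tr$positions[i, 1], tr$positions[i, 2])
  expect_equal(tr$tether_counts[i, 2], 0)
})

test_that("ATP consumption counts every dissociation over the accounted time", {
  st <- init_state(small_params("fig4", nA = 5), seed = 1)
  expect_equal(atp_consumption_rate(st, duration = 100), 0)
  expect_error(atp_consumption_rate(st), "duration")
  # no plasmid: rate = kd * theta at steady state
  p <- par_params(kh = 0.5642, Dh = 0.056760, nA = 200, np = 0)
  tr <- par_run(p, duration = 300, burn_in = 60, sampling_interval = 60,
                seed = 17)
  theta <- 200 * 0.19 / 0.20
  expect_rel(atp_consumption_rate(tr), 0.01 * theta, 0.15)
})

test_that("kymograph rows sum to the instantaneous bound count", {
  # raw list input: one immobile dimer occupies a single bin
  k <- para_kymograph(list(c(0.5), c(0.5), c(0.5)), n_bins = 10, L = 2.5)
  expect_equal(dim(k), c(3, 10))
  expect_equal(rowSums(k), rep(1, 3))
  expect_equal(sum(colSums(k) > 0), 1)
  # empty samples give zero rows, not an error
  expect_equal(rowSums(para_kymograph(list(numeric(0)), 5, L = 1)), 0)
  # simulated: row sums match the recorded bound counts
  p <- par_params(kh = 0.5642, Dh = 0.056760, nA = 60, np = 0)
  tr <- par_run(p, duration = 120, burn_in = 30, sampling_interval = 10,
                seed = 19, record_dimers = TRUE)
  k2 <- para_kymograph(tr, n_bins = 20)
  expect_equal(unname(rowSums(k2)), tr$bound_counts)
})

test_that("non-commensurate intervals are rejected", {
  p <- small_params("fig4", nA = 5)
  expect_error(par_run(p, duration = 100.0005, burn_in = 0,
                       sampling_interval = 1, seed = 1), "multiple")
  expect_error(par_run(p, duration = 100, burn_in = 0,
                       sampling_interval = 0.0001, seed = 1), "at least dt")
  expect_error(par_run(p, duration = 90, burn_in = 0,
                       sampling_interval = 60, seed = 1), "multiple")
})
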