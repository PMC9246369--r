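test_that("local quadratic smoothing reproduces polynomials and reduces noise", {
  tt <- seq(0, 16200, 90)
  const <- turbidity_trace(tt, rep(2.5, length(tt)))
  expect_equal(smooth_trace(const)$turbidity, const$turbidity,
               tolerance = 1e-12)

  quad <- turbidity_trace(tt, 0.1 + 2e-5 * tt + 3e-9 * tt^2)
  expect_equal(smooth_trace(quad)$turbidity, quad$turbidity,
               tolerance = 1e-9)

  expect_error(smooth_trace(const, window = 4), "odd")
  expect_error(smooth_trace(turbidity_trace(c(0, 90), c(0, 1))), "short")

  # derivative RMSE on a noisy logistic improves over raw differencing
  set.seed(7)
  clean <- 1 / (1 + exp(-0.001 * (tt - 8000)))
  noisy <- turbidity_trace(tt, clean * exp(rnorm(length(tt), 0, 0.02)))
  true_d <- 0.001 * clean * (1 - clean)
  sg_d <- crystagg:::smoothed_derivative(noisy, window = 11)
  raw_d <- c(NA, diff(noisy$turbidity) / 90)
  idx <- 2:length(tt)
  rmse_sg <- sqrt(mean((sg_d[idx] - true_d[idx])^2))
  rmse_raw <- sqrt(mean((raw_d[idx] - true_d[idx])^2))
  expect_lt(rmse_sg, rmse_raw)
})

test_that("tangent fit is exact on the logistic closed form at 90 s sampling", {
  # max rate L*k/4 at t0; apparent lag t0 - 2/k
  cases <- list(c(L = 1, k = 0.02, t0 = 6000),
                c(L = 0.8, k = 0.001, t0 = 8000),
                c(L = 2, k = 0.005, t0 = 4000))
  for (cs in cases) {
    tr <- logistic_trace(L = cs["L"], k = cs["k"], t0 = cs["t0"])
    f <- tangent_fit(tr, baseline = 0)
    expect_equal(f$max_rate, cs[["L"]] * cs[["k"]] / 4,
                 tolerance = 0.005)
    expect_equal(f$lag_time, cs[["t0"]] - 2 / cs[["k"]],
                 tolerance = 0.005)
    expect_equal(f$t_at_max, cs[["t0"]], tolerance = 0.005 * cs[["t0"]])
  }
})

test_that("tangent fit handles ramps and scaling linearly", {
  tt <- seq(0, 9000, 90)
  a <- 1e-4
  ramp <- turbidity_trace(tt, a * tt)
  f <- tangent_fit(ramp, baseline = 0)
  expect_equal(f$max_rate, a, tolerance = 1e-9)
  expect_equal(f$lag_time, 0, tolerance = 1e-6)

  # rate scaling: same trace scaled by 0.65 gives a 0.65 rate ratio
  tr <- logistic_trace()
  tr65 <- turbidity_trace(tr$time, tr$turbidity * 0.65)
  f1 <- tangent_fit(tr, baseline = 0)
  f2 <- tangent_fit(tr65, baseline = 0)
  expect_equal(f2$max_rate / f1$max_rate, 0.65, tolerance = 1e-6)
  expect_equal(f2$lag_time, f1$lag_time, tolerance = 1)

  # time-shift equivariance
  tr_sh <- logistic_trace(t0 = 6900)
  f3 <- tangent_fit(tr_sh, baseline = 0)
  expect_equal(f3$lag_time - f1$lag_time, 900, tolerance = 1)
  expect_equal(f3$t_at_max - f1$t_at_max, 900, tolerance = 1)

  # a decreasing trace has no growth phase
  dec <- turbidity_trace(tt, 1 - a * tt)
  expect_error(tangent_fit(dec, baseline = 0), "no growth phase")
})

test_that("phase segmentation separates time-shifted logistic phases", {
  tt <- seq(0, 16200, 90)
  one <- logistic_trace()
  expect_equal(nrow(segment_phases(one)), 1L)

  ramp <- turbidity_trace(tt, 1e-4 * tt)
  ph <- segment_phases(ramp)
  expect_equal(nrow(ph), 1L)
  expect_equal(ph$start_idx, 1L)
  expect_equal(ph$end_idx, length(tt))

  two <- turbidity_trace(tt,
    1 / (1 + exp(-0.01 * (tt - 3000))) +
      1.5 / (1 + exp(-0.01 * (tt - 10000))))
  ph2 <- segment_phases(two)
  expect_equal(nrow(ph2), 2L)
  # second-phase tangent recovers the second logistic's L*k/4
  f2 <- tangent_fit(two, phase_rule = "second_phase")
  expect_equal(f2$max_rate, 1.5 * 0.01 / 4, tolerance = 0.01)
  expect_equal(f2$phase_index, 2L)
  expect_equal(f2$n_phases, 2L)
  # global-max rule picks the taller second phase here
  fg <- tangent_fit(two, phase_rule = "global_max")
  expect_equal(fg$phase_index, 2L)
})

test_that("endpoint turbidity averages the requested tail", {
  tt <- seq(0, 16200, 90)
  expect_equal(endpoint_turbidity(turbidity_trace(tt, rep(0.7, length(tt)))),
               0.7)
  expect_equal(endpoint_turbidity(logistic_trace()), 1, tolerance = 1e-6)
  expect_error(endpoint_turbidity(logistic_trace(), tail_points = 0),
               "tail_points")
})

test_that("endpoint turbidity anti-correlates with soluble fraction", {
  x <- c(0.1, 0.5, 0.9)
  y <- c(0.9, 0.5, 0.1)
  r <- turbidity_soluble_correlation(x, y)
  expect_equal(r$r, -1, tolerance = 1e-12)
  expect_equal(r$slope, -1, tolerance = 1e-12)
  expect_error(turbidity_soluble_correlation(c(1, 1, 1), y), "variance")

  # model property: with w_P = w_G turbidity is proportional to
  # aggregated = 1 - soluble mass, so |r| is essentially 1
  p <- mk_params(w_P = 0.02, w_G = 0.02)
  doses <- c(0, 50, 100, 200, 400)
  ends <- numeric(length(doses)); sol <- numeric(length(doses))
  for (i in seq_along(doses)) {
    init <- system_state(N = 40, GSSG = 0.5, inositol = doses[i])
    traj <- simulate_aggregation(p, init, assay_times(interval = 180))
    fin <- traj$state[nrow(traj$state), ]
    ends[i] <- endpoint_turbidity(turbidity_observable(traj))
    sol[i] <- (fin[["N"]] + fin[["Ired"]] + fin[["Iox"]] + fin[["D"]]) / 40
  }
  res <- turbidity_soluble_correlation(ends, sol)
  expect_gt(abs(res$r), 0.99)
  expect_lt(res$r, 0)

  # permutation null: shuffled pairings carry no correlation
  set.seed(11)
  rs <- replicate(200, turbidity_soluble_correlation(ends, sample(sol))$r)
  expect_lt(abs(mean(rs)), 0.15)
})

test_that("dose-response normalizes rates and recovers the inhibition constant", {
  doses <- c(0, 50, 100, 250)
  rates <- 1 / (1 + doses / 150)
  dr <- dose_response(doses, rates)
  expect_equal(dr$normalized_rate[1], 1)
  expect_equal(attr(dr, "K_I"), 150, tolerance = 1e-6)

  # flat response: K_I flagged infinite
  flat <- dose_response(doses, rep(0.02, 4))
  expect_equal(attr(flat, "K_I_flag"), "infinite")

  # single nonzero dose: closed form
  one <- dose_response(c(0, 100), c(0.01, 0.004))
  expect_equal(attr(one, "K_I"), 100 * 0.4 / 0.6, tolerance = 1e-9)

  expect_error(dose_response(c(0, 50), c(0, 1)), "zero-dose")
  expect_error(dose_response(c(50, 100), c(1, 2)), "zero dose")

  # lag changes as percent of zero-dose lag
  dr2 <- dose_response(doses, rates, lags = c(1000, 1200, 1400, 2000))
  expect_equal(dr2$lag_change_pct, c(0, 20, 40, 100))
})

test_that("K_I recovery from noisy synthetic dose-response is well calibrated", {
  # coverage check over quadruplicate noisy dose series:
  # |K_hat - K| <= 2 SE in at least 90% of seeds
  dose_grid <- rep(c(0, 25, 50, 100, 250, 500), each = 4)
  true_K <- 150
  hits <- 0; n_seeds <- 100
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    rates <- 0.01 / (1 + dose_grid / true_K) *
      exp(rnorm(length(dose_grid), 0, 0.02))
    dr <- dose_response(dose_grid, rates)
    K <- attr(dr, "K_I"); se <- attr(dr, "K_I_se")
    if (is.finite(K) && is.finite(se) && abs(K - true_K) <= 2 * se)
      hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.90)
})
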