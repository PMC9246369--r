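test_that("inhibition factor follows the one-parameter noncompetitive form", {
  expect_equal(inhibition_factor(0, 186), 1.0)
  expect_equal(inhibition_factor(186, 186), 0.5)
  expect_equal(inhibition_factor(100, 186), 1 / (1 + 100 / 186),
               tolerance = 1e-12)
  expect_equal(round(inhibition_factor(100, 186), 4), 0.6503)
  expect_error(inhibition_factor(-1, 100), "inositol")
  expect_error(inhibition_factor(10, 0), "K_I")
})

test_that("derivative function conserves mass and vanishes for zero rates", {
  zero <- mk_params(k_mis = 0, k_fold = 0, k_ox = 0, k_red = 0, k_dim = 0,
                    k_diss = 0, k_nuc = 0, k_elong = 0, k_coal = 0,
                    k_settle = 0)
  rhs0 <- build_rhs(zero)
  s <- system_state(N = 10, Ired = 2, Iox = 5, D = 4, P0 = 1, P1 = 6,
                    G1 = 3, S1 = 1, GSH = 1.6, GSSG = 0.2, inositol = 50)
  expect_true(all(rhs0(0, s) == 0))

  # monomer-equivalent and glutathione derivatives sum to zero for
  # arbitrary states under the full scheme, Model 1 and Model 2
  for (m2 in c(FALSE, TRUE)) {
    rhs <- build_rhs(mk_params(dim_oxidizes = m2))
    set.seed(42)
    for (i in 1:20) {
      st <- system_state(N = runif(1, 0, 50), Ired = runif(1, 0, 10),
                         Iox = runif(1, 0, 30), D = runif(1, 0, 5),
                         P0 = runif(1, 0, 2), P1 = runif(1, 0, 30),
                         G1 = runif(1, 0, 20), S1 = runif(1, 0, 10),
                         GSH = runif(1, 0, 2), GSSG = runif(1, 0, 0.5),
                         inositol = runif(1, 0, 300))
      d <- rhs(0, st)
      prot <- d[["N"]] + d[["Ired"]] + d[["Iox"]] + d[["D"]] +
        d[["P1"]] + d[["G1"]] + d[["S1"]]
      gsx <- d[["GSH"]] + 2 * d[["GSSG"]]
      expect_lt(abs(prot), 1e-12)
      expect_lt(abs(gsx), 1e-15)
    }
  }
})

test_that("trajectories conserve monomer equivalents and glutathione", {
  p <- default_params()
  init <- system_state(N = 40, GSH = 0.1, GSSG = 0.45, inositol = 20)
  traj <- simulate_aggregation(p, init, assay_times())
  prot <- rowSums(traj$state[, c("N", "Ired", "Iox", "D", "P1", "G1",
                                 "S1")])
  gsx <- traj$state[, "GSH"] + 2 * traj$state[, "GSSG"]
  expect_lt(max(abs(prot - prot[1])) / prot[1], 1e-6)
  expect_lt(max(abs(gsx - gsx[1])) / gsx[1], 1e-6)
  expect_true(all(traj$state >= 0))
})

test_that("aggregation is entirely redox-dependent: no oxidant, no aggregate", {
  p <- default_params()
  init <- system_state(N = 40, GSH = 2, GSSG = 0)
  traj <- simulate_aggregation(p, init, assay_times())
  final <- traj$state[nrow(traj$state), ]
  agg <- final[["P1"]] + final[["G1"]] + final[["S1"]] + final[["D"]]
  expect_lt(agg, 0.001 * 40)
  tr <- turbidity_observable(traj)
  expect_lt(max(tr$turbidity), 1e-6)
})

test_that("inositol lowers the maximum tangent slope of sigmoidal traces", {
  tr0 <- sim_trace(40, 0, 1, 1)
  tr1 <- sim_trace(40, 100, 1, 1)
  f0 <- tangent_fit(tr0)
  f1 <- tangent_fit(tr1)
  expect_gt(f0$max_rate, f1$max_rate)
  # sigmoidal: the steepest point sits well inside the trace and above
  # a fifth of the final turbidity rise
  expect_gt(f0$t_at_max, 500)
  expect_lt(f0$t_at_max, 16000)
})

test_that("turbidity observable weights aggregated mass as specified", {
  p <- default_params()
  init <- system_state(N = 10, GSH = 2, GSSG = 0)  # nothing aggregates
  traj <- simulate_aggregation(p, init, seq(0, 900, 90))
  expect_true(all(turbidity_observable(traj)$turbidity < 1e-9))

  # with w_P = w_G = c, turbidity is c * total aggregated mass
  init2 <- system_state(N = 40, GSSG = 0.5)
  traj2 <- simulate_aggregation(p, init2, assay_times())
  tr <- turbidity_observable(traj2, w_P = 0.03, w_G = 0.03)
  agg <- rowSums(traj2$state[, c("P1", "G1", "S1")])
  expect_equal(tr$turbidity, 0.03 * unname(agg), tolerance = 1e-12)
  expect_error(turbidity_observable(traj2, w_P = -1, w_G = 1), "weights")
})

test_that("soluble thiol distribution maps species to free-thiol classes", {
  s_all_native <- system_state(N = 10)
  expect_equal(soluble_thiol_distribution(s_all_native, 4),
               c("4" = 1, "2" = 0))
  s_half <- system_state(N = 5, Iox = 5)
  expect_equal(soluble_thiol_distribution(s_half, 4),
               c("4" = 0.5, "2" = 0.5))
  s_six <- system_state(N = 3, Iox = 1)
  expect_equal(soluble_thiol_distribution(s_six, 6),
               c("6" = 0.75, "4" = 0.25))
  # aggregated pools are excluded from the denominator
  s_mix <- system_state(N = 2, Iox = 2, P1 = 10, G1 = 5)
  expect_equal(soluble_thiol_distribution(s_mix, 4),
               c("4" = 0.5, "2" = 0.5))
  expect_error(soluble_thiol_distribution(system_state(P1 = 10), 4),
               "no soluble protein")
})

test_that("addition events dilute, mix inositol, and disrupt as specified", {
  s <- system_state(N = 100, inositol = 0, volume = 60)
  s2 <- apply_event(s, added_volume = 40, added_inositol = 0)
  expect_equal(s2[["N"]], 60)
  expect_equal(s2[["volume"]], 100)

  s3 <- apply_event(s, added_volume = 40, added_inositol = 250)
  expect_equal(s3[["inositol"]], 100)  # 250 * 40 / 100

  # disruption moves extended-aggregate mass back to locked precursor
  s4 <- system_state(Iox = 1, P0 = 2, P1 = 10, volume = 100)
  s5 <- apply_event(s4, 0, 0, disruption_fraction = 0.5)
  expect_equal(s5[["P1"]], 5)
  expect_equal(s5[["Iox"]], 6)
  expect_equal(s5[["P0"]], 1)
  expect_equal(monomer_equivalents(s5), monomer_equivalents(s4))
})

test_that("ODE solution matches a fine-step explicit-Euler oracle on a reduced network", {
  # reduced scheme N <-> I (k_mis, k_fold), 2I -> D (k_dim), realised by
  # the Model-2 dimerization channel with all other rates zero
  km <- 1e-3; kf <- 5e-4; kd <- 1e-3
  p <- mk_params(k_mis = km, k_fold = kf, k_dim = kd, k_ox = 0, k_red = 0,
                 k_diss = 0, k_nuc = 0, k_elong = 0, k_coal = 0,
                 k_settle = 0, dim_oxidizes = TRUE, K_I = 100)
  t_grid <- seq(0, 2000, by = 100)
  traj <- simulate_aggregation(p, system_state(N = 10), t_grid)

  # independent explicit-Euler integration at a fine step
  dt <- 0.01
  n_steps <- 2000 / dt
  N <- 10; I <- 0; D <- 0
  out <- matrix(NA_real_, nrow = length(t_grid), ncol = 3)
  out[1, ] <- c(N, I, D)
  next_idx <- 2
  for (step in seq_len(n_steps)) {
    dN <- -km * N + kf * I
    dI <- km * N - kf * I - 2 * kd * I^2
    dD <- 2 * kd * I^2
    N <- N + dt * dN; I <- I + dt * dI; D <- D + dt * dD
    t_now <- step * dt
    if (next_idx <= length(t_grid) &&
        abs(t_now - t_grid[next_idx]) < dt / 2) {
      out[next_idx, ] <- c(N, I, D)
      next_idx <- next_idx + 1
    }
  }
  for (j in 1:3) {
    sp <- c("N", "Ired", "D")[j]
    scale <- max(abs(out[, j]))
    expect_lt(max(abs(traj$state[, sp] - out[, j])) / scale, 1e-4)
  }
})

test_that("degenerate inputs are handled: zero protein gives a flat zero trace", {
  tr <- sim_trace(0, 0, 1, 1)
  expect_true(all(tr$turbidity == 0))
})

test_that("trajectory long-format export is tidy and unit-labelled", {
  p <- default_params()
  traj <- simulate_aggregation(p, system_state(N = 10, GSSG = 0.5),
                               seq(0, 900, 90))
  df <- trajectory_long(traj)
  expect_setequal(unique(df$species),
                  c("N", "Ired", "Iox", "D", "P0", "P1", "G1", "S1",
                    "GSH", "GSSG", "inositol", "volume"))
  expect_equal(nrow(df), 12 * length(traj$time))
  expect_equal(df$value[df$species == "N" & df$time_s == 0], 10)
  expect_equal(unique(df$units[df$species == "GSH"]), "mM")
})
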