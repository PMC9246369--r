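test_that("noise-free plate traces equal the kinetic model output exactly", {
  conds <- list(A1 = well_condition(40, 0, 1, 1),
                A2 = well_condition(40, 100, 1, 1))
  des <- plate_design(conds, noise_sigma = 0, baseline_sd = 0, seed = 3)
  plate <- make_plate(des)
  direct <- sim_trace(40, 100, 1, 1)
  expect_identical(plate$A2$turbidity, direct$turbidity)
  expect_named(plate, c("A1", "A2"))
})

test_that("plate generation is deterministic by seed with independent wells", {
  conds <- list(A1 = well_condition(40, 0, 1, 1),
                A2 = well_condition(40, 100, 1, 1))
  des <- plate_design(conds, replicates = 2, seed = 11)
  p1 <- make_plate(des)
  p2 <- make_plate(des)
  for (w in names(p1)) expect_identical(p1[[w]]$turbidity, p2[[w]]$turbidity)

  # distinct wells and replicates get distinct noise realisations
  expect_false(identical(p1$`A1.1`$turbidity, p1$`A1.2`$turbidity))

  # substreams do not depend on well order within the design
  des_r <- plate_design(rev(conds), replicates = 2, seed = 11)
  p3 <- make_plate(des_r)
  expect_identical(p1$`A1.1`$turbidity, p3$`A1.1`$turbidity)

  # a different seed changes the noise
  p4 <- make_plate(plate_design(conds, replicates = 2, seed = 12))
  expect_false(identical(p1$`A1.1`$turbidity, p4$`A1.1`$turbidity))
})

test_that("noise-free inositol series has monotonically non-increasing rates", {
  doses <- c(0, 25, 50, 100, 200, 350, 500)
  conds <- lapply(doses, function(d) well_condition(40, d, 1, 1))
  names(conds) <- paste0("W", seq_along(doses))
  des <- plate_design(conds, noise_sigma = 0, baseline_sd = 0)
  plate <- make_plate(des)
  rates <- vapply(plate, function(tr) tangent_fit(tr)$max_rate, numeric(1))
  expect_true(all(diff(rates) <= 1e-12))
})

test_that("late addition continues the control arm and responds to dose", {
  conds <- list(W1 = well_condition(75, 0, 0.2, 2),
                W2 = well_condition(75, 0, 0.2, 2))
  des <- plate_design(conds, noise_sigma = 0, baseline_sd = 0,
                      duration_s = 12600)
  plate <- late_addition_plate(des, addition_time_s = 5400,
                               added_inositol_mM = c(0, 250),
                               added_volume_uL = 40)
  blank <- plate$W1; dosed <- plate$W2
  # dead-time gap: one read dropped and the next flagged
  expect_false(5490 %in% blank$time)
  expect_equal(blank$flags[blank$time == 5580], 1L)
  # pre-event readings identical
  pre <- blank$time < 5400
  expect_equal(blank$turbidity[pre], dosed$turbidity[pre])
  # turbidity continuous across a blank-buffer addition up to the
  # dilution factor 60/(60+40) = 0.6
  i_ev <- which(blank$time == 5580)
  ratio <- blank$turbidity[i_ev] / blank$turbidity[i_ev - 1]
  expect_gt(ratio, 0.55)
  expect_lt(ratio, 0.80)
  # dosed arm aggregates more slowly afterwards
  post <- blank$time > 7200
  d_blank <- diff(blank$turbidity[post])
  d_dosed <- diff(dosed$turbidity[post])
  expect_gt(sum(d_blank), sum(d_dosed))

  # addition at t = 0 is a plain run at the diluted composition
  des1 <- plate_design(list(W = well_condition(100, 0, 1, 1,
                                               volume_uL = 60)),
                       noise_sigma = 0, baseline_sd = 0,
                       duration_s = 5400)
  pl0 <- late_addition_plate(des1, 0, 250, 40)
  # the diluted composition: 60 uM protein, 100 mM inositol, and the
  # glutathione total diluted from 1 to 0.6 mM
  ref <- sim_trace(60, 100, 1, 0.6, times = seq(0, 5400, 90))
  shared <- intersect(pl0$W$time, ref$time)
  expect_equal(pl0$W$turbidity[match(shared, pl0$W$time)],
               ref$turbidity[match(shared, ref$time)], tolerance = 1e-6)
})

test_that("plate CSV round-trips losslessly and rejects malformed input", {
  conds <- list(B1 = well_condition(40, 0, 1, 1),
                B2 = well_condition(40, 100, 1, 1))
  des <- plate_design(conds, seed = 5, duration_s = 3600)
  plate <- make_plate(des)
  path <- tempfile(fileext = ".csv")
  write_plate_csv(plate, path)
  back <- read_plate_csv(path)
  expect_setequal(names(back), names(plate))
  for (w in names(plate)) {
    expect_equal(back[[w]]$turbidity, plate[[w]]$turbidity,
                 tolerance = 1e-9)
    expect_equal(back[[w]]$time, plate[[w]]$time)
    expect_equal(back[[w]]$condition$inositol_mM,
                 plate[[w]]$condition$inositol_mM)
  }

  # interleaved wells are demultiplexed by well id
  df <- utils::read.csv(path)
  df <- df[order(df$time_s, df$well), ]
  path2 <- tempfile(fileext = ".csv")
  utils::write.csv(df, path2, row.names = FALSE)
  back2 <- read_plate_csv(path2)
  expect_equal(back2$B1$turbidity, back$B1$turbidity)

  # missing column is named in the error
  df3 <- df[, setdiff(names(df), "oxd")]
  path3 <- tempfile(fileext = ".csv")
  utils::write.csv(df3, path3, row.names = FALSE)
  expect_error(read_plate_csv(path3), "oxd")

  # non-monotone time is reported with its line
  df4 <- utils::read.csv(path)
  df4$time_s[5] <- df4$time_s[4]
  path4 <- tempfile(fileext = ".csv")
  utils::write.csv(df4, path4, row.names = FALSE)
  expect_error(read_plate_csv(path4), "non-monotone")
})

test_that("plate simulation failures name the offending well", {
  bad <- well_condition(40, 0, 1, 1)
  bad$events <- list(list(time_s = 100, added_volume_uL = 10),
                     list(time_s = 100, added_volume_uL = 10))
  des <- plate_design(list(OK = well_condition(10, 0, 1, 1), BAD = bad),
                      duration_s = 900)
  expect_error(make_plate(des), "BAD")
})

test_that("synthetic morphometry has the requested count and size structure", {
  rec <- synth_morphometry(n_images = 30, treatments = "0",
                           mean_particles = c(extended = 5, globular = 5),
                           seed = 21)
  # Poisson(5) counts over 30 images: total near 150 per class
  n_ext <- sum(rec$class == "extended")
  expect_lt(abs(n_ext - 150), 4 * sqrt(150))

  # scale shift moves the whole rank-size curve down
  rec2 <- synth_morphometry(n_images = 20, treatments = c("0", "100"),
                            effect = list("100" = c(extended = 1,
                                                    globular = 0.5)),
                            seed = 8)
  r0 <- rank_size(rec2, "globular", "0")
  r1 <- rank_size(rec2, "globular", "100")
  m <- min(nrow(r0), nrow(r1))
  expect_gt(mean(r0$size_nm[1:m] - r1$size_nm[1:m]), 0)

  # reproducible by seed
  expect_identical(synth_morphometry(n_images = 5, seed = 4),
                   synth_morphometry(n_images = 5, seed = 4))
})

test_that("morphometry generator satisfies the KS null under identical settings", {
  # two independent draws from the same generator: p-values ~ Uniform(0,1)
  set.seed(123)
  pvals <- replicate(200, {
    x <- rlnorm(50, 4.8, 0.7)
    y <- rlnorm(50, 4.8, 0.7)
    ks_two_sample(x, y)$p
  })
  # the exact two-sample p is mildly discrete at n = m = 50, so
  # uniformity is checked on bins rather than by a meta-KS test
  expect_lt(abs(mean(pvals) - 0.5), 0.06)
  for (q in c(0.25, 0.5, 0.75))
    expect_lt(abs(mean(pvals <= q) - q), 0.15)
})
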