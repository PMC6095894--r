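test_that("despiking removes spikes and only spikes", {
  # noiseless exponential: nothing to remove
  tr <- exp_trajectory(n = 120)
  expect_identical(remove_spike_outliers(tr)$n_removed, 0L)

  # locally constant series with one huge outlier: exactly that frame goes
  # (zero-MAD path: absolute tolerance around the median)
  t <- seq(0, by = 10, length.out = 60)
  v <- rep(1000, 60); v[30] <- 5000
  tr2 <- remove_spike_outliers(trajectory("c", t, v))
  expect_identical(tr2$n_removed, 1L)
  expect_false(tr2$retained[30])

  # seeded noisy exponential with 3 injected x3 spikes: all removed,
  # at most 1 false positive per 500 frames
  set.seed(42)
  n <- 500
  t <- seq(0, by = 10, length.out = n)
  v <- 1500 * exp(0.04 * t / 60) * exp(rnorm(n, 0, 0.02))
  spikes <- c(100, 250, 400)
  v[spikes] <- v[spikes] * 3
  tr3 <- remove_spike_outliers(trajectory("c", t, v))
  expect_true(all(!tr3$retained[spikes]))
  expect_lte(tr3$n_removed - 3L, 1L)

  # idempotence: a second pass removes nothing further
  tr4 <- remove_spike_outliers(tr3)
  expect_identical(tr4$n_removed, 0L)

  expect_error(remove_spike_outliers(tr, window = 4), "odd")
})

test_that("smoothing matches a direct convolution oracle", {
  # constant series unchanged
  t <- seq(0, by = 10, length.out = 50)
  tr <- smooth_trajectory(trajectory("c", t, rep(500, 50)))
  expect_equal(tr$volume, rep(500, 50))

  # linear series unchanged in the interior
  v_lin <- 100 + 3 * seq_len(50)
  tr2 <- smooth_trajectory(trajectory("c", t, v_lin))
  expect_equal(tr2$volume[4:47], v_lin[4:47], tolerance = 1e-12)

  # step series: interior values equal the 7-frame moving mean
  v_step <- c(rep(100, 25), rep(200, 25))
  tr3 <- smooth_trajectory(trajectory("c", t, v_step))
  oracle <- as.numeric(stats::filter(v_step, rep(1 / 7, 7), sides = 2))
  expect_equal(tr3$volume[4:47], oracle[4:47], tolerance = 1e-12)

  # long stationary series keeps its mean (edge shrinkage is unbiased here)
  set.seed(1)
  v_noise <- rnorm(600, 1000, 20)
  tr4 <- smooth_trajectory(trajectory("c", seq(0, by = 10,
                                               length.out = 600), v_noise))
  expect_lt(abs(mean(tr4$volume) / mean(v_noise) - 1), 0.001)
})

test_that("Theil-Sen growth speed is exact, accurate, and robust", {
  # V = 100 + 6 t (t in hours): speed 6 at every interior frame
  t <- seq(0, by = 10, length.out = 40)
  tr <- trajectory("c", t, 100 + 6 * t / 60)
  sp <- instantaneous_growth_speed(tr)
  expect_equal(sp$dvdt_um3_per_h[sp$valid], rep(6, sum(sp$valid)))
  expect_false(any(sp$valid[c(1:4, 37:40)]))

  # exponential: within 1% of alpha * V(t) at each interior frame
  alpha <- 0.0462
  tr2 <- exp_trajectory(V0 = 1000, alpha = alpha, n = 60)
  sp2 <- instantaneous_growth_speed(tr2)
  ok <- sp2$valid
  expect_true(all(abs(sp2$dvdt_um3_per_h[ok] /
                        (alpha * sp2$volume_um3[ok]) - 1) < 0.01))

  # one 5x outlier inside the window leaves the slope untouched,
  # and the windowed slope equals the brute-force pairwise-median oracle
  v <- 100 + 6 * t / 60
  v[20] <- 5 * v[20]
  tr3 <- trajectory("c", t, v)
  sp3 <- instantaneous_growth_speed(tr3)
  expect_lt(abs(sp3$dvdt_um3_per_h[25] - 6), 1e-6)
  sel <- 16:24 # window centered on frame 20 holds the outlier
  expect_equal(sp3$dvdt_um3_per_h[20],
               theil_sen_oracle(t[sel] / 60, v[sel]),
               tolerance = 1e-12)

  # speed error shrinks as the sampling gets finer (5 vs 10 vs 15 min)
  err <- vapply(c(5, 10, 15), function(fi) {
    trx <- exp_trajectory(V0 = 1000, alpha = 0.05, n = 200,
                          frame_interval = fi)
    spx <- instantaneous_growth_speed(trx)
    okx <- spx$valid
    max(abs(spx$dvdt_um3_per_h[okx] / (0.05 * spx$volume_um3[okx]) - 1))
  }, numeric(1))
  expect_true(all(diff(err) > 0))
})

test_that("pooled growth-speed regression recovers the growth law", {
  # exponential growers with one alpha: slope of speed vs volume = alpha
  mk <- function(id, V0, alpha = 0.05) {
    sp <- instantaneous_growth_speed(exp_trajectory(V0, alpha, n = 80,
                                                    cell_id = id))
    sp <- sp[sp$valid, ]
    data.frame(cell_id = id, volume = sp$volume_um3,
               dvdt = sp$dvdt_um3_per_h)
  }
  pool <- do.call(rbind, lapply(1:8, function(i) mk(i, 800 + 100 * i)))
  res <- growth_speed_vs_volume_bins(pool, n_bins = 10)
  expect_equal(res$growth_rate, 0.05, tolerance = 0.02 * 0.05)

  # linear growers: slope ~ 0, intercept ~ the common speed c
  mk_lin <- function(id, V0, c = 30) {
    t <- seq(0, by = 10, length.out = 80)
    sp <- instantaneous_growth_speed(trajectory(id, t, V0 + c * t / 60))
    sp <- sp[sp$valid, ]
    data.frame(cell_id = id, volume = sp$volume_um3,
               dvdt = sp$dvdt_um3_per_h)
  }
  pool2 <- do.call(rbind, lapply(1:12, function(i) mk_lin(i, 650 + 50 * i)))
  res2 <- growth_speed_vs_volume_bins(pool2, n_bins = 8)
  expect_lt(abs(res2$growth_rate), 1e-6)
  expect_equal(res2$fit$intercept, 30, tolerance = 1e-6)

  # two subpopulations: per-group slopes keep their order
  fast <- do.call(rbind, lapply(1:8, function(i)
    mk(paste0("f", i), 700 + 90 * i, alpha = 0.06)))
  slow <- do.call(rbind, lapply(1:8, function(i)
    mk(paste0("s", i), 700 + 90 * i, alpha = 0.03)))
  a_fast <- growth_speed_vs_volume_bins(fast, n_bins = 8)$growth_rate
  a_slow <- growth_speed_vs_volume_bins(slow, n_bins = 8)$growth_rate
  expect_gt(a_fast, a_slow)

  expect_error(growth_speed_vs_volume_bins(mk(1, 1000)), "distinct cells")
})

test_that("percentile grouping is deterministic and sums to n", {
  g <- percentile_groups(1:10)
  expect_identical(as.integer(table(g)), c(2L, 6L, 2L))

  expect_warning(g2 <- percentile_groups(rep(5, 12)), "degenerate")
  expect_true(all(g2 == "mid"))

  set.seed(9)
  g3 <- percentile_groups(runif(100))
  expect_identical(as.integer(table(g3)), c(20L, 60L, 20L))
  expect_identical(length(g3), 100L)

  expect_error(percentile_groups(1:5), "at least 10")
})
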