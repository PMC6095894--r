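test_that("replicative growth mean and derived gamma are exact arithmetic", {
  d <- data.frame(V_birth = c(100, 200), V_mitosis = c(200, 400))
  expect_equal(replicative_growth_mean(d), log(2))
  d2 <- data.frame(V_birth = c(100, 200), V_mitosis = c(100, 200))
  expect_equal(replicative_growth_mean(d2), 0)

  expect_equal(estimate_gamma_derived(0.5, 0, log(2))$gamma, 0.5 / log(2))
  expect_equal(estimate_gamma_derived(0, 0, log(2))$gamma, 0)
  expect_error(estimate_gamma_derived(0.5, 0, -1), "mean_G")
})

test_that("theta and gamma are recovered across the coupling grid", {
  grid <- expand.grid(theta = c(-0.2, 0, 0.3, 0.6),
                      gamma = c(-0.2, 0, 0.3, 0.6))
  for (i in seq_len(nrow(grid))) {
    th0 <- grid$theta[i]; ga0 <- grid$gamma[i]
    cells <- simulate_dataset(model_params(theta = th0, gamma = ga0),
                              mechanistic_mode("linear_response"),
                              n_cells = 5000, seed = 100 + i)
    th <- estimate_theta(cells, binn = 8, minn = 4)
    ga <- estimate_gamma_direct(cells, binn = 8, minn = 4)
    la <- estimate_lambda(cells, binn = 8, minn = 4)
    expect_lt(abs(th$theta - th0), 0.05)
    expect_lt(abs(ga$gamma - ga0), 0.05)
    # balance relation: lambda = (theta + gamma) <G> within 2 combined SE
    mG <- replicative_growth_mean(cells)
    gap <- la$lambda - (th$theta + ga$gamma) * mG
    se <- sqrt(la$se^2 + (mG * th$se)^2 + (mG * ga$se)^2)
    expect_lt(abs(gap), max(2 * se, 0.02))
  }
})

test_that("derived gamma is consistent with the direct estimate", {
  cells <- simulate_dataset(model_params(theta = 0.4, gamma = 0.3),
                            mechanistic_mode("linear_response"),
                            n_cells = 5000, seed = 21)
  th <- estimate_theta(cells, binn = 8, minn = 4)
  la <- estimate_lambda(cells, binn = 8, minn = 4)
  ga_dir <- estimate_gamma_direct(cells, binn = 8, minn = 4)
  ga_der <- estimate_gamma_derived(la$lambda, th$theta,
                                   replicative_growth_mean(cells),
                                   se_lambda = la$se, se_theta = th$se)
  se <- sqrt(ga_dir$se^2 + ga_der$se^2)
  expect_lt(abs(ga_der$gamma - ga_dir$gamma), max(2 * se, 0.05))
})

test_that("a deterministic-sizer population has theta <alpha><tau> near 1", {
  # tau = (log V* - log V_birth) / alpha: slope -1/<alpha>
  cells <- simulate_dataset(stationary_params(),
                            mechanistic_mode("sizer"), n_cells = 5000,
                            seed = 22)
  th <- estimate_theta(cells, binn = 8, minn = 4)
  expect_equal(th$theta * mean(cells$alpha) * th$mean_tau, 1,
               tolerance = 0.1)
})

test_that("<G> equals <alpha><tau> at stationarity", {
  cells <- simulate_dataset(stationary_params(theta = 0.3, gamma = 0.2),
                            mechanistic_mode("linear_response"),
                            n_cells = 5000, seed = 23)
  expect_equal(replicative_growth_mean(cells),
               mean(cells$alpha) * mean(cells$tau), tolerance = 0.01)
  expect_equal(replicative_growth_mean(cells), log(2), tolerance = 0.01)
})

test_that("lambda, theta, gamma are invariant under volume rescaling", {
  cells <- simulate_dataset(model_params(theta = 0.3, gamma = 0.2),
                            mechanistic_mode("linear_response"),
                            n_cells = 2000, seed = 24)
  scaled <- cells
  for (col in c("V_birth", "V_G1S", "V_mitosis"))
    scaled[[col]] <- scaled[[col]] * 37.5
  for (est in list(function(d) estimate_lambda(d, binn = 8, minn = 4)[[1]],
                   function(d) estimate_theta(d, binn = 8, minn = 4)[[1]],
                   function(d) estimate_gamma_direct(d, binn = 8,
                                                     minn = 4)[[1]]))
    expect_equal(est(cells), est(scaled), tolerance = 1e-10)
})

test_that("the mechanistic-adder test separates the hypotheses", {
  # fixed split fraction f: dV_SG2 = 2 * dV_G1 exactly -> slope 2
  set.seed(25)
  dv1 <- runif(500, 100, 500)
  d <- data.frame(V_birth = 1000, V_G1S = 1000 + dv1,
                  V_mitosis = 1000 + 3 * dv1)
  fit <- mechanistic_adder_test(d, binn = 8, minn = 4)
  expect_equal(fit$slope, 2, tolerance = 1e-9)
  expect_equal(fit$distance_to_minus1, 3, tolerance = 1e-9)

  # independent phase-wise adders: slope ~ 0
  d2 <- data.frame(V_birth = 1000,
                   V_G1S = 1000 + rnorm(4000, 400, 60))
  d2$V_mitosis <- d2$V_G1S + rnorm(4000, 500, 60)
  fit2 <- mechanistic_adder_test(d2, binn = 8, minn = 4)
  expect_lt(abs(fit2$slope), 0.1)

  # fixed total added volume, random split: slope -1
  cells <- simulate_dataset(stationary_params(),
                            mechanistic_mode("mechanistic_adder",
                                             mode_sd = 0),
                            n_cells = 4000, seed = 26)
  fit3 <- mechanistic_adder_test(cells, binn = 8, minn = 4)
  expect_equal(fit3$slope, -1, tolerance = 0.02)
})

test_that("sister asymmetry is corrected as the division rule dictates", {
  # symmetric divisions: all ratios exactly 1, degenerate test
  p0 <- model_params(division_asymmetry_sd = 0, stationary = TRUE)
  cells0 <- simulate_lineages(p0, mechanistic_mode("adder"),
                              n_founders = 400, n_generations = 8,
                              seed = 27, burn_in = 4)
  sa0 <- sister_asymmetry(cells0)
  expect_true(all(sa0$birth_ratio == 1))

  # adder with sigma_f = 0.1: relative difference roughly halves by mitosis
  pa <- model_params(division_asymmetry_sd = 0.1, stationary = TRUE)
  cells <- simulate_lineages(pa, mechanistic_mode("adder"),
                             n_founders = 1000, n_generations = 9,
                             seed = 28, burn_in = 4,
                             max_population = 2000)
  sa <- sister_asymmetry(cells)
  expect_gt(sa$n_pairs, 200)
  expect_lt(abs(sa$correction_factor - 0.5), 0.1)
  expect_lt(sa$p_value, 1e-6)

  # sizer: mitosis ratios near 1 whatever the birth asymmetry
  cellsz <- simulate_lineages(pa, mechanistic_mode("sizer"),
                              n_founders = 1000, n_generations = 9,
                              seed = 29, burn_in = 4,
                              max_population = 2000)
  saz <- sister_asymmetry(cellsz)
  expect_lt(mean(saz$mitosis_ratio), 1.1)
  expect_gt(mean(saz$birth_ratio), 1.2)

  expect_error(sister_asymmetry(cells0[1:5, ]), "sister pairs")
})

test_that("steadiness QC flags constructed drift and nothing else", {
  cells <- simulate_dataset(stationary_params(theta = 0.3, gamma = 0.1),
                            mechanistic_mode("linear_response"),
                            n_cells = 3000, seed = 30)
  qc <- steadiness_qc(cells, binn = 8, minn = 4)
  expect_false(qc$drift_flag)

  drifted <- cells
  span <- diff(range(drifted$t_birth))
  drifted$V_birth <- drifted$V_birth *
    (1 - 0.15 * (drifted$t_birth - min(drifted$t_birth)) / span)
  qc2 <- steadiness_qc(drifted, binn = 8, minn = 4)
  expect_true(qc2$drift_flag)

  # identical replicates: t-test cannot tell them apart
  two <- rbind(cells, cells)
  two$replicate <- rep(c("a", "b"), each = nrow(cells))
  qc3 <- steadiness_qc(two, binn = 8, minn = 4)
  expect_true(all(qc3$replicate_tests > 0.05, na.rm = TRUE))
})

test_that("the theta-gamma plane places archetypes where they belong", {
  # pure timer: the origin
  tm <- simulate_dataset(stationary_params(), mechanistic_mode("timer"),
                         n_cells = 5000, seed = 31)
  s_tm <- homeostasis_summary(tm, binn = 8, minn = 4, name = "timer")
  pl <- theta_gamma_plane(s_tm)
  expect_lt(abs(pl$x), 0.07)
  expect_lt(abs(pl$y), 0.07)

  # pure time-modulated sizer: (0, lambda ~ 1)
  sz <- simulate_dataset(stationary_params(theta = 1 / log(2), gamma = 0),
                         mechanistic_mode("linear_response"),
                         n_cells = 5000, seed = 32)
  s_sz <- homeostasis_summary(sz, binn = 8, minn = 4, name = "sizer-like")
  pl2 <- theta_gamma_plane(s_sz)
  expect_lt(abs(pl2$x), 0.1)
  expect_equal(pl2$y, 1, tolerance = 0.1)
  expect_equal(pl2$lambda, 1, tolerance = 0.1)

  # balance identity carried per row
  expect_lt(abs(pl2$balance_gap), 2 * pl2$balance_se + 0.05)

  # adder family: x + y ~ 0.5
  ad <- simulate_dataset(stationary_params(), mechanistic_mode("adder"),
                         n_cells = 5000, seed = 33)
  s_ad <- homeostasis_summary(ad, binn = 8, minn = 4, name = "adder",
                              gamma_mode = "derived")
  pl3 <- theta_gamma_plane(s_ad)
  expect_equal(pl3$x + pl3$y, 0.5, tolerance = 0.07)
})
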