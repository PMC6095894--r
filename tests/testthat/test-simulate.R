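test_that("simulation is reproducible given a seed", {
  p <- stationary_params(theta = 0.3, gamma = 0.1)
  a <- simulate_lineages(p, n_founders = 50, n_generations = 7, seed = 7)
  b <- simulate_lineages(p, n_founders = 50, n_generations = 7, seed = 7)
  expect_identical(a, b)
  c2 <- simulate_lineages(p, n_founders = 50, n_generations = 7, seed = 8)
  expect_false(identical(a$V_birth, c2$V_birth))
})

test_that("degenerate archetypes behave exactly", {
  # sizer with zero dispersion: every mitotic volume equals the target
  p <- stationary_params()
  sz <- simulate_lineages(p, mechanistic_mode("sizer", mode_sd = 0),
                          n_founders = 100, n_generations = 7, seed = 1)
  expect_true(all(sz$V_mitosis == 2 * exp(p$mean_log_birth_volume)))

  # symmetric division: each daughter gets exactly half the mitotic volume
  ps <- model_params(division_asymmetry_sd = 0, stationary = TRUE)
  cells <- simulate_lineages(ps, mechanistic_mode("adder"),
                             n_founders = 60, n_generations = 4, seed = 2,
                             burn_in = 0)
  kid <- cells[!is.na(cells$parent_id), ]
  parent_vm <- cells$V_mitosis[match(kid$parent_id, cells$cell_id)]
  ok <- !is.na(parent_vm)
  expect_true(any(ok))
  expect_equal(kid$V_birth[ok], parent_vm[ok] / 2, tolerance = 1e-12)

  # record invariants: tau = G / alpha, sisters share parent and birth time
  expect_equal(cells$tau,
               log(cells$V_mitosis / cells$V_birth) / cells$alpha,
               tolerance = 1e-9)
  sis <- match(kid$sister_id, cells$cell_id)
  ok <- !is.na(sis)
  expect_equal(kid$parent_id[ok], cells$parent_id[sis][ok])
  expect_equal(kid$t_birth[ok], cells$t_birth[sis][ok])
})

test_that("unphysical draws are discarded with a warning", {
  p <- stationary_params()
  # enormous sizer dispersion: many draws below the birth volume
  expect_warning(
    simulate_lineages(p, mechanistic_mode("sizer", mode_sd = 3000),
                      n_founders = 300, n_generations = 3, seed = 3,
                      burn_in = 0),
    "discarded")
})

test_that("timer noise accumulates birth-size variance like a random walk", {
  # with alpha fixed and symmetric division, log V_birth performs a random
  # walk with step sd <alpha> * sd_tau; oracle: var_g = var_0 + g * step^2
  p <- model_params(division_asymmetry_sd = 0, sd_alpha = 0,
                    founder_log_sd = 0.05, stationary = TRUE)
  step_sd <- p$mean_growth_rate * 2 # timer mode_sd = 2 h
  cells <- simulate_lineages(p, mechanistic_mode("timer", mode_sd = 2),
                             n_founders = 3000, n_generations = 7, seed = 4,
                             burn_in = 0, max_population = 3000)
  v <- tapply(log(cells$V_birth), cells$generation, var)
  gens <- as.integer(names(v))
  oracle <- 0.05^2 + gens * step_sd^2
  expect_true(all(diff(v) > 0)) # variance grows every generation
  expect_equal(as.numeric(v[-1]), oracle[-1], tolerance = 0.15)
})

test_that("linear response reaches a stationary size distribution", {
  p <- stationary_params(theta = 0.4, gamma = 0.1)
  cells <- simulate_lineages(p, n_founders = 800, n_generations = 31,
                             seed = 5, burn_in = 0, max_population = 800)
  s <- tapply(log(cells$V_birth), cells$generation, sd)
  expect_lt(abs(s["30"] / s["10"] - 1), 0.10)
  # mean replicative growth of the stationary population is log 2
  late <- cells[cells$generation >= 10, ]
  expect_equal(replicative_growth_mean(late), log(2), tolerance = 0.01)
})

test_that("linear-response instability is rejected up front", {
  expect_error(
    simulate_lineages(stationary_params(theta = 1.5, gamma = 1),
                      n_founders = 10, n_generations = 2, seed = 1),
    "instability")
})

test_that("phase simulation honours the G1 floor and S-G2 modes", {
  p <- model_params(founder_log_sd = 0.1, stationary = TRUE)
  ph <- phase_params(g1_mean = 4.5, g1_slope = 8, g1_min = 4, g1_sd = 0,
                     sg2_mode = "timer", sg2_mean = 10, sg2_sd = 0)
  cells <- simulate_phases(p, ph, n_cells = 2000, seed = 6)
  delta <- log(cells$V_birth) - p$mean_log_birth_volume
  big <- delta > (ph$g1_mean - ph$g1_min) / ph$g1_slope
  expect_true(any(big))
  expect_true(all(cells$tau_G1[big] == 4))
  # noiseless S-G2 timer: identical durations
  expect_true(all(cells$tau_SG2 == 10))
  expect_equal(cells$tau, cells$tau_G1 + cells$tau_SG2, tolerance = 1e-12)

  # S-G2 adder: added volume uncorrelated with size at G1/S
  ph2 <- phase_params(sg2_mode = "adder", sg2_mean = 700, sg2_sd = 100)
  cells2 <- simulate_phases(p, ph2, n_cells = 4000, seed = 7)
  d <- data.frame(V_G1S = cells2$V_G1S,
                  dV_SG2 = cells2$V_mitosis - cells2$V_G1S)
  fit <- homeostasis_regression(d, "V_G1S", "dV_SG2", binn = 8, minn = 4)
  expect_lt(abs(fit$slope), 0.05)
})
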