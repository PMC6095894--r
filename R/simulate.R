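# Lineage simulator: vectorized generation-by-generation growth/division.

# truncated normal draw for the division fraction, by rejection
rtrunc_fraction <- function(n, sd, bounds) {
  if (sd == 0) return(rep(0.5, n))
  f <- 0.5 + stats::rnorm(n, 0, sd)
  bad <- which(f <= bounds[1] | f >= bounds[2])
  while (length(bad)) {
    f[bad] <- 0.5 + stats::rnorm(length(bad), 0, sd)
    bad <- bad[f[bad] <= bounds[1] | f[bad] >= bounds[2]]
  }
  f
}

# default archetype target / dispersion given model params
mode_defaults <- function(mode, params) {
  vb <- exp(params$mean_log_birth_volume)
  switch(mode$mode,
    sizer = {
      target <- if (is.null(mode$target)) 2 * vb else mode$target
      sd <- if (is.null(mode$mode_sd)) 0.05 * target else mode$mode_sd
      list(target = target, sd = sd)
    },
    adder = ,
    mechanistic_adder = {
      target <- if (is.null(mode$target)) vb else mode$target
      cv <- if (mode$mode == "adder") 0.15 else 0.10
      sd <- if (is.null(mode$mode_sd)) cv * target else mode$mode_sd
      list(target = target, sd = sd)
    },
    timer = {
      target <- if (is.null(mode$target)) params$mean_cycle_duration else
        mode$target
      sd <- if (is.null(mode$mode_sd)) 0.10 * target else mode$mode_sd
      list(target = target, sd = sd)
    },
    list(target = NA_real_, sd = NA_real_))
}

#' Simulate lineages of growing and dividing cells
#'
#' Generates completed cell cycles generation by generation. Each cell grows
#' exponentially from its birth volume and divides into two daughters with
#' fractions `f` and `1 - f` of the mitotic volume, where `f` is a truncated
#' normal around 0.5. How the mitotic volume (or the cycle duration) is set
#' depends on the [mechanistic_mode()]: the linear-response rule modulates
#' `alpha` and `tau` with the log birth-size deviation, while the archetypes
#' implement the classic sizer / adder / timer rules and the mechanistic
#' adder (fixed total added volume split across phases).
#'
#' Cells whose draw is unphysical (non-positive growth rate, volume not
#' increasing) are discarded and counted; a warning is emitted when more than
#' 1% of cycles are discarded. The population is capped at `max_population`
#' cells per generation by uniform subsampling of daughters, so long runs stay
#' cheap while the birth-size distribution remains unbiased.
#'
#' @param params A [model_params()] object.
#' @param mode A [mechanistic_mode()] object. Default linear response.
#' @param n_founders Number of founder cells (generation 0).
#' @param n_generations Number of generations simulated (generations
#'   `0 .. n_generations - 1` each contribute one completed cycle per cell).
#' @param seed Optional integer seed for reproducibility.
#' @param max_population Cap on cells per generation. Default 5000.
#' @param burn_in Generations dropped from the returned table (transient
#'   relaxation to the stationary size distribution). Default 5.
#' @param tau_floor Duration floor in hours, guards against negative `tau`
#'   from additive noise. Default 0.1.
#'
#' @return A `data.frame` with one row per completed cycle and columns
#'   `cell_id, parent_id, sister_id, generation, t_birth, V_birth, V_G1S,
#'   V_mitosis, tau_G1, tau_SG2, tau, alpha` (volumes um^3, times h).
#'   Attribute `n_discarded` counts unphysical draws.
#' @export
#' @examples
#' cells <- simulate_lineages(model_params(stationary = TRUE),
#'                            mechanistic_mode("adder"),
#'                            n_founders = 100, n_generations = 8, seed = 1)
#' head(cells)
simulate_lineages <- function(params,
                              mode = mechanistic_mode("linear_response"),
                              n_founders = 200, n_generations = 10,
                              seed = NULL, max_population = 5000,
                              burn_in = 5, tau_floor = 0.1) {
  stopifnot(inherits(params, "model_params"), inherits(mode, "mechanistic_mode"))
  if (n_founders < 1 || n_generations < 1)
    stop("n_founders and n_generations must be >= 1")
  if (mode$mode == "linear_response" && params$lambda_implied > 1.5)
    stop("linear-response instability: (theta + gamma)<alpha><tau> = ",
         format(params$lambda_implied), " > 1.5")
  if (!is.null(seed)) set.seed(seed)

  mu <- params$mean_log_birth_volume
  md <- mode_defaults(mode, params)

  Vb <- exp(stats::rnorm(n_founders, mu, params$founder_log_sd))
  tb <- rep(0, n_founders)
  ids <- seq_len(n_founders)
  parent <- rep(NA_integer_, n_founders)
  sister <- rep(NA_integer_, n_founders)
  next_id <- n_founders + 1L

  out <- vector("list", n_generations)
  n_discarded <- 0L
  n_attempted <- 0L

  for (g in seq_len(n_generations) - 1L) {
    n <- length(Vb)
    n_attempted <- n_attempted + n
    delta <- log(Vb) - mu
    VG1S <- tauG1 <- tauSG2 <- rep(NA_real_, n)

    if (mode$mode == "linear_response") {
      alpha <- params$mean_growth_rate * (1 - params$gamma * delta) +
        stats::rnorm(n, 0, params$sd_alpha)
      tau <- pmax(tau_floor,
                  params$mean_cycle_duration * (1 - params$theta * delta) +
                    stats::rnorm(n, 0, params$sd_tau))
      Vm <- Vb * exp(alpha * tau)
      ok <- alpha > 0
    } else if (mode$mode == "sizer") {
      Vm <- stats::rnorm(n, md$target, md$sd)
      alpha <- stats::rnorm(n, params$mean_growth_rate, params$sd_alpha)
      ok <- alpha > 0 & Vm > Vb
      tau <- rep(NA_real_, n)
      tau[ok] <- log(Vm[ok] / Vb[ok]) / alpha[ok]
    } else if (mode$mode == "adder") {
      dV <- stats::rnorm(n, md$target, md$sd)
      alpha <- stats::rnorm(n, params$mean_growth_rate, params$sd_alpha)
      ok <- alpha > 0 & dV > 0
      Vm <- Vb + dV
      tau <- rep(NA_real_, n)
      tau[ok] <- log(Vm[ok] / Vb[ok]) / alpha[ok]
    } else if (mode$mode == "timer") {
      tau <- pmax(tau_floor, stats::rnorm(n, md$target, md$sd))
      alpha <- params$mean_growth_rate * (1 - params$gamma * delta) +
        stats::rnorm(n, 0, params$sd_alpha)
      ok <- alpha > 0
      Vm <- Vb * exp(alpha * tau)
    } else { # mechanistic_adder
      dV <- stats::rnorm(n, md$target, md$sd)
      u <- stats::runif(n, mode$split_range[1], mode$split_range[2])
      alpha <- stats::rnorm(n, params$mean_growth_rate, params$sd_alpha)
      ok <- alpha > 0 & dV > 0
      VG1S <- Vb + u * dV
      Vm <- Vb + dV
      tau <- tauG1 <- rep(NA_real_, n)
      tau[ok] <- log(Vm[ok] / Vb[ok]) / alpha[ok]
      tauG1[ok] <- log(VG1S[ok] / Vb[ok]) / alpha[ok]
      tauSG2 <- tau - tauG1
    }

    ok <- ok & is.finite(Vm) & Vm > 0
    n_discarded <- n_discarded + sum(!ok)
    if (!any(ok)) {
      out <- out[seq_len(g)]
      break
    }
    Vb <- Vb[ok]; tb <- tb[ok]; ids <- ids[ok]
    parent <- parent[ok]; sister <- sister[ok]
    alpha <- alpha[ok]; tau <- tau[ok]; Vm <- Vm[ok]
    VG1S <- VG1S[ok]; tauG1 <- tauG1[ok]; tauSG2 <- tauSG2[ok]
    n <- length(Vb)

    out[[g + 1L]] <- data.frame(
      cell_id = ids, parent_id = parent, sister_id = sister,
      generation = g, t_birth = tb, V_birth = Vb, V_G1S = VG1S,
      V_mitosis = Vm, tau_G1 = tauG1, tau_SG2 = tauSG2, tau = tau,
      alpha = alpha)

    if (g == n_generations - 1L) break

    f <- rtrunc_fraction(n, params$division_asymmetry_sd,
                         params$division_fraction_bounds)
    id1 <- next_id + 2L * (seq_len(n) - 1L)
    id2 <- id1 + 1L
    next_id <- next_id + 2L * n
    Vb <- c(f * Vm, (1 - f) * Vm)
    tb <- rep(tb + tau, 2L)
    parent <- rep(ids, 2L)
    sister <- c(id2, id1)
    ids <- c(id1, id2)
    if (length(Vb) > max_population) {
      keep <- sample(length(Vb), max_population)
      Vb <- Vb[keep]; tb <- tb[keep]; parent <- parent[keep]
      sister <- sister[keep]; ids <- ids[keep]
    }
  }

  cells <- do.call(rbind, out)
  if (n_discarded > 0.01 * n_attempted)
    warning(sprintf("%d of %d simulated cycles discarded as unphysical",
                    n_discarded, n_attempted))
  if (params$measurement_noise_cv > 0) {
    sdlog <- sqrt(log(1 + params$measurement_noise_cv^2))
    for (col in c("V_birth", "V_G1S", "V_mitosis"))
      cells[[col]] <- cells[[col]] *
        exp(stats::rnorm(nrow(cells), -sdlog^2 / 2, sdlog))
  }
  cells <- cells[cells$generation >= burn_in, , drop = FALSE]
  rownames(cells) <- NULL
  attr(cells, "n_discarded") <- n_discarded
  cells
}

#' Simulate independent cell cycles with G1 / S-G2 phase structure
#'
#' Draws `n_cells` independent cycles (no lineage links): birth volumes are
#' lognormal around the configured mean; G1 duration decreases linearly with
#' log birth volume down to the floor `g1_min`; growth is exponential at a
#' per-cell rate (optionally gamma-coupled to birth size); S-G2 then behaves
#' as a timer or an adder according to the [phase_params()].
#'
#' @inheritParams simulate_lineages
#' @param phases A [phase_params()] object.
#' @param n_cells Number of cycles to draw.
#' @return A `data.frame` with the same columns as [simulate_lineages()]
#'   (lineage columns are `NA`).
#' @export
simulate_phases <- function(params, phases, n_cells, seed = NULL,
                            tau_floor = 0.1) {
  stopifnot(inherits(params, "model_params"), inherits(phases, "phase_params"))
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  mu <- params$mean_log_birth_volume
  Vb <- exp(stats::rnorm(n_cells, mu, params$founder_log_sd))
  delta <- log(Vb) - mu
  alpha <- params$mean_growth_rate * (1 - params$gamma * delta) +
    stats::rnorm(n_cells, 0, params$sd_alpha)
  tauG1 <- pmax(phases$g1_min,
                phases$g1_mean - phases$g1_slope * delta +
                  stats::rnorm(n_cells, 0, phases$g1_sd))
  VG1S <- Vb * exp(alpha * tauG1)
  if (phases$sg2_mode == "timer") {
    tauSG2 <- pmax(tau_floor, stats::rnorm(n_cells, phases$sg2_mean,
                                           phases$sg2_sd))
    Vm <- VG1S * exp(alpha * tauSG2)
    ok <- alpha > 0
  } else {
    dV <- stats::rnorm(n_cells, phases$sg2_mean, phases$sg2_sd)
    ok <- alpha > 0 & dV > 0
    Vm <- VG1S + dV
    tauSG2 <- rep(NA_real_, n_cells)
    tauSG2[ok] <- log(Vm[ok] / VG1S[ok]) / alpha[ok]
  }
  n_discarded <- sum(!ok)
  if (n_discarded > 0.01 * n_cells)
    warning(sprintf("%d of %d simulated cycles discarded as unphysical",
                    n_discarded, n_cells))
  cells <- data.frame(
    cell_id = seq_len(n_cells), parent_id = NA_integer_,
    sister_id = NA_integer_, generation = 0L, t_birth = 0,
    V_birth = Vb, V_G1S = VG1S, V_mitosis = Vm,
    tau_G1 = tauG1, tau_SG2 = tauSG2, tau = tauG1 + tauSG2,
    alpha = alpha)[ok, , drop = FALSE]
  if (params$measurement_noise_cv > 0) {
    sdlog <- sqrt(log(1 + params$measurement_noise_cv^2))
    for (col in c("V_birth", "V_G1S", "V_mitosis"))
      cells[[col]] <- cells[[col]] *
        exp(stats::rnorm(nrow(cells), -sdlog^2 / 2, sdlog))
  }
  rownames(cells) <- NULL
  attr(cells, "n_discarded") <- n_discarded
  cells
}

#' Simulate a fixed-size analysis dataset
#'
#' Convenience wrapper around [simulate_lineages()] that sizes founders,
#' generations and the population cap so that at least `n_cells` post-burn-in
#' cycles are produced, then returns exactly the first `n_cells` of them.
#'
#' @inheritParams simulate_lineages
#' @param n_cells Number of completed cycles wanted after burn-in.
#' @param analysis_generations Number of post-burn-in generations pooled.
#' @return A lineage `data.frame` with `n_cells` rows.
#' @export
simulate_dataset <- function(params, mode, n_cells = 5000, seed = NULL,
                             burn_in = 5, analysis_generations = 5) {
  per_gen <- ceiling(n_cells / analysis_generations)
  cells <- simulate_lineages(params, mode,
                             n_founders = per_gen,
                             n_generations = burn_in + analysis_generations,
                             seed = seed, max_population = per_gen,
                             burn_in = burn_in)
  if (nrow(cells) < n_cells)
    stop("simulation produced only ", nrow(cells), " cycles, wanted ", n_cells)
  cells[seq_len(n_cells), , drop = FALSE]
}
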