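#' Simulator parameters for a growing, dividing cell population
#'
#' Bundles the parameters of the linear-response model of cell-size
#' homeostasis: cells grow exponentially at a per-cell rate `alpha` for a
#' per-cell duration `tau`, and both may be modulated (to linear order) by the
#' deviation `delta = log(V_birth) - mean_log_birth_volume` of the log birth
#' volume from its configured mean:
#' \deqn{\alpha = \langle\alpha\rangle (1 - \gamma \delta) + \epsilon_\alpha,
#'       \quad
#'       \tau = \langle\tau\rangle (1 - \theta \delta) + \epsilon_\tau.}
#' `theta` is the strength of size control through cell-cycle-duration
#' modulation, `gamma` the strength through growth-rate modulation; the
#' effective homeostatic exponent is
#' `lambda = (theta + gamma) * mean_growth_rate * mean_cycle_duration`.
#'
#' @param mean_log_birth_volume Mean of the natural-log birth volume
#'   (volume in um^3). Default 7.3 (~1480 um^3), typical of cultured
#'   epithelial lines.
#' @param mean_cycle_duration Mean cell-cycle duration `<tau>` in hours.
#' @param mean_growth_rate Mean exponential growth rate `<alpha>` in 1/h.
#'   The default `log(2)/mean_cycle_duration` makes the population double on
#'   average (stationary size distribution).
#' @param theta,gamma Dimensionless modulation strengths (per unit
#'   log-volume). Positive values contribute to size control.
#' @param sd_tau Additive s.d. of cycle duration, hours.
#' @param sd_alpha Additive s.d. of growth rate, 1/h.
#' @param division_asymmetry_sd S.d. of the division fraction `f` around 0.5
#'   (truncated to `division_fraction_bounds`); dimensionless, must be < 0.3.
#' @param measurement_noise_cv Multiplicative lognormal CV applied to the
#'   exported volume readings (the underlying dynamics stay exact). Default 0.
#' @param founder_log_sd S.d. of founder log birth volumes. Default 0.15, a
#'   typical birth-size CV for cycling cell populations.
#' @param division_fraction_bounds Truncation bounds for the division
#'   fraction. Default `c(0.2, 0.8)`.
#' @param stationary If `TRUE`, require `<alpha><tau> = log(2)` to machine
#'   precision so the population is size-stationary on average.
#'
#' @return An object of class `"model_params"`.
#' @seealso [simulate_lineages()], [simulate_phases()], [mechanistic_mode()]
#' @export
#' @examples
#' p <- model_params(theta = 0.4, gamma = 0.3, stationary = TRUE)
#' p$lambda_implied # (theta + gamma) * <alpha> * <tau>
model_params <- function(mean_log_birth_volume = 7.3,
                         mean_cycle_duration = 20,
                         mean_growth_rate = log(2) / mean_cycle_duration,
                         theta = 0,
                         gamma = 0,
                         sd_tau = 1.5,
                         sd_alpha = 0.003,
                         division_asymmetry_sd = 0.05,
                         measurement_noise_cv = 0,
                         founder_log_sd = 0.15,
                         division_fraction_bounds = c(0.2, 0.8),
                         stationary = FALSE) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
    x
  }
  mean_log_birth_volume <- num1(mean_log_birth_volume, "mean_log_birth_volume")
  mean_cycle_duration <- num1(mean_cycle_duration, "mean_cycle_duration")
  if (mean_cycle_duration <= 0) stop("mean_cycle_duration must be > 0")
  mean_growth_rate <- num1(mean_growth_rate, "mean_growth_rate")
  theta <- num1(theta, "theta"); gamma <- num1(gamma, "gamma")
  sd_tau <- num1(sd_tau, "sd_tau"); sd_alpha <- num1(sd_alpha, "sd_alpha")
  division_asymmetry_sd <- num1(division_asymmetry_sd, "division_asymmetry_sd")
  measurement_noise_cv <- num1(measurement_noise_cv, "measurement_noise_cv")
  founder_log_sd <- num1(founder_log_sd, "founder_log_sd")

  if (mean_growth_rate <= 0) stop("mean_growth_rate must be > 0")
  if (mean_cycle_duration <= 0) stop("mean_cycle_duration must be > 0")
  if (sd_tau < 0 || sd_alpha < 0 || measurement_noise_cv < 0 ||
      founder_log_sd < 0)
    stop("standard deviations and noise CVs must be >= 0")
  if (division_asymmetry_sd < 0 || division_asymmetry_sd >= 0.3)
    stop("division_asymmetry_sd must be in [0, 0.3)")
  if (!is.numeric(division_fraction_bounds) ||
      length(division_fraction_bounds) != 2L ||
      division_fraction_bounds[1] <= 0 || division_fraction_bounds[2] >= 1 ||
      diff(division_fraction_bounds) <= 0)
    stop("division_fraction_bounds must be increasing and inside (0, 1)")
  if (isTRUE(stationary) &&
      abs(mean_growth_rate * mean_cycle_duration - log(2)) >= 1e-9)
    stop("stationary = TRUE requires <alpha><tau> = log(2); got ",
         format(mean_growth_rate * mean_cycle_duration))

  structure(
    list(mean_log_birth_volume = mean_log_birth_volume,
         mean_growth_rate = mean_growth_rate,
         mean_cycle_duration = mean_cycle_duration,
         theta = theta, gamma = gamma,
         sd_tau = sd_tau, sd_alpha = sd_alpha,
         division_asymmetry_sd = division_asymmetry_sd,
         measurement_noise_cv = measurement_noise_cv,
         founder_log_sd = founder_log_sd,
         division_fraction_bounds = division_fraction_bounds,
         stationary = isTRUE(stationary),
         lambda_implied = (theta + gamma) * mean_growth_rate *
           mean_cycle_duration),
    class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Cell-cycle model parameters\n")
  cat(sprintf("  <log V_birth> = %.3f  (V ~ %.0f um^3, founder log-sd %.2f)\n",
              x$mean_log_birth_volume, exp(x$mean_log_birth_volume),
              x$founder_log_sd))
  cat(sprintf("  <alpha> = %.4f /h   <tau> = %.2f h   <alpha><tau> = %.4f\n",
              x$mean_growth_rate, x$mean_cycle_duration,
              x$mean_growth_rate * x$mean_cycle_duration))
  cat(sprintf("  theta = %.3f   gamma = %.3f   lambda implied = %.3f\n",
              x$theta, x$gamma, x$lambda_implied))
  cat(sprintf("  sd_tau = %.2f h   sd_alpha = %.4f /h   asymmetry sd = %.3f\n",
              x$sd_tau, x$sd_alpha, x$division_asymmetry_sd))
  invisible(x)
}

#' Division-rule archetype for the lineage simulator
#'
#' Selects how the size at mitotic entry (or the cycle duration) is set:
#' `"linear_response"` uses the theta/gamma couplings of [model_params()];
#' `"sizer"` draws the mitotic volume around a fixed target; `"adder"` adds a
#' size-independent volume increment; `"timer"` draws the cycle duration
#' independently of size; `"mechanistic_adder"` draws a total added volume per
#' cell and splits it between G1 and S-G2 by an independent uniform fraction.
#'
#' @param mode One of `"linear_response"`, `"sizer"`, `"adder"`, `"timer"`,
#'   `"mechanistic_adder"`.
#' @param mode_sd Dispersion of the archetype quantity, in its own units
#'   (um^3 for sizer target / added volume, hours for the timer duration).
#'   `NULL` picks a default CV relative to the target (5% sizer, 15% adder,
#'   10% timer/mechanistic adder); 0 gives the deterministic archetype.
#' @param target Archetype target: mitotic volume (sizer), mean added volume
#'   (adder, mechanistic adder) or mean duration (timer). `NULL` derives a
#'   stationary-consistent default from the model parameters (sizer: twice
#'   the mean birth volume; adder: the mean birth volume; timer: `<tau>`).
#' @param split_range For `"mechanistic_adder"`: range of the uniform G1
#'   share of the total added volume. Default `c(0.3, 0.7)`.
#'
#' @return An object of class `"mechanistic_mode"`.
#' @export
#' @examples
#' mechanistic_mode("adder", mode_sd = 150)
mechanistic_mode <- function(mode = c("linear_response", "sizer", "adder",
                                      "timer", "mechanistic_adder"),
                             mode_sd = NULL, target = NULL,
                             split_range = c(0.3, 0.7)) {
  mode <- match.arg(mode)
  if (!is.null(mode_sd)) {
    if (!is.numeric(mode_sd) || length(mode_sd) != 1L || !is.finite(mode_sd) ||
        mode_sd < 0)
      stop("mode_sd must be a single finite number >= 0")
  }
  if (!is.null(target)) {
    if (!is.numeric(target) || length(target) != 1L || !is.finite(target) ||
        target <= 0)
      stop("target must be a single finite number > 0")
  }
  if (!is.numeric(split_range) || length(split_range) != 2L ||
      split_range[1] < 0 || split_range[2] > 1 || diff(split_range) < 0)
    stop("split_range must be an increasing pair inside [0, 1]")
  structure(list(mode = mode, mode_sd = mode_sd, target = target,
                 split_range = split_range),
            class = "mechanistic_mode")
}

#' Cell-cycle phase structure parameters
#'
#' Parameters of the two-phase (G1 then S-G2) cycle used by
#' [simulate_phases()]. G1 duration shortens linearly with log birth volume
#' down to a hard floor `g1_min` (large cells spend only a minimal time,
#' about 4 h, in G1); S-G2 behaves either as a timer (duration independent of
#' size) or as an adder (size-independent added volume).
#'
#' @param g1_mean Mean G1 duration at the reference birth size, hours.
#' @param g1_slope Decrease of G1 duration per unit log birth volume, h.
#' @param g1_min Minimum G1 duration, hours. Default 4.
#' @param g1_sd Additive s.d. of G1 duration, hours.
#' @param sg2_mode `"timer"` or `"adder"`.
#' @param sg2_mean Mean S-G2 duration (h, timer) or mean added volume
#'   (um^3, adder).
#' @param sg2_sd S.d. of the S-G2 quantity, same units as `sg2_mean`.
#'
#' @return An object of class `"phase_params"`.
#' @export
phase_params <- function(g1_mean = 7, g1_slope = 4, g1_min = 4, g1_sd = 1,
                         sg2_mode = c("timer", "adder"),
                         sg2_mean = 10, sg2_sd = 1.5) {
  sg2_mode <- match.arg(sg2_mode)
  if (g1_min < 0) stop("g1_min must be >= 0")
  if (g1_mean < g1_min) stop("g1_mean must be >= g1_min")
  if (g1_sd < 0 || sg2_sd < 0) stop("standard deviations must be >= 0")
  if (sg2_mean <= 0) stop("sg2_mean must be > 0")
  structure(list(g1_mean = g1_mean, g1_slope = g1_slope, g1_min = g1_min,
                 g1_sd = g1_sd, sg2_mode = sg2_mode, sg2_mean = sg2_mean,
                 sg2_sd = sg2_sd),
            class = "phase_params")
}
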