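# Homeostasis estimators: lambda (effective size control) and its
# decomposition into timing (theta) and growth-rate (gamma) modulation,
# linked by the balance relation lambda = (theta + gamma) <alpha><tau>.

#' Mean replicative growth
#'
#' The replicative growth of a cycle is `G = log(V_mitosis / V_birth)`; under
#' exponential growth `G = alpha * tau`, so the population mean `<G>`
#' approximates `<alpha><tau>` and equals `log(2)` for a size-stationary
#' population.
#'
#' @param cells A `data.frame` with positive `V_birth`, `V_mitosis`.
#' @return `mean(log(V_mitosis / V_birth))`.
#' @export
replicative_growth_mean <- function(cells) {
  stopifnot(all(c("V_birth", "V_mitosis") %in% names(cells)))
  if (any(cells$V_birth <= 0 | cells$V_mitosis <= 0, na.rm = TRUE))
    stop("volumes must be > 0")
  mean(log(cells$V_mitosis / cells$V_birth), na.rm = TRUE)
}

#' Estimate the homeostatic exponent lambda
#'
#' Count-weighted binned regression of replicative growth
#' `G = log(V_mitosis / V_birth)` on `log(V_birth)`; lambda is minus the
#' slope. lambda = 1 behaves like a sizer, 0.5 like an adder, and 0 means no
#' size control (cells double on average regardless of birth size).
#'
#' @param cells Cell-cycle records (filters already applied), n >= 30.
#' @param ... Bin policy arguments passed to [homeostasis_regression()].
#' @return A list with `lambda`, `se`, and the underlying `fit`.
#' @export
#' @examples
#' cells <- simulate_dataset(model_params(stationary = TRUE),
#'                           mechanistic_mode("adder"), n_cells = 2000,
#'                           seed = 1)
#' estimate_lambda(cells)$lambda # ~ 0.5
estimate_lambda <- function(cells, ...) {
  if (nrow(cells) < 30) stop("need at least 30 cycles")
  d <- data.frame(log_V_birth = log(cells$V_birth),
                  G = log(cells$V_mitosis / cells$V_birth))
  fit <- homeostasis_regression(d, "log_V_birth", "G", ...)
  list(lambda = -fit$slope, se = fit$se_slope, fit = fit)
}

#' Estimate the timing-modulation strength theta
#'
#' Regression of cycle duration `tau` on `log(V_birth)`: the slope equals
#' `-<tau> * theta`, so `theta = -slope / mean(tau)`. Positive theta means
#' larger-born cells cycle faster, contributing to size control. The standard
#' error combines the slope SE and the SE of `mean(tau)` by first-order
#' (delta-method) propagation.
#'
#' @inheritParams estimate_lambda
#' @return A list with `theta`, `se`, `mean_tau`, and the underlying `fit`.
#' @export
estimate_theta <- function(cells, ...) {
  stopifnot(all(c("V_birth", "tau") %in% names(cells)))
  d <- data.frame(log_V_birth = log(cells$V_birth), tau = cells$tau)
  d <- d[is.finite(d$tau) & is.finite(d$log_V_birth), ]
  fit <- homeostasis_regression(d, "log_V_birth", "tau", ...)
  mt <- mean(d$tau)
  se_mt <- stats::sd(d$tau) / sqrt(nrow(d))
  theta <- -fit$slope / mt
  se <- sqrt((fit$se_slope / mt)^2 + (fit$slope * se_mt / mt^2)^2)
  list(theta = theta, se = se, mean_tau = mt, fit = fit)
}

#' Estimate the growth-rate-modulation strength gamma (direct)
#'
#' Regression of the per-cell growth rate `alpha` on `log(V_birth)`: the
#' slope equals `-<alpha> * gamma`, so `gamma = -slope / mean(alpha)`.
#' Positive gamma means larger-born cells grow slower. When no `alpha` column
#' is present it is derived as `G / tau` and the result carries
#' `alpha_derived = TRUE`.
#'
#' @inheritParams estimate_lambda
#' @return A list with `gamma`, `se`, `mean_alpha`, `alpha_derived`, `fit`.
#' @export
estimate_gamma_direct <- function(cells, ...) {
  derived <- FALSE
  alpha <- cells$alpha
  if (is.null(alpha) || all(!is.finite(alpha))) {
    alpha <- log(cells$V_mitosis / cells$V_birth) / cells$tau
    derived <- TRUE
  }
  d <- data.frame(log_V_birth = log(cells$V_birth), alpha = alpha)
  d <- d[is.finite(d$alpha) & is.finite(d$log_V_birth), ]
  fit <- homeostasis_regression(d, "log_V_birth", "alpha", ...)
  ma <- mean(d$alpha)
  se_ma <- stats::sd(d$alpha) / sqrt(nrow(d))
  gamma <- -fit$slope / ma
  se <- sqrt((fit$se_slope / ma)^2 + (fit$slope * se_ma / ma^2)^2)
  list(gamma = gamma, se = se, mean_alpha = ma, alpha_derived = derived,
       fit = fit)
}

#' Derive gamma from lambda, theta and the mean replicative growth
#'
#' Uses the balance relation `lambda = (theta + gamma) <alpha><tau>` with
#' `<alpha><tau>` approximated by `<G>`: `gamma = lambda / <G> - theta`.
#' This is the route for datasets without single-cell growth rates.
#'
#' @param lambda,theta Estimates.
#' @param mean_G Mean replicative growth, > 0.
#' @param se_lambda,se_theta,se_G Standard errors (default 0) combined by
#'   first-order propagation.
#' @return A list with `gamma` and `se`.
#' @export
#' @examples
#' estimate_gamma_derived(0.5, 0, log(2))$gamma # ~ 0.7213
estimate_gamma_derived <- function(lambda, theta, mean_G,
                                   se_lambda = 0, se_theta = 0, se_G = 0) {
  if (!is.finite(mean_G) || mean_G <= 0) stop("mean_G must be > 0")
  gamma <- lambda / mean_G - theta
  se <- sqrt((se_lambda / mean_G)^2 + se_theta^2 +
               (lambda * se_G / mean_G^2)^2)
  list(gamma = gamma, se = se)
}

#' One-stop homeostasis summary for a dataset
#'
#' Computes lambda, theta, gamma (directly from per-cell growth rates when
#' available, otherwise derived through the balance relation), `<G>`, `<tau>`
#' and `<alpha>`, plus the normalized coordinates `theta * norm` and
#' `gamma * norm` used on the theta-gamma plane, with `norm = <alpha><tau>`
#' when growth rates are available and `<G>` otherwise.
#'
#' @inheritParams estimate_lambda
#' @param gamma_mode `"auto"` (direct when `alpha` present), `"direct"` or
#'   `"derived"`.
#' @param name Optional dataset label.
#' @return An object of class `"homeostasis_summary"` (also a one-row
#'   `data.frame` via [as.data.frame()]).
#' @export
homeostasis_summary <- function(cells, gamma_mode = c("auto", "direct",
                                                      "derived"),
                                name = NA_character_, ...) {
  gamma_mode <- match.arg(gamma_mode)
  la <- estimate_lambda(cells, ...)
  th <- if ("tau" %in% names(cells) && any(is.finite(cells$tau)))
    estimate_theta(cells, ...) else NULL
  mG <- replicative_growth_mean(cells)
  se_G <- stats::sd(log(cells$V_mitosis / cells$V_birth)) / sqrt(nrow(cells))
  have_alpha <- "alpha" %in% names(cells) && any(is.finite(cells$alpha))
  if (gamma_mode == "auto") gamma_mode <- if (have_alpha) "direct" else
    "derived"
  if (gamma_mode == "direct") {
    ga <- estimate_gamma_direct(cells, ...)
    gamma <- ga$gamma; se_gamma <- ga$se
  } else {
    if (is.null(th)) stop("derived gamma needs tau (for theta)")
    ga <- estimate_gamma_derived(la$lambda, th$theta, mG,
                                 se_lambda = la$se, se_theta = th$se,
                                 se_G = se_G)
    gamma <- ga$gamma; se_gamma <- ga$se
  }
  mean_tau <- if (!is.null(th)) th$mean_tau else NA_real_
  mean_alpha <- if (have_alpha) mean(cells$alpha, na.rm = TRUE) else NA_real_
  norm <- if (is.finite(mean_alpha) && is.finite(mean_tau))
    mean_alpha * mean_tau else mG
  theta <- if (!is.null(th)) th$theta else NA_real_
  se_theta <- if (!is.null(th)) th$se else NA_real_
  structure(list(name = name, n = nrow(cells),
                 lambda = la$lambda, se_lambda = la$se,
                 theta = theta, se_theta = se_theta,
                 gamma = gamma, se_gamma = se_gamma,
                 gamma_mode = gamma_mode,
                 mean_G = mG, se_G = se_G,
                 mean_tau = mean_tau, mean_alpha = mean_alpha,
                 norm = norm,
                 norm_theta = theta * norm, norm_gamma = gamma * norm),
            class = "homeostasis_summary")
}

#' @export
print.homeostasis_summary <- function(x, ...) {
  cat(sprintf("Homeostasis summary%s (n = %d)\n",
              if (is.na(x$name)) "" else paste0(" [", x$name, "]"), x$n))
  cat(sprintf("  lambda = %.3f +/- %.3f\n", x$lambda, x$se_lambda))
  cat(sprintf("  theta  = %.3f +/- %.3f   gamma = %.3f +/- %.3f (%s)\n",
              x$theta, x$se_theta, x$gamma, x$se_gamma, x$gamma_mode))
  cat(sprintf("  <G> = %.4f   theta*norm = %.3f   gamma*norm = %.3f\n",
              x$mean_G, x$norm_theta, x$norm_gamma))
  invisible(x)
}

#' @export
as.data.frame.homeostasis_summary <- function(x, ...) {
  data.frame(name = x$name, n = x$n, lambda = x$lambda,
             se_lambda = x$se_lambda, theta = x$theta, se_theta = x$se_theta,
             gamma = x$gamma, se_gamma = x$se_gamma,
             gamma_mode = x$gamma_mode, mean_G = x$mean_G,
             mean_tau = x$mean_tau, mean_alpha = x$mean_alpha,
             norm = x$norm, norm_theta = x$norm_theta,
             norm_gamma = x$norm_gamma, stringsAsFactors = FALSE)
}

#' Test the mechanistic-adder hypothesis
#'
#' If a fixed total volume added from birth to mitosis is the rate-limiting
#' quantity, the volume added in S-G2 must compensate the volume added in G1:
#' `dV_SG2 = <dV_TOT> - dV_G1`, i.e. a slope of -1 in the count-weighted
#' binned regression of `dV_SG2` on `dV_G1`. Independent phase-wise adders
#' give slope 0 instead.
#'
#' @param cells Records with `V_birth`, `V_G1S`, `V_mitosis`.
#' @param ... Bin policy arguments for [homeostasis_regression()].
#' @return A [weighted_binned_fit()] result with an extra field
#'   `distance_to_minus1 = |slope + 1|`.
#' @export
mechanistic_adder_test <- function(cells, ...) {
  stopifnot(all(c("V_birth", "V_G1S", "V_mitosis") %in% names(cells)))
  d <- data.frame(dV_G1 = cells$V_G1S - cells$V_birth,
                  dV_SG2 = cells$V_mitosis - cells$V_G1S)
  d <- d[is.finite(d$dV_G1) & is.finite(d$dV_SG2), ]
  fit <- homeostasis_regression(d, "dV_G1", "dV_SG2", ...)
  fit$distance_to_minus1 <- abs(fit$slope + 1)
  fit
}

#' Sister-cell volume asymmetry at birth and at the next mitosis
#'
#' For each complete sister pair the asymmetry is summarised as the
#' larger/smaller volume ratio (>= 1) and the relative difference
#' `|V1 - V2| / (V1 + V2)`, at birth and at the next mitotic entry. A
#' one-sided paired Wilcoxon signed-rank test asks whether the ratio at
#' mitosis is lower than at birth, i.e. whether the asymmetry created at
#' division is (partially) corrected within one cycle -- an adder halves the
#' relative difference, a sizer erases it.
#'
#' @param cells Lineage records with `cell_id`, `sister_id`, `V_birth`,
#'   `V_mitosis`.
#' @return A list with the per-pair `birth_ratio` and `mitosis_ratio`
#'   vectors, mean relative differences `rel_diff_birth` /
#'   `rel_diff_mitosis`, their ratio `correction_factor`
#'   (mitosis / birth), the Wilcoxon `p_value`, and counts `n_pairs`,
#'   `n_incomplete`.
#' @export
sister_asymmetry <- function(cells) {
  stopifnot(all(c("cell_id", "sister_id", "V_birth", "V_mitosis")
                %in% names(cells)))
  idx <- match(cells$sister_id, cells$cell_id)
  has_sister <- !is.na(idx)
  first <- which(has_sister & cells$cell_id < cells$sister_id)
  n_incomplete <- sum(!is.na(cells$sister_id) & !has_sister)
  if (length(first) < 10)
    stop("need at least 10 complete sister pairs, found ", length(first))
  v1b <- cells$V_birth[first];   v2b <- cells$V_birth[idx[first]]
  v1m <- cells$V_mitosis[first]; v2m <- cells$V_mitosis[idx[first]]
  birth_ratio <- pmax(v1b, v2b) / pmin(v1b, v2b)
  mitosis_ratio <- pmax(v1m, v2m) / pmin(v1m, v2m)
  rel_b <- abs(v1b - v2b) / (v1b + v2b)
  rel_m <- abs(v1m - v2m) / (v1m + v2m)
  p <- tryCatch(
    stats::wilcox.test(mitosis_ratio, birth_ratio, paired = TRUE,
                       alternative = "less", exact = FALSE)$p.value,
    error = function(e) NA_real_)
  list(birth_ratio = birth_ratio, mitosis_ratio = mitosis_ratio,
       rel_diff_birth = mean(rel_b), rel_diff_mitosis = mean(rel_m),
       correction_factor = mean(rel_m) / mean(rel_b),
       p_value = p, n_pairs = length(first), n_incomplete = n_incomplete)
}

#' Steadiness quality control
#'
#' Checks that the culture is in a steady state over the recording: the
#' binned, count-weighted regression of `V_birth` on `t_birth` quantifies the
#' drift of the birth-size distribution (flagged when the relative drift over
#' the recorded span exceeds `drift_tol`), and, when a `replicate` column is
#' present, pairwise t-tests compare mean growth rates across replicates.
#'
#' @param cells Records with `t_birth`, `V_birth`; optional `replicate` and
#'   `alpha` columns.
#' @param drift_tol Relative drift threshold. Default 0.1.
#' @param ... Bin policy arguments.
#' @return A list with `drift` (relative drift over the span), `drift_flag`,
#'   the underlying `fit`, and `replicate_tests` (pairwise t-test p-values or
#'   `NULL`).
#' @export
steadiness_qc <- function(cells, drift_tol = 0.1, ...) {
  stopifnot(all(c("t_birth", "V_birth") %in% names(cells)))
  fit <- homeostasis_regression(cells, "t_birth", "V_birth", ...)
  span <- diff(range(cells$t_birth, finite = TRUE))
  drift <- fit$slope * span / mean(cells$V_birth, na.rm = TRUE)
  tests <- NULL
  if ("replicate" %in% names(cells) &&
      length(unique(cells$replicate)) >= 2 &&
      "alpha" %in% names(cells)) {
    tests <- stats::pairwise.t.test(cells$alpha, cells$replicate,
                                    p.adjust.method = "none")$p.value
  }
  list(drift = drift, drift_flag = abs(drift) > drift_tol, fit = fit,
       replicate_tests = tests)
}

#' Normalized theta-gamma plane coordinates
#'
#' Places each dataset on the plane of normalized growth-rate modulation
#' (`x = gamma * norm`) versus normalized timing modulation
#' (`y = theta * norm`), where `norm = <alpha><tau>` when growth rates are
#' available and `<G>` otherwise. By the balance relation `x + y = lambda`,
#' so archetypes sit on straight lines: the adder family on `x + y = 0.5`,
#' sizers on `x + y = 1`, timers at the origin.
#'
#' @param summaries A list of [homeostasis_summary()] objects (or a single
#'   one).
#' @return A `data.frame` with one row per dataset: `name`, `x`
#'   (gamma-normalized), `y` (theta-normalized), `lambda`, `balance_gap`
#'   (`x + y - lambda`) and `balance_se` (combined SE of the gap).
#' @export
theta_gamma_plane <- function(summaries) {
  if (inherits(summaries, "homeostasis_summary")) summaries <-
      list(summaries)
  rows <- lapply(summaries, function(s) {
    stopifnot(inherits(s, "homeostasis_summary"))
    x <- s$norm_gamma; y <- s$norm_theta
    gap <- x + y - s$lambda
    se <- sqrt((s$se_gamma * s$norm)^2 + (s$se_theta * s$norm)^2 +
                 s$se_lambda^2)
    data.frame(name = s$name, x = x, y = y, lambda = s$lambda,
               balance_gap = gap, balance_se = se, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
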