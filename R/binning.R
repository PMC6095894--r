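# Count-weighted binned regression: the statistical workhorse behind every
# size-homeostasis plot (median bins along x, line fit weighted by bin counts).

#' Bin-policy lookup by dataset size
#'
#' Returns the number of equal-width bins (`binn`) and the minimum events per
#' retained bin (`minn`) used for the homeostasis regressions. Microbe
#' datasets follow the published size-dependent table; animal-cell datasets
#' (typically 80-300 cycles) use 8 bins (6 below 150 cycles) with at least 4
#' events per bin.
#'
#' @param n Number of observations in the dataset.
#' @param organism_class `"animal"` or `"microbe"`.
#' @return A list with `binn` and `minn`.
#' @export
#' @examples
#' select_bin_params(2000, "microbe") # binn 13, minn 60
select_bin_params <- function(n, organism_class = c("animal", "microbe")) {
  organism_class <- match.arg(organism_class)
  if (n < 1) stop("n must be >= 1")
  if (organism_class == "microbe") {
    if (n < 100)        list(binn = 8L,  minn = 8L)
    else if (n < 1000)  list(binn = 10L, minn = 15L)
    else if (n < 5000)  list(binn = 13L, minn = 60L)
    else                list(binn = 15L, minn = 150L)
  } else {
    list(binn = if (n >= 150) 8L else 6L, minn = 4L)
  }
}

#' Bin paired observations along x
#'
#' Splits the x range into `binn` equal-width intervals (rightmost edge
#' inclusive), keeps bins holding at least `minn` events, and summarises each
#' retained bin by the chosen statistic of x and y, the event count, and the
#' s.d. of y.
#'
#' @param x,y Numeric vectors of equal length.
#' @param binn Number of equal-width bins.
#' @param minn Minimum events per retained bin.
#' @param statistic `"median"` (default) or `"mean"`.
#' @return A `data.frame` of class `"size_bins"` with columns `x_stat`,
#'   `y_stat`, `count`, `y_sd`. Fails when fewer than 2 bins survive.
#' @export
#' @examples
#' b <- make_bins(1:10, (1:10)^2, binn = 2, minn = 1)
#' b$x_stat # medians 3 and 8
make_bins <- function(x, y, binn, minn, statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  if (length(x) != length(y)) stop("x and y lengths differ")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < binn) stop("fewer observations (", length(x),
                             ") than bins (", binn, ")")
  rng <- range(x)
  if (rng[1] == rng[2])
    stop("all x values identical: a single bin cannot support a regression")
  edges <- seq(rng[1], rng[2], length.out = binn + 1)
  bin <- findInterval(x, edges, rightmost.closed = TRUE)
  fstat <- if (statistic == "median") stats::median else mean
  parts <- split(seq_along(x), bin)
  bins <- do.call(rbind, lapply(parts, function(i) {
    data.frame(x_stat = fstat(x[i]), y_stat = fstat(y[i]),
               count = length(i), y_sd = stats::sd(y[i]))
  }))
  bins <- bins[bins$count >= minn, , drop = FALSE]
  if (nrow(bins) < 2)
    stop("fewer than 2 bins retained (binn = ", binn, ", minn = ", minn,
         "): regression impossible")
  rownames(bins) <- NULL
  class(bins) <- c("size_bins", "data.frame")
  attr(bins, "statistic") <- statistic
  bins
}

#' Weighted linear fit on bins
#'
#' Least-squares line through the bin statistics, weighted by the event count
#' of each bin. The slope standard error and two-sided p-value use a t
#' distribution with `#bins - 2` degrees of freedom; R-squared is the
#' weighted coefficient of determination on the bins. With exactly 2 bins the
#' line is exact and the standard error is reported missing.
#'
#' @param bins A `"size_bins"` table (from [make_bins()]), or any data.frame
#'   with columns `x_stat`, `y_stat`, `count`.
#' @return An object of class `"binned_fit"`: list with `slope`, `intercept`,
#'   `se_slope`, `p_slope`, `r2`, `n_bins`, `n_cells`, `bins`.
#' @export
weighted_binned_fit <- function(bins) {
  stopifnot(all(c("x_stat", "y_stat", "count") %in% names(bins)))
  if (nrow(bins) < 2) stop("need at least 2 bins")
  if (length(unique(bins$x_stat)) < 2) stop("bins must span distinct x")
  fit <- stats::lm(y_stat ~ x_stat, data = bins, weights = count)
  cf <- stats::coef(fit)
  nb <- nrow(bins)
  if (nb > 2) {
    # exact lines (deterministic constructions) are legitimate here
    sm <- suppressWarnings(summary(fit))
    se <- sm$coefficients["x_stat", "Std. Error"]
    p <- sm$coefficients["x_stat", "Pr(>|t|)"]
    r2 <- sm$r.squared
  } else {
    se <- NA_real_; p <- NA_real_; r2 <- 1
  }
  structure(list(slope = unname(cf["x_stat"]),
                 intercept = unname(cf["(Intercept)"]),
                 se_slope = se, p_slope = p, r2 = r2,
                 n_bins = nb, n_cells = sum(bins$count),
                 bins = bins),
            class = "binned_fit")
}

#' @export
print.binned_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Weighted binned fit (%d bins, %d events)\n", x$n_bins,
              x$n_cells))
  cat(sprintf("  slope = %s +/- %s   p = %s   R2 = %s   intercept = %s\n",
              format(x$slope, digits = digits),
              format(x$se_slope, digits = digits),
              format(x$p_slope, digits = 3),
              format(x$r2, digits = 3),
              format(x$intercept, digits = digits)))
  invisible(x)
}

#' Generic binned-regression driver for homeostasis plots
#'
#' The one pattern behind every size-control panel: optionally log-transform
#' x, bin along x with the dataset-size policy, and fit a count-weighted
#' line. Used for e.g. added volume vs birth volume, mitotic vs birth volume,
#' phase duration vs log volume, or replicative growth vs log birth volume.
#'
#' @param data A `data.frame` of cell-cycle records (filters already applied).
#' @param x,y Column names.
#' @param log_x Log-transform x (natural log) before binning.
#' @param binn,minn Bin policy; `NULL` (default) picks by [select_bin_params()].
#' @param organism_class Passed to [select_bin_params()].
#' @param statistic Bin statistic. Default `"median"`.
#' @return A [weighted_binned_fit()] result.
#' @export
#' @examples
#' cells <- simulate_dataset(model_params(stationary = TRUE),
#'                           mechanistic_mode("adder"), n_cells = 1000,
#'                           seed = 1)
#' homeostasis_regression(cells, "V_birth", "V_mitosis") # slope ~ 1
homeostasis_regression <- function(data, x, y, log_x = FALSE,
                                   binn = NULL, minn = NULL,
                                   organism_class = "animal",
                                   statistic = "median") {
  missing_cols <- setdiff(c(x, y), names(data))
  if (length(missing_cols))
    stop("columns not found: ", paste(missing_cols, collapse = ", "))
  xv <- data[[x]]
  if (log_x) {
    if (any(xv <= 0, na.rm = TRUE)) stop("log_x requires positive ", x)
    xv <- log(xv)
  }
  yv <- data[[y]]
  n <- sum(is.finite(xv) & is.finite(yv))
  if (is.null(binn) || is.null(minn)) {
    bp <- select_bin_params(n, organism_class)
    if (is.null(binn)) binn <- bp$binn
    if (is.null(minn)) minn <- bp$minn
  }
  weighted_binned_fit(make_bins(xv, yv, binn, minn, statistic))
}
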