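# Outlier filters applied before the homeostasis regressions.

filter_report <- function(rule, n_in, removed_ids) {
  structure(list(rule = rule, n_in = n_in, n_removed = length(removed_ids),
                 removed_ids = removed_ids),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Filter '%s': removed %d of %d rows\n",
              x$rule, x$n_removed, x$n_in))
  invisible(x)
}

#' Remove rows outside mean +/- 3 s.d.
#'
#' Single-pass filter used for animal-cell datasets: a row is removed when
#' any of the listed columns lies outside the column mean plus or minus three
#' standard deviations, both moments computed on the input table. Columns with
#' zero variance trigger no removals.
#'
#' @param data A `data.frame`.
#' @param columns Character vector of numeric column names to screen.
#' @param k Multiplier. Default 3.
#' @return A list with `data` (the filtered table) and `report`
#'   (a filter report with rule, counts and removed row ids).
#' @export
#' @examples
#' d <- data.frame(cell_id = 1:101, V = c(rnorm(100), 10))
#' filter_3sd(d, "V")$report
filter_3sd <- function(data, columns, k = 3) {
  stopifnot(is.data.frame(data))
  if (nrow(data) < 10) stop("need at least 10 rows")
  missing_cols <- setdiff(columns, names(data))
  if (length(missing_cols))
    stop("columns not found: ", paste(missing_cols, collapse = ", "))
  bad <- rep(FALSE, nrow(data))
  for (col in columns) {
    x <- data[[col]]
    if (!is.numeric(x)) stop("column '", col, "' is not numeric")
    m <- mean(x, na.rm = TRUE)
    s <- stats::sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) next
    bad <- bad | (!is.na(x) & abs(x - m) > k * s)
  }
  ids <- if ("cell_id" %in% names(data)) data$cell_id[bad] else which(bad)
  list(data = data[!bad, , drop = FALSE],
       report = filter_report("three_sd", nrow(data), ids))
}

#' Remove rows outside median +/- 1.5 IQR of log volumes
#'
#' Filter used for microbe datasets: a row is removed when `log(V_birth)`
#' falls outside the band `median +/- 1.5 * IQR` of `log(V_birth)`, or
#' likewise for `log(V_mitosis)` (band centred on the median, as opposed to
#' quartile-based fences). A zero IQR keeps only exact-median values and
#' emits a warning.
#'
#' @param data A `data.frame` with positive `V_birth` and `V_mitosis`.
#' @param k IQR multiplier. Default 1.5.
#' @return A list with `data` and `report`, as [filter_3sd()].
#' @export
filter_iqr <- function(data, k = 1.5) {
  stopifnot(is.data.frame(data),
            all(c("V_birth", "V_mitosis") %in% names(data)))
  if (any(data$V_birth <= 0) || any(data$V_mitosis <= 0))
    stop("V_birth and V_mitosis must be > 0")
  bad <- rep(FALSE, nrow(data))
  for (col in c("V_birth", "V_mitosis")) {
    x <- log(data[[col]])
    med <- stats::median(x)
    iqr <- stats::IQR(x)
    if (iqr == 0)
      warning("zero IQR in log(", col, "): only exact-median values retained")
    bad <- bad | x < med - k * iqr | x > med + k * iqr
  }
  ids <- if ("cell_id" %in% names(data)) data$cell_id[bad] else which(bad)
  list(data = data[!bad, , drop = FALSE],
       report = filter_report("iqr", nrow(data), ids))
}
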