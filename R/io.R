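# Readers/writers for lineage tables and trajectories, a minimal TOML config
# reader, and the end-to-end pipeline driver.

lineage_columns <- c("cell_id", "parent_id", "sister_id", "generation",
                     "t_birth", "V_birth", "V_G1S", "V_mitosis",
                     "tau_G1", "tau_SG2", "tau", "alpha")

fmt6 <- function(x) {
  if (is.numeric(x)) {
    out <- ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
    out
  } else as.character(x)
}

#' Write a lineage table as CSV
#'
#' Writes the canonical column set (`cell_id, parent_id, sister_id,
#' generation, t_birth, V_birth, V_G1S, V_mitosis, tau_G1, tau_SG2, tau,
#' alpha`) with numeric values at 6 significant digits.
#'
#' @param cells Lineage `data.frame`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_lineage_table <- function(cells, path) {
  missing_cols <- setdiff(lineage_columns, names(cells))
  for (col in missing_cols) cells[[col]] <- NA_real_
  out <- cells[, lineage_columns]
  for (col in lineage_columns) {
    if (col %in% c("cell_id", "parent_id", "sister_id", "generation")) next
    out[[col]] <- fmt6(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read and validate a lineage table
#'
#' Reads a delimited text file of per-cycle records, optionally renaming user
#' columns to the canonical schema through `column_map` (a named character
#' vector `c(canonical = "file_column")`). Rows violating the record
#' invariants (non-positive `V_birth` / `V_mitosis`, non-positive `tau`) are
#' dropped and counted in the `n_dropped` attribute.
#'
#' @param path Input path.
#' @param column_map Optional named character vector mapping canonical names
#'   to the file's column names. A mapped column absent from the file is a
#'   hard error naming it.
#' @param sep Field delimiter. Default `","`.
#' @param dec Decimal mark. Default `"."` (use `","` for decimal-comma
#'   dialects).
#' @return A lineage `data.frame` with attribute `n_dropped`.
#' @export
read_lineage_table <- function(path, column_map = NULL, sep = ",",
                               dec = ".") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, dec = dec,
                           stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    missing_cols <- setdiff(unname(column_map), names(raw))
    if (length(missing_cols))
      stop("mapped columns missing from file: ",
           paste(missing_cols, collapse = ", "))
    for (i in seq_along(column_map))
      names(raw)[names(raw) == column_map[i]] <- names(column_map)[i]
  }
  for (col in setdiff(lineage_columns, names(raw))) raw[[col]] <- NA_real_
  cells <- raw[, lineage_columns]
  for (col in c("t_birth", "V_birth", "V_G1S", "V_mitosis", "tau_G1",
                "tau_SG2", "tau", "alpha"))
    cells[[col]] <- as.numeric(cells[[col]])
  bad <- (!is.na(cells$V_birth) & cells$V_birth <= 0) |
    (!is.na(cells$V_mitosis) & cells$V_mitosis <= 0) |
    (!is.na(cells$tau) & cells$tau <= 0)
  cells <- cells[!bad, , drop = FALSE]
  rownames(cells) <- NULL
  attr(cells, "n_dropped") <- sum(bad)
  cells
}

#' Write / read trajectories in long format
#'
#' Long CSV with columns `cell_id, frame, t_min, volume_um3, reporter`
#' (reporter may be empty). Only retained frames are written.
#'
#' @param trajs A list of [trajectory()] objects (or a single one).
#' @param path File path.
#' @return `write_trajectories` returns the path invisibly;
#'   `read_trajectories` returns a list of trajectories.
#' @export
write_trajectories <- function(trajs, path) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  rows <- lapply(trajs, function(tr) {
    idx <- which(tr$retained)
    data.frame(cell_id = tr$cell_id, frame = idx,
               t_min = fmt6(tr$t[idx]),
               volume_um3 = fmt6(tr$volume[idx]),
               reporter = if (is.null(tr$reporter)) "" else
                 fmt6(tr$reporter[idx]))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "frame", "t_min", "volume_um3")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop("trajectory file lacks columns: ",
         paste(missing_cols, collapse = ", "))
  has_rep <- "reporter" %in% names(d) && !all(is.na(d$reporter) |
                                                d$reporter == "")
  lapply(split(d, d$cell_id), function(dd) {
    dd <- dd[order(dd$t_min), ]
    trajectory(cell_id = dd$cell_id[1], t = as.numeric(dd$t_min),
               volume = as.numeric(dd$volume_um3),
               reporter = if (has_rep) as.numeric(dd$reporter) else NULL)
  })
}

# ---- minimal TOML subset reader: [sections], key = value, arrays, strings,
# numbers, booleans. Enough for pipeline configs; nested tables via dotted
# section headers.

parse_toml_value <- function(s) {
  s <- trimws(s)
  if (grepl("^\\[.*\\]$", s)) {
    inner <- substr(s, 2, nchar(s) - 1)
    if (trimws(inner) == "") return(list())
    parts <- strsplit(inner, ",")[[1]]
    return(unlist(lapply(parts, parse_toml_value), use.names = FALSE))
  }
  if (grepl('^".*"$', s)) return(gsub('^"|"$', "", s))
  if (s %in% c("true", "false")) return(s == "true")
  num <- suppressWarnings(as.numeric(s))
  if (!is.na(num)) return(num)
  stop("cannot parse TOML value: ", s)
}

#' Read a (subset of) TOML configuration file
#'
#' Supports `[section]` and dotted `[a.b]` headers, `key = value` pairs with
#' strings, numbers, booleans and flat arrays, and `#` comments. This covers
#' pipeline configs; it is not a general TOML parser.
#'
#' @param path File path.
#' @return A nested named list.
#' @export
read_toml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  section <- character()
  for (ln in lines) {
    ln <- sub('#(?=([^"]*"[^"]*")*[^"]*$).*', "", ln, perl = TRUE)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[[^]]+\\]$", ln)) {
      section <- strsplit(gsub("^\\[|\\]$", "", ln), ".", fixed = TRUE)[[1]]
      next
    }
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("malformed TOML line: ", ln)
    key <- trimws(substr(ln, 1, eq - 1))
    val <- parse_toml_value(substr(ln, eq + 1, nchar(ln)))
    keys <- c(section, key)
    out <- modify_nested(out, keys, val)
  }
  out
}

modify_nested <- function(lst, keys, value) {
  if (length(keys) == 1) {
    lst[[keys]] <- value
    return(lst)
  }
  head_key <- keys[1]
  if (is.null(lst[[head_key]])) lst[[head_key]] <- list()
  lst[[head_key]] <- modify_nested(lst[[head_key]], keys[-1], value)
  lst
}

#' Read and validate a pipeline configuration
#'
#' A config must carry a `seed` and a `[datasets.<name>]` table per dataset.
#' Each dataset is either `type = "simulate"` (with `mode`, `n_cells`, and
#' optional `theta`, `gamma`, `measurement_noise_cv`) or `type = "file"`
#' (with `path`, optional `delimiter`, `decimal`, and a
#' `[datasets.<name>.columns]` mapping). Unknown dataset keys are rejected.
#'
#' @param path TOML file path.
#' @return The validated config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- read_toml(path)
  if (is.null(cfg$seed)) stop("config must set a seed")
  cfg$seed <- as.integer(cfg$seed)
  if (is.null(cfg$datasets) || !length(cfg$datasets))
    stop("config defines no [datasets.*]")
  known <- c("type", "mode", "n_cells", "theta", "gamma", "path",
             "delimiter", "decimal", "columns", "organism_class", "filter",
             "binn", "minn", "measurement_noise_cv", "mode_sd", "target")
  for (nm in names(cfg$datasets)) {
    ds <- cfg$datasets[[nm]]
    extra <- setdiff(names(ds), known)
    if (length(extra))
      stop("unknown keys in dataset '", nm, "': ",
           paste(extra, collapse = ", "))
    if (is.null(ds$type) || !ds$type %in% c("simulate", "file"))
      stop("dataset '", nm, "' needs type = \"simulate\" or \"file\"")
    if (ds$type == "file" && is.null(ds$path))
      stop("dataset '", nm, "' of type file needs a path")
  }
  cfg
}

# per-dataset RNG sub-stream keyed by the dataset name, independent of
# dataset order; kept below 2^31
dataset_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131)
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

run_one_dataset <- function(name, ds, cfg, out_dir) {
  sd_i <- dataset_seed(cfg$seed, name)
  if (ds$type == "simulate") {
    params <- model_params(
      theta = if (is.null(ds$theta)) 0 else ds$theta,
      gamma = if (is.null(ds$gamma)) 0 else ds$gamma,
      measurement_noise_cv = if (is.null(ds$measurement_noise_cv)) 0 else
        ds$measurement_noise_cv,
      stationary = TRUE)
    mode <- mechanistic_mode(
      if (is.null(ds$mode)) "linear_response" else ds$mode,
      mode_sd = ds$mode_sd, target = ds$target)
    n_cells <- if (is.null(ds$n_cells)) 5000 else ds$n_cells
    cells <- simulate_dataset(params, mode, n_cells = n_cells, seed = sd_i)
  } else {
    cmap <- if (!is.null(ds$columns)) unlist(ds$columns) else NULL
    cells <- read_lineage_table(
      ds$path, column_map = cmap,
      sep = if (is.null(ds$delimiter)) "," else ds$delimiter,
      dec = if (is.null(ds$decimal)) "." else ds$decimal)
  }
  rule <- if (is.null(ds$filter)) "3sd" else ds$filter
  flt <- if (rule == "iqr") filter_iqr(cells) else
    filter_3sd(cells, c("V_birth", "V_mitosis"))
  oc <- if (is.null(ds$organism_class)) "animal" else ds$organism_class
  summ <- homeostasis_summary(flt$data, name = name, organism_class = oc,
                              binn = ds$binn, minn = ds$minn)
  lam_fit <- estimate_lambda(flt$data, organism_class = oc,
                             binn = ds$binn, minn = ds$minn)$fit
  fit_row <- data.frame(dataset = name, analysis = "lambda",
                        slope = lam_fit$slope, intercept = lam_fit$intercept,
                        se = lam_fit$se_slope, p = lam_fit$p_slope,
                        r2 = lam_fit$r2, n_bins = lam_fit$n_bins)
  utils::write.table(
    data.frame(lapply(fit_row, fmt6)),
    file.path(out_dir, paste0(name, "_lambda_fit.tsv")),
    sep = "\t", row.names = FALSE, quote = FALSE)
  bins <- lam_fit$bins
  utils::write.table(
    data.frame(lapply(bins, fmt6)),
    file.path(out_dir, paste0(name, "_lambda_bins.tsv")),
    sep = "\t", row.names = FALSE, quote = FALSE)
  list(summary = summ, filter = flt$report, seed = sd_i)
}

#' Run the full analysis pipeline from a configuration
#'
#' For each configured dataset: simulate or read a lineage table, apply the
#' configured outlier filter, estimate the homeostasis summary
#' (lambda/theta/gamma), and write a summary TSV + JSON plus per-analysis
#' fit/bin TSVs into the output directory. Failures are recorded per dataset
#' and the remaining datasets continue. Deterministic given config + seed
#' (per-dataset sub-streams are keyed by dataset name, so dataset order does
#' not matter); numeric outputs carry 6 significant digits.
#'
#' @param config A config list from [read_pipeline_config()], or a path to a
#'   TOML file.
#' @param out_dir Output directory; created if missing. Defaults to the
#'   config's `output_dir` or `"."`.
#' @return An invisible run report: list with `summaries` (data.frame),
#'   `filters`, `failures`, `seed`, `version`, `timestamp`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (is.null(out_dir))
    out_dir <- if (!is.null(config$output_dir)) config$output_dir else "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summaries <- list()
  filters <- list()
  failures <- list()
  for (nm in names(config$datasets)) {
    res <- tryCatch(
      run_one_dataset(nm, config$datasets[[nm]], config, out_dir),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[nm]] <- conditionMessage(res)
      message("dataset '", nm, "' failed: ", conditionMessage(res))
    } else {
      summaries[[nm]] <- as.data.frame(res$summary)
      summaries[[nm]]$filter_rule <- res$filter$rule
      summaries[[nm]]$n_removed <- res$filter$n_removed
      filters[[nm]] <- res$filter
    }
  }
  summary_df <- if (length(summaries)) do.call(rbind, summaries) else
    data.frame()
  rownames(summary_df) <- NULL
  if (nrow(summary_df)) {
    out <- summary_df
    for (col in names(out)) out[[col]] <- fmt6(out[[col]])
    utils::write.table(out, file.path(out_dir, "summary.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    jsonlite::write_json(summary_df, file.path(out_dir, "summary.json"),
                         dataframe = "rows", digits = NA, auto_unbox = TRUE)
  }
  report <- list(summaries = summary_df, filters = filters,
                 failures = failures, seed = config$seed,
                 version = as.character(utils::packageVersion("sizecontrol")),
                 timestamp = format(Sys.time(), tz = "UTC"))
  class(report) <- "run_report"
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Pipeline run (seed %d, %d dataset(s), %d failure(s))\n",
              x$seed, nrow(x$summaries) + length(x$failures),
              length(x$failures)))
  if (nrow(x$summaries))
    print(x$summaries[, c("name", "n", "lambda", "theta", "gamma",
                          "gamma_mode")])
  for (nm in names(x$failures)) cat("  FAILED ", nm, ": ", x$failures[[nm]],
                                    "\n", sep = "")
  invisible(x)
}
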