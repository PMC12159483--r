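#' Read a storage-series CSV
#'
#' Long-format schema: columns `index_name, temperature_C, day, value,
#' units, direction` (comma-separated, `.` decimal, UTF-8), one row per
#' (index, temperature, day).  Rows are grouped into one
#' [storage_series()] per (index, temperature) pair.
#'
#' @param path Path to the CSV file.
#' @return Named list of `storage_series` objects, keyed
#'   `"<index>@<temperature>"`.
#' @export
read_storage_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (!nrow(df)) stop("empty storage file: ", path, call. = FALSE)
  if (!is.null(df$units)) df$units <- as.character(df$units)
  required <- c("index_name", "temperature_C", "day", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("storage file lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in c("temperature_C", "day", "value")) {
    if (!is.numeric(df[[col]]))
      stop("non-numeric values in column '", col, "'", call. = FALSE)
  }
  key <- paste(df$index_name, df$temperature_C, df$day, sep = "|")
  if (anyDuplicated(key)) {
    rows <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop("duplicate (index, temperature, day) rows: ",
         paste(rows + 1L, collapse = ", "), " (including header line)",
         call. = FALSE)
  }
  if (is.null(df$units)) df$units <- ""
  df$units[is.na(df$units)] <- ""
  groups <- split(df, paste0(df$index_name, "@", df$temperature_C))
  out <- lapply(groups, function(g) {
    g <- g[order(g$day), , drop = FALSE]
    storage_series(g$index_name[1L], g$temperature_C[1L], g$day, g$value,
                   units = g$units[1L],
                   direction = if ("direction" %in% names(g))
                     g$direction[1L] else NULL)
  })
  out[order(names(out))]
}

#' Write storage series back to the long CSV schema
#'
#' Inverse of [read_storage_csv()]; a read/write round trip is lossless.
#'
#' @param series_list Named or unnamed list of [storage_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_storage_csv <- function(series_list, path) {
  rows <- lapply(series_list, function(s)
    data.frame(index_name = s$index_name, temperature_C = s$temperature,
               day = s$days, value = s$values, units = s$units,
               direction = s$direction, stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  df <- df[order(df$index_name, df$temperature_C, df$day), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read desirability goals from a YAML config
#'
#' Expected structure:
#' ```yaml
#' goals:
#'   - {response: juice, kind: maximize, low: 5, high: 9.5,
#'      weight: 1, importance: 3}
#' ```
#'
#' @param path Path to the YAML file.
#' @return List of [desirability_goal()] objects.
#' @export
read_goals_yaml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$goals) || !length(cfg$goals))
    stop("no 'goals' entry in ", path, call. = FALSE)
  lapply(cfg$goals, function(g)
    desirability_goal(response = g$response, kind = g$kind, low = g$low,
                      high = g$high, target = g$target,
                      weight = if (is.null(g$weight)) 1 else g$weight,
                      importance = if (is.null(g$importance)) 1L
                                   else g$importance))
}

## fixed column formats for report files: rates 4 dp, R^2 3 dp, times 2 dp
.report_formats <- list(
  k = 4L, k0 = 4L, k1 = 4L, k2 = 4L, k_selected = 4L, k_ref = 4L,
  r2 = 3L, r2_0 = 3L, r2_1 = 3L, r2_2 = 3L, arrhenius_r2 = 3L,
  eyring_r2 = 3L, ball_r2 = 3L,
  t_half = 2L, D_ref = 2L, Z = 2L, shelf_life_days = 2L)

.format_report <- function(df) {
  for (nm in names(df)) {
    if (nm %in% names(.report_formats)) {
      df[[nm]] <- formatC(df[[nm]], format = "f",
                          digits = .report_formats[[nm]])
    } else if (is.numeric(df[[nm]])) {
      df[[nm]] <- formatC(df[[nm]], format = "g", digits = 6L)
    }
    df[[nm]][df[[nm]] %in% c("NA", " NA", "NaN")] <- ""
  }
  df
}

#' Write an analysis report with deterministic formatting
#'
#' Writes a data frame (e.g. a [stability_report()]) as CSV or aligned
#' plain text with fixed rounding — rate constants to 4 decimals,
#' R-squared to 3, half-lives and D-values to 2 — and deterministic row
#' order, so identical inputs produce byte-identical files.  A
#' `stability_report`'s per-index temperature-model table is appended to
#' the text rendering and written alongside the CSV as
#' `<path>_temperature_models.csv`.
#'
#' @param results A data frame of results.
#' @param path Output path.
#' @param format `"csv"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("csv", "text")) {
  format <- match.arg(format)
  if (!is.data.frame(results))
    stop("'results' must be a data frame", call. = FALSE)
  if (!nrow(results))
    warning("writing a header-only report (no result rows)", call. = FALSE)
  main <- .format_report(as.data.frame(results))
  tm <- attr(results, "temperature_models")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path: ", dir, call. = FALSE)
  if (format == "csv") {
    utils::write.csv(main, path, row.names = FALSE, quote = FALSE)
    if (!is.null(tm)) {
      tm_path <- sub("(\\.csv)?$", "_temperature_models.csv", path)
      utils::write.csv(.format_report(tm), tm_path, row.names = FALSE,
                       quote = FALSE)
    }
  } else {
    lines <- utils::capture.output(print(main, row.names = FALSE))
    if (!is.null(tm)) {
      lines <- c(lines, "", "Temperature models:",
                 utils::capture.output(print(.format_report(tm),
                                             row.names = FALSE)))
    }
    writeLines(lines, path)
  }
  invisible(path)
}
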