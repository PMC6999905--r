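#' Read N-of-1 series from CSV
#'
#' Long format: columns `time` (1-based consecutive integers), `series`
#' (`"A"`, `"B"` or `"diff"`), `value` (numeric). Wide format (with
#' `wide = TRUE`): one column per series plus an optional `time` column.
#' Times must be gap-free within each series — the tests assume equal
#' spacing with no missing observations, so gaps are an error rather than
#' silently tolerated.
#'
#' @param path path to a CSV file.
#' @param wide the file has one column per series instead of long format.
#' @return A list of class `"nof1_series"`: either `diff` (numeric vector)
#'   for pre-differenced input, or `a` and `b`. A/B input with matching
#'   times also carries `diff = a - b` for paired analyses.
#' @export
read_series_csv <- function(path, wide = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (wide) {
    cols <- setdiff(names(df), "time")
    if ("time" %in% names(df)) check_times(df$time, "time")
    out <- lapply(df[cols], check_numeric_col, path = path)
    names(out) <- tolower(names(out))
  } else {
    need <- c("time", "series", "value")
    if (!all(need %in% names(df)))
      stop("long-format CSV needs columns time, series, value", call. = FALSE)
    out <- lapply(split(df, tolower(df$series)), function(g) {
      g <- g[order(g$time), ]
      check_times(g$time, g$series[1])
      check_numeric_col(g$value, path)
    })
  }
  if (!is.null(out$a) && !is.null(out$b) && length(out$a) == length(out$b))
    out$diff <- out$a - out$b
  structure(out, class = "nof1_series")
}

check_times <- function(times, label) {
  times <- suppressWarnings(as.integer(times))
  if (anyNA(times) || !identical(times, seq_len(length(times))))
    stop("unequally spaced or missing observations not supported ",
         "(series '", label, "': times must be 1..m with no gaps or duplicates)",
         call. = FALSE)
  invisible(times)
}

check_numeric_col <- function(v, path) {
  vn <- suppressWarnings(as.numeric(v))
  if (anyNA(vn)) {
    bad <- which(is.na(vn))[1]
    stop("non-numeric value in ", path, " at row ", bad, call. = FALSE)
  }
  vn
}

#' Write an N-of-1 series to CSV (long format)
#'
#' @param series a named list of numeric vectors (e.g. `list(A = ..., B = ...)`)
#'   or a single numeric vector (written with series label `"diff"`).
#' @param path output path.
#' @export
write_series_csv <- function(series, path) {
  if (is.numeric(series)) series <- list(diff = series)
  df <- do.call(rbind, lapply(names(series), function(nm)
    data.frame(time = seq_along(series[[nm]]), series = nm,
               value = series[[nm]])))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged worked-example data
#'
#' Two published N-of-1 data sets used throughout the documentation and
#' tests, with the reference values printed alongside them in their sources.
#'
#' * Six fibromyalgia patients from a series of amitriptyline-vs-placebo
#'   randomized multiple-crossover trials: each entry is the series of
#'   within-pair "active minus placebo" questionnaire differences (positive
#'   favors amitriptyline), with the published mean, SD, Fuller serial r and
#'   one-sided p-values (usual and serial paired level-change tests).
#' * One opioid-dependence patient's delay-discounting indifference points
#'   (percent of a delayed $1,000) measured at eight increasing delays,
#'   before and after a 12-week treatment — a bi-phase pre/post design —
#'   with the published OLS s and Fuller r under the level- and rate-change
#'   models and the four reported serial t statistics.
#'
#' @param name optional fixture name (`"patient_9"`, `"patient_18"`,
#'   `"patient_23"`, `"patient_17"`, `"patient_15"`, `"patient_12"`,
#'   `"patient_1390"`); `NULL` returns all as a named list.
#' @return A fixture (list with `differences` or `pre`/`post` series and a
#'   `reference` list of printed values), or a named list of all fixtures.
#' @export
nof1_fixtures <- function(name = NULL) {
  fib <- function(diffs, mean, sd, r, p_usual, p_serial)
    list(design = "paired_level", differences = diffs,
         reference = list(mean = mean, sd = sd, serial_r = r,
                          p_usual = p_usual, p_serial = p_serial))
  fx <- list(
    patient_9  = fib(c(0.05, -0.22, 0.57, 0.36), 0.19, 0.35, 0.24, 0.18, 0.25),
    patient_18 = fib(c(0.64, 1.08, -0.36, 0.79, -0.64, 1.50), 0.50, 0.83,
                     -0.49, 0.10, 0.02),
    patient_23 = fib(c(1.22, 1.07, -0.08, 0.50), 0.68, 0.59, 0.38, 0.05, 0.17),
    patient_17 = fib(c(-0.08, 0.86, 1.07, 1.15), 0.75, 0.57, 0.41, 0.04, 0.15),
    patient_15 = fib(c(0.86, 1.43, 0.65, 1.86), 1.20, 0.55, -0.42, 0.01, 0.01),
    patient_12 = fib(c(4.29, 3.15, 0.78, 4.49), 3.18, 1.70, -0.07, 0.02, 0.01),
    patient_1390 = list(
      design = "two_sample",
      pre  = c(92, 76, 68, 58, 50, 38, 18, 2),
      post = c(98, 92, 90, 84, 72, 56, 2, 2),
      difference = c(-6, -16, -22, -26, -22, -18, 16, 0),  # pre - post
      reference = list(
        level = list(s_two_sample = 34.9, r_two_sample = 0.69,
                     s_paired = 14.2, r_paired = 0.50,
                     t_two_sample = -0.27, df_two_sample = 2.29,
                     t_paired = -1.32, df_paired = 2.22),
        rate = list(s_two_sample = 12.4, r_two_sample = 0.46,
                    s_paired = 13.7, r_paired = 0.32,
                    t_two_sample = -0.61, df_two_sample = 3.98,
                    t_paired = 0.91, df_paired = 2.94))))
  if (is.null(name)) return(fx)
  if (!name %in% names(fx))
    stop("unknown fixture '", name, "'; see ?nof1_fixtures", call. = FALSE)
  fx[[name]]
}

#' Render a result as text, JSON or CSV
#'
#' Deterministic rendering of test, planning and simulation results. JSON
#' carries all numeric fields at full precision; text rounds for reading.
#'
#' @param x a `"serial_ttest"`, `"nof1_planning"` or `"sim_summary"` object,
#'   or a planning matrix from [planning_table()].
#' @param format `"text"`, `"json"` or `"csv"`.
#' @return A character string (invisibly for `"text"`, which also prints).
#' @export
nof1_report <- function(x, format = c("text", "json", "csv")) {
  format <- match.arg(format)
  if (format == "text") {
    txt <- paste(utils::capture.output(print(x)), collapse = "\n")
    cat(txt, "\n")
    return(invisible(txt))
  }
  flat <- report_fields(x)
  if (format == "json")
    return(as.character(jsonlite::toJSON(flat, auto_unbox = TRUE, digits = NA,
                                         null = "null")))
  if (is.matrix(x)) {
    con <- textConnection("csvout", "w", local = TRUE)
    utils::write.csv(cbind(rho = rownames(x), as.data.frame(x)), con,
                     row.names = FALSE, quote = FALSE)
    close(con)
    return(paste(csvout, collapse = "\n"))
  }
  scalars <- flat[vapply(flat, function(v)
    is.atomic(v) && length(v) == 1L, logical(1))]
  paste(paste(names(scalars), collapse = ","),
        paste(vapply(scalars, format_csv_value, character(1)), collapse = ","),
        sep = "\n")
}

format_csv_value <- function(v) {
  if (is.numeric(v)) format(v, digits = 15) else as.character(v)
}

report_fields <- function(x) {
  if (is.matrix(x)) {
    return(list(rows = rownames(x), cols = colnames(x),
                values = unname(apply(x, 1, as.numeric, simplify = FALSE))))
  }
  out <- unclass(x)
  out$kernels <- lapply(out$kernels, unclass)
  out$r_details <- if (!is.null(out$r_details)) {
    if (inherits(out$r_details, "serial_r")) unclass(out$r_details)
    else lapply(out$r_details, unclass)
  }
  out$config <- if (!is.null(out$config)) unclass(out$config)
  out[!vapply(out, is.null, logical(1))]
}

#' @export
print.nof1_series <- function(x, ...) {
  for (nm in names(x))
    cat(sprintf("%s (m = %d): %s\n", nm, length(x[[nm]]),
                paste(format(x[[nm]]), collapse = ", ")))
  invisible(x)
}
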