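#' Fermentation time-series tables
#'
#' A `ferm_timeseries` is a data frame holding a replicated multi-variable
#' fermentation time course in summary form: a `time_h` column (sampling
#' time in hours, strictly increasing) plus, for each measured variable, a
#' triplet of columns `<var>_mean`, `<var>_sd`, `<var>_n` (per-time mean,
#' standard deviation and replicate count). Recognised variables are
#' `ph`, `tta_pct` (titratable acidity, % lactic acid), `glucose_pct`,
#' `lab_log10cfu` (lactic acid bacteria) and `tvc_log10cfu` (total viable
#' count); other variable names are accepted and carried through.
#'
#' @param data data frame in the wide layout described above.
#' @param batch_label free-text label for the batch.
#' @return A validated `ferm_timeseries` object.
#' @examples
#' ts <- ferm_fixture("slurry_timecourse")
#' ts_variables(ts)
#' ts_means(ts, "ph")
#' @export
ferm_timeseries <- function(data, batch_label = "") {
  data <- as.data.frame(data)
  obj <- structure(data,
                   batch_label = as.character(batch_label),
                   class = c("ferm_timeseries", "data.frame"))
  validate_ferm_timeseries(obj)
}

validate_ferm_timeseries <- function(x) {
  if (!"time_h" %in% names(x))
    stop("time series must contain a 'time_h' column", call. = FALSE)
  t <- x$time_h
  if (anyNA(t) || !is.numeric(t))
    stop("non-numeric or missing sampling time", call. = FALSE)
  dup <- which(duplicated(t))
  if (length(dup))
    stop(sprintf("duplicate time point at row %d (t = %g h)", dup[1], t[dup[1]]),
         call. = FALSE)
  if (is.unsorted(t)) {
    x <- x[order(t), , drop = FALSE]
    rownames(x) <- NULL
  }
  for (v in ts_variables(x)) {
    m <- x[[paste0(v, "_mean")]]
    s <- x[[paste0(v, "_sd")]]
    n <- x[[paste0(v, "_n")]]
    if (is.null(s) || is.null(n))
      stop(sprintf("variable '%s' lacks its _sd or _n column", v), call. = FALSE)
    if (any(!is.na(s) & s < 0))
      stop(sprintf("negative standard deviation for '%s'", v), call. = FALSE)
    if (any(!is.na(n) & n < 1))
      stop(sprintf("replicate count below 1 for '%s'", v), call. = FALSE)
    if (v %in% c("tta_pct", "glucose_pct") && any(!is.na(m) & m < 0))
      stop(sprintf("'%s' must be non-negative", v), call. = FALSE)
  }
  x
}

#' @describeIn ferm_timeseries names of the variables present in the table.
#' @param x a `ferm_timeseries`.
#' @export
ts_variables <- function(x) {
  nm <- grep("_mean$", names(x), value = TRUE)
  sub("_mean$", "", nm)
}

#' @describeIn ferm_timeseries per-time means of one variable.
#' @param variable variable name, e.g. `"ph"`.
#' @export
ts_means <- function(x, variable) ts_col(x, variable, "mean")

#' @describeIn ferm_timeseries per-time standard deviations of one variable.
#' @export
ts_sds <- function(x, variable) ts_col(x, variable, "sd")

#' @describeIn ferm_timeseries per-time replicate counts of one variable.
#' @export
ts_ns <- function(x, variable) ts_col(x, variable, "n")

ts_col <- function(x, variable, what) {
  col <- paste0(variable, "_", what)
  if (!col %in% names(x))
    stop(sprintf("variable '%s' not present in time series", variable),
         call. = FALSE)
  x[[col]]
}

#' @export
print.ferm_timeseries <- function(x, ...) {
  lab <- attr(x, "batch_label")
  cat("Fermentation time series",
      if (nzchar(lab)) paste0(" [", lab, "]"), "\n", sep = "")
  cat(sprintf("  %d time points over %g-%g h; variables: %s\n",
              nrow(x), min(x$time_h), max(x$time_h),
              paste(ts_variables(x), collapse = ", ")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Read or write a fermentation time-series CSV
#'
#' The CSV dialect is comma-separated, "." decimal, UTF-8, one header row.
#' The header must name `time_h` and `<var>_mean`/`<var>_sd` pairs; a
#' missing `<var>_n` column defaults to 3 replicates (triplicate readings
#' being the usual bench practice).
#'
#' @param path file path.
#' @param batch_label free-text label attached to the result.
#' @return `read_timeseries_csv()` returns a validated [ferm_timeseries];
#'   `write_timeseries_csv()` invisibly returns `path`.
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' write_timeseries_csv(ferm_fixture("slurry_timecourse"), tmp)
#' ts <- read_timeseries_csv(tmp)
#' @export
read_timeseries_csv <- function(path, batch_label = "") {
  df <- read_ferm_csv(path)
  if (!"time_h" %in% names(df))
    stop(sprintf("'%s': header must name a 'time_h' column", path),
         call. = FALSE)
  df <- default_n_columns(df, exclude = "time_h")
  ferm_timeseries(df, batch_label = batch_label)
}

#' @rdname read_timeseries_csv
#' @param x a [ferm_timeseries].
#' @export
write_timeseries_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

read_ferm_csv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  names(df) <- tolower(names(df))
  num <- setdiff(names(df), c("batch_label"))
  for (cn in num) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      if (anyNA(conv) && !all(is.na(v)))
        stop(sprintf("'%s': non-numeric value in column '%s' (row %d)",
                     path, cn, which(is.na(conv))[1]), call. = FALSE)
      df[[cn]] <- conv
    }
  }
  df
}

# add <var>_n = 3 where a mean/sd pair has no replicate-count column
default_n_columns <- function(df, exclude) {
  vars <- sub("_mean$", "", grep("_mean$", names(df), value = TRUE))
  for (v in setdiff(vars, exclude)) {
    ncol_ <- paste0(v, "_n")
    if (!ncol_ %in% names(df)) df[[ncol_]] <- 3L
  }
  df
}
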