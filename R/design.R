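#' Factorial starter-culture design tables
#'
#' A `ferm_design` is a data frame holding the response summary of a
#' three-factor inoculum experiment: columns `x1`, `x2`, `x3` give the
#' inoculum concentration (% w/w) of each starter culture, and each
#' response contributes `<resp>_mean`, `<resp>_sd`, `<resp>_n` columns.
#' The usual responses are `ph`, `tta_pct` and `viscosity_mpas`. The
#' canonical layout is the 2^3 factorial (two levels per culture) plus a
#' centre point.
#'
#' @param data data frame in the wide layout above.
#' @param factor_names character vector of three labels for the cultures.
#' @return A validated `ferm_design` object.
#' @examples
#' d <- ferm_fixture("starter_design")
#' design_responses(d)
#' @export
ferm_design <- function(data, factor_names = c("x1", "x2", "x3")) {
  data <- as.data.frame(data)
  stopifnot(length(factor_names) == 3)
  obj <- structure(data,
                   factor_names = as.character(factor_names),
                   class = c("ferm_design", "data.frame"))
  validate_ferm_design(obj)
}

validate_ferm_design <- function(x) {
  fac <- c("x1", "x2", "x3")
  if (!all(fac %in% names(x)))
    stop("design must contain factor columns x1, x2, x3", call. = FALSE)
  for (f in fac) {
    v <- x[[f]]
    if (!is.numeric(v) || anyNA(v))
      stop(sprintf("non-numeric inoculum level in '%s'", f), call. = FALSE)
    if (any(v <= 0))
      stop(sprintf("inoculum levels must be positive ('%s' has %g)",
                   f, min(v)), call. = FALSE)
  }
  for (r in design_responses(x)) {
    s <- x[[paste0(r, "_sd")]]
    n <- x[[paste0(r, "_n")]]
    if (is.null(s) || is.null(n))
      stop(sprintf("response '%s' lacks its _sd or _n column", r), call. = FALSE)
    if (any(!is.na(s) & s < 0))
      stop(sprintf("negative standard deviation for '%s'", r), call. = FALSE)
    if (r == "viscosity_mpas" && any(x[[paste0(r, "_mean")]] < 0))
      stop("viscosity means must be non-negative", call. = FALSE)
  }
  x
}

#' @describeIn ferm_design names of the responses present in the table.
#' @param x a `ferm_design`.
#' @export
design_responses <- function(x) {
  nm <- grep("_mean$", names(x), value = TRUE)
  sub("_mean$", "", nm)
}

#' @export
print.ferm_design <- function(x, ...) {
  cat(sprintf("Factorial starter-culture design: %d runs, responses: %s\n",
              nrow(x), paste(design_responses(x), collapse = ", ")))
  cat("  factors:", paste(attr(x, "factor_names"), collapse = ", "), "\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Read or write a factorial design CSV
#'
#' Same CSV dialect as [read_timeseries_csv()]. The header must name the
#' three factor columns `x1`, `x2`, `x3` and `<resp>_mean`/`<resp>_sd`
#' pairs; a missing `<resp>_n` column defaults to 3.
#'
#' @param path file path.
#' @param factor_names labels for the three cultures.
#' @return `read_design_csv()` returns a validated [ferm_design];
#'   `write_design_csv()` invisibly returns `path`.
#' @export
read_design_csv <- function(path, factor_names = c("x1", "x2", "x3")) {
  df <- read_ferm_csv(path)
  if (sum(c("x1", "x2", "x3") %in% names(df)) < 3)
    stop(sprintf("'%s': header must name three factor columns x1, x2, x3",
                 path), call. = FALSE)
  df <- default_n_columns(df, exclude = c("x1", "x2", "x3"))
  ferm_design(df, factor_names = factor_names)
}

#' @rdname read_design_csv
#' @param x a [ferm_design].
#' @export
write_design_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}
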