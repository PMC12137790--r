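# Curve tables, fit-result JSON and run manifests.

#' Read a sampled curve from CSV
#'
#' Expects columns `time_s` and `value` (and optionally `sigma`).
#'
#' @param path CSV file path.
#' @return A [SampledCurve-class] object.
#' @seealso [writeCurveTable()]
#' @export
readCurveTable <- function(path) {
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e)
                   stop("could not parse '", path, "': ", conditionMessage(e),
                        call. = FALSE))
  for (col in c("time_s", "value")) {
    if (!col %in% names(df))
      stop("curve table '", path, "' is missing required column '", col, "'",
           call. = FALSE)
  }
  bad <- which(!is.finite(df$time_s) | !is.finite(df$value))
  if (length(bad))
    stop("curve table '", path, "': non-numeric entry at data line ", bad[1],
         call. = FALSE)
  sigma <- if ("sigma" %in% names(df)) df$sigma[1] else NA_real_
  SampledCurve(df$time_s, df$value, sigma)
}

#' Write a sampled curve to CSV
#'
#' Columns `time_s`, `value` and, when known, `sigma`; round-trips
#' losslessly through [readCurveTable()] (values are written with full
#' precision).
#'
#' @param curve a [SampledCurve-class] object.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
writeCurveTable <- function(curve, path) {
  stopifnot(is(curve, "SampledCurve"))
  df <- data.frame(time_s = format(curveTimes(curve), digits = 17),
                   value = format(curveValues(curve), digits = 17))
  if (!is.na(curveSigma(curve)))
    df$sigma <- format(curveSigma(curve), digits = 17)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a fit result as JSON
#'
#' @param fit a [FitResult-class] object.
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
writeFitResult <- function(fit, path) {
  stopifnot(is(fit, "FitResult"))
  e <- estimates(fit)
  jsonlite::write_json(list(
    vp = vp(e), ve = ve(e), kep = kep(e), Ktrans = ktrans(e),
    rss = rss(fit), converged = converged(fit),
    variant = fit@variant, dt_s = fit@dt),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run bit-identically: the
#' configuration, every seed, and the package version.
#'
#' @param config a named list of configuration values (seeds included).
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
writeManifest <- function(config, path) {
  manifest <- c(config, list(
    package = "taetofts",
    version = as.character(utils::packageVersion("taetofts")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' Accepts JSON (flat object) or `key = value` / `key: value` text; used for
#' AIF and SPGR overrides on the command line.
#'
#' @param path config file path.
#' @return Named list of values (numbers parsed as numeric).
#' @export
readFlatConfig <- function(path) {
  txt <- readLines(path, warn = FALSE)
  joined <- paste(txt, collapse = "\n")
  if (grepl("^\\s*\\{", joined)) {
    return(jsonlite::parse_json(joined, simplifyVector = TRUE))
  }
  out <- list()
  for (i in seq_along(txt)) {
    line <- sub("#.*$", "", txt[i])
    if (!nzchar(trimws(line))) next
    m <- regmatches(line, regexec("^\\s*([A-Za-z0-9_.]+)\\s*[:=]\\s*(.*)$",
                                  line))[[1]]
    if (length(m) != 3L)
      stop("config '", path, "': cannot parse line ", i, ": ", txt[i],
           call. = FALSE)
    val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[m[2]]] <- if (!is.na(num)) num else val
  }
  out
}
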