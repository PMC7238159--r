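#' Read an isothermal DSC thermogram from CSV
#'
#' Expects a comma-separated file with a header row and "." as decimal mark.
#' Lines starting with `#` are treated as comments; a comment of the form
#' `# temperature_K=363` sets the hold temperature. Column names are mapped
#' through `columns`, and the time unit is converted to seconds on import.
#'
#' @param path Path to the CSV file.
#' @param columns Named list mapping the fields `time` and `heat_flow` to the
#'   column names in the file.
#' @param time_unit Unit of the time column: seconds, minutes or hours.
#' @param exo_positive Set to `FALSE` when the instrument writes exothermic
#'   heat flow as negative; the column is then negated so the crystallization
#'   exotherm is stored positive.
#' @param temperature Hold temperature in kelvin; overridden by a
#'   `temperature_K=` comment tag when present.
#'
#' @return A [thermogram()].
#' @export
read_thermogram <- function(path,
                            columns = list(time = "time", heat_flow = "heat_flow"),
                            time_unit = c("s", "min", "h"),
                            exo_positive = TRUE,
                            temperature = 363) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop("amorphkin: file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  tagged <- .parse_tags(lines)
  if (!is.na(tagged$temperature)) temperature <- tagged$temperature
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) < 2L) stop("amorphkin: empty or header-only CSV: ", path, call. = FALSE)
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        check.names = FALSE, stringsAsFactors = FALSE)
  for (field in c("time", "heat_flow")) {
    col <- columns[[field]]
    if (is.null(col) || !col %in% names(df)) {
      stop("amorphkin: missing required column '",
           if (is.null(col)) field else col, "' in ", path, call. = FALSE)
    }
  }
  scale <- switch(time_unit, s = 1, min = 60, h = 3600)
  tvals <- as.numeric(df[[columns$time]]) * scale
  hvals <- as.numeric(df[[columns$heat_flow]]) * if (exo_positive) 1 else -1
  thermogram(time = tvals, heat_flow = hvals, temperature = temperature,
             label = basename(path))
}

.parse_tags <- function(lines) {
  out <- list(temperature = NA_real_, elapsed = NA_real_)
  tagl <- grep("^\\s*#", lines, value = TRUE)
  m <- regmatches(tagl, regexec("temperature_K\\s*=\\s*([0-9.eE+-]+)", tagl))
  hit <- vapply(m, length, 1L) == 2L
  if (any(hit)) out$temperature <- as.numeric(m[hit][[1]][2])
  m <- regmatches(tagl, regexec("elapsed_s\\s*=\\s*([0-9.eE+-]+)", tagl))
  hit <- vapply(m, length, 1L) == 2L
  if (any(hit)) out$elapsed <- as.numeric(m[hit][[1]][2])
  out
}

#' Read a series of dielectric spectra
#'
#' Accepts either a directory of CSV files (one spectrum each) or a single
#' file with blank-line-separated blocks. Each spectrum must carry a comment
#' tag line, `# temperature_K=<value>` and/or `# elapsed_s=<value>`, followed
#' by a header row with the columns `frequency`, `eps_real`, `eps_imag`.
#' Spectra are returned sorted in ascending order of the chosen tag.
#'
#' @param path File or directory path.
#' @param tag Which tag orders the series: `"temperature"` (temperature scan)
#'   or `"elapsed_time"` (isothermal crystallization run).
#'
#' @return A list of [dielectric_spectrum()] objects, class
#'   `"spectra_series"`.
#' @export
read_spectra <- function(path, tag = c("temperature", "elapsed_time")) {
  tag <- match.arg(tag)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
    if (length(files) == 0L) stop("amorphkin: no CSV files in ", path, call. = FALSE)
    blocks <- lapply(files, readLines, warn = FALSE)
  } else if (file.exists(path)) {
    lines <- readLines(path, warn = FALSE)
    idx <- cumsum(!nzchar(trimws(lines)))
    keep <- nzchar(trimws(lines))
    blocks <- split(lines[keep], idx[keep])
  } else {
    stop("amorphkin: path not found: ", path, call. = FALSE)
  }
  spectra <- lapply(blocks, .parse_spectrum_block)
  key <- vapply(spectra, function(s) {
    v <- if (tag == "temperature") s$temperature else s$elapsed_time
    if (is.na(v)) stop("amorphkin: spectrum block lacks the '", tag,
                       "' tag required for ordering", call. = FALSE)
    v
  }, numeric(1))
  structure(unname(spectra[order(key)]), class = "spectra_series")
}

.parse_spectrum_block <- function(lines) {
  tags <- .parse_tags(lines)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) < 2L) stop("amorphkin: empty spectrum block", call. = FALSE)
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("frequency", "eps_real", "eps_imag")) {
    if (!col %in% names(df)) {
      stop("amorphkin: spectrum block missing column '", col, "'", call. = FALSE)
    }
  }
  dielectric_spectrum(frequency = df$frequency, eps_real = df$eps_real,
                      eps_imag = df$eps_imag,
                      temperature = tags$temperature,
                      elapsed_time = tags$elapsed)
}

#' @export
print.spectra_series <- function(x, ...) {
  cat(sprintf("<spectra_series> %d spectra\n", length(x)))
  invisible(x)
}

#' Serialize an analysis result to JSON
#'
#' Writes any of the package's fit/result objects (or a plain list of them)
#' to a JSON file with full double precision, so that
#' `read_report(write_report(x))` reproduces every numeric field exactly.
#' The S3 class is stored alongside the fields and restored on read.
#'
#' @param x A result object (e.g. an `avramov_fit`, `vft_fit`,
#'   `nucleation_scales`, ...) or a list of such objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  payload <- .reportify(x)
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("amorphkin: cannot write ", path, call. = FALSE))
  on.exit(close(con))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              null = "null", na = "null"), con)
  invisible(path)
}

.reportify <- function(x) {
  if (is.list(x)) {
    out <- lapply(unclass(x), .reportify)
    cls <- class(x)
    if (!identical(cls, "list")) out[["_class"]] <- cls[1]
    return(out)
  }
  x
}

#' Read back a JSON report written by [write_report()]
#'
#' @param path Path to a JSON report file.
#' @return The deserialized object with its S3 class restored.
#' @export
read_report <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  .dereportify(raw)
}

.dereportify <- function(x) {
  if (!is.list(x)) return(x)
  cls <- x[["_class"]]
  x[["_class"]] <- NULL
  out <- lapply(x, .dereportify)
  if (!is.null(cls)) class(out) <- cls
  out
}
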