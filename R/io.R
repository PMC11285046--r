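# Delimited-text I/O. All files carry a two-line header:
#   # units: nm, <absorbance|M-1cm-1|counts>
#   <column names>
# Delimiter (comma or tab) is auto-detected from the column-name line.

.unit_aliases <- c("absorbance" = "absorbance",
                   "M-1cm-1" = "M-1cm-1", "M^-1cm^-1" = "M-1cm-1",
                   "counts" = "counts")

.read_header <- function(path) {
  lines <- readLines(path, n = 64L, warn = FALSE)
  if (length(lines) < 2L)
    .stopf("%s: file too short for a units header + column names", path,
           class = "photokin_format")
  if (!grepl("^#\\s*units\\s*:", lines[1L]))
    .stopf("%s: missing '# units: ...' header on line 1", path,
           class = "photokin_format")
  units <- trimws(strsplit(sub("^#\\s*units\\s*:", "", lines[1L]),
                           "[,\t]")[[1L]])
  sep <- if (grepl("\t", lines[2L])) "\t" else ","
  list(units = units, sep = sep)
}

.parse_numeric_cols <- function(df, path, skip_col = integer()) {
  for (j in setdiff(seq_along(df), skip_col)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]) & trimws(df[[j]]) != "")
    if (length(bad) || anyNA(v))
      .stopf("%s: non-numeric cell at data row %d, column %d ('%s')",
             path, if (length(bad)) bad[1L] else which(is.na(v))[1L], j,
             df[[j]][if (length(bad)) bad[1L] else which(is.na(v))[1L]],
             class = "photokin_parse")
    df[[j]] <- v
  }
  df
}

#' Read a spectrum from delimited text
#'
#' Expects a two-line header: `# units: nm, <unit>` followed by column
#' names; comma or tab delimited (auto-detected). Duplicate or non-monotone
#' wavelengths are rejected.
#'
#' @param path File path.
#' @param label Label to attach; defaults to the file name.
#' @return A `photokin_spectrum`.
#' @export
read_spectrum <- function(path, label = basename(path)) {
  hd <- .read_header(path)
  if (length(hd$units) < 2L || !hd$units[2L] %in% names(.unit_aliases))
    .stopf("%s: units header must name a value unit among %s", path,
           paste(unique(.unit_aliases), collapse = ", "),
           class = "photokin_format")
  df <- utils::read.table(path, sep = hd$sep, header = TRUE, skip = 1L,
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2L)
    .stopf("%s: expected at least 2 columns", path, class = "photokin_format")
  df <- .parse_numeric_cols(df, path)
  if (anyDuplicated(df[[1L]]))
    .stopf("%s: duplicate wavelength %g nm", path,
           df[[1L]][anyDuplicated(df[[1L]])], class = "photokin_monotonicity")
  spectrum_new(df[[1L]], df[[2L]], .unit_aliases[[hd$units[2L]]], label)
}

#' Write a spectrum to delimited text
#'
#' @param spectrum A `photokin_spectrum`.
#' @param path Output file path.
#' @param sep Delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path, sep = ",") {
  stopifnot(inherits(spectrum, "photokin_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# units: nm, %s", spectrum$unit), con)
  writeLines(paste("wavelength_nm", "value", sep = sep), con)
  utils::write.table(
    data.frame(w = spectrum$wavelength, v = spectrum$value),
    con, sep = sep, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an absorbance time series
#'
#' Two layouts are accepted. A wide file has the two-line header, a first
#' column `wavelength_nm` and one column per timestamp named `t<seconds>`
#' (e.g. `t0, t30, t60`). A directory must contain per-timestamp spectrum
#' files plus `manifest.csv` with columns `filename,time_s`.
#'
#' @param path Wide file or directory path.
#' @return A `photokin_sts`.
#' @export
read_time_series <- function(path) {
  if (dir.exists(path)) return(.read_sts_dir(path))
  hd <- .read_header(path)
  df <- utils::read.table(path, sep = hd$sep, header = TRUE, skip = 1L,
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2L)
    .stopf("%s: wide time series needs wavelength plus >= 1 time column",
           path, class = "photokin_format")
  tn <- names(df)[-1L]
  if (!all(grepl("^t[0-9.]+$", tn)))
    .stopf("%s: time columns must be named t<seconds>, got '%s'", path,
           tn[!grepl("^t[0-9.]+$", tn)][1L], class = "photokin_format")
  times <- as.numeric(sub("^t", "", tn))
  df <- .parse_numeric_cols(df, path)
  if (anyDuplicated(df[[1L]]))
    .stopf("%s: duplicate wavelength %g nm", path,
           df[[1L]][anyDuplicated(df[[1L]])], class = "photokin_monotonicity")
  spectra <- lapply(seq_along(times), function(i)
    spectrum_new(df[[1L]], df[[i + 1L]], "absorbance", tn[i]))
  time_series_new(times, spectra)
}

.read_sts_dir <- function(path) {
  man <- file.path(path, "manifest.csv")
  if (!file.exists(man))
    .stopf("%s: directory layout requires manifest.csv (filename,time_s)",
           path, class = "photokin_format")
  m <- utils::read.csv(man, colClasses = c("character", "numeric"))
  if (!all(c("filename", "time_s") %in% names(m)))
    .stopf("%s: manifest must have columns filename,time_s", man,
           class = "photokin_format")
  m <- m[order(m$time_s), , drop = FALSE]
  spectra <- lapply(file.path(path, m$filename), read_spectrum)
  spectra <- common_grid(spectra)
  time_series_new(m$time_s, spectra)
}

#' Write an absorbance time series as a wide delimited file
#'
#' Round-trippable with [read_time_series()].
#'
#' @param sts A `photokin_sts`.
#' @param path Output file path.
#' @param sep Delimiter.
#' @return `path`, invisibly.
#' @export
write_time_series <- function(sts, path, sep = ",") {
  stopifnot(inherits(sts, "photokin_sts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# units: nm, absorbance", con)
  writeLines(paste(c("wavelength_nm",
                     sprintf("t%g", sts$times)), collapse = sep), con)
  utils::write.table(cbind(sts$wavelength, sts$absorbance), con, sep = sep,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a thermopile power log
#'
#' Delimited text with header columns `time_s,power_W` (an optional
#' `# units:` comment line is tolerated). Logs exported with columns
#' `timestamp,power,unit` are normalized to watts: accepted units are
#' `W`, `mW`, `uW`.
#'
#' @param path File path.
#' @param on_interval Optional length-2 numeric `[t_start, t_end]` in s
#'   marking the LED-on window; if `NULL` it is auto-detected later by
#'   [detect_on_interval()].
#' @return A `photokin_power_trace`.
#' @export
read_power_trace <- function(path, on_interval = NULL) {
  first <- readLines(path, n = 1L, warn = FALSE)
  skip <- if (grepl("^#", first)) 1L else 0L
  hl <- readLines(path, n = skip + 1L, warn = FALSE)[skip + 1L]
  sep <- if (grepl("\t", hl)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, skip = skip,
                          colClasses = "character", check.names = FALSE)
  nm <- tolower(names(df))
  if (all(c("time_s", "power_w") %in% nm)) {
    df <- .parse_numeric_cols(df, path)
    t <- df[[which(nm == "time_s")]]
    p <- df[[which(nm == "power_w")]]
  } else if (all(c("timestamp", "power", "unit") %in% nm)) {
    ucol <- which(nm == "unit")
    df <- .parse_numeric_cols(df, path, skip_col = ucol)
    fac <- c(W = 1, mW = 1e-3, uW = 1e-6)[df[[ucol]]]
    if (anyNA(fac))
      .stopf("%s: unknown power unit '%s'", path,
             df[[ucol]][which(is.na(fac))[1L]], class = "photokin_parse")
    t <- df[[which(nm == "timestamp")]]
    p <- df[[which(nm == "power")]] * fac
  } else {
    .stopf("%s: expected columns time_s,power_W or timestamp,power,unit",
           path, class = "photokin_format")
  }
  power_trace_new(t, p, on_interval)
}

#' Serialize a power result as key-value text
#'
#' @param result A `photokin_power_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_power_result <- function(result, path) {
  stopifnot(inherits(result, "photokin_power_result"))
  writeLines(c(sprintf("mean_power_W=%.10g", result$mean_power),
               sprintf("std_power_W=%.10g", result$std_power),
               sprintf("n=%d", result$n_samples),
               sprintf("correction_applied=%s",
                       tolower(as.character(result$correction_applied)))),
             path)
  invisible(path)
}
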