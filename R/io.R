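#' Read a trace from delimited text
#'
#' Reads a two-column (time, value) delimited text file into a [ca_trace()].
#' Column positions are explicit configuration, never sniffed. A single
#' leading header or comment line starting with a non-numeric token is
#' skipped; a comment line of the form `# catransient ...` written by
#' [write_trace()] restores the signal kind and label.
#'
#' @param path Path to a delimited text file with at least 2 data rows.
#' @param delim Field delimiter, default `","`.
#' @param time_col,value_col 1-based column positions of the time and value
#'   columns.
#' @param time_units `"ms"` (default) or `"s"`; seconds are converted to
#'   milliseconds on input so all rate constants stay per-ms.
#' @param signal_kind,label Metadata applied when the file carries none.
#' @return A [ca_trace()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("time,F", "0,1.0", "1,1.1", "2,1.2"), f)
#' read_trace(f)
#' @export
read_trace <- function(path, delim = ",", time_col = 1L, value_col = 2L,
                       time_units = c("ms", "s"), signal_kind = "raw",
                       label = "") {
  time_units <- match.arg(time_units)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("file is empty: ", path, call. = FALSE)

  meta <- parse_trace_meta(lines[1L])
  if (!is.null(meta)) {
    signal_kind <- meta$signal_kind %||% signal_kind
    label <- meta$label %||% label
    lines <- lines[-1L]
  }
  if (length(lines) == 0L) stop("no data rows in ", path, call. = FALSE)

  first_fields <- strsplit(lines[1L], delim, fixed = TRUE)[[1L]]
  probe <- first_fields[min(time_col, length(first_fields))]
  if (is.na(suppressWarnings(as.numeric(probe)))) {
    lines <- lines[-1L]  # header row such as "time,F"
  }
  if (length(lines) < 2L) {
    stop("need at least 2 data rows in ", path, call. = FALSE)
  }

  fields <- strsplit(lines, delim, fixed = TRUE)
  ncols <- lengths(fields)
  need <- max(time_col, value_col)
  if (any(ncols < need)) {
    bad <- which(ncols < need)[1L]
    stop("ragged row ", bad, " in ", path, ": has ", ncols[bad],
         " fields, need ", need, call. = FALSE)
  }
  time <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", time_col)))
  value <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", value_col)))
  if (anyNA(time)) {
    stop("non-numeric time entry at data row ", which(is.na(time))[1L],
         " in ", path, call. = FALSE)
  }
  if (anyNA(value)) {
    stop("non-numeric value entry at data row ", which(is.na(value))[1L],
         " in ", path, call. = FALSE)
  }
  if (time_units == "s") time <- time * 1000
  ca_trace(time, value, signal_kind = signal_kind, label = label)
}

# "# catransient signal_kind=<kind> label=<label>" -> list, else NULL
parse_trace_meta <- function(line) {
  if (!startsWith(line, "# catransient")) return(NULL)
  out <- list()
  m <- regmatches(line, regexec("signal_kind=([a-zA-Z0-9_]+)", line))[[1L]]
  if (length(m) == 2L) out$signal_kind <- m[2L]
  m <- regmatches(line, regexec("label=(.*)$", line))[[1L]]
  if (length(m) == 2L) out$label <- m[2L]
  out
}

#' Write a trace to delimited text
#'
#' Writes one `time<delim>value` row per sample, preceded by a `time,value`
#' column header. When the trace carries a label or a non-raw signal kind, a
#' single metadata comment line is written first so [read_trace()]
#' round-trips the trace exactly; a plain raw unlabelled trace gets no
#' metadata line.
#'
#' @param trace A [ca_trace()].
#' @param path Output file path.
#' @param delim Field delimiter, default `","`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, delim = ",") {
  trace <- assert_trace(trace)
  lines <- character(0)
  if (nzchar(trace_label(trace)) || signal_kind(trace) != "raw") {
    lines <- sprintf("# catransient signal_kind=%s label=%s",
                     signal_kind(trace), trace_label(trace))
  }
  lines <- c(lines,
             paste("time", "value", sep = delim),
             paste(format(trace$time, digits = 15, trim = TRUE, scientific = FALSE),
                   format(trace$value, digits = 15, trim = TRUE),
                   sep = delim))
  tryCatch(writeLines(lines, path),
           error = function(e) stop("cannot write trace to ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}
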