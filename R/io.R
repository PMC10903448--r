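#' Read a delimited input table with header and unit checking
#'
#' Parses the comma-delimited dialects used by the pipeline. Required columns
#' are checked against the dialect, numeric columns are validated cell by
#' cell, and malformed rows are reported with their line numbers.
#' Concentration columns may be given in molar (`conc_molar`) or micromolar
#' (`conc_um`, converted to molar on load).
#'
#' Dialects:
#' \describe{
#'   \item{`trace`}{`time_s, signal, construct, condition, replicate`}
#'   \item{`mst`}{`conc_molar` (or `conc_um`), `fnorm`, `replicate`, and
#'     optionally `construct`}
#'   \item{`sensorgram`}{`time_s, response_ru, conc_molar` (or `conc_um`),
#'     `phase`, and optionally `flow_cell`, `construct`}
#'   \item{`raw_trace`}{`time_s, fluorescence`}
#' }
#'
#' @param path file path.
#' @param dialect one of `"trace"`, `"mst"`, `"sensorgram"`, `"raw_trace"`.
#' @return data.frame with canonical column names (`time`, `signal`, `conc`
#'   in molar, ...).
#' @export
read_table <- function(path,
                       dialect = c("trace", "mst", "sensorgram",
                                   "raw_trace")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0)
    stop("empty input (header only): ", path, call. = FALSE)

  spec <- switch(dialect,
    trace = list(req = c("time_s", "signal", "construct", "condition",
                         "replicate"),
                 num = c("time_s", "signal")),
    mst = list(req = c("fnorm", "replicate"), num = c("fnorm"),
               conc = TRUE),
    sensorgram = list(req = c("time_s", "response_ru", "phase"),
                      num = c("time_s", "response_ru"), conc = TRUE),
    raw_trace = list(req = c("time_s", "fluorescence"),
                     num = c("time_s", "fluorescence")))

  missing_cols <- setdiff(spec$req, names(df))
  if (length(missing_cols))
    stop("missing columns in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  conc_cols <- c()
  if (isTRUE(spec$conc)) {
    if ("conc_molar" %in% names(df)) {
      conc_cols <- "conc_molar"
    } else if ("conc_um" %in% names(df)) {
      conc_cols <- "conc_um"
    } else stop("missing concentration column (conc_molar or conc_um) in ",
                path, call. = FALSE)
  }

  for (col in c(spec$num, conc_cols)) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop("non-numeric values in column '", col, "' of ", path,
           " at line(s) ", paste(bad + 1L, collapse = ", "),
           call. = FALSE)
    df[[col]] <- v
  }
  if (length(conc_cols)) {
    df$conc <- if (conc_cols == "conc_um") df[[conc_cols]] * 1e-6
    else df[[conc_cols]]
    df[[conc_cols]] <- NULL
  }
  names(df)[names(df) == "time_s"] <- "time"
  names(df)[names(df) == "response_ru"] <- "response"
  df
}

#' Write a structured result report
#'
#' Serialises a result list to JSON with stable key order and full numeric
#' precision, so that `read_report(write_report(x))` reproduces every number
#' exactly and repeated writes are byte-identical. Reports should carry
#' their provenance (input files, config, seed) alongside the estimates.
#'
#' @param report a named list (nested lists, vectors and data.frames).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_report <- function(report, path) {
  stopifnot(is.list(report))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path path to the JSON report.
#' @return the report list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
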