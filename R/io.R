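#' Read a dynamic series from disk
#'
#' Reads a time-by-pixel concentration matrix (each row one frame, each
#' column one pixel). Supported formats: delimited text (CSV/TSV; a leading
#' `time` column, when present, supplies the timestamps) and RDS array
#' containers holding either a ready-made [dynamic_series()] or a bare
#' matrix. MATLAB `.mat` matrices are not readable in this build; export
#' them as delimited text first.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"`, or `"rds"`.
#' @param frame_interval frame spacing in minutes used when the file carries
#'   no timestamps (default 0.5 min, i.e. one frame every 30 s).
#' @param times explicit timestamps overriding both the file and
#'   `frame_interval`.
#' @param transpose set when the file stores pixels as rows.
#' @param shape optional grid dimensions to attach.
#' @return a [dynamic_series()].
#' @export
read_series <- function(path, format = c("auto", "csv", "tsv", "rds"),
                        frame_interval = 0.5, times = NULL,
                        transpose = FALSE, shape = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (format == "auto") {
    if (ext == "mat")
      stop("MATLAB .mat input is not supported by this build; export the ",
           "matrix as CSV/TSV (rows = frames, columns = pixels) instead")
    format <- switch(ext, rds = "rds", tsv = "tsv", txt = "tsv", "csv")
  }
  if (format == "rds") {
    obj <- readRDS(path)
    if (inherits(obj, "dynamic_series")) return(obj)
    values <- as.matrix(obj)
    if (transpose) values <- t(values)
    return(dynamic_series(values, times = times,
                          frame_interval = frame_interval, shape = shape))
  }
  dt <- data.table::fread(path, header = TRUE,
                          sep = if (format == "tsv") "\t" else ",")
  if (tolower(names(dt)[1]) %in% c("time", "times", "t")) {
    if (is.null(times)) times <- as.numeric(dt[[1]])
    dt <- dt[, -1]
  }
  values <- suppressWarnings(
    matrix(as.numeric(as.matrix(dt)), nrow(dt), ncol(dt)))
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric or missing cell at row %d, column %d of %s",
                 bad[1, 1], bad[1, 2], path))
  if (transpose) values <- t(values)
  dynamic_series(values, times = times, frame_interval = frame_interval,
                 shape = shape)
}

#' Write a dynamic series as delimited text
#'
#' The inverse of [read_series()]: frames as rows, pixels as columns, with a
#' leading `time` column in minutes. Values are written at full precision so
#' the round trip is lossless to numerical resolution.
#'
#' @param series a [dynamic_series()].
#' @param path output file (`.csv` or `.tsv` by extension).
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  vals <- series$values
  colnames(vals) <- paste0("px", seq_len(ncol(vals)))
  dt <- data.table::data.table(time = series$times)
  dt <- cbind(dt, data.table::as.data.table(vals))
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  data.table::fwrite(dt, path, sep = sep)
  invisible(path)
}

#' Serialize a preprocess report
#' @param report a [preprocess_report()].
#' @param path output `.json` file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
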