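# Plain-text I/O: traces and event logs as CSV, parameters and reports as
# JSON, so runs diff cleanly under version control.

#' Write an EMG trace as CSV
#'
#' Columns `time_s`, `emg_mV`. Uses data.table's writer; traces can run to
#' millions of rows.
#' @param trace an [emg_trace()].
#' @param path output file.
#' @export
write_trace_csv <- function(trace, path) {
  tt <- trace$start_time + (seq_along(trace$samples) - 1) / trace$sampling_rate
  data.table::fwrite(data.table::data.table(time_s = tt,
                                            emg_mV = trace$samples), path)
  invisible(path)
}

#' Read an EMG trace CSV
#'
#' Expects uniform sampling; the rate is recovered from the time column.
#' @param path CSV with columns `time_s`, `emg_mV`.
#' @return an [emg_trace()].
#' @export
read_trace_csv <- function(path) {
  d <- data.table::fread(path)
  if (!all(c("time_s", "emg_mV") %in% names(d)))
    stop("trace CSV needs columns time_s, emg_mV")
  dt <- diff(d$time_s)
  if (length(dt) < 1 || any(abs(dt - dt[1]) > 1e-6 * dt[1]))
    stop("trace is not uniformly sampled")
  emg_trace(d$emg_mV, sampling_rate = 1 / dt[1], start_time = d$time_s[1])
}

#' Write a JSON file with stable formatting
#' @param x object serializable by jsonlite.
#' @param path output file.
#' @export
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
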