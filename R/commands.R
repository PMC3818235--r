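# End-to-end command surface behind the CLI: simulate a cohort to disk,
# score it, analyze the pooled table, and the blot counterparts. Each
# command takes a plain config list so the CLI stays a thin flag parser.

msg <- function(verbose, ...) if (isTRUE(verbose)) message(...)

#' Simulate a cohort and write traces, logs and a manifest
#'
#' @param config list with `design`, `seed`, `out` (output directory) and
#'   optional `params` (a [sim_params()] or a named list of overrides),
#'   `overrides` (protocol overrides), `verbose`.
#' @return manifest list, invisibly; files written: one trace CSV and one
#'   event-log CSV per animal plus `manifest.json` recording every
#'   parameter and derived seed (and file checksums).
#' @export
cmd_simulate <- function(config) {
  stopifnot(!is.null(config$design), !is.null(config$out))
  params <- config$params
  if (!inherits(params, "sim_params"))
    params <- do.call(sim_params, as.list(params))
  if (!is.null(config$seed)) params$seed <- as.integer(config$seed)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$out)) stop("cannot create output dir: ", config$out)
  protocol <- build_protocol(config$design, config$overrides %||% list())
  cohort <- simulate_cohort(protocol, params)
  files <- list()
  for (i in seq_along(cohort)) {
    tf <- file.path(config$out, sprintf("animal%02d_trace.csv", i))
    ef <- file.path(config$out, sprintf("animal%02d_events.csv", i))
    write_trace_csv(cohort[[i]]$trace, tf)
    write_event_log(cohort[[i]]$events, ef)
    files[[i]] <- list(animal = i, trace = basename(tf), events = basename(ef),
                       seed = cohort[[i]]$seed,
                       md5_trace = unname(tools::md5sum(tf)),
                       md5_events = unname(tools::md5sum(ef)))
    msg(config$verbose, "wrote animal ", i)
  }
  manifest <- list(design = config$design,
                   params = unclass(params),
                   n_animals = length(cohort),
                   files = files)
  write_json_file(manifest, file.path(config$out, "manifest.json"))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score a simulated/recorded cohort directory
#'
#' @param config list with `in_dir` (holding `animalNN_trace.csv` /
#'   `animalNN_events.csv` pairs), `out` directory, and optional
#'   `background`, `normalizer_scope`, `verbose`.
#' @return list with pooled `records` and `table`, invisibly; writes
#'   per-animal record CSVs and pooled `vmr_records.csv` /
#'   `vmr_table.csv`.
#' @export
cmd_score <- function(config) {
  stopifnot(!is.null(config$in_dir), !is.null(config$out))
  traces <- sort(list.files(config$in_dir, "^animal[0-9]+_trace\\.csv$",
                            full.names = TRUE))
  if (length(traces) == 0) stop("no trace files in ", config$in_dir)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  all_rec <- list(); all_tab <- list()
  for (tf in traces) {
    ef <- sub("_trace\\.csv$", "_events.csv", tf)
    if (!file.exists(ef)) stop("trace/log mismatch: missing ", ef)
    id <- as.integer(sub("^animal([0-9]+)_trace\\.csv$", "\\1", basename(tf)))
    trace <- read_trace_csv(tf)
    events <- read_event_log(ef)
    res <- score_experiment(trace, events, animal = id,
                            background = config$background %||% "pre_window",
                            normalizer_scope =
                              config$normalizer_scope %||% "experiment")
    write.csv(res$records,
              file.path(config$out, sprintf("animal%02d_records.csv", id)),
              row.names = FALSE)
    all_rec[[length(all_rec) + 1L]] <- res$records
    all_tab[[length(all_tab) + 1L]] <- res$table
    msg(config$verbose, "scored animal ", id)
  }
  records <- do.call(rbind, all_rec)
  table <- do.call(rbind, all_tab)
  write.csv(records, file.path(config$out, "vmr_records.csv"), row.names = FALSE)
  write.csv(table, file.path(config$out, "vmr_table.csv"), row.names = FALSE)
  invisible(list(records = records, table = table))
}

#' Analyze a pooled VMR table for a design
#'
#' @param config list with `design`, `in_dir` (holding `vmr_table.csv`) and
#'   optional `alpha`, `out` (report files are written there as
#'   `report.json` and `report.txt`), `verbose`.
#' @return the `ubd_report`, invisibly.
#' @export
cmd_analyze <- function(config) {
  stopifnot(!is.null(config$design), !is.null(config$in_dir))
  tab_file <- file.path(config$in_dir, "vmr_table.csv")
  if (!file.exists(tab_file)) stop("no vmr_table.csv in ", config$in_dir)
  table <- read.csv(tab_file)
  report <- analyze_design(table, config$design,
                           alpha = config$alpha %||% 0.05)
  out <- config$out %||% config$in_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_json_file(report_to_list(report), file.path(out, "report.json"))
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(out, "report.txt"))
  invisible(report)
}

#' Simulate blot lanes to CSV
#'
#' @param config list with `out` directory and optional `seed`, `params`
#'   (a [blot_sim_params()] or override list).
#' @return the lane table, invisibly; writes `blot_lanes.csv` and a
#'   manifest.
#' @export
cmd_blot_sim <- function(config) {
  stopifnot(!is.null(config$out))
  params <- config$params
  if (!inherits(params, "blot_sim_params"))
    params <- do.call(blot_sim_params, as.list(params))
  if (!is.null(config$seed)) params$seed <- as.integer(config$seed)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  lanes <- simulate_blot_lanes(params)
  write.csv(lanes, file.path(config$out, "blot_lanes.csv"), row.names = FALSE)
  write_json_file(list(params = unclass(params)),
                  file.path(config$out, "blot_manifest.json"))
  invisible(lanes)
}

#' Analyze a blot lane CSV
#'
#' @param config list with `in_dir` (holding `blot_lanes.csv`) and optional
#'   `alpha`, `out`.
#' @return the [blot_analysis()] result, invisibly; writes
#'   `blot_report.json`.
#' @export
cmd_blot_analyze <- function(config) {
  stopifnot(!is.null(config$in_dir))
  f <- file.path(config$in_dir, "blot_lanes.csv")
  if (!file.exists(f)) stop("no blot_lanes.csv in ", config$in_dir)
  lanes <- read.csv(f)
  res <- blot_analysis(lanes, alpha = config$alpha %||% 0.05)
  out <- config$out %||% config$in_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_json_file(list(perk2 = report_to_list(res$perk2),
                       perk1 = report_to_list(res$perk1)),
                  file.path(out, "blot_report.json"))
  invisible(res)
}
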