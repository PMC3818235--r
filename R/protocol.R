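# Experimental protocols: distension schedules with anesthesia and body
# temperature context. All times are seconds; t = 0 is the start of testing
# (end of anesthesia stabilization), so surgery is not part of the timeline.

GRADED_PRESSURES <- c(15, 30, 45, 60, 75)
UBD_DESIGNS <- c("fig2_short", "fig2_long", "fig3_temp",
                 "fig4_ramp", "fig4_const", "fig5_blot")

#' Anesthesia step-down schedule
#'
#' The two isoflurane induction schedules in common use before bladder
#' distension testing: a *short* method (immediate drop to 1.0%, 10 min
#' stabilization, roughly 30 min total) and a *long* method (1.5% stepped
#' down by 0.125% every 15 min to 1.0%, then 15 min stabilization, roughly
#' 90 min total).
#'
#' @param method `"short"` or `"long"`.
#' @param final_pct isoflurane concentration (volume %) held during testing.
#'   Defaults to 1.0; blot experiments use 0.875.
#' @return An object of class `anesthesia_schedule` with elements `method`,
#'   `steps` (data.frame of `time_offset_min`, `iso_pct`, offsets relative to
#'   the end of surgery), `stabilization_min` and `final_pct`.
#' @export
anesthesia_schedule <- function(method = c("short", "long"), final_pct = 1.0) {
  method <- match.arg(method)
  if (method == "short") {
    steps <- data.frame(time_offset_min = 0, iso_pct = final_pct)
    stab <- 10
  } else {
    pct <- seq(1.5, 1.0, by = -0.125)
    if (final_pct < 1.0)
      pct <- c(pct, seq(1.0 - 0.125, final_pct, by = -0.125))
    steps <- data.frame(time_offset_min = 15 * (seq_along(pct) - 1), iso_pct = pct)
    stab <- 15
  }
  if (is.unsorted(rev(steps$iso_pct)))
    stop("isoflurane percentages must be monotone non-increasing")
  structure(list(method = method, steps = steps,
                 stabilization_min = stab, final_pct = final_pct),
            class = "anesthesia_schedule")
}

#' Body temperature schedule
#'
#' @param segments data.frame with columns `start_time_s` (seconds from start
#'   of testing) and `target_temp_C`. Temperatures must lie in
#'   \[33.5, 37.5\] degrees C, the range covered by the suppression model.
#' @param stabilization_s settling time inserted before a set whenever the
#'   target temperature changes (default 300 s).
#' @return An object of class `temperature_schedule`.
#' @export
temperature_schedule <- function(segments, stabilization_s = 300) {
  stopifnot(is.data.frame(segments),
            all(c("start_time_s", "target_temp_C") %in% names(segments)))
  if (any(segments$target_temp_C < 33.5 | segments$target_temp_C > 37.5))
    stop("target temperatures must lie within [33.5, 37.5] degrees C")
  if (is.unsorted(segments$start_time_s, strictly = TRUE))
    stop("temperature segments must be strictly time-ordered")
  structure(list(segments = segments, stabilization_s = stabilization_s),
            class = "temperature_schedule")
}

#' Temperature at a given testing time
#' @param schedule a [temperature_schedule()].
#' @param t time in seconds from start of testing.
#' @return temperature in degrees C.
#' @export
temperature_at <- function(schedule, t) {
  seg <- schedule$segments
  idx <- findInterval(t, seg$start_time_s)
  if (any(idx < 1)) stop("time precedes first temperature segment")
  seg$target_temp_C[idx]
}

#' Distension set description
#'
#' @param pressures ordered distension pressures in mmHg. The graded set is
#'   `c(15, 30, 45, 60, 75)`; fixed-pressure sets use a single value.
#' @param replicates_per_pressure distensions per pressure (default 3).
#' @param label free-text label.
#' @return An object of class `distension_set`.
#' @export
distension_set <- function(pressures = GRADED_PRESSURES,
                           replicates_per_pressure = 3,
                           label = "graded") {
  stopifnot(length(pressures) >= 1, all(pressures >= 0),
            replicates_per_pressure >= 1)
  if (is.unsorted(pressures, strictly = TRUE) && length(pressures) > 1)
    stop("pressures within a set must ascend (graded testing order)")
  structure(list(pressures = pressures,
                 replicates_per_pressure = as.integer(replicates_per_pressure),
                 label = label),
            class = "distension_set")
}

# Append one set's events to a timeline. Each event occupies
# pre_interval + duration + iti seconds; onset is the stimulus start.
append_set_events <- function(cursor, set, set_index, is_sensitization,
                              pre, dur, iti) {
  rows <- list()
  for (p in set$pressures) {
    for (r in seq_len(set$replicates_per_pressure)) {
      rows[[length(rows) + 1L]] <- data.frame(
        onset_s = cursor + pre, duration_s = dur, pressure_mmHg = p,
        pre_interval_s = pre, iti_s = iti,
        set_index = set_index, replicate_index = r,
        is_sensitization = is_sensitization)
      cursor <- cursor + pre + dur + iti
    }
  }
  list(cursor = cursor, events = do.call(rbind, rows))
}

#' Build a named experimental protocol
#'
#' Constructs the fully timed event timeline for one of the standard designs:
#' \describe{
#'   \item{`fig2_short`, `fig2_long`}{three graded distension sets
#'     (15--75 mmHg, 3 replicates each) at constant 37.5 C after the short or
#'     long isoflurane induction.}
#'   \item{`fig3_temp`}{three graded sets at 37.5, 33.5 and 35.5 C (in that
#'     order) after long induction.}
#'   \item{`fig4_ramp`}{nine sets of three 60 mmHg distensions while body
#'     temperature steps 37.5 -> 33.5 -> 37.5 C in 1 C increments.}
#'   \item{`fig4_const`}{the same nine-set timing with temperature held at
#'     37.5 C throughout (anesthesia-duration control).}
#'   \item{`fig5_blot`}{five 75 mmHg distensions after long induction to
#'     0.875% isoflurane, at a single temperature (37.5 or 33.5 C), used
#'     before spinal-cord harvest for pERK blotting; no sensitization
#'     distensions.}
#' }
#' Scored designs are preceded by three 60 mmHg sensitization distensions
#' (set index 0, flagged, excluded from scoring). Per-event timing is
#' 20 s pre-distension interval, 20 s stimulus, 60 s intertrial interval
#' unless overridden. A 300 s stabilization gap is inserted before any set
#' whose target temperature differs from the previous one (and before every
#' post-first set of the fig4 designs, so ramp and constant controls share a
#' timeline).
#'
#' @param design one of `"fig2_short"`, `"fig2_long"`, `"fig3_temp"`,
#'   `"fig4_ramp"`, `"fig4_const"`, `"fig5_blot"`.
#' @param overrides named list of overrides: `pre_interval_s`, `duration_s`,
#'   `iti_s`, `replicates_per_pressure`, `stabilization_s`, `temp_C`
#'   (fig5_blot only), `sensitization` (logical).
#' @return An object of class `ubd_protocol`: list with `design`, `events`
#'   (data.frame with onset, duration, pressure, windows, set/replicate
#'   indices, sensitization flag, and per-event `temp_C` and `iso_pct`
#'   context), `anesthesia`, `temperature`, and `timing`.
#' @examples
#' p <- build_protocol("fig2_long")
#' nrow(p$events)  # 48: 3 sensitization + 3 sets x 15
#' @export
build_protocol <- function(design, overrides = list()) {
  if (!is.character(design) || length(design) != 1 || !design %in% UBD_DESIGNS)
    stop("unknown design: ", paste(design, collapse = ", "),
         " (expected one of ", paste(UBD_DESIGNS, collapse = ", "), ")")
  ov <- function(name, default) if (!is.null(overrides[[name]])) overrides[[name]] else default
  pre  <- ov("pre_interval_s", 20)
  dur  <- ov("duration_s", 20)
  iti  <- ov("iti_s", 60)
  stab <- ov("stabilization_s", 300)
  reps <- ov("replicates_per_pressure", 3)
  if (pre <= 0 || dur <= 0 || iti < 0) stop("pre_interval and duration must be > 0, ITI >= 0")

  anesthesia <- switch(design,
    fig2_short = anesthesia_schedule("short"),
    fig5_blot  = anesthesia_schedule("long", final_pct = 0.875),
    anesthesia_schedule("long"))

  set_temps <- switch(design,
    fig3_temp  = c(37.5, 33.5, 35.5),
    fig4_ramp  = c(37.5, 36.5, 35.5, 34.5, 33.5, 34.5, 35.5, 36.5, 37.5),
    fig4_const = rep(37.5, 9),
    fig5_blot  = ov("temp_C", 37.5),
    rep(37.5, 3))
  if (design == "fig5_blot" &&
      (set_temps < 33.5 || set_temps > 37.5))
    stop("fig5_blot temp_C must lie within [33.5, 37.5]")

  sets <- switch(design,
    fig2_short = ,
    fig2_long  = ,
    fig3_temp  = replicate(3, distension_set(GRADED_PRESSURES, reps), simplify = FALSE),
    fig4_ramp  = ,
    fig4_const = replicate(9, distension_set(60, reps, label = "fixed60"), simplify = FALSE),
    fig5_blot  = list(distension_set(75, ov("replicates_per_pressure", 5),
                                     label = "fixed75")))

  sensitize <- ov("sensitization", design != "fig5_blot")

  cursor <- 0
  events <- list()
  seg <- data.frame(start_time_s = 0, target_temp_C = set_temps[1])
  if (isTRUE(sensitize)) {
    out <- append_set_events(cursor, distension_set(60, 3, "sensitization"),
                             0L, TRUE, pre, dur, iti)
    cursor <- out$cursor
    events[[1]] <- out$events
  }
  prev_temp <- set_temps[1]
  for (i in seq_along(sets)) {
    temp_i <- set_temps[min(i, length(set_temps))]
    gap <- if (design %in% c("fig4_ramp", "fig4_const")) i > 1 else temp_i != prev_temp
    if (gap) {
      cursor <- cursor + stab
      seg <- rbind(seg, data.frame(start_time_s = cursor, target_temp_C = temp_i))
    }
    out <- append_set_events(cursor, sets[[i]], i, FALSE, pre, dur, iti)
    cursor <- out$cursor
    events[[length(events) + 1L]] <- out$events
    prev_temp <- temp_i
  }
  events <- do.call(rbind, events)
  rownames(events) <- NULL

  temperature <- temperature_schedule(seg, stabilization_s = stab)
  events$temp_C <- temperature_at(temperature, events$onset_s)
  events$iso_pct <- anesthesia$final_pct

  proto <- structure(
    list(design = design, events = events, sets = sets,
         anesthesia = anesthesia, temperature = temperature,
         timing = list(pre_interval_s = pre, duration_s = dur, iti_s = iti,
                       stabilization_s = stab)),
    class = "ubd_protocol")
  validate_protocol(proto)
  proto
}

#' Validate protocol invariants
#'
#' Checks time ordering, non-overlap (gap between stimulus offsets and the
#' next pre-interval of at least the ITI), positive windows, and resolvable
#' temperature/isoflurane context on every event.
#' @param protocol a `ubd_protocol`.
#' @return the protocol, invisibly; errors on violation.
#' @export
validate_protocol <- function(protocol) {
  ev <- protocol$events
  stopifnot(is.data.frame(ev), nrow(ev) >= 1)
  if (any(ev$duration_s <= 0) || any(ev$pre_interval_s <= 0))
    stop("durations and pre-intervals must be positive")
  if (any(ev$pressure_mmHg < 0)) stop("pressures must be non-negative")
  if (is.unsorted(ev$onset_s, strictly = TRUE))
    stop("events must be strictly time-ordered")
  start <- ev$onset_s - ev$pre_interval_s
  end   <- ev$onset_s + ev$duration_s
  if (nrow(ev) > 1) {
    gap <- start[-1] - end[-nrow(ev)]
    if (any(gap < ev$iti_s[-nrow(ev)] - 1e-9))
      stop("events overlap or violate the intertrial interval")
  }
  if (anyNA(ev$temp_C) || anyNA(ev$iso_pct))
    stop("every event must carry temperature and isoflurane context")
  invisible(protocol)
}

#' Total event time in a protocol
#'
#' Sum over events of pre-interval + stimulus duration + ITI; stabilization
#' gaps between sets are excluded. One graded set (15 distensions at
#' 20 + 20 + 60 s each) spans 1500 s, consistent with a roughly 30 min set.
#'
#' @param protocol a `ubd_protocol`, or a data.frame of events.
#' @return total seconds (0 for an empty event table).
#' @export
event_duration_total <- function(protocol) {
  ev <- if (inherits(protocol, "ubd_protocol")) protocol$events else protocol
  if (is.null(ev) || nrow(ev) == 0) return(0)
  sum(ev$pre_interval_s + ev$duration_s + ev$iti_s)
}

# Recording length needed to cover the timeline (through the last ITI).
protocol_span_s <- function(protocol) {
  ev <- protocol$events
  max(ev$onset_s + ev$duration_s + ev$iti_s)
}

#' @export
print.ubd_protocol <- function(x, ...) {
  ev <- x$events
  cat("UBD protocol '", x$design, "': ", nrow(ev), " events (",
      sum(ev$is_sensitization), " sensitization), ",
      length(x$sets), " sets, ", x$anesthesia$method,
      " induction, temperatures ",
      paste(unique(ev$temp_C), collapse = "/"), " C\n", sep = "")
  cat("event time ", event_duration_total(x), " s; recording span ",
      protocol_span_s(x), " s\n", sep = "")
  invisible(x)
}

#' Serialize a protocol to JSON
#' @param protocol a `ubd_protocol`.
#' @param path optional file path; if `NULL`, the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
protocol_to_json <- function(protocol, path = NULL) {
  obj <- list(design = protocol$design,
              timing = protocol$timing,
              anesthesia = list(method = protocol$anesthesia$method,
                                steps = protocol$anesthesia$steps,
                                stabilization_min = protocol$anesthesia$stabilization_min,
                                final_pct = protocol$anesthesia$final_pct),
              temperature = list(segments = protocol$temperature$segments,
                                 stabilization_s = protocol$temperature$stabilization_s),
              events = protocol$events)
  js <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Write an event log as CSV
#' @param events event data.frame (or a `ubd_protocol`).
#' @param path output file.
#' @export
write_event_log <- function(events, path) {
  if (inherits(events, "ubd_protocol")) events <- events$events
  write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' Read an event log CSV
#' @param path CSV written by [write_event_log()].
#' @return event data.frame.
#' @export
read_event_log <- function(path) {
  ev <- read.csv(path)
  needed <- c("onset_s", "duration_s", "pressure_mmHg", "pre_interval_s",
              "set_index", "replicate_index", "is_sensitization")
  missing <- setdiff(needed, names(ev))
  if (length(missing))
    stop("event log is missing columns: ", paste(missing, collapse = ", "))
  ev$is_sensitization <- as.logical(ev$is_sensitization)
  ev
}
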