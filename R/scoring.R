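# VMR scoring: per-event background subtraction, rectification, trapezoidal
# integration over the stimulus and pre-distension windows, normalization by
# the smallest pre-distension AUC of the session, and triplicate averaging.

#' Uniformly sampled EMG trace
#'
#' @param samples voltage samples in mV (finite numeric vector).
#' @param sampling_rate Hz, > 0.
#' @param start_time time of the first sample, seconds (default 0).
#' @return object of class `emg_trace`.
#' @export
emg_trace <- function(samples, sampling_rate, start_time = 0) {
  stopifnot(is.numeric(samples), length(samples) >= 2,
            sampling_rate > 0, is.finite(start_time))
  if (!all(is.finite(samples))) stop("samples must be finite")
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate,
                 start_time = start_time),
            class = "emg_trace")
}

#' @export
print.emg_trace <- function(x, ...) {
  cat("EMG trace: ", length(x$samples), " samples at ", x$sampling_rate,
      " Hz (", round(length(x$samples) / x$sampling_rate, 2), " s), sd ",
      signif(sd(x$samples), 3), " mV\n", sep = "")
  invisible(x)
}

# Index range of samples lying in the closed window [start, end].
window_indices <- function(trace, window) {
  fs <- trace$sampling_rate
  eps <- 1e-6 / fs
  start <- window[1]; end <- window[2]
  if (end <= start) stop("window end must exceed start")
  i0 <- ceiling((start - trace$start_time) * fs - eps) + 1
  i1 <- floor((end - trace$start_time) * fs + eps) + 1
  n <- length(trace$samples)
  if (i0 < 1 || i1 > n)
    stop(sprintf("window [%g, %g] lies outside the trace", start, end))
  if (i1 - i0 < 1) stop("window must contain at least two samples")
  c(i0, i1)
}

#' Rectified area under the curve
#'
#' Trapezoidal integral of `|v(t) - background|` over a closed window
#' `[start, end]` at the trace's native sampling; no resampling or
#' filtering. Windows are additive across a shared sample point:
#' `AUC[a, c] = AUC[a, b] + AUC[b, c]`.
#'
#' @param trace an [emg_trace()].
#' @param window numeric `c(start_s, end_s)` within the trace.
#' @param background DC background in mV, subtracted before rectification
#'   (default 0; see [estimate_background()]).
#' @return integral in mV s (non-negative; 0 iff the signal equals the
#'   background throughout the window).
#' @examples
#' tr <- emg_trace(rep(2, 2001), 100)
#' rectified_auc(tr, c(0, 20))  # 40 mV s
#' @export
rectified_auc <- function(trace, window, background = 0) {
  idx <- window_indices(trace, window)
  i <- idx[1]:idx[2]
  tt <- trace$start_time + (i - 1) / trace$sampling_rate
  pracma::trapz(tt, abs(trace$samples[i] - background))
}

#' Estimate DC background from a window
#'
#' Mean voltage over the window, intended for the event's own 20 s
#' pre-distension interval (a DC-offset estimate; for zero-mean EMG noise it
#' shrinks toward 0 as the window grows).
#'
#' @inheritParams rectified_auc
#' @return background estimate in mV.
#' @export
estimate_background <- function(trace, window) {
  idx <- window_indices(trace, window)
  mean(trace$samples[idx[1]:idx[2]])
}

#' Score a session: rectified-integrated VMRs with session-minimum
#' normalization
#'
#' For every distension event, computes the rectified AUC over the 20 s
#' stimulus window and, with the same operator, over the 20 s pre-distension
#' window; the background subtracted before rectification is by default the
#' mean of the event's own pre-distension window. Each stimulus AUC is then
#' divided by the smallest pre-distension AUC among the session's
#' non-sensitization events, and normalized VMRs are averaged over
#' replicates per (set, pressure). Sensitization events (set 0) are scored
#' but excluded from the normalizer and from the table.
#'
#' @param trace an [emg_trace()] covering all events.
#' @param events event data.frame (see [build_protocol()]); must contain at
#'   least one non-sensitization event.
#' @param background `"pre_window"` (per-event DC estimate from the event's
#'   pre-distension window, the default) or `"global"` (whole-trace mean).
#' @param normalizer_scope `"experiment"` (minimum over the whole session,
#'   the default) or `"set"` (per-set minima).
#' @param animal optional animal identifier carried into the outputs.
#' @return list with `records` (one row per event: windows, `stim_auc`,
#'   `pre_auc`, `normalized_vmr`, flags) and `table` (mean normalized VMR
#'   per set x pressure, sensitization excluded), plus `normalizer`.
#' @export
score_experiment <- function(trace, events,
                             background = c("pre_window", "global"),
                             normalizer_scope = c("experiment", "set"),
                             animal = NA) {
  background <- match.arg(background)
  normalizer_scope <- match.arg(normalizer_scope)
  stopifnot(inherits(trace, "emg_trace"), is.data.frame(events),
            nrow(events) >= 1)
  if (!any(!events$is_sensitization))
    stop("no scorable events: all events are flagged as sensitization")
  ev <- events[order(events$onset_s), , drop = FALSE]
  if (nrow(ev) > 1 &&
      any(ev$onset_s[-1] - ev$pre_interval_s[-1] <
          ev$onset_s[-nrow(ev)] + ev$duration_s[-nrow(ev)] - 1e-9))
    stop("events overlap")

  global_bg <- mean(trace$samples)
  n <- nrow(ev)
  stim_auc <- pre_auc <- bg <- numeric(n)
  for (i in seq_len(n)) {
    pre_win  <- c(ev$onset_s[i] - ev$pre_interval_s[i], ev$onset_s[i])
    stim_win <- c(ev$onset_s[i], ev$onset_s[i] + ev$duration_s[i])
    bg[i] <- if (background == "pre_window")
      estimate_background(trace, pre_win) else global_bg
    stim_auc[i] <- rectified_auc(trace, stim_win, bg[i])
    pre_auc[i]  <- rectified_auc(trace, pre_win, bg[i])
  }

  scored <- !ev$is_sensitization
  norm_of <- function(idx, label) {
    m <- min(pre_auc[idx])
    if (m <= .Machine$double.eps) {
      worst <- which(idx)[which.min(pre_auc[idx])]
      stop("degenerate silent baseline: pre-distension AUC is 0 for event ",
           "at onset ", ev$onset_s[worst], " s (set ", ev$set_index[worst],
           ", replicate ", ev$replicate_index[worst], ") in ", label)
    }
    m
  }
  if (normalizer_scope == "experiment") {
    normalizer <- norm_of(scored, "experiment")
    norm_vec <- rep(normalizer, n)
  } else {
    normalizer <- vapply(split(seq_len(n)[scored], ev$set_index[scored]),
                         function(ii) {
                           m <- min(pre_auc[ii]); m
                         }, numeric(1))
    if (any(normalizer <= .Machine$double.eps))
      stop("degenerate silent baseline in at least one set")
    norm_vec <- rep(NA_real_, n)
    norm_vec[scored] <- normalizer[as.character(ev$set_index[scored])]
    norm_vec[!scored] <- min(normalizer)
  }

  records <- data.frame(
    animal = animal,
    onset_s = ev$onset_s, pressure_mmHg = ev$pressure_mmHg,
    set_index = ev$set_index, replicate_index = ev$replicate_index,
    is_sensitization = ev$is_sensitization,
    temp_C = if ("temp_C" %in% names(ev)) ev$temp_C else NA_real_,
    background_mV = bg, stim_auc = stim_auc, pre_auc = pre_auc,
    normalized_vmr = stim_auc / norm_vec)

  sc <- records[!records$is_sensitization, , drop = FALSE]
  if (all(is.na(sc$temp_C))) sc$temp_C <- -1  # placeholder so aggregate keeps rows
  table <- aggregate(normalized_vmr ~ set_index + pressure_mmHg + temp_C,
                     data = sc, FUN = mean)
  counts <- aggregate(normalized_vmr ~ set_index + pressure_mmHg + temp_C,
                      data = sc, FUN = length)
  table$temp_C[table$temp_C == -1] <- NA_real_
  names(table)[names(table) == "normalized_vmr"] <- "mean_vmr"
  table$n_replicates <- counts$normalized_vmr
  if (length(unique(table$n_replicates)) > 1)
    warning("unequal replicate counts across (set, pressure) cells; ",
            "means taken over available replicates")
  table$animal <- animal
  table <- table[order(table$set_index, table$pressure_mmHg),
                 c("animal", "set_index", "pressure_mmHg", "temp_C",
                   "n_replicates", "mean_vmr")]
  rownames(table) <- NULL
  list(records = records, table = table, normalizer = normalizer)
}

#' Score a simulated cohort
#'
#' Applies [score_experiment()] to each animal of a [simulate_cohort()]
#' result (each animal is its own session with its own normalizer) and
#' stacks the outputs.
#'
#' @param cohort list of `(trace, events)` pairs.
#' @param ... passed to [score_experiment()].
#' @return list with pooled `records` and `table` data.frames.
#' @export
score_cohort <- function(cohort, ...) {
  scored <- lapply(cohort, function(a) {
    id <- if (!is.null(a$events$animal)) a$events$animal[1] else NA
    score_experiment(a$trace, a$events, animal = id, ...)
  })
  list(records = do.call(rbind, lapply(scored, `[[`, "records")),
       table   = do.call(rbind, lapply(scored, `[[`, "table")))
}
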