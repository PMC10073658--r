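#' Zeitgeber-time bin grid
#'
#' Bins are aligned to ZT0 (lights-on) and half-open; with the default 6-min
#' bins a 24-h day holds exactly 240 bins. The two 30-min windows of
#' interest each span exactly 5 six-min bins: `end_of_dark` is ZT
#' `[23.5, 24)` (clock 06:30-07:00 under the default schedule) and
#' `end_of_light` is ZT `[11.5, 12)` (18:30-19:00).
#'
#' @param bin_length_min bin length in minutes (default 6).
#' @return Data frame with `bin_start_zt` (hours) and `phase` per bin.
#' @export
zt_bins <- function(bin_length_min = 6) {
  # rounded so bin identities survive a text (CSV) round trip
  starts <- round(seq(0, 24 - bin_length_min / 60, by = bin_length_min / 60), 9)
  data.frame(bin_start_zt = starts, phase = light_phase(starts))
}

#' @rdname zt_bins
#' @param window `"end_of_dark"` or `"end_of_light"`.
#' @return `window_bins()` returns the `bin_start_zt` values of the 5 bins of
#'   the requested window.
#' @export
window_bins <- function(window = c("end_of_dark", "end_of_light"),
                        bin_length_min = 6) {
  window <- match.arg(window)
  lim <- if (window == "end_of_dark") c(23.5, 24) else c(11.5, 12)
  starts <- zt_bins(bin_length_min)$bin_start_zt
  starts[starts >= lim[1] & starts < lim[2]]
}

zt_bin_start <- function(zt, bin_length_min = 6) {
  w <- bin_length_min / 60
  round(floor((zt %% 24) / w) * w, 9)
}

#' Cage-floor distance per zeitgeber-time bin
#'
#' Per mouse, sums the Euclidean displacement between consecutive position
#' fixes, assigning each step to the bin of its starting fix; per cage, sums
#' over mice. Missing fixes simply contribute nothing.
#'
#' @param records activity data frame (see [read_activity()]) with position
#'   rows (`x_mm`, `y_mm`, `mouse_id`).
#' @param schedule a [light_schedule()].
#' @param bin_length_min bin length (default 6 min).
#' @return Data frame: `cage_id`, `day`, `bin_start_zt`, `phase`,
#'   `distance_mm`, one row per cage x day x observed bin.
#' @export
distance_per_bin <- function(records, schedule = light_schedule(),
                             bin_length_min = 6) {
  pos <- records[!is.na(records$x_mm) & !is.na(records$y_mm), , drop = FALSE]
  pieces <- lapply(split(pos, interaction(pos$cage_id, pos$mouse_id, drop = TRUE)),
                   function(g) {
    g <- g[order(g$timestamp), ]
    if (nrow(g) < 2) return(NULL)
    step <- sqrt(diff(g$x_mm)^2 + diff(g$y_mm)^2)
    data.frame(cage_id = g$cage_id[-nrow(g)],
               day = g$day_of_recording[-nrow(g)],
               bin_start_zt = zt_bin_start(zeitgeber_time(g$timestamp[-nrow(g)],
                                                          schedule),
                                           bin_length_min),
               distance_mm = step)
  })
  steps <- do.call(rbind, pieces)
  if (is.null(steps))
    return(data.frame(cage_id = character(), day = integer(),
                      bin_start_zt = numeric(), phase = character(),
                      distance_mm = numeric()))
  out <- aggregate(distance_mm ~ cage_id + day + bin_start_zt, steps, sum)
  out$phase <- light_phase(out$bin_start_zt, schedule)
  out[order(out$cage_id, out$day, out$bin_start_zt),
      c("cage_id", "day", "bin_start_zt", "phase", "distance_mm")]
}

#' Cage climbing seconds per zeitgeber-time bin
#'
#' Anchors a frame-label series to wall-clock time and accumulates climbing
#' seconds per bin: per bin, `climbing_s` is the climbing-frame count times
#' the frame duration. Summed over a full day the bins recover
#' [frames_to_seconds()] of the total climbing-frame count exactly.
#'
#' @param labels 0/1 frame-label series for one cage.
#' @param anchor `POSIXct` wall-clock time of frame 0.
#' @param cage_id,day identifiers for the output rows.
#' @param schedule a [light_schedule()].
#' @param frame_duration_ms frame duration (default 40 ms).
#' @param bin_length_min bin length (default 6 min).
#' @return Data frame: `cage_id`, `day`, `bin_start_zt`, `phase`,
#'   `climbing_s`, one row per bin overlapped by the recording.
#' @export
climbing_per_bin <- function(labels, anchor, cage_id = "cage", day = 1L,
                             schedule = light_schedule(),
                             frame_duration_ms = 40, bin_length_min = 6) {
  n <- length(labels)
  if (n == 0) stop("empty label series")
  t_h <- as.numeric(anchor - trunc(anchor, "days"), units = "hours") +
    (seq_len(n) - 1) * frame_duration_ms / 3.6e6
  zt <- (t_h - schedule$lights_on) %% 24
  bin <- zt_bin_start(zt, bin_length_min)
  counts <- tapply(as.integer(labels), bin, sum)
  out <- data.frame(cage_id = cage_id, day = day,
                    bin_start_zt = as.numeric(names(counts)),
                    climbing_s = frames_to_seconds(as.integer(counts),
                                                   frame_duration_ms))
  out$phase <- light_phase(out$bin_start_zt, schedule)
  out <- out[order(out$bin_start_zt),
             c("cage_id", "day", "bin_start_zt", "phase", "climbing_s")]
  rownames(out) <- NULL
  out
}

#' Mean activity over the 30-min transition windows
#'
#' Averages a binned activity value over the 5 six-min bins of a window of
#' interest, per cage and day. Cages/days missing any of the 5 bins are
#' reported with `NA` (and a warning), never imputed.
#'
#' @param binned data frame with `cage_id`, `day`, `bin_start_zt` and the
#'   value column (e.g. output of [distance_per_bin()], [climbing_per_bin()]
#'   or [generate_activity()]).
#' @param value_col name of the activity column to average.
#' @param window `"end_of_dark"` (ZT 23.5-24, clock 06:30-07:00) or
#'   `"end_of_light"` (ZT 11.5-12, 18:30-19:00).
#' @param bin_length_min bin length (default 6 min).
#' @return Data frame: `cage_id`, `day`, `window`, `mean_activity`, one row
#'   per cage x day.
#' @export
window_means <- function(binned, value_col,
                         window = c("end_of_dark", "end_of_light"),
                         bin_length_min = 6) {
  window <- match.arg(window)
  wb <- window_bins(window, bin_length_min)
  sub <- binned[round(binned$bin_start_zt, 6) %in% round(wb, 6), , drop = FALSE]
  groups <- unique(binned[c("cage_id", "day")])
  out <- lapply(seq_len(nrow(groups)), function(g) {
    rows <- sub[sub$cage_id == groups$cage_id[g] & sub$day == groups$day[g], ]
    v <- if (nrow(rows) == length(wb)) mean(rows[[value_col]]) else NA_real_
    data.frame(cage_id = groups$cage_id[g], day = groups$day[g],
               window = window, mean_activity = v)
  })
  out <- do.call(rbind, out)
  if (anyNA(out$mean_activity))
    warning("missing bins: window mean reported as NA for ",
            sum(is.na(out$mean_activity)), " cage-day(s)", call. = FALSE)
  out[order(out$cage_id, out$day), ]
}

#' Mean activity over a light phase
#'
#' Like [window_means()] but over all bins of the light or dark phase
#' (120 six-min bins each under the 12:12 schedule).
#'
#' @inheritParams window_means
#' @param phase `"light"` or `"dark"`.
#' @return Data frame: `cage_id`, `day`, `phase`, `mean_activity`.
#' @export
phase_means <- function(binned, value_col, phase = c("light", "dark")) {
  phase <- match.arg(phase)
  sub <- binned[binned$phase == phase, , drop = FALSE]
  out <- aggregate(sub[[value_col]],
                   by = list(cage_id = sub$cage_id, day = sub$day),
                   FUN = mean)
  names(out)[3] <- "mean_activity"
  out$phase <- phase
  out[order(out$cage_id, out$day), c("cage_id", "day", "phase", "mean_activity")]
}
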