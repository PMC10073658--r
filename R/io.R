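#' Frame stack container
#'
#' An ordered stack of 8-bit grayscale frames with its frame rate. Frames are
#' stored as an integer array `[height, width, n]` with origin at the top-left
#' pixel; intensities lie in 0..255. Frame indices are 0-based throughout the
#' package, so frame `i` starts at `i * frame_duration_ms` milliseconds. At
#' the default 25 frames/s each frame lasts exactly 40 ms.
#'
#' @param frames integer array of dimension `c(height, width, n_frames)`.
#' @param frame_rate_hz frames per second (default 25).
#' @return An object of class `frame_stack`: a list with elements `frames`,
#'   `frame_rate_hz` and `frame_duration_ms` (`= 1000 / frame_rate_hz`).
#' @export
frame_stack <- function(frames, frame_rate_hz = 25) {
  if (length(dim(frames)) != 3L)
    stop("`frames` must be a 3-d array [height, width, n_frames]")
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0)
    stop("`frame_rate_hz` must be positive")
  storage.mode(frames) <- "integer"
  structure(
    list(frames = frames, frame_rate_hz = frame_rate_hz,
         frame_duration_ms = 1000 / frame_rate_hz),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames of %d x %d px at %g fps (%g ms/frame)\n",
              d[3], d[1], d[2], x$frame_rate_hz, x$frame_duration_ms))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack a [frame_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[3]

#' Rectangular region of interest
#'
#' Pixel offsets are 0-based and inclusive; the region covers columns
#' `x0 .. x0 + width - 1` and rows `y0 .. y0 + height - 1`. The default
#' 690 x 385 px matches the cage-lid region the climbing detector was
#' designed around.
#'
#' @param x0,y0 0-based pixel offsets of the top-left corner.
#' @param width,height region extent in pixels.
#' @return An object of class `roi`.
#' @export
roi <- function(x0 = 0, y0 = 0, width = 690, height = 385) {
  if (width <= 0 || height <= 0) stop("roi width and height must be positive")
  if (x0 < 0 || y0 < 0) stop("roi offsets must be non-negative")
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 width = as.integer(width), height = as.integer(height)),
            class = "roi")
}

#' Crop a frame stack to a region of interest
#' @param stack a [frame_stack()].
#' @param region a [roi()]; `NULL` returns the stack unchanged.
#' @return A `frame_stack` whose frames cover only the region.
#' @export
crop_frames <- function(stack, region) {
  if (is.null(region)) return(stack)
  d <- dim(stack$frames)
  if (region$y0 + region$height > d[1] || region$x0 + region$width > d[2])
    stop("roi extends past the frame bounds")
  frame_stack(stack$frames[region$y0 + seq_len(region$height),
                           region$x0 + seq_len(region$width), , drop = FALSE],
              stack$frame_rate_hz)
}

RAW_STACK_MAGIC <- "CLMB"

#' Read and write raw frame stacks
#'
#' A minimal binary container for grayscale video: a little-endian header
#' (4-byte magic `"CLMB"`, int32 height, width, n_frames, double
#' frame_rate_hz) followed by the frames as unsigned bytes, row-major within
#' each frame. `read_frame_stack()` also accepts a directory of PNG images
#' (lexicographic order defines frame order; colour images are reduced to
#' grayscale by the ITU-R BT.601 luma, 0.299 R + 0.587 G + 0.114 B).
#'
#' @param path file (raw stack) or directory (PNG frames) to read, or file to
#'   write.
#' @param region optional [roi()]; frames are cropped after reading.
#' @param stack a [frame_stack()] to write.
#' @return `read_frame_stack()` returns a `frame_stack`;
#'   `write_frame_stack()` returns `path` invisibly.
#' @export
read_frame_stack <- function(path, region = NULL) {
  if (dir.exists(path)) return(read_frame_dir(path, region))
  if (!file.exists(path)) stop("unreadable file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4))
  if (!identical(magic, RAW_STACK_MAGIC))
    stop("unreadable file: not a raw frame stack (bad magic)")
  h <- readBin(con, "integer", 1, endian = "little")
  w <- readBin(con, "integer", 1, endian = "little")
  n <- readBin(con, "integer", 1, endian = "little")
  rate <- readBin(con, "double", 1, endian = "little")
  px <- readBin(con, "raw", as.numeric(h) * w * n)
  if (length(px) != h * w * n) stop("unreadable file: truncated pixel data")
  frames <- aperm(array(as.integer(px), dim = c(w, h, n)), c(2, 1, 3))
  crop_frames(frame_stack(frames, rate), region)
}

read_frame_dir <- function(path, region) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("reading PNG frame directories requires the 'png' package")
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("unreadable file: no PNG frames in ", path)
  mats <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3)
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    round(img * 255)
  })
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent frame sizes in ", path)
  frames <- array(unlist(mats), dim = c(dims[1, 1], dims[2, 1], length(mats)))
  crop_frames(frame_stack(frames), region)
}

#' @rdname read_frame_stack
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(RAW_STACK_MAGIC), con)
  writeBin(as.integer(d[c(1, 2, 3)]), con, endian = "little")
  writeBin(as.double(stack$frame_rate_hz), con, endian = "little")
  writeBin(as.raw(aperm(stack$frames, c(2, 1, 3))), con)
  invisible(path)
}

BOUT_COLS <- c("segment_id", "annotator_id", "start_frame", "end_frame", "label")

#' Construct and validate a bout table
#'
#' Bout intervals are half-open `[start_frame, end_frame)` on 0-based frame
#' indices; a bout `(0, 10)` covers frames 0..9. Overlapping or touching
#' intervals for the same (segment, annotator, label) are merged, with a
#' warning when actual overlap was present.
#'
#' @param df data frame with columns `segment_id`, `annotator_id`,
#'   `start_frame`, `end_frame`, `label`.
#' @return A normalized bout table (data frame).
#' @export
bout_table <- function(df) {
  miss <- setdiff(BOUT_COLS, names(df))
  if (length(miss)) stop("missing bout table columns: ", paste(miss, collapse = ", "))
  df <- df[BOUT_COLS]
  df$start_frame <- as.integer(df$start_frame)
  df$end_frame <- as.integer(df$end_frame)
  if (any(is.na(df$start_frame)) || any(is.na(df$end_frame)))
    stop("non-integer frame bounds in bout table")
  if (any(df$start_frame < 0)) stop("negative start_frame in bout table")
  if (any(df$start_frame >= df$end_frame))
    stop("empty or inverted bout interval (start_frame >= end_frame)")
  normalize_bouts(df)
}

#' Merge overlapping bout intervals
#'
#' @param df a bout table.
#' @return The table with intervals unioned per (segment, annotator, label),
#'   sorted by segment, annotator, start frame.
#' @export
normalize_bouts <- function(df) {
  if (nrow(df) == 0) return(df)
  key <- interaction(df$segment_id, df$annotator_id, df$label, drop = TRUE)
  pieces <- lapply(split(df, key), function(g) {
    g <- g[order(g$start_frame, g$end_frame), ]
    merged <- interval_union(g$start_frame, g$end_frame)
    if (nrow(merged) < nrow(g))
      warning("merged overlapping bout intervals for annotator ",
              g$annotator_id[1], call. = FALSE)
    data.frame(segment_id = g$segment_id[1], annotator_id = g$annotator_id[1],
               start_frame = merged$start, end_frame = merged$end,
               label = g$label[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$segment_id, out$annotator_id, out$start_frame), ]
  rownames(out) <- NULL
  out
}

# union of half-open intervals; inputs sorted by start
interval_union <- function(start, end) {
  ns <- ne <- integer(0)
  cur_s <- start[1]; cur_e <- end[1]
  for (k in seq_along(start)[-1]) {
    if (start[k] <= cur_e) {
      cur_e <- max(cur_e, end[k])
    } else {
      ns <- c(ns, cur_s); ne <- c(ne, cur_e)
      cur_s <- start[k]; cur_e <- end[k]
    }
  }
  data.frame(start = c(ns, cur_s), end = c(ne, cur_e))
}

#' Read / write bout tables as CSV
#'
#' @param path CSV file with a header naming the five bout columns.
#' @param table a bout table.
#' @return `read_bout_table()` returns a normalized bout table;
#'   `write_bout_table()` returns `path` invisibly.
#' @export
read_bout_table <- function(path) {
  bout_table(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_bout_table
#' @export
write_bout_table <- function(table, path) {
  write.csv(table[BOUT_COLS], path, row.names = FALSE)
  invisible(path)
}

#' Light schedule and zeitgeber time
#'
#' Zeitgeber time (ZT) is hours since lights-on: ZT0 at `lights_on`, ZT12 at
#' `lights_off` under the default 12:12 schedule (light 07:00-19:00). The
#' dark phase is the half-open ZT interval starting at lights-off, so a
#' timestamp exactly at 19:00 is dark.
#'
#' @param lights_on,lights_off times of day as `"HH:MM"` strings.
#' @return `light_schedule()` returns an object of class `light_schedule`.
#' @export
light_schedule <- function(lights_on = "07:00", lights_off = "19:00") {
  on_h <- parse_time_of_day(lights_on)
  off_h <- parse_time_of_day(lights_off)
  if (isTRUE(all.equal(on_h, off_h))) stop("lights_on and lights_off must differ")
  structure(list(lights_on = on_h, lights_off = off_h,
                 light_hours = (off_h - on_h) %% 24),
            class = "light_schedule")
}

parse_time_of_day <- function(x) {
  if (is.numeric(x)) return(x %% 24)
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (length(parts) < 2) stop("time of day must be 'HH:MM'")
  as.numeric(parts[1]) + as.numeric(parts[2]) / 60 +
    if (length(parts) > 2) as.numeric(parts[3]) / 3600 else 0
}

#' @rdname light_schedule
#' @param timestamps `POSIXct` vector (or numeric hours of day).
#' @param schedule a [light_schedule()].
#' @return `zeitgeber_time()` returns hours in `[0, 24)`.
#' @export
zeitgeber_time <- function(timestamps, schedule = light_schedule()) {
  hod <- if (inherits(timestamps, "POSIXt")) {
    lt <- as.POSIXlt(timestamps)
    lt$hour + lt$min / 60 + lt$sec / 3600
  } else {
    as.numeric(timestamps)
  }
  (hod - schedule$lights_on) %% 24
}

#' @rdname light_schedule
#' @param zt zeitgeber times in hours.
#' @return `light_phase()` returns `"light"` or `"dark"` per element; under
#'   the 12:12 default, dark is ZT `[12, 24)`.
#' @export
light_phase <- function(zt, schedule = light_schedule()) {
  ifelse((zt %% 24) < schedule$light_hours, "light", "dark")
}

#' Read an activity table
#'
#' Reads a CSV of per-mouse position fixes and/or per-cage climbing records.
#' Columns: `timestamp` (ISO-8601), `cage_id`, `day_of_recording`, and either
#' the position pair `x_mm`,`y_mm` (with `mouse_id`) or `climbing_s` — exactly
#' one of the two per record. Records are annotated with zeitgeber time and
#' light phase.
#'
#' @param path CSV file.
#' @param schedule a [light_schedule()].
#' @param tz timezone for timestamp parsing (default UTC).
#' @return Data frame with added columns `zt` (hours) and `phase`.
#' @export
read_activity <- function(path, schedule = light_schedule(), tz = "UTC") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "cage_id", "day_of_recording")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing activity columns: ", paste(miss, collapse = ", "))
  ts <- tryCatch(
    as.POSIXct(df$timestamp, tz = tz,
               tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS")),
    error = function(e) NA)
  if (any(is.na(ts))) stop("unparseable timestamps in ", path)
  df$timestamp <- ts
  for (col in c("mouse_id", "x_mm", "y_mm", "climbing_s"))
    if (is.null(df[[col]])) df[[col]] <- NA
  has_pos <- !is.na(df$x_mm) & !is.na(df$y_mm)
  has_climb <- !is.na(df$climbing_s)
  if (any(has_pos == has_climb))
    stop("each activity record must carry exactly one of a position pair or climbing_s")
  if (any(df$climbing_s < 0, na.rm = TRUE)) stop("negative climbing_s")
  for (cage in unique(df$cage_id)) {
    tsc <- df$timestamp[df$cage_id == cage]
    if (is.unsorted(tsc)) stop("non-monotone timestamps within cage ", cage)
  }
  df$zt <- zeitgeber_time(df$timestamp, schedule)
  df$phase <- light_phase(df$zt, schedule)
  df
}
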