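#' Expand bout intervals to a frame-label series
#'
#' @param table a bout table (see [bout_table()]).
#' @param annotator_id,segment_id which annotator's bouts on which segment.
#' @param n_frames length of the label series.
#' @param label bout label to expand (default `"climbing"`; ignored if the
#'   table has no matching rows for other labels).
#' @return Integer 0/1 vector of length `n_frames`; `labels[f + 1] = 1` iff
#'   0-based frame `f` lies inside some bout (half-open intervals).
#' @export
bouts_to_labels <- function(table, annotator_id, segment_id, n_frames,
                            label = "climbing") {
  rows <- table[table$annotator_id == annotator_id &
                table$segment_id == segment_id &
                table$label == label, , drop = FALSE]
  if (nrow(rows) && any(rows$end_frame > n_frames))
    stop("bout exceeds n_frames")
  out <- integer(n_frames)
  for (k in seq_len(nrow(rows)))
    out[(rows$start_frame[k] + 1):rows$end_frame[k]] <- 1L
  out
}

#' Collapse a frame-label series to bout intervals
#'
#' @param labels 0/1 vector.
#' @param segment_id,annotator_id,label identifiers for the output rows.
#' @return A bout table with one row per maximal run of 1s (half-open,
#'   0-based). `bouts_to_labels()` of the result recovers `labels` exactly.
#' @export
labels_to_bouts <- function(labels, segment_id = "seg", annotator_id = "auto",
                            label = "climbing") {
  r <- rle(as.integer(labels))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values == 1L
  nb <- sum(keep)
  data.frame(segment_id = rep(segment_id, nb),
             annotator_id = rep(annotator_id, nb),
             start_frame = starts[keep], end_frame = ends[keep],
             label = rep(label, nb), stringsAsFactors = FALSE)
}

#' Multi-annotator consensus labels
#'
#' Combines per-annotator frame-label series into a single gold standard.
#' Under `"majority"` a frame is climbing iff more than half of the
#' annotators marked it (the gold-standard rule; requires an odd count
#' unless `even_tie` resolves ties). Under `"any"` a frame is climbing iff at
#' least one annotator marked it (the rule used to build training labels, so
#' that no example of climbing is missed).
#'
#' @param series list of equal-length 0/1 vectors, one per annotator.
#' @param rule `"majority"` or `"any"`.
#' @param even_tie with an even annotator count under `"majority"`, how to
#'   resolve exact ties: `"error"` (default), `"nonclimbing"` or
#'   `"climbing"`.
#' @return 0/1 consensus vector. For any annotator set, the `"any"` consensus
#'   dominates the `"majority"` consensus pointwise.
#' @export
consensus <- function(series, rule = c("majority", "any"),
                      even_tie = c("error", "nonclimbing", "climbing")) {
  rule <- match.arg(rule)
  even_tie <- match.arg(even_tie)
  if (length(series) < 1) stop("need at least one annotator")
  n <- length(series[[1]])
  if (any(vapply(series, length, 1L) != n))
    stop("annotator series have mismatched lengths")
  votes <- Reduce(`+`, lapply(series, as.integer))
  m <- length(series)
  if (rule == "any") return(as.integer(votes >= 1))
  if (m %% 2 == 0 && even_tie == "error")
    stop("even annotator count under majority rule requires an explicit even_tie")
  out <- as.integer(votes > m / 2)
  if (m %% 2 == 0 && even_tie == "climbing")
    out[votes == m / 2] <- 1L
  out
}

#' Convert a frame count to seconds
#'
#' Time spent climbing in seconds is `n_frames * frame_duration_ms / 1000`;
#' at the default 40 ms frames this is `n_frames * 40 / 1000`, so 1,000
#' frames are exactly 40 s.
#'
#' @param n_frames non-negative frame count(s).
#' @param frame_duration_ms frame duration (default 40 ms, i.e. 25 fps).
#' @return Seconds.
#' @export
frames_to_seconds <- function(n_frames, frame_duration_ms = 40) {
  if (any(n_frames < 0)) stop("negative frame count")
  n_frames * frame_duration_ms / 1000
}
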