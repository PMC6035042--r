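#' Fluorescence intensity trace at one surface location
#'
#' @param value Numeric fluorescence values, one per frame.
#' @param schedule The [acquisition_schedule()] the trace was recorded on; if
#'   omitted, a plain 1 s-frame schedule covering the trace is assumed.
#' @param missing Logical mask of frames with no data (defaults to the
#'   schedule's red-interleave frames).
#' @param location_id Label of the surface location.
#'
#' @return An `intensity_trace`: tibble with columns `time_s`, `value`,
#'   `missing`.
#' @export
intensity_trace <- function(value, schedule = NULL, missing = NULL,
                            location_id = "loc") {
  if (is.null(schedule)) {
    schedule <- acquisition_schedule(
      frame_duration = 1, green_block_length = length(value),
      red_interleave_length = 0, total_duration = length(value)
    )
  }
  stopifnot(length(value) == schedule$n_frames)
  if (is.null(missing)) missing <- is_red_frame(schedule)
  stopifnot(length(missing) == length(value), is.logical(missing))
  out <- tibble::tibble(
    time_s = frame_start_times(schedule),
    value = as.numeric(value),
    missing = missing
  )
  attr(out, "schedule") <- schedule
  attr(out, "location_id") <- location_id
  class(out) <- c("intensity_trace", class(out))
  out
}

#' Binary presence trace at one surface location
#'
#' @param present Logical vector, one entry per frame; `NA` marks missing
#'   frames (no green-channel data).
#' @param schedule The [acquisition_schedule()].
#' @param location_id Label of the surface location.
#' @return A `presence_trace` object.
#' @export
presence_trace <- function(present, schedule, location_id = "loc") {
  stopifnot(inherits(schedule, "cosmos_schedule"), length(present) == schedule$n_frames)
  structure(
    list(
      location_id = location_id,
      present = as.logical(present),
      schedule = schedule
    ),
    class = "presence_trace"
  )
}

#' @export
print.presence_trace <- function(x, ...) {
  cat(sprintf(
    "<presence_trace> %s: %d frames, %d present, %d missing\n",
    x$location_id, length(x$present),
    sum(x$present, na.rm = TRUE), sum(is.na(x$present))
  ))
  invisible(x)
}

#' Centered sliding-window average of an intensity trace
#'
#' Replaces each value by the mean of the values inside a centered window of
#' `window` frames, skipping missing frames (the mean is taken over the
#' non-missing frames in the window; near the trace edges the window is
#' truncated). The missing-frame mask is left unchanged. The default window
#' of five frames matches standard practice for suppressing frame noise
#' before spot detection.
#'
#' The operation is linear: `sliding_average(a*x + b*y) ==
#' a*sliding_average(x) + b*sliding_average(y)` frame by frame.
#'
#' @param trace An [intensity_trace()].
#' @param window Odd window length in frames (>= 1).
#' @return An `intensity_trace` of the same length.
#' @export
sliding_average <- function(trace, window = 5L) {
  stopifnot(inherits(trace, "intensity_trace"))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("window must be odd and >= 1", call. = FALSE)
  }
  n <- nrow(trace)
  if (window > n) stop("window larger than trace", call. = FALSE)
  if (window == 1L) {
    return(trace)
  }
  half <- window %/% 2L
  v <- ifelse(trace$missing, 0, trace$value)
  w <- as.numeric(!trace$missing)
  # running sums via padded cumulative sums
  cs_v <- cumsum(c(0, v))
  cs_w <- cumsum(c(0, w))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  sums <- cs_v[hi + 1L] - cs_v[lo]
  cnts <- cs_w[hi + 1L] - cs_w[lo]
  avg <- ifelse(cnts > 0, sums / cnts, NA_real_)
  out <- trace
  out$value <- avg
  out
}

#' Binarize an intensity trace with hysteresis thresholds
#'
#' Two-level (Schmitt-trigger) thresholding: the trace switches *on* when the
#' value reaches `on_level` and back *off* only when it falls below
#' `off_level`. Using `on_level > off_level` makes the binarization robust to
#' flicker around a single threshold. The state is carried across missing
#' frames; a missing frame is then reported with the state its observed
#' neighbors agree on, or absent when they disagree.
#'
#' @param trace An [intensity_trace()].
#' @param on_level Threshold to switch on (value >= on_level).
#' @param off_level Threshold to switch off (value < off_level); must be
#'   <= `on_level`.
#' @return A [presence_trace()].
#' @export
threshold_trace <- function(trace, on_level, off_level = on_level) {
  stopifnot(inherits(trace, "intensity_trace"), on_level >= off_level)
  n <- nrow(trace)
  present <- rep(NA, n)
  state <- FALSE
  for (i in seq_len(n)) {
    if (trace$missing[i]) next
    v <- trace$value[i]
    state <- if (state) v >= off_level else v >= on_level
    present[i] <- state
  }
  # resolve missing frames: inherit the state both observed neighbors agree
  # on, otherwise absent
  miss <- which(is.na(present) & trace$missing)
  obs <- which(!trace$missing)
  for (i in miss) {
    before <- obs[obs < i]
    after <- obs[obs > i]
    prev_state <- if (length(before)) present[max(before)] else NA
    next_state <- if (length(after)) present[min(after)] else NA
    present[i] <- isTRUE(prev_state) && isTRUE(next_state)
  }
  sched <- attr(trace, "schedule")
  presence_trace(present, sched, location_id = attr(trace, "location_id"))
}
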