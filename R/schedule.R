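#' Acquisition schedule for alternating-excitation imaging
#'
#' Describes the frame timing of a CoSMoS movie in which blocks of
#' green-excitation frames (the channel reporting labeled subcomplex binding)
#' alternate with short red-excitation blocks used to re-locate the tethered
#' RNA molecules. The default reproduces the standard design: one-second
#' frames, 100 green frames followed by a single red frame, for a total of
#' 2,400 s.
#'
#' Frames are numbered 1..`n_frames`; frame `i` covers the half-open time
#' window `[(i-1)*frame_duration, i*frame_duration)`. Red-interleave frames
#' carry no green-channel data and are treated downstream as *missing*, not as
#' absence of binding.
#'
#' @param frame_duration Frame length in seconds.
#' @param green_block_length Number of consecutive green frames per cycle.
#' @param red_interleave_length Number of red frames inserted after each green
#'   block.
#' @param total_duration Total experiment duration in seconds; must be a whole
#'   number of frames.
#'
#' @return An object of class `cosmos_schedule`.
#' @export
#' @examples
#' sched <- acquisition_schedule()
#' sum(is_red_frame(sched))  # 23 red frames in 2,400 s
acquisition_schedule <- function(frame_duration = 1,
                                 green_block_length = 100,
                                 red_interleave_length = 1,
                                 total_duration = 2400) {
  stopifnot(
    frame_duration > 0,
    green_block_length >= 1,
    red_interleave_length >= 0,
    total_duration > 0
  )
  n_frames <- total_duration / frame_duration
  if (abs(n_frames - round(n_frames)) > 1e-9) {
    stop("total_duration must be a whole number of frames", call. = FALSE)
  }
  structure(
    list(
      frame_duration = frame_duration,
      green_block_length = as.integer(green_block_length),
      red_interleave_length = as.integer(red_interleave_length),
      total_duration = total_duration,
      n_frames = as.integer(round(n_frames))
    ),
    class = "cosmos_schedule"
  )
}

#' @export
print.cosmos_schedule <- function(x, ...) {
  cat(sprintf(
    "<cosmos_schedule> %g s frames, %d green + %d red per cycle, %g s total (%d frames)\n",
    x$frame_duration, x$green_block_length, x$red_interleave_length,
    x$total_duration, x$n_frames
  ))
  invisible(x)
}

#' Which frames are red-interleave (missing green data)?
#'
#' @param schedule A [acquisition_schedule()] object.
#' @return Logical vector of length `schedule$n_frames`.
#' @export
is_red_frame <- function(schedule) {
  stopifnot(inherits(schedule, "cosmos_schedule"))
  cyc <- schedule$green_block_length + schedule$red_interleave_length
  ((seq_len(schedule$n_frames) - 1L) %% cyc) >= schedule$green_block_length
}

#' Frame start times in seconds
#' @param schedule A [acquisition_schedule()] object.
#' @return Numeric vector of frame start times.
#' @export
frame_start_times <- function(schedule) {
  stopifnot(inherits(schedule, "cosmos_schedule"))
  (seq_len(schedule$n_frames) - 1) * schedule$frame_duration
}

# Cumulative green-excitation exposure (s) accrued by wall time t.
# Photobleaching clocks run on this scale, not on wall time.
green_exposure_at <- function(schedule, t) {
  fd <- schedule$frame_duration
  g_s <- schedule$green_block_length * fd
  cyc_s <- (schedule$green_block_length + schedule$red_interleave_length) * fd
  t <- pmin(pmax(t, 0), schedule$total_duration)
  nc <- floor(t / cyc_s)
  rem <- t - nc * cyc_s
  nc * g_s + pmin(rem, g_s)
}

# Wall time at which `exposure` additional seconds of green excitation have
# accrued, starting from wall time t0. Inf if the experiment ends first.
green_to_wall <- function(schedule, t0, exposure) {
  fd <- schedule$frame_duration
  g_s <- schedule$green_block_length * fd
  cyc_s <- (schedule$green_block_length + schedule$red_interleave_length) * fd
  target <- green_exposure_at(schedule, t0) + exposure
  total_green <- green_exposure_at(schedule, schedule$total_duration)
  if (target >= total_green) {
    return(Inf)
  }
  nc <- floor(target / g_s)
  rem <- target - nc * g_s
  if (rem == 0 && nc > 0) {
    (nc - 1) * cyc_s + g_s
  } else {
    nc * cyc_s + rem
  }
}
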