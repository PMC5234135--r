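#' Acquisition frame schedule
#'
#' A frame schedule holds the start and end times (in minutes) of each
#' reconstructed frame of a dynamic PET acquisition. Frames must be
#' non-overlapping and strictly ordered; gaps are permitted.
#'
#' @param frame_start numeric vector of frame start times, minutes.
#' @param frame_end numeric vector of frame end times, minutes.
#' @return An object of class `frame_schedule` with fields `frame_start`,
#'   `frame_end` and derived `mid` (frame mid-times, minutes).
#' @examples
#' sch <- frame_schedule(c(0, 1, 2), c(1, 2, 4))
#' sch$mid
#' @export
frame_schedule <- function(frame_start, frame_end) {
  frame_start <- as.numeric(frame_start)
  frame_end <- as.numeric(frame_end)
  if (length(frame_start) != length(frame_end)) {
    stop("frame_start and frame_end must have equal length", call. = FALSE)
  }
  if (length(frame_start) == 0L) stop("schedule must contain at least one frame", call. = FALSE)
  if (any(!is.finite(frame_start)) || any(!is.finite(frame_end))) {
    stop("frame times must be finite", call. = FALSE)
  }
  if (any(diff(frame_start) <= 0)) {
    stop("frame starts must be strictly increasing", call. = FALSE)
  }
  if (any(frame_end <= frame_start)) {
    stop("each frame_end must exceed its frame_start", call. = FALSE)
  }
  n <- length(frame_start)
  if (n > 1L && any(frame_start[-1] < frame_end[-n] - 1e-9)) {
    stop("frames must not overlap", call. = FALSE)
  }
  structure(
    list(
      frame_start = frame_start,
      frame_end = frame_end,
      mid = (frame_start + frame_end) / 2
    ),
    class = "frame_schedule"
  )
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf(
    "<frame_schedule> %d frames, %.2f-%.2f min\n",
    n_frames(x), x$frame_start[1], x$frame_end[n_frames(x)]
  ))
  invisible(x)
}

#' Number of frames in a schedule
#' @param schedule a [frame_schedule()].
#' @return Integer frame count.
#' @export
n_frames <- function(schedule) length(schedule$frame_start)

#' Frame durations in minutes
#' @param schedule a [frame_schedule()].
#' @return Numeric vector of frame durations, minutes.
#' @export
frame_durations <- function(schedule) schedule$frame_end - schedule$frame_start

#' Default FEPPA dynamic acquisition schedule
#'
#' The standard 125-min [18F]-FEPPA HRRT acquisition reconstructed into 34
#' frames: one initial frame of variable length (until activity appears in
#' the field of view), then 5 x 30 s, 1 x 45 s, 2 x 60 s, 1 x 90 s,
#' 1 x 120 s, 1 x 210 s and 22 x 300 s. The fixed frame durations sum to
#' 7335 s. The initial frame length is not standardised and defaults to 30 s.
#'
#' @param initial_s duration of the initial variable-length frame, seconds.
#' @return A [frame_schedule()] of 34 frames starting at 0 min.
#' @examples
#' sch <- feppa_frame_schedule()
#' n_frames(sch)
#' sum(frame_durations(sch)[-1]) * 60  # 7335 s
#' @export
feppa_frame_schedule <- function(initial_s = 30) {
  if (!is.numeric(initial_s) || length(initial_s) != 1L || initial_s <= 0) {
    stop("initial_s must be a positive scalar", call. = FALSE)
  }
  dur_s <- c(initial_s, rep(30, 5), 45, rep(60, 2), 90, 120, 210, rep(300, 22))
  ends <- cumsum(dur_s) / 60
  frame_schedule(c(0, ends[-length(ends)]), ends)
}

schedules_equal <- function(a, b, tol = 1e-9) {
  n_frames(a) == n_frames(b) &&
    max(abs(a$frame_start - b$frame_start)) <= tol &&
    max(abs(a$frame_end - b$frame_end)) <= tol
}
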