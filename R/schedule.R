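#' Build a contiguous dynamic-PET frame schedule
#'
#' A dynamic acquisition is reconstructed into consecutive frames of varying
#' duration (short frames early, when the tracer bolus changes quickly; long
#' frames late). The schedule is specified the way scanner protocols are
#' written: an ordered list of (count, duration) blocks.
#'
#' @param spec list of length-2 numeric vectors `c(count, duration_s)`,
#'   in acquisition order.
#' @return An object of class `frame_schedule` with elements `starts` and
#'   `durations`, both in seconds. Frames are contiguous and start at t = 0.
#' @examples
#' sched <- frame_schedule(list(c(6, 10), c(8, 30), c(5, 60), c(5, 120), c(8, 300)))
#' n_frames(sched)          # 32
#' total_duration(sched)    # 3600 s
#' @export
frame_schedule <- function(spec) {
  if (length(spec) == 0L) stop("frame specification is empty")
  counts <- vapply(spec, function(x) x[[1]], numeric(1))
  durs <- vapply(spec, function(x) x[[2]], numeric(1))
  if (any(counts < 1) || any(counts != round(counts)))
    stop("frame counts must be positive integers")
  if (any(durs <= 0)) stop("frame durations must be positive")
  durations <- rep(durs, counts)
  starts <- cumsum(c(0, durations[-length(durations)]))
  new_frame_schedule(starts, durations)
}

new_frame_schedule <- function(starts, durations) {
  stopifnot(length(starts) == length(durations))
  if (any(durations <= 0)) stop("frame durations must be positive")
  if (length(starts) > 1) {
    if (any(diff(starts) <= 0)) stop("frame starts must be strictly increasing")
    gap <- starts[-1] - (starts[-length(starts)] + durations[-length(durations)])
    if (any(abs(gap) > 1e-9)) stop("frames must be contiguous")
  }
  if (abs(starts[1]) > 1e-9) stop("schedule must start at t = 0")
  structure(list(starts = as.numeric(starts), durations = as.numeric(durations)),
            class = "frame_schedule")
}

#' The 60-min 32-frame acquisition schedule
#'
#' Six 10-s, eight 30-s, five 1-min, five 2-min and eight 5-min frames:
#' the standard one-hour dynamic TSPO protocol this package targets.
#' @return A [frame_schedule] of 32 frames totalling 3600 s.
#' @export
dpa_frame_schedule <- function() {
  frame_schedule(list(c(6, 10), c(8, 30), c(5, 60), c(5, 120), c(8, 300)))
}

#' @rdname frame_schedule
#' @param x a `frame_schedule`
#' @export
n_frames <- function(x) length(x$starts)

#' @rdname frame_schedule
#' @export
total_duration <- function(x) sum(x$durations)

#' Frame mid-times in seconds (or minutes)
#' @param x a `frame_schedule`
#' @param unit `"s"` or `"min"`
#' @export
frame_mid <- function(x, unit = c("s", "min")) {
  unit <- match.arg(unit)
  m <- x$starts + x$durations / 2
  if (unit == "min") m / 60 else m
}

frame_end <- function(x) x$starts + x$durations

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule> %d frames, %.0f s total (%.1f min)\n",
              n_frames(x), total_duration(x), total_duration(x) / 60))
  invisible(x)
}

schedules_equal <- function(a, b, tol = 1e-9) {
  n_frames(a) == n_frames(b) &&
    max(abs(a$starts - b$starts)) < tol &&
    max(abs(a$durations - b$durations)) < tol
}

#' Uniform fine time grid spanning a schedule
#'
#' Kinetic simulation and basis-function convolution run on a fine uniform
#' grid (default 1 s) which is then averaged over frames.
#' @param schedule a [frame_schedule]
#' @param dt_s grid step, seconds
#' @return numeric vector of times in seconds, starting at 0
#' @export
fine_times <- function(schedule, dt_s = 1) {
  seq(0, total_duration(schedule), by = dt_s)
}

#' Frame-averaging weight matrix
#'
#' Returns W (n_frames x n_fine) such that `W %*% v` is the trapezoidal
#' average of a fine-grid curve `v` over each frame. Frame boundaries must
#' lie on the fine grid.
#' @keywords internal
frame_weights <- function(schedule, t_fine) {
  dt <- t_fine[2] - t_fine[1]
  nf <- n_frames(schedule)
  W <- matrix(0, nf, length(t_fine))
  ends <- frame_end(schedule)
  for (f in seq_len(nf)) {
    i0 <- which.min(abs(t_fine - schedule$starts[f]))
    i1 <- which.min(abs(t_fine - ends[f]))
    if (abs(t_fine[i0] - schedule$starts[f]) > 1e-6 ||
        abs(t_fine[i1] - ends[f]) > 1e-6)
      stop("frame boundaries must lie on the fine time grid")
    w <- rep(dt, i1 - i0 + 1)
    w[1] <- dt / 2
    w[length(w)] <- dt / 2
    W[f, i0:i1] <- w / schedule$durations[f]
  }
  W
}

#' Average a fine-grid curve over the frames of a schedule
#' @param v fine-grid values (vector or matrix with time in rows)
#' @param schedule a [frame_schedule]
#' @param t_fine time grid matching `v`
#' @return per-frame averages (vector, or matrix n_frames x ncol(v))
#' @export
frame_average <- function(v, schedule, t_fine) {
  W <- frame_weights(schedule, t_fine)
  if (is.matrix(v)) W %*% v else as.vector(W %*% v)
}
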