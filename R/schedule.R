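#' Canonical 22-hour assay schedule
#'
#' Builds the timeline of the homecage assay: a 6 h daytime phase (white
#' background), a 6 h nighttime phase (red background), a 6 h nighttime phase
#' during which three visual stimuli are presented (a rotating moth and two
#' sets of moving lines, 2 h apart), and a closing 4 h daytime phase.  The
#' assay is summarized in 10-minute "periods" (132 of them at full scale);
#' periods are indexed 1-based, so the first stimulus onset at elapsed 12 h
#' opens period 73.
#'
#' @param frame_interval seconds between frames (default 1 s).
#' @param scale multiplicative time scale; `scale = 1` is the full 22 h assay.
#'   Smaller values shrink every phase, onset and period proportionally and
#'   are intended for fast tests and examples.
#' @return an object of class `assay_schedule`: a list with `total_duration`
#'   (s), `phases` (data.frame: label, start_s, end_s), `stimulus_onsets`
#'   (data.frame: label, onset_s), `period_length` (s), `n_periods`,
#'   and `frame_interval`.
#' @examples
#' sch <- make_schedule()
#' sch$total_duration  # 79200
#' sch$n_periods       # 132
#' @export
make_schedule <- function(frame_interval = 1, scale = 1) {
  stopifnot(frame_interval > 0, scale > 0)
  h <- 3600 * scale
  phases <- data.frame(
    label   = c("day1", "night1", "night_stim", "day2"),
    start_s = c(0, 6, 12, 18) * h,
    end_s   = c(6, 12, 18, 22) * h,
    stringsAsFactors = FALSE
  )
  onsets <- data.frame(
    label   = c("moth", "lines1", "lines2"),
    onset_s = c(12, 14, 16) * h,
    stringsAsFactors = FALSE
  )
  out <- list(
    total_duration  = 22 * h,
    phases          = phases,
    stimulus_onsets = onsets,
    period_length   = 600 * scale,
    n_periods       = 132L,
    frame_interval  = frame_interval,
    scale           = scale
  )
  class(out) <- "assay_schedule"
  out
}

#' @export
print.assay_schedule <- function(x, ...) {
  cat("assay_schedule:", x$total_duration, "s,",
      nrow(x$phases), "phases,", x$n_periods, "periods of",
      x$period_length, "s\n")
  invisible(x)
}

#' Frame timestamps of a schedule
#'
#' @param schedule an `assay_schedule`.
#' @return numeric vector of frame start times, one per frame interval.
#' @export
schedule_times <- function(schedule) {
  seq(0, schedule$total_duration - schedule$frame_interval,
      by = schedule$frame_interval)
}

#' Phase label at given times
#'
#' @param schedule an `assay_schedule`.
#' @param time_s numeric vector of times in seconds.
#' @return character vector of phase labels.
#' @export
phase_at <- function(schedule, time_s) {
  ph <- schedule$phases
  idx <- findInterval(time_s, ph$start_s)
  idx[time_s < 0 | time_s >= schedule$total_duration] <- NA_integer_
  ph$label[idx]
}

#' Time window of a 10-minute period
#'
#' Periods are 1-based 10-minute bins of the assay; period 73 starts at
#' elapsed 12 h and covers the first stimulus presentation.
#'
#' @param schedule an `assay_schedule`.
#' @param period integer period id in `1:schedule$n_periods`.
#' @return numeric `c(start_s, end_s)`, end exclusive.
#' @export
period_window <- function(schedule, period) {
  stopifnot(period >= 1, period <= schedule$n_periods)
  c((period - 1) * schedule$period_length, period * schedule$period_length)
}

#' Whether times fall during night phases
#' @param schedule an `assay_schedule`.
#' @param time_s numeric vector of times.
#' @return logical vector.
#' @export
is_night <- function(schedule, time_s) {
  phase_at(schedule, time_s) %in% c("night1", "night_stim")
}
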