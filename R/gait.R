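#' Construct a gait run from a footfall event log
#'
#' @param events data.frame of footfall events (one row per paw contact;
#'   columns paw, contact_start_s, contact_end_s, x, y and the per-print
#'   geometry/intensity fields).
#' @param run_start_s,run_end_s run bounds (default: first contact start
#'   to last contact end).
#' @return a `gait_run` object.
#' @export
gait_run <- function(events, run_start_s = NULL, run_end_s = NULL) {
  stopifnot(nrow(events) > 0,
            all(c("paw", "contact_start_s", "contact_end_s", "x", "y")
                %in% names(events)))
  if (any(events$contact_end_s <= events$contact_start_s))
    stop("contact_end_s must exceed contact_start_s")
  events <- events[order(events$contact_start_s), , drop = FALSE]
  rownames(events) <- NULL
  dx <- diff(events$x)
  direction <- if (sum(dx) >= 0) 1L else -1L
  out <- list(events = events,
              direction = direction,
              run_start_s = run_start_s %||% min(events$contact_start_s),
              run_end_s = run_end_s %||% max(events$contact_end_s))
  class(out) <- "gait_run"
  out
}

#' @export
print.gait_run <- function(x, ...) {
  cat("gait_run:", nrow(x$events), "footfalls,",
      round(x$run_end_s - x$run_start_s, 3), "s\n")
  invisible(x)
}

#' Run compliance check
#'
#' A compliant run is a one-directional walk across the walkway
#' completed in under 10 seconds.  Direction reversals beyond a small
#' backtrack tolerance, or a duration of 10 s or more, make the run
#' non-compliant.
#'
#' @param run a [gait_run()].
#' @param max_duration_s compliance limit (default 10 s).
#' @param backtrack_tol tolerated backward progression between
#'   consecutive steps, as a fraction of the total span.
#' @return logical; attribute `reasons` lists the failed checks.
#' @export
validate_run <- function(run, max_duration_s = 10, backtrack_tol = 0.05) {
  if (nrow(run$events) == 0) stop("empty run")
  reasons <- character(0)
  dur <- run$run_end_s - run$run_start_s
  if (dur >= max_duration_s)
    reasons <- c(reasons, sprintf("duration %.2f s >= %g s", dur, max_duration_s))
  prog <- run$direction * run$events$x
  span <- max(prog) - min(prog)
  if (span <= 0) {
    reasons <- c(reasons, "no progression along the walkway")
  } else if (any(diff(prog) < -backtrack_tol * span)) {
    reasons <- c(reasons, "direction reversal mid-run")
  }
  structure(length(reasons) == 0, reasons = reasons)
}

#' Per-paw timing parameters
#'
#' Stand: mean contact duration of the paw.  Step cycle: mean time
#' between two consecutive initial contacts of the paw.  Swing: step
#' cycle minus stand.
#'
#' @param run a [gait_run()].
#' @param paw one of "RF", "LF", "RH", "LH".
#' @return named numeric: stand, step_cycle, swing (step_cycle and swing
#'   NA with fewer than two contacts).
#' @export
paw_timing <- function(run, paw) {
  ev <- run$events[run$events$paw == paw, ]
  if (nrow(ev) == 0)
    return(c(stand = NA_real_, step_cycle = NA_real_, swing = NA_real_))
  stand <- mean(ev$contact_end_s - ev$contact_start_s)
  sc <- if (nrow(ev) >= 2) mean(diff(ev$contact_start_s)) else NA_real_
  c(stand = stand, step_cycle = sc, swing = sc - stand)
}

#' Whole-run step statistics
#'
#' @param run a compliant [gait_run()].
#' @param duration_from "steps" (first to last contact start; default) or
#'   "run" (the run bounds).
#' @return named numeric: duration, number_of_steps, cadence.  The
#'   alternative duration convention is attached as attribute.
#' @export
run_stats <- function(run, duration_from = c("steps", "run")) {
  duration_from <- match.arg(duration_from)
  ev <- run$events
  d_steps <- max(ev$contact_start_s) - min(ev$contact_start_s)
  d_run <- run$run_end_s - run$run_start_s
  dur <- if (duration_from == "steps") d_steps else d_run
  if (dur <= 0) stop("zero-duration run")
  out <- c(duration = dur, number_of_steps = nrow(ev),
           cadence = nrow(ev) / dur)
  attr(out, "duration_run_bounds") <- d_run
  out
}

# paw-combination class of a contact set
.support_class <- function(paws) {
  k <- length(paws)
  if (k == 0) return("zero")
  if (k == 1) return("single")
  if (k == 3) return("three")
  if (k == 4) return("four")
  s <- paste(sort(paws), collapse = "-")
  if (s %in% c("LF-RF", "LH-RH")) return("girdle")
  if (s %in% c("RF-RH", "LF-LH")) return("lateral")
  if (s %in% c("LH-RF", "LF-RH")) return("diagonal")
  stop("unclassifiable paw set: ", s)
}

#' Support percentages
#'
#' Partitions the run window by the set of paws simultaneously in
#' contact with the walkway and reports the share of run time in each
#' class: zero, single, diagonal (RF-LH or LF-RH), girdle (RF-LF or
#' RH-LH), lateral (RF-RH or LF-LH), three and four paws.
#'
#' @param run a [gait_run()].
#' @return named percentages summing to 100.
#' @export
support_percentages <- function(run) {
  ev <- run$events
  t0 <- run$run_start_s; t1 <- run$run_end_s
  cuts <- sort(unique(c(t0, t1,
                        ev$contact_start_s[ev$contact_start_s > t0 & ev$contact_start_s < t1],
                        ev$contact_end_s[ev$contact_end_s > t0 & ev$contact_end_s < t1])))
  classes <- c("zero", "single", "diagonal", "girdle", "lateral", "three", "four")
  acc <- stats::setNames(numeric(length(classes)), classes)
  for (k in seq_len(length(cuts) - 1)) {
    mid <- (cuts[k] + cuts[k + 1]) / 2
    down <- unique(ev$paw[ev$contact_start_s <= mid & ev$contact_end_s > mid])
    cl <- .support_class(down)
    acc[cl] <- acc[cl] + (cuts[k + 1] - cuts[k])
  }
  100 * acc / (t1 - t0)
}

# all cyclic rotations of the six normal step sequence patterns
.nssp_windows <- function() {
  rot <- function(p) lapply(0:3, function(k)
    p[((seq_len(4) - 1 + k) %% 4) + 1])
  u <- unique(unlist(lapply(NSSP_PATTERNS, function(p)
    vapply(rot(p), paste, character(1), collapse = "-")), use.names = FALSE))
  u
}

#' Percentage of steps in a normal step sequence pattern
#'
#' Scans the paw-order sequence in sliding windows of four steps; a
#' window is normal when it matches one of the six normal step sequence
#' patterns (cruciate Ca/Cb, alternate Aa/Ab, rotary Ra/Rb) under cyclic
#' continuation.  Returns 100 x normal windows / total windows.  A
#' duration-weighted variant (windows weighted by the time spanned by
#' their four steps) is attached as attribute `time_weighted`.
#'
#' @param run a [gait_run()].
#' @return percentage in [0, 100]; NA with fewer than 4 steps.
#' @export
step_sequence_nssp <- function(run) {
  ev <- run$events
  n <- nrow(ev)
  if (n < 4) return(NA_real_)
  normal <- .nssp_windows()
  w <- vapply(seq_len(n - 3), function(i)
    paste(ev$paw[i:(i + 3)], collapse = "-") %in% normal, logical(1))
  dt <- vapply(seq_len(n - 3), function(i)
    ev$contact_start_s[i + 3] - ev$contact_start_s[i], numeric(1))
  out <- 100 * mean(w)
  attr(out, "time_weighted") <-
    if (sum(dt) > 0) 100 * sum(dt[w]) / sum(dt) else out
  out
}

#' Base of support
#'
#' Mean absolute lateral (y) separation between successive left/right
#' placements of the front or the hind paw pair.
#'
#' @param run a [gait_run()].
#' @param pair "front" or "hind".
#' @return mean width in walkway length units; NA if a paw of the pair
#'   never touches down.
#' @export
base_of_support <- function(run, pair = c("front", "hind")) {
  pair <- match.arg(pair)
  paws <- if (pair == "front") c("LF", "RF") else c("LH", "RH")
  ev <- run$events[run$events$paw %in% paws, ]
  if (!all(paws %in% ev$paw)) return(NA_real_)
  left <- ev[substr(ev$paw, 1, 1) == "L", ]
  right <- ev[substr(ev$paw, 1, 1) == "R", ]
  # pair each left placement with the nearest-in-time right placement
  j <- vapply(left$contact_start_s, function(t)
    which.min(abs(right$contact_start_s - t)), integer(1))
  mean(abs(left$y - right$y[j]))
}

#' Paw angle relative to the body axis
#'
#' Signed acute angle between each print's orientation and the
#' instantaneous body axis, estimated as the local direction of travel
#' (the chord through the neighbouring footfall positions).  Reported in
#' degrees in (-90, 90].
#'
#' @param run a [gait_run()].
#' @return numeric vector, one angle per footfall event (requires a
#'   `print_orientation` column in degrees).
#' @export
paw_angle_body_axis <- function(run) {
  ev <- run$events
  n <- nrow(ev)
  if (!"print_orientation" %in% names(ev))
    stop("events carry no print_orientation")
  i0 <- pmax(1, seq_len(n) - 1); i1 <- pmin(n, seq_len(n) + 1)
  axis <- atan2(ev$y[i1] - ev$y[i0], ev$x[i1] - ev$x[i0]) * 180 / pi
  a <- ev$print_orientation - axis
  a <- ((a + 90) %% 180) - 90
  a[a == -90] <- 90
  a
}

# the per-run scalar gait parameters
.run_gait_params <- function(run) {
  rs <- run_stats(run)
  sup <- support_percentages(run)
  nssp <- step_sequence_nssp(run)
  angles <- if ("print_orientation" %in% names(run$events))
    paw_angle_body_axis(run) else rep(NA_real_, nrow(run$events))
  paw_fields <- c("print_length", "toe_spread", "intermediate_toe_spread",
                  "print_area", "max_contact_area", "mean_intensity",
                  "min_intensity")
  per_paw <- unlist(lapply(c("RF", "LF", "RH", "LH"), function(p) {
    sel <- run$events$paw == p
    tim <- paw_timing(run, p)
    geo <- vapply(paw_fields, function(f)
      if (f %in% names(run$events) && any(sel))
        mean(run$events[[f]][sel], na.rm = TRUE) else NA_real_, numeric(1))
    ang <- if (any(sel)) mean(angles[sel], na.rm = TRUE) else NA_real_
    stats::setNames(c(tim, geo, paw_angle_body_axis = ang),
                    paste0(p, ".", c(names(tim), paw_fields,
                                     "paw_angle_body_axis")))
  }))
  c(duration = unname(rs["duration"]),
    number_of_steps = unname(rs["number_of_steps"]),
    cadence = unname(rs["cadence"]),
    nssp = as.numeric(nssp),
    nssp_time_weighted = attr(nssp, "time_weighted") %||% NA_real_,
    stats::setNames(as.numeric(sup), paste0("support.", names(sup))),
    base_of_support.front = base_of_support(run, "front"),
    base_of_support.hind = base_of_support(run, "hind"),
    per_paw)
}

#' Per-animal gait parameter table
#'
#' Validates each animal's runs, drops non-compliant ones, and averages
#' every gait parameter over the remaining runs.  Animals with fewer
#' than `min_runs` compliant runs are excluded (and reported in the
#' `excluded` attribute).
#'
#' @param runs named list: one list of [gait_run()]s per animal.
#' @param min_runs minimum compliant runs per animal (default 3).
#' @return data.frame, one row per retained animal, with an `animal`
#'   column followed by the gait parameters.
#' @export
gait_table <- function(runs, min_runs = 3) {
  rows <- list(); excluded <- character(0)
  for (an in names(runs)) {
    ok <- Filter(function(r) isTRUE(validate_run(r)), runs[[an]])
    if (length(ok) < min_runs) { excluded <- c(excluded, an); next }
    mat <- do.call(rbind, lapply(ok, .run_gait_params))
    rows[[an]] <- colMeans(mat, na.rm = TRUE)
  }
  if (!length(rows)) {
    out <- data.frame(animal = character(0))
  } else {
    out <- data.frame(animal = names(rows),
                      do.call(rbind, rows), check.names = FALSE,
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
  }
  attr(out, "excluded") <- excluded
  out
}
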