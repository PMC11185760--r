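#' Filter a pose track by keypoint likelihood
#'
#' Marks keypoint samples with likelihood strictly below the threshold as
#' invalid; invalid samples are excluded from all downstream statistics.
#' Coordinates are left untouched.  The boundary value (likelihood equal
#' to the threshold) is kept.
#'
#' @param pose a `pose_track`.
#' @param threshold likelihood cutoff in [0, 1] (default 0.90).
#' @return the pose track with a `valid` logical column added to every
#'   part.
#' @export
filter_pose <- function(pose, threshold = 0.90) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  pose$parts <- lapply(pose$parts, function(p) {
    p$valid <- p$likelihood >= threshold
    p
  })
  pose$likelihood_threshold <- threshold
  pose
}

#' Per-second speed series
#'
#' Euclidean displacement between consecutive valid samples divided by
#' their time gap.  Undefined (NA) wherever either endpoint is invalid.
#' The first sample is undefined by construction.
#'
#' @param x,y coordinate vectors.
#' @param time_s timestamps.
#' @param valid logical validity per sample (default all valid, with NA
#'   coordinates treated as invalid).
#' @return numeric speed vector (px/s), same length as `x`.
#' @export
speed_series <- function(x, y, time_s, valid = NULL) {
  if (is.null(valid)) valid <- !is.na(x) & !is.na(y)
  n <- length(x)
  if (n < 2) return(rep(NA_real_, n))
  sp <- c(NA_real_, sqrt(diff(x)^2 + diff(y)^2) / diff(time_s))
  ok <- c(FALSE, valid[-n] & valid[-1])
  sp[!ok] <- NA_real_
  sp
}

#' Classify speeds into motion classes
#'
#' Bins per-second speeds into still / scoot / move / burst / escape.
#' With the default thresholds (2, 10, 40, 80 px/s): still < 2 <= scoot
#' < 10 <= move < 40 <= burst < 80 <= escape.  "% movement" counts any
#' class above still.
#'
#' @param speed numeric speed vector (px/s).
#' @param thresholds strictly increasing cut points, length 4.
#' @return factor with levels still, scoot, move, burst, escape (NA where
#'   speed is NA).
#' @export
classify_motion <- function(speed, thresholds = c(2, 10, 40, 80)) {
  if (length(thresholds) != 4 || any(diff(thresholds) <= 0))
    stop("thresholds must be 4 strictly increasing values")
  cut(speed, breaks = c(-Inf, thresholds, Inf), right = FALSE,
      labels = c("still", "scoot", "move", "burst", "escape"))
}

#' Percentage of qualifying time in an interval
#'
#' 100 x (qualifying valid samples) / (valid samples) over
#' `[interval[1], interval[2])`.  Returns NA when no valid sample falls
#' in the interval.
#'
#' @param qualify logical vector (TRUE = qualifying).
#' @param time_s timestamps.
#' @param interval numeric `c(start_s, end_s)`, end exclusive.
#' @param valid logical validity (default: `!is.na(qualify)`).
#' @return percentage in [0, 100] or NA.
#' @export
interval_percent <- function(qualify, time_s, interval, valid = NULL) {
  if (is.null(valid)) valid <- !is.na(qualify)
  sel <- time_s >= interval[1] & time_s < interval[2] & valid
  if (!any(sel)) return(NA_real_)
  100 * sum(qualify[sel], na.rm = TRUE) / sum(sel)
}

#' Mean of a series over an interval
#' @param x numeric series.
#' @param time_s timestamps.
#' @param interval `c(start_s, end_s)`, end exclusive.
#' @return mean of defined values, or NA.
#' @export
interval_mean <- function(x, time_s, interval) {
  sel <- time_s >= interval[1] & time_s < interval[2] & !is.na(x)
  if (!any(sel)) return(NA_real_)
  mean(x[sel])
}

#' Acclimation to the cage
#'
#' Change of a measure across the first hour: its value in the last
#' 10-minute bin of hour 1 minus its value in the first 10-minute bin
#' (percentage points for percentage measures; negative values mean the
#' animal settles down).
#'
#' @param qualify logical qualifying vector, or numeric series when
#'   `percent = FALSE` (then bin means are differenced).
#' @param time_s timestamps.
#' @param schedule the assay schedule (defines the hour and bin scale).
#' @param valid logical validity.
#' @param percent treat `qualify` as a percentage measure?
#' @return last-bin minus first-bin value.
#' @export
acclimation <- function(qualify, time_s, schedule, valid = NULL,
                        percent = TRUE) {
  bin <- 600 * schedule$scale
  first <- c(0, bin)
  last <- c(3600 * schedule$scale - bin, 3600 * schedule$scale)
  if (percent) {
    interval_percent(qualify, time_s, last, valid) -
      interval_percent(qualify, time_s, first, valid)
  } else {
    interval_mean(qualify, time_s, last) - interval_mean(qualify, time_s, first)
  }
}

#' Habituation to a stimulus
#'
#' The level of a measure in the 10-minute window following a stimulus
#' onset.
#'
#' @param qualify logical qualifying vector (or numeric series with
#'   `percent = FALSE`).
#' @param time_s timestamps.
#' @param onset_s stimulus onset (s).
#' @param schedule the assay schedule.
#' @param valid logical validity.
#' @param percent percentage measure?
#' @return percentage (or mean) over `[onset, onset + 600 s)`.
#' @export
habituation <- function(qualify, time_s, onset_s, schedule, valid = NULL,
                        percent = TRUE) {
  win <- c(onset_s, onset_s + 600 * schedule$scale)
  if (percent) interval_percent(qualify, time_s, win, valid)
  else interval_mean(qualify, time_s, win)
}

# interval helpers tied to the schedule
.hour1 <- function(s) c(0, 3600 * s$scale)
.hour7 <- function(s) {
  n1 <- s$phases$start_s[s$phases$label == "night1"]
  c(n1, n1 + 3600 * s$scale)
}
.phase_sel <- function(s, time_s, labels) {
  phase_at(s, time_s) %in% labels
}
.pct_where <- function(qualify, valid, sel) {
  keep <- sel & valid
  if (!any(keep)) return(NA_real_)
  100 * sum(qualify[keep], na.rm = TRUE) / sum(keep)
}

#' Tracking-derived (Fiji-style) behavior parameters
#'
#' Computes the 15 centroid-tracking behavioral parameters: movement
#' percentages for the first hour (M1), daytime (MD), the 7th hour - the
#' first hour of nighttime (M7), nighttime (MN), and their difference
#' (N-D); acclimation in % movement (AM) and in % stretch-attend posture
#' (AS); habituation to the moth and the two moving-line stimuli (HMM,
#' HL1M, HL2M); and quadrant occupancy (Home, Wall, Food, Window, with
#' Out = Wall + Window).  Time in the hut counts as home-quadrant time;
#' other missing-position frames are excluded from denominators.
#'
#' @param track a `mouse_track`.
#' @param geometry a [cage_geometry()].
#' @param schedule the assay schedule.
#' @param move_threshold speed (px/s) above which a frame counts as
#'   movement (the still/scoot boundary).
#' @param sap detection options passed to [detect_sap()].
#' @return named numeric vector of the 15 parameters.
#' @export
tracking_params <- function(track, geometry, schedule,
                            move_threshold = 2, sap = list()) {
  t <- track$time_s
  speed <- speed_series(track$x, track$y, t)
  moving <- speed >= move_threshold
  vmov <- !is.na(speed)
  sapv <- do.call(detect_sap, c(list(track), sap))
  vsap <- !is.na(track$elongation)
  day <- .phase_sel(schedule, t, c("day1", "day2"))
  night <- .phase_sel(schedule, t, c("night1", "night_stim"))
  on <- schedule$stimulus_onsets
  M1 <- interval_percent(moving, t, .hour1(schedule), vmov)
  MD <- .pct_where(moving, vmov, day)
  M7 <- interval_percent(moving, t, .hour7(schedule), vmov)
  MN <- .pct_where(moving, vmov, night)
  quad <- track$quadrant
  vis <- !is.na(track$x)
  denom <- sum(vis | track$in_hut)
  qp <- function(q) if (denom == 0) NA_real_ else
    100 * sum(vis & quad == q, na.rm = TRUE) / denom
  Home <- if (denom == 0) NA_real_ else
    100 * (sum(track$in_hut) + sum(vis & quad == "home", na.rm = TRUE)) / denom
  Wall <- qp("wall"); Food <- qp("food"); Window <- qp("window")
  c(M1 = M1, MD = MD, M7 = M7, MN = MN, `N-D` = MN - MD,
    AM = acclimation(moving, t, schedule, vmov),
    AS = acclimation(sapv, t, schedule, vsap),
    HMM = habituation(moving, t, on$onset_s[on$label == "moth"], schedule, vmov),
    HL1M = habituation(moving, t, on$onset_s[on$label == "lines1"], schedule, vmov),
    HL2M = habituation(moving, t, on$onset_s[on$label == "lines2"], schedule, vmov),
    Home = Home, Wall = Wall, Food = Food, Window = Window,
    Out = Wall + Window)
}

#' Location and sociability measures from a pose track
#'
#' Home (% frames with the center keypoint inside the hut), Peek (% with
#' the center inside the hut but the nose outside), Window (% within the
#' window radius of the window center), Wall and Food (mean over frames
#' of the closest distance to any wall segment / food point, px; the
#' minima over time are attached as attributes), and DWindow (mean
#' distance to the window center, px).
#'
#' @param pose a likelihood-filtered `pose_track`.
#' @param geometry a [cage_geometry()].
#' @return named numeric vector Home, Peek, Window, Wall, Food, DWindow.
#' @export
location_params <- function(pose, geometry) {
  ctr <- pose$parts$center
  nose <- pose$parts$nose
  v <- ctr$valid %||% rep(TRUE, nrow(ctr))
  if (!any(v)) return(c(Home = NA_real_, Peek = NA_real_, Window = NA_real_,
                        Wall = NA_real_, Food = NA_real_, DWindow = NA_real_))
  x <- ctr$x[v]; y <- ctr$y[v]
  hut <- in_hut(x, y, geometry)
  vn <- (nose$valid %||% rep(TRUE, nrow(nose)))[v]
  nose_out <- !in_hut(nose$x[v], nose$y[v], geometry)
  peek <- hut & vn & nose_out
  dwin <- sqrt((x - geometry$window_center[[1]])^2 +
               (y - geometry$window_center[[2]])^2)
  wd <- wall_distance(x, y, geometry)
  fd <- food_distance(x, y, geometry)
  out <- c(Home = 100 * mean(hut),
           Peek = 100 * sum(peek) / length(hut),
           Window = 100 * mean(dwin <= geometry$window_radius),
           Wall = mean(wd), Food = mean(fd), DWindow = mean(dwin))
  attr(out, "min_wall") <- min(wd)
  attr(out, "min_food") <- min(fd)
  out
}

#' Window co-occupancy with the partner mouse
#'
#' Percentage of the focal mouse's near-window frames during which the
#' partner mouse (visible through the window hole of the adjacent cage)
#' is also near its own window.  The unconditional percentage (relative
#' to all frames valid in both tracks) is attached as attribute
#' `unconditional`.
#'
#' @param pose_a,pose_b likelihood-filtered `pose_track`s on the same
#'   time grid (focal, partner).
#' @param geometry_a,geometry_b the two cages' geometries (`geometry_b`
#'   defaults to `geometry_a`).
#' @return conditional percentage, or NA when the focal mouse never
#'   visits the window.
#' @export
window_partner <- function(pose_a, pose_b, geometry_a,
                           geometry_b = geometry_a) {
  if (length(pose_a$time_s) != length(pose_b$time_s) ||
      any(pose_a$time_s != pose_b$time_s))
    stop("pose tracks are not on the same time grid")
  near <- function(pose, geom) {
    ctr <- pose$parts$center
    v <- ctr$valid %||% rep(TRUE, nrow(ctr))
    d <- sqrt((ctr$x - geom$window_center[[1]])^2 +
              (ctr$y - geom$window_center[[2]])^2)
    list(near = d <= geom$window_radius, valid = v)
  }
  a <- near(pose_a, geometry_a); b <- near(pose_b, geometry_b)
  both_valid <- a$valid & b$valid
  na <- a$near & both_valid
  if (!any(na)) {
    out <- NA_real_
  } else out <- 100 * sum(na & b$near) / sum(na)
  attr(out, "unconditional") <-
    if (!any(both_valid)) NA_real_ else
      100 * sum(na & b$near) / sum(both_valid)
  out
}

# ids of the 52 pose-derived parameters, in table order
POSE_PARAM_IDS <- c(
  "M1", "MD", "M7", "MN", "MN-D",
  "Sc1", "ScD", "Sc7", "ScN", "ScN-D",
  "B1", "BD", "B7", "BN", "BN-D",
  "E1", "ED", "E7", "EN", "EN-D",
  "Sp1", "SpD", "Sp7", "SpN", "SpN-D",
  "AM", "ASc", "AB", "AE", "ASp",
  "HMM", "HL1M", "HL2M", "HMSc", "HL1Sc", "HL2Sc",
  "HMB", "HL1B", "HL2B", "HME", "HL1E", "HL2E",
  "HMSp", "HL1Sp", "HL2Sp",
  "Home", "Peek", "Window", "Wall", "Food", "DWindow", "Window Partner")

# ids of the 15 tracking-derived parameters
TRACK_PARAM_IDS <- c("M1", "MD", "M7", "MN", "N-D", "AM", "AS",
                     "HMM", "HL1M", "HL2M",
                     "Home", "Wall", "Food", "Window", "Out")

#' Pose-derived (DeepLabCut-style) behavior parameters
#'
#' Computes the 52 pose-track behavioral parameters: movement, scoot,
#' burst and escape percentages and mean speed (px/s) over the first
#' hour, daytime, the 7th hour and nighttime, with night-day
#' differences; acclimation in each measure; habituation to the three
#' stimuli in each measure; and the location/sociability block
#' ([location_params()], [window_partner()]).  Movement uses the center
#' keypoint; samples failing the likelihood filter are excluded.
#'
#' @param pose a `pose_track` (filtered with [filter_pose()] if not
#'   already).
#' @param partner the partner mouse's `pose_track`, or NULL (Window
#'   Partner then NA).
#' @param geometry a [cage_geometry()].
#' @param schedule the assay schedule.
#' @param thresholds motion-class cut points for [classify_motion()].
#' @param likelihood_threshold applied when `pose` is unfiltered.
#' @return named numeric vector of the 52 parameters (names
#'   `POSE_PARAM_IDS`).
#' @export
pose_params <- function(pose, partner = NULL, geometry = cage_geometry(),
                        schedule = make_schedule(),
                        thresholds = c(2, 10, 40, 80),
                        likelihood_threshold = 0.90) {
  if (is.null(pose$parts$center$valid))
    pose <- filter_pose(pose, likelihood_threshold)
  if (!is.null(partner) && is.null(partner$parts$center$valid))
    partner <- filter_pose(partner, likelihood_threshold)
  ctr <- pose$parts$center
  t <- pose$time_s
  speed <- speed_series(ctr$x, ctr$y, t, ctr$valid)
  cls <- classify_motion(speed, thresholds)
  v <- !is.na(speed)
  day <- .phase_sel(schedule, t, c("day1", "day2"))
  night <- .phase_sel(schedule, t, c("night1", "night_stim"))
  h1 <- .hour1(schedule); h7 <- .hour7(schedule)
  on <- schedule$stimulus_onsets
  onset <- stats::setNames(on$onset_s, on$label)

  block <- function(qualify, percent = TRUE, series = NULL) {
    if (percent) {
      c(interval_percent(qualify, t, h1, v),
        .pct_where(qualify, v, day),
        interval_percent(qualify, t, h7, v),
        .pct_where(qualify, v, night)) -> vals
      c(vals, vals[4] - vals[2])
    } else {
      vals <- c(interval_mean(series, t, h1),
                {sel <- day & !is.na(series); if (any(sel)) mean(series[sel]) else NA_real_},
                interval_mean(series, t, h7),
                {sel <- night & !is.na(series); if (any(sel)) mean(series[sel]) else NA_real_})
      c(vals, vals[4] - vals[2])
    }
  }
  moving <- cls != "still"
  scoot <- cls == "scoot"
  burst <- cls == "burst"
  escape <- cls == "escape"
  out <- c(
    block(moving), block(scoot), block(burst), block(escape),
    block(NULL, percent = FALSE, series = speed),
    AM = acclimation(moving, t, schedule, v),
    ASc = acclimation(scoot, t, schedule, v),
    AB = acclimation(burst, t, schedule, v),
    AE = acclimation(escape, t, schedule, v),
    ASp = acclimation(speed, t, schedule, percent = FALSE),
    vapply(c("moth", "lines1", "lines2"), function(s)
      habituation(moving, t, onset[[s]], schedule, v), numeric(1)),
    vapply(c("moth", "lines1", "lines2"), function(s)
      habituation(scoot, t, onset[[s]], schedule, v), numeric(1)),
    vapply(c("moth", "lines1", "lines2"), function(s)
      habituation(burst, t, onset[[s]], schedule, v), numeric(1)),
    vapply(c("moth", "lines1", "lines2"), function(s)
      habituation(escape, t, onset[[s]], schedule, v), numeric(1)),
    vapply(c("moth", "lines1", "lines2"), function(s)
      habituation(speed, t, onset[[s]], schedule, percent = FALSE), numeric(1)),
    location_params(pose, geometry),
    `Window Partner` = if (is.null(partner)) NA_real_ else
      as.numeric(window_partner(pose, partner, geometry))
  )
  out <- stats::setNames(as.numeric(out), POSE_PARAM_IDS)
  out
}

#' Assemble the 67 supervised behavior parameters of one mouse
#'
#' Evaluates the 15 tracking-derived and 52 pose-derived parameters and
#' returns them as one named vector with `fiji_` and `dlc_` prefixes
#' (the two blocks share ids such as M1).
#'
#' @param track a `mouse_track`.
#' @param pose,partner_pose `pose_track`s.
#' @param geometry a [cage_geometry()].
#' @param schedule the assay schedule.
#' @param ... passed to [pose_params()].
#' @return named numeric vector of length 67.
#' @export
compute_param_vector <- function(track, pose, partner_pose = NULL,
                                 geometry = cage_geometry(),
                                 schedule = make_schedule(), ...) {
  tp <- tracking_params(track, geometry, schedule)
  pp <- pose_params(pose, partner_pose, geometry, schedule, ...)
  out <- c(stats::setNames(tp, paste0("fiji_", names(tp))),
           stats::setNames(pp, paste0("dlc_", names(pp))))
  stopifnot(length(out) == 67)
  out
}
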