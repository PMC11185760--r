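#' Experimental group specification
#'
#' Describes one experimental group of the assay design: genotype (WT or
#' 3xTg-AD), age stage, drug treatment, and the named offsets the simulator
#' applies to its behavior-state parameters.  The reference group (WT,
#' untreated) has all offsets zero.
#'
#' @param genotype "WT" or "AD".
#' @param age "young", "old" or "aged".
#' @param treatment "none", "csa" (cyclosporine A), "neb" (nebivolol) or
#'   "cab" (cabozantinib).
#' @param effects named numeric vector of offsets applied on top of the
#'   built-in genotype/age/treatment effect structure (see
#'   [group_effects()]); useful for planting custom effects in tests.
#' @return an object of class `group_spec`.
#' @export
group_spec <- function(genotype = c("WT", "AD"),
                       age = c("young", "old", "aged"),
                       treatment = c("none", "csa", "neb", "cab"),
                       effects = NULL) {
  genotype <- match.arg(genotype)
  age <- match.arg(age)
  treatment <- match.arg(treatment)
  eff <- group_effects(genotype, age, treatment)
  if (!is.null(effects)) {
    stopifnot(all(is.finite(effects)), !is.null(names(effects)))
    for (nm in names(effects)) eff[nm] <- eff[nm] %||% 0 + effects[[nm]]
    # unknown keys are added as-is so tests can plant bespoke offsets
    new <- setdiff(names(effects), names(eff))
    for (nm in new) eff[nm] <- effects[[nm]]
  }
  structure(list(genotype = genotype, age = age, treatment = treatment,
                 effects = eff,
                 label = paste(genotype, age, treatment, sep = "_")),
            class = "group_spec")
}

`%||%` <- function(a, b)
  if (is.null(a) || length(a) == 0 || (length(a) == 1 && is.na(a))) b else a

#' Built-in genotype x age x treatment effect structure
#'
#' Encodes, as simulator offsets, the qualitative group differences the
#' assay is designed to detect: 3xTg-AD mice move less in the first hour
#' and the first hour of nighttime (with a smaller share of fast
#' burst/escape locomotion), acclimate differently (flatter decline of
#' stretch-attend posture and movement), respond less to the moth and the
#' first set of moving lines, sit further from the cage walls, and
#' synchronize less with the partner mouse at the window.  Ageing lowers
#' overall activity and raises hut occupancy in both genotypes.  Drug
#' treatments pull the AD offsets back toward zero (csa the furthest,
#' then neb, then cab).
#'
#' Offsets are additive on probabilities/fractions, px for `wall_bias`.
#'
#' @param genotype,age,treatment group labels as in [group_spec()].
#' @return named numeric vector of offsets.
#' @export
group_effects <- function(genotype, age, treatment = "none") {
  eff <- c(act1 = 0, act7 = 0, act_day = 0, act_night = 0,
           mix_fast = 0, accl = 0, sap_accl = 0,
           hab_moth = 0, hab_lines1 = 0, hab_lines2 = 0,
           hut = 0, wall_bias = 0, cooc = 0,
           syl_focus = 0, syl_dur = 0)
  if (age %in% c("old", "aged")) {
    k <- if (age == "old") 1 else 1.6
    eff["act_day"] <- eff["act_day"] - 0.05 * k
    eff["act_night"] <- eff["act_night"] - 0.07 * k
    eff["act1"] <- eff["act1"] - 0.05 * k
    eff["act7"] <- eff["act7"] - 0.05 * k
    eff["hut"] <- eff["hut"] + 0.06 * k
  }
  if (genotype == "AD") {
    ad <- c(act1 = -0.14, act7 = -0.16, act_day = 0, act_night = -0.05,
            mix_fast = -0.45, accl = 0.35, sap_accl = 0.5,
            hab_moth = -0.18, hab_lines1 = -0.15, hab_lines2 = 0,
            hut = 0.04, wall_bias = 18, cooc = -0.16,
            syl_focus = 0.8, syl_dur = 0.9)
    rescue <- switch(treatment, none = 0, csa = 0.85, neb = 0.6, cab = 0.45)
    eff[names(ad)] <- eff[names(ad)] + ad * (1 - rescue)
  }
  eff
}

#' Simulator configuration
#'
#' @param n_mice_per_group mice per experimental group.
#' @param seed base integer seed.
#' @param frame_interval seconds between frames (1 s).
#' @param image_height,image_width composite frame size in pixels.
#' @param likelihood_noise fraction of keypoint samples drawn below the
#'   0.90 likelihood threshold.
#' @param scale time scale passed to [make_schedule()].
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_mice_per_group = 8, seed = 1, frame_interval = 1,
                       image_height = 640, image_width = 960,
                       likelihood_noise = 0.10, scale = 1) {
  stopifnot(frame_interval > 0, image_height > 0, image_width > 0,
            likelihood_noise >= 0, likelihood_noise <= 1)
  structure(list(n_mice_per_group = n_mice_per_group, seed = seed,
                 frame_interval = frame_interval,
                 image_height = image_height, image_width = image_width,
                 likelihood_noise = likelihood_noise, scale = scale),
            class = "sim_config")
}

# the 8 tracked body parts, in DeepLabCut column order
POSE_PARTS <- c("nose", "right ear", "left ear", "head", "neck",
                "center", "hip", "tail base")

# speed-class bins (px/s): still < 2 <= scoot < 10 <= move < 40 <= burst
# < 80 <= escape; simulator state speeds sit in the middle of each bin so
# classification is exact by construction on noiseless tracks
MOTION_STATES <- c(still = 0, scoot = 5, move = 20, burst = 55, escape = 110)

#' Baseline simulator behavior-state parameters
#'
#' The reference (young, untreated WT) behavior-state parameters, with a
#' group's effect offsets applied.  All probabilities are clamped to
#' [0.01, 0.98] after applying offsets.
#'
#' @param group a [group_spec()].
#' @return named list of simulator parameters.
#' @export
sim_params <- function(group = group_spec()) {
  e <- group$effects
  clamp <- function(p) pmin(pmax(p, 0.01), 0.98)
  mix_fast <- clamp(0.20 * (1 + e[["mix_fast"]]))
  list(
    act_day    = clamp(0.35 + e[["act_day"]]),
    act_night  = clamp(0.62 + e[["act_night"]]),
    act1       = clamp(0.60 + e[["act1"]]),    # first hour in the cage
    act7       = clamp(0.70 + e[["act7"]]),    # first hour of nighttime
    accl_slope = clamp(0.55 * (1 - e[["accl"]])), # first-hour decline depth
    sap_start  = clamp(0.45 * (1 - e[["sap_accl"]] * 0.0)), # SAP share of rest, start of hour 1
    sap_slope  = clamp(0.80 * (1 - e[["sap_accl"]])),       # SAP decline depth over hour 1
    sap_base   = 0.06,                         # SAP share of rest after hour 1
    hab        = clamp(c(moth   = 0.62 + e[["hab_moth"]],
                         lines1 = 0.55 + e[["hab_lines1"]],
                         lines2 = 0.48 + e[["hab_lines2"]])),
    # share of scoot/move/burst/escape among active bouts
    state_mix  = c(scoot = 0.45, move = 0.35,
                   burst = mix_fast * 0.65, escape = mix_fast * 0.35),
    hut_occ    = clamp(0.30 + e[["hut"]]),
    peek_frac  = 0.20,
    window_occ = 0.10,
    cooc       = clamp(0.50 + e[["cooc"]]),
    wall_bias  = max(0, e[["wall_bias"]]),
    bout_mean_s = 6,
    hut_bout_mean_s = 240,
    window_bout_mean_s = 30,
    syl_focus  = e[["syl_focus"]],
    syl_dur    = e[["syl_dur"]]
  )
}

# alternating two-state renewal layer covering `total` seconds: returns a
# logical per-frame vector with TRUE-fraction ~ occ; bouts exponential
.renewal_layer <- function(n, dt, occ, mean_on_s) {
  if (occ <= 0) return(rep(FALSE, n))
  if (occ >= 1) return(rep(TRUE, n))
  mean_off_s <- mean_on_s * (1 - occ) / occ
  total <- n * dt
  est <- ceiling(total / (occ * mean_on_s + (1 - occ) * mean_off_s) * 3) + 10
  on_d  <- stats::rexp(est, 1 / mean_on_s)
  off_d <- stats::rexp(est, 1 / mean_off_s)
  # start in the stationary state
  start_on <- stats::runif(1) < occ
  d <- as.vector(rbind(if (start_on) on_d else off_d,
                       if (start_on) off_d else on_d))
  states <- rep(c(start_on, !start_on), est)
  frames <- pmax(1L, round(d / dt))
  keep <- cumsum(frames) < n + max(frames)
  out <- rep(states[keep], frames[keep])
  length(out) <- n
  out[is.na(out)] <- FALSE
  out
}

# fold positions into [lo, hi] by reflection
.fold <- function(p, lo, hi) {
  w <- hi - lo
  if (w <= 0) stop("geometry smaller than mouse template")
  q <- (p - lo) %% (2 * w)
  lo + ifelse(q > w, 2 * w - q, q)
}

#' Simulate a full-assay pose track
#'
#' Generates one mouse's DeepLabCut-style pose track over the whole assay:
#' a five-state switching random walk (still / scoot / move / burst /
#' escape) whose per-state speeds sit inside the speed-class bins used by
#' [classify_motion()], with activity probability modulated by phase
#' (day/night), a first-hour acclimation decline, and 10-minute
#' post-stimulus response windows; an alternating-renewal hut-occupancy
#' layer (with "peek" sub-bouts: center inside the hut, nose outside);
#' a window-visit layer; and stretch-attend-posture bouts during rest.
#' Keypoint likelihoods are drawn so a configured fraction falls below the
#' 0.90 filter threshold.
#'
#' The generated ground truth (per-frame state, hut/peek/window
#' indicators, true center position and elongation) is attached as
#' `attr(x, "truth")`.
#'
#' @param group a [group_spec()].
#' @param schedule an [make_schedule()] schedule.
#' @param geometry a [cage_geometry()].
#' @param seed integer seed.
#' @param config a [sim_config()] (for `likelihood_noise`).
#' @param params simulator parameters, default [sim_params()] of `group`.
#' @param pose_jitter keypoint placement noise SD in px.
#' @return a `pose_track` object: list with `time_s` and `parts` (named
#'   list of data.frames x/y/likelihood), plus the truth attribute.
#' @export
simulate_pose_track <- function(group = group_spec(),
                                schedule = make_schedule(),
                                geometry = cage_geometry(),
                                seed = 1,
                                config = sim_config(),
                                params = sim_params(group),
                                pose_jitter = 0.5) {
  set.seed(seed)
  dt <- schedule$frame_interval
  times <- schedule_times(schedule)
  n <- length(times)
  margin <- 16
  lo_x <- margin + params$wall_bias; hi_x <- geometry$width - margin - params$wall_bias
  lo_y <- margin + params$wall_bias; hi_y <- geometry$height - margin - params$wall_bias
  if (hi_x <= lo_x || hi_y <= lo_y) stop("geometry smaller than mouse template")
  # keep the free walk clear of the window corner, so near-window time
  # comes from the deliberate visit layer and its rate stays recoverable
  # (skipped when the cage is too small to afford the clearance)
  cl <- (geometry$window_radius + 12) / sqrt(2)
  if (min(geometry$window_center[[1]] - cl - lo_x,
          geometry$window_center[[2]] - cl - lo_y) >= 20) {
    hi_x <- min(hi_x, geometry$window_center[[1]] - cl)
    hi_y <- min(hi_y, geometry$window_center[[2]] - cl)
  }

  # activity probability at time t
  act_at <- function(t) {
    night <- is_night(schedule, t)
    a <- ifelse(night, params$act_night, params$act_day)
    # first hour in the cage: linear decline from act1 down by accl_slope
    h1 <- 3600 * schedule$scale
    in1 <- t < h1
    a[in1] <- params$act1 * (1 - params$accl_slope * t[in1] / h1)
    # first hour of nighttime overrides the night baseline
    n1 <- schedule$phases$start_s[schedule$phases$label == "night1"]
    in7 <- t >= n1 & t < n1 + h1
    a[in7] <- params$act7
    # post-stimulus 10-minute windows
    for (k in seq_len(nrow(schedule$stimulus_onsets))) {
      o <- schedule$stimulus_onsets$onset_s[k]
      lab <- schedule$stimulus_onsets$label[k]
      w <- t >= o & t < o + 600 * schedule$scale
      a[w] <- params$hab[[lab]]
    }
    a
  }

  # bout skeleton: alternating-duration semi-Markov over motion states
  mean_frames <- max(1, params$bout_mean_s / dt)
  est <- ceiling(n / mean_frames * 2) + 20
  durs <- stats::rgeom(est, 1 / mean_frames) + 1L
  starts <- cumsum(c(1L, durs))[seq_len(est)]
  keep <- starts <= n
  durs <- durs[keep]; starts <- starts[keep]
  nb <- length(durs)
  a_b <- act_at(times[starts])
  active <- stats::runif(nb) < a_b
  mix <- params$state_mix / sum(params$state_mix)
  st <- rep("still", nb)
  st[active] <- sample(names(mix), sum(active), replace = TRUE, prob = mix)
  # SAP: a share of rest bouts, declining over the first hour
  h1 <- 3600 * schedule$scale
  sap_p <- ifelse(times[starts] < h1,
                  params$sap_start * (1 - params$sap_slope * times[starts] / h1),
                  params$sap_base)
  sap_b <- !active & stats::runif(nb) < sap_p
  state <- rep(st, durs); length(state) <- n
  state[is.na(state)] <- "still"
  sap <- rep(sap_b, durs); length(sap) <- n
  sap[is.na(sap)] <- FALSE

  # occupancy layers; bout lengths follow the schedule's time scale
  hut <- .renewal_layer(n, dt, params$hut_occ,
                        max(3 * dt, params$hut_bout_mean_s * schedule$scale))
  win <- .renewal_layer(n, dt, params$window_occ,
                        max(3 * dt, params$window_bout_mean_s * schedule$scale)) & !hut
  # peek: the tail of each hut bout
  peek <- rep(FALSE, n)
  r <- rle(hut)
  ends <- cumsum(r$lengths)
  for (k in which(r$values)) {
    len <- r$lengths[k]
    np <- floor(len * params$peek_frac)
    if (np > 0) peek[(ends[k] - np + 1):ends[k]] <- TRUE
  }

  # free motion path
  speed <- unname(MOTION_STATES[state])
  speed[hut | win] <- 0
  theta <- cumsum(stats::rnorm(n, 0, 0.35))
  x <- .fold(geometry$width / 2 + cumsum(speed * dt * cos(theta)), lo_x, hi_x)
  y <- .fold(geometry$height / 2 + cumsum(speed * dt * sin(theta)), lo_y, hi_y)
  # overrides: hut and window positions
  hx <- mean(range(geometry$hut[, 1])); hy <- mean(range(geometry$hut[, 2]))
  x[hut] <- hx; y[hut] <- hy
  nwin <- sum(win)
  if (nwin) {
    rr <- geometry$window_radius * 0.55 * sqrt(stats::runif(nwin))
    aa <- stats::runif(nwin, 0, 2 * pi)
    x[win] <- pmin(pmax(geometry$window_center[[1]] + rr * cos(aa), 1), geometry$width - 1)
    y[win] <- pmin(pmax(geometry$window_center[[2]] + rr * sin(aa), 1), geometry$height - 1)
  }
  state[hut | win] <- "still"
  sap[hut | win] <- FALSE
  elong <- ifelse(sap, 2.5, 1.3)

  # keypoints along the body axis
  ux <- cos(theta); uy <- sin(theta)
  vx <- -uy; vy <- ux
  offs <- list("nose" = c(14, 0), "right ear" = c(8, 4), "left ear" = c(8, -4),
               "head" = c(9, 0), "neck" = c(5, 0), "center" = c(0, 0),
               "hip" = c(-8, 0), "tail base" = c(-14, 0))
  parts <- lapply(offs, function(o) {
    px <- x + o[1] * ux + o[2] * vx + stats::rnorm(n, 0, pose_jitter)
    py <- y + o[1] * uy + o[2] * vy + stats::rnorm(n, 0, pose_jitter)
    bad <- stats::runif(n) < config$likelihood_noise
    lik <- ifelse(bad, stats::runif(n, 0.30, 0.8999), stats::runif(n, 0.92, 1.0))
    data.frame(x = px, y = py, likelihood = lik)
  })
  # peek frames: nose placed just outside the hut's lower edge
  if (any(peek)) {
    parts$nose$x[peek] <- hx
    parts$nose$y[peek] <- max(geometry$hut[, 2]) + 4
  }
  out <- list(time_s = times, parts = parts)
  class(out) <- "pose_track"
  attr(out, "truth") <- list(state = state, sap = sap, in_hut = hut,
                             at_window = win, peek = peek,
                             x = x, y = y, elongation = elong,
                             theta = theta, params = params)
  out
}

#' @export
print.pose_track <- function(x, ...) {
  cat("pose_track:", length(x$time_s), "frames,",
      length(x$parts), "body parts\n")
  invisible(x)
}

#' Ground-truth centroid track of a simulated pose track
#'
#' Converts a simulated pose track's ground truth into the centroid-track
#' form produced by the image-tracking stage (a `mouse_track`
#' data.frame), with centroids missing while the mouse is inside the hut.
#'
#' @param pose a simulated [simulate_pose_track()] output.
#' @param geometry the matching [cage_geometry()].
#' @return a `mouse_track` data.frame.
#' @export
truth_track <- function(pose, geometry = cage_geometry()) {
  tr <- attr(pose, "truth")
  if (is.null(tr)) stop("pose track carries no ground truth")
  n <- length(pose$time_s)
  x <- tr$x; y <- tr$y
  x[tr$in_hut] <- NA_real_; y[tr$in_hut] <- NA_real_
  quad <- rep(NA_character_, n)
  vis <- !is.na(x)
  quad[vis] <- assign_quadrant(x[vis], y[vis], geometry)
  out <- data.frame(time_s = pose$time_s, x = x, y = y,
                    head_x = x, head_y = y,
                    area = ifelse(vis, 620, NA_real_),
                    elongation = ifelse(vis, tr$elongation, NA_real_),
                    in_hut = tr$in_hut, quadrant = quad,
                    stringsAsFactors = FALSE)
  class(out) <- c("mouse_track", "data.frame")
  out
}

#' Correlate a partner track's window visits with a focal track
#'
#' Rewrites the partner's window-visit layer so that, for each frame where
#' the focal mouse is near the window, the partner is also near its window
#' with probability `cooc` (decided per focal visit bout, so visits remain
#' contiguous).  Used to plant a recoverable sociability (Window Partner)
#' rate.
#'
#' @param partner,focal `pose_track` objects on the same time grid.
#' @param geometry the partner's [cage_geometry()].
#' @param cooc target co-occurrence probability.
#' @param seed integer seed.
#' @return the modified partner `pose_track`.
#' @export
correlate_window_visits <- function(partner, focal, geometry, cooc, seed = 1) {
  set.seed(seed)
  trf <- attr(focal, "truth"); trp <- attr(partner, "truth")
  stopifnot(length(partner$time_s) == length(focal$time_s))
  r <- rle(trf$at_window)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  join <- stats::runif(length(r$lengths)) < cooc
  at <- trp$at_window
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    idx <- starts[k]:ends[k]
    at[idx] <- join[k]
  }
  # a joined window visit takes precedence over a hut bout (the partner
  # leaves the hut to visit); its hut occupancy shrinks marginally
  trp$in_hut[at] <- FALSE
  # frames that lose their window visit are moved to the cage interior
  off <- trp$at_window & !at
  if (any(off)) {
    trp$x[off] <- geometry$width / 2
    trp$y[off] <- geometry$height / 2
    partner$parts$center$x[off] <- trp$x[off]
    partner$parts$center$y[off] <- trp$y[off]
  }
  nwin <- sum(at)
  wx <- geometry$window_center[[1]]; wy <- geometry$window_center[[2]]
  rr <- geometry$window_radius * 0.55 * sqrt(stats::runif(max(nwin, 1)))
  aa <- stats::runif(max(nwin, 1), 0, 2 * pi)
  if (nwin) {
    trp$x[at] <- pmin(pmax(wx + rr[seq_len(nwin)] * cos(aa[seq_len(nwin)]), 1),
                      geometry$width - 1)
    trp$y[at] <- pmin(pmax(wy + rr[seq_len(nwin)] * sin(aa[seq_len(nwin)]), 1),
                      geometry$height - 1)
    partner$parts$center$x[at] <- trp$x[at]
    partner$parts$center$y[at] <- trp$y[at]
  }
  trp$at_window <- at
  attr(partner, "truth") <- trp
  partner
}

#' The 29-syllable alphabet
#'
#' The retained behavioral-syllable ids (sparse in 0..63) with their
#' human-readable labels, as produced by unsupervised keypoint-based
#' behavioral classification of the assay.
#'
#' @return data.frame with columns `id` (integer) and `label`.
#' @export
syllable_alphabet <- function() {
  data.frame(
    id = c(0:16, 20, 21, 24, 27, 28, 31, 34, 42, 46, 50, 61, 63),
    label = c("groom_hunch", "burst_turn", "hunch_look", "burst_short",
              "freeze_look", "rear", "stretch_burst", "groom_quick",
              "burst_home", "groom_small", "rear_climb", "stretch_sit",
              "ball", "curl", "rear_fast", "burst_single", "stay",
              "food", "stretch", "groom_tail", "loop", "sleep",
              "groom_still", "turn_behind", "turn", "look", "turn_away",
              "freeze_hunch", "small_burst"),
    stringsAsFactors = FALSE
  )
}

#' Simulate a behavioral-syllable sequence
#'
#' Semi-Markov generator: bout labels follow a row-stochastic transition
#' matrix (self-transitions ignored; bouts are maximal runs by
#' construction) and bout durations are geometric in frames with the
#' requested per-label mean, emulating the 2-4 s average syllable length
#' of the trained classifier.
#'
#' @param transition square row-stochastic matrix; dimnames give the
#'   alphabet (defaults to a uniform matrix over the 29-syllable alphabet).
#' @param mean_durations named per-label mean bout durations in seconds
#'   (default 3 s each).
#' @param schedule an [make_schedule()] schedule.
#' @param seed integer seed.
#' @return a `syllable_seq` data.frame (time_s, label) with the alphabet
#'   as attribute.
#' @export
simulate_syllables <- function(transition = NULL, mean_durations = NULL,
                               schedule = make_schedule(), seed = 1) {
  set.seed(seed)
  if (is.null(transition)) {
    ids <- as.character(syllable_alphabet()$id)
    m <- length(ids)
    transition <- matrix(1 / (m - 1), m, m, dimnames = list(ids, ids))
    diag(transition) <- 0
  }
  ids <- rownames(transition)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(transition)) - 1)
  if (any(abs(rowSums(transition) - 1) > 1e-8))
    stop("transition matrix rows must sum to 1")
  if (is.null(mean_durations))
    mean_durations <- stats::setNames(rep(3, length(ids)), ids)
  if (any(mean_durations <= 0)) stop("mean durations must be positive")
  dt <- schedule$frame_interval
  n <- length(schedule_times(schedule))
  mean_fr <- pmax(1, mean_durations / dt)
  est <- ceiling(n / min(mean_fr) * 1.3) + 30
  labs <- integer(est)
  labs[1] <- sample.int(length(ids), 1)
  # bout-level Markov chain
  cum <- t(apply(transition, 1, cumsum))
  u <- stats::runif(est)
  for (k in 2:est) {
    labs[k] <- findInterval(u[k], cum[labs[k - 1], ]) + 1L
    # identity rows (absorbing states) stay put
    if (labs[k] > length(ids)) labs[k] <- labs[k - 1]
    if (transition[labs[k - 1], labs[k - 1]] >= 1 - 1e-12) labs[k] <- labs[k - 1]
  }
  durs <- stats::rgeom(est, 1 / mean_fr[labs]) + 1L
  total <- cumsum(durs)
  nb <- which(total >= n)[1]
  if (is.na(nb)) nb <- est
  lab <- rep(ids[labs[seq_len(nb)]], durs[seq_len(nb)])[seq_len(n)]
  out <- data.frame(time_s = schedule_times(schedule), label = lab,
                    stringsAsFactors = FALSE)
  class(out) <- c("syllable_seq", "data.frame")
  attr(out, "alphabet") <- ids
  out
}

#' Group-biased syllable transition matrix
#'
#' Builds a transition matrix over the 29-syllable alphabet whose
#' stationary usage concentrates on a subset of syllables as `focus`
#' grows (emulating the reduced syllable repertoire of old 3xTg-AD mice),
#' and per-label mean durations lengthened for the stretch and tail-groom
#' syllables as `dur_bias` grows.
#'
#' @param focus concentration strength (0 = uniform usage).
#' @param dur_bias duration-effect strength (0 = 3 s everywhere).
#' @return list with `transition` and `mean_durations`.
#' @export
syllable_generator_params <- function(focus = 0, dur_bias = 0) {
  alpha <- syllable_alphabet()
  ids <- as.character(alpha$id)
  m <- length(ids)
  # target usage weights: geometric decay across the alphabet under focus;
  # syllables 14 and 50 are down-weighted first (frequency effects)
  rank <- seq_len(m)
  w <- exp(-focus * 3 * (rank - 1) / (m - 1))
  w[ids %in% c("14", "50")] <- w[ids %in% c("14", "50")] * exp(-focus * 2)
  w <- w / sum(w)
  transition <- matrix(rep(w, each = m), m, m, dimnames = list(ids, ids))
  diag(transition) <- 0
  transition <- transition / rowSums(transition)
  md <- stats::setNames(rep(3, m), ids)
  md[c("21", "24")] <- 3 + 2 * dur_bias   # duration effects (stretch, groom_tail)
  list(transition = transition, mean_durations = md)
}

# the six normal step sequence patterns (cruciate, alternate, rotary)
NSSP_PATTERNS <- list(
  Ca = c("RF", "LF", "RH", "LH"), Cb = c("LF", "RF", "LH", "RH"),
  Aa = c("RF", "RH", "LF", "LH"), Ab = c("LF", "RH", "RF", "LH"),
  Ra = c("RF", "LF", "LH", "RH"), Rb = c("LF", "RF", "RH", "LH"))

#' Default print geometry and intensity parameters for footfall simulation
#' @return named list of per-print means (front and hind).
#' @export
print_spec <- function() {
  list(print_length = c(front = 7.5, hind = 8.5),
       toe_spread = c(front = NA, hind = 9.0),
       intermediate_toe_spread = c(front = 3.5, hind = 4.5),
       print_area = c(front = 35, hind = 45),
       max_contact_area = c(front = 30, hind = 40),
       mean_intensity = c(front = 120, hind = 140),
       min_intensity = c(front = 60, hind = 80),
       base_of_support = c(front = 18, hind = 26),
       jitter = 0.04)
}

#' Simulate a walkway crossing (footfall event log)
#'
#' Generates one gait run: paw contacts cycling in the requested step
#' sequence pattern, with stand/swing timing, positions advancing along
#' the walkway, and per-print geometry and intensity fields drawn around
#' `spec`.
#'
#' @param pattern one of "Ca","Cb","Aa","Ab","Ra","Rb" or "random".
#' @param n_steps total number of footfall events (>= 4).
#' @param run_speed walkway progression speed (length units / s).
#' @param spec a [print_spec()] list.
#' @param seed integer seed.
#' @param step_cycle_s per-paw step cycle duration (s).
#' @param duty_factor stand fraction of the step cycle.
#' @param jitter_sd timing jitter SD (s).
#' @return a `gait_run` object.
#' @export
simulate_footfalls <- function(pattern = "Aa", n_steps = 16, run_speed = 20,
                               spec = print_spec(), seed = 1,
                               step_cycle_s = 0.5, duty_factor = 0.6,
                               jitter_sd = 0) {
  set.seed(seed)
  stopifnot(n_steps >= 4)
  if (pattern == "random") {
    paws <- sample(c("RF", "LF", "RH", "LH"), n_steps, replace = TRUE)
  } else if (pattern %in% names(NSSP_PATTERNS)) {
    paws <- rep(NSSP_PATTERNS[[pattern]], length.out = n_steps)
  } else stop("unknown step sequence pattern: ", pattern)
  t0 <- (seq_len(n_steps) - 1) * step_cycle_s / 4 +
    if (jitter_sd > 0) stats::rnorm(n_steps, 0, jitter_sd) else 0
  t0 <- pmax(0, t0)
  stand <- step_cycle_s * duty_factor *
    (1 + if (jitter_sd > 0) stats::rnorm(n_steps, 0, jitter_sd) else 0)
  kind <- ifelse(substr(paws, 2, 2) == "F", "front", "hind")
  side <- ifelse(substr(paws, 1, 1) == "R", 1, -1)
  bos <- spec$base_of_support
  jit <- function(mu) mu * (1 + stats::rnorm(n_steps, 0, spec$jitter))
  x <- t0 * run_speed
  y <- side * unname(bos[kind]) / 2
  events <- data.frame(
    paw = paws,
    contact_start_s = t0,
    contact_end_s = t0 + stand,
    x = x, y = y,
    print_length = jit(unname(spec$print_length[kind])),
    toe_spread = ifelse(kind == "hind", jit(unname(spec$toe_spread["hind"])), NA_real_),
    intermediate_toe_spread = jit(unname(spec$intermediate_toe_spread[kind])),
    print_area = jit(unname(spec$print_area[kind])),
    max_contact_area = jit(unname(spec$max_contact_area[kind])),
    mean_intensity = jit(unname(spec$mean_intensity[kind])),
    min_intensity = jit(unname(spec$min_intensity[kind])) * 0.5,
    print_orientation = stats::rnorm(n_steps, 0, 2),
    stringsAsFactors = FALSE
  )
  events$min_intensity <- pmin(events$min_intensity, events$mean_intensity)
  events <- events[order(events$contact_start_s), ]
  gait_run(events)
}
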