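# shared fixtures: small schedules/geometries and hand-built inputs

tiny_schedule <- function(scale = 1 / 600) make_schedule(scale = scale)

small_geometry <- function() cage_geometry(width = 60, height = 80)

# a hand-constructed mouse track on a 1 s grid: piecewise-constant speeds,
# no hut visits, known quadrants
hand_track <- function(n = 1000, geometry = cage_geometry()) {
  t <- seq_len(n) - 1
  # walk right at 3 px/s for the first half, rest for the second
  x <- pmin(20 + cumsum(rep(c(3, 0), each = n / 2)), geometry$width - 10)
  y <- rep(geometry$height / 2 + 10, n)
  elong <- rep(1.3, n)
  # a stationary elongated stretch in the resting half
  sap_idx <- (n / 2 + 10):(n / 2 + 59)
  elong[sap_idx] <- 2.5
  out <- data.frame(time_s = t, x = x, y = y, head_x = x + 5, head_y = y,
                    area = 600, elongation = elong, in_hut = FALSE,
                    quadrant = assign_quadrant(x, y, geometry),
                    stringsAsFactors = FALSE)
  class(out) <- c("mouse_track", "data.frame")
  attr(out, "sap_idx") <- sap_idx
  out
}

# build a pose_track directly from coordinate vectors (all parts collapsed
# onto the center trajectory unless offsets given)
hand_pose <- function(x, y, likelihood = 1, time_s = seq_along(x) - 1,
                      nose_dx = 10) {
  n <- length(x)
  lik <- rep_len(likelihood, n)
  mk <- function(dx = 0, dy = 0)
    data.frame(x = x + dx, y = y + dy, likelihood = lik)
  parts <- list("nose" = mk(nose_dx), "right ear" = mk(5, 3),
                "left ear" = mk(5, -3), "head" = mk(7), "neck" = mk(3),
                "center" = mk(), "hip" = mk(-5), "tail base" = mk(-10))
  out <- list(time_s = time_s, parts = parts)
  class(out) <- "pose_track"
  out
}

# footfall log from explicit vectors
hand_run <- function(paw, start, end, x = NULL, y = 0, ...) {
  n <- length(paw)
  ev <- data.frame(paw = paw, contact_start_s = start, contact_end_s = end,
                   x = if (is.null(x)) seq_len(n) else x,
                   y = rep_len(y, n), stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) ev[[nm]] <- rep_len(extra[[nm]], n)
  gait_run(ev)
}
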