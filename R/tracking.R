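#' Segment the mouse in one cage frame
#'
#' Thresholds the red channel (the mouse is a dark blob on a bright or red
#' background under both day and night illumination), labels connected
#' components, and keeps the largest component inside the cage bounds that
#' exceeds a minimum area.  Returns the blob's centroid, area, body-axis
#' orientation, major/minor elongation and the two boundary endpoints
#' along the major axis, or `NULL` when no qualifying blob exists (e.g.
#' the mouse is inside the hut).
#'
#' @param frame `height x width x 3` RGB array (or a plain matrix treated
#'   as the red channel).
#' @param geometry a [cage_geometry()]; frame dimensions must match.
#' @param threshold red-channel threshold; pixels darker than this are
#'   candidate mouse pixels.  `NULL` selects Otsu's threshold.
#' @param min_area minimum blob area in px^2.
#' @return list(centroid = c(x, y), area, orientation, elongation,
#'   end1, end2) or NULL.
#' @export
segment_mouse <- function(frame, geometry, threshold = 0.5, min_area = 50) {
  red <- if (length(dim(frame)) == 3) frame[, , 1] else frame
  if (is.null(dim(red)) || nrow(red) == 0 || ncol(red) == 0)
    stop("empty frame")
  if (nrow(red) != geometry$height || ncol(red) != geometry$width)
    stop("frame dimensions do not match geometry")
  if (is.null(threshold)) threshold <- EBImage::otsu(EBImage::Image(red))
  mask <- red < threshold
  if (!any(mask)) return(NULL)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- EBImage::imageData(lab)
  tab <- tabulate(lab[lab > 0])
  if (!length(tab) || max(tab) < min_area) return(NULL)
  best <- which.max(tab)
  idx <- which(lab == best, arr.ind = TRUE)
  # pixel centers: column j center at x = j - 0.5, row i at y = i - 0.5
  x <- idx[, 2] - 0.5; y <- idx[, 1] - 0.5
  cx <- mean(x); cy <- mean(y)
  cxx <- mean((x - cx)^2); cyy <- mean((y - cy)^2); cxy <- mean((x - cx) * (y - cy))
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2), symmetric = TRUE)
  l <- pmax(ev$values, 1e-9)
  u <- ev$vectors[, 1]
  proj <- (x - cx) * u[1] + (y - cy) * u[2]
  i1 <- which.max(proj); i2 <- which.min(proj)
  list(centroid = c(x = cx, y = cy), area = length(x),
       orientation = atan2(u[2], u[1]),
       elongation = sqrt(l[1] / l[2]),
       end1 = c(x = x[i1], y = y[i1]), end2 = c(x = x[i2], y = y[i2]))
}

#' Track the mouse through a frame sequence
#'
#' Applies [segment_mouse()] to every frame, estimates the head position
#' as the blob-boundary endpoint farthest along the motion-direction
#' axis, assigns the centroid's cage quadrant, and marks frames as
#' in-hut when the centroid is missing for at least `hut_dwell`
#' consecutive frames.
#'
#' @param frames list of RGB arrays, one per schedule frame.
#' @param geometry a [cage_geometry()].
#' @param schedule the matching schedule; `length(frames)` must equal the
#'   schedule's frame count.
#' @param threshold,min_area passed to [segment_mouse()].
#' @param hut_dwell minimum missing-centroid run (frames) interpreted as
#'   a hut visit.
#' @return a `mouse_track` data.frame: time_s, x, y, head_x, head_y,
#'   area, elongation, in_hut, quadrant.
#' @export
track_frames <- function(frames, geometry, schedule,
                         threshold = 0.5, min_area = 50, hut_dwell = 3) {
  times <- schedule_times(schedule)
  if (length(frames) != length(times))
    stop("frame count does not match schedule length")
  n <- length(frames)
  x <- y <- hx <- hy <- area <- elong <- rep(NA_real_, n)
  last_head_dir <- c(1, 0)
  ends <- vector("list", n)
  for (i in seq_len(n)) {
    night <- is_night(schedule, times[i])
    b <- segment_mouse(frames[[i]], geometry, threshold, min_area)
    if (is.null(b)) next
    x[i] <- b$centroid[1]; y[i] <- b$centroid[2]
    area[i] <- b$area; elong[i] <- b$elongation
    ends[[i]] <- list(b$end1, b$end2)
  }
  # head: endpoint agreeing with the motion direction (previous direction
  # is kept while the mouse is static)
  prev <- NULL
  dir <- c(1, 0)
  for (i in seq_len(n)) {
    if (is.na(x[i])) { prev <- NULL; next }
    if (!is.null(prev)) {
      d <- c(x[i] - prev[1], y[i] - prev[2])
      if (sqrt(sum(d^2)) > 0.5) dir <- d / sqrt(sum(d^2))
    }
    e <- ends[[i]]
    s1 <- (e[[1]][1] - x[i]) * dir[1] + (e[[1]][2] - y[i]) * dir[2]
    s2 <- (e[[2]][1] - x[i]) * dir[1] + (e[[2]][2] - y[i]) * dir[2]
    h <- if (s1 >= s2) e[[1]] else e[[2]]
    hx[i] <- h[1]; hy[i] <- h[2]
    prev <- c(x[i], y[i])
  }
  in_hut <- rep(FALSE, n)
  r <- rle(is.na(x))
  pos <- cumsum(c(1, r$lengths))
  for (k in seq_along(r$lengths)) {
    if (r$values[k] && r$lengths[k] >= hut_dwell)
      in_hut[pos[k]:(pos[k + 1] - 1)] <- TRUE
  }
  quad <- rep(NA_character_, n)
  vis <- !is.na(x)
  if (any(vis)) {
    xs <- pmin(pmax(x[vis], 0), geometry$width)
    ys <- pmin(pmax(y[vis], 0), geometry$height)
    quad[vis] <- assign_quadrant(xs, ys, geometry)
  }
  out <- data.frame(time_s = times, x = x, y = y, head_x = hx, head_y = hy,
                    area = area, elongation = elong, in_hut = in_hut,
                    quadrant = quad, stringsAsFactors = FALSE)
  class(out) <- c("mouse_track", "data.frame")
  out
}

#' Detect stretch-attend posture frames
#'
#' A frame is flagged as stretch-attend posture (SAP) when the blob is
#' elongated at least `elong_threshold` and the centroid moves at most
#' `speed_threshold` px/s — the elongated, near-stationary
#' risk-assessment posture.
#'
#' @param track a `mouse_track` data.frame.
#' @param elong_threshold minimum major/minor axis ratio (default 2.0).
#' @param speed_threshold maximum centroid speed in px/s (default 2.0).
#' @return logical vector, one value per frame (FALSE where the centroid
#'   or elongation is missing).
#' @export
detect_sap <- function(track, elong_threshold = 2.0, speed_threshold = 2.0) {
  n <- nrow(track)
  dt <- c(NA, diff(track$time_s))
  disp <- c(NA, sqrt(diff(track$x)^2 + diff(track$y)^2))
  speed <- disp / dt
  # the first defined frame of a bout inherits its successor's speed
  speed[1] <- if (n > 1) speed[2] else 0
  sap <- !is.na(track$elongation) & track$elongation >= elong_threshold &
    !is.na(speed) & speed <= speed_threshold
  sap[is.na(sap)] <- FALSE
  sap
}
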