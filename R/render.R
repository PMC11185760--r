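#' Render synthetic assay frames
#'
#' Draws one frame per pose-track sample: a dark elliptical mouse blob
#' (oriented along the head-tail axis, elongated during stretch-attend
#' posture) on a white background during day phases and a red background
#' during night phases.  The hut is drawn as a red block and the mouse is
#' omitted from view while inside it.  Frames are `height x width x 3`
#' arrays in [0, 1].
#'
#' @param pose a [simulate_pose_track()] output (its truth drives the
#'   rendering).
#' @param geometry the matching [cage_geometry()].
#' @param schedule the matching schedule (day/night backgrounds).
#' @param frames which frame indices to render (default all).
#' @param blob_area mouse blob area in px^2.
#' @return list of RGB arrays.
#' @export
simulate_frames <- function(pose, geometry, schedule,
                            frames = seq_along(pose$time_s),
                            blob_area = 620) {
  tr <- attr(pose, "truth")
  if (is.null(tr)) stop("pose track carries no ground truth")
  lapply(frames, function(i) {
    render_frame(
      x = tr$x[i], y = tr$y[i], theta = tr$theta[i],
      elongation = tr$elongation[i], visible = !tr$in_hut[i],
      night = is_night(schedule, pose$time_s[i]),
      geometry = geometry, blob_area = blob_area)
  })
}

#' Render a single cage frame
#'
#' @param x,y mouse centroid (px; pixel centers at integer - 0.5).
#' @param theta body-axis angle (radians).
#' @param elongation major/minor axis ratio of the blob.
#' @param visible draw the mouse? (FALSE while in the hut).
#' @param night red background if TRUE, white otherwise.
#' @param geometry a [cage_geometry()].
#' @param blob_area blob area in px^2.
#' @return `height x width x 3` RGB array in [0, 1].
#' @export
render_frame <- function(x, y, theta = 0, elongation = 1.3, visible = TRUE,
                         night = FALSE, geometry = cage_geometry(),
                         blob_area = 620) {
  h <- geometry$height; w <- geometry$width
  img <- array(0, dim = c(h, w, 3))
  if (night) {
    img[, , 1] <- 1; img[, , 2] <- 0.15; img[, , 3] <- 0.15
  } else img[, , ] <- 1
  # hut: red block (bright in the red channel, so it never segments as mouse)
  hr <- round(range(geometry$hut[, 2])); hc <- round(range(geometry$hut[, 1]))
  hr <- pmin(pmax(hr, 1), h); hc <- pmin(pmax(hc, 1), w)
  img[hr[1]:hr[2], hc[1]:hc[2], 1] <- 0.80
  img[hr[1]:hr[2], hc[1]:hc[2], 2] <- 0.10
  img[hr[1]:hr[2], hc[1]:hc[2], 3] <- 0.10
  if (visible && is.finite(x) && is.finite(y)) {
    b <- sqrt(blob_area / (pi * elongation)); a <- elongation * b
    r0 <- max(1, floor(y - a)); r1 <- min(h, ceiling(y + a))
    c0 <- max(1, floor(x - a)); c1 <- min(w, ceiling(x + a))
    if (r1 >= r0 && c1 >= c0) {
      rows <- r0:r1; cols <- c0:c1
      py <- rows - 0.5 - y
      px <- cols - 0.5 - x
      # rotate into the body frame
      lon <- outer(py, px, function(yy, xx) xx * cos(theta) + yy * sin(theta))
      lat <- outer(py, px, function(yy, xx) -xx * sin(theta) + yy * cos(theta))
      inside <- (lon / a)^2 + (lat / b)^2 <= 1
      for (ch in 1:3) {
        sub <- img[rows, cols, ch]
        sub[inside] <- 0.12
        img[rows, cols, ch] <- sub
      }
    }
  }
  img
}

#' Assemble a 2 x 4 composite frame from eight cage frames
#'
#' @param cage_frames list of 8 equally sized RGB arrays (row-major order:
#'   cages 1-4 on the top row).
#' @return single composite RGB array.
#' @export
compose_frames <- function(cage_frames) {
  stopifnot(length(cage_frames) == 8)
  d <- dim(cage_frames[[1]])
  rows <- lapply(c(0, 4), function(off) {
    do.call(function(...) .abind_cols(list(...)), cage_frames[off + 1:4])
  })
  out <- array(0, dim = c(2 * d[1], 4 * d[2], 3))
  out[1:d[1], , ] <- rows[[1]]
  out[d[1] + 1:d[1], , ] <- rows[[2]]
  out
}

.abind_cols <- function(arrs) {
  d <- dim(arrs[[1]])
  out <- array(0, dim = c(d[1], d[2] * length(arrs), 3))
  for (k in seq_along(arrs))
    out[, (k - 1) * d[2] + 1:d[2], ] <- arrs[[k]]
  out
}

#' Crop a composite frame sequence into per-cage sequences
#'
#' @param frames list of composite RGB arrays.
#' @param rects data.frame with columns x0, y0, x1, y1 (pixels, inclusive
#'   1-based bounds), one row per cage.
#' @return list with one frame list per cage rectangle.
#' @export
crop_composite <- function(frames, rects) {
  d <- dim(frames[[1]])
  if (any(rects$x0 < 1 | rects$y0 < 1 | rects$x1 > d[2] | rects$y1 > d[1]))
    stop("crop rectangle out of composite bounds")
  # overlapping rectangles are suspicious but tolerated
  if (nrow(rects) > 1) {
    for (i in seq_len(nrow(rects) - 1)) for (j in (i + 1):nrow(rects)) {
      if (rects$x0[i] <= rects$x1[j] && rects$x1[i] >= rects$x0[j] &&
          rects$y0[i] <= rects$y1[j] && rects$y1[i] >= rects$y0[j])
        warning("crop rectangles ", i, " and ", j, " overlap")
    }
  }
  lapply(seq_len(nrow(rects)), function(k) {
    lapply(frames, function(f)
      f[rects$y0[k]:rects$y1[k], rects$x0[k]:rects$x1[k], , drop = FALSE])
  })
}

#' The default 2 x 4 cage rectangle layout of a composite
#' @param height,width composite size in pixels.
#' @return data.frame of 8 rectangles (x0, y0, x1, y1).
#' @export
composite_layout <- function(height = 640, width = 960) {
  ch <- height / 2; cw <- width / 4
  grid <- expand.grid(col = 0:3, row = 0:1)
  data.frame(x0 = grid$col * cw + 1, y0 = grid$row * ch + 1,
             x1 = (grid$col + 1) * cw, y1 = (grid$row + 1) * ch)
}
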