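#' Cage geometry for one cage of the 8-cage assay
#'
#' Describes one cage in pixel coordinates (origin top-left, x rightward,
#' y downward): the cage bounds, the four quadrant polygons (home, wall,
#' food, window), the hut region (inside the home quadrant), the window
#' center and its proximity radius (40 px by default), food points, and
#' wall segments.  The default layout places the hut in the bottom-left
#' (home) quadrant and the window hole near the bottom-right corner,
#' mirroring the assay's cage arrangement.
#'
#' @param width,height cage size in pixels (defaults 240 x 320, one cage of
#'   the 640 x 960 two-by-four composite).
#' @param quadrants optional named list of polygons (matrices with columns
#'   x, y) partitioning the cage; names must be home, wall, food, window.
#' @param hut optional hut polygon; must lie inside the home quadrant.
#' @param window_center,window_radius window hole center point and the
#'   proximity radius in pixels used for "near the window" measures.
#' @param food_points matrix of food pellet locations (columns x, y).
#' @return an object of class `cage_geometry`.
#' @examples
#' geom <- cage_geometry()
#' names(geom$quadrants)
#' @export
cage_geometry <- function(width = 240, height = 320,
                          quadrants = NULL, hut = NULL,
                          window_center = NULL, window_radius = 40,
                          food_points = NULL) {
  stopifnot(width > 0, height > 0, window_radius > 0)
  rect <- function(x0, y0, x1, y1)
    cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
  xm <- width / 2; ym <- height / 2
  if (is.null(quadrants)) {
    quadrants <- list(
      wall   = rect(0, 0, xm, ym),          # top-left
      food   = rect(xm, 0, width, ym),      # top-right
      home   = rect(0, ym, xm, height),     # bottom-left, holds the hut
      window = rect(xm, ym, width, height)  # bottom-right, holds the hole
    )
  }
  stopifnot(setequal(names(quadrants), c("home", "wall", "food", "window")))
  if (is.null(hut))
    hut <- rect(0.1 * width, height - 0.38 * height,
                0.42 * width, height - 0.06 * height)
  if (is.null(window_center))
    window_center <- c(x = 0.9 * width, y = 0.92 * height)
  if (is.null(food_points))
    food_points <- cbind(x = c(0.75, 0.9) * width,
                         y = c(0.12, 0.2) * height)
  walls <- rbind(
    c(0, 0, width, 0), c(width, 0, width, height),
    c(width, height, 0, height), c(0, height, 0, 0))
  colnames(walls) <- c("x0", "y0", "x1", "y1")
  out <- list(width = width, height = height,
              quadrants = quadrants, hut = hut,
              window_center = window_center, window_radius = window_radius,
              food_points = food_points, wall_segments = walls)
  class(out) <- "cage_geometry"
  # the hut must sit inside the home quadrant
  stopifnot(all(point_in_polygon(out$hut[, 1], out$hut[, 2],
                                 quadrants$home, on_boundary = TRUE)))
  out
}

#' @export
print.cage_geometry <- function(x, ...) {
  cat("cage_geometry:", x$width, "x", x$height, "px; window radius",
      x$window_radius, "px\n")
  invisible(x)
}

#' Point-in-polygon test (ray casting)
#'
#' Even-odd ray casting with an optional tolerance for boundary points.
#' Small closed polygons only; vertices need not repeat the first point.
#'
#' @param x,y numeric vectors of point coordinates.
#' @param poly polygon matrix with columns x, y.
#' @param on_boundary if TRUE, points on (within `eps` of) an edge count as
#'   inside.
#' @param eps boundary tolerance in pixels.
#' @return logical vector.
#' @export
point_in_polygon <- function(x, y, poly, on_boundary = FALSE, eps = 1e-9) {
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  j <- c(n, seq_len(n - 1))
  inside <- rep(FALSE, length(x))
  for (k in seq_len(n)) {
    xi <- px[k]; yi <- py[k]; xj <- px[j[k]]; yj <- py[j[k]]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
  }
  if (on_boundary) {
    d <- rep(Inf, length(x))
    for (k in seq_len(n)) {
      d <- pmin(d, .dist_point_segment(x, y, px[k], py[k], px[j[k]], py[j[k]]))
    }
    inside <- inside | d <= eps
  }
  inside
}

# distance from points (x, y) to the segment (x0, y0)-(x1, y1), vectorized
# over the points
.dist_point_segment <- function(x, y, x0, y0, x1, y1) {
  dx <- x1 - x0; dy <- y1 - y0
  len2 <- dx * dx + dy * dy
  t <- if (len2 == 0) rep(0, length(x)) else
    pmin(1, pmax(0, ((x - x0) * dx + (y - y0) * dy) / len2))
  sqrt((x - (x0 + t * dx))^2 + (y - (y0 + t * dy))^2)
}

#' Minimum distance from points to any wall segment
#' @param x,y point coordinates.
#' @param geometry a `cage_geometry`.
#' @return numeric vector of distances in pixels.
#' @export
wall_distance <- function(x, y, geometry) {
  w <- geometry$wall_segments
  d <- rep(Inf, length(x))
  for (k in seq_len(nrow(w)))
    d <- pmin(d, .dist_point_segment(x, y, w[k, 1], w[k, 2], w[k, 3], w[k, 4]))
  d
}

#' Minimum distance from points to any food point
#' @param x,y point coordinates.
#' @param geometry a `cage_geometry`.
#' @return numeric vector of distances in pixels.
#' @export
food_distance <- function(x, y, geometry) {
  fp <- geometry$food_points
  d <- rep(Inf, length(x))
  for (k in seq_len(nrow(fp)))
    d <- pmin(d, sqrt((x - fp[k, 1])^2 + (y - fp[k, 2])^2))
  d
}

#' Assign points to cage quadrants
#'
#' Returns the quadrant (home, wall, food or window) containing each point.
#' Boundary points resolve to the quadrant whose centroid is nearest, so the
#' quadrants always partition the cage.
#'
#' @param x,y point coordinates (must lie inside the cage bounds).
#' @param geometry a `cage_geometry`.
#' @return character vector of quadrant names.
#' @export
assign_quadrant <- function(x, y, geometry) {
  stopifnot(length(x) == length(y))
  out_of_cage <- x < 0 | x > geometry$width | y < 0 | y > geometry$height
  if (any(out_of_cage & !is.na(x)))
    stop("point outside cage bounds")
  qn <- names(geometry$quadrants)
  res <- rep(NA_character_, length(x))
  for (nm in qn) {
    hit <- point_in_polygon(x, y, geometry$quadrants[[nm]]) & is.na(res)
    res[hit] <- nm
  }
  # boundary points: nearest quadrant centroid wins
  miss <- which(is.na(res) & !is.na(x))
  if (length(miss)) {
    cents <- vapply(geometry$quadrants, colMeans, numeric(2))
    d <- vapply(qn, function(nm)
      (x[miss] - cents[1, nm])^2 + (y[miss] - cents[2, nm])^2,
      numeric(length(miss)))
    d <- matrix(d, nrow = length(miss))
    res[miss] <- qn[max.col(-d)]
  }
  res
}

#' Is a point inside the hut region?
#' @param x,y point coordinates.
#' @param geometry a `cage_geometry`.
#' @return logical vector.
#' @export
in_hut <- function(x, y, geometry) {
  point_in_polygon(x, y, geometry$hut, on_boundary = TRUE)
}
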