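#' Write a pose track in the DeepLabCut CSV dialect
#'
#' Three header rows (scorer / bodyparts / coords) followed by one row
#' per frame: a 0-based frame index and x, y, likelihood per body part.
#'
#' @param pose a `pose_track`.
#' @param path output file.
#' @param scorer scorer name for the first header row.
#' @export
write_pose_table <- function(pose, path, scorer = "homecage8") {
  parts <- names(pose$parts)
  h1 <- c("scorer", rep(scorer, 3 * length(parts)))
  h2 <- c("bodyparts", rep(parts, each = 3))
  h3 <- c("coords", rep(c("x", "y", "likelihood"), length(parts)))
  dat <- do.call(cbind, lapply(pose$parts, function(p)
    cbind(p$x, p$y, p$likelihood)))
  dat <- cbind(seq_len(nrow(dat)) - 1L, dat)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(h1, collapse = ","),
               paste(h2, collapse = ","),
               paste(h3, collapse = ",")), con)
  utils::write.table(dat, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a DeepLabCut-dialect pose table
#'
#' Parses the 3-header-row CSV dialect and extracts the eight required
#' mouse body parts by name.  Extra markers (cage features, stimuli) are
#' retained unparsed in the `extra_parts` attribute.  A missing required
#' part is an error naming the part.
#'
#' @param path CSV file.
#' @param frame_interval seconds between frames (reconstructs
#'   timestamps from the frame index).
#' @param required body part names that must be present.
#' @return a `pose_track`.
#' @export
read_pose_table <- function(path, frame_interval = 1,
                            required = POSE_PARTS) {
  head3 <- readLines(path, n = 3)
  if (length(head3) < 3 || !startsWith(head3[1], "scorer") ||
      !startsWith(head3[2], "bodyparts") || !startsWith(head3[3], "coords"))
    stop("malformed pose table header (expected scorer/bodyparts/coords rows)")
  bodyparts <- strsplit(head3[2], ",", fixed = TRUE)[[1]][-1]
  coords <- strsplit(head3[3], ",", fixed = TRUE)[[1]][-1]
  dat <- utils::read.csv(path, skip = 3, header = FALSE)
  missing <- setdiff(required, unique(bodyparts))
  if (length(missing))
    stop("pose table is missing required body part(s): ",
         paste(missing, collapse = ", "))
  parts <- lapply(required, function(pt) {
    cols <- which(bodyparts == pt) + 1L  # +1 for the frame-index column
    nm <- coords[cols - 1L]
    df <- data.frame(x = dat[[cols[nm == "x"]]],
                     y = dat[[cols[nm == "y"]]],
                     likelihood = dat[[cols[nm == "likelihood"]]])
    df
  })
  names(parts) <- required
  out <- list(time_s = (dat[[1]]) * frame_interval, parts = parts)
  class(out) <- "pose_track"
  attr(out, "extra_parts") <- setdiff(unique(bodyparts), required)
  out
}

#' Write a centroid track CSV
#' @param track a `mouse_track`.
#' @param path output file.
#' @export
write_track <- function(track, path) {
  df <- data.frame(time_s = track$time_s,
                   centroid_x = track$x, centroid_y = track$y,
                   head_x = track$head_x, head_y = track$head_y,
                   area = track$area, elongation = track$elongation,
                   in_hut = track$in_hut, quadrant = track$quadrant)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a centroid track CSV
#' @param path CSV produced by [write_track()].
#' @return a `mouse_track`.
#' @export
read_track <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "centroid_x", "centroid_y", "in_hut")
  if (!all(need %in% names(df)))
    stop("track CSV is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  out <- data.frame(time_s = df$time_s, x = df$centroid_x,
                    y = df$centroid_y,
                    head_x = df$head_x %||% NA_real_,
                    head_y = df$head_y %||% NA_real_,
                    area = df$area %||% NA_real_,
                    elongation = df$elongation %||% NA_real_,
                    in_hut = df$in_hut,
                    quadrant = df$quadrant %||% NA_character_,
                    stringsAsFactors = FALSE)
  class(out) <- c("mouse_track", "data.frame")
  out
}

#' Write / read a syllable sequence CSV
#' @param seq a `syllable_seq`.
#' @param path CSV file.
#' @export
write_syllables <- function(seq, path) {
  utils::write.csv(seq[, c("time_s", "label")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_syllables
#' @param alphabet optional alphabet to attach on read.
#' @export
read_syllables <- function(path, alphabet = NULL) {
  df <- utils::read.csv(path, colClasses = c("numeric", "character"))
  if (!all(c("time_s", "label") %in% names(df)))
    stop("syllable CSV must have time_s and label columns")
  class(df) <- c("syllable_seq", "data.frame")
  attr(df, "alphabet") <- alphabet %||% sort(unique(df$label))
  df
}

#' Write / read a footfall event log CSV
#' @param run a `gait_run`.
#' @param path CSV file.
#' @export
write_footfalls <- function(run, path) {
  utils::write.csv(run$events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_footfalls
#' @export
read_footfalls <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  gait_run(ev)
}

#' Write a behavioral-profile table CSV
#'
#' One row per profile; columns ordered syllable durations (d*), then
#' syllable frequencies (f*), then the pose-derived block, then the
#' tracking-derived block.
#'
#' @param profiles a `behavior_profiles` matrix.
#' @param path CSV file.
#' @export
write_profiles <- function(profiles, path) {
  cn <- colnames(profiles)
  ord <- c(grep("^d", cn), grep("^f", cn),
           grep("^dlc_", cn), grep("^fiji_", cn))
  ord <- unique(c(ord, seq_along(cn)))
  df <- data.frame(id = rownames(profiles),
                   group = attr(profiles, "group") %||% NA_character_,
                   profiles[, ord, drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, setdiff(names(df), c("id", "group")), drop = FALSE])
  rownames(mat) <- df$id
  structure(mat, group = if ("group" %in% names(df)) df$group else NULL,
            class = c("behavior_profiles", "matrix", "array"))
}

#' Write frames as numbered PNG files
#' @param frames list of RGB arrays.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return character vector of file paths.
#' @export
write_frames <- function(frames, dir, prefix = "frame") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_%06d.png", prefix,
                                  seq_along(frames)))
  for (k in seq_along(frames)) png::writePNG(frames[[k]], paths[k])
  invisible(paths)
}

#' Read a directory of numbered PNG frames
#' @param dir directory of PNG files.
#' @return list of RGB arrays in file-name order.
#' @export
read_frames <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop("no PNG frames in ", dir)
  lapply(files, function(f) {
    a <- png::readPNG(f)
    if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
    a[, , 1:3]
  })
}
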