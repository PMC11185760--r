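#' Segment a syllable sequence into bouts
#'
#' A bout is a maximal run of identical labels; the concatenation of
#' bouts reconstructs the sequence exactly.
#'
#' @param seq a `syllable_seq` data.frame (time_s, label).
#' @return data.frame with columns label, start_s, end_s (end exclusive,
#'   on the frame grid).
#' @export
segment_bouts <- function(seq) {
  if (nrow(seq) == 0) stop("empty syllable sequence")
  r <- rle(seq$label)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dt <- if (nrow(seq) > 1) seq$time_s[2] - seq$time_s[1] else 1
  data.frame(label = r$values,
             start_s = seq$time_s[starts],
             end_s = seq$time_s[ends] + dt,
             stringsAsFactors = FALSE)
}

#' Summarize a syllable sequence
#'
#' Per-syllable usage frequency (share of bout onsets), mean bout
#' duration (s), and the bout-level transition matrix (self-transitions
#' are impossible since bouts are maximal runs).  A frame-share
#' frequency variant is attached as attribute `frame_share`.
#'
#' @param seq a `syllable_seq`.
#' @param interval optional `c(start_s, end_s)` restriction (bouts are
#'   assigned to the interval containing their onset).
#' @param alphabet label alphabet (default from the sequence attribute,
#'   else the observed labels).
#' @return a `syllable_summary` list: `frequency`, `duration`,
#'   `transition`, `n_expressed`, `n_bouts`; all-NA sentinel summary if
#'   the interval holds no bout onset.
#' @export
syllable_summary <- function(seq, interval = NULL, alphabet = NULL) {
  if (is.null(alphabet))
    alphabet <- attr(seq, "alphabet") %||% sort(unique(seq$label))
  alphabet <- as.character(alphabet)
  bouts <- segment_bouts(seq)
  if (!is.null(interval))
    bouts <- bouts[bouts$start_s >= interval[1] & bouts$start_s < interval[2], ]
  m <- length(alphabet)
  if (nrow(bouts) == 0) {
    out <- list(frequency = stats::setNames(rep(NA_real_, m), alphabet),
                duration = stats::setNames(rep(NA_real_, m), alphabet),
                transition = matrix(NA_real_, m, m,
                                    dimnames = list(alphabet, alphabet)),
                n_expressed = 0L, n_bouts = 0L)
    class(out) <- "syllable_summary"
    return(out)
  }
  lab <- factor(bouts$label, levels = alphabet)
  counts <- table(lab)
  freq <- as.numeric(counts) / nrow(bouts)
  dur <- tapply(bouts$end_s - bouts$start_s, lab, mean)
  dur <- as.numeric(dur)  # NA for unexpressed syllables
  freq[is.na(freq)] <- 0
  trans <- matrix(0, m, m, dimnames = list(alphabet, alphabet))
  if (nrow(bouts) > 1) {
    from <- as.integer(lab[-nrow(bouts)]); to <- as.integer(lab[-1])
    ok <- !is.na(from) & !is.na(to)
    for (k in which(ok)) trans[from[k], to[k]] <- trans[from[k], to[k]] + 1
    rs <- rowSums(trans)
    never_left <- rs == 0 & as.numeric(counts) > 0
    trans <- trans / ifelse(rs > 0, rs, 1)
    attr(trans, "never_left") <- alphabet[never_left]
  }
  # frame-share frequency variant
  frame_share <- tapply(bouts$end_s - bouts$start_s, lab, sum)
  frame_share[is.na(frame_share)] <- 0
  frame_share <- as.numeric(frame_share) / sum(bouts$end_s - bouts$start_s)
  out <- list(frequency = stats::setNames(freq, alphabet),
              duration = stats::setNames(dur, alphabet),
              transition = trans,
              n_expressed = sum(counts > 0),
              n_bouts = nrow(bouts))
  attr(out, "frame_share") <- stats::setNames(frame_share, alphabet)
  class(out) <- "syllable_summary"
  out
}

#' @export
print.syllable_summary <- function(x, ...) {
  cat("syllable_summary:", x$n_bouts, "bouts,", x$n_expressed,
      "of", length(x$frequency), "syllables expressed\n")
  invisible(x)
}

#' Per-period syllable summaries
#'
#' Applies [syllable_summary()] to each requested 10-minute period of
#' the assay.
#'
#' @param seq a `syllable_seq`.
#' @param schedule the assay schedule.
#' @param periods integer period ids (1-based).
#' @param alphabet optional label alphabet.
#' @return named list of `syllable_summary`, one per period.
#' @export
period_frequencies <- function(seq, schedule, periods,
                               alphabet = NULL) {
  stopifnot(all(periods >= 1), all(periods <= schedule$n_periods))
  out <- lapply(periods, function(p)
    syllable_summary(seq, period_window(schedule, p), alphabet))
  names(out) <- paste0("period", periods)
  out
}

#' Syllable block of a behavioral profile
#'
#' Emits the 29 frequency and 29 duration profile entries (`f<id>`,
#' `d<id>`) of a summary over the full alphabet, in stable order.
#' Unexpressed syllables get frequency 0 and an undefined (NA) duration.
#'
#' @param summary a `syllable_summary` over the 29-id alphabet.
#' @return named numeric vector of 58 entries.
#' @export
syllable_profile_entries <- function(summary) {
  ids <- names(summary$frequency)
  c(stats::setNames(as.numeric(summary$frequency), paste0("f", ids)),
    stats::setNames(as.numeric(summary$duration), paste0("d", ids)))
}

#' Export a transition graph as an edge list
#'
#' One node per expressed syllable; edge weights are the transition
#' probabilities.
#'
#' @param summary a `syllable_summary`.
#' @param min_weight drop edges below this probability.
#' @return data.frame from, to, weight.
#' @export
transition_edges <- function(summary, min_weight = 0) {
  tr <- summary$transition
  idx <- which(tr > min_weight, arr.ind = TRUE)
  data.frame(from = rownames(tr)[idx[, 1]],
             to = colnames(tr)[idx[, 2]],
             weight = tr[idx],
             stringsAsFactors = FALSE)
}
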