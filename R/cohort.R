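#' Simulate a cohort and compute its behavior-parameter table
#'
#' For every requested group and mouse: simulates a pose track and an
#' independent partner track (window visits correlated at the group's
#' co-occurrence rate), derives the centroid track from the generator
#' ground truth, simulates a syllable sequence with the group's
#' transition bias, and computes the 67 supervised parameters plus the
#' 58 syllable profile entries.
#'
#' Per-mouse seeds are derived deterministically from `seed` so the
#' whole cohort is reproducible.
#'
#' @param groups list of [group_spec()]s.
#' @param n_per_group mice per group.
#' @param schedule,geometry assay schedule and cage geometry.
#' @param config a [sim_config()].
#' @param seed base integer seed.
#' @param timepoint_from_age use the group's age as the screen timepoint
#'   column (default TRUE).
#' @return data.frame: mouse, group, genotype, age, treatment,
#'   timepoint, the 67 parameter columns (fiji_/dlc_ prefixes) and the
#'   58 syllable columns (f*/d*).
#' @export
simulate_cohort <- function(groups, n_per_group = 8,
                            schedule = make_schedule(),
                            geometry = cage_geometry(),
                            config = sim_config(),
                            seed = 1,
                            timepoint_from_age = TRUE) {
  rows <- list()
  counter <- 0L
  for (g in groups) {
    for (m in seq_len(n_per_group)) {
      counter <- counter + 1L
      s <- (seed * 1000L + counter * 7L) %% .Machine$integer.max
      pars <- sim_params(g)
      pose <- simulate_pose_track(g, schedule, geometry, seed = s,
                                  config = config, params = pars)
      partner <- simulate_pose_track(group_spec("WT", g$age), schedule,
                                     geometry, seed = s + 1L,
                                     config = config)
      partner <- correlate_window_visits(partner, pose, geometry,
                                         cooc = pars$cooc, seed = s + 2L)
      track <- truth_track(pose, geometry)
      sg <- syllable_generator_params(focus = pars$syl_focus,
                                      dur_bias = pars$syl_dur)
      syl <- simulate_syllables(sg$transition, sg$mean_durations,
                                schedule, seed = s + 3L)
      pv <- compute_param_vector(track, filter_pose(pose),
                                 filter_pose(partner), geometry, schedule)
      se <- syllable_profile_entries(syllable_summary(syl))
      row <- data.frame(mouse = sprintf("%s_m%02d", g$label, m),
                        group = g$label, genotype = g$genotype,
                        age = g$age, treatment = g$treatment,
                        timepoint = if (timepoint_from_age) g$age else "t1",
                        t(c(pv, se)), check.names = FALSE,
                        stringsAsFactors = FALSE)
      rows[[counter]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' The full treatment-study design
#'
#' The ten experimental groups clustered in the assay: untreated WT and
#' 3xTg-AD mice plus cyclosporine-, nebivolol- and cabozantinib-treated
#' 3xTg-AD mice, each at the young and old timepoints.
#'
#' @return list of [group_spec()]s.
#' @export
study_groups <- function() {
  out <- list()
  for (age in c("young", "old")) {
    out <- c(out, list(group_spec("WT", age)))
    for (tr in c("none", "csa", "neb", "cab"))
      out <- c(out, list(group_spec("AD", age, tr)))
  }
  out
}

#' The untreated screening design
#'
#' Untreated WT and 3xTg-AD mice at the three screening timepoints
#' (young, old, aged).
#'
#' @return list of [group_spec()]s.
#' @export
screen_groups <- function() {
  out <- list()
  for (age in c("young", "old", "aged"))
    out <- c(out, list(group_spec("WT", age), group_spec("AD", age)))
  out
}
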