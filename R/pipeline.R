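#' Default pipeline configuration
#'
#' All tunable thresholds of the pipeline in one declarative list:
#' likelihood filter (0.90), window proximity radius (40 px),
#' motion-class cut points (2/10/40/80 px/s), stretch-attend-posture
#' thresholds (elongation 2.0, speed 2 px/s), significance level, assay
#' time scale and cohort size.  Unknown keys passed in `...` are
#' rejected.
#'
#' @param ... overrides of the default fields.
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    out_dir = tempfile("homecage8_run_"),
    seed = 1L,
    n_per_group = 8L,
    scale = 1,
    design = "screen",            # "screen" or "study"
    likelihood_threshold = 0.90,
    window_radius = 40,
    motion_thresholds = c(2, 10, 40, 80),
    sap_elongation = 2.0,
    sap_speed = 2.0,
    alpha = 0.05,
    cluster_k = 3L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with `run_config` fields.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the analysis pipeline
#'
#' Executes the pipeline stages in dependency order on a simulated
#' cohort: `simulate` (cohort parameter table), `screen` (per-parameter
#' Wilcoxon screens, untreated AD vs WT), `profile` (group-level
#' 125-parameter profiles, PCA, PC1 weights, weighted Ward clustering).
#' Artifacts are written under `config$out_dir` together with a run log
#' echoing every threshold and seed.
#'
#' @param config a [run_config()].
#' @param stages which stages to run (default all, in order).
#' @return invisibly, a list with the in-memory artifacts (`cohort`,
#'   `screens`, `profiles`, `pca`, `weights`, `clustering`, `paths`).
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "screen", "profile")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  logln <- function(...) cat(..., "\n", sep = "", file = log_path,
                             append = TRUE)
  cat("", file = log_path)
  logln("homecage8 run ", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  for (nm in names(unclass(config)))
    logln("config ", nm, " = ", paste(format(config[[nm]]), collapse = " "))
  out <- list(paths = character(0))
  schedule <- make_schedule(scale = config$scale)
  geometry <- cage_geometry(window_radius = config$window_radius)

  if ("simulate" %in% stages) {
    groups <- if (config$design == "study") study_groups() else
      screen_groups()
    cohort <- simulate_cohort(groups, config$n_per_group, schedule,
                              geometry, sim_config(seed = config$seed),
                              seed = config$seed)
    p <- file.path(config$out_dir, "cohort_params.csv")
    utils::write.csv(cohort, p, row.names = FALSE)
    out$cohort <- cohort
    out$paths <- c(out$paths, p)
    logln("stage simulate: ", nrow(cohort), " mice -> ", p)
  }
  cohort <- out$cohort
  if (is.null(cohort)) {
    p <- file.path(config$out_dir, "cohort_params.csv")
    if (!file.exists(p))
      stop("missing upstream artifact ", p, "; run the simulate stage first")
    cohort <- utils::read.csv(p, check.names = FALSE,
                              stringsAsFactors = FALSE)
    out$cohort <- cohort
  }

  if ("screen" %in% stages) {
    fiji <- grep("^fiji_", names(cohort), value = TRUE)
    dlc <- grep("^dlc_", names(cohort), value = TRUE)
    sub <- cohort[cohort$treatment == "none", ]
    sub$group <- sub$genotype  # screens compare genotypes within timepoint
    screens <- list(
      fiji = wilcoxon_screen(sub, fiji, c("WT", "AD"), config$alpha),
      dlc = wilcoxon_screen(sub, dlc, c("WT", "AD"), config$alpha))
    res <- rbind(cbind(table = "fiji", screens$fiji$results),
                 cbind(table = "dlc", screens$dlc$results))
    p <- file.path(config$out_dir, "screen_results.csv")
    utils::write.csv(res, p, row.names = FALSE)
    out$screens <- screens
    out$paths <- c(out$paths, p)
    logln("stage screen: fiji ", screens$fiji$n_significant_any,
          ", dlc ", screens$dlc$n_significant_any,
          " significant parameter(s) -> ", p)
  }

  if ("profile" %in% stages) {
    param_cols <- grep("^(fiji|dlc)_", names(cohort), value = TRUE)
    syl_cols <- grep("^[fd](\\d+)$", names(cohort), value = TRUE)
    profiles <- assemble_profiles(
      cohort[, c("mouse", "group", param_cols)],
      cohort[, c("mouse", syl_cols)], by_group = TRUE)
    pca <- profile_pca(profiles)
    w <- pc1_weights(pca)
    wc <- weighted_cluster(profiles, w, k = config$cluster_k)
    rep3 <- cluster_report(wc, k = config$cluster_k)
    p1 <- file.path(config$out_dir, "profiles.csv")
    write_profiles(profiles, p1)
    p2 <- file.path(config$out_dir, "dendrogram.nwk")
    writeLines(rep3$newick, p2)
    p3 <- file.path(config$out_dir, "pc1_weights.csv")
    utils::write.csv(data.frame(parameter = names(w), weight = w,
                                row.names = NULL), p3, row.names = FALSE)
    out$profiles <- profiles; out$pca <- pca; out$weights <- w
    out$clustering <- wc; out$report <- rep3
    out$paths <- c(out$paths, p1, p2, p3)
    logln("stage profile: ", nrow(profiles), " group profiles, PC1+PC2 = ",
          round(100 * sum(pca$explained[1:2]), 1), "% -> ", p1)
  }
  invisible(out)
}
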