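#' Shapiro-Wilk normality gate
#'
#' Records, per group, whether a sample passes the Shapiro-Wilk
#' normality test at `alpha` (used to justify the nonparametric tests
#' downstream).  Degenerate samples (fewer than 3 values, or constant)
#' are flagged as not normal with an NA p-value.
#'
#' @param samples list of numeric vectors (one per group).
#' @param alpha significance level (default 0.05).
#' @return data.frame: group, n, p, normal.
#' @export
normality_gate <- function(samples, alpha = 0.05) {
  if (is.null(names(samples)))
    names(samples) <- paste0("group", seq_along(samples))
  rows <- lapply(names(samples), function(g) {
    x <- samples[[g]][!is.na(samples[[g]])]
    if (length(x) < 3 || stats::sd(x) == 0)
      return(data.frame(group = g, n = length(x), p = NA_real_,
                        normal = NA))
    p <- stats::shapiro.test(x)$p.value
    data.frame(group = g, n = length(x), p = p, normal = p >= alpha)
  })
  do.call(rbind, rows)
}

#' Per-parameter Wilcoxon rank-sum screens
#'
#' For every parameter column and every age timepoint, runs the unpaired
#' two-sided Wilcoxon rank-sum (Mann-Whitney) test between the two
#' groups (exact null distribution for small tie-free samples, normal
#' approximation with tie correction otherwise), reports the direction
#' of the effect as the median difference (second minus first group),
#' and counts the parameters significant in at least one timepoint.
#' No multiple-testing correction is applied by default (each parameter
#' is screened at raw p < alpha); set `adjust = "BH"` for a
#' Benjamini-Hochberg variant.
#'
#' @param data data.frame holding the parameter columns plus `group` and
#'   `timepoint` columns.
#' @param params character vector of parameter column names.
#' @param groups length-2 character: the two group labels to compare
#'   (direction is `groups[2]` minus `groups[1]`).
#' @param alpha significance level.
#' @param adjust "none" (default) or "BH" across parameters within a
#'   timepoint.
#' @return a `wilcoxon_screen` list: `results` (tidy data.frame:
#'   parameter, timepoint, statistic, p, direction, significant),
#'   `significant_any` (parameters significant in >= 1 timepoint),
#'   `n_significant_any`.
#' @export
wilcoxon_screen <- function(data, params, groups, alpha = 0.05,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(length(groups) == 2,
            all(c("group", "timepoint") %in% names(data)))
  tps <- unique(data$timepoint)
  rows <- list()
  for (tp in tps) {
    sub <- data[data$timepoint == tp, ]
    ps <- rep(NA_real_, length(params))
    for (j in seq_along(params)) {
      x <- sub[[params[j]]][sub$group == groups[1]]
      y <- sub[[params[j]]][sub$group == groups[2]]
      if (!length(x) || !length(y)) stop("empty group for ", params[j])
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (!length(x) || !length(y)) {
        # the parameter is undefined throughout one group: no test
        rows[[length(rows) + 1]] <- data.frame(
          parameter = params[j], timepoint = tp, statistic = NA_real_,
          p = NA_real_, direction = "none", stringsAsFactors = FALSE)
        ps[j] <- NA_real_
        next
      }
      if (stats::sd(c(x, y)) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          parameter = params[j], timepoint = tp, statistic = NA_real_,
          p = 1, direction = "none", stringsAsFactors = FALSE)
        ps[j] <- 1
        next
      }
      wt <- suppressWarnings(stats::wilcox.test(y, x, exact = NULL))
      dirn <- stats::median(y) - stats::median(x)
      rows[[length(rows) + 1]] <- data.frame(
        parameter = params[j], timepoint = tp,
        statistic = unname(wt$statistic), p = wt$p.value,
        direction = if (dirn > 0) "increase" else if (dirn < 0)
          "decrease" else "none",
        stringsAsFactors = FALSE)
      ps[j] <- wt$p.value
    }
    if (adjust == "BH") {
      padj <- stats::p.adjust(ps, method = "BH")
      for (j in seq_along(params))
        rows[[length(rows) - length(params) + j]]$p <- padj[j]
    }
  }
  res <- do.call(rbind, rows)
  res$significant <- !is.na(res$p) & res$p < alpha
  sig_any <- sort(unique(res$parameter[res$significant]))
  structure(list(results = res, significant_any = sig_any,
                 n_significant_any = length(sig_any),
                 alpha = alpha, groups = groups),
            class = "wilcoxon_screen")
}

#' @export
print.wilcoxon_screen <- function(x, ...) {
  cat("wilcoxon_screen:", x$groups[2], "vs", x$groups[1], "-",
      x$n_significant_any, "parameter(s) significant in >= 1 timepoint",
      "at alpha", x$alpha, "\n")
  invisible(x)
}

#' Kruskal-Wallis omnibus with Dunn's post hoc test
#'
#' Rank-based omnibus test across three or more groups (with tie
#' correction), followed by Dunn's two-sided z-tests on mean ranks for
#' all group pairs.  Degenerate data (all values identical) is flagged
#' with NA statistics.
#'
#' @param samples named list of numeric vectors, one per group.
#' @param alpha significance level.
#' @param p_adjust p-value adjustment for the Dunn pairwise tests
#'   (default "none", matching a raw-alpha screen; any
#'   [stats::p.adjust()] method is accepted).
#' @return list: `omnibus` (htest-like list with statistic, df, p),
#'   `dunn` (data.frame: group1, group2, z, p, significant),
#'   `degenerate`.
#' @export
kruskal_dunn <- function(samples, alpha = 0.05, p_adjust = "none") {
  if (is.null(names(samples)))
    names(samples) <- paste0("group", seq_along(samples))
  if (any(vapply(samples, length, integer(1)) == 0))
    stop("empty group")
  if (length(samples) < 3) stop("need >= 3 groups for the omnibus test")
  x <- unlist(samples, use.names = FALSE)
  g <- factor(rep(names(samples), vapply(samples, length, integer(1))),
              levels = names(samples))
  if (stats::sd(x) == 0) {
    return(list(omnibus = list(statistic = NA_real_, df = NA_integer_,
                               p.value = NA_real_),
                dunn = NULL, degenerate = TRUE))
  }
  kw <- stats::kruskal.test(x, g)
  # Dunn: z-tests on mean ranks with tie correction
  n <- length(x)
  r <- rank(x)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_rank <- tapply(r, g, mean)
  ni <- tapply(r, g, length)
  pairs <- utils::combn(names(samples), 2)
  dunn <- data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    z = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ni[[a]] + 1 / ni[[b]]))
    z <- (mean_rank[[a]] - mean_rank[[b]]) / se
    dunn$z[k] <- z
    dunn$p[k] <- 2 * stats::pnorm(-abs(z))
  }
  dunn$p <- stats::p.adjust(dunn$p, method = p_adjust)
  dunn$significant <- dunn$p < alpha
  list(omnibus = list(statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p.value = kw$p.value),
       dunn = dunn, degenerate = FALSE)
}

#' Two-way ANOVA with conditional Tukey HSD
#'
#' Genotype x age (or any two crossed factors) analysis of variance;
#' when the interaction is significant at `alpha`, Tukey's HSD is run on
#' the cell means (and recorded as skipped otherwise).
#'
#' @param values numeric response.
#' @param factor1,factor2 the two crossed factors.
#' @param alpha significance level for the interaction gate.
#' @return list: `anova` (the summary table as data.frame), `tukey`
#'   (TukeyHSD result or NULL), `tukey_run` (logical).
#' @export
anova2_tukey <- function(values, factor1, factor2, alpha = 0.05) {
  f1 <- factor(factor1); f2 <- factor(factor2)
  if (nlevels(f1) < 2 || nlevels(f2) < 2)
    stop("both factors need >= 2 levels (a level row/column of cells is empty)")
  if (any(table(f1, f2) == 0)) stop("empty factor cell")
  fit <- stats::aov(values ~ f1 * f2)
  tab <- summary(fit)[[1]]
  names(tab) <- trimws(names(tab))
  p_int <- tab[["Pr(>F)"]][3]
  tukey_run <- is.finite(p_int) && p_int < alpha
  tk <- if (tukey_run) stats::TukeyHSD(fit) else NULL
  list(anova = as.data.frame(tab), tukey = tk, tukey_run = tukey_run)
}
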