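#' Assemble 125-parameter behavioral profiles
#'
#' Concatenates, per mouse, the 15 tracking-derived parameters, the 52
#' pose-derived parameters and the 58 syllable entries (29 usage
#' frequencies + 29 mean bout durations) into one named 125-vector, and
#' optionally averages mice into group-level profiles.  Undefined
#' entries are imputed by the group (or cohort) mean of the parameter
#' and flagged in the `imputed` attribute.
#'
#' @param param_table data.frame of the 67 supervised parameters, one
#'   row per mouse (columns as produced by [compute_param_vector()]),
#'   plus `mouse` and `group` columns.
#' @param syllable_entries data.frame of the 58 syllable entries
#'   (`f*`/`d*` columns), one row per mouse, with a `mouse` column.
#' @param by_group average mice into per-group profiles?
#' @return a `behavior_profiles` object: numeric matrix (profiles x 125
#'   parameters) with rownames = mouse or group labels; attributes
#'   `group` (per-row group label) and `imputed`.
#' @export
assemble_profiles <- function(param_table, syllable_entries,
                              by_group = FALSE) {
  stopifnot(all(c("mouse", "group") %in% names(param_table)),
            "mouse" %in% names(syllable_entries))
  if (!all(param_table$mouse %in% syllable_entries$mouse))
    stop("missing syllable block for some mice")
  idx <- match(param_table$mouse, syllable_entries$mouse)
  sy <- syllable_entries[idx, setdiff(names(syllable_entries), "mouse"),
                         drop = FALSE]
  pa <- param_table[, setdiff(names(param_table), c("mouse", "group")),
                    drop = FALSE]
  mat <- as.matrix(cbind(pa, sy))
  rownames(mat) <- param_table$mouse
  if (ncol(mat) != 125)
    stop("expected 125 parameters, got ", ncol(mat))
  grp <- param_table$group
  # impute undefined entries by group mean (cohort mean as fallback)
  imputed <- which(is.na(mat), arr.ind = TRUE)
  if (nrow(imputed)) {
    for (k in seq_len(nrow(imputed))) {
      i <- imputed[k, 1]; j <- imputed[k, 2]
      same <- grp == grp[i]
      v <- mat[same, j]
      fill <- if (any(!is.na(v))) mean(v, na.rm = TRUE) else
        mean(mat[, j], na.rm = TRUE)
      mat[i, j] <- fill
    }
  }
  if (by_group) {
    glev <- unique(grp)
    gm <- t(vapply(glev, function(g)
      colMeans(mat[grp == g, , drop = FALSE]), numeric(ncol(mat))))
    rownames(gm) <- glev
    mat <- gm
    grp <- glev
  }
  structure(mat, group = grp,
            imputed = if (nrow(imputed)) imputed else NULL,
            class = c("behavior_profiles", "matrix", "array"))
}

#' Principal component analysis of behavioral profiles
#'
#' PCA of the per-parameter z-scored profile matrix.  Zero-variance
#' parameters are dropped with a warning.  Loadings are sign-fixed so
#' the largest-magnitude loading of each component is positive.
#'
#' @param profiles profile matrix (profiles x parameters).
#' @param standardize z-score each parameter first (default TRUE).
#' @return list: `loadings` (parameters x components), `explained`
#'   (variance ratios, summing to 1), `scores`, `dropped` (names of
#'   zero-variance parameters).
#' @export
profile_pca <- function(profiles, standardize = TRUE) {
  x <- as.matrix(profiles)
  if (nrow(x) < 3) stop("need at least 3 profiles for PCA")
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0 | is.na(sds)]
  if (length(dropped)) {
    warning("dropping zero-variance parameters: ",
            paste(dropped, collapse = ", "))
    x <- x[, !(colnames(x) %in% dropped), drop = FALSE]
  }
  p <- stats::prcomp(x, center = TRUE, scale. = standardize)
  load <- p$rotation
  scores <- p$x
  for (k in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, k])), k] < 0) {
      load[, k] <- -load[, k]
      scores[, k] <- -scores[, k]
    }
  }
  expl <- p$sdev^2 / sum(p$sdev^2)
  list(loadings = load, explained = expl, scores = scores,
       dropped = dropped)
}

#' PC1-loading weights
#'
#' Per-parameter weights proportional to the magnitude of the loading on
#' the first principal component, normalized so the largest weight is 1.
#' Parameters dropped from the PCA (zero variance) get weight 0.
#'
#' @param pca a [profile_pca()] result.
#' @param mode "abs" (|loading|, default), "raw" (negative loadings give
#'   weight 0 after normalization by the maximum) or "squared".
#' @return named weight vector over all parameters seen by the PCA
#'   (including dropped ones).
#' @export
pc1_weights <- function(pca, mode = c("abs", "raw", "squared")) {
  mode <- match.arg(mode)
  l1 <- pca$loadings[, 1]
  if (all(l1 == 0)) stop("all-zero PC1")
  w <- switch(mode,
              abs = abs(l1),
              raw = pmax(l1, 0),
              squared = l1^2)
  if (max(w) == 0) stop("degenerate PC1 weights")
  w <- w / max(w)
  if (length(pca$dropped))
    w <- c(w, stats::setNames(rep(0, length(pca$dropped)), pca$dropped))
  w
}

#' Weighted hierarchical clustering of behavioral profiles
#'
#' Z-scores each parameter, multiplies by its weight, computes pairwise
#' Euclidean distances and applies Ward linkage (the Ward.D2 convention,
#' operating on the distances themselves).  With all weights 1 this is
#' exactly unweighted Ward clustering on z-scored data.
#'
#' @param profiles profile matrix (profiles x parameters).
#' @param weights named weight vector (default all 1); keys must cover
#'   the profile parameters.
#' @param k optional number of flat clusters to cut.
#' @return list: `hclust` (stable leaf order via [stats::hclust()]),
#'   `clusters` (named integer vector if `k` given), `weighted` (the
#'   weighted z-scored matrix).
#' @export
weighted_cluster <- function(profiles, weights = NULL, k = NULL) {
  x <- as.matrix(profiles)
  if (is.null(weights))
    weights <- stats::setNames(rep(1, ncol(x)), colnames(x))
  if (!all(colnames(x) %in% names(weights)))
    stop("weights do not cover all profile parameters")
  if (!is.null(k) && k > nrow(x)) stop("k exceeds the number of profiles")
  z <- scale(x)
  z[, attr(z, "scaled:scale") == 0] <- 0
  zw <- sweep(z, 2, weights[colnames(x)], `*`)
  d <- stats::dist(zw, method = "euclidean")
  hc <- stats::hclust(d, method = "ward.D2")
  clusters <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  list(hclust = hc, clusters = clusters, weighted = zw)
}

#' Cluster report
#'
#' Leaf ordering, per-cluster membership and the weighted standardized
#' matrix in heatmap (leaf) order.
#'
#' @param wc a [weighted_cluster()] result.
#' @param k number of flat clusters (default 3).
#' @return list: `order` (leaf labels in dendrogram order), `members`
#'   (list of label vectors per cluster), `matrix` (weighted z-scored
#'   profiles in leaf order), `newick` (dendrogram in Newick format).
#' @export
cluster_report <- function(wc, k = 3) {
  hc <- wc$hclust
  labs <- hc$labels %||% as.character(seq_along(hc$order))
  cl <- stats::cutree(hc, k = min(k, length(labs)))
  members <- split(names(cl), cl)
  nwk <- if (length(labs) > 2)
    ape::write.tree(ape::as.phylo(hc)) else
      paste0("(", paste(labs, collapse = ","), ");")
  list(order = labs[hc$order],
       members = members,
       matrix = wc$weighted[hc$order, , drop = FALSE],
       newick = nwk)
}
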