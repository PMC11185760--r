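# build a compact synthetic cohort table without running the simulators:
# 67 supervised parameters + 58 syllable entries with controlled effects
fake_cohort <- function(n_per_group = 6, groups = c("WT_old", "AD_old"),
                        shift_params = character(0), shift = 0,
                        sd = 1, seed = 1) {
  set.seed(seed)
  pnames <- c(paste0("fiji_", c("M1", "MD", "M7", "MN", "N-D", "AM", "AS",
                                "HMM", "HL1M", "HL2M", "Home", "Wall",
                                "Food", "Window", "Out")),
              paste0("dlc_", sprintf("p%02d", 1:52)))
  snames <- c(paste0("f", syllable_alphabet()$id),
              paste0("d", syllable_alphabet()$id))
  rows <- list()
  for (g in groups) for (m in seq_len(n_per_group)) {
    v <- stats::rnorm(125, 10, sd)
    names(v) <- c(pnames, snames)
    if (g == groups[2]) v[shift_params] <- v[shift_params] + shift
    rows[[paste(g, m)]] <- data.frame(
      mouse = paste0(g, "_m", m), group = g, t(v),
      check.names = FALSE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

split_cohort <- function(co) {
  syl <- grep("^[fd]\\d+$", names(co), value = TRUE)
  par <- setdiff(names(co), c("mouse", "group", syl))
  list(params = co[, c("mouse", "group", par)],
       syllables = co[, c("mouse", syl)])
}

test_that("assembled profiles have exactly 125 named parameters", {
  co <- split_cohort(fake_cohort())
  pr <- assemble_profiles(co$params, co$syllables)
  expect_equal(ncol(pr), 125)
  expect_equal(sum(startsWith(colnames(pr), "fiji_")), 15)
  expect_equal(sum(startsWith(colnames(pr), "dlc_")), 52)
  expect_equal(sum(grepl("^f\\d+$", colnames(pr))), 29)
  expect_equal(sum(grepl("^d\\d+$", colnames(pr))), 29)
  expect_error(assemble_profiles(co$params, co$syllables[1:3, ]),
               "missing syllable block")
})

test_that("group profiles are the member means; identical mice collapse", {
  co <- split_cohort(fake_cohort(n_per_group = 4))
  pr <- assemble_profiles(co$params, co$syllables)
  gr <- assemble_profiles(co$params, co$syllables, by_group = TRUE)
  expect_equal(nrow(gr), 2)
  wt <- attr(pr, "group") == "WT_old"
  expect_equal(unname(gr["WT_old", ]), unname(colMeans(pr[wt, ])))
  # identical mice: group profile equals each mouse
  co2 <- split_cohort(fake_cohort(n_per_group = 3, sd = 0))
  g2 <- assemble_profiles(co2$params, co2$syllables, by_group = TRUE)
  p2 <- assemble_profiles(co2$params, co2$syllables)
  expect_equal(unname(g2["AD_old", ]),
               unname(p2[attr(p2, "group") == "AD_old", ][1, ]))
})

test_that("undefined entries are imputed by the group mean and flagged", {
  co <- split_cohort(fake_cohort(n_per_group = 3, seed = 4))
  co$params$fiji_M1[1] <- NA
  pr <- assemble_profiles(co$params, co$syllables)
  expect_false(any(is.na(pr)))
  expect_equal(pr[1, "fiji_M1"],
               mean(co$params$fiji_M1[2:3]))
  expect_equal(unname(attr(pr, "imputed")[1, ]), c(1, 1))
})

test_that("PCA ratios are normalized, ordered and sign-fixed", {
  co <- split_cohort(fake_cohort(n_per_group = 5, seed = 2))
  pr <- assemble_profiles(co$params, co$syllables)
  pca <- profile_pca(pr)
  expect_equal(sum(pca$explained), 1, tolerance = 1e-12)
  expect_true(all(diff(pca$explained) <= 1e-12))
  for (k in seq_len(ncol(pca$loadings)))
    expect_gte(pca$loadings[which.max(abs(pca$loadings[, k])), k], 0)
  # duplicated profile set: identical ratios
  pca2 <- profile_pca(rbind(pr, pr))
  expect_equal(pca2$explained[1:5], pca$explained[1:5], tolerance = 1e-8)
  expect_error(profile_pca(pr[1:2, ]), "at least 3")
})

test_that("two planted orthogonal axes explain all the variance", {
  set.seed(8)
  a <- stats::rnorm(12); b <- stats::rnorm(12)
  base <- matrix(5, 12, 6, dimnames = list(NULL, paste0("p", 1:6)))
  x <- base + cbind(a, a, a, b, b, 0 * b)
  expect_warning(pca <- profile_pca(x, standardize = FALSE),
                 "zero-variance")
  expect_equal(sum(pca$explained[1:2]), 1, tolerance = 1e-9)
})

test_that("PC1 weights match an independent eigendecomposition", {
  set.seed(5)
  x <- matrix(stats::rnorm(20), 5, 4, dimnames = list(NULL, letters[1:4]))
  pca <- profile_pca(x)
  w <- pc1_weights(pca)
  # oracle: eigenvectors of the correlation matrix
  ev <- eigen(stats::cor(x))$vectors[, 1]
  w_oracle <- abs(ev) / max(abs(ev))
  expect_equal(unname(w[letters[1:4]]), w_oracle, tolerance = 1e-9)
  expect_equal(max(w), 1)
  # a zero-loading parameter gets weight zero
  pca0 <- list(loadings = cbind(PC1 = c(a = 0.8, b = 0, c = 0.4)),
               dropped = character(0))
  w0 <- pc1_weights(pca0)
  expect_equal(unname(w0), c(1, 0, 0.5))
  expect_error(pc1_weights(list(loadings = cbind(PC1 = c(0, 0)),
                                dropped = character(0))), "all-zero")
})

test_that("weight modes agree on the extremes", {
  pca <- list(loadings = cbind(PC1 = c(a = -0.6, b = 0.3)),
              dropped = character(0))
  expect_equal(unname(pc1_weights(pca, "abs")), c(1, 0.5))
  expect_equal(unname(pc1_weights(pca, "squared")), c(1, 0.25))
  expect_equal(unname(pc1_weights(pca, "raw")), c(0, 1))
})

test_that("weighted Ward clustering separates planted groups perfectly", {
  co <- split_cohort(fake_cohort(
    n_per_group = 8, shift_params = paste0("dlc_", sprintf("p%02d", 1:10)),
    shift = 12, sd = 1, seed = 11))
  pr <- assemble_profiles(co$params, co$syllables)
  pca <- profile_pca(pr)
  w <- pc1_weights(pca)
  wc <- weighted_cluster(pr, w, k = 2)
  truth <- as.integer(factor(attr(pr, "group")))
  expect_equal(mclust::adjustedRandIndex(wc$clusters, truth), 1.0)
  # PC1 loadings concentrate on the planted parameters
  top <- names(sort(abs(pca$loadings[, 1]), decreasing = TRUE))[1:10]
  planted <- paste0("dlc_", sprintf("p%02d", 1:10))
  jac <- length(intersect(top, planted)) / length(union(top, planted))
  expect_gte(jac, 0.8)
})

test_that("clustering is invariant to profile and parameter order", {
  co <- split_cohort(fake_cohort(n_per_group = 5, seed = 13))
  pr <- assemble_profiles(co$params, co$syllables)
  w <- stats::setNames(rep(1, ncol(pr)), colnames(pr))
  h1 <- weighted_cluster(pr, w)$hclust
  perm <- sample(nrow(pr))
  h2 <- weighted_cluster(pr[perm, ], w)$hclust
  expect_equal(sort(h1$height), sort(h2$height))
  pperm <- sample(ncol(pr))
  h3 <- weighted_cluster(pr[, pperm], w)$hclust
  expect_equal(h1$height, h3$height)
})

test_that("unit weights reduce to plain Ward clustering of z-scores", {
  co <- split_cohort(fake_cohort(n_per_group = 4, seed = 17))
  pr <- assemble_profiles(co$params, co$syllables)
  w1 <- stats::setNames(rep(1, ncol(pr)), colnames(pr))
  got <- weighted_cluster(pr, w1)$hclust
  ref <- stats::hclust(stats::dist(scale(pr)), method = "ward.D2")
  expect_equal(got$height, ref$height)
  expect_equal(got$merge, ref$merge)
})

test_that("identical profiles merge at height zero", {
  x <- matrix(3, 4, 10, dimnames = list(paste0("m", 1:4), paste0("p", 1:10)))
  wc <- weighted_cluster(x)
  expect_true(all(wc$hclust$height == 0))
  expect_error(weighted_cluster(x, k = 9), "exceeds")
})

test_that("cluster reports round-trip and export valid Newick", {
  co <- split_cohort(fake_cohort(
    n_per_group = 4, groups = c("WT_old", "AD_old", "WT_young"),
    shift_params = "fiji_M1", shift = 10, seed = 19))
  pr <- assemble_profiles(co$params, co$syllables, by_group = TRUE)
  # three groups cluster by construction when one axis separates them
  co_m <- assemble_profiles(co$params, co$syllables)
  wc <- weighted_cluster(co_m, k = 3)
  rep3 <- cluster_report(wc, k = 3)
  expect_setequal(unlist(rep3$members), rownames(co_m))
  expect_setequal(rep3$order, rownames(co_m))
  tree <- ape::read.tree(text = rep3$newick)
  expect_setequal(tree$tip.label, rownames(co_m))
  expect_equal(rownames(rep3$matrix), rep3$order)
})
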