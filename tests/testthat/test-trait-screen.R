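test_that("weight groups are half-open 10-kg bins anchored per breed", {
  expect_identical(assign_weight_groups(84.93, start = 80), 1L)
  expect_identical(assign_weight_groups(90, start = 80), 2L)   # lower edge in
  expect_identical(assign_weight_groups(89.999, start = 80), 1L)
  expect_warning(g <- assign_weight_groups(c(75, 85), start = 80),
                 "unassigned")
  expect_identical(g, c(NA_integer_, 1L))
  # uniform coverage fills every group
  bw <- seq(80.5, 159.5, length.out = 257)
  expect_setequal(unique(assign_weight_groups(bw, start = 80)), 1:8)
})

test_that("dressing percentage implements cw/bw * 100 with domain checks", {
  expect_equal(dressing_percentage(75, 100), 75)
  expect_equal(dressing_percentage(50, 100), 50)
  expect_error(dressing_percentage(100, 100), "smaller")
  expect_error(dressing_percentage(-1, 100), "positive")
  # generator consistency: CW is bw * DP / 100 by construction
  sl <- simulate_slaughter(synthetic_herd_spec(), seed = 5)
  tt <- sl$traits
  expect_equal(dressing_percentage(tt$CW, tt$body_weight), tt$DP,
               tolerance = 1e-12)
  # programmed lean baseline 70% at the range start
  g1 <- tt[tt$breed == "YP" & tt$weight_group == 1, ]
  expect_lt(abs(mean(g1$DP) - (70 + 0.15 * mean(g1$body_weight - 80))),
            3 * 1 / sqrt(nrow(g1)))
})

test_that("group_test reproduces the hand-worked ANOVA decomposition", {
  # groups (2,3,4), (4,5,6), (8,9,10): means 3, 5, 9, grand mean 17/3;
  # SSB = 3[(3-17/3)^2 + (5-17/3)^2 + (9-17/3)^2] = 56, each group
  # contributes within-SS 2 so SSW = 6; F = (56/2)/(6/6) = 28 on (2, 6) df
  v <- c(2, 3, 4, 4, 5, 6, 8, 9, 10)
  g <- rep(1:3, each = 3)
  gt <- group_test(v, g)
  expect_equal(gt$f_statistic, 28, tolerance = 1e-10)
  expect_identical(c(gt$df_between, gt$df_within), c(2L, 6L))
  expect_equal(gt$p_value, stats::pf(28, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(gt$p_value, 9.063e-4, tolerance = 1e-3)
  expect_identical(nrow(gt$tukey), 3L)
  expect_true(all(gt$tukey$p_adj >= 0 & gt$tukey$p_adj <= 1))
})

test_that("group_test falls back to the t-test and flags degeneracy", {
  set.seed(3)
  v <- c(rnorm(6), rnorm(6, 2))
  g <- rep(1:2, each = 6)
  gt <- group_test(v, g)
  expect_identical(gt$method, "t-test")
  expect_equal(gt$p_value, stats::t.test(v ~ g)$p.value)

  # identical constants within each group: zero within-group variance
  gt0 <- group_test(rep(c(1, 2, 3), each = 3), rep(1:3, each = 3))
  expect_true(gt0$degenerate)
  expect_true(is.na(gt0$p_value))

  expect_warning(group_test(c(1, 2, 3, 4, 5), c(1, 1, 2, 2, 3)), "excluded")
  expect_error(suppressWarnings(group_test(c(1, 2, 3), c(1, 2, 3))),
               "at least 2 groups")
})

test_that("classify_trend assigns directions from significance and correlation sign", {
  bw <- seq(80.5, 159.5, length.out = 80)
  up <- classify_trend(bw, bw, trait_name = "t")
  expect_identical(up$direction, "up")
  expect_equal(up$bw_correlation, 1)

  set.seed(9)
  dn <- classify_trend(-bw + rnorm(length(bw), 0, 1), bw)
  expect_identical(dn$direction, "down")
  expect_lt(dn$bw_correlation, 0)

  cst <- classify_trend(rep(5, length(bw)), bw)
  expect_identical(cst$direction, "unchanged")
  expect_true(cst$zero_variance)
})

test_that("trend direction is invariant to positive affine rescaling", {
  set.seed(21)
  bw <- rep(seq(85, 155, by = 10), each = 8)
  for (i in 1:10) {
    tr <- 0.05 * bw + rnorm(length(bw), 0, 2)
    d1 <- classify_trend(tr, bw)$direction
    d2 <- classify_trend(3.7 * tr + 100, bw)$direction
    expect_identical(d1, d2)
  }
})

test_that("correlation matrix matches the brute-force formula and flags constants", {
  set.seed(13)
  x <- as.data.frame(matrix(rnorm(60), ncol = 5))
  cm <- trait_correlations(x)
  expect_true(isSymmetric(cm))
  expect_equal(unname(diag(cm)), rep(1, 5))
  for (i in 1:5) for (j in 1:5) {
    expect_equal(cm[i, j], brute_cor(x[[i]], x[[j]]), tolerance = 1e-12)
  }
  x$dup <- x$V1
  expect_equal(trait_correlations(x)["V1", "dup"], 1)
  x$neg <- -x$V2
  expect_equal(trait_correlations(x)["V2", "neg"], -1)
  x$const <- 1
  expect_warning(cm2 <- trait_correlations(x), "constant")
  expect_true(all(is.na(cm2["const", setdiff(colnames(cm2), "const")])))
})

test_that("generator block structure shows up in the correlation matrix", {
  # one block rises with body weight, the other falls: within-block r > 0.5,
  # between-block r < 0
  spec <- synthetic_herd_spec()
  sl <- simulate_slaughter(spec, seed = 8)
  qy <- sl$traits[sl$traits$breed == "QYP", ]
  up_block <- c("body_weight", "CW", "CL1", "CL2")
  dn_block <- c("LP", "L2", "MC")
  cm <- trait_correlations(qy[c(up_block, dn_block)])
  within_up <- cm[up_block, up_block][upper.tri(diag(4))]
  within_dn <- cm[dn_block, dn_block][upper.tri(diag(3))]
  between <- cm[up_block, dn_block]
  expect_gt(mean(within_up), 0.5)
  expect_gt(mean(within_dn), 0.5)
  expect_lt(max(between), 0)
})

test_that("hierarchical clustering is deterministic with sensible merges", {
  x <- rbind(a = c(0, 0), b = c(0, 0), c = c(5, 5))
  hc <- cluster_traits(x, scale. = FALSE)$hclust
  expect_equal(hc$height[1], 0)           # identical items merge at height 0
  x2 <- cbind(c(0, 1, 10), c(0, 1, 10))
  hc2 <- cluster_traits(x2, scale. = FALSE)$hclust
  expect_setequal(abs(hc2$merge[1, ]), c(1, 2))  # nearest pair {0,1} first
  expect_error(cluster_traits(rbind(c(1, NA), c(2, 3))), "non-finite")
})

test_that("smooth-trend group means cluster adjacent weight groups first", {
  sl <- simulate_slaughter(synthetic_herd_spec(), seed = 12)
  qy <- sl$traits[sl$traits$breed == "QYP", ]
  gm <- group_trait_means(qy)
  cl <- cluster_traits(gm, k = 2)
  # with monotone trait trends, the 2-cluster cut splits the weight axis
  # into two contiguous runs of groups
  ord <- cl$clusters[order(as.integer(names(cl$clusters)))]
  expect_equal(sum(diff(ord) != 0), 1L)
})

test_that("PCA behaves on degenerate, isotropic and structured inputs", {
  # two perfectly correlated traits: PC1 carries all variance
  x <- data.frame(a = 1:10, b = 2 * (1:10) + 3)
  p <- trait_pca(x)
  expect_equal(p$explained[1], 1, tolerance = 1e-12)

  set.seed(31)
  iso <- as.data.frame(matrix(rnorm(4 * 2000), ncol = 4))
  pe <- trait_pca(iso)$explained
  expect_lt(max(pe) / min(pe), 1.5)

  # reconstruction at full rank restores the centred-scaled table
  set.seed(32)
  m <- as.data.frame(matrix(rnorm(8 * 30), ncol = 8))
  pf <- trait_pca(m)
  rec <- pf$scores %*% t(pf$loadings)
  expect_equal(rec, as.matrix(scale(as.matrix(m))), tolerance = 1e-10,
               ignore_attr = TRUE)
  # orthonormal loadings, sign convention deterministic
  expect_equal(crossprod(pf$loadings), diag(8), tolerance = 1e-10,
               ignore_attr = TRUE)
  for (j in 1:8) {
    expect_gt(pf$loadings[which.max(abs(pf$loadings[, j])), j], 0)
  }
})

test_that("PCA separates breeds with programmed multi-trait mean shifts", {
  sl <- simulate_slaughter(synthetic_herd_spec(), seed = 4)
  tt <- sl$traits
  sub <- tt[c("LMA", "LP", "CL1", "CL2", "MC")]
  p <- trait_pca(sub)
  s1 <- p$scores[tt$breed == "YP", 1]
  s2 <- p$scores[tt$breed == "QYP", 1]
  expect_true(min(s1) > max(s2) || min(s2) > max(s1))
})

test_that("screen_traits recovers programmed directions on a noise-light table", {
  spec <- synthetic_herd_spec()
  # remove trait noise entirely: trends driven by the responses alone
  for (b in names(spec$traits)) {
    for (nm in names(spec$traits[[b]])) spec$traits[[b]][[nm]]$sd <- 0
  }
  sl <- simulate_slaughter(spec, seed = 2)
  tr <- screen_traits(sl$traits)
  m <- merge(tr, sl$truth, by = c("breed", "trait"))
  prog <- m[m$direction.y %in% c("up", "down"), ]
  expect_identical(prog$direction.x, prog$direction.y)
})

test_that("Benjamini-Hochberg switch only reduces the significant set", {
  sl <- simulate_slaughter(synthetic_herd_spec(), seed = 6)
  raw <- screen_traits(sl$traits)
  adj <- screen_traits(sl$traits, p_adjust = "BH")
  n_sig_raw <- sum(raw$direction != "unchanged")
  n_sig_adj <- sum(adj$direction != "unchanged")
  expect_lte(n_sig_adj, n_sig_raw)
})
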