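#' Assign animals to 10-kg slaughter weight groups
#'
#' Bins body weights into consecutive half-open intervals
#' `[start + (g-1) w, start + g w)`, `g = 1..n_groups`. Weights outside the
#' configured range are returned as `NA` with a warning (they stay in the
#' table, flagged as unassigned).
#'
#' @param bw Body weights, kg (positive).
#' @param start Lower edge of group 1, kg (e.g. 80 for the lean-type range
#'   80–160 kg, 60 for the fat-type range 60–140 kg).
#' @param bin_width Group width, kg (default 10).
#' @param n_groups Number of groups (default 8).
#' @return Integer vector of group indices in `1..n_groups`, `NA` where
#'   unassigned.
#' @export
assign_weight_groups <- function(bw, start, bin_width = 10, n_groups = 8) {
  if (any(!is.finite(bw)) || any(bw <= 0)) {
    stop("'bw' must be positive and finite", call. = FALSE)
  }
  g <- floor((bw - start) / bin_width) + 1
  g[g < 1 | g > n_groups] <- NA_integer_
  if (anyNA(g)) {
    warning(sum(is.na(g)), " animal(s) outside [", start, ", ",
            start + n_groups * bin_width, ") kg left unassigned")
  }
  as.integer(g)
}

#' Dressing percentage
#'
#' Carcass weight as a percentage of live body weight at slaughter:
#' `(cw / bw) * 100`.
#'
#' @param cw Hot carcass weight(s), kg.
#' @param bw Live body weight(s) at slaughter, kg.
#' @return Dressing percentage(s) in (0, 100).
#' @export
dressing_percentage <- function(cw, bw) {
  if (any(!is.finite(cw)) || any(!is.finite(bw)) || any(cw <= 0) || any(bw <= 0)) {
    stop("'cw' and 'bw' must be positive and finite", call. = FALSE)
  }
  if (any(cw >= bw)) {
    stop("carcass weight must be smaller than live body weight", call. = FALSE)
  }
  100 * cw / bw
}

#' Across-group test of a trait
#'
#' One-way ANOVA with Tukey HSD pairwise comparisons across weight groups;
#' with exactly two usable groups it falls back to the two-sample t-test.
#' Groups with fewer than 2 observations are excluded with a warning. A trait
#' with zero within-group variance everywhere is degenerate: no F-test is
#' possible and the result is flagged.
#'
#' @param values Numeric trait values.
#' @param group Group labels (coerced to factor), same length as `values`.
#' @param tukey Compute Tukey HSD pairwise p-values (ANOVA case only)?
#' @return A list with `p_value`, `method` (`"anova"`, `"t-test"` or
#'   `"degenerate"`), `tukey` (data frame of pairwise comparisons or `NULL`),
#'   `group_means`, `df_between`, `df_within`, `f_statistic`,
#'   `degenerate` flag.
#' @export
group_test <- function(values, group, tukey = TRUE) {
  ok <- is.finite(values) & !is.na(group)
  values <- values[ok]
  group <- factor(group[ok])
  sizes <- table(group)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("group(s) with < 2 observations excluded: ",
            paste(small, collapse = ", "))
    keep <- !(group %in% small)
    values <- values[keep]; group <- droplevels(group[keep])
  }
  k <- nlevels(group)
  if (k < 2L) stop("need at least 2 groups with >= 2 observations", call. = FALSE)
  group_means <- tapply(values, group, mean)

  within_var <- tapply(values, group, stats::var)
  if (all(within_var == 0)) {
    return(list(p_value = NA_real_, method = "degenerate", tukey = NULL,
                group_means = group_means, df_between = k - 1L,
                df_within = length(values) - k, f_statistic = NA_real_,
                degenerate = TRUE))
  }

  if (k == 2L) {
    tt <- stats::t.test(values ~ group)
    return(list(p_value = tt$p.value, method = "t-test", tukey = NULL,
                group_means = group_means, df_between = 1L,
                df_within = length(values) - 2L,
                f_statistic = unname(tt$statistic)^2, degenerate = FALSE))
  }

  fit <- stats::aov(values ~ group)
  tab <- summary(fit)[[1]]
  tk <- NULL
  if (tukey) {
    th <- stats::TukeyHSD(fit)$group
    tk <- data.frame(comparison = rownames(th), diff = th[, "diff"],
                     lwr = th[, "lwr"], upr = th[, "upr"],
                     p_adj = th[, "p adj"], row.names = NULL)
  }
  list(p_value = tab[["Pr(>F)"]][1], method = "anova", tukey = tk,
       group_means = group_means,
       df_between = as.integer(tab[["Df"]][1]),
       df_within = as.integer(tab[["Df"]][2]),
       f_statistic = tab[["F value"]][1], degenerate = FALSE)
}

#' Classify a trait's trend across the body-weight range
#'
#' A trait is "up" when the across-group ANOVA is significant at `alpha` and
#' its Pearson correlation with body weight is positive, "down" when
#' significant with negative correlation, and "unchanged" otherwise. Constant
#' traits are "unchanged" with a zero-variance flag.
#'
#' @param trait Numeric trait values.
#' @param bw Body weights, kg, paired with `trait`.
#' @param group Weight-group labels; if `NULL`, 10-kg bins anchored at
#'   `10 * floor(min(bw)/10)` are used.
#' @param alpha Significance level (default 0.05).
#' @param trait_name,breed Optional labels carried into the result.
#' @return A one-row data frame (class `trend_result`) with columns `trait`,
#'   `breed`, `direction`, `anova_p`, `bw_correlation`, `zero_variance`, and
#'   the per-group means as an attribute `"group_means"`.
#' @export
classify_trend <- function(trait, bw, group = NULL, alpha = 0.05,
                           trait_name = NA_character_, breed = NA_character_) {
  stopifnot(length(trait) == length(bw))
  if (is.null(group)) {
    origin <- 10 * floor(min(bw) / 10)
    group <- floor((bw - origin) / 10) + 1
  }
  ok <- is.finite(trait) & is.finite(bw) & !is.na(group)
  trait <- trait[ok]; bw <- bw[ok]; group <- group[ok]

  if (stats::var(trait) == 0) {
    res <- data.frame(trait = trait_name, breed = breed,
                      direction = "unchanged", anova_p = NA_real_,
                      bw_correlation = NA_real_, zero_variance = TRUE,
                      stringsAsFactors = FALSE)
    class(res) <- c("trend_result", class(res))
    return(res)
  }

  gt <- group_test(trait, group, tukey = FALSE)
  r <- stats::cor(trait, bw)
  direction <- if (!is.na(gt$p_value) && gt$p_value <= alpha) {
    if (r > 0) "up" else if (r < 0) "down" else "unchanged"
  } else "unchanged"

  res <- data.frame(trait = trait_name, breed = breed, direction = direction,
                    anova_p = gt$p_value, bw_correlation = r,
                    zero_variance = FALSE, stringsAsFactors = FALSE)
  attr(res, "group_means") <- gt$group_means
  class(res) <- c("trend_result", class(res))
  res
}

#' Screen every trait of a slaughter table for weight-dependent trends
#'
#' Runs [classify_trend()] per breed and trait over a slaughter trait table
#' (one row per animal).
#'
#' @param trait_table Data frame with columns `breed`, `body_weight`,
#'   `weight_group` and numeric trait columns.
#' @param traits Character vector of trait columns to screen; default all
#'   numeric columns other than the bookkeeping ones.
#' @param alpha Per-trait significance level (default 0.05, uncorrected); set
#'   `p_adjust = "BH"` for a Benjamini–Hochberg screen instead.
#' @param p_adjust `"none"` (default) or any method of [stats::p.adjust()],
#'   applied within breed.
#' @return Data frame with one row per breed x trait: `trait`, `breed`,
#'   `direction`, `anova_p`, `bw_correlation`, `zero_variance`.
#' @export
screen_traits <- function(trait_table, traits = NULL, alpha = 0.05,
                          p_adjust = "none") {
  need <- c("breed", "body_weight", "weight_group")
  if (!all(need %in% names(trait_table))) {
    stop("'trait_table' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(traits)) {
    num <- vapply(trait_table, is.numeric, logical(1))
    traits <- setdiff(names(trait_table)[num],
                      c("body_weight", "weight_group", "animal_id"))
  }
  out <- list()
  for (b in unique(trait_table$breed)) {
    tb <- trait_table[trait_table$breed == b, , drop = FALSE]
    rows <- lapply(traits, function(tr) {
      classify_trend(tb[[tr]], tb$body_weight, group = tb$weight_group,
                     alpha = alpha, trait_name = tr, breed = b)
    })
    res <- do.call(rbind, lapply(rows, as.data.frame))
    if (p_adjust != "none") {
      padj <- stats::p.adjust(res$anova_p, method = p_adjust)
      sig <- !is.na(padj) & padj <= alpha
      res$anova_p_adj <- padj
      res$direction <- ifelse(sig,
                              ifelse(res$bw_correlation > 0, "up", "down"),
                              "unchanged")
    }
    out[[b]] <- res
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Trait correlation matrix
#'
#' Pairwise-complete correlation matrix over the numeric trait columns.
#' Constant columns yield `NA` entries and are reported in a warning rather
#' than silently zeroed.
#'
#' @param trait_table Data frame (numeric trait columns; non-numeric and
#'   bookkeeping columns dropped) or numeric matrix.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Symmetric correlation matrix with unit diagonal (where defined).
#' @export
trait_correlations <- function(trait_table, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- as.data.frame(trait_table)
  x <- x[vapply(x, is.numeric, logical(1))]
  x$weight_group <- NULL
  if (nrow(x) < 3L) stop("need at least 3 animals", call. = FALSE)
  sds <- vapply(x, stats::sd, numeric(1), na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE)) {
    warning("constant column(s) give undefined correlations: ",
            paste(names(x)[which(sds == 0)], collapse = ", "))
  }
  suppressWarnings(
    stats::cor(as.matrix(x), use = "pairwise.complete.obs", method = method)
  )
}

#' Hierarchical clustering of traits or weight groups
#'
#' Average-linkage hierarchical clustering on Euclidean distances, by default
#' after column-wise z-scoring (sample SD). Ties in merge height are broken
#' deterministically by [stats::hclust()] (lowest index first).
#'
#' @param x Numeric matrix (rows = items to cluster, e.g. weight-group trait
#'   means; columns = variables).
#' @param scale. Z-score the columns first (default `TRUE`).
#' @param linkage Agglomeration method (default `"average"`).
#' @param k Optional number of flat clusters to cut.
#' @return List with `hclust` (the tree) and `clusters` (integer vector from
#'   [stats::cutree()], or `NULL` when `k` is missing).
#' @export
cluster_traits <- function(x, scale. = TRUE, linkage = "average", k = NULL) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("non-finite entries in clustering input", call. = FALSE)
  if (nrow(x) < 2L) stop("need at least 2 items to cluster", call. = FALSE)
  if (scale.) {
    sds <- apply(x, 2, stats::sd)
    x <- scale(x[, sds > 0, drop = FALSE])
  }
  hc <- stats::hclust(stats::dist(x), method = linkage)
  list(hclust = hc,
       clusters = if (!is.null(k)) stats::cutree(hc, k = k) else NULL)
}

#' Principal component analysis of a trait table
#'
#' PCA on the centred, z-scored trait columns. Missing values are
#' mean-imputed with a warning; zero-variance columns are dropped with a
#' warning; when there are more traits than animals the rank is capped (with
#' a warning). The sign of each component is fixed so that its
#' largest-magnitude loading is positive.
#'
#' @param trait_table Data frame or matrix of numeric trait columns.
#' @param scale. Z-score columns (default `TRUE`, sample SD).
#' @return List with `scores` (animals x PCs), `loadings` (traits x PCs,
#'   orthonormal columns), `sdev`, and `explained` (proportion of total
#'   variance per PC).
#' @export
trait_pca <- function(trait_table, scale. = TRUE) {
  x <- as.data.frame(trait_table)
  x <- x[vapply(x, is.numeric, logical(1))]
  x$weight_group <- NULL
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("need at least 2 animals and 2 traits", call. = FALSE)
  }
  if (anyNA(x)) {
    warning(sum(is.na(x)), " missing value(s) mean-imputed for PCA")
    for (j in seq_len(ncol(x))) {
      x[is.na(x[, j]), j] <- mean(x[, j], na.rm = TRUE)
    }
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance column(s) dropped: ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  if (ncol(x) > nrow(x)) {
    warning("more traits than animals; component rank capped at n - 1")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = scale.)
  # deterministic sign: largest-magnitude loading of each PC positive
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  list(scores = pc$x, loadings = pc$rotation, sdev = pc$sdev,
       explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' Per-weight-group trait means
#'
#' Convenience matrix of group mean trait values (rows = weight groups),
#' the usual input to [cluster_traits()].
#'
#' @param trait_table Slaughter trait table (see [screen_traits()]).
#' @param traits Trait columns to include (default: all numeric traits).
#' @return Numeric matrix, rows named by weight group.
#' @export
group_trait_means <- function(trait_table, traits = NULL) {
  if (is.null(traits)) {
    num <- vapply(trait_table, is.numeric, logical(1))
    traits <- setdiff(names(trait_table)[num],
                      c("body_weight", "weight_group", "animal_id"))
  }
  g <- trait_table$weight_group
  keep <- !is.na(g)
  out <- sapply(traits, function(tr) {
    tapply(trait_table[[tr]][keep], g[keep], mean, na.rm = TRUE)
  })
  as.matrix(out)
}
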