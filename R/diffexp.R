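# Per-contrast differential expression: Wilcoxon rank-sum p values,
# Benjamini-Hochberg adjustment, median-based log2 fold changes, Cohen's d,
# and the combined deregulated/significant calls.
#
# Deregulated: |log2FC| > 1 and |Cohen's d| > 0.5.
# Significant: |log2FC| > 1 and BH-adjusted p < 0.05.

#' Two-sided Wilcoxon rank-sum p value
#'
#' Exact mode enumerates the permutation distribution of the rank sum over
#' all assignments of the pooled values to the two groups, using mid-ranks
#' for ties, and returns `min(1, 2 * min(P(W <= w), P(W >= w)))`. The normal
#' approximation uses the tie-corrected variance with continuity correction.
#' `auto` picks exact when `length(a) + length(b) <= 12` and no tied value
#' spans the two groups, else the normal approximation.
#'
#' @param a,b Non-empty numeric vectors.
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @return p value in `[0, 1]`.
#' @export
wilcoxon_rank_sum <- function(a, b, mode = c("auto", "exact",
                                             "normal_approx")) {
  mode <- match.arg(mode)
  if (length(a) < 1L || length(b) < 1L) {
    stopf("wilcoxon_rank_sum needs non-empty groups")
  }
  if (anyNA(a) || anyNA(b)) stopf("wilcoxon_rank_sum cannot handle NA values")
  if (mode == "auto") {
    cross_tie <- length(intersect(a, b)) > 0L
    mode <- if (length(a) + length(b) <= 12L && !cross_tie) "exact"
            else "normal_approx"
  }
  if (mode == "exact") .wilcox_exact(a, b) else .wilcox_normal(a, b)
}

.wilcox_exact <- function(a, b) {
  na <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(na)])
  combos <- utils::combn(length(pooled), na)
  w_all <- colSums(matrix(r[combos], nrow = na))
  eps <- 1e-9
  p_lo <- mean(w_all <= w_obs + eps)
  p_hi <- mean(w_all >= w_obs - eps)
  min(1, 2 * min(p_lo, p_hi))
}

.wilcox_normal <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  n <- na + nb
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- table(r)
  sigma2 <- (na * nb / 12) *
    ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- u - na * nb / 2
  correction <- sign(z) * 0.5
  z <- (z - correction) / sqrt(sigma2)
  min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values, in input order, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0L))
  if (anyNA(p) || any(p < 0 | p > 1)) stopf("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Median-based log2 fold change
#'
#' `median(log2(a + pseudocount)) - median(log2(b + pseudocount))`; the
#' even-length median is the midpoint of the two central values. On a single
#' expression axis this equals the log2 ratio of the (geometric) medians of
#' the shifted values, since the median commutes with the monotone log.
#'
#' @param a,b Non-empty non-negative rpmm vectors (group A minus group B).
#' @param pseudocount Positive shift before the log (default 1).
#' @return Real log2 fold change.
#' @export
median_log2_fc <- function(a, b, pseudocount = 1) {
  if (length(a) < 1L || length(b) < 1L) stopf("groups must be non-empty")
  if (any(a < 0) || any(b < 0)) stopf("rpmm values must be >= 0")
  stats::median(log2(a + pseudocount)) - stats::median(log2(b + pseudocount))
}

#' Geometric-mean log2 fold change (alternative mode)
#'
#' `mean(log2(a + pseudocount)) - mean(log2(b + pseudocount))`, i.e. the log2
#' ratio of geometric means of the shifted values.
#'
#' @inheritParams median_log2_fc
#' @return Real log2 fold change.
#' @export
geomean_log2_fc <- function(a, b, pseudocount = 1) {
  if (length(a) < 1L || length(b) < 1L) stopf("groups must be non-empty")
  if (any(a < 0) || any(b < 0)) stopf("rpmm values must be >= 0")
  mean(log2(a + pseudocount)) - mean(log2(b + pseudocount))
}

#' Cohen's d with pooled standard deviation
#'
#' `(mean(a) - mean(b)) / s_pooled`. When the pooled SD is zero the result is
#' 0 for equal means and a signed infinite sentinel for unequal means (the
#' sentinel passes any magnitude threshold).
#'
#' @param a,b Numeric vectors with at least two values each.
#' @return Real effect size (possibly `Inf`/`-Inf`).
#' @export
cohens_d <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  if (na < 2L || nb < 2L) {
    stopf("cohens_d needs at least two values per group")
  }
  s2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  delta <- mean(a) - mean(b)
  if (s2 <= 0) {
    if (delta == 0) return(0)
    return(sign(delta) * Inf)
  }
  delta / sqrt(s2)
}

#' Define a two-group contrast from sample metadata
#'
#' @param metadata Sample metadata data frame.
#' @param tissue Tissue to restrict to.
#' @param condition_a,condition_b Condition labels for the two groups
#'   (FL/HGC/VGC), or `NULL` to split by `age_a`/`age_b` instead.
#' @param age_a,age_b Optional age labels defining the groups (used for the
#'   3M-vs-8M contrasts; combine with `condition` to restrict).
#' @param age,cohort,condition Optional stratum restrictions applied to both
#'   groups.
#' @param label Contrast label; autogenerated when `NULL`.
#' @return List with `tissue`, `label`, `samples_a`, `samples_b`.
#' @export
contrast_spec <- function(metadata, tissue, condition_a = NULL,
                          condition_b = NULL, age_a = NULL, age_b = NULL,
                          age = NULL, cohort = NULL, condition = NULL,
                          label = NULL) {
  md <- metadata[metadata$tissue == tissue, , drop = FALSE]
  if (!is.null(age)) md <- md[md$age == age, , drop = FALSE]
  if (!is.null(cohort)) md <- md[md$cohort == cohort, , drop = FALSE]
  if (!is.null(condition)) md <- md[md$condition == condition, , drop = FALSE]
  if (!is.null(condition_a)) {
    sa <- md$sample_id[md$condition == condition_a]
    sb <- md$sample_id[md$condition == condition_b]
    lab <- paste0(condition_a, "_vs_", condition_b)
  } else if (!is.null(age_a)) {
    sa <- md$sample_id[md$age == age_a]
    sb <- md$sample_id[md$age == age_b]
    lab <- paste0(age_a, "_vs_", age_b)
  } else {
    stopf("contrast_spec needs either conditions or ages for the two groups")
  }
  if (!is.null(age)) lab <- paste0(lab, "@", age)
  if (!is.null(condition)) lab <- paste0(lab, "@", condition)
  if (length(intersect(sa, sb)) > 0L) stopf("contrast groups overlap")
  list(tissue = tissue, label = label %||% lab,
       samples_a = sa, samples_b = sb)
}

#' Run one differential-expression contrast
#'
#' Tests every feature of the log2 matrix with the Wilcoxon rank-sum test,
#' BH-adjusts p values across the features of this tissue-contrast family,
#' computes the median-based log2 fold change on the rpmm matrix and Cohen's
#' d on the log2 values, and sets the `significant` and `deregulated` flags.
#'
#' @param log2_expr [expr_matrix()] on the log2_rpmm scale (test + effect
#'   size input).
#' @param rpmm_expr [expr_matrix()] on the rpmm scale (fold-change input);
#'   must share features and samples with `log2_expr`.
#' @param contrast A [contrast_spec()] (or any list with `tissue`, `label`,
#'   `samples_a`, `samples_b`).
#' @param fc_thresh Absolute log2 fold-change gate (default 1).
#' @param d_thresh Absolute Cohen's d gate for deregulation (default 0.5).
#' @param alpha Adjusted-p gate for significance (default 0.05).
#' @param min_group_size Minimum samples per group (default 3); smaller
#'   groups skip the contrast with a warning and return `NULL`.
#' @param mode Wilcoxon mode passed to [wilcoxon_rank_sum()].
#' @param fc_mode `"median"` (default) or `"geomean"` fold-change estimator.
#' @return Data frame of per-feature records (`feature_id`, `tissue`,
#'   `label`, `log2fc`, `cohens_d`, `p_raw`, `p_adj`, `n_a`, `n_b`,
#'   `direction`, `significant`, `deregulated`), or `NULL` when skipped.
#' @export
run_contrast <- function(log2_expr, rpmm_expr, contrast, fc_thresh = 1,
                         d_thresh = 0.5, alpha = 0.05, min_group_size = 3,
                         mode = "auto", fc_mode = c("median", "geomean")) {
  fc_mode <- match.arg(fc_mode)
  if (log2_expr$scale != "log2_rpmm") stopf("log2_expr must be log2_rpmm")
  if (rpmm_expr$scale != "rpmm") stopf("rpmm_expr must be rpmm")
  if (!identical(rownames(log2_expr$values), rownames(rpmm_expr$values)) ||
      !identical(colnames(log2_expr$values), colnames(rpmm_expr$values))) {
    stopf("log2 and rpmm matrices must share features and samples")
  }
  sa <- intersect(contrast$samples_a, colnames(log2_expr$values))
  sb <- intersect(contrast$samples_b, colnames(log2_expr$values))
  if (length(sa) < min_group_size || length(sb) < min_group_size) {
    warnf("contrast %s/%s skipped: group sizes %d vs %d below minimum %d",
          contrast$tissue, contrast$label, length(sa), length(sb),
          min_group_size)
    return(NULL)
  }
  la <- log2_expr$values[, sa, drop = FALSE]
  lb <- log2_expr$values[, sb, drop = FALSE]
  ra <- rpmm_expr$values[, sa, drop = FALSE]
  rb <- rpmm_expr$values[, sb, drop = FALSE]
  feats <- rownames(la)
  fc_fun <- if (fc_mode == "median") median_log2_fc else geomean_log2_fc

  p_raw <- numeric(length(feats))
  log2fc <- numeric(length(feats))
  d <- numeric(length(feats))
  for (i in seq_along(feats)) {
    p_raw[i] <- wilcoxon_rank_sum(la[i, ], lb[i, ], mode = mode)
    log2fc[i] <- fc_fun(ra[i, ], rb[i, ])
    d[i] <- cohens_d(la[i, ], lb[i, ])
  }
  p_adj <- bh_adjust(p_raw)
  direction <- ifelse(log2fc > 0, "up", ifelse(log2fc < 0, "down", "none"))
  fc_pass <- abs(log2fc) > fc_thresh
  data.frame(feature_id = feats,
             tissue = contrast$tissue,
             label = contrast$label,
             log2fc = log2fc,
             cohens_d = d,
             p_raw = p_raw,
             p_adj = p_adj,
             n_a = length(sa),
             n_b = length(sb),
             direction = direction,
             significant = fc_pass & p_adj < alpha,
             deregulated = fc_pass & abs(d) > d_thresh,
             stringsAsFactors = FALSE)
}

#' Run the standard condition contrasts for every tissue
#'
#' Convenience driver computing FL vs HGC, FL vs VGC and HGC vs VGC per
#' tissue (optionally stratified by age), plus the 3M-vs-8M contrast within
#' FL when `with_age` is set.
#'
#' @param log2_expr,rpmm_expr Matched expression matrices (see
#'   [run_contrast()]).
#' @param filter Optional result of [detection_filter()]; each tissue is
#'   restricted to its retained feature set.
#' @param with_age Also compute age-stratified FL-vs-HGC and the 3M-vs-8M
#'   within-FL contrasts (default FALSE).
#' @param ... Passed on to [run_contrast()].
#' @return Nested list: `results[[tissue]][[label]]` data frames.
#' @export
run_standard_contrasts <- function(log2_expr, rpmm_expr, filter = NULL,
                                   with_age = FALSE, ...) {
  md <- log2_expr$metadata
  if (is.null(md)) stopf("expression matrices need sample metadata")
  tissues <- unique(md$tissue)
  out <- list()
  for (tis in tissues) {
    le <- log2_expr
    re <- rpmm_expr
    if (!is.null(filter)) {
      feats <- filter$per_tissue[[tis]]
      le <- subset_features(le, feats)
      re <- subset_features(re, feats)
    }
    specs <- list(
      contrast_spec(md, tis, "FL", "HGC"),
      contrast_spec(md, tis, "FL", "VGC"),
      contrast_spec(md, tis, "HGC", "VGC"))
    if (with_age) {
      specs <- c(specs, list(
        contrast_spec(md, tis, "FL", "HGC", age = "3M"),
        contrast_spec(md, tis, "FL", "HGC", age = "8M"),
        contrast_spec(md, tis, age_a = "3M", age_b = "8M",
                      condition = "FL")))
    }
    res <- list()
    for (cs in specs) {
      r <- run_contrast(le, re, cs, ...)
      if (!is.null(r)) res[[cs$label]] <- r
    }
    out[[tis]] <- res
  }
  out
}
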