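# Detection filtering and reads-per-million-mapped (rpmm) normalization.

#' Detection filter for raw miRNA counts
#'
#' Within each tissue, a feature is retained only if in *every* condition
#' group of that tissue the fraction of samples with raw count >=
#' `min_count` is at least `min_fraction` (inclusive at the boundary). The
#' per-tissue sets and their union are returned; cross-tissue analyses use
#' the union.
#'
#' @param x A [count_matrix()] with metadata.
#' @param min_count Minimum raw count for a sample to count as detecting the
#'   feature (default 5).
#' @param min_fraction Minimum fraction of samples per group that must detect
#'   it (default 0.10).
#' @param groups Optional custom grouping: character vector, one group label
#'   per sample, overriding the default condition-within-tissue grouping.
#' @return List with `per_tissue` (named list of feature id vectors),
#'   `union` (character vector) and the filter parameters.
#' @export
detection_filter <- function(x, min_count = 5, min_fraction = 0.10,
                             groups = NULL) {
  if (!inherits(x, "count_matrix")) stopf("x must be a count_matrix")
  if (min_count < 1) stopf("min_count must be >= 1")
  if (min_fraction <= 0 || min_fraction > 1) {
    stopf("min_fraction must be in (0, 1]")
  }
  md <- .require_metadata(x)
  detected <- x$counts >= min_count

  if (!is.null(groups)) {
    groups <- as.character(groups)
    if (length(groups) != ncol(x$counts)) {
      stopf("groups must have one label per sample")
    }
    tissue_of <- rep("all", length(groups))
  } else {
    groups <- paste(md$tissue, md$condition, sep = ":")
    tissue_of <- md$tissue
  }
  if (is.factor(groups)) {
    empty <- setdiff(levels(groups), unique(as.character(groups)))
    if (length(empty) > 0L) {
      stopf("grouping has zero samples in group(s): %s",
            paste(empty, collapse = ", "))
    }
  }

  tissues <- unique(tissue_of)
  per_tissue <- lapply(tissues, function(tis) {
    grp <- unique(groups[tissue_of == tis])
    pass <- rep(TRUE, nrow(x$counts))
    for (g in grp) {
      cols <- which(groups == g)
      if (length(cols) == 0L) stopf("group '%s' has zero samples", g)
      frac <- rowMeans(detected[, cols, drop = FALSE])
      pass <- pass & (frac >= min_fraction)
    }
    rownames(x$counts)[pass]
  })
  names(per_tissue) <- tissues
  list(per_tissue = per_tissue,
       union = unique(unlist(per_tissue, use.names = FALSE)),
       min_count = min_count, min_fraction = min_fraction)
}

#' Subset a count matrix to a feature set (and optionally to samples)
#'
#' @param x A [count_matrix()] or [expr_matrix()].
#' @param features Character vector of feature ids to keep (file/input order
#'   preserved from `x`).
#' @param samples Optional character vector of sample ids to keep.
#' @return Object of the same class, subset.
#' @export
subset_features <- function(x, features, samples = NULL) {
  mat_name <- if (inherits(x, "count_matrix")) "counts" else "values"
  m <- x[[mat_name]]
  keep <- rownames(m) %in% features
  m <- m[keep, , drop = FALSE]
  md <- x$metadata
  if (!is.null(samples)) {
    m <- m[, colnames(m) %in% samples, drop = FALSE]
    if (!is.null(md)) md <- md[md$sample_id %in% samples, , drop = FALSE]
  }
  x[[mat_name]] <- m
  x$metadata <- md
  x
}

#' Reads-per-million-mapped normalization
#'
#' Scales each sample to `count / denominator * 1e6`. With the default
#' `column_sum` denominator each sample's values sum to exactly one million;
#' `metadata_mapped_reads` divides by the `mapped_reads` metadata column
#' instead, reproducing normalization against total genome-mapped reads when
#' those totals are available.
#'
#' @param x A [count_matrix()].
#' @param denominator `"column_sum"` (default) or `"metadata_mapped_reads"`.
#' @return An [expr_matrix()] on the rpmm scale.
#' @export
rpmm_normalize <- function(x,
                           denominator = c("column_sum",
                                           "metadata_mapped_reads")) {
  if (!inherits(x, "count_matrix")) stopf("x must be a count_matrix")
  denominator <- match.arg(denominator)
  if (denominator == "column_sum") {
    den <- colSums(x$counts)
  } else {
    md <- .require_metadata(x)
    if (!"mapped_reads" %in% names(md) || anyNA(md$mapped_reads)) {
      stopf("metadata_mapped_reads denominator needs a complete 'mapped_reads' column")
    }
    den <- md$mapped_reads[match(colnames(x$counts), md$sample_id)]
  }
  zero <- colnames(x$counts)[den <= 0]
  if (length(zero) > 0L) {
    stopf("zero normalization denominator for sample(s): %s",
          paste(zero, collapse = ", "))
  }
  vals <- sweep(x$counts, 2L, den, "/") * 1e6
  expr_matrix(vals, x$metadata, scale = "rpmm")
}

#' Log2 transform of rpmm values
#'
#' `value <- log2(value + pseudocount)`; with the default pseudocount of 1 a
#' zero stays zero and all transformed values are non-negative.
#'
#' @param expr An [expr_matrix()] on the rpmm scale.
#' @param pseudocount Positive real added before the log (default 1).
#' @return An [expr_matrix()] on the log2_rpmm scale.
#' @export
log2_transform <- function(expr, pseudocount = 1) {
  if (!inherits(expr, "expr_matrix")) stopf("expr must be an expr_matrix")
  if (expr$scale != "rpmm") {
    stopf("log2_transform expects rpmm input, got scale '%s'", expr$scale)
  }
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    stopf("pseudocount must be > 0")
  }
  out <- expr
  out$values <- log2(expr$values + pseudocount)
  out$scale <- "log2_rpmm"
  out
}
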