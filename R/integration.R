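# miRNA-mRNA integration: pseudobulk aggregation, target-score percentile
# filtering, the top-deregulated-mRNA rule, deregulated pair discovery,
# most-targeted ranking and the validated-pair cross-check.

#' Aggregate cell-level counts into per-sample pseudobulk
#'
#' Sums, per gene, the counts of all cells labeled with each sample.
#' Integer-preserving; total counts per gene are conserved.
#'
#' @param cell_counts A [count_matrix()] over cells (metadata optional) or a
#'   plain genes x cells matrix.
#' @param cell_to_sample Character vector, one sample label per cell. `NA`
#'   or empty labels are an error.
#' @param metadata Optional per-sample metadata for the result.
#' @return A [count_matrix()] over samples.
#' @export
pseudobulk <- function(cell_counts, cell_to_sample, metadata = NULL) {
  m <- if (inherits(cell_counts, "count_matrix")) cell_counts$counts
       else as.matrix(cell_counts)
  cell_to_sample <- as.character(cell_to_sample)
  if (length(cell_to_sample) != ncol(m)) {
    stopf("cell_to_sample must label every cell (one per column)")
  }
  if (anyNA(cell_to_sample) || any(!nzchar(cell_to_sample))) {
    stopf("unlabeled cell(s) at position(s): %s",
          paste(which(is.na(cell_to_sample) | !nzchar(cell_to_sample)),
                collapse = ", "))
  }
  agg <- t(rowsum(t(m), group = cell_to_sample))
  count_matrix(agg, metadata)
}

#' Percentile filter on target-pair scores
#'
#' The threshold is the `q`-quantile (linear interpolation between order
#' statistics) of the chosen strength statistic over the whole table; pairs
#' with strength strictly greater than the threshold are retained. The
#' default strength is `|score|`, since weighted context++-style scores are
#' non-positive with more negative meaning stronger predicted repression;
#' `raw_score` is kept for exact-replication attempts.
#'
#' @param targets Non-empty target-pair table (`mirna_id`, `gene_id`,
#'   `score`, optionally `validated`).
#' @param q Quantile in `[0, 1]`, default 0.75.
#' @param strength `"abs_score"` (default) or `"raw_score"`.
#' @return The retained rows of `targets`.
#' @export
filter_targets_by_percentile <- function(targets, q = 0.75,
                                         strength = c("abs_score",
                                                      "raw_score")) {
  strength <- match.arg(strength)
  if (nrow(targets) == 0L) stopf("target table is empty")
  s <- if (strength == "abs_score") abs(targets$score) else targets$score
  threshold <- unname(stats::quantile(s, probs = q, type = 7))
  targets[s > threshold, , drop = FALSE]
}

#' Top fraction of deregulated mRNAs
#'
#' With more than `min_total` deregulated records, keeps the
#' `ceiling(top_frac * n)` records with the largest absolute log2 fold
#' change (ties broken by smaller raw p, then lexicographic id); otherwise
#' all records are kept.
#'
#' @param records Data frame of deregulated mRNA DE records.
#' @param top_frac Fraction to keep, default 0.10.
#' @param min_total Size above which the rule engages (strictly more than;
#'   default 100).
#' @return The selected rows of `records`.
#' @export
top_deregulated_mrna <- function(records, top_frac = 0.10,
                                 min_total = 100L) {
  n <- nrow(records)
  if (n <= min_total) return(records)
  ord <- order(-abs(records$log2fc), records$p_raw, records$feature_id)
  records[ord[seq_len(ceiling(top_frac * n))], , drop = FALSE]
}

#' Deregulated miRNA-mRNA pair hits
#'
#' All (miRNA, gene) pairs where the miRNA is in the deregulated set, the
#' gene is in the top-deregulated mRNA subset, and the pair is present in
#' the (already percentile-filtered) target table. No direction-concordance
#' filter is applied: miRNA-target regulation is not always anti-correlated,
#' so both concordant and discordant pairs are reported.
#'
#' @param dereg_mirnas A [directional_set()] (or named direction vector) of
#'   deregulated miRNAs.
#' @param top_mrnas Data frame of selected mRNA records with `feature_id`
#'   and `direction` columns.
#' @param targets Filtered target table (`mirna_id`, `gene_id`, `score`,
#'   optionally `validated`).
#' @param tissue Tissue label for the hits.
#' @return Data frame of hits (`tissue`, `mirna_id`, `gene_id`,
#'   `mirna_direction`, `gene_direction`, `score`, `validated`).
#' @export
pair_hits <- function(dereg_mirnas, top_mrnas, targets, tissue = "") {
  mir <- .as_members(dereg_mirnas)
  if (inherits(dereg_mirnas, "directional_set") &&
      nzchar(dereg_mirnas$tissue) && !nzchar(tissue)) {
    tissue <- dereg_mirnas$tissue
  }
  hits <- targets[targets$mirna_id %in% names(mir) &
                    targets$gene_id %in% top_mrnas$feature_id, ,
                  drop = FALSE]
  gene_dir <- stats::setNames(top_mrnas$direction, top_mrnas$feature_id)
  out <- data.frame(
    tissue = rep(tissue, nrow(hits)),
    mirna_id = hits$mirna_id,
    gene_id = hits$gene_id,
    mirna_direction = unname(mir[hits$mirna_id]),
    gene_direction = unname(gene_dir[hits$gene_id]),
    score = hits$score,
    validated = if ("validated" %in% names(hits)) hits$validated
                else rep(NA, nrow(hits)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Rank genes by the number of distinct deregulated miRNAs targeting them
#'
#' @param hits Data frame from [pair_hits()] (possibly concatenated over
#'   tissues). Duplicate (tissue, miRNA, gene) rows count once.
#' @return Data frame (`gene_id`, `tissue`, `n_targeting_mirnas`) sorted by
#'   descending count with lexicographic tie-break on gene then tissue.
#' @export
most_targeted <- function(hits) {
  if (nrow(hits) == 0L) {
    return(data.frame(gene_id = character(0L), tissue = character(0L),
                      n_targeting_mirnas = integer(0L),
                      stringsAsFactors = FALSE))
  }
  uniq <- unique(hits[, c("tissue", "mirna_id", "gene_id")])
  agg <- stats::aggregate(mirna_id ~ gene_id + tissue, data = uniq,
                          FUN = length)
  names(agg)[names(agg) == "mirna_id"] <- "n_targeting_mirnas"
  agg <- agg[order(-agg$n_targeting_mirnas, agg$gene_id, agg$tissue), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg[, c("gene_id", "tissue", "n_targeting_mirnas")]
}

#' Cross-check hits against experimentally validated pairs
#'
#' @param hits Data frame from [pair_hits()].
#' @param validated Table of validated pairs (`mirna_id`, `gene_id`).
#' @return List with `n_total`, `n_validated`, and `hits` carrying an
#'   updated logical `validated` column in input order.
#' @export
validated_crosscheck <- function(hits, validated) {
  key <- function(tab) paste(tab$mirna_id, tab$gene_id, sep = "\r")
  flags <- if (nrow(validated) > 0L) key(hits) %in% key(validated)
           else rep(FALSE, nrow(hits))
  hits$validated <- flags
  list(n_total = nrow(hits), n_validated = sum(flags), hits = hits)
}
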