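# Set enrichment over term annotations: hypergeometric overrepresentation,
# pre-ranked GSEA with a signed -log10(p) ranking score, ontology redundancy
# reduction, Jaccard term clustering and frequent-word cluster labels.

#' Overrepresentation analysis (one-sided hypergeometric)
#'
#' Per term, the upper-tail probability of drawing at least
#' `k = |query intersect term|` members when sampling `|query|` features
#' from the universe containing `|term intersect universe|` members. BH
#' adjustment across all tested terms.
#'
#' @param query Character vector of features of interest; must be a subset
#'   of `universe`.
#' @param universe Character vector of all considered features (e.g. the
#'   detected features of the analyzed tissue/contrast).
#' @param annotation A `term_annotation` (see [term_annotation()] /
#'   [read_gmt()]). Member sets are intersected with the universe before
#'   testing; terms with no members in the universe are skipped.
#' @param alpha Adjusted-p significance cutoff, default 0.05.
#' @return Data frame (`term_id`, `term_name`, `k`, `term_size`,
#'   `query_size`, `universe_size`, `fold_enrichment`, `p_raw`, `p_adj`,
#'   `significant`) ordered by `p_raw`.
#' @export
ora <- function(query, universe, annotation, alpha = 0.05) {
  query <- unique(query)
  universe <- unique(universe)
  if (length(setdiff(query, universe)) > 0L) {
    stopf("query contains features outside the universe: %s",
          paste(utils::head(setdiff(query, universe), 5L), collapse = ", "))
  }
  n_univ <- length(universe)
  n_query <- length(query)
  rows <- lapply(annotation, function(term) {
    members <- intersect(term$members, universe)
    size <- length(members)
    if (size == 0L) return(NULL)
    k <- length(intersect(query, members))
    p <- stats::phyper(k - 1L, size, n_univ - size, n_query,
                       lower.tail = FALSE)
    expected <- n_query * size / n_univ
    data.frame(term_id = term$term_id, term_name = term$term_name,
               k = k, term_size = size, query_size = n_query,
               universe_size = n_univ,
               fold_enrichment = if (expected > 0) k / expected else NA_real_,
               p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term_id = character(0L), term_name = character(0L),
                      k = integer(0L), term_size = integer(0L),
                      query_size = integer(0L), universe_size = integer(0L),
                      fold_enrichment = numeric(0L), p_raw = numeric(0L),
                      p_adj = numeric(0L), significant = logical(0L),
                      stringsAsFactors = FALSE))
  }
  out$p_adj <- bh_adjust(out$p_raw)
  out$significant <- out$p_adj < alpha
  out <- out[order(out$p_raw, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the signed ranking score list for GSEA
#'
#' `score = -log10(max(p_raw, p_floor)) * sign(log2fc)`; features with a
#' zero fold change score 0. The list is ordered by descending score, ties
#' broken by descending `|log2fc|`, then by id, so the order is total.
#'
#' @param records DE record data frame with `feature_id`, `p_raw`, `log2fc`.
#' @param p_floor Floor applied to raw p values so scores stay finite
#'   (default 1e-300).
#' @return Data frame (`feature_id`, `score`) in rank order.
#' @export
make_ranked_list <- function(records, p_floor = 1e-300) {
  score <- -log10(pmax(records$p_raw, p_floor)) * sign(records$log2fc)
  ord <- order(-score, -abs(records$log2fc), records$feature_id)
  out <- data.frame(feature_id = records$feature_id[ord],
                    score = score[ord], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Unweighted Kolmogorov-Smirnov-style running sum: +1/|S| at members,
# -1/(N - |S|) elsewhere; ES is the signed extremum of the walk, the
# earliest one on an exact tie. The walk is accumulated in integers
# (member step n_out, non-member step -n_in, one division at the end) so
# ties are exact and the result is rounding-free.
.gsea_es <- function(ranked_ids, member_set) {
  is_member <- ranked_ids %in% member_set
  n_in <- sum(is_member)
  n_out <- length(ranked_ids) - n_in
  if (n_in == 0L || n_out == 0L) return(NA_real_)
  walk <- cumsum(ifelse(is_member, n_out, -n_in))
  walk[which.max(abs(walk))] / (n_in * n_out)
}

#' Pre-ranked gene-set enrichment analysis
#'
#' Enrichment score from the unweighted running sum over the ranked list;
#' the permutation null redraws the term's membership uniformly from the
#' ranked universe (feature-label permutation), `p = (1 + #{|ES*| >= |ES|})
#' / (1 + n_perm)`. BH adjustment across tested terms.
#'
#' @param ranked Data frame from [make_ranked_list()] (or any data frame
#'   with an ordered `feature_id` column).
#' @param annotation A `term_annotation`.
#' @param n_perm Number of permutations (default 1000; below 100 warns).
#' @param seed Optional integer seed making the permutation p values
#'   reproducible.
#' @param min_size,max_size Term-size window after intersection with the
#'   ranked universe (defaults 5 and 500). Terms covering the whole list are
#'   skipped with a warning.
#' @param alpha Adjusted-p cutoff, default 0.05.
#' @return Data frame (`term_id`, `term_name`, `term_size`, `es`,
#'   `direction`, `p_raw`, `p_adj`, `significant`) ordered by `p_raw`.
#' @export
gsea <- function(ranked, annotation, n_perm = 1000L, seed = NULL,
                 min_size = 5L, max_size = 500L, alpha = 0.05) {
  if (n_perm < 1L) stopf("gsea needs at least one permutation")
  if (n_perm < 100L) warnf("n_perm = %d is small; p values will be coarse",
                           n_perm)
  if (!is.null(seed)) set.seed(seed)
  ids <- ranked$feature_id
  n <- length(ids)
  rows <- lapply(annotation, function(term) {
    members <- intersect(term$members, ids)
    size <- length(members)
    if (size == n && n > 0L) {
      warnf("term '%s' covers the whole ranked list; skipped", term$term_id)
      return(NULL)
    }
    if (size < min_size || size > max_size) return(NULL)
    es <- .gsea_es(ids, members)
    null_abs <- vapply(seq_len(n_perm), function(i) {
      abs(.gsea_es(ids, sample(ids, size)))
    }, numeric(1L))
    p <- (1 + sum(null_abs >= abs(es))) / (1 + n_perm)
    data.frame(term_id = term$term_id, term_name = term$term_name,
               term_size = size, es = es,
               direction = if (es > 0) "enriched" else "depleted",
               p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term_id = character(0L), term_name = character(0L),
                      term_size = integer(0L), es = numeric(0L),
                      direction = character(0L), p_raw = numeric(0L),
                      p_adj = numeric(0L), significant = logical(0L),
                      stringsAsFactors = FALSE))
  }
  out$p_adj <- bh_adjust(out$p_raw)
  out$significant <- out$p_adj < alpha
  out <- out[order(out$p_raw, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Transitive ancestor sets over child -> parent edges.
.ancestors <- function(term, parent_of) {
  seen <- character(0L)
  frontier <- parent_of[[term]] %||% character(0L)
  while (length(frontier) > 0L) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(lapply(new, function(t)
      parent_of[[t]] %||% character(0L)), use.names = FALSE))
  }
  seen
}

#' Reduce a term set to its minimal (most specific) members
#'
#' Removes every term that is a transitive ancestor of another term in the
#' set, leaving only the most specific representatives. Terms absent from
#' the ontology pass through with a warning.
#'
#' @param terms Character vector of term ids.
#' @param ontology Ontology edge table (`child_id`, `parent_id`), acyclic.
#' @return Character vector, the reduced set (original order preserved).
#' @export
minimal_set <- function(terms, ontology) {
  nodes <- unique(c(ontology$child_id, ontology$parent_id))
  unknown <- setdiff(terms, nodes)
  if (length(unknown) > 0L) {
    warnf("term(s) not in the ontology pass through unchanged: %s",
          paste(unknown, collapse = ", "))
  }
  parent_of <- split(ontology$parent_id, ontology$child_id)
  ancestors_in_set <- unique(unlist(lapply(terms, function(t) {
    intersect(.ancestors(t, parent_of), terms)
  }), use.names = FALSE))
  terms[!terms %in% ancestors_in_set]
}

#' Cluster significant terms by member-set similarity
#'
#' Pairwise similarity is the Jaccard index of the terms' member sets
#' (optionally intersected with an analysis universe); average-linkage
#' hierarchical clustering is cut at `1 - similarity_threshold`. Singleton
#' clusters are allowed.
#'
#' @param records Enrichment record data frame (rows with
#'   `significant == TRUE` are clustered; pass a pre-filtered frame to
#'   override).
#' @param annotation A `term_annotation` providing member sets.
#' @param similarity_threshold Similarity at which clusters merge (default
#'   0.25).
#' @param universe Optional feature universe to intersect member sets with.
#' @return Named list of character vectors of term ids (clusters).
#' @export
cluster_terms <- function(records, annotation, similarity_threshold = 0.25,
                          universe = NULL) {
  keep <- if ("significant" %in% names(records)) records$significant
          else rep(TRUE, nrow(records))
  ids <- records$term_id[keep]
  if (length(ids) == 0L) stopf("no significant terms to cluster")
  term_ids <- vapply(annotation, `[[`, character(1L), "term_id")
  sets <- lapply(ids, function(id) {
    m <- annotation[[match(id, term_ids)]]$members
    if (!is.null(universe)) m <- intersect(m, universe)
    m
  })
  names(sets) <- ids
  if (length(ids) == 1L) return(list(cluster_1 = ids))
  k <- length(ids)
  sim <- matrix(1, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      u <- length(union(sets[[i]], sets[[j]]))
      s <- if (u == 0L) 0 else length(intersect(sets[[i]], sets[[j]])) / u
      sim[i, j] <- s
      sim[j, i] <- s
    }
  }
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  assignment <- stats::cutree(hc, h = 1 - similarity_threshold)
  clusters <- split(ids, assignment)
  names(clusters) <- paste0("cluster_", seq_along(clusters))
  clusters
}

.DEFAULT_STOPWORDS <- c("of", "the", "to", "in", "by", "and", "a", "an",
                        "via", "for", "on", "or")

#' Label term clusters with their frequent name words
#'
#' Term names are tokenized on whitespace, lowercased, stripped of
#' punctuation-only tokens and stop words; per cluster, the words occurring
#' at least `min_freq` times are reported, ordered by descending frequency
#' then alphabetically.
#'
#' @param clusters Named list of term-id vectors (from [cluster_terms()]).
#' @param term_names Named character vector mapping term ids to names (or a
#'   `term_annotation`).
#' @param min_freq Minimum word frequency (default 2).
#' @param stopwords Words to ignore.
#' @return Named list of character vectors (possibly empty) of label words.
#' @export
label_clusters <- function(clusters, term_names, min_freq = 2L,
                           stopwords = .DEFAULT_STOPWORDS) {
  if (inherits(term_names, "term_annotation")) {
    term_names <- stats::setNames(
      vapply(term_names, `[[`, character(1L), "term_name"),
      vapply(term_names, `[[`, character(1L), "term_id"))
  }
  lapply(clusters, function(ids) {
    words <- tolower(unlist(strsplit(term_names[ids], "\\s+"),
                            use.names = FALSE))
    words <- gsub("[^a-z0-9'-]", "", words)
    words <- words[nzchar(words) & !words %in% stopwords]
    if (length(words) == 0L) return(character(0L))
    freq <- table(words)
    freq <- freq[freq >= min_freq]
    if (length(freq) == 0L) return(character(0L))
    names(freq)[order(-as.integer(freq), names(freq))]
  })
}
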