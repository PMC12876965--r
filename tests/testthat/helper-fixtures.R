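# Shared fixture builders: everything is generated in code.

toy_metadata <- function(tissues = "liver", conditions = c("FL", "HGC"),
                         n_per_group = 3L, ages = "3M", cohort = "LAR") {
  grid <- expand.grid(rep = seq_len(n_per_group), condition = conditions,
                      age = ages, tissue = tissues,
                      stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("s%03d", seq_len(nrow(grid))),
             tissue = grid$tissue, condition = grid$condition,
             age = grid$age, cohort = cohort, stringsAsFactors = FALSE)
}

toy_counts <- function(metadata, n_features = 10L, seed = 1L,
                       lambda = 50) {
  set.seed(seed)
  m <- matrix(rpois(n_features * nrow(metadata), lambda),
              nrow = n_features,
              dimnames = list(sprintf("miR-%02d", seq_len(n_features)),
                              metadata$sample_id))
  count_matrix(m, metadata)
}

# Minimal differential-expression record table for set-logic tests.
toy_records <- function(ids, log2fc, deregulated = rep(TRUE, length(ids)),
                        tissue = "liver", label = "FL_vs_HGC",
                        p_raw = rep(0.01, length(ids))) {
  n <- length(ids)
  data.frame(feature_id = ids, tissue = rep(tissue, n),
             label = rep(label, n),
             log2fc = log2fc, cohens_d = sign(log2fc) * 2,
             p_raw = p_raw, p_adj = p_raw,
             n_a = rep(5L, n), n_b = rep(5L, n),
             direction = ifelse(log2fc > 0, "up",
                                ifelse(log2fc < 0, "down", "none")),
             significant = deregulated, deregulated = deregulated,
             stringsAsFactors = FALSE)
}

# Independent mid-rank computation (used by enumeration oracles).
oracle_midranks <- function(x) {
  vapply(x, function(v) sum(x < v) + (1 + sum(x == v)) / 2, numeric(1L))
}

# Brute-force two-sided exact Wilcoxon p: enumerate every bitmask subset of
# the pooled values with |a| members as "group a".
oracle_wilcox_exact <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  r <- oracle_midranks(pooled)
  w_obs <- sum(r[seq_len(na)])
  ws <- c()
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    if (sum(bits) != na) next
    ws <- c(ws, sum(r[bits == 1L]))
  }
  min(1, 2 * min(mean(ws <= w_obs + 1e-9), mean(ws >= w_obs - 1e-9)))
}

# Hand-written BH step-up oracle.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- p[ord] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[ord] <- q
  out
}

# Brute-force hypergeometric upper tail by enumerating all query draws.
oracle_ora_p <- function(universe, term, n_query, k_obs) {
  draws <- combn(length(universe), n_query)
  term_idx <- which(universe %in% term)
  overlaps <- apply(draws, 2L, function(ix) sum(ix %in% term_idx))
  mean(overlaps >= k_obs)
}

# Brute-force unweighted running-sum enrichment score: integer walk
# (member +n_out, non-member -n_in), earliest extremum on exact ties,
# one division at the end.
oracle_gsea_es <- function(ranked_ids, members) {
  n_in <- sum(ranked_ids %in% members)
  n_out <- length(ranked_ids) - n_in
  best <- 0
  run <- 0
  for (id in ranked_ids) {
    run <- run + if (id %in% members) n_out else -n_in
    if (abs(run) > abs(best)) best <- run
  }
  best / (n_in * n_out)
}
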