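test_that("ORA p equals the closed-form hypergeometric tail", {
  universe <- paste0("f", 1:10)
  term <- term_annotation(list(T1 = universe[1:4]))
  query <- c(universe[1:4], universe[10])
  out <- ora(query, universe, term)
  expect_equal(out$p_raw, 6 / 252, tolerance = 1e-12)  # C(4,4)C(6,1)/C(10,5)

  full <- ora(universe[1:5], universe, term_annotation(list(T = universe)))
  expect_equal(full$p_raw, 1.0)

  zero <- ora(universe[6:10], universe, term)
  expect_lte(zero$p_raw, 1)
  expect_gt(zero$p_raw, 0.9)  # k = 0 on a small term

  expect_error(ora(c("f1", "zz"), universe, term), "outside the universe")
})

test_that("ORA matches the enumeration oracle on small universes", {
  set.seed(71)
  for (rep in 1:8) {
    n_univ <- sample(8:14, 1)
    universe <- paste0("u", seq_len(n_univ))
    term_m <- sample(universe, sample(2:5, 1))
    n_query <- sample(3:6, 1)
    query <- sample(universe, n_query)
    k <- length(intersect(query, term_m))
    out <- ora(query, universe, term_annotation(list(T = term_m)))
    expect_equal(out$p_raw, oracle_ora_p(universe, term_m, n_query, k),
                 tolerance = 1e-12)
  }
})

test_that("ranked lists carry signed -log10 p scores with total order", {
  recs <- toy_records(c("a", "b", "c", "d"),
                      c(2, -1, 0.5, 0.5),
                      p_raw = c(0.01, 0.1, 1.0, 1.0))
  rl <- make_ranked_list(recs)
  expect_equal(rl$score[rl$feature_id == "a"], 2.0)
  expect_equal(rl$score[rl$feature_id == "b"], -1.0)
  expect_equal(rl$score[rl$feature_id == "c"], 0.0)
  expect_identical(rl$feature_id[1], "a")
  expect_identical(rl$feature_id[4], "b")
  # the p floor keeps scores finite
  tiny <- toy_records("z", 1, p_raw = 0)
  expect_true(is.finite(make_ranked_list(tiny)$score))
})

test_that("GSEA enrichment score is the signed running-sum extremum", {
  ranked <- data.frame(feature_id = c("a", "b", "c", "d"),
                       stringsAsFactors = FALSE)
  ann <- term_annotation(list(TOP = c("a", "b"), BOT = c("c", "d")))
  out <- gsea(ranked, ann, n_perm = 100, seed = 1, min_size = 1)
  expect_equal(out$es[out$term_id == "TOP"], 1.0)
  expect_equal(out$es[out$term_id == "BOT"], -1.0)
  expect_identical(out$direction[out$term_id == "TOP"], "enriched")

  whole <- term_annotation(list(ALL = c("a", "b", "c", "d")))
  expect_warning(res <- gsea(ranked, whole, n_perm = 100, seed = 1,
                             min_size = 1),
                 "whole ranked list")
  expect_identical(nrow(res), 0L)
})

test_that("GSEA ES equals the brute-force oracle and p is seed-stable", {
  set.seed(72)
  for (rep in 1:20) {
    n <- sample(10:50, 1)
    ids <- sprintf("f%03d", sample(1000, n))
    members <- sample(ids, sample(3:(n - 1), 1))
    ranked <- data.frame(feature_id = ids, stringsAsFactors = FALSE)
    out <- gsea(ranked, term_annotation(list(T = members)), n_perm = 100,
                seed = rep, min_size = 1)
    expect_equal(out$es, oracle_gsea_es(ids, members), tolerance = 1e-15)
  }
  ranked <- data.frame(feature_id = sprintf("f%02d", 1:30),
                       stringsAsFactors = FALSE)
  ann <- term_annotation(list(T = sprintf("f%02d", c(2, 3, 5, 8, 13))))
  p1 <- gsea(ranked, ann, n_perm = 500, seed = 9)$p_raw
  p2 <- gsea(ranked, ann, n_perm = 500, seed = 9)$p_raw
  expect_identical(p1, p2)
})

test_that("minimal_set removes transitive ancestors only", {
  edges <- data.frame(child_id = c("B", "C"), parent_id = c("A", "B"),
                      stringsAsFactors = FALSE)
  expect_identical(minimal_set(c("A", "B"), edges), "B")
  expect_identical(minimal_set("A", edges), "A")
  expect_identical(minimal_set(c("A", "B", "C"), edges), "C")
  expect_warning(out <- minimal_set(c("C", "X"), edges), "not in the ontology")
  expect_identical(out, c("C", "X"))
})

test_that("minimal_set output has no ancestor-related pair", {
  set.seed(73)
  # random DAG over 15 nodes: edges only from higher to lower index
  nodes <- paste0("n", 1:15)
  edges <- do.call(rbind, lapply(2:15, function(i) {
    parents <- sample(seq_len(i - 1), sample(0:2, 1))
    if (length(parents) == 0) return(NULL)
    data.frame(child_id = nodes[i], parent_id = nodes[parents],
               stringsAsFactors = FALSE)
  }))
  reach <- function(t) {
    # independent reachability by iterated expansion
    anc <- character(0)
    front <- edges$parent_id[edges$child_id == t]
    while (length(front) > 0) {
      anc <- union(anc, front)
      front <- unique(edges$parent_id[edges$child_id %in% front])
      front <- setdiff(front, anc)
    }
    anc
  }
  in_graph <- intersect(nodes, unique(c(edges$child_id, edges$parent_id)))
  for (rep in 1:5) {
    terms <- sample(in_graph, 8)
    out <- minimal_set(terms, edges)
    for (t in out) expect_length(intersect(reach(t), out), 0)
  }
})

test_that("term clustering groups by Jaccard member overlap", {
  ann <- term_annotation(list(A = c("x", "y", "z", "w"),
                              B = c("x", "y"),
                              C = c("p", "q")))
  recs <- data.frame(term_id = c("A", "B", "C"), significant = TRUE,
                     stringsAsFactors = FALSE)
  cl <- cluster_terms(recs, ann, similarity_threshold = 0.25)
  grp_of <- function(id) which(vapply(cl, function(x) id %in% x,
                                      logical(1)))
  expect_identical(grp_of("A"), grp_of("B"))  # Jaccard 0.5 merges
  expect_false(grp_of("C") == grp_of("A"))    # disjoint stays apart

  twin <- term_annotation(list(T1 = c("a", "b"), T2 = c("a", "b")))
  recs2 <- data.frame(term_id = c("T1", "T2"), significant = TRUE,
                      stringsAsFactors = FALSE)
  cl2 <- cluster_terms(recs2, twin, similarity_threshold = 0.99)
  expect_length(cl2, 1)
})

test_that("cluster labels report words occurring at least twice", {
  labels <- label_clusters(list(c1 = c("T1", "T2")),
                           c(T1 = "lung development",
                             T2 = "bone development"))
  expect_identical(labels$c1, "development")
  expect_identical(label_clusters(list(c1 = "T1"),
                                  c(T1 = "ion binding"))$c1,
                   character(0))
  labels3 <- label_clusters(list(c1 = c("T1", "T2", "T3")),
                            c(T1 = "DNA repair", T2 = "DNA replication",
                              T3 = "DNA binding"))
  expect_identical(labels3$c1, "dna")
})
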