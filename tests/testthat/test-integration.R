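test_that("pseudobulk sums cell counts per sample and conserves totals", {
  m <- matrix(c(1, 0, 2,
                0, 4, 1), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
  pb <- pseudobulk(m, c("s1", "s1", "s1"))
  expect_equal(unname(pb$counts[, "s1"]), c(3, 5))

  one <- pseudobulk(m[, 1, drop = FALSE], "s9")
  expect_equal(unname(one$counts[, "s9"]), unname(m[, 1]))

  set.seed(61)
  big <- matrix(rpois(20 * 50, 3), nrow = 20,
                dimnames = list(sprintf("g%02d", 1:20),
                                sprintf("c%02d", 1:50)))
  labels <- sample(c("s1", "s2", "s3"), 50, replace = TRUE)
  pb2 <- pseudobulk(big, labels)
  expect_equal(rowSums(pb2$counts), rowSums(big))
  # hand-summed oracle on a toy slice
  expect_equal(unname(pb2$counts[, "s2"]),
               unname(rowSums(big[, labels == "s2", drop = FALSE])))

  expect_error(pseudobulk(m, c("s1", NA, "s1")), "unlabeled")
})

test_that("percentile filter keeps pairs strictly above the interpolated quantile", {
  tab <- data.frame(mirna_id = paste0("m", 1:4), gene_id = paste0("g", 1:4),
                    score = -c(0.1, 0.2, 0.3, 0.4), validated = FALSE,
                    stringsAsFactors = FALSE)
  out <- filter_targets_by_percentile(tab, q = 0.75)
  expect_identical(out$mirna_id, "m4")  # threshold 0.325, only |−0.4| above

  all_equal <- tab
  all_equal$score <- -0.2
  expect_identical(nrow(filter_targets_by_percentile(all_equal)), 0L)

  out0 <- filter_targets_by_percentile(tab, q = 0)
  expect_setequal(out0$mirna_id, c("m2", "m3", "m4"))
})

test_that("percentile filter equals the sort-and-slice oracle", {
  set.seed(62)
  for (rep in 1:10) {
    n <- sample(50:1000, 1)
    tab <- data.frame(mirna_id = sprintf("m%04d", 1:n),
                      gene_id = sprintf("g%04d", sample(n)),
                      score = -round(runif(n, 0, 1), 2),
                      stringsAsFactors = FALSE)
    q <- sample(c(0.25, 0.5, 0.75, 0.9), 1)
    out <- filter_targets_by_percentile(tab, q = q)
    thr <- unname(quantile(abs(tab$score), q, type = 7))
    oracle <- tab[abs(tab$score) > thr, ]
    expect_identical(out$mirna_id, oracle$mirna_id)
  }
})

test_that("the top-fraction mRNA rule engages strictly above min_total", {
  mk <- function(n) {
    set.seed(63)
    toy_records(sprintf("g%03d", 1:n),
                sample(c(-1, 1), n, TRUE) * runif(n, 1.01, 5),
                p_raw = runif(n))
  }
  r200 <- mk(200)
  top <- top_deregulated_mrna(r200)
  expect_identical(nrow(top), 20L)
  ord <- order(-abs(r200$log2fc), r200$p_raw, r200$feature_id)
  expect_setequal(top$feature_id, r200$feature_id[ord[1:20]])

  expect_identical(nrow(top_deregulated_mrna(mk(50))), 50L)
  expect_identical(nrow(top_deregulated_mrna(mk(100))), 100L)
  expect_identical(nrow(top_deregulated_mrna(mk(101))), 11L)
})

test_that("pair hits join deregulated partners without a direction filter", {
  mirs <- directional_set("liver", "spaceflight",
                          c("miR-x" = "up", "miR-z" = "down"))
  mrnas <- data.frame(feature_id = c("GeneY", "GeneW"),
                      direction = c("down", "up"),
                      stringsAsFactors = FALSE)
  targets <- data.frame(
    mirna_id = c("miR-x", "miR-x", "miR-q"),
    gene_id = c("GeneY", "GeneW", "GeneY"),
    score = c(-0.5, -0.6, -0.7), validated = c(TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  hits <- pair_hits(mirs, mrnas, targets)
  expect_identical(nrow(hits), 2L)  # discordant miR-x/GeneW still a hit
  expect_setequal(hits$gene_id, c("GeneY", "GeneW"))
  expect_identical(hits$tissue, c("liver", "liver"))
  # absent pair is never a hit
  expect_false(any(hits$mirna_id == "miR-z"))
})

test_that("adding a deregulated miRNA never removes existing hits", {
  set.seed(64)
  targets <- data.frame(mirna_id = sample(paste0("m", 1:20), 100, TRUE),
                        gene_id = sample(paste0("g", 1:30), 100, TRUE),
                        score = -runif(100), stringsAsFactors = FALSE)
  targets <- targets[!duplicated(paste(targets$mirna_id,
                                       targets$gene_id)), ]
  mrnas <- data.frame(feature_id = paste0("g", 1:30), direction = "up",
                      stringsAsFactors = FALSE)
  small <- setNames(rep("up", 5), paste0("m", 1:5))
  big <- setNames(rep("up", 10), paste0("m", 1:10))
  h_small <- pair_hits(small, mrnas, targets, tissue = "t")
  h_big <- pair_hits(big, mrnas, targets, tissue = "t")
  key <- function(h) paste(h$mirna_id, h$gene_id)
  expect_true(all(key(h_small) %in% key(h_big)))
})

test_that("most_targeted counts distinct regulators with stable ties", {
  hits <- data.frame(tissue = "t",
                     mirna_id = c("m1", "m2", "m1", "m1"),
                     gene_id = c("G", "G", "H", "G"),
                     stringsAsFactors = FALSE)
  out <- most_targeted(hits)
  expect_identical(out$gene_id, c("G", "H"))
  expect_identical(out$n_targeting_mirnas, c(2L, 1L))
  expect_identical(nrow(most_targeted(hits[0, ])), 0L)
})

test_that("validated cross-check flags hits in input order", {
  hits <- data.frame(tissue = "t", mirna_id = c("m1", "m2", "m3"),
                     gene_id = c("gA", "gB", "gC"),
                     stringsAsFactors = FALSE)
  validated <- data.frame(mirna_id = "m2", gene_id = "gB",
                          stringsAsFactors = FALSE)
  out <- validated_crosscheck(hits, validated)
  expect_identical(out$n_total, 3L)
  expect_identical(out$n_validated, 1L)
  expect_identical(out$hits$validated, c(FALSE, TRUE, FALSE))

  none <- validated_crosscheck(hits, validated[0, ])
  expect_identical(none$n_validated, 0L)
  all_val <- validated_crosscheck(hits, hits[, c("mirna_id", "gene_id")])
  expect_identical(all_val$n_validated, all_val$n_total)
})
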