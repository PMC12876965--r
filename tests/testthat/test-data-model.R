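test_that("count TSV round-trips values and order", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1\ts2", "mA\t0\t5", "mB\t3\t1"), tmp)
  cm <- read_count_matrix(tmp, "tsv")
  expect_identical(rownames(cm$counts), c("mA", "mB"))
  expect_identical(colnames(cm$counts), c("s1", "s2"))
  expect_equal(unname(cm$counts), matrix(c(0, 3, 5, 1), nrow = 2))
})

test_that("parsers reject invariant-violating counts with located errors", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1\ts2", "mA\t0\t5", "mB\t-3\t1"), tmp)
  expect_error(read_count_matrix(tmp, "tsv"), "mB.*s1")
  writeLines(c("feature_id\ts1\ts2", "mA\t0\t5", "mA\t3\t1"), tmp)
  expect_error(read_count_matrix(tmp, "tsv"), "duplicated feature")
  expect_error(count_matrix(matrix(c(0.5, 1, 2, 3), 2,
                                   dimnames = list(c("a", "b"),
                                                   c("s1", "s2")))),
               "non-integer")
})

test_that("MTX triplet expands to the dense matrix the triplets describe", {
  dir <- withr::local_tempdir()
  mtx <- file.path(dir, "m.mtx")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 3 3", "1 1 4", "2 2 7", "1 3 2"), mtx)
  writeLines(c("mA", "mB"), file.path(dir, "m.features.tsv"))
  writeLines(c("s1", "s2", "s3"), file.path(dir, "m.samples.tsv"))
  cm <- read_count_matrix(mtx, "mtx_triplet")
  # expand triplets by brute force
  dense <- matrix(0, 2, 3, dimnames = list(c("mA", "mB"),
                                           c("s1", "s2", "s3")))
  dense["mA", "s1"] <- 4
  dense["mB", "s2"] <- 7
  dense["mA", "s3"] <- 2
  expect_equal(cm$counts, dense)
})

test_that("metadata parsing validates enums and uniqueness", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\ttissue\tcondition\tage\tcohort",
               "s1\tliver\tFL\t3M\tLAR"), tmp)
  md <- read_metadata(tmp)
  expect_identical(md$tissue, "liver")
  expect_identical(md$condition, "FL")

  writeLines(c("sample_id\ttissue\tcondition\tage\tcohort",
               "s1\tliver\tFLT\t3M\tLAR"), tmp)
  expect_error(read_metadata(tmp), "FL, HGC, VGC")

  writeLines(c("sample_id\ttissue\tcondition\tage\tcohort",
               "s1\tliver\tFL\t3M\tLAR", "s1\tliver\tHGC\t3M\tLAR"), tmp)
  expect_error(read_metadata(tmp), "duplicated sample_id")

  writeLines(c("sample_id\ttissue\tcondition\tage\tcohort\tbatch",
               "s1\tliver\tFL\t3M\tLAR\tb2"), tmp)
  expect_identical(read_metadata(tmp)$batch, "b2")
})

test_that("auxiliary tables are typed and invariant-checked", {
  tmp <- withr::local_tempfile(fileext = ".gmt")
  writeLines("T1\tdesc\ta\tb", tmp)
  ann <- read_auxiliary(tmp, "gmt")
  expect_s3_class(ann, "term_annotation")
  expect_identical(ann[[1]]$members, c("a", "b"))
  writeLines("T1\tdesc", tmp)
  expect_error(read_auxiliary(tmp, "gmt"), "empty member set")

  edges <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("child_id\tparent_id", "A\tB", "B\tA"), edges)
  expect_error(read_auxiliary(edges, "ontology_edges"), "cycle")
  writeLines(c("child_id\tparent_id", "B\tA", "C\tB"), edges)
  expect_silent(read_auxiliary(edges, "ontology_edges"))

  tg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mirna_id\tgene_id\tscore\tvalidated",
               "miR-x\tGeneY\t-0.3\t0", "miR-x\tGeneY\t-0.5\t1"), tg)
  expect_error(read_auxiliary(tg, "target_table"), "duplicated target pair")

  fam <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mirna_id\tfamily_id", "miR-1\tMIR-1", "miR-1\tMIR-2"), fam)
  expect_error(read_auxiliary(fam, "family_map"), "multiple families")
})

test_that("write_results round-trips tables and handles empty results", {
  dir <- withr::local_tempdir()
  recs <- toy_records(c("m1", "m2"), c(1.23456789012, -2.5))
  manifest <- write_results(list(diffexp = recs), dir, seed = 3L,
                            params = list(alpha = 0.05))
  expect_true(file.exists(file.path(dir, "run_summary.json")))
  back <- read_results_table(manifest$path[1])
  expect_equal(back$log2fc, recs$log2fc, tolerance = 1e-12)
  expect_identical(back$feature_id, recs$feature_id)

  empty <- recs[0, , drop = FALSE]
  write_results(list(empty = empty), dir)
  back2 <- read_results_table(file.path(dir, "empty.tsv"))
  expect_identical(nrow(back2), 0L)
  expect_identical(names(back2), names(recs))
})

test_that("pvca_result fractions survive a write/read cycle to 1e-12", {
  dir <- withr::local_tempdir()
  pv <- structure(list(fractions = c(tissue = 1 / 3, condition = 1 / 7,
                                     residual = 1 - 1 / 3 - 1 / 7),
                       n_pcs = 2L, eigen_fractions = c(0.7, 0.2)),
                  class = "pvca_result")
  write_results(list(pvca = pv), dir)
  back <- read_results_table(file.path(dir, "pvca.tsv"))
  expect_equal(back$fraction, unname(pv$fractions), tolerance = 1e-12)
})
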