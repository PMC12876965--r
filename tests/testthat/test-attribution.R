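test_that("direction match requires a shared strict sign", {
  expect_true(direction_match(1.2, 2.0))
  expect_false(direction_match(1.2, -0.3))
  expect_false(direction_match(0.0, 1.0))
  expect_identical(direction_match(c(1, -1, 0), c(2, -2, 2)),
                   c(TRUE, TRUE, FALSE))
})

test_that("directional intersection keeps agreeing deregulated features", {
  a <- toy_records(c("m1", "m2"), c(2, -2))
  b <- toy_records(c("m1", "m3"), c(1.5, 1.5), label = "FL_vs_VGC")
  out <- intersect_directional(a, b)
  expect_identical(names(out$members), "m1")
  expect_identical(unname(out$members), "up")

  conflict <- intersect_directional(toy_records("m1", 2),
                                    toy_records("m1", -2))
  expect_length(conflict$members, 0)

  same <- toy_records(c("m1", "m2"), c(2, -2))
  out2 <- intersect_directional(same, same)
  expect_identical(sort(names(out2$members)), c("m1", "m2"))
})

test_that("non-deregulated records never enter an intersection", {
  a <- toy_records(c("m1", "m2"), c(2, 2), deregulated = c(TRUE, FALSE))
  b <- toy_records(c("m1", "m2"), c(2, 2))
  expect_identical(names(intersect_directional(a, b)$members), "m1")
})

test_that("spaceflight sets count cross-tissue multiplicity", {
  res <- list(
    liver = list(FL_vs_HGC = toy_records("m1", 2, tissue = "liver"),
                 FL_vs_VGC = toy_records("m1", 2, tissue = "liver",
                                         label = "FL_vs_VGC")),
    heart = list(FL_vs_HGC = toy_records(c("m1", "m4"), c(2, -2),
                                         tissue = "heart"),
                 FL_vs_VGC = toy_records(c("m1", "m4"), c(2, -2),
                                         tissue = "heart",
                                         label = "FL_vs_VGC")))
  sf <- spaceflight_sets(res)
  expect_identical(sf$multiplicity$feature_id[1], "m1")
  expect_identical(sf$multiplicity$n_tissues[1], 2L)
  expect_true(sf$multiplicity$systemic[1])
  expect_identical(sf$multiplicity$n_tissues[sf$multiplicity$feature_id ==
                                               "m4"], 1L)

  empty <- spaceflight_sets(list(liver = list(
    FL_vs_HGC = toy_records(character(0), numeric(0)),
    FL_vs_VGC = toy_records(character(0), numeric(0)))))
  expect_identical(nrow(empty$multiplicity), 0L)
  expect_length(empty$sets$liver$members, 0)
})

test_that("housing attribution reuses the directional intersection", {
  res <- list(liver = list(
    FL_vs_HGC = toy_records("m9", 2),
    FL_vs_VGC = toy_records(c("m1", "m2"), c(2, -2), label = "FL_vs_VGC"),
    HGC_vs_VGC = toy_records(c("m1", "m3"), c(2, 2),
                             label = "HGC_vs_VGC")))
  hs <- housing_sets(res)
  expect_identical(names(hs$sets$liver$members), "m1")
  expect_identical(hs$sets$liver$label, "housing")
})

test_that("fold-change correlations handle exact collinearity and batching", {
  a <- toy_records(paste0("m", 1:4), c(1, 2, 3, 4))
  b <- toy_records(paste0("m", 1:4), c(2, 4, 6, 8), label = "FL_vs_VGC")
  rec <- fc_correlation(a, b)
  expect_equal(rec$r, 1.0, tolerance = 1e-12)
  expect_equal(rec$p_raw, 0)

  anti <- fc_correlation(a, toy_records(paste0("m", 1:4), -c(1, 2, 3, 4)))
  expect_equal(anti$r, -1.0, tolerance = 1e-12)

  # t-transform closed form on a non-degenerate pair
  set.seed(51)
  fc1 <- rnorm(30)
  fc2 <- fc1 + rnorm(30)
  rec2 <- fc_correlation(toy_records(paste0("m", 1:30), fc1),
                         toy_records(paste0("m", 1:30), fc2))
  r <- cor(fc1, fc2)
  tstat <- r * sqrt(28 / (1 - r^2))
  expect_equal(rec2$p_raw, 2 * pt(-abs(tstat), 28), tolerance = 1e-12)

  batch <- fc_correlation_batch(rbind(rec, rec2), criterion = "adjp")
  expect_equal(batch$p_adj, bh_adjust(batch$p_raw), tolerance = 1e-15)
  strict <- fc_correlation_batch(rbind(rec, rec2),
                                 criterion = "adjp_and_abs_r")
  expect_true(all(!strict$passes | abs(strict$r) > 0.5))
})

test_that("too few shared features yields an undefined correlation", {
  a <- toy_records(c("m1", "m2"), c(1, 2))
  b <- toy_records(c("m1", "m2"), c(2, 1))
  rec <- fc_correlation(a, b)
  expect_true(is.na(rec$r))
  expect_false(rec$passes)
})

test_that("age-dependent sets pair the condition and age contrasts", {
  cond3 <- toy_records(c("m1", "m2", "m5"), c(2, 2, -2),
                       label = "FL_vs_HGC@3M")
  cond8 <- toy_records("m6", 2, label = "FL_vs_HGC@8M")
  agefl <- toy_records(c("m1", "m2", "m6"), c(2, -2, 2),
                       label = "3M_vs_8M@FL")
  out <- age_dependent_sets(cond3, cond8, agefl)
  # m1 up in both -> flight_3m member
  expect_identical(names(out$flight_3m$members), "m1")
  # m2 conflicting -> no match
  m2 <- out$match_table[out$match_table$feature_id == "m2" &
                          out$match_table$age_group == "3M", ]
  expect_identical(m2$category, "no_match")
  # m5 only in the condition comparison
  m5 <- out$match_table[out$match_table$feature_id == "m5" &
                          out$match_table$age_group == "3M", ]
  expect_identical(m5$category, "only_one_comparison")
  # m6: up in FL_vs_HGC@8M and up in 3M_vs_8M@FL, i.e. DOWN in 8M-vs-3M,
  # so it conflicts after the sign flip
  expect_false("m6" %in% names(out$flight_8m$members))
  m6 <- out$match_table[out$match_table$feature_id == "m6" &
                          out$match_table$age_group == "8M", ]
  expect_identical(m6$category, "no_match")
})

test_that("family summaries require two members and report concordance", {
  fam <- data.frame(mirna_id = c("miR-200a-3p", "miR-200b-3p", "miR-1"),
                    family_id = c("MIR-8", "MIR-8", "MIR-1"),
                    stringsAsFactors = FALSE)
  dset <- directional_set("heart", "spaceflight",
                          c("miR-200a-3p" = "up", "miR-200b-3p" = "up",
                            "miR-1" = "down"))
  out <- family_summary(dset, fam)
  expect_identical(out$family_id, "MIR-8")
  expect_equal(out$concordance, 1.0)

  opp <- directional_set("heart", "spaceflight",
                         c("miR-200a-3p" = "up", "miR-200b-3p" = "down"))
  out2 <- family_summary(opp, fam)
  expect_equal(out2$concordance, 0.5)
})

test_that("circulating detectability is inclusive at the threshold", {
  ref <- data.frame(
    mirna_id = c("m1", "m2", "m2", "m3", "m3", "m3"),
    compartment = c("blood", "serum", "blood", "blood", "plasma", "serum"),
    mean_rpmm = c(12, 10, 1, 9.9, 9.9, 9.9),
    stringsAsFactors = FALSE)
  out <- circulating_overlap(c("m1", "m2", "m3"), ref)
  expect_identical(out$flags$detectable, c(TRUE, TRUE, FALSE))
  expect_identical(out$summary$n_detectable, 2L)
})

test_that("n-way directional support honors the minimum-support rule", {
  s1 <- toy_records(c("m1", "m2"), c(2, 2))
  s2 <- toy_records(c("m1", "m2"), c(2, -2))
  s3 <- toy_records("m1", 2)
  out <- directional_support(list(s1, s2, s3), min_support = 2)
  expect_identical(sort(names(out$members)), "m1")
  out2 <- directional_support(list(s1, s2), min_support = 1)
  expect_setequal(names(out2$members), c("m1", "m2"))
})
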