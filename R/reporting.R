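# End-to-end orchestration on synthetic data and recovery scoring against
# the planted truth.

# Expected deregulation direction of a planted feature in the contrasts that
# define its class set (positive planted sign means upregulated in FL).
.expected_direction <- function(sign) ifelse(sign > 0, "up", "down")

#' Score a called directional set against the planted truth
#'
#' Sign-aware: a called feature counts as recovered only if it is planted in
#' the scored class *and* its called direction matches the planted sign;
#' everything else called is a false discovery.
#'
#' @param called A [directional_set()] or named direction vector (feature ->
#'   up/down).
#' @param truth Truth table from [simulate_mirna_counts()].
#' @param effect_class The planted class(es) to score against
#'   (`"spaceflight"`, `"housing"`, `"age_dep_3m"`, `"age_dep_8m"`). A
#'   vector scores against the union: a call is a true recovery when it is
#'   planted in any listed class with a matching direction. Age-dependent
#'   flight effects are themselves spaceflight effects, so the spaceflight
#'   set's false discoveries are naturally assessed against
#'   `c("spaceflight", "age_dep_3m", "age_dep_8m")`.
#' @return One-row data frame: `effect_class`, `n_planted`, `n_called`,
#'   `n_recovered`, `sensitivity`, `fdp`. An empty call set has FDP 0 by the
#'   `max(n_called, 1)` convention.
#' @export
score_recovery <- function(called, truth, effect_class) {
  members <- .as_members(called)
  planted <- truth[truth$effect_class %in% effect_class, , drop = FALSE]
  expected <- stats::setNames(.expected_direction(planted$sign),
                              planted$feature_id)
  hit <- names(members)[members == expected[names(members)] &
                          names(members) %in% names(expected)]
  n_called <- length(members)
  n_recovered <- length(hit)
  data.frame(effect_class = paste(effect_class, collapse = "+"),
             n_planted = nrow(planted),
             n_called = n_called,
             n_recovered = n_recovered,
             sensitivity = if (nrow(planted) > 0L)
               n_recovered / nrow(planted) else NA_real_,
             fdp = (n_called - n_recovered) / max(n_called, 1L),
             stringsAsFactors = FALSE)
}

.union_members <- function(sets) {
  out <- character(0L)
  for (s in sets) {
    m <- .as_members(s)
    keep <- setdiff(names(m), names(out))
    out <- c(out, m[keep])
  }
  out
}

#' Run the full synthetic pipeline
#'
#' Simulates the design, miRNA and mRNA counts, targets and annotation,
#' then executes detection filtering, rpmm normalization, all standard
#' contrasts, PVCA, spaceflight/housing/age attribution, miRNA-mRNA
#' integration and enrichment, and scores recovery of every planted effect
#' class. Deterministic given `config$seed`: stage seeds are derived by
#' fixed offsets.
#'
#' @param config List with elements `params` (a [sim_params()] list,
#'   defaulted when absent), `seed` (integer, default 1), `n_perm` (GSEA
#'   permutations, default 200), `pvca_coverage` (default 0.9), and
#'   optionally `out_dir` to write all tables plus a run summary.
#' @return List with `recovery` (data frame over effect classes), `pvca`,
#'   `de` (nested contrast results), `spaceflight`, `housing`, `age_sets`,
#'   `integration`, `enrichment`, `truth`, `stages` (runtimes), and the
#'   `manifest` when `out_dir` was given.
#' @export
run_all <- function(config = list()) {
  params <- config$params %||% sim_params()
  seed <- as.integer(config$seed %||% 1L)
  n_perm <- config$n_perm %||% 200L
  pvca_coverage <- config$pvca_coverage %||% 0.9

  stages <- list()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    stages[[name]] <<- proc.time()[["elapsed"]] - t0
    val
  }

  design <- tick("simulate_design", simulate_design(params, seed + 11L))
  sim <- tick("simulate_mirna", simulate_mirna_counts(design, params,
                                                      seed + 23L))
  mrna <- tick("simulate_mrna", simulate_mrna_and_targets(sim$truth, design,
                                                          params,
                                                          seed + 37L))
  ann <- tick("simulate_annotation", simulate_annotation(sim$truth, params,
                                                         seed + 41L))

  filt <- tick("detection_filter", detection_filter(sim$counts))
  rpmm <- tick("rpmm", rpmm_normalize(sim$counts))
  lg <- log2_transform(rpmm)
  de <- tick("diffexp", suppressWarnings(
    run_standard_contrasts(lg, rpmm, filter = filt, with_age = TRUE)))

  lg_f <- subset_features(lg, filt$union)
  factors <- c("tissue", "condition", "age")
  factors <- factors[vapply(factors, function(f)
    length(unique(lg_f$metadata[[f]])) >= 2L, logical(1L))]
  pv <- tick("pvca", pvca(lg_f, factors = factors,
                          pc_coverage = pvca_coverage))

  sf <- tick("spaceflight_sets", spaceflight_sets(de))
  hs <- tick("housing_sets", housing_sets(de))
  age_sets <- tick("age_sets", lapply(names(de), function(tis) {
    res <- de[[tis]]
    need <- c("FL_vs_HGC@3M", "FL_vs_HGC@8M", "3M_vs_8M@FL")
    if (!all(need %in% names(res))) return(NULL)
    age_dependent_sets(res[["FL_vs_HGC@3M"]], res[["FL_vs_HGC@8M"]],
                       res[["3M_vs_8M@FL"]], tissue = tis)
  }))
  names(age_sets) <- names(de)

  # mRNA side: same machinery on the gene-level pseudobulk counts
  integration <- tick("integration", {
    g_rpmm <- rpmm_normalize(mrna$counts)
    g_lg <- log2_transform(g_rpmm)
    targets_f <- filter_targets_by_percentile(
      mrna$targets[, c("mirna_id", "gene_id", "score", "validated")])
    hits_all <- list()
    for (tis in names(sf$sets)) {
      cs <- contrast_spec(design, tis, "FL", "HGC")
      g_de <- suppressWarnings(run_contrast(g_lg, g_rpmm, cs))
      if (is.null(g_de)) next
      dereg <- g_de[g_de$deregulated, , drop = FALSE]
      top <- top_deregulated_mrna(dereg)
      hits_all[[tis]] <- pair_hits(sf$sets[[tis]], top, targets_f,
                                   tissue = tis)
    }
    hits <- do.call(rbind, hits_all) %||%
      data.frame(tissue = character(0L), mirna_id = character(0L),
                 gene_id = character(0L), score = numeric(0L),
                 stringsAsFactors = FALSE)
    rownames(hits) <- NULL
    crosscheck <- validated_crosscheck(
      hits, mrna$targets[mrna$targets$validated, , drop = FALSE])
    list(filtered_targets = targets_f, hits = hits,
         most_targeted = most_targeted(hits),
         n_hits = crosscheck$n_total,
         n_validated = crosscheck$n_validated)
  })

  enrichment <- tick("enrichment", {
    sf_union <- .union_members(sf$sets)
    universe <- filt$union
    query <- intersect(names(sf_union), universe)
    ora_res <- ora(query, universe, ann$annotation)
    first_tissue <- names(de)[1L]
    ranked <- make_ranked_list(de[[first_tissue]]$FL_vs_HGC)
    gsea_res <- gsea(ranked, ann$annotation, n_perm = n_perm,
                     seed = seed + 53L)
    sig <- ora_res[ora_res$significant, , drop = FALSE]
    clusters <- if (nrow(sig) > 0L) {
      cl <- cluster_terms(sig, ann$annotation)
      list(clusters = cl, labels = label_clusters(cl, ann$annotation))
    } else {
      list(clusters = list(), labels = list())
    }
    c(list(ora = ora_res, gsea = gsea_res), clusters)
  })

  recovery <- rbind(
    score_recovery(.union_members(sf$sets), sim$truth, "spaceflight"),
    score_recovery(.union_members(sf$sets), sim$truth,
                   c("spaceflight", "age_dep_3m", "age_dep_8m")),
    score_recovery(.union_members(hs$sets), sim$truth, "housing"),
    score_recovery(.union_members(lapply(
      Filter(Negate(is.null), age_sets), `[[`, "flight_3m")),
      sim$truth, "age_dep_3m"),
    score_recovery(.union_members(lapply(
      Filter(Negate(is.null), age_sets), `[[`, "flight_8m")),
      sim$truth, "age_dep_8m"))

  stage_tab <- data.frame(stage = names(stages),
                          seconds = round(unlist(stages), 4),
                          stringsAsFactors = FALSE)
  rownames(stage_tab) <- NULL

  report <- list(recovery = recovery, pvca = pv, de = de,
                 spaceflight = sf, housing = hs, age_sets = age_sets,
                 integration = integration, enrichment = enrichment,
                 truth = sim$truth, stages = stage_tab, seed = seed)

  if (!is.null(config$out_dir)) {
    de_flat <- do.call(rbind, unlist(de, recursive = FALSE))
    rownames(de_flat) <- NULL
    sf_flat <- do.call(rbind, lapply(sf$sets, as.data.frame)) %||%
      data.frame()
    rownames(sf_flat) <- NULL
    report$manifest <- write_results(
      list(recovery = recovery,
           pvca = pv,
           diffexp = de_flat,
           spaceflight_sets = sf_flat,
           spaceflight_multiplicity = sf$multiplicity,
           most_targeted = integration$most_targeted,
           ora = enrichment$ora,
           gsea = enrichment$gsea,
           truth = sim$truth),
      config$out_dir, seed = seed,
      params = params[c("n_tissues", "n_mirnas", "n_genes",
                        "samples_per_group", "nb_dispersion",
                        "effect_log2_shift")])
  }
  report
}
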