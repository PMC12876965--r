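# Synthetic-data generator: negative-binomial miRNA counts over the
# 3-condition x 2-age design with planted spaceflight, housing and
# age-dependent effects, miRNA family structure, target-linked mRNA shifts,
# and matching annotation/ontology/circulating-reference tables. Every
# output is a pure function of (params, seed), and the planted truth is
# recorded for recovery scoring.

.EFFECT_CLASSES <- c("spaceflight", "housing", "age_dep_3m", "age_dep_8m",
                     "null")

#' Simulation parameters
#'
#' Defaults describe the reference recovery experiment: 300 miRNAs over two
#' tissues, 8 samples per tissue x condition x age cell, negative-binomial
#' counts with dispersion 0.1, planted log2 shifts of 2, and effect
#' fractions of 10% spaceflight, 10% housing and 5% per age-dependent
#' class.
#'
#' @param n_tissues Number of tissues (default 2).
#' @param n_mirnas Number of miRNA features (default 300).
#' @param n_genes Number of mRNA features (default 400).
#' @param samples_per_group Replicates per tissue x condition x age cell
#'   (default 8; must be >= 3).
#' @param baseline_log2_mean Range of per-feature baseline log2 expected
#'   counts at nominal depth (default c(3, 10)).
#' @param nb_dispersion Shared negative-binomial dispersion (default 0.1).
#' @param effect_log2_shift Planted shift magnitude on the log2 mean scale
#'   (default 2).
#' @param fractions Named numeric over effect classes `spaceflight`,
#'   `housing`, `age_dep_3m`, `age_dep_8m`, `null`; must sum to 1.
#' @param family_size_probs Probabilities of family sizes 1..k (default
#'   `c(0.7, 0.15, 0.10, 0.05)`).
#' @param target_density Fraction of random miRNA-gene pairs in the target
#'   table (default 0.02).
#' @param planted_targets_per_mirna Planted target genes per affected miRNA
#'   (default 3).
#' @param gene_shift_direction `"opposite"` (canonical repression, default)
#'   or `"same"`: orientation of the induced mRNA shift relative to its
#'   regulator.
#' @param libsize_log_sd Log-sd of the log-normal library-size factor around
#'   1e6 (default 0.3).
#' @param validated_fraction Fraction of planted pairs flagged validated
#'   (default 0.3).
#' @return Named list of validated parameters.
#' @export
sim_params <- function(n_tissues = 2L, n_mirnas = 300L, n_genes = 400L,
                       samples_per_group = 8L,
                       baseline_log2_mean = c(3, 10), nb_dispersion = 0.1,
                       effect_log2_shift = 2,
                       fractions = c(spaceflight = 0.10, housing = 0.10,
                                     age_dep_3m = 0.05, age_dep_8m = 0.05,
                                     null = 0.70),
                       family_size_probs = c(0.7, 0.15, 0.10, 0.05),
                       target_density = 0.02,
                       planted_targets_per_mirna = 3L,
                       gene_shift_direction = c("opposite", "same"),
                       libsize_log_sd = 0.3,
                       validated_fraction = 0.3) {
  gene_shift_direction <- match.arg(gene_shift_direction)
  if (samples_per_group < 3L) stopf("samples_per_group must be >= 3")
  if (nb_dispersion <= 0) stopf("nb_dispersion must be > 0")
  missing <- setdiff(.EFFECT_CLASSES, names(fractions))
  if (length(missing) > 0L) {
    stopf("fractions is missing class(es): %s",
          paste(missing, collapse = ", "))
  }
  if (abs(sum(fractions) - 1) > 1e-9) stopf("fractions must sum to 1")
  if (any(fractions < 0)) stopf("fractions must be non-negative")
  list(n_tissues = n_tissues, n_mirnas = n_mirnas, n_genes = n_genes,
       samples_per_group = samples_per_group,
       baseline_log2_mean = baseline_log2_mean,
       nb_dispersion = nb_dispersion,
       effect_log2_shift = effect_log2_shift,
       fractions = fractions[.EFFECT_CLASSES],
       family_size_probs = family_size_probs,
       target_density = target_density,
       planted_targets_per_mirna = planted_targets_per_mirna,
       gene_shift_direction = gene_shift_direction,
       libsize_log_sd = libsize_log_sd,
       validated_fraction = validated_fraction)
}

#' Simulate the sample design
#'
#' Full crossing of tissue x condition (FL/HGC/VGC) x age (3M/8M) with
#' `samples_per_group` replicates, all in the LAR cohort.
#'
#' @param params From [sim_params()].
#' @param seed Optional integer seed (the design itself is deterministic;
#'   the seed only fixes the mapped-read library sizes).
#' @return Metadata data frame with a `mapped_reads` column.
#' @export
simulate_design <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tissues <- sprintf("tissue%02d", seq_len(params$n_tissues))
  grid <- expand.grid(replicate = seq_len(params$samples_per_group),
                      age = .AGES, condition = .CONDITIONS,
                      tissue = tissues, stringsAsFactors = FALSE)
  grid <- grid[, c("tissue", "condition", "age", "replicate")]
  md <- data.frame(
    sample_id = sprintf("s%04d", seq_len(nrow(grid))),
    tissue = grid$tissue,
    condition = grid$condition,
    age = grid$age,
    cohort = "LAR",
    mapped_reads = round(stats::rlnorm(nrow(grid), log(1e6),
                                       params$libsize_log_sd)),
    stringsAsFactors = FALSE)
  .validate_metadata(md)
}

# Partition features into families and assign effect classes and signs at
# the family level, so family members share class and sign.
.assign_families <- function(params) {
  sizes <- integer(0L)
  while (sum(sizes) < params$n_mirnas) {
    sizes <- c(sizes, sample(seq_along(params$family_size_probs), 1L,
                             prob = params$family_size_probs))
  }
  sizes[length(sizes)] <- sizes[length(sizes)] -
    (sum(sizes) - params$n_mirnas)
  sizes <- sizes[sizes > 0L]
  family_id <- rep(sprintf("MIR-%03d", seq_along(sizes)), times = sizes)
  class_per_family <- sample(.EFFECT_CLASSES, length(sizes), replace = TRUE,
                             prob = params$fractions)
  sign_per_family <- sample(c(1, -1), length(sizes), replace = TRUE)
  data.frame(feature_id = sprintf("miR-%04d", seq_len(params$n_mirnas)),
             family_id = family_id,
             effect_class = rep(class_per_family, times = sizes),
             sign = rep(sign_per_family, times = sizes),
             stringsAsFactors = FALSE)
}

# Which design cells carry a feature's planted shift.
.shift_mask <- function(effect_class, metadata) {
  switch(effect_class,
         spaceflight = metadata$condition == "FL",
         housing = metadata$condition %in% c("FL", "HGC"),
         age_dep_3m = metadata$condition == "FL" & metadata$age == "3M",
         age_dep_8m = metadata$condition == "FL" & metadata$age == "8M",
         null = rep(FALSE, nrow(metadata)))
}

#' Simulate miRNA counts with planted effects
#'
#' Counts are negative-binomial with per-feature baseline log2 means and a
#' shared dispersion; planted shifts act on the log2 mean scale in the
#' design cells of their effect class (spaceflight: FL; housing: FL and
#' HGC; age-dependent: FL within one age). Family members share class and
#' sign. Library-size factors multiply all means of a sample.
#'
#' @param design Metadata from [simulate_design()].
#' @param params From [sim_params()].
#' @param seed Optional integer seed.
#' @return List with `counts` (a [count_matrix()]) and `truth` (data frame
#'   `feature_id`, `family_id`, `effect_class`, `sign`, `shift`).
#' @export
simulate_mirna_counts <- function(design, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  truth <- .assign_families(params)
  truth$shift <- ifelse(truth$effect_class == "null", 0,
                        params$effect_log2_shift) * truth$sign
  base <- stats::runif(params$n_mirnas, params$baseline_log2_mean[1L],
                       params$baseline_log2_mean[2L])
  depth <- design$mapped_reads / 1e6
  n_s <- nrow(design)
  mu <- matrix(0, nrow = params$n_mirnas, ncol = n_s)
  log2mu <- matrix(rep(base, n_s), ncol = n_s)
  for (cls in setdiff(.EFFECT_CLASSES, "null")) {
    rows <- which(truth$effect_class == cls)
    if (length(rows) == 0L) next
    cols <- which(.shift_mask(cls, design))
    if (length(cols) == 0L) next
    log2mu[rows, cols] <- log2mu[rows, cols] + truth$shift[rows]
  }
  mu <- sweep(2^log2mu, 2L, depth, "*")
  counts <- matrix(
    stats::rnbinom(length(mu), mu = mu, size = 1 / params$nb_dispersion),
    nrow = params$n_mirnas,
    dimnames = list(truth$feature_id, design$sample_id))
  list(counts = count_matrix(counts, design), truth = truth)
}

#' Simulate mRNA pseudobulk counts and a target table
#'
#' The target table mixes random background pairs at `target_density` with
#' planted (regulator, target) pairs whose |score| lies above the table's
#' 75th percentile. Genes with planted regulators receive log2 shifts in
#' exactly the samples where their regulators are shifted (default
#' direction: opposite to the regulator, i.e. canonical repression);
#' contributions of multiple regulators add. A random subset of planted
#' pairs is flagged validated.
#'
#' @param truth Truth table from [simulate_mirna_counts()].
#' @param design Metadata from [simulate_design()].
#' @param params From [sim_params()].
#' @param seed Optional integer seed.
#' @return List with `counts` (gene-level [count_matrix()]), `targets`
#'   (target-pair table with `validated` flags), `gene_truth` (data frame
#'   `gene_id`, `regulators`, `n_regulators`).
#' @export
simulate_mrna_and_targets <- function(truth, design, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(params$n_genes))

  # planted pairs: affected miRNAs target genes from a small pool so some
  # genes accumulate several regulators; scores sit above the background
  affected <- truth$feature_id[truth$effect_class != "null"]
  pool <- genes[seq_len(max(params$planted_targets_per_mirna,
                            ceiling(params$n_genes * 0.1)))]
  planted <- do.call(rbind, lapply(affected, function(m) {
    tg <- sample(pool, min(params$planted_targets_per_mirna, length(pool)))
    data.frame(mirna_id = m, gene_id = tg,
               score = -stats::runif(length(tg), 0.45, 0.80),
               planted = rep(TRUE, length(tg)), stringsAsFactors = FALSE)
  }))
  n_planted <- if (is.null(planted)) 0L else nrow(planted)

  # background pairs: uniform over the miRNA x gene grid, weak scores; kept
  # at no less than 4x the planted count (when density > 0) so the planted
  # pairs genuinely occupy the top score quartile of the table
  n_bg <- round(params$target_density * params$n_mirnas * params$n_genes)
  if (params$target_density > 0) n_bg <- max(n_bg, 4L * n_planted)
  n_bg <- min(n_bg, params$n_mirnas * params$n_genes)
  bg_idx <- sample(params$n_mirnas * params$n_genes, n_bg)
  bg <- data.frame(
    mirna_id = truth$feature_id[(bg_idx - 1L) %% params$n_mirnas + 1L],
    gene_id = genes[(bg_idx - 1L) %/% params$n_mirnas + 1L],
    score = -stats::runif(n_bg, 0.01, 0.40),
    planted = rep(FALSE, n_bg), stringsAsFactors = FALSE)
  if (is.null(planted)) {
    planted <- bg[0, , drop = FALSE]
  }
  targets <- rbind(bg, planted)
  # keep the planted version when a background pair collides with it
  targets <- targets[order(!targets$planted), , drop = FALSE]
  targets <- targets[!duplicated(paste(targets$mirna_id, targets$gene_id,
                                       sep = "\r")), , drop = FALSE]
  rownames(targets) <- NULL
  targets$validated <- FALSE
  pl <- which(targets$planted)
  n_val <- round(params$validated_fraction * length(pl))
  if (n_val > 0L) targets$validated[sample(pl, n_val)] <- TRUE

  # gene expression: baseline + summed shifts from planted regulators
  dir_factor <- if (params$gene_shift_direction == "opposite") -1 else 1
  base <- stats::runif(params$n_genes, params$baseline_log2_mean[1L],
                       params$baseline_log2_mean[2L])
  n_s <- nrow(design)
  log2mu <- matrix(rep(base, n_s), ncol = n_s,
                   dimnames = list(genes, design$sample_id))
  planted_tab <- targets[targets$planted, c("mirna_id", "gene_id")]
  for (i in seq_len(nrow(planted_tab))) {
    ti <- match(planted_tab$mirna_id[i], truth$feature_id)
    gi <- match(planted_tab$gene_id[i], genes)
    cols <- which(.shift_mask(truth$effect_class[ti], design))
    if (length(cols) == 0L) next
    log2mu[gi, cols] <- log2mu[gi, cols] + dir_factor * truth$shift[ti]
  }
  depth <- design$mapped_reads / 1e6
  mu <- sweep(2^log2mu, 2L, depth, "*")
  counts <- matrix(
    stats::rnbinom(length(mu), mu = mu, size = 1 / params$nb_dispersion),
    nrow = params$n_genes, dimnames = dimnames(log2mu))

  regs <- split(planted_tab$mirna_id, planted_tab$gene_id)
  gene_truth <- data.frame(
    gene_id = names(regs),
    regulators = vapply(regs, function(r) paste(sort(unique(r)),
                                                collapse = ","),
                        character(1L)),
    n_regulators = vapply(regs, function(r) length(unique(r)), integer(1L)),
    stringsAsFactors = FALSE)
  rownames(gene_truth) <- NULL
  list(counts = count_matrix(counts, design),
       targets = targets[, c("mirna_id", "gene_id", "score", "validated",
                             "planted")],
       gene_truth = gene_truth)
}

#' Simulate annotation, ontology and circulating-reference tables
#'
#' One term per planted effect class (its member miRNAs), plus random terms
#' of varied size; a small ontology DAG containing a known ancestor chain
#' over the random terms; and a circulating table in which a known subset of
#' miRNAs is detectable at mean rpmm >= 10 in at least one compartment.
#'
#' @param truth Truth table from [simulate_mirna_counts()].
#' @param params From [sim_params()].
#' @param seed Optional integer seed.
#' @param n_random_terms Number of random terms (default 10).
#' @return List with `annotation` (a `term_annotation`), `ontology` (edge
#'   data frame), `circulating` (reference table) and `detectable_truth`
#'   (the miRNAs planted as circulating-detectable).
#' @export
simulate_annotation <- function(truth, params, seed = NULL,
                                n_random_terms = 10L) {
  if (!is.null(seed)) set.seed(seed)
  mirnas <- truth$feature_id
  members <- list()
  nm <- character(0L)
  word_pool <- c("membrane", "development", "remodeling", "repair",
                 "binding", "signaling", "adhesion", "matrix", "channel",
                 "organization", "response", "regulation")
  for (cls in setdiff(.EFFECT_CLASSES, "null")) {
    ids <- mirnas[truth$effect_class == cls]
    if (length(ids) == 0L) next
    tid <- paste0("TERM_", cls)
    members[[tid]] <- ids
    nm <- c(nm, stats::setNames(paste(cls, "planted response"), tid))
  }
  for (i in seq_len(n_random_terms)) {
    tid <- sprintf("TERM_rand%02d", i)
    members[[tid]] <- sample(mirnas, sample(5:20, 1L))
    nm <- c(nm, stats::setNames(
      paste(sample(word_pool, 2L), collapse = " "), tid))
  }
  annotation <- term_annotation(members, unname(nm[names(members)]))

  rand_ids <- grep("^TERM_rand", names(members), value = TRUE)
  chain <- rand_ids[seq_len(min(3L, length(rand_ids)))]
  ontology <- data.frame(child_id = character(0L),
                         parent_id = character(0L),
                         stringsAsFactors = FALSE)
  if (length(chain) >= 2L) {
    ontology <- data.frame(child_id = chain[-1L],
                           parent_id = chain[-length(chain)],
                           stringsAsFactors = FALSE)
  }

  detectable <- sample(mirnas, round(length(mirnas) / 2))
  circulating <- do.call(rbind, lapply(.COMPARTMENTS, function(cp) {
    data.frame(mirna_id = mirnas, compartment = cp,
               mean_rpmm = stats::runif(length(mirnas), 0, 9.5),
               stringsAsFactors = FALSE)
  }))
  boost <- sample(.COMPARTMENTS, length(detectable), replace = TRUE)
  for (i in seq_along(detectable)) {
    row <- circulating$mirna_id == detectable[i] &
      circulating$compartment == boost[i]
    circulating$mean_rpmm[row] <- stats::runif(1L, 10, 1000)
  }
  list(annotation = annotation, ontology = ontology,
       circulating = circulating, detectable_truth = sort(detectable))
}
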