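# Cross-contrast set logic: attribution of deregulation to spaceflight vs
# housing, fold-change correlation structure, age-dependent flight sets,
# MIR-family aggregation and circulating-detectability overlap.

#' Do two fold changes share a strict direction?
#'
#' @param fc1,fc2 Numeric log2 fold changes (vectorized).
#' @return Logical; `TRUE` iff `fc1 * fc2 > 0`. A zero fold change has no
#'   direction and never matches.
#' @export
direction_match <- function(fc1, fc2) {
  fc1 * fc2 > 0
}

#' Build a directional set
#'
#' @param tissue,label Identifying strings.
#' @param members Named character vector: names are feature ids, values
#'   `"up"` or `"down"`.
#' @return Object of class `directional_set`.
#' @export
directional_set <- function(tissue, label, members) {
  members <- members[order(names(members))]
  if (any(!members %in% c("up", "down"))) {
    stopf("directional set members must be 'up' or 'down'")
  }
  structure(list(tissue = tissue, label = label, members = members),
            class = "directional_set")
}

#' @export
print.directional_set <- function(x, ...) {
  cat(sprintf("directional_set %s/%s: %d features (%d up, %d down)\n",
              x$tissue, x$label, length(x$members),
              sum(x$members == "up"), sum(x$members == "down")))
  invisible(x)
}

#' @export
as.data.frame.directional_set <- function(x, ...) {
  data.frame(tissue = rep(x$tissue, length(x$members)),
             label = rep(x$label, length(x$members)),
             feature_id = names(x$members),
             direction = unname(x$members),
             stringsAsFactors = FALSE)
}

# Extract (feature -> direction) for deregulated records of one table.
.dereg_members <- function(records) {
  keep <- records$deregulated & records$direction != "none"
  stats::setNames(records$direction[keep], records$feature_id[keep])
}

.as_members <- function(x) {
  if (inherits(x, "directional_set")) return(x$members)
  if (is.data.frame(x)) return(.dereg_members(x))
  if (is.character(x) && !is.null(names(x))) return(x)
  stopf("expected a directional_set, a DE record table or a named direction vector")
}

#' Intersect two deregulated sets with matching directions
#'
#' Members are the features deregulated in both inputs whose deregulation
#' directions agree; the reported direction is taken from the first input.
#'
#' @param setA,setB Differential-expression record data frames (only
#'   `deregulated` rows are used), `directional_set` objects, or named
#'   direction vectors.
#' @param tissue,label Labels for the result (default from `setA` when it
#'   carries them).
#' @return A [directional_set()].
#' @export
intersect_directional <- function(setA, setB, tissue = NULL, label = NULL) {
  ma <- .as_members(setA)
  mb <- .as_members(setB)
  shared <- intersect(names(ma), names(mb))
  agree <- shared[ma[shared] == mb[shared]]
  if (is.null(tissue)) {
    tissue <- if (inherits(setA, "directional_set")) setA$tissue
              else if (is.data.frame(setA) && nrow(setA) > 0L) setA$tissue[1L]
              else ""
  }
  if (is.null(label)) label <- "intersection"
  directional_set(tissue, label, ma[agree])
}

#' Sign-flip a directional set or record table
#'
#' Used to reorient a 3M-vs-8M contrast into 8M-vs-3M.
#'
#' @param x A `directional_set`, DE record data frame, or named direction
#'   vector.
#' @return Object of the same shape with `up`/`down` swapped (for record
#'   tables, `log2fc`, `cohens_d` and `direction` are negated/swapped).
#' @export
flip_direction <- function(x) {
  if (is.data.frame(x)) {
    x$log2fc <- -x$log2fc
    x$cohens_d <- -x$cohens_d
    x$direction <- c(up = "down", down = "up", none = "none")[x$direction]
    return(x)
  }
  m <- .as_members(x)
  flipped <- stats::setNames(c(up = "down", down = "up")[m], names(m))
  if (inherits(x, "directional_set")) {
    return(directional_set(x$tissue, x$label, flipped))
  }
  flipped
}

#' Generalized n-way directional intersection with minimum support
#'
#' A feature qualifies when it is deregulated with one common direction in
#' at least `min_support` of the supplied sets.
#'
#' @param sets List of DE record tables / directional sets / named vectors.
#' @param min_support Minimum number of sets a feature must appear in with
#'   the same direction (default: all of them).
#' @param tissue,label Result labels.
#' @return A [directional_set()]; direction is the shared one.
#' @export
directional_support <- function(sets, min_support = length(sets),
                                tissue = "", label = "support") {
  members <- lapply(sets, .as_members)
  all_feats <- unique(unlist(lapply(members, names), use.names = FALSE))
  out <- character(0L)
  for (f in all_feats) {
    dirs <- unlist(lapply(members, function(m)
      if (f %in% names(m)) m[[f]] else NULL))
    for (d in c("up", "down")) {
      if (sum(dirs == d) >= min_support) {
        out[[f]] <- d
        break
      }
    }
  }
  directional_set(tissue, label, out)
}

#' Per-tissue spaceflight sets and cross-tissue multiplicity
#'
#' Spaceflight-attributed miRNAs are those deregulated in the same direction
#' in both FL-vs-HGC and FL-vs-VGC of a tissue. The multiplicity table
#' counts, for each feature, the number of tissues whose spaceflight set
#' contains it; features appearing in more than one tissue are flagged
#' systemic.
#'
#' @param results Nested list `results[[tissue]]` with elements `FL_vs_HGC`
#'   and `FL_vs_VGC` (DE record data frames), e.g. from
#'   [run_standard_contrasts()].
#' @return List with `sets` (per-tissue [directional_set()]s) and
#'   `multiplicity` (data frame feature_id, n_tissues, systemic).
#' @export
spaceflight_sets <- function(results) {
  sets <- list()
  for (tis in names(results)) {
    res <- results[[tis]]
    if (is.null(res$FL_vs_HGC) || is.null(res$FL_vs_VGC)) next
    sets[[tis]] <- intersect_directional(res$FL_vs_HGC, res$FL_vs_VGC,
                                         tissue = tis, label = "spaceflight")
  }
  feats <- unlist(lapply(sets, function(s) names(s$members)),
                  use.names = FALSE)
  if (length(feats) == 0L) {
    mult <- data.frame(feature_id = character(0L), n_tissues = integer(0L),
                       systemic = logical(0L), stringsAsFactors = FALSE)
  } else {
    tab <- table(feats)
    mult <- data.frame(feature_id = names(tab),
                       n_tissues = as.integer(tab),
                       stringsAsFactors = FALSE)
    mult$systemic <- mult$n_tissues > 1L
    mult <- mult[order(-mult$n_tissues, mult$feature_id), , drop = FALSE]
    rownames(mult) <- NULL
  }
  list(sets = sets, multiplicity = mult)
}

#' Housing sets (spaceflight-independent environment effects)
#'
#' Same directional-intersection logic as [spaceflight_sets()], applied to
#' FL-vs-VGC and HGC-vs-VGC: features responding to the ISS-style housing
#' whether or not the animals flew.
#'
#' @param results Nested list `results[[tissue]]` with `FL_vs_VGC` and
#'   `HGC_vs_VGC` elements.
#' @return List with `sets` and `multiplicity` as in [spaceflight_sets()].
#' @export
housing_sets <- function(results) {
  renamed <- lapply(results, function(res) {
    list(FL_vs_HGC = res$FL_vs_VGC, FL_vs_VGC = res$HGC_vs_VGC)
  })
  out <- spaceflight_sets(renamed)
  out$sets <- lapply(out$sets, function(s) {
    s$label <- "housing"
    s
  })
  out
}

#' Pearson correlation of fold changes between two contrasts
#'
#' @param resA,resB DE record data frames from one tissue; fold changes are
#'   paired on shared feature ids with finite values.
#' @param tissue Optional tissue label (default from `resA`).
#' @return One-row data frame (`tissue`, `label_a`, `label_b`, `n`, `r`,
#'   `p_raw`, `p_adj`, `passes`); `r` is `NA` (and `passes` `FALSE`) with
#'   fewer than 3 shared finite pairs or a zero-variance vector. `p_adj`
#'   equals `p_raw` until adjusted in a batch by [fc_correlation_batch()].
#' @export
fc_correlation <- function(resA, resB, tissue = NULL) {
  m <- merge(resA[, c("feature_id", "log2fc")],
             resB[, c("feature_id", "log2fc")],
             by = "feature_id", suffixes = c("_a", "_b"))
  m <- m[is.finite(m$log2fc_a) & is.finite(m$log2fc_b), , drop = FALSE]
  tissue <- tissue %||% (if (nrow(resA) > 0L) resA$tissue[1L] else "")
  la <- if (nrow(resA) > 0L) resA$label[1L] else ""
  lb <- if (nrow(resB) > 0L) resB$label[1L] else ""
  n <- nrow(m)
  if (n < 3L || stats::var(m$log2fc_a) == 0 || stats::var(m$log2fc_b) == 0) {
    return(data.frame(tissue = tissue, label_a = la, label_b = lb, n = n,
                      r = NA_real_, p_raw = NA_real_, p_adj = NA_real_,
                      passes = FALSE, stringsAsFactors = FALSE))
  }
  r <- stats::cor(m$log2fc_a, m$log2fc_b)
  # two-sided p from the t transform; exact collinearity gives t = Inf, p = 0
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  data.frame(tissue = tissue, label_a = la, label_b = lb, n = n, r = r,
             p_raw = p, p_adj = p, passes = NA, stringsAsFactors = FALSE)
}

#' BH-adjust a batch of fold-change correlations and set the pass flag
#'
#' @param records Data frame of rows from [fc_correlation()] computed
#'   together (one BH family).
#' @param criterion `"adjp"` (adjusted p < alpha) or `"adjp_and_abs_r"`
#'   (additionally `|r| > r_thresh`).
#' @param alpha Adjusted-p cutoff, default 0.05.
#' @param r_thresh Absolute correlation cutoff for the stricter criterion,
#'   default 0.5.
#' @return The records with `p_adj` and `passes` filled in.
#' @export
fc_correlation_batch <- function(records,
                                 criterion = c("adjp", "adjp_and_abs_r"),
                                 alpha = 0.05, r_thresh = 0.5) {
  criterion <- match.arg(criterion)
  ok <- !is.na(records$p_raw)
  records$p_adj <- NA_real_
  records$p_adj[ok] <- bh_adjust(records$p_raw[ok])
  passes <- ok & records$p_adj < alpha
  if (criterion == "adjp_and_abs_r") {
    passes <- passes & !is.na(records$r) & abs(records$r) > r_thresh
  }
  records$passes <- passes
  records
}

#' Age-dependent flight sets
#'
#' `flight_3m` collects features deregulated in the same direction in
#' FL-vs-HGC within 3M and in 3M-vs-8M within FL; `flight_8m` analogously
#' pairs FL-vs-HGC within 8M with the sign-flipped age contrast
#' (8M-vs-3M within FL). The match table categorizes every feature
#' deregulated in either member of each pairing as `equal_direction`,
#' `no_match`, or `only_one_comparison`.
#'
#' @param res_fl_hgc_3m,res_fl_hgc_8m FL-vs-HGC records within the 3M / 8M
#'   stratum of one tissue.
#' @param res_age_fl 3M-vs-8M records within FL of the same tissue.
#' @param tissue Optional tissue label.
#' @return List with `flight_3m`, `flight_8m` ([directional_set()]s) and
#'   `match_table` (feature_id, age_group, category).
#' @export
age_dependent_sets <- function(res_fl_hgc_3m, res_fl_hgc_8m, res_age_fl,
                               tissue = NULL) {
  tissue <- tissue %||%
    (if (nrow(res_fl_hgc_3m) > 0L) res_fl_hgc_3m$tissue[1L] else "")
  age_flipped <- flip_direction(res_age_fl)
  flight_3m <- intersect_directional(res_fl_hgc_3m, res_age_fl,
                                     tissue = tissue, label = "flight_3m")
  flight_8m <- intersect_directional(res_fl_hgc_8m, age_flipped,
                                     tissue = tissue, label = "flight_8m")

  categorize <- function(cond_members, age_members) {
    feats <- union(names(cond_members), names(age_members))
    vapply(feats, function(f) {
      in_cond <- f %in% names(cond_members)
      in_age <- f %in% names(age_members)
      if (in_cond && in_age) {
        if (cond_members[[f]] == age_members[[f]]) "equal_direction"
        else "no_match"
      } else "only_one_comparison"
    }, character(1L))
  }
  m3 <- categorize(.as_members(res_fl_hgc_3m), .as_members(res_age_fl))
  m8 <- categorize(.as_members(res_fl_hgc_8m), .as_members(age_flipped))
  match_table <- rbind(
    data.frame(feature_id = names(m3), age_group = "3M",
               category = unname(m3), stringsAsFactors = FALSE),
    data.frame(feature_id = names(m8), age_group = "8M",
               category = unname(m8), stringsAsFactors = FALSE))
  rownames(match_table) <- NULL
  list(flight_3m = flight_3m, flight_8m = flight_8m,
       match_table = match_table)
}

#' Summarize MIR families within a directional set
#'
#' @param dset A [directional_set()].
#' @param family_map Data frame with columns `mirna_id`, `family_id`.
#' @param min_members Minimum deregulated members for a family to be
#'   reported (default 2).
#' @return Data frame (`family_id`, `tissue`, `n_members`, `members`,
#'   `directions`, `concordance`); concordance is the fraction of members
#'   sharing the family's majority direction.
#' @export
family_summary <- function(dset, family_map, min_members = 2L) {
  members <- dset$members
  fam <- family_map$family_id[match(names(members), family_map$mirna_id)]
  keep <- !is.na(fam)
  members <- members[keep]
  fam <- fam[keep]
  out <- lapply(unique(fam), function(fid) {
    idx <- fam == fid
    if (sum(idx) < min_members) return(NULL)
    dirs <- members[idx]
    conc <- max(table(dirs)) / length(dirs)
    data.frame(family_id = fid, tissue = dset$tissue,
               n_members = sum(idx),
               members = paste(names(dirs), collapse = ","),
               directions = paste(unname(dirs), collapse = ","),
               concordance = conc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(family_id = character(0L), tissue = character(0L),
                      n_members = integer(0L), members = character(0L),
                      directions = character(0L), concordance = numeric(0L),
                      stringsAsFactors = FALSE)
  } else {
    out <- out[order(-out$n_members, out$family_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Circulating-detectability overlap
#'
#' A feature is flagged detectable when its mean rpmm reaches `threshold`
#' (inclusive) in at least one of blood, plasma or serum.
#'
#' @param features Character vector of miRNA ids.
#' @param reference Circulating reference table (`mirna_id`, `compartment`,
#'   `mean_rpmm`).
#' @param threshold Minimum mean rpmm, default 10.
#' @return List with `flags` (data frame feature_id, detectable,
#'   compartments) and `summary` (n_features, n_detectable).
#' @export
circulating_overlap <- function(features, reference, threshold = 10) {
  ref <- reference[reference$compartment %in% .COMPARTMENTS, , drop = FALSE]
  flags <- lapply(features, function(f) {
    rows <- ref[ref$mirna_id == f & ref$mean_rpmm >= threshold, ,
                drop = FALSE]
    data.frame(feature_id = f,
               detectable = nrow(rows) > 0L,
               compartments = paste(sort(unique(rows$compartment)),
                                    collapse = ","),
               stringsAsFactors = FALSE)
  })
  flags <- do.call(rbind, flags) %||%
    data.frame(feature_id = character(0L), detectable = logical(0L),
               compartments = character(0L), stringsAsFactors = FALSE)
  list(flags = flags,
       summary = data.frame(n_features = length(features),
                            n_detectable = sum(flags$detectable)))
}
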