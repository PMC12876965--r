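# Principal variance component analysis (PVCA).
#
# PCA over samples on the feature-centered log2 expression matrix; the
# smallest set of leading PCs covering the requested variance fraction is
# retained. Each retained PC score is decomposed into random-intercept
# variance components (REML, non-negative by construction) for every design
# factor and, optionally, every pairwise factor interaction. Per-PC
# component fractions are averaged with eigenvalue weights, so the final
# fractions sum to one.

#' Retain leading principal components up to a coverage fraction
#'
#' Features are centered before the decomposition. `k` is the smallest
#' number of components whose cumulative explained-variance fraction reaches
#' `coverage`.
#'
#' @param expr An [expr_matrix()] (log2 scale expected for the pipeline, any
#'   numeric content accepted).
#' @param coverage Target cumulative variance fraction in (0, 1], default
#'   0.9.
#' @return List with `scores` (samples x k matrix) and `eigen_fractions`
#'   (per-PC explained-variance fractions, length k).
#' @export
pca_retain <- function(expr, coverage = 0.9) {
  if (coverage <= 0 || coverage > 1) stopf("coverage must be in (0, 1]")
  x <- if (inherits(expr, "expr_matrix")) expr$values else as.matrix(expr)
  if (ncol(x) < 2L) stopf("pca_retain needs at least 2 samples")
  centered <- x - rowMeans(x)
  pc <- stats::prcomp(t(centered), center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  total <- sum(ev)
  if (total <= 0) stopf("expression matrix has no variance")
  frac <- ev / total
  # numerical rank cutoff: discard components carrying only rounding noise
  nonzero <- frac > 1e-12
  frac <- frac[nonzero]
  cum <- cumsum(frac)
  k <- which(cum >= coverage - 1e-12)[1L]
  if (is.na(k)) k <- length(frac)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       eigen_fractions = frac[seq_len(k)])
}

#' Random-intercept variance components for one response
#'
#' Restricted maximum likelihood estimates of the variance attributable to
#' each grouping (random intercepts) plus the residual. Components are
#' non-negative; boundary estimates come back as 0. Groupings with a single
#' represented level are fixed at 0 with a warning.
#'
#' @param y Numeric response, one value per sample.
#' @param groupings Named list of grouping vectors (each length `length(y)`).
#' @return Named numeric vector of raw variance components, last element
#'   `residual`.
#' @export
variance_components <- function(y, groupings) {
  if (!is.list(groupings) || is.null(names(groupings)) ||
      any(!nzchar(names(groupings)))) {
    stopf("groupings must be a fully named list")
  }
  n <- length(y)
  if (any(lengths(groupings) != n)) {
    stopf("each grouping must have one label per sample")
  }
  comps <- stats::setNames(numeric(length(groupings)), names(groupings))
  if (stats::var(y) == 0) {
    return(c(comps, residual = 0))
  }
  usable <- vapply(groupings, function(g) length(unique(g)) >= 2L,
                   logical(1L))
  if (any(!usable)) {
    warnf("grouping(s) with a single level fixed at 0: %s",
          paste(names(groupings)[!usable], collapse = ", "))
  }
  active <- names(groupings)[usable]
  if (length(active) == 0L) {
    return(c(comps, residual = stats::var(y)))
  }
  dat <- data.frame(.y = y)
  for (nm in active) dat[[nm]] <- factor(groupings[[nm]])
  form <- stats::as.formula(paste(
    ".y ~", paste(sprintf("(1 | `%s`)", active), collapse = " + ")))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = dat, REML = TRUE,
               control = lme4::lmerControl(
                 check.nobs.vs.nlev = "ignore",
                 check.nobs.vs.nRE = "ignore",
                 check.conv.singular = "ignore",
                 calc.derivs = FALSE))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  for (i in seq_len(nrow(vc))) {
    grp <- vc$grp[i]
    if (grp == "Residual") next
    comps[[grp]] <- max(0, vc$vcov[i])
  }
  resid_var <- max(0, vc$vcov[vc$grp == "Residual"][1L])
  c(comps, residual = resid_var)
}

.pvca_groupings <- function(metadata, factors, pairwise) {
  groupings <- lapply(factors, function(f) {
    if (!f %in% names(metadata)) stopf("factor '%s' not found in metadata", f)
    as.character(metadata[[f]])
  })
  names(groupings) <- factors
  if (pairwise && length(factors) >= 2L) {
    pairs <- utils::combn(factors, 2L, simplify = FALSE)
    for (pr in pairs) {
      nm <- paste(pr, collapse = ":")
      groupings[[nm]] <- paste(groupings[[pr[1L]]], groupings[[pr[2L]]],
                               sep = ":")
    }
  }
  groupings
}

#' Principal variance component analysis
#'
#' @param expr An [expr_matrix()] on the log2 scale with metadata (or pass
#'   `metadata` explicitly).
#' @param factors Character vector of metadata columns to decompose over
#'   (e.g. `c("tissue", "age", "condition")`).
#' @param metadata Optional metadata override; defaults to the matrix's own.
#' @param include_pairwise_interactions Include all pairwise label
#'   interactions (default TRUE). Set FALSE for the two-factor convenience
#'   mode that compares exactly the named factors.
#' @param pc_coverage Variance coverage for PC retention (default 0.9).
#' @return Object of class `pvca_result`: `fractions` (named, includes
#'   `residual`, sums to 1), `n_pcs`, `eigen_fractions`.
#' @export
pvca <- function(expr, factors, metadata = NULL,
                 include_pairwise_interactions = TRUE, pc_coverage = 0.9) {
  if (length(factors) == 0L) stopf("factors must be non-empty")
  md <- metadata %||% expr$metadata
  if (is.null(md)) stopf("pvca needs sample metadata")
  x <- if (inherits(expr, "expr_matrix")) expr$values else as.matrix(expr)
  md <- md[match(colnames(x), md$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) stopf("metadata does not cover all samples")

  pcs <- pca_retain(expr, pc_coverage)
  groupings <- .pvca_groupings(md, factors, include_pairwise_interactions)

  k <- ncol(pcs$scores)
  weights <- pcs$eigen_fractions / sum(pcs$eigen_fractions)
  frac_mat <- matrix(0, nrow = length(groupings) + 1L, ncol = k,
                     dimnames = list(c(names(groupings), "residual"), NULL))
  for (j in seq_len(k)) {
    comps <- variance_components(pcs$scores[, j], groupings)
    total <- sum(comps)
    frac_mat[, j] <- if (total > 0) comps / total else
      c(rep(0, length(groupings)), 1)
  }
  fractions <- as.numeric(frac_mat %*% weights)
  names(fractions) <- rownames(frac_mat)
  structure(list(fractions = fractions, n_pcs = k,
                 eigen_fractions = pcs$eigen_fractions),
            class = "pvca_result")
}

#' @export
print.pvca_result <- function(x, ...) {
  cat(sprintf("PVCA over %d principal components\n", x$n_pcs))
  fr <- sort(x$fractions, decreasing = TRUE)
  for (nm in names(fr)) cat(sprintf("  %-24s %6.2f%%\n", nm, 100 * fr[nm]))
  invisible(x)
}
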