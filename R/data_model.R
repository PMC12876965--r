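# Core data containers and readers/writers for the tabular interchange formats.
#
# Canonical dialect: tab-separated, UTF-8, '#' comment lines ignored, first
# column is the feature/sample identifier. Reals are serialized with 12
# significant digits so regression comparisons survive a write/read cycle.

.CONDITIONS <- c("FL", "HGC", "VGC")
.AGES <- c("3M", "8M")
.COHORTS <- c("LAR", "TERM")
.COMPARTMENTS <- c("blood", "plasma", "serum")
.METADATA_COLS <- c("sample_id", "tissue", "condition", "age", "cohort")

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Design factor levels
#'
#' The three housing conditions (FL spaceflight, HGC habitat ground control,
#' VGC vivarium ground control), the two age groups and the two euthanasia
#' cohorts (live animal return, on-orbit termination) recognized by all
#' metadata validators.
#'
#' @return Named list of character vectors with elements `condition`, `age`
#'   and `cohort`.
#' @export
design_levels <- function() {
  list(condition = .CONDITIONS, age = .AGES, cohort = .COHORTS)
}

.validate_metadata <- function(metadata) {
  if (!is.data.frame(metadata)) stopf("metadata must be a data.frame")
  missing <- setdiff(.METADATA_COLS, names(metadata))
  if (length(missing) > 0L) {
    stopf("metadata is missing required column(s): %s",
          paste(missing, collapse = ", "))
  }
  dup <- metadata$sample_id[duplicated(metadata$sample_id)]
  if (length(dup) > 0L) {
    stopf("duplicated sample_id in metadata: %s",
          paste(unique(dup), collapse = ", "))
  }
  for (col in c("condition", "age", "cohort")) {
    allowed <- switch(col,
                      condition = .CONDITIONS, age = .AGES, cohort = .COHORTS)
    bad <- setdiff(unique(as.character(metadata[[col]])), allowed)
    if (length(bad) > 0L) {
      stopf("metadata column '%s' contains value(s) %s; allowed: %s",
            col, paste(bad, collapse = ", "), paste(allowed, collapse = ", "))
    }
  }
  if ("mapped_reads" %in% names(metadata)) {
    mr <- metadata$mapped_reads
    if (!is.numeric(mr) || any(!is.na(mr) & (mr < 0 | mr != round(mr)))) {
      stopf("metadata column 'mapped_reads' must hold non-negative integers")
    }
  }
  metadata$sample_id <- as.character(metadata$sample_id)
  metadata$tissue <- as.character(metadata$tissue)
  for (col in c("condition", "age", "cohort")) {
    metadata[[col]] <- as.character(metadata[[col]])
  }
  metadata
}

.check_count_values <- function(counts, what = "counts") {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stopf("%s must be a numeric matrix", what)
  }
  bad <- which(!is.finite(counts) | counts < 0 |
                 abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stopf("%s contains a non-integer or negative value at row '%s', column '%s'",
          what,
          rownames(counts)[bad[1L, 1L]] %||% bad[1L, 1L],
          colnames(counts)[bad[1L, 2L]] %||% bad[1L, 2L])
  }
  invisible(counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_ids <- function(ids, what) {
  if (is.null(ids)) stopf("%s identifiers are missing", what)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stopf("duplicated %s identifier(s): %s", what,
          paste(unique(dup), collapse = ", "))
  }
  invisible(ids)
}

#' Construct a count matrix bound to sample metadata
#'
#' @param counts Integer matrix, features in rows, samples in columns, with
#'   feature/sample identifiers as dimnames. Values must be non-negative
#'   integers.
#' @param metadata Data frame with at least `sample_id`, `tissue`,
#'   `condition`, `age`, `cohort` (and optionally `mapped_reads`), one row per
#'   column of `counts`. May be `NULL` for a bare matrix; operations that need
#'   the design will refuse to run until metadata is attached.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, metadata = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  .check_count_values(counts)
  .check_ids(rownames(counts), "feature")
  .check_ids(colnames(counts), "sample")
  if (!is.null(metadata)) {
    metadata <- .validate_metadata(metadata)
    missing <- setdiff(colnames(counts), metadata$sample_id)
    if (length(missing) > 0L) {
      stopf("sample(s) without metadata: %s", paste(missing, collapse = ", "))
    }
    metadata <- metadata[match(colnames(counts), metadata$sample_id), ,
                         drop = FALSE]
    rownames(metadata) <- NULL
  }
  structure(list(counts = counts, metadata = metadata),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$metadata)) " (no metadata)" else ""))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

.require_metadata <- function(x) {
  if (is.null(x$metadata)) {
    stopf("this operation needs sample metadata; attach it with count_matrix()")
  }
  x$metadata
}

#' Construct a normalized expression matrix
#'
#' @param values Numeric matrix of finite non-negative values with dimnames.
#' @param metadata Optional sample metadata (see [count_matrix()]).
#' @param scale Either `"rpmm"` (reads per million mapped) or `"log2_rpmm"`.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, metadata = NULL,
                        scale = c("rpmm", "log2_rpmm")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values))) {
    stopf("expression values must be finite numerics")
  }
  .check_ids(rownames(values), "feature")
  .check_ids(colnames(values), "sample")
  if (!is.null(metadata)) {
    metadata <- .validate_metadata(metadata)
    metadata <- metadata[match(colnames(values), metadata$sample_id), ,
                         drop = FALSE]
    if (anyNA(metadata$sample_id)) stopf("sample(s) without metadata")
    rownames(metadata) <- NULL
  }
  structure(list(values = values, metadata = metadata, scale = scale),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix [%s]: %d features x %d samples\n",
              x$scale, nrow(x$values), ncol(x$values)))
  invisible(x)
}

.read_tsv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    quote = "")
}

#' Read a raw count matrix
#'
#' Supports a plain TSV (feature identifiers in the first column, sample
#' identifiers in the header) and a MatrixMarket coordinate triplet with two
#' side files listing feature and sample identifiers, one per line.
#'
#' @param path Path to the TSV or `.mtx` file.
#' @param format `"tsv"` or `"mtx_triplet"`.
#' @param features_path,samples_path Identifier side files for the MTX
#'   triplet; default to `<path without .mtx>.features.tsv` and
#'   `.samples.tsv`.
#' @param metadata Optional metadata data frame to bind (see
#'   [count_matrix()]).
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, format = c("tsv", "mtx_triplet"),
                              features_path = NULL, samples_path = NULL,
                              metadata = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- .read_tsv(path)
    if (ncol(tab) < 2L) stopf("count TSV '%s' has no sample columns", path)
    ids <- as.character(tab[[1L]])
    mat <- as.matrix(tab[, -1L, drop = FALSE])
    if (!is.numeric(mat)) {
      stopf("count TSV '%s' contains non-numeric entries", path)
    }
    rownames(mat) <- ids
    return(count_matrix(mat, metadata))
  }
  stem <- sub("\\.mtx$", "", path)
  features_path <- features_path %||% paste0(stem, ".features.tsv")
  samples_path <- samples_path %||% paste0(stem, ".samples.tsv")
  for (p in c(path, features_path, samples_path)) {
    if (!file.exists(p)) stopf("file not found: %s", p)
  }
  m <- as.matrix(Matrix::readMM(path))
  feats <- readLines(features_path)
  samps <- readLines(samples_path)
  feats <- feats[nzchar(feats)]
  samps <- samps[nzchar(samps)]
  if (length(feats) != nrow(m) || length(samps) != ncol(m)) {
    stopf("MTX dimensions (%d x %d) do not match id files (%d x %d)",
          nrow(m), ncol(m), length(feats), length(samps))
  }
  dimnames(m) <- list(feats, samps)
  count_matrix(m, metadata)
}

#' Read a sample metadata table
#'
#' Required columns: `sample_id`, `tissue`, `condition` (FL/HGC/VGC), `age`
#' (3M/8M), `cohort` (LAR/TERM). Extra columns are preserved untouched.
#'
#' @param path Path to a metadata TSV.
#' @return A validated data frame.
#' @export
read_metadata <- function(path) {
  .validate_metadata(.read_tsv(path))
}

#' Read an auxiliary annotation table
#'
#' @param path File path.
#' @param kind One of `"family_map"` (columns mirna_id, family_id),
#'   `"target_table"` (mirna_id, gene_id, score, validated in 0/1),
#'   `"gmt"` (standard gene-set format), `"ontology_edges"` (child_id,
#'   parent_id; must be acyclic), `"circulating_reference"` (mirna_id,
#'   compartment in blood/plasma/serum, mean_rpmm).
#' @return A typed table: data frame for the tabular kinds, a
#'   `term_annotation` list for GMT.
#' @export
read_auxiliary <- function(path,
                           kind = c("family_map", "target_table", "gmt",
                                    "ontology_edges",
                                    "circulating_reference")) {
  kind <- match.arg(kind)
  if (kind == "gmt") return(read_gmt(path))
  tab <- .read_tsv(path)
  need <- switch(kind,
                 family_map = c("mirna_id", "family_id"),
                 target_table = c("mirna_id", "gene_id", "score", "validated"),
                 ontology_edges = c("child_id", "parent_id"),
                 circulating_reference = c("mirna_id", "compartment",
                                           "mean_rpmm"))
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L) {
    stopf("%s table '%s' is missing column(s): %s", kind, path,
          paste(missing, collapse = ", "))
  }
  switch(kind,
         family_map = {
           dup <- tab$mirna_id[duplicated(tab$mirna_id)]
           if (length(dup) > 0L) {
             stopf("family map assigns multiple families to: %s",
                   paste(unique(dup), collapse = ", "))
           }
           tab
         },
         target_table = validate_target_table(tab),
         ontology_edges = {
           .check_acyclic(tab)
           tab
         },
         circulating_reference = {
           bad <- setdiff(unique(tab$compartment), .COMPARTMENTS)
           if (length(bad) > 0L) {
             stopf("unknown circulating compartment(s): %s; allowed: %s",
                   paste(bad, collapse = ", "),
                   paste(.COMPARTMENTS, collapse = ", "))
           }
           tab
         })
}

#' Validate a miRNA-target pair table
#'
#' @param tab Data frame with columns mirna_id, gene_id, score, validated.
#' @return The validated table with `validated` as logical.
#' @export
validate_target_table <- function(tab) {
  key <- paste(tab$mirna_id, tab$gene_id, sep = "\r")
  dup <- key[duplicated(key)]
  if (length(dup) > 0L) {
    stopf("duplicated target pair(s): %s",
          paste(gsub("\r", " -> ", unique(dup)), collapse = ", "))
  }
  if (!is.numeric(tab$score)) stopf("target scores must be numeric")
  if (is.numeric(tab$validated)) {
    if (any(!tab$validated %in% c(0, 1))) {
      stopf("target 'validated' flags must be 0 or 1")
    }
    tab$validated <- tab$validated == 1
  }
  if (!is.logical(tab$validated)) stopf("target 'validated' must be 0/1")
  tab
}

#' Read a GMT gene-set file
#'
#' Each line is `term_id<TAB>term_name<TAB>member1<TAB>member2...`.
#'
#' @param path Path to a GMT file.
#' @return A `term_annotation`: list of terms, each with `term_id`,
#'   `term_name` and a character vector `members`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  terms <- lapply(lines, function(line) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) {
      stopf("GMT term '%s' has an empty member set", parts[1L])
    }
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0L) {
      stopf("GMT term '%s' has an empty member set", parts[1L])
    }
    list(term_id = parts[1L], term_name = parts[2L], members = members)
  })
  ids <- vapply(terms, `[[`, character(1L), "term_id")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stopf("duplicated GMT term id(s): %s", paste(unique(dup), collapse = ", "))
  }
  structure(terms, class = "term_annotation")
}

#' Build a term annotation in code
#'
#' @param members Named list mapping term ids to member id vectors.
#' @param term_names Optional character vector of descriptive names (defaults
#'   to the ids).
#' @return A `term_annotation` list.
#' @export
term_annotation <- function(members, term_names = NULL) {
  ids <- names(members)
  .check_ids(ids, "term")
  if (is.null(term_names)) term_names <- ids
  if (any(lengths(members) == 0L)) {
    stopf("term(s) with empty member set: %s",
          paste(ids[lengths(members) == 0L], collapse = ", "))
  }
  structure(Map(function(id, nm, mem) {
    list(term_id = id, term_name = nm, members = unique(as.character(mem)))
  }, ids, term_names, members, USE.NAMES = FALSE),
  class = "term_annotation")
}

# Kahn's algorithm; errors on any cycle among child -> parent edges.
.check_acyclic <- function(edges) {
  nodes <- unique(c(edges$child_id, edges$parent_id))
  if (length(nodes) == 0L) return(invisible(TRUE))
  out <- split(edges$parent_id, factor(edges$child_id, levels = nodes))
  indeg <- table(factor(edges$parent_id, levels = nodes))
  queue <- nodes[indeg == 0L]
  seen <- 0L
  indeg <- as.integer(indeg)
  names(indeg) <- nodes
  while (length(queue) > 0L) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    seen <- seen + 1L
    for (w in out[[v]] %||% character(0L)) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  if (seen < length(nodes)) {
    stopf("ontology edge set contains a cycle involving: %s",
          paste(names(indeg)[indeg > 0L], collapse = ", "))
  }
  invisible(TRUE)
}

.format_real <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (is.infinite(v)) return(if (v > 0) "Inf" else "-Inf")
    sprintf("%.12g", v)
  }, character(1L))
  out
}

.write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  out <- df
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- .format_real(out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

.as_result_table <- function(x) {
  if (is.data.frame(x)) return(x)
  if (inherits(x, "pvca_result")) {
    return(data.frame(component = names(x$fractions),
                      fraction = unname(x$fractions),
                      stringsAsFactors = FALSE))
  }
  if (inherits(x, "directional_set")) return(as.data.frame(x))
  stopf("cannot serialize result of class %s", paste(class(x), collapse = "/"))
}

#' Write pipeline results to a directory
#'
#' Each named element is written as a TSV (reals with 12 significant digits);
#' a `run_summary.json` records the parameters, seed and MD5 digests of the
#' written tables.
#'
#' @param results Named list of data frames (or `pvca_result` /
#'   `directional_set` objects, which are tabularized).
#' @param out_dir Output directory, created if needed.
#' @param seed Optional integer recorded in the run summary.
#' @param params Optional named list of parameters recorded in the summary.
#' @return Invisibly, a data frame manifest of written files.
#' @export
write_results <- function(results, out_dir, seed = NULL, params = list()) {
  if (is.null(names(results)) || any(!nzchar(names(results)))) {
    stopf("results must be a fully named list")
  }
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) stopf("cannot create output directory: %s", out_dir)
  files <- character(0L)
  for (nm in names(results)) {
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    .write_tsv(.as_result_table(results[[nm]]), path)
    files <- c(files, path)
  }
  digests <- as.character(tools::md5sum(files))
  summary <- list(tables = basename(files),
                  digests = digests,
                  seed = seed,
                  parameters = params)
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(data.frame(name = names(results), path = files,
                       md5 = digests, stringsAsFactors = FALSE))
}

#' Read back a results table written by [write_results()]
#'
#' @param path Path to a TSV written by [write_results()].
#' @return Data frame.
#' @export
read_results_table <- function(path) {
  .read_tsv(path)
}
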