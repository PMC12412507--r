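#' Construct a protein abundance matrix
#'
#' Container for a samples-by-proteins abundance table with a domain tag
#' marking whether the data is the labeled reference or the target to be
#' deconvolved. Missing values are not allowed; use [load_expression()] to
#' read files with missing entries (imputed to zero with a logged count).
#'
#' @param values Numeric matrix, samples in rows, proteins in columns.
#' @param sample_ids Character vector of unique sample identifiers
#'   (defaults to rownames).
#' @param feature_ids Character vector of unique protein identifiers
#'   (defaults to colnames).
#' @param domain Either `"reference"` or `"target"`.
#' @return An object of class `protein_matrix` with fields `values`,
#'   `sample_ids`, `feature_ids`, `domain`.
#' @export
protein_matrix <- function(values, sample_ids = rownames(values),
                           feature_ids = colnames(values),
                           domain = c("reference", "target")) {
  domain <- match.arg(domain)
  values <- as.matrix(values)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(feature_ids)) feature_ids <- paste0("P", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  storage.mode(values) <- "double"
  dimnames(values) <- list(sample_ids, feature_ids)
  out <- structure(
    list(values = values, sample_ids = sample_ids,
         feature_ids = feature_ids, domain = domain),
    class = "protein_matrix")
  validate_protein_matrix(out)
  out
}

validate_protein_matrix <- function(x) {
  stopifnot(inherits(x, "protein_matrix"))
  if (anyDuplicated(x$sample_ids))
    stop("duplicate sample_ids in protein_matrix")
  if (anyDuplicated(x$feature_ids))
    stop("duplicate feature_ids in protein_matrix")
  if (length(x$sample_ids) != nrow(x$values) ||
      length(x$feature_ids) != ncol(x$values))
    stop("protein_matrix id lists inconsistent with matrix shape")
  if (any(!is.finite(x$values)))
    stop("protein_matrix values must be finite")
  invisible(x)
}

#' @export
print.protein_matrix <- function(x, ...) {
  cat(sprintf("protein_matrix [%s]: %d samples x %d proteins\n",
              x$domain, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Construct a cell-type annotation
#'
#' @param cell_ids Character vector of cell identifiers.
#' @param labels Character vector of cell-type names, one per cell.
#' @param type_universe Ordered character vector of the distinct cell-type
#'   names; defaults to the sorted unique labels.
#' @return An object of class `cell_type_annotation`.
#' @export
cell_type_annotation <- function(cell_ids, labels,
                                 type_universe = sort(unique(labels))) {
  cell_ids <- as.character(cell_ids)
  labels <- as.character(labels)
  type_universe <- as.character(type_universe)
  if (length(cell_ids) != length(labels))
    stop("cell_ids and labels must have the same length")
  if (anyDuplicated(type_universe))
    stop("type_universe must be distinct")
  if (!all(labels %in% type_universe))
    stop("every label must belong to type_universe")
  structure(list(cell_ids = cell_ids, labels = labels,
                 type_universe = type_universe),
            class = "cell_type_annotation")
}

#' Construct a cell-type proportion matrix
#'
#' Rows are samples, columns cell types; all entries are non-negative and
#' every row sums to one (tolerance 1e-6).
#'
#' @param values Numeric matrix (samples x cell types).
#' @param sample_ids Character sample identifiers (defaults to rownames).
#' @param type_universe Character cell-type names (defaults to colnames).
#' @return An object of class `proportion_matrix`.
#' @export
proportion_matrix <- function(values, sample_ids = rownames(values),
                              type_universe = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(type_universe))
    type_universe <- paste0("T", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  type_universe <- as.character(type_universe)
  storage.mode(values) <- "double"
  dimnames(values) <- list(sample_ids, type_universe)
  out <- structure(list(values = values, sample_ids = sample_ids,
                        type_universe = type_universe),
                   class = "proportion_matrix")
  validate_proportion_matrix(out)
  out
}

validate_proportion_matrix <- function(x, tol = 1e-6) {
  stopifnot(inherits(x, "proportion_matrix"))
  if (anyDuplicated(x$sample_ids))
    stop("duplicate sample_ids in proportion_matrix")
  if (any(x$values < 0))
    stop("proportion_matrix entries must be non-negative")
  rs <- rowSums(x$values)
  if (any(abs(rs - 1) > tol))
    stop(sprintf("proportion_matrix rows must sum to 1 (max deviation %.3g)",
                 max(abs(rs - 1))))
  invisible(x)
}

#' @export
print.proportion_matrix <- function(x, ...) {
  cat(sprintf("proportion_matrix: %d samples x %d cell types\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Load an expression matrix from disk
#'
#' Reads a delimited (CSV/TSV, header row + index column) or MatrixMarket
#' (`.mtx` plus `<path>.rows` / `<path>.cols` sidecar id files) abundance
#' matrix. Missing or non-finite entries are imputed to zero; the number of
#' imputed cells is reported via a message and stored in the
#' `imputed_count` attribute of the result.
#'
#' @param path File path.
#' @param format One of `"csv"`, `"tsv"`, `"mtx"`.
#' @param domain `"reference"` or `"target"`.
#' @param quiet Suppress the imputation message.
#' @return A [protein_matrix()].
#' @export
load_expression <- function(path, format = c("csv", "tsv", "mtx"),
                            domain = c("reference", "target"),
                            quiet = FALSE) {
  format <- match.arg(format)
  domain <- match.arg(domain)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    dt <- tryCatch(
      data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE),
      error = function(e) stop("failed to parse ", path, ": ",
                               conditionMessage(e)))
    if (ncol(dt) < 2) stop("expected an index column plus >=1 feature column")
    ids <- as.character(dt[[1]])
    vals <- as.matrix(dt[, -1, drop = FALSE])
    storage.mode(vals) <- "double"
    rownames(vals) <- ids
  } else {
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) stop("failed to parse ", path, ": ",
                                           conditionMessage(e)))
    rows <- readLines(paste0(path, ".rows"))
    cols <- readLines(paste0(path, ".cols"))
    vals <- as.matrix(m)
    if (length(rows) != nrow(vals) || length(cols) != ncol(vals))
      stop("sidecar id files inconsistent with MTX dimensions")
    dimnames(vals) <- list(rows, cols)
  }
  n_missing <- sum(!is.finite(vals))
  if (n_missing > 0) {
    vals[!is.finite(vals)] <- 0
    gd_message(sprintf("load_expression: imputed %d missing entries to 0",
                       n_missing), quiet = quiet)
  }
  out <- protein_matrix(vals, domain = domain)
  attr(out, "imputed_count") <- n_missing
  out
}

#' Write an expression matrix to disk
#'
#' Inverse of [load_expression()]; same formats and sidecar conventions.
#'
#' @param x A [protein_matrix()].
#' @param path Output path.
#' @param format One of `"csv"`, `"tsv"`, `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, format = c("csv", "tsv", "mtx")) {
  format <- match.arg(format)
  validate_protein_matrix(x)
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    dt <- data.frame(sample_id = x$sample_ids, x$values,
                     check.names = FALSE)
    data.table::fwrite(dt, path, sep = sep)
  } else {
    Matrix::writeMM(Matrix::Matrix(x$values, sparse = TRUE), path)
    writeLines(x$sample_ids, paste0(path, ".rows"))
    writeLines(x$feature_ids, paste0(path, ".cols"))
  }
  invisible(path)
}

#' Load a two-column cell-type label file
#'
#' @param path TSV file with columns `cell_id`, `cell_type` (header
#'   optional: detected from the first line).
#' @return A [cell_type_annotation()].
#' @export
load_labels <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = "auto",
                          data.table = FALSE)
  if (ncol(dt) < 2) stop("label file must have two columns")
  cell_type_annotation(dt[[1]], dt[[2]])
}

#' Restrict reference and target to their shared proteins
#'
#' Both matrices are subset to the intersection of their feature ids, in a
#' canonical (lexicographic) column order, so they can be fed jointly to the
#' autoencoder.
#'
#' @param ref,tgt [protein_matrix()] objects.
#' @return A list with elements `ref` and `tgt`.
#' @export
align_shared_features <- function(ref, tgt) {
  validate_protein_matrix(ref)
  validate_protein_matrix(tgt)
  shared <- sort(intersect(ref$feature_ids, tgt$feature_ids))
  if (length(shared) == 0)
    stop(sprintf(
      "no shared features between reference (%d features) and target (%d features)",
      length(ref$feature_ids), length(tgt$feature_ids)))
  if (length(shared) < 2)
    stop("need at least 2 shared features, got ", length(shared))
  list(
    ref = protein_matrix(ref$values[, shared, drop = FALSE], domain = ref$domain),
    tgt = protein_matrix(tgt$values[, shared, drop = FALSE], domain = tgt$domain))
}

#' Keep the k highest-variance features
#'
#' Variance is computed on the reference matrix; both matrices are subset
#' identically, columns ordered by decreasing variance (ties broken by
#' lexicographic feature id).
#'
#' @param ref,tgt Feature-aligned [protein_matrix()] objects.
#' @param k Number of features to keep.
#' @return A list with elements `ref` and `tgt`.
#' @export
select_top_variance_features <- function(ref, tgt, k) {
  validate_protein_matrix(ref)
  validate_protein_matrix(tgt)
  if (!identical(ref$feature_ids, tgt$feature_ids))
    stop("ref and tgt must be feature-aligned (run align_shared_features first)")
  if (k <= 0) stop("k must be a positive integer")
  if (k > length(ref$feature_ids))
    stop("k exceeds the number of shared features")
  v <- apply(ref$values, 2L, stats::var)
  ord <- order(-v, ref$feature_ids)
  keep <- ref$feature_ids[ord[seq_len(k)]]
  list(
    ref = protein_matrix(ref$values[, keep, drop = FALSE], domain = ref$domain),
    tgt = protein_matrix(tgt$values[, keep, drop = FALSE], domain = tgt$domain))
}

#' Write predicted proportions as a delimited table
#'
#' Samples as rows, cell types as columns, header row, index column. The
#' matrix is validated before writing (rows must sum to 1).
#'
#' @param props A [proportion_matrix()].
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_proportions <- function(props, path, sep = ",") {
  validate_proportion_matrix(props)
  dt <- data.frame(sample_id = props$sample_ids, props$values,
                   check.names = FALSE)
  data.table::fwrite(dt, path, sep = sep)
  invisible(path)
}

#' Read a proportion table written by [write_proportions()]
#'
#' @param path File path.
#' @param sep Field separator.
#' @return A [proportion_matrix()].
#' @export
read_proportions <- function(path, sep = ",") {
  dt <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE)
  vals <- as.matrix(dt[, -1, drop = FALSE])
  rownames(vals) <- as.character(dt[[1]])
  proportion_matrix(vals)
}

#' Min-max scale each feature to [0, 1], per dataset
#'
#' Optional preprocessing: every feature is scaled to its own range
#' *within each dataset separately* (reference by reference statistics,
#' target by target statistics). Per-dataset scaling is the conventional
#' first-order batch correction in proteomics deconvolution pipelines: a
#' global per-protein shift or scale between runs is removed before the
#' autoencoder sees the data, so reference and target samples can mix in
#' the latent space. Constant features map to zero.
#'
#' @param ref,tgt Feature-aligned [protein_matrix()] objects.
#' @return A list with elements `ref` and `tgt`.
#' @export
minmax_scale_features <- function(ref, tgt) {
  stopifnot(identical(ref$feature_ids, tgt$feature_ids))
  sc <- function(v) {
    lo <- apply(v, 2L, min)
    rng <- apply(v, 2L, max) - lo
    rng[rng == 0] <- 1
    sweep(sweep(v, 2L, lo, "-"), 2L, rng, "/")
  }
  list(ref = protein_matrix(sc(ref$values), domain = ref$domain),
       tgt = protein_matrix(sc(tgt$values), domain = tgt$domain))
}
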