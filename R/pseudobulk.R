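#' Build one pseudo-bulk sample from chosen cells
#'
#' The pseudo-sample's expression is the arithmetic mean of the chosen
#' cells' protein abundances, and its composition vector is the realized
#' count of each cell type divided by the total number of chosen cells.
#'
#' @param cells A [protein_matrix()] of single cells (cells x proteins).
#' @param ann A [cell_type_annotation()] covering the cells.
#' @param chosen_indices Integer row indices of the cells to mix.
#' @return A list with `expression` (numeric vector over proteins) and
#'   `proportions` (numeric vector over `ann$type_universe`).
#' @export
make_pseudo_sample <- function(cells, ann, chosen_indices) {
  if (length(chosen_indices) == 0) stop("chosen_indices must be non-empty")
  if (any(chosen_indices < 1 | chosen_indices > nrow(cells$values)))
    stop("chosen_indices out of range")
  expr <- colMeans(cells$values[chosen_indices, , drop = FALSE])
  counts <- table(factor(ann$labels[chosen_indices],
                         levels = ann$type_universe))
  props <- as.numeric(counts) / length(chosen_indices)
  names(props) <- ann$type_universe
  list(expression = expr, proportions = props)
}

#' Generate a pseudo-bulk set by mixup
#'
#' For each pseudo-sample a composition is drawn from a flat Dirichlet over
#' the cell types, `cells_per_sample` cells are allocated to types by a
#' multinomial draw on that composition, and cells are picked uniformly
#' within each type (with replacement only when a type pool is smaller than
#' the requested count). The recorded proportions are the realized cell
#' counts, so rows sum to one exactly.
#'
#' @param sc Single-cell [protein_matrix()].
#' @param ann [cell_type_annotation()] for the cells.
#' @param n_samples Number of pseudo-samples to generate.
#' @param cells_per_sample Cells mixed into each pseudo-sample
#'   (protocol presets: 15, 50, or 200).
#' @param seed Integer seed; generation is reproducible given the seed.
#' @param domain Domain tag for the resulting expression matrix.
#' @return An object of class `pseudobulk_set` with fields `expr`
#'   ([protein_matrix()]), `props` ([proportion_matrix()]),
#'   `cells_per_sample`, `seed`, and `cell_indices` (list of the chosen
#'   row indices per pseudo-sample).
#' @export
generate_pseudobulk <- function(sc, ann, n_samples, cells_per_sample = 50,
                                seed = 0,
                                domain = c("reference", "target")) {
  domain <- match.arg(domain)
  validate_protein_matrix(sc)
  if (n_samples <= 0) stop("n_samples must be positive")
  if (cells_per_sample <= 0) stop("cells_per_sample must be positive")
  if (nrow(sc$values) < cells_per_sample)
    stop("fewer cells than cells_per_sample")
  if (length(ann$labels) != nrow(sc$values))
    stop("annotation must cover all cells")
  types <- ann$type_universe
  n_types <- length(types)
  pools <- lapply(types, function(tp) which(ann$labels == tp))
  names(pools) <- types

  with_seed(seed, {
    expr <- matrix(0, n_samples, ncol(sc$values))
    props <- matrix(0, n_samples, n_types)
    idx_list <- vector("list", n_samples)
    for (i in seq_len(n_samples)) {
      gam <- stats::rgamma(n_types, shape = 1)
      pvec <- gam / sum(gam)
      counts <- as.vector(stats::rmultinom(1, cells_per_sample, pvec))
      chosen <- integer(0)
      for (t in seq_len(n_types)) {
        if (counts[t] == 0) next
        pool <- pools[[t]]
        if (length(pool) == 0) { counts[t] <- 0; next }
        replace <- length(pool) < counts[t]
        chosen <- c(chosen,
                    pool[sample.int(length(pool), counts[t],
                                    replace = replace)])
      }
      # counts may have been zeroed for empty pools; renormalize over what
      # was actually drawn
      expr[i, ] <- colMeans(sc$values[chosen, , drop = FALSE])
      props[i, ] <- counts / length(chosen)
      idx_list[[i]] <- chosen
    }
    rownames(expr) <- sprintf("pb%s_%d", substr(domain, 1, 1),
                              seq_len(n_samples))
    colnames(expr) <- sc$feature_ids
    structure(
      list(expr = protein_matrix(expr, domain = domain),
           props = proportion_matrix(props, sample_ids = rownames(expr),
                                     type_universe = types),
           cells_per_sample = cells_per_sample, seed = seed,
           cell_indices = idx_list),
      class = "pseudobulk_set")
  })
}

#' @export
print.pseudobulk_set <- function(x, ...) {
  cat(sprintf("pseudobulk_set: %d samples (%d cells each) x %d proteins, %d cell types\n",
              nrow(x$expr$values), x$cells_per_sample,
              ncol(x$expr$values), length(x$props$type_universe)))
  invisible(x)
}
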