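#' Specification for the synthetic single-cell proteomics generator
#'
#' The generator emulates a labeled single-cell proteomics pool measured in
#' several runs (batches): each cell type has a log-normal protein
#' archetype; batches add a per-protein shift and multiplicative scale in
#' log space (run/technology batch effects); cells add log-normal noise;
#' optional dropout zeroes entries.
#'
#' @param n_types Number of cell types.
#' @param n_proteins Number of proteins.
#' @param cells_per_type_per_batch Pool size per type per batch.
#' @param archetype_scale SD of the per-type log-abundance archetypes
#'   (between-type separation, log units).
#' @param noise_sd Per-cell log-normal noise SD (log units).
#' @param batch_shift_sd SD of the per-batch per-protein additive log
#'   shift; 0 disables the batch effect.
#' @param batch_scale_range Length-2 interval for the per-batch
#'   multiplicative per-protein scale, around 1.
#' @param dropout_rate Probability an entry is zeroed (in \[0, 1)).
#' @param seed Integer seed for the archetypes and all draws.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_types = 4, n_proteins = 200,
                           cells_per_type_per_batch = 500,
                           archetype_scale = 1.0, noise_sd = 0.5,
                           batch_shift_sd = 0.8,
                           batch_scale_range = c(0.8, 1.25),
                           dropout_rate = 0, seed = 0) {
  stopifnot(n_types >= 1, n_proteins >= 1, cells_per_type_per_batch >= 1,
            archetype_scale > 0, noise_sd >= 0, batch_shift_sd >= 0,
            length(batch_scale_range) == 2,
            batch_scale_range[1] > 0,
            batch_scale_range[2] >= batch_scale_range[1],
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(n_types = n_types, n_proteins = n_proteins,
                 cells_per_type_per_batch = cells_per_type_per_batch,
                 archetype_scale = archetype_scale, noise_sd = noise_sd,
                 batch_shift_sd = batch_shift_sd,
                 batch_scale_range = batch_scale_range,
                 dropout_rate = dropout_rate, seed = seed),
            class = "synthetic_spec")
}

# Archetypes depend only on the spec seed so every batch shares them.
synthetic_archetypes <- function(spec) {
  with_seed(spec$seed, {
    matrix(stats::rnorm(spec$n_types * spec$n_proteins,
                        sd = spec$archetype_scale),
           spec$n_types, spec$n_proteins,
           dimnames = list(paste0("type", seq_len(spec$n_types)),
                           sprintf("prot%03d", seq_len(spec$n_proteins))))
  })
}

#' Simulate one batch of labeled single cells
#'
#' Cell expression is `exp(archetype + batch_shift + log(batch_scale) +
#' noise)`, per protein, followed by optional dropout. Deterministic per
#' `(spec$seed, batch_id)`.
#'
#' @param spec A [synthetic_spec()].
#' @param batch_id Integer batch identifier (0, 1, ...).
#' @return A list with `cells` ([protein_matrix()], domain tagged
#'   reference for batch 0 and target otherwise) and `annotation`
#'   ([cell_type_annotation()]).
#' @export
simulate_cells <- function(spec, batch_id = 0) {
  stopifnot(inherits(spec, "synthetic_spec"))
  arch <- synthetic_archetypes(spec)
  n_cells <- spec$n_types * spec$cells_per_type_per_batch
  p <- spec$n_proteins
  with_seed(spec$seed * 100003L + batch_id + 1L, {
    shift <- stats::rnorm(p, sd = spec$batch_shift_sd)
    scl <- stats::runif(p, spec$batch_scale_range[1],
                        spec$batch_scale_range[2])
    labels <- rep(rownames(arch), each = spec$cells_per_type_per_batch)
    logx <- arch[labels, , drop = FALSE]
    logx <- sweep(logx, 2L, shift + log(scl), "+")
    logx <- logx + matrix(stats::rnorm(n_cells * p, sd = spec$noise_sd),
                          n_cells, p)
    x <- exp(logx)
    if (spec$dropout_rate > 0) {
      drop <- matrix(stats::runif(n_cells * p) < spec$dropout_rate,
                     n_cells, p)
      x[drop] <- 0
    }
    rownames(x) <- sprintf("b%d_cell%05d", batch_id, seq_len(n_cells))
    cells <- protein_matrix(
      x, domain = if (batch_id == 0) "reference" else "target")
    list(cells = cells,
         annotation = cell_type_annotation(rownames(x), labels,
                                           rownames(arch)))
  })
}

#' Build a paired reference/target pseudo-bulk benchmark
#'
#' Reference pseudo-samples are mixed from batch-0 cells and target
#' pseudo-samples from batch-1 cells, so the two domains differ by the
#' spec's batch effect. The target truth is retained for evaluation only.
#'
#' @param spec A [synthetic_spec()].
#' @param n_ref_samples,n_tgt_samples Pseudo-sample counts.
#' @param cells_per_sample Cells mixed per pseudo-sample.
#' @return A list with `ref` and `tgt`, both `pseudobulk_set`s.
#' @export
make_benchmark_pair <- function(spec, n_ref_samples = 2000,
                                n_tgt_samples = 500,
                                cells_per_sample = 50) {
  b0 <- simulate_cells(spec, batch_id = 0)
  b1 <- simulate_cells(spec, batch_id = 1)
  ref <- generate_pseudobulk(b0$cells, b0$annotation, n_ref_samples,
                             cells_per_sample, seed = spec$seed * 7L + 1L,
                             domain = "reference")
  tgt <- generate_pseudobulk(b1$cells, b1$annotation, n_tgt_samples,
                             cells_per_sample, seed = spec$seed * 7L + 2L,
                             domain = "target")
  list(ref = ref, tgt = tgt)
}
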