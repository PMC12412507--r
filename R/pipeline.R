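#' Run the full deconvolution pipeline
#'
#' End-to-end protocol on in-memory data: optional feature selection and
#' scaling, autoencoder projection of reference and target into a shared
#' latent space, construction of the reference / target / joint kNN
#' similarity graphs, homophily re-weighting of the reference graph with
#' the known compositions, adversarial training of the multi-channel
#' GraphSAGE model, and the two-pass (re-weighted) target prediction.
#'
#' @param ref A `pseudobulk_set` (labeled reference), e.g. from
#'   [generate_pseudobulk()] or [make_benchmark_pair()].
#' @param tgt Target [protein_matrix()].
#' @param config A [deconv_config()].
#' @param quiet Suppress progress messages.
#' @return A list of class `deconv_result`: `proportions`
#'   ([proportion_matrix()] for the target), `model`, `ae`, `graphs`,
#'   `latents`, `history`, `config`.
#' @export
deconvolve <- function(ref, tgt, config = deconv_config(), quiet = TRUE) {
  stopifnot(inherits(ref, "pseudobulk_set"))
  ref_expr <- ref$expr
  if (!identical(ref_expr$feature_ids, tgt$feature_ids)) {
    al <- align_shared_features(ref_expr, tgt)
    ref_expr <- al$ref; tgt <- al$tgt
  }
  if (!is.null(config$top_k_features)) {
    sel <- select_top_variance_features(ref_expr, tgt,
                                        config$top_k_features)
    ref_expr <- sel$ref; tgt <- sel$tgt
  }
  if (config$scale_features) {
    sc <- minmax_scale_features(ref_expr, tgt)
    ref_expr <- sc$ref; tgt <- sc$tgt
  }
  ref <- ref; ref$expr <- ref_expr

  gd_message("training autoencoder ...", quiet = quiet)
  ae <- train_autoencoder(ref_expr, tgt, latent_dim = config$latent_dim,
                          epochs = config$ae_epochs, lr = config$lr,
                          seed = config$seed)
  latents <- list(ref = ae_encode(ref_expr, ae), tgt = ae_encode(tgt, ae))

  gd_message("building similarity graphs ...", quiet = quiet)
  g_r <- build_knn_graph(latents$ref, k = config$k, kind = "reference",
                         node_ids = ref_expr$sample_ids)
  g_t <- build_knn_graph(latents$tgt, k = config$k, kind = "target",
                         node_ids = tgt$sample_ids)
  g_j <- build_joint_graph(latents$ref, latents$tgt, k = config$k,
                           ref_ids = ref_expr$sample_ids,
                           tgt_ids = tgt$sample_ids)
  if (!config$no_reweight)
    g_r <- reweight_edges(g_r, ref$props)

  gd_message("fitting deconvolution model ...", quiet = quiet)
  model <- fit_deconv(ref, tgt, list(ref = g_r, tgt = g_t, joint = g_j),
                      latents, config, quiet = quiet)
  props <- predict_proportions(model, tgt, g_t, config)
  structure(list(proportions = props, model = model, ae = ae,
                 graphs = list(ref = g_r, tgt = g_t, joint = g_j),
                 latents = latents, history = attr(model, "history"),
                 config = config),
            class = "deconv_result")
}

#' @export
print.deconv_result <- function(x, ...) {
  cat(sprintf(
    "deconv_result: %d target samples x %d cell types (stopped at iteration %d, best %d)\n",
    nrow(x$proportions$values), length(x$proportions$type_universe),
    attr(x$model, "stopped_at"), attr(x$model, "best_iteration")))
  invisible(x)
}

#' File-based pipeline run
#'
#' Orchestrates a full run from files: loads the reference expression and
#' composition tables and the target expression table, runs
#' [deconvolve()], writes the predicted proportions, a loss log, and a
#' JSON manifest (config + seed) under `out_dir`; when a target truth
#' table is supplied the metric report is computed and written too.
#'
#' @param ref_expr_path,ref_props_path,tgt_expr_path Input file paths
#'   (delimited; `format` applies to the expression matrices).
#' @param out_dir Output directory (created if absent).
#' @param config A [deconv_config()].
#' @param format Expression file format (`"csv"`, `"tsv"`, `"mtx"`).
#' @param truth_path Optional target truth proportion table.
#' @param quiet Suppress progress messages.
#' @return The `deconv_result`, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(ref_expr_path, ref_props_path, tgt_expr_path,
                         out_dir, config = deconv_config(),
                         format = "csv", truth_path = NULL,
                         quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref_expr <- load_expression(ref_expr_path, format, "reference",
                              quiet = quiet)
  ref_props <- read_proportions(ref_props_path)
  tgt <- load_expression(tgt_expr_path, format, "target", quiet = quiet)
  if (!identical(ref_expr$sample_ids, ref_props$sample_ids))
    stop("reference expression and proportion tables disagree on samples")
  ref <- structure(list(expr = ref_expr, props = ref_props,
                        cells_per_sample = NA_integer_,
                        seed = config$seed, cell_indices = NULL),
                   class = "pseudobulk_set")
  res <- deconvolve(ref, tgt, config, quiet = quiet)
  write_proportions(res$proportions, file.path(out_dir, "proportions.csv"))
  utils::write.csv(res$history, file.path(out_dir, "loss_log.csv"),
                   row.names = FALSE)
  manifest <- list(seed = config$seed,
                   config = unclass(config)[!vapply(config, is.null,
                                                    TRUE)],
                   n_ref = nrow(ref_expr$values),
                   n_tgt = nrow(tgt$values),
                   n_features = ncol(tgt$values),
                   stopped_at = attr(res$model, "stopped_at"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(truth_path)) {
    truth <- read_proportions(truth_path)
    rep <- evaluate_deconv(res$proportions, truth)
    utils::write.csv(rep$per_sample,
                     file.path(out_dir, "metrics_per_sample.csv"),
                     row.names = FALSE)
    if (!is.null(rep$per_celltype))
      utils::write.csv(rep$per_celltype,
                       file.path(out_dir, "metrics_per_celltype.csv"),
                       row.names = FALSE)
    jsonlite::write_json(rep$aggregate,
                         file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(res)
}
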