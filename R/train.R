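#' Training configuration
#'
#' Defaults follow the published protocol: Adam at learning rate 0.001,
#' up to 3000 iterations with early stopping after 100 non-improving
#' iterations but never before iteration 1500, 10\% of the reference
#' reserved for validation, triplet margin 0.3, loss weights alpha = 0.01
#' and beta = 1. One iteration is one full-batch epoch consisting of two
#' steps (separate reference/target graphs, then the joint graph).
#'
#' @param lr Learning rate.
#' @param iterations Maximum iterations.
#' @param min_iterations Early stopping cannot fire before this iteration.
#' @param patience Non-improving validation iterations tolerated.
#' @param val_fraction Fraction of reference samples held out for
#'   validation (stratified by dominant cell type).
#' @param m Triplet margin.
#' @param alpha Triplet loss weight.
#' @param beta Domain-adversarial loss weight.
#' @param seed Integer seed (initialization + validation split).
#' @param latent_dim Autoencoder latent width.
#' @param ae_epochs Autoencoder training epochs.
#' @param k Neighbours per node in the similarity graphs.
#' @param hidden_dim GraphSAGE hidden width per channel.
#' @param n_channels Number of GraphSAGE channels.
#' @param head_dim,disc_dim Head / discriminator hidden widths.
#' @param fixed_fusion Freeze the layer-fusion weights at (0.7, 0.3).
#' @param unweighted_agg Plain mean aggregation (ignore edge weights).
#' @param no_gnn Ablation: replace each channel by an MLP of matched
#'   width on the raw features (neighbourhood aggregation zeroed).
#' @param no_triplet Ablation: drop the triplet loss (alpha = 0).
#' @param no_reweight Ablation: skip all edge re-weighting.
#' @param scale_features Min-max scale features before the pipeline.
#' @param top_k_features Optional variance-based feature selection count.
#' @param disc_label_smooth Label smoothing for the discriminator's
#'   cross-entropy targets (reference = 1 - s, target = s); keeps the
#'   adversarial game away from the saturated zero-gradient regime.
#' @param disc_lr_factor Learning-rate multiplier for the discriminator
#'   parameters (two-time-scale updates; < 1 slows the discriminator so
#'   it cannot outrun the encoder and collapse training).
#' @param adversarial_mode How the encoder plays against the
#'   discriminator: `"grl"` (gradient reversal) or `"alternating"` (the
#'   non-saturating form: the encoder minimizes the cross-entropy of the
#'   flipped domain labels against the frozen discriminator).
#' @param grl_ramp Ramp the reversed-gradient strength linearly from 0 to
#'   `beta` over the run (default) instead of applying full strength from
#'   the first iteration.
#' @return A `deconv_config` list.
#' @export
deconv_config <- function(lr = 0.001, iterations = 3000,
                          min_iterations = 1500, patience = 100,
                          val_fraction = 0.10, m = 0.3, alpha = 0.01,
                          beta = 1, seed = 0, latent_dim = 16,
                          ae_epochs = 200, k = 10, hidden_dim = 256,
                          n_channels = 3, head_dim = 128, disc_dim = 64,
                          fixed_fusion = FALSE, unweighted_agg = FALSE,
                          no_gnn = FALSE, no_triplet = FALSE,
                          no_reweight = FALSE, scale_features = FALSE,
                          top_k_features = NULL, disc_label_smooth = 0,
                          disc_lr_factor = 1,
                          adversarial_mode = c("grl", "alternating"),
                          grl_ramp = TRUE) {
  adversarial_mode <- match.arg(adversarial_mode)
  cfg <- as.list(environment())
  stopifnot(cfg$lr > 0, cfg$iterations > 0, cfg$min_iterations > 0,
            cfg$patience > 0, cfg$val_fraction > 0, cfg$val_fraction < 1,
            cfg$m >= 0, cfg$alpha >= 0, cfg$beta >= 0)
  if (cfg$no_triplet) cfg$alpha <- 0
  structure(cfg, class = "deconv_config")
}

#' Desk-scale benchmark configuration
#'
#' The configuration used by the package's synthetic benchmark: the
#' iteration budget is reduced to 500 (early stopping from 250, patience
#' 50), the encoder is slimmed to 2 channels of width 128 (sizes chosen so
#' a full run completes in minutes on one CPU), and per-dataset min-max
#' scaling is enabled, which tames the heavy-tailed raw intensities and
#' removes first-order run shifts before the autoencoder and GNN; all
#' other settings equal [deconv_config()] defaults.
#'
#' @param ... Overrides passed to [deconv_config()].
#' @return A `deconv_config` list.
#' @export
benchmark_config <- function(...) {
  args <- list(...)
  base <- list(iterations = 500, min_iterations = 250, patience = 50,
               hidden_dim = 128, n_channels = 2, scale_features = TRUE)
  do.call(deconv_config, utils::modifyList(base, args))
}

#' Ablate a pipeline component
#'
#' @param config A [deconv_config()].
#' @param component `"gnn"` (replace the GNN by an MLP of matched width),
#'   `"triplet"` (alpha = 0), or `"reweight"` (skip edge re-weighting).
#' @return The modified configuration.
#' @export
ablate <- function(config, component = c("gnn", "triplet", "reweight")) {
  component <- match.arg(component)
  switch(component,
         gnn = { config$no_gnn <- TRUE },
         triplet = { config$no_triplet <- TRUE; config$alpha <- 0 },
         reweight = { config$no_reweight <- TRUE })
  config
}

# Stratified validation split on the dominant cell type of each row.
stratified_val_split <- function(Y, val_fraction, seed) {
  dominant <- max.col(Y, ties.method = "first")
  with_seed(seed, {
    val <- integer(0)
    for (cl in unique(dominant)) {
      rows <- which(dominant == cl)
      n_val <- round(length(rows) * val_fraction)
      if (n_val > 0)
        val <- c(val, rows[sample.int(length(rows), n_val)])
    }
    sort(val)
  })
}

# Sample-wise mean CCC (validation metric for early stopping).
mean_sample_ccc <- function(Y, P, rows = seq_len(nrow(Y))) {
  v <- vapply(rows, function(i)
    tryCatch(ccc(Y[i, ], P[i, ]), error = function(e) NA_real_), 0)
  mean(v, na.rm = TRUE)
}

# Assemble everything the two-step epoch needs.
trainer_init <- function(ref, tgt, graphs, latents, config) {
  X_r <- ref$expr$values
  Y_r <- ref$props$values
  X_t <- if (inherits(tgt, "protein_matrix")) tgt$values else as.matrix(tgt)
  n_r <- nrow(X_r); n_t <- nrow(X_t)
  model <- init_gnn(ncol(X_r), ncol(Y_r), hidden_dim = config$hidden_dim,
                    n_channels = config$n_channels,
                    head_dim = config$head_dim, disc_dim = config$disc_dim,
                    seed = config$seed)
  model$type_universe <- ref$props$type_universe
  ops <- list(A_r = NULL, A_t = NULL, A_j = NULL)
  if (!config$no_gnn) {
    ops$A_r <- graph_operator(graphs$ref, unweighted = config$unweighted_agg)
    ops$A_t <- graph_operator(graphs$tgt, unweighted = config$unweighted_agg)
    ops$A_j <- graph_operator(graphs$joint, unweighted = config$unweighted_agg)
  }
  tops <- lapply(ops, function(A) if (is.null(A)) NULL else Matrix::t(A))
  # layer-1 inputs are constant for fixed graphs; precompute once
  U1s <- list(
    r = if (is.null(ops$A_r)) NULL else cbind(X_r, as.matrix(ops$A_r %*% X_r)),
    t = if (is.null(ops$A_t)) NULL else cbind(X_t, as.matrix(ops$A_t %*% X_t)),
    j = if (is.null(ops$A_j)) NULL else {
      X_j <- rbind(X_r, X_t)
      cbind(X_j, as.matrix(ops$A_j %*% X_j))
    })
  tri <- NULL
  if (config$alpha > 0) {
    tri <- list(r = mine_triplets(cosine_similarity_matrix(latents$ref)),
                t = mine_triplets(cosine_similarity_matrix(latents$tgt)),
                j = mine_triplets(cosine_similarity_matrix(
                  rbind(latents$ref, latents$tgt))))
    attr(tri$r, "inc") <- triplet_incidence(tri$r, n_r)
    attr(tri$t, "inc") <- triplet_incidence(tri$t, n_t)
    attr(tri$j, "inc") <- triplet_incidence(tri$j, n_r + n_t)
  }
  val_rows <- stratified_val_split(Y_r, config$val_fraction,
                                   config$seed + 1L)
  train_rows <- setdiff(seq_len(n_r), val_rows)
  list(model = model, X_r = X_r, Y_r = Y_r, X_t = X_t,
       X_j = rbind(X_r, X_t), n_r = n_r, n_t = n_t,
       is_ref = c(rep(TRUE, n_r), rep(FALSE, n_t)),
       ops = ops, tops = tops, U1s = U1s, tri = tri,
       train_rows = train_rows, val_rows = val_rows,
       opt = adam_init(model$par), config = config)
}

acc_grads <- function(...) {
  gs <- list(...)
  out <- gs[[1]]
  for (g in gs[-1]) for (nm in names(g))
    out[[nm]] <- if (is.null(out[[nm]])) g[[nm]] else out[[nm]] + g[[nm]]
  out
}

# One full-batch epoch: step 1 on the separate reference and target
# graphs (MSE + triplet + adversarial domain loss), step 2 on the joint
# graph (MSE + triplet only). Returns the updated state and the losses.
train_one_iteration <- function(st) {
  cfg <- st$config
  skip <- if (cfg$fixed_fusion)
    grep("_fus$", names(st$model$par), value = TRUE) else character(0)
  denom <- st$n_r + st$n_t
  # gradient-reversal warm-up: the adversarial weight ramps linearly from
  # 0 to beta over the full run, so the encoder converges on the
  # composition task before the domain alignment pressure becomes strong
  st$iter <- (st$iter %||% 0L) + 1L
  prog <- st$iter / cfg$iterations
  lam <- if (isTRUE(cfg$grl_ramp)) cfg$beta * prog else cfg$beta

  # parameters being validated this iteration (the step-1 forward below
  # uses them); checkpointing must snapshot these, not the post-update set
  st$validated_par <- st$model$par

  # --- step 1: per-domain graphs ---
  fwr <- gnn_forward_core(st$X_r, st$ops$A_r, st$model, U1 = st$U1s$r)
  fwt <- gnn_forward_core(st$X_t, st$ops$A_t, st$model, U1 = st$U1s$t)
  head1 <- head_mse_grad(fwr$Z, st$model, st$Y_r, st$train_rows)
  dZr <- head1$dZ
  dZt <- matrix(0, st$n_t, ncol(fwt$Z))
  L_tri <- 0
  if (cfg$alpha > 0) {
    tg_r <- triplet_grad(fwr$Z, st$tri$r, cfg$m, denom)
    tg_t <- triplet_grad(fwt$Z, st$tri$t, cfg$m, denom)
    L_tri <- tg_r$loss + tg_t$loss
    dZr <- dZr + cfg$alpha * tg_r$dZ
    dZt <- dZt + cfg$alpha * tg_t$dZ
  }
  dd <- disc_grl_grad(rbind(fwr$Z, fwt$Z), st$model, st$is_ref,
                      beta = cfg$beta, lambda = lam,
                      label_smooth = cfg$disc_label_smooth %||% 0,
                      mode = cfg$adversarial_mode %||% "grl")
  dZr <- dZr + dd$dZ_encoder[seq_len(st$n_r), , drop = FALSE]
  dZt <- dZt + dd$dZ_encoder[st$n_r + seq_len(st$n_t), , drop = FALSE]
  g1 <- acc_grads(head1$grads, dd$grads,
                  gnn_backward_core(fwr, st$tops$A_r, st$model, dZr),
                  gnn_backward_core(fwt, st$tops$A_t, st$model, dZt))
  L1 <- total_loss(head1$loss, L_tri, dd$L_dom, cfg$alpha, cfg$beta)
  if (!is.finite(L1)) stop("non-finite loss in step 1")
  dfac <- cfg$disc_lr_factor %||% 1
  lr_scale <- if (dfac != 1)
    function(nm) if (grepl("^Wq|^bq", nm)) dfac else 1 else NULL
  upd <- adam_step(st$model$par, g1, st$opt, cfg$lr, skip = skip,
                   lr_scale = lr_scale)
  st$model$par <- upd$par; st$opt <- upd$opt

  # validation predictions from the step-1 reference forward
  val_ccc <- if (length(st$val_rows))
    mean_sample_ccc(st$Y_r, head1$P, st$val_rows) else NA_real_

  # --- step 2: joint graph ---
  fwj <- gnn_forward_core(st$X_j, st$ops$A_j, st$model, U1 = st$U1s$j)
  head2 <- head_mse_grad(fwj$Z, st$model, st$Y_r, st$train_rows,
                         loss_only = TRUE)
  dZj <- head2$dZ
  L_tri2 <- 0
  if (cfg$alpha > 0) {
    tg_j <- triplet_grad(fwj$Z, st$tri$j, cfg$m, denom)
    L_tri2 <- tg_j$loss
    dZj <- dZj + cfg$alpha * tg_j$dZ
  }
  g2 <- acc_grads(head2$grads,
                  gnn_backward_core(fwj, st$tops$A_j, st$model, dZj))
  if (!is.finite(head2$loss)) stop("non-finite loss in step 2")
  upd <- adam_step(st$model$par, g2, st$opt, cfg$lr, skip = skip)
  st$model$par <- upd$par; st$opt <- upd$opt

  st$last <- list(L_dec = head1$loss, L_tri = L_tri, L_dom = dd$L_dom,
                  L_total = L1, L_dec_joint = head2$loss,
                  L_tri_joint = L_tri2, val_ccc = val_ccc)
  st
}

#' Fit the deconvolution model
#'
#' Stage-2 training: each iteration is a full-batch epoch with two steps
#' (reference and target graphs with MSE + triplet + domain-adversarial
#' losses, then the joint graph with MSE + triplet only). A stratified 10\%
#' validation split of the reference drives early stopping on the
#' sample-wise mean CCC: training stops when the metric has not improved
#' for `patience` consecutive iterations and at least `min_iterations`
#' have run; the best-validation checkpoint is returned.
#'
#' @param ref A `pseudobulk_set` (reference expression + known
#'   proportions).
#' @param tgt Target [protein_matrix()], feature-aligned with `ref`.
#' @param graphs List with `similarity_graph`s `ref`, `tgt`, `joint` (the
#'   reference graph already re-weighted unless ablated).
#' @param latents List with AE latent matrices `ref` and `tgt` (used once
#'   to mine the triplets).
#' @param config A [deconv_config()].
#' @param quiet Suppress progress messages.
#' @return A trained `gnn_model` with attributes `history` (per-iteration
#'   loss record), `best_iteration` and `stopped_at`.
#' @export
fit_deconv <- function(ref, tgt, graphs, latents,
                       config = deconv_config(), quiet = TRUE) {
  st <- trainer_init(ref, tgt, graphs, latents, config)
  best_val <- -Inf
  best_par <- st$model$par
  best_iter <- 0L
  stall <- 0L
  hist <- vector("list", config$iterations)
  it <- 0L
  while (it < config$iterations) {
    it <- it + 1L
    st <- train_one_iteration(st)
    hist[[it]] <- data.frame(iteration = it, st$last)
    if (!is.na(st$last$val_ccc) && st$last$val_ccc > best_val) {
      best_val <- st$last$val_ccc
      best_par <- st$validated_par
      best_iter <- it
      stall <- 0L
    } else stall <- stall + 1L
    if (it %% 50 == 0)
      gd_message(sprintf(
        "iter %d: L_dec %.4f L_tri %.4f L_dom %.4f val_CCC %.4f",
        it, st$last$L_dec, st$last$L_tri, st$last$L_dom,
        st$last$val_ccc), quiet = quiet)
    if (stall >= config$patience && it >= config$min_iterations) break
  }
  model <- st$model
  model$par <- best_par
  attr(model, "history") <- do.call(rbind, hist[seq_len(it)])
  attr(model, "best_iteration") <- best_iter
  attr(model, "stopped_at") <- it
  attr(model, "best_val_ccc") <- best_val
  model
}

#' Predict target cell-type proportions
#'
#' Stage-3/4 protocol: an initial forward pass on the target graph yields
#' provisional proportions, the target graph's edges are re-weighted with
#' those predictions, and a second forward pass on the adjusted graph
#' produces the final estimate. With `config$no_reweight` (or
#' `config$no_gnn`) the single-pass prediction is returned.
#'
#' @param model A fitted `gnn_model` from [fit_deconv()].
#' @param tgt Target [protein_matrix()].
#' @param g_t Target `similarity_graph`.
#' @param config The [deconv_config()] used at fit time.
#' @return A [proportion_matrix()] for the target samples. The initial
#'   single-pass estimate is attached as attribute `initial`.
#' @export
predict_proportions <- function(model, tgt, g_t, config = deconv_config()) {
  X_t <- if (inherits(tgt, "protein_matrix")) tgt$values else as.matrix(tgt)
  ids <- if (inherits(tgt, "protein_matrix")) tgt$sample_ids
         else rownames(X_t) %||% paste0("S", seq_len(nrow(X_t)))
  A_t <- if (config$no_gnn) NULL
         else graph_operator(g_t, unweighted = config$unweighted_agg)
  Z1 <- gnn_forward_core(X_t, A_t, model)$Z
  P1 <- deconv_head(Z1, model)
  init <- proportion_matrix(P1, sample_ids = ids,
                            type_universe = model$type_universe)
  if (config$no_reweight || config$no_gnn) {
    attr(init, "initial") <- init
    return(init)
  }
  g2 <- reweight_target_graph(g_t, init)
  A2 <- graph_operator(g2, unweighted = config$unweighted_agg)
  Z2 <- gnn_forward_core(X_t, A2, model)$Z
  P2 <- deconv_head(Z2, model)
  out <- proportion_matrix(P2, sample_ids = ids,
                           type_universe = model$type_universe)
  attr(out, "initial") <- init
  out
}
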