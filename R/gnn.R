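#' Initialize the multi-channel GraphSAGE model state
#'
#' `C` independently initialized two-layer GraphSAGE channels over the same
#' graph, each with layer-fusion weights (softmax-normalized global
#' scalars, initialized at (0.7, 0.3)), a softmax deconvolution head and a
#' sigmoid domain discriminator, both two-layer perceptrons over the
#' concatenated channel embeddings.
#'
#' @param n_features Input feature width (proteins).
#' @param n_types Number of cell types (deconvolution output width).
#' @param hidden_dim GraphSAGE hidden width per channel (default 256).
#' @param n_channels Number of channels C (default 3).
#' @param n_layers GraphSAGE depth L (fixed at 2).
#' @param head_dim Deconvolution-head hidden width (default 128).
#' @param disc_dim Discriminator hidden width (default 64).
#' @param fusion_init Initial fusion weights over the L layers.
#' @param seed Integer seed for the initialization.
#' @return An object of class `gnn_model`: flat named parameter list
#'   `par` plus a `dims` descriptor.
#' @export
init_gnn <- function(n_features, n_types, hidden_dim = 256, n_channels = 3,
                     n_layers = 2, head_dim = 128, disc_dim = 64,
                     fusion_init = c(0.7, 0.3), seed = 0) {
  if (n_layers != 2) stop("only L = 2 GraphSAGE layers are supported")
  stopifnot(all(fusion_init > 0), length(fusion_init) == n_layers)
  h <- hidden_dim
  with_seed(seed, {
    par <- list()
    for (c in seq_len(n_channels)) {
      par[[paste0("ch", c, "_W1")]] <- glorot(2 * n_features, h)
      par[[paste0("ch", c, "_W2")]] <- glorot(2 * h, h)
      # softmax(log w) = w: initializes fusion exactly at fusion_init
      par[[paste0("ch", c, "_fus")]] <- log(fusion_init / sum(fusion_init))
    }
    zc <- n_channels * h
    par$Wd1 <- glorot(zc, head_dim);  par$bd1 <- rep(0, head_dim)
    # output layers start near zero so the softmax head opens at the
    # uniform distribution and the discriminator at 0.5 (no early
    # saturation of either)
    par$Wd2 <- 0.01 * glorot(head_dim, n_types); par$bd2 <- rep(0, n_types)
    par$Wq1 <- glorot(zc, disc_dim);  par$bq1 <- rep(0, disc_dim)
    par$Wq2 <- 0.01 * glorot(disc_dim, 1);   par$bq2 <- 0
    structure(list(par = par,
                   dims = list(p = n_features, n_types = n_types,
                               hidden_dim = h, n_channels = n_channels,
                               n_layers = n_layers, head_dim = head_dim,
                               disc_dim = disc_dim)),
              class = "gnn_model")
  })
}

#' @export
print.gnn_model <- function(x, ...) {
  d <- x$dims
  cat(sprintf(
    "gnn_model: %d channels x %d-dim GraphSAGE (L = %d) on %d features -> %d cell types\n",
    d$n_channels, d$hidden_dim, d$n_layers, d$p, d$n_types))
  invisible(x)
}

#' Mean-aggregate a node's neighbourhood
#'
#' Weighted (or plain) mean of the neighbours' previous-layer embeddings.
#' Exposed mainly for inspection; the training path uses the equivalent
#' sparse-matrix form.
#'
#' @param node Node index.
#' @param graph A `similarity_graph`.
#' @param H_prev Previous-layer embedding matrix (nodes x dim).
#' @param unweighted Use the plain (uniform) mean.
#' @return Aggregated embedding vector.
#' @export
sage_aggregate <- function(node, graph, H_prev, unweighted = FALSE) {
  e <- graph$edges
  sel <- e$i == node | e$j == node
  if (!any(sel)) stop("node ", node, " is isolated")
  nb <- ifelse(e$i[sel] == node, e$j[sel], e$i[sel])
  w <- if (unweighted) rep(1, length(nb)) else e$weight[sel]
  as.numeric(crossprod(H_prev[nb, , drop = FALSE], w) / sum(w))
}

#' GraphSAGE node update
#'
#' `sigma(W_k %*% concat(h_self, h_agg))` with ReLU activation.
#'
#' @param h_self Node's previous representation.
#' @param h_agg Aggregated neighbourhood embedding.
#' @param W_k Weight matrix (`length(h_self)+length(h_agg)` rows).
#' @return Updated embedding vector.
#' @export
sage_update <- function(h_self, h_agg, W_k) {
  as.numeric(relu(c(h_self, h_agg) %*% W_k))
}

#' Layer-wise weighted fusion of GraphSAGE outputs
#'
#' Convex combination `M = sum_l s_l * h_l` of the per-layer embeddings;
#' the weights must lie on the simplex (learned fusion logits are
#' softmax-projected before use).
#'
#' @param per_layer List of per-layer embedding matrices (equal shapes).
#' @param fusion Numeric weights, one per layer, summing to 1.
#' @return Fused embedding matrix.
#' @export
fuse_layers <- function(per_layer, fusion) {
  if (length(per_layer) != length(fusion)) stop("one weight per layer")
  if (any(fusion < 0) || abs(sum(fusion) - 1) > 1e-8)
    stop("fusion weights must be non-negative and sum to 1")
  out <- fusion[1] * per_layer[[1]]
  for (l in seq_along(per_layer)[-1]) out <- out + fusion[l] * per_layer[[l]]
  out
}

# Full multi-channel forward. A is the row-normalized sparse operator from
# graph_operator() (or NULL for the no-GNN ablation: aggregation = 0, which
# reduces each channel to an MLP of matched width on the raw features —
# realized by multiplying only the self half of each weight matrix, which
# is algebraically identical and skips the zero blocks).
# U1 = cbind(X, A %*% X) is constant across training iterations for a
# fixed graph and may be supplied precomputed.
# Returns Z (n x C*h) and the per-channel caches needed for backprop.
gnn_forward_core <- function(X, A, model, U1 = NULL) {
  d <- model$dims
  n <- nrow(X)
  h <- d$hidden_dim
  no_graph <- is.null(A)
  if (!no_graph && is.null(U1)) U1 <- cbind(X, as.matrix(A %*% X))
  caches <- vector("list", d$n_channels)
  Z <- matrix(0, n, d$n_channels * h)
  for (c in seq_len(d$n_channels)) {
    W1 <- model$par[[paste0("ch", c, "_W1")]]
    W2 <- model$par[[paste0("ch", c, "_W2")]]
    s <- softmax_vec(model$par[[paste0("ch", c, "_fus")]])
    if (no_graph) {
      P1 <- X %*% W1[seq_len(ncol(X)), , drop = FALSE]
      H1 <- relu(P1)
      U2 <- NULL
      P2 <- H1 %*% W2[seq_len(h), , drop = FALSE]
    } else {
      P1 <- U1 %*% W1
      H1 <- relu(P1)
      U2 <- cbind(H1, as.matrix(A %*% H1))
      P2 <- U2 %*% W2
    }
    H2 <- relu(P2)
    M <- s[1] * H1 + s[2] * H2
    Z[, ((c - 1) * h + 1):(c * h)] <- M
    caches[[c]] <- list(P1 = P1, H1 = H1, U2 = U2, P2 = P2, H2 = H2, s = s)
  }
  list(Z = Z, U1 = U1, X = if (no_graph) X else NULL, caches = caches)
}

# Backprop dZ through all channels; returns the per-channel weight and
# fusion-logit gradients. At is t(A) (NULL for the no-GNN ablation, whose
# aggregation blocks receive exactly zero gradient).
gnn_backward_core <- function(fw, At, model, dZ) {
  d <- model$dims
  h <- d$hidden_dim
  no_graph <- is.null(At) && !is.null(fw$X)
  g <- list()
  for (c in seq_len(d$n_channels)) {
    ca <- fw$caches[[c]]
    W1 <- model$par[[paste0("ch", c, "_W1")]]
    W2 <- model$par[[paste0("ch", c, "_W2")]]
    dM <- dZ[, ((c - 1) * h + 1):(c * h), drop = FALSE]
    g1 <- sum(dM * ca$H1)
    g2 <- sum(dM * ca$H2)
    gs <- c(g1, g2)
    g[[paste0("ch", c, "_fus")]] <- ca$s * (gs - sum(ca$s * gs))
    dH2 <- ca$s[2] * dM
    dH1 <- ca$s[1] * dM
    dP2 <- dH2 * (ca$P2 > 0)
    if (no_graph) {
      p_in <- nrow(W1) / 2L
      dW2 <- rbind(crossprod(ca$H1, dP2), matrix(0, h, h))
      dH1 <- dH1 + tcrossprod(dP2, W2[seq_len(h), , drop = FALSE])
      dP1 <- dH1 * (ca$P1 > 0)
      dW1 <- rbind(crossprod(fw$X, dP1), matrix(0, p_in, ncol(W1)))
    } else {
      dW2 <- crossprod(ca$U2, dP2)
      dU2 <- tcrossprod(dP2, W2)
      dH1 <- dH1 + dU2[, 1:h, drop = FALSE]
      dH1 <- dH1 + as.matrix(At %*% dU2[, (h + 1):(2 * h), drop = FALSE])
      dP1 <- dH1 * (ca$P1 > 0)
      dW1 <- crossprod(fw$U1, dP1)
    }
    g[[paste0("ch", c, "_W2")]] <- dW2
    g[[paste0("ch", c, "_W1")]] <- dW1
  }
  g
}

#' Multi-channel GraphSAGE forward pass
#'
#' Runs every channel over the same graph and concatenates the fused
#' per-channel embeddings into `Z_GNN` (samples x C*hidden_dim).
#'
#' @param X A [protein_matrix()] or numeric matrix whose rows correspond
#'   to the graph's nodes.
#' @param graph A `similarity_graph` (or NULL for the no-GNN ablation).
#' @param model A [init_gnn()] state.
#' @param unweighted Use the plain mean aggregator (ignore edge weights).
#' @return List with `Z` (the concatenated embedding) and per-channel
#'   fused embeddings `M` (list of matrices).
#' @export
multi_channel_forward <- function(X, graph, model, unweighted = FALSE) {
  vals <- if (inherits(X, "protein_matrix")) X$values else as.matrix(X)
  A <- NULL
  if (!is.null(graph)) {
    if (graph$n_nodes != nrow(vals))
      stop("graph nodes do not match matrix rows")
    A <- graph_operator(graph, unweighted = unweighted)
  }
  fw <- gnn_forward_core(vals, A, model)
  h <- model$dims$hidden_dim
  M <- lapply(seq_len(model$dims$n_channels), function(c)
    fw$Z[, ((c - 1) * h + 1):(c * h), drop = FALSE])
  list(Z = fw$Z, M = M)
}

#' Deconvolution head
#'
#' Two-layer ReLU perceptron over the concatenated channel embeddings
#' followed by a row-wise softmax, so each output row is a valid
#' proportion vector.
#'
#' @param Z Embedding matrix (samples x C*hidden_dim) or a single row.
#' @param model A [init_gnn()] state.
#' @return Matrix of predicted proportions (rows sum to 1).
#' @export
deconv_head <- function(Z, model) {
  Z <- rbind(Z)  # promote a vector to one row
  H <- relu(sweep(Z %*% model$par$Wd1, 2L, model$par$bd1, "+"))
  O <- sweep(H %*% model$par$Wd2, 2L, model$par$bd2, "+")
  softmax_rows(O)
}

#' Domain discriminator
#'
#' Two-layer perceptron with sigmoid output; the result is interpreted as
#' the probability that the sample comes from the reference domain.
#'
#' @param Z Embedding matrix or a single row.
#' @param model A [init_gnn()] state.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
domain_discriminator <- function(Z, model) {
  Z <- rbind(Z)
  H <- relu(sweep(Z %*% model$par$Wq1, 2L, model$par$bq1, "+"))
  o <- as.numeric(H %*% model$par$Wq2) + model$par$bq2
  1 / (1 + exp(-o))
}
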