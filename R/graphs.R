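#' Cosine similarity of two vectors
#'
#' @param u,v Non-zero numeric vectors of equal length.
#' @return Scalar in \[-1, 1\].
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("length mismatch")
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0)
    stop("cosine similarity undefined for a zero-norm vector")
  sum(u * v) / (nu * nv)
}

# All-pairs cosine similarity of the rows of Z; errors on zero-norm rows.
cosine_similarity_matrix <- function(Z) {
  Z <- as.matrix(Z)
  nz <- row_norms(Z)
  if (any(nz == 0))
    stop("zero-norm latent vector(s) at row(s): ",
         paste(utils::head(which(nz == 0), 5), collapse = ", "))
  Zn <- Z / nz
  S <- tcrossprod(Zn)
  S[S > 1] <- 1; S[S < -1] <- -1
  S
}

#' Build a k-nearest-neighbour similarity graph
#'
#' Each sample (node) is linked to its `k` most cosine-similar other
#' samples in the latent space; the edge set is symmetrized by union (an
#' edge is kept if either endpoint selects the other) and weighted by the
#' similarity score. Ties in the top-k are broken by smaller node index.
#' No self-loops are stored: the GraphSAGE update concatenates each node's
#' own representation separately.
#'
#' @param Z Latent matrix (samples x latent_dim), e.g. from [ae_encode()].
#' @param k Neighbours per node (must be positive and < node count).
#' @param kind Graph kind: `"reference"`, `"target"`, or `"joint"`.
#' @param node_ids Optional node identifiers.
#' @param node_domain Optional per-node domain tags.
#' @return An object of class `similarity_graph`: `edges` data.frame
#'   `(i, j, weight)` with `i < j`, plus `node_ids`, `node_domain`,
#'   `kind`, `k`.
#' @export
build_knn_graph <- function(Z, k = 10,
                            kind = c("reference", "target", "joint"),
                            node_ids = NULL, node_domain = NULL) {
  kind <- match.arg(kind)
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (k <= 0) stop("k must be positive")
  if (k >= n) stop("k must be smaller than the node count")
  S <- cosine_similarity_matrix(Z)
  diag(S) <- -Inf
  # per-node top-k; order() breaks similarity ties by smaller index
  ei <- integer(n * k); ej <- integer(n * k)
  for (v in seq_len(n)) {
    nb <- order(-S[v, ])[seq_len(k)]
    ei[((v - 1) * k + 1):(v * k)] <- v
    ej[((v - 1) * k + 1):(v * k)] <- nb
  }
  a <- pmin(ei, ej); b <- pmax(ei, ej)
  keep <- !duplicated(cbind(a, b))
  a <- a[keep]; b <- b[keep]
  ord <- order(a, b)
  a <- a[ord]; b <- b[ord]
  edges <- data.frame(i = a, j = b, weight = S[cbind(a, b)])
  structure(list(
    edges = edges,
    node_ids = node_ids %||% paste0("n", seq_len(n)),
    node_domain = node_domain %||% rep(kind, n),
    kind = kind, k = k, n_nodes = n),
    class = "similarity_graph")
}

#' Build the joint reference-target graph
#'
#' kNN graph over the row-concatenation of the two latent matrices, so
#' edges may link reference and target samples.
#'
#' @param Z_ref,Z_tgt Latent matrices with equal column counts.
#' @param k Neighbours per node.
#' @param ref_ids,tgt_ids Optional node identifiers.
#' @return A `similarity_graph` with `kind = "joint"`.
#' @export
build_joint_graph <- function(Z_ref, Z_tgt, k = 10, ref_ids = NULL,
                              tgt_ids = NULL) {
  Z_ref <- as.matrix(Z_ref); Z_tgt <- as.matrix(Z_tgt)
  if (ncol(Z_ref) != ncol(Z_tgt)) stop("latent dimensions differ")
  n_r <- nrow(Z_ref); n_t <- nrow(Z_tgt)
  build_knn_graph(
    rbind(Z_ref, Z_tgt), k = k, kind = "joint",
    node_ids = c(ref_ids %||% paste0("r", seq_len(n_r)),
                 tgt_ids %||% paste0("t", seq_len(n_t))),
    node_domain = c(rep("reference", n_r), rep("target", n_t)))
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("similarity_graph [%s]: %d nodes, %d undirected edges (k = %d)\n",
              x$kind, x$n_nodes, nrow(x$edges), x$k))
  invisible(x)
}

#' Homophily weight of an edge from its endpoints' label vectors
#'
#' Cosine similarity between the two proportion (label) vectors.
#'
#' @param z_i_label,z_j_label Proportion vectors (ground-truth or
#'   predicted compositions).
#' @return Scalar homophily weight.
#' @export
label_homophily_weight <- function(z_i_label, z_j_label) {
  cosine_similarity(z_i_label, z_j_label)
}

#' Re-weight graph edges by label homophily
#'
#' For each edge the homophily `w_ij` is the cosine similarity of the two
#' endpoints' proportion vectors; the similarity weight `s` becomes
#' `1.5 * s` when `w_ij > threshold` (strict) and `down * s` otherwise.
#' The topology is unchanged. Used with ground-truth compositions for the
#' reference graph and with predicted compositions for the target graph.
#'
#' @param g A `similarity_graph`.
#' @param labels A [proportion_matrix()] whose rows correspond to the
#'   graph's nodes, in order.
#' @param threshold Homophily threshold (default 0.5, strict comparison).
#' @param up Factor for homophilic edges (default 1.5).
#' @param down Factor for the rest (default 0.8).
#' @return A `similarity_graph` with re-weighted edges.
#' @export
reweight_edges <- function(g, labels, threshold = 0.5, up = 1.5,
                           down = 0.8) {
  stopifnot(inherits(g, "similarity_graph"))
  L <- if (inherits(labels, "proportion_matrix")) labels$values
       else as.matrix(labels)
  if (nrow(L) < g$n_nodes)
    stop("labels must cover all ", g$n_nodes, " nodes of the graph")
  nz <- row_norms(L)
  if (any(nz == 0)) stop("zero label vector(s) in re-weighting")
  Ln <- L / nz
  w <- rowSums(Ln[g$edges$i, , drop = FALSE] * Ln[g$edges$j, , drop = FALSE])
  g$edges$weight <- ifelse(w > threshold, up, down) * g$edges$weight
  g
}

#' Re-weight the target graph with predicted compositions
#'
#' The iterative prediction protocol: after an initial forward pass on the
#' target graph, its edges are re-weighted using the predicted cell-type
#' ratios, exactly as [reweight_edges()] does with ground truth.
#'
#' @param g_t Target `similarity_graph`.
#' @param predicted Predicted [proportion_matrix()] for the target nodes.
#' @param ... Passed to [reweight_edges()].
#' @return A re-weighted `similarity_graph`.
#' @export
reweight_target_graph <- function(g_t, predicted, ...) {
  reweight_edges(g_t, predicted, ...)
}

# Row-normalized (weighted-mean) sparse aggregation operator of a graph.
# With unweighted = TRUE every neighbour counts 1/|N(v)| (the literal mean
# aggregator); otherwise edge weights act as weighted-mean coefficients.
graph_operator <- function(g, unweighted = FALSE) {
  e <- g$edges
  n <- g$n_nodes
  w <- if (unweighted) rep(1, nrow(e)) else e$weight
  A <- Matrix::sparseMatrix(i = c(e$i, e$j), j = c(e$j, e$i),
                            x = c(w, w), dims = c(n, n))
  rs <- Matrix::rowSums(A)
  if (any(rs == 0)) stop("graph has isolated or zero-weight-degree nodes")
  Matrix::Diagonal(x = 1 / rs) %*% A
}
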