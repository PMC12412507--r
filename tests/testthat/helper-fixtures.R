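# Small in-code fixtures shared across test files.

# A labeled single-cell pool with clearly separated type archetypes.
tiny_cells <- function(n_types = 3, cells_per_type = 20, n_proteins = 12,
                       seed = 7) {
  graphdeconv:::with_seed(seed, {
    arch <- matrix(stats::runif(n_types * n_proteins, 0.5, 4),
                   n_types, n_proteins)
    labels <- rep(paste0("T", seq_len(n_types)), each = cells_per_type)
    x <- arch[rep(seq_len(n_types), each = cells_per_type), ] +
      matrix(stats::rnorm(length(labels) * n_proteins, sd = 0.1),
             length(labels), n_proteins)
    x <- pmax(x, 0)
    rownames(x) <- paste0("c", seq_along(labels))
    colnames(x) <- paste0("p", seq_len(n_proteins))
    list(cells = protein_matrix(x, domain = "reference"),
         annotation = cell_type_annotation(rownames(x), labels))
  })
}

# A random valid proportion matrix.
random_props <- function(n, k, seed = 1) {
  graphdeconv:::with_seed(seed, {
    v <- matrix(stats::rgamma(n * k, 1), n, k)
    proportion_matrix(v / rowSums(v),
                      sample_ids = paste0("s", seq_len(n)),
                      type_universe = paste0("T", seq_len(k)))
  })
}

# Independent brute-force kNN graph: all-pairs cosine, per-node top-k by
# a plain sort, union symmetrization. Written as loops on purpose.
brute_knn_edges <- function(Z, k) {
  n <- nrow(Z)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    S[i, j] <- sum(Z[i, ] * Z[j, ]) /
      (sqrt(sum(Z[i, ]^2)) * sqrt(sum(Z[j, ]^2)))
  }
  pairs <- NULL
  for (v in seq_len(n)) {
    s <- S[v, ]; s[v] <- -Inf
    nb <- order(-s)[seq_len(k)]
    pairs <- rbind(pairs, cbind(pmin(v, nb), pmax(v, nb)))
  }
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  data.frame(i = pairs[, 1], j = pairs[, 2],
             weight = S[pairs])
}

# Independent per-node GraphSAGE forward for one channel (explicit loops).
slow_channel_forward <- function(X, edges, n, W1, W2, s, weighted = TRUE) {
  agg <- function(H) {
    out <- matrix(0, n, ncol(H))
    for (v in seq_len(n)) {
      sel <- which(edges$i == v | edges$j == v)
      nb <- ifelse(edges$i[sel] == v, edges$j[sel], edges$i[sel])
      w <- if (weighted) edges$weight[sel] else rep(1, length(sel))
      acc <- rep(0, ncol(H))
      for (q in seq_along(nb)) acc <- acc + w[q] * H[nb[q], ]
      out[v, ] <- acc / sum(w)
    }
    out
  }
  H1 <- pmax(cbind(X, agg(X)) %*% W1, 0)
  H2 <- pmax(cbind(H1, agg(H1)) %*% W2, 0)
  s[1] * H1 + s[2] * H2
}

# Apply a node permutation to a similarity graph.
permute_graph <- function(g, perm) {
  inv <- order(perm)  # inv[old] = new position when rows reordered by perm
  e <- g$edges
  a <- pmin(inv[e$i], inv[e$j]); b <- pmax(inv[e$i], inv[e$j])
  ord <- order(a, b)
  g$edges <- data.frame(i = a[ord], j = b[ord], weight = e$weight[ord])
  g$node_ids <- g$node_ids[perm]
  g$node_domain <- g$node_domain[perm]
  g
}
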