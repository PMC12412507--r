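test_that("cosine similarity follows the dot/norm definition", {
  expect_equal(cosine_similarity(c(1, 0), c(1, 0)), 1.0)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0.0)
  expect_equal(cosine_similarity(c(1, 2, 3), c(2, 4, 6)), 1.0)
  set.seed(10)
  for (r in 1:10) {
    u <- rnorm(5); v <- rnorm(5)
    expect_equal(cosine_similarity(u, v),
                 sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
  }
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero-norm")
})

test_that("kNN graphs equal the brute-force all-pairs construction", {
  set.seed(12)
  for (case in 1:6) {
    n <- sample(20:60, 1)
    Z <- matrix(abs(rnorm(n * 8)) + 0.05, n, 8)
    k <- sample(2:8, 1)
    g <- build_knn_graph(Z, k, "reference")
    oracle <- brute_knn_edges(Z, k)
    expect_equal(g$edges$i, oracle$i)
    expect_equal(g$edges$j, oracle$j)
    expect_equal(g$edges$weight, oracle$weight, tolerance = 1e-12)
  }
  expect_error(build_knn_graph(matrix(1, 5, 2), 0), "positive")
  expect_error(build_knn_graph(matrix(1, 5, 2), 5), "smaller")
})

test_that("identical points give unit-weight edges; clusters stay separate", {
  Z <- matrix(1, 3, 2)
  g <- build_knn_graph(Z, 1, "reference")
  expect_true(all(abs(g$edges$weight - 1) < 1e-12))
  expect_true(all(g$edges$i < g$edges$j))

  # two well-separated direction clusters: no cross-cluster edges at k=2
  set.seed(14)
  c1 <- cbind(1 + rnorm(5, sd = 0.01), rnorm(5, sd = 0.01))
  c2 <- cbind(rnorm(5, sd = 0.01), 1 + rnorm(5, sd = 0.01))
  g2 <- build_knn_graph(abs(rbind(c1, c2)), 2, "reference")
  side <- function(v) v <= 5
  expect_true(all(side(g2$edges$i) == side(g2$edges$j)))
})

test_that("the joint graph is the kNN graph of the stacked latents", {
  # identical single ref and tgt points -> one cross-domain edge, weight 1
  g <- build_joint_graph(matrix(c(1, 1), 1, 2), matrix(c(1, 1), 1, 2), k = 1)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$weight, 1.0)
  expect_identical(g$node_domain, c("reference", "target"))

  set.seed(15)
  Zr <- matrix(abs(rnorm(20 * 4)) + 0.05, 20, 4)
  Zt <- matrix(abs(rnorm(10 * 4)) + 0.05, 10, 4)
  gj <- build_joint_graph(Zr, Zt, k = 4)
  oracle <- brute_knn_edges(rbind(Zr, Zt), 4)
  expect_equal(gj$edges$i, oracle$i)
  expect_equal(gj$edges$j, oracle$j)

  # shared two-cluster geometry: every node gains a cross-domain edge
  base <- rbind(c(1, 0.05), c(0.05, 1))
  mkc <- function(n, seed) {
    set.seed(seed)
    abs(base[rep(1:2, each = n / 2), ] + matrix(rnorm(n * 2, sd = 0.01), n, 2))
  }
  gj2 <- build_joint_graph(mkc(10, 1), mkc(10, 2), k = 6)
  dom <- gj2$node_domain
  cross <- dom[gj2$edges$i] != dom[gj2$edges$j]
  touched <- sort(unique(c(gj2$edges$i[cross], gj2$edges$j[cross])))
  expect_identical(touched, 1:20)
})

test_that("homophily re-weighting scales weights by exactly 1.5 or 0.8", {
  expect_equal(label_homophily_weight(c(1, 0), c(1, 0)), 1.0)
  expect_equal(label_homophily_weight(c(1, 0), c(0, 1)), 0.0)
  expect_equal(label_homophily_weight(c(0.5, 0.5), c(0.5, 0.5)), 1.0)

  # worked factors: s = 0.4 with w = 0.6 -> 0.60; with w = 0.4 -> 0.32
  g <- structure(list(
    edges = data.frame(i = c(1L, 1L), j = c(2L, 3L), weight = c(0.4, 0.4)),
    node_ids = c("a", "b", "c"), node_domain = rep("reference", 3),
    kind = "reference", k = 1L, n_nodes = 3L), class = "similarity_graph")
  lab <- proportion_matrix(rbind(c(1, 0), c(0.8, 0.2), c(0.2, 0.8)),
                           sample_ids = c("a", "b", "c"),
                           type_universe = c("A", "B"))
  w12 <- label_homophily_weight(c(1, 0), c(0.8, 0.2))  # > 0.5
  w13 <- label_homophily_weight(c(1, 0), c(0.2, 0.8))  # < 0.5
  expect_gt(w12, 0.5); expect_lt(w13, 0.5)
  rg <- reweight_edges(g, lab)
  expect_equal(rg$edges$weight, c(0.60, 0.32))
  # topology unchanged, factors drawn only from {1.5, 0.8}
  expect_identical(rg$edges[, c("i", "j")], g$edges[, c("i", "j")])
  expect_true(all(round(rg$edges$weight / g$edges$weight, 10) %in% c(1.5, 0.8)))

  # identical label rows -> always the homophilic factor
  lab2 <- proportion_matrix(matrix(0.5, 3, 2), sample_ids = c("a", "b", "c"),
                            type_universe = c("A", "B"))
  expect_equal(reweight_edges(g, lab2)$edges$weight, c(0.6, 0.6))
})

test_that("target-graph re-weighting uses predictions like reference truth", {
  set.seed(16)
  Z <- matrix(abs(rnorm(12 * 3)) + 0.1, 12, 3)
  g <- build_knn_graph(Z, 3, "target")
  pred <- random_props(12, 3, seed = 4)
  expect_equal(reweight_target_graph(g, pred)$edges$weight,
               reweight_edges(g, pred)$edges$weight)

  # two anti-correlated one-hot prediction groups
  oneshot <- matrix(0, 12, 3)
  oneshot[1:6, 1] <- 1; oneshot[7:12, 2] <- 1
  ph <- proportion_matrix(oneshot, sample_ids = paste0("s", 1:12),
                          type_universe = c("A", "B", "C"))
  rg <- reweight_target_graph(g, ph)
  grp <- function(v) v <= 6
  fac <- rg$edges$weight / g$edges$weight
  same <- grp(rg$edges$i) == grp(rg$edges$j)
  expect_true(all(abs(fac[same] - 1.5) < 1e-12))
  expect_true(all(abs(fac[!same] - 0.8) < 1e-12))

  # uniform predictions: every edge homophilic
  pu <- proportion_matrix(matrix(1 / 3, 12, 3),
                          sample_ids = paste0("s", 1:12),
                          type_universe = c("A", "B", "C"))
  expect_equal(reweight_edges(g, pu)$edges$weight, 1.5 * g$edges$weight)
})

test_that("node permutations yield isomorphic graphs", {
  set.seed(17)
  Z <- matrix(abs(rnorm(25 * 5)) + 0.05, 25, 5)
  g <- build_knn_graph(Z, 4, "reference")
  perm <- sample(25)
  gp <- build_knn_graph(Z[perm, ], 4, "reference")
  expect_identical(gp$edges[, c("i", "j")],
                   permute_graph(g, perm)$edges[, c("i", "j")])
  expect_equal(gp$edges$weight, permute_graph(g, perm)$edges$weight,
               tolerance = 1e-12)
})
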