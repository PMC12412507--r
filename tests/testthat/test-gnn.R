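make_toy_graph <- function(n, k = 3, d = 4, seed = 20) {
  set.seed(seed)
  Z <- matrix(abs(rnorm(n * d)) + 0.05, n, d)
  build_knn_graph(Z, k, "reference")
}

test_that("neighbourhood aggregation matches an explicit neighbour loop", {
  g <- make_toy_graph(10)
  set.seed(21)
  H <- matrix(rnorm(10 * 3), 10, 3)
  # single/uniform neighbour sanity
  g1 <- structure(list(
    edges = data.frame(i = 1L, j = 2L, weight = 1),
    node_ids = c("a", "b"), node_domain = rep("reference", 2),
    kind = "reference", k = 1L, n_nodes = 2L), class = "similarity_graph")
  expect_equal(sage_aggregate(1, g1, rbind(c(0, 0), c(2, 4))), c(2, 4))
  g2 <- structure(list(
    edges = data.frame(i = c(1L, 1L), j = c(2L, 3L), weight = c(1, 1)),
    node_ids = letters[1:3], node_domain = rep("reference", 3),
    kind = "reference", k = 2L, n_nodes = 3L), class = "similarity_graph")
  expect_equal(sage_aggregate(1, g2, rbind(c(0, 0), c(0, 0), c(2, 2))),
               c(1, 1))
  # weighted-mean oracle on a random graph
  for (v in c(1, 4, 10)) {
    sel <- g$edges$i == v | g$edges$j == v
    nb <- ifelse(g$edges$i[sel] == v, g$edges$j[sel], g$edges$i[sel])
    w <- g$edges$weight[sel]
    acc <- rep(0, 3)
    for (q in seq_along(nb)) acc <- acc + w[q] * H[nb[q], ]
    expect_equal(sage_aggregate(v, g, H), acc / sum(w))
    expect_equal(sage_aggregate(v, g, H, unweighted = TRUE),
                 colMeans(H[nb, , drop = FALSE]))
  }
})

test_that("the SAGE update is a ReLU of the concatenated linear map", {
  expect_equal(sage_update(c(1, 2), c(3, 4), matrix(0, 4, 3)), rep(0, 3))
  W_self <- rbind(diag(2), matrix(0, 2, 2))
  expect_equal(sage_update(c(5, 7), c(-1, -1), W_self), c(5, 7))
  set.seed(22)
  hs <- rnorm(3); ha <- rnorm(3); W <- matrix(rnorm(18), 6, 3)
  man <- pmax(as.numeric(c(hs, ha) %*% W), 0)
  expect_equal(sage_update(hs, ha, W), man)
})

test_that("layer fusion is the stated convex combination", {
  expect_equal(fuse_layers(list(rbind(c(1, 0)), rbind(c(0, 1))), c(0.7, 0.3)),
               rbind(c(0.7, 0.3)))
  h1 <- matrix(1:6, 2, 3); h2 <- matrix(6:1, 2, 3)
  expect_equal(fuse_layers(list(h1, h2), c(1, 0)), h1)
  set.seed(23)
  s <- runif(1); M <- fuse_layers(list(h1, h2), c(s, 1 - s))
  expect_true(all(M >= pmin(h1, h2) - 1e-12 & M <= pmax(h1, h2) + 1e-12))
  expect_error(fuse_layers(list(h1, h2), c(0.5, 0.6)), "sum to 1")
})

test_that("multi-channel forward concatenates independent channels", {
  g <- make_toy_graph(12)
  set.seed(24)
  X <- matrix(abs(rnorm(12 * 5)), 12, 5)
  m1 <- init_gnn(5, 3, hidden_dim = 4, n_channels = 1, seed = 31)
  out1 <- multi_channel_forward(X, g, m1)
  expect_equal(out1$Z, out1$M[[1]])

  m3 <- init_gnn(5, 3, hidden_dim = 4, n_channels = 3, seed = 31)
  out3 <- multi_channel_forward(X, g, m3)
  # each channel equals a single-channel model carrying its weights
  for (c in 1:3) {
    mc <- m1
    mc$par$ch1_W1 <- m3$par[[paste0("ch", c, "_W1")]]
    mc$par$ch1_W2 <- m3$par[[paste0("ch", c, "_W2")]]
    mc$par$ch1_fus <- m3$par[[paste0("ch", c, "_fus")]]
    expect_equal(out3$M[[c]], multi_channel_forward(X, g, mc)$Z)
  }
  # zeroing a channel zeroes exactly its slice of Z
  m3$par$ch2_W1[] <- 0; m3$par$ch2_W2[] <- 0
  outz <- multi_channel_forward(X, g, m3)
  expect_true(all(outz$Z[, 5:8] == 0))
  expect_false(all(outz$Z[, 1:4] == 0))
  expect_error(multi_channel_forward(X[1:5, ], g, m3), "match")
})

test_that("channel outputs match the slow per-node GraphSAGE oracle", {
  g <- make_toy_graph(9, k = 2)
  set.seed(25)
  X <- matrix(abs(rnorm(9 * 4)), 9, 4)
  m <- init_gnn(4, 2, hidden_dim = 3, n_channels = 2, seed = 5)
  out <- multi_channel_forward(X, g, m)
  for (c in 1:2) {
    slow <- slow_channel_forward(
      X, g$edges, 9,
      m$par[[paste0("ch", c, "_W1")]], m$par[[paste0("ch", c, "_W2")]],
      graphdeconv:::softmax_vec(m$par[[paste0("ch", c, "_fus")]]))
    expect_equal(out$M[[c]], slow, tolerance = 1e-12)
  }
  # plain-mean variant
  outu <- multi_channel_forward(X, g, m, unweighted = TRUE)
  slow_u <- slow_channel_forward(
    X, g$edges, 9, m$par$ch1_W1, m$par$ch1_W2,
    graphdeconv:::softmax_vec(m$par$ch1_fus), weighted = FALSE)
  expect_equal(outu$M[[1]], slow_u, tolerance = 1e-12)
})

test_that("the deconvolution head is an exp-normalized MLP", {
  m <- init_gnn(4, 5, hidden_dim = 3, n_channels = 1, head_dim = 4, seed = 6)
  # equal logits -> uniform
  mu <- m; mu$par$Wd2[] <- 0; mu$par$bd2[] <- 0
  P <- deconv_head(matrix(rnorm(6), 2, 3), mu)
  expect_equal(P, matrix(0.2, 2, 5), ignore_attr = TRUE)
  # a dominant logit -> near one-hot
  mh <- mu; mh$par$bd2 <- c(50, 0, 0, 0, 0)
  expect_gt(deconv_head(rnorm(3), mh)[1, 1], 0.999)
  # exp-normalize oracle + simplex contract
  set.seed(26)
  z <- matrix(rnorm(9), 3, 3)
  P2 <- deconv_head(z, m)
  H <- pmax(sweep(z %*% m$par$Wd1, 2, m$par$bd1, "+"), 0)
  O <- sweep(H %*% m$par$Wd2, 2, m$par$bd2, "+")
  for (i in 1:3) expect_equal(P2[i, ], exp(O[i, ]) / sum(exp(O[i, ])))
  expect_equal(unname(rowSums(P2)), rep(1, 3), tolerance = 1e-12)
  expect_true(all(P2 > 0 & P2 < 1))
})

test_that("the domain discriminator is a sigmoid two-layer perceptron", {
  m <- init_gnn(4, 2, hidden_dim = 3, n_channels = 1, disc_dim = 4, seed = 7)
  mz <- m
  mz$par$Wq1[] <- 0; mz$par$bq1[] <- 0; mz$par$Wq2[] <- 0; mz$par$bq2 <- 0
  expect_equal(domain_discriminator(matrix(rnorm(6), 2, 3), mz),
               c(0.5, 0.5))
  # monotone in the output bias (pre-sigmoid logit)
  z <- rnorm(3)
  m2 <- m; m2$par$bq2 <- m$par$bq2 + 2
  expect_gt(domain_discriminator(z, m2), domain_discriminator(z, m))
  # hand-coded forward
  set.seed(27)
  Z <- matrix(rnorm(12), 4, 3)
  d <- domain_discriminator(Z, m)
  H <- pmax(sweep(Z %*% m$par$Wq1, 2, m$par$bq1, "+"), 0)
  o <- as.numeric(H %*% m$par$Wq2) + m$par$bq2
  expect_equal(d, 1 / (1 + exp(-o)))
  expect_true(all(d > 0 & d < 1))
})

test_that("the model is permutation-equivariant", {
  g <- make_toy_graph(14, k = 3)
  set.seed(28)
  X <- matrix(abs(rnorm(14 * 4)), 14, 4)
  m <- init_gnn(4, 3, hidden_dim = 5, n_channels = 2, seed = 8)
  Z <- multi_channel_forward(X, g, m)$Z
  perm <- sample(14)
  Zp <- multi_channel_forward(X[perm, ], permute_graph(g, perm), m)$Z
  expect_equal(Zp, Z[perm, ], tolerance = 1e-10)
})

test_that("analytic gradients match central finite differences", {
  set.seed(42)
  n_r <- 8; n_t <- 6; p <- 5; nt <- 3
  Xr <- matrix(abs(rnorm(n_r * p)), n_r, p)
  Xt <- matrix(abs(rnorm(n_t * p)), n_t, p)
  Y <- random_props(n_r, nt, seed = 2)$values
  Zl_r <- matrix(abs(rnorm(n_r * 3)) + 0.05, n_r, 3)
  Zl_t <- matrix(abs(rnorm(n_t * 3)) + 0.05, n_t, 3)
  g_r <- build_knn_graph(Zl_r, 3, "reference")
  g_t <- build_knn_graph(Zl_t, 2, "target")
  model <- init_gnn(p, nt, hidden_dim = 4, n_channels = 2, head_dim = 6,
                    disc_dim = 5, seed = 1)
  A_r <- graphdeconv:::graph_operator(g_r)
  A_t <- graphdeconv:::graph_operator(g_t)
  tri_r <- mine_triplets(graphdeconv:::cosine_similarity_matrix(Zl_r))
  tri_t <- mine_triplets(graphdeconv:::cosine_similarity_matrix(Zl_t))
  alpha <- 0.01; beta <- 1; m <- 0.3
  rows <- 1:6
  is_ref <- c(rep(TRUE, n_r), rep(FALSE, n_t))
  denom <- n_r + n_t

  loss_fn <- function(par) {
    model$par <- par
    fwr <- graphdeconv:::gnn_forward_core(Xr, A_r, model)
    fwt <- graphdeconv:::gnn_forward_core(Xt, A_t, model)
    hd <- graphdeconv:::head_mse_grad(fwr$Z, model, Y, rows)
    t_r <- loss_triplet(fwr$Z, tri_r, m, denom)
    t_t <- loss_triplet(fwt$Z, tri_t, m, denom)
    dd <- graphdeconv:::disc_grl_grad(rbind(fwr$Z, fwt$Z), model, is_ref,
                                      beta)
    list(enc = hd$loss + alpha * (t_r + t_t) + beta * dd$L_dom,
         disc = -beta * dd$L_dom)
  }
  analytic <- local({
    fwr <- graphdeconv:::gnn_forward_core(Xr, A_r, model)
    fwt <- graphdeconv:::gnn_forward_core(Xt, A_t, model)
    hd <- graphdeconv:::head_mse_grad(fwr$Z, model, Y, rows)
    tg_r <- graphdeconv:::triplet_grad(fwr$Z, tri_r, m, denom)
    tg_t <- graphdeconv:::triplet_grad(fwt$Z, tri_t, m, denom)
    dd <- graphdeconv:::disc_grl_grad(rbind(fwr$Z, fwt$Z), model, is_ref,
                                      beta)
    dZr <- hd$dZ + alpha * tg_r$dZ +
      dd$dZ_encoder[seq_len(n_r), , drop = FALSE]
    dZt <- alpha * tg_t$dZ + dd$dZ_encoder[n_r + seq_len(n_t), , drop = FALSE]
    graphdeconv:::acc_grads(
      hd$grads, dd$grads,
      graphdeconv:::gnn_backward_core(fwr, Matrix::t(A_r), model, dZr),
      graphdeconv:::gnn_backward_core(fwt, Matrix::t(A_t), model, dZt))
  })
  epsv <- 1e-5
  for (nm in names(model$par)) {
    pa <- model$par[[nm]]
    num <- pa * 0
    for (i in seq_along(pa)) {
      pp <- model$par
      pp[[nm]][i] <- pp[[nm]][i] + epsv
      lp <- loss_fn(pp)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * epsv
      lm_ <- loss_fn(pp)
      obj <- if (grepl("^Wq|^bq", nm)) "disc" else "enc"
      num[i] <- (lp[[obj]] - lm_[[obj]]) / (2 * epsv)
    }
    rel <- max(abs(analytic[[nm]] - num)) / max(1e-8, max(abs(num)))
    expect_lt(rel, 1e-6)
  }
})

test_that("loss weights gate their gradient paths", {
  set.seed(50)
  n_r <- 8; n_t <- 5; p <- 4; nt <- 3
  Xr <- matrix(abs(rnorm(n_r * p)), n_r, p)
  Xt <- matrix(abs(rnorm(n_t * p)), n_t, p)
  Y <- random_props(n_r, nt, seed = 3)$values
  Zl_r <- matrix(abs(rnorm(n_r * 3)) + 0.05, n_r, 3)
  Zl_t <- matrix(abs(rnorm(n_t * 3)) + 0.05, n_t, 3)
  graphs <- list(ref = build_knn_graph(Zl_r, 3, "reference"),
                 tgt = build_knn_graph(Zl_t, 2, "target"),
                 joint = build_joint_graph(Zl_r, Zl_t, 3))
  latents <- list(ref = Zl_r, tgt = Zl_t)
  ref <- structure(list(
    expr = protein_matrix(Xr, domain = "reference"),
    props = proportion_matrix(Y), cells_per_sample = 5L, seed = 0L,
    cell_indices = NULL), class = "pseudobulk_set")
  tgt <- protein_matrix(Xt, domain = "target")
  step_par <- function(cfg, latents_in) {
    st <- graphdeconv:::trainer_init(ref, tgt, graphs, latents_in, cfg)
    graphdeconv:::train_one_iteration(st)$model$par
  }
  base <- deconv_config(iterations = 5, min_iterations = 1, patience = 1,
                        hidden_dim = 4, n_channels = 1, head_dim = 5,
                        disc_dim = 4, seed = 2, val_fraction = 0.2)
  # alpha = 0: updates are independent of the mined triplets entirely
  cfg0 <- base; cfg0$alpha <- 0
  latents_shuf <- list(ref = Zl_r[c(2:n_r, 1), ], tgt = Zl_t)
  expect_identical(step_par(cfg0, latents), step_par(cfg0, latents_shuf))
  # beta = 0: the discriminator receives no update and the encoder none
  # from the domain path
  cfgb <- base; cfgb$beta <- 0
  p1 <- step_par(cfgb, latents)
  st0 <- graphdeconv:::trainer_init(ref, tgt, graphs, latents, cfgb)
  expect_identical(p1$Wq1, st0$model$par$Wq1)
  expect_identical(p1$Wq2, st0$model$par$Wq2)
  # with beta > 0 the discriminator does move
  pb <- step_par(base, latents)
  expect_false(identical(pb$Wq1, st0$model$par$Wq1))
})
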