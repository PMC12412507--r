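#' Deconvolution (MSE) loss
#'
#' Mean over samples of the squared L2 distance between predicted and true
#' proportion rows.
#'
#' @param pred,truth Numeric matrices (samples x cell types) or
#'   [proportion_matrix()] objects of equal shape.
#' @return Scalar loss.
#' @export
loss_dec <- function(pred, truth) {
  P <- if (inherits(pred, "proportion_matrix")) pred$values else rbind(pred)
  Y <- if (inherits(truth, "proportion_matrix")) truth$values else rbind(truth)
  if (!all(dim(P) == dim(Y))) stop("shape mismatch")
  sum((P - Y)^2) / nrow(P)
}

#' Mine one triplet per anchor from a similarity matrix
#'
#' For each anchor the off-diagonal maximum-similarity sample is the
#' positive and the minimum-similarity sample the negative; ties are
#' broken by the lowest index.
#'
#' @param S Square similarity matrix (at least 3 samples).
#' @return A `triplet_set`: data.frame `(anchor, pos, neg)`.
#' @export
mine_triplets <- function(S) {
  S <- as.matrix(S)
  n <- nrow(S)
  if (n != ncol(S)) stop("similarity matrix must be square")
  if (n < 3) stop("triplet mining needs at least 3 samples")
  pos <- integer(n); neg <- integer(n)
  for (i in seq_len(n)) {
    s <- S[i, ]
    s[i] <- NA
    pos[i] <- which.max(s)  # ties -> lowest index
    neg[i] <- which.min(s)
  }
  structure(data.frame(anchor = seq_len(n), pos = pos, neg = neg),
            class = c("triplet_set", "data.frame"))
}

#' Cosine triplet margin loss
#'
#' Mean over anchors of `max(cos(z_a, z_neg) - cos(z_a, z_pos) + m, 0)`.
#'
#' @param Z Embedding matrix whose rows are indexed by the triplets.
#' @param triplets A [mine_triplets()] result (columns anchor/pos/neg).
#' @param m Non-negative margin (default 0.3).
#' @param denom Optional denominator overriding the anchor count (used
#'   when a batch's anchors are split across forward passes).
#' @return Scalar loss.
#' @export
loss_triplet <- function(Z, triplets, m = 0.3, denom = NULL) {
  tg <- triplet_grad(as.matrix(Z), triplets, m,
                     denom %||% nrow(triplets), want_grad = FALSE)
  tg$loss
}

# Loss and (optionally) gradient of the cosine triplet hinge w.r.t. Z.
# `tri` is a triplet set (data.frame anchor/pos/neg); when it carries a
# precomputed sparse incidence matrix (attribute "inc", built by
# triplet_incidence()) the scatter-add uses one sparse product instead of
# rowsum(), which matters in the training hot loop.
triplet_grad <- function(Z, tri, m, denom, want_grad = TRUE) {
  eps <- 1e-12
  ia <- as.integer(tri$anchor); ip <- as.integer(tri$pos)
  im <- as.integer(tri$neg)
  a <- Z[ia, , drop = FALSE]
  p <- Z[ip, , drop = FALSE]
  ng <- Z[im, , drop = FALSE]
  na <- pmax(row_norms(a), eps)
  np <- pmax(row_norms(p), eps)
  nn <- pmax(row_norms(ng), eps)
  can <- rowSums(a * ng) / (na * nn)
  cap <- rowSums(a * p) / (na * np)
  hinge <- can - cap + m
  act <- hinge > 0
  loss <- sum(hinge[act]) / denom
  if (!want_grad) return(list(loss = loss))
  if (!any(act))
    return(list(loss = loss, dZ = matrix(0, nrow(Z), ncol(Z))))
  w <- as.numeric(act) / denom  # inactive triplets contribute zero
  # fused per-row scalings (a matrix times a length-n vector recycles the
  # vector down rows, i.e. scales row i by element i)
  c_an <- w / (na * nn)
  c_ap <- w / (na * np)
  dA <- ng * c_an - p * c_ap + a * (w * (cap - can) / na^2)
  dP <- p * (w * cap / np^2) - a * c_ap
  dN <- a * c_an - ng * (w * can / nn^2)
  inc <- attr(tri, "inc")
  if (is.null(inc)) inc <- triplet_incidence(tri, nrow(Z))
  dZ <- if (is.null(inc$A)) dA
        else as.matrix(inc$A %*% dA)
  dZ <- dZ + as.matrix(inc$P %*% dP) + as.matrix(inc$N %*% dN)
  list(loss = loss, dZ = dZ)
}

# Static scatter operators of a triplet set: row v of P collects the
# positive-slot gradient rows of every triplet whose positive is v (same
# for N and, when the anchors are not simply 1..n, A).
triplet_incidence <- function(tri, n_nodes) {
  m <- nrow(tri)
  sm <- function(idx) Matrix::sparseMatrix(i = idx, j = seq_len(m), x = 1,
                                           dims = c(n_nodes, m))
  A <- if (identical(as.integer(tri$anchor), seq_len(n_nodes))) NULL
       else sm(as.integer(tri$anchor))
  list(A = A, P = sm(as.integer(tri$pos)), N = sm(as.integer(tri$neg)))
}

#' Domain-adaptation loss (discriminator objective)
#'
#' The printed adversarial objective `mean(log d_ref) + mean(log(1 -
#' d_tgt))`, which the discriminator maximizes and the encoder, through
#' gradient reversal, minimizes. Probabilities are clipped to
#' `[eps, 1 - eps]`.
#'
#' @param d_ref Discriminator outputs on reference samples.
#' @param d_tgt Discriminator outputs on target samples.
#' @param eps Clipping constant (default 1e-7).
#' @return Scalar (non-positive; 0 means perfect discrimination).
#' @export
loss_domain <- function(d_ref, d_tgt, eps = 1e-7) {
  d_ref <- pmin(pmax(d_ref, eps), 1 - eps)
  d_tgt <- pmin(pmax(d_tgt, eps), 1 - eps)
  mean(log(d_ref)) + mean(log(1 - d_tgt))
}

#' Total training loss
#'
#' `L = L_dec + alpha * L_tri + beta * L_dom`.
#'
#' @param L_dec,L_tri,L_dom Component losses.
#' @param alpha Triplet weight (default 0.01).
#' @param beta Domain weight (default 1).
#' @return Scalar.
#' @export
total_loss <- function(L_dec, L_tri, L_dom, alpha = 0.01, beta = 1) {
  L_dec + alpha * L_tri + beta * L_dom
}

# --- internal head forward/backward used by the trainer ----------------

# Softmax deconvolution head with MSE on the labeled rows. With
# `loss_only = TRUE` the head runs only over the labeled rows (cheaper;
# used on the joint graph, where the other rows' predictions are unused)
# and dZ carries zeros elsewhere; otherwise predictions for all rows are
# returned (needed for validation).
head_mse_grad <- function(Z, model, Y, rows, loss_only = FALSE) {
  par <- model$par
  n_all <- nrow(Z)
  if (loss_only) Z <- Z[rows, , drop = FALSE]
  Hp <- sweep(Z %*% par$Wd1, 2L, par$bd1, "+")
  H <- relu(Hp)
  O <- sweep(H %*% par$Wd2, 2L, par$bd2, "+")
  P <- softmax_rows(O)
  nlab <- length(rows)
  prow <- if (loss_only) seq_len(nlab) else rows
  loss <- sum((P[prow, , drop = FALSE] - Y[rows, , drop = FALSE])^2) / nlab
  dP <- matrix(0, nrow(P), ncol(P))
  dP[prow, ] <- 2 * (P[prow, , drop = FALSE] - Y[rows, , drop = FALSE]) / nlab
  dO <- P * (dP - rowSums(dP * P))
  g <- list(Wd2 = crossprod(H, dO), bd2 = colSums(dO))
  dH <- tcrossprod(dO, par$Wd2) * (Hp > 0)
  g$Wd1 <- crossprod(Z, dH)
  g$bd1 <- colSums(dH)
  dZsub <- tcrossprod(dH, par$Wd1)
  if (loss_only) {
    dZ <- matrix(0, n_all, ncol(dZsub))
    dZ[rows, ] <- dZsub
    P_out <- NULL
  } else {
    dZ <- dZsub
    P_out <- P
  }
  list(loss = loss, P = P_out, grads = g, dZ = dZ)
}

# Discriminator BCE (= -loss_domain with per-domain means) with gradient
# reversal: discriminator parameters get +beta * dL_D, while the encoder
# receives -lambda * dL_D through dZ (lambda is the ramped reversal
# strength; beta = 0 fully decouples the discriminator from training).
disc_grl_grad <- function(Z, model, is_ref, beta, lambda = beta,
                          eps = 1e-7, label_smooth = 0,
                          mode = c("grl", "alternating")) {
  mode <- match.arg(mode)
  par <- model$par
  Hp <- sweep(Z %*% par$Wq1, 2L, par$bq1, "+")
  H <- relu(Hp)
  o <- as.numeric(H %*% par$Wq2) + par$bq2
  d <- 1 / (1 + exp(-o))
  dc <- pmin(pmax(d, eps), 1 - eps)
  n_r <- sum(is_ref); n_t <- sum(!is_ref)
  L_dom <- mean(log(dc[is_ref])) + mean(log(1 - dc[!is_ref]))
  # dL_D/do with L_D = -L_dom; classes weighted by their own means.
  # Smoothed targets (1 - s for reference, s for target) keep the
  # discriminator away from the saturated, zero-gradient regime.
  s <- label_smooth
  do_ <- numeric(length(o))
  do_[is_ref] <- (d[is_ref] - (1 - s)) / n_r
  do_[!is_ref] <- (d[!is_ref] - s) / n_t
  g <- list(Wq2 = beta * crossprod(H, matrix(do_)), bq2 = beta * sum(do_))
  dH <- (matrix(do_) %*% t(par$Wq2)) * (Hp > 0)
  g$Wq1 <- beta * crossprod(Z, dH)
  g$bq1 <- beta * colSums(dH)
  dZ_disc <- tcrossprod(dH, par$Wq1)
  if (mode == "grl") {
    dZ_enc <- -lambda * dZ_disc
  } else {
    # alternating / non-saturating form: the encoder minimizes the BCE of
    # the *flipped* domain labels against the frozen discriminator
    do_f <- numeric(length(o))
    do_f[is_ref] <- d[is_ref] / n_r
    do_f[!is_ref] <- (d[!is_ref] - 1) / n_t
    dHf <- (matrix(do_f) %*% t(par$Wq2)) * (Hp > 0)
    dZ_enc <- lambda * tcrossprod(dHf, par$Wq1)
  }
  list(L_dom = L_dom, d = d, grads = g, dZ_encoder = dZ_enc)
}
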