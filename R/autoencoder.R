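#' Initialize an autoencoder state
#'
#' Architecture `[input, latent_dim, input]`: one rectified encoding layer
#' and one rectified decoding layer (deeper variants can be requested
#' through `hidden`, a vector of intermediate encoder widths, mirrored in
#' the decoder). The rectifier is leaky (slope 0.01 below zero) so that no
#' sample can end up with an all-zero latent row, which would make its
#' cosine similarities undefined during graph construction.
#'
#' @param n_features Input width (shared proteins).
#' @param latent_dim Latent width (default 16).
#' @param hidden Optional integer vector of extra encoder hidden widths
#'   between input and latent.
#' @param seed Integer seed for the initialization.
#' @return An object of class `autoencoder_state` with `encoder` and
#'   `decoder` lists of `(W, b)` layers and `latent_dim`.
#' @export
init_autoencoder <- function(n_features, latent_dim = 16, hidden = integer(0),
                             seed = 0) {
  dims_enc <- c(n_features, hidden, latent_dim)
  dims_dec <- c(latent_dim, rev(hidden), n_features)
  with_seed(seed, {
    mk <- function(dims) lapply(seq_len(length(dims) - 1L), function(l)
      list(W = glorot(dims[l], dims[l + 1L]), b = rep(0, dims[l + 1L])))
    structure(list(encoder = mk(dims_enc), decoder = mk(dims_dec),
                   latent_dim = latent_dim),
              class = "autoencoder_state")
  })
}

ae_layers_forward <- function(X, layers) {
  H <- X
  for (ly in layers) H <- lrelu(sweep(H %*% ly$W, 2L, ly$b, "+"))
  H
}

#' Encode samples into the latent space
#'
#' Applies `H = phi(W H + b)` per encoder layer (phi = leaky ReLU, slope
#' 0.01); the final layer output is the latent representation used for
#' graph construction.
#'
#' @param X A [protein_matrix()] or numeric matrix whose column count
#'   matches the encoder input width.
#' @param state An [init_autoencoder()] state.
#' @return Numeric matrix (samples x latent_dim).
#' @export
ae_encode <- function(X, state) {
  vals <- if (inherits(X, "protein_matrix")) X$values else as.matrix(X)
  if (ncol(vals) != nrow(state$encoder[[1]]$W))
    stop("feature count does not match encoder input width")
  ae_layers_forward(vals, state$encoder)
}

#' Decode latent representations back to feature space
#'
#' @param Z Numeric matrix (samples x latent_dim).
#' @param state An [init_autoencoder()] state.
#' @return Reconstructed matrix (samples x input width).
#' @export
ae_decode <- function(Z, state) {
  Z <- as.matrix(Z)
  if (ncol(Z) != nrow(state$decoder[[1]]$W))
    stop("latent width does not match decoder input width")
  ae_layers_forward(Z, state$decoder)
}

#' Autoencoder reconstruction loss
#'
#' Squared error summed over features, averaged over samples:
#' `(1/n) * sum_i sum_j (X_ij - Xrec_ij)^2`.
#'
#' @param X Original matrix.
#' @param X_rec Reconstruction of the same shape.
#' @return Scalar loss.
#' @export
reconstruction_loss <- function(X, X_rec) {
  X <- if (inherits(X, "protein_matrix")) X$values else as.matrix(X)
  X_rec <- as.matrix(X_rec)
  if (!all(dim(X) == dim(X_rec))) stop("shape mismatch")
  sum((X - X_rec)^2) / nrow(X)
}

#' Train the autoencoder on concatenated reference and target samples
#'
#' Full-batch Adam on the `[input, 16, input]` rectified autoencoder; one
#' shared
#' state encodes both domains so reference and target mix in the latent
#' space. The returned state is the running-best (lowest-loss) checkpoint,
#' so its reconstruction loss never exceeds the initial loss. The loss
#' trajectory is attached as attribute `loss_trace` (and the running best
#' as `best_trace`).
#'
#' @param ref,tgt Feature-aligned [protein_matrix()] objects.
#' @param latent_dim Latent width (default 16).
#' @param epochs Full-batch gradient steps (default 200).
#' @param lr Adam learning rate (default 0.001).
#' @param seed Integer seed (initialization).
#' @return A trained `autoencoder_state`.
#' @export
train_autoencoder <- function(ref, tgt, latent_dim = 16, epochs = 200,
                              lr = 1e-3, seed = 0) {
  stopifnot(identical(ref$feature_ids, tgt$feature_ids))
  X <- rbind(ref$values, tgt$values)
  n <- nrow(X)
  state <- init_autoencoder(ncol(X), latent_dim, seed = seed)
  if (epochs == 0) return(state)
  par <- list(We = state$encoder[[1]]$W, be = state$encoder[[1]]$b,
              Wd = state$decoder[[1]]$W, bd = state$decoder[[1]]$b)
  # start the ReLU output layer at the per-feature mean so no output unit
  # is born dead (zero pre-activation would freeze its gradient at 0)
  par$bd <- colMeans(X)
  opt <- adam_init(par)
  trace <- numeric(epochs)
  best <- Inf
  best_par <- par
  for (e in seq_len(epochs)) {
    Zp <- sweep(X %*% par$We, 2L, par$be, "+")
    Zh <- lrelu(Zp)
    Rp <- sweep(Zh %*% par$Wd, 2L, par$bd, "+")
    Rh <- lrelu(Rp)
    loss <- sum((X - Rh)^2) / n
    if (!is.finite(loss))
      stop("autoencoder training diverged (non-finite loss at epoch ", e, ")")
    trace[e] <- loss
    if (loss < best) { best <- loss; best_par <- par }
    dR <- 2 * (Rh - X) / n
    dRp <- dR * lrelu_grad(Rp)
    g <- list(We = NULL, be = NULL, Wd = crossprod(Zh, dRp),
              bd = colSums(dRp))
    dZh <- dRp %*% t(par$Wd)
    dZp <- dZh * lrelu_grad(Zp)
    g$We <- crossprod(X, dZp)
    g$be <- colSums(dZp)
    upd <- adam_step(par, g, opt, lr)
    par <- upd$par; opt <- upd$opt
  }
  state$encoder[[1]]$W <- best_par$We
  state$encoder[[1]]$b <- best_par$be
  state$decoder[[1]]$W <- best_par$Wd
  state$decoder[[1]]$b <- best_par$bd
  attr(state, "loss_trace") <- trace
  attr(state, "best_trace") <- cummin(trace)
  state
}
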