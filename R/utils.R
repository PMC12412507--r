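# Internal helpers shared across modules.

relu <- function(x) pmax(x, 0)

# Leaky rectifier (slope 0.01 below zero): used in the autoencoder, where
# a fully dead ReLU row would leave a sample with a zero-norm latent and
# no gradient path to recover.
lrelu <- function(x) pmax(x, 0.01 * x)
lrelu_grad <- function(pre) ifelse(pre > 0, 1, 0.01)

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Row-wise softmax of a matrix.
softmax_rows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

row_norms <- function(x) sqrt(rowSums(x * x))

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Glorot-uniform weight matrix, drawn from the current RNG stream.
glorot <- function(nin, nout) {
  r <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -r, r), nin, nout)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

gd_message <- function(..., quiet = FALSE) {
  if (!quiet) message(...)
  invisible(NULL)
}
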