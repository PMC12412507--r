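# Minimal Adam optimizer over a named list of numeric arrays.

adam_init <- function(par) {
  zeros <- lapply(par, function(p) p * 0)
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(par, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, skip = character(0),
                      lr_scale = NULL) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(par)) {
    g <- grads[[nm]]
    if (is.null(g) || nm %in% skip) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    sc <- if (!is.null(lr_scale)) lr_scale(nm) else 1
    step <- sc * lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
    par[[nm]] <- par[[nm]] - step
  }
  list(par = par, opt = opt)
}
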