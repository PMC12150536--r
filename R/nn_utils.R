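# Small neural-net plumbing: initializers, activations, parameter-tree
# arithmetic and the Adam optimizer. Parameters live in nested named
# lists of numeric matrices; gradients mirror the same tree shape.

glorotMatrix <- function(dIn, dOut) {
  lim <- sqrt(6 / (dIn + dOut))
  matrix(stats::runif(dIn * dOut, -lim, lim), dIn, dOut)
}

leakyRelu <- function(x, slope = 0.01) {
  pmax(x, 0) + slope * pmin(x, 0)
}

leakyReluGrad <- function(x, slope = 0.01) {
  slope + (1 - slope) * (x > 0)
}

softmaxVec <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# elementwise map over two parameter trees with identical structure
treeMap2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- treeMap2(f, a[[nm]], b[[nm]])
    out
  } else {
    f(a, b)
  }
}

treeMap <- function(f, a) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- treeMap(f, a[[nm]])
    out
  } else {
    f(a)
  }
}

treeZeroLike <- function(a) treeMap(function(x) x * 0, a)

treeAdd <- function(a, b) treeMap2(`+`, a, b)

# Adam state holds first/second moment trees plus the step counter
adamInit <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = treeZeroLike(params), v = treeZeroLike(params))
}

adamStep <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  opt$m <- treeMap2(function(m, g) opt$beta1 * m + (1 - opt$beta1) * g,
                    opt$m, grads)
  opt$v <- treeMap2(function(v, g) opt$beta2 * v + (1 - opt$beta2) * g^2,
                    opt$v, grads)
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  step <- treeMap2(function(m, v)
    opt$lr * (m / bc1) / (sqrt(v / bc2) + opt$eps), opt$m, opt$v)
  params <- treeMap2(`-`, params, step)
  list(opt = opt, params = params)
}
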