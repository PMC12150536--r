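# Multi-scale Adaptive Convolution Module (MACM).
#
# One MACM layer computes, for scales k = 1..K,
#     h_k = Anorm^k tanh(X W^(k)),
# pools each scale over spots, learns softmax importance weights from
# the pooled summary with a small MLP, and returns the importance-
# weighted sum of the scales. Anorm^k is never materialized: h_k is
# obtained by k successive sparse products.

# y = Anorm^k X via the compiled CSC kernel (general CSC required)
.spkmul <- function(Anorm, X, k) {
  if (k == 0L) return(X)
  if (!is(Anorm, "dgCMatrix"))
    Anorm <- methods::as(methods::as(Anorm, "generalMatrix"),
                         "CsparseMatrix")
  .spmulIterCpp(Anorm@p, Anorm@i, Anorm@x, X, as.integer(k))
}

#' Initialize MACM layer parameters
#'
#' Allocates `K` Glorot-initialized projection matrices `W^(k)`
#' (`dIn x dOut`) and the importance MLP (one tanh hidden layer of
#' width `ceiling(K * dOut / 2)`, then a linear map to `K` logits).
#'
#' @param dIn,dOut input and output widths.
#' @param K scale count (k-order, default 4).
#' @return Parameter list with elements `Ws` (list of K matrices) and
#'   `mlp` (`W1`, `b1`, `W2`, `b2`).
#' @export
macmInit <- function(dIn, dOut, K = 4) {
  hid <- max(1L, ceiling(K * dOut / 2))
  list(
    Ws = lapply(seq_len(K), function(k) glorotMatrix(dIn, dOut)),
    mlp = list(
      W1 = glorotMatrix(K * dOut, hid),
      b1 = matrix(0, 1, hid),
      W2 = glorotMatrix(hid, K),
      b2 = matrix(0, 1, K)
    )
  )
}

#' MACM forward pass
#'
#' @param X spots x dIn input matrix.
#' @param Anorm normalized adjacency (sparse, spots x spots).
#' @param par parameters from [macmInit()].
#' @param forceUniform if TRUE, bypass the importance MLP and weight
#'   all scales equally (diagnostic use).
#' @return A list: `fused` (spots x dOut), `hScales` (list of K
#'   matrices), `hPooled` (length K*dOut vector), `importance`
#'   (softmax weights, length K), and `cache` for the backward pass.
#' @export
macmForward <- function(X, Anorm, par, forceUniform = FALSE) {
  K <- length(par$Ws)
  if (nrow(X) != nrow(Anorm))
    stop("X has ", nrow(X), " rows but Anorm is ", nrow(Anorm), " square")
  if (ncol(X) != nrow(par$Ws[[1]]))
    stop("X has ", ncol(X), " columns but W expects ",
         nrow(par$Ws[[1]]))
  n <- nrow(X)
  Ts <- vector("list", K)
  hs <- vector("list", K)
  for (k in seq_len(K)) {
    Ts[[k]] <- tanh(X %*% par$Ws[[k]])
    hs[[k]] <- .spkmul(Anorm, Ts[[k]], k)
  }
  hm <- unlist(lapply(hs, colMeans), use.names = FALSE)
  if (forceUniform || K == 1L) {
    w <- rep(1 / K, K)
    u <- NULL; logits <- NULL
  } else {
    pre <- drop(hm %*% par$mlp$W1) + drop(par$mlp$b1)
    u <- tanh(pre)
    logits <- drop(u %*% par$mlp$W2) + drop(par$mlp$b2)
    w <- softmaxVec(logits)
  }
  fused <- hs[[1]] * w[1]
  if (K > 1) for (k in 2:K) fused <- fused + hs[[k]] * w[k]
  list(fused = fused, hScales = hs, hPooled = hm, importance = w,
       cache = list(X = X, Ts = Ts, hs = hs, hm = hm, u = u, w = w,
                    uniform = forceUniform || K == 1L))
}

#' MACM backward pass
#'
#' Reverse-mode gradients of a scalar loss through [macmForward()].
#'
#' @param dFused gradient of the loss w.r.t. `fused`.
#' @param Anorm the (symmetric) normalized adjacency used forward.
#' @param par,out parameters and the forward result (with `cache`).
#' @return list with `dX` (gradient w.r.t. the input) and `grads`
#'   (parameter-tree gradient matching `par`).
#' @export
macmBackward <- function(dFused, Anorm, par, out) {
  cache <- out$cache
  K <- length(par$Ws)
  n <- nrow(cache$X)
  w <- cache$w
  dhs <- lapply(seq_len(K), function(k) dFused * w[k])
  grads <- treeZeroLike(par)
  if (!cache$uniform) {
    dw <- vapply(seq_len(K),
                 function(k) sum(dFused * cache$hs[[k]]), 0)
    # softmax jacobian
    dlogits <- w * (dw - sum(dw * w))
    u <- cache$u
    grads$mlp$W2 <- outer(u, dlogits)
    grads$mlp$b2 <- matrix(dlogits, 1)
    du <- drop(par$mlp$W2 %*% dlogits)
    dpre <- du * (1 - u^2)
    grads$mlp$W1 <- outer(cache$hm, dpre)
    grads$mlp$b1 <- matrix(dpre, 1)
    dhm <- drop(par$mlp$W1 %*% dpre)
    # pooled-summary path: colMeans contributes dhm/n to every row
    for (k in seq_len(K)) {
      seg <- dhm[((k - 1) * ncol(dFused) + 1):(k * ncol(dFused))]
      dhs[[k]] <- dhs[[k]] + matrix(seg / n, n, ncol(dFused),
                                    byrow = TRUE)
    }
  }
  dX <- matrix(0, n, ncol(cache$X))
  for (k in seq_len(K)) {
    # Anorm symmetric, so (Anorm^k)^T = Anorm^k
    dT <- .spkmul(Anorm, dhs[[k]], k)
    dP <- dT * (1 - cache$Ts[[k]]^2)
    grads$Ws[[k]] <- crossprod(cache$X, dP)
    dX <- dX + dP %*% t(par$Ws[[k]])
  }
  list(dX = dX, grads = grads)
}
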