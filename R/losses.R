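# The four training losses and their analytic gradients.
#
# L_R : autoencoder reconstruction MSE, summed over modalities.
# L_G : graph-decoder reconstruction MSE against the neighbor-
#       aggregated input Anorm %*% x, summed over modalities.
# L_S : structural binary cross-entropy between sigmoid(Z Z^T) and the
#       binary adjacency, averaged over all N^2 ordered pairs
#       (diagonal included with target 0).
# L_con : spatial InfoNCE, negatives-only form: the per-spot
#       log-ratio numerator runs over neighbors (positives) and the
#       denominator over non-neighbors only, so the ratio can exceed 1
#       and the loss can be negative.
# MSE convention: mean over all matrix entries (1 / (n * d));
# `perSpot = TRUE` switches to Frobenius^2 / n.

.mseScale <- function(x, perSpot) if (perSpot) nrow(x) else length(x)

#' Autoencoder reconstruction loss
#'
#' @param xList,xReconList lists of original and reconstructed
#'   modality matrices (matched shapes).
#' @param perSpot use the per-spot (Frobenius^2 / n) convention instead
#'   of the entry-mean default.
#' @return Non-negative scalar.
#' @export
reconLoss <- function(xList, xReconList, perSpot = FALSE) {
  if (is.matrix(xList)) xList <- list(xList)
  if (is.matrix(xReconList)) xReconList <- list(xReconList)
  tot <- 0
  for (i in seq_along(xList)) {
    if (!identical(dim(xList[[i]]), dim(xReconList[[i]])))
      stop("shape mismatch in modality ", i)
    r <- xReconList[[i]] - xList[[i]]
    tot <- tot + sum(r^2) / .mseScale(xList[[i]], perSpot)
  }
  tot
}

#' Graph feature reconstruction loss
#'
#' Mean squared error of each graph-decoder output against the
#' neighbor-aggregated input `Anorm %*% x`, summed over modalities.
#'
#' @param ZomicsList list of graph-decoder outputs.
#' @param Anorm normalized adjacency.
#' @param xList list of branch inputs.
#' @param perSpot see [reconLoss()].
#' @return Non-negative scalar.
#' @export
graphReconLoss <- function(ZomicsList, Anorm, xList, perSpot = FALSE) {
  if (is.matrix(ZomicsList)) ZomicsList <- list(ZomicsList)
  if (is.matrix(xList)) xList <- list(xList)
  tot <- 0
  for (i in seq_along(xList)) {
    tgt <- as.matrix(Anorm %*% xList[[i]])
    if (!identical(dim(ZomicsList[[i]]), dim(tgt)))
      stop("shape mismatch in modality ", i)
    r <- ZomicsList[[i]] - tgt
    tot <- tot + sum(r^2) / .mseScale(tgt, perSpot)
  }
  tot
}

#' Structural binary cross-entropy
#'
#' Reconstructs the graph as `A' = sigmoid(Z Z^T)` and scores it
#' against the binary adjacency with BCE averaged over all N^2 ordered
#' pairs; probabilities are clamped to `[eps, 1 - eps]`.
#'
#' @param Z fused embedding (spots x d).
#' @param A binary adjacency with zero diagonal (dense or sparse).
#' @param eps clamp bound (default 1e-7).
#' @return Non-negative scalar.
#' @export
structuralBce <- function(Z, A, eps = 1e-7) {
  A <- as.matrix(A)
  n <- nrow(Z)
  P <- stats::plogis(tcrossprod(Z))
  P <- pmin(pmax(P, eps), 1 - eps)
  -sum(A * log(P) + (1 - A) * log(1 - P)) / n^2
}

# gradient of structuralBce w.r.t. Z (clamp ignored in the gradient;
# sigmoid(s)-A is the exact unclamped derivative and is bounded)
gradStructuralBce <- function(Z, A) {
  A <- as.matrix(A)
  n <- nrow(Z)
  P <- stats::plogis(tcrossprod(Z))
  G <- (P - A) / n^2
  2 * (G %*% Z)
}

.cosineParts <- function(Z, eps = 1e-12) {
  nrm <- sqrt(rowSums(Z^2))
  nrm <- pmax(nrm, eps)
  Zh <- Z / nrm
  list(Zh = Zh, nrm = nrm, C = tcrossprod(Zh))
}

#' Spatial InfoNCE contrastive loss
#'
#' For each spot i with neighbor set N_i,
#' `-log( sum_{j in N_i} exp(cos(Z_i, Z_j)/tau)
#'        / sum_{j not in N_i, j != i} exp(cos(Z_i, Z_j)/tau) )`,
#' averaged over spots. Implemented exactly in this form (denominator
#' over negatives only), so the value may be negative. With
#' `standardInfonce = TRUE` the denominator instead runs over all
#' spots except i itself (the textbook formulation, guaranteed
#' non-negative contributions per positive-singleton spot).
#'
#' @param Z embedding matrix.
#' @param nbrSets list of neighbor index vectors (or a
#'   [NeighborGraph-class]).
#' @param tau temperature (default 1; see the methods vignette).
#' @param standardInfonce switch described above.
#' @return Scalar loss.
#' @export
infonceLoss <- function(Z, nbrSets, tau = 1,
                        standardInfonce = FALSE) {
  if (is(nbrSets, "NeighborGraph")) nbrSets <- neighborSets(nbrSets)
  n <- nrow(Z)
  cp <- .cosineParts(Z)
  E <- exp(cp$C / tau)
  pos <- vapply(seq_len(n), function(i) sum(E[i, nbrSets[[i]]]), 0)
  nNbr <- lengths(nbrSets)
  if (any(nNbr == 0))
    stop("spot(s) without neighbors: ",
         paste(utils::head(which(nNbr == 0), 5), collapse = ", "))
  if (any(nNbr >= n - 1) && !standardInfonce)
    stop("spot(s) without negatives: ",
         paste(utils::head(which(nNbr >= n - 1), 5), collapse = ", "))
  if (standardInfonce) {
    den <- rowSums(E) - diag(E)
  } else {
    den <- rowSums(E) - diag(E) - pos
  }
  -mean(log(pos / den))
}

# gradient of infonceLoss w.r.t. Z
gradInfonce <- function(Z, nbrSets, tau = 1,
                        standardInfonce = FALSE) {
  if (is(nbrSets, "NeighborGraph")) nbrSets <- neighborSets(nbrSets)
  n <- nrow(Z)
  cp <- .cosineParts(Z)
  E <- exp(cp$C / tau)
  Apos <- matrix(0, n, n)
  for (i in seq_len(n)) Apos[i, nbrSets[[i]]] <- 1
  pos <- rowSums(Apos * E)
  offdiag <- 1 - diag(n)
  if (standardInfonce) {
    Aneg <- offdiag
  } else {
    Aneg <- (1 - Apos) * offdiag
  }
  den <- rowSums(Aneg * E)
  # dL/dC_ij, rows index the "anchor" spot of each per-spot term
  G <- (-(Apos * E) / pos + (Aneg * E) / den) / (n * tau)
  M <- G + t(G)
  R <- M %*% cp$Zh
  s <- rowSums(M * cp$C)
  (R - s * cp$Zh) / cp$nrm
}

#' Total training loss
#'
#' Computes all four components and their unweighted sum, honoring the
#' ablation flags `no_nce` (drop L_con) and `no_bce` (drop L_S).
#'
#' @param xList,xReconList,ZomicsList per-modality matrices.
#' @param Z fused embedding.
#' @param graph a [NeighborGraph-class] (supplies `A`, `A_norm`,
#'   neighbor sets).
#' @param tau InfoNCE temperature.
#' @param flags ablation flags.
#' @param perSpot,standardInfonce loss-convention switches.
#' @return A loss breakdown list: `L_R`, `L_G`, `L_S`, `L_con`,
#'   `total`.
#' @export
totalLoss <- function(xList, xReconList, ZomicsList, Z, graph,
                      tau = 1, flags = character(),
                      perSpot = FALSE, standardInfonce = FALSE) {
  lr <- reconLoss(xList, xReconList, perSpot)
  lg <- graphReconLoss(ZomicsList, normAdjacency(graph), xList, perSpot)
  ls <- if ("no_bce" %in% flags) 0 else
    structuralBce(Z, adjacency(graph))
  lc <- if ("no_nce" %in% flags) 0 else
    infonceLoss(Z, neighborSets(graph), tau, standardInfonce)
  list(L_R = lr, L_G = lg, L_S = ls, L_con = lc,
       total = lr + lg + ls + lc)
}
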