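# Training loop: full-graph and batched gradient descent with Adam.

#' Sigma (attribute/structure mixing) presets by dataset type
#'
#' Shipped defaults for the mixing coefficient `a`, keyed by dataset
#' type: 0.7 for spot-level CITE-seq-style lymphoid/spleen/thymus
#' tissue, 0.5 for simulated and developing-brain/cortex data, 0.4 for
#' MERFISH-class single-cell panels, 0.3 for single-cell multi-omics
#' and tumor sections, 0.2 for whole-embryo sections.
#'
#' @return Named numeric vector of presets.
#' @export
sigmaPresets <- function() {
  c(lymph_node = 0.7, spleen = 0.7, thymus = 0.7,
    simulated = 0.5, brain_e15 = 0.5, mpfc = 0.5,
    merfish = 0.4, melanoma = 0.4, cortex = 0.4, hippocampus = 0.4,
    placenta = 0.3, breast_cancer = 0.3, bronchial = 0.3,
    embryo = 0.2)
}

#' Training configuration
#'
#' @param epochs gradient steps over the full graph (default 200).
#' @param learningRate Adam learning rate (default 1e-3).
#' @param seed integer seed controlling every stochastic component
#'   (initialization, batching, K-means restarts).
#' @param a attribute/structure mixing coefficient; if `datasetType`
#'   matches a [sigmaPresets()] name, that preset is used instead.
#' @param tau InfoNCE temperature (default 1).
#' @param kNeighbors spatial KNN parameter (default 3).
#' @param K MACM scale count (default 4).
#' @param layerDims encoder widths (default c(256, 128, 64)).
#' @param batchSize spots per training block, or NULL for full-graph
#'   training.
#' @param ablation subset of
#'   `c("no_macm", "no_maf", "no_ai", "no_nce", "no_bce")`.
#' @param datasetType optional preset key for `a`.
#' @param perSpot,standardInfonce loss-convention switches (see
#'   [reconLoss()], [infonceLoss()]).
#' @return Config list.
#' @export
trainConfig <- function(epochs = 200, learningRate = 1e-3, seed = 2020,
                        a = 0.5, tau = 1, kNeighbors = 3, K = 4,
                        layerDims = c(256, 128, 64), batchSize = NULL,
                        ablation = character(), datasetType = NULL,
                        perSpot = FALSE, standardInfonce = FALSE) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (!is.null(batchSize) && batchSize < 2)
    stop("batchSize must be >= 2")
  known <- c("no_macm", "no_maf", "no_ai", "no_nce", "no_bce")
  if (length(bad <- setdiff(ablation, known)))
    stop("unknown ablation flag(s): ", paste(bad, collapse = ", "))
  if (!is.null(datasetType)) {
    ps <- sigmaPresets()
    if (datasetType %in% names(ps)) a <- unname(ps[datasetType])
  }
  if (a < 0 || a > 1) stop("a must lie in [0, 1]")
  list(epochs = as.integer(epochs), learningRate = learningRate,
       seed = as.integer(seed), a = a, tau = tau,
       kNeighbors = as.integer(kNeighbors), K = as.integer(K),
       layerDims = as.integer(layerDims),
       batchSize = if (is.null(batchSize)) NULL else
         as.integer(batchSize),
       ablation = ablation, perSpot = perSpot,
       standardInfonce = standardInfonce)
}

# precomputed per-graph context for the pairwise (N^2) loss terms
.graphCtx <- function(graph, standardInfonce = FALSE) {
  Ad <- as.matrix(adjacency(graph))
  n <- nrow(Ad)
  offdiag <- 1 - diag(n)
  list(graph = graph, Ad = Ad, n = n,
       Aneg = if (standardInfonce) offdiag else (1 - Ad) * offdiag)
}

# structural BCE + negatives-only InfoNCE: values and gradient w.r.t. Z in
# one pass (compiled kernel), sharing the Z Z^T product. Spots
# without a positive or a negative are skipped in the InfoNCE mean
# (relevant in induced batch subgraphs). The BCE gradient uses the
# exact unclamped derivative.
.pairLossGrads <- function(Z, ctx, tau, doBce, doNce, eps = 1e-7) {
  .pairLossGradsCpp(Z, ctx$Ad, ctx$Aneg, tau, doBce, doNce, eps)
}

# one forward + backward pass over a (sub)graph; returns losses,
# parameter gradients and the forward result
.lossAndGrads <- function(xList, graph, state, config, ctx = NULL) {
  if (is.null(ctx)) ctx <- .graphCtx(graph, config$standardInfonce)
  fw <- modelForward(xList, normAdjacency(graph), state)
  n <- nrow(fw$Z)
  flags <- state$flags
  pl <- .pairLossGrads(fw$Z, ctx, config$tau,
                       doBce = !"no_bce" %in% flags,
                       doNce = !"no_nce" %in% flags)
  ls <- pl$L_S; lc <- pl$L_con
  dZ <- pl$dZ
  Anorm <- normAdjacency(graph)
  lr <- 0; lg <- 0
  grads <- list()
  col0 <- 0L
  for (nm in names(xList)) {
    br <- fw$branches[[nm]]
    x <- xList[[nm]]
    d3 <- ncol(br$H)
    cols <- (col0 + 1L):(col0 + d3)
    col0 <- col0 + d3
    scR <- if (config$perSpot) n else length(x)
    rR <- br$xRecon - x
    lr <- lr + sum(rR^2) / scR
    tgt <- .spkmul(Anorm, x, 1L)
    rG <- br$Zomics - tgt
    lg <- lg + sum(rG^2) / scR
    grads[[nm]] <- branchBackward(
      br, Anorm, state$params[[nm]],
      dH = dZ[, cols, drop = FALSE],
      dZomics = 2 * rG / scR,
      dxRecon = 2 * rR / scR)
  }
  list(losses = list(L_R = lr, L_G = lg, L_S = ls, L_con = lc,
                     total = lr + lg + ls + lc),
       grads = grads, fw = fw)
}

.checkFinite <- function(losses, epoch) {
  for (nm in c("L_R", "L_G", "L_S", "L_con"))
    if (!is.finite(losses[[nm]]))
      stop("non-finite loss component ", nm, " at epoch ", epoch,
           " (value: ", losses[[nm]], ")")
}

.asXList <- function(dataset) {
  if (is(dataset, "SpatialMultiOmics"))
    lapply(modalities(dataset), function(m) m@values)
  else dataset
}

#' Fit the model on the full graph
#'
#' Adam gradient descent on the total loss (reconstruction +
#' graph reconstruction + structural BCE + spatial InfoNCE) for a
#' fixed number of epochs. All randomness (weight initialization and
#' any downstream clustering) derives from `config$seed`.
#'
#' @param dataset a [SpatialMultiOmics-class] with preprocessed
#'   modalities, or a named list of spots x features matrices.
#' @param graph a [NeighborGraph-class] over the same spots.
#' @param config a [trainConfig()].
#' @param logPath optional CSV path receiving the per-epoch loss
#'   breakdown.
#' @return list with `state` (trained parameters), `embedding` (the
#'   final forward pass: per-branch features and fused `Z`), and `log`
#'   (data.frame epoch x loss components).
#' @export
fitModel <- function(dataset, graph, config = trainConfig(),
                     logPath = NULL) {
  xList <- .asXList(dataset)
  set.seed(config$seed)
  state <- modelInit(
    vapply(xList, ncol, 0L),
    layerDims = config$layerDims, a = config$a, K = config$K,
    flags = config$ablation)
  opt <- adamInit(state$params, lr = config$learningRate)
  ctx <- .graphCtx(graph, config$standardInfonce)
  log <- matrix(0, config$epochs, 5,
                dimnames = list(NULL,
                  c("L_R", "L_G", "L_S", "L_con", "total")))
  for (ep in seq_len(config$epochs)) {
    lg <- .lossAndGrads(xList, graph, state, config, ctx)
    .checkFinite(lg$losses, ep)
    log[ep, ] <- unlist(lg$losses)
    stepped <- adamStep(opt, state$params, lg$grads)
    opt <- stepped$opt
    state$params <- stepped$params
  }
  fw <- modelForward(xList, normAdjacency(graph), state)
  log <- data.frame(epoch = seq_len(config$epochs), log)
  if (!is.null(logPath))
    utils::write.csv(log, logPath, row.names = FALSE)
  list(state = state, embedding = fw, log = log)
}

#' Fit the model with batched training
#'
#' Each epoch partitions the spots into random blocks of at most
#' `batchSize`; every block trains on its induced subgraph (adjacency
#' restricted to the block and re-normalized, neighbor sets recomputed
#' within the block), so the pairwise loss terms cost
#' O(batchSize^2) instead of O(N^2). Blocks without any edge are
#' skipped with a warning. With `batchSize >= N` this reduces to
#' [fitModel()].
#'
#' @inheritParams fitModel
#' @return As [fitModel()]; the log holds per-epoch means over blocks.
#' @export
fitBatched <- function(dataset, graph, config, logPath = NULL) {
  xList <- .asXList(dataset)
  n <- nrow(xList[[1]])
  bs <- config$batchSize
  if (is.null(bs)) stop("config$batchSize must be set for fitBatched")
  if (bs >= n) return(fitModel(dataset, graph, config, logPath))
  set.seed(config$seed)
  state <- modelInit(
    vapply(xList, ncol, 0L),
    layerDims = config$layerDims, a = config$a, K = config$K,
    flags = config$ablation)
  opt <- adamInit(state$params, lr = config$learningRate)
  A <- adjacency(graph)
  log <- matrix(0, config$epochs, 5,
                dimnames = list(NULL,
                  c("L_R", "L_G", "L_S", "L_con", "total")))
  nBlocks <- ceiling(n / bs)
  sizes <- rep(floor(n / nBlocks), nBlocks)
  if (n %% nBlocks) sizes[seq_len(n %% nBlocks)] <-
    sizes[seq_len(n %% nBlocks)] + 1L
  ends <- cumsum(sizes)
  for (ep in seq_len(config$epochs)) {
    perm <- sample.int(n)
    acc <- numeric(5); nb <- 0
    for (b in seq_len(nBlocks)) {
      idx <- perm[(ends[b] - sizes[b] + 1):ends[b]]
      idx <- sort(idx)
      Asub <- A[idx, idx, drop = FALSE]
      if (sum(Asub) == 0) {
        warning("epoch ", ep, ": block without edges skipped")
        next
      }
      gsub <- .newGraph(Asub, graph@k)
      xs <- lapply(xList, function(x) x[idx, , drop = FALSE])
      lgb <- .lossAndGrads(xs, gsub, state, config)
      .checkFinite(lgb$losses, ep)
      acc <- acc + unlist(lgb$losses)
      nb <- nb + 1
      stepped <- adamStep(opt, state$params, lgb$grads)
      opt <- stepped$opt
      state$params <- stepped$params
    }
    log[ep, ] <- if (nb > 0) acc / nb else NA_real_
  }
  fw <- modelForward(xList, normAdjacency(graph), state)
  log <- data.frame(epoch = seq_len(config$epochs), log)
  if (!is.null(logPath))
    utils::write.csv(log, logPath, row.names = FALSE)
  list(state = state, embedding = fw, log = log)
}
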