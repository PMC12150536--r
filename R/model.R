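# Per-omics model branch: a fully connected autoencoder extracting
# attribute features, a 3-layer MACM graph encoder performing
# multi-step attribute/structure fusion (mixing coefficient `a`,
# the "sigma" preset), and a mirrored 3-layer MACM graph decoder
# reconstructing neighbor-aggregated inputs. Branch outputs are
# concatenated across modalities into the fused embedding Z.

#' Branch configuration
#'
#' @param inputDim feature width of the (preprocessed) modality.
#' @param layerDims widths of the three encoder layers; the graph
#'   encoder mirrors them layer-for-layer (the fusion equations require
#'   equal widths).
#' @param a attribute/structure mixing coefficient in [0, 1]; `a = 1`
#'   uses only structural features (the "no multi-step attribute
#'   fusion" ablation), `a = 0` reduces the branch to the autoencoder.
#' @param K MACM scale count (k-order, default 4).
#' @return A validated config list.
#' @export
branchConfig <- function(inputDim, layerDims = c(256, 128, 64), a = 0.5,
                         K = 4) {
  if (length(layerDims) != 3) stop("layerDims must have length 3")
  if (a < 0 || a > 1) stop("a must lie in [0, 1]")
  if (K < 1) stop("K must be >= 1")
  list(inputDim = as.integer(inputDim),
       layerDims = as.integer(layerDims), a = a, K = as.integer(K))
}

#' Initialize one model branch
#'
#' Glorot-uniform initialization of the autoencoder (3 FC layers with 2
#' LeakyReLU, linear latent and output), graph encoder (3 MACM layers)
#' and graph decoder (3 MACM layers with mirrored widths).
#'
#' @param config a [branchConfig()].
#' @return Parameter tree with elements `enc`, `dec`, `genc`, `gdec`.
#' @export
branchInit <- function(config) {
  d <- config$inputDim; ds <- config$layerDims; K <- config$K
  fc <- function(i, o) list(W = glorotMatrix(i, o), b = matrix(0, 1, o))
  list(
    enc = list(fc(d, ds[1]), fc(ds[1], ds[2]), fc(ds[2], ds[3])),
    dec = list(fc(ds[3], ds[2]), fc(ds[2], ds[1]), fc(ds[1], d)),
    genc = list(macmInit(d, ds[1], K), macmInit(ds[1], ds[2], K),
                macmInit(ds[2], ds[3], K)),
    gdec = list(macmInit(ds[3], ds[2], K), macmInit(ds[2], ds[1], K),
                macmInit(ds[1], d, K))
  )
}

.affine <- function(X, layer) sweep(X %*% layer$W, 2, drop(layer$b), `+`)

#' Autoencoder forward pass
#'
#' Encoder: FC-LeakyReLU-FC-LeakyReLU-FC (linear latent); decoder
#' mirrors the encoder to reconstruct the input.
#'
#' @param x spots x inputDim matrix.
#' @param par branch parameter tree from [branchInit()].
#' @return list with `attrFeats` (list of h1, h2, hLatent), `xRecon`,
#'   and `cache`.
#' @export
autoencoderForward <- function(x, par) {
  z1 <- .affine(x, par$enc[[1]]); h1 <- leakyRelu(z1)
  z2 <- .affine(h1, par$enc[[2]]); h2 <- leakyRelu(z2)
  h3 <- .affine(h2, par$enc[[3]])
  y1 <- .affine(h3, par$dec[[1]]); g1 <- leakyRelu(y1)
  y2 <- .affine(g1, par$dec[[2]]); g2 <- leakyRelu(y2)
  xr <- .affine(g2, par$dec[[3]])
  list(attrFeats = list(h1 = h1, h2 = h2, hLatent = h3), xRecon = xr,
       cache = list(x = x, z1 = z1, h1 = h1, z2 = z2, h2 = h2, h3 = h3,
                    y1 = y1, g1 = g1, y2 = y2, g2 = g2))
}

#' Graph encoder forward pass with multi-step attribute fusion
#'
#' `H_1 = MACM_1(x)`; `H_i = MACM_i(a H_{i-1} + (1-a) h_{i-1})` for
#' i = 2, 3; the branch embedding is `H = a H_3 + (1-a) h_latent`.
#' With `zeroAttr = TRUE` the attribute features are replaced by zeros
#' (the "no attribute information" ablation).
#'
#' @param x input matrix; `Anorm` normalized adjacency; `attrFeats`
#'   the autoencoder features; `par` the branch parameters; `a` the
#'   mixing coefficient.
#' @param Anorm,attrFeats,par,a,zeroAttr see description.
#' @return list with `structFeats` (H1, H2, H3), `H` (branch
#'   embedding) and `cache`.
#' @export
graphEncoderForward <- function(x, Anorm, attrFeats, par, a,
                                zeroAttr = FALSE) {
  af <- attrFeats
  if (zeroAttr)
    af <- lapply(af, function(m) m * 0)
  m1 <- macmForward(x, Anorm, par$genc[[1]])
  in2 <- a * m1$fused + (1 - a) * af$h1
  m2 <- macmForward(in2, Anorm, par$genc[[2]])
  in3 <- a * m2$fused + (1 - a) * af$h2
  m3 <- macmForward(in3, Anorm, par$genc[[3]])
  H <- a * m3$fused + (1 - a) * af$hLatent
  list(structFeats = list(H1 = m1$fused, H2 = m2$fused, H3 = m3$fused),
       H = H, cache = list(m1 = m1, m2 = m2, m3 = m3))
}

#' Graph decoder forward pass
#'
#' Three MACM layers with widths mirroring the encoder
#' (d3 -> d2 -> d1 -> d), reconstructing a full-width embedding from
#' the branch embedding.
#'
#' @param H branch embedding (spots x d3); `Anorm` normalized
#'   adjacency; `par` branch parameters.
#' @param Anorm,par see description.
#' @return list with `Z` (spots x inputDim) and `cache`.
#' @export
graphDecoderForward <- function(H, Anorm, par) {
  m1 <- macmForward(H, Anorm, par$gdec[[1]])
  m2 <- macmForward(m1$fused, Anorm, par$gdec[[2]])
  m3 <- macmForward(m2$fused, Anorm, par$gdec[[3]])
  list(Z = m3$fused, cache = list(m1 = m1, m2 = m2, m3 = m3))
}

#' Single-branch forward pass
#'
#' Runs the autoencoder, graph encoder and graph decoder of one
#' modality branch.
#'
#' @param x preprocessed modality matrix.
#' @param Anorm normalized adjacency.
#' @param par branch parameters.
#' @param config branch config (supplies `a`).
#' @param flags character vector of ablation flags (`no_maf` forces
#'   a = 1, `no_ai` zeroes attribute features in the fusion).
#' @return list with all branch intermediates and caches.
#' @export
branchForward <- function(x, Anorm, par, config, flags = character()) {
  a <- if ("no_maf" %in% flags) 1 else config$a
  ae <- autoencoderForward(x, par)
  ge <- graphEncoderForward(x, Anorm, ae$attrFeats, par, a,
                            zeroAttr = "no_ai" %in% flags)
  gd <- graphDecoderForward(ge$H, Anorm, par)
  list(attrFeats = ae$attrFeats, xRecon = ae$xRecon,
       structFeats = ge$structFeats, H = ge$H, Zomics = gd$Z,
       cache = list(ae = ae$cache, ge = ge$cache, gd = gd$cache, a = a,
                    zeroAttr = "no_ai" %in% flags, x = x))
}

# Backward through one branch. dH: gradient w.r.t. the branch
# embedding (from Z-level losses), dZomics: w.r.t. the graph-decoder
# output (L_G), dxRecon: w.r.t. the autoencoder reconstruction (L_R).
branchBackward <- function(fw, Anorm, par, dH, dZomics, dxRecon) {
  cache <- fw$cache
  a <- cache$a
  grads <- treeZeroLike(par)

  # graph decoder chain
  gd <- cache$gd
  b3 <- macmBackward(dZomics, Anorm, par$gdec[[3]], gd$m3)
  grads$gdec[[3]] <- b3$grads
  b2 <- macmBackward(b3$dX, Anorm, par$gdec[[2]], gd$m2)
  grads$gdec[[2]] <- b2$grads
  b1 <- macmBackward(b2$dX, Anorm, par$gdec[[1]], gd$m1)
  grads$gdec[[1]] <- b1$grads
  dH <- dH + b1$dX

  # graph encoder with multi-step fusion
  ge <- cache$ge
  useAttr <- !cache$zeroAttr
  dG3 <- a * dH
  dh3 <- if (useAttr) (1 - a) * dH else 0
  e3 <- macmBackward(dG3, Anorm, par$genc[[3]], ge$m3)
  grads$genc[[3]] <- e3$grads
  dG2 <- a * e3$dX
  dh2 <- if (useAttr) (1 - a) * e3$dX else 0
  e2 <- macmBackward(dG2, Anorm, par$genc[[2]], ge$m2)
  grads$genc[[2]] <- e2$grads
  dG1 <- a * e2$dX
  dh1 <- if (useAttr) (1 - a) * e2$dX else 0
  e1 <- macmBackward(dG1, Anorm, par$genc[[1]], ge$m1)
  grads$genc[[1]] <- e1$grads

  # decoder of the autoencoder
  ae <- cache$ae
  dy3 <- dxRecon
  grads$dec[[3]]$W <- crossprod(ae$g2, dy3)
  grads$dec[[3]]$b <- matrix(colSums(dy3), 1)
  dg2 <- dy3 %*% t(par$dec[[3]]$W)
  dy2 <- dg2 * leakyReluGrad(ae$y2)
  grads$dec[[2]]$W <- crossprod(ae$g1, dy2)
  grads$dec[[2]]$b <- matrix(colSums(dy2), 1)
  dg1 <- dy2 %*% t(par$dec[[2]]$W)
  dy1 <- dg1 * leakyReluGrad(ae$y1)
  grads$dec[[1]]$W <- crossprod(ae$h3, dy1)
  grads$dec[[1]]$b <- matrix(colSums(dy1), 1)
  dh3 <- dh3 + dy1 %*% t(par$dec[[1]]$W)

  # encoder (accumulating fusion-path gradients on h1, h2, h3)
  dz3 <- dh3
  grads$enc[[3]]$W <- crossprod(ae$h2, dz3)
  grads$enc[[3]]$b <- matrix(colSums(dz3), 1)
  dh2 <- dh2 + dz3 %*% t(par$enc[[3]]$W)
  dz2 <- dh2 * leakyReluGrad(ae$z2)
  grads$enc[[2]]$W <- crossprod(ae$h1, dz2)
  grads$enc[[2]]$b <- matrix(colSums(dz2), 1)
  dh1 <- dh1 + dz2 %*% t(par$enc[[2]]$W)
  dz1 <- dh1 * leakyReluGrad(ae$z1)
  grads$enc[[1]]$W <- crossprod(ae$x, dz1)
  grads$enc[[1]]$b <- matrix(colSums(dz1), 1)

  grads
}

#' Concatenate per-omics embeddings
#'
#' Column-binds branch embeddings in fixed modality order (first
#' modality first). With a single modality this is the identity
#' (single-omics mode).
#'
#' @param HList list of spots x d3 matrices with equal spot counts.
#' @return The concatenated embedding Z.
#' @export
fuseOmics <- function(HList) {
  ns <- vapply(HList, nrow, 0L)
  if (length(unique(ns)) != 1L)
    stop("spot-count mismatch across modalities: ",
         paste(ns, collapse = ", "))
  do.call(cbind, HList)
}

#' Initialize the full model
#'
#' @param inputDims named integer vector of per-modality input widths.
#' @param layerDims,a,K shared branch hyperparameters (see
#'   [branchConfig()]).
#' @param flags ablation flags; `no_macm` replaces every MACM layer by
#'   a plain single-scale graph convolution (K = 1).
#' @return Model state: per-modality configs and parameter trees.
#' @export
modelInit <- function(inputDims, layerDims = c(256, 128, 64), a = 0.5,
                      K = 4, flags = character()) {
  if ("no_macm" %in% flags) K <- 1L
  configs <- lapply(inputDims, function(d)
    branchConfig(d, layerDims, a, K))
  params <- lapply(configs, branchInit)
  list(configs = configs, params = params, flags = flags,
       modalities = names(inputDims))
}

#' Full model forward pass
#'
#' Runs every modality branch and concatenates the branch embeddings.
#'
#' @param xList named list of preprocessed modality matrices.
#' @param Anorm normalized adjacency.
#' @param state model state from [modelInit()].
#' @return An embedding set: per-modality branch outputs plus the
#'   fused `Z`.
#' @export
modelForward <- function(xList, Anorm, state) {
  branches <- lapply(names(xList), function(nm)
    branchForward(xList[[nm]], Anorm, state$params[[nm]],
                  state$configs[[nm]], state$flags))
  names(branches) <- names(xList)
  Z <- fuseOmics(lapply(branches, `[[`, "H"))
  list(branches = branches, Z = Z)
}
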