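test_that("autoencoder forward matches a hand-rolled layer-by-layer oracle", {
  set.seed(71)
  cfg <- branchConfig(4, c(5, 3, 2))
  par <- branchInit(cfg)
  x <- matrix(rnorm(20), 5, 4)
  out <- autoencoderForward(x, par)
  lrelu <- function(z) pmax(z, 0) + 0.01 * pmin(z, 0)
  aff <- function(h, l) sweep(h %*% l$W, 2, drop(l$b), `+`)
  h1 <- lrelu(aff(x, par$enc[[1]]))
  h2 <- lrelu(aff(h1, par$enc[[2]]))
  h3 <- aff(h2, par$enc[[3]])
  g1 <- lrelu(aff(h3, par$dec[[1]]))
  g2 <- lrelu(aff(g1, par$dec[[2]]))
  xr <- aff(g2, par$dec[[3]])
  expect_matrix_equal(out$attrFeats$h1, h1, 1e-12)
  expect_matrix_equal(out$attrFeats$h2, h2, 1e-12)
  expect_matrix_equal(out$attrFeats$hLatent, h3, 1e-12)
  expect_matrix_equal(out$xRecon, xr, 1e-12)

  # zero parameters give zero latent and reconstruction
  par0 <- spaFuse:::treeMap(function(m) m * 0, par)
  out0 <- autoencoderForward(x, par0)
  expect_equal(max(abs(out0$attrFeats$hLatent)), 0)
  expect_equal(max(abs(out0$xRecon)), 0)

  # identity-initialized square toy on positive input: latent = x
  cfgI <- branchConfig(2, c(2, 2, 2))
  parI <- branchInit(cfgI)
  for (i in 1:3) {
    parI$enc[[i]]$W <- diag(2); parI$enc[[i]]$b[] <- 0
    parI$dec[[i]]$W <- diag(2); parI$dec[[i]]$b[] <- 0
  }
  xp <- matrix(abs(rnorm(8)) + 0.1, 4, 2)
  outI <- autoencoderForward(xp, parI)
  expect_matrix_equal(outI$attrFeats$hLatent, xp, 1e-12)
  expect_matrix_equal(outI$xRecon, xp, 1e-12)
})

test_that("graph encoder mixing follows the multi-step fusion equations", {
  set.seed(73)
  n <- 6
  g <- randomGraph(n)
  An <- normAdjacency(g)
  cfg <- branchConfig(4, c(5, 3, 2), a = 0.5, K = 2)
  par <- branchInit(cfg)
  x <- matrix(rnorm(n * 4), n, 4)
  ae <- autoencoderForward(x, par)

  # literal-equation oracle at a = 0.5
  ge <- graphEncoderForward(x, An, ae$attrFeats, par, a = 0.5)
  H1 <- macmForward(x, An, par$genc[[1]])$fused
  in2 <- 0.5 * H1 + 0.5 * ae$attrFeats$h1
  H2 <- macmForward(in2, An, par$genc[[2]])$fused
  in3 <- 0.5 * H2 + 0.5 * ae$attrFeats$h2
  H3 <- macmForward(in3, An, par$genc[[3]])$fused
  expect_matrix_equal(ge$structFeats$H1, H1, 1e-10)
  expect_matrix_equal(ge$structFeats$H3, H3, 1e-10)
  expect_matrix_equal(ge$H, 0.5 * H3 + 0.5 * ae$attrFeats$hLatent,
                      1e-10)

  # a = 0: the branch embedding is exactly the autoencoder latent
  ge0 <- graphEncoderForward(x, An, ae$attrFeats, par, a = 0)
  expect_matrix_equal(ge0$H, ae$attrFeats$hLatent, 1e-12)

  # a = 1: output ignores the attribute features entirely
  ge1 <- graphEncoderForward(x, An, ae$attrFeats, par, a = 1)
  other <- lapply(ae$attrFeats, function(m) m + 100)
  ge1b <- graphEncoderForward(x, An, other, par, a = 1)
  expect_matrix_equal(ge1$H, ge1b$H, 1e-12)

  # zeroed attribute features (the attribute-information ablation)
  geZ <- graphEncoderForward(x, An, ae$attrFeats, par, a = 0.5,
                             zeroAttr = TRUE)
  zeroF <- lapply(ae$attrFeats, function(m) m * 0)
  geZo <- graphEncoderForward(x, An, zeroF, par, a = 0.5)
  expect_matrix_equal(geZ$H, geZo$H, 1e-12)
})

test_that("graph decoder mirrors widths and is permutation-equivariant", {
  set.seed(79)
  n <- 7L
  g <- randomGraph(n)
  An <- normAdjacency(g)
  cfg <- branchConfig(6, c(5, 4, 3), K = 2)
  par <- branchInit(cfg)
  H <- matrix(rnorm(n * 3), n, 3)
  out <- graphDecoderForward(H, An, par)
  expect_identical(dim(out$Z), c(n, 6L))

  perm <- sample(n)
  P <- diag(n)[perm, ]
  Anp <- Matrix::Matrix(P %*% as.matrix(An) %*% t(P), sparse = TRUE)
  outP <- graphDecoderForward(H[perm, ], Anp, par)
  expect_matrix_equal(outP$Z, out$Z[perm, ], 1e-8)
})

test_that("omics fusion concatenates in fixed order and round-trips", {
  A <- matrix(1:6, 3, 2)
  B <- matrix(7:12, 3, 2)
  Z <- fuseOmics(list(rna = A, adt = B))
  expect_identical(dim(Z), c(3L, 4L))
  expect_identical(Z[, 1:2], A)
  expect_identical(Z[, 3:4], B)
  expect_identical(fuseOmics(list(only = A)), A)
  expect_error(fuseOmics(list(A, matrix(0, 4, 2))), "mismatch")
})

test_that("model forward populates consistent shapes and is seed-deterministic", {
  fx <- tinyDataset()
  set.seed(83)
  st <- modelInit(vapply(fx$xl, ncol, 0L), layerDims = c(8, 5, 3),
                  K = 2)
  fw <- modelForward(fx$xl, normAdjacency(fx$g), st)
  n <- nrow(fx$xl[[1]])
  expect_identical(dim(fw$Z), c(n, 6L))
  for (nm in names(fx$xl)) {
    br <- fw$branches[[nm]]
    expect_identical(dim(br$xRecon), dim(fx$xl[[nm]]))
    expect_identical(dim(br$Zomics), dim(fx$xl[[nm]]))
    expect_identical(ncol(br$H), 3L)
  }
  # single modality: Z is the lone branch embedding
  st1 <- modelInit(c(omics1 = ncol(fx$xl[[1]])),
                   layerDims = c(8, 5, 3), K = 2)
  fw1 <- modelForward(fx$xl[1], normAdjacency(fx$g), st1)
  expect_identical(ncol(fw1$Z), 3L)

  # same seed, same init, same forward
  set.seed(83)
  st2 <- modelInit(vapply(fx$xl, ncol, 0L), layerDims = c(8, 5, 3),
                   K = 2)
  fw2 <- modelForward(fx$xl, normAdjacency(fx$g), st2)
  expect_identical(fw$Z, fw2$Z)
})

test_that("branch backward matches finite differences through all paths", {
  set.seed(89)
  n <- 5
  g <- randomGraph(n)
  An <- normAdjacency(g)
  cfg <- branchConfig(4, c(4, 3, 2), a = 0.4, K = 2)
  par <- branchInit(cfg)
  x <- matrix(rnorm(n * 4), n, 4)
  # composite scalar loss touching H, Zomics and xRecon
  lossOf <- function(par) {
    fw <- branchForward(x, An, par, cfg)
    sum(fw$H^2) + sum(fw$Zomics^2) + sum(fw$xRecon^2)
  }
  fw <- branchForward(x, An, par, cfg)
  grads <- spaFuse:::branchBackward(fw, An, par, dH = 2 * fw$H,
                          dZomics = 2 * fw$Zomics,
                          dxRecon = 2 * fw$xRecon)
  eps <- 1e-6
  paths <- list(c("enc", 1, "W"), c("enc", 3, "b"), c("dec", 2, "W"),
                c("genc", 1, "Ws", 2), c("genc", 3, "mlp", "W2"),
                c("gdec", 2, "Ws", 1), c("gdec", 3, "mlp", "W1"))
  getL <- function(tree, path) {
    for (p in path)
      tree <- tree[[if (grepl("^[0-9]+$", p)) as.integer(p) else p]]
    tree
  }
  setL <- function(tree, path, idx, v) {
    p <- path[1]
    key <- if (grepl("^[0-9]+$", p)) as.integer(p) else p
    if (length(path) == 1) tree[[key]][idx] <- v
    else tree[[key]] <- setL(tree[[key]], path[-1], idx, v)
    tree
  }
  for (path in paths) {
    leaf <- getL(par, path)
    idx <- sample(length(leaf), 1)
    p2 <- setL(par, path, idx, leaf[idx] + eps)
    p3 <- setL(par, path, idx, leaf[idx] - eps)
    fd <- (lossOf(p2) - lossOf(p3)) / (2 * eps)
    an <- getL(grads, path)[idx]
    expect_equal(an, fd, tolerance = 1e-3,
                 label = paste(path, collapse = "/"))
  }
})
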