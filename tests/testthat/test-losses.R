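test_that("reconstruction loss is a per-modality entry-mean MSE", {
  x <- matrix(rnorm(12), 3, 4)
  expect_equal(reconLoss(x, x), 0)
  expect_equal(reconLoss(matrix(0, 1, 2), matrix(1, 1, 2)), 1)
  r <- matrix(rnorm(12), 3, 4)
  expect_equal(reconLoss(x, x + 2 * r), 4 * reconLoss(x, x + r))
  # sums across modalities; per-spot convention divides by n only
  expect_equal(reconLoss(list(x, x), list(x + r, x)),
               reconLoss(x, x + r))
  expect_equal(reconLoss(x, x + r, perSpot = TRUE),
               sum(r^2) / nrow(x))
  expect_error(reconLoss(x, matrix(0, 2, 2)), "shape")
})

test_that("graph reconstruction loss targets the neighbor-aggregated input", {
  # 3-node path graph hand oracle
  A <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  g <- spaFuse:::.newGraph(Matrix::Matrix(A, sparse = TRUE), 1L)
  An <- as.matrix(normAdjacency(g))
  x <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2)
  tgt <- An %*% x
  Z <- tgt + 1
  expect_equal(graphReconLoss(Z, normAdjacency(g), x), 1)
  expect_equal(graphReconLoss(tgt, normAdjacency(g), x), 0)
  byHand <- mean((Z - tgt)^2)
  expect_equal(graphReconLoss(Z, normAdjacency(g), x), byHand)

  # edgeless graph: Anorm = I, reduces to plain MSE
  g0 <- spaFuse:::.newGraph(Matrix::Matrix(0, 3, 3, sparse = TRUE), 1L)
  expect_equal(graphReconLoss(Z, normAdjacency(g0), x),
               mean((Z - x)^2))
})

test_that("structural BCE matches the scalar double-loop oracle", {
  # zero embedding: all probabilities 1/2
  A <- randomAdjacency(4)
  expect_equal(structuralBce(matrix(0, 4, 2), A), log(2))

  set.seed(97)
  Z <- matrix(rnorm(8), 4, 2)
  expect_equal(structuralBce(Z, A), bceOracle(Z, A), tolerance = 1e-12)

  # perfect-separation limit: when the off-diagonal Gram signs match
  # the adjacency, scaling Z sends the off-diagonal BCE to zero. The
  # diagonal (target 0, Gram always >= 0) keeps a floor, so the limit
  # is tested on the off-diagonal contribution.
  Zp <- matrix(c(1, 1, -1, -1) / 2, 4, 1)
  Ap <- matrix(0, 4, 4); Ap[1, 2] <- Ap[2, 1] <- Ap[3, 4] <- Ap[4, 3] <- 1
  offDiagBce <- function(Z) {
    n <- nrow(Z)
    P <- pmin(pmax(plogis(tcrossprod(Z)), 1e-7), 1 - 1e-7)
    contrib <- Ap * log(P) + (1 - Ap) * log(1 - P)
    -(sum(contrib) - sum(diag(contrib))) / n^2
  }
  expect_lt(offDiagBce(Zp * 6), offDiagBce(Zp * 2))
  expect_lt(offDiagBce(Zp * 20), 1e-3)
  # and the exported loss equals off-diagonal + diagonal parts
  dPart <- -sum(log(1 - pmin(plogis(rowSums(Zp^2)), 1 - 1e-7))) / 16
  expect_equal(structuralBce(Zp, Ap), offDiagBce(Zp) + dPart)

  # permutation invariance
  perm <- sample(4)
  expect_equal(structuralBce(Z[perm, ], A[perm, perm]),
               structuralBce(Z, A))
})

test_that("InfoNCE follows the printed negatives-only form", {
  # identical embeddings: every ratio is pos-count / neg-count
  Z <- matrix(1, 3, 2)
  nbr <- list(2L, 1L, 1L)  # each spot: one positive, one negative
  expect_equal(infonceLoss(Z, nbr, tau = 0.7), 0)

  # aligned positives (cos 1), orthogonal negatives (cos 0), tau = 1:
  # per-spot term -log(e / 2) = -1 + log 2 with two negatives each
  Z2 <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  nbr2 <- list(2L, 1L, 4L, 3L)
  expect_equal(infonceLoss(Z2, nbr2, tau = 1), -1 + log(2))

  # brute-force double-loop oracle on a random instance
  set.seed(101)
  Z3 <- matrix(rnorm(12), 6, 2)
  g <- randomGraph(6)
  nbr3 <- neighborSets(g)
  expect_equal(infonceLoss(Z3, nbr3, tau = 0.5),
               infonceOracle(Z3, nbr3, 0.5), tolerance = 1e-8)
  expect_equal(infonceLoss(Z3, nbr3, tau = 0.5, standardInfonce = TRUE),
               infonceOracle(Z3, nbr3, 0.5, standard = TRUE),
               tolerance = 1e-8)

  # empty neighbor / negative sets are rejected with the spot named
  expect_error(infonceLoss(Z, list(integer(), 1L, 1L), 1), "1")
  expect_error(infonceLoss(Z, list(c(2L, 3L), 1L, 1L), 1),
               "negatives")

  # monotonicity: raising one positive pair's cosine, with every
  # other pairwise cosine pinned at 0 by orthogonal constructions,
  # strictly lowers the loss
  zAt <- function(theta) rbind(c(1, 0, 0),
                               c(cos(theta), sin(theta), 0),
                               c(0, 0, 1))
  nbrM <- list(2L, 1L, 1L)
  lossAt <- function(theta) infonceLoss(zAt(theta), nbrM, tau = 0.5)
  expect_lt(lossAt(pi / 6), lossAt(pi / 3))
  expect_lt(lossAt(pi / 12), lossAt(pi / 6))
})

test_that("total loss sums the four components and honors ablations", {
  fx <- tinyDataset(nSide = 4, seed = 103, nFeatures = c(6, 5))
  set.seed(104)
  st <- modelInit(vapply(fx$xl, ncol, 0L), layerDims = c(5, 4, 3),
                  K = 2)
  fw <- modelForward(fx$xl, normAdjacency(fx$g), st)
  xr <- lapply(fw$branches, `[[`, "xRecon")
  zo <- lapply(fw$branches, `[[`, "Zomics")
  bl <- totalLoss(fx$xl, xr, zo, fw$Z, fx$g, tau = 1)
  expect_equal(bl$total, bl$L_R + bl$L_G + bl$L_S + bl$L_con)
  expect_gte(bl$L_R, 0); expect_gte(bl$L_G, 0); expect_gte(bl$L_S, 0)
  expect_equal(bl$L_R, reconLoss(fx$xl, xr))
  expect_equal(bl$L_S, structuralBce(fw$Z, adjacency(fx$g)))

  blN <- totalLoss(fx$xl, xr, zo, fw$Z, fx$g, flags = "no_nce")
  expect_equal(blN$L_con, 0)
  blB <- totalLoss(fx$xl, xr, zo, fw$Z, fx$g, flags = "no_bce")
  expect_equal(blB$L_S, 0)
  expect_equal(blB$total, blB$L_R + blB$L_G + blB$L_con)
})

test_that("training gradients of the total loss match finite differences", {
  fx <- tinyDataset(nSide = 4, seed = 107, nFeatures = c(6, 5))
  set.seed(108)
  st <- modelInit(vapply(fx$xl, ncol, 0L), layerDims = c(5, 4, 3),
                  K = 2)
  cfg <- trainConfig(epochs = 1, layerDims = c(5, 4, 3), K = 2,
                     seed = 108)
  lg <- spaFuse:::.lossAndGrads(fx$xl, fx$g, st, cfg)
  lossAt <- function(st) spaFuse:::.lossAndGrads(fx$xl, fx$g, st,
                                                 cfg)$losses$total
  eps <- 1e-6
  for (probe in 1:10) {
    nm <- sample(names(st$params), 1)
    leafIdx <- sample(c("encW", "decW", "gencW", "mlp"), 1)
    st2 <- st; st3 <- st
    if (leafIdx == "encW") {
      l <- sample(3, 1); idx <- sample(length(st$params[[nm]]$enc[[l]]$W), 1)
      st2$params[[nm]]$enc[[l]]$W[idx] <- st$params[[nm]]$enc[[l]]$W[idx] + eps
      st3$params[[nm]]$enc[[l]]$W[idx] <- st$params[[nm]]$enc[[l]]$W[idx] - eps
      an <- lg$grads[[nm]]$enc[[l]]$W[idx]
    } else if (leafIdx == "decW") {
      l <- sample(3, 1); idx <- sample(length(st$params[[nm]]$dec[[l]]$W), 1)
      st2$params[[nm]]$dec[[l]]$W[idx] <- st$params[[nm]]$dec[[l]]$W[idx] + eps
      st3$params[[nm]]$dec[[l]]$W[idx] <- st$params[[nm]]$dec[[l]]$W[idx] - eps
      an <- lg$grads[[nm]]$dec[[l]]$W[idx]
    } else if (leafIdx == "gencW") {
      l <- sample(3, 1); k <- sample(2, 1)
      idx <- sample(length(st$params[[nm]]$genc[[l]]$Ws[[k]]), 1)
      st2$params[[nm]]$genc[[l]]$Ws[[k]][idx] <-
        st$params[[nm]]$genc[[l]]$Ws[[k]][idx] + eps
      st3$params[[nm]]$genc[[l]]$Ws[[k]][idx] <-
        st$params[[nm]]$genc[[l]]$Ws[[k]][idx] - eps
      an <- lg$grads[[nm]]$genc[[l]]$Ws[[k]][idx]
    } else {
      l <- sample(3, 1)
      idx <- sample(length(st$params[[nm]]$gdec[[l]]$mlp$W1), 1)
      st2$params[[nm]]$gdec[[l]]$mlp$W1[idx] <-
        st$params[[nm]]$gdec[[l]]$mlp$W1[idx] + eps
      st3$params[[nm]]$gdec[[l]]$mlp$W1[idx] <-
        st$params[[nm]]$gdec[[l]]$mlp$W1[idx] - eps
      an <- lg$grads[[nm]]$gdec[[l]]$mlp$W1[idx]
    }
    fd <- (lossAt(st2) - lossAt(st3)) / (2 * eps)
    expect_equal(an, fd, tolerance = 1e-3)
  }
})
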