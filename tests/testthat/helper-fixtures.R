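# Shared fixtures and small oracles for the test suite.

# tiny two-modality dataset with a graph, for model-level tests
tinyDataset <- function(nSide = 6, seed = 42, nFeatures = c(12, 10)) {
  ds <- makeLayered(nSide = nSide, nDomains = 2, nFeatures = nFeatures,
                    seed = seed)
  g <- buildKnnGraph(ds, k = 2)
  xl <- lapply(modalities(ds), function(m) {
    v <- spaFuse::values(m)
    v / stats::sd(v)
  })
  list(ds = ds, g = g, xl = xl)
}

# random symmetric binary adjacency with zero diagonal
randomAdjacency <- function(n, p = 0.3) {
  A <- matrix(stats::rbinom(n * n, 1, p), n, n)
  A[lower.tri(A, diag = TRUE)] <- 0
  A <- A + t(A)
  A
}

randomGraph <- function(n, p = 0.3) {
  A <- randomAdjacency(n, p)
  # guarantee every spot one neighbor and one non-neighbor
  for (i in seq_len(n)) {
    if (sum(A[i, ]) == 0) {
      j <- if (i == 1) 2 else i - 1
      A[i, j] <- A[j, i] <- 1
    }
    if (sum(A[i, ]) >= n - 1) {
      j <- if (i == 1) 2 else i - 1
      A[i, j] <- A[j, i] <- 0
    }
  }
  spaFuse:::.newGraph(Matrix::Matrix(A, sparse = TRUE), 1L)
}

# scalar double-loop InfoNCE oracle (printed form)
infonceOracle <- function(Z, nbrSets, tau, standard = FALSE) {
  n <- nrow(Z)
  cosij <- function(i, j) {
    sum(Z[i, ] * Z[j, ]) /
      (sqrt(sum(Z[i, ]^2)) * sqrt(sum(Z[j, ]^2)))
  }
  tot <- 0
  for (i in seq_len(n)) {
    num <- 0; den <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      e <- exp(cosij(i, j) / tau)
      if (j %in% nbrSets[[i]]) num <- num + e
      if (standard || !(j %in% nbrSets[[i]])) den <- den + e
    }
    tot <- tot + log(num / den)
  }
  -tot / n
}

# scalar double-loop structural BCE oracle
bceOracle <- function(Z, A, eps = 1e-7) {
  n <- nrow(Z)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    p <- 1 / (1 + exp(-sum(Z[i, ] * Z[j, ])))
    p <- min(max(p, eps), 1 - eps)
    tot <- tot + A[i, j] * log(p) + (1 - A[i, j]) * log(1 - p)
  }
  -tot / n^2
}

# dense matrix-power MACM oracle
macmOracle <- function(X, AnormDense, par) {
  K <- length(par$Ws)
  n <- nrow(X)
  hs <- lapply(seq_len(K), function(k) {
    Ak <- diag(n)
    for (s in seq_len(k)) Ak <- Ak %*% AnormDense
    Ak %*% tanh(X %*% par$Ws[[k]])
  })
  hm <- unlist(lapply(hs, colMeans))
  if (K == 1) {
    w <- 1
  } else {
    u <- tanh(drop(hm %*% par$mlp$W1) + drop(par$mlp$b1))
    logits <- drop(u %*% par$mlp$W2) + drop(par$mlp$b2)
    e <- exp(logits - max(logits))
    w <- e / sum(e)
  }
  Reduce(`+`, lapply(seq_len(K), function(k) hs[[k]] * w[k]))
}

expect_matrix_equal <- function(a, b, tol = 1e-8) {
  expect_lt(max(abs(a - b)), tol)
}
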