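test_that("K-means domain calling is seeded and canonically relabeled", {
  set.seed(137)
  Z <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 8), 20, 2))
  truth <- rep(0:1, each = 20)
  lab <- kmeansDomains(Z, 2, seed = 2020)
  expect_equal(ariScore(lab, truth), 1)
  expect_identical(lab, kmeansDomains(Z, 2, seed = 2020))
  expect_identical(lab[1], 0L)  # first-occurrence relabeling
  expect_error(kmeansDomains(Z, 1, seed = 1), "nClusters")
  expect_error(kmeansDomains(Z, 41, seed = 1), "exceeds")
})

test_that("pair counts classify all spot pairs per the a/b/c/d definitions", {
  pc <- pairCounts(c(0, 0, 1, 1), c(0, 1, 0, 1))
  expect_equal(pc, list(a = 0, b = 2, c = 2, d = 2))
  pcSame <- pairCounts(c(1, 1, 2, 2), c(5, 5, 6, 6))
  expect_equal(pcSame$b + pcSame$c, 0)
  set.seed(139)
  for (r in 1:5) {
    p <- sample(0:3, 30, replace = TRUE)
    t <- sample(0:2, 30, replace = TRUE)
    pc <- pairCounts(p, t)
    expect_equal(pc$a + pc$b + pc$c + pc$d, choose(30, 2))
  }
  expect_error(pairCounts(1:3, 1:4), "length")
})

test_that("pair-count ARI matches the printed formula and the standard form", {
  expect_equal(ariScore(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)
  expect_equal(ariScore(c(0, 1, 2, 0), c(5, 7, 9, 5)), 1)
  expect_warning(one <- ariScore(rep(1, 5), rep(2, 5)), "degenerate")
  expect_equal(one, 1)
  # equivalence with the Hubert-Arabie implementation in mclust
  skip_if_not_installed("mclust")
  set.seed(149)
  for (r in 1:200) {
    p <- sample(0:sample(1:5, 1), 40, replace = TRUE)
    t <- sample(0:sample(1:5, 1), 40, replace = TRUE)
    expect_equal(ariScore(p, t), mclust::adjustedRandIndex(p, t),
                 tolerance = 1e-12)
  }
})

test_that("information-theoretic metrics are exact on identical partitions", {
  p <- sample(0:3, 50, replace = TRUE)
  relab <- c(9, 7, 5, 3)[p + 1]
  for (f in list(ariScore, nmiScore, amiScore, homogeneityScore,
                 completenessScore))
    expect_equal(f(relab, p), 1)
  # symmetry where mathematically symmetric
  q <- sample(0:2, 50, replace = TRUE)
  expect_equal(nmiScore(p, q), nmiScore(q, p))
  expect_equal(amiScore(p, q), amiScore(q, p))
  expect_equal(ariScore(p, q), ariScore(q, p))
  expect_equal(homogeneityScore(p, q), completenessScore(q, p))
})

test_that("MI on a 2x2 contingency toy equals the scalar oracle", {
  # pred: 0 0 1 1 1; truth: 0 1 0 1 1 -> contingency rows (1,1),(1,2)
  p <- c(0, 0, 1, 1, 1); t <- c(0, 1, 0, 1, 1)
  ct <- table(p, t)
  n <- 5
  miHand <- 0
  for (i in 1:2) for (j in 1:2) {
    pij <- ct[i, j] / n
    if (pij > 0)
      miHand <- miHand +
        pij * log(pij / ((sum(ct[i, ]) / n) * (sum(ct[, j]) / n)))
  }
  expect_equal(spaFuse:::.mutualInfo(ct), miHand)
  hu <- spaFuse:::.entropy(rowSums(ct))
  hv <- spaFuse:::.entropy(colSums(ct))
  expect_equal(nmiScore(p, t), 2 * miHand / (hu + hv))
})

test_that("AMI is chance-corrected: near zero for independent labelings", {
  set.seed(151)
  n <- 500
  p <- sample(0:4, n, replace = TRUE)
  t <- sample(0:4, n, replace = TRUE)
  ami <- amiScore(p, t)
  nmi <- nmiScore(p, t)
  expect_lt(abs(ami), 0.05)
  expect_gt(nmi, ami)
})

test_that("Hungarian matching equals brute-force assignment enumeration", {
  # label permutation is recovered exactly
  t <- sample(0:3, 60, replace = TRUE)
  p <- c(3, 0, 2, 1)[t + 1]
  map <- hungarianMatch(p, t)
  expect_identical(unname(map[as.character(c(3, 0, 2, 1))]),
                   as.character(0:3))

  set.seed(157)
  for (r in 1:10) {
    p <- sample(0:2, 25, replace = TRUE)
    t <- sample(0:1, 25, replace = TRUE)
    ct <- table(p, t)
    map <- hungarianMatch(p, t)
    # total matched overlap
    ov <- sum(vapply(rownames(ct), function(r2) {
      m <- map[r2]
      if (is.na(m)) 0 else ct[r2, m]
    }, 0))
    # enumerate all injections of truth columns into pred rows
    best <- 0
    perms <- function(v) if (length(v) <= 1) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(rest) c(v[i], rest))))
    for (rows in perms(seq_len(nrow(ct)))) {
      tot <- sum(vapply(seq_len(ncol(ct)), function(j)
        ct[rows[j], j], 0))
      best <- max(best, tot)
    }
    expect_equal(ov, best)
    # one-to-one: no truth label matched twice
    expect_false(any(duplicated(stats::na.omit(map))))
  }
})

test_that("per-domain F1 scores the Hungarian-matched cluster", {
  t <- rep(c(0, 1, 2), times = c(10, 10, 10))
  expect_equal(domainF1(t, t, 2), 1)
  # predicted cluster covers half the true domain and nothing else:
  # precision 1, recall 0.5 -> F1 = 2/3
  p <- t
  p[t == 2] <- c(rep(9, 5), rep(1, 5))
  expect_equal(domainF1(p, t, 2), 2 / 3)
  # invariant to relabeling non-target domains
  p2 <- p; p2[p == 0] <- 7
  expect_equal(domainF1(p2, t, 2), domainF1(p, t, 2))
  expect_error(domainF1(p, t, 42), "absent")
})

test_that("Wilcoxon marker ranking finds perfect markers and matches rank sums", {
  set.seed(163)
  lab <- rep(0:1, each = 8)
  X <- matrix(rpois(16 * 6, 5), 16, 6,
              dimnames = list(NULL, sprintf("f%d", 1:6)))
  X[, 3] <- ifelse(lab == 0, 50, 0) + rpois(16, 1)  # domain-0 marker
  mk <- rankMarkersWilcoxon(X, lab, topN = 3)
  expect_identical(mk$feature[mk$domain == 0][1], "f3")
  expect_identical(max(mk$rank), 3L)
  expect_true(all(c("statistic", "p", "q") %in% names(mk)))

  # 4-vs-4 rank-sum statistic equals the exhaustive rank computation
  x <- c(1.2, 3.4, 2.2, 5.1, 0.3, 0.9, 2.0, 4.4)
  grp <- rep(0:1, each = 4)
  W <- unname(wilcox.test(x[grp == 0], x[grp == 1],
                          alternative = "greater", exact = FALSE,
                          correct = FALSE)$statistic)
  ranks <- rank(x)
  expect_equal(W, sum(ranks[grp == 0]) - 4 * 5 / 2)

  # constant features are skipped
  Xc <- cbind(X, const = 1)
  mkc <- rankMarkersWilcoxon(Xc, lab)
  expect_false("const" %in% mkc$feature)
  expect_error(rankMarkersWilcoxon(X, rep(0, 16)), "2 domains")
})
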