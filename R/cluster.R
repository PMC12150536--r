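# Domain calling and clustering evaluation: K-means on the fused
# embedding, pair-count metrics (ARI), information-theoretic metrics
# (NMI, AMI, homogeneity, completeness), Hungarian matching and
# per-domain F1, and Wilcoxon marker ranking.

#' K-means spatial domain calling
#'
#' Seeded K-means with multiple restarts on the fused embedding.
#' Labels are relabeled to 0..K-1 by first occurrence so runs are
#' comparable.
#'
#' @param Z spots x d embedding matrix.
#' @param nClusters number of domains (>= 2, supplied by the user).
#' @param seed RNG seed for the restarts.
#' @param nStart restarts (default 10).
#' @return Integer vector of 0-based domain labels.
#' @export
kmeansDomains <- function(Z, nClusters, seed = 2020, nStart = 10) {
  Z <- as.matrix(Z)
  if (nClusters < 2) stop("nClusters must be >= 2")
  if (nClusters > nrow(Z))
    stop("nClusters (", nClusters, ") exceeds the spot count (",
         nrow(Z), ")")
  if (any(!is.finite(Z))) stop("embedding contains non-finite values")
  set.seed(seed)
  km <- stats::kmeans(Z, centers = nClusters, nstart = nStart,
                      iter.max = 100)
  relabelByFirstOccurrence(km$cluster)
}

#' @rdname kmeansDomains
#' @param labels any integer/factor labeling to canonicalize.
#' @export
relabelByFirstOccurrence <- function(labels) {
  u <- unique(labels)
  match(labels, u) - 1L
}

#' Pair counts between two partitions
#'
#' Classifies all N(N-1)/2 spot pairs: `a` same cluster in both truth
#' and prediction, `b` same in truth only, `c` same in prediction
#' only, `d` same in neither.
#'
#' @param pred,truth equal-length label vectors.
#' @return list with `a`, `b`, `c`, `d`.
#' @export
pairCounts <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("pred (", length(pred), ") and truth (", length(truth),
         ") differ in length")
  ct <- table(pred, truth)
  choose2 <- function(x) sum(x * (x - 1) / 2)
  a <- choose2(ct)
  sameTruth <- choose2(colSums(ct))
  samePred <- choose2(rowSums(ct))
  n <- length(pred)
  tot <- n * (n - 1) / 2
  b <- sameTruth - a
  cc <- samePred - a
  list(a = a, b = b, c = cc, d = tot - a - b - cc)
}

#' Adjusted Rand index (pair-count form)
#'
#' `ARI = 2(ad - bc) / ((a+b)(b+d) + (a+c)(c+d))` over the pair counts
#' of [pairCounts()]; equals 1 for identical partitions (up to label
#' permutation). When both partitions are a single cluster the
#' denominator vanishes and 1 is returned by convention, with a
#' warning.
#'
#' @param pred,truth equal-length label vectors.
#' @return Scalar in [-1, 1].
#' @export
ariScore <- function(pred, truth) {
  pc <- pairCounts(pred, truth)
  den <- (pc$a + pc$b) * (pc$b + pc$d) + (pc$a + pc$c) * (pc$c + pc$d)
  if (den == 0) {
    warning("degenerate partitions (denominator 0); returning 1")
    return(1)
  }
  2 * (pc$a * pc$d - pc$b * pc$c) / den
}

.entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

.mutualInfo <- function(ct) {
  n <- sum(ct)
  mi <- 0
  rs <- rowSums(ct); cs <- colSums(ct)
  for (i in seq_len(nrow(ct))) for (j in seq_len(ncol(ct))) {
    nij <- ct[i, j]
    if (nij > 0)
      mi <- mi + (nij / n) * log(nij * n / (rs[i] * cs[j]))
  }
  unname(mi)
}

# exact expected mutual information under the hypergeometric
# permutation model
.expectedMI <- function(ct) {
  n <- sum(ct)
  rs <- rowSums(ct); cs <- colSums(ct)
  emi <- 0
  for (ai in rs) for (bj in cs) {
    lo <- max(1, ai + bj - n)
    hi <- min(ai, bj)
    if (lo > hi) next
    for (nij in lo:hi) {
      term <- (nij / n) * log(n * nij / (ai * bj))
      lw <- lgamma(ai + 1) + lgamma(bj + 1) + lgamma(n - ai + 1) +
        lgamma(n - bj + 1) - lgamma(n + 1) - lgamma(nij + 1) -
        lgamma(ai - nij + 1) - lgamma(bj - nij + 1) -
        lgamma(n - ai - bj + nij + 1)
      emi <- emi + term * exp(lw)
    }
  }
  unname(emi)
}

#' Information-theoretic clustering metrics
#'
#' `nmiScore` is mutual information normalized by the arithmetic mean
#' of the two label entropies (`2 MI / (H(U) + H(V))`). `amiScore` is
#' the chance-adjusted version, `(MI - E[MI]) / (mean(H) - E[MI])`,
#' with the expected mutual information computed exactly under the
#' hypergeometric permutation model. `homogeneityScore` is
#' `1 - H(truth|pred) / H(truth)` (each predicted domain contains one
#' true domain); `completenessScore` is `1 - H(pred|truth) / H(pred)`.
#' Degenerate conventions: when both partitions are single-cluster all
#' four metrics are 1; when only one is, NMI and AMI are 0 and the
#' conditional-entropy metrics treat `0/0` as 1.
#'
#' @param pred,truth equal-length label vectors.
#' @return Scalar metric value.
#' @export
nmiScore <- function(pred, truth) {
  ct <- table(pred, truth)
  hu <- .entropy(rowSums(ct)); hv <- .entropy(colSums(ct))
  if (hu == 0 && hv == 0) return(1)
  if (hu == 0 || hv == 0) return(0)
  2 * .mutualInfo(ct) / (hu + hv)
}

#' @rdname nmiScore
#' @export
amiScore <- function(pred, truth) {
  ct <- table(pred, truth)
  hu <- .entropy(rowSums(ct)); hv <- .entropy(colSums(ct))
  if (hu == 0 && hv == 0) return(1)
  if (hu == 0 || hv == 0) return(0)
  mi <- .mutualInfo(ct)
  emi <- .expectedMI(ct)
  den <- (hu + hv) / 2 - emi
  if (abs(den) < 1e-15) return(0)
  (mi - emi) / den
}

#' @rdname nmiScore
#' @export
homogeneityScore <- function(pred, truth) {
  ct <- table(pred, truth)
  hv <- .entropy(colSums(ct))
  if (hv == 0) return(1)
  .mutualInfo(ct) / hv
}

#' @rdname nmiScore
#' @export
completenessScore <- function(pred, truth) {
  homogeneityScore(truth, pred)
}

# min-cost assignment via shortest augmenting paths (O(n^3)),
# rectangular with nr <= nc; returns the column assigned to each row
.solveAssignment <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  stopifnot(nr <= nc)
  u <- numeric(nr)
  v <- numeric(nc + 1)
  p <- integer(nc + 1)   # p[j+1]: row matched to column j (0 = free)
  way <- integer(nc)
  for (i in seq_len(nr)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, nc)
    used <- logical(nc + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf; j1 <- 0
      for (j in seq_len(nc)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0] - v[j + 1]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in 0:nc) {
        if (used[j + 1]) {
          if (p[j + 1] > 0) u[p[j + 1]] <- u[p[j + 1]] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  assign <- integer(nr)
  for (j in seq_len(nc)) if (p[j + 1] > 0) assign[p[j + 1]] <- j
  assign
}

#' Hungarian matching of predicted clusters to true domains
#'
#' Finds the one-to-one assignment between predicted cluster labels
#' and true domain labels that maximizes total contingency-table
#' overlap. Surplus predicted clusters (when prediction has more
#' clusters than truth) map to `NA`.
#'
#' @param pred,truth equal-length label vectors.
#' @return Named vector: for each predicted cluster label, the matched
#'   truth label (or NA).
#' @export
hungarianMatch <- function(pred, truth) {
  ct <- table(pred, truth)
  nr <- nrow(ct); nc <- ncol(ct)
  s <- max(nr, nc)
  cost <- matrix(0, s, s)
  cost[seq_len(nr), seq_len(nc)] <- -as.matrix(ct)
  assign <- .solveAssignment(cost)
  predLevels <- rownames(ct)
  truthLevels <- colnames(ct)
  out <- rep(NA_character_, nr)
  for (i in seq_len(nr))
    if (assign[i] <= nc) out[i] <- truthLevels[assign[i]]
  stats::setNames(out, predLevels)
}

#' Per-domain F1 after Hungarian matching
#'
#' Matches predicted clusters to true domains with [hungarianMatch()],
#' then scores the predicted cluster assigned to `targetDomain` as a
#' binary classifier of that domain (precision/recall harmonic mean).
#' Returns 0 when no predicted cluster is matched to the target.
#'
#' @param pred,truth equal-length label vectors.
#' @param targetDomain the true domain of interest (must occur in
#'   truth).
#' @return F1 in [0, 1].
#' @export
domainF1 <- function(pred, truth, targetDomain) {
  if (!as.character(targetDomain) %in% as.character(unique(truth)))
    stop("target domain ", targetDomain, " absent from truth")
  map <- hungarianMatch(pred, truth)
  hit <- names(map)[!is.na(map) & map == as.character(targetDomain)]
  if (!length(hit)) return(0)
  predPos <- as.character(pred) == hit
  truthPos <- as.character(truth) == as.character(targetDomain)
  tp <- sum(predPos & truthPos)
  if (tp == 0) return(0)
  prec <- tp / sum(predPos)
  rec <- tp / sum(truthPos)
  2 * prec * rec / (prec + rec)
}

#' Rank domain markers with one-vs-rest Wilcoxon tests
#'
#' For every domain, each feature is tested domain-vs-rest with a
#' one-sided (greater) Wilcoxon rank-sum test; features are ranked by
#' ascending p-value (ties by descending rank-sum statistic) and the
#' top `topN` are reported with Benjamini-Hochberg q-values. Constant
#' features are skipped.
#'
#' @param X a normalized [OmicsMatrix-class] or a spots x features
#'   matrix.
#' @param labels per-spot domain labels (>= 2 domains, each with >= 2
#'   spots).
#' @param topN markers reported per domain (default 3).
#' @return data.frame with columns domain, feature, statistic, p, q,
#'   rank.
#' @export
rankMarkersWilcoxon <- function(X, labels, topN = 3) {
  if (is(X, "OmicsMatrix")) X <- X@values
  if (nrow(X) != length(labels))
    stop("labels length must match the spot count")
  doms <- sort(unique(labels))
  if (length(doms) < 2) stop("need at least 2 domains")
  if (any(table(labels) < 2)) stop("every domain needs >= 2 spots")
  feats <- colnames(X) %||% sprintf("feat%d", seq_len(ncol(X)))
  out <- list()
  for (d in doms) {
    inD <- labels == d
    stat <- p <- rep(NA_real_, ncol(X))
    for (j in seq_len(ncol(X))) {
      xj <- X[, j]
      if (max(xj) == min(xj)) next  # constant feature: skipped
      wt <- stats::wilcox.test(xj[inD], xj[!inD],
                               alternative = "greater", exact = FALSE,
                               correct = FALSE)
      stat[j] <- unname(wt$statistic)
      p[j] <- wt$p.value
    }
    ok <- !is.na(p)
    q <- rep(NA_real_, ncol(X))
    q[ok] <- stats::p.adjust(p[ok], method = "BH")
    ord <- order(p, -stat, na.last = TRUE)[seq_len(min(topN, sum(ok)))]
    out[[as.character(d)]] <- data.frame(
      domain = d, feature = feats[ord], statistic = stat[ord],
      p = p[ord], q = q[ord], rank = seq_along(ord))
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
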