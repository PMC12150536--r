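# Per-modality preprocessing pipelines.
#
# RNA (high gene coverage): filter genes by spot support -> library-size
# log-normalization -> highly variable gene selection -> PCA.
# Protein (ADT): centered log-ratio -> PCA to n-1 components.
# Chromatin (ATAC peaks): LSI (TF-IDF + truncated SVD).
# Low-coverage panels / generic features: log-normalize -> PCA.
# Every op preserves spot count and order, and advances the
# raw -> normalized -> reduced state machine.

.checkState <- function(X, expected, op) {
  if (!X@state %in% expected)
    stop(op, " expects state ", paste(expected, collapse = "/"),
         ", got '", X@state, "'")
}

#' Remove genes detected in too few spots
#'
#' Drops features with a nonzero value in fewer than `minSpots` spots
#' (default 10, the usual support filter for spot-level transcriptomics).
#'
#' @param X raw [OmicsMatrix-class].
#' @param minSpots minimum number of spots with nonzero counts.
#' @return The filtered [OmicsMatrix-class], still `raw`.
#' @export
filterGenesMinSpots <- function(X, minSpots = 10) {
  .checkState(X, "raw", "filterGenesMinSpots")
  keep <- colSums(X@values != 0) >= minSpots
  if (!any(keep))
    stop("no features remain after filtering at minSpots = ", minSpots)
  OmicsMatrix(X@values[, keep, drop = FALSE], X@modality,
              spotIds = X@spotIds, featureIds = X@featureIds[keep],
              state = "raw")
}

#' Library-size normalization and log transform
#'
#' Scales each spot's counts to `targetSum` total, then applies
#' `log1p`. All-zero spots are left as all-zero rows with a warning.
#'
#' @param X raw [OmicsMatrix-class] of counts.
#' @param targetSum per-spot total after scaling (default 1e4).
#' @return A `normalized` [OmicsMatrix-class].
#' @export
logNormalize <- function(X, targetSum = 1e4) {
  .checkState(X, "raw", "logNormalize")
  tot <- rowSums(X@values)
  zero <- tot == 0
  if (any(zero))
    warning(sum(zero), " spot(s) with zero total count left as zeros")
  sf <- ifelse(zero, 1, tot / targetSum)
  out <- log1p(X@values / sf)
  OmicsMatrix(out, X@modality, spotIds = X@spotIds,
              featureIds = X@featureIds, state = "normalized")
}

#' Select highly variable genes
#'
#' Ranks features by Seurat-flavor normalized dispersion: dispersion
#' (variance / mean) is z-standardized within 20 equal-frequency mean
#' bins, and the top `nTop` features are kept.
#'
#' @param X normalized [OmicsMatrix-class].
#' @param nTop number of features to keep (default 3000).
#' @param nBins mean-expression bins for dispersion standardization.
#' @return The subset [OmicsMatrix-class], still `normalized`.
#' @export
selectHVG <- function(X, nTop = 3000, nBins = 20) {
  .checkState(X, "normalized", "selectHVG")
  p <- ncol(X@values)
  if (nTop >= p) {
    message("selectHVG: nTop >= feature count; keeping all ", p,
            " features")
    return(X)
  }
  mu <- colMeans(X@values)
  v <- apply(X@values, 2, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  nb <- max(1L, min(nBins, floor(p / 2)))
  bins <- if (nb == 1L) rep(1L, p) else
    cut(rank(mu, ties.method = "first"), breaks = nb, labels = FALSE)
  z <- disp
  for (b in unique(bins)) {
    idx <- bins == b
    m <- mean(disp[idx]); s <- stats::sd(disp[idx])
    z[idx] <- if (is.na(s) || s == 0) 0 else (disp[idx] - m) / s
  }
  keep <- order(z, decreasing = TRUE)[seq_len(nTop)]
  keep <- sort(keep)
  OmicsMatrix(X@values[, keep, drop = FALSE], X@modality,
              spotIds = X@spotIds, featureIds = X@featureIds[keep],
              state = "normalized")
}

#' Principal component reduction
#'
#' Exact (deterministic) PCA on centered features; scores are returned
#' as the reduced matrix with columns ordered by decreasing explained
#' variance.
#'
#' @param X normalized [OmicsMatrix-class].
#' @param nComponents number of components; must be smaller than both
#'   the spot and feature counts.
#' @return A `reduced` [OmicsMatrix-class] with `nComponents` columns.
#' @export
pcaReduce <- function(X, nComponents) {
  .checkState(X, "normalized", "pcaReduce")
  n <- nrow(X@values); p <- ncol(X@values)
  if (nComponents < 1 || nComponents >= min(n, p))
    stop("nComponents must be in [1, min(spots, features) - 1], got ",
         nComponents)
  pc <- stats::prcomp(X@values, center = TRUE, scale. = FALSE)
  sc <- pc$x[, seq_len(nComponents), drop = FALSE]
  OmicsMatrix(sc, X@modality, spotIds = X@spotIds,
              featureIds = sprintf("PC%d", seq_len(nComponents)),
              state = "reduced")
}

#' Centered log-ratio normalization for protein counts
#'
#' Per-spot CLR with pseudocount 1:
#' `y_ij = log(1 + p_ij) - mean_j log(1 + p_ij)`. Every output row sums
#' to zero; all-zero spots map to all-zero rows.
#'
#' @param P raw [OmicsMatrix-class] of ADT counts.
#' @return A `normalized` [OmicsMatrix-class].
#' @export
clrNormalize <- function(P) {
  .checkState(P, "raw", "clrNormalize")
  lp <- log1p(P@values)
  out <- lp - rowMeans(lp)
  OmicsMatrix(out, P@modality, spotIds = P@spotIds,
              featureIds = P@featureIds, state = "normalized")
}

#' PCA for protein panels: first n - 1 components
#'
#' Convention for ADT panels with `n` proteins: keep the first `n - 1`
#' principal components of the CLR-normalized matrix.
#'
#' @param P CLR-normalized [OmicsMatrix-class] with `n >= 2` features.
#' @return A `reduced` [OmicsMatrix-class] with `n - 1` columns.
#' @export
adtPCA <- function(P) {
  n <- ncol(P@values)
  if (n < 2) stop("adtPCA needs at least 2 features, got ", n)
  pcaReduce(P, n - 1L)
}

#' Latent semantic indexing for peak counts
#'
#' TF-IDF weighting of the raw peak count matrix followed by truncated
#' SVD: `tf_ij = x_ij / rowsum_i`, `idf_j = log(1 + n / (1 + df_j))`,
#' scores are the left singular vectors scaled by singular values.
#'
#' @param peaks raw [OmicsMatrix-class] of ATAC peak counts.
#' @param nComponents output dimension (default 200).
#' @return A `reduced` [OmicsMatrix-class].
#' @export
lsiReduce <- function(peaks, nComponents = 200) {
  .checkState(peaks, "raw", "lsiReduce")
  x <- peaks@values
  n <- nrow(x); p <- ncol(x)
  if (nComponents < 1 || nComponents > min(n, p))
    stop("nComponents must be in [1, min(spots, features)], got ",
         nComponents)
  rs <- rowSums(x)
  tf <- x / ifelse(rs == 0, 1, rs)
  df <- colSums(x > 0)
  idf <- log(1 + n / (1 + df))
  ti <- sweep(tf, 2, idf, `*`)
  sv <- svd(ti, nu = nComponents, nv = 0)
  sc <- sv$u %*% diag(sv$d[seq_len(nComponents)], nComponents)
  OmicsMatrix(sc, peaks@modality, spotIds = peaks@spotIds,
              featureIds = sprintf("LSI%d", seq_len(nComponents)),
              state = "reduced")
}

#' Run the standard preprocessing pipeline for one modality
#'
#' Dispatches on the modality tag: `rna` runs
#' filter -> log-normalize -> HVG -> PCA (PCA skipped when
#' `nComponents` is NULL, the single-omics convention of working at HVG
#' dimension); `adt` runs CLR -> PCA(n-1); `atac` runs LSI; `generic`
#' (and low-coverage panels) runs log-normalize -> PCA.
#'
#' @param X an [OmicsMatrix-class] in `raw` state.
#' @param nComponents target dimension where PCA/LSI applies; NULL for
#'   the modality default (skip PCA for rna, n-1 for adt, 200 for atac,
#'   20 for generic).
#' @param minSpots,nTop RNA filter and HVG parameters.
#' @return A processed [OmicsMatrix-class].
#' @export
preprocessModality <- function(X, nComponents = NULL, minSpots = 10,
                               nTop = 3000) {
  switch(X@modality,
    rna = {
      X <- selectHVG(logNormalize(filterGenesMinSpots(X, minSpots)),
                     nTop = nTop)
      if (!is.null(nComponents)) X <- pcaReduce(X, nComponents)
      X
    },
    adt = adtPCA(clrNormalize(X)),
    atac = lsiReduce(X, nComponents %||% 200),
    generic = {
      X <- logNormalize(X)
      nc <- nComponents %||% min(20L, ncol(X@values) - 1L)
      pcaReduce(X, nc)
    },
    stop("unknown modality: ", X@modality))
}
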