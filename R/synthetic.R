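# Ground-truthed synthetic spatial multi-omics generators.
#
# Count model: every feature f gets a per-domain log-mean mu_fd
# (baseline 0, markers baseline + signal); a spot's count is
# Poisson(exp(mu_fd + eps)) with eps ~ Normal(0, noise). With
# noise = 0 the Poisson draw is replaced by round(exp(mu_fd)) so the
# noiseless dataset is exactly separable. Geometry is a regular
# nSide x nSide grid in arbitrary units (not a hex lattice).
# Regimes emulated: contiguous layered bands; a plus-shaped domain
# whose two bars are marked in different modalities (recoverable only
# by joint spatial analysis); one domain realized as several discrete
# blobs; multi-slice replicates with slice-specific log-scale batch
# offsets.
#
# Every generator is split into a deterministic "plan" (labels,
# coordinates, log-mean matrices; consumes a seeded RNG prefix) and
# the count-sampling step, so makeMultislice can redraw counts from
# the identical plan and regenerateTruth() is bit-reproducible.

.gridCoords <- function(nSide) {
  cbind(x = rep(seq_len(nSide), times = nSide),
        y = rep(seq_len(nSide), each = nSide))
}

# draw marker feature sets: one random subset per domain per modality
.markerSets <- function(nDomains, nFeatures, frac = 0.2) {
  nMark <- max(2L, round(frac * nFeatures))
  lapply(seq_len(nDomains), function(d) sample.int(nFeatures, nMark))
}

.sampleCounts <- function(mu, noise) {
  if (noise == 0) {
    cnt <- round(exp(mu))
  } else {
    eps <- matrix(stats::rnorm(length(mu), 0, noise), nrow(mu))
    cnt <- matrix(stats::rpois(length(mu), exp(mu + eps)), nrow(mu))
  }
  storage.mode(cnt) <- "double"
  cnt
}

# plan dispatch: seeds the RNG and rebuilds labels/coords/log-means
.truthPlan <- function(params) {
  set.seed(params$seed)
  switch(params$generator,
         makeLayered = .planLayered(params),
         makeCross = .planCross(params),
         makeDiscrete = .planDiscrete(params),
         stop("unknown generator: ", params$generator))
}

.planLayered <- function(p) {
  coords <- .gridCoords(p$nSide)
  band <- pmin(floor((coords[, "y"] - 1) * p$nDomains / p$nSide),
               p$nDomains - 1)
  labels <- as.integer(band)
  muList <- lapply(p$nFeatures, function(nf) {
    mk <- .markerSets(p$nDomains, nf)
    mu <- matrix(0, p$nSide^2, nf)
    for (d in seq_len(p$nDomains))
      mu[labels == d - 1L, mk[[d]]] <- p$signal
    mu
  })
  list(muList = muList, labels = labels, coords = coords)
}

.planCross <- function(p) {
  nBands <- 4L
  nSide <- p$nSide
  coords <- .gridCoords(nSide)
  w <- ceiling(nSide / 6)
  lo <- floor((nSide - w) / 2) + 1L
  hi <- lo + w - 1L
  inHbar <- coords[, "y"] >= lo & coords[, "y"] <= hi
  inVbar <- coords[, "x"] >= lo & coords[, "x"] <= hi
  inCross <- inHbar | inVbar
  band <- pmin(floor((coords[, "y"] - 1) * nBands / nSide), nBands - 1)
  labels <- as.integer(ifelse(inCross, 0L, band + 1L))
  s1 <- 2 * p$signalSplit * p$signal
  s2 <- 2 * (1 - p$signalSplit) * p$signal
  mkMu <- function(nf, crossMask, crossSignal) {
    mk <- .markerSets(nBands + 1L, nf)   # [[1]] = cross markers
    m <- matrix(0, nSide^2, nf)
    for (d in seq_len(nBands))
      m[labels == d, mk[[d + 1L]]] <- p$signal
    # cross spots are baseline in this modality except on the bar it
    # marks: the other arm carries no signature here, so this modality
    # alone cannot link the two arms
    m[crossMask, mk[[1L]]] <- crossSignal
    m
  }
  muList <- list(mkMu(p$nFeatures[1], inHbar, s1),
                 mkMu(p$nFeatures[2], inVbar, s2))
  list(muList = muList, labels = labels, coords = coords,
       masks = list(cross = inCross, hbar = inHbar, vbar = inVbar))
}

.planDiscrete <- function(p) {
  nSide <- p$nSide
  r <- p$radius
  centers <- cbind(nSide * (seq_len(p$nBlobs) - 0.5) / p$nBlobs,
                   nSide * (seq_len(p$nBlobs) - 0.5) / p$nBlobs)
  cdist <- as.matrix(stats::dist(centers))
  diag(cdist) <- Inf
  if (min(cdist) < 2 * r + p$minGap)
    stop("blobs of radius ", r, " would overlap (min center distance ",
         round(min(cdist), 2), ", required ", 2 * r + p$minGap, ")")
  coords <- .gridCoords(nSide)
  blobOf <- rep(0L, nSide^2)
  for (b in seq_len(p$nBlobs)) {
    d2 <- (coords[, "x"] - centers[b, 1])^2 +
      (coords[, "y"] - centers[b, 2])^2
    blobOf[d2 <= r^2] <- b
  }
  half <- coords[, "y"] > nSide / 2
  labels <- as.integer(ifelse(blobOf > 0, 2L, ifelse(half, 1L, 0L)))
  nDom <- 3L
  muList <- lapply(p$nFeatures, function(nf) {
    mk <- .markerSets(nDom, nf)
    m <- matrix(0, nSide^2, nf)
    for (d in seq_len(nDom))
      m[labels == d - 1L, mk[[d]]] <- p$signal
    m
  })
  list(muList = muList, labels = labels, coords = coords,
       blobOf = blobOf, centers = centers)
}

.assembleTruth <- function(plan, noise, params,
                           modNames = c("omics1", "omics2")) {
  mods <- list()
  for (i in seq_along(plan$muList)) {
    cnt <- .sampleCounts(plan$muList[[i]], noise)
    rownames(cnt) <- sprintf("spot%d", seq_len(nrow(cnt)))
    colnames(cnt) <- sprintf("%s_f%d", modNames[i], seq_len(ncol(cnt)))
    mods[[modNames[i]]] <- OmicsMatrix(cnt, "generic")
  }
  SpatialMultiOmics(mods, coords = plan$coords, labels = plan$labels,
                    params = params)
}

#' Layered-band synthetic dataset
#'
#' A regular grid split into `nDomains` horizontal bands (the
#' contiguous-tissue regime). Each domain elevates a random marker
#' subset (20% of features) in each modality by `signal` on the log
#' scale.
#'
#' @param nSide grid side length (nSide^2 spots).
#' @param nDomains number of bands (2..nSide).
#' @param signal log-scale marker effect (default 1.5).
#' @param noise log-normal jitter SD (default 0.3); 0 gives
#'   deterministic counts.
#' @param nFeatures features per modality (one entry per modality).
#' @param seed RNG seed; the recorded params regenerate the dataset
#'   bit-identically via [regenerateTruth()].
#' @return A [SpatialMultiOmics-class] with `trueLabels` and a params
#'   record.
#' @export
makeLayered <- function(nSide = 20, nDomains = 4, signal = 1.5,
                        noise = 0.3, nFeatures = c(50, 50),
                        seed = 2020) {
  if (nDomains > nSide) stop("nDomains must be <= nSide")
  if (nDomains < 2) stop("nDomains must be >= 2")
  params <- list(generator = "makeLayered", nSide = nSide,
                 nDomains = nDomains, signal = signal, noise = noise,
                 nFeatures = nFeatures, seed = seed)
  .assembleTruth(.truthPlan(params), noise, params)
}

#' Cross-shaped synthetic dataset (joint-modality domain)
#'
#' Four horizontal background bands plus a plus-shaped Domain 0. The
#' horizontal bar of the cross carries its marker signature only in
#' modality 1 (vertical-bar spots are baseline there); symmetrically,
#' the vertical bar is marked only in modality 2. Either modality
#' alone therefore sees just one arm of the cross as a marked region
#' and cannot link the two arms into one domain; recovering the full
#' cross requires the joint analysis. `signalSplit` apportions the
#' cross's total marker signal between the modalities (0.5 =
#' symmetric: each bar gets `signal`).
#'
#' @inheritParams makeLayered
#' @param signalSplit fraction of the cross signal in modality 1
#'   (0 < signalSplit < 1).
#' @return A [SpatialMultiOmics-class]; Domain 0 is the cross, domains
#'   1-4 the bands (5 domains in total). The geometry masks are
#'   recoverable via [crossMasks()].
#' @export
makeCross <- function(nSide = 30, signalSplit = 0.5, signal = 1.5,
                      noise = 0.3, nFeatures = c(50, 50),
                      seed = 2020) {
  if (signalSplit <= 0 || signalSplit >= 1)
    stop("signalSplit must lie strictly between 0 and 1")
  params <- list(generator = "makeCross", nSide = nSide,
                 signalSplit = signalSplit, signal = signal,
                 noise = noise, nFeatures = nFeatures, seed = seed)
  .assembleTruth(.truthPlan(params), noise, params)
}

#' Cross geometry masks
#'
#' @param params the params record of a [makeCross()] dataset.
#' @return list of logical masks `cross`, `hbar`, `vbar` over spots.
#' @export
crossMasks <- function(params) .truthPlan(params)$masks

#' Discrete-blob synthetic dataset
#'
#' One domain realized as `nBlobs` spatially separated circular blobs
#' sharing a single marker signature (the discretely distributed
#' same-domain regime); the remaining tissue is two contiguous
#' background domains (upper and lower half). Blob centers sit on the
#' grid diagonal; an error is raised if the requested radius makes
#' blobs approach within `minGap`.
#'
#' @inheritParams makeLayered
#' @param nBlobs number of blobs (>= 2).
#' @param radius blob radius in grid units (default nSide / 8).
#' @param minGap minimum blob-boundary separation (default 2).
#' @return A [SpatialMultiOmics-class]; the blob domain has label 2.
#' @export
makeDiscrete <- function(nSide = 24, nBlobs = 3, signal = 1.5,
                         noise = 0.3, nFeatures = c(50, 50),
                         radius = NULL, minGap = 2, seed = 2020) {
  if (nBlobs < 2) stop("nBlobs must be >= 2")
  params <- list(generator = "makeDiscrete", nSide = nSide,
                 nBlobs = nBlobs, signal = signal, noise = noise,
                 nFeatures = nFeatures,
                 radius = radius %||% max(2, round(nSide / 8)),
                 minGap = minGap, seed = seed)
  .assembleTruth(.truthPlan(params), noise, params)
}

#' Multi-slice synthetic dataset with batch effects
#'
#' Replicates a synthetic base dataset across `nSlices` slices: every
#' slice redraws counts from the base generator's log-mean plan
#' shifted by a slice-specific additive log-scale offset of magnitude
#' `batchScale` (slice offsets are centered and spaced by
#' `batchScale`: slice s gets `batchScale * (s - (nSlices+1)/2)`).
#' This emulates the dominant slice-to-slice technical effect —
#' capture-efficiency differences that scale every feature of a slice
#' — which embedding pipelines are expected to normalize away while
#' preserving domain structure. Coordinates are reused per slice
#' (separate coordinate frames); `sliceIds` is populated and truth
#' labels are tiled.
#'
#' @param base a [SpatialMultiOmics-class] produced by one of the
#'   generators above (its params record is reused).
#' @param nSlices number of slices (>= 2).
#' @param batchScale log-scale batch offset magnitude; 0 gives iid
#'   replicate slices.
#' @param seed RNG seed.
#' @return A multi-slice [SpatialMultiOmics-class].
#' @export
makeMultislice <- function(base, nSlices = 3, batchScale = 0.5,
                           seed = 2020) {
  if (nSlices < 2) stop("nSlices must be >= 2")
  baseParams <- base@params[setdiff(names(base@params), "multislice")]
  plan <- .truthPlan(baseParams)
  noise <- baseParams$noise
  set.seed(seed)
  modNames <- names(modalities(base))
  sliceCounts <- vector("list", nSlices)
  for (s in seq_len(nSlices)) {
    off <- batchScale * (s - (nSlices + 1) / 2)
    sliceCounts[[s]] <- lapply(plan$muList, function(m)
      .sampleCounts(m + off, noise))
  }
  n <- nrow(plan$coords)
  mods <- list()
  for (i in seq_along(modNames)) {
    cnt <- do.call(rbind, lapply(sliceCounts, `[[`, i))
    rownames(cnt) <- sprintf("spot%d", seq_len(nrow(cnt)))
    colnames(cnt) <- sprintf("%s_f%d", modNames[i], seq_len(ncol(cnt)))
    mods[[modNames[i]]] <- OmicsMatrix(cnt, "generic")
  }
  SpatialMultiOmics(
    mods,
    coords = do.call(rbind, replicate(nSlices, plan$coords,
                                      simplify = FALSE)),
    sliceId = rep(sprintf("s%d", seq_len(nSlices)), each = n),
    labels = rep(plan$labels, nSlices),
    params = c(baseParams,
               list(multislice = list(nSlices = nSlices,
                                      batchScale = batchScale,
                                      seed = seed))))
}

#' Regenerate a synthetic dataset from its params record
#'
#' @param params the `params` list of a generated
#'   [SpatialMultiOmics-class]; reruns the recorded generator with the
#'   recorded arguments, yielding a bit-identical dataset.
#' @return A [SpatialMultiOmics-class].
#' @export
regenerateTruth <- function(params) {
  base <- params[setdiff(names(params), c("generator", "multislice"))]
  ds <- do.call(params$generator, base)
  if (!is.null(params$multislice))
    ds <- do.call(makeMultislice, c(list(base = ds), params$multislice))
  ds
}
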