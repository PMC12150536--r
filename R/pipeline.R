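# End-to-end pipeline: preprocess -> graph -> fit -> K-means ->
# metrics (-> markers). Used by the command-line entry point and the
# acceptance script.

#' Run the full spatial-domain identification pipeline
#'
#' Preprocesses every modality with its standard pipeline
#' ([preprocessModality()]), rescales each processed matrix to unit
#' overall standard deviation (keeping relative component variances
#' while avoiding activation saturation), builds the spatial KNN graph
#' (per slice, assembled block-diagonally for multi-slice data), fits
#' the model (batched if `config$batchSize` is set), clusters the
#' fused embedding with seeded K-means, and computes evaluation
#' metrics when ground-truth labels are available.
#'
#' @param dataset a [SpatialMultiOmics-class] with raw modalities.
#' @param nClusters number of spatial domains to call.
#' @param config a [trainConfig()].
#' @param nComponents per-modality target dimension passed to
#'   [preprocessModality()] (default 20 for generic modalities).
#' @param useModalities optional character subset of modality names
#'   (single-omics mode drops the other branch).
#' @param markers if TRUE, also rank per-domain markers on the first
#'   modality's log-normalized matrix.
#' @return list with `labels` (0-based domains), `matchedLabels`
#'   (Hungarian-matched to truth, when truth exists), `metrics`
#'   (ari/nmi/ami/homogeneity/completeness), `embedding`, `fit`,
#'   `graph`, `processed` and optionally `markers`.
#' @export
runPipeline <- function(dataset, nClusters, config = trainConfig(),
                        nComponents = NULL, useModalities = NULL,
                        markers = FALSE) {
  mods <- modalities(dataset)
  if (!is.null(useModalities)) {
    bad <- setdiff(useModalities, names(mods))
    if (length(bad))
      stop("unknown modalities: ", paste(bad, collapse = ", "))
    mods <- mods[useModalities]
  }
  processed <- lapply(mods, preprocessModality,
                      nComponents = nComponents)
  xList <- lapply(processed, function(m) {
    v <- m@values
    s <- stats::sd(v)
    if (s > 0) v / s else v
  })
  graph <- buildKnnGraph(dataset, k = config$kNeighbors)
  fit <- if (!is.null(config$batchSize))
    fitBatched(xList, graph, config)
  else
    fitModel(xList, graph, config)
  labels <- kmeansDomains(fit$embedding$Z, nClusters,
                          seed = config$seed)
  out <- list(labels = labels, embedding = fit$embedding$Z, fit = fit,
              graph = graph, processed = processed)
  truth <- trueLabels(dataset)
  if (!is.null(truth)) {
    out$metrics <- c(
      ari = ariScore(labels, truth),
      nmi = nmiScore(labels, truth),
      ami = amiScore(labels, truth),
      homogeneity = homogeneityScore(labels, truth),
      completeness = completenessScore(labels, truth))
    map <- hungarianMatch(labels, truth)
    out$matchedLabels <- suppressWarnings(
      as.integer(map[as.character(labels)]))
  }
  if (markers) {
    first <- mods[[1]]
    norm <- if (first@state == "raw") logNormalize(first) else first
    out$markers <- rankMarkersWilcoxon(norm, labels)
  }
  out
}
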