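#' Accessors for spaFuse data classes
#'
#' `values()` returns the numeric matrix of an [OmicsMatrix-class];
#' `modality()` and `matrixState()` its modality tag and processing
#' state; `spotIds()`/`featureIds()` its identifiers. On a
#' [SpatialMultiOmics-class], `modalities()` returns the named list of
#' OmicsMatrix objects, `spotCoords()` the coordinate matrix,
#' `sliceIds()` the per-spot slice labels and `trueLabels()` the
#' ground-truth domains (or NULL). On a [NeighborGraph-class],
#' `adjacency()` returns the binary adjacency, `normAdjacency()` the
#' symmetric normalization and `neighborSets()` the per-spot neighbor
#' index sets.
#'
#' @param x an object of the documented class.
#' @return See details per accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("values", function(x) standardGeneric("values"))
#' @rdname accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))
#' @rdname accessors
#' @export
setGeneric("matrixState", function(x) standardGeneric("matrixState"))
#' @rdname accessors
#' @export
setGeneric("spotIds", function(x) standardGeneric("spotIds"))
#' @rdname accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))
#' @rdname accessors
#' @export
setGeneric("modalities", function(x) standardGeneric("modalities"))
#' @rdname accessors
#' @export
setGeneric("spotCoords", function(x) standardGeneric("spotCoords"))
#' @rdname accessors
#' @export
setGeneric("sliceIds", function(x) standardGeneric("sliceIds"))
#' @rdname accessors
#' @export
setGeneric("trueLabels", function(x) standardGeneric("trueLabels"))
#' @rdname accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
#' @rdname accessors
#' @export
setGeneric("normAdjacency", function(x) standardGeneric("normAdjacency"))
#' @rdname accessors
#' @export
setGeneric("neighborSets", function(x) standardGeneric("neighborSets"))

#' @rdname accessors
setMethod("values", "OmicsMatrix", function(x) x@values)
#' @rdname accessors
setMethod("modality", "OmicsMatrix", function(x) x@modality)
#' @rdname accessors
setMethod("matrixState", "OmicsMatrix", function(x) x@state)
#' @rdname accessors
setMethod("spotIds", "OmicsMatrix", function(x) x@spotIds)
#' @rdname accessors
setMethod("featureIds", "OmicsMatrix", function(x) x@featureIds)
#' @rdname accessors
setMethod("modalities", "SpatialMultiOmics", function(x) x@modalities)
#' @rdname accessors
setMethod("spotCoords", "SpatialMultiOmics", function(x) x@coords)
#' @rdname accessors
setMethod("sliceIds", "SpatialMultiOmics", function(x) x@sliceId)
#' @rdname accessors
setMethod("trueLabels", "SpatialMultiOmics", function(x) x@labels)
#' @rdname accessors
setMethod("spotIds", "SpatialMultiOmics",
          function(x) x@modalities[[1]]@spotIds)
#' @rdname accessors
setMethod("adjacency", "NeighborGraph", function(x) x@A)
#' @rdname accessors
setMethod("normAdjacency", "NeighborGraph", function(x) x@Anorm)
#' @rdname accessors
setMethod("neighborSets", "NeighborGraph", function(x) x@neighborSets)

setMethod("show", "OmicsMatrix", function(object) {
  cat(sprintf("OmicsMatrix [%s, %s]: %d spots x %d features\n",
              object@modality, object@state,
              nrow(object@values), ncol(object@values)))
})

setMethod("show", "SpatialMultiOmics", function(object) {
  cat(sprintf("SpatialMultiOmics: %d spots, %d slice(s)\n",
              nrow(object@coords), length(unique(object@sliceId))))
  for (nm in names(object@modalities)) {
    m <- object@modalities[[nm]]
    cat(sprintf("  %s: %s/%s, %d features\n", nm, m@modality, m@state,
                ncol(m@values)))
  }
  if (!is.null(object@labels))
    cat(sprintf("  ground truth: %d domains\n",
                length(unique(object@labels))))
})

setMethod("show", "NeighborGraph", function(object) {
  cat(sprintf("NeighborGraph: %d spots, k = %d, %d undirected edges\n",
              nrow(object@A), object@k, as.integer(sum(object@A) / 2)))
})
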