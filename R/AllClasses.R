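#' @import methods
#' @importFrom Matrix Matrix Diagonal rowSums colSums t readMM writeMM sparseMatrix bdiag
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("integerOrNULL", c("integer", "NULL"))

#' OmicsMatrix: one modality's spot-by-feature matrix with processing state
#'
#' Container for a single omics modality measured on a set of spots.
#' Rows are spots (capture locations / cells), columns are features
#' (genes, surface proteins, chromatin peaks, ...). The `state` slot
#' records where the matrix is in its preprocessing pipeline; the only
#' legal transitions are raw -> normalized -> reduced, enforced by the
#' preprocessing functions.
#'
#' @slot values numeric spots x features matrix.
#' @slot modality one of `"rna"`, `"adt"`, `"atac"`, `"generic"`.
#' @slot state one of `"raw"`, `"normalized"`, `"reduced"`.
#' @slot spotIds character vector, one id per row.
#' @slot featureIds character vector, one id per column.
#'
#' @seealso [OmicsMatrix()] for the constructor,
#'   [filterGenesMinSpots()], [logNormalize()], [selectHVG()],
#'   [pcaReduce()], [clrNormalize()], [adtPCA()], [lsiReduce()].
#' @export
setClass("OmicsMatrix",
  slots = c(
    values     = "matrix",
    modality   = "character",
    state      = "character",
    spotIds    = "character",
    featureIds = "character"
  )
)

setValidity("OmicsMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (!is.numeric(v)) msg <- c(msg, "'values' must be numeric")
  if (!object@modality %in% c("rna", "adt", "atac", "generic"))
    msg <- c(msg, "modality must be one of rna/adt/atac/generic")
  if (!object@state %in% c("raw", "normalized", "reduced"))
    msg <- c(msg, "state must be one of raw/normalized/reduced")
  if (length(object@spotIds) != nrow(v))
    msg <- c(msg, "length(spotIds) must equal nrow(values)")
  if (length(object@featureIds) != ncol(v))
    msg <- c(msg, "length(featureIds) must equal ncol(values)")
  if (any(!is.finite(v)))
    msg <- c(msg, "values must be finite")
  if (identical(object@state, "raw") && nrow(v) && any(v < 0))
    msg <- c(msg, "raw values must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsMatrix
#'
#' @param values spots x features numeric matrix (dense or coercible).
#' @param modality `"rna"`, `"adt"`, `"atac"` or `"generic"`.
#' @param spotIds,featureIds identifiers; defaults derived from dimnames
#'   or synthesized.
#' @param state processing state, default `"raw"`.
#' @return An [OmicsMatrix-class] object.
#' @examples
#' om <- OmicsMatrix(matrix(rpois(30, 2), 6, 5), "rna")
#' dim(values(om))
#' @export
OmicsMatrix <- function(values, modality = "generic",
                        spotIds = NULL, featureIds = NULL,
                        state = "raw") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(spotIds))
    spotIds <- rownames(values) %||% sprintf("spot%d", seq_len(nrow(values)))
  if (is.null(featureIds))
    featureIds <- colnames(values) %||% sprintf("feat%d", seq_len(ncol(values)))
  rownames(values) <- spotIds
  colnames(values) <- featureIds
  new("OmicsMatrix", values = values, modality = modality, state = state,
      spotIds = as.character(spotIds), featureIds = as.character(featureIds))
}

#' SpatialMultiOmics: a spatial multi-omics dataset
#'
#' Bundles one or more [OmicsMatrix-class] modalities sharing a common
#' spot ordering with 2-D spot coordinates, an optional per-spot slice
#' label (for multi-slice datasets) and optional ground-truth domain
#' labels (populated by the synthetic generators).
#'
#' @slot modalities named list of [OmicsMatrix-class] objects; the
#'   modality order is preserved in downstream concatenation (RNA first
#'   by convention).
#' @slot coords spots x 2 numeric matrix of spatial coordinates.
#' @slot sliceId character vector, one slice label per spot.
#' @slot labels integer ground-truth domain per spot, or NULL.
#' @slot params list recording generation parameters (synthetic data).
#' @export
setClass("SpatialMultiOmics",
  slots = c(
    modalities = "list",
    coords     = "matrix",
    sliceId    = "character",
    labels     = "integerOrNULL",
    params     = "list"
  )
)

setValidity("SpatialMultiOmics", function(object) {
  msg <- character()
  if (!length(object@modalities))
    msg <- c(msg, "at least one modality required")
  if (!all(vapply(object@modalities, is, TRUE, "OmicsMatrix")))
    msg <- c(msg, "all modalities must be OmicsMatrix objects")
  n <- nrow(object@coords)
  if (ncol(object@coords) != 2) msg <- c(msg, "coords must have 2 columns")
  if (any(!is.finite(object@coords))) msg <- c(msg, "coords must be finite")
  for (m in object@modalities)
    if (nrow(m@values) != n)
      msg <- c(msg, "all modalities must have one row per coordinate row")
  if (length(object@sliceId) != n)
    msg <- c(msg, "sliceId must have one entry per spot")
  if (!is.null(object@labels) && length(object@labels) != n)
    msg <- c(msg, "labels must have one entry per spot")
  if (length(msg)) msg else TRUE
})

#' Construct a SpatialMultiOmics dataset
#'
#' @param modalities named list of [OmicsMatrix-class] objects with equal
#'   spot counts and identical spot ordering.
#' @param coords spots x 2 coordinate matrix.
#' @param sliceId per-spot slice labels (default: single slice `"s1"`).
#' @param labels optional integer ground-truth domain labels.
#' @param params optional generation-parameter record.
#' @return A [SpatialMultiOmics-class] object.
#' @export
SpatialMultiOmics <- function(modalities, coords, sliceId = NULL,
                              labels = NULL, params = list()) {
  if (is(modalities, "OmicsMatrix")) modalities <- list(modalities)
  if (is.null(names(modalities)) || any(names(modalities) == ""))
    names(modalities) <- vapply(modalities, function(m) m@modality, "")
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (is.null(colnames(coords))) colnames(coords) <- c("x", "y")
  if (is.null(sliceId)) sliceId <- rep("s1", nrow(coords))
  ids <- lapply(modalities, function(m) m@spotIds)
  if (length(ids) > 1L) {
    ref <- ids[[1]]
    for (i in seq_along(ids)[-1]) {
      if (!identical(ids[[i]], ref)) {
        bad <- union(setdiff(ids[[i]], ref), setdiff(ref, ids[[i]]))
        if (!length(bad)) bad <- "(same set, different order)"
        stop("spot id mismatch between modalities '", names(modalities)[1],
             "' and '", names(modalities)[i], "': ",
             paste(utils::head(bad, 5), collapse = ", "))
      }
    }
  }
  new("SpatialMultiOmics", modalities = modalities, coords = coords,
      sliceId = as.character(sliceId),
      labels = if (is.null(labels)) NULL else as.integer(labels),
      params = params)
}

#' NeighborGraph: spatial KNN neighborhood graph
#'
#' Holds the binary spot adjacency `A` (symmetric, zero diagonal), its
#' symmetric normalization `A_norm = D^{-1/2} (A + I) D^{-1/2}` and the
#' per-spot neighbor sets used as InfoNCE positives.
#'
#' @slot A sparse binary adjacency (dgCMatrix semantics).
#' @slot Anorm sparse normalized adjacency including self-loops.
#' @slot k integer, neighbors requested per spot.
#' @slot neighborSets list of integer vectors, `N_i` per spot.
#' @seealso [buildKnnGraph()], [normalizeAdjacency()],
#'   [assembleMultislice()]
#' @export
setClass("NeighborGraph",
  slots = c(
    A            = "Matrix",
    Anorm        = "Matrix",
    k            = "integer",
    neighborSets = "list"
  )
)

setValidity("NeighborGraph", function(object) {
  msg <- character()
  A <- object@A
  if (nrow(A) != ncol(A)) msg <- c(msg, "A must be square")
  if (length(A@x) && any(A@x != 1)) msg <- c(msg, "A must be binary")
  if (any(Matrix::diag(A) != 0)) msg <- c(msg, "A must have zero diagonal")
  if (!Matrix::isSymmetric(A)) msg <- c(msg, "A must be symmetric")
  if (length(object@neighborSets) &&
      length(object@neighborSets) != nrow(A))
    msg <- c(msg, "one neighbor set per spot required")
  if (length(msg)) msg else TRUE
})

`%||%` <- function(a, b) if (is.null(a)) b else a
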