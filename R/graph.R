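# Spatial neighbor graph construction, normalization and multi-slice
# assembly.

#' Build a spatial K-nearest-neighbor graph
#'
#' For each spot the `k` Euclidean-nearest other spots are selected as
#' directed neighbors (distance ties broken by ascending spot index for
#' deterministic builds), and the adjacency is symmetrized with logical
#' OR (`A_ij = 1` iff j is among i's k nearest or vice versa), matching
#' the undirected graph assumed by the normalization and the
#' adjacency-based losses. The binary `A` has zero diagonal; self-loops
#' enter only through the normalization.
#'
#' @param coords spots x 2 coordinate matrix (or a
#'   [SpatialMultiOmics-class], whose coordinates are used; multi-slice
#'   datasets get per-slice graphs assembled block-diagonally).
#' @param k neighbors per spot (default 3).
#' @param symmetrize if FALSE, keep the directed adjacency (no OR).
#' @return A [NeighborGraph-class] with `A`, `A_norm` and neighbor sets.
#' @export
buildKnnGraph <- function(coords, k = 3, symmetrize = TRUE) {
  if (is(coords, "SpatialMultiOmics")) {
    sl <- sliceIds(coords)
    xy <- spotCoords(coords)
    if (length(unique(sl)) > 1L) {
      graphs <- lapply(unique(sl), function(s)
        buildKnnGraph(xy[sl == s, , drop = FALSE], k, symmetrize))
      return(assembleMultislice(graphs))
    }
    coords <- xy
  }
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (k >= n) stop("k (", k, ") must be smaller than the spot count (",
                   n, ")")
  if (anyDuplicated(coords))
    warning("duplicated coordinates present; ties broken by spot index")
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  ii <- integer(n * k); jj <- integer(n * k)
  for (i in seq_len(n)) {
    # order() breaks ties by index, giving deterministic neighbor sets
    nn <- order(d[i, ])[seq_len(k)]
    ii[((i - 1) * k + 1):(i * k)] <- i
    jj[((i - 1) * k + 1):(i * k)] <- nn
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  if (symmetrize) {
    A <- A + Matrix::t(A)
    A@x[] <- 1
  }
  .newGraph(A, as.integer(k))
}

.newGraph <- function(A, k) {
  A <- methods::as(methods::as(A, "generalMatrix"), "CsparseMatrix")
  diag(A) <- 0
  A <- Matrix::drop0(A)
  g <- new("NeighborGraph", A = A, Anorm = .normalizeAdj(A), k = k,
           neighborSets = .neighborSets(A))
  g
}

.normalizeAdj <- function(A) {
  Ai <- A + Matrix::Diagonal(nrow(A))
  dhalf <- 1 / sqrt(Matrix::rowSums(Ai))
  D <- Matrix::Diagonal(x = dhalf)
  methods::as(D %*% Ai %*% D, "CsparseMatrix")
}

.neighborSets <- function(A) {
  At <- methods::as(A, "TsparseMatrix")
  split(At@j + 1L, factor(At@i + 1L, levels = seq_len(nrow(A))))
}

#' Symmetrically normalize a neighbor graph's adjacency
#'
#' Recomputes `A_norm = D^{-1/2} (A + I) D^{-1/2}` where `D` is the
#' degree matrix of `A + I`. Self-loops guarantee positive degrees, so
#' the operation is defined for every graph, and the result is
#' symmetric with spectral radius at most 1.
#'
#' @param graph a [NeighborGraph-class].
#' @return The graph with `A_norm` refreshed.
#' @export
normalizeAdjacency <- function(graph) {
  graph@Anorm <- .normalizeAdj(graph@A)
  graph
}

#' Assemble per-slice graphs into one block-diagonal graph
#'
#' Concatenates slice graphs in list order:
#' `A = diag(A_1, ..., A_n)` with no cross-slice edges, for parallel
#' multi-slice analysis.
#'
#' @param graphs list of [NeighborGraph-class] objects (length >= 1).
#' @return The combined [NeighborGraph-class].
#' @export
assembleMultislice <- function(graphs) {
  if (!length(graphs)) stop("need at least one graph")
  if (length(graphs) == 1L) return(graphs[[1]])
  A <- Reduce(Matrix::bdiag, lapply(graphs, adjacency))
  .newGraph(A, graphs[[1]]@k)
}
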