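#' Read a spatial omics dataset from MTX + TSV + coordinate CSV
#'
#' Reads one modality stored in Matrix Market format alongside
#' `features.tsv` (one feature id per line), `barcodes.tsv` (one spot
#' barcode per line) and a coordinate CSV with columns
#' `barcode,x,y[,slice]`. The coordinate table must contain exactly the
#' barcodes of the matrix; spots are reordered to the barcode order of
#' the matrix so matrices and coordinates always share spot ordering.
#'
#' @param mtx path to the Matrix Market file (spots are columns, as in
#'   CellRanger-style exports, or rows; disambiguated by the barcode
#'   count).
#' @param features,barcodes paths to the id files.
#' @param coords path to the coordinate CSV.
#' @param modality modality tag for the resulting [OmicsMatrix-class].
#' @return A [SpatialMultiOmics-class] with one modality, `raw` state.
#' @export
readMtxDataset <- function(mtx, features, barcodes, coords,
                           modality = "rna") {
  for (p in c(mtx, features, barcodes, coords))
    if (!file.exists(p)) stop("file not found: ", p)
  m <- as.matrix(Matrix::readMM(mtx))
  feats <- readLines(features)
  bcs <- readLines(barcodes)
  if (nrow(m) == length(bcs) && ncol(m) == length(feats)) {
    # spots x features already
  } else if (ncol(m) == length(bcs) && nrow(m) == length(feats)) {
    m <- t(m)
  } else {
    stop("matrix dimensions (", nrow(m), "x", ncol(m),
         ") match neither barcodes (", length(bcs), ") x features (",
         length(feats), ") nor its transpose")
  }
  ct <- utils::read.csv(coords, stringsAsFactors = FALSE)
  if (!all(c("barcode", "x", "y") %in% names(ct)))
    stop("coordinate CSV must have columns barcode,x,y[,slice]")
  missing <- setdiff(bcs, ct$barcode)
  extra <- setdiff(ct$barcode, bcs)
  if (length(missing) || length(extra))
    stop("barcode mismatch between matrix and coordinates; missing: [",
         paste(utils::head(missing, 5), collapse = ", "), "], extra: [",
         paste(utils::head(extra, 5), collapse = ", "), "]")
  ct <- ct[match(bcs, ct$barcode), , drop = FALSE]
  om <- OmicsMatrix(m, modality, spotIds = bcs, featureIds = feats)
  SpatialMultiOmics(
    stats::setNames(list(om), modality),
    coords = cbind(x = ct$x, y = ct$y),
    sliceId = if ("slice" %in% names(ct)) as.character(ct$slice) else NULL
  )
}

#' Write / read the annotated directory container
#'
#' A plain-text annotated-matrix container holding a whole
#' [SpatialMultiOmics-class] dataset: one MTX layer + features TSV per
#' modality, shared `barcodes.tsv`, `coords.csv` (with slice column),
#' optional `labels.tsv` for ground truth and a `meta.json` with
#' modality tags, processing states and generation parameters.
#' Round-trips are lossless for values, ids, coordinates, slices and
#' labels.
#'
#' @param x a [SpatialMultiOmics-class] object.
#' @param dir directory to create / read.
#' @return `writeAnnotatedDir` returns `dir` invisibly;
#'   `readAnnotatedDir` returns the reconstructed
#'   [SpatialMultiOmics-class].
#' @export
writeAnnotatedDir <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(spotIds(x), file.path(dir, "barcodes.tsv"))
  ct <- data.frame(barcode = spotIds(x), x = x@coords[, 1],
                   y = x@coords[, 2], slice = x@sliceId)
  utils::write.csv(ct, file.path(dir, "coords.csv"), row.names = FALSE)
  meta <- list(modalities = list())
  for (nm in names(x@modalities)) {
    m <- x@modalities[[nm]]
    Matrix::writeMM(Matrix::Matrix(m@values, sparse = TRUE),
                    file.path(dir, paste0(nm, ".mtx")))
    writeLines(m@featureIds, file.path(dir, paste0(nm, ".features.tsv")))
    meta$modalities[[nm]] <- list(modality = m@modality, state = m@state)
  }
  if (!is.null(x@labels))
    utils::write.table(
      data.frame(barcode = spotIds(x), domain = x@labels),
      file.path(dir, "labels.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
  meta$params <- x@params
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname writeAnnotatedDir
#' @export
readAnnotatedDir <- function(dir) {
  if (!dir.exists(dir)) stop("not a directory: ", dir)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  bcs <- readLines(file.path(dir, "barcodes.tsv"))
  ct <- utils::read.csv(file.path(dir, "coords.csv"),
                        stringsAsFactors = FALSE)
  ct <- ct[match(bcs, ct$barcode), , drop = FALSE]
  mods <- list()
  # read in meta order so modality ordering survives the round trip
  for (nm in names(meta$modalities)) {
    info <- meta$modalities[[nm]]
    v <- as.matrix(Matrix::readMM(file.path(dir, paste0(nm, ".mtx"))))
    feats <- readLines(file.path(dir, paste0(nm, ".features.tsv")))
    mods[[nm]] <- OmicsMatrix(v, info$modality, spotIds = bcs,
                              featureIds = feats, state = info$state)
  }
  labels <- NULL
  lp <- file.path(dir, "labels.tsv")
  if (file.exists(lp)) {
    lt <- utils::read.table(lp, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    labels <- lt$domain[match(bcs, lt$barcode)]
  }
  SpatialMultiOmics(mods, coords = cbind(x = ct$x, y = ct$y),
                    sliceId = as.character(ct$slice), labels = labels,
                    params = meta$params %||% list())
}

#' Export a graph edge list for inspection
#'
#' @param graph a [NeighborGraph-class].
#' @param path TSV output path; columns `i`, `j` (1-based, i < j).
#' @export
writeEdgeList <- function(graph, path) {
  A <- as(adjacency(graph), "TsparseMatrix")
  keep <- A@i < A@j
  utils::write.table(
    data.frame(i = A@i[keep] + 1L, j = A@j[keep] + 1L),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
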