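## File interfaces: multi-page 16-bit TIFFs, JSON ground-truth sidecars
## with run-length-encoded masks, YAML round-tripping of scene specs, and
## the CSV tables written by the pipeline.

#' Write a rendered scene as a multi-page TIFF plus a ground-truth sidecar
#'
#' One 16-bit unsigned page per channel, in the fixed order gfp, dapi,
#' membrane. The sidecar (`<basename>_truth.json`) stores, per cell, the
#' id, phenotype, infection flag, tip-to-tip axis endpoints, and
#' run-length-encoded cell and nucleus masks (1-based column-major pixel
#' indices, `[start, length]` pairs).
#'
#' @param render a [SceneRender].
#' @param path output TIFF path.
#' @param sidecar optional path for the JSON sidecar; `NULL` derives it
#'   from `path`, `NA` skips it.
#' @return invisibly, the TIFF path.
#' @export
writeSceneTiff <- function(render, path, sidecar = NULL) {
  imgs <- lapply(sceneImages(render), function(m) {
    ## tiff::writeTIFF expects [0, 1]; 16-bit unsigned counts
    pmin(pmax(m, 0), 65535) / 65535
  })
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L, compression = "none")
  if (is.null(sidecar)) {
    sidecar <- paste0(sub("\\.tiff?$", "", path, ignore.case = TRUE),
                      "_truth.json")
  }
  if (!is.na(sidecar)) writeGroundTruthJson(groundTruth(render), sidecar)
  invisible(path)
}

#' Read a multi-page TIFF written by [writeSceneTiff()]
#'
#' @param path TIFF path.
#' @param channels channel names to assign to the pages.
#' @return named list of integer count matrices.
#' @export
readSceneTiff <- function(path, channels = c("gfp", "dapi", "membrane")) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < length(channels)) {
    channels <- channels[seq_along(pages)]
  }
  out <- lapply(pages[seq_along(channels)], function(p) {
    matrix(round(p * 65535), nrow(p), ncol(p))
  })
  names(out) <- channels
  out
}

writeGroundTruthJson <- function(gt, path) {
  cells <- lapply(gt$cells, function(cl) {
    list(
      id = cl$id,
      phenotype = cl$phenotype,
      infected = cl$infected,
      axisP0 = cl$axisP0,
      axisP1 = cl$axisP1,
      lengthPx = cl$lengthPx,
      meanDensity = as.list(cl$meanDensity),
      maskRle = rleEncodeIndices(cl$pixels),
      nucleusMaskRle = rleEncodeIndices(cl$nucleusPixels)
    )
  })
  jsonlite::write_json(
    list(imageShape = dim(gt$label), cells = cells),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a ground-truth JSON sidecar
#'
#' @param path sidecar path.
#' @return list with `imageShape` and per-cell entries whose masks are
#'   decoded back to 1-based linear pixel indices.
#' @export
readGroundTruthJson <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  list(
    imageShape = as.integer(unlist(raw$imageShape)),
    cells = lapply(raw$cells, function(cl) {
      list(
        id = as.integer(cl$id),
        phenotype = cl$phenotype,
        infected = as.logical(cl$infected),
        axisP0 = as.numeric(unlist(cl$axisP0)),
        axisP1 = as.numeric(unlist(cl$axisP1)),
        lengthPx = as.numeric(cl$lengthPx),
        meanDensity = unlist(cl$meanDensity),
        pixels = rleDecodeIndices(cl$maskRle),
        nucleusPixels = rleDecodeIndices(cl$nucleusMaskRle)
      )
    })
  )
}

#' Serialize a SceneSpec to YAML (and back)
#'
#' @param spec a [SceneSpec].
#' @param path YAML file path.
#' @return `sceneSpecToYaml` invisibly returns `path`;
#'   `sceneSpecFromYaml` returns the reconstructed [SceneSpec].
#' @export
sceneSpecToYaml <- function(spec, path) {
  asPlain <- function(obj) {
    slots <- slotNames(class(obj))
    out <- lapply(slots, function(s) slot(obj, s))
    names(out) <- slots
    out
  }
  lst <- list(
    imageShape = spec@imageShape,
    seed = spec@seed,
    optics = asPlain(spec@optics),
    cells = lapply(spec@cells, asPlain)
  )
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname sceneSpecToYaml
#' @export
sceneSpecFromYaml <- function(path) {
  lst <- yaml::read_yaml(path)
  optics <- do.call(OpticsModel, lapply(lst$optics, as.numeric))
  cells <- lapply(lst$cells, function(cl) {
    cl$infected <- as.logical(cl$infected)
    do.call(CellSpec, cl)
  })
  SceneSpec(imageShape = lst$imageShape, cells = cells, optics = optics,
            seed = lst$seed)
}

#' Write a label image of cell ROIs as TIFF
#'
#' @param rois list of [CellROI].
#' @param path output TIFF path.
#' @return invisibly, `path`.
#' @export
writeLabelTiff <- function(rois, path) {
  dims <- rois[[1L]]@imageDim
  lab <- matrix(0, dims[1L], dims[2L])
  for (roi in rois) lab[roi@pixels] <- roi@cellId
  tiff::writeTIFF(lab / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read a label image TIFF into an integer matrix
#'
#' @param path label TIFF path.
#' @return integer matrix of cell labels (0 = background).
#' @export
readLabelTiff <- function(path) {
  p <- tiff::readTIFF(path)
  if (length(dim(p)) == 3L) p <- p[, , 1L]
  matrix(as.integer(round(p * 65535)), nrow(p), ncol(p))
}

#' Tabulate ROIs for export
#'
#' @param rois list of [CellROI].
#' @return data.frame with one row per cell (centroid, axis endpoints,
#'   length, infection flag), 0-based coordinates.
#' @export
roiTable <- function(rois) {
  do.call(rbind, lapply(rois, function(r) {
    data.frame(
      cellId = r@cellId,
      centroidRow = r@centroid[1L], centroidCol = r@centroid[2L],
      axisP0Row = r@axisP0[1L], axisP0Col = r@axisP0[2L],
      axisP1Row = r@axisP1[1L], axisP1Col = r@axisP1[2L],
      lengthPx = r@lengthPx,
      areaPx = length(r@pixels),
      infected = r@infected
    )
  }))
}

#' Tabulate phenotype calls for export
#'
#' @param calls list of [PhenotypeCall].
#' @return data.frame (cellId, score, call).
#' @export
callTable <- function(calls) {
  do.call(rbind, lapply(calls, function(cl) {
    data.frame(cellId = cl@cellId, score = cl@score, call = cl@call)
  }))
}

#' Tabulate nucleus quantifications for export
#'
#' @param quants list of [NucleusQuant].
#' @param group optional group label column.
#' @return data.frame (cellId, group, maskArea, meanDapi, background,
#'   meanMinusBackground).
#' @export
nucleusTable <- function(quants, group = NA_character_) {
  do.call(rbind, lapply(quants, function(q) {
    data.frame(cellId = q@cellId, group = group, maskArea = q@maskArea,
               meanDapi = q@meanDapi, background = q@background,
               meanMinusBackground = meanMinusBackground(q))
  }))
}
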