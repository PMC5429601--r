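#' ROIMask class: labelled pixel set
#'
#' A region of interest is a label plus the set of pixel coordinates it
#' covers (histology registration happens upstream; masks enter as
#' coordinates).
#'
#' @slot label Region label (free-form; e.g. `"tumor"`, `"healthy"`).
#' @slot coords Integer matrix (x, y).
#' @export
setClass("ROIMask",
  representation(label = "character", coords = "matrix"),
  validity = function(object) {
    if (nrow(object@coords) == 0) return("mask must be non-empty")
    if (anyDuplicated(object@coords) > 0) return("mask pixels must be unique")
    TRUE
  }
)

#' Construct an ROI mask
#' @param label Region label.
#' @param coords Two-column integer matrix or data.frame of (x, y) pixels.
#' @return An [ROIMask-class].
#' @export
ROIMask <- function(label, coords) {
  m <- as.matrix(coords)
  storage.mode(m) <- "integer"
  colnames(m) <- c("x", "y")
  new("ROIMask", label = label, coords = m)
}

#' @describeIn ROIMask-class region label accessor
#' @param x An `ROIMask`.
#' @export
roiLabel <- function(x) x@label

setMethod("show", "ROIMask", function(object) {
  cat(sprintf("ROIMask '%s': %d pixels\n", object@label,
              nrow(object@coords)))
})

#' Write ROI masks to JSON
#'
#' @param masks List of [ROIMask-class] objects.
#' @param path Output JSON path.
#' @export
writeRoiMasks <- function(masks, path) {
  payload <- lapply(masks, function(m) {
    list(label = roiLabel(m),
         pixels = unname(apply(m@coords, 1, as.list)))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read ROI masks from JSON
#'
#' @param path JSON file written by [writeRoiMasks()] (or hand-authored in
#'   the same `label` + `pixels` layout).
#' @return Named list of [ROIMask-class] objects.
#' @export
readRoiMasks <- function(path) {
  if (!file.exists(path)) stop("no such mask file: ", path)
  payload <- jsonlite::read_json(path)
  masks <- lapply(payload, function(p) {
    coords <- do.call(rbind, lapply(p$pixels, function(px) {
      c(as.integer(px[[1]]), as.integer(px[[2]]))
    }))
    ROIMask(p$label, coords)
  })
  stats::setNames(masks, vapply(masks, roiLabel, character(1)))
}

#' Pixel indices of a mask within a dataset
#'
#' @param ds An [MSIDataset-class].
#' @param mask An [ROIMask-class]; every mask pixel must exist in the
#'   dataset.
#' @return Integer vector of pixel indices.
#' @export
maskIndices <- function(ds, mask) {
  key <- function(m) paste(m[, 1], m[, 2])
  idx <- match(key(mask@coords), key(pixelCoords(ds)))
  if (anyNA(idx)) {
    stop(sprintf("mask '%s' references %d pixel(s) absent from the dataset",
                 roiLabel(mask), sum(is.na(idx))))
  }
  idx
}
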