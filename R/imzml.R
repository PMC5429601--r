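#' MSIDataset class: on-disk imzML mass spectrometry imaging dataset
#'
#' Pixel spectra stay on disk (imzML XML + ibd binary pair) and are read on
#' demand, so full-profile FTICR datasets never have to fit in memory as a
#' dense matrix.  Continuous-mode datasets share one m/z axis, which is
#' loaded once; processed-mode datasets carry per-pixel axes.
#'
#' @slot imzmlPath,ibdPath File paths.
#' @slot mode `"continuous"` or `"processed"`.
#' @slot polarity `"positive"` or `"negative"`.
#' @slot coords Integer matrix (x, y), one row per pixel; rows unique.
#' @slot mzAxis Shared m/z axis (continuous mode; empty otherwise).
#' @slot arrays `data.frame` of external-binary offsets/lengths per pixel.
#' @slot mzRange Numeric length-2 acquisition m/z range.
#' @slot pixelSizeUm Pixel pitch in micrometers.
#' @slot metadata List of free-form metadata echoed by the writer.
#' @export
setClass("MSIDataset",
  representation(imzmlPath = "character", ibdPath = "character",
                 mode = "character", polarity = "character",
                 coords = "matrix", mzAxis = "numeric",
                 arrays = "data.frame", mzRange = "numeric",
                 pixelSizeUm = "numeric", metadata = "list"),
  validity = function(object) {
    if (!object@mode %in% c("continuous", "processed")) {
      return("mode must be 'continuous' or 'processed'")
    }
    if (anyDuplicated(object@coords) > 0) {
      return("pixel coordinates must be unique")
    }
    if (object@mode == "continuous" && length(object@mzAxis) > 1 &&
        any(diff(object@mzAxis) <= 0)) {
      return("m/z axis must be strictly increasing")
    }
    TRUE
  }
)

setMethod("show", "MSIDataset", function(object) {
  cat(sprintf("MSIDataset (%s, %s mode): %d pixels, m/z %.1f - %.1f\n",
              basename(object@imzmlPath), object@mode,
              nrow(object@coords), object@mzRange[1], object@mzRange[2]))
  cat(sprintf("  pixel size %.0f um", object@pixelSizeUm))
  if (object@mode == "continuous") {
    cat(sprintf(", shared axis of %d points", length(object@mzAxis)))
  }
  cat("\n")
})

#' @describeIn MSIDataset-class number of pixels
#' @param x An `MSIDataset`.
#' @export
nPixels <- function(x) nrow(x@coords)

#' @describeIn MSIDataset-class pixel coordinate matrix accessor
#' @export
pixelCoords <- function(x) x@coords

#' @describeIn MSIDataset-class shared m/z axis (continuous mode)
#' @export
sharedMzAxis <- function(x) x@mzAxis

.sizeOf <- c(double = 8L, float = 4L)

## ---- writer -----------------------------------------------------------

#' Open an imzML writer
#'
#' Streaming writer: spectra are appended one pixel at a time with
#' [imzmlWriteSpectrum()] so a full dataset never has to be held in
#' memory, then [imzmlWriterClose()] emits the XML.  m/z values are stored
#' as 64-bit floats, intensities as 32-bit floats.  No timestamps are
#' written, so identical content yields byte-identical files.
#'
#' @param path Output `.imzML` path (the `.ibd` is written alongside).
#' @param mode `"continuous"` (shared axis, passed here) or
#'   `"processed"` (per-pixel axes passed per spectrum).
#' @param polarity `"positive"` or `"negative"`.
#' @param mzAxis Shared m/z axis (continuous mode only).
#' @param mzRange Acquisition m/z range; defaults to the axis range.
#' @param pixelSizeUm Pixel pitch (micrometers).
#' @param uuid 16-byte raw vector identifying the ibd; supply one derived
#'   from the generation seed for reproducible output.
#' @return A writer handle (environment).
#' @export
imzmlWriterOpen <- function(path, mode = c("continuous", "processed"),
                            polarity = c("positive", "negative"),
                            mzAxis = NULL, mzRange = NULL,
                            pixelSizeUm = 125,
                            uuid = as.raw(rep(0L, 16L))) {
  mode <- match.arg(mode)
  polarity <- match.arg(polarity)
  if (mode == "continuous" && is.null(mzAxis)) {
    stop("continuous mode requires a shared mzAxis")
  }
  ibdPath <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibdPath, path)) ibdPath <- paste0(path, ".ibd")
  con <- file(ibdPath, "wb")
  writeBin(uuid, con)
  w <- new.env(parent = emptyenv())
  w$path <- path; w$ibdPath <- ibdPath
  w$mode <- mode; w$polarity <- polarity
  w$con <- con; w$offset <- 16
  w$mzAxis <- mzAxis
  w$mzRange <- if (is.null(mzRange) && !is.null(mzAxis)) range(mzAxis)
               else mzRange
  w$pixelSizeUm <- pixelSizeUm
  w$uuid <- uuid
  w$entries <- list()
  if (mode == "continuous") {
    writeBin(as.numeric(mzAxis), con, size = 8)
    w$sharedMzOffset <- 16
    w$sharedMzLength <- length(mzAxis)
    w$offset <- w$offset + 8 * length(mzAxis)
  }
  w
}

#' Append one pixel spectrum to an open imzML writer
#'
#' @param w Writer handle from [imzmlWriterOpen()].
#' @param x,y Integer pixel coordinates.
#' @param intensity Intensity vector (stored as 32-bit float).
#' @param mz Per-pixel m/z axis (processed mode only; must be omitted in
#'   continuous mode).
#' @export
imzmlWriteSpectrum <- function(w, x, y, intensity, mz = NULL) {
  if (w$mode == "continuous") {
    if (!is.null(mz)) stop("continuous mode uses the shared axis")
    if (length(intensity) != w$sharedMzLength) {
      stop("intensity length does not match the shared axis")
    }
    mzOffset <- w$sharedMzOffset
    mzLength <- w$sharedMzLength
  } else {
    if (is.null(mz)) stop("processed mode requires a per-pixel mz axis")
    if (length(mz) != length(intensity)) stop("mz/intensity length mismatch")
    mzOffset <- w$offset
    mzLength <- length(mz)
    writeBin(as.numeric(mz), w$con, size = 8)
    w$offset <- w$offset + 8 * mzLength
  }
  intOffset <- w$offset
  writeBin(as.numeric(intensity), w$con, size = 4)
  w$offset <- w$offset + 4 * length(intensity)
  w$entries[[length(w$entries) + 1]] <-
    list(x = as.integer(x), y = as.integer(y),
         mzOffset = mzOffset, mzLength = mzLength,
         intOffset = intOffset, intLength = length(intensity))
  invisible(w)
}

.cv <- function(cvRef, accession, name, value = NULL, unit = NULL) {
  v <- if (is.null(value)) "" else sprintf(' value="%s"', value)
  u <- if (is.null(unit)) "" else
    sprintf(' unitCvRef="UO" unitAccession="%s" unitName="%s"',
            unit[1], unit[2])
  sprintf('<cvParam cvRef="%s" accession="%s" name="%s"%s%s/>',
          cvRef, accession, name, v, u)
}

#' Close an imzML writer and emit the XML
#'
#' @param w Writer handle.
#' @return Invisibly, the `.imzML` path.
#' @export
imzmlWriterClose <- function(w) {
  close(w$con)
  uuidStr <- paste0("{", paste(format(w$uuid), collapse = ""), "}")
  modeAcc <- if (w$mode == "continuous") {
    .cv("IMS", "IMS:1000030", "continuous")
  } else {
    .cv("IMS", "IMS:1000031", "processed")
  }
  polAcc <- if (w$polarity == "positive") {
    .cv("MS", "MS:1000130", "positive scan")
  } else {
    .cv("MS", "MS:1000129", "negative scan")
  }
  maxX <- max(vapply(w$entries, `[[`, integer(1), "x"))
  maxY <- max(vapply(w$entries, `[[`, integer(1), "y"))
  specXml <- vapply(seq_along(w$entries), function(i) {
    e <- w$entries[[i]]
    paste0(
      sprintf('<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">',
              i - 1, i, e$intLength),
      '<scanList count="1">', '<scan>',
      .cv("IMS", "IMS:1000050", "position x", e$x),
      .cv("IMS", "IMS:1000051", "position y", e$y),
      "</scan></scanList>",
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="mzArray"/>',
      .cv("IMS", "IMS:1000102", "external offset", e$mzOffset),
      .cv("IMS", "IMS:1000103", "external array length", e$mzLength),
      .cv("IMS", "IMS:1000104", "external encoded length", 8 * e$mzLength),
      "<binary/></binaryDataArray>",
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="intensityArray"/>',
      .cv("IMS", "IMS:1000102", "external offset", e$intOffset),
      .cv("IMS", "IMS:1000103", "external array length", e$intLength),
      .cv("IMS", "IMS:1000104", "external encoded length", 4 * e$intLength),
      "<binary/></binaryDataArray>",
      "</binaryDataArrayList></spectrum>")
  }, character(1))
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<cvList count="3">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="http://psidev.info/ms/mzML/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>',
    '<cv id="IMS" fullName="Imaging MS Ontology" URI="http://www.maldi-msi.org/download/imzml/imagingMS.obo"/>',
    "</cvList>",
    "<fileDescription><fileContent>",
    .cv("IMS", "IMS:1000080", "universally unique identifier", uuidStr),
    modeAcc, polAcc,
    sprintf('<userParam name="lowest observed m/z" value="%.6f"/>',
            w$mzRange[1]),
    sprintf('<userParam name="highest observed m/z" value="%.6f"/>',
            w$mzRange[2]),
    sprintf('<userParam name="isotope table" value="%s"/>',
            ISOTOPE_TABLE_VERSION),
    "</fileContent></fileDescription>",
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    .cv("MS", "MS:1000514", "m/z array"),
    .cv("MS", "MS:1000523", "64-bit float"),
    .cv("IMS", "IMS:1000101", "external data", "true"),
    "</referenceableParamGroup>",
    '<referenceableParamGroup id="intensityArray">',
    .cv("MS", "MS:1000515", "intensity array"),
    .cv("MS", "MS:1000521", "32-bit float"),
    .cv("IMS", "IMS:1000101", "external data", "true"),
    "</referenceableParamGroup>",
    "</referenceableParamGroupList>",
    '<scanSettingsList count="1"><scanSettings id="scanSettings1">',
    .cv("IMS", "IMS:1000042", "max count of pixel x", maxX),
    .cv("IMS", "IMS:1000043", "max count of pixel y", maxY),
    .cv("IMS", "IMS:1000046", "pixel size x", w$pixelSizeUm),
    "</scanSettings></scanSettingsList>",
    sprintf('<run id="run1"><spectrumList count="%d">',
            length(w$entries)),
    paste(specXml, collapse = ""),
    "</spectrumList></run></mzML>\n")
  writeLines(xml, w$path, sep = "")
  invisible(w$path)
}

## ---- reader -----------------------------------------------------------

.imsParam <- function(node, accession) {
  p <- xml2::xml_find_first(node, sprintf(".//cvParam[@accession='%s']",
                                          accession))
  if (inherits(p, "xml_missing")) return(NA_character_)
  v <- xml2::xml_attr(p, "value")
  if (is.na(v)) "" else v
}

#' Read an imzML dataset
#'
#' Supports both the continuous (shared m/z axis) and processed (per-pixel
#' axis) dialects with 32/64-bit float encodings.  Array offsets are
#' validated against the ibd file size: a truncated ibd is an error, never
#' a silent partial load.
#'
#' @param path Path to the `.imzML` file (the `.ibd` must sit alongside).
#' @return An [MSIDataset-class].
#' @export
readImzML <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ibdPath <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (!file.exists(ibdPath)) stop("missing ibd file: ", ibdPath)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  fc <- xml2::xml_find_first(doc, ".//fileContent")
  mode <- if (!is.na(.imsParam(fc, "IMS:1000030"))) "continuous"
          else if (!is.na(.imsParam(fc, "IMS:1000031"))) "processed"
          else stop("imzML file declares neither continuous nor processed mode")
  polarity <- if (!is.na(.imsParam(fc, "MS:1000129"))) "negative"
              else "positive"
  ## encoding per referenceable param group
  groups <- xml2::xml_find_all(doc, ".//referenceableParamGroup")
  enc <- list()
  for (g in groups) {
    id <- xml2::xml_attr(g, "id")
    sz <- if (!is.na(.imsParam(g, "MS:1000523"))) 8L
          else if (!is.na(.imsParam(g, "MS:1000521"))) 4L
          else stop("unsupported binary encoding in group '", id, "'")
    enc[[id]] <- sz
  }
  specs <- xml2::xml_find_all(doc, ".//spectrum")
  n <- length(specs)
  if (n == 0) stop("imzML file contains no spectra")
  coords <- matrix(0L, n, 2, dimnames = list(NULL, c("x", "y")))
  arr <- data.frame(mzOffset = numeric(n), mzLength = integer(n),
                    mzSize = integer(n), intOffset = numeric(n),
                    intLength = integer(n), intSize = integer(n))
  for (i in seq_len(n)) {
    s <- specs[[i]]
    coords[i, ] <- c(as.integer(.imsParam(s, "IMS:1000050")),
                     as.integer(.imsParam(s, "IMS:1000051")))
    bdas <- xml2::xml_find_all(s, ".//binaryDataArray")
    for (b in bdas) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(b, ".//referenceableParamGroupRef"), "ref")
      off <- as.numeric(.imsParam(b, "IMS:1000102"))
      len <- as.integer(.imsParam(b, "IMS:1000103"))
      if (identical(ref, "mzArray")) {
        arr$mzOffset[i] <- off; arr$mzLength[i] <- len
        arr$mzSize[i] <- enc[[ref]]
      } else if (identical(ref, "intensityArray")) {
        arr$intOffset[i] <- off; arr$intLength[i] <- len
        arr$intSize[i] <- enc[[ref]]
      }
    }
  }
  ibdSize <- file.size(ibdPath)
  needed <- max(arr$mzOffset + arr$mzLength * arr$mzSize,
                arr$intOffset + arr$intLength * arr$intSize)
  if (needed > ibdSize) {
    stop(sprintf("truncated ibd: %s has %d bytes but arrays extend to %d",
                 ibdPath, ibdSize, needed))
  }
  mzAxis <- numeric(0)
  if (mode == "continuous") {
    con <- file(ibdPath, "rb")
    on.exit(close(con))
    seek(con, arr$mzOffset[1])
    mzAxis <- readBin(con, "numeric", n = arr$mzLength[1],
                      size = arr$mzSize[1])
  }
  lo <- as.numeric(xml2::xml_attr(xml2::xml_find_first(
    doc, ".//userParam[@name='lowest observed m/z']"), "value"))
  hi <- as.numeric(xml2::xml_attr(xml2::xml_find_first(
    doc, ".//userParam[@name='highest observed m/z']"), "value"))
  px <- as.numeric(.imsParam(
    xml2::xml_find_first(doc, ".//scanSettings"), "IMS:1000046"))
  mzRange <- if (!is.na(lo) && !is.na(hi)) c(lo, hi)
             else if (length(mzAxis) > 0) range(mzAxis) else c(NA, NA)
  new("MSIDataset", imzmlPath = path, ibdPath = ibdPath, mode = mode,
      polarity = polarity, coords = coords, mzAxis = mzAxis, arrays = arr,
      mzRange = mzRange, pixelSizeUm = if (is.na(px)) 125 else px,
      metadata = list())
}

## run f(con) with an open ibd connection
.withIbd <- function(ds, f) {
  con <- file(ds@ibdPath, "rb")
  on.exit(close(con))
  f(con)
}

.readSlice <- function(con, offset, n, size) {
  seek(con, offset)
  readBin(con, "numeric", n = n, size = size)
}

#' Read one pixel spectrum
#'
#' @param ds An [MSIDataset-class].
#' @param i Pixel index (row of `pixelCoords(ds)`).
#' @return List with elements `mz` and `intensity`.
#' @export
getSpectrum <- function(ds, i) {
  stopifnot(i >= 1, i <= nPixels(ds))
  a <- ds@arrays[i, ]
  .withIbd(ds, function(con) {
    mz <- if (ds@mode == "continuous") ds@mzAxis
          else .readSlice(con, a$mzOffset, a$mzLength, a$mzSize)
    list(mz = mz,
         intensity = .readSlice(con, a$intOffset, a$intLength, a$intSize))
  })
}
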