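#' Label-free protein quantification from peptide areas
#'
#' Per replicate, the protein area is the sum of its tryptic peptide
#' areas; mean and standard deviation are then taken across replicates
#' within each region.  Peptides mapping to more than one protein are, by
#' default, counted for every parent and flagged (`sharedPolicy =
#' "count"`); `"unique"` drops them.  Proteins with zero quantified
#' peptides are excluded (with a message).
#'
#' @param idtab An [IdTable-class] (or a peptide `data.frame` with columns
#'   `accession`, `region`, `peptide`, `replicate`, `area`).
#' @param sharedPolicy `"count"` (default) or `"unique"`.
#' @return `data.frame`: `accession`, `region`, `nReplicates`, `meanArea`,
#'   `sdArea` (NA for < 2 replicates), `hasShared`, plus one
#'   `area_<replicate>` column per replicate.
#' @export
proteinLFQ <- function(idtab, sharedPolicy = c("count", "unique")) {
  sharedPolicy <- match.arg(sharedPolicy)
  pep <- if (is(idtab, "IdTable")) idPeptides(idtab) else idtab
  ## shared = same peptide sequence under more than one accession
  parents <- tapply(pep$accession, pep$peptide,
                    function(a) length(unique(a)))
  pep$shared <- parents[pep$peptide] > 1
  if (sharedPolicy == "unique") pep <- pep[!pep$shared, , drop = FALSE]
  if (nrow(pep) == 0) {
    return(data.frame(accession = character(0), region = character(0),
                      nReplicates = integer(0), meanArea = numeric(0),
                      sdArea = numeric(0), hasShared = logical(0)))
  }
  reps <- sort(unique(pep$replicate))
  key <- interaction(pep$accession, pep$region, drop = TRUE)
  out <- lapply(split(pep, key), function(g) {
    perRep <- vapply(reps, function(r) {
      a <- g$area[g$replicate == r & !is.na(g$area)]
      if (length(a) == 0) NA_real_ else sum(a)
    }, numeric(1))
    quantified <- perRep[!is.na(perRep)]
    if (length(quantified) == 0) return(NULL)
    row <- data.frame(accession = g$accession[1], region = g$region[1],
                      nReplicates = length(quantified),
                      meanArea = mean(quantified),
                      sdArea = if (length(quantified) >= 2) {
                        stats::sd(quantified)
                      } else NA_real_,
                      hasShared = any(g$shared), stringsAsFactors = FALSE)
    for (i in seq_along(reps)) {
      row[[paste0("area_", reps[i])]] <- perRep[i]
    }
    row
  })
  dropped <- sum(vapply(out, is.null, logical(1)))
  if (dropped > 0) {
    message(dropped, " protein-region record(s) had no quantified peptides",
            " and were excluded")
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

#' MSI summary intensity of an assigned protein in one ROI
#'
#' Mean over the mask pixels of the single-isotope ion image extracted at
#' the assignment's apex m/z (reading a single isotopologue keeps the
#' readout molecularly specific when envelopes of different species
#' interleave; pass an alternative `mzRead` to read a non-shared isotope
#' when the apex itself is shared with an isobar).
#'
#' @param ds An [MSIDataset-class].
#' @param mask An [ROIMask-class].
#' @param apexMz Apex m/z of the assigned envelope (Th).
#' @param tolPpm Extraction half-window (ppm).
#' @param mzRead Optional override of the read-out isotopologue m/z.
#' @return Numeric mean intensity.
#' @export
msiProteinIntensity <- function(ds, mask, apexMz, tolPpm = 10,
                                mzRead = NULL) {
  mzc <- if (is.null(mzRead)) apexMz else mzRead
  img <- ionImage(ds, mzc, tolPpm = tolPpm, stat = "max")
  idx <- mask@coords
  mean(img[cbind(idx[, "y"], idx[, "x"])])
}

#' Apex height of the peak nearest a target m/z
#'
#' Resolution-specific intensity readout from a picked-peak table: the
#' height of the peak within `tolPpm` of `mz`, or 0 when no such peak
#' exists.  Because neighboring species are resolved into separate peaks
#' at FTICR resolving power, this readout is more interference-robust
#' than an ion-image window that may clip a resolved neighbor's tail.
#'
#' @param peaks Peak table from [pickPeaks()].
#' @param mz Target m/z (Th).
#' @param tolPpm Matching half-window (ppm).
#' @return Numeric peak height (0 if absent).
#' @export
peakHeightAt <- function(peaks, mz, tolPpm = 5) {
  if (nrow(peaks) == 0) return(0)
  d <- abs(peaks$mz - mz)
  j <- which.min(d)
  if (d[j] <= tolPpm * 1e-6 * mz) peaks$intensity[j] else 0
}

#' Fold-change concordance between MSI and LC-MS/MS quantification
#'
#' Computes per-accession fold changes (numerator region over denominator
#' region) on both sides with pseudo-count stabilization, flags direction
#' agreement, and summarizes the direction-agreement fraction and the
#' Spearman rank correlation across shared accessions.  Proteins whose
#' larger |log2 FC| on the LC-MS/MS side is below `minEffect` are reported
#' but excluded from the headline agreement fraction (no real effect means
#' agreement is a coin flip).
#'
#' @param msiQuant `data.frame`: `accession`, `intensityNum`,
#'   `intensityDen` (ROI mean intensities for the two regions).
#' @param lcmsQuant Output of [proteinLFQ()] covering both regions.
#' @param numRegion,denRegion Region labels (numerator / denominator).
#' @param pseudo Pseudo-count; default half the smallest nonzero mean area
#'   (LC-MS/MS side) and half the smallest nonzero intensity (MSI side).
#' @param minEffect Minimum |log2 FC| for the headline summary
#'   (default 0.5).
#' @return List with `records` (per-accession `data.frame`: both fold
#'   changes, `agree`, `oneSided`, `usedInSummary`) and `summary`
#'   (`nShared`, `agreementFraction`, `spearman`).
#' @export
concordance <- function(msiQuant, lcmsQuant, numRegion, denRegion,
                        pseudo = NULL, minEffect = 0.5) {
  lnum <- lcmsQuant[lcmsQuant$region == numRegion, ]
  lden <- lcmsQuant[lcmsQuant$region == denRegion, ]
  shared <- intersect(msiQuant$accession,
                      union(lnum$accession, lden$accession))
  if (length(shared) == 0) stop("no shared accessions between MSI and LC-MS/MS")
  areas <- c(lnum$meanArea, lden$meanArea)
  pseudoL <- if (is.null(pseudo)) min(areas[areas > 0]) / 2 else pseudo
  ints <- c(msiQuant$intensityNum, msiQuant$intensityDen)
  pseudoM <- if (is.null(pseudo)) {
    if (any(ints > 0)) min(ints[ints > 0]) / 2 else 1
  } else pseudo
  rec <- do.call(rbind, lapply(shared, function(acc) {
    aNum <- lnum$meanArea[match(acc, lnum$accession)]
    aDen <- lden$meanArea[match(acc, lden$accession)]
    oneSided <- is.na(aNum) || is.na(aDen)
    aNum <- if (is.na(aNum)) 0 else aNum
    aDen <- if (is.na(aDen)) 0 else aDen
    fcL <- (aNum + pseudoL) / (aDen + pseudoL)
    i <- match(acc, msiQuant$accession)
    fcM <- (msiQuant$intensityNum[i] + pseudoM) /
      (msiQuant$intensityDen[i] + pseudoM)
    data.frame(accession = acc, msiFC = fcM, lcmsFC = fcL,
               agree = sign(log(fcM)) == sign(log(fcL)),
               oneSided = oneSided,
               usedInSummary = abs(log2(fcL)) >= minEffect,
               stringsAsFactors = FALSE)
  }))
  used <- rec[rec$usedInSummary, , drop = FALSE]
  summary <- list(
    nShared = nrow(rec),
    nUsed = nrow(used),
    agreementFraction = if (nrow(used) > 0) mean(used$agree) else NA_real_,
    spearman = if (nrow(rec) > 2) {
      stats::cor(log(rec$msiFC), log(rec$lcmsFC), method = "spearman")
    } else NA_real_)
  list(records = rec, summary = summary)
}

#' Bar-chart of protein LFQ (mean area +/- sd per region)
#'
#' @param lfq Output of [proteinLFQ()].
#' @param accessions Accessions to plot (default: all, up to 12).
#' @export
plotProteinQuant <- function(lfq, accessions = NULL) {
  if (is.null(accessions)) {
    accessions <- utils::head(unique(lfq$accession), 12)
  }
  sub <- lfq[lfq$accession %in% accessions, ]
  regions <- unique(sub$region)
  mat <- matrix(0, length(regions), length(accessions),
                dimnames = list(regions, accessions))
  sds <- mat
  for (i in seq_len(nrow(sub))) {
    mat[sub$region[i], sub$accession[i]] <- sub$meanArea[i]
    sds[sub$region[i], sub$accession[i]] <-
      ifelse(is.na(sub$sdArea[i]), 0, sub$sdArea[i])
  }
  bp <- graphics::barplot(mat, beside = TRUE, legend.text = regions,
                          las = 2, ylab = "summed peptide area",
                          ylim = c(0, max(mat + sds) * 1.1))
  graphics::arrows(bp, mat, bp, mat + sds, angle = 90, length = 0.03)
  invisible(bp)
}
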