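## djb2-style hash of a config list, echoed into every report for
## provenance (two runs with equal hashes used identical settings)
.configHash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}

.reportHeader <- function(config, seed = NULL) {
  lines <- c(
    sprintf("# proteoMSI %s", as.character(utils::packageVersion("proteoMSI"))),
    sprintf("# isotope table: %s", ISOTOPE_TABLE_VERSION),
    sprintf("# config hash: %s", .configHash(config)))
  if (!is.null(seed)) lines <- c(lines, sprintf("# seed: %d", seed))
  for (k in names(config)) {
    v <- config[[k]]
    if (is.atomic(v) && length(v) <= 6) {
      lines <- c(lines, sprintf("# %s = %s", k, paste(v, collapse = ",")))
    }
  }
  lines
}

.writeReport <- function(df, path, config, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.reportHeader(config, seed), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plain key = value run configuration
#'
#' One `key = value` per line; `#` starts a comment.  Dotted keys group
#' settings (`match.ppm = 10`).  Unknown keys are rejected so typos never
#' silently fall back to defaults.
#'
#' @param path Config file.
#' @return Named list of character values.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  known <- c("paths.imzml", "paths.masks", "paths.idtable", "paths.fasta",
             "paths.library", "paths.out", "match.ppm", "match.rmin",
             "search.maxTotalMods", "search.massWindowLow",
             "search.massWindowHigh", "sim.nProteins", "sim.grid",
             "sim.seed", "seed", "metabolite.polarity",
             "metabolite.ionType", "metabolite.derivDelta",
             "metabolite.tolPpm", "decoys.n")
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: '", ln, "'")
    k <- trimws(kv[1]); v <- trimws(kv[2])
    if (!k %in% known) {
      stop("unknown config key '", k, "'; known keys: ",
           paste(known, collapse = ", "))
    }
    cfg[[k]] <- v
  }
  cfg
}

#' Run the full synthetic-data generation stage
#'
#' Generates a ground-truth proteome, renders the MSI dataset (imzML +
#' ROI masks + truth manifest) and writes the replicate-level
#' identification/quant tables and FASTA, all under one seed.
#'
#' @param dir Output directory.
#' @param seed Integer seed (mandatory; seeds are never implicit).
#' @param nProteins,massRange,instrument,grid,nReplicates,peptideCV
#'   Forwarded to the generators.
#' @param ... Further arguments to [simulateProteome()].
#' @return List: `truth`, `msi` (see [simulateMSI()]), `quant` (see
#'   [simulateQuantTables()]), `manifestPath`.
#' @export
runSimulate <- function(dir, seed, nProteins = 50,
                        massRange = c(3500, 16000),
                        instrument = InstrumentModel(), grid = c(4, 4),
                        nReplicates = 3, peptideCV = 0.2, ...) {
  if (missing(seed)) stop("seed is mandatory")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- simulateProteome(nProteins = nProteins, massRange = massRange,
                            seed = seed, ...)
  msi <- simulateMSI(truth, instrument = instrument, grid = grid,
                     seed = seed + 1, dir = dir)
  quant <- simulateQuantTables(truth, nReplicates = nReplicates,
                               peptideCV = peptideCV, seed = seed + 2,
                               dir = dir)
  manifestPath <- file.path(dir, "bundle_manifest.json")
  jsonlite::write_json(
    list(seed = seed,
         files = c(basename(msi$dataset@imzmlPath),
                   basename(msi$dataset@ibdPath),
                   basename(msi$manifestPath),
                   basename(quant$idTablePath),
                   basename(quant$fastaPath),
                   "bundle_manifest.json")),
    manifestPath, auto_unbox = TRUE, digits = NA)
  list(truth = truth, msi = msi, quant = quant,
       manifestPath = manifestPath)
}

#' End-to-end protein annotation and concordance workflow
#'
#' ROI-average spectra -> peak picking -> envelope extraction ->
#' region-restricted accurate-mass + envelope-correlation assignment ->
#' charge-state corroboration -> decoy competition -> label-free
#' quantification concordance.  All reports are written with a config
#' echo and version header.
#'
#' @param imzmlPath Continuous imzML dataset.
#' @param maskPath ROI mask JSON (labels must match the identification
#'   table's region labels).
#' @param idTablePath Identification/quant table (TSV).
#' @param fastaPath Companion FASTA.
#' @param outDir Report directory.
#' @param matchCfg A [MatchConfig-class].
#' @param searchCfg A [SearchSpaceConfig-class].
#' @param snrMin Peak-picking SNR threshold.
#' @param nDecoys Decoy replicates (0 disables the decoy stage).
#' @param seed Seed for the decoy shuffles.
#' @param fcRegions Length-2 region labels (numerator, denominator) for
#'   the concordance stage; default = first two mask labels.
#' @return List: per-region `envelopes`, `assignments`, `primary`,
#'   `chargeGroups`, `decoys`, plus `lfq`, `concordance`, `reportPaths`.
#' @export
runProteinWorkflow <- function(imzmlPath, maskPath, idTablePath,
                               fastaPath, outDir = tempfile("reports"),
                               matchCfg = MatchConfig(),
                               searchCfg = SearchSpaceConfig(),
                               snrMin = 5, nDecoys = 1, seed = 1,
                               fcRegions = NULL) {
  for (p in c(imzmlPath, maskPath, idTablePath, fastaPath)) {
    if (!file.exists(p)) stop("input not found: ", p)
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cfgEcho <- list(imzml = imzmlPath, masks = maskPath,
                  idTable = idTablePath, fasta = fastaPath,
                  ppm = matchCfg@tolerancePpm, rmin = matchCfg@rMin,
                  snrMin = snrMin, nDecoys = nDecoys)
  ds <- tryCatch(readImzML(imzmlPath),
                 error = function(e) stop("[stage: read-imzml] ",
                                          conditionMessage(e)))
  masks <- tryCatch(readRoiMasks(maskPath),
                    error = function(e) stop("[stage: read-masks] ",
                                             conditionMessage(e)))
  idtab <- tryCatch(loadIdTable(idTablePath, fasta = fastaPath),
                    error = function(e) stop("[stage: load-idtable] ",
                                             conditionMessage(e)))
  records <- idRecords(idtab)
  candidates <- tryCatch(enumerateAllCandidates(idtab, searchCfg),
                         error = function(e) stop("[stage: enumerate] ",
                                                  conditionMessage(e)))
  perRegion <- list()
  allAssignments <- list()
  for (lab in names(masks)) {
    avg <- roiAverageSpectrum(ds, masks[[lab]])
    peaks <- pickPeaks(avg, snrMin = snrMin)
    envs <- findEnvelopes(peaks)
    cands <- restrictByRegion(candidates, lab)
    res <- assignRoi(envs, cands, matchCfg, roiLabel = lab)
    groups <- corroborateCharges(res$assignments,
                                 tolPpm = matchCfg@tolerancePpm)
    decoys <- NULL
    if (nDecoys > 0) {
      regRecs <- Filter(function(r) r$region == lab, records)
      decoys <- decoyAssign(envs, cands, regRecs, matchCfg, searchCfg,
                            nDecoys = nDecoys, seed = seed)
    }
    perRegion[[lab]] <- list(average = avg, peaks = peaks,
                             envelopes = envs, assignments = res,
                             chargeGroups = groups, decoys = decoys)
    if (nrow(res$assignments) > 0) {
      allAssignments[[lab]] <- res$assignments
    }
  }
  assignAll <- do.call(rbind, allAssignments)
  reportPaths <- character(0)
  if (!is.null(assignAll)) {
    p <- file.path(outDir, "assignments.tsv")
    .writeReport(assignAll, p, cfgEcho, seed)
    reportPaths <- c(reportPaths, p)
  }
  ## LFQ + concordance over primary-assigned accessions
  lfq <- proteinLFQ(idtab)
  conc <- NULL
  regs <- if (is.null(fcRegions)) names(masks)[1:2] else fcRegions
  prim <- do.call(rbind, lapply(names(masks), function(lab) {
    perRegion[[lab]]$assignments$primary
  }))
  assigned <- unique(stats::na.omit(unlist(lapply(perRegion, function(pr) {
    pr$assignments$primary$accession
  }))))
  assigned <- setdiff(assigned, NA)
  if (length(assigned) > 0 && length(regs) == 2) {
    msiQuant <- do.call(rbind, lapply(assigned, function(acc) {
      ## read out the accession's strongest assigned envelope apex
      apexes <- unlist(lapply(perRegion, function(pr) {
        pr$assignments$primary$apexMz[
          which(pr$assignments$primary$accession == acc)]
      }))
      if (length(apexes) == 0) return(NULL)
      mzc <- apexes[1]
      data.frame(accession = acc,
                 intensityNum = msiProteinIntensity(ds, masks[[regs[1]]],
                                                    mzc),
                 intensityDen = msiProteinIntensity(ds, masks[[regs[2]]],
                                                    mzc),
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(msiQuant) &&
        length(intersect(msiQuant$accession, lfq$accession)) > 0) {
      conc <- concordance(msiQuant, lfq, regs[1], regs[2])
      p <- file.path(outDir, "concordance.tsv")
      .writeReport(conc$records, p, cfgEcho, seed)
      reportPaths <- c(reportPaths, p)
    }
  }
  p <- file.path(outDir, "protein_lfq.tsv")
  .writeReport(lfq, p, cfgEcho, seed)
  reportPaths <- c(reportPaths, p)
  list(regions = perRegion, lfq = lfq, concordance = conc,
       reportPaths = reportPaths)
}

#' Metabolite annotation workflow
#'
#' Annotates per-region peak lists against a reference library by
#' accurate mass and isotope pattern, computes per-mass-class region fold
#' changes with pseudo-count stabilization, and rolls annotations up by
#' pathway with up/down direction.
#'
#' @param peaksByRegion Named list of peak `data.frame`s (`mz`,
#'   `intensity`), one per region; first name is the fold-change
#'   numerator.
#' @param libraryPath Metabolite library TSV (or a library `data.frame`).
#' @param mode An [IonMode-class].
#' @param tolPpm Matching tolerance (ppm).
#' @param outDir Report directory (NULL suppresses files).
#' @return List: `annotations` (per region), `foldChanges`
#'   (per mass-class), `pathways` (roll-up), `reportPaths`.
#' @export
runMetaboliteWorkflow <- function(peaksByRegion, libraryPath,
                                  mode, tolPpm = 2, outDir = NULL) {
  if (length(peaksByRegion) == 0) stop("no peak lists supplied")
  lib <- if (is.data.frame(libraryPath)) libraryPath
         else readMetaboliteLibrary(libraryPath)
  if (nrow(lib) == 0) {
    warning("empty metabolite library: empty report")
  }
  regs <- names(peaksByRegion)
  ann <- lapply(peaksByRegion, annotateLibrary, library = lib,
                mode = mode, tolPpm = tolPpm)
  ## per-mass-class fold change (region 1 over region 2)
  fc <- NULL
  if (length(regs) >= 2) {
    keys <- unique(unlist(lapply(ann, function(a) a$formula)))
    getI <- function(a, k) {
      i <- match(k, a$formula)
      if (is.na(i)) 0 else a$intensity[i]
    }
    iNum <- vapply(keys, getI, numeric(1), a = ann[[regs[1]]])
    iDen <- vapply(keys, getI, numeric(1), a = ann[[regs[2]]])
    pseudo <- if (any(c(iNum, iDen) > 0)) {
      min(c(iNum, iDen)[c(iNum, iDen) > 0]) / 2
    } else 1
    nameOf <- function(k) {
      for (a in ann) {
        i <- match(k, a$formula)
        if (!is.na(i)) return(a$names[i])
      }
      ""
    }
    pathOf <- function(k) {
      for (a in ann) {
        i <- match(k, a$formula)
        if (!is.na(i)) return(a$pathway[i])
      }
      ""
    }
    fc <- data.frame(formula = keys,
                     names = vapply(keys, nameOf, character(1)),
                     pathway = vapply(keys, pathOf, character(1)),
                     intensityNum = iNum, intensityDen = iDen,
                     foldChange = (iNum + pseudo) / (iDen + pseudo),
                     stringsAsFactors = FALSE)
    fc$direction <- ifelse(fc$foldChange > 1, "up", "down")
    rownames(fc) <- NULL
  }
  pathways <- NULL
  if (!is.null(fc) && nrow(fc) > 0) {
    pathways <- do.call(rbind, lapply(split(fc, fc$pathway), function(g) {
      data.frame(pathway = g$pathway[1], nClasses = nrow(g),
                 nUp = sum(g$direction == "up"),
                 nDown = sum(g$direction == "down"),
                 stringsAsFactors = FALSE)
    }))
    rownames(pathways) <- NULL
  }
  reportPaths <- character(0)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    cfgEcho <- list(tolPpm = tolPpm, polarity = mode@polarity,
                    ionType = mode@ionType)
    for (r in regs) {
      p <- file.path(outDir, paste0("metabolites_", r, ".tsv"))
      .writeReport(ann[[r]], p, cfgEcho)
      reportPaths <- c(reportPaths, p)
    }
    if (!is.null(fc)) {
      p <- file.path(outDir, "metabolite_foldchanges.tsv")
      .writeReport(fc, p, cfgEcho)
      reportPaths <- c(reportPaths, p)
    }
  }
  list(annotations = ann, foldChanges = fc, pathways = pathways,
       reportPaths = reportPaths)
}
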