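#' InstrumentModel class: synthetic FT mass analyzer
#'
#' FTICR mode: resolving power scales as `R(m/z) = R_ref * mzRef / mz`
#' (longer effective transient at low m/z), the default being the minimal
#' resolving power consistent with full isotopic resolution of singly
#' charged protein ions up to m/z 16,000.  The profile axis is uniform in
#' 1/mz (the FT frequency domain), which yields a constant number of
#' samples per peak width everywhere.  TOF-emulation mode uses a constant
#' resolving power (linear-TOF-like) for contrast experiments; its
#' isotopologues of intact proteins merge into single broad peaks.
#'
#' @slot analyzer `"fticr"` or `"tof"`.
#' @slot resolvingPower Resolving power at `refMz` (FTICR) or everywhere
#'   (TOF).
#' @slot refMz Reference m/z for the FTICR scaling.
#' @slot peakShape `"gaussian"` (default; analytic apex math) or
#'   `"lorentzian"`.
#' @slot calibrationPpmSd Per-dataset mass-calibration error s.d. (ppm),
#'   truncated at 2 s.d.
#' @slot jitterPpm Per-peak centroid jitter s.d. (ppm).
#' @slot noiseFloor Additive noise s.d. (intensity units).
#' @slot pixelCV Per-pixel multiplicative (log-normal) abundance CV.
#' @slot mzRange Acquisition m/z window.
#' @slot samplesPerFwhm Axis sampling density.
#' @export
setClass("InstrumentModel",
  representation(analyzer = "character", resolvingPower = "numeric",
                 refMz = "numeric", peakShape = "character",
                 calibrationPpmSd = "numeric", jitterPpm = "numeric",
                 noiseFloor = "numeric", pixelCV = "numeric",
                 mzRange = "numeric", samplesPerFwhm = "numeric"),
  validity = function(object) {
    if (object@resolvingPower <= 0) return("resolvingPower must be > 0")
    if (!object@analyzer %in% c("fticr", "tof")) {
      return("analyzer must be 'fticr' or 'tof'")
    }
    if (!object@peakShape %in% c("gaussian", "lorentzian")) {
      return("peakShape must be 'gaussian' or 'lorentzian'")
    }
    TRUE
  }
)

#' Construct an instrument model
#'
#' @param analyzer `"fticr"` (default) or `"tof"`.
#' @param resolvingPower R at `refMz` (default 50,000 at m/z 16,000 for
#'   FTICR; 1,000 for TOF emulation).
#' @param refMz Reference m/z.
#' @param peakShape `"gaussian"` or `"lorentzian"`.
#' @param calibrationPpmSd Calibration error s.d. (ppm).
#' @param jitterPpm Per-peak centroid jitter (ppm).
#' @param noiseFloor Additive noise s.d.
#' @param pixelCV Per-pixel abundance CV.
#' @param mzRange Acquisition window (protein default 3,500-16,500, the
#'   isotopically resolved regime).
#' @param samplesPerFwhm Profile samples per peak FWHM (default 4).
#' @return An [InstrumentModel-class].
#' @export
InstrumentModel <- function(analyzer = c("fticr", "tof"),
                            resolvingPower = NULL, refMz = 16000,
                            peakShape = "gaussian",
                            calibrationPpmSd = 1.5, jitterPpm = 0.2,
                            noiseFloor = 1, pixelCV = 0.25,
                            mzRange = c(3500, 16500),
                            samplesPerFwhm = 4) {
  analyzer <- match.arg(analyzer)
  if (is.null(resolvingPower)) {
    resolvingPower <- if (analyzer == "fticr") 50000 else 1000
  }
  new("InstrumentModel", analyzer = analyzer,
      resolvingPower = resolvingPower, refMz = refMz,
      peakShape = peakShape, calibrationPpmSd = calibrationPpmSd,
      jitterPpm = jitterPpm, noiseFloor = noiseFloor, pixelCV = pixelCV,
      mzRange = as.numeric(mzRange), samplesPerFwhm = samplesPerFwhm)
}

setMethod("show", "InstrumentModel", function(object) {
  cat(sprintf(
    "InstrumentModel (%s): R = %g at m/z %g, %s peaks, m/z %g-%g\n",
    object@analyzer, object@resolvingPower, object@refMz,
    object@peakShape, object@mzRange[1], object@mzRange[2]))
})

#' Peak FWHM of an instrument at a given m/z
#' @param instrument An [InstrumentModel-class].
#' @param mz m/z (Th).
#' @return FWHM in Th.
#' @export
peakFwhm <- function(instrument, mz) {
  if (instrument@analyzer == "fticr") {
    mz^2 / (instrument@resolvingPower * instrument@refMz)
  } else {
    mz / instrument@resolvingPower
  }
}

#' Profile m/z axis of an instrument model
#'
#' FTICR: uniform in 1/mz so that the sample spacing tracks the
#' quadratically growing FWHM; TOF: log-spaced (constant relative width).
#'
#' @param instrument An [InstrumentModel-class].
#' @return Strictly increasing numeric m/z axis.
#' @export
instrumentAxis <- function(instrument) {
  lo <- instrument@mzRange[1]; hi <- instrument@mzRange[2]
  if (instrument@analyzer == "fticr") {
    du <- 1 / (instrument@samplesPerFwhm * instrument@resolvingPower *
                 instrument@refMz)
    u <- seq(1 / lo, 1 / hi, by = -du)
    1 / u
  } else {
    dl <- 1 / (instrument@samplesPerFwhm * instrument@resolvingPower)
    exp(seq(log(lo), log(hi), by = dl))
  }
}

## precompute one ion's profile contribution on the axis: the shape is
## pixel-invariant, so per pixel only `y[lo:hi] += intensity * vals`
## remains.  Returns NULL if the ion misses the axis entirely.
.ionShape <- function(axis, instrument, mzs, abund) {
  n <- length(axis)
  fw <- peakFwhm(instrument, mzs)
  lo <- findInterval(min(mzs) - 5 * max(fw), axis) + 1
  hi <- findInterval(max(mzs) + 5 * max(fw), axis)
  lo <- max(lo, 1); hi <- min(hi, n)
  if (hi < lo) return(NULL)
  x <- axis[lo:hi]
  vals <- numeric(length(x))
  for (i in seq_along(mzs)) {
    if (instrument@peakShape == "gaussian") {
      sigma <- fw[i] / 2.354820045
      vals <- vals + abund[i] * exp(-0.5 * ((x - mzs[i]) / sigma)^2)
    } else {
      hw <- fw[i] / 2
      vals <- vals + abund[i] * hw^2 / ((x - mzs[i])^2 + hw^2)
    }
  }
  list(lo = lo, hi = hi, vals = vals)
}

## add one species' envelope to a profile spectrum; thin wrapper kept for
## one-off rendering (tests, small fixtures)
.renderSpecies <- function(y, axis, instrument, mzs, abund, intensity) {
  sh <- .ionShape(axis, instrument, mzs, abund)
  if (is.null(sh)) return(y)
  y[sh$lo:sh$hi] <- y[sh$lo:sh$hi] + intensity * sh$vals
  y
}

## vertebrate-average residue frequencies (order = rownames(.residueTable))
.residueFreq <- c(
  G = 0.074, A = 0.074, S = 0.081, P = 0.050, V = 0.068, T = 0.062,
  C = 0.025, L = 0.076, I = 0.038, N = 0.044, D = 0.059, Q = 0.037,
  K = 0.072, E = 0.058, M = 0.018, H = 0.029, F = 0.040, R = 0.042,
  Y = 0.033, W = 0.013
)

## random protein-like sequence reaching (just exceeding) a target mass
.randomSequence <- function(targetMass, freq = .residueFreq) {
  res <- names(freq)
  p <- freq / sum(freq)
  aa <- "M"
  m <- .residueMonoMass[["M"]] + WATER_MONO_MASS
  while (m < targetMass) {
    r <- sample(res, 1, prob = p)
    aa <- c(aa, r)
    m <- m + .residueMonoMass[[r]]
  }
  paste(aa, collapse = "")
}

#' Simulate a region-structured proteome with known proteoforms
#'
#' Generates random protein sequences with realistic residue composition,
#' plants region-specific abundances (a fraction exclusive to one region,
#' the rest shared with planted fold changes), and gives a subset of
#' proteins histone-like PTM ladders (mono-/di-/tri-methyl and acetyl
#' proteoforms) emitted at multiple charge states.  Everything is driven
#' by one seed; identical inputs reproduce identical output.
#'
#' @param nProteins Number of backbone proteins.
#' @param massRange Neutral monoisotopic mass window (Da) the backbones
#'   are drawn from.
#' @param regions Character vector of region labels (first = "up" region
#'   for positive fold changes).
#' @param pExclusive Fraction of proteins exclusive to one region (split
#'   evenly).
#' @param log2fcChoices Planted log2 fold changes (region 1 over region 2)
#'   for shared proteins, drawn uniformly.
#' @param pModStack Fraction of proteins given a PTM ladder.
#' @param charges Charge states every species may be emitted at (clipped
#'   to the instrument window at dataset-simulation time).
#' @param abundanceRange Base abundance range (log-uniform).
#' @param seed Integer seed (mandatory).
#' @return A ground-truth list: `sequences` (named), `species`
#'   (`data.frame` with accession, proteoform tag, modification counts,
#'   adduct, formula, neutral masses, per-region abundance columns
#'   `abund_<region>`), `regions`, `params`.
#' @export
simulateProteome <- function(nProteins = 50, massRange = c(3500, 16000),
                             regions = c("tumor", "healthy"),
                             pExclusive = 0.2,
                             log2fcChoices = c(-2, -1, 0, 1, 2),
                             pModStack = 0.2, charges = 1:3,
                             abundanceRange = c(50, 500), seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(nProteins >= 1, massRange[1] < massRange[2])
  if (massRange[2] > 30000) stop("infeasible mass range (> 30 kDa)")
  set.seed(seed)
  regs <- regions
  targets <- exp(stats::runif(nProteins, log(massRange[1]),
                              log(massRange[2])))
  seqs <- character(nProteins)
  accs <- sprintf("SIM%03d", seq_len(nProteins))
  rows <- list()
  modNames <- c("methyl", "acetyl", "oxidation", "deamidation",
                "disulfide")
  ladder <- list(c(methyl = 0), c(methyl = 1), c(methyl = 2),
                 c(methyl = 3), c(acetyl = 1))
  ladderScale <- c(1, 0.8, 0.6, 0.45, 0.7)
  for (i in seq_len(nProteins)) {
    seqs[i] <- .randomSequence(targets[i])
    base <- exp(stats::runif(1, log(abundanceRange[1]),
                             log(abundanceRange[2])))
    u <- stats::runif(1)
    if (u < pExclusive / 2) {
      ab <- stats::setNames(c(base, 0), regs)
      fc <- Inf
    } else if (u < pExclusive) {
      ab <- stats::setNames(c(0, base), regs)
      fc <- -Inf
    } else {
      l2 <- sample(log2fcChoices, 1)
      ab <- stats::setNames(c(base * 2^l2, base), regs)
      fc <- l2
    }
    comp0 <- compositionFromSequence(seqs[i])
    stack <- if (stats::runif(1) < pModStack) seq_along(ladder) else 1L
    for (si in stack) {
      mods <- stats::setNames(integer(length(modNames)), modNames)
      mods[names(ladder[[si]])] <- ladder[[si]]
      comp <- comp0
      for (mn in names(mods)) {
        if (mods[[mn]] > 0) {
          comp <- applyDelta(comp, modificationDelta(mn), mods[[mn]])
        }
      }
      tag <- .modTag(mods)
      row <- data.frame(accession = accs[i], variant = "full",
                        stringsAsFactors = FALSE)
      for (mn in modNames) row[[mn]] <- mods[[mn]]
      row$adduct <- "proton"
      row$proteoform <- paste(accs[i], "full", tag, "proton", sep = "|")
      row$formula <- formulaString(comp)
      row$neutralMono <- monoisotopicMass(comp)
      row$charges <- paste(charges, collapse = ",")
      row$log2fc <- fc
      for (r in regs) {
        row[[paste0("abund_", r)]] <- ab[[r]] * ladderScale[si]
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  species <- do.call(rbind, rows)
  rownames(species) <- NULL
  names(seqs) <- accs
  list(sequences = seqs, species = species, regions = regs,
       params = list(nProteins = nProteins, massRange = massRange,
                     pExclusive = pExclusive,
                     log2fcChoices = log2fcChoices,
                     pModStack = pModStack, charges = charges,
                     abundanceRange = abundanceRange, seed = seed))
}

## deterministic 16-byte uuid from a seed
.seedUuid <- function(seed) {
  x <- as.integer(seed)
  set.seed(x)
  as.raw(sample(0:255, 16, replace = TRUE))
}

#' Render and write a synthetic MSI dataset (imzML + ROI masks + manifest)
#'
#' Renders every ground-truth species at every charge state whose ion
#' falls inside the instrument window: the exact isotope envelope (from
#' the species' elemental composition) convolved with the instrument peak
#' shape, scaled by the species' region abundance and a per-pixel
#' log-normal factor, shifted by a per-dataset calibration error and
#' per-peak jitter, on top of additive Gaussian noise.  Pixels are
#' streamed straight to a continuous imzML file.  The ground-truth
#' manifest (JSON) records every rendered ion with its calibrated apex
#' m/z.
#'
#' @param truth Output of [simulateProteome()] (or a compatible list).
#' @param instrument An [InstrumentModel-class].
#' @param grid `c(nx, ny)` pixel grid (default 4 x 4).
#' @param roiLayout Optional named list `label -> 2-column coordinate
#'   matrix`; default splits the grid into left/right halves in the order
#'   of `truth$regions`.  Labels may not overlap.
#' @param seed Integer seed (mandatory).
#' @param dir Output directory (created if needed).
#' @param name Dataset base name.
#' @return List: `dataset` ([MSIDataset-class]), `masks` (named
#'   [ROIMask-class] list), `ions` (`data.frame` of rendered ions with
#'   truth apex m/z), `manifestPath`, `calibrationPpm`.
#' @export
simulateMSI <- function(truth, instrument = InstrumentModel(),
                        grid = c(4, 4), roiLayout = NULL, seed,
                        dir = tempfile("msi"), name = "simulated") {
  if (missing(seed)) stop("seed is mandatory")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  nx <- grid[1]; ny <- grid[2]
  regs <- truth$regions
  if (is.null(roiLayout)) {
    half <- floor(nx / 2)
    stopifnot(length(regs) == 2)
    g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
    roiLayout <- list(as.matrix(g[g$x <= half, ]),
                      as.matrix(g[g$x > half, ]))
    names(roiLayout) <- regs
  }
  ## overlap check
  allPix <- do.call(rbind, roiLayout)
  if (anyDuplicated(allPix) > 0) {
    stop("ROI labels overlap on at least one pixel")
  }
  masks <- lapply(names(roiLayout), function(l) ROIMask(l, roiLayout[[l]]))
  names(masks) <- names(roiLayout)

  axis <- instrumentAxis(instrument)
  calibPpm <- max(-2, min(2, stats::rnorm(1))) * instrument@calibrationPpmSd
  calib <- 1 + calibPpm * 1e-6

  ## theoretical ion envelopes for every species x charge in window
  sp <- truth$species
  ions <- list()
  for (i in seq_len(nrow(sp))) {
    neutral <- isotopeDistribution(ElementalComposition(sp$formula[i]),
                                   pruneThreshold = 0.01)
    for (z in as.integer(strsplit(sp$charges[i], ",")[[1]])) {
      env <- ionize(neutral, z, "proton")
      am <- apexMz(env)
      if (am < instrument@mzRange[1] || am > instrument@mzRange[2]) next
      jitter <- stats::rnorm(length(mzValues(env)), 0,
                             instrument@jitterPpm * 1e-6) + calib
      ions[[length(ions) + 1]] <- list(
        speciesRow = i, charge = z,
        mz = mzValues(env) * jitter, abund = abundances(env),
        apexTrue = am * calib)
    }
  }
  ionTab <- do.call(rbind, lapply(ions, function(io) {
    data.frame(accession = sp$accession[io$speciesRow],
               proteoform = sp$proteoform[io$speciesRow],
               label = paste0(sp$proteoform[io$speciesRow], "|z",
                              io$charge),
               charge = io$charge, apexMz = io$apexTrue,
               neutralMono = sp$neutralMono[io$speciesRow],
               stringsAsFactors = FALSE)
  }))
  for (r in regs) {
    ionTab[[paste0("abund_", r)]] <- vapply(seq_along(ions), function(k) {
      sp[[paste0("abund_", r)]][ions[[k]]$speciesRow]
    }, numeric(1))
  }

  ## pixel -> region lookup
  pixRegion <- matrix(NA_character_, ny, nx)
  for (l in names(roiLayout)) {
    m <- roiLayout[[l]]
    pixRegion[cbind(m[, 2], m[, 1])] <- l
  }

  imzmlPath <- file.path(dir, paste0(name, ".imzML"))
  w <- imzmlWriterOpen(imzmlPath, mode = "continuous",
                       polarity = "positive", mzAxis = axis,
                       pixelSizeUm = 125, uuid = .seedUuid(seed + 1))
  shapes <- lapply(ions, function(io) {
    .ionShape(axis, instrument, io$mz, io$abund)
  })
  coordsAll <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  for (p in seq_len(nrow(coordsAll))) {
    px <- coordsAll$x[p]; py <- coordsAll$y[p]
    reg <- pixRegion[py, px]
    ## additive detector noise; not clipped at zero, as in FT magnitude
    ## residuals after baseline removal
    y <- stats::rnorm(length(axis), 0, instrument@noiseFloor)
    if (!is.na(reg)) {
      abCol <- paste0("abund_", reg)
      for (k in seq_along(ions)) {
        sh <- shapes[[k]]
        if (is.null(sh)) next
        ab <- sp[[abCol]][ions[[k]]$speciesRow]
        if (ab <= 0) next
        intensity <- ab * stats::rlnorm(1, 0, instrument@pixelCV)
        y[sh$lo:sh$hi] <- y[sh$lo:sh$hi] + intensity * sh$vals
      }
    }
    imzmlWriteSpectrum(w, px, py, y)
  }
  imzmlWriterClose(w)
  maskPath <- file.path(dir, paste0(name, "_rois.json"))
  writeRoiMasks(masks, maskPath)
  manifestPath <- file.path(dir, paste0(name, "_truth.json"))
  jsonlite::write_json(
    list(seed = seed, calibrationPpm = calibPpm,
         isotopeTable = ISOTOPE_TABLE_VERSION,
         instrument = list(analyzer = instrument@analyzer,
                           resolvingPower = instrument@resolvingPower,
                           refMz = instrument@refMz,
                           mzRange = instrument@mzRange),
         regions = regs, ions = ionTab,
         files = c(basename(imzmlPath),
                   sub("\\.imzML$", ".ibd", basename(imzmlPath)),
                   basename(maskPath), basename(manifestPath))),
    manifestPath, auto_unbox = TRUE, digits = NA)
  list(dataset = readImzML(imzmlPath), masks = masks, ions = ionTab,
       manifestPath = manifestPath, calibrationPpm = calibPpm)
}

#' Simulate replicate-level identification and peptide-area tables
#'
#' In-silico tryptic digestion (cleave after K/R, not before P, up to 2
#' missed cleavages) of every ground-truth protein present in a region,
#' with log-normal peptide areas scaled by the planted region abundances:
#' protein abundance x a per-peptide ionization factor (log-normal,
#' shared across replicates and regions) x per-replicate noise with the
#' requested CV.
#'
#' @param truth Output of [simulateProteome()].
#' @param nReplicates Replicates per region (sections; default 3).
#' @param peptideCV Replicate-level coefficient of variation.
#' @param missedCleavages Maximum missed cleavages (default 2).
#' @param seed Integer seed (mandatory).
#' @param dir Output directory.
#' @param name Base name for the table and FASTA.
#' @return List: `idTablePath`, `fastaPath`, `table` (the long-format
#'   `data.frame`).
#' @export
simulateQuantTables <- function(truth, nReplicates = 3, peptideCV = 0.2,
                                missedCleavages = 2, seed,
                                dir = tempfile("quant"),
                                name = "identifications") {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(nReplicates >= 1)
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- truth$species
  regs <- truth$regions
  ## backbone-level region abundance = sum over proteoform species
  accs <- unique(sp$accession)
  rows <- list()
  sigma <- sqrt(log(1 + peptideCV^2))
  for (acc in accs) {
    peps <- trypticPeptides(truth$sequences[[acc]],
                            missedCleavages = missedCleavages)
    if (nrow(peps) == 0) next
    ionization <- stats::rlnorm(nrow(peps), 0, 1)
    for (r in regs) {
      ab <- sum(sp[[paste0("abund_", r)]][sp$accession == acc])
      if (ab <= 0) next
      for (rep in seq_len(nReplicates)) {
        areas <- ab * 1000 * ionization *
          stats::rlnorm(nrow(peps), -sigma^2 / 2, sigma)
        rows[[length(rows) + 1]] <- data.frame(
          accession = acc, region = r,
          description = paste("synthetic protein", acc),
          peptide = peps$peptide, missed = peps$missed,
          replicate = paste0("rep", rep), area = areas,
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  idTablePath <- file.path(dir, paste0(name, ".tsv"))
  utils::write.table(tab, idTablePath, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  fastaPath <- file.path(dir, paste0(name, ".fasta"))
  writeProteinFasta(truth$sequences, fastaPath)
  list(idTablePath = idTablePath, fastaPath = fastaPath, table = tab)
}

#' Simulate metabolite peak lists per region
#'
#' For every library compound compatible with the ionization mode,
#' computes the ion m/z (with a per-dataset calibration error), renders
#' the isotope pattern to M+2 from the exact composition, scales
#' intensities by a planted per-region fold-change design, adds
#' relative-intensity noise, and drops peaks below the noise floor.
#' Polarity-incompatible compounds are skipped with a message.
#'
#' @param library Metabolite library `data.frame`
#'   (see [readMetaboliteLibrary()]).
#' @param mode An [IonMode-class].
#' @param design `data.frame` with `name`, `log2fc` (region 1 over
#'   region 2); compounds absent from it get log2fc 0.
#' @param regions Region labels (length 2).
#' @param snr Apex signal-to-noise of a fold-change-1 compound.
#' @param calibrationPpmSd Calibration error s.d. (ppm).
#' @param intensityCV Multiplicative intensity noise CV.
#' @param seed Integer seed (mandatory).
#' @return List: `peaks` (named list of per-region `data.frame`s with
#'   `mz`, `intensity`), `truth` (`data.frame` per compound),
#'   `calibrationPpm`.
#' @export
simulateMetabolitePeaks <- function(library, mode,
                                    design = NULL,
                                    regions = c("tumor", "healthy"),
                                    snr = 50, calibrationPpmSd = 1,
                                    intensityCV = 0.05, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  calibPpm <- max(-2, min(2, stats::rnorm(1))) * calibrationPpmSd
  calib <- 1 + calibPpm * 1e-6
  noiseFloor <- 1
  compatible <- function(pol) {
    pol == "both" || (pol == "pos") == (mode@polarity == "positive")
  }
  truthRows <- list()
  peaks <- stats::setNames(
    rep(list(data.frame(mz = numeric(0), intensity = numeric(0))),
        length(regions)), regions)
  for (i in seq_len(nrow(library))) {
    if (!compatible(library$polarity[i])) {
      message("skipping '", library$name[i],
              "': polarity incompatible with the mode")
      next
    }
    if (mode@ionType == "derivatized" && !isTRUE(library$amine[i])) next
    comp <- ElementalComposition(library$formula[i])
    env <- isotopeDistribution(comp, pruneThreshold = 1e-4)
    nIso <- min(3, length(mzValues(env)))
    theoM <- mzValues(env)[seq_len(nIso)]
    theoAb <- abundances(env)[seq_len(nIso)]
    ionMzs <- vapply(theoM, modeIonMz, numeric(1), mode = mode) * calib
    if (ionMzs[1] < mode@mzRange[1] || ionMzs[1] > mode@mzRange[2]) next
    l2 <- 0
    if (!is.null(design)) {
      j <- match(library$name[i], design$name)
      if (!is.na(j)) l2 <- design$log2fc[j]
    }
    base <- snr * noiseFloor * stats::rlnorm(1, 0, 0.3)
    intens <- stats::setNames(c(base * 2^l2, base), regions)
    for (r in regions) {
      hh <- intens[[r]] * theoAb *
        stats::rlnorm(nIso, 0, intensityCV)
      keep <- hh > 3 * noiseFloor
      if (!any(keep)) next
      peaks[[r]] <- rbind(peaks[[r]],
                          data.frame(mz = ionMzs[keep],
                                     intensity = hh[keep]))
    }
    truthRows[[length(truthRows) + 1]] <- data.frame(
      name = library$name[i], formula = library$formula[i],
      ionMz = ionMzs[1], log2fc = l2, stringsAsFactors = FALSE)
  }
  for (r in regions) {
    p <- peaks[[r]][order(peaks[[r]]$mz), , drop = FALSE]
    ## coincident species (structural isomers) appear as one summed
    ## peak, as they would in a real spectrum
    if (nrow(p) > 1) {
      grp <- cumsum(c(1, diff(p$mz) > pmax(2e-6 * p$mz[-1], 0.002)))
      p <- do.call(rbind, lapply(split(p, grp), function(g) {
        data.frame(mz = stats::weighted.mean(g$mz, g$intensity),
                   intensity = sum(g$intensity))
      }))
    }
    rownames(p) <- NULL
    peaks[[r]] <- p
  }
  truth <- if (length(truthRows) > 0) do.call(rbind, truthRows) else
    data.frame(name = character(0), formula = character(0),
               ionMz = numeric(0), log2fc = numeric(0))
  list(peaks = peaks, truth = truth, calibrationPpm = calibPpm)
}

## ---- scenario presets -------------------------------------------------

#' Preset: two region-exclusive proteins with interspersed, isobaric
#' isotopologues
#'
#' Builds one ~9 kDa glutamine-rich backbone and a second protein of the
#' same length in which eleven Gln are substituted by Lys (same nominal
#' residue mass, +0.036 Da exact each): the species differ by ~0.40 Da
#' monoisotopic / ~0.48 Da average mass, so their isotopologue series
#' share nominal masses and interleave on the m/z axis, resolvable only
#' at high resolving power.  (Eleven swaps also keep the interleaving
#' offset well away from the 1.00235/3 Th charge-3 spacing, so envelope
#' extraction cannot mistake the two interleaved z=1 combs for one z=3
#' series.)  The first protein is exclusive to the first region, the
#' second to the second.
#'
#' @param seed Integer seed (mandatory).
#' @param targetMass Approximate backbone mass (Da).
#' @param nSwaps Number of Q->K substitutions (default 11: ~ +0.40 Da
#'   monoisotopic, ~ +0.48 Da average).
#' @param abundance Abundance of both species.
#' @param regions Region labels.
#' @return A ground-truth list compatible with [simulateMSI()].
#' @export
presetIsobaricPair <- function(seed, targetMass = 9000, nSwaps = 11,
                               abundance = 300,
                               regions = c("tumor", "healthy")) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  freq <- .residueFreq
  freq[["Q"]] <- 0.15   # ensure enough substitution sites
  repeat {
    seqA <- .randomSequence(targetMass, freq)
    if (sum(strsplit(seqA, "")[[1]] == "Q") >= nSwaps) break
  }
  aa <- strsplit(seqA, "")[[1]]
  qPos <- which(aa == "Q")
  swap <- sample(qPos, nSwaps)
  aaB <- aa
  aaB[swap] <- "K"
  seqB <- paste(aaB, collapse = "")
  seqs <- c(ISOA = seqA, ISOB = seqB)
  modNames <- c("methyl", "acetyl", "oxidation", "deamidation",
                "disulfide")
  mkRow <- function(acc, s, abA, abB) {
    comp <- compositionFromSequence(s)
    row <- data.frame(accession = acc, variant = "full",
                      stringsAsFactors = FALSE)
    for (mn in modNames) row[[mn]] <- 0L
    row$adduct <- "proton"
    row$proteoform <- paste(acc, "full", "unmod", "proton", sep = "|")
    row$formula <- formulaString(comp)
    row$neutralMono <- monoisotopicMass(comp)
    row$charges <- "1"
    row$log2fc <- if (abB == 0) Inf else -Inf
    row[[paste0("abund_", regions[1])]] <- abA
    row[[paste0("abund_", regions[2])]] <- abB
    row
  }
  species <- rbind(mkRow("ISOA", seqA, abundance, 0),
                   mkRow("ISOB", seqB, 0, abundance))
  list(sequences = seqs, species = species, regions = regions,
       params = list(preset = "isobaricPair", seed = seed,
                     targetMass = targetMass, nSwaps = nSwaps))
}

#' Preset: histone-like proteoform ladder at charges 1-3
#'
#' One ~11 kDa backbone emitted as the unmodified, mono-, di-,
#' tri-methylated and acetylated proteoforms, each at charge states 1, 2
#' and 3, with the acetylated forms up-regulated in the first region --
#' the internal-verification scenario where every proteoform's identity
#' is corroborated by consistent neutral masses across charge states.
#'
#' @param seed Integer seed (mandatory).
#' @param targetMass Backbone mass (Da); default 11,300.
#' @param abundance Base abundance.
#' @param regions Region labels.
#' @return A ground-truth list compatible with [simulateMSI()].
#' @export
presetHistoneLadder <- function(seed, targetMass = 11300,
                                abundance = 300,
                                regions = c("tumor", "healthy")) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  s <- .randomSequence(targetMass)
  acc <- "HIST1"
  modNames <- c("methyl", "acetyl", "oxidation", "deamidation",
                "disulfide")
  ladder <- list(c(methyl = 0L), c(methyl = 1L), c(methyl = 2L),
                 c(methyl = 3L), c(acetyl = 1L))
  scaleT <- c(1, 0.8, 0.6, 0.45, 0.9)   # tumor: acetyl up
  scaleH <- c(1, 0.8, 0.6, 0.45, 0.3)
  comp0 <- compositionFromSequence(s)
  rows <- list()
  for (si in seq_along(ladder)) {
    mods <- stats::setNames(integer(length(modNames)), modNames)
    mods[names(ladder[[si]])] <- ladder[[si]]
    comp <- comp0
    for (mn in names(mods)) {
      if (mods[[mn]] > 0) {
        comp <- applyDelta(comp, modificationDelta(mn), mods[[mn]])
      }
    }
    row <- data.frame(accession = acc, variant = "full",
                      stringsAsFactors = FALSE)
    for (mn in modNames) row[[mn]] <- mods[[mn]]
    row$adduct <- "proton"
    row$proteoform <- paste(acc, "full", .modTag(mods), "proton",
                            sep = "|")
    row$formula <- formulaString(comp)
    row$neutralMono <- monoisotopicMass(comp)
    row$charges <- "1,2,3"
    row$log2fc <- log2(scaleT[si] / scaleH[si])
    row[[paste0("abund_", regions[1])]] <- abundance * scaleT[si]
    row[[paste0("abund_", regions[2])]] <- abundance * scaleH[si]
    rows[[length(rows) + 1]] <- row
  }
  species <- do.call(rbind, rows)
  list(sequences = stats::setNames(s, acc), species = species,
       regions = regions,
       params = list(preset = "histoneLadder", seed = seed,
                     targetMass = targetMass))
}
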