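test_that("tryptic digestion obeys cleavage rules and missed-cleavage caps", {
  ## cleave after K/R, not before P: the blocked site yields no split
  p <- trypticPeptides("MAAAKPCCCK", missedCleavages = 0, minLength = 1)
  expect_equal(p$peptide, "MAAAKPCCCK")
  p2 <- trypticPeptides("MAAAKGGGRCCCK", missedCleavages = 2,
                        minLength = 1)
  expect_true(all(p2$missed <= 2))
  expect_true("MAAAK" %in% p2$peptide)
  expect_true("MAAAKGGGR" %in% p2$peptide)          # 1 missed
  expect_true("MAAAKGGGRCCCK" %in% p2$peptide)      # 2 missed
  ## no K/R: the whole chain is the single peptide
  p3 <- trypticPeptides("MAAAAAAGGGW", missedCleavages = 2, minLength = 1)
  expect_equal(p3$peptide, "MAAAAAAGGGW")
  ## fragments never span an allowed cleavage site internally
  internal <- substr(p2$peptide[p2$missed == 0], 1,
                     nchar(p2$peptide[p2$missed == 0]) - 1)
  expect_false(any(grepl("K|R", internal) &
                     !grepl("KP|RP", internal)))
})

test_that("proteome simulation is deterministic and region-structured", {
  t1 <- simulateProteome(nProteins = 6, massRange = c(4000, 7000),
                         seed = 99)
  t2 <- simulateProteome(nProteins = 6, massRange = c(4000, 7000),
                         seed = 99)
  expect_identical(t1$sequences, t2$sequences)
  expect_identical(t1$species, t2$species)
  expect_error(simulateProteome(nProteins = 3, seed = 1,
                                massRange = c(4000, 40000)),
               "infeasible")
  expect_error(simulateProteome(nProteins = 3), "seed")
  ## masses respect the window (sequences just exceed the draw target)
  expect_true(all(t1$species$neutralMono[t1$species$nMods == 0 |
                                           TRUE] > 3900))
})

test_that("single-species noiseless pixels equal the rendered envelope", {
  truth <- simulateProteome(nProteins = 1, massRange = c(5000, 5200),
                            pExclusive = 0, log2fcChoices = 0,
                            pModStack = 0, charges = 1L, seed = 31)
  quiet <- InstrumentModel(calibrationPpmSd = 0, jitterPpm = 0,
                           noiseFloor = 0, pixelCV = 0,
                           mzRange = c(4900, 5600))
  msi <- simulateMSI(truth, quiet, grid = c(2, 2), seed = 32)
  axis <- sharedMzAxis(msi$dataset)
  env <- ionize(isotopeDistribution(
    ElementalComposition(truth$species$formula[1])), 1, "proton")
  expected <- proteoMSI:::.renderSpecies(
    numeric(length(axis)), axis, quiet, mzValues(env), abundances(env),
    truth$species$abund_tumor[1])
  s <- getSpectrum(msi$dataset, 1)
  expect_equal(s$intensity, expected, tolerance = 1e-6)
  ## all pixels of the same region identical
  s2 <- getSpectrum(msi$dataset, 2)
  expect_equal(s$intensity, s2$intensity)
})

test_that("dataset generation is byte-identical under a fixed seed", {
  truth <- simulateProteome(nProteins = 2, massRange = c(4000, 5000),
                            seed = 77)
  inst <- InstrumentModel(mzRange = c(3500, 5600))
  d1 <- tempfile(); d2 <- tempfile()
  m1 <- simulateMSI(truth, inst, grid = c(2, 2), seed = 78, dir = d1)
  m2 <- simulateMSI(truth, inst, grid = c(2, 2), seed = 78, dir = d2)
  expect_identical(unname(tools::md5sum(m1$dataset@ibdPath)),
                   unname(tools::md5sum(m2$dataset@ibdPath)))
  expect_identical(readLines(m1$dataset@imzmlPath),
                   readLines(m2$dataset@imzmlPath))
  expect_identical(readLines(m1$manifestPath),
                   readLines(m2$manifestPath))
  expect_error(simulateMSI(truth, inst), "seed")
})

test_that("overlapping ROI labels on one pixel are rejected", {
  truth <- simulateProteome(nProteins = 1, massRange = c(4000, 4500),
                            seed = 5)
  inst <- InstrumentModel(mzRange = c(3500, 5200))
  layout <- list(tumor = rbind(c(1, 1), c(2, 1)),
                 healthy = rbind(c(2, 1)))
  expect_error(simulateMSI(truth, inst, grid = c(2, 1),
                           roiLayout = layout, seed = 6), "overlap")
})

test_that("whole-image average equals the abundance-weighted rendering", {
  truth <- simulateProteome(nProteins = 2, massRange = c(4200, 5000),
                            pExclusive = 0, log2fcChoices = 0,
                            pModStack = 0, charges = 1L, seed = 41)
  inst <- InstrumentModel(mzRange = c(4000, 5800), noiseFloor = 0.5,
                          pixelCV = 0.1, calibrationPpmSd = 0,
                          jitterPpm = 0)
  msi <- simulateMSI(truth, inst, grid = c(4, 4), seed = 42)
  allMask <- ROIMask("all", as.matrix(expand.grid(x = 1:4, y = 1:4)))
  avg <- roiAverageSpectrum(msi$dataset, allMask)
  axis <- avg$mz
  expected <- numeric(length(axis))
  for (i in seq_len(nrow(truth$species))) {
    env <- ionize(isotopeDistribution(
      ElementalComposition(truth$species$formula[i])), 1, "proton")
    expected <- proteoMSI:::.renderSpecies(
      expected, axis, inst, mzValues(env), abundances(env),
      truth$species$abund_tumor[i])
  }
  ## agreement within noise/sqrt(N): pixel log-normal CV 0.1 over 16 px
  apexes <- expected > 0.3 * max(expected)
  relErr <- abs(avg$intensity[apexes] - expected[apexes]) /
    expected[apexes]
  expect_lt(stats::median(relErr), 0.1)
})

test_that("histone ladder preset plants the documented proteoform series", {
  hp <- presetHistoneLadder(seed = 7)
  expect_equal(nrow(hp$species), 5)
  expect_equal(hp$species$methyl, c(0, 1, 2, 3, 0))
  expect_equal(hp$species$acetyl, c(0, 0, 0, 0, 1))
  masses <- hp$species$neutralMono
  expect_equal(masses[2] - masses[1], 14.01565, tolerance = 1e-4)
  expect_equal(masses[4] - masses[1], 42.04695, tolerance = 1e-4)
  expect_equal(masses[5] - masses[1], 42.01057, tolerance = 1e-4)
  expect_true(all(hp$species$charges == "1,2,3"))
})

test_that("isobaric pair preset interleaves at ~0.4 Da with equal nominal mass", {
  ip <- presetIsobaricPair(seed = 3)
  d <- diff(ip$species$neutralMono)
  expect_equal(d, 0.4002, tolerance = 1e-3)
  mt <- sapply(ip$sequences, function(s) {
    massTriple(compositionFromSequence(s))
  })
  expect_equal(mt["average", 2] - mt["average", 1], 0.477,
               tolerance = 0.01)
  ## one species per region, exclusively
  expect_equal(ip$species$abund_tumor[2], 0)
  expect_equal(ip$species$abund_healthy[1], 0)
  expect_equal(nchar(ip$sequences[[1]]), nchar(ip$sequences[[2]]))
})

test_that("quant tables carry planted fold changes at log-normal noise", {
  truth <- simulateProteome(nProteins = 10, massRange = c(4000, 9000),
                            pExclusive = 0, log2fcChoices = 1,
                            pModStack = 0, seed = 51)
  tabs <- simulateQuantTables(truth, nReplicates = 3, peptideCV = 0.2,
                              seed = 52)
  expect_true(all(tabs$table$missed <= 2))
  idtab <- loadIdTable(tabs$idTablePath, tabs$fastaPath)
  lfq <- proteinLFQ(idtab)
  t <- lfq[lfq$region == "tumor", ]
  h <- lfq[lfq$region == "healthy", ]
  ratio <- t$meanArea[match(h$accession, t$accession)] / h$meanArea
  ## planted FC 2 recovered within 3 sd of the replicate noise
  expect_true(all(abs(log2(ratio) - 1) < 3 * 0.2 / log(2) / sqrt(3) + 0.5))
  ## determinism
  tabs2 <- simulateQuantTables(truth, nReplicates = 3, peptideCV = 0.2,
                               seed = 52)
  expect_identical(tabs$table, tabs2$table)
})

test_that("metabolite peak simulation honors polarity and abundance", {
  lib <- readMetaboliteLibrary(system.file("extdata",
                                           "metabolite_library.tsv",
                                           package = "proteoMSI"))
  neg <- IonMode("negative", "deprotonated", mzRange = c(50, 1000))
  sub <- lib[lib$name %in% c("glycine", "glucose 6-phosphate",
                             "citrate"), ]
  expect_message(
    sim <- simulateMetabolitePeaks(sub, neg,
                                   design = data.frame(
                                     name = "glucose 6-phosphate",
                                     log2fc = 1.5),
                                   seed = 61),
    "polarity")   # glycine is positive-only and is skipped
  expect_false("glycine" %in% sim$truth$name)
  g6p <- sim$truth[sim$truth$name == "glucose 6-phosphate", ]
  iT <- sim$peaks$tumor$intensity[
    which.min(abs(sim$peaks$tumor$mz - g6p$ionMz))]
  iH <- sim$peaks$healthy$intensity[
    which.min(abs(sim$peaks$healthy$mz - g6p$ionMz))]
  expect_gt(iT / iH, 1.5)
  expect_error(simulateMetabolitePeaks(sub, neg), "seed")
})

test_that("TOF emulation merges protein isotopologues into one broad peak", {
  truth <- simulateProteome(nProteins = 1, massRange = c(8000, 8300),
                            pExclusive = 0, log2fcChoices = 0,
                            pModStack = 0, charges = 1L, seed = 71)
  tof <- InstrumentModel("tof", noiseFloor = 0.01, pixelCV = 0,
                         calibrationPpmSd = 0, jitterPpm = 0,
                         mzRange = c(7500, 9000))
  msi <- simulateMSI(truth, tof, grid = c(2, 1), seed = 72)
  s <- getSpectrum(msi$dataset, 1)
  ## the TOF axis is coarse (~2 Th steps), so noise windows must span
  ## many samples for a stable estimate
  pk <- pickPeaks(data.frame(mz = s$mz, intensity = s$intensity),
                  snrMin = 5, noiseWindowTh = 300)
  apex <- msi$ions$apexMz[1]
  near <- pk[abs(pk$mz - apex) < 15, ]
  ## FWHM (8 Th) exceeds the 1 Th isotope spacing: one merged peak
  ## where the FTICR mode shows a dozen isotopologues
  expect_lte(nrow(near), 2)
  expect_gt(peakFwhm(tof, 8200), 1.00235)
})
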