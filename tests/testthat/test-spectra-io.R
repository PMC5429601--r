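writeTestDataset <- function(intensities, axis, dir = tempfile()) {
  dir.create(dir)
  path <- file.path(dir, "ds.imzML")
  w <- imzmlWriterOpen(path, "continuous", "positive", mzAxis = axis)
  for (i in seq_along(intensities)) {
    imzmlWriteSpectrum(w, x = ((i - 1) %% 4) + 1, y = ((i - 1) %/% 4) + 1,
                       intensity = intensities[[i]])
  }
  imzmlWriterClose(w)
  readImzML(path)
}

test_that("continuous imzML round-trips spectra to float precision", {
  axis <- seq(1000, 1020, by = 0.01)
  y1 <- abs(sin(axis)) * 100
  y2 <- abs(cos(axis)) * 50
  ds <- writeTestDataset(list(y1, y2), axis)
  expect_equal(ds@mode, "continuous")
  expect_equal(nPixels(ds), 2)
  expect_equal(sharedMzAxis(ds), axis, tolerance = 1e-12)
  s <- getSpectrum(ds, 1)
  expect_equal(s$intensity, y1, tolerance = 1e-6)   # 32-bit float storage
  s2 <- getSpectrum(ds, 2)
  expect_equal(s2$intensity, y2, tolerance = 1e-6)
})

test_that("processed-mode files average like their continuous re-grid", {
  axis <- seq(1000, 1010, by = 0.02)
  shape <- function(c0) 100 * exp(-0.5 * ((axis - c0) / 0.05)^2)
  dir <- tempfile(); dir.create(dir)
  path <- file.path(dir, "proc.imzML")
  w <- imzmlWriterOpen(path, "processed", "positive",
                       mzRange = range(axis))
  ## per-pixel axes: shifted sub-grids of the common axis
  for (i in 1:2) {
    sub <- seq(1000 + 0.005 * i, 1010, by = 0.02)
    y <- 100 * exp(-0.5 * ((sub - 1005) / 0.05)^2) * i
    imzmlWriteSpectrum(w, i, 1, y, mz = sub)
  }
  imzmlWriterClose(w)
  ds <- readImzML(path)
  expect_equal(ds@mode, "processed")
  avg <- roiAverageSpectrum(ds, ROIMask("all", rbind(c(1, 1), c(2, 1))),
                            axis = axis)
  direct <- (shape(1005) * 1 + shape(1005) * 2) / 2
  ## interpolation tolerance: grids offset by < one step
  expect_lt(max(abs(avg$intensity - direct)) / max(direct), 0.05)
  expect_error(roiAverageSpectrum(ds, ROIMask("all", rbind(c(1, 1)))),
               "axis")
})

test_that("a truncated ibd is an error, not a partial load", {
  axis <- seq(1000, 1001, by = 0.01)
  ds <- writeTestDataset(list(axis * 0 + 1), axis)
  ibd <- ds@ibdPath
  sz <- file.size(ibd)
  con <- file(ibd, "r+b")
  truncate(con, sz - 10)
  close(con)
  expect_error(readImzML(ds@imzmlPath), "truncated")
})

test_that("ROI averaging is the arithmetic pixel mean and is linear", {
  axis <- seq(1000, 1005, by = 0.01)
  base <- abs(sin(axis))
  ds <- writeTestDataset(list(base, 3 * base, 5 * base, 7 * base), axis)
  one <- roiAverageSpectrum(ds, ROIMask("a", rbind(c(1, 1))))
  expect_equal(one$intensity, base, tolerance = 1e-6)
  two <- roiAverageSpectrum(ds, ROIMask("b", rbind(c(1, 1), c(2, 1))))
  expect_equal(two$intensity, 2 * base, tolerance = 1e-6)
  ## union of disjoint masks = pixel-count-weighted mean of the averages
  m1 <- ROIMask("m1", rbind(c(1, 1)))
  m2 <- ROIMask("m2", rbind(c(2, 1), c(3, 1), c(4, 1)))
  u <- roiAverageSpectrum(ds, ROIMask("u", rbind(c(1, 1), c(2, 1),
                                                 c(3, 1), c(4, 1))))
  w <- (1 * roiAverageSpectrum(ds, m1)$intensity +
          3 * roiAverageSpectrum(ds, m2)$intensity) / 4
  expect_lt(max(abs(u$intensity - w)) / max(w), 1e-6)
  expect_error(roiAverageSpectrum(ds, integer(0)), "empty")
  expect_error(ROIMask("x", matrix(numeric(0), 0, 2)), "non-empty")
})

test_that("ROI masks round-trip through JSON", {
  masks <- list(ROIMask("tumor", rbind(c(1, 1), c(2, 1))),
                ROIMask("healthy", rbind(c(3, 1))))
  p <- tempfile(fileext = ".json")
  writeRoiMasks(masks, p)
  back <- readRoiMasks(p)
  expect_setequal(names(back), c("tumor", "healthy"))
  expect_equal(back$tumor@coords, masks[[1]]@coords)
})

test_that("peak picking finds analytic apexes and respects resolution", {
  axis <- seq(999, 1011, by = 0.005)
  gauss <- function(c0, h, s) h * exp(-0.5 * ((axis - c0) / s)^2)
  ## single noiseless Gaussian: apex within 1e-4 x FWHM
  fwhm <- 0.05 * 2.3548
  y <- gauss(1005.0123, 100, 0.05)
  pk <- pickPeaks(data.frame(mz = axis, intensity = y), snrMin = 3)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$mz - 1005.0123), 1e-4 * fwhm)
  ## flat zero spectrum: empty list
  expect_equal(nrow(pickPeaks(data.frame(mz = axis,
                                         intensity = axis * 0))), 0)
  ## two Gaussians 2 x FWHM apart resolve; 0.3 x FWHM apart merge
  y2 <- gauss(1004, 100, 0.05) + gauss(1004 + 2 * fwhm, 80, 0.05)
  expect_equal(nrow(pickPeaks(data.frame(mz = axis, intensity = y2),
                              snrMin = 3)), 2)
  y3 <- gauss(1004, 100, 0.05) + gauss(1004 + 0.3 * fwhm, 80, 0.05)
  expect_equal(nrow(pickPeaks(data.frame(mz = axis, intensity = y3),
                              snrMin = 3)), 1)
})

test_that("envelope extraction infers charge and separates interleaved combs", {
  ## clean z=1 and z=2 envelopes built from theory
  comp <- compositionFromSequence(strrep("MKWVTFISLL", 8))
  for (z in 1:3) {
    theo <- ionize(isotopeDistribution(comp), z, "proton")
    peaks <- data.frame(mz = mzValues(theo), intensity = abundances(theo))
    envs <- extractEnvelope(peaks, which.max(peaks$intensity),
                            charges = 1:3)
    expect_equal(chargeState(envs[[1]]), z)
    expect_equal(length(envs[[1]]@mz), nrow(peaks))
  }
  ## seed with no neighbors: single-member envelope, low completeness
  lone <- data.frame(mz = 9000, intensity = 5)
  envs <- extractEnvelope(lone, 1)
  expect_equal(length(envs[[1]]@mz), 1)
  expect_lt(envs[[1]]@completeness, 0.2)
})

test_that("interleaved isobaric series yield disjoint envelopes", {
  comp <- compositionFromSequence(strrep("MKWVTFISLL", 8))
  theo <- ionize(isotopeDistribution(comp), 1, "proton")
  combA <- data.frame(mz = mzValues(theo), intensity = abundances(theo))
  combB <- data.frame(mz = mzValues(theo) + 0.40,
                      intensity = abundances(theo) * 0.8)
  peaks <- rbind(combA, combB)
  peaks <- peaks[order(peaks$mz), ]
  envs <- findEnvelopes(peaks, minMembers = 3)
  expect_equal(length(envs), 2)
  shared <- intersect(envs[[1]]@memberIdx, envs[[2]]@memberIdx)
  expect_length(shared, 0)
  apexes <- sort(vapply(envs, envelopeApexMz, numeric(1)))
  expect_equal(diff(apexes), 0.40, tolerance = 1e-6)
})

test_that("multi-humped proteoform combs split at deep valleys", {
  comp <- compositionFromSequence(strrep("MKWVTFISLL", 8))
  e0 <- isotopeDistribution(comp, pruneThreshold = 0.005)
  me <- applyDelta(comp, modificationDelta("methyl"))
  e1 <- isotopeDistribution(me, pruneThreshold = 0.005)
  peaks <- rbind(
    data.frame(mz = mzValues(ionize(e0, 1, "proton")),
               intensity = abundances(e0)),
    data.frame(mz = mzValues(ionize(e1, 1, "proton")),
               intensity = abundances(e1) * 0.8))
  peaks <- peaks[order(peaks$mz), ]
  ## the ladder offset (14.016 vs 14 x 1.00235 Th) is far below the
  ## instrument peak width, so coinciding members appear as single
  ## summed peaks: merge anything closer than 0.05 Th
  merged <- list()
  i <- 1
  while (i <= nrow(peaks)) {
    j <- i
    while (j < nrow(peaks) && peaks$mz[j + 1] - peaks$mz[j] < 0.05) {
      j <- j + 1
    }
    merged[[length(merged) + 1]] <-
      data.frame(mz = weighted.mean(peaks$mz[i:j],
                                    peaks$intensity[i:j]),
                 intensity = sum(peaks$intensity[i:j]))
    i <- j + 1
  }
  peaks <- do.call(rbind, merged)
  envs <- findEnvelopes(peaks, minMembers = 3)
  expect_equal(length(envs), 2)
})

test_that("ion images localize species and respect the tolerance window", {
  axis <- seq(4999, 5003, by = 0.002)
  gauss <- function(c0, h) h * exp(-0.5 * ((axis - c0) / 0.01)^2)
  dir <- tempfile(); dir.create(dir)
  path <- file.path(dir, "img.imzML")
  w <- imzmlWriterOpen(path, "continuous", "positive", mzAxis = axis)
  ## species at 5000.5 only in pixels x=1..2; species at 5001.5 in x=3..4
  for (x in 1:4) {
    y <- if (x <= 2) gauss(5000.5, 100) else gauss(5001.5, 80)
    imzmlWriteSpectrum(w, x, 1, y)
  }
  imzmlWriterClose(w)
  ds <- readImzML(path)
  imgA <- ionImage(ds, 5000.5, tolPpm = 10)
  imgB <- ionImage(ds, 5001.5, tolPpm = 10)
  expect_true(all(imgA[1, 1:2] > 50) && all(imgA[1, 3:4] < 1))
  expect_true(all(imgB[1, 3:4] > 40) && all(imgB[1, 1:2] < 1))
  ## window between peaks: all-zero image
  imgZ <- ionImage(ds, 5002.6, tolPpm = 5)
  expect_true(all(imgZ == 0))
  expect_error(ionImage(ds, 8000, tolPpm = 5), "outside")
  ## plain-text matrix writer
  p <- tempfile(fileext = ".tsv")
  writeIonImage(imgA, p)
  back <- as.matrix(read.delim(p, header = FALSE))
  expect_equal(unname(back), unname(imgA), tolerance = 1e-6,
               ignore_attr = TRUE)
})
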