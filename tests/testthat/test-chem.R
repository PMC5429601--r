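test_that("sequence compositions match textbook formulas", {
  expect_equal(formulaString(compositionFromSequence("G")), "C2H5NO2")
  expect_equal(formulaString(compositionFromSequence("GG")), "C4H8N2O3")
  expect_equal(formulaString(compositionFromSequence("G",
                                                     includeWater = FALSE)),
               "C2H3NO")
  expect_error(compositionFromSequence(""), "empty")
  expect_error(compositionFromSequence("GX"), "position 2")
})

test_that("composition arithmetic is element-wise and never negative", {
  a <- ElementalComposition("C2H5NO2")
  b <- ElementalComposition("CH2")
  expect_equal(formulaString(a + b), "C3H7NO2")
  expect_equal(formulaString((a + b) - b), formulaString(a))
  expect_error(b - a, "negative")
  expect_error(applyDelta(b, c(O = -1)), "negative")
  expect_equal(formulaString(2 * b), "C2H4")
  expect_error(ElementalComposition("C2Xx3"), "unknown element")
})

test_that("modification deltas carry the documented mass shifts", {
  expect_equal(attr(modificationDelta("acetyl"), "monoMass"), 42.01057,
               tolerance = 1e-5)
  expect_equal(attr(modificationDelta("methyl"), "monoMass"), 14.01565,
               tolerance = 1e-5)
  expect_equal(attr(modificationDelta("disulfide"), "monoMass"), -2.01565,
               tolerance = 1e-5)
  expect_equal(attr(modificationDelta("deamidation"), "monoMass"), 0.98402,
               tolerance = 1e-5)
  ## trimethyl vs acetyl: the histone-proteoform resolution case
  tri <- 3 * attr(modificationDelta("methyl"), "monoMass")
  expect_equal(tri - attr(modificationDelta("acetyl"), "monoMass"),
               0.036385, tolerance = 1e-4)
  expect_error(modificationDelta("phospho"), "registry")
})

test_that("modification deltas are additive and order-independent", {
  comp <- compositionFromSequence("MKWVTFISLLLK")
  d1 <- modificationDelta("methyl")
  d2 <- modificationDelta("oxidation")
  viaA <- applyDelta(applyDelta(comp, d1, 2), d2)
  viaB <- applyDelta(applyDelta(comp, d2), d1, 2)
  expect_equal(formulaString(viaA), formulaString(viaB))
  expect_equal(monoisotopicMass(viaA),
               monoisotopicMass(comp) + 2 * attr(d1, "monoMass") +
                 attr(d2, "monoMass"),
               tolerance = 1e-9)
})

test_that("single-atom and closed-form distributions are exact", {
  e <- isotopeDistribution(ElementalComposition("C"),
                           pruneThreshold = 1e-4)
  expect_equal(mzValues(e), c(12, 13.00335), tolerance = 1e-5)
  expect_equal(abundances(e)[2] / abundances(e)[1], 0.0107 / 0.9893,
               tolerance = 1e-6)
  ## C100 monoisotopic bin holds 0.9893^100 of the total probability
  c100 <- isotopeDistribution(ElementalComposition("C100"),
                              pruneThreshold = 1e-9)
  ab <- abundances(c100)
  expect_equal(ab[1] / sum(ab), 0.9893^100, tolerance = 1e-9)
})

test_that("engine matches the brute-force expansion oracle", {
  set.seed(71)
  for (i in 1:50) {
    counts <- randomComposition(60)
    comp <- ElementalComposition(counts)
    got <- isotopeDistribution(comp, pruneThreshold = 1e-9)
    want <- oracleDistribution(counts)
    ## align on the first envelope bin (no end-pruning differences at
    ## 1e-9 on <= 60 atoms within oracle's nonzero support)
    off <- which.min(abs(want$mz - mzValues(got)[1]))
    idx <- off:(off + length(mzValues(got)) - 1)
    expect_lt(max(abs(abundances(got) - want$ab[idx])), 1e-9)
    ## centroids agree wherever the bin has non-negligible abundance
    ## (per-step pruning may nudge the fine-structure mean of ~1e-9 bins)
    vis <- abundances(got) >= 1e-6
    expect_lt(max(abs(mzValues(got)[vis] - want$mz[idx][vis])), 1e-6)
  }
})

test_that("mass triple is consistent with atomic masses", {
  mt <- massTriple(ElementalComposition("H2O"))
  expect_equal(unname(mt["monoisotopic"]), 18.01056, tolerance = 1e-5)
  mt2 <- massTriple(ElementalComposition("C6H12O6"))
  expect_equal(unname(mt2["monoisotopic"]), 180.06339, tolerance = 1e-5)
  ## one-isotope dominance collapses the triple
  mtH <- massTriple(ElementalComposition("H"))
  expect_equal(unname(mtH["monoisotopic"]), unname(mtH["mostAbundant"]))
  expect_equal(unname(mtH["average"]), 1.00783, tolerance = 2e-4)
  ## large composition: mono <= mostAbundant, mono < average
  big <- compositionFromSequence(strrep("ACDEFGHIKLMNPQRSTVWY", 5))
  mtB <- massTriple(big)
  expect_lt(mtB["monoisotopic"], mtB["mostAbundant"])
  expect_lt(mtB["monoisotopic"], mtB["average"])
})

test_that("average mass equals the abundance-weighted envelope mean", {
  comp <- compositionFromSequence("MKWVTFISLLLKHMQAA")
  mt <- massTriple(comp)
  e <- isotopeDistribution(comp, pruneThreshold = 1e-9)
  ab <- abundances(e)
  wmean <- sum(mzValues(e) * ab) / sum(ab)
  expect_equal(wmean, unname(mt["average"]), tolerance = 1e-6 * wmean)
})

test_that("ionization follows the stated carrier arithmetic", {
  fake <- proteoMSI:::.newEnvelope(1000, 1, 0L)
  expect_equal(mzValues(ionize(fake, 1, "proton")), 1001.00728,
               tolerance = 1e-5)
  expect_equal(mzValues(ionize(fake, 2, "proton")), 501.00728,
               tolerance = 1e-5)
  glc <- isotopeDistribution(ElementalComposition("C6H12O6"))
  expect_equal(apexMz(ionize(glc, 1, "deprotonation")), 179.05611,
               tolerance = 1e-5)
})

test_that("ionize then deionize recovers neutral centroids", {
  comp <- compositionFromSequence("MKWVTFISLLLKHMQAA")
  neutral <- isotopeDistribution(comp)
  for (z in 1:3) {
    for (carrier in c("proton", "sodium", "potassium")) {
      back <- deionize(ionize(neutral, z, carrier))
      expect_lt(max(abs(mzValues(back) - mzValues(neutral))), 1e-9)
    }
  }
})

test_that("pruning is idempotent and keeps interior bins", {
  comp <- compositionFromSequence(strrep("MKWVTFISLL", 8))
  e <- isotopeDistribution(comp, pruneThreshold = 1e-6)
  p1 <- pruneEnvelope(e, 0.01)
  p2 <- pruneEnvelope(p1, 0.01)
  expect_equal(mzValues(p1), mzValues(p2))
  expect_equal(abundances(p1), abundances(p2))
  expect_true(all(abundances(p1)[1] >= 0.01,
                  abundances(p1)[length(abundances(p1))] >= 0.01))
  expect_equal(max(abundances(p1)), 1)
  expect_equal(sum(abundances(p1) == 1), 1)
})

test_that("envelope validity enforces the documented invariants", {
  expect_error(new("IsotopeEnvelope", mz = c(2, 1), abundance = c(1, 0.5),
                   charge = 0L, carrier = "none", nCarriers = 0L),
               "increasing")
  expect_error(new("IsotopeEnvelope", mz = c(1, 2), abundance = c(0.5, 0.4),
                   charge = 0L, carrier = "none", nCarriers = 0L),
               "max-normalized")
  ## protein-like spacing invariant
  e <- ionize(isotopeDistribution(compositionFromSequence(
    strrep("MKWVTFISLL", 5))), 2, "proton")
  sp <- diff(mzValues(e))
  expect_true(all(abs(sp - 1.00235 / 2) < 0.01 / 2))
})
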