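smallSearchCfg <- function() {
  SearchSpaceConfig(modBounds = c(methyl = 3L, acetyl = 1L,
                                  oxidation = 1L, deamidation = 1L,
                                  disulfide = 1L),
                    maxTotalMods = 3L, charges = 1:3,
                    massWindow = c(500, 30000))
}

test_that("self-match yields r = 1 and zero ppm; shifts trip the gate", {
  rec <- makeRecord("P1", "MKWVTFISLLLKAAQEGHMKWVTFISLLLK")
  cands <- enumerateCandidates(rec, smallSearchCfg())
  cand <- cands[cands$nMods == 0 & cands$adduct == "proton" &
                  cands$charge == 1, ][1, ]
  theo <- candidateEnvelope(cand)
  env <- envFromTheory(theo)
  sc <- scoreMatch(env, cand)
  expect_true(sc$accepted)
  expect_equal(sc$r, 1, tolerance = 1e-9)
  expect_lt(abs(sc$ppm), 1e-6)
  ## +50 ppm shift: r still 1, rejected on mass
  sc50 <- scoreMatch(envFromTheory(theo, shiftPpm = 50), cand)
  expect_false(sc50$accepted)
  expect_equal(sc50$reason, "mass gate")
  expect_equal(sc50$ppm, 50, tolerance = 0.01)
})

test_that("near-isobaric modification stacks report the exact ppm offset", {
  ## truth trimethyl vs candidate acetyl (delta 0.03638 Da) on a z = 2 ion
  seq14 <- strrep("MKWVTFISLLLKHQ", 9)
  rec <- makeRecord("H1", seq14)
  cands <- enumerateCandidates(rec, smallSearchCfg())
  truthCand <- cands[cands$methyl == 3 & cands$acetyl == 0 &
                       cands$nMods == 3 & cands$adduct == "proton" &
                       cands$charge == 2 & cands$variant == "full", ][1, ]
  acCand <- cands[cands$acetyl == 1 & cands$nMods == 1 &
                    cands$adduct == "proton" & cands$charge == 2 &
                    cands$variant == "full", ][1, ]
  env <- envFromTheory(candidateEnvelope(truthCand))
  sc <- scoreMatch(env, acCand)
  expectedPpm <- 0.03638 / 2 / apexMz(candidateEnvelope(acCand)) * 1e6
  expect_equal(abs(sc$ppm), expectedPpm, tolerance = 0.1)
  ## inside the 10 ppm gate: the documented outcome is an ambiguity
  ## cluster, not a silent misassignment
  res <- assignRoi(list(env),
                   cands[cands$charge == 2 & cands$variant == "full", ],
                   MatchConfig(), roiLabel = "tumor")
  expect_equal(res$primary$ties >= 1, TRUE)
  coset <- c(res$primary$label,
             strsplit(res$primary$tiedLabels, ";")[[1]])
  expect_true(truthCand$label %in% coset)
  expect_true(acCand$label %in% coset)
  ## parsimony orders the cluster: 1 modification before 3
  expect_equal(res$primary$label, acCand$label)
})

test_that("insufficient envelopes are rejections, not passes", {
  rec <- makeRecord("P1", "MKWVTFISLLLKAAQEGHMKWVTFISLLLK")
  cands <- enumerateCandidates(rec, smallSearchCfg())
  cand <- cands[cands$nMods == 0 & cands$adduct == "proton" &
                  cands$charge == 1, ][1, ]
  theo <- candidateEnvelope(cand)
  tiny <- new("ExperimentalEnvelope", mz = apexMz(theo), intensity = 1,
              charge = 1L, apexIdx = 1L, completeness = 0.1, score = 1,
              memberIdx = 1L)
  sc <- scoreMatch(tiny, cand)
  expect_false(sc$accepted)
  expect_equal(sc$reason, "insufficient envelope")
})

test_that("tightening either gate never grows the accepted set", {
  set.seed(5)
  recs <- lapply(1:3, function(i) {
    makeRecord(sprintf("P%d", i),
               proteoMSI:::.randomSequence(runif(1, 6000, 9000)))
  })
  cands <- do.call(rbind, lapply(recs, enumerateCandidates,
                                 cfg = smallSearchCfg()))
  ## noisy envelopes from a few candidates
  envs <- lapply(seq(1, nrow(cands), length.out = 6), function(i) {
    theo <- candidateEnvelope(cands[round(i), ])
    e <- envFromTheory(theo, shiftPpm = rnorm(1, 0, 4))
    e@intensity <- e@intensity * exp(rnorm(length(e@intensity), 0, 0.1))
    e@apexIdx <- which.max(e@intensity)
    e
  })
  acceptedSet <- function(ppm, rmin) {
    res <- assignRoi(envs, cands,
                     MatchConfig(tolerancePpm = ppm, rMin = rmin))
    paste(res$assignments$envelope, res$assignments$label)
  }
  sets <- list()
  for (ppm in c(20, 10, 5)) {
    for (rmin in c(0.90, 0.95, 0.99)) {
      sets[[sprintf("%g_%g", ppm, rmin)]] <- acceptedSet(ppm, rmin)
    }
  }
  for (ppm in c(20, 10, 5)) {
    expect_true(all(sets[[sprintf("%g_0.95", ppm)]] %in%
                      sets[[sprintf("%g_0.9", ppm)]]))
    expect_true(all(sets[[sprintf("%g_0.99", ppm)]] %in%
                      sets[[sprintf("%g_0.95", ppm)]]))
  }
  for (rmin in c(0.90, 0.95, 0.99)) {
    expect_true(all(sets[[sprintf("10_%g", rmin)]] %in%
                      sets[[sprintf("20_%g", rmin)]]))
    expect_true(all(sets[[sprintf("5_%g", rmin)]] %in%
                      sets[[sprintf("10_%g", rmin)]]))
  }
})

test_that("charge groups corroborate consistent neutral masses", {
  rec <- makeRecord("H1", strrep("MKWVTFISLLLKHQ", 8))
  cands <- enumerateCandidates(rec, smallSearchCfg())
  unmod <- cands[cands$nMods == 0 & cands$adduct == "proton" &
                   cands$variant == "full", ]
  envs <- lapply(unmod$charge, function(z) {
    envFromTheory(candidateEnvelope(unmod[unmod$charge == z, ]))
  })
  res <- assignRoi(envs, cands, MatchConfig())
  groups <- corroborateCharges(res$assignments)
  g <- groups[groups$proteoform == unmod$proteoform[1], ]
  expect_equal(g$nCharges, 3)
  expect_equal(g$verdict, "corroborated")
  expect_lt(g$dispersionPpm, 1)
  ## single charge state cannot corroborate
  one <- assignRoi(envs[1], cands, MatchConfig())
  g1 <- corroborateCharges(one$assignments)
  expect_true(all(g1$verdict == "single-state"))
})

test_that("conflicting same-envelope claims stay in separate groups", {
  a <- data.frame(envelope = 1L, apexMz = 5000, charge = 1L,
                  accession = "A", region = "tumor", variant = "full",
                  adduct = "proton", neutralMono = 4995,
                  proteoform = "A|full|unmod|proton",
                  label = "A|full|unmod|proton|z1", ppm = 1, r = 0.99,
                  rankScore = 0.9, nPairs = 8L, nMods = 0L,
                  theoApex = 5000, decoy = FALSE)
  b <- a
  b$accession <- "B"
  b$proteoform <- "B|full|unmod|proton"
  b$label <- "B|full|unmod|proton|z1"
  groups <- corroborateCharges(rbind(a, b))
  expect_equal(nrow(groups), 2)
})

test_that("decoy machinery validates inputs and preserves structure", {
  rec <- makeRecord("P1", "MKWVTFISLLLKAAQEGHMKWVTFISLLLK")
  cands <- enumerateCandidates(rec, smallSearchCfg())
  env <- envFromTheory(candidateEnvelope(cands[1, ]))
  expect_error(decoyAssign(list(env), cands, list(rec), nDecoys = 0),
               "nDecoys")
  set.seed(1)
  drecs <- decoyRecords(list(rec, makeRecord("P2", "MAGTKLLNQWERTYHK")))
  expect_equal(nchar(drecs[[1]]$sequence), 30)
  expect_equal(nchar(drecs[[2]]$sequence), 16)
  expect_match(drecs[[1]]$accession, "^DECOY_")
  ## pooled residues are conserved
  pool0 <- sort(strsplit(paste0("MKWVTFISLLLKAAQEGHMKWVTFISLLLK",
                                "MAGTKLLNQWERTYHK"), "")[[1]])
  pool1 <- sort(strsplit(paste0(drecs[[1]]$sequence,
                                drecs[[2]]$sequence), "")[[1]])
  expect_equal(pool0, pool1)
})

test_that("relaxing the gates strictly admits more decoy pairs", {
  set.seed(8)
  recs <- lapply(1:4, function(i) {
    makeRecord(sprintf("P%d", i),
               proteoMSI:::.randomSequence(runif(1, 5000, 9000)))
  })
  cfg <- smallSearchCfg()
  cands <- do.call(rbind, lapply(recs, enumerateCandidates, cfg = cfg))
  envs <- lapply(c(10, 400, 900), function(i) {
    envFromTheory(candidateEnvelope(cands[i, ]))
  })
  strict <- decoyAssign(envs, cands, recs, MatchConfig(), cfg,
                        nDecoys = 2, seed = 3)
  loose <- decoyAssign(envs, cands, recs,
                       MatchConfig(tolerancePpm = 100, rMin = 0.01),
                       cfg, nDecoys = 2, seed = 3)
  expect_gt(loose$acceptedDecoyPairs, strict$acceptedDecoyPairs)
})
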