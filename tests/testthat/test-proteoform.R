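writeToyIdTable <- function(dir = tempfile()) {
  dir.create(dir)
  seqs <- c(P1 = "MKWVTFISLLLKAAQEGH", P2 = "MAGTKLLNQWERTYHKDD",
            P3 = "MLLSSTTPPGGHHKKRRE")
  fasta <- file.path(dir, "toy.fasta")
  writeProteinFasta(seqs, fasta)
  rows <- rbind(
    data.frame(accession = "P1", region = "tumor", peptide = "WVTFISLLLK",
               replicate = "rep1", area = 100),
    data.frame(accession = "P1", region = "healthy", peptide = "WVTFISLLLK",
               replicate = "rep1", area = 50),
    data.frame(accession = "P2", region = "tumor", peptide = "LLNQWER",
               replicate = "rep1", area = 70),
    ## duplicate accession rows within a region must merge
    data.frame(accession = "P2", region = "tumor", peptide = "TYHK",
               replicate = "rep1", area = 30),
    data.frame(accession = "P3", region = "healthy", peptide = "SSTTPPGGHHK",
               replicate = "rep1", area = NA)
  )
  path <- file.path(dir, "ids.tsv")
  write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  list(path = path, fasta = fasta, seqs = seqs)
}

test_that("identification tables group by accession x region", {
  toy <- writeToyIdTable()
  idtab <- loadIdTable(toy$path, toy$fasta)
  prot <- idProteins(idtab)
  expect_equal(nrow(prot), 4)   # P1 twice (2 regions), P2 and P3 once
  recs <- idRecords(idtab)
  expect_length(recs, 4)
  p2 <- Filter(function(r) r$accession == "P2", recs)[[1]]
  expect_equal(nrow(p2$peptides), 2)   # merged duplicate rows
  ## missing area stays NA, not zero
  p3 <- Filter(function(r) r$accession == "P3", recs)[[1]]
  expect_true(is.na(p3$peptides$area[1]))
})

test_that("missing columns and missing sequences are rejected by name", {
  toy <- writeToyIdTable()
  bad <- read.delim(toy$path)
  bad$region <- NULL
  p <- tempfile(fileext = ".tsv")
  write.table(bad, p, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(loadIdTable(p, toy$fasta), "region")
  ## accession absent from FASTA
  tab <- read.delim(toy$path)
  tab$accession[1] <- "MISSING"
  p2 <- tempfile(fileext = ".tsv")
  write.table(tab, p2, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(loadIdTable(p2, toy$fasta), "MISSING")
})

test_that("candidate counts follow the closed-form product", {
  rec <- makeRecord("P1", "MKWVTFISLLLKAAQEGH")
  ## degenerate space: 2 chain variants only
  cfg0 <- SearchSpaceConfig(modBounds = c(methyl = 0L), maxTotalMods = 0L,
                            charges = 1L,
                            adducts = defaultAdducts()[1, ],
                            massWindow = c(500, 30000))
  c0 <- enumerateCandidates(rec, cfg0)
  expect_equal(nrow(c0), 2)
  expect_setequal(c0$variant, c("full", "Met-loss"))
  ## 2 variants x 4 methyl x 2 acetyl x 2 charges = 32
  cfg1 <- SearchSpaceConfig(modBounds = c(methyl = 3L, acetyl = 1L),
                            maxTotalMods = 4L, charges = 1:2,
                            adducts = defaultAdducts()[1, ],
                            massWindow = c(500, 30000))
  c1 <- enumerateCandidates(rec, cfg1)
  expect_equal(nrow(c1), 2 * 4 * 2 * 2)
  ## brute-force product over a small space with adducts
  cfg2 <- SearchSpaceConfig(modBounds = c(methyl = 2L, oxidation = 1L),
                            maxTotalMods = 3L, charges = 1:3,
                            adducts = defaultAdducts(),
                            massWindow = c(500, 30000))
  c2 <- enumerateCandidates(rec, cfg2)
  expect_equal(nrow(c2), 2 * (3 * 2) * 4 * 3)
})

test_that("mass window excludes out-of-range candidates", {
  rec <- makeRecord("TINY", "MKWVTFISLLLK")   # ~1.4 kDa
  cfg <- SearchSpaceConfig(massWindow = c(3500, 30000))
  expect_equal(nrow(enumerateCandidates(rec, cfg)), 0)
})

test_that("combinatorial cap triggers an instructive error", {
  rec <- makeRecord("P1", "MKWVTFISLLLKAAQEGH")
  cfg <- SearchSpaceConfig(maxCandidates = 10L)
  expect_error(enumerateCandidates(rec, cfg), "tighten")
})

test_that("candidate masses are additive in modification deltas", {
  rec <- makeRecord("P1", "MKWVTFISLLLKAAQEGH")
  cfg <- SearchSpaceConfig(massWindow = c(500, 30000), charges = 1L)
  cands <- enumerateCandidates(rec, cfg)
  base <- cands[cands$variant == "full" & cands$nMods == 0 &
                  cands$adduct == "proton", ]
  ## deltas recomputed from the pinned atomic masses, independently
  tab <- isotopeTable()
  monoOf <- function(el) {
    sub <- tab[tab$element == el, ]
    sub$mass[which.min(sub$shift)]
  }
  mC <- monoOf("C"); mH <- monoOf("H"); mO <- monoOf("O"); mN <- monoOf("N")
  deltas <- c(methyl = mC + 2 * mH, acetyl = 2 * mC + 2 * mH + mO,
              oxidation = mO, deamidation = mO - mN - mH,
              disulfide = -2 * mH)
  sub <- cands[cands$variant == "full" & cands$adduct == "proton", ]
  predicted <- base$neutralMono +
    as.matrix(sub[, names(deltas)]) %*% deltas
  expect_lt(max(abs(predicted - sub$neutralMono)), 1e-9 * max(sub$neutralMono))
})

test_that("region restriction separates and covers the candidate set", {
  toy <- writeToyIdTable()
  idtab <- loadIdTable(toy$path, toy$fasta)
  cfg <- SearchSpaceConfig(modBounds = c(methyl = 1L), maxTotalMods = 1L,
                           charges = 1L, adducts = defaultAdducts()[1, ],
                           massWindow = c(500, 30000))
  cands <- enumerateAllCandidates(idtab, cfg)
  tum <- restrictByRegion(cands, "tumor")
  hea <- restrictByRegion(cands, "healthy")
  expect_true(all(tum$region == "tumor"))
  expect_true(!"P3" %in% tum$accession)   # P3 is healthy-only
  expect_true("P1" %in% tum$accession && "P1" %in% hea$accession)
  expect_equal(nrow(tum) + nrow(hea), nrow(cands))
  ## unknown label against a declared vocabulary errors; absent label
  ## without vocabulary yields an empty set
  expect_error(restrictByRegion(cands, "cortex",
                                vocabulary = c("tumor", "healthy")),
               "cortex")
  expect_equal(nrow(restrictByRegion(cands, "cortex")), 0)
})

test_that("candidate envelopes are memoized and correctly charged", {
  rec <- makeRecord("P1", "MKWVTFISLLLKAAQEGH")
  cfg <- SearchSpaceConfig(modBounds = c(methyl = 1L), maxTotalMods = 1L,
                           charges = 2L, adducts = defaultAdducts()[1, ],
                           massWindow = c(500, 30000))
  cands <- enumerateCandidates(rec, cfg)
  env <- candidateEnvelope(cands[1, ])
  expect_s4_class(env, "IsotopeEnvelope")
  expect_equal(chargeState(env), 2L)
  expect_equal(neutralMass(apexMz(env), 2) -
                 (cands$neutralMono[1] +
                    (apexIndex(env) - 1) * 1.00235) < 0.05, TRUE)
})
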