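# Brute-force isotope-distribution oracle: convolves the molecule one
# atom at a time on the nominal-mass (neutron-shift) grid, tracking both
# bin probability and probability-weighted mass, with no pruning and no
# repeated squaring.  Deliberately independent of the package's engine.
oracleDistribution <- function(counts) {
  tab <- isotopeTable()
  p <- 1
  s <- 0
  mono <- 0
  for (el in names(counts)) {
    sub <- tab[tab$element == el, ]
    K <- max(sub$shift)
    ap <- numeric(K + 1)
    as_ <- numeric(K + 1)
    ap[sub$shift + 1] <- sub$abundance
    as_[sub$shift + 1] <- sub$abundance * sub$mass
    for (a in seq_len(counts[[el]])) {
      np <- numeric(length(p) + K)
      ns <- numeric(length(p) + K)
      for (i in seq_along(p)) {
        idx <- i:(i + K)
        np[idx] <- np[idx] + p[i] * ap
        ns[idx] <- ns[idx] + p[i] * as_ + s[i] * ap
      }
      p <- np
      s <- ns
    }
  }
  keep <- p > 0
  list(mz = (s / p)[keep], ab = p[keep] / max(p[keep]))
}

# random CHNOPS composition with at most maxAtoms atoms
randomComposition <- function(maxAtoms = 60) {
  els <- c("C", "H", "N", "O", "P", "S")
  n <- sample(2:maxAtoms, 1)
  draw <- sample(els, n, replace = TRUE,
                 prob = c(0.3, 0.42, 0.08, 0.12, 0.03, 0.05))
  counts <- table(draw)
  stats::setNames(as.integer(counts), names(counts))
}

# noiseless experimental envelope rendered directly from a theoretical
# ion envelope (heights equal theoretical abundances)
envFromTheory <- function(theo, shiftPpm = 0) {
  mz <- mzValues(theo) * (1 + shiftPpm * 1e-6)
  ab <- abundances(theo)
  new("ExperimentalEnvelope", mz = mz, intensity = ab,
      charge = chargeState(theo), apexIdx = which.max(ab),
      completeness = 1, score = sum(ab),
      memberIdx = seq_along(mz))
}

# minimal identification record
makeRecord <- function(accession, sequence, region = "tumor") {
  list(accession = accession, region = region, description = "",
       sequence = sequence,
       peptides = data.frame(accession = character(0)))
}
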