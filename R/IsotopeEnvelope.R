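#' IsotopeEnvelope class
#'
#' Paired centroid m/z and relative-abundance arrays for one molecular (or
#' ion) species, aggregated into nominal-mass isotopologue bins.  The
#' centroid of each bin is the abundance-weighted mean mass of its fine
#' structure; fine structure itself is never reported because it is
#' unresolved for intact proteins at the resolving powers this package
#' targets.
#'
#' @slot mz Numeric, strictly increasing centroid m/z (Th; neutral masses
#'   when `charge == 0`).
#' @slot abundance Numeric in (0, 1], max-normalized (exactly one element
#'   equals 1).
#' @slot charge Integer, 0 for a neutral-mass envelope, >= 1 for ions.
#' @slot carrier Character: `"none"` for neutrals, else the charge carrier
#'   (`"proton"`, `"sodium"`, `"potassium"`, `"deprotonation"`).
#' @slot nCarriers Integer number of charge carriers.
#' @export
setClass("IsotopeEnvelope",
  representation(mz = "numeric", abundance = "numeric", charge = "integer",
                 carrier = "character", nCarriers = "integer"),
  prototype(charge = 0L, carrier = "none", nCarriers = 0L),
  validity = function(object) {
    if (length(object@mz) != length(object@abundance)) {
      return("mz and abundance must have equal length")
    }
    if (length(object@mz) == 0) return("envelope must be non-empty")
    if (any(diff(object@mz) <= 0)) return("mz must be strictly increasing")
    ab <- object@abundance
    if (any(ab <= 0) || any(ab > 1 + 1e-12)) {
      return("abundances must lie in (0, 1]")
    }
    if (abs(max(ab) - 1) > 1e-9) return("abundances must be max-normalized")
    if (object@charge < 0) return("charge must be >= 0")
    TRUE
  }
)

.newEnvelope <- function(mz, abundance, charge = 0L, carrier = "none",
                         nCarriers = 0L) {
  ab <- abundance / max(abundance)
  new("IsotopeEnvelope", mz = as.numeric(mz), abundance = as.numeric(ab),
      charge = as.integer(charge), carrier = carrier,
      nCarriers = as.integer(nCarriers))
}

#' @describeIn IsotopeEnvelope-class centroid m/z accessor
#' @param x,object An `IsotopeEnvelope`.
#' @export
setGeneric("mzValues", function(x) standardGeneric("mzValues"))

#' @rdname IsotopeEnvelope-class
#' @export
setMethod("mzValues", "IsotopeEnvelope", function(x) x@mz)

#' @describeIn IsotopeEnvelope-class relative abundance accessor
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname IsotopeEnvelope-class
#' @export
setMethod("abundances", "IsotopeEnvelope", function(x) x@abundance)

#' @describeIn IsotopeEnvelope-class charge accessor
#' @export
setGeneric("chargeState", function(x) standardGeneric("chargeState"))

#' @rdname IsotopeEnvelope-class
#' @export
setMethod("chargeState", "IsotopeEnvelope", function(x) x@charge)

#' Apex (most abundant isotopologue) index of an envelope
#' @param x An `IsotopeEnvelope`.
#' @return Integer index into `mzValues(x)`.
#' @export
apexIndex <- function(x) which.max(abundances(x))

#' Apex centroid m/z of an envelope
#' @param x An `IsotopeEnvelope`.
#' @return Numeric apex m/z (Th).
#' @export
apexMz <- function(x) mzValues(x)[apexIndex(x)]

setMethod("show", "IsotopeEnvelope", function(object) {
  cat(sprintf("IsotopeEnvelope: %d isotopologues, charge %d (%s)\n",
              length(object@mz), object@charge, object@carrier))
  cat(sprintf("  apex %.5f, span %.5f - %.5f\n",
              apexMz(object), min(object@mz), max(object@mz)))
})

#' Prune an envelope at a relative-abundance threshold
#'
#' Discards bins below `threshold` times the apex abundance from both ends
#' of the envelope (interior bins are retained), then renormalizes to
#' max = 1.  Pruning twice at the same threshold is a no-op.
#'
#' @param x An `IsotopeEnvelope`.
#' @param threshold Relative abundance in (0, 1).
#' @return A pruned `IsotopeEnvelope`.
#' @export
pruneEnvelope <- function(x, threshold = 0.01) {
  stopifnot(threshold > 0, threshold < 1)
  ab <- abundances(x)
  keep <- which(ab >= threshold * max(ab))
  idx <- seq(min(keep), max(keep))
  .newEnvelope(mzValues(x)[idx], ab[idx], chargeState(x), x@carrier,
               x@nCarriers)
}

## ---- nominal-mass isotopologue distribution engine --------------------

## Distribution representation: list(p, s) over neutron shifts 0..K where
## p[k+1] = probability of shift k and s[k+1] = sum(p_i * m_i) over the
## fine structure in bin k (so centroid = s/p).

.atomDistribution <- function(element) {
  sub <- .isotopeTable[.isotopeTable$element == element, ]
  K <- max(sub$shift)
  p <- numeric(K + 1)
  s <- numeric(K + 1)
  p[sub$shift + 1] <- sub$abundance
  s[sub$shift + 1] <- sub$abundance * sub$mass
  list(p = p, s = s)
}

## convolve two (p, s) distributions; prune bins < prune * max(p)
.convDist <- function(d1, d2, prune = 1e-10) {
  n1 <- length(d1$p); n2 <- length(d2$p)
  p <- numeric(n1 + n2 - 1)
  s <- numeric(n1 + n2 - 1)
  ## loop over the shorter one
  if (n1 > n2) { tmp <- d1; d1 <- d2; d2 <- tmp; n1 <- length(d1$p) }
  for (i in seq_len(n1)) {
    pi <- d1$p[i]
    if (pi == 0 && d1$s[i] == 0) next
    idx <- i:(i + length(d2$p) - 1)
    p[idx] <- p[idx] + pi * d2$p
    s[idx] <- s[idx] + pi * d2$s + d1$s[i] * d2$p
  }
  .pruneDist(list(p = p, s = s), prune)
}

.pruneDist <- function(d, prune) {
  mx <- max(d$p)
  drop <- d$p < prune * mx
  d$p[drop] <- 0
  d$s[drop] <- 0
  keep <- which(d$p > 0)
  idx <- seq(min(keep), max(keep))
  shift0 <- min(keep) - 1L
  list(p = d$p[idx], s = d$s[idx], shift0 = shift0)
}

## repeated-squaring power of a distribution
.powDist <- function(d, n, prune = 1e-10) {
  stopifnot(n >= 1)
  result <- NULL
  base <- d
  while (n > 0) {
    if (n %% 2 == 1) {
      result <- if (is.null(result)) base else .convDist(result, base, prune)
    }
    n <- n %/% 2
    if (n > 0) base <- .convDist(base, base, prune)
  }
  result
}

#' Nominal-mass isotopologue distribution of a composition
#'
#' Computes the aggregated (nominal-mass binned) isotopologue distribution
#' of a neutral molecule by repeated-squaring polynomial convolution of
#' per-element distributions, with per-step pruning at 1e-10 relative
#' abundance.  Bin centroids are abundance-weighted mean masses of the
#' underlying fine structure.
#'
#' @param comp An [ElementalComposition-class].
#' @param pruneThreshold Relative abundance below which bins are discarded
#'   from both ends of the final envelope (default 0.01 = 1 percent of the
#'   apex, which is roughly what is visible above noise in imaging data).
#' @return A neutral (`charge == 0`) [IsotopeEnvelope-class].
#' @export
#' @examples
#' isotopeDistribution(ElementalComposition("C100"))
isotopeDistribution <- function(comp, pruneThreshold = 0.01) {
  stopifnot(is(comp, "ElementalComposition"))
  stopifnot(pruneThreshold > 0, pruneThreshold < 1)
  cnt <- elementCounts(comp)
  if (sum(cnt) < 1) stop("empty composition")
  total <- NULL
  for (el in names(cnt)) {
    de <- .powDist(.atomDistribution(el), cnt[[el]])
    total <- if (is.null(total)) de else .convDist(total, de)
  }
  keep <- total$p > 0
  mz <- (total$s / total$p)[keep]
  p <- total$p[keep]
  env <- .newEnvelope(mz, p, charge = 0L)
  pruneEnvelope(env, pruneThreshold)
}

## ---- mass triple ------------------------------------------------------

#' Monoisotopic, average and most-abundant-isotopologue mass
#'
#' @param comp An [ElementalComposition-class].
#' @return Named numeric vector with elements `monoisotopic`, `average`,
#'   `mostAbundant` (Da).
#' @export
#' @examples
#' massTriple(ElementalComposition("H2O"))
massTriple <- function(comp) {
  stopifnot(is(comp, "ElementalComposition"))
  cnt <- elementCounts(comp)
  mono <- sum(.monoMasses[names(cnt)] * cnt)
  avg <- sum(.avgMasses[names(cnt)] * cnt)
  env <- isotopeDistribution(comp, pruneThreshold = 1e-6)
  c(monoisotopic = mono, average = avg, mostAbundant = apexMz(env))
}

#' Monoisotopic mass of a composition (Da)
#' @param comp An [ElementalComposition-class].
#' @return Numeric mass in Da.
#' @export
monoisotopicMass <- function(comp) {
  cnt <- elementCounts(comp)
  sum(.monoMasses[names(cnt)] * cnt)
}

## ---- ionization -------------------------------------------------------

.carrierMass <- c(
  proton = PROTON_MASS,
  sodium = 22.9897692820 - ELECTRON_MASS,
  potassium = 38.9637064864 - ELECTRON_MASS,
  deprotonation = -PROTON_MASS
)

#' Ionize a neutral envelope
#'
#' Converts neutral isotopologue masses to ion m/z.  Positive carriers add
#' the cation mass (electron mass already accounted for: a proton weighs
#' 1.007276 Da); `"deprotonation"` removes a proton (the electron stays).
#' Abundances are unchanged.  Whether the molecule actually has enough
#' exchangeable hydrogens for the requested deprotonation count is not
#' checked.
#'
#' @param envelope A neutral [IsotopeEnvelope-class].
#' @param charge Integer >= 1.
#' @param carrier One of `"proton"`, `"sodium"`, `"potassium"`,
#'   `"deprotonation"`.
#' @param nCarriers Number of carriers (default = `charge`).
#' @return An ion `IsotopeEnvelope` with `m/z = (M + n * m_carrier) / z`.
#' @export
#' @examples
#' env <- isotopeDistribution(ElementalComposition("C6H12O6"))
#' ionize(env, 1, "deprotonation")
ionize <- function(envelope, charge,
                   carrier = c("proton", "sodium", "potassium",
                               "deprotonation"),
                   nCarriers = charge) {
  carrier <- match.arg(carrier)
  stopifnot(charge >= 1)
  if (chargeState(envelope) != 0) stop("envelope is already ionized")
  mz <- (mzValues(envelope) + nCarriers * .carrierMass[[carrier]]) / charge
  .newEnvelope(mz, abundances(envelope), charge, carrier, nCarriers)
}

#' Recover neutral centroid masses from an ion envelope
#'
#' Inverse of [ionize()]: `M = z * m/z - n * m_carrier`.
#'
#' @param envelope An ion `IsotopeEnvelope`.
#' @return A neutral `IsotopeEnvelope`.
#' @export
deionize <- function(envelope) {
  z <- chargeState(envelope)
  if (z == 0) return(envelope)
  m <- mzValues(envelope) * z -
    envelope@nCarriers * .carrierMass[[envelope@carrier]]
  .newEnvelope(m, abundances(envelope), 0L, "none", 0L)
}

#' Neutral mass corresponding to an observed ion m/z
#'
#' @param mz Observed m/z (Th).
#' @param charge Charge state.
#' @param carrier Charge carrier (see [ionize()]).
#' @param nCarriers Number of carriers (default = `charge`).
#' @return Neutral mass in Da.
#' @export
neutralMass <- function(mz, charge, carrier = "proton", nCarriers = charge) {
  mz * charge - nCarriers * .carrierMass[[carrier]]
}

#' Ion m/z for a neutral mass
#' @param m Neutral mass (Da).
#' @inheritParams neutralMass
#' @return m/z in Th.
#' @export
ionMz <- function(m, charge, carrier = "proton", nCarriers = charge) {
  (m + nCarriers * .carrierMass[[carrier]]) / charge
}
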