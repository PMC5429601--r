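#' IonMode class: metabolite ionization settings
#'
#' Metabolite acquisitions are either negative mode (deprotonated species;
#' organic acids, adenylates, sugar phosphates on 9-AA matrix) or positive
#' mode (protonated species, or amine metabolites carrying a charge-tag
#' derivatization modeled as a configurable mass delta; DHB matrix).  The
#' derivatization delta ships without a default: it must be stated
#' explicitly in the configuration because it depends on the reagent
#' chemistry.
#'
#' @slot polarity `"positive"` or `"negative"`.
#' @slot ionType `"protonated"`, `"deprotonated"` or `"derivatized"`.
#' @slot derivMassDelta Neutral-to-ion mass delta (Da) for
#'   `"derivatized"`; the derivatized species is already a cation, so no
#'   extra proton is added.
#' @slot matrixTag Free-form matrix annotation (e.g. `"9-AA"`, `"DHB"`).
#' @slot mzRange Acquisition m/z range.
#' @export
setClass("IonMode",
  representation(polarity = "character", ionType = "character",
                 derivMassDelta = "numeric", matrixTag = "character",
                 mzRange = "numeric"),
  validity = function(object) {
    if (!object@polarity %in% c("positive", "negative")) {
      return("polarity must be 'positive' or 'negative'")
    }
    if (!object@ionType %in% c("protonated", "deprotonated",
                               "derivatized")) {
      return("unknown ionType")
    }
    if (object@ionType == "deprotonated" && object@polarity != "negative") {
      return("deprotonated species are negative mode")
    }
    if (object@ionType %in% c("protonated", "derivatized") &&
        object@polarity != "positive") {
      return("protonated/derivatized species are positive mode")
    }
    if (object@ionType == "derivatized" &&
        (length(object@derivMassDelta) != 1 ||
         is.na(object@derivMassDelta))) {
      return("derivatized mode requires an explicit derivMassDelta")
    }
    TRUE
  }
)

#' Construct an ion mode
#'
#' @param polarity `"positive"` or `"negative"`.
#' @param ionType `"protonated"`, `"deprotonated"`, `"derivatized"`.
#' @param derivMassDelta Mass delta (Da) for derivatized mode (no
#'   default).
#' @param matrixTag Matrix annotation.
#' @param mzRange Acquisition m/z range.
#' @return An [IonMode-class].
#' @export
IonMode <- function(polarity, ionType, derivMassDelta = NA_real_,
                    matrixTag = "", mzRange = c(50, 1000)) {
  new("IonMode", polarity = polarity, ionType = ionType,
      derivMassDelta = derivMassDelta, matrixTag = matrixTag,
      mzRange = as.numeric(mzRange))
}

#' Expected ion m/z of a neutral mass under an ion mode
#'
#' @param m Neutral monoisotopic mass (Da).
#' @param mode An [IonMode-class].
#' @return m/z in Th.
#' @export
modeIonMz <- function(m, mode) {
  switch(mode@ionType,
         protonated = m + PROTON_MASS,
         deprotonated = m - PROTON_MASS,
         derivatized = m + mode@derivMassDelta)
}

## inverse of modeIonMz
.modeNeutralMass <- function(mz, mode) {
  switch(mode@ionType,
         protonated = mz - PROTON_MASS,
         deprotonated = mz + PROTON_MASS,
         derivatized = mz - mode@derivMassDelta)
}

#' Ring-plus-double-bond equivalents of a CHNOPS formula
#'
#' `RDBE = C + 1 + (N + P)/2 - H/2`; half-integer values are allowed for
#' the plausibility filter (>= 0 by default).
#'
#' @param counts Named vector with any of C, H, N, O, P, S.
#' @return Numeric RDBE.
#' @export
rdbe <- function(counts) {
  g <- function(e) if (e %in% names(counts)) counts[[e]] else 0
  g("C") + 1 + (g("N") + g("P")) / 2 - g("H") / 2
}

#' Default element-count bounds for formula generation (m/z <= 1000)
#'
#' Covers adenylates, sugar phosphates and TCA-cycle intermediates.
#' @return Named integer vector of maxima.
#' @export
defaultFormulaBounds <- function() {
  c(C = 40L, H = 80L, N = 10L, O = 30L, P = 4L, S = 3L)
}

#' Generate elemental formula candidates for an accurate mass
#'
#' Exhaustive CHNOPS enumeration within `bounds`: the neutral mass is
#' back-computed from the ion type, candidate H counts are solved directly
#' from the residual mass over each (C, N, O, P, S) combination, and
#' survivors are filtered by ppm tolerance, RDBE >= `rdbeMin` (and, by
#' default, integer-valued, as required of a neutral closed-shell
#' molecule) and element-ratio plausibility windows (H/C, N/C, O/C, P/C,
#' S/C), then sorted by |ppm|.
#'
#' @param mz Observed ion m/z (Th), within the mode's range.
#' @param mode An [IonMode-class].
#' @param tolPpm Mass tolerance in ppm (default 2; the package's declared
#'   default for "accurate mass" formula work, configurable).
#' @param bounds Named element maxima (see [defaultFormulaBounds()]).
#' @param rdbeMin Minimum RDBE (default 0).
#' @param ratios Plausibility windows: list with `HC`, `NC`, `OC`, `PC`,
#'   `SC` length-2 numerics.
#' @param integerRdbe Require integer RDBE (default TRUE).
#' @param minOPerP Minimum oxygens required per phosphorus (default 3:
#'   biological phosphorus occurs as phosphate; set 0 to disable).
#' @param cap Error out if more than this many raw combinations would be
#'   enumerated.
#' @return `data.frame`: `formula`, `C`..`S`, `neutralMono`, `ionMz`,
#'   `ppm`, `rdbe`, sorted by |ppm|.
#' @export
#' @examples
#' neg <- IonMode("negative", "deprotonated")
#' generateFormulas(179.05611, neg, tolPpm = 2)
generateFormulas <- function(mz, mode, tolPpm = 2,
                             bounds = defaultFormulaBounds(), rdbeMin = 0,
                             ratios = list(HC = c(0, 3.2), NC = c(0, 1.3),
                                           OC = c(0, 3), PC = c(0, 0.5),
                                           SC = c(0, 0.8)),
                             integerRdbe = TRUE, minOPerP = 3,
                             cap = 2e7) {
  if (mz < mode@mzRange[1] || mz > mode@mzRange[2]) {
    stop(sprintf("m/z %.4f outside the mode's range [%g, %g]",
                 mz, mode@mzRange[1], mode@mzRange[2]))
  }
  M <- .modeNeutralMass(mz, mode)
  tolDa <- tolPpm * 1e-6 * mz
  nComb <- prod(bounds[c("C", "N", "O", "P", "S")] + 1)
  if (nComb > cap) stop("bounds enumerate too many combinations; tighten them")
  mC <- .monoMasses[["C"]]; mH <- .monoMasses[["H"]]
  mN <- .monoMasses[["N"]]; mO <- .monoMasses[["O"]]
  mP <- .monoMasses[["P"]]; mS <- .monoMasses[["S"]]
  rows <- list()
  oVec <- 0:bounds[["O"]]
  for (cc in 0:bounds[["C"]]) for (nn in 0:bounds[["N"]]) {
    for (pp in 0:bounds[["P"]]) for (ss in 0:bounds[["S"]]) {
      baseMass <- cc * mC + nn * mN + pp * mP + ss * mS + oVec * mO
      resid <- M - baseMass
      hLo <- ceiling((resid - tolDa) / mH)
      hHi <- floor((resid + tolDa) / mH)
      ok <- which(hHi >= pmax(hLo, 0) & hLo <= bounds[["H"]])
      for (k in ok) {
        for (hh in max(hLo[k], 0):min(hHi[k], bounds[["H"]])) {
          rows[[length(rows) + 1]] <- c(cc, hh, nn, oVec[k], pp, ss)
        }
      }
    }
  }
  empty <- data.frame(formula = character(0), C = integer(0),
                      H = integer(0), N = integer(0), O = integer(0),
                      P = integer(0), S = integer(0),
                      neutralMono = numeric(0), ionMz = numeric(0),
                      ppm = numeric(0), rdbe = numeric(0))
  if (length(rows) == 0) return(empty)
  m <- do.call(rbind, rows)
  colnames(m) <- c("C", "H", "N", "O", "P", "S")
  neutral <- m %*% c(mC, mH, mN, mO, mP, mS)
  ion <- vapply(neutral, modeIonMz, numeric(1), mode = mode)
  ppm <- (mz - ion) / ion * 1e6
  rd <- m[, "C"] + 1 + (m[, "N"] + m[, "P"]) / 2 - m[, "H"] / 2
  keep <- abs(ppm) <= tolPpm & rd >= rdbeMin & m[, "C"] >= 1
  if (integerRdbe) keep <- keep & abs(rd - round(rd)) < 1e-9
  hc <- m[, "H"] / pmax(m[, "C"], 1)
  nc <- m[, "N"] / pmax(m[, "C"], 1)
  oc <- m[, "O"] / pmax(m[, "C"], 1)
  pc <- m[, "P"] / pmax(m[, "C"], 1)
  sc <- m[, "S"] / pmax(m[, "C"], 1)
  keep <- keep & hc >= ratios$HC[1] & hc <= ratios$HC[2] &
    nc >= ratios$NC[1] & nc <= ratios$NC[2] &
    oc >= ratios$OC[1] & oc <= ratios$OC[2] &
    pc >= ratios$PC[1] & pc <= ratios$PC[2] &
    sc >= ratios$SC[1] & sc <= ratios$SC[2]
  keep <- keep & (m[, "P"] == 0 | m[, "O"] >= minOPerP * m[, "P"])
  if (!any(keep)) return(empty)
  m <- m[keep, , drop = FALSE]
  res <- data.frame(
    formula = apply(m, 1, function(cc) {
      formulaString(ElementalComposition(cc[cc > 0]))
    }),
    m, neutralMono = neutral[keep], ionMz = ion[keep], ppm = ppm[keep],
    rdbe = rd[keep], stringsAsFactors = FALSE)
  res <- res[order(abs(res$ppm)), ]
  rownames(res) <- NULL
  res
}

#' Score a formula candidate's isotope pattern against observed peaks
#'
#' Pearson correlation between the candidate's theoretical isotopologue
#' heights (M, M+1, M+2, from the exact composition) and the observed peak
#' heights at those positions; a theoretical member predicted at >= 1
#' percent abundance but absent from the peaks counts as height 0 in the
#' correlation and deducts 0.05 from the score (a three-point Pearson is
#' apex-dominated and barely reacts to a deleted M+1 on its own).  An
#' absent apex (M) peak is a rejection; fewer than two observable members
#' leaves the pattern unscored (`NA`, flagged `"pattern-unscored"`).
#'
#' @param peaks `data.frame` with `mz`, `intensity` (centroids).
#' @param formula Formula string or `ElementalComposition`.
#' @param mode An [IonMode-class].
#' @param tolPpm Peak-pairing tolerance (ppm).
#' @return List: `score` (Pearson r or NA), `status` (`"scored"`,
#'   `"no apex"`, `"pattern-unscored"`), `observed`, `theoretical`.
#' @export
scoreIsotopePattern <- function(peaks, formula, mode, tolPpm = 5) {
  comp <- if (is(formula, "ElementalComposition")) formula
          else ElementalComposition(formula)
  env <- isotopeDistribution(comp, pruneThreshold = 0.01)
  nIso <- min(3, length(mzValues(env)))
  theoM <- mzValues(env)[seq_len(nIso)]
  theoAb <- abundances(env)[seq_len(nIso)]
  theoMz <- vapply(theoM, modeIonMz, numeric(1), mode = mode)
  obs <- vapply(theoMz, function(t) {
    d <- abs(peaks$mz - t)
    if (length(d) == 0) return(NA_real_)
    j <- which.min(d)
    if (d[j] <= pmax(tolPpm * 1e-6 * t, 5e-4)) peaks$intensity[j]
    else NA_real_
  }, numeric(1))
  if (is.na(obs[1])) {
    return(list(score = NA_real_, status = "no apex", observed = obs,
                theoretical = theoAb))
  }
  ## missing members predicted >= 1% count as zero in the correlation
  ## AND carry an explicit score deduction: a three-point Pearson is
  ## dominated by the apex and barely reacts to a deleted M+1 on its own
  nMissing <- sum(is.na(obs) & theoAb >= 0.01)
  obs[is.na(obs) & theoAb >= 0.01] <- 0
  usable <- !is.na(obs)
  if (sum(usable) < 2) {
    return(list(score = NA_real_, status = "pattern-unscored",
                observed = obs, theoretical = theoAb))
  }
  o <- obs[usable] / max(obs[usable])
  t <- theoAb[usable] / max(theoAb[usable])
  r <- if (stats::sd(o) == 0 || stats::sd(t) == 0) 0 else stats::cor(o, t)
  list(score = r - 0.05 * nMissing, status = "scored", observed = obs,
       theoretical = theoAb)
}

#' Read a metabolite reference library
#'
#' Tab-separated text with columns `name`, `formula`, plus optional
#' `pathway`, `amine` (logical: primary amine, derivatizable), `polarity`
#' (`"pos"`, `"neg"` or `"both"`).
#'
#' @param path TSV file.
#' @return `data.frame` with normalized columns.
#' @export
readMetaboliteLibrary <- function(path) {
  lib <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("name", "formula"), names(lib))
  if (length(miss) > 0) {
    stop("library is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!"pathway" %in% names(lib)) lib$pathway <- ""
  if (!"amine" %in% names(lib)) lib$amine <- FALSE
  if (!"polarity" %in% names(lib)) lib$polarity <- "both"
  lib$amine <- as.logical(lib$amine)
  ## validate formulas early
  for (i in seq_len(nrow(lib))) {
    tryCatch(ElementalComposition(lib$formula[i]),
             error = function(e) {
               stop("unparsable formula '", lib$formula[i], "' for '",
                    lib$name[i], "': ", conditionMessage(e))
             })
  }
  lib
}

#' Annotate metabolite peaks against a reference library
#'
#' Computes each library entry's expected ion m/z under the mode (amine
#' metabolites use the derivatization delta when the derivatized mode is
#' active; non-amine metabolites are skipped in that mode), matches peaks
#' within `tolPpm`, scores isotope patterns where possible, and collapses
#' entries sharing one elemental formula into a single mass-class carrying
#' all names: structural isomers are indistinguishable by mass alone and
#' are never disambiguated.
#'
#' @param peaks `data.frame` with `mz`, `intensity`.
#' @param library Library `data.frame` (see [readMetaboliteLibrary()]).
#' @param mode An [IonMode-class].
#' @param tolPpm Matching tolerance (ppm, default 2).
#' @return `data.frame`, one row per matched mass-class: `formula`,
#'   `names` (slash-separated), `pathway`, `expectedMz`, `observedMz`,
#'   `intensity`, `ppm`, `patternScore`, `patternStatus`, `nIsomers`.
#' @export
annotateLibrary <- function(peaks, library, mode, tolPpm = 2) {
  if (nrow(peaks) == 0) {
    return(data.frame(formula = character(0), names = character(0),
                      pathway = character(0), expectedMz = numeric(0),
                      observedMz = numeric(0), intensity = numeric(0),
                      ppm = numeric(0), patternScore = numeric(0),
                      patternStatus = character(0), nIsomers = integer(0)))
  }
  lib <- library
  if (mode@ionType == "derivatized") lib <- lib[lib$amine, , drop = FALSE]
  ## canonical formula key collapses isomers
  lib$key <- vapply(lib$formula, function(f) {
    formulaString(ElementalComposition(f))
  }, character(1))
  out <- lapply(split(lib, lib$key), function(g) {
    M <- monoisotopicMass(ElementalComposition(g$key[1]))
    expMz <- modeIonMz(M, mode)
    d <- abs(peaks$mz - expMz)
    j <- which.min(d)
    if (d[j] > tolPpm * 1e-6 * expMz) return(NULL)
    patt <- scoreIsotopePattern(peaks, g$key[1], mode, tolPpm = 3 * tolPpm)
    data.frame(
      formula = g$key[1],
      names = paste(sort(unique(g$name)), collapse = "/"),
      pathway = paste(sort(unique(g$pathway[nzchar(g$pathway)])),
                      collapse = "/"),
      expectedMz = expMz, observedMz = peaks$mz[j],
      intensity = peaks$intensity[j],
      ppm = (peaks$mz[j] - expMz) / expMz * 1e6,
      patternScore = patt$score, patternStatus = patt$status,
      nIsomers = length(unique(g$name)), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    return(annotateLibrary(peaks[0, , drop = FALSE], library, mode, tolPpm))
  }
  rownames(res) <- NULL
  res[order(res$expectedMz), ]
}

#' Re-rank formula candidates using the observed isotope pattern
#'
#' Attaches to each candidate its isotope-pattern Pearson score and a
#' pattern deviation (sum of absolute differences between max-normalized
#' observed and theoretical heights at M..M+2, divided by the summed
#' theoretical heights), then orders candidates by pattern deviation and
#' |ppm|.  A three-point Pearson correlation barely separates M+1-ratio
#' differences, so the deviation is the primary sort key; accurate mass
#' breaks ties.  Candidates whose pattern cannot be scored sort last
#' among themselves by |ppm|.
#'
#' @param peaks Observed peak `data.frame` (`mz`, `intensity`).
#' @param candidates Output of [generateFormulas()].
#' @param mode An [IonMode-class].
#' @param tolPpm Peak-pairing tolerance forwarded to
#'   [scoreIsotopePattern()].
#' @return `candidates` with added `patternScore`, `patternDeviation`,
#'   `patternStatus`, re-ordered.
#' @export
rankFormulaCandidates <- function(peaks, candidates, mode, tolPpm = 5) {
  if (nrow(candidates) == 0) {
    candidates$patternScore <- numeric(0)
    candidates$patternDeviation <- numeric(0)
    candidates$patternStatus <- character(0)
    return(candidates)
  }
  sc <- lapply(candidates$formula, function(f) {
    patt <- scoreIsotopePattern(peaks, f, mode, tolPpm = tolPpm)
    dev <- NA_real_
    if (patt$status == "scored") {
      obs <- patt$observed
      theo <- patt$theoretical
      usable <- !is.na(obs)
      o <- obs[usable] / max(obs[usable])
      t <- theo[usable] / max(theo[usable])
      dev <- sum(abs(o - t)) / sum(t)
    }
    list(score = patt$score, dev = dev, status = patt$status)
  })
  candidates$patternScore <- vapply(sc, `[[`, numeric(1), "score")
  candidates$patternDeviation <- vapply(sc, `[[`, numeric(1), "dev")
  candidates$patternStatus <- vapply(sc, `[[`, character(1), "status")
  ord <- order(is.na(candidates$patternDeviation),
               candidates$patternDeviation, abs(candidates$ppm))
  out <- candidates[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
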