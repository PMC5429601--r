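#' MatchConfig class: acceptance gates for proteoform assignment
#'
#' Assignments must pass two gates: accurate mass (|ppm| below
#' `tolerancePpm`, measured on the apex isotopologue, default 10 ppm) and
#' envelope-shape agreement (Pearson r of max-normalized heights at least
#' `rMin`, default 0.95).  The correlation runs over theoretical
#' isotopologues with relative abundance at least `theoryThreshold` of the
#' apex; a theoretical member with no experimental counterpart contributes
#' an experimental height of 0 (penalizing incomplete envelopes) under the
#' default `missingPolicy = "zero"`, or is dropped under `"drop"`.
#'
#' @slot tolerancePpm Mass tolerance (ppm), > 0.
#' @slot rMin Minimum Pearson correlation, in (0, 1].
#' @slot theoryThreshold Relative-abundance floor defining which
#'   theoretical isotopologues enter the correlation (default 0.05).
#' @slot missingPolicy `"zero"` or `"drop"`.
#' @slot tieEpsilon Rank-score window within which co-assignments are
#'   reported as ties.
#' @slot pairTolPpm Tolerance for pairing theoretical and experimental
#'   members by position (ppm).
#' @slot massIndistPpm,massIndistDa Window (ppm, and an absolute floor in
#'   Da on the neutral scale) within which two candidates' theoretical
#'   apex masses are considered indistinguishable given realistic
#'   calibration error; the Da floor (default 0.04) covers the classic
#'   near-isobaric modification pairs differing by CH4-vs-O (36.4 mDa,
#'   e.g. trimethyl vs acetyl, methyl vs oxidation+disulfide), which no
#'   mass measurement at 5-16 kDa can separate.  Such candidates form one
#'   ambiguity cluster reported as co-assignments, ordered by
#'   modification parsimony.
#' @export
setClass("MatchConfig",
  representation(tolerancePpm = "numeric", rMin = "numeric",
                 theoryThreshold = "numeric", missingPolicy = "character",
                 tieEpsilon = "numeric", pairTolPpm = "numeric",
                 massIndistPpm = "numeric", massIndistDa = "numeric"),
  validity = function(object) {
    if (object@tolerancePpm <= 0) return("tolerancePpm must be > 0")
    if (object@rMin <= 0 || object@rMin > 1) return("rMin must be in (0, 1]")
    if (!object@missingPolicy %in% c("zero", "drop")) {
      return("missingPolicy must be 'zero' or 'drop'")
    }
    TRUE
  }
)

#' Construct a match configuration
#'
#' @param tolerancePpm Mass tolerance in ppm (default 10).
#' @param rMin Minimum Pearson r (default 0.95).
#' @param theoryThreshold Theoretical-abundance floor (default 0.05).
#' @param missingPolicy `"zero"` (default) or `"drop"`.
#' @param tieEpsilon Tie window on the rank score (default 0.005).
#' @param pairTolPpm Member-pairing tolerance in ppm (default 6).
#' @param massIndistPpm Mass-indistinguishability window in ppm
#'   (default 5).
#' @param massIndistDa Absolute indistinguishability floor in Da on the
#'   neutral mass (default 0.04).
#' @return A [MatchConfig-class].
#' @export
MatchConfig <- function(tolerancePpm = 10, rMin = 0.95,
                        theoryThreshold = 0.05, missingPolicy = "zero",
                        tieEpsilon = 0.005, pairTolPpm = 6,
                        massIndistPpm = 5, massIndistDa = 0.04) {
  new("MatchConfig", tolerancePpm = tolerancePpm, rMin = rMin,
      theoryThreshold = theoryThreshold, missingPolicy = missingPolicy,
      tieEpsilon = tieEpsilon, pairTolPpm = pairTolPpm,
      massIndistPpm = massIndistPpm, massIndistDa = massIndistDa)
}

setMethod("show", "MatchConfig", function(object) {
  cat(sprintf(
    "MatchConfig: |ppm| < %g, r >= %g (theory >= %g%%, missing = %s)\n",
    object@tolerancePpm, object@rMin, 100 * object@theoryThreshold,
    object@missingPolicy))
})

#' Score one candidate against one experimental envelope
#'
#' The ppm error is the signed offset between the experimental apex m/z
#' and the theoretical apex-isotopologue m/z (the monoisotopic peak of a
#' 5-16 kDa protein is weak or absent at realistic SNR, so the apex is the
#' robust anchor).  The Pearson correlation pairs each theoretical
#' isotopologue above `theoryThreshold` with the experimental height at
#' that position, both vectors max-normalized.  A result is accepted iff
#' both gates pass; fewer than 3 usable pairs is a rejection flagged
#' `"insufficient envelope"`, never a pass.
#'
#' @param env An [ExperimentalEnvelope-class].
#' @param candidate One-row candidate `data.frame` (see
#'   [enumerateCandidates()]); its theoretical envelope is computed via
#'   [candidateEnvelope()].  Alternatively pass a precomputed theoretical
#'   ion [IsotopeEnvelope-class] via `theoretical`.
#' @param cfg A [MatchConfig-class].
#' @param theoretical Optional precomputed theoretical ion envelope.
#' @return A one-row `data.frame`: `ppm`, `r`, `rankScore`, `nPairs`,
#'   `accepted`, `reason`.
#' @export
scoreMatch <- function(env, candidate = NULL, cfg = MatchConfig(),
                       theoretical = NULL) {
  stopifnot(is(env, "ExperimentalEnvelope"))
  theo <- if (is.null(theoretical)) {
    candidateEnvelope(candidate, pruneThreshold = cfg@theoryThreshold)
  } else theoretical
  theo <- pruneEnvelope(theo, cfg@theoryThreshold)
  tMz <- mzValues(theo)
  tAb <- abundances(theo)
  expApex <- envelopeApexMz(env)
  apexIdxT <- which.max(tAb)
  theoApex <- tMz[apexIdxT]
  ppm <- (expApex - theoApex) / theoApex * 1e6
  ## apex-position correction: when the top two theoretical bins are
  ## nearly degenerate (>= 70% relative abundance), envelope noise can
  ## flip the experimental argmax to the neighboring isotopologue; the
  ## mass error is then measured against that member, not the nominal
  ## apex, so a one-bin argmax flip does not masquerade as a ~1 Da error
  apexShifted <- FALSE
  j <- which.min(abs(tMz - expApex))
  if (j != apexIdxT && abs(j - apexIdxT) == 1 && tAb[j] >= 0.7) {
    ppm <- (expApex - tMz[j]) / tMz[j] * 1e6
    apexShifted <- TRUE
  }
  ## pair theoretical members with experimental heights by position,
  ## after aligning the theoretical grid onto the experimental apex: the
  ## coherent mass offset (calibration + candidate error) is already
  ## captured by the ppm gate, so the correlation measures shape only
  anchor <- if (apexShifted) tMz[j] else theoApex
  shift <- expApex - anchor
  pairTol <- pmax(cfg@pairTolPpm * 1e-6 * tMz, 0.002)
  expHeight <- vapply(seq_along(tMz), function(i) {
    d <- abs(env@mz - (tMz[i] + shift))
    k <- which.min(d)
    if (length(k) == 1 && d[k] <= pairTol[i]) env@intensity[k] else NA_real_
  }, numeric(1))
  if (cfg@missingPolicy == "zero") {
    expHeight[is.na(expHeight)] <- 0
  } else {
    keep <- !is.na(expHeight)
    tAb <- tAb[keep]
    expHeight <- expHeight[keep]
  }
  nPairs <- length(expHeight)
  base <- data.frame(ppm = ppm, r = NA_real_, rankScore = NA_real_,
                     nPairs = nPairs, apexShifted = apexShifted,
                     accepted = FALSE, reason = "",
                     stringsAsFactors = FALSE)
  if (nPairs < 3 || sum(expHeight > 0) < 2) {
    base$reason <- "insufficient envelope"
    return(base)
  }
  eNorm <- expHeight / max(expHeight)
  tNorm <- tAb / max(tAb)
  r <- if (stats::sd(eNorm) == 0 || stats::sd(tNorm) == 0) 0
       else stats::cor(eNorm, tNorm)
  base$r <- r
  base$rankScore <- r * (1 - abs(ppm) / cfg@tolerancePpm)
  if (abs(ppm) >= cfg@tolerancePpm) {
    base$reason <- "mass gate"
  } else if (r < cfg@rMin) {
    base$reason <- "correlation gate"
  } else {
    base$accepted <- TRUE
    base$reason <- "accepted"
  }
  base
}

#' Assign region-restricted candidates to the envelopes of one ROI
#'
#' Scores every candidate of the matching charge whose theoretical apex
#' can fall near the observed apex (cheap neutral-mass prefilter), keeps
#' the accepted ones, ranks them by `r x (1 - |ppm|/tolerance)`, and
#' reports the top-ranked candidate as the primary assignment with ties
#' within `tieEpsilon` flagged as co-assignments.  Candidates must already
#' be region-restricted ([restrictByRegion()]); unassigned envelopes are
#' reported with `accession = NA`.
#'
#' @param envelopes List of [ExperimentalEnvelope-class] (one ROI).
#' @param candidates Region-restricted candidate `data.frame`.
#' @param cfg A [MatchConfig-class].
#' @param roiLabel Region label stamped into the result rows.
#' @param decoy Logical flag stamped into the result rows.
#' @return List with `assignments` (one row per accepted
#'   envelope-candidate pair, ranked within envelope) and `primary` (one
#'   row per envelope: top assignment or NA).
#' @export
assignRoi <- function(envelopes, candidates, cfg = MatchConfig(),
                      roiLabel = NA_character_, decoy = FALSE) {
  ## apex neutron shift never exceeds ~25 for <= 30 kDa; prefilter window
  rows <- list()
  for (ei in seq_along(envelopes)) {
    env <- envelopes[[ei]]
    z <- chargeState(env)
    expNeutralApex <- neutralMass(envelopeApexMz(env), z, "proton")
    if (nrow(candidates) > 0) {
      ## the apex sits ~0.000572 x M neutron shifts above the
      ## monoisotopic mass, so only candidates in a narrow mono window
      ## below the observed apex can ever match
      shiftMax <- 6.2e-4 * expNeutralApex + 1.5
      sel <- candidates$charge == z &
        candidates$neutralMono > expNeutralApex - shiftMax &
        candidates$neutralMono < expNeutralApex + 1
      sub <- candidates[sel, , drop = FALSE]
    } else {
      sub <- candidates
    }
    for (ci in seq_len(nrow(sub))) {
      cand <- sub[ci, , drop = FALSE]
      sc <- scoreMatch(env, cand, cfg)
      if (isTRUE(sc$accepted)) {
        isDecoy <- if ("decoy" %in% names(cand)) cand$decoy else decoy
        nMods <- if ("nMods" %in% names(cand)) cand$nMods else 0L
        rows[[length(rows) + 1]] <- cbind(
          data.frame(envelope = ei, apexMz = envelopeApexMz(env),
                     charge = z, stringsAsFactors = FALSE),
          cand[c("accession", "region", "variant", "adduct",
                 "neutralMono", "proteoform", "label")],
          sc[c("ppm", "r", "rankScore", "nPairs")],
          data.frame(nMods = nMods,
                     theoApex = envelopeApexMz(env) / (1 + sc$ppm * 1e-6),
                     decoy = isDecoy))
      }
    }
  }
  assignments <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(envelope = integer(0), apexMz = numeric(0),
               charge = integer(0), accession = character(0),
               region = character(0), variant = character(0),
               adduct = character(0), neutralMono = numeric(0),
               proteoform = character(0), label = character(0),
               ppm = numeric(0), r = numeric(0), rankScore = numeric(0),
               nPairs = integer(0), nMods = integer(0),
               theoApex = numeric(0), decoy = logical(0))
  rownames(assignments) <- NULL
  primary <- do.call(rbind, lapply(seq_along(envelopes), function(ei) {
    sub <- assignments[assignments$envelope == ei, , drop = FALSE]
    if (nrow(sub) == 0) {
      return(data.frame(envelope = ei,
                        apexMz = envelopeApexMz(envelopes[[ei]]),
                        charge = chargeState(envelopes[[ei]]),
                        accession = NA_character_,
                        proteoform = NA_character_, label = NA_character_,
                        ppm = NA_real_, r = NA_real_,
                        rankScore = NA_real_, ties = 0L,
                        tiedLabels = "", region = roiLabel,
                        stringsAsFactors = FALSE))
    }
    sub <- sub[order(-sub$rankScore), , drop = FALSE]
    ## ambiguity cluster: candidates whose theoretical apex masses lie
    ## within the calibration-limited indistinguishability window of the
    ## top-ranked one cannot be separated by mass; order them by
    ## modification parsimony (then rank score) and report all as
    ## co-assignments
    dNeutral <- abs(sub$theoApex - sub$theoApex[1]) * sub$charge
    inCluster <- dNeutral <= pmax(
      cfg@massIndistPpm * 1e-6 * sub$theoApex[1] * sub$charge,
      cfg@massIndistDa) |
      sub$rankScore >= sub$rankScore[1] - cfg@tieEpsilon
    cl <- sub[inCluster, , drop = FALSE]
    ## parsimony = departures from the plain protonated full chain:
    ## each modification, a non-proton adduct, and a chain truncation
    ## all count as one assumption
    parsimony <- cl$nMods + (cl$adduct != "proton") +
      (cl$variant != "full")
    cl <- cl[order(parsimony, -cl$rankScore), , drop = FALSE]
    ## one co-assignment per distinct proteoform mass-class
    coLabels <- unique(cl$label)
    data.frame(envelope = ei, apexMz = cl$apexMz[1],
               charge = cl$charge[1], accession = cl$accession[1],
               proteoform = cl$proteoform[1], label = cl$label[1],
               ppm = cl$ppm[1], r = cl$r[1],
               rankScore = cl$rankScore[1],
               ties = length(coLabels) - 1L,
               tiedLabels = paste(setdiff(coLabels, cl$label[1]),
                                  collapse = ";"),
               region = roiLabel, stringsAsFactors = FALSE)
  }))
  list(assignments = assignments, primary = primary)
}

#' Corroborate assignments across charge states
#'
#' Groups accepted assignments by proteoform identity, recomputes the
#' neutral (apex) mass from each charge state's observed apex m/z, and
#' declares a group corroborated when at least two charge states agree
#' within the ppm tolerance.  Detecting the same proteoform at several
#' charge states with consistent neutral mass is internal verification of
#' the assignment.
#'
#' @param assignments Assignment `data.frame` from [assignRoi()].
#' @param tolPpm Dispersion tolerance in ppm (default 10; groups under
#'   1 ppm on clean data).
#' @return `data.frame` with one row per proteoform group: `proteoform`,
#'   `nCharges`, `charges`, `neutralApexMean`, `dispersionPpm`,
#'   `verdict` (`"corroborated"` / `"single-state"` / `"discordant"`).
#' @export
corroborateCharges <- function(assignments, tolPpm = 10) {
  if (nrow(assignments) == 0) {
    return(data.frame(proteoform = character(0), nCharges = integer(0),
                      charges = character(0), neutralApexMean = numeric(0),
                      dispersionPpm = numeric(0), verdict = character(0)))
  }
  out <- lapply(split(assignments, assignments$proteoform), function(g) {
    zs <- sort(unique(g$charge))
    neutral <- vapply(seq_len(nrow(g)), function(i) {
      neutralMass(g$apexMz[i], g$charge[i], "proton")
    }, numeric(1))
    mu <- mean(neutral)
    disp <- if (length(neutral) > 1) {
      (max(neutral) - min(neutral)) / mu * 1e6
    } else 0
    verdict <- if (length(zs) < 2) "single-state"
               else if (disp < tolPpm) "corroborated"
               else "discordant"
    data.frame(proteoform = g$proteoform[1], nCharges = length(zs),
               charges = paste(zs, collapse = ","),
               neutralApexMean = mu, dispersionPpm = disp,
               verdict = verdict, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build shuffled-sequence decoy records
#'
#' Pools the residues of all target sequences, permutes the pool, and
#' re-splits it at the original lengths: the length and overall mass
#' distribution of the list are preserved while individual masses are
#' scrambled.  (A within-protein permutation would preserve each exact
#' composition and make every decoy a guaranteed self-match, which is why
#' the shuffle is pooled; reversal is equally useless for mass-only
#' matching.)
#'
#' @param records Identification records ([idRecords()]).
#' @param tag Accession prefix for the decoys.
#' @return A list of decoy records.
#' @export
decoyRecords <- function(records, tag = "DECOY_") {
  seqs <- vapply(records, function(r) r$sequence, character(1))
  lens <- nchar(seqs)
  pool <- strsplit(paste(seqs, collapse = ""), "")[[1]]
  shuffled <- sample(pool)
  stops <- cumsum(lens)
  starts <- c(1, utils::head(stops, -1) + 1)
  lapply(seq_along(records), function(i) {
    r <- records[[i]]
    r$sequence <- paste(shuffled[starts[i]:stops[i]], collapse = "")
    r$accession <- paste0(tag, r$accession)
    r
  })
}

#' Estimate false-assignment behavior with shuffled-sequence decoys
#'
#' Competitive target-decoy assessment: decoy candidates (from
#' [decoyRecords()], enumerated under the identical search space) are
#' pooled with the target candidates and the envelopes are assigned
#' against the combined list.  Reported are (i) the accepted decoy
#' *pair* count/rate (decoy candidates passing both gates anywhere, a
#' direct readout of how permissive the gates are) and (ii) the decoy
#' *primary* rate: the fraction of envelopes whose top-ranked assignment
#' is a decoy, i.e. the rate at which the pipeline would actually report
#' a false identity.
#'
#' @param envelopes List of [ExperimentalEnvelope-class] (one ROI).
#' @param targetCandidates Region-restricted target candidate
#'   `data.frame`.
#' @param records Identification records behind the target list (used to
#'   build decoys); restrict to the same ROI as the envelopes.
#' @param cfg A [MatchConfig-class].
#' @param searchCfg A [SearchSpaceConfig-class].
#' @param nDecoys Number of decoy proteome replicates (>= 1).
#' @param seed Integer seed for the decoy shuffles.
#' @return List: `nEnvelopes`, `nDecoys`, `acceptedDecoyPairs`,
#'   `pairRate` (pairs per envelope per replicate), `decoyPrimary`,
#'   `primaryRate` (decoy-primary envelopes / (envelopes x replicates)).
#' @export
decoyAssign <- function(envelopes, targetCandidates, records,
                        cfg = MatchConfig(),
                        searchCfg = SearchSpaceConfig(), nDecoys = 1,
                        seed = 1) {
  if (nDecoys < 1) stop("nDecoys must be >= 1")
  pairCount <- 0L
  primaryCount <- 0L
  target <- targetCandidates
  if (nrow(target) > 0) target$decoy <- FALSE
  set.seed(seed)
  for (d in seq_len(nDecoys)) {
    dRecs <- decoyRecords(records, tag = paste0("DECOY", d, "_"))
    dCands <- do.call(rbind, lapply(dRecs, enumerateCandidates,
                                    cfg = searchCfg))
    if (nrow(dCands) > 0) dCands$decoy <- TRUE
    combined <- rbind(target, dCands)
    res <- assignRoi(envelopes, combined, cfg)
    pairCount <- pairCount + sum(res$assignments$decoy)
    primaryCount <- primaryCount +
      sum(!is.na(res$primary$accession) &
            grepl("^DECOY", res$primary$accession))
  }
  n <- length(envelopes) * nDecoys
  list(nEnvelopes = length(envelopes), nDecoys = nDecoys,
       acceptedDecoyPairs = pairCount, pairRate = pairCount / n,
       decoyPrimary = primaryCount, primaryRate = primaryCount / n)
}
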