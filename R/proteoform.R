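#' SearchSpaceConfig class
#'
#' Bounds of the proteoform candidate search space: per-modification count
#' limits, a cap on total modifications, the charge range, the adduct list
#' (as signed elemental deltas on the neutral species) and the neutral-mass
#' window restricting candidates to the instrument range.
#'
#' @slot modBounds Named integer vector of per-modification maxima.
#' @slot maxTotalMods Integer cap on the summed modification count.
#' @slot charges Integer vector of charge states to enumerate.
#' @slot adducts `data.frame` with columns `name`, `gain`, `loss` (formula
#'   strings applied to the neutral composition; `proton` rows are empty).
#' @slot massWindow Numeric length-2 neutral monoisotopic mass window (Da).
#' @slot maxCandidates Combinatorial cap; enumeration beyond it is an
#'   error asking the user to tighten bounds.
#' @slot registry Modification registry `data.frame`.
#' @export
setClass("SearchSpaceConfig",
  representation(modBounds = "integer", maxTotalMods = "integer",
                 charges = "integer", adducts = "data.frame",
                 massWindow = "numeric", maxCandidates = "integer",
                 registry = "data.frame"),
  validity = function(object) {
    if (any(object@modBounds < 0)) return("modification bounds must be >= 0")
    if (any(object@charges < 1)) return("charges must be >= 1")
    if (length(object@massWindow) != 2 ||
        object@massWindow[1] >= object@massWindow[2]) {
      return("massWindow must be an increasing length-2 numeric")
    }
    bad <- setdiff(names(object@modBounds), object@registry$name)
    if (length(bad) > 0) {
      return(paste0("modBounds name(s) not in registry: ",
                    paste(bad, collapse = ", ")))
    }
    TRUE
  }
)

#' Default MALDI adduct table
#'
#' Protonated species plus sodium/potassium salt exchange (+Na-H, +K-H on
#' the neutral, then protonated to the target charge) and a matrix adduct.
#' The matrix adduct defaults to sinapinic acid minus water (+C11H10O4);
#' both the compound and the delta are configurable because matrix-adduct
#' composition is preparation dependent.
#'
#' @param matrixGain,matrixLoss Formula strings for the matrix adduct
#'   delta.
#' @return `data.frame` with columns `name`, `gain`, `loss`.
#' @export
defaultAdducts <- function(matrixGain = "C11H10O4", matrixLoss = "") {
  data.frame(
    name = c("proton", "sodium", "potassium", "matrix"),
    gain = c("", "Na", "K", matrixGain),
    loss = c("", "H", "H", matrixLoss),
    stringsAsFactors = FALSE
  )
}

#' Construct a search-space configuration
#'
#' Defaults cover every mass shift searched for histone-type proteoforms:
#' up to trimethylation, two acetylations, double oxidation, one
#' deamidation and one disulfide, at most 4 modifications in total, charges
#' 1-3, H+/Na+/K+/matrix adducts, and a neutral-mass window matching the
#' intact-protein acquisition range.
#'
#' @param modBounds Named integer vector of per-modification maxima.
#' @param maxTotalMods Cap on total modification count.
#' @param charges Integer charge states.
#' @param adducts Adduct `data.frame` (see [defaultAdducts()]).
#' @param massWindow Neutral monoisotopic mass window (Da).
#' @param maxCandidates Enumeration cap per record.
#' @param registry Modification registry.
#' @return A [SearchSpaceConfig-class].
#' @export
SearchSpaceConfig <- function(modBounds = c(methyl = 3L, acetyl = 2L,
                                            oxidation = 2L,
                                            deamidation = 1L,
                                            disulfide = 1L),
                              maxTotalMods = 4L,
                              charges = 1:3,
                              adducts = defaultAdducts(),
                              massWindow = c(3500, 30000),
                              maxCandidates = 200000L,
                              registry = defaultModificationRegistry()) {
  new("SearchSpaceConfig",
      modBounds = stats::setNames(as.integer(modBounds), names(modBounds)),
      maxTotalMods = as.integer(maxTotalMods),
      charges = as.integer(charges), adducts = adducts,
      massWindow = as.numeric(massWindow),
      maxCandidates = as.integer(maxCandidates), registry = registry)
}

setMethod("show", "SearchSpaceConfig", function(object) {
  cat("SearchSpaceConfig\n")
  cat("  mod bounds:",
      paste(sprintf("%s<=%d", names(object@modBounds), object@modBounds),
            collapse = ", "),
      sprintf("(total <= %d)\n", object@maxTotalMods))
  cat("  charges:", paste(object@charges, collapse = ", "), "\n")
  cat("  adducts:", paste(object@adducts$name, collapse = ", "), "\n")
  cat(sprintf("  neutral mass window: [%g, %g] Da\n",
              object@massWindow[1], object@massWindow[2]))
})

## signed delta vector for an adduct row
.adductDelta <- function(adducts, name) {
  i <- match(name, adducts$name)
  if (is.na(i)) stop("unknown adduct '", name, "'")
  gain <- .parseFormula(adducts$gain[i])
  loss <- .parseFormula(adducts$loss[i])
  els <- union(names(gain), names(loss))
  delta <- stats::setNames(integer(length(els)), els)
  delta[names(gain)] <- delta[names(gain)] + gain
  delta[names(loss)] <- delta[names(loss)] - loss
  delta[delta != 0]
}

## ---- identification tables -------------------------------------------

#' IdTable class: parsed bottom-up identification/quantification export
#'
#' @slot proteins `data.frame` with one row per accession x region:
#'   `accession`, `region`, `description`, `sequence`.
#' @slot peptides `data.frame` of peptide-level evidence: `accession`,
#'   `region`, `peptide`, `replicate`, `area` (NA = not quantified in that
#'   replicate, which is distinct from zero).
#' @export
setClass("IdTable",
  representation(proteins = "data.frame", peptides = "data.frame"))

setMethod("show", "IdTable", function(object) {
  cat(sprintf("IdTable: %d protein-region records, %d peptide rows, regions: %s\n",
              nrow(object@proteins), nrow(object@peptides),
              paste(unique(object@proteins$region), collapse = ", ")))
})

#' @describeIn IdTable-class protein-level records accessor
#' @param x An `IdTable`.
#' @export
idProteins <- function(x) x@proteins

#' @describeIn IdTable-class peptide-level evidence accessor
#' @export
idPeptides <- function(x) x@peptides

#' Load a bottom-up identification table
#'
#' Reads a delimited export with mandatory columns `accession`, `region`,
#' `peptide`, `replicate`, `area`, plus optional `description` and
#' `sequence`.  Protein sequences missing from the table must be present
#' in the companion FASTA.  Duplicate accession rows within a region are
#' merged; their peptide evidence is concatenated.  Missing areas are kept
#' as `NA` (absent), never coerced to zero.
#'
#' @param path Delimited text file (tab-separated by default).
#' @param fasta Optional FASTA path or named sequence vector supplying
#'   protein sequences.
#' @param sep Field separator.
#' @return An [IdTable-class].
#' @export
loadIdTable <- function(path, fasta = NULL, sep = "\t") {
  tab <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("accession", "region", "peptide", "replicate", "area")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("identification table is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (!"description" %in% names(tab)) tab$description <- ""
  seqs <- NULL
  if (!is.null(fasta)) {
    seqs <- if (is.character(fasta) && length(fasta) == 1 &&
                file.exists(fasta)) readProteinFasta(fasta) else fasta
  }
  prot <- unique(tab[c("accession", "region")])
  prot$description <- vapply(seq_len(nrow(prot)), function(i) {
    d <- tab$description[tab$accession == prot$accession[i]]
    d <- d[nzchar(d)]
    if (length(d) > 0) d[1] else ""
  }, character(1))
  getSeq <- function(acc) {
    if ("sequence" %in% names(tab)) {
      s <- tab$sequence[tab$accession == acc]
      s <- s[!is.na(s) & nzchar(s)]
      if (length(s) > 0) return(s[1])
    }
    if (!is.null(seqs) && acc %in% names(seqs)) return(unname(seqs[[acc]]))
    stop("no sequence for accession '", acc,
         "' in table or companion FASTA")
  }
  prot$sequence <- vapply(prot$accession, getSeq, character(1))
  rownames(prot) <- NULL
  pep <- tab[c("accession", "region", "peptide", "replicate", "area")]
  pep$area <- as.numeric(pep$area)
  new("IdTable", proteins = prot, peptides = pep)
}

#' Identification records grouped by accession x region
#'
#' @param x An [IdTable-class].
#' @return A list of records, each a list with elements `accession`,
#'   `region`, `description`, `sequence`, `peptides` (evidence
#'   `data.frame`).
#' @export
idRecords <- function(x) {
  prot <- idProteins(x)
  pep <- idPeptides(x)
  lapply(seq_len(nrow(prot)), function(i) {
    sel <- pep$accession == prot$accession[i] & pep$region == prot$region[i]
    list(accession = prot$accession[i], region = prot$region[i],
         description = prot$description[i], sequence = prot$sequence[i],
         peptides = pep[sel, , drop = FALSE])
  })
}

## ---- candidate enumeration -------------------------------------------

## all modification count vectors within bounds and total cap
.modCountGrid <- function(bounds, maxTotal) {
  grids <- lapply(bounds, function(b) 0:b)
  grid <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[rowSums(grid) <= maxTotal, , drop = FALSE]
  rownames(grid) <- NULL
  grid
}

## short proteoform tag, e.g. "2me1ac|Met-loss|sodium|z2"
.modTag <- function(mods) {
  abbr <- c(methyl = "me", acetyl = "ac", oxidation = "ox",
            deamidation = "de", disulfide = "ss")
  on <- mods[mods > 0]
  if (length(on) == 0) return("unmod")
  tags <- names(on)
  short <- ifelse(tags %in% names(abbr), abbr[tags], tags)
  paste0(on, short, collapse = "")
}

#' Enumerate proteoform candidates for one identification record
#'
#' Cartesian product of chain variants (full chain; initiator-Met-removed
#' when the sequence starts with M) x modification count vectors within the
#' configured bounds x adducts x charge states, filtered to the configured
#' neutral monoisotopic mass window.  Compositions are carried as formula
#' strings; theoretical envelopes are computed lazily via
#' [candidateEnvelope()] with caching, because only the mass-window
#' survivors near an observed envelope ever need one.
#'
#' @param record One element of [idRecords()] (a list with `accession`,
#'   `region`, `sequence`, `description`).
#' @param cfg A [SearchSpaceConfig-class].
#' @return `data.frame` with one row per candidate: `accession`, `region`,
#'   `variant`, one count column per modification, `adduct`, `charge`,
#'   `neutralMono`, `formula`, `proteoform` (identity tag excluding
#'   charge), `label` (identity tag including charge).
#' @export
enumerateCandidates <- function(record, cfg = SearchSpaceConfig()) {
  stopifnot(is(cfg, "SearchSpaceConfig"))
  seqs <- c(full = record$sequence)
  if (substr(record$sequence, 1, 1) == "M" && nchar(record$sequence) > 1) {
    seqs <- c(seqs, `Met-loss` = substr(record$sequence, 2,
                                        nchar(record$sequence)))
  }
  modGrid <- .modCountGrid(cfg@modBounds, cfg@maxTotalMods)
  nTotal <- length(seqs) * nrow(modGrid) * nrow(cfg@adducts) *
    length(cfg@charges)
  if (nTotal > cfg@maxCandidates) {
    stop(sprintf(paste0("candidate space for '%s' has %d combinations, ",
                        "exceeding the cap of %d; tighten the bounds"),
                 record$accession, nTotal, cfg@maxCandidates))
  }
  modNames <- names(cfg@modBounds)
  modDeltas <- lapply(modNames, modificationDelta, registry = cfg@registry)
  names(modDeltas) <- modNames
  modMasses <- vapply(modDeltas, attr, numeric(1), "monoMass")
  adductDeltas <- lapply(cfg@adducts$name, .adductDelta,
                         adducts = cfg@adducts)
  names(adductDeltas) <- cfg@adducts$name
  adductMasses <- vapply(adductDeltas, deltaMass, numeric(1))

  ## element universe and mod-delta matrix (nMods x nElements)
  els <- Reduce(union, c(lapply(modDeltas, names),
                         lapply(adductDeltas, names),
                         list(colnames(.residueTable))))
  D <- matrix(0L, length(modNames), length(els),
              dimnames = list(modNames, els))
  for (mn in modNames) D[mn, names(modDeltas[[mn]])] <- modDeltas[[mn]]
  G <- as.matrix(modGrid)                   # grid rows x mods
  modTags <- apply(G, 1, function(m) .modTag(stats::setNames(m, modNames)))
  gridDelta <- G %*% D                      # grid rows x elements
  gridMass <- as.vector(G %*% modMasses)

  out <- list()
  for (v in names(seqs)) {
    baseComp <- compositionFromSequence(seqs[[v]])
    baseMass <- monoisotopicMass(baseComp)
    baseCnt <- stats::setNames(integer(length(els)), els)
    baseCnt[names(elementCounts(baseComp))] <- elementCounts(baseComp)
    for (an in cfg@adducts$name) {
      aCnt <- stats::setNames(integer(length(els)), els)
      aCnt[names(adductDeltas[[an]])] <- adductDeltas[[an]]
      cnts <- sweep(gridDelta, 2, baseCnt + aCnt, "+")
      mass <- baseMass + gridMass + adductMasses[[an]]
      ok <- apply(cnts >= 0, 1, all) &
        mass >= cfg@massWindow[1] & mass <= cfg@massWindow[2]
      if (!any(ok)) next
      formulas <- apply(cnts[ok, , drop = FALSE], 1, function(cc) {
        formulaString(new("ElementalComposition",
                          counts = as.integer(cc[cc != 0]) |>
                            stats::setNames(names(cc)[cc != 0])))
      })
      pf <- paste(record$accession, v, modTags[ok], an, sep = "|")
      base <- data.frame(accession = record$accession,
                         region = record$region, variant = v,
                         stringsAsFactors = FALSE)
      modCols <- as.data.frame(G[ok, , drop = FALSE])
      for (z in cfg@charges) {
        out[[length(out) + 1]] <- cbind(
          base[rep(1, sum(ok)), , drop = FALSE], modCols,
          data.frame(nMods = rowSums(G[ok, , drop = FALSE]),
                     adduct = an, charge = z, neutralMono = mass[ok],
                     formula = formulas, proteoform = pf,
                     label = paste0(pf, "|z", z),
                     stringsAsFactors = FALSE))
      }
    }
  }
  if (length(out) == 0) {
    cols <- c("accession", "region", "variant", modNames, "nMods",
              "adduct", "charge", "neutralMono", "formula", "proteoform",
              "label")
    df <- as.data.frame(stats::setNames(rep(list(character(0)),
                                            length(cols)), cols))
    return(df)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Enumerate candidates for every record of an identification table
#'
#' @param idtab An [IdTable-class] or list of records.
#' @param cfg A [SearchSpaceConfig-class].
#' @return Row-bound candidate `data.frame` (see [enumerateCandidates()]).
#' @export
enumerateAllCandidates <- function(idtab, cfg = SearchSpaceConfig()) {
  recs <- if (is(idtab, "IdTable")) idRecords(idtab) else idtab
  do.call(rbind, lapply(recs, enumerateCandidates, cfg = cfg))
}

#' Restrict candidates to one region of interest
#'
#' Implements region-specific assignment: peaks from one ROI are only ever
#' compared against proteins identified in that same microdissected
#' region.
#'
#' @param candidates Candidate `data.frame`.
#' @param roiLabel Region label.
#' @param vocabulary Optional character vector of allowed labels; labels
#'   outside it are an error (defaults to the labels present plus
#'   `roiLabel` being checked against the candidates' own labels).
#' @return The candidate subset carrying `roiLabel` (possibly empty).
#' @export
restrictByRegion <- function(candidates, roiLabel, vocabulary = NULL) {
  if (!is.null(vocabulary) && !roiLabel %in% vocabulary) {
    stop("unknown region label '", roiLabel, "'; vocabulary: ",
         paste(vocabulary, collapse = ", "))
  }
  candidates[candidates$region == roiLabel, , drop = FALSE]
}

## ---- lazy theoretical envelopes --------------------------------------

.envelopeCache <- new.env(parent = emptyenv())

#' Theoretical ion envelope of one candidate row
#'
#' Computes (and memoizes by formula x charge x prune threshold) the
#' nominal-mass isotopologue envelope of the candidate's neutral
#' composition, protonated to the candidate's charge.  Na/K/matrix adducts
#' are already part of the neutral composition (salt exchange), so the
#' charge carriers are always protons.
#'
#' @param candidate One row of a candidate `data.frame`.
#' @param pruneThreshold Relative-abundance prune threshold.
#' @return An ion [IsotopeEnvelope-class].
#' @export
candidateEnvelope <- function(candidate, pruneThreshold = 0.01) {
  key <- paste0(candidate$formula, "|z", candidate$charge, "|p",
                pruneThreshold)
  hit <- .envelopeCache[[key]]
  if (!is.null(hit)) return(hit)
  neutral <- isotopeDistribution(ElementalComposition(candidate$formula),
                                 pruneThreshold = pruneThreshold)
  env <- ionize(neutral, charge = as.integer(candidate$charge),
                carrier = "proton")
  .envelopeCache[[key]] <- env
  env
}
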