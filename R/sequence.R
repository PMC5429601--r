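#' Elemental composition of a peptide or protein sequence
#'
#' Sums the residue compositions of a standard 20-letter amino-acid
#' sequence; with `includeWater = TRUE` (the default) one water is added,
#' giving the intact chain.  Cysteines are treated as free thiols; a
#' disulfide is an explicit modification (`-H2` per bond).
#'
#' @param sequence Non-empty amino-acid string (standard 20 letters).
#' @param includeWater Add one H2O for the intact chain termini.
#' @return An [ElementalComposition-class].
#' @export
#' @examples
#' compositionFromSequence("G")   # free glycine: C2H5NO2
compositionFromSequence <- function(sequence, includeWater = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (!nzchar(sequence)) stop("empty sequence")
  sequence <- toupper(sequence)
  aa <- strsplit(sequence, "")[[1]]
  bad <- which(!aa %in% rownames(.residueTable))
  if (length(bad) > 0) {
    stop(sprintf("unknown residue '%s' at position %d", aa[bad[1]], bad[1]))
  }
  tab <- table(factor(aa, levels = rownames(.residueTable)))
  cnt <- as.vector(tab %*% .residueTable)
  names(cnt) <- colnames(.residueTable)
  if (includeWater) cnt <- cnt + c(C = 0, H = 2, N = 0, O = 1, S = 0)
  ElementalComposition(cnt)
}

#' Monoisotopic mass of a sequence (fast path)
#'
#' Residue-mass table lookup; used in enumeration hot loops where full
#' compositions are not needed.
#'
#' @inheritParams compositionFromSequence
#' @return Numeric mass in Da.
#' @export
sequenceMonoMass <- function(sequence, includeWater = TRUE) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  m <- .residueMonoMass[aa]
  if (anyNA(m)) {
    bad <- which(is.na(m))[1]
    stop(sprintf("unknown residue '%s' at position %d", aa[bad], bad))
  }
  sum(m) + if (includeWater) WATER_MONO_MASS else 0
}

#' Read protein sequences from FASTA
#'
#' Thin wrapper over `Biostrings::readAAStringSet`; names are truncated at
#' the first whitespace (accession only), full headers are kept as an
#' attribute.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences, with attribute
#'   `descriptions`.
#' @export
readProteinFasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  headers <- names(seqs)
  names(seqs) <- sub("\\s.*$", "", headers)
  attr(seqs, "descriptions") <- sub("^\\S+\\s*", "", headers)
  seqs
}

#' Write protein sequences to FASTA
#'
#' @param sequences Named character vector.
#' @param path Output file.
#' @export
writeProteinFasta <- function(sequences, path) {
  aa <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' In-silico tryptic digestion
#'
#' Cleaves after K or R, not before P, and returns all peptides with up to
#' `missedCleavages` internal missed cleavage sites.
#'
#' @param sequence Amino-acid string.
#' @param missedCleavages Maximum number of missed cleavages (default 2).
#' @param minLength Minimum peptide length to report (default 6, a typical
#'   detectability floor for bottom-up LC-MS/MS).
#' @return `data.frame` with columns `peptide`, `start`, `end`,
#'   `missed`.
#' @export
#' @examples
#' trypticPeptides("MKWVTFISLLLLFSSAYSR", missedCleavages = 1)
trypticPeptides <- function(sequence, missedCleavages = 2, minLength = 6) {
  stopifnot(missedCleavages >= 0)
  aa <- strsplit(toupper(sequence), "")[[1]]
  n <- length(aa)
  ## cleavage after position i if aa[i] in KR and aa[i+1] != P
  cut <- which(aa %in% c("K", "R"))
  cut <- cut[cut < n]
  cut <- cut[aa[cut + 1] != "P"]
  bounds <- c(0, cut, n)   # fragment i spans (bounds[i]+1):bounds[i+1]
  nfrag <- length(bounds) - 1
  out <- list()
  for (i in seq_len(nfrag)) {
    for (m in 0:min(missedCleavages, nfrag - i)) {
      s <- bounds[i] + 1
      e <- bounds[i + 1 + m]
      if (e - s + 1 < minLength) next
      out[[length(out) + 1]] <- data.frame(
        peptide = paste(aa[s:e], collapse = ""),
        start = s, end = e, missed = m, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(peptide = character(0), start = integer(0),
                      end = integer(0), missed = integer(0)))
  }
  do.call(rbind, out)
}
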