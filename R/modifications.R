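#' Modification registry
#'
#' The default registry holds the mass shifts searched when assigning
#' intact-protein imaging peaks: histone-type PTMs (methylation up to
#' trimethyl via the `methyl` counter, acetylation) and chemical
#' modifications (single/double oxidation via the `oxidation` counter,
#' deamidation, disulfide bond formation).  Each entry is a signed
#' elemental delta expressed as a `gain` and a `loss` formula.
#'
#' @return A `data.frame` with columns `name`, `gain`, `loss`.
#' @export
#' @examples
#' defaultModificationRegistry()
defaultModificationRegistry <- function() {
  data.frame(
    name = c("methyl", "acetyl", "oxidation", "deamidation", "disulfide"),
    gain = c("CH2", "C2H2O", "O", "O", ""),
    loss = c("", "", "", "HN", "H2"),
    stringsAsFactors = FALSE
  )
}

#' Read a user modification registry from a delimited file
#'
#' Tab-separated text with columns `name`, `gain`, `loss` (empty string for
#' no gain/loss).  The result can be passed to [modificationDelta()] and
#' [SearchSpaceConfig()] to extend or replace the default search space.
#'
#' @param path Path to the TSV file.
#' @return A registry `data.frame`.
#' @export
readModificationRegistry <- function(path) {
  reg <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = character(0))
  need <- c("name", "gain", "loss")
  miss <- setdiff(need, names(reg))
  if (length(miss) > 0) {
    stop("registry is missing column(s): ", paste(miss, collapse = ", "))
  }
  reg[need]
}

#' Signed elemental delta of a named modification
#'
#' @param name Modification identifier present in `registry`.
#' @param registry A registry `data.frame` (default
#'   [defaultModificationRegistry()]).
#' @return Named integer vector of signed element-count changes, with
#'   attribute `monoMass` giving the monoisotopic mass shift in Da.
#' @export
#' @examples
#' modificationDelta("acetyl")
modificationDelta <- function(name, registry = defaultModificationRegistry()) {
  i <- match(name, registry$name)
  if (is.na(i)) {
    stop("unknown modification '", name, "'; registry has: ",
         paste(registry$name, collapse = ", "))
  }
  gain <- .parseFormula(registry$gain[i])
  loss <- .parseFormula(registry$loss[i])
  els <- union(names(gain), names(loss))
  delta <- stats::setNames(integer(length(els)), els)
  delta[names(gain)] <- delta[names(gain)] + gain
  delta[names(loss)] <- delta[names(loss)] - loss
  delta <- delta[delta != 0]
  attr(delta, "monoMass") <- deltaMass(delta)
  delta
}
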