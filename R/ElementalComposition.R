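#' ElementalComposition class
#'
#' Multiset of element counts describing a neutral molecule (or molecular
#' chain).  Counts are non-negative integers; signed changes (modification
#' gains/losses) are applied through [applyDelta()], which refuses to drive
#' any count negative.
#'
#' @slot counts Named integer vector of per-element atom counts.
#' @export
setClass("ElementalComposition",
  representation(counts = "integer"),
  validity = function(object) {
    cnt <- object@counts
    if (is.null(names(cnt)) || any(!nzchar(names(cnt)))) {
      return("counts must be a named integer vector")
    }
    bad <- setdiff(names(cnt), .knownElements)
    if (length(bad) > 0) {
      return(paste0("unknown element(s): ", paste(bad, collapse = ", ")))
    }
    if (any(cnt < 0)) return("element counts must be >= 0")
    TRUE
  }
)

#' Create an elemental composition
#'
#' @param x Either a molecular formula string (e.g. `"C6H12O6"`) or a named
#'   numeric vector of element counts.
#' @return An [ElementalComposition-class] object.
#' @export
#' @examples
#' ElementalComposition("C6H12O6")
#' ElementalComposition(c(C = 2, H = 5, N = 1, O = 2))
ElementalComposition <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1)
    cnt <- .parseFormula(x)
  } else if (is.numeric(x)) {
    cnt <- x
  } else {
    stop("x must be a formula string or a named numeric vector")
  }
  cnt <- cnt[cnt != 0]
  ## merge duplicate names
  if (anyDuplicated(names(cnt))) {
    cnt <- tapply(cnt, names(cnt), sum)
    cnt <- cnt[cnt != 0]
  }
  stor <- as.integer(round(cnt))
  names(stor) <- names(cnt)
  new("ElementalComposition", counts = stor)
}

## "C6H12O6" -> c(C = 6, H = 12, O = 6); signed terms allowed ("C2H-2")
.parseFormula <- function(s) {
  s <- gsub("[[:space:]]", "", s)
  if (!nzchar(s)) return(integer(0))
  m <- gregexpr("([A-Z][a-z]?)(-?[0-9]*)", s)[[1]]
  pieces <- regmatches(s, gregexpr("([A-Z][a-z]?)(-?[0-9]*)", s))[[1]]
  if (sum(nchar(pieces)) != nchar(s)) {
    stop("cannot parse formula: '", s, "'")
  }
  el <- sub("^([A-Z][a-z]?).*$", "\\1", pieces)
  nstr <- sub("^[A-Z][a-z]?", "", pieces)
  n <- ifelse(nzchar(nstr), as.integer(nstr), 1L)
  bad <- setdiff(el, .knownElements)
  if (length(bad) > 0) {
    stop("unknown element(s) in formula '", s, "': ",
         paste(bad, collapse = ", "))
  }
  stats::setNames(n, el)
}

#' @describeIn ElementalComposition-class element counts accessor
#' @param object,x An `ElementalComposition`.
#' @export
elementCounts <- function(x) {
  stopifnot(is(x, "ElementalComposition"))
  x@counts
}

#' Total number of atoms in a composition
#' @param x An `ElementalComposition`.
#' @return Integer atom count.
#' @export
totalAtoms <- function(x) sum(elementCounts(x))

#' Canonical formula string (Hill-ish order: C, H, then alphabetical)
#' @param x An `ElementalComposition`.
#' @return Character scalar like `"C6H12O6"`.
#' @export
formulaString <- function(x) {
  cnt <- elementCounts(x)
  ord <- c(intersect(c("C", "H"), names(cnt)),
           sort(setdiff(names(cnt), c("C", "H"))))
  cnt <- cnt[ord]
  paste0(names(cnt), ifelse(cnt == 1, "", cnt), collapse = "")
}

setMethod("show", "ElementalComposition", function(object) {
  cat("ElementalComposition:", formulaString(object),
      sprintf("(%d atoms)\n", totalAtoms(object)))
})

.combineCounts <- function(a, b, sign = 1L) {
  els <- union(names(a), names(b))
  out <- stats::setNames(integer(length(els)), els)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + sign * as.integer(b)
  out[out != 0]
}

#' @export
setMethod("+", signature("ElementalComposition", "ElementalComposition"),
  function(e1, e2) {
    new("ElementalComposition",
        counts = .combineCounts(e1@counts, e2@counts, 1L))
  })

#' @export
setMethod("-", signature("ElementalComposition", "ElementalComposition"),
  function(e1, e2) {
    cnt <- .combineCounts(e1@counts, e2@counts, -1L)
    if (any(cnt < 0)) {
      stop("subtraction would yield negative count for: ",
           paste(names(cnt)[cnt < 0], collapse = ", "))
    }
    new("ElementalComposition", counts = cnt)
  })

#' @export
setMethod("*", signature("ElementalComposition", "numeric"),
  function(e1, e2) {
    stopifnot(length(e2) == 1, e2 >= 0, e2 == round(e2))
    new("ElementalComposition", counts = e1@counts * as.integer(e2))
  })

#' @export
setMethod("*", signature("numeric", "ElementalComposition"),
  function(e1, e2) e2 * e1)

#' Apply a signed elemental delta to a composition
#'
#' Modification and adduct deltas are signed named integer vectors (e.g.
#' `c(H = -1, N = -1, O = 1)` for deamidation).  Applying a delta that
#' would drive any element count negative is an error.
#'
#' @param x An `ElementalComposition`.
#' @param delta Named integer vector (possibly signed) of element changes.
#' @param n Number of times to apply the delta.
#' @return An `ElementalComposition`.
#' @export
applyDelta <- function(x, delta, n = 1L) {
  stopifnot(is(x, "ElementalComposition"), n >= 0)
  if (n == 0 || length(delta) == 0) return(x)
  cnt <- .combineCounts(x@counts, round(delta * n), 1L)
  if (any(cnt < 0)) {
    stop("delta would yield negative count for: ",
         paste(names(cnt)[cnt < 0], collapse = ", "))
  }
  new("ElementalComposition", counts = cnt)
}

#' Monoisotopic mass of a signed delta (Da)
#' @param delta Named numeric vector of element changes.
#' @return Numeric mass shift in Da.
#' @export
deltaMass <- function(delta) {
  if (length(delta) == 0) return(0)
  bad <- setdiff(names(delta), .knownElements)
  if (length(bad) > 0) stop("unknown element(s): ", paste(bad, collapse = ", "))
  sum(.monoMasses[names(delta)] * delta)
}
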