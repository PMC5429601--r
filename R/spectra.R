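#' ROI-average spectrum
#'
#' Arithmetic mean of the member-pixel spectra.  Continuous-mode datasets
#' average on the native shared axis; processed-mode datasets are first
#' re-gridded by linear interpolation onto `axis` (mandatory in that
#' case).  The default is an unnormalized mean; `normalize = "tic"`
#' rescales each pixel spectrum to unit total ion current first.
#'
#' @param ds An [MSIDataset-class].
#' @param mask An [ROIMask-class] (or integer pixel indices).
#' @param normalize `"none"` (default) or `"tic"`.
#' @param axis Re-grid axis for processed-mode data.
#' @return `data.frame` with columns `mz`, `intensity`.
#' @export
roiAverageSpectrum <- function(ds, mask, normalize = c("none", "tic"),
                               axis = NULL) {
  normalize <- match.arg(normalize)
  idx <- if (is(mask, "ROIMask")) maskIndices(ds, mask) else as.integer(mask)
  if (length(idx) == 0) stop("empty mask")
  if (ds@mode == "continuous") {
    outMz <- ds@mzAxis
    acc <- numeric(length(outMz))
    .withIbd(ds, function(con) {
      for (i in idx) {
        a <- ds@arrays[i, ]
        y <- .readSlice(con, a$intOffset, a$intLength, a$intSize)
        if (normalize == "tic") {
          s <- sum(y)
          if (s > 0) y <- y / s
        }
        acc <<- acc + y
      }
    })
  } else {
    if (is.null(axis)) stop("processed-mode averaging requires an axis")
    outMz <- axis
    acc <- numeric(length(outMz))
    .withIbd(ds, function(con) {
      for (i in idx) {
        a <- ds@arrays[i, ]
        mz <- .readSlice(con, a$mzOffset, a$mzLength, a$mzSize)
        y <- .readSlice(con, a$intOffset, a$intLength, a$intSize)
        if (normalize == "tic") {
          s <- sum(y)
          if (s > 0) y <- y / s
        }
        yi <- stats::approx(mz, y, xout = outMz, rule = 1)$y
        yi[is.na(yi)] <- 0
        acc <<- acc + yi
      }
    })
  }
  data.frame(mz = outMz, intensity = acc / length(idx))
}

## ---- peak picking -----------------------------------------------------

## robust local noise in ~5 Th windows (step function).  A plain MAD
## breaks down where isotopologue peaks of intact proteins occupy more
## than half the window (high m/z: peak FWHM approaches the 1 Th
## spacing), so the baseline s.d. is estimated from the lower tail of
## the window's intensity distribution: for Gaussian baseline noise,
## sigma = (q25 - q05) / 0.9708, which tolerates up to ~75% of samples
## being in-peak.
.localNoise <- function(mz, y, windowTh = 5) {
  edges <- seq(min(mz), max(mz) + windowTh, by = windowTh)
  bin <- findInterval(mz, edges)
  est <- vapply(split(y, bin), function(v) {
    q <- stats::quantile(v, c(0.05, 0.25), names = FALSE, type = 5)
    (q[2] - q[1]) / 0.9708
  }, numeric(1))
  noise <- est[match(bin, as.integer(names(est)))]
  ## guard against all-signal or all-zero windows
  floorVal <- stats::median(noise[noise > 0])
  if (is.na(floorVal) || floorVal == 0) floorVal <- .Machine$double.eps
  pmax(noise, floorVal * 0.1)
}

#' Pick peaks from a profile spectrum
#'
#' Local maxima exceeding `snrMin` times a robust local noise estimate
#' (median absolute deviation, scaled, in a sliding ~5 Th window).  Apex
#' m/z is refined by three-point parabolic interpolation.
#'
#' @param spectrum `data.frame` with `mz`, `intensity` (profile mode).
#' @param snrMin Minimum signal-to-noise ratio (default 5).
#' @param noiseWindowTh Width of the noise-estimation window in Th.
#' @return `data.frame` with columns `mz`, `intensity`, `noise`, `snr`,
#'   sorted by m/z; zero rows when nothing exceeds the threshold.
#' @export
pickPeaks <- function(spectrum, snrMin = 5, noiseWindowTh = 5) {
  mz <- spectrum$mz
  y <- spectrum$intensity
  n <- length(y)
  empty <- data.frame(mz = numeric(0), intensity = numeric(0),
                      noise = numeric(0), snr = numeric(0))
  if (n < 3 || all(y <= 0)) return(empty)
  isMax <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                    y[2:(n - 1)] >= y[3:n], FALSE)
  noise <- .localNoise(mz, y, noiseWindowTh)
  cand <- which(isMax & y > snrMin * noise)
  if (length(cand) == 0) return(empty)
  ## three-point parabolic apex refinement; log-space when all three
  ## heights are positive (exact for Gaussian line shapes, also correct
  ## on the non-uniform axis), raw-space fallback otherwise
  refine <- function(i) {
    x0 <- mz[i - 1]; x1 <- mz[i]; x2 <- mz[i + 1]
    y0 <- y[i - 1]; y1 <- y[i]; y2 <- y[i + 1]
    useLog <- y0 > 0 && y2 > 0
    v0 <- if (useLog) log(y0) else y0
    v1 <- if (useLog) log(y1) else y1
    v2 <- if (useLog) log(y2) else y2
    d1 <- (v1 - v0) / (x1 - x0)
    d2 <- (v2 - v1) / (x2 - x1)
    a <- (d2 - d1) / (x2 - x0)
    if (a >= 0) return(c(x1, y1))
    b <- d1 - a * (x0 + x1)
    xv <- -b / (2 * a)
    if (xv < x0 || xv > x2) return(c(x1, y1))
    vv <- a * xv^2 + b * xv + (v1 - a * x1^2 - b * x1)
    c(xv, if (useLog) exp(vv) else vv)
  }
  ref <- vapply(cand, refine, numeric(2))
  data.frame(mz = ref[1, ], intensity = ref[2, ], noise = noise[cand],
             snr = y[cand] / noise[cand])
}

## ---- experimental envelopes ------------------------------------------

#' ExperimentalEnvelope class
#'
#' A set of picked peaks interpreted as one isotopologue series: members
#' spaced by ~1.00235/z Th, the apex being the most intense member.
#' `completeness` is the fraction of members expected above 5 percent of
#' the apex (for an average protein-like composition at the implied mass)
#' that were actually observed.
#'
#' @slot mz,intensity Member peak positions and heights.
#' @slot charge Inferred charge state.
#' @slot apexIdx Index of the apex member.
#' @slot completeness Observed / expected member fraction.
#' @slot score Charge-hypothesis ranking score (completeness x summed
#'   member intensity).
#' @slot memberIdx Indices of the members in the source peak table.
#' @export
setClass("ExperimentalEnvelope",
  representation(mz = "numeric", intensity = "numeric", charge = "integer",
                 apexIdx = "integer", completeness = "numeric",
                 score = "numeric", memberIdx = "integer"),
  validity = function(object) {
    if (length(object@mz) != length(object@intensity)) {
      return("mz and intensity must have equal length")
    }
    if (length(object@mz) > 1 && any(diff(object@mz) <= 0)) {
      return("member m/z must be strictly increasing")
    }
    TRUE
  }
)

setMethod("show", "ExperimentalEnvelope", function(object) {
  cat(sprintf(
    "ExperimentalEnvelope: %d members, z=%d, apex %.5f, completeness %.2f\n",
    length(object@mz), object@charge, object@mz[object@apexIdx],
    object@completeness))
})

#' @describeIn ExperimentalEnvelope-class member m/z accessor
#' @param x An `ExperimentalEnvelope`.
#' @export
setMethod("mzValues", "ExperimentalEnvelope", function(x) x@mz)

#' @describeIn ExperimentalEnvelope-class charge accessor
#' @export
setMethod("chargeState", "ExperimentalEnvelope", function(x) x@charge)

#' Apex m/z of an experimental envelope
#' @param x An `ExperimentalEnvelope`.
#' @return Numeric m/z.
#' @export
envelopeApexMz <- function(x) x@mz[x@apexIdx]

#' Expected isotopologue count above a threshold for a protein-like mass
#'
#' Poisson approximation to the aggregated isotopologue distribution of an
#' average protein-like composition: the mean neutron shift grows linearly
#' with mass (about 5.7e-4 per Da).  Used only as a completeness
#' denominator during envelope extraction, never for theoretical
#' envelopes.
#'
#' @param neutralMassDa Neutral mass (Da).
#' @param threshold Relative abundance threshold (default 0.05).
#' @return Integer expected member count.
#' @export
expectedIsotopologues <- function(neutralMassDa, threshold = 0.05) {
  lambda <- max(5.714e-4 * neutralMassDa, 1e-6)
  k <- 0:max(10, ceiling(lambda + 8 * sqrt(lambda)))
  p <- stats::dpois(k, lambda)
  sum(p >= threshold * max(p))
}

#' Extract isotopologue envelopes around a seed peak
#'
#' For each hypothesized charge, greedily collects peaks at
#' `seed +/- k * 1.00235/z` within a ppm-scaled tolerance, stopping after
#' two consecutive missing members on either side.  Hypotheses are ranked
#' by completeness x summed member intensity, which resolves the
#' half-spacing ambiguity: a z-hypothesis that explains only every other
#' member loses on intensity, one that implies a too-dense grid loses on
#' completeness.
#'
#' @param peaks Peak table from [pickPeaks()].
#' @param seedIdx Row index of the seed peak.
#' @param charges Charge hypotheses (default 1:3).
#' @param tolPpm Member matching tolerance in ppm (default 6).
#' @param carrier Assumed charge carrier for the implied-mass computation.
#' @return List of [ExperimentalEnvelope-class], one per viable charge,
#'   sorted by decreasing score.
#' @export
extractEnvelope <- function(peaks, seedIdx, charges = 1:3, tolPpm = 6,
                            carrier = "proton") {
  stopifnot(seedIdx >= 1, seedIdx <= nrow(peaks))
  seedMz <- peaks$mz[seedIdx]
  out <- list()
  for (z in charges) {
    sp <- ISOTOPE_SPACING / z
    tol <- pmax(tolPpm * 1e-6 * seedMz, 0.002)
    members <- seedIdx
    for (dir in c(1, -1)) {
      miss <- 0
      k <- 1
      while (miss < 2) {
        target <- seedMz + dir * k * sp
        d <- abs(peaks$mz - target)
        j <- which.min(d)
        if (length(j) == 1 && d[j] <= tol && !(j %in% members)) {
          members <- c(members, j)
          miss <- 0
        } else {
          miss <- miss + 1
        }
        k <- k + 1
      }
    }
    members <- sort(members)
    mzs <- peaks$mz[members]
    ints <- peaks$intensity[members]
    implied <- neutralMass(seedMz, z, carrier)
    expN <- expectedIsotopologues(implied)
    completeness <- min(1, length(members) / expN)
    out[[length(out) + 1]] <- new("ExperimentalEnvelope",
      mz = mzs, intensity = ints, charge = as.integer(z),
      apexIdx = which.max(ints), completeness = completeness,
      score = completeness * sum(ints), memberIdx = as.integer(members))
  }
  out[order(vapply(out, function(e) e@score, numeric(1)),
            decreasing = TRUE)]
}

## Split a member chain into unimodal humps at deep valleys.  Proteoform
## ladders (e.g. methylation series 14 Da apart) produce one continuous
## isotopologue comb whose per-species humps are separated by deep local
## minima; each hump is one species' envelope.  A valley splits when its
## depth falls below `frac` of the smaller neighboring hump maximum.
.splitHumps <- function(intensity, frac = 0.25) {
  n <- length(intensity)
  if (n < 3) return(list(seq_len(n)))
  ## local maxima and minima of the member sequence
  segments <- list()
  start <- 1
  i <- 2
  lastMax <- intensity[1]
  while (i < n) {
    isMin <- intensity[i] < intensity[i - 1] && intensity[i] <= intensity[i + 1]
    if (isMin) {
      ## max after this valley until the next valley-or-end
      j <- i + 1
      nextMax <- intensity[j]
      while (j < n && intensity[j + 1] >= intensity[j]) {
        j <- j + 1
        nextMax <- max(nextMax, intensity[j])
      }
      ## deepest-point comparison against both flanking hump maxima
      if (intensity[i] < frac * min(lastMax, nextMax)) {
        segments[[length(segments) + 1]] <- start:i
        start <- i + 1
        lastMax <- nextMax
      } else {
        lastMax <- max(lastMax, nextMax)
      }
      i <- j
    } else {
      lastMax <- max(lastMax, intensity[i])
      i <- i + 1
    }
  }
  segments[[length(segments) + 1]] <- start:n
  segments
}

#' Find all isotopologue envelopes in a peak table
#'
#' Greedy decomposition: seeds at the most intense unclaimed peak, keeps
#' the best-charge envelope (if it has at least `minMembers` members), and
#' marks its members as claimed.  Interspersed envelopes are recovered
#' because claimed peaks are excluded from later extractions, so
#' interleaved series share no members.
#'
#' @param peaks Peak table from [pickPeaks()].
#' @param charges Charge hypotheses.
#' @param tolPpm Member matching tolerance (ppm).
#' @param minMembers Minimum members to keep an envelope (default 3).
#' @return List of [ExperimentalEnvelope-class] with `memberIdx` referring
#'   to rows of `peaks`.
#' @export
findEnvelopes <- function(peaks, charges = 1:3, tolPpm = 6,
                          minMembers = 3) {
  claimed <- rep(FALSE, nrow(peaks))
  envs <- list()
  while (any(!claimed)) {
    free <- which(!claimed)
    sub <- peaks[free, , drop = FALSE]
    seedLocal <- which.max(sub$intensity)
    cands <- extractEnvelope(sub, seedLocal, charges = charges,
                             tolPpm = tolPpm)
    best <- cands[[1]]
    membersGlobal <- free[best@memberIdx]
    claimed[membersGlobal] <- TRUE
    ## a chain crossing a proteoform ladder is multi-humped: emit each
    ## hump as its own envelope
    for (seg in .splitHumps(best@intensity)) {
      if (length(seg) < minMembers) next
      expN <- expectedIsotopologues(
        neutralMass(best@mz[seg][which.max(best@intensity[seg])],
                    best@charge, "proton"))
      envs[[length(envs) + 1]] <- new("ExperimentalEnvelope",
        mz = best@mz[seg], intensity = best@intensity[seg],
        charge = best@charge,
        apexIdx = which.max(best@intensity[seg]),
        completeness = min(1, length(seg) / expN),
        score = best@score,
        memberIdx = as.integer(membersGlobal[seg]))
    }
  }
  envs
}

## ---- ion images -------------------------------------------------------

#' Single-isotope ion image
#'
#' Per-pixel maximum (or integrated) intensity within `+/- tolPpm` of
#' `mzCenter`.  Imaging a single isotopologue rather than a whole envelope
#' preserves molecular specificity when envelopes of different species
#' interleave.
#'
#' @param ds An [MSIDataset-class] (continuous mode).
#' @param mzCenter Center m/z (Th).
#' @param tolPpm Half-window in ppm.
#' @param stat `"max"` (default) or `"sum"`.
#' @return Numeric matrix indexed `[y, x]` (missing pixels are 0), with
#'   attribute `mzWindow`.
#' @export
ionImage <- function(ds, mzCenter, tolPpm = 10, stat = c("max", "sum")) {
  stat <- match.arg(stat)
  stopifnot(tolPpm > 0)
  lo <- mzCenter * (1 - tolPpm * 1e-6)
  hi <- mzCenter * (1 + tolPpm * 1e-6)
  if (hi < ds@mzRange[1] || lo > ds@mzRange[2]) {
    stop(sprintf("window [%.4f, %.4f] lies outside the dataset m/z range",
                 lo, hi))
  }
  coords <- pixelCoords(ds)
  img <- matrix(0, max(coords[, "y"]), max(coords[, "x"]))
  f <- if (stat == "max") max else sum
  if (ds@mode == "continuous") {
    i0 <- findInterval(lo, ds@mzAxis) + 1
    i1 <- findInterval(hi, ds@mzAxis)
    if (i1 < i0) {
      attr(img, "mzWindow") <- c(lo, hi)
      return(img)
    }
    .withIbd(ds, function(con) {
      for (i in seq_len(nPixels(ds))) {
        a <- ds@arrays[i, ]
        y <- .readSlice(con, a$intOffset + (i0 - 1) * a$intSize,
                        i1 - i0 + 1, a$intSize)
        img[coords[i, "y"], coords[i, "x"]] <<- f(y)
      }
    })
  } else {
    .withIbd(ds, function(con) {
      for (i in seq_len(nPixels(ds))) {
        a <- ds@arrays[i, ]
        mz <- .readSlice(con, a$mzOffset, a$mzLength, a$mzSize)
        yv <- .readSlice(con, a$intOffset, a$intLength, a$intSize)
        sel <- mz >= lo & mz <= hi
        img[coords[i, "y"], coords[i, "x"]] <<-
          if (any(sel)) f(yv[sel]) else 0
      }
    })
  }
  attr(img, "mzWindow") <- c(lo, hi)
  img
}

#' Write an ion image as a plain-text matrix (and optionally PNG)
#'
#' @param img Matrix from [ionImage()].
#' @param path Output path for the tab-separated matrix.
#' @param png Optional PNG path (written only if the `png` package is
#'   available).
#' @export
writeIonImage <- function(img, path, png = NULL) {
  utils::write.table(img, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  if (!is.null(png) && requireNamespace("png", quietly = TRUE)) {
    mx <- max(img)
    norm <- if (mx > 0) img / mx else img
    png::writePNG(norm, png)
  }
  invisible(path)
}
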