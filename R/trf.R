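#' @include AllClasses.R
NULL

#' Construct a molecular-length marker ladder
#'
#' @param lengthsKbp marker lengths, kbp
#' @param positions migration positions (increasing = further down the gel);
#'   lengths must strictly decrease with increasing migration
#' @return a \linkS4class{MarkerLadder}
#' @export
markerLadder <- function(lengthsKbp, positions) {
    o <- order(positions)
    new("MarkerLadder", lengthsKbp = lengthsKbp[o], positions = positions[o])
}

#' Default TRF ladder lengths (kbp)
#'
#' The six marker lengths of the standard telomere-length ladder.
#'
#' @return numeric vector of lengths in kbp, descending
#' @export
defaultLadderLengths <- function() c(23.13, 9.42, 6.66, 4.36, 2.32, 2.02)

setMethod("show", "MarkerLadder", function(object) {
    cat("MarkerLadder:", length(object@lengthsKbp), "markers,",
        paste(object@lengthsKbp, collapse = "/"), "kbp\n")
})

#' Fit a gel-migration calibration curve to a ladder
#'
#' Default functional form is log-linear (log10 length linear in migration
#' position), standard practice for agarose gels; a reciprocal form
#' (1/length linear in position) is available as an alternative.
#'
#' @param ladder a \linkS4class{MarkerLadder}
#' @param form \code{"loglinear"} (default) or \code{"reciprocal"}
#' @return list with the fitted \code{predict(position)} mapping (kbp),
#'   \code{rSquared}, the calibrated \code{range} of positions, and
#'   \code{form}
#' @examples
#' lad <- markerLadder(c(1, 0.1), c(10, 20))  # too few markers: see details
#' @export
fitMarkerCurve <- function(ladder, form = c("loglinear", "reciprocal")) {
    form <- match.arg(form)
    stopifnot(is(ladder, "MarkerLadder"))
    pos <- ladder@positions
    y <- switch(form, loglinear = log10(ladder@lengthsKbp),
                reciprocal = 1 / ladder@lengthsKbp)
    fit <- stats::lm(y ~ pos)
    b <- unname(coef(fit))
    pred <- switch(form,
        loglinear = function(p) 10^(b[1] + b[2] * p),
        reciprocal = function(p) 1 / (b[1] + b[2] * p))
    list(predict = pred, rSquared = suppressWarnings(summary(fit)$r.squared),
         range = range(pos), form = form, coef = b)
}

#' Construct a lane densitometry profile
#'
#' @param positions migration positions, strictly increasing
#' @param od optical densities, non-negative
#' @param background constant background offset; NA (default) to estimate at
#'   use time from the profile tails
#' @return a \linkS4class{LaneProfile}
#' @export
laneProfile <- function(positions, od, background = NA_real_) {
    o <- order(positions)
    new("LaneProfile", positions = positions[o], od = od[o],
        background = background)
}

setMethod("show", "LaneProfile", function(object) {
    cat("LaneProfile:", length(object@positions), "bins, OD",
        sprintf("%.3g-%.3g", min(object@od), max(object@od)), "\n")
})

.laneBackground <- function(profile, tailFraction = 0.05) {
    n <- length(profile@od)
    k <- max(1L, floor(n * tailFraction))
    mean(c(profile@od[seq_len(k)], profile@od[seq(n - k + 1L, n)]))
}

#' Hybridization-corrected mean telomere length from a TRF lane
#'
#' Longer restriction fragments carry more repeat units and therefore bind
#' proportionally more probe, so raw optical density over-weights long
#' telomeres.  The corrected mean is
#' \deqn{MTL = \sum_i OD_i / \sum_i (OD_i / L_i)}
#' over background-subtracted bins, with bin lengths \eqn{L_i} read off the
#' marker calibration.  Bins outside the calibrated ladder range are dropped
#' unless \code{extrapolate = TRUE} (then included with a warning).
#'
#' @param profile a \linkS4class{LaneProfile}
#' @param curve calibration from \code{\link{fitMarkerCurve}}
#' @param extrapolate include bins beyond the ladder range
#' @param tailFraction fraction of bins at each profile end used to estimate
#'   a constant background when the profile does not carry one
#' @return mean telomere length, bp
#' @examples
#' lad <- markerLadder(defaultLadderLengths(),
#'                     seq(10, 60, length.out = 6))
#' cv <- fitMarkerCurve(lad)
#' @export
trfMTL <- function(profile, curve, extrapolate = FALSE,
                   tailFraction = 0.05) {
    stopifnot(is(profile, "LaneProfile"), is.list(curve),
              is.function(curve$predict))
    bg <- profile@background
    if (is.na(bg)) bg <- .laneBackground(profile, tailFraction)
    od <- pmax(0, profile@od - bg)
    pos <- profile@positions
    inRange <- pos >= curve$range[1] & pos <= curve$range[2]
    if (!extrapolate) {
        od <- od[inRange]
        pos <- pos[inRange]
    } else if (any(!inRange)) {
        warning("profile extends beyond the calibrated ladder range; ",
                "extrapolated bins included")
    }
    if (length(od) == 0L || sum(od) <= 0)
        stop("no positive optical density within the calibrated range")
    lenBp <- curve$predict(pos) * 1000
    sum(od) / sum(od / lenBp)
}

#' Synthesize a TRF lane profile from a known fragment-length distribution
#'
#' Forward model for fixture generation and round-trip testing: fragment
#' lengths are drawn from a delta or log-normal number distribution, mapped
#' to migration positions through an exactly log-linear ladder placement,
#' and converted to optical density with probe hybridization proportional to
#' fragment length (so the trace itself is length-weighted, as on a blot).
#' At zero noise \code{\link{trfMTL}} recovers the number-mean fragment
#' length of the distribution up to binning error.
#'
#' @param distribution \code{"delta"} or \code{"lognormal"}
#' @param meanBp delta location, or log-normal mean length
#'   \code{exp(meanlog + sdlog^2/2)}, bp
#' @param sdlog log-normal shape parameter (ignored for delta)
#' @param ladder a \linkS4class{MarkerLadder} defining the position scale;
#'   default: the six standard markers at the positions an ideal log-linear
#'   gel (spanning positions 10..60) would place them
#' @param nBins number of profile bins across the ladder range
#' @param noiseSd multiplicative OD noise (lognormal sd on the log scale)
#' @param seed RNG seed
#' @return list with the \linkS4class{LaneProfile}, the ladder, and the true
#'   number-mean length (\code{trueMeanBp})
#' @export
synthLane <- function(distribution = c("lognormal", "delta"),
                      meanBp = 7000, sdlog = 0.2, ladder = NULL,
                      nBins = 400L, noiseSd = 0, seed = 1L) {
    distribution <- match.arg(distribution)
    if (is.null(ladder)) {
        # place markers where an ideal log-linear gel puts them
        lens <- defaultLadderLengths()
        lg <- log10(lens)
        posIdeal <- 10 + 50 * (lg[1] - lg) / (lg[1] - lg[length(lg)])
        ladder <- markerLadder(lens, posIdeal)
    }
    set.seed(seed)
    # exactly log-linear position scale anchored on the ladder ends
    lk <- log10(ladder@lengthsKbp * 1000)
    posRange <- range(ladder@positions)
    slope <- (lk[length(lk)] - lk[1]) / (posRange[2] - posRange[1])
    intercept <- lk[1] - slope * posRange[1]
    pos <- seq(posRange[1], posRange[2], length.out = nBins)
    lenBp <- 10^(intercept + slope * pos)
    if (distribution == "delta") {
        dens <- as.numeric(abs(log(lenBp) - log(meanBp)) ==
                           min(abs(log(lenBp) - log(meanBp))))
        trueMean <- lenBp[which.max(dens)]
    } else {
        meanlog <- log(meanBp) - sdlog^2 / 2
        # number density per position bin: f(L) |dL/dpos|
        dens <- stats::dlnorm(lenBp, meanlog, sdlog) *
            abs(slope * log(10)) * lenBp
        trueMean <- exp(meanlog + sdlog^2 / 2)
    }
    od <- dens * lenBp  # probe binding proportional to fragment length
    if (noiseSd > 0) od <- od * stats::rlnorm(nBins, 0, noiseSd)
    if (max(od) > 0) od <- od / max(od)
    list(profile = laneProfile(pos, od, background = 0),
         ladder = ladder, trueMeanBp = trueMean)
}
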