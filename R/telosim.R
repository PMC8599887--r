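#' @include AllClasses.R AllGenerics.R probe-design.R quant-core.R
NULL

#' Construct a simulation configuration
#'
#' @param tractLengths telomere tract length (bp) per distinct template
#'   molecule; ignored when \code{target} is given
#' @param target optional \linkS4class{RepeatTarget}: the tract is generated
#'   from the repeat unit (or its variant pattern) and junction fidelity is
#'   decided by \code{\link{checkLigationJunction}} against \code{probe}
#' @param variantBase concrete base at the variant wildcard when
#'   \code{target} carries one
#' @param templateCopies copies of each template
#' @param tilingMode \code{"saturating"} (default; deterministic maximal
#'   abutting packing) or \code{"stochastic"} (random sequential adsorption,
#'   which jams below maximal packing)
#' @param pLigateMatch ligation probability at a matched junction (default 1)
#' @param pLigateMismatch leak probability at a mismatched junction
#'   (default 0.01)
#' @param backgroundCircles expected template-independent circles (Poisson
#'   mean, default 0)
#' @param calibration \linkS4class{ExpCalibration} (default) or
#'   \linkS4class{StandardCurve} mapping circles to Cq
#' @param cqNoiseSd Gaussian Cq noise, cycles (default 0)
#' @param geometry a \linkS4class{ProbeGeometry}
#' @param probe probe used for sequence-level junction checks (default: the
#'   built-in telomeric probe)
#' @param seed RNG seed (mandatory; stochastic draws are reproducible)
#' @return a \linkS4class{SimConfig}
#' @export
simConfig <- function(tractLengths = 800, target = NULL,
                      variantBase = NULL, templateCopies = 1,
                      tilingMode = c("saturating", "stochastic"),
                      pLigateMatch = 1, pLigateMismatch = 0.01,
                      backgroundCircles = 0,
                      calibration = expCalibration(), cqNoiseSd = 0,
                      geometry = probeGeometry(), probe = defaultProbe(),
                      seed = 1L) {
    tilingMode <- match.arg(tilingMode)
    if (!is.null(target)) {
        stopifnot(is(target, "RepeatTarget"))
        seqs <- as.character(targetSequence(target, variantBase))
        tractLengths <- nchar(seqs)
        attr(tractLengths, "sequence") <- seqs
    }
    cfg <- new("SimConfig", tractLengths = as.numeric(tractLengths),
               target = target, templateCopies = templateCopies,
               tilingMode = tilingMode, pLigateMatch = pLigateMatch,
               pLigateMismatch = pLigateMismatch,
               backgroundCircles = backgroundCircles,
               calibration = calibration, cqNoiseSd = cqNoiseSd,
               geometry = geometry, probe = probe, seed = as.integer(seed))
    if (!is.null(target)) attr(cfg@tractLengths, "sequence") <- seqs
    cfg
}

setMethod("show", "SimConfig", function(object) {
    cat(sprintf(
        "SimConfig: %d template(s) x %g copies, %s tiling, p(ligate) %g/%g, bg %g, Cq sd %g, seed %d\n",
        length(object@tractLengths), object@templateCopies,
        object@tilingMode, object@pLigateMatch, object@pLigateMismatch,
        object@backgroundCircles, object@cqNoiseSd, object@seed))
})

# random sequential adsorption of probes on one tract: each probe requires a
# free hybridized footprint and excludes one occlusion width around its
# start; jams below the saturating count
.rsaTile <- function(tractLength, geometry) {
    fp <- geometry@footprintHyb
    oc <- geometry@occlusion
    if (tractLength < fp) return(0L)
    starts <- numeric(0)
    free <- list(c(0, tractLength - fp))  # feasible start intervals
    while (length(free)) {
        lens <- vapply(free, function(iv) iv[2] - iv[1], numeric(1))
        pick <- sample.int(length(free), 1L, prob = lens + 1e-12)
        iv <- free[[pick]]
        s <- runif(1, iv[1], iv[2])
        starts <- c(starts, s)
        free <- free[-pick]
        # carve the exclusion zone [s - oc, s + oc] out of the interval
        lo <- c(iv[1], min(iv[2], s + oc))
        hi <- c(max(iv[1], s - oc), iv[2])
        for (k in 1:2)
            if (hi[k] - lo[k] > 0) free <- c(free, list(c(lo[k], hi[k])))
    }
    length(starts)
}

# does the configured probe ligate on this template?
.junctionMatched <- function(config) {
    seqs <- attr(config@tractLengths, "sequence")
    if (is.null(seqs)) return(rep(TRUE, length(config@tractLengths)))
    vapply(seqs, function(s) {
        nH <- nchar(config@probe@arm3) + nchar(config@probe@arm5)
        if (nchar(s) < nH) return(FALSE)
        checkLigationJunction(config@probe, s)$verdict == "ligatable"
    }, logical(1), USE.NAMES = FALSE)
}

#' Simulate the full assay forward
#'
#' For each replicate: tile every template with probes (deterministically at
#' saturation, or by random sequential adsorption), draw ligation successes
#' at the match or mismatch probability according to junction fidelity, add
#' Poisson background circles, and map the circle count to a quantification
#' cycle through the inverted calibration plus Gaussian noise.  Runs are
#' fully reproducible from the config seed; replicates yielding fewer than
#' one circle are reported as non-detects, not errors.
#'
#' @param config a \linkS4class{SimConfig}
#' @param replicates number of replicate assays
#' @return a \linkS4class{SimResult}
#' @examples
#' sim <- simulateAssay(simConfig(tractLengths = 800,
#'                                templateCopies = 35750), replicates = 3)
#' sim@replicates$circularized
#' @export
simulateAssay <- function(config, replicates = 1L) {
    stopifnot(is(config, "SimConfig"), replicates >= 1L)
    set.seed(config@seed)
    matched <- .junctionMatched(config)
    pEff <- ifelse(matched, config@pLigateMatch, config@pLigateMismatch)
    satCounts <- tileProbes(config@tractLengths, config@geometry)
    rows <- lapply(seq_len(replicates), function(r) {
        perTemplate <- if (config@tilingMode == "saturating") satCounts
            else vapply(config@tractLengths, .rsaTile, numeric(1),
                        geometry = config@geometry)
        tiled <- sum(perTemplate * config@templateCopies)
        # one binomial draw per template class over all its copies
        lig <- sum(mapply(function(n, p) {
            tot <- round(n * config@templateCopies)
            if (tot == 0 || p == 0) 0
            else if (p == 1 && config@tilingMode == "saturating") tot
            else rbinom(1L, tot, p)
        }, perTemplate, pEff))
        circles <- lig +
            if (config@backgroundCircles > 0)
                rpois(1L, config@backgroundCircles) else 0L
        if (circles < 1) {
            cq <- NA_real_
        } else {
            cq <- cqFromCopies(circles, config@calibration)
            if (config@cqNoiseSd > 0)
                cq <- cq + rnorm(1L, 0, config@cqNoiseSd)
        }
        data.frame(replicate = r, tiled = tiled, circularized = circles,
                   cq = cq, nondetect = is.na(cq))
    })
    new("SimResult",
        trueTotalTL = sum(config@tractLengths * config@templateCopies),
        replicates = do.call(rbind, rows), config = config)
}

setMethod("show", "SimResult", function(object) {
    cat(sprintf(
        "SimResult: %d replicate(s), true total TL %g bp, circles %s\n",
        nrow(object@replicates), object@trueTotalTL,
        paste(utils::head(object@replicates$circularized, 5),
              collapse = ", ")))
})

#' Recover telomere lengths from simulated quantification cycles
#'
#' Runs the quantification calculus end to end on a simulation's Cq values
#' and compares with the simulated truth.  Per-template recovery (default)
#' divides the estimated circle count by the template copy number before
#' applying the occlusion-length formula, which is exact for noiseless
#' saturating tracts on the length lattice \code{48(N-1)+32} and biased low
#' by less than one occlusion width per template off the lattice.  Setting
#' \code{perTemplate = FALSE} applies the formula to the total count first
#' and divides afterwards (the batch-validation order of operations).
#'
#' @param sim a \linkS4class{SimResult}
#' @param calibration calibration used for recovery; default: the one the
#'   simulation used.  Supplying a different one is flagged with a warning
#'   (calibration mismatch).
#' @param geometry recovery geometry; default: the simulation's
#' @param perTemplate see Details
#' @return list with a per-replicate data frame (\code{estimate} = recovered
#'   per-template length when \code{perTemplate}, else total length),
#'   \code{truth}, \code{bias} and \code{sd} of the estimates
#' @export
recoverAssay <- function(sim, calibration = NULL, geometry = NULL,
                         perTemplate = TRUE) {
    stopifnot(is(sim, "SimResult"))
    cfg <- sim@config
    if (is.null(calibration)) {
        calibration <- cfg@calibration
    } else if (!identical(calibration, cfg@calibration)) {
        warning("recovery calibration differs from the simulation's ",
                "(calibration mismatch)")
    }
    if (is.null(geometry)) geometry <- cfg@geometry
    det <- sim@replicates[!sim@replicates$nondetect, , drop = FALSE]
    if (nrow(det) == 0L) stop("all replicates are non-detects")
    copies <- copiesFromCq(det$cq, calibration)
    nTemplates <- length(cfg@tractLengths)
    if (perTemplate) {
        nPer <- copies / (cfg@templateCopies * nTemplates)
        est <- tlFromCount(nPer, geometry)
        truth <- mean(cfg@tractLengths)
    } else {
        est <- tlFromCount(copies, geometry) /
            (cfg@templateCopies * nTemplates)
        truth <- mean(cfg@tractLengths)
    }
    out <- data.frame(replicate = det$replicate, cq = det$cq,
                      copies = copies, estimate = est)
    list(estimates = out, truth = truth,
         bias = mean(est) - truth,
         sd = if (nrow(out) > 1L) sd(est) else NA_real_)
}

#' First-order (delta-method) prediction of recovery spread
#'
#' Predicted standard deviation of the recovered per-template length for a
#' given Cq noise: \code{sd(TL) = occlusion * k * Ncp * sd(Cq) /
#' templateCopies} under the exponential calibration (and the analogous
#' log-linear expression for a fitted curve).
#'
#' @param circles expected circle count
#' @param templateCopies template copies the count is divided by
#' @param cqNoiseSd Cq noise, cycles
#' @param calibration \linkS4class{ExpCalibration} or
#'   \linkS4class{StandardCurve}
#' @param geometry a \linkS4class{ProbeGeometry}
#' @return predicted sd of the per-template length, bp
#' @export
deltaMethodSd <- function(circles, templateCopies, cqNoiseSd,
                          calibration = expCalibration(),
                          geometry = probeGeometry()) {
    k <- if (is(calibration, "ExpCalibration")) calibration@decay
         else log(10) / abs(calibration@slope)
    geometry@occlusion * k * circles * cqNoiseSd / templateCopies
}
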