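#' @include AllClasses.R AllGenerics.R probe-design.R
NULL

#' Fit a log-linear qPCR standard curve
#'
#' Least-squares fit of Cq on log10(copies).  The amplification efficiency is
#' derived from the slope as \code{10^(-1/slope) - 1} (slope -3.3219 is
#' perfect doubling).
#'
#' @param copies template copy numbers, all > 0, at >= 3 distinct levels
#' @param cq observed quantification cycles, same length
#' @return a \linkS4class{StandardCurve}
#' @examples
#' copies <- 10^(2:7)
#' sc <- fitStandardCurve(copies, 38 - 3.3649 * log10(copies))
#' efficiency(sc)
#' @export
fitStandardCurve <- function(copies, cq) {
    if (length(copies) != length(cq))
        stop("copies and cq must have the same length")
    if (any(is.na(copies)) || any(copies <= 0))
        stop("all copy levels must be positive")
    if (length(unique(copies)) < 3L)
        stop("need at least 3 distinct copy levels")
    fit <- stats::lm(cq ~ log10(copies))
    b <- unname(coef(fit))
    if (!(b[2] < 0))
        stop("fitted slope is non-negative; Cq must decrease with copies")
    r2 <- suppressWarnings(summary(fit)$r.squared)
    new("StandardCurve", slope = b[2], intercept = b[1],
        rSquared = r2, efficiency = 10^(-1 / b[2]) - 1)
}

#' Construct a standard curve from known coefficients
#'
#' @param slope Cq per log10(copies), negative
#' @param intercept Cq at one copy
#' @param rSquared optional fit quality (NA when constructed, not fitted)
#' @return a \linkS4class{StandardCurve}
#' @export
standardCurve <- function(slope, intercept, rSquared = NA_real_) {
    new("StandardCurve", slope = slope, intercept = intercept,
        rSquared = rSquared, efficiency = 10^(-1 / slope) - 1)
}

#' @describeIn efficiency efficiency slot of a fitted curve
#' @export
setMethod("efficiency", "StandardCurve", function(x) x@efficiency)

setMethod("show", "StandardCurve", function(object) {
    cat(sprintf(
        "StandardCurve: Cq = %.4f %+.4f log10(copies)  (eff %.1f%%, R2 %s)\n",
        object@intercept, object@slope, 100 * object@efficiency,
        ifelse(is.na(object@rSquared), "NA",
               sprintf("%.4f", object@rSquared))))
})

#' Construct an exponential copies-from-Cq calibration
#'
#' @param amplitude copies at Cq = 0 (default 4e11)
#' @param decay per-cycle decay constant (default 0.691)
#' @return an \linkS4class{ExpCalibration}
#' @export
expCalibration <- function(amplitude = 4e11, decay = 0.691) {
    new("ExpCalibration", amplitude = amplitude, decay = decay)
}

setMethod("show", "ExpCalibration", function(object) {
    cat(sprintf("ExpCalibration: copies = %.3g * exp(-%.3f * Cq)\n",
                object@amplitude, object@decay))
})

#' @describeIn copiesFromCq exponential form \code{A * exp(-k * Cq)}
#' @export
setMethod("copiesFromCq", signature(cq = "numeric",
                                    calibration = "ExpCalibration"),
    function(cq, calibration) {
        if (any(is.na(cq)))
            stop("non-detect Cq passed to copiesFromCq; gate backgrounds first")
        calibration@amplitude * exp(-calibration@decay * cq)
    })

#' @describeIn copiesFromCq inverted log-linear curve
#'   \code{10^((Cq - intercept)/slope)}
#' @export
setMethod("copiesFromCq", signature(cq = "numeric",
                                    calibration = "StandardCurve"),
    function(cq, calibration) {
        if (any(is.na(cq)))
            stop("non-detect Cq passed to copiesFromCq; gate backgrounds first")
        10^((cq - calibration@intercept) / calibration@slope)
    })

#' @describeIn cqFromCopies exponential form inverted
#' @export
setMethod("cqFromCopies", signature(copies = "numeric",
                                    calibration = "ExpCalibration"),
    function(copies, calibration) {
        stopifnot(all(copies > 0))
        -log(copies / calibration@amplitude) / calibration@decay
    })

#' @describeIn cqFromCopies log-linear curve evaluated forward
#' @export
setMethod("cqFromCopies", signature(copies = "numeric",
                                    calibration = "StandardCurve"),
    function(copies, calibration) {
        stopifnot(all(copies > 0))
        calibration@intercept + calibration@slope * log10(copies)
    })

#' Total telomere length from a circularized-probe count
#'
#' The occlusion-length formula: \code{TL = occlusion * (Ncp - 1) +
#' footprint} (defaults 48 and 32 bp).  Counts may be non-integer
#' (population averages); they are carried as reals and rounded only at
#' final reporting.
#'
#' @param nCp circularized-probe count(s), >= 0 (vectorized)
#' @param geometry a \linkS4class{ProbeGeometry}
#' @return total telomere length(s), bp (real-valued)
#' @examples
#' tlFromCount(1)       # 32
#' tlFromCount(610338)  # 29296208
#' @export
tlFromCount <- function(nCp, geometry = probeGeometry()) {
    stopifnot(is(geometry, "ProbeGeometry"))
    if (any(is.na(nCp)) || any(nCp < 0))
        stop("nCp must be non-negative")
    if (any(nCp > 0 & nCp < 1))
        warning("nCp below one probe; formula extrapolated below one ",
                "footprint (floored at 0 bp)")
    out <- pmax(0, geometry@occlusion * (nCp - 1) + geometry@footprintHyb)
    out[nCp == 0] <- 0
    if (any(nCp == 0)) warning("zero circularized probes: length 0")
    out
}

#' Built-in validation plasmid specifications
#'
#' The two synthetic-telomere plasmids used to validate the assay: 800 and
#' 1600 bp telomere inserts on a 2400 bp backbone, with published
#' molecules-per-microgram constants.
#'
#' @param name \code{"pSXneo135"} or \code{"pSXneo270"}
#' @return a \linkS4class{PlasmidSpec}
#' @export
plasmidPreset <- function(name = c("pSXneo135", "pSXneo270")) {
    name <- match.arg(name)
    switch(name,
        pSXneo135 = new("PlasmidSpec", name = name, insertLength = 800,
                        moleculesPerUg = 2.86e11),
        pSXneo270 = new("PlasmidSpec", name = name, insertLength = 1600,
                        moleculesPerUg = 2.29e11))
}

#' Construct a plasmid specification
#'
#' When \code{moleculesPerUg} is not supplied it is computed from the total
#' plasmid length at an average 650 g/mol per base pair:
#' \code{N_A * 1e-6 / (650 * totalLength)}, which reproduces the published
#' constants within 2 percent.
#'
#' @param name plasmid name
#' @param insertLength synthetic telomere insert, bp
#' @param backboneLength backbone, bp (default 2400)
#' @param moleculesPerUg molecules per microgram; computed if NULL
#' @return a \linkS4class{PlasmidSpec}
#' @export
plasmidSpec <- function(name, insertLength, backboneLength = 2400,
                        moleculesPerUg = NULL) {
    if (is.null(moleculesPerUg)) {
        total <- insertLength + backboneLength
        moleculesPerUg <- 6.02214076e23 * 1e-6 / (650 * total)
    }
    new("PlasmidSpec", name = name, insertLength = insertLength,
        moleculesPerUg = moleculesPerUg)
}

setMethod("show", "PlasmidSpec", function(object) {
    cat(sprintf("PlasmidSpec %s: %g bp insert, %.3g molecules/ug\n",
                object@name, object@insertLength, object@moleculesPerUg))
})

#' Convert a DNA mass to molecule count
#'
#' @param massPg mass in picograms, > 0
#' @param spec a \linkS4class{PlasmidSpec}
#' @return molecule count (real-valued)
#' @examples
#' massToMolecules(0.125, plasmidPreset("pSXneo135"))  # 35750
#' @export
massToMolecules <- function(massPg, spec) {
    stopifnot(is(spec, "PlasmidSpec"))
    if (any(is.na(massPg)) || any(massPg <= 0))
        stop("massPg must be positive")
    massPg * 1e-6 * spec@moleculesPerUg
}

#' Per-template telomere length
#'
#' @param totalTL total telomere length, bp
#' @param templateCopies number of template molecules (plasmids, genomes), > 0
#' @return length per template, rounded to the nearest bp
#' @examples
#' perCopyLength(29296208, 35750)  # 819
#' @export
perCopyLength <- function(totalTL, templateCopies) {
    if (any(is.na(templateCopies)) || any(templateCopies <= 0))
        stop("templateCopies must be positive")
    if (any(totalTL < 0)) stop("totalTL must be non-negative")
    round(totalTL / templateCopies)
}

#' Partition qPCR records into signal and background
#'
#' Negative-control circularization produces Cq values at or above about 40
#' cycles; records at or beyond the threshold, and non-detects, are gated
#' out as background.
#'
#' @param records data frame with at least a \code{cq} column (NA =
#'   non-detect); see \code{\link{readQPCRTable}}
#' @param threshold background Cq threshold, default 40
#' @return list with \code{signal} and \code{background} data frames and an
#'   integer \code{counts} vector
#' @export
backgroundGate <- function(records, threshold = 40) {
    stopifnot(is.data.frame(records), "cq" %in% names(records))
    isBg <- is.na(records$cq) | records$cq >= threshold
    list(signal = records[!isBg, , drop = FALSE],
         background = records[isBg, , drop = FALSE],
         counts = c(signal = sum(!isBg), background = sum(isBg)))
}

#' Quantify telomere length from qPCR records
#'
#' The full quantification chain for a batch of records: background gating,
#' copies from Cq, total telomere length via the occlusion formula, and
#' (when template copy numbers are known) per-template length following the
#' published order of operations (occlusion formula applied to the total
#' circularized count, then division by template copies).  Replicates are
#' aggregated by mean Cq, with the standard deviation of length propagated
#' by a first-order delta method.
#'
#' @param records data frame with columns \code{sample_id}, \code{assay},
#'   \code{cq}, \code{replicate}
#' @param calibration an \linkS4class{ExpCalibration} (default: published
#'   constants) or fitted \linkS4class{StandardCurve}
#' @param geometry a \linkS4class{ProbeGeometry}
#' @param templateCopies optional named vector (by sample_id) or scalar of
#'   template molecule counts, enabling per-template lengths
#' @param backgroundThreshold Cq gate, default 40
#' @return list with \code{perReplicate} and \code{summary} data frames and
#'   the gated \code{background} records
#' @export
quantifyTelomeres <- function(records, calibration = expCalibration(),
                              geometry = probeGeometry(),
                              templateCopies = NULL,
                              backgroundThreshold = 40) {
    stopifnot(is.data.frame(records),
              all(c("sample_id", "cq") %in% names(records)))
    gate <- backgroundGate(records, backgroundThreshold)
    sig <- gate$signal
    if (nrow(sig) == 0L) stop("no records pass the background gate")
    copies <- copiesFromCq(sig$cq, calibration)
    totalTL <- tlFromCount(copies, geometry)
    per <- data.frame(sig, copies = copies, total_tl = totalTL)
    lookupCopies <- function(ids) {
        if (is.null(templateCopies)) return(rep(NA_real_, length(ids)))
        if (length(templateCopies) == 1L && is.null(names(templateCopies)))
            return(rep(templateCopies, length(ids)))
        unname(templateCopies[ids])
    }
    tc <- lookupCopies(per$sample_id)
    per$per_copy_tl <- ifelse(is.na(tc), NA_real_,
                              round(per$total_tl / tc))
    # per-cycle sensitivity of copies: d copies / d Cq
    dCopies <- function(meanCq) {
        n <- copiesFromCq(meanCq, calibration)
        if (is(calibration, "ExpCalibration")) n * calibration@decay
        else n * log(10) / abs(calibration@slope)
    }
    agg <- lapply(split(per, per$sample_id), function(d) {
        meanCq <- mean(d$cq)
        sdCq <- if (nrow(d) > 1L) sd(d$cq) else NA_real_
        n <- copiesFromCq(meanCq, calibration)
        tl <- tlFromCount(n, geometry)
        sdTL <- geometry@occlusion * dCopies(meanCq) * sdCq
        tcs <- lookupCopies(d$sample_id[1L])
        data.frame(sample_id = d$sample_id[1L], n_replicates = nrow(d),
                   mean_cq = meanCq, sd_cq = sdCq, copies = n,
                   total_tl = tl, sd_total_tl = sdTL,
                   per_copy_tl = if (is.na(tcs)) NA_real_
                                 else round(tl / tcs),
                   sd_per_copy_tl = if (is.na(tcs)) NA_real_
                                    else sdTL / tcs)
    })
    list(perReplicate = per,
         summary = do.call(rbind, c(agg, make.row.names = FALSE)),
         background = gate$background)
}
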