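#' @include AllClasses.R AllGenerics.R quant-core.R
NULL

.KARYOTYPE_PRESETS <- data.frame(
    name   = c("CP-A", "HEK-293", "MDA-MB-231", "MCF-7", "K-562"),
    low    = c(47L, 64L, 52L, 66L, 67L),
    modal  = c(47L, 64L, 64L, 82L, 67L),
    high   = c(47L, 64L, 68L, 87L, 67L),
    stable = c(TRUE, TRUE, FALSE, FALSE, TRUE),
    # K-562 telomere counts are implied by the karyotype, never printed in a
    # primary source; flagged so reports can disclose it
    derived = c(FALSE, FALSE, FALSE, FALSE, TRUE))

#' Built-in karyotype presets
#'
#' Chromosome-count brackets (low/modal/high) for the five cell lines
#' supported out of the box.  CP-A is near-diploid (47, trisomy 20);
#' HEK-293 has a stable modal number of 64; MDA-MB-231 is near-triploid
#' (52-68, modal 64); MCF-7 is aneuploid (66-87, modal 82); K-562 is
#' aneuploid with a stable modal number of 67.
#'
#' @return data frame of presets
#' @export
karyotypePresets <- function() .KARYOTYPE_PRESETS

#' Construct (or look up) a karyotype model
#'
#' @param name preset name (see \code{\link{karyotypePresets}}) or a label
#'   for a custom model
#' @param low,modal,high chromosome counts; omit to use a preset
#' @param stable is the modal number documented as stable
#' @return a \linkS4class{KaryotypeModel}
#' @examples
#' karyotypeModel("CP-A")
#' karyotypeModel("custom", low = 45, modal = 46, high = 47)
#' @export
karyotypeModel <- function(name, low = NULL, modal = NULL, high = NULL,
                           stable = TRUE) {
    if (is.null(modal)) {
        p <- .KARYOTYPE_PRESETS[.KARYOTYPE_PRESETS$name == name, ]
        if (nrow(p) != 1L)
            stop("unknown karyotype preset '", name, "'; supply counts or ",
                 "one of: ",
                 paste(.KARYOTYPE_PRESETS$name, collapse = ", "))
        return(new("KaryotypeModel", name = name, low = p$low,
                   modal = p$modal, high = p$high, stable = p$stable,
                   derived = p$derived))
    }
    if (is.null(low)) low <- modal
    if (is.null(high)) high <- modal
    new("KaryotypeModel", name = name, low = as.integer(low),
        modal = as.integer(modal), high = as.integer(high),
        stable = stable, derived = FALSE)
}

setMethod("show", "KaryotypeModel", function(object) {
    cat(sprintf(
        "KaryotypeModel %s: %d/%d/%d chromosomes (low/modal/high)%s%s\n",
        object@name, object@low, object@modal, object@high,
        if (object@stable) ", stable" else "",
        if (object@derived) " [telomere count derived from karyotype]"
        else ""))
})

#' Telomere count under a ploidy scenario and cell-cycle stage
#'
#' Each chromosome carries two telomeres, so the count is twice the
#' chromosome number; after DNA replication (G2/M) sister chromatids double
#' it again.
#'
#' @param karyotype a \linkS4class{KaryotypeModel}
#' @param stage \code{"G1"} or \code{"G2M"} (\code{"ambiguous"} is an error:
#'   resolve the stage first)
#' @param scenario \code{"low"}, \code{"modal"} or \code{"high"}
#' @return telomere count
#' @examples
#' telomereCount(karyotypeModel("CP-A"))            # 94
#' telomereCount(karyotypeModel("HEK-293"))         # 128
#' @export
telomereCount <- function(karyotype, stage = c("G1", "G2M"),
                          scenario = c("modal", "low", "high")) {
    stopifnot(is(karyotype, "KaryotypeModel"))
    if (identical(stage, "ambiguous"))
        stop("cell-cycle stage is ambiguous; resolve it before counting")
    stage <- match.arg(stage)
    scenario <- match.arg(scenario)
    chrom <- slot(karyotype, scenario)
    2L * chrom * if (stage == "G2M") 2L else 1L
}

#' Fit a DNA-content (pg) vs Cq calibration for a single-copy gene
#'
#' Same log-linear machinery as the copy-number standard curve, but the
#' abscissa is picograms of genomic DNA: a single-copy gene's Cq reports the
#' DNA content of the cell and hence its cell-cycle stage.
#'
#' @param pg genomic DNA amounts, pg, > 0, >= 3 distinct levels
#' @param cq observed Cq values
#' @return a \linkS4class{StandardCurve} (slope/intercept on the pg scale)
#' @export
fitScgCurve <- function(pg, cq) fitStandardCurve(pg, cq)

#' Infer DNA content and cell-cycle stage from a single-copy-gene Cq
#'
#' The pg estimate is compared with the diploid G1 reference (6.6 pg for
#' human cells).  Ratios below the dead zone call G1; above it, G2/M; inside
#' it, ambiguous.
#'
#' @param cq single-copy-gene quantification cycle (non-detect is an error)
#' @param scgCurve calibration from \code{\link{fitScgCurve}}
#' @param diploidPg diploid G1 DNA content reference, pg (default 6.6)
#' @param deadZone ratio interval called ambiguous (default c(1.4, 1.6),
#'   around a G2 threshold of 1.5)
#' @return a \linkS4class{CellCycleCall}
#' @export
dnaContentFromSCG <- function(cq, scgCurve, diploidPg = 6.6,
                              deadZone = c(1.4, 1.6)) {
    if (is.na(cq)) stop("non-detect Cq cannot report DNA content")
    stopifnot(is(scgCurve, "StandardCurve"), length(deadZone) == 2L,
              deadZone[1] <= deadZone[2])
    pg <- copiesFromCq(cq, scgCurve)  # curve fitted on the pg scale
    ratio <- pg / diploidPg
    stage <- if (ratio < deadZone[1]) "G1"
             else if (ratio > deadZone[2]) "G2M"
             else "ambiguous"
    new("CellCycleCall", stage = stage, dnaPg = pg, ratioToDiploid = ratio)
}

setMethod("show", "CellCycleCall", function(object) {
    cat(sprintf("CellCycleCall: %.2f pg (%.2fx diploid) -> %s\n",
                object@dnaPg, object@ratioToDiploid, object@stage))
})

#' Mean telomere length under the three ploidy scenarios
#'
#' Divides a total per-cell telomere length by the telomere count implied by
#' each ploidy scenario (low/modal/high) at the given cell-cycle stage.
#' With ordered counts the scenario MTLs are ordered the opposite way
#' (more telomeres, shorter mean).
#'
#' @param totalTL total telomere length per cell, bp, >= 0
#' @param karyotype a \linkS4class{KaryotypeModel}
#' @param stage \code{"G1"} (default) or \code{"G2M"}
#' @param countSource \code{"karyotype"} (counts from the model) or
#'   \code{"measured"} (caller-verified DNA content), recorded in the result
#' @return an \linkS4class{MTLResult}
#' @examples
#' computeMTL(94 * 5000, karyotypeModel("CP-A"))
#' @export
computeMTL <- function(totalTL, karyotype, stage = c("G1", "G2M"),
                       countSource = c("karyotype", "measured")) {
    stage <- match.arg(stage)
    countSource <- match.arg(countSource)
    if (is.na(totalTL) || totalTL < 0) stop("totalTL must be >= 0")
    counts <- vapply(c(low = "low", modal = "modal", high = "high"),
                     function(s) telomereCount(karyotype, stage, s),
                     numeric(1))
    new("MTLResult", totalTL = totalTL, telomereCounts = counts,
        mtl = totalTL / counts, stage = stage, countSource = countSource)
}

setMethod("show", "MTLResult", function(object) {
    cat(sprintf("MTLResult (%s, counts from %s): total %.0f bp\n",
                object@stage, object@countSource, object@totalTL))
    m <- object@mtl
    k <- object@telomereCounts
    for (s in c("low", "modal", "high"))
        cat(sprintf("  %-5s: %3d telomeres -> MTL %.0f bp%s\n", s, k[[s]],
                    m[[s]], if (s == "modal") "  *" else ""))
})
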