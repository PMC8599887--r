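#' @import methods
#' @importFrom stats lm coef rbinom rpois rnorm runif predict quantile sd setNames
#' @importFrom utils read.delim write.table
NULL

.DNA_ALPHABET <- c("A", "C", "G", "T")

.validDNA <- function(x) {
    nzchar(x) && all(strsplit(x, "")[[1]] %in% .DNA_ALPHABET)
}

#' RepeatTarget: a tandem-repeat telomeric target
#'
#' Describes a tract of tandem repeats on the G-rich strand, written 5'->3'
#' (human telomeres: \code{TTAGGG}).  An optional variant pattern with a
#' single wildcard position (\code{N}) models subtelomeric repeat variants
#' such as \code{TTNAGGG}.
#'
#' @slot unit single repeat unit, G-strand 5'->3'
#' @slot nUnits number of repeat units in the tract
#' @slot variantPattern optional variant unit with exactly one \code{N}
#'   wildcard, same length as the unit or one base longer; \code{NA} if unused
#' @slot strandConvention fixed at \code{"G_strand_5to3"}
#' @export
setClass("RepeatTarget",
    representation(unit = "character", nUnits = "integer",
                   variantPattern = "character",
                   strandConvention = "character"),
    prototype(unit = "TTAGGG", nUnits = 1L, variantPattern = NA_character_,
              strandConvention = "G_strand_5to3"))

setValidity("RepeatTarget", function(object) {
    msg <- NULL
    if (!.validDNA(object@unit))
        msg <- c(msg, "unit must be a non-empty A/C/G/T string")
    if (length(object@nUnits) != 1L || is.na(object@nUnits) ||
        object@nUnits < 1L)
        msg <- c(msg, "nUnits must be a positive integer")
    vp <- object@variantPattern
    if (!is.na(vp)) {
        ok <- nchar(vp) %in% (nchar(object@unit) + 0:1) &&
            sum(strsplit(vp, "")[[1]] == "N") == 1L &&
            all(strsplit(vp, "")[[1]] %in% c(.DNA_ALPHABET, "N"))
        if (!ok)
            msg <- c(msg,
                "variantPattern must match unit length (or +1) with exactly one N")
    }
    if (!identical(object@strandConvention, "G_strand_5to3"))
        msg <- c(msg, "strandConvention must be 'G_strand_5to3'")
    if (is.null(msg)) TRUE else msg
})

#' OmegaProbe: a segmented circularizable probe
#'
#' A linear oligonucleotide whose 5'- and 3'-terminal arms hybridize to
#' adjacent positions of a tandem-repeat target so that its ends abut,
#' enabling target-templated ligation into a circle.  Between the arms sit
#' (in 5'->3' order) the reverse-primer binding region, the forward primer,
#' and the hydrolysis-probe binding region, so that only circularized probes
#' amplify during qPCR.
#'
#' @slot arm5 5'-terminal arm (C-rich, as synthesized)
#' @slot prBinding reverse-primer binding region (reverse complement of the
#'   reverse primer)
#' @slot pf forward primer region, verbatim
#' @slot hp hydrolysis-probe binding region
#' @slot arm3 3'-terminal arm
#' @slot phosphorylated is the 5' end phosphorylated (required for ligation)
#' @export
setClass("OmegaProbe",
    representation(arm5 = "character", prBinding = "character",
                   pf = "character", hp = "character", arm3 = "character",
                   phosphorylated = "logical"))

setValidity("OmegaProbe", function(object) {
    segs <- c(arm5 = object@arm5, prBinding = object@prBinding,
              pf = object@pf, hp = object@hp, arm3 = object@arm3)
    bad <- names(segs)[!vapply(segs, .validDNA, logical(1))]
    msg <- NULL
    if (length(bad))
        msg <- c(msg, paste0("segment(s) not non-empty DNA: ",
                             paste(bad, collapse = ", ")))
    if (length(object@phosphorylated) != 1L || is.na(object@phosphorylated))
        msg <- c(msg, "phosphorylated must be TRUE or FALSE")
    if (is.null(msg)) TRUE else msg
})

#' OmegaORF: the linearized rotation of a circularized probe
#'
#' The same sequence content as the circular probe, rotated so the forward
#' primer is at the 5' end (and the reverse-primer binding region at the
#' 3' end); this linear form amplifies like a circularized probe and is used
#' to build the qPCR standard curve.
#'
#' @slot sequence the rotated sequence, 5'->3'
#' @export
setClass("OmegaORF", representation(sequence = "character"))

setValidity("OmegaORF", function(object) {
    if (!.validDNA(object@sequence)) "sequence must be non-empty DNA" else TRUE
})

#' ProbeGeometry: the occlusion constants of the length calculus
#'
#' Houses the two constants of the occlusion-length formula
#' \code{TL = occlusion * (Ncp - 1) + footprintHyb}: each circularized probe
#' hybridizes \code{footprintHyb} bases (default 32) and, through its
#' stem-loops, occludes \code{occlusion} bases (default 48) where two probes
#' abut.
#'
#' @slot footprintHyb bases hybridized per circularized probe
#' @slot occlusion bases occluded per abutting probe
#' @export
setClass("ProbeGeometry",
    representation(footprintHyb = "numeric", occlusion = "numeric"),
    prototype(footprintHyb = 32, occlusion = 48))

setValidity("ProbeGeometry", function(object) {
    if (length(object@footprintHyb) != 1L || length(object@occlusion) != 1L ||
        !(object@occlusion >= object@footprintHyb) ||
        !(object@footprintHyb > 0))
        "requires occlusion >= footprintHyb > 0" else TRUE
})

#' StandardCurve: log-linear Cq vs log10(copies) calibration
#'
#' @slot slope Cq per log10(copies); negative
#' @slot intercept Cq at one copy
#' @slot rSquared coefficient of determination of the fit
#' @slot efficiency amplification efficiency, \code{10^(-1/slope) - 1}
#' @export
setClass("StandardCurve",
    representation(slope = "numeric", intercept = "numeric",
                   rSquared = "numeric", efficiency = "numeric"))

setValidity("StandardCurve", function(object) {
    msg <- NULL
    if (!(object@slope < 0)) msg <- c(msg, "slope must be negative")
    if (!is.na(object@rSquared) &&
        (object@rSquared < 0 || object@rSquared > 1))
        msg <- c(msg, "rSquared must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' ExpCalibration: exponential copies-from-Cq calibration
#'
#' The closed-form calibration \code{copies = A * exp(-k * Cq)}.  The default
#' constants (A = 4e11, k = 0.691) are a published calibration of
#' circularized-probe copies against quantification cycle.
#'
#' @slot amplitude copies at Cq = 0
#' @slot decay per-cycle exponential decay constant
#' @export
setClass("ExpCalibration",
    representation(amplitude = "numeric", decay = "numeric"),
    prototype(amplitude = 4e11, decay = 0.691))

setValidity("ExpCalibration", function(object) {
    if (!(object@amplitude > 0) || !(object@decay > 0))
        "amplitude and decay must both be positive" else TRUE
})

#' PlasmidSpec: a validation plasmid carrying a synthetic telomere
#'
#' @slot name plasmid name
#' @slot insertLength length of the synthetic telomere insert, bp
#' @slot moleculesPerUg plasmid molecules per microgram
#' @export
setClass("PlasmidSpec",
    representation(name = "character", insertLength = "numeric",
                   moleculesPerUg = "numeric"))

setValidity("PlasmidSpec", function(object) {
    if (!(object@insertLength > 0) || !(object@moleculesPerUg > 0))
        "insertLength and moleculesPerUg must be positive" else TRUE
})

#' KaryotypeModel: chromosome counts bracketing a cell line's ploidy
#'
#' @slot name cell-line name
#' @slot low,modal,high chromosome counts for the low / modal / high ploidy
#'   scenarios (equal for karyotypically stable lines)
#' @slot stable is the modal chromosome number documented as stable
#' @slot derived TRUE when the implied telomere count is inferred from the
#'   karyotype rather than printed in a primary source
#' @export
setClass("KaryotypeModel",
    representation(name = "character", low = "integer", modal = "integer",
                   high = "integer", stable = "logical", derived = "logical"),
    prototype(stable = TRUE, derived = FALSE))

setValidity("KaryotypeModel", function(object) {
    if (!(object@low > 0L) || !(object@low <= object@modal) ||
        !(object@modal <= object@high))
        "requires 0 < low <= modal <= high" else TRUE
})

#' CellCycleCall: cell-cycle stage inferred from DNA content
#'
#' @slot stage one of \code{"G1"}, \code{"G2M"}, \code{"ambiguous"}
#' @slot dnaPg estimated DNA content, pg per cell
#' @slot ratioToDiploid ratio of the estimate to the diploid G1 reference
#' @export
setClass("CellCycleCall",
    representation(stage = "character", dnaPg = "numeric",
                   ratioToDiploid = "numeric"))

setValidity("CellCycleCall", function(object) {
    msg <- NULL
    if (!object@stage %in% c("G1", "G2M", "ambiguous"))
        msg <- c(msg, "stage must be G1, G2M or ambiguous")
    if (!(object@ratioToDiploid > 0))
        msg <- c(msg, "ratioToDiploid must be positive")
    if (is.null(msg)) TRUE else msg
})

#' MTLResult: mean telomere length under three ploidy scenarios
#'
#' @slot totalTL total telomere length per cell, bp
#' @slot telomereCounts named counts for the low/modal/high scenarios
#' @slot mtl named mean telomere lengths (bp) for each scenario
#' @slot stage cell-cycle stage used
#' @slot countSource \code{"karyotype"} or \code{"measured"}
#' @export
setClass("MTLResult",
    representation(totalTL = "numeric", telomereCounts = "numeric",
                   mtl = "numeric", stage = "character",
                   countSource = "character"))

setValidity("MTLResult", function(object) {
    msg <- NULL
    if (object@totalTL < 0) msg <- c(msg, "totalTL must be >= 0")
    need <- c("low", "modal", "high")
    if (!all(need %in% names(object@telomereCounts)) ||
        !all(need %in% names(object@mtl)))
        msg <- c(msg, "telomereCounts and mtl need low/modal/high entries")
    if (is.null(msg)) TRUE else msg
})

#' MarkerLadder: molecular-length ladder of a TRF gel
#'
#' @slot lengthsKbp marker lengths in kbp
#' @slot positions migration positions (increasing = further migrated)
#' @export
setClass("MarkerLadder",
    representation(lengthsKbp = "numeric", positions = "numeric"))

setValidity("MarkerLadder", function(object) {
    msg <- NULL
    if (length(object@lengthsKbp) < 3L)
        msg <- c(msg, "need at least 3 ladder entries")
    if (length(object@lengthsKbp) != length(object@positions))
        msg <- c(msg, "lengths and positions differ in length")
    o <- order(object@positions)
    if (any(diff(object@positions[o]) <= 0) ||
        any(diff(object@lengthsKbp[o]) >= 0))
        msg <- c(msg,
            "lengths must strictly decrease with increasing migration")
    if (is.null(msg)) TRUE else msg
})

#' LaneProfile: 1-D densitometry trace of one TRF lane
#'
#' @slot positions migration positions, strictly increasing
#' @slot od optical density at each position, non-negative
#' @slot background constant background offset already estimated (NA to
#'   estimate from the profile tails at use time)
#' @export
setClass("LaneProfile",
    representation(positions = "numeric", od = "numeric",
                   background = "numeric"),
    prototype(background = NA_real_))

setValidity("LaneProfile", function(object) {
    msg <- NULL
    if (length(object@positions) != length(object@od))
        msg <- c(msg, "positions and od differ in length")
    if (any(diff(object@positions) <= 0))
        msg <- c(msg, "positions must be strictly increasing")
    if (any(object@od < 0)) msg <- c(msg, "od must be non-negative")
    if (is.null(msg)) TRUE else msg
})

#' SimConfig: forward-simulation settings for the full assay
#'
#' @slot tractLengths telomere tract length (bp) of each distinct template;
#'   ignored when \code{target} is set
#' @slot target optional \linkS4class{RepeatTarget} supplying an explicit
#'   repeat sequence (junction fidelity is then derived from the sequence)
#' @slot templateCopies number of copies of each template
#' @slot tilingMode \code{"saturating"} (deterministic maximal abutting
#'   packing) or \code{"stochastic"} (random sequential adsorption)
#' @slot pLigateMatch ligation probability at a matched junction
#' @slot pLigateMismatch leak ligation probability at a mismatched junction
#' @slot backgroundCircles expected template-independent circles (Poisson)
#' @slot calibration an \linkS4class{ExpCalibration} or
#'   \linkS4class{StandardCurve} used to map circle counts to Cq
#' @slot cqNoiseSd Gaussian noise on Cq, cycles
#' @slot geometry the \linkS4class{ProbeGeometry} in force
#' @slot probe probe used for sequence-level junction checks
#' @slot seed RNG seed (mandatory)
#' @export
setClass("SimConfig",
    representation(tractLengths = "numeric", target = "ANY",
                   templateCopies = "numeric", tilingMode = "character",
                   pLigateMatch = "numeric", pLigateMismatch = "numeric",
                   backgroundCircles = "numeric", calibration = "ANY",
                   cqNoiseSd = "numeric", geometry = "ProbeGeometry",
                   probe = "ANY", seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- NULL
    p <- c(object@pLigateMatch, object@pLigateMismatch)
    if (any(p < 0 | p > 1)) msg <- c(msg, "probabilities must lie in [0, 1]")
    if (object@pLigateMismatch > object@pLigateMatch)
        msg <- c(msg, "pLigateMismatch must not exceed pLigateMatch")
    if (!object@tilingMode %in% c("saturating", "stochastic"))
        msg <- c(msg, "tilingMode must be saturating or stochastic")
    if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "a scalar seed is mandatory")
    if (object@backgroundCircles < 0)
        msg <- c(msg, "backgroundCircles must be >= 0")
    if (object@cqNoiseSd < 0) msg <- c(msg, "cqNoiseSd must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' SimResult: outcome of a forward simulation
#'
#' @slot trueTotalTL true total telomere length across all template copies, bp
#' @slot replicates per-replicate table (tiled, circularized, cq, nondetect)
#' @slot config the \linkS4class{SimConfig} that produced it
#' @export
setClass("SimResult",
    representation(trueTotalTL = "numeric", replicates = "data.frame",
                   config = "SimConfig"))
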