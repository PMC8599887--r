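#' @include AllClasses.R
NULL

#' Full probe or target sequence
#'
#' @param x an object with a natural full sequence
#' @param ... unused
#' @return a \link[Biostrings]{DNAString}
#' @export
setGeneric("probeSequence", function(x, ...) standardGeneric("probeSequence"))

#' Hybridized footprint of a probe, in bases
#'
#' @param x an \linkS4class{OmegaProbe}
#' @return total arm length, bases
#' @export
setGeneric("hybridizedFootprint",
    function(x) standardGeneric("hybridizedFootprint"))

#' The two target bases spanning the ligated junction
#'
#' @param x an \linkS4class{OmegaProbe}
#' @return two-character string, target 5'->3' (e.g. \code{"TA"})
#' @export
setGeneric("junctionTarget", function(x) standardGeneric("junctionTarget"))

#' Amplification efficiency of a calibration
#'
#' @param x a \linkS4class{StandardCurve}
#' @return efficiency as a fraction (1 = perfect doubling)
#' @export
setGeneric("efficiency", function(x) standardGeneric("efficiency"))

#' Convert a quantification cycle to starting copies
#'
#' @param cq quantification cycle(s); NA marks non-detects
#' @param calibration an \linkS4class{ExpCalibration} or
#'   \linkS4class{StandardCurve}
#' @return estimated starting copies (real-valued)
#' @export
setGeneric("copiesFromCq",
    function(cq, calibration) standardGeneric("copiesFromCq"))

#' Convert starting copies to an expected quantification cycle
#'
#' @param copies starting copies, > 0
#' @param calibration an \linkS4class{ExpCalibration} or
#'   \linkS4class{StandardCurve}
#' @return expected Cq
#' @export
setGeneric("cqFromCopies",
    function(copies, calibration) standardGeneric("cqFromCopies"))
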