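#' @include AllClasses.R AllGenerics.R
NULL

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.revcomp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Default segment sequences of the telomeric Omega-probe
#'
#' The five segments whose 5'->3' concatenation is the published 88-mer
#' telomeric Omega-probe.  The segment boundaries are stored explicitly
#' (rather than inferred from arm-length conventions) because the only
#' segmentation consistent with the published probe and reverse-primer
#' strings places 17 bases in the 5' arm and 14 in the 3' arm; the
#' quantification calculus nevertheless uses the independent geometry
#' constant of 32 hybridized bases per probe (see
#' \code{\link{probeGeometry}}).
#'
#' @return named list of character segments
#'   (\code{arm5}, \code{prBinding}, \code{pf}, \code{hp}, \code{arm3})
#' @examples
#' nchar(paste(unlist(defaultProbeSegments()), collapse = ""))  # 88
#' @export
defaultProbeSegments <- function() {
    list(arm5      = "AACCCTAACCCTAACCC",
         prBinding = "CGCGCTAGACTAAGCGCTC",
         pf        = "CAGTGACTCAGCAGCTACCCG",
         hp        = "GCAACTAGATGCCGCCC",
         arm3      = "CTAACCCTAACCCT")
}

#' Reference oligonucleotides of the assay
#'
#' Forward primer, reverse primer and hydrolysis-probe core sequences used
#' with the default telomeric probe.
#'
#' @return named character vector
#' @export
assayOligos <- function() {
    c(pf  = "CAGTGACTCAGCAGCTACCCG",
      pr  = "GAGCGCTTAGTCTAGCGCG",
      scgPf = "CAGCAAGTGGGAAGGTGTAATCC",
      scgPr = "CCCATTCTATCATCAACGGGTACAA",
      hydrolysisProbe = "CAACTAGATGCCGCCC")
}

#' Build an Omega-probe from its five segments
#'
#' Concatenation order is arm5 -> reverse-primer binding -> forward primer ->
#' hydrolysis-probe region -> arm3 (5'->3').  The arms are written as
#' synthesized (C-rich for a G-strand telomeric target); complementarity
#' checks reverse-complement internally.
#'
#' @param arm5,prBinding,pf,hp,arm3 DNA segment strings
#' @param phosphorylated logical; the 5' end must be phosphorylated for
#'   ligation
#' @return an \linkS4class{OmegaProbe}
#' @examples
#' probe <- do.call(buildProbe, defaultProbeSegments())
#' nchar(as.character(probeSequence(probe)))  # 88
#' @export
buildProbe <- function(arm5, prBinding, pf, hp, arm3, phosphorylated = TRUE) {
    segs <- list(arm5 = arm5, prBinding = prBinding, pf = pf, hp = hp,
                 arm3 = arm3)
    for (nm in names(segs)) {
        s <- segs[[nm]]
        if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s))
            stop("segment '", nm, "' must be a non-empty string")
        if (!.validDNA(s))
            stop("segment '", nm, "' contains non-DNA characters")
    }
    new("OmegaProbe", arm5 = arm5, prBinding = prBinding, pf = pf, hp = hp,
        arm3 = arm3, phosphorylated = phosphorylated)
}

#' The default telomeric Omega-probe
#'
#' @return an \linkS4class{OmegaProbe} whose full sequence is the published
#'   88-mer telomeric probe
#' @export
defaultProbe <- function() do.call(buildProbe, defaultProbeSegments())

#' @describeIn probeSequence full 5'->3' sequence of a probe
#' @export
setMethod("probeSequence", "OmegaProbe", function(x, ...) {
    Biostrings::DNAString(paste0(x@arm5, x@prBinding, x@pf, x@hp, x@arm3))
})

#' @describeIn probeSequence sequence of a linearized probe
#' @export
setMethod("probeSequence", "OmegaORF", function(x, ...) {
    Biostrings::DNAString(x@sequence)
})

#' @describeIn hybridizedFootprint summed arm length of a probe
#' @export
setMethod("hybridizedFootprint", "OmegaProbe", function(x) {
    nchar(x@arm5) + nchar(x@arm3)
})

#' @describeIn junctionTarget target dinucleotide paired by the abutting
#'   probe ends (5'->3' on the target strand)
#' @export
setMethod("junctionTarget", "OmegaProbe", function(x) {
    first5 <- substr(x@arm5, 1L, 1L)
    last3 <- substr(x@arm3, nchar(x@arm3), nchar(x@arm3))
    # target 5'->3': base paired by the arm5 5'-terminus precedes the base
    # paired by the arm3 3'-terminus (the probe anneals antiparallel)
    paste0(.COMPLEMENT[[first5]], .COMPLEMENT[[last3]])
})

setMethod("show", "OmegaProbe", function(object) {
    cat("OmegaProbe (", nchar(as.character(probeSequence(object))),
        " nt, 5'", if (object@phosphorylated) " phosphorylated" else "",
        ")\n", sep = "")
    cat("  arms: 5' ", object@arm5, " | 3' ", object@arm3, "\n", sep = "")
    cat("  hybridized footprint:", hybridizedFootprint(object),
        "bases; junction target:", junctionTarget(object), "\n")
})

setMethod("show", "OmegaORF", function(object) {
    cat("OmegaORF (", nchar(object@sequence), " nt)\n  ",
        object@sequence, "\n", sep = "")
})

#' Linearize a probe to its open-reading-frame rotation
#'
#' Returns the cyclic rotation of the full probe sequence beginning at the
#' first base of the forward primer, i.e. the linear form whose qPCR
#' behaviour matches a circularized probe (forward primer at the 5' end,
#' reverse-primer binding region at the 3' end).
#'
#' @param probe an \linkS4class{OmegaProbe}
#' @return an \linkS4class{OmegaORF}
#' @examples
#' orf <- linearizeToORF(defaultProbe())
#' @export
linearizeToORF <- function(probe) {
    stopifnot(is(probe, "OmegaProbe"))
    full <- as.character(probeSequence(probe))
    at <- regexpr(probe@pf, full, fixed = TRUE)
    if (at < 0L)
        stop("malformed probe: forward primer not found in full sequence")
    rotated <- paste0(substr(full, at, nchar(full)),
                      substr(full, 1L, at - 1L))
    new("OmegaORF", sequence = rotated)
}

#' Construct a tandem-repeat target
#'
#' @param unit repeat unit on the G-rich strand, 5'->3'
#' @param nUnits number of repeats
#' @param variantPattern optional variant unit with one \code{N} wildcard
#'   (subtelomeric repeat variants)
#' @return a \linkS4class{RepeatTarget}
#' @export
repeatTarget <- function(unit = "TTAGGG", nUnits = 1L,
                         variantPattern = NA_character_) {
    new("RepeatTarget", unit = toupper(unit), nUnits = as.integer(nUnits),
        variantPattern = as.character(variantPattern))
}

#' Generate the tract sequence of a repeat target
#'
#' @param target a \linkS4class{RepeatTarget}
#' @param variantBase when the target carries a variant pattern, the concrete
#'   base substituted at the \code{N} wildcard; required in that case
#' @return a \link[Biostrings]{DNAString} of length
#'   \code{nUnits * nchar(unit)} (canonical) or
#'   \code{nUnits * nchar(variantPattern)} (variant)
#' @export
targetSequence <- function(target, variantBase = NULL) {
    stopifnot(is(target, "RepeatTarget"))
    unit <- target@unit
    if (!is.na(target@variantPattern)) {
        if (is.null(variantBase))
            stop("variantBase required for a target with a variant pattern")
        stopifnot(variantBase %in% .DNA_ALPHABET)
        unit <- sub("N", variantBase, target@variantPattern, fixed = TRUE)
    }
    Biostrings::DNAString(strrep(unit, target@nUnits))
}

setMethod("show", "RepeatTarget", function(object) {
    cat("RepeatTarget: (", object@unit, ")n with n = ", object@nUnits,
        if (!is.na(object@variantPattern))
            paste0(", variant ", object@variantPattern) else "",
        "\n", sep = "")
})

#' Check ligatability of a probe at its junction on a target window
#'
#' The junction-spanning hybrid stretch (3' arm followed by 5' arm, the order
#' in which they lie across the nick of the circularized probe) is aligned
#' antiparallel against the supplied target window at the complementarity-
#' maximizing offset (ties resolved toward the smallest offset, i.e. the
#' designed phase).  The verdict is \code{"ligatable"} only when both target
#' bases spanning the nick are Watson-Crick complementary to the abutting
#' probe ends; a single mismatch at either base aborts ligation.  This is the
#' discrimination that rejects subtelomeric repeat variants.
#'
#' Ligation also presumes the probe is stably hybridized at all: each arm
#' may carry at most \code{maxArmMismatches} mismatches at the chosen
#' alignment (short padlock arms tolerate essentially none at the ligation
#' temperature), which is what rejects repeat variants whose phase slippage
#' leaves the arms half-paired even when the two junction bases happen to
#' find partners.
#'
#' @param probe an \linkS4class{OmegaProbe}
#' @param targetWindow target strand window, 5'->3', covering at least the
#'   full hybridized footprint
#' @param offset optional fixed alignment offset (0-based from the window
#'   5' end); when NULL the best-scoring offset is used
#' @param maxArmMismatches mismatches tolerated per arm before hybridization
#'   (and hence ligation) is considered abolished (default 2)
#' @return list with elements \code{verdict} ("ligatable" or "mismatch"),
#'   \code{offset}, \code{junctionBases} (the two aligned target bases,
#'   5'->3') and \code{matches} (arm bases paired at the chosen offset)
#' @examples
#' win <- strrep("TTAGGG", 8)
#' checkLigationJunction(defaultProbe(), win)$verdict
#' @export
checkLigationJunction <- function(probe, targetWindow, offset = NULL,
                                  maxArmMismatches = 2L) {
    stopifnot(is(probe, "OmegaProbe"))
    targetWindow <- toupper(targetWindow)
    if (!.validDNA(targetWindow))
        stop("targetWindow must be a non-empty A/C/G/T string")
    hyb <- paste0(probe@arm3, probe@arm5)  # 5'->3' across the nick
    nH <- nchar(hyb)
    nW <- nchar(targetWindow)
    if (nW < nH)
        stop("target window (", nW, " nt) shorter than the hybridized ",
             "footprint (", nH, " nt)")
    wchars <- strsplit(targetWindow, "")[[1]]
    hchars <- strsplit(hyb, "")[[1]]
    compH <- unname(.COMPLEMENT[hchars])  # base each H position must see
    score1 <- function(o) {
        # H position i pairs window position o + nH - i + 1 (antiparallel)
        sum(wchars[o + rev(seq_len(nH))] == compH)
    }
    offsets <- 0:(nW - nH)
    if (is.null(offset)) {
        scores <- vapply(offsets, score1, numeric(1))
        offset <- offsets[which.max(scores)]
    } else if (!offset %in% offsets) {
        stop("offset out of range for this window")
    }
    nArm3 <- nchar(probe@arm3)
    w3 <- offset + nH - nArm3 + 1L   # pairs the arm3 3'-terminal base
    w5 <- offset + nH - nArm3       # pairs the arm5 5'-terminal base
    junctionOk <- wchars[w3] == compH[nArm3] &&
        wchars[w5] == compH[nArm3 + 1L]
    paired <- wchars[offset + rev(seq_len(nH))] == compH
    armsOk <- sum(!paired[seq_len(nArm3)]) <= maxArmMismatches &&
        sum(!paired[(nArm3 + 1L):nH]) <= maxArmMismatches
    ok <- junctionOk && armsOk
    list(verdict = if (ok) "ligatable" else "mismatch",
         offset = offset,
         junctionBases = paste0(wchars[w5], wchars[w3]),
         matches = score1(offset))
}

#' Construct the occlusion geometry
#'
#' @param footprintHyb hybridized bases per circularized probe (default 32)
#' @param occlusion bases occluded per abutting probe, footprint plus
#'   stem-loop exclusion (default 48)
#' @return a \linkS4class{ProbeGeometry}
#' @export
probeGeometry <- function(footprintHyb = 32, occlusion = 48) {
    new("ProbeGeometry", footprintHyb = footprintHyb, occlusion = occlusion)
}

setMethod("show", "ProbeGeometry", function(object) {
    cat("ProbeGeometry: footprint", object@footprintHyb,
        "bp hybridized,", object@occlusion, "bp occluded per probe\n")
})

#' Number of probes tiling a tract under saturating hybridization
#'
#' Deterministic maximal abutting packing: the first probe consumes its
#' hybridized footprint, each further abutting probe consumes the occlusion
#' width.  This is the exact inverse image of the occlusion-length formula
#' \code{TL = occlusion * (N - 1) + footprint}.
#'
#' @param tractLength tract length(s), bp (vectorized)
#' @param geometry a \linkS4class{ProbeGeometry}
#' @return integer probe count(s); 0 for tracts shorter than one footprint
#' @examples
#' tileProbes(c(32, 800, 1600))  # 1, 17, 33
#' @export
tileProbes <- function(tractLength, geometry = probeGeometry()) {
    stopifnot(is(geometry, "ProbeGeometry"))
    if (any(is.na(tractLength)) || any(tractLength < 0))
        stop("tractLength must be non-negative")
    fp <- geometry@footprintHyb
    oc <- geometry@occlusion
    as.integer(ifelse(tractLength < fp, 0L,
                      floor((tractLength - fp) / oc) + 1))
}

## Nearest-neighbor thermodynamic tables.
## Unified parameters: SantaLucia PNAS 1998 (dH kcal/mol, dS cal/mol/K);
## alternative set: Breslauer et al. PNAS 1986.
.NN_TABLES <- list(
    santalucia1998 = list(
        dH = c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
               CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0),
        dS = c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
               CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9),
        initGC = c(dH = 0.1, dS = -2.8),
        initAT = c(dH = 2.3, dS = 4.1),
        saltMode = "entropy"),
    breslauer1986 = list(
        dH = c(AA = -9.1, AT = -8.6, TA = -6.0, CA = -5.8, GT = -6.5,
               CT = -7.8, GA = -5.6, CG = -11.9, GC = -11.1, GG = -11.0),
        dS = c(AA = -24.0, AT = -23.9, TA = -16.9, CA = -12.9, GT = -17.3,
               CT = -20.8, GA = -13.5, CG = -27.8, GC = -26.7, GG = -26.6),
        init = c(dH = 0, dS = -10.8),
        saltMode = "tm166"))

.nnKey <- function(dinuc) {
    # fold complementary dinucleotides onto the tabulated strand
    fold <- c(TT = "AA", TG = "CA", AC = "GT", AG = "CT", TC = "GA",
              CC = "GG")
    ifelse(dinuc %in% names(fold), fold[dinuc], dinuc)
}

#' Nearest-neighbor melting temperature of a probe arm
#'
#' Advisory duplex Tm estimate for designing arms against non-default
#' targets, computed from nearest-neighbor stacking thermodynamics with a
#' monovalent-salt correction.  Values are advisory: the assay fixes
#' hybridization empirically by a slow temperature ramp, and no secondary
#' structure is modeled.
#'
#' @param arm DNA string, length >= 8
#' @param na monovalent cation concentration, mol/L (default 0.05)
#' @param conc total oligo strand concentration, mol/L (default 2.5e-7)
#' @param paramSet \code{"santalucia1998"} (unified parameters; default) or
#'   \code{"breslauer1986"}
#' @return melting temperature, degrees C
#' @export
armMeltingTemperature <- function(arm, na = 0.05, conc = 2.5e-7,
                                  paramSet = c("santalucia1998",
                                               "breslauer1986")) {
    paramSet <- match.arg(paramSet)
    arm <- toupper(arm)
    if (!.validDNA(arm)) stop("arm must be a non-empty A/C/G/T string")
    n <- nchar(arm)
    if (n < 8L) stop("arm too short for a nearest-neighbor estimate (< 8 nt)")
    stopifnot(na > 0, conc > 0)
    tab <- .NN_TABLES[[paramSet]]
    ch <- strsplit(arm, "")[[1]]
    dinucs <- .nnKey(paste0(ch[-n], ch[-1]))
    dH <- sum(tab$dH[dinucs])           # kcal/mol
    dS <- sum(tab$dS[dinucs])           # cal/mol/K
    if (paramSet == "santalucia1998") {
        for (end in c(ch[1], ch[n])) {
            ini <- if (end %in% c("G", "C")) tab$initGC else tab$initAT
            dH <- dH + ini[["dH"]]
            dS <- dS + ini[["dS"]]
        }
        dS <- dS + 0.368 * (n - 1) * log(na)
    } else {
        dH <- dH + tab$init[["dH"]]
        dS <- dS + tab$init[["dS"]]
    }
    R <- 1.9872  # cal/mol/K
    tmK <- dH * 1000 / (dS + R * log(conc / 4))
    tm <- tmK - 273.15
    if (tab$saltMode == "tm166") tm <- tm + 16.6 * log10(na)
    unname(tm)
}
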