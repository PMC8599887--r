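# Reference strings of the built-in telomeric probe system (as published).
PROBE_88MER <- paste0(
    "AACCCTAACCCTAACCCCGCGCTAGACTAAGCGCTCCAGTGACTCAGCAGCTACCCG",
    "GCAACTAGATGCCGCCCCTAACCCTAACCCT")
ORF_88MER <- paste0(
    "CAGTGACTCAGCAGCTACCCGGCAACTAGATGCCGCCCCTAACC",
    "CTAACCCTAACCCTAACCCTAACCCCGCGCTAGACTAAGCGCTC")

revcompChr <- function(x) {
    paste(rev(chartr("ACGT", "TGCA", strsplit(x, "")[[1]])), collapse = "")
}

# brute-force check that a C-rich arm is the reverse complement of some
# contiguous window of an infinitely repeated G-strand unit
armMatchesSomePhase <- function(arm, unit = "TTAGGG") {
    tract <- strrep(unit, ceiling(nchar(arm) / nchar(unit)) + 2L)
    grepl(revcompChr(arm), tract, fixed = TRUE)
}

# exactly log-linear 3+ marker ladder for TRF oracles
loglinearLadder <- function(lengthsKbp = c(10, 1, 0.1),
                            positions = c(10, 20, 30)) {
    markerLadder(lengthsKbp, positions)
}
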