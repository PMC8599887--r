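#' @include AllClasses.R quant-core.R telosim.R trf.R
NULL

.NONDETECT_TOKENS <- c("Undetermined", "undetermined", "ND", "NA", "NaN", "")

#' Read a tabular qPCR export
#'
#' Expects delimited text (tab by default; comma detected from the header)
#' with columns \code{sample_id}, \code{assay}, \code{cq}, \code{replicate}.
#' Non-detect wells may carry \code{Undetermined}, \code{ND} or an empty
#' field: they are preserved as \code{NA} Cq with \code{nondetect = TRUE},
#' never encoded as zero.  Malformed Cq fields and duplicated
#' (sample, assay, replicate) keys are rejected with their line numbers.
#'
#' @param path file path
#' @return data frame with columns \code{sample_id}, \code{assay},
#'   \code{cq} (numeric, NA = non-detect), \code{replicate},
#'   \code{nondetect}
#' @export
readQPCRTable <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
    raw <- utils::read.delim(path, sep = sep, colClasses = "character",
                             check.names = FALSE, strip.white = TRUE)
    need <- c("sample_id", "assay", "cq", "replicate")
    missing <- setdiff(need, names(raw))
    if (length(missing))
        stop("missing required column(s): ", paste(missing, collapse = ", "))
    lineNo <- seq_len(nrow(raw)) + 1L  # header is line 1
    nondetect <- raw$cq %in% .NONDETECT_TOKENS
    cq <- suppressWarnings(as.numeric(raw$cq))
    bad <- !nondetect & is.na(cq)
    if (any(bad))
        stop("unparseable cq value(s) at line(s) ",
             paste(lineNo[bad], collapse = ", "))
    if (any(!nondetect & cq <= 0))
        stop("non-positive cq at line(s) ",
             paste(lineNo[!nondetect & cq <= 0], collapse = ", "))
    rep <- suppressWarnings(as.integer(raw$replicate))
    if (any(is.na(rep)))
        stop("unparseable replicate at line(s) ",
             paste(lineNo[is.na(rep)], collapse = ", "))
    key <- paste(raw$sample_id, raw$assay, rep, sep = "\r")
    dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
    if (any(duplicated(key)))
        stop("duplicated (sample_id, assay, replicate) key at line(s) ",
             paste(lineNo[dup], collapse = ", "))
    cq[nondetect] <- NA_real_
    data.frame(sample_id = raw$sample_id, assay = raw$assay, cq = cq,
               replicate = rep, nondetect = nondetect)
}

#' Write a result table as tab-delimited text
#'
#' @param table data frame of results
#' @param path output path
#' @return invisibly, the path
#' @export
writeResultsTable <- function(table, path) {
    stopifnot(is.data.frame(table))
    utils::write.table(table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

#' Read back a result table written by \code{writeResultsTable}
#'
#' @param path file path
#' @return data frame
#' @export
readResultsTable <- function(path) {
    utils::read.delim(path, sep = "\t", check.names = FALSE)
}

#' Write the built-in probe and assay oligos as FASTA
#'
#' @param path output FASTA path
#' @return invisibly, the path
#' @export
writeProbeFasta <- function(path) {
    probe <- defaultProbe()
    oligos <- assayOligos()
    seqs <- Biostrings::DNAStringSet(c(
        omega_probe = as.character(probeSequence(probe)),
        omega_orf = as.character(probeSequence(linearizeToORF(probe))),
        oligos))
    Biostrings::writeXStringSet(seqs, path)
    invisible(path)
}

#' Generate the bundled desk-scale fixture set
#'
#' Writes, deterministically under \code{seed}: the probe/oligo FASTA; a
#' plasmid-validation qPCR table (the two synthetic-telomere plasmids at
#' their published masses and quantification cycles) with its plasmid copy
#' table; a simulated single-cell qPCR batch; and a synthetic TRF lane with
#' its ladder.
#'
#' @param dir output directory (created if needed)
#' @param seed RNG seed for the simulated components
#' @return named character vector of the files written
#' @export
makeFixtures <- function(dir, seed = 1L) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out <- c()
    f <- file.path(dir, "probe_oligos.fasta")
    writeProbeFasta(f)
    out["fasta"] <- f

    # plasmid validation replica: published masses and Cq values
    plas <- data.frame(
        sample_id = c("pSXneo135", "pSXneo270"),
        assay = "omega",
        cq = c(19.380, 17.741),
        replicate = 1L)
    f <- file.path(dir, "plasmid_qpcr.tsv")
    writeResultsTable(plas, f)
    out["plasmid_qpcr"] <- f
    copies <- data.frame(
        sample_id = c("pSXneo135", "pSXneo270"),
        mass_pg = c(0.125, 0.250),
        molecules = c(massToMolecules(0.125, plasmidPreset("pSXneo135")),
                      massToMolecules(0.250, plasmidPreset("pSXneo270"))))
    f <- file.path(dir, "plasmid_copies.tsv")
    writeResultsTable(copies, f)
    out["plasmid_copies"] <- f

    # simulated single-cell batch: 10 near-diploid cells, ~5 kb telomeres
    sim <- simulateAssay(
        simConfig(tractLengths = 5000, templateCopies = 94,
                  cqNoiseSd = 0.1, seed = seed),
        replicates = 10L)
    sc <- data.frame(sample_id = sprintf("cell%02d", 1:10),
                     assay = "omega", cq = round(sim@replicates$cq, 3),
                     replicate = 1L)
    f <- file.path(dir, "singlecell_qpcr.tsv")
    writeResultsTable(sc, f)
    out["singlecell_qpcr"] <- f

    # synthetic TRF lane + ladder
    lane <- synthLane("lognormal", meanBp = 7000, sdlog = 0.2,
                      noiseSd = 0.02, seed = seed)
    f <- file.path(dir, "trf_lane.tsv")
    writeResultsTable(data.frame(position = lane$profile@positions,
                                 od = signif(lane$profile@od, 6)), f)
    out["trf_lane"] <- f
    f <- file.path(dir, "trf_ladder.tsv")
    writeResultsTable(data.frame(length_kbp = lane$ladder@lengthsKbp,
                                 position = lane$ladder@positions), f)
    out["trf_ladder"] <- f
    out
}
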