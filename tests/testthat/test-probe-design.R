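test_that("built probe reproduces the published 88-mer and its segments", {
    probe <- defaultProbe()
    expect_identical(as.character(probeSequence(probe)), PROBE_88MER)
    expect_true(probe@phosphorylated)
    # the Pr-binding region is the reverse complement of the reverse primer
    expect_identical(probe@prBinding, revcompChr(unname(assayOligos()["pr"])))
    # the hydrolysis-probe core is contained in the hp region
    expect_true(grepl(assayOligos()[["hydrolysisProbe"]], probe@hp,
                      fixed = TRUE))
})

test_that("buildProbe concatenates in order and validates segments", {
    p <- buildProbe("A", "C", "G", "T", "A")
    expect_identical(as.character(probeSequence(p)), "ACGTA")
    expect_error(buildProbe("A", "C", "G", "T", ""), "non-empty")
    expect_error(buildProbe("A", "C", "G", "T", "AXG"), "non-DNA")
})

test_that("probe arms are reverse-complementary to a phase of the repeat", {
    probe <- defaultProbe()
    expect_true(armMatchesSomePhase(probe@arm5))
    expect_true(armMatchesSomePhase(probe@arm3))
    # a 12-nt (CCCTAA)-phased arm pair built for the unit passes the same
    # brute-force check across all 6 phases
    for (phase in 0:5) {
        tract <- strrep("TTAGGG", 4)
        window <- substr(tract, phase + 1L, phase + 12L)
        arm <- revcompChr(window)
        expect_true(armMatchesSomePhase(arm),
                    info = paste("phase", phase))
    }
})

test_that("linearized form is the published rotation and conserves content", {
    probe <- defaultProbe()
    orf <- linearizeToORF(probe)
    expect_identical(as.character(probeSequence(orf)), ORF_88MER)
    full <- as.character(probeSequence(probe))
    # pure rotation: the rotated sequence occurs in the doubled original
    expect_true(grepl(as.character(probeSequence(orf)),
                      paste0(full, full), fixed = TRUE))
    expect_identical(sort(strsplit(ORF_88MER, "")[[1]]),
                     sort(strsplit(full, "")[[1]]))
    # a probe whose full sequence already starts with pf rotates to itself
    p0 <- buildProbe("ACGTT", "CC", "ACGTT", "GG", "TT")
    expect_identical(as.character(probeSequence(linearizeToORF(p0))),
                     as.character(probeSequence(p0)))
})

test_that("junction discrimination accepts the canonical TA and rejects any substitution", {
    probe <- defaultProbe()
    expect_identical(junctionTarget(probe), "TA")
    win <- strrep("TTAGGG", 8)
    v <- checkLigationJunction(probe, win)
    expect_identical(v$verdict, "ligatable")
    expect_identical(v$junctionBases, "TA")
    # locate the two junction-covered bases at the chosen alignment and
    # substitute each; only the complementary base at each slot ligates
    nArm3 <- nchar(probe@arm3)
    nH <- nArm3 + nchar(probe@arm5)
    w5 <- v$offset + nH - nArm3
    for (pos in c(w5, w5 + 1L)) {
        original <- substr(win, pos, pos)
        verdicts <- vapply(c("A", "C", "G", "T"), function(b) {
            w <- win
            substr(w, pos, pos) <- b
            checkLigationJunction(probe, w, offset = v$offset)$verdict
        }, character(1))
        expect_identical(sum(verdicts == "ligatable"), 1L)
        expect_identical(names(verdicts)[verdicts == "ligatable"], original)
    }
})

test_that("junction verdicts are phase-consistent across repeat units", {
    probe <- defaultProbe()
    base <- strrep("TTAGGG", 12)
    verdicts <- vapply(0:3, function(k) {
        win <- substr(base, 1L + 6L * k, 42L + 6L * k)
        checkLigationJunction(probe, win)$verdict
    }, character(1))
    expect_true(all(verdicts == "ligatable"))
    expect_error(checkLigationJunction(probe, "TTAGGG"), "shorter")
})

test_that("subtelomeric variant repeats are rejected at the junction", {
    # TTNAGGG variant units with any concrete base break the designed
    # junction geometry
    for (b in c("A", "C", "G", "T")) {
        tgt <- repeatTarget("TTAGGG", 8, variantPattern = "TTNAGGG")
        win <- as.character(targetSequence(tgt, variantBase = b))
        v <- checkLigationJunction(defaultProbe(), win)
        expect_identical(v$verdict, "mismatch", info = paste("variant", b))
    }
})

test_that("tiling is the saturating inverse of the occlusion formula", {
    expect_identical(tileProbes(32), 1L)
    expect_identical(tileProbes(800), 17L)   # floor((800-32)/48)+1
    expect_identical(tileProbes(1600), 33L)
    expect_identical(tileProbes(31), 0L)
    expect_identical(tileProbes(0), 0L)
    expect_error(tileProbes(-1), "non-negative")
    # exact inverse on the whole lattice, and monotone between points
    N <- 1:1e6
    lattice <- 48 * (N - 1) + 32
    expect_identical(tileProbes(lattice), N)
    L <- seq(0, 5000, by = 7)
    expect_true(all(diff(tileProbes(L)) >= 0L))
})

test_that("tiling respects non-default geometry", {
    g <- probeGeometry(footprintHyb = 20, occlusion = 25)
    expect_identical(tileProbes(c(19, 20, 45, 44), g), c(0L, 1L, 2L, 1L))
    expect_error(probeGeometry(footprintHyb = 30, occlusion = 20))
})

test_that("nearest-neighbor Tm orders GC content and length sensibly", {
    polyA <- strrep("A", 16)
    gcRich <- strrep("GC", 8)
    expect_gt(armMeltingTemperature(gcRich), armMeltingTemperature(polyA))
    arm <- defaultProbeSegments()$arm5
    expect_gte(armMeltingTemperature(strrep("CCCTAA", 6)),   # 36-mer
               armMeltingTemperature(strrep("CCCTAA", 3)))   # 18-mer
    # the built-in arm lands in the generic oligo range under both
    # parameter sets (advisory check, two independent NN tables)
    tmS <- armMeltingTemperature(arm, paramSet = "santalucia1998")
    tmB <- armMeltingTemperature(arm, paramSet = "breslauer1986")
    expect_true(tmS > 40 && tmS < 60)
    expect_true(tmB > 40 && tmB < 60)
    expect_lt(abs(tmS - tmB), 12)  # parameter sets agree to within ~10 C
    expect_error(armMeltingTemperature("ACGTACG"), "too short")
})
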