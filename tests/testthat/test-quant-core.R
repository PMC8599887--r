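test_that("standard-curve efficiency follows the slope", {
    copies <- 10^(2:7)
    # perfect doubling: slope -1/log10(2)
    sc <- fitStandardCurve(copies, 40 - log10(copies) / log10(2))
    expect_equal(efficiency(sc), 1.0, tolerance = 1e-3)
    # published slope
    sc2 <- fitStandardCurve(copies, 38 - 3.3649 * log10(copies))
    expect_equal(efficiency(sc2), 0.982, tolerance = 5e-4)
    expect_equal(sc2@rSquared, 1.0, tolerance = 1e-12)
    # efficiency strictly decreasing in |slope| beyond perfect doubling
    effs <- vapply(c(3.33, 3.5, 3.8, 4.2), function(s)
        efficiency(fitStandardCurve(copies, 38 - s * log10(copies))),
        numeric(1))
    expect_true(all(diff(effs) < 0))
    expect_error(fitStandardCurve(c(10, 100), c(30, 27)), "3 distinct")
    expect_error(fitStandardCurve(c(0, 10, 100), c(33, 30, 27)), "positive")
})

test_that("fitted curves round-trip their own input points", {
    set.seed(42)
    copies <- 10^(2:7)
    cq <- 38 - 3.4 * log10(copies) + rnorm(6, 0, 0.05)
    sc <- fitStandardCurve(copies, cq)
    pred <- cqFromCopies(copies, sc)
    resid <- cq - pred
    expect_lt(max(abs(resid)), 0.2)
    # and inversion is exact: copiesFromCq(cqFromCopies(x)) == x
    expect_equal(copiesFromCq(cqFromCopies(copies, sc), sc), copies,
                 tolerance = 1e-9)
})

test_that("exponential calibration matches the published worked values", {
    cal <- expCalibration()
    expect_equal(copiesFromCq(0, cal), 4e11)
    # published tabulated counts, within 0.5% (rounded constants)
    expect_equal(copiesFromCq(19.380, cal), 610338, tolerance = 0.005)
    expect_equal(copiesFromCq(17.741, cal), 1896839, tolerance = 0.005)
    expect_true(all(diff(copiesFromCq(seq(10, 35, 0.5), cal)) < 0))
    expect_error(copiesFromCq(NA_real_, cal), "non-detect")
})

test_that("the two calibration parameterizations agree when cross-fitted", {
    cal <- expCalibration()
    copies <- 10^seq(3, 10, by = 0.5)
    sc <- fitStandardCurve(copies, cqFromCopies(copies, cal))
    cq <- seq(10, 35, by = 0.25)
    rel <- copiesFromCq(cq, sc) / copiesFromCq(cq, cal) - 1
    expect_lt(max(abs(rel)), 0.01)
})

test_that("occlusion-length formula and published totals agree", {
    expect_equal(tlFromCount(1), 32)
    expect_equal(tlFromCount(610338), 29296208)
    expect_equal(tlFromCount(1896839), 91048256)
    expect_warning(out <- tlFromCount(0), "zero")
    expect_equal(out, 0)
    expect_error(tlFromCount(-1), "non-negative")
    # non-integer counts carried as reals
    expect_equal(tlFromCount(2.5), 48 * 1.5 + 32)
})

test_that("occlusion formula and tiling are mutual inverses on the lattice", {
    N <- c(1:1000, sample.int(1e6, 200))
    lattice <- 48 * (N - 1) + 32
    expect_identical(tileProbes(lattice), as.integer(N))
    expect_equal(tlFromCount(tileProbes(lattice)), lattice)
})

test_that("mass-to-molecules reproduces the published plasmid counts", {
    expect_equal(massToMolecules(0.125, plasmidPreset("pSXneo135")), 35750)
    expect_equal(massToMolecules(0.250, plasmidPreset("pSXneo270")), 57250)
    expect_equal(massToMolecules(1e6, plasmidPreset("pSXneo135")), 2.86e11)
    expect_error(massToMolecules(0, plasmidPreset("pSXneo135")), "positive")
    # derived molecules-per-ug from length at 650 g/mol/bp lands within 2%
    d135 <- plasmidSpec("d135", 800)
    d270 <- plasmidSpec("d270", 1600)
    expect_equal(d135@moleculesPerUg, 2.86e11, tolerance = 0.02)
    expect_equal(d270@moleculesPerUg, 2.29e11, tolerance = 0.02)
})

test_that("per-copy length reproduces the published 819 and 1590 bp", {
    expect_identical(perCopyLength(29296208, 35750), 819)
    expect_identical(perCopyLength(91048256, 57250), 1590)
    expect_identical(perCopyLength(0, 100), 0)
    expect_error(perCopyLength(100, 0), "positive")
})

test_that("background gating splits records at the negative-control band", {
    rec <- data.frame(
        sample_id = sprintf("s%02d", 1:10), assay = "omega",
        cq = c(19.38, 22.1, 41, 18.3, 25.0, 40.2, 30.1, 33.3, 21.7, 28.8),
        replicate = 1L)
    g <- backgroundGate(rec)
    expect_identical(unname(g$counts), c(8L, 2L))
    expect_true(all(g$background$cq >= 40))
    # non-detects always gate to background
    rec$cq[1] <- NA
    expect_identical(unname(backgroundGate(rec)$counts["background"]), 3L)
    # a 41-cycle well is background, a 19.38 well is signal
    expect_identical(nrow(backgroundGate(
        data.frame(cq = 41))$signal), 0L)
    expect_identical(nrow(backgroundGate(
        data.frame(cq = 19.38))$signal), 1L)
})

test_that("batch quantification runs the published order of operations", {
    rec <- data.frame(
        sample_id = c("pSXneo135", "pSXneo270"), assay = "omega",
        cq = c(19.380, 17.741), replicate = 1L)
    copies <- c(pSXneo135 = massToMolecules(0.125, plasmidPreset("pSXneo135")),
                pSXneo270 = massToMolecules(0.250, plasmidPreset("pSXneo270")))
    out <- quantifyTelomeres(rec, templateCopies = copies)
    s <- out$summary
    # per-template lengths recovered within 1% of the published 819/1590
    expect_equal(s$per_copy_tl[s$sample_id == "pSXneo135"], 819,
                 tolerance = 0.01)
    expect_equal(s$per_copy_tl[s$sample_id == "pSXneo270"], 1590,
                 tolerance = 0.01)
})

test_that("replicate aggregation propagates Cq spread to length", {
    set.seed(7)
    cqs <- 22 + rnorm(6, 0, 0.1)
    rec <- data.frame(sample_id = "s1", assay = "omega", cq = cqs,
                      replicate = 1:6)
    out <- quantifyTelomeres(rec)
    s <- out$summary
    expect_identical(s$n_replicates, 6L)
    expect_equal(s$sd_cq, sd(cqs))
    # delta-method sd: occlusion * k * Ncp * sd_cq
    cal <- expCalibration()
    pred <- 48 * cal@decay * copiesFromCq(mean(cqs), cal) * sd(cqs)
    expect_equal(s$sd_total_tl, pred, tolerance = 1e-9)
    expect_identical(nrow(out$perReplicate), 6L)
})
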