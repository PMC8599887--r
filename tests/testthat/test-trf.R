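test_that("marker calibration interpolates log-linearly", {
    # exact log-linear 3-marker ladder: midpoint of a decade is 10^0.5
    cv <- fitMarkerCurve(loglinearLadder())
    expect_equal(cv$rSquared, 1.0, tolerance = 1e-12)
    # 1 kbp at position 20, 0.1 kbp at 30: the midpoint maps to 10^-0.5 kbp
    expect_equal(cv$predict(25), 0.3162278, tolerance = 1e-6)
    expect_equal(cv$predict(15), 3.162278, tolerance = 1e-6)
    # the six standard markers placed exactly log-linearly fit perfectly
    lens <- defaultLadderLengths()
    lg <- log10(lens)
    pos <- 10 + 50 * (lg[1] - lg) / (lg[1] - lg[6])
    cv6 <- fitMarkerCurve(markerLadder(lens, pos))
    expect_equal(cv6$rSquared, 1.0, tolerance = 1e-12)
    expect_equal(cv6$predict(pos), lens, tolerance = 1e-9)
    expect_error(markerLadder(c(2, 1), c(1, 2)), "3 ladder")
    expect_error(markerLadder(c(1, 2, 3), c(1, 2, 3)))
})

test_that("noisy marker positions still calibrate within 5%", {
    lens <- defaultLadderLengths()
    lg <- log10(lens)
    pos <- 10 + 50 * (lg[1] - lg) / (lg[1] - lg[6])
    set.seed(11)
    for (i in 1:5) {
        noisy <- pos + rnorm(6, 0, 0.3)
        cv <- fitMarkerCurve(markerLadder(lens, noisy))
        expect_lt(max(abs(cv$predict(noisy) / lens - 1)), 0.05)
    }
})

test_that("reciprocal calibration form fits a reciprocal-law gel exactly", {
    # 1/length exactly linear in position: 0.1, 0.2, 0.3 per kbp
    lad <- markerLadder(c(10, 5, 10 / 3), c(10, 20, 30))
    cv <- fitMarkerCurve(lad, form = "reciprocal")
    expect_equal(cv$rSquared, 1.0, tolerance = 1e-12)
    expect_equal(cv$predict(15), 1 / 0.15, tolerance = 1e-9)
    p <- seq(10, 30, by = 1)
    expect_true(all(diff(cv$predict(p)) < 0))
})

test_that("hybridization-corrected MTL matches the hand-worked two-bin case", {
    cv <- fitMarkerCurve(loglinearLadder(c(10, 4, 1), c(0, 50, 100)))
    # place two equal-OD bins at exactly 2 and 6 kbp
    posOf <- function(kbp) (log10(kbp) - cv$coef[1]) / cv$coef[2]
    prof <- laneProfile(posOf(c(6, 2)), c(1, 1), background = 0)
    # 2 / (1/2 + 1/6) = 3 kbp
    expect_equal(trfMTL(prof, cv), 3000, tolerance = 1e-9)
    # single nonzero bin: MTL equals that bin's length
    prof1 <- laneProfile(posOf(c(6, 2)), c(0, 1), background = 0)
    expect_equal(trfMTL(prof1, cv), 2000, tolerance = 1e-9)
    # scale invariance in OD
    prof2 <- laneProfile(posOf(c(6, 2)), c(37.5, 37.5), background = 0)
    expect_equal(trfMTL(prof2, cv), 3000, tolerance = 1e-9)
    # all-zero profile errors
    prof0 <- laneProfile(posOf(c(6, 2)), c(0, 0), background = 0)
    expect_error(trfMTL(prof0, cv), "no positive")
})

test_that("MTL is bounded by the nonzero-OD bin lengths and shift-monotone", {
    cv <- fitMarkerCurve(loglinearLadder(c(20, 5, 1), c(0, 50, 100)))
    set.seed(3)
    pos <- seq(10, 90, length.out = 50)
    od <- runif(50)
    prof <- laneProfile(pos, od, background = 0)
    m <- trfMTL(prof, cv)
    lens <- cv$predict(pos) * 1000
    expect_gte(m, min(lens[od > 0]))
    expect_lte(m, max(lens[od > 0]))
    # shifting the smear toward smaller migration (longer fragments)
    # strictly increases MTL
    shifted <- laneProfile(pos - 5, od, background = 0)
    expect_gt(trfMTL(shifted, cv), m)
})

test_that("the hybridization correction lowers an OD-uniform smear mean", {
    cv <- fitMarkerCurve(loglinearLadder(c(20, 5, 1), c(0, 50, 100)))
    posOf <- function(kbp) (log10(kbp) - cv$coef[1]) / cv$coef[2]
    pos <- posOf(seq(2, 10, length.out = 100))
    prof <- laneProfile(pos, rep(1, 100), background = 0)
    corrected <- trfMTL(prof, cv)
    lens <- sort(cv$predict(sort(pos)) * 1000)
    uncorrected <- mean(lens)  # plain OD-weighted mean length
    expect_lt(corrected, uncorrected)
})

test_that("synthetic lanes round-trip through the estimator", {
    # delta at 7 kbp recovers within one (log-spaced) bin width
    d <- synthLane("delta", meanBp = 7000, seed = 5)
    cv <- fitMarkerCurve(d$ladder)
    expect_equal(trfMTL(d$profile, cv), 7000, tolerance = 0.01)
    # log-normal smear at zero noise recovers the number-mean within 2%
    # (oracle: E[L] = exp(meanlog + sdlog^2/2), the generator's trueMeanBp)
    ln <- synthLane("lognormal", meanBp = 7000, sdlog = 0.2, seed = 5)
    expect_equal(trfMTL(ln$profile, fitMarkerCurve(ln$ladder)),
                 ln$trueMeanBp, tolerance = 0.02)
    # deterministic under a fixed seed even with noise
    a <- synthLane("lognormal", meanBp = 5000, noiseSd = 0.05, seed = 9)
    b <- synthLane("lognormal", meanBp = 5000, noiseSd = 0.05, seed = 9)
    expect_identical(a$profile@od, b$profile@od)
})

test_that("bins outside the ladder range are excluded unless extrapolating", {
    cv <- fitMarkerCurve(loglinearLadder(c(10, 4, 1), c(0, 50, 100)))
    prof <- laneProfile(c(-20, 50), c(1, 1), background = 0)
    inOnly <- trfMTL(prof, cv)
    expect_equal(inOnly, cv$predict(50) * 1000, tolerance = 1e-9)
    expect_warning(both <- trfMTL(prof, cv, extrapolate = TRUE), "beyond")
    expect_gt(both, inOnly)
})
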