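binPhases <- function(K = 8) 360 * (seq_len(K) - 0.5) / K

test_that("single-harmonic curves are recovered exactly", {
    th <- binPhases()
    f <- fitFFH(5 + 2 * cos((th - 0) * pi / 180))
    expect_equal(f$a0, 5, tolerance = 1e-12)
    expect_equal(f$a1, 2, tolerance = 1e-12)
    expect_equal(f$phase, 0, tolerance = 1e-9)
    f90 <- fitFFH(5 + 2 * cos((th - 90) * pi / 180))
    expect_equal(f90$phase, 90, tolerance = 1e-9)
    expect_equal(f90$a1, 2, tolerance = 1e-12)
})

test_that("random single-harmonic curves are recovered to 1e-9", {
    th <- binPhases()
    set.seed(101)
    for (k in 1:100) {
        a0 <- runif(1, 1, 50); a1 <- runif(1, 0.01, a0)
        phi <- runif(1, 0, 360)
        f <- fitFFH(a0 + a1 * cos((th - phi) * pi / 180))
        expect_lt(abs(f$a0 - a0), 1e-9 * a0)
        expect_lt(abs(f$a1 - a1), 1e-9 * max(1, a1))
        dphi <- abs(f$phase - phi)
        expect_lt(min(dphi, 360 - dphi), 1e-9 * 360)
    }
})

test_that("constant curves are flagged undefined", {
    f <- fitFFH(rep(7, 8))
    expect_false(f$defined)
    expect_equal(f$a1, 0)
    expect_true(is.na(f$phase))
    expect_error(fitFFH(c(1, 2)), "three")
})

test_that("low-amplitude discard drops the right points", {
    # distinct amplitudes: exactly the five smallest go
    fits <- data.frame(a0 = 10, a1 = (1:100) / 10,
                       phase = runif(100, 0, 360), defined = TRUE)
    kept <- discardLowAmplitude(fits, 0.05)
    expect_equal(nrow(kept), 95L)
    expect_equal(sort(kept$a1)[1], 0.6)
    # three constant curves count toward the quota, then the two smallest
    fits2 <- fits
    fits2$defined[c(10, 50, 90)] <- FALSE
    fits2$a1[c(10, 50, 90)] <- 0
    kept2 <- discardLowAmplitude(fits2, 0.05)
    expect_equal(nrow(kept2), 95L)
    expect_false(any(!kept2$defined))
    gone <- setdiff(seq_len(100), as.integer(rownames(kept2)))
    expect_setequal(gone, c(10, 50, 90, 1, 2))
    # all-equal amplitudes: the lowest indices go
    fits3 <- data.frame(a0 = 1, a1 = rep(1, 40), phase = 1, defined = TRUE)
    kept3 <- discardLowAmplitude(fits3, 0.05)
    expect_equal(nrow(kept3), 38L)
    expect_setequal(setdiff(seq_len(40), as.integer(rownames(kept3))),
                    c(1L, 2L))
})

test_that("phase histogram uses left-closed one-degree bins", {
    h <- phaseHistogram(c(0.5, 359.999, 0.0))
    expect_equal(h[1], 2L)
    expect_equal(h[360], 1L)
    expect_equal(sum(h), 3L)
    set.seed(5)
    ph <- runif(500, 0, 360)
    expect_equal(sum(phaseHistogram(ph)), 500L)
    expect_error(phaseHistogram(c(-1)), "0, 360")
    expect_error(phaseHistogram(c(360)), "0, 360")
})

test_that("summary indices match their closed forms", {
    # degenerate: all phases in one bin
    r1 <- summarizePhases(rep(123.4, 50))
    expect_equal(phaseBandwidth(r1), 1)
    expect_equal(phaseStd(r1), 0)
    expect_equal(phaseEntropy(r1), 0)
    # uniform occupancy of all 360 bins
    r2 <- summarizePhases((0:359) + 0.5)
    expect_equal(phaseEntropy(r2), 100)
    expect_equal(phaseBandwidth(r2), 342)   # 0.95 * 360
    # two-point wrap-around case
    r3 <- summarizePhases(c(10, 350))
    expect_equal(phaseStd(r3), sd(c(10, -10)), tolerance = 1e-9)
    expect_equal(phaseStd(r3), 14.1421356, tolerance = 1e-6)
    expect_error(summarizePhases(numeric(0)), "at least one")
})

test_that("a global phase shift moves the arc but not the indices", {
    set.seed(7)
    ph <- (rnorm(300, 180, 25)) %% 360
    base <- summarizePhases(ph)
    for (shift in c(45, 170, 300)) {
        sh <- summarizePhases((ph + shift) %% 360)
        expect_equal(phaseBandwidth(sh), phaseBandwidth(base), tolerance = 1)
        expect_equal(phaseStd(sh), phaseStd(base), tolerance = 0.5)
        expect_equal(phaseEntropy(sh), phaseEntropy(base), tolerance = 0.5)
    }
})

test_that("sampling tracks a single hot voxel and static series give flat curves", {
    spec <- tinySpec()
    d <- c(24L, 24L, 8L)
    # static series: constant TACs everywhere
    vol <- phantomFrame(spec, 0)
    stat <- new("GatedImageSeries",
                data = array(rep(vol, 4), c(d, 4)), voxelSize = 4,
                provenance = list())
    grid <- midWallSamplingGrid(spec, nTheta = 12, nZ = 4)
    tac <- sampleMyocardium(stat, grid)
    expect_true(all(abs(tac - tac[, 1]) < 1e-12))
    # a hot voxel on a sample point's search segment dominates its TAC
    pt <- grid@points[1, ]
    rMid <- grid@radii[which.min(abs(grid@radii * 4 -
        (spec@epicardialRadius + spec@endocardialRadius) / 2))]
    x <- round(pt$cx + rMid * cos(pt$theta * pi / 180))
    y <- round(pt$cy + rMid * sin(pt$theta * pi / 180))
    z <- round(pt$z)
    hot <- array(0, c(d, 3))
    hot[x, y, z, ] <- c(3, 7, 5)
    hs <- new("GatedImageSeries", data = hot, voxelSize = 4,
              provenance = list())
    tacH <- sampleMyocardium(hs, grid)
    # the nearest point's curve follows the voxel's bin values up to the
    # fixed interpolation weight of its off-node position
    expect_equal(tacH[1, ] / max(tacH[1, ]), c(3, 7, 5) / 7,
                 tolerance = 1e-9)
})

test_that("sector delays in the phantom shift sampled phases accordingly", {
    spec <- tinySpec(sectorDelay = c(0, 0, 60, 0, 0, 0))
    B <- 8
    frames <- vapply(360 * (seq_len(B) - 0.5) / B,
                     function(ph) phantomFrame(spec, ph),
                     array(0, spec@gridShape))
    ser <- new("GatedImageSeries", data = frames, voxelSize = 4,
               provenance = list())
    grid <- midWallSamplingGrid(spec)
    fits <- fitFFH(sampleMyocardium(ser, grid))
    mp <- sectorMeanPhases(fits, grid, 6)
    # delayed sector lags the others by the programmed 60 degrees
    ref <- circMean(mp[-3])
    expect_lt(abs((mp[3] - ref) %% 360 - 60), 3)
})

test_that("the full phase analysis pipeline runs and respects its contracts", {
    spec <- tinySpec(sectorDelay = c(0, 30, 60, 90, 0, 0))
    B <- 8
    frames <- vapply(360 * (seq_len(B) - 0.5) / B,
                     function(ph) phantomFrame(spec, ph),
                     array(0, spec@gridShape))
    ser <- new("GatedImageSeries", data = frames, voxelSize = 4,
               provenance = list())
    grid <- midWallSamplingGrid(spec)
    res <- phaseAnalysis(ser, grid)
    expect_s4_class(res, "PhaseAnalysisResult")
    expect_equal(sum(phaseHistogramCounts(res)), length(retainedPhases(res)))
    expect_gte(phaseBandwidth(res), 60)   # spans the programmed delays
})
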