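test_that("zero-variance RR series gives identical beats", {
    b <- generateRRSeries(1.0, 0.0, 10.0, seed = 1)
    expect_length(rrIntervals(b), 10L)
    expect_true(all(rrIntervals(b) == 1.0))
    expect_equal(triggerTimes(b), 0:9)
})

test_that("RR series sample moments match the requested distribution", {
    # tolerance from a Monte-Carlo oracle: for n ~ 1000 i.i.d. N(1, 0.1)
    # draws the SE of the mean is ~0.003 and of the SD ~0.002, so 0.01
    # bounds both at > 3 sigma
    b <- generateRRSeries(1.0, 0.1, 1000.0, seed = 42)
    rr <- rrIntervals(b)
    expect_gt(length(rr), 900L)
    expect_lt(abs(mean(rr) - 1.0), 0.01)
    expect_lt(abs(sd(rr) - 0.1), 0.01)
    expect_true(all(rr >= 0.3))
    # identical seed reproduces the series bit for bit
    expect_identical(rrIntervals(generateRRSeries(1.0, 0.1, 1000.0, seed = 42)), rr)
})

test_that("RR series rejects invalid parameters", {
    expect_error(generateRRSeries(0.0, 0.1, 10.0), "meanRR")
    expect_error(generateRRSeries(1.0, 0.1, 0.5), "totalTime")
    expect_error(generateRRSeries(1.0, -0.1, 10.0), "sdRR")
})

test_that("wall counts are minimal at end-diastole and maximal at end-systole", {
    spec <- tinySpec()
    totals <- vapply(seq(0, 350, by = 10),
                     function(ph) sum(phantomFrame(spec, ph)), numeric(1))
    expect_equal(which.min(totals), 1L)          # phase 0
    expect_equal(which.max(totals), 19L)         # phase 180
    # monotone rise to the peak for a synchronous wall
    expect_true(all(diff(totals[1:19]) > 0))
})

test_that("a delayed sector's count-phase curve is the reference curve shifted", {
    delay <- 90
    spec <- tinySpec(sectorDelay = c(0, 0, delay, 0, 0, 0))
    g <- gatedSPECT:::phantomGridCache(spec)
    phases <- seq(0, 359, by = 1)
    sectorSum <- function(ph, s) {
        f <- phantomFrame(spec, ph)
        sum(f[g$sector == s & g$r <= spec@epicardialRadius &
              g$r >= spec@endocardialRadius - 3 &
              g$z >= spec@zExtent[1] & g$z <= spec@zExtent[2]])
    }
    ref <- vapply(phases, sectorSum, numeric(1), s = 1L)
    del <- vapply(phases, sectorSum, numeric(1), s = 3L)
    # peak of the delayed sector lags by the programmed delay
    lag <- (phases[which.max(del)] - phases[which.max(ref)]) %% 360
    expect_equal(lag, delay)
})

test_that("phantom spec validity catches inconsistent parameters", {
    expect_error(lvPhantomSpec(endocardialRadius = 31), "endocardialRadius")
    expect_error(lvPhantomSpec(contractionFraction = 1), "contractionFraction")
    expect_error(lvPhantomSpec(sectorDelay = rep(400, 6)), "delays")
})

test_that("static zero-HRV acquisition fills all bins equally", {
    spec <- tinySpec(contractionFraction = 0)
    model <- tinyModel()
    # RR exactly nBins * Delta and dwell an integer number of beats:
    # every (angle, bin) sees exactly dwell/8 seconds
    beats <- generateRRSeries(0.8, 0.0, 16 * 4.8 + 2, seed = 1)
    sim <- simulateGatedSinogram(spec, beats, model, gateConfig(),
                                 dwellTime = 4.8, seed = 2)
    expect_equal(sim$tau, matrix(4.8 / 8, 16, 8), tolerance = 1e-9)
    lamBinTotals <- apply(sim$lambda, 2, sum)
    expect_equal(max(abs(lamBinTotals / lamBinTotals[1] - 1)), 0,
                 tolerance = 1e-9)
    # AR of expected counts is 100%
    expect_equal(activityRatio(lamBinTotals), 100, tolerance = 1e-6)
})

test_that("heart-rate variability starves the last bin of acquisition time", {
    spec <- tinySpec()
    model <- tinyModel()
    beats <- generateRRSeries(0.9, 0.09, 16 * 5 + 2, seed = 3)
    sim <- simulateGatedSinogram(spec, beats, model, gateConfig(),
                                 dwellTime = 5, seed = 4)
    expect_lt(sum(sim$tau[, 8]), sum(sim$tau[, 1]))
    # brute-force beat-by-beat oracle for the integrated activity per
    # (angle, bin): re-derive beat windows, acceptance, overlaps and
    # midpoint frames independently of the simulator's accumulation
    acc <- acceptBeats(beats, gateConfig())
    delta <- binLength(acc)
    tt <- triggerTimes(beats); rr <- rrIntervals(beats)
    L <- length(projectionAngles(model))
    oracle <- matrix(0, L, 8)
    tauOracle <- matrix(0, L, 8)
    for (i in seq_along(rr)) {
        l <- floor(tt[i] / 5) + 1
        if (l > L || !acceptedBeats(acc)[i]) next
        for (b in 1:8) {
            dur <- max(0, min(b * delta, rr[i]) - (b - 1) * delta)
            if (dur <= 0) next
            mid <- (b - 1) * delta + dur / 2
            fr <- phantomFrame(spec, mid / rr[i] * 360)
            oracle[l, b] <- oracle[l, b] +
                dur * sum(forwardProject(fr, l, model))
            tauOracle[l, b] <- tauOracle[l, b] + dur
        }
    }
    expect_equal(apply(sim$lambda, c(1, 2), sum), oracle, tolerance = 1e-6)
    expect_equal(sim$tau, tauOracle, tolerance = 1e-12)
})

test_that("simulation is deterministic under a fixed seed", {
    spec <- tinySpec()
    model <- tinyModel()
    beats <- generateRRSeries(0.9, 0.05, 16 * 5 + 2, seed = 5)
    s1 <- simulateGatedSinogram(spec, beats, model, gateConfig(), 5, seed = 6)
    s2 <- simulateGatedSinogram(spec, beats, model, gateConfig(), 5, seed = 6)
    expect_identical(counts(s1$sinogram), counts(s2$sinogram))
    expect_identical(s1$tau, s2$tau)
    expect_identical(imageData(s1$truth), imageData(s2$truth))
})

test_that("simulator rejects a dwell shorter than one beat", {
    spec <- tinySpec()
    model <- tinyModel()
    beats <- generateRRSeries(0.9, 0.0, 90, seed = 1)
    expect_error(simulateGatedSinogram(spec, beats, model, gateConfig(),
                                       dwellTime = 0.5),
                 "dwell")
})
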