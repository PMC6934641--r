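test_that("beat acceptance follows the single-pass mean window", {
    # hand arithmetic: mean of [1, 1, 1, 0.7] is 0.925, +/-20% window is
    # [0.74, 1.11], so the 0.7 s beat is rejected
    acc <- acceptBeats(c(1, 1, 1, 0.7), gateConfig())
    expect_equal(acceptedBeats(acc), c(TRUE, TRUE, TRUE, FALSE))
    expect_equal(acc@meanAcceptedRR, 1.0)
    expect_equal(binLength(acc), 0.125)
})

test_that("identical beats are all accepted with zero variability", {
    acc <- acceptBeats(rep(0.9, 20), gateConfig())
    expect_true(all(acceptedBeats(acc)))
    expect_equal(sdRRNormalized(acc), 0)
})

test_that("accepted-beat statistics satisfy the ratio identity", {
    # the normalized SD must equal SD/mean of the accepted beats on any
    # input (the consistency that links a normalized SD of 0.011 to
    # 9.1 ms at a mean accepted R-R of ~827 ms)
    set.seed(11)
    for (k in 1:20) {
        rr <- rnorm(50, runif(1, 0.6, 1.2), runif(1, 0, 0.15))
        rr <- pmax(rr, 0.2)
        acc <- acceptBeats(rr, gateConfig())
        kept <- rr[acceptedBeats(acc)]
        expect_equal(acc@sdRRNormalized * acc@meanAcceptedRR,
                     acc@sdAcceptedRR, tolerance = 1e-12)
        expect_equal(acc@meanAcceptedRR, mean(kept), tolerance = 1e-12)
        if (length(kept) > 1)
            expect_equal(acc@sdAcceptedRR, sd(kept), tolerance = 1e-12)
    }
    expect_error(acceptBeats(0.9), "two beats")
})

test_that("acquisition-time maps follow interval-overlap arithmetic", {
    # exact multiples fill every bin
    expect_equal(computeTau(list(1.0), 0.125, 8), matrix(0.125, 1, 8))
    # a short beat truncates only the last bin
    expect_equal(computeTau(list(0.95), 0.125, 8),
                 matrix(c(rep(0.125, 7), 0.075), 1), tolerance = 1e-12)
    # an over-length beat discards time beyond the last bin
    expect_equal(computeTau(list(1.1), 0.125, 8), matrix(0.125, 1, 8))
    # accumulation over beats and the total-time identity
    rr <- c(0.8, 0.95, 1.3, 1.0)
    tau <- computeTau(list(rr), 0.125, 8)
    expect_equal(sum(tau), sum(pmin(rr, 8 * 0.125)), tolerance = 1e-12)
    expect_true(all(diff(as.vector(tau)) <= 1e-12))  # non-increasing in b
})

test_that("event binning respects bin edges and beat acceptance", {
    rr <- c(1, 1, 1.1, 0.7)
    beats <- new("BeatSeries", rrIntervals = rr,
                 triggerTimes = cumsum(c(0, rr[-4])), seed = 1L)
    acc <- acceptBeats(beats, gateConfig())   # 0.7 s beat rejected
    expect_equal(acceptedBeats(acc), c(TRUE, TRUE, TRUE, FALSE))
    delta <- binLength(acc)                   # mean(1, 1, 1.1)/8
    ev <- data.frame(
        time = c(0.0,                # left edge -> bin 1
                 7.5 * delta,        # -> bin 8
                 2 + 1.05,           # beat 3: elapsed beyond 8 * delta -> dropped
                 3.1 + 0.1),         # inside rejected beat -> dropped
        u = 1L, v = 1L, angle = 1L)
    suppressMessages(
        sino <- binEvents(ev, beats, acc, gateConfig(), nAngles = 1,
                          nU = 1, nV = 1))
    cnt <- counts(sino)
    expect_equal(sum(cnt), 2L)
    expect_equal(cnt[1, 1, 1, 1], 1L)
    expect_equal(cnt[1, 8, 1, 1], 1L)
    expect_message(binEvents(ev, beats, acc, gateConfig(), 1, 1, 1),
                   "discarded 2")
})

test_that("last-bin thinning hits its target and leaves other bins alone", {
    set.seed(7)
    cnt <- array(0L, c(2, 8, 4, 3))
    cnt[] <- as.integer(rpois(length(cnt), 200))
    sino <- new("GatedSinogram", counts = cnt, angles = c(0, 90), binSize = 4)
    tau <- matrix(0.6, 2, 8)
    cur <- sum(cnt[, 8, , ]) / mean(apply(cnt[, 1:5, , ], 2, sum))
    # target equal to current ratio: p = 1, nothing changes
    same <- thinLastBin(sino, tau, cur, seed = 1)
    expect_identical(counts(same$sinogram), cnt)
    expect_equal(same$tau, tau)
    # halving: binomial oracle puts the retained total within 3 sigma
    th <- thinLastBin(sino, tau, cur / 2, seed = 2)
    n <- sum(cnt[, 8, , ])
    expect_lt(abs(sum(counts(th$sinogram)[, 8, , ]) - n / 2),
              3 * sqrt(n * 0.25))
    # bins 1..7 bit-identical
    expect_identical(counts(th$sinogram)[, 1:7, , ], cnt[, 1:7, , ])
    # tau scaling contract
    expect_equal(th$tau[, 8], tau[, 8] * th$p, tolerance = 1e-12)
    expect_equal(th$tau[, 1:7], tau[, 1:7])
    # cannot add counts
    expect_error(thinLastBin(sino, tau, cur * 1.2, seed = 3), "cannot add")
})

test_that("binned event stream matches the simulator expectation (chi-square)", {
    spec <- tinySpec(contractionFraction = 0, wallActivity = 6,
                     backgroundActivity = 0.3)
    model <- tinyModel()
    beats <- generateRRSeries(0.9, 0.04, 4 * 5 + 2, seed = 21)
    geomSmall <- spectGeometry(nAngles = 4L, nU = 24L, nV = 8L,
                               binSize = 4, radius = 100)
    mSmall <- systemModel(geomSmall, cdrModel(), c(24L, 24L, 8L), 4)
    sim <- simulateGatedSinogram(spec, beats, mSmall, gateConfig(), 5,
                                 seed = 22, events = TRUE)
    reb <- suppressMessages(
        binEvents(sim$events, beats, sim$acceptance, gateConfig(),
                  nAngles = 4, nU = 24, nV = 8))
    # independent binning reproduces the simulator's own counts exactly
    expect_identical(counts(reb), counts(sim$sinogram))
    # and the counts are Poisson around lambda: chi-square over
    # (angle, bin) cells with adequate expectation
    obs <- apply(counts(sim$sinogram), c(1, 2), sum)
    lam <- apply(sim$lambda, c(1, 2), sum)
    keep <- lam > 20
    x2 <- sum((obs[keep] - lam[keep])^2 / lam[keep])
    p <- stats::pchisq(x2, df = sum(keep), lower.tail = FALSE)
    expect_gt(p, 0.001)
})

test_that("tau totals equal the accepted-beat time budget per angle", {
    spec <- tinySpec()
    model <- tinyModel()
    beats <- generateRRSeries(0.85, 0.07, 16 * 5 + 2, seed = 31)
    sim <- simulateGatedSinogram(spec, beats, model, gateConfig(), 5, seed = 32)
    acc <- sim$acceptance
    delta <- binLength(acc)
    tt <- triggerTimes(beats); rr <- rrIntervals(beats)
    for (l in c(1, 7, 16)) {
        sel <- floor(tt / 5) + 1 == l & acceptedBeats(acc)
        expect_equal(sum(sim$tau[l, ]), sum(pmin(rr[sel], 8 * delta)),
                     tolerance = 1e-9)
    }
})
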