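test_that("the EM update has its scalar closed form on a one-voxel system", {
    # single voxel, single angle, no blur: H = [tau * p] with p = 1, so one
    # update from any positive start lands on f = c / (tau * p)
    m <- microModel("tosem")
    g <- array(10, c(1, 1, 1))
    for (f0 in c(0.1, 1, 7)) {
        f <- osemUpdate(array(f0, c(1, 1, 1)), 1L, g, m, tau = 2)
        expect_equal(as.numeric(f), 5, tolerance = 1e-12)
    }
    # OSEM ignores tau: fixed point is c / p = 10
    fo <- osemUpdate(array(3, c(1, 1, 1)), 1L, g, microModel("osem"))
    expect_equal(as.numeric(fo), 10, tolerance = 1e-12)
})

test_that("an exactly consistent image is a fixed point of the update", {
    m <- tinyModel()
    # interior-supported truth: every positive voxel is seen by every subset
    f <- phantomFrame(tinySpec(backgroundActivity = 0), 120)
    g <- projectAll(f, m)
    cfg <- reconConfig(nSubsets = 4L)
    sched <- gatedSPECT:::subsetSchedule(16L, cfg)
    upd <- f
    for (sub in sched) upd <- osemUpdate(upd, sub, g, m, cfg = cfg)
    expect_lt(max(abs(upd - f)), 1e-10 * max(f))
})

test_that("all-zero projections drive the image to zero in one iteration", {
    m <- tinyModel()
    g <- array(0, c(16, 24, 8))
    f <- reconstructBin(g, m, cfg = reconConfig(nIterations = 1L,
                                                nSubsets = 4L))
    expect_true(all(f == 0))
})

test_that("negative counts are rejected", {
    m <- tinyModel()
    g <- array(-1, c(16, 24, 8))
    expect_error(osemUpdate(array(1, c(24, 24, 8)), 1L, g, m), "negative")
})

test_that("TOSEM with unit times equals OSEM; constant times rescale exactly", {
    mo <- tinyModel("osem")
    mt <- tinyModel("tosem")
    set.seed(41)
    f <- phantomFrame(tinySpec(), 200)
    g <- projectAll(f, mo)
    g[] <- rpois(length(g), g * 3)
    cfg <- reconConfig(nIterations = 3L, nSubsets = 4L)
    fo <- reconstructBin(g, mo, cfg = cfg)
    ft1 <- reconstructBin(g, mt, tau = rep(1, 16), cfg = cfg)
    ft2 <- reconstructBin(g, mt, tau = rep(2, 16), cfg = cfg)
    expect_lt(max(abs(fo - ft1)), 1e-10)
    expect_lt(max(abs(ft2 - fo / 2)), 1e-8 * max(fo))
})

test_that("MLEM increases the Poisson likelihood and conserves counts", {
    m <- tinyModel()
    spec <- tinySpec()
    fTrue <- phantomFrame(spec, 90)
    set.seed(43)
    g <- projectAll(fTrue, m)
    gNoisy <- g
    gNoisy[] <- rpois(length(g), g)
    cfg <- reconConfig(nIterations = 1L, nSubsets = 1L)
    sched <- gatedSPECT:::subsetSchedule(16L, cfg)
    f <- array(1, c(24, 24, 8))
    ll <- poissonLogLik(f, gNoisy, m)
    for (it in 1:50) {
        f <- osemUpdate(f, sched[[1]], gNoisy, m, cfg = cfg)
        llNew <- poissonLogLik(f, gNoisy, m)
        expect_gte(llNew, ll - 1e-9 * abs(ll))
        ll <- llNew
        expect_true(all(f >= 0))
    }
    # noiseless system at (near) convergence conserves total counts
    f2 <- reconstructBin(g, m, cfg = reconConfig(nIterations = 60L,
                                                 nSubsets = 1L))
    expect_equal(sum(projectAll(f2, m)), sum(g), tolerance = 1e-3)
})

test_that("TOSEM equalises per-bin totals that OSEM leaves shortened", {
    # static phantom, last bin thinned to half: the time-modified
    # reconstruction compensates the missing acquisition time
    spec <- tinySpec(contractionFraction = 0, wallActivity = 10,
                     backgroundActivity = 0.5)
    mo <- tinyModel("osem"); mt <- tinyModel("tosem")
    beats <- generateRRSeries(0.8, 0, 16 * 4.8 + 2, seed = 51)
    sim <- simulateGatedSinogram(spec, beats, mo, gateConfig(), 4.8,
                                 seed = 52)
    th <- thinLastBin(sim$sinogram, sim$tau, 0.5, seed = 53)
    cfg <- reconConfig(nIterations = 5L, nSubsets = 4L)
    so <- reconstructSeries(th$sinogram, NULL, mo, cfg)
    st <- reconstructSeries(th$sinogram, th$tau, mt, cfg)
    to <- binTotals(so); tt <- binTotals(st)
    expect_lt(abs(to[8] / mean(to[1:5]) - 0.5), 0.05)
    expect_lt(abs(tt[8] / mean(tt[1:5]) - 1.0), 0.05)
    # a one-bin series is just reconstructBin
    one <- new("GatedSinogram",
               counts = counts(sim$sinogram)[, 1, , , drop = FALSE],
               angles = sim$sinogram@angles, binSize = 4)
    s1 <- reconstructSeries(one, sim$tau[, 1, drop = FALSE], mt, cfg)
    direct <- reconstructBin(
        array(as.numeric(counts(one)[, 1, , ]), c(16, 24, 8)), mt,
        tau = sim$tau[, 1], cfg = cfg)
    expect_equal(imageData(s1)[, , , 1], direct)
})

test_that("an empty bin is an error for TOSEM, not silent zeros", {
    mt <- tinyModel("tosem")
    g <- array(0, c(16, 24, 8))
    expect_error(reconstructBin(g, mt, tau = rep(0, 16)), "unrecoverable")
})

test_that("angle count must divide by the subset count", {
    m <- tinyModel()
    g <- array(1, c(16, 24, 8))
    expect_error(reconstructBin(g, m, cfg = reconConfig(nSubsets = 5L)),
                 "divisible")
})

test_that("post-processing smooths, conserves interior mass and masks", {
    d <- c(24L, 24L, 8L)
    imp <- array(0, c(d, 2))
    # impulse more than one kernel width from every face, so no mirror
    # fold reaches it and mass is conserved exactly
    imp[12, 12, 5, 1] <- 1
    imp[12, 12, 5, 2] <- 1
    imp[2, 2, 1, 2] <- 5          # hot blob outside the mask
    ser <- new("GatedImageSeries", data = imp, voxelSize = 4,
               provenance = list())
    # sigma 0 and no mask: identity
    expect_identical(imageData(postprocessSeries(ser, 0))[, , , 1],
                     imp[, , , 1])
    # interior impulse: total preserved, peak equals the discrete 3-D
    # kernel normalisation constant
    sm <- imageData(postprocessSeries(ser, 1))[, , , 1]
    expect_equal(sum(sm), 1, tolerance = 1e-6)
    w <- exp(-(-3:3)^2 / 2); w <- w / sum(w)
    expect_equal(max(sm), w[4]^3, tolerance = 1e-9)
    expect_equal(which(sm == max(sm)),
                 12L + (12L - 1L) * 24L + (5L - 1L) * 24L * 24L)
    # masking zeroes the blob exactly
    mask <- cylindricalMask(d, radius = 8, zRange = c(2, 7))
    pm <- imageData(postprocessSeries(ser, 1, mask))[, , , 2]
    expect_equal(pm[2, 2, 1], 0)
    expect_error(postprocessSeries(ser, 1, array(FALSE, d)), "mask")
})

test_that("reconstruction is deterministic", {
    m <- tinyModel()
    set.seed(61)
    g <- array(rpois(16 * 24 * 8, 20), c(16, 24, 8))
    cfg <- reconConfig(nIterations = 2L, nSubsets = 4L)
    expect_identical(reconstructBin(g, m, cfg = cfg),
                     reconstructBin(g, m, cfg = cfg))
})
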