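#' Construct a beating LV phantom specification
#'
#' Defaults describe a desk-scale short-axis left ventricle: a 48 x 48 x 16
#' grid of 4 mm voxels with an 8 mm thick end-diastolic wall (epicardial
#' radius 30 mm) that thickens by up to 30% at end-systole.  The wall is
#' divided into angular sectors; giving a sector a positive
#' \code{sectorDelay} postpones its peak thickening by that many degrees of
#' the cardiac cycle, emulating regionally delayed contraction.
#'
#' @param gridShape integer(3), voxels along x, y, z.
#' @param voxelSize voxel edge in mm.
#' @param epicardialRadius epicardial radius in mm.
#' @param endocardialRadius end-diastolic endocardial radius in mm.
#' @param wallActivity expected counts/s/voxel at end-diastolic thickness.
#' @param backgroundActivity counts/s/voxel outside the wall.
#' @param contractionFraction peak fractional wall thickening, in [0, 1).
#' @param nSectors number of angular sectors.
#' @param sectorDelay per-sector delay in degrees of cardiac cycle.
#' @param zExtent integer(2), axial slice range containing the wall.
#' @return An [LVPhantomSpec-class].
#' @examples
#' spec <- lvPhantomSpec(sectorDelay = c(0, 0, 45, 45, 0, 0))
#' @export
lvPhantomSpec <- function(gridShape = c(48L, 48L, 16L), voxelSize = 4,
                          epicardialRadius = 30, endocardialRadius = 22,
                          wallActivity = 2, backgroundActivity = 0.1,
                          contractionFraction = 0.3, nSectors = 6L,
                          sectorDelay = rep(0, nSectors),
                          zExtent = c(4L, 13L)) {
    new("LVPhantomSpec", gridShape = as.integer(gridShape),
        voxelSize = voxelSize, epicardialRadius = epicardialRadius,
        endocardialRadius = endocardialRadius, wallActivity = wallActivity,
        backgroundActivity = backgroundActivity,
        contractionFraction = contractionFraction,
        nSectors = as.integer(nSectors), sectorDelay = as.numeric(sectorDelay),
        zExtent = as.integer(zExtent))
}

#' Simulate an R-R interval series
#'
#' Beats are drawn i.i.d. from a Gaussian truncated below at 0.3 times the
#' mean (non-physical ultra-short beats are rejected and redrawn) and
#' appended until the cumulative time reaches \code{totalTime}.
#'
#' @param meanRR mean R-R interval in seconds (> 0).
#' @param sdRR R-R standard deviation in seconds (>= 0).
#' @param totalTime minimum cumulative duration in seconds (> meanRR).
#' @param seed integer seed; identical seed gives an identical series.
#' @return A [BeatSeries-class].
#' @examples
#' beats <- generateRRSeries(1.0, 0.05, 60, seed = 1)
#' @export
generateRRSeries <- function(meanRR, sdRR, totalTime, seed = 1L) {
    if (!is.finite(meanRR) || meanRR <= 0)
        stop("meanRR must be positive")
    if (!is.finite(sdRR) || sdRR < 0)
        stop("sdRR must be non-negative")
    if (!is.finite(totalTime) || totalTime <= meanRR)
        stop("totalTime must exceed meanRR")
    set.seed(as.integer(seed))
    lower <- 0.3 * meanRR
    rr <- numeric(0)
    total <- 0
    while (total < totalTime) {
        n <- max(16L, ceiling((totalTime - total) / meanRR) + 8L)
        draw <- rnorm(n, meanRR, sdRR)
        while (any(bad <- draw < lower))
            draw[bad] <- rnorm(sum(bad), meanRR, sdRR)
        cum <- total + cumsum(draw)
        keep <- which(cum - draw < totalTime)  # beats starting before totalTime
        rr <- c(rr, draw[keep])
        total <- total + sum(draw[keep])
        if (length(keep) < n) break
    }
    new("BeatSeries", rrIntervals = rr,
        triggerTimes = cumsum(c(0, rr[-length(rr)])), seed = as.integer(seed))
}

#' Render one frame of the beating LV phantom
#'
#' Local wall thickness at cycle phase theta in sector s is
#' \deqn{t(\theta, s) = t_{ED} (1 + c \, (1 - \cos(\theta - \delta_s))/2)}
#' with \code{c} the contraction fraction and \code{delta_s} the sector
#' delay; the wall thickens inward (fixed epicardium) and voxel activity is
#' proportional to local thickness, so wall counts are minimal at
#' end-diastole (phase 0 for an undelayed sector) and peak at end-systole.
#'
#' @param spec an [LVPhantomSpec-class].
#' @param phase cardiac cycle phase in degrees, [0, 360).
#' @return numeric array \code{[x, y, z]} of activity rates
#'   (counts/s/voxel).
#' @examples
#' ed <- phantomFrame(lvPhantomSpec(), 0)    # end-diastole
#' es <- phantomFrame(lvPhantomSpec(), 180)  # end-systole
#' sum(es) > sum(ed)
#' @export
phantomFrame <- function(spec, phase) {
    stopifnot(is(spec, "LVPhantomSpec"))
    if (!is.finite(phase)) stop("phase must be finite")
    phase <- phase %% 360
    geomc <- phantomGridCache(spec)
    tED <- spec@epicardialRadius - spec@endocardialRadius
    tSec <- tED * (1 + spec@contractionFraction *
                   (1 - cos((phase - spec@sectorDelay) * pi / 180)) / 2)
    rEndoSec <- spec@epicardialRadius - tSec
    vol <- array(spec@backgroundActivity, spec@gridShape)
    inZ <- geomc$z >= spec@zExtent[1L] & geomc$z <= spec@zExtent[2L]
    wall <- inZ & geomc$r <= spec@epicardialRadius &
        geomc$r >= rEndoSec[geomc$sector]
    vol[wall] <- spec@wallActivity * (tSec / tED)[geomc$sector[wall]]
    vol
}

# Voxel-centre radius/sector/z lookup, cached per spec geometry.
phantomGridCache <- local({
    cache <- new.env(parent = emptyenv())
    function(spec) {
        key <- paste(c(spec@gridShape, spec@voxelSize, spec@nSectors),
                     collapse = "_")
        if (!is.null(cache[[key]])) return(cache[[key]])
        nx <- spec@gridShape[1L]; ny <- spec@gridShape[2L]
        nz <- spec@gridShape[3L]
        cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
        xs <- ((1:nx) - cx) * spec@voxelSize
        ys <- ((1:ny) - cy) * spec@voxelSize
        x <- array(xs, c(nx, ny, nz))
        y <- array(rep(ys, each = nx), c(nx, ny, nz))
        z <- array(rep(1:nz, each = nx * ny), c(nx, ny, nz))
        theta <- (atan2(y, x) * 180 / pi) %% 360
        sector <- pmin(spec@nSectors,
                       floor(theta / (360 / spec@nSectors)) + 1L)
        out <- list(r = sqrt(x^2 + y^2), sector = sector, z = z)
        cache[[key]] <- out
        out
    }
})

#' Simulate a noisy ECG-gated sinogram
#'
#' Emulates a step-and-shoot gated acquisition: the camera dwells
#' \code{dwellTime} seconds at each projection angle, consuming a fresh
#' contiguous stretch of the beat series (beats are assigned to the angle
#' whose dwell window contains their R trigger).  Fixed forward gating with
#' a global bin length (mean accepted R-R / nBins) is applied; for every
#' accepted beat, each (beat x bin) overlap contributes its duration times
#' the forward projection of the phantom at the overlap's midpoint cardiac
#' phase (midpoint quadrature), with within-beat phase equal to
#' elapsed/RR x 360 degrees.  Observed counts are Poisson draws around the
#' accumulated expectation.
#'
#' The heart completes one cycle per beat while gating bins have fixed
#' length, so beats shorter than the mean leave the last bin(s) partly
#' unfilled: this is the heart-rate-variability data-shortage mechanism, and
#' the returned acquisition-time map records the exact integrated seconds
#' per (angle, bin).
#'
#' @param spec an [LVPhantomSpec-class].
#' @param beats a [BeatSeries-class] covering at least
#'   \code{length(angles) * dwellTime} seconds.
#' @param model a [SystemModel-class] whose grid matches the phantom.
#' @param gate a [GateConfig-class].
#' @param dwellTime seconds of acquisition per projection angle.
#' @param seed integer seed for the Poisson noise.
#' @param events if TRUE, also return a list-mode event stream (time,
#'   detector u, v, angle) and derive the counts from it; intended for
#'   small fixtures.
#' @param noise if FALSE, return rounded expected counts instead of Poisson
#'   draws (the expectation is also always returned as \code{lambda}).
#' @return list with elements \code{sinogram} ([GatedSinogram-class]),
#'   \code{tau} (angle x bin matrix of acquisition seconds), \code{truth}
#'   (time-averaged ground-truth [GatedImageSeries-class], one volume per
#'   bin), \code{acceptance} ([AcceptanceResult-class]), \code{lambda}
#'   (expected counts array) and optionally \code{events}.
#' @export
simulateGatedSinogram <- function(spec, beats, model, gate = gateConfig(),
                                  dwellTime = 10, seed = 1L,
                                  events = FALSE, noise = TRUE) {
    stopifnot(is(spec, "LVPhantomSpec"), is(beats, "BeatSeries"),
              is(model, "SystemModel"), is(gate, "GateConfig"))
    rr <- beats@rrIntervals
    if (dwellTime < mean(rr))
        stop("dwell time shorter than one beat")
    L <- length(model@geometry@angles)
    if (beats@triggerTimes[length(rr)] + rr[length(rr)] < L * dwellTime - 1e-9)
        stop("beat series shorter than the acquisition (need L * dwellTime seconds)")
    acc <- acceptBeats(beats, gate)
    delta <- acc@binLength
    B <- gate@nBins
    nU <- model@geometry@nU; nV <- model@geometry@nV
    lambda <- array(0, c(L, B, nU, nV))
    tau <- matrix(0, L, B)
    truthNum <- array(0, c(spec@gridShape, B))
    truthDen <- numeric(B)
    # beats are assigned to the angle whose dwell window contains their R
    # trigger; beats triggered after the acquisition end are ignored
    angleOfBeat <- floor(beats@triggerTimes / dwellTime) + 1L
    evt <- if (events) list() else NULL
    if (events) set.seed(as.integer(seed))
    for (l in seq_len(L)) {
        idx <- which(angleOfBeat == l & acc@accepted)
        # duration-weighted activity accumulated per bin at this angle; the
        # projector is linear, so one projection per (angle, bin) suffices
        accum <- array(0, c(spec@gridShape, B))
        for (i in idx) {
            RR <- rr[i]
            for (b in seq_len(B)) {
                lo <- (b - 1) * delta
                hi <- min(b * delta, RR)
                if (hi <= lo) break
                dur <- hi - lo
                mid <- (lo + hi) / 2
                frame <- phantomFrame(spec, mid / RR * 360)
                accum[, , , b] <- accum[, , , b] + dur * frame
                tau[l, b] <- tau[l, b] + dur
                truthDen[b] <- truthDen[b] + dur
                if (events) {
                    proj <- forwardProject(frame, l, model)
                    n <- rpois(length(proj), dur * proj)
                    tot <- sum(n)
                    if (tot > 0) {
                        uv <- arrayInd(rep.int(seq_along(n), n), c(nU, nV))
                        evt[[length(evt) + 1L]] <- data.frame(
                            time = beats@triggerTimes[i] + runif(tot, lo, hi),
                            u = uv[, 1L], v = uv[, 2L], angle = l)
                    }
                }
            }
        }
        for (b in seq_len(B)) {
            if (tau[l, b] > 0)
                lambda[l, b, , ] <- forwardProject(accum[, , , b], l, model)
        }
        truthNum <- truthNum + accum
    }
    if (events) {
        ev <- if (length(evt)) do.call(rbind, evt)
              else data.frame(time = numeric(0), u = integer(0),
                              v = integer(0), angle = integer(0))
        ev <- ev[order(ev$time), , drop = FALSE]
        rownames(ev) <- NULL
        # counts derived from the drawn events so that event-level and
        # bin-level views are identical
        cnt <- eventCountArray(ev, beats, acc, gate, L, nU, nV)
    } else {
        set.seed(as.integer(seed))
        cnt <- if (noise) array(rpois(length(lambda), lambda), dim(lambda))
               else round(lambda)
        storage.mode(cnt) <- "integer"
    }
    truth <- truthNum
    for (b in seq_len(B))
        if (truthDen[b] > 0) truth[, , , b] <- truthNum[, , , b] / truthDen[b]
    out <- list(
        sinogram = new("GatedSinogram", counts = cnt,
                       angles = model@geometry@angles,
                       binSize = model@geometry@binSize),
        tau = tau,
        truth = new("GatedImageSeries", data = truth,
                    voxelSize = spec@voxelSize,
                    provenance = list(mode = "truth", seed = as.integer(seed))),
        acceptance = acc,
        lambda = lambda)
    if (events) out$events <- ev
    out
}

# Bin a simulated event stream back into a counts array (internal; the
# exported event binning lives in the gating module).
eventCountArray <- function(ev, beats, acc, gate, L, nU, nV) {
    B <- gate@nBins
    cnt <- array(0L, c(L, B, nU, nV))
    if (is.null(ev) || nrow(ev) == 0L) return(cnt)
    beat <- findInterval(ev$time, beats@triggerTimes)
    elapsed <- ev$time - beats@triggerTimes[beat]
    b <- floor(elapsed / acc@binLength) + 1L
    ok <- beat >= 1L & acc@accepted[beat] & b <= B
    tab <- table(factor(ev$angle[ok], levels = seq_len(L)),
                 factor(b[ok], levels = seq_len(B)),
                 factor(ev$u[ok], levels = seq_len(nU)),
                 factor(ev$v[ok], levels = seq_len(nV)))
    cnt[] <- as.integer(tab)
    cnt
}
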