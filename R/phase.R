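#' Mid-wall myocardial sampling grid
#'
#' Places \code{nTheta x nZ} sample points on the LV mid-wall (the
#' phantom's wall surfaces are known analytically, so no surface detection
#' is needed) and attaches a common radial search segment spanning the wall
#' with a small margin; activity at a point is later taken as the maximum
#' interpolated value along its segment (max-count sampling).
#'
#' @param spec the [LVPhantomSpec-class] the series was generated from (or
#'   any spec describing where the wall sits in an externally supplied
#'   series).
#' @param nTheta angular samples (default 36).
#' @param nZ axial samples (default 12), spread over the wall's axial
#'   extent with half-slice margins.
#' @param marginMM radial search margin beyond the wall surfaces, mm.
#' @param stepMM radial search step, mm.
#' @return A [SamplingGrid-class].
#' @export
midWallSamplingGrid <- function(spec, nTheta = 36L, nZ = 12L, marginMM = 2,
                                stepMM = 1) {
    stopifnot(is(spec, "LVPhantomSpec"))
    if (nTheta * nZ > 1008L) stop("at most 1008 sample points supported")
    v <- spec@voxelSize
    tMax <- (spec@epicardialRadius - spec@endocardialRadius) *
        (1 + spec@contractionFraction)
    rIn <- max(0, spec@epicardialRadius - tMax - marginMM) / v
    rOut <- (spec@epicardialRadius + marginMM) / v
    radii <- seq(rIn, rOut, by = stepMM / v)
    theta <- 360 * (seq_len(nTheta) - 0.5) / nTheta
    z <- seq(spec@zExtent[1L] + 0.5, spec@zExtent[2L] - 0.5, length.out = nZ)
    pts <- expand.grid(theta = theta, z = z)
    pts$cx <- (spec@gridShape[1L] + 1) / 2
    pts$cy <- (spec@gridShape[2L] + 1) / 2
    new("SamplingGrid", points = pts, radii = radii)
}

# Vectorised trilinear interpolation of a 3-D array at fractional voxel
# coordinates; coordinates are clamped to the valid interpolation box.
trilinear <- function(arr, x, y, z) {
    d <- dim(arr)
    x <- pmin(pmax(x, 1), d[1L] - 1e-9)
    y <- pmin(pmax(y, 1), d[2L] - 1e-9)
    z <- pmin(pmax(z, 1), d[3L] - 1e-9)
    x0 <- pmin(floor(x), d[1L] - 1L); y0 <- pmin(floor(y), d[2L] - 1L)
    z0 <- pmin(floor(z), d[3L] - 1L)
    fx <- x - x0; fy <- y - y0; fz <- z - z0
    at <- function(i, j, k) arr[cbind(i, j, k)]
    (1 - fx) * (1 - fy) * (1 - fz) * at(x0, y0, z0) +
        fx * (1 - fy) * (1 - fz) * at(x0 + 1, y0, z0) +
        (1 - fx) * fy * (1 - fz) * at(x0, y0 + 1, z0) +
        fx * fy * (1 - fz) * at(x0 + 1, y0 + 1, z0) +
        (1 - fx) * (1 - fy) * fz * at(x0, y0, z0 + 1) +
        fx * (1 - fy) * fz * at(x0 + 1, y0, z0 + 1) +
        (1 - fx) * fy * fz * at(x0, y0 + 1, z0 + 1) +
        fx * fy * fz * at(x0 + 1, y0 + 1, z0 + 1)
}

#' Sample myocardial time-activity curves
#'
#' For every sample point and ECG bin, the activity is the maximum
#' trilinearly interpolated value along the point's radial search segment.
#'
#' @param series a [GatedImageSeries-class].
#' @param grid a [SamplingGrid-class] in the same voxel coordinate frame.
#' @return numeric matrix \code{[point, bin]} of time-activity curves.
#' @export
sampleMyocardium <- function(series, grid) {
    stopifnot(is(series, "GatedImageSeries"), is(grid, "SamplingGrid"))
    d <- dim(series@data)
    pts <- grid@points
    nP <- nrow(pts); nR <- length(grid@radii); B <- d[4L]
    ct <- cos(pts$theta * pi / 180); st <- sin(pts$theta * pi / 180)
    x <- outer(ct, grid@radii) + pts$cx     # [point, radius]
    y <- outer(st, grid@radii) + pts$cy
    z <- matrix(pts$z, nP, nR)
    if (any(x < 0.5 | x > d[1L] + 0.5 | y < 0.5 | y > d[2L] + 0.5 |
            z < 0.5 | z > d[3L] + 0.5))
        stop("sampling segment outside the image grid")
    tac <- matrix(0, nP, B)
    for (b in seq_len(B)) {
        vals <- trilinear(series@data[, , , b], as.vector(x), as.vector(y),
                          as.vector(z))
        tac[, b] <- apply(matrix(vals, nP, nR), 1L, max)
    }
    tac
}

#' Fit a first Fourier harmonic to time-activity curves
#'
#' Each K-bin curve is sampled at the bin-centre phases
#' \code{theta_k = 360 (k - 1/2) / K} and modelled as
#' \code{A0 + A1 cos(theta - phi)}; for equispaced samples the discrete
#' Fourier coefficients recover A0, A1 and phi exactly when the curve
#' contains only DC and first-harmonic content.  \code{phi} is the phase of
#' the curve maximum, wrapped to [0, 360).  Constant curves get amplitude 0
#' and an undefined-phase flag.
#'
#' @param tac numeric vector (one curve) or matrix \code{[point, bin]}.
#' @return data.frame with columns \code{a0}, \code{a1}, \code{phase}
#'   (degrees, NA when undefined) and \code{defined}.
#' @examples
#' th <- 360 * (1:8 - 0.5) / 8
#' fitFFH(5 + 2 * cos((th - 90) * pi / 180))
#' @export
fitFFH <- function(tac) {
    if (is.null(dim(tac))) tac <- matrix(tac, 1L)
    K <- ncol(tac)
    if (K < 3L) stop("at least three ECG bins required for an FFH fit")
    th <- 2 * pi * (seq_len(K) - 0.5) / K
    a0 <- rowMeans(tac)
    ca <- (2 / K) * as.vector(tac %*% cos(th))
    sa <- (2 / K) * as.vector(tac %*% sin(th))
    a1 <- sqrt(ca^2 + sa^2)
    tol <- pmax(1e-12, 1e-9 * abs(a0))
    defined <- a1 > tol
    phase <- ifelse(defined, (atan2(sa, ca) * 180 / pi) %% 360, NA_real_)
    # a tiny negative angle can round to exactly 360 under %%; keep [0, 360)
    phase[!is.na(phase) & phase >= 360] <- 0
    data.frame(a0 = a0, a1 = ifelse(defined, a1, 0), phase = phase,
               defined = defined)
}

#' Discard the lowest-amplitude fits
#'
#' Drops the \code{ceiling(fraction * n)} fits with the smallest
#' first-harmonic amplitude.  Undefined-phase (constant-curve) fits are
#' always dropped first and count towards the quota; amplitude ties are
#' broken by sample-point index, lower index dropped first.
#'
#' @param fits data.frame from [fitFFH()].
#' @param fraction fraction to discard (default 0.05).
#' @return the retained subset of \code{fits}.
#' @export
discardLowAmplitude <- function(fits, fraction = 0.05) {
    n <- nrow(fits)
    if (n < 1L) stop("at least one fit required")
    nDrop <- ceiling(fraction * n)
    ord <- order(!fits$defined, -fits$a1, -seq_len(n), decreasing = TRUE)
    drop <- union(which(!fits$defined), ord[seq_len(nDrop)])
    keep <- setdiff(seq_len(n), drop)
    fits[keep, , drop = FALSE]
}

#' Build the 360-bin phase histogram
#'
#' Bin i (1-based) counts phases in \code{[i-1, i)} degrees.
#'
#' @param phases numeric vector of phases in [0, 360).
#' @return integer(360) of counts.
#' @export
phaseHistogram <- function(phases) {
    if (any(!is.finite(phases)) || any(phases < 0 | phases >= 360))
        stop("phases must lie in [0, 360)")
    tabulate(floor(phases) + 1L, nbins = 360L)
}

#' Summarise a phase distribution into dyssynchrony indices
#'
#' BW is the length in degrees of the smallest contiguous circular arc of
#' whole-degree bins containing at least \code{coverage} (default 95%) of
#' the retained samples.  StD is the sample standard deviation of the
#' phases after re-centering each phase into (mu - 180, mu + 180] about the
#' circular mean mu.  ENT is the histogram entropy normalised by
#' log2(360), in percent.
#'
#' @param phases numeric vector of retained phases, degrees in [0, 360).
#' @param coverage BW arc coverage fraction.
#' @return A [PhaseAnalysisResult-class].
#' @examples
#' summarizePhases(c(10, 350))  # StD 14.14 deg
#' @export
summarizePhases <- function(phases, coverage = 0.95) {
    if (length(phases) < 1L) stop("at least one phase required")
    h <- phaseHistogram(phases)
    n <- length(phases)
    # smallest circular window of whole-degree bins with >= coverage * n
    need <- coverage * n - 1e-9
    h2 <- c(h, h)
    cs <- c(0, cumsum(h2))
    bw <- 360L
    for (wlen in seq_len(360L)) {
        if (max(cs[(wlen + 1):(360 + wlen)] - cs[1:360]) >= need) {
            bw <- wlen
            break
        }
    }
    rad <- phases * pi / 180
    mu <- (atan2(sum(sin(rad)), sum(cos(rad))) * 180 / pi) %% 360
    centered <- ((phases - mu + 180) %% 360) - 180  # in (-180, 180]
    centered[centered == -180] <- 180
    stdev <- if (n > 1L) sd(centered) else 0
    p <- h[h > 0] / n
    ent <- 100 * (-sum(p * log2(p))) / log2(360)
    new("PhaseAnalysisResult", phases = as.numeric(phases), histogram = h,
        bw = as.numeric(bw), std = stdev, ent = ent, coverage = coverage)
}

#' Full phase analysis of a gated image series
#'
#' Samples mid-wall time-activity curves, fits first Fourier harmonics,
#' discards the lowest-amplitude fraction and summarises the retained
#' phases into the BW/StD/ENT dyssynchrony indices.
#'
#' @param series a [GatedImageSeries-class] (typically smoothed and
#'   masked).
#' @param grid a [SamplingGrid-class].
#' @param amplitudeCut fraction of lowest-amplitude fits to discard.
#' @param coverage BW arc coverage fraction.
#' @return A [PhaseAnalysisResult-class].
#' @export
phaseAnalysis <- function(series, grid, amplitudeCut = 0.05,
                          coverage = 0.95) {
    tac <- sampleMyocardium(series, grid)
    fits <- fitFFH(tac)
    kept <- discardLowAmplitude(fits, amplitudeCut)
    if (nrow(kept) < 1L) stop("no sample points retained")
    summarizePhases(kept$phase, coverage)
}

#' Per-sector circular mean phases
#'
#' Averages fitted first-harmonic phases within each angular sector of the
#' sampling grid.  Sample points adjacent to a sector boundary can be
#' excluded: reconstruction and smoothing blur activity across boundaries,
#' which biases boundary phases towards the neighbouring sector.
#'
#' @param fits data.frame from [fitFFH()] for the grid's sample points (in
#'   grid order).
#' @param grid the [SamplingGrid-class] the curves were sampled on.
#' @param nSectors number of angular sectors.
#' @param excludeBoundary number of angular sample rings to drop on each
#'   side of every sector boundary (default 1).
#' @return numeric vector of per-sector circular mean phases in degrees,
#'   NA for sectors without defined phases.
#' @export
sectorMeanPhases <- function(fits, grid, nSectors = 6L, excludeBoundary = 1L) {
    th <- grid@points$theta
    width <- 360 / nSectors
    thetaStep <- 360 / length(unique(th))
    margin <- excludeBoundary * thetaStep
    vapply(seq_len(nSectors), function(s) {
        lo <- (s - 1) * width; hi <- s * width
        sel <- th >= lo + margin & th <= hi - margin & fits$defined
        if (!any(sel)) return(NA_real_)
        p <- fits$phase[sel] * pi / 180
        (atan2(mean(sin(p)), mean(cos(p))) * 180 / pi) %% 360
    }, numeric(1L))
}
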