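#' @import methods
#' @importFrom stats rnorm rpois rbinom runif sd cor
#' @importFrom utils head tail
#' @useDynLib gatedSPECT, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Beating left-ventricle phantom specification
#'
#' Describes a short-axis annular LV phantom whose wall thickens through the
#' cardiac cycle.  Regional dyssynchrony is modelled by per-sector phase
#' delays: sector \code{s} reaches peak thickening \code{sectorDelay[s]}
#' degrees of cardiac cycle after the reference sector.  Voxel activity is
#' proportional to local wall thickness, emulating the partial-volume count
#' brightening that phase analysis of perfusion SPECT relies on.
#'
#' @slot gridShape integer(3), voxels along x, y, z.
#' @slot voxelSize numeric(1), mm.
#' @slot epicardialRadius numeric(1), mm.
#' @slot endocardialRadius numeric(1), end-diastolic endocardial radius (mm).
#' @slot wallActivity numeric(1), expected counts/s/voxel at end-diastolic
#'   wall thickness.
#' @slot backgroundActivity numeric(1), counts/s/voxel outside the wall.
#' @slot contractionFraction numeric(1), peak fractional wall thickening in
#'   [0, 1).
#' @slot nSectors integer(1), angular sectors.
#' @slot sectorDelay numeric, per-sector contraction delay in degrees of
#'   cardiac cycle, each in [0, 360).
#' @slot zExtent integer(2), first and last axial slice containing wall.
#'
#' @seealso [lvPhantomSpec()], [phantomFrame()]
#' @export
setClass("LVPhantomSpec",
    representation(
        gridShape = "integer",
        voxelSize = "numeric",
        epicardialRadius = "numeric",
        endocardialRadius = "numeric",
        wallActivity = "numeric",
        backgroundActivity = "numeric",
        contractionFraction = "numeric",
        nSectors = "integer",
        sectorDelay = "numeric",
        zExtent = "integer"
    )
)

setValidity("LVPhantomSpec", function(object) {
    msg <- character()
    if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
        msg <- c(msg, "gridShape must be three positive integers")
    if (object@voxelSize <= 0) msg <- c(msg, "voxelSize must be positive")
    if (object@endocardialRadius >= object@epicardialRadius)
        msg <- c(msg, "endocardialRadius must be smaller than epicardialRadius")
    if (object@wallActivity < 0 || object@backgroundActivity < 0)
        msg <- c(msg, "activities must be non-negative")
    if (object@contractionFraction < 0 || object@contractionFraction >= 1)
        msg <- c(msg, "contractionFraction must be in [0, 1)")
    if (length(object@sectorDelay) != object@nSectors)
        msg <- c(msg, "sectorDelay must have one entry per sector")
    if (any(object@sectorDelay < 0 | object@sectorDelay >= 360))
        msg <- c(msg, "sector delays must be in [0, 360)")
    if (length(object@zExtent) != 2L ||
        object@zExtent[1L] < 1L || object@zExtent[2L] > object@gridShape[3L] ||
        object@zExtent[1L] > object@zExtent[2L])
        msg <- c(msg, "zExtent must be an increasing slice range inside the grid")
    if (length(msg)) msg else TRUE
})

#' Series of simulated heart beats
#'
#' R-trigger times and R-R intervals of a simulated ECG, the raw material of
#' fixed forward gating.
#'
#' @slot rrIntervals numeric, beat lengths in seconds, all positive.
#' @slot triggerTimes numeric, cumulative R-trigger times in seconds
#'   (\code{triggerTimes[i+1] - triggerTimes[i] == rrIntervals[i]}).
#' @slot seed integer(1), seed used to draw the series.
#'
#' @seealso [generateRRSeries()]
#' @export
setClass("BeatSeries",
    representation(rrIntervals = "numeric", triggerTimes = "numeric",
                   seed = "integer")
)

setValidity("BeatSeries", function(object) {
    msg <- character()
    if (any(object@rrIntervals <= 0)) msg <- c(msg, "all rrIntervals must be > 0")
    if (length(object@triggerTimes) != length(object@rrIntervals))
        msg <- c(msg, "one trigger per beat required")
    n <- length(object@triggerTimes)
    if (n > 1L) {
        d <- diff(object@triggerTimes)
        if (any(d <= 0)) msg <- c(msg, "triggerTimes must be strictly increasing")
        if (any(abs(d - object@rrIntervals[-n]) > 1e-9))
            msg <- c(msg, "trigger spacing must equal rrIntervals")
    }
    if (length(msg)) msg else TRUE
})

#' Fixed forward gating configuration
#'
#' @slot nBins integer(1), number of ECG bins (>= 2).
#' @slot acceptanceWindow numeric(1), half-width of the beat acceptance
#'   window as a fraction of the mean R-R interval (0.20 means +/-20%).
#'
#' @seealso [gateConfig()], [acceptBeats()]
#' @export
setClass("GateConfig",
    representation(nBins = "integer", acceptanceWindow = "numeric")
)

setValidity("GateConfig", function(object) {
    msg <- character()
    if (object@nBins < 2L) msg <- c(msg, "nBins must be >= 2")
    if (object@acceptanceWindow <= 0 || object@acceptanceWindow >= 1)
        msg <- c(msg, "acceptanceWindow must be in (0, 1)")
    if (length(msg)) msg else TRUE
})

#' Result of the beat acceptance step
#'
#' Holds the per-beat acceptance mask, the statistics of the accepted beats
#' (including the normalized R-R standard deviation, SD_R-R) and the ECG bin
#' length, computed as the mean accepted R-R interval divided by the number
#' of bins.
#'
#' @slot accepted logical, one flag per beat.
#' @slot meanAcceptedRR numeric(1), seconds.
#' @slot sdAcceptedRR numeric(1), sample (n-1) standard deviation, seconds.
#' @slot sdRRNormalized numeric(1), \code{sdAcceptedRR / meanAcceptedRR}.
#' @slot binLength numeric(1), seconds per ECG bin.
#' @slot nBins integer(1).
#'
#' @seealso [acceptBeats()]
#' @export
setClass("AcceptanceResult",
    representation(accepted = "logical", meanAcceptedRR = "numeric",
                   sdAcceptedRR = "numeric", sdRRNormalized = "numeric",
                   binLength = "numeric", nBins = "integer")
)

setValidity("AcceptanceResult", function(object) {
    msg <- character()
    if (object@meanAcceptedRR < 0 || object@sdAcceptedRR < 0 ||
        object@sdRRNormalized < 0 || object@binLength < 0)
        msg <- c(msg, "statistics must be non-negative")
    if (abs(object@binLength - object@meanAcceptedRR / object@nBins) > 1e-9)
        msg <- c(msg, "binLength must equal meanAcceptedRR / nBins")
    if (length(msg)) msg else TRUE
})

#' Acquisition geometry of a parallel-beam SPECT camera
#'
#' @slot angles numeric, projection angles in degrees, strictly increasing.
#' @slot nU integer(1), transaxial detector bins.
#' @slot nV integer(1), axial detector bins.
#' @slot binSize numeric(1), detector bin size in mm.
#' @slot radius numeric, centre-of-rotation to detector distance in mm; a
#'   single value for a circular orbit or one value per angle for a
#'   noncircular orbit.
#'
#' @seealso [spectGeometry()]
#' @export
setClass("SpectGeometry",
    representation(angles = "numeric", nU = "integer", nV = "integer",
                   binSize = "numeric", radius = "numeric")
)

setValidity("SpectGeometry", function(object) {
    msg <- character()
    if (length(object@angles) < 1L || any(diff(object@angles) <= 0))
        msg <- c(msg, "angles must be strictly increasing")
    if (!(length(object@radius) %in% c(1L, length(object@angles))))
        msg <- c(msg, "radius must be scalar or one value per angle")
    if (any(object@radius <= 0)) msg <- c(msg, "radius must be positive")
    if (object@binSize <= 0) msg <- c(msg, "binSize must be positive")
    if (length(msg)) msg else TRUE
})

#' Distance-dependent Gaussian collimator-detector response
#'
#' The blur of a parallel-hole collimator is modelled as a Gaussian whose
#' full width at half maximum grows linearly with the source-detector
#' distance d: \code{FWHM(d) = fwhm0 + slope * d}, and
#' \code{sigma(d) = FWHM(d) / 2.3548}.
#'
#' @slot fwhm0 numeric(1), intrinsic FWHM in mm (>= 0).
#' @slot slope numeric(1), mm of FWHM per mm of distance (>= 0).
#'
#' @seealso [cdrModel()]
#' @export
setClass("CDRModel", representation(fwhm0 = "numeric", slope = "numeric"))

setValidity("CDRModel", function(object) {
    msg <- character()
    if (object@fwhm0 < 0) msg <- c(msg, "fwhm0 must be >= 0")
    if (object@slope < 0) msg <- c(msg, "slope must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Gaussian-interpolation rotation operator for one projection angle
#'
#' Sparse matrix mapping a vectorised transaxial slice to its rotated copy.
#' Every interior output row is normalised to unit weight sum so that
#' rotation preserves counts.
#'
#' @slot weights sparse \code{dgCMatrix} of interpolation weights.
#' @slot angle numeric(1), rotation angle in degrees.
#' @slot sigma numeric(1), Gaussian interpolation kernel width in voxels.
#'
#' @seealso [buildRotation()]
#' @export
setClass("RotationOperator",
    representation(weights = "Matrix", angle = "numeric", sigma = "numeric")
)

#' System model: geometry, response and reconstruction mode
#'
#' Bundles the acquisition geometry, the collimator-detector response, the
#' image grid and the reconstruction mode (plain OSEM or time-modified
#' OSEM).  Rotation operators and per-depth blur kernels are precomputed and
#' cached when the model is created.
#'
#' @slot geometry a [SpectGeometry-class].
#' @slot cdr a [CDRModel-class].
#' @slot gridShape integer(3), image voxels along x, y, z.
#' @slot voxelSize numeric(1), mm.
#' @slot mode character(1), \code{"osem"} or \code{"tosem"}.
#' @slot sigmaR numeric(1), rotation interpolation kernel width (voxels).
#' @slot cache environment holding precomputed operators.
#'
#' @seealso [systemModel()], [forwardProject()], [backProject()]
#' @export
setClass("SystemModel",
    representation(geometry = "SpectGeometry", cdr = "CDRModel",
                   gridShape = "integer", voxelSize = "numeric",
                   mode = "character", sigmaR = "numeric",
                   cache = "environment")
)

setValidity("SystemModel", function(object) {
    msg <- character()
    if (!object@mode %in% c("osem", "tosem"))
        msg <- c(msg, "mode must be 'osem' or 'tosem'")
    if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
        msg <- c(msg, "gridShape must be three positive integers")
    if (object@sigmaR <= 0) msg <- c(msg, "sigmaR must be positive")
    half <- max(object@gridShape[1:2]) * object@voxelSize / 2
    if (any(object@geometry@radius <= half))
        msg <- c(msg, "detector radius must exceed the image half-extent")
    if (object@geometry@nU != object@gridShape[2L] ||
        object@geometry@nV != object@gridShape[3L])
        msg <- c(msg, "detector bins must match the image grid (nU = ny, nV = nz)")
    if (length(msg)) msg else TRUE
})

#' OSEM/TOSEM reconstruction configuration
#'
#' @slot nIterations integer(1), outer iterations (default 10).
#' @slot nSubsets integer(1), ordered subsets (default 8); the number of
#'   projection angles must be divisible by it.
#' @slot epsilon numeric(1), positivity guard in ratio denominators.
#' @slot initValue numeric(1), value of the uniform initial image.
#' @slot subsetOrder character(1), \code{"bitrev"} (maximal angular
#'   separation between consecutive subsets) or \code{"sequential"}.
#'
#' @seealso [reconConfig()], [reconstructBin()]
#' @export
setClass("ReconConfig",
    representation(nIterations = "integer", nSubsets = "integer",
                   epsilon = "numeric", initValue = "numeric",
                   subsetOrder = "character")
)

setValidity("ReconConfig", function(object) {
    msg <- character()
    if (object@nIterations < 1L) msg <- c(msg, "nIterations must be >= 1")
    if (object@nSubsets < 1L) msg <- c(msg, "nSubsets must be >= 1")
    if (object@epsilon <= 0) msg <- c(msg, "epsilon must be > 0")
    if (object@initValue <= 0) msg <- c(msg, "initValue must be > 0")
    if (!object@subsetOrder %in% c("bitrev", "sequential"))
        msg <- c(msg, "subsetOrder must be 'bitrev' or 'sequential'")
    if (length(msg)) msg else TRUE
})

#' ECG-gated sinogram
#'
#' Measured counts indexed by projection angle, ECG bin and detector bin.
#'
#' @slot counts integer array \code{[angle, bin, u, v]} of non-negative
#'   counts.
#' @slot angles numeric, projection angles in degrees.
#' @slot binSize numeric(1), detector bin size in mm.
#'
#' @seealso [simulateGatedSinogram()], [thinLastBin()]
#' @export
setClass("GatedSinogram",
    representation(counts = "array", angles = "numeric", binSize = "numeric")
)

setValidity("GatedSinogram", function(object) {
    msg <- character()
    d <- dim(object@counts)
    if (length(d) != 4L) msg <- c(msg, "counts must be a 4-D [angle, bin, u, v] array")
    else if (d[1L] != length(object@angles))
        msg <- c(msg, "first counts dimension must match the angle list")
    if (!is.integer(object@counts))
        msg <- c(msg, "counts must be integer")
    else if (any(object@counts < 0L))
        msg <- c(msg, "counts must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Gated image series
#'
#' One reconstructed (or ground-truth) activity volume per ECG bin.
#'
#' @slot data numeric array \code{[x, y, z, bin]}, non-negative.
#' @slot voxelSize numeric(1), mm.
#' @slot provenance list of free-form provenance fields (mode, config,
#'   seed).
#'
#' @seealso [reconstructSeries()], [postprocessSeries()], [phaseAnalysis()]
#' @export
setClass("GatedImageSeries",
    representation(data = "array", voxelSize = "numeric", provenance = "list")
)

setValidity("GatedImageSeries", function(object) {
    msg <- character()
    if (length(dim(object@data)) != 4L)
        msg <- c(msg, "data must be a 4-D [x, y, z, bin] array")
    if (any(!is.finite(object@data)))
        msg <- c(msg, "data must be finite")
    else if (any(object@data < 0))
        msg <- c(msg, "data must be non-negative")
    if (object@voxelSize <= 0) msg <- c(msg, "voxelSize must be positive")
    if (length(msg)) msg else TRUE
})

#' Mid-wall myocardial sampling grid
#'
#' Sample points on the LV mid-wall (angular x axial grid) with a radial
#' search segment per point; activity is sampled as the maximum interpolated
#' value along the segment.
#'
#' @slot points data.frame with columns \code{theta} (degrees), \code{z}
#'   (voxel coordinate), \code{cx}, \code{cy} (LV axis, voxel coordinates).
#' @slot radii numeric, radial search positions in voxels (common to all
#'   points).
#'
#' @seealso [midWallSamplingGrid()], [sampleMyocardium()]
#' @export
setClass("SamplingGrid",
    representation(points = "data.frame", radii = "numeric")
)

setValidity("SamplingGrid", function(object) {
    msg <- character()
    if (nrow(object@points) < 1L) msg <- c(msg, "at least one sample point required")
    if (nrow(object@points) > 1008L)
        msg <- c(msg, "at most 1008 sample points supported")
    if (length(object@radii) < 1L || any(object@radii < 0))
        msg <- c(msg, "radii must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Phase analysis result
#'
#' Retained first-harmonic phases, their 360-bin histogram (one degree per
#' bin) and the three dyssynchrony indices: histogram bandwidth (BW), phase
#' standard deviation (StD) and normalized entropy (ENT).
#'
#' @slot phases numeric, retained phases in degrees, [0, 360).
#' @slot histogram integer(360) of phase counts.
#' @slot bw numeric(1), degrees in [1, 360].
#' @slot std numeric(1), degrees, >= 0.
#' @slot ent numeric(1), percent in [0, 100].
#' @slot coverage numeric(1), arc coverage fraction used for BW.
#'
#' @seealso [summarizePhases()], [phaseAnalysis()]
#' @export
setClass("PhaseAnalysisResult",
    representation(phases = "numeric", histogram = "integer", bw = "numeric",
                   std = "numeric", ent = "numeric", coverage = "numeric")
)

setValidity("PhaseAnalysisResult", function(object) {
    msg <- character()
    if (length(object@histogram) != 360L)
        msg <- c(msg, "histogram must have 360 bins")
    if (sum(object@histogram) != length(object@phases))
        msg <- c(msg, "histogram total must equal the number of retained phases")
    if (object@bw < 1 || object@bw > 360) msg <- c(msg, "bw must be in [1, 360]")
    if (object@std < 0) msg <- c(msg, "std must be >= 0")
    if (object@ent < 0 || object@ent > 100) msg <- c(msg, "ent must be in [0, 100]")
    if (length(msg)) msg else TRUE
})

#' Lin's concordance correlation coefficient with its decomposition
#'
#' @slot ccc numeric(1), concordance correlation coefficient.
#' @slot r numeric(1), Pearson correlation.
#' @slot cb numeric(1), bias correction factor in (0, 1].
#' @slot sdX,sdY numeric(1), standard deviations of the two vectors.
#' @slot covXY numeric(1), covariance.
#' @slot meanX,meanY numeric(1), means.
#' @slot sample logical(1), TRUE if sample (n-1) moments were used.
#'
#' @seealso [linCCC()]
#' @export
setClass("CCCResult",
    representation(ccc = "numeric", r = "numeric", cb = "numeric",
                   sdX = "numeric", sdY = "numeric", covXY = "numeric",
                   meanX = "numeric", meanY = "numeric", sample = "logical")
)

setValidity("CCCResult", function(object) {
    msg <- character()
    if (is.na(object@ccc) != is.na(object@r))
        msg <- c(msg, "ccc and r must be NA together")
    if (!is.na(object@ccc) && abs(object@ccc - object@r * object@cb) > 1e-12)
        msg <- c(msg, "ccc must equal r * cb")
    if (object@cb <= 0 || object@cb > 1 + 1e-12)
        msg <- c(msg, "cb must be in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' Synthetic population specification for the experiment pipelines
#'
#' Per-subject parameters (mean R-R, HRV level, dyssynchrony delays, count
#' scale) are drawn deterministically from the master seed.
#'
#' @slot nSubjects integer(1).
#' @slot meanRRRange numeric(2), seconds.
#' @slot hrvRange numeric(2), normalized R-R standard deviation range.
#' @slot delayRange numeric(2), delayed-sector contraction delay range
#'   (degrees).
#' @slot nDelayedSectors integer(1), adjacent sectors sharing the delay.
#' @slot masterSeed integer(1).
#'
#' @seealso [populationSpec()], [runPart1()], [runPart2()], [runPart3()]
#' @export
setClass("PopulationSpec",
    representation(nSubjects = "integer", meanRRRange = "numeric",
                   hrvRange = "numeric", delayRange = "numeric",
                   nDelayedSectors = "integer", masterSeed = "integer")
)

setValidity("PopulationSpec", function(object) {
    msg <- character()
    if (object@nSubjects < 2L) msg <- c(msg, "nSubjects must be >= 2")
    for (s in c("meanRRRange", "hrvRange", "delayRange")) {
        v <- slot(object, s)
        if (length(v) != 2L || v[1L] > v[2L])
            msg <- c(msg, sprintf("%s must be an increasing pair", s))
    }
    if (any(object@meanRRRange <= 0)) msg <- c(msg, "meanRRRange must be positive")
    if (any(object@hrvRange < 0)) msg <- c(msg, "hrvRange must be non-negative")
    if (length(msg)) msg else TRUE
})
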