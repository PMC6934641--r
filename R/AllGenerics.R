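#' Accessors for gatedSPECT objects
#'
#' Small accessor generics so that downstream code never touches slots
#' directly.
#'
#' @param x a gatedSPECT object.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("rrIntervals", function(x) standardGeneric("rrIntervals"))
#' @rdname accessors
#' @export
setMethod("rrIntervals", "BeatSeries", function(x) x@rrIntervals)

#' @rdname accessors
#' @export
setGeneric("triggerTimes", function(x) standardGeneric("triggerTimes"))
#' @rdname accessors
#' @export
setMethod("triggerTimes", "BeatSeries", function(x) x@triggerTimes)

#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
#' @rdname accessors
#' @export
setMethod("counts", "GatedSinogram", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("projectionAngles", function(x) standardGeneric("projectionAngles"))
#' @rdname accessors
#' @export
setMethod("projectionAngles", "GatedSinogram", function(x) x@angles)
#' @rdname accessors
#' @export
setMethod("projectionAngles", "SpectGeometry", function(x) x@angles)
#' @rdname accessors
#' @export
setMethod("projectionAngles", "SystemModel", function(x) x@geometry@angles)

#' @rdname accessors
#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))
#' @rdname accessors
#' @export
setMethod("imageData", "GatedImageSeries", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setMethod("voxelSize", "GatedImageSeries", function(x) x@voxelSize)
#' @rdname accessors
#' @export
setMethod("voxelSize", "LVPhantomSpec", function(x) x@voxelSize)

#' @rdname accessors
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))
#' @rdname accessors
#' @export
setMethod("nBins", "GatedSinogram", function(x) dim(x@counts)[2L])
#' @rdname accessors
#' @export
setMethod("nBins", "GatedImageSeries", function(x) dim(x@data)[4L])
#' @rdname accessors
#' @export
setMethod("nBins", "GateConfig", function(x) x@nBins)
#' @rdname accessors
#' @export
setMethod("nBins", "AcceptanceResult", function(x) x@nBins)

#' @rdname accessors
#' @export
setGeneric("binLength", function(x) standardGeneric("binLength"))
#' @rdname accessors
#' @export
setMethod("binLength", "AcceptanceResult", function(x) x@binLength)

#' @rdname accessors
#' @export
setGeneric("acceptedBeats", function(x) standardGeneric("acceptedBeats"))
#' @rdname accessors
#' @export
setMethod("acceptedBeats", "AcceptanceResult", function(x) x@accepted)

#' @rdname accessors
#' @export
setGeneric("sdRRNormalized", function(x) standardGeneric("sdRRNormalized"))
#' @rdname accessors
#' @export
setMethod("sdRRNormalized", "AcceptanceResult", function(x) x@sdRRNormalized)

#' Per-bin total activity of a gated image series
#'
#' @param x a [GatedImageSeries-class].
#' @return numeric vector of per-bin voxel-value totals.
#' @export
setGeneric("binTotals", function(x) standardGeneric("binTotals"))
#' @rdname binTotals
#' @export
setMethod("binTotals", "GatedImageSeries",
    function(x) apply(x@data, 4L, sum))

#' @rdname accessors
#' @export
setGeneric("phaseBandwidth", function(x) standardGeneric("phaseBandwidth"))
#' @rdname accessors
#' @export
setMethod("phaseBandwidth", "PhaseAnalysisResult", function(x) x@bw)

#' @rdname accessors
#' @export
setGeneric("phaseStd", function(x) standardGeneric("phaseStd"))
#' @rdname accessors
#' @export
setMethod("phaseStd", "PhaseAnalysisResult", function(x) x@std)

#' @rdname accessors
#' @export
setGeneric("phaseEntropy", function(x) standardGeneric("phaseEntropy"))
#' @rdname accessors
#' @export
setMethod("phaseEntropy", "PhaseAnalysisResult", function(x) x@ent)

#' @rdname accessors
#' @export
setGeneric("retainedPhases", function(x) standardGeneric("retainedPhases"))
#' @rdname accessors
#' @export
setMethod("retainedPhases", "PhaseAnalysisResult", function(x) x@phases)

#' @rdname accessors
#' @export
setGeneric("phaseHistogramCounts",
    function(x) standardGeneric("phaseHistogramCounts"))
#' @rdname accessors
#' @export
setMethod("phaseHistogramCounts", "PhaseAnalysisResult",
    function(x) x@histogram)

#' @rdname accessors
#' @export
setGeneric("cccValue", function(x) standardGeneric("cccValue"))
#' @rdname accessors
#' @export
setMethod("cccValue", "CCCResult", function(x) x@ccc)

setMethod("show", "BeatSeries", function(object) {
    rr <- object@rrIntervals
    cat(sprintf("BeatSeries: %d beats over %.1f s (mean RR %.3f s, SD %.3f s)\n",
                length(rr), object@triggerTimes[length(rr)] + rr[length(rr)],
                mean(rr), stats::sd(rr)))
})

setMethod("show", "AcceptanceResult", function(object) {
    cat(sprintf(paste0("AcceptanceResult: %d/%d beats accepted; mean RR %.3f s,",
                       " SD_R-R %.4f (%.1f ms); bin length %.4f s x %d bins\n"),
                sum(object@accepted), length(object@accepted),
                object@meanAcceptedRR, object@sdRRNormalized,
                1000 * object@sdAcceptedRR, object@binLength, object@nBins))
})

setMethod("show", "GatedSinogram", function(object) {
    d <- dim(object@counts)
    cat(sprintf("GatedSinogram: %d angles x %d bins x %d x %d detector bins, %d counts\n",
                d[1L], d[2L], d[3L], d[4L], sum(object@counts)))
})

setMethod("show", "GatedImageSeries", function(object) {
    d <- dim(object@data)
    mode <- object@provenance$mode
    cat(sprintf("GatedImageSeries: %dx%dx%d voxels (%.2f mm), %d ECG bins%s\n",
                d[1L], d[2L], d[3L], object@voxelSize, d[4L],
                if (is.null(mode)) "" else sprintf(" [%s]", mode)))
})

setMethod("show", "PhaseAnalysisResult", function(object) {
    cat(sprintf("PhaseAnalysisResult: %d phases; BW %.1f deg, StD %.2f deg, ENT %.2f%%\n",
                length(object@phases), object@bw, object@std, object@ent))
})

setMethod("show", "CCCResult", function(object) {
    cat(sprintf("CCC %.4f = r %.4f x C_b %.4f (means %.3f/%.3f, SDs %.3f/%.3f)\n",
                object@ccc, object@r, object@cb, object@meanX, object@meanY,
                object@sdX, object@sdY))
})

setMethod("show", "SystemModel", function(object) {
    g <- object@geometry
    cat(sprintf("SystemModel [%s]: %d angles, grid %dx%dx%d @ %.2f mm, CDR %.1f + %.3f*d mm FWHM\n",
                toupper(object@mode), length(g@angles), object@gridShape[1L],
                object@gridShape[2L], object@gridShape[3L], object@voxelSize,
                object@cdr@fwhm0, object@cdr@slope))
})
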