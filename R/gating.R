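#' Fixed forward gating configuration
#'
#' Defaults follow common clinical practice for gated myocardial perfusion
#' SPECT: eight ECG bins and a +/-20% beat acceptance window.
#'
#' @param nBins number of ECG bins (>= 2).
#' @param acceptanceWindow acceptance half-width as a fraction of the mean
#'   R-R interval.
#' @return A [GateConfig-class].
#' @export
gateConfig <- function(nBins = 8L, acceptanceWindow = 0.20) {
    new("GateConfig", nBins = as.integer(nBins),
        acceptanceWindow = acceptanceWindow)
}

#' Accept beats and derive gating statistics
#'
#' The acceptance reference is the single-pass arithmetic mean of all R-R
#' intervals; beat i is accepted iff
#' \code{|RR_i - mean| <= acceptanceWindow * mean}.  The mean and sample
#' (n-1) standard deviation of the accepted beats give the normalized R-R
#' variability SD_R-R and the ECG bin length (mean accepted R-R divided by
#' the number of bins).
#'
#' @param beats a [BeatSeries-class] (or numeric vector of R-R intervals)
#'   with at least two beats.
#' @param cfg a [GateConfig-class].
#' @return An [AcceptanceResult-class].
#' @examples
#' acceptBeats(generateRRSeries(0.9, 0.05, 60, seed = 2))
#' @export
acceptBeats <- function(beats, cfg = gateConfig()) {
    rr <- if (is(beats, "BeatSeries")) beats@rrIntervals else as.numeric(beats)
    if (length(rr) < 2L) stop("at least two beats required")
    ref <- mean(rr)
    accepted <- abs(rr - ref) <= cfg@acceptanceWindow * ref
    if (!any(accepted)) stop("gating failure: no beats accepted")
    m <- mean(rr[accepted])
    s <- if (sum(accepted) > 1L) sd(rr[accepted]) else 0
    new("AcceptanceResult", accepted = accepted, meanAcceptedRR = m,
        sdAcceptedRR = s, sdRRNormalized = s / m, binLength = m / cfg@nBins,
        nBins = cfg@nBins)
}

#' Per-angle, per-bin acquisition-time map
#'
#' For each projection angle, sums over its accepted beats the overlap of
#' the fixed gating bins \code{[(b-1) delta, b delta)} with the beat
#' \code{[0, RR)}.  Beats shorter than \code{nBins * delta} leave late bins
#' partly or wholly unfilled (the data-shortage mechanism); beat time beyond
#' the last bin is discarded.
#'
#' @param rrByAngle list of numeric vectors: accepted R-R intervals at each
#'   projection angle.
#' @param delta ECG bin length in seconds (> 0).
#' @param nBins number of bins.
#' @return numeric matrix \code{[angle, bin]} of acquisition seconds.
#' @examples
#' computeTau(list(0.95), delta = 0.125, nBins = 8)
#' @export
computeTau <- function(rrByAngle, delta, nBins = 8L) {
    if (!is.list(rrByAngle)) rrByAngle <- list(rrByAngle)
    if (delta <= 0) stop("delta must be positive")
    edges <- (0:nBins) * delta
    t(vapply(rrByAngle, function(rr) {
        tau <- numeric(nBins)
        for (RR in rr)
            tau <- tau + pmax(0, pmin(edges[-1L], RR) - pmin(edges[-(nBins + 1L)], RR))
        tau
    }, numeric(nBins)))
}

#' Bin list-mode events into a gated sinogram
#'
#' An event at time t inside accepted beat i goes to bin
#' \code{floor((t - trigger_i) / delta) + 1}; events beyond the last bin, in
#' rejected beats, or before the first trigger are discarded (the number of
#' discarded events is reported via a message).
#'
#' @param events data.frame with columns \code{time} (s), \code{u},
#'   \code{v} (detector bin indices) and \code{angle} (projection angle
#'   index).
#' @param beats the [BeatSeries-class] the events were acquired over.
#' @param acceptance an [AcceptanceResult-class] for those beats.
#' @param cfg a [GateConfig-class].
#' @param nAngles total number of projection angles.
#' @param nU,nV detector dimensions.
#' @param angles projection angle list in degrees (for the sinogram
#'   metadata).
#' @param binSize detector bin size in mm.
#' @return A [GatedSinogram-class].
#' @export
binEvents <- function(events, beats, acceptance, cfg = gateConfig(),
                      nAngles, nU, nV, angles = seq_len(nAngles), binSize = 1) {
    stopifnot(all(c("time", "u", "v", "angle") %in% names(events)))
    early <- events$time < beats@triggerTimes[1L]
    cnt <- eventCountArray(events[!early, , drop = FALSE], beats, acceptance,
                           cfg, nAngles, nU, nV)
    kept <- sum(cnt)
    dropped <- nrow(events) - kept
    if (dropped > 0L)
        message(sprintf("binEvents: discarded %d of %d events (%d before first trigger)",
                        dropped, nrow(events), sum(early)))
    new("GatedSinogram", counts = cnt, angles = as.numeric(angles),
        binSize = binSize)
}

# Raw-count analogue of the activity ratio: last-bin total over the mean of
# the first five bins.  Used as the thinning/exclusion proxy for AR.
sinogramCountRatio <- function(sino) {
    tot <- apply(counts(sino), 2L, sum)
    if (length(tot) < 6L) stop("at least six ECG bins required")
    tot[length(tot)] / mean(tot[1:5])
}

#' Thin the last ECG bin to a target activity ratio
#'
#' Emulates the list-mode rebinning used to generate reduced activity-ratio
#' data sets: last-bin counts are discarded uniformly across all projection
#' angles by binomial thinning with retention probability
#' \code{p = targetRatio * mean(total counts of bins 1-5) / (total counts of
#' the last bin)}, and the last-bin acquisition times are scaled by the same
#' factor.  All other bins are untouched.
#'
#' @param sino a [GatedSinogram-class] with at least six bins.
#' @param tau acquisition-time matrix \code{[angle, bin]} matching the
#'   sinogram.
#' @param targetRatio desired last-bin/first-five-bins count ratio, in
#'   (0, current ratio].
#' @param seed integer seed for the binomial thinning.
#' @return list with the thinned \code{sinogram} and scaled \code{tau}, plus
#'   the applied retention probability \code{p}.
#' @export
thinLastBin <- function(sino, tau, targetRatio, seed = 1L) {
    stopifnot(is(sino, "GatedSinogram"))
    cnt <- counts(sino)
    B <- dim(cnt)[2L]
    if (B < 6L) stop("at least six ECG bins required")
    if (!identical(dim(tau), c(dim(cnt)[1L], B)))
        stop("tau shape must match the sinogram (angles x bins)")
    cur <- sinogramCountRatio(sino)
    if (targetRatio <= 0) stop("targetRatio must be positive")
    p <- targetRatio / cur
    if (p > 1 + 1e-9)
        stop(sprintf("target ratio %.3f above current ratio %.3f: cannot add counts",
                     targetRatio, cur))
    p <- min(p, 1)
    last <- cnt[, B, , , drop = FALSE]
    set.seed(as.integer(seed))
    thinned <- array(rbinom(length(last), as.vector(last), p), dim(last))
    cnt[, B, , ] <- thinned
    storage.mode(cnt) <- "integer"
    tau[, B] <- tau[, B] * p
    list(sinogram = new("GatedSinogram", counts = cnt, angles = sino@angles,
                        binSize = sino@binSize),
         tau = tau, p = p)
}
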