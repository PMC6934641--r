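#' Activity ratio of a gated series
#'
#' The data-shortage index: total activity of the last ECG bin divided by
#' the mean total activity of the first five bins, in percent.  Invariant
#' to any common rescaling of all bins.
#'
#' @param x a [GatedImageSeries-class] or a numeric vector of per-bin
#'   totals (>= 6 bins).
#' @return numeric(1), AR in percent.
#' @examples
#' activityRatio(c(100, 100, 100, 100, 100, 95, 90, 80))  # 80
#' @export
setGeneric("activityRatio", function(x) standardGeneric("activityRatio"))

#' @rdname activityRatio
#' @export
setMethod("activityRatio", "GatedImageSeries",
    function(x) activityRatio(binTotals(x)))

#' @rdname activityRatio
#' @export
setMethod("activityRatio", "numeric", function(x) {
    if (length(x) < 6L) stop("at least six ECG bins required")
    if (any(x < 0)) stop("bin totals must be non-negative")
    denom <- mean(x[1:5])
    if (denom <= 0) stop("zero activity in the first five bins")
    100 * x[length(x)] / denom
})

#' Pearson correlation with degenerate-input checks
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return numeric(1), the product-moment correlation.
#' @export
pearsonR <- function(x, y) {
    if (length(x) != length(y) || length(x) < 3L)
        stop("need two equal-length vectors with n >= 3")
    if (sd(x) == 0 || sd(y) == 0)
        stop("undefined correlation: constant vector")
    cor(x, y)
}

#' Lin's concordance correlation coefficient
#'
#' \deqn{CCC = r \cdot C_b = \frac{\sigma_{xy}}{\sigma_x \sigma_y} \cdot
#'       \frac{2 \sigma_x \sigma_y}{\sigma_x^2 + \sigma_y^2 +
#'       (\mu_x - \mu_y)^2}}
#' computed with population (1/n) moments by default (Lin's original
#' estimator); \code{sample = TRUE} switches to n-1 moments.
#'
#' @param x,y numeric vectors, equal length >= 3, nonzero variance.
#' @param sample use sample instead of population moments.
#' @return A [CCCResult-class] with the full decomposition.
#' @examples
#' cccValue(linCCC(c(1, 2, 3), c(2, 3, 4)))  # 4/7
#' @export
linCCC <- function(x, y, sample = FALSE) {
    if (length(x) != length(y) || length(x) < 3L)
        stop("need two equal-length vectors with n >= 3")
    n <- length(x)
    mx <- mean(x); my <- mean(y)
    denomN <- if (sample) n - 1 else n
    vx <- sum((x - mx)^2) / denomN
    vy <- sum((y - my)^2) / denomN
    cxy <- sum((x - mx) * (y - my)) / denomN
    if (vx == 0 || vy == 0) stop("undefined CCC: constant vector")
    sx <- sqrt(vx); sy <- sqrt(vy)
    r <- cxy / (sx * sy)
    cb <- 2 * sx * sy / (vx + vy + (mx - my)^2)
    new("CCCResult", ccc = r * cb, r = r, cb = cb, sdX = sx, sdY = sy,
        covXY = cxy, meanX = mx, meanY = my, sample = sample)
}

#' Change of phase-analysis indices between reconstruction algorithms
#'
#' Returns TOSEM minus OSEM for each dyssynchrony index, so a positive
#' delta means the time-modified reconstruction yields the larger value.
#'
#' @param osem,tosem [PhaseAnalysisResult-class] objects from the same
#'   gated data reconstructed with the two algorithms.
#' @return named numeric: \code{dBW} (degrees), \code{dStD} (degrees),
#'   \code{dENT} (percentage points).
#' @export
deltaPhaseParams <- function(osem, tosem) {
    stopifnot(is(osem, "PhaseAnalysisResult"), is(tosem, "PhaseAnalysisResult"))
    c(dBW = tosem@bw - osem@bw,
      dStD = tosem@std - osem@std,
      dENT = tosem@ent - osem@ent)
}
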