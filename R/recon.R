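#' OSEM/TOSEM reconstruction configuration
#'
#' Defaults follow common clinical cardiac practice: ten iterations with
#' eight ordered subsets, uniform unit initial image, and a 1e-12 positivity
#' guard in the ratio denominators.  Subsets are the angle classes
#' \code{l == s (mod nSubsets)}, processed in bit-reversed order so that
#' consecutive subsets are maximally separated in angle.
#'
#' @param nIterations outer iterations.
#' @param nSubsets ordered subsets; the angle count must be divisible by
#'   it.
#' @param epsilon positivity guard.
#' @param initValue uniform initial image value.
#' @param subsetOrder \code{"bitrev"} or \code{"sequential"}.
#' @return A [ReconConfig-class].
#' @export
reconConfig <- function(nIterations = 10L, nSubsets = 8L, epsilon = 1e-12,
                        initValue = 1, subsetOrder = "bitrev") {
    new("ReconConfig", nIterations = as.integer(nIterations),
        nSubsets = as.integer(nSubsets), epsilon = epsilon,
        initValue = initValue, subsetOrder = subsetOrder)
}

# Angle indices of each ordered subset, in processing order.
subsetSchedule <- function(L, cfg) {
    N <- cfg@nSubsets
    if (L %% N != 0L)
        stop(sprintf("number of angles (%d) not divisible by number of subsets (%d)",
                     L, N))
    order <- if (cfg@subsetOrder == "bitrev" && N > 1L) {
        bits <- ceiling(log2(N))
        if (2^bits == N) {
            rev <- vapply(0:(N - 1L), function(s) {
                r <- 0L
                for (b in seq_len(bits)) {
                    r <- bitwOr(bitwShiftL(r, 1L), bitwAnd(s, 1L))
                    s <- bitwShiftR(s, 1L)
                }
                r
            }, integer(1L))
            rev
        } else 0:(N - 1L)
    } else 0:(N - 1L)
    lapply(order, function(s) which((seq_len(L) - 1L) %% N == s))
}

#' One OSEM/TOSEM subset update
#'
#' Applies the multiplicative EM update restricted to one ordered subset:
#' \deqn{f \gets \frac{f}{\sum_{l \in S} H_l^T 1}\;
#'       \sum_{l \in S} H_l^T \frac{g_l}{\max(H_l f, \epsilon)}}
#' where the transition block is \eqn{H_l = P_l R_l} for OSEM and
#' \eqn{H_l = \tau_l P_l R_l} for TOSEM (\eqn{\tau_l} the acquisition time
#' of angle l, which then enters both the forward model and the
#' sensitivity).  Voxels with zero sensitivity are set to zero and frozen.
#'
#' @param f current image array \code{[x, y, z]}, positive.
#' @param subset integer vector of angle indices.
#' @param g projection array \code{[angle, u, v]} for one ECG bin (all
#'   angles; only the subset rows are used).
#' @param model a [SystemModel-class]; its \code{mode} selects OSEM or
#'   TOSEM.
#' @param tau per-angle acquisition times (seconds), required for TOSEM.
#' @param cfg a [ReconConfig-class] (only \code{epsilon} is used).
#' @return updated image array.
#' @export
osemUpdate <- function(f, subset, g, model, tau = NULL, cfg = reconConfig()) {
    if (any(g < 0)) stop("negative counts in projections")
    tosem <- model@mode == "tosem"
    if (tosem && is.null(tau)) stop("TOSEM requires acquisition times")
    num <- array(0, dim(f))
    sens <- array(0, dim(f))
    for (l in subset) {
        tl <- if (tosem) tau[l] else 1
        if (tl == 0) next
        fp <- tl * forwardProject(f, l, model)
        ratio <- g[l, , ] / pmax(fp, cfg@epsilon)
        num <- num + tl * backProject(ratio, l, model)
        sens <- sens + tl * backProjectOnes(l, model)
    }
    upd <- array(0, dim(f))
    pos <- sens > 0
    upd[pos] <- f[pos] * num[pos] / sens[pos]
    upd
}

#' Reconstruct a single ECG bin
#'
#' Runs the configured number of iterations over the ordered subsets,
#' starting from a uniform positive image.  Deterministic given its inputs.
#'
#' @param g projection array \code{[angle, u, v]} of measured counts for
#'   one ECG bin.
#' @param model a [SystemModel-class].
#' @param tau per-angle acquisition times for this bin (TOSEM; ignored for
#'   OSEM).
#' @param cfg a [ReconConfig-class].
#' @return image array \code{[x, y, z]}.
#' @export
reconstructBin <- function(g, model, tau = NULL, cfg = reconConfig()) {
    L <- length(model@geometry@angles)
    stopifnot(dim(g)[1L] == L)
    if (model@mode == "tosem") {
        if (is.null(tau) || length(tau) != L)
            stop("TOSEM requires one acquisition time per angle")
        if (all(tau == 0))
            stop("unrecoverable ECG bin: zero acquisition time at every angle")
    }
    sched <- subsetSchedule(L, cfg)
    f <- array(cfg@initValue, model@gridShape)
    for (it in seq_len(cfg@nIterations))
        for (sub in sched)
            f <- osemUpdate(f, sub, g, model, tau, cfg)
    f
}

#' Reconstruct a gated series bin by bin
#'
#' Each ECG bin is reconstructed independently.  With TOSEM, the
#' acquisition time of every (angle, bin) scales the corresponding
#' transition block, so the per-bin images live on a common activity-rate
#' scale (counts per second): the total activity stays constant from bin to
#' bin even when the last bin was acquired for a shorter time.  Plain OSEM
#' ignores the acquisition times and reproduces the last-bin activity drop.
#'
#' @param sino a [GatedSinogram-class].
#' @param tau acquisition-time matrix \code{[angle, bin]} (required for
#'   TOSEM).
#' @param model a [SystemModel-class]; its \code{mode} selects the
#'   algorithm.
#' @param cfg a [ReconConfig-class].
#' @return A [GatedImageSeries-class].
#' @export
reconstructSeries <- function(sino, tau = NULL, model, cfg = reconConfig()) {
    stopifnot(is(sino, "GatedSinogram"))
    cnt <- counts(sino)
    B <- dim(cnt)[2L]
    if (model@mode == "tosem" &&
        (is.null(tau) || !identical(dim(tau), c(dim(cnt)[1L], B))))
        stop("TOSEM requires a full angle x bin acquisition-time map")
    vols <- array(0, c(model@gridShape, B))
    for (b in seq_len(B)) {
        g <- array(as.numeric(cnt[, b, , ]), dim(cnt)[-2L])
        vols[, , , b] <- reconstructBin(g, model,
                                        tau = if (is.null(tau)) NULL else tau[, b],
                                        cfg = cfg)
    }
    new("GatedImageSeries", data = vols, voxelSize = model@voxelSize,
        provenance = list(mode = model@mode,
                          nIterations = cfg@nIterations,
                          nSubsets = cfg@nSubsets))
}

# Separable 3-D Gaussian smoothing with mirror boundary handling.
gaussianSmooth3D <- function(x, sigma) {
    if (sigma <= 0) return(x)
    half <- ceiling(3 * sigma)
    w <- exp(-((-half):half)^2 / (2 * sigma^2))
    w <- w / sum(w)
    smooth1 <- function(m, n) {
        # m: n x k matrix, smooth along rows with mirror boundary
        idx <- seq_len(n)
        out <- 0
        for (j in seq_along(w)) {
            o <- j - half - 1L
            src <- idx + o
            src[src < 1L] <- 1L - (src[src < 1L] - 1L)   # mirror
            src[src > n] <- 2L * n - src[src > n] + 1L
            out <- out + w[j] * m[src, , drop = FALSE]
        }
        out
    }
    d <- dim(x)
    # x axis
    m <- matrix(x, d[1L], d[2L] * d[3L])
    x <- array(smooth1(m, d[1L]), d)
    # y axis
    m <- matrix(aperm(x, c(2L, 1L, 3L)), d[2L], d[1L] * d[3L])
    x <- aperm(array(smooth1(m, d[2L]), d[c(2L, 1L, 3L)]), c(2L, 1L, 3L))
    # z axis
    m <- matrix(aperm(x, c(3L, 1L, 2L)), d[3L], d[1L] * d[2L])
    aperm(array(smooth1(m, d[3L]), d[c(3L, 1L, 2L)]), c(2L, 3L, 1L))
}

#' Cylindrical mask around the LV
#'
#' @param gridShape integer(3).
#' @param radius mask radius in voxels.
#' @param zRange integer(2), axial slices kept.
#' @param center numeric(2), transaxial centre in voxel coordinates
#'   (defaults to the grid centre).
#' @return logical array \code{[x, y, z]}.
#' @export
cylindricalMask <- function(gridShape, radius, zRange = c(1L, gridShape[3L]),
                            center = (gridShape[1:2] + 1) / 2) {
    nx <- gridShape[1L]; ny <- gridShape[2L]; nz <- gridShape[3L]
    r2 <- outer((seq_len(nx) - center[1L])^2, (seq_len(ny) - center[2L])^2, "+")
    plane <- r2 <= radius^2
    mask <- array(FALSE, gridShape)
    for (z in seq_len(nz))
        if (z >= zRange[1L] && z <= zRange[2L]) mask[, , z] <- plane
    mask
}

# Default mask: cylinder two voxels beyond the epicardium over the wall's
# axial extent (one slice margin).
defaultMask <- function(spec) {
    cylindricalMask(spec@gridShape,
                    radius = spec@epicardialRadius / spec@voxelSize + 2,
                    zRange = c(max(1L, spec@zExtent[1L] - 1L),
                               min(spec@gridShape[3L], spec@zExtent[2L] + 1L)))
}

#' Post-process a reconstructed gated series
#'
#' Applies 3-D Gaussian smoothing (mirror boundary) followed by a binary
#' mask that removes extracardiac activity, in that order.
#'
#' @param series a [GatedImageSeries-class].
#' @param sigma smoothing standard deviation in voxels (default 1; 0
#'   disables smoothing).
#' @param mask logical array matching the grid, e.g. from
#'   [cylindricalMask()]; NULL keeps everything.
#' @return A [GatedImageSeries-class].
#' @export
postprocessSeries <- function(series, sigma = 1, mask = NULL) {
    stopifnot(is(series, "GatedImageSeries"))
    if (sigma < 0) stop("sigma must be >= 0")
    d <- dim(series@data)
    if (!is.null(mask)) {
        if (!identical(dim(mask), d[1:3])) stop("mask shape mismatch")
        if (!any(mask)) stop("mask excludes every voxel")
    }
    out <- series@data
    for (b in seq_len(d[4L])) {
        v <- gaussianSmooth3D(out[, , , b], sigma)
        if (!is.null(mask)) v <- v * mask
        out[, , , b] <- v
    }
    new("GatedImageSeries", data = out, voxelSize = series@voxelSize,
        provenance = c(series@provenance, list(smoothed = sigma,
                                               masked = !is.null(mask))))
}

#' Poisson log-likelihood of a gated-bin image
#'
#' \eqn{\sum_l \sum_{u} [ g \log(\max(Hf, \epsilon)) - Hf ]}, the objective
#' MLEM monotonically increases.
#'
#' @param f image array.
#' @param g projection array \code{[angle, u, v]}.
#' @param model a [SystemModel-class].
#' @param tau per-angle acquisition times (TOSEM).
#' @param epsilon floor inside the logarithm.
#' @return numeric(1).
#' @export
poissonLogLik <- function(f, g, model, tau = NULL, epsilon = 1e-12) {
    tosem <- model@mode == "tosem"
    ll <- 0
    for (l in seq_along(model@geometry@angles)) {
        tl <- if (tosem) tau[l] else 1
        fp <- tl * forwardProject(f, l, model)
        ll <- ll + sum(g[l, , ] * log(pmax(fp, epsilon)) - fp)
    }
    ll
}
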