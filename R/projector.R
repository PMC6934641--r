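#' Parallel-beam acquisition geometry
#'
#' Desk-scale default: 32 projection angles evenly spaced over 180 degrees
#' on a circular orbit of 150 mm.  \code{clinicalScale = TRUE} switches to the
#' clinical preset of 64 angles over 180 degrees with 96 x 96 detector bins
#' of 6.22 mm.
#'
#' @param nAngles number of projection angles.
#' @param span angular span in degrees (angles are
#'   \code{span * (0:(nAngles-1)) / nAngles}).
#' @param nU,nV transaxial and axial detector bins; must match the image
#'   grid used for reconstruction.
#' @param binSize detector bin size in mm.
#' @param radius orbit radius in mm; scalar (circular) or per-angle vector
#'   (noncircular).
#' @param angles explicit angle list (overrides \code{nAngles}/\code{span}).
#' @param clinicalScale if TRUE, use the clinical-scale preset.
#' @return A [SpectGeometry-class].
#' @export
spectGeometry <- function(nAngles = 32L, span = 180, nU = 48L, nV = 16L,
                          binSize = 4, radius = 150, angles = NULL,
                          clinicalScale = FALSE) {
    if (clinicalScale) {
        nAngles <- 64L; nU <- 96L; binSize <- 6.22; radius <- 320
    }
    if (is.null(angles))
        angles <- span * (seq_len(nAngles) - 1L) / nAngles
    new("SpectGeometry", angles = as.numeric(angles), nU = as.integer(nU),
        nV = as.integer(nV), binSize = binSize, radius = radius)
}

#' Distance-dependent Gaussian collimator-detector response model
#'
#' Defaults (intrinsic FWHM 3 mm, 0.045 mm FWHM per mm distance, about
#' 7.5 mm FWHM at 10 cm) are typical of a low-energy high-resolution
#' parallel-hole collimator.
#'
#' @param fwhm0 intrinsic FWHM in mm.
#' @param slope mm of FWHM per mm of source-detector distance.
#' @return A [CDRModel-class].
#' @export
cdrModel <- function(fwhm0 = 3.0, slope = 0.045) {
    new("CDRModel", fwhm0 = fwhm0, slope = slope)
}

#' Build a Gaussian-interpolation rotation operator
#'
#' Each rotated-grid voxel takes the normalised Gaussian-weighted sum of the
#' source voxels within three kernel widths of its back-rotated centre
#' (weights proportional to \code{exp(-r^2 / (2 sigma^2))}, row-normalised).
#' When the back-rotated centre coincides with a grid node (to 1e-6 voxel)
#' the value is taken from that node alone, so rotation by 0 degrees is the
#' identity and rotation by 90 degrees on a square grid is a permutation.
#'
#' @param angle rotation angle in degrees (content rotated by this angle).
#' @param grid integer(2), transaxial grid shape (nx, ny).
#' @param sigma kernel width in voxels (default 0.42, about one voxel
#'   FWHM).
#' @return A [RotationOperator-class].
#' @export
buildRotation <- function(angle, grid, sigma = 0.42) {
    if (sigma <= 0) stop("sigma must be positive")
    nx <- as.integer(grid[1L]); ny <- as.integer(grid[2L])
    cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
    a <- -angle * pi / 180  # back-rotation of output centres
    out <- expand.grid(i = seq_len(nx), j = seq_len(ny))
    dx <- out$i - cx; dy <- out$j - cy
    sx <- cos(a) * dx - sin(a) * dy + cx
    sy <- sin(a) * dx + cos(a) * dy + cy
    half <- max(1L, ceiling(3 * sigma))
    off <- expand.grid(ox = -half:half, oy = -half:half)
    n <- nrow(out)
    rows <- cols <- d2s <- vector("list", nrow(off))
    r2max <- (3 * sigma)^2
    bx <- floor(sx); by <- floor(sy)
    for (k in seq_len(nrow(off))) {
        gx <- bx + off$ox[k]; gy <- by + off$oy[k]
        d2 <- (gx - sx)^2 + (gy - sy)^2
        ok <- d2 <= r2max & gx >= 1 & gx <= nx & gy >= 1 & gy <= ny
        rows[[k]] <- which(ok)
        cols[[k]] <- (gy[ok] - 1) * nx + gx[ok]
        d2s[[k]] <- d2[ok]
    }
    rows <- unlist(rows); cols <- unlist(cols); d2 <- unlist(d2s)
    w <- exp(-d2 / (2 * sigma^2))
    # snap rows whose back-rotated centre hits a grid node
    hit <- d2 < 1e-12
    if (any(hit)) {
        snapRows <- unique(rows[hit])
        drop <- rows %in% snapRows & !hit
        rows <- rows[!drop]; cols <- cols[!drop]; w <- w[!drop]
        w[rows %in% snapRows] <- 1
    }
    W <- Matrix::sparseMatrix(i = rows, j = cols, x = w, dims = c(n, n))
    rs <- Matrix::rowSums(W)
    rs[rs == 0] <- 1
    W <- Matrix::Diagonal(x = 1 / rs) %*% W
    new("RotationOperator", weights = methods::as(W, "CsparseMatrix"),
        angle = angle, sigma = sigma)
}

#' Apply a rotation operator to a 2-D slice or 3-D volume
#'
#' @param op a [RotationOperator-class].
#' @param x matrix (nx x ny) or array (nx x ny x nz); each transaxial slice
#'   is rotated.
#' @return object of the same shape.
#' @export
applyRotation <- function(op, x) {
    d <- dim(x)
    m <- if (length(d) == 2L) matrix(as.numeric(x), ncol = 1L)
         else matrix(as.numeric(x), d[1L] * d[2L], d[3L])
    y <- as.matrix(op@weights %*% m)
    array(y, d)
}

# Per-depth CDR kernel cubes for one orbit radius.
cdrKernels <- function(cdr, radius, nDepth, nU, nV, voxel) {
    cx <- (nDepth + 1) / 2
    ku <- array(0, c(nU, nU, nDepth))
    kv <- array(0, c(nV, nV, nDepth))
    for (i in seq_len(nDepth)) {
        d <- max(0, radius - (i - cx) * voxel)
        sig <- (cdr@fwhm0 + cdr@slope * d) / 2.3548 / voxel
        ku[, , i] <- gaussKernelMatrix(nU, sig)
        kv[, , i] <- gaussKernelMatrix(nV, sig)
    }
    list(ku = ku, kv = kv)
}

# Banded matrix of a normalised discrete Gaussian; near-zero sigma gives the
# identity (pure ray sum).
gaussKernelMatrix <- function(n, sigma) {
    if (sigma < 1e-6) return(diag(n))
    half <- ceiling(3 * sigma)
    w <- exp(-((-half):half)^2 / (2 * sigma^2))
    w <- w / sum(w)
    K <- matrix(0, n, n)
    for (j in seq_along(w)) {
        o <- j - half - 1L
        idx <- seq_len(n)
        src <- idx - o
        ok <- src >= 1L & src <= n
        K[cbind(idx[ok], src[ok])] <- K[cbind(idx[ok], src[ok])] + w[j]
    }
    K
}

#' Build a system model
#'
#' Precomputes the Gaussian-interpolation rotation operator for every
#' projection angle and the per-depth collimator-response kernels, and
#' caches per-angle sensitivity backprojections as they are first needed.
#'
#' @param geometry a [SpectGeometry-class]; \code{nU}/\code{nV} must equal
#'   the grid's y/z extent and \code{binSize} the voxel size.
#' @param cdr a [CDRModel-class].
#' @param gridShape integer(3), image grid.
#' @param voxelSize voxel size in mm.
#' @param mode \code{"osem"} (acquisition time ignored) or \code{"tosem"}
#'   (transition-matrix blocks scaled by per-angle acquisition time).
#' @param sigmaR rotation kernel width in voxels.
#' @return A [SystemModel-class].
#' @export
systemModel <- function(geometry = spectGeometry(), cdr = cdrModel(),
                        gridShape = c(48L, 48L, 16L), voxelSize = 4,
                        mode = c("osem", "tosem"), sigmaR = 0.42) {
    mode <- match.arg(mode)
    gridShape <- as.integer(gridShape)
    if (abs(geometry@binSize - voxelSize) > 1e-9)
        stop("detector bin size must equal the voxel size")
    cache <- new.env(parent = emptyenv())
    model <- new("SystemModel", geometry = geometry, cdr = cdr,
                 gridShape = gridShape, voxelSize = voxelSize, mode = mode,
                 sigmaR = sigmaR, cache = cache)
    L <- length(geometry@angles)
    cache$rot <- lapply(seq_len(L), function(l)
        buildRotation(-geometry@angles[l], gridShape[1:2], sigmaR))
    radii <- if (length(geometry@radius) == 1L)
        rep(geometry@radius, L) else geometry@radius
    uniq <- unique(radii)
    kern <- lapply(uniq, function(r)
        cdrKernels(cdr, r, gridShape[1L], geometry@nU, geometry@nV, voxelSize))
    cache$kernels <- kern[match(radii, uniq)]
    cache$bp1 <- vector("list", L)
    model
}

#' Forward project one angle
#'
#' Rotates the volume into the detector frame of angle \code{l}, blurs each
#' constant-distance plane with the distance-dependent Gaussian
#' collimator-detector response and sums along the ray axis.  The result is
#' in expected counts per second per detector bin when the input is in
#' counts per second per voxel; the acquisition-time factor of TOSEM is
#' applied by the reconstruction, not here.
#'
#' @param f numeric array \code{[x, y, z]} (finite, non-negative for
#'   physical use).
#' @param l projection angle index.
#' @param model a [SystemModel-class].
#' @return numeric matrix \code{[u, v]}.
#' @export
forwardProject <- function(f, l, model) {
    g <- model@gridShape
    if (!identical(dim(f), as.integer(g)))
        stop("image shape does not match the model grid")
    rot <- applyRotation(model@cache$rot[[l]], f)
    cube <- aperm(rot, c(2L, 3L, 1L))  # (u = y, v = z, depth = x)
    k <- model@cache$kernels[[l]]
    .cdrBlurSum(cube, k$ku, k$kv)
}

#' Back project one angle (exact adjoint of [forwardProject()])
#'
#' @param p numeric matrix \code{[u, v]}.
#' @param l projection angle index.
#' @param model a [SystemModel-class].
#' @return numeric array \code{[x, y, z]}.
#' @export
backProject <- function(p, l, model) {
    g <- model@gridShape
    if (!identical(as.integer(dim(p)),
                   as.integer(c(model@geometry@nU, model@geometry@nV))))
        stop("projection shape does not match the detector")
    k <- model@cache$kernels[[l]]
    cube <- .cdrBlurSpread(p, k$ku, k$kv)
    arr <- aperm(cube, c(3L, 1L, 2L))
    m <- matrix(as.numeric(arr), g[1L] * g[2L], g[3L])
    y <- as.matrix(Matrix::crossprod(model@cache$rot[[l]]@weights, m))
    array(y, g)
}

# Cached backprojection of a unit projection (per-angle sensitivity term).
backProjectOnes <- function(l, model) {
    b <- model@cache$bp1[[l]]
    if (is.null(b)) {
        ones <- matrix(1, model@geometry@nU, model@geometry@nV)
        b <- backProject(ones, l, model)
        model@cache$bp1[[l]] <- b
    }
    b
}
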