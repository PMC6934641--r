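# Shared small fixtures: a reduced LV phantom and camera so that unit tests
# run in fractions of a second.  Models are built once per test run.

tinySpec <- function(...) {
    lvPhantomSpec(gridShape = c(24L, 24L, 8L), voxelSize = 4,
                  epicardialRadius = 20, endocardialRadius = 14,
                  zExtent = c(2L, 7L), ...)
}

tinyGeometry <- function(nAngles = 16L)
    spectGeometry(nAngles = nAngles, nU = 24L, nV = 8L, binSize = 4,
                  radius = 100)

.fixtures <- new.env()

tinyModel <- function(mode = "osem") {
    key <- paste0("model_", mode)
    if (is.null(.fixtures[[key]]))
        .fixtures[[key]] <- systemModel(tinyGeometry(), cdrModel(),
                                        c(24L, 24L, 8L), 4, mode)
    .fixtures[[key]]
}

# Single-voxel system: one angle, no blur, identity rotation.  The EM
# update reduces to its scalar closed form on it.
microModel <- function(mode = "osem") {
    key <- paste0("micro_", mode)
    if (is.null(.fixtures[[key]]))
        .fixtures[[key]] <- systemModel(
            spectGeometry(nAngles = 1L, nU = 1L, nV = 1L, binSize = 1,
                          radius = 10),
            cdrModel(fwhm0 = 0, slope = 0), c(1L, 1L, 1L), 1, mode)
    .fixtures[[key]]
}

# Noiseless projections of an image under a model (per-bin layout
# [angle, u, v]), optionally scaled by per-angle times.
projectAll <- function(f, model, tau = NULL) {
    L <- length(projectionAngles(model))
    g <- array(0, c(L, dim(f)[2L], dim(f)[3L]))
    for (l in seq_len(L)) {
        tl <- if (is.null(tau)) 1 else tau[l]
        g[l, , ] <- tl * forwardProject(f, l, model)
    }
    g
}

circMean <- function(p) {
    r <- p * pi / 180
    (atan2(mean(sin(r)), mean(cos(r))) * 180 / pi) %% 360
}
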