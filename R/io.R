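#' Write and read a gated image series as 4-D NIfTI
#'
#' The series is stored as a single 4-D file (x, y, z, ECG bin) in double
#' precision with the voxel size in the pixdim header fields; provenance is
#' stored in a JSON sidecar next to the image.
#'
#' @param series a [GatedImageSeries-class].
#' @param path output file (".nii" or ".nii.gz").
#' @return \code{writeGatedSeries} returns \code{path} invisibly;
#'   \code{readGatedSeries} returns a [GatedImageSeries-class].
#' @export
writeGatedSeries <- function(series, path) {
    stopifnot(is(series, "GatedImageSeries"))
    img <- RNifti::asNifti(series@data)
    RNifti::pixdim(img) <- c(rep(series@voxelSize, 3L), 1)
    RNifti::writeNifti(img, path, datatype = "double")
    side <- sidecarPath(path)
    jsonlite::write_json(series@provenance, side, auto_unbox = TRUE,
                         digits = NA, null = "null")
    invisible(path)
}

#' @rdname writeGatedSeries
#' @export
readGatedSeries <- function(path) {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 4L)
        stop("format error: expected a 4-D (x, y, z, bin) NIfTI file")
    pd <- RNifti::pixdim(img)
    side <- sidecarPath(path)
    prov <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
            else list()
    new("GatedImageSeries", data = array(as.numeric(img), d),
        voxelSize = pd[1L], provenance = as.list(prov))
}

sidecarPath <- function(path)
    paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")

#' Write and read a gated sinogram container
#'
#' The counts live in a 4-D NIfTI file (angle, ECG bin, u, v) and the named
#' metadata datasets — acquisition-time map \code{tau} (angle x bin),
#' \code{angles}, \code{rr_intervals} and the detector bin size — in a JSON
#' sidecar.  Reading enforces integer counts and consistent shapes.
#'
#' @param sino a [GatedSinogram-class].
#' @param tau acquisition-time matrix (angle x bin).
#' @param path output file for the counts (".nii" or ".nii.gz"); the
#'   sidecar takes the same name with a ".json" extension.
#' @param rrIntervals optional R-R series to store alongside.
#' @return \code{writeGatedSinogram} returns \code{path} invisibly;
#'   \code{readGatedSinogram} returns a list with \code{sinogram},
#'   \code{tau} and \code{rrIntervals}.
#' @export
writeGatedSinogram <- function(sino, tau, path, rrIntervals = NULL) {
    stopifnot(is(sino, "GatedSinogram"))
    d <- dim(sino@counts)
    if (!identical(dim(tau), d[1:2]))
        stop("tau shape must be angles x bins, matching the counts")
    img <- RNifti::asNifti(sino@counts)
    RNifti::writeNifti(img, path, datatype = "int32")
    meta <- list(tau = unname(apply(tau, 1L, identity, simplify = FALSE)),
                 angles = sino@angles, bin_size = sino@binSize,
                 rr_intervals = rrIntervals)
    jsonlite::write_json(meta, sidecarPath(path), auto_unbox = FALSE,
                         digits = NA, null = "null")
    invisible(path)
}

#' @rdname writeGatedSinogram
#' @export
readGatedSinogram <- function(path) {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 4L)
        stop("format error: expected a 4-D (angle, bin, u, v) counts file")
    side <- sidecarPath(path)
    if (!file.exists(side)) stop("format error: missing metadata sidecar")
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    for (ds in c("tau", "angles", "bin_size"))
        if (is.null(meta[[ds]]))
            stop(sprintf("format error: missing dataset '%s'", ds))
    cnt <- array(as.numeric(img), d)
    if (max(abs(cnt - round(cnt))) > 0)
        stop("format error: counts must be integer")
    storage.mode(cnt) <- "integer"
    tau <- if (is.matrix(meta$tau)) {
        matrix(as.numeric(meta$tau), nrow(meta$tau))
    } else {
        do.call(rbind, lapply(meta$tau, as.numeric))
    }
    if (!identical(dim(tau), d[1:2]))
        stop("format error: tau shape does not match the counts")
    if (length(meta$angles) != d[1L])
        stop("format error: angle list does not match the counts")
    list(sinogram = new("GatedSinogram", counts = cnt,
                        angles = as.numeric(meta$angles),
                        binSize = as.numeric(meta$bin_size)),
         tau = tau,
         rrIntervals = if (is.null(meta$rr_intervals)) NULL
                       else as.numeric(meta$rr_intervals))
}

# Allowed keys of the run configuration schema.
runConfigSchema <- function() {
    list(
        seed = NULL, output = NULL, verbosity = NULL,
        geometry = c("n_angles", "span", "n_u", "n_v", "bin_size", "radius",
                     "clinical_scale"),
        gating = c("n_bins", "acceptance_window"),
        recon = c("iterations", "subsets", "epsilon", "mode"),
        phase = c("n_theta", "n_z", "amplitude_cut", "bw_coverage"),
        population = c("n_subjects", "mean_rr_range", "hrv_range",
                       "delay_range", "n_delayed_sectors"),
        phantom = c("grid", "voxel_size", "epi_radius", "endo_radius",
                    "wall_activity", "background_activity",
                    "contraction_fraction", "n_sectors", "z_extent"),
        acquisition = c("dwell_time")
    )
}

#' Read and validate a run configuration
#'
#' YAML configuration with sections \code{geometry}, \code{gating},
#' \code{recon}, \code{phase}, \code{population}, \code{phantom},
#' \code{acquisition} plus top-level \code{seed}, \code{output} and
#' \code{verbosity}.  Unknown sections or keys are rejected before any
#' stage runs.
#'
#' @param path YAML file.
#' @return named list of validated sections.
#' @export
readRunConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    schema <- runConfigSchema()
    unknown <- setdiff(names(cfg), names(schema))
    if (length(unknown))
        stop("unknown configuration section(s): ",
             paste(unknown, collapse = ", "))
    for (sec in names(cfg)) {
        allowed <- schema[[sec]]
        if (is.null(allowed)) next
        bad <- setdiff(names(cfg[[sec]]), allowed)
        if (length(bad))
            stop(sprintf("unknown key(s) in section '%s': %s", sec,
                         paste(bad, collapse = ", ")))
    }
    cfg
}
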