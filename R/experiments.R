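#' Synthetic population specification
#'
#' Defaults emulate an unselected perfusion-SPECT population: 44 subjects,
#' mean R-R drawn uniformly from 0.8-1.0 s, normalized R-R variability
#' spanning 0.02-0.12 (assigned as an evenly spaced grid so the whole range
#' is always covered), and a contiguous pair of delayed sectors per subject
#' with contraction delay drawn from 0-90 degrees.  All per-subject draws
#' and seeds derive deterministically from the master seed.
#'
#' @param nSubjects number of subjects (44 by default for the population
#'   studies; the thinning/reliability study typically uses 14).
#' @param meanRRRange seconds.
#' @param hrvRange normalized R-R standard deviation range.
#' @param delayRange degrees of contraction delay for the delayed sectors.
#' @param nDelayedSectors number of adjacent delayed sectors.
#' @param masterSeed integer.
#' @return A [PopulationSpec-class].
#' @export
populationSpec <- function(nSubjects = 44L, meanRRRange = c(0.8, 1.0),
                           hrvRange = c(0.02, 0.12), delayRange = c(0, 90),
                           nDelayedSectors = 2L, masterSeed = 1L) {
    new("PopulationSpec", nSubjects = as.integer(nSubjects),
        meanRRRange = as.numeric(meanRRRange), hrvRange = as.numeric(hrvRange),
        delayRange = as.numeric(delayRange),
        nDelayedSectors = as.integer(nDelayedSectors),
        masterSeed = as.integer(masterSeed))
}

#' Draw the per-subject parameter table of a population
#'
#' @param pop a [PopulationSpec-class].
#' @param nSectors number of phantom sectors.
#' @return data.frame with one row per subject: \code{meanRR},
#'   \code{sdNorm}, \code{delay}, \code{delayStart}, \code{seed}.
#' @export
subjectParams <- function(pop, nSectors = 6L) {
    set.seed(pop@masterSeed)
    n <- pop@nSubjects
    hrv <- seq(pop@hrvRange[1L], pop@hrvRange[2L], length.out = n)
    data.frame(
        subject = seq_len(n),
        meanRR = runif(n, pop@meanRRRange[1L], pop@meanRRRange[2L]),
        sdNorm = hrv[sample.int(n)],
        delay = runif(n, pop@delayRange[1L], pop@delayRange[2L]),
        delayStart = sample.int(nSectors, n, replace = TRUE),
        seed = sample.int(.Machine$integer.max - 1L, n))
}

# Phantom spec for one subject: nDelayed adjacent sectors share the delay.
subjectPhantom <- function(par, template, nDelayed) {
    delay <- template@sectorDelay
    idx <- ((par$delayStart - 1L + seq_len(nDelayed) - 1L) %%
            template@nSectors) + 1L
    delay[idx] <- par$delay
    methods::initialize(template, sectorDelay = delay)
}

# Simulate one subject's gated acquisition.
simulateSubject <- function(par, template, model, gate, dwellTime,
                            nDelayed = 2L) {
    spec <- subjectPhantom(par, template, nDelayed)
    L <- length(model@geometry@angles)
    beats <- generateRRSeries(par$meanRR, par$sdNorm * par$meanRR,
                              totalTime = L * dwellTime + 2 * par$meanRR,
                              seed = par$seed)
    sim <- simulateGatedSinogram(spec, beats, model, gate, dwellTime,
                                 seed = par$seed + 1L)
    sim$spec <- spec
    sim
}

# Shared experiment machinery: models, recon + phase of one sinogram.
experimentModels <- function(geometry, cdr, gridShape, voxelSize, sigmaR) {
    list(osem = systemModel(geometry, cdr, gridShape, voxelSize, "osem", sigmaR),
         tosem = systemModel(geometry, cdr, gridShape, voxelSize, "tosem", sigmaR))
}

reconAndPhase <- function(sino, tau, model, cfg, spec, grid, sigma = 1) {
    series <- reconstructSeries(sino, tau, model, cfg)
    post <- postprocessSeries(series, sigma = sigma, mask = defaultMask(spec))
    list(series = post, phase = phaseAnalysis(post, grid),
         ar = activityRatio(post))
}

#' Association between heart-rate variability and last-bin data shortage
#'
#' For each subject: simulate the gated acquisition, reconstruct with plain
#' OSEM, post-process, and compute the activity ratio (AR) and the
#' normalized standard deviation of the accepted R-R intervals (SD_R-R).
#' Returns the scatter table and their Pearson correlation.
#'
#' @param pop a [PopulationSpec-class].
#' @param template phantom template ([LVPhantomSpec-class]).
#' @param geometry,cdr,recon acquisition and reconstruction settings.
#' @param gate a [GateConfig-class].
#' @param dwellTime seconds per projection angle.
#' @param verbose print per-subject progress.
#' @return list with \code{table} (subject, sdRR, ar) and \code{r}
#'   (Pearson correlation; NA with a warning when SD_R-R is degenerate).
#' @export
runPart1 <- function(pop, template = lvPhantomSpec(),
                     geometry = spectGeometry(), cdr = cdrModel(),
                     gate = gateConfig(), recon = reconConfig(),
                     dwellTime = 10, verbose = FALSE) {
    model <- systemModel(geometry, cdr, template@gridShape,
                         template@voxelSize, "osem")
    pars <- subjectParams(pop, template@nSectors)
    grid <- midWallSamplingGrid(template)
    rows <- lapply(seq_len(nrow(pars)), function(i) {
        par <- pars[i, ]
        sim <- simulateSubject(par, template, model, gate, dwellTime,
                               pop@nDelayedSectors)
        series <- reconstructSeries(sim$sinogram, tau = NULL, model, recon)
        post <- postprocessSeries(series, 1, defaultMask(sim$spec))
        if (verbose)
            message(sprintf("part1 subject %d/%d: SD_R-R %.3f, AR %.1f%%",
                            i, nrow(pars), sim$acceptance@sdRRNormalized,
                            activityRatio(post)))
        data.frame(subject = par$subject,
                   sdRR = sim$acceptance@sdRRNormalized,
                   ar = activityRatio(post))
    })
    tab <- do.call(rbind, rows)
    r <- if (sd(tab$sdRR) == 0 || sd(tab$ar) == 0) {
        warning("degenerate population: correlation undefined")
        NA_real_
    } else pearsonR(tab$sdRR, tab$ar)
    list(table = tab, r = r)
}

# Thin a subject's sinogram to a target count ratio, optionally refining
# the retention probability against a reconstructed activity ratio.
thinToAR <- function(sino, tau, target, seed, refine = FALSE, model = NULL,
                     cfg = NULL, spec = NULL) {
    th <- thinLastBin(sino, tau, target, seed)
    if (refine) {
        series <- reconstructSeries(th$sinogram, NULL, model, cfg)
        arRec <- activityRatio(postprocessSeries(series, 1,
                                                 defaultMask(spec))) / 100
        adj <- target * target / arRec
        th <- thinLastBin(sino, tau, min(adj, sinogramCountRatio(sino)), seed)
    }
    th
}

#' Reliability of phase analysis under last-bin count reduction
#'
#' Emulates the list-mode rebinning study: each subject's last ECG bin is
#' thinned to a set of activity-ratio levels, each level is reconstructed
#' (OSEM and/or TOSEM), phase analysis is run, and Lin's CCC is computed
#' for each dyssynchrony index between the top level and every lower
#' level across subjects.
#'
#' Subjects whose native (unthinned) last-bin count ratio is below the top
#' level cannot be thinned to it.  With \code{levelPolicy = "exclude"}
#' (default, mirroring the selection of patients with AR above the top
#' level) they are dropped with a log entry; with \code{levelPolicy =
#' "cap"} each subject's level is capped at its native ratio, so every
#' subject is retained and the top "level" of a high-variability subject is
#' its native data.
#'
#' @param pop a [PopulationSpec-class].
#' @param arLevels target count-ratio levels, decreasing, in (0, 1].
#' @param modes reconstruction algorithms to run.
#' @param levelPolicy \code{"exclude"} or \code{"cap"}.
#' @param refine recalibrate thinning against a reconstructed activity
#'   ratio (one extra OSEM reconstruction per level).
#' @param template,geometry,cdr,gate,recon,dwellTime as in [runPart1()].
#' @param verbose print per-subject progress.
#' @return list with \code{phase} (long table: subject, level, mode, BW,
#'   StD, ENT, effective ratio), \code{ccc} (mode, index, level, ccc, r,
#'   cb), and \code{excluded} (subject ids).
#' @export
runPart2 <- function(pop, arLevels = c(0.9, 0.8, 0.7, 0.6, 0.5),
                     modes = c("osem", "tosem"),
                     levelPolicy = c("exclude", "cap"), refine = FALSE,
                     template = lvPhantomSpec(), geometry = spectGeometry(),
                     cdr = cdrModel(), gate = gateConfig(),
                     recon = reconConfig(), dwellTime = 10, verbose = FALSE) {
    levelPolicy <- match.arg(levelPolicy)
    arLevels <- sort(arLevels, decreasing = TRUE)
    models <- experimentModels(geometry, cdr, template@gridShape,
                               template@voxelSize, 0.42)
    pars <- subjectParams(pop, template@nSectors)
    grid <- midWallSamplingGrid(template)
    excluded <- integer(0)
    rows <- list()
    for (i in seq_len(nrow(pars))) {
        par <- pars[i, ]
        sim <- simulateSubject(par, template, models$osem, gate, dwellTime,
                               pop@nDelayedSectors)
        native <- sinogramCountRatio(sim$sinogram)
        if (levelPolicy == "exclude" && native < max(arLevels)) {
            message(sprintf("part2: subject %d excluded (native ratio %.2f below top level %.2f)",
                            par$subject, native, max(arLevels)))
            excluded <- c(excluded, par$subject)
            next
        }
        for (k in seq_along(arLevels)) {
            target <- if (levelPolicy == "cap") min(arLevels[k], native)
                      else arLevels[k]
            th <- thinToAR(sim$sinogram, sim$tau, target,
                           seed = par$seed + k, refine = refine,
                           model = models$osem, cfg = recon, spec = sim$spec)
            for (m in modes) {
                res <- reconAndPhase(th$sinogram, th$tau, models[[m]],
                                     recon, sim$spec, grid)
                rows[[length(rows) + 1L]] <- data.frame(
                    subject = par$subject, level = arLevels[k],
                    effectiveRatio = target, mode = m,
                    bw = res$phase@bw, std = res$phase@std,
                    ent = res$phase@ent, ar = res$ar)
            }
        }
        if (verbose)
            message(sprintf("part2 subject %d/%d done (native ratio %.2f)",
                            i, nrow(pars), native))
    }
    phase <- do.call(rbind, rows)
    if (is.null(phase)) stop("no subjects retained in part 2")
    top <- max(arLevels)
    cccRows <- list()
    for (m in unique(phase$mode)) {
        for (idx in c("bw", "std", "ent")) {
            ref <- phase[phase$mode == m & phase$level == top, ]
            ref <- ref[order(ref$subject), ]
            for (lev in arLevels) {
                cmp <- phase[phase$mode == m & phase$level == lev, ]
                cmp <- cmp[order(cmp$subject), ]
                # the top level against itself is the trivial ccc = 1;
                # fewer than three retained subjects leave ccc undefined
                cc <- if (nrow(ref) < 3L) {
                    warning("fewer than three retained subjects: CCC undefined")
                    new("CCCResult", ccc = NA_real_, r = NA_real_, cb = 1,
                        sdX = 0, sdY = 0, covXY = 0, meanX = 0, meanY = 0,
                        sample = FALSE)
                } else linCCC(ref[[idx]], cmp[[idx]])
                cccRows[[length(cccRows) + 1L]] <- data.frame(
                    mode = m, index = toupper(idx), level = lev,
                    ccc = cc@ccc, r = cc@r, cb = cc@cb)
            }
        }
    }
    list(phase = phase, ccc = do.call(rbind, cccRows), excluded = excluded)
}

#' OSEM vs TOSEM differences across a population
#'
#' Each subject's native (unthinned) gated data are reconstructed with both
#' OSEM and TOSEM; phase analysis is run on both, and the changes of the
#' dyssynchrony indices (TOSEM minus OSEM) are correlated with the
#' activity ratio.
#'
#' @inheritParams runPart1
#' @return list with \code{table} (per subject: sdRR, ar, indices per
#'   mode, deltas) and \code{correlations} (named: AR vs dBW, dStD,
#'   dENT).
#' @export
runPart3 <- function(pop, template = lvPhantomSpec(),
                     geometry = spectGeometry(), cdr = cdrModel(),
                     gate = gateConfig(), recon = reconConfig(),
                     dwellTime = 10, verbose = FALSE) {
    models <- experimentModels(geometry, cdr, template@gridShape,
                               template@voxelSize, 0.42)
    pars <- subjectParams(pop, template@nSectors)
    grid <- midWallSamplingGrid(template)
    rows <- lapply(seq_len(nrow(pars)), function(i) {
        par <- pars[i, ]
        sim <- simulateSubject(par, template, models$osem, gate, dwellTime,
                               pop@nDelayedSectors)
        o <- reconAndPhase(sim$sinogram, sim$tau, models$osem, recon,
                           sim$spec, grid)
        t <- reconAndPhase(sim$sinogram, sim$tau, models$tosem, recon,
                           sim$spec, grid)
        d <- deltaPhaseParams(o$phase, t$phase)
        if (verbose)
            message(sprintf("part3 subject %d/%d: AR %.1f%%, dENT %.2f",
                            i, nrow(pars), o$ar, d[["dENT"]]))
        data.frame(subject = par$subject, sdRR = sim$acceptance@sdRRNormalized,
                   ar = o$ar,
                   bwOsem = o$phase@bw, stdOsem = o$phase@std,
                   entOsem = o$phase@ent,
                   bwTosem = t$phase@bw, stdTosem = t$phase@std,
                   entTosem = t$phase@ent,
                   dBW = d[["dBW"]], dStD = d[["dStD"]], dENT = d[["dENT"]])
    })
    tab <- do.call(rbind, rows)
    safeCor <- function(x, y) {
        if (length(x) < 3L || sd(x) == 0 || sd(y) == 0) {
            warning("degenerate population: correlation undefined")
            return(NA_real_)
        }
        pearsonR(x, y)
    }
    corrs <- c(dBW = safeCor(tab$ar, tab$dBW),
               dStD = safeCor(tab$ar, tab$dStD),
               dENT = safeCor(tab$ar, tab$dENT))
    list(table = tab, correlations = corrs)
}
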