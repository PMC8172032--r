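#' Band specification for the synthetic spectrum generator
#'
#' @param centre band centre, cm^-1.
#' @param amplitudeByClass named numeric vector: mean peak amplitude per
#'   class (arbitrary units).  Classes sharing one value make the band
#'   non-discriminative filler.
#' @param width half-width at half-maximum, cm^-1 (default 8, typical of
#'   tissue Raman bands).
#' @param shape `"lorentzian"` (the natural Raman line shape, default) or
#'   `"gaussian"`.
#' @return a list of class `"BandSpec"`.
#' @export
bandSpec <- function(centre, amplitudeByClass, width = 8,
                     shape = c("lorentzian", "gaussian")) {
    shape <- match.arg(shape)
    if (width <= 0) stop("width must be positive")
    if (any(amplitudeByClass < 0)) stop("amplitudes must be non-negative")
    if (is.null(names(amplitudeByClass)))
        stop("amplitudeByClass must be named by class")
    structure(list(centre = centre, width = width, shape = shape,
                   amplitudeByClass = amplitudeByClass),
              class = "BandSpec")
}

.bandProfile <- function(band, wn, amplitude) {
    d <- wn - band$centre
    if (band$shape == "lorentzian")
        amplitude / (1 + (d / band$width)^2)
    else
        amplitude * exp(-d^2 / (2 * (band$width / sqrt(2 * log(2)))^2))
}

#' Synthetic collection configuration
#'
#' Defines a labelled synthetic Raman data set: per-class Lorentzian (or
#' Gaussian) band templates, a fluorescence-like polynomial background, a
#' multiplicative log-normal patient amplitude effect (so patients — not
#' only spectra — differ, and spectrum-level splits leak patient identity
#' the way real map scans do), additive Gaussian channel noise, and
#' Poisson-count cosmic-ray spikes at uniform random channels.
#'
#' @param bands list of [bandSpec()] objects; all must name the same
#'   classes.
#' @param nPatientsByClass named integer vector: patients per class.
#' @param axis wavenumber axis (default [defaultAxis()]).
#' @param spectraPerPatient spectra in each patient's map scan (default
#'   100).
#' @param patientAmplitudeSd sdlog of the per-patient log-normal amplitude
#'   multiplier (default 0.10).
#' @param spectrumNoiseSd additive Gaussian noise sd per channel (default
#'   0.05).
#' @param baselineCoef polynomial coefficients (constant first) evaluated on
#'   the axis rescaled to `[0, 1]`; the default is a broad fluorescence-like
#'   hump.
#' @param spikeRate expected cosmic-ray spikes per spectrum (default 0.05).
#' @param spikeAmplitudeRange uniform range of spike heights (default
#'   5 to 50, far above any band).
#' @param seed integer RNG seed.
#' @return a validated list of class `"SyntheticConfig"`.
#' @export
syntheticConfig <- function(bands, nPatientsByClass,
                            axis = defaultAxis(), spectraPerPatient = 100L,
                            patientAmplitudeSd = 0.10,
                            spectrumNoiseSd = 0.05,
                            baselineCoef = c(3, 2, -3.5),
                            spikeRate = 0.05,
                            spikeAmplitudeRange = c(5, 50), seed = 1L) {
    if (!length(bands)) stop("at least one band is required")
    classes <- names(bands[[1L]]$amplitudeByClass)
    for (b in bands)
        if (!identical(sort(names(b$amplitudeByClass)), sort(classes)))
            stop("all bands must name the same classes")
    if (is.null(names(nPatientsByClass)) ||
        !all(names(nPatientsByClass) %in% classes))
        stop("nPatientsByClass must be named by the bands' classes")
    if (spectraPerPatient < 1L) stop("spectraPerPatient must be >= 1")
    if (patientAmplitudeSd < 0 || spectrumNoiseSd < 0 || spikeRate < 0)
        stop("sds and spikeRate must be non-negative")
    structure(list(axis = as.numeric(axis), bands = bands,
                   nPatientsByClass = nPatientsByClass,
                   spectraPerPatient = as.integer(spectraPerPatient),
                   patientAmplitudeSd = patientAmplitudeSd,
                   spectrumNoiseSd = spectrumNoiseSd,
                   baselineCoef = baselineCoef, spikeRate = spikeRate,
                   spikeAmplitudeRange = spikeAmplitudeRange,
                   seed = as.integer(seed)),
              class = "SyntheticConfig")
}

# Filler bands present identically in every class: common tissue Raman
# features, so classification cannot succeed on overall intensity alone.
.fillerBands <- function(classes) {
    centres <- c(621, 757, 852, 936, 1065, 1127, 1208, 1340, 1555, 1617)
    amps <- c(0.9, 1.2, 1.0, 0.8, 0.7, 1.1, 0.9, 1.5, 1.0, 0.8)
    mapply(function(ct, a)
        bandSpec(ct, stats::setNames(rep(a, length(classes)), classes)),
        centres, amps, SIMPLIFY = FALSE)
}

.discriminativeBands <- function(classes, amps, nPatients, ...) {
    centres <- c(1003, 1252, 1304, 1449, 1657)
    disc <- lapply(seq_along(centres), function(i)
        bandSpec(centres[i],
                 stats::setNames(vapply(amps, `[`, 0, i), classes)))
    args <- list(...)
    if (!is.null(args$nPatientsByClass)) {  # cohort override
        nPatients <- args$nPatientsByClass
        args$nPatientsByClass <- NULL
    }
    do.call(syntheticConfig,
            c(list(c(disc, .fillerBands(classes)), nPatients), args))
}

#' Default synthetic configurations mirroring the study designs
#'
#' `defaultUCConfig`: ulcerative-colitis mucosal-healing experiment — 33
#' active-inflammation and 9 mucosal-healing patients, 100 spectra each,
#' discriminative band amplitudes at 1003/1252/1304/1449/1657 cm^-1 set to
#' the reported relative intensities of the two class mean SOMDI spectra
#' (active: 3.30, 1.44, 1.27, 3.92, 1.93; healing: 2.69, 1.11, 1.54, 3.73,
#' 1.83), plus identical filler bands.  `defaultCDConfig` is the Crohn's
#' analogue (22 active / 10 healing; active: 3.60, 1.40, 1.30, 4.11, 2.32;
#' healing: 2.63, 1.40, 1.46, 3.30, 1.30).  `defaultThreeClassConfig` is
#' the pre- vs post-biologic vs healthy-control design for either disease.
#'
#' @param ... overrides passed to [syntheticConfig()] (e.g.
#'   `spectraPerPatient`, `spectrumNoiseSd`, `seed`).
#' @return a `"SyntheticConfig"` list.
#' @export
defaultUCConfig <- function(...) {
    .discriminativeBands(
        c("UC_active", "UC_MH"),
        list(UC_active = c(3.30, 1.44, 1.27, 3.92, 1.93),
             UC_MH = c(2.69, 1.11, 1.54, 3.73, 1.83)),
        c(UC_active = 33L, UC_MH = 9L), ...)
}

#' @rdname defaultUCConfig
#' @export
defaultCDConfig <- function(...) {
    .discriminativeBands(
        c("CD_active", "CD_MH"),
        list(CD_active = c(3.60, 1.40, 1.30, 4.11, 2.32),
             CD_MH = c(2.63, 1.40, 1.46, 3.30, 1.30)),
        c(CD_active = 22L, CD_MH = 10L), ...)
}

#' @rdname defaultUCConfig
#' @param disease `"UC"` or `"CD"` for the three-class design.
#' @export
defaultThreeClassConfig <- function(disease = c("UC", "CD"), ...) {
    disease <- match.arg(disease)
    if (disease == "UC")
        .discriminativeBands(
            c("pre_biologic", "post_biologic", "healthy_control"),
            list(pre_biologic = c(2.85, 1.13, 1.17, 3.42, 1.84),
                 post_biologic = c(2.72, 1.04, 1.10, 3.24, 1.68),
                 healthy_control = c(2.32, 0.99, 1.16, 2.91, 1.32)),
            c(pre_biologic = 6L, post_biologic = 6L, healthy_control = 9L),
            ...)
    else
        .discriminativeBands(
            c("pre_biologic", "post_biologic", "healthy_control"),
            list(pre_biologic = c(3.38, 1.32, 1.10, 3.66, 1.89),
                 post_biologic = c(2.49, 1.24, 1.05, 2.90, 1.84),
                 healthy_control = c(2.29, 0.98, 1.27, 2.87, 1.17)),
            c(pre_biologic = 8L, post_biologic = 8L, healthy_control = 9L),
            ...)
}

#' Band centres whose amplitude differs between classes
#'
#' @param config a `"SyntheticConfig"` list.
#' @return numeric vector of discriminative band centres, cm^-1.
#' @export
discriminativeCentres <- function(config) {
    stopifnot(inherits(config, "SyntheticConfig"))
    keep <- vapply(config$bands, function(b)
        diff(range(b$amplitudeByClass)) > 0, TRUE)
    vapply(config$bands[keep], `[[`, 0, "centre")
}

#' Simulate a labelled synthetic Raman collection
#'
#' For each class and patient a log-normal amplitude multiplier scales the
#' class band template; each spectrum adds the polynomial background,
#' Gaussian channel noise and a Poisson number of cosmic-ray spikes at
#' uniform random channels.  Every latent quantity (templates, baseline,
#' multipliers, spike positions and heights) is returned as ground truth,
#' and the whole draw is deterministic for a given seed.
#'
#' @param config a [syntheticConfig()] list.
#' @return list with `spectra` (a [RamanSpectra-class]) and `truth` (list:
#'   `config`, `classTemplates` channels x classes, `baseline`,
#'   `patientMultipliers`, `spikes` per-spectrum list of `channel` /
#'   `amplitude`).
#' @export
simulateCollection <- function(config) {
    stopifnot(inherits(config, "SyntheticConfig"))
    wn <- config$axis
    nch <- length(wn)
    classes <- names(config$nPatientsByClass)
    templates <- vapply(classes, function(cl)
        Reduce(`+`, lapply(config$bands, function(b)
            .bandProfile(b, wn, b$amplitudeByClass[[cl]]))),
        numeric(nch))
    u <- (wn - min(wn)) / diff(range(wn))
    baseline <- drop(outer(u, seq_along(config$baselineCoef) - 1, `^`) %*%
                     config$baselineCoef)
    set.seed(config$seed)
    nTot <- sum(config$nPatientsByClass) * config$spectraPerPatient
    ints <- matrix(0, nch, nTot)
    pids <- character(nTot)
    labs <- character(nTot)
    spikes <- vector("list", nTot)
    mult <- numeric(0)
    j <- 0L
    for (cl in classes) {
        for (p in seq_len(config$nPatientsByClass[[cl]])) {
            pid <- sprintf("%s_P%02d", cl, p)
            m <- rlnorm(1L, 0, config$patientAmplitudeSd)
            mult[pid] <- m
            clean <- m * templates[, cl] + baseline
            for (s in seq_len(config$spectraPerPatient)) {
                j <- j + 1L
                y <- clean
                if (config$spectrumNoiseSd > 0)
                    y <- y + rnorm(nch, 0, config$spectrumNoiseSd)
                ns <- rpois(1L, config$spikeRate)
                if (ns > 0L) {
                    ch <- sample.int(nch, ns)
                    amp <- runif(ns, config$spikeAmplitudeRange[1L],
                                 config$spikeAmplitudeRange[2L])
                    y[ch] <- y[ch] + amp
                    spikes[[j]] <- list(channel = ch, amplitude = amp)
                } else spikes[[j]] <- list(channel = integer(0),
                                           amplitude = numeric(0))
                ints[, j] <- y
                pids[j] <- pid
                labs[j] <- cl
            }
        }
    }
    spectra <- ramanSpectra(ints, wn, patientId = pids, classLabel = labs)
    list(spectra = spectra,
         truth = list(config = config, classTemplates = templates,
                      baseline = baseline, patientMultipliers = mult,
                      spikes = spikes))
}

#' Check pipeline outputs against planted synthetic truth
#'
#' Reports whichever of the following the supplied arguments allow:
#' despiking recall and false positives against planted spike positions;
#' per-band class amplitude recovery (peak height of baseline-corrected
#' mean class spectra vs configured amplitude) and the worst relative error
#' of between-class band-amplitude ratios; and whether a reported band
#' table covers the planted discriminative band set within a tolerance.
#'
#' @param sim the list returned by [simulateCollection()].
#' @param flagged per-spectrum list of despiked channel indices (from
#'   [despikeSpectra()] or the [runPreprocess()] audit).
#' @param corrected baseline-corrected, un-normalised [RamanSpectra-class]
#'   to score band recovery on.
#' @param bandTable data.frame with a `wavenumber` column (from
#'   [topDiscriminatingBands()]).
#' @param tol matching tolerance for band coverage, cm^-1 (default 10).
#' @return list with elements `spikeRecall`, `spikeFalsePositives`,
#'   `bandRecovery`, `maxRatioErrPct`, `bandCoverage` (those not computable
#'   from the inputs are `NULL`).
#' @export
truthCheck <- function(sim, flagged = NULL, corrected = NULL,
                       bandTable = NULL, tol = 10) {
    stopifnot(is.list(sim), !is.null(sim$truth))
    truth <- sim$truth
    config <- truth$config
    out <- list(spikeRecall = NULL, spikeFalsePositives = NULL,
                bandRecovery = NULL, maxRatioErrPct = NULL,
                bandCoverage = NULL)
    if (!is.null(flagged)) {
        if (length(flagged) != length(truth$spikes))
            stop("flagged list does not match simulated spectrum count")
        planted <- hit <- fp <- 0L
        for (j in seq_along(flagged)) {
            ch <- truth$spikes[[j]]$channel
            planted <- planted + length(ch)
            hit <- hit + sum(ch %in% flagged[[j]])
            fp <- fp + sum(!flagged[[j]] %in% ch)
        }
        out$spikeRecall <- if (planted) hit / planted else NA_real_
        out$spikeFalsePositives <- fp
    }
    if (!is.null(corrected)) {
        stopifnot(methods::is(corrected, "RamanSpectra"))
        labs <- classLabels(corrected)
        classes <- names(config$nPatientsByClass)
        centres <- discriminativeCentres(config)
        rec <- expand.grid(centre = centres, class = classes,
                           stringsAsFactors = FALSE)
        rec$configured <- mapply(function(ct, cl) {
            b <- config$bands[[which(vapply(config$bands, `[[`, 0,
                                            "centre") == ct)]]
            b$amplitudeByClass[[cl]]
        }, rec$centre, rec$class)
        rec$measured <- mapply(function(ct, cl) {
            cls <- corrected[, labs == cl]
            mn <- ramanSpectra(rowMeans(intensityMatrix(cls)),
                               wavenumbers(cls), "mean", cl)
            bandIntensity(mn, ct, halfWindow = 5)[[1L]]
        }, rec$centre, rec$class)
        rec$rel_err_pct <- 100 * (rec$measured / rec$configured - 1)
        out$bandRecovery <- rec
        # ratio of measured class amplitudes vs configured, worst band/pair
        ratioErr <- 0
        for (ct in centres) {
            sub <- rec[rec$centre == ct, ]
            for (i in seq_len(nrow(sub) - 1L)) for (k in (i + 1L):nrow(sub)) {
                got <- sub$measured[i] / sub$measured[k]
                want <- sub$configured[i] / sub$configured[k]
                ratioErr <- max(ratioErr, abs(got / want - 1) * 100)
            }
        }
        out$maxRatioErrPct <- ratioErr
    }
    if (!is.null(bandTable)) {
        centres <- discriminativeCentres(config)
        out$bandCoverage <- vapply(centres, function(ct)
            any(abs(bandTable$wavenumber - ct) <= tol), TRUE)
        names(out$bandCoverage) <- centres
    }
    out
}
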