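#' Preprocessing configuration
#'
#' Bundles the parameters of the spectral conditioning chain, applied in the
#' fixed order despike -> baseline -> crop -> normalise (spikes corrupt
#' baseline fits; normalisation only makes sense after background removal).
#'
#' @param despikeWindow odd integer >= 3, channel window for spike
#'   replacement.
#' @param despikeZThreshold positive modified z-score threshold on the
#'   first-difference series.
#' @param baselineLambda second-difference penalty weight of the asymmetric
#'   least-squares baseline (larger = stiffer baseline).
#' @param baselineP asymmetry parameter in (0, 0.5): weight given to points
#'   above the running baseline estimate.
#' @param baselineIterations fixed-point reweighting iterations.
#' @param cropLow,cropHigh retained wavenumber range, cm^-1 (closed
#'   interval; the fingerprint window 550-1670 by default).
#' @param normalisation `"vector_l2"`, `"area"` or `"none"`.
#' @return a validated list of class `"PreprocessConfig"`.
#' @export
preprocessConfig <- function(despikeWindow = 7L, despikeZThreshold = 8,
                             baselineLambda = 1e5, baselineP = 0.01,
                             baselineIterations = 10L,
                             cropLow = 550, cropHigh = 1670,
                             normalisation = c("vector_l2", "area", "none")) {
    normalisation <- match.arg(normalisation)
    despikeWindow <- as.integer(despikeWindow)
    if (despikeWindow < 3L || despikeWindow %% 2L == 0L)
        stop("despikeWindow must be an odd integer >= 3")
    if (despikeZThreshold <= 0) stop("despikeZThreshold must be positive")
    if (baselineLambda <= 0) stop("baselineLambda must be positive")
    if (baselineP <= 0 || baselineP >= 0.5)
        stop("baselineP must lie in (0, 0.5)")
    if (baselineIterations < 1L) stop("baselineIterations must be >= 1")
    if (cropLow >= cropHigh) stop("cropLow must be < cropHigh")
    structure(list(despikeWindow = despikeWindow,
                   despikeZThreshold = despikeZThreshold,
                   baselineLambda = baselineLambda, baselineP = baselineP,
                   baselineIterations = as.integer(baselineIterations),
                   cropLow = cropLow, cropHigh = cropHigh,
                   normalisation = normalisation),
              class = "PreprocessConfig")
}

# Modified z-scores of a first-difference series.  MAD is the primary
# scale, with two guards for (near-)noiseless spectra where a robust scale
# collapses toward zero and every smooth feature would otherwise blow up:
# the mean absolute deviation takes over when MAD is exactly 0, and the
# scale is floored at 1% of the spectrum's intensity range (cosmic-ray
# impulses are far larger than that; smooth band slopes are not).
.diffZ <- function(d, yrange) {
    med <- median(d)
    dev <- abs(d - med)
    madv <- median(dev)
    scale <- if (madv > 0) madv / 0.6745 else mean(dev) * 1.253314
    scale <- max(scale, 0.01 * yrange)
    if (scale == 0) return(rep(0, length(d)))
    dev / scale
}

# Despike one intensity vector.  A cosmic-ray hit is an impulse: the two
# first differences flanking the channel are both extreme and of opposite
# sign (band edges produce runs of same-sign differences and are left
# alone).  Boundary channels use the single available difference, provided
# the inner neighbour was not itself the impulse.
.despike1 <- function(y, window, zthr) {
    n <- length(y)
    if (window > n)
        stop(sprintf("despike window (%d) larger than spectrum length (%d)",
                     window, n))
    d <- diff(y)
    z <- .diffZ(d, diff(range(y)))
    hi <- z > zthr
    flagged <- logical(n)
    i <- 2:(n - 1L)
    flagged[i] <- hi[i - 1L] & hi[i] & (sign(d[i - 1L]) * sign(d[i]) < 0)
    if (hi[1L] && !flagged[2L]) flagged[1L] <- TRUE
    if (hi[n - 1L] && !flagged[n - 1L]) flagged[n] <- TRUE
    idx <- which(flagged)
    if (length(idx)) {
        half <- (window - 1L) %/% 2L
        for (i in idx) {
            nb <- max(1L, i - half):min(n, i + half)
            nb <- setdiff(nb, idx)
            while (!length(nb)) {  # widen until a clean neighbour exists
                half <- half * 2L
                nb <- setdiff(max(1L, i - half):min(n, i + half), idx)
            }
            y[i] <- median(y[nb])
        }
    }
    list(y = y, flagged = idx)
}

#' Remove cosmic-ray spikes
#'
#' Channels whose modified z-score of the first-difference series exceeds
#' `zThreshold` in the impulse pattern characteristic of a cosmic-ray hit
#' are replaced by the median of unflagged neighbours within `window`
#' channels.  Only flagged channels change, and re-running the filter flags
#' nothing new.
#'
#' @param x a [RamanSpectra-class] object.
#' @param window odd integer replacement window (channels).
#' @param zThreshold positive modified z-score threshold.
#' @return list with `spectra` (despiked [RamanSpectra-class]) and
#'   `flagged` (per-spectrum integer vectors of corrected channel indices).
#' @export
despikeSpectra <- function(x, window = 7L, zThreshold = 8) {
    stopifnot(methods::is(x, "RamanSpectra"))
    window <- as.integer(window)
    if (window < 3L || window %% 2L == 0L)
        stop("window must be an odd integer >= 3")
    if (zThreshold <= 0) stop("zThreshold must be positive")
    ints <- intensityMatrix(x)
    flagged <- vector("list", ncol(ints))
    for (j in seq_len(ncol(ints))) {
        r <- .despike1(ints[, j], window, zThreshold)
        ints[, j] <- r$y
        flagged[[j]] <- r$flagged
    }
    out <- x
    SummarizedExperiment::assay(out, "intensity") <- ints
    list(spectra = out, flagged = flagged)
}

#' Asymmetric least-squares baseline estimation and subtraction
#'
#' Eilers-style baseline: a smooth curve minimising an asymmetrically
#' weighted least-squares criterion with a second-difference penalty.
#' Points above the baseline (Raman bands) get small weight `p`, points
#' below get `1 - p`, so the fit hugs the fluorescence background under the
#' peaks.  The corrected spectrum (`intensity - baseline`) may contain small
#' negative values.
#'
#' @param x a [RamanSpectra-class] object (despiked).
#' @param lambda positive smoothness penalty (default 1e5).
#' @param p asymmetry in (0, 0.5) (default 0.01).
#' @param iterations reweighting iterations (default 10).
#' @return list with `baseline` (channels x spectra matrix) and `corrected`
#'   (a [RamanSpectra-class]).
#' @export
baselineALS <- function(x, lambda = 1e5, p = 0.01, iterations = 10L) {
    stopifnot(methods::is(x, "RamanSpectra"))
    if (lambda <= 0) stop("lambda must be positive")
    if (p <= 0 || p >= 0.5) stop("p must lie in (0, 0.5)")
    ints <- intensityMatrix(x)
    base <- matrix(0, nrow(ints), ncol(ints), dimnames = dimnames(ints))
    for (j in seq_len(ncol(ints)))
        base[, j] <- cpp_als_baseline(ints[, j], lambda, p,
                                      as.integer(iterations))
    out <- x
    SummarizedExperiment::assay(out, "intensity") <- ints - base
    list(baseline = base, corrected = out)
}

#' Crop spectra to a wavenumber range
#'
#' Retains exactly the channels with `low <= wavenumber <= high` (closed
#' interval, so the printed endpoints of an acquisition range are kept).
#'
#' @param x a [RamanSpectra-class] object.
#' @param low,high range bounds in cm^-1.
#' @return the cropped [RamanSpectra-class].
#' @export
cropSpectra <- function(x, low = 550, high = 1670) {
    stopifnot(methods::is(x, "RamanSpectra"))
    if (low >= high) stop("low must be < high")
    wn <- wavenumbers(x)
    keep <- wn >= low - 1e-9 & wn <= high + 1e-9
    if (!any(keep))
        stop(sprintf("crop range %g-%g does not intersect axis %g-%g",
                     low, high, min(wn), max(wn)))
    x[keep, ]
}

#' Normalise spectra
#'
#' `vector_l2` scales each spectrum to unit Euclidean norm — the common
#' chemometric convention that makes relative band intensities comparable
#' across spectra; `area` scales to unit trapezoidal integral over the axis;
#' `none` is the identity.
#'
#' @param x a [RamanSpectra-class] object.
#' @param mode `"vector_l2"`, `"area"` or `"none"`.
#' @return the normalised [RamanSpectra-class].
#' @export
normaliseSpectra <- function(x, mode = c("vector_l2", "area", "none")) {
    mode <- match.arg(mode)
    stopifnot(methods::is(x, "RamanSpectra"))
    if (mode == "none") return(x)
    ints <- intensityMatrix(x)
    wn <- wavenumbers(x)
    for (j in seq_len(ncol(ints))) {
        y <- ints[, j]
        s <- if (mode == "vector_l2") sqrt(sum(y^2))
             else sum(diff(wn) * (head(y, -1) + y[-1]) / 2)
        if (s == 0)
            stop(sprintf("cannot normalise all-zero spectrum %d (patient %s)",
                         j, patientIds(x)[j]))
        ints[, j] <- y / s
    }
    out <- x
    SummarizedExperiment::assay(out, "intensity") <- ints
    out
}

#' Run the full preprocessing chain
#'
#' Applies despike -> asymmetric-least-squares baseline subtraction -> crop
#' -> normalise to every spectrum, in that fixed order, and returns an audit
#' table of the spike corrections so every altered channel is traceable.
#'
#' @param x a [RamanSpectra-class] object.
#' @param config a [preprocessConfig()] list.
#' @return list with `spectra` (processed [RamanSpectra-class]), `audit`
#'   (data.frame: patient_id, spectrum_index, n_spikes, channels) and
#'   `baseline` (the subtracted background, channels x spectra, pre-crop).
#' @export
runPreprocess <- function(x, config = preprocessConfig()) {
    stopifnot(methods::is(x, "RamanSpectra"),
              inherits(config, "PreprocessConfig"))
    ints <- intensityMatrix(x)
    base <- matrix(0, nrow(ints), ncol(ints), dimnames = dimnames(ints))
    pid <- patientIds(x)
    sidx <- spectrumIndex(x)
    flagged <- vector("list", ncol(ints))
    for (j in seq_len(ncol(ints))) {
        res <- tryCatch({
            r <- .despike1(ints[, j], config$despikeWindow,
                           config$despikeZThreshold)
            b <- cpp_als_baseline(r$y, config$baselineLambda,
                                  config$baselineP,
                                  config$baselineIterations)
            list(y = r$y - b, b = b, flagged = r$flagged)
        }, error = function(e)
            stop(sprintf("patient %s, spectrum %d: %s",
                         pid[j], sidx[j], conditionMessage(e)), call. = FALSE))
        ints[, j] <- res$y
        base[, j] <- res$b
        flagged[[j]] <- res$flagged
    }
    out <- x
    SummarizedExperiment::assay(out, "intensity") <- ints
    out <- cropSpectra(out, config$cropLow, config$cropHigh)
    if (config$normalisation != "none")
        out <- normaliseSpectra(out, config$normalisation)
    audit <- data.frame(
        patient_id = pid, spectrum_index = sidx,
        n_spikes = vapply(flagged, length, 0L),
        channels = vapply(flagged, paste, "", collapse = ";"))
    list(spectra = out, audit = audit, baseline = base)
}

#' Peak intensity within a band window
#'
#' The maximum intensity within `centre +/- halfWindow` cm^-1 (closed
#' window), per spectrum — the quantity used to report relative band
#' intensities of mean class spectra.
#'
#' @param x a [RamanSpectra-class] object.
#' @param centre band centre, cm^-1.
#' @param halfWindow half-width of the search window, cm^-1.
#' @return numeric vector, one value per spectrum.
#' @export
bandIntensity <- function(x, centre, halfWindow = 5) {
    stopifnot(methods::is(x, "RamanSpectra"))
    wn <- wavenumbers(x)
    keep <- wn >= centre - halfWindow - 1e-9 & wn <= centre + halfWindow + 1e-9
    if (!any(keep))
        stop(sprintf("band window %g +/- %g does not intersect axis %g-%g",
                     centre, halfWindow, min(wn), max(wn)))
    apply(intensityMatrix(x)[keep, , drop = FALSE], 2L, max)
}
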