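#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx median mad rnorm runif rlnorm rpois sd
#' @importFrom utils read.csv write.csv head
#' @useDynLib RamanSOM, .registration = TRUE
NULL

#' RamanSpectra: a collection of Raman spectra on a shared wavenumber axis
#'
#' `RamanSpectra` extends
#' [SummarizedExperiment::SummarizedExperiment-class]: rows are spectral
#' channels (Raman shifts in cm^-1, stored in `rowData(x)$wavenumber`),
#' columns are individual spectra, and `colData` carries `patient_id`,
#' `class_label` and `spectrum_index` (the position of the spectrum within a
#' patient's map scan).  All standard SummarizedExperiment subsetting and
#' accessor machinery applies.
#'
#' Validity requires a strictly increasing, finite wavenumber axis of length
#' >= 2, finite intensities, and non-empty patient and class labels for every
#' spectrum.
#'
#' @seealso [ramanSpectra()] for construction, [wavenumbers()],
#'   [intensityMatrix()], [patientIds()], [classLabels()].
#' @export
setClass("RamanSpectra", contains = "SummarizedExperiment")

.validRamanSpectra <- function(object) {
    msg <- character()
    wn <- SummarizedExperiment::rowData(object)$wavenumber
    if (is.null(wn))
        return("rowData must contain a 'wavenumber' column")
    if (length(wn) < 2L)
        msg <- c(msg, "wavenumber axis must have length >= 2")
    if (any(!is.finite(wn)))
        msg <- c(msg, "wavenumber axis must be finite")
    if (length(wn) >= 2L && any(diff(wn) <= 0))
        msg <- c(msg, "wavenumber axis must be strictly increasing")
    if (!"intensity" %in% SummarizedExperiment::assayNames(object))
        return(c(msg, "assay 'intensity' is required"))
    if (ncol(object) > 0L) {
        if (any(!is.finite(SummarizedExperiment::assay(object, "intensity"))))
            msg <- c(msg, "all intensities must be finite")
        cd <- SummarizedExperiment::colData(object)
        for (fld in c("patient_id", "class_label")) {
            v <- cd[[fld]]
            if (is.null(v) || any(is.na(v)) || any(!nzchar(as.character(v))))
                msg <- c(msg, sprintf("every spectrum needs a non-empty %s", fld))
        }
    }
    if (length(msg)) msg else TRUE
}
setValidity("RamanSpectra", .validRamanSpectra)

#' Construct a RamanSpectra object
#'
#' @param intensity numeric matrix, channels x spectra (a vector is treated
#'   as a single spectrum).
#' @param wavenumbers numeric vector of Raman shifts (cm^-1), strictly
#'   increasing, one per row of `intensity`.
#' @param patientId character vector (recycled) of patient identifiers.
#' @param classLabel character vector (recycled) of class labels.
#' @param spectrumIndex integer vector of within-patient spectrum positions;
#'   defaults to a running index within each patient.
#' @return A [RamanSpectra-class] object.
#' @examples
#' rs <- ramanSpectra(cbind(c(1, 2, 3), c(4, 5, 6)), c(550, 551, 552),
#'                    patientId = "P1", classLabel = "active")
#' wavenumbers(rs)
#' @export
ramanSpectra <- function(intensity, wavenumbers, patientId = "unknown",
                         classLabel = "unlabelled", spectrumIndex = NULL) {
    if (is.vector(intensity)) intensity <- matrix(intensity, ncol = 1L)
    intensity <- as.matrix(intensity)
    storage.mode(intensity) <- "double"
    n <- ncol(intensity)
    patientId <- as.character(rep_len(patientId, if (n) n else length(patientId)))
    classLabel <- as.character(rep_len(classLabel, if (n) n else length(classLabel)))
    if (is.null(spectrumIndex)) {
        spectrumIndex <- integer(n)
        if (n) spectrumIndex <- stats::ave(seq_len(n), patientId[seq_len(n)],
                                           FUN = seq_along)
    }
    cd <- S4Vectors::DataFrame(patient_id = patientId[seq_len(n)],
                               class_label = classLabel[seq_len(n)],
                               spectrum_index = as.integer(spectrumIndex))
    rd <- S4Vectors::DataFrame(wavenumber = as.numeric(wavenumbers))
    colnames(intensity) <- sprintf("S%04d", seq_len(n))
    rownames(cd) <- colnames(intensity)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = intensity), rowData = rd, colData = cd)
    methods::new("RamanSpectra", se)
}

#' Self-organising map model with class-augmented weights
#'
#' A trained (or freshly initialised) hexagonal-lattice Kohonen map.  Each
#' neuron carries a spectral weight vector (one value per wavenumber channel)
#' and a class-association weight vector (one value per class).  Class
#' weights are updated alongside the spectral weights during training but are
#' excluded from best-matching-unit distances, which is what makes the map a
#' supervised classifier (the SKiNET design).
#'
#' @slot codebook numeric matrix, channels x neurons: spectral weights.
#' @slot classWeights numeric matrix, classes x neurons.
#' @slot positions integer matrix, neurons x 2: axial hex coordinates (q, r),
#'   row-major over the rows x cols lattice.
#' @slot wavenumbers numeric vector, the spectral axis.
#' @slot classNames character vector of class labels, fixed order.
#' @slot config list of training hyperparameters (see [somConfig()]).
#' @slot trainingLog numeric vector of per-epoch mean quantisation error
#'   (empty until trained).
#' @slot trained logical scalar.
#' @export
setClass("SOMModel",
    representation(codebook = "matrix", classWeights = "matrix",
                   positions = "matrix", wavenumbers = "numeric",
                   classNames = "character", config = "list",
                   trainingLog = "numeric", trained = "logical"))

setValidity("SOMModel", function(object) {
    msg <- character()
    nneu <- ncol(object@codebook)
    if (nrow(object@codebook) != length(object@wavenumbers))
        msg <- c(msg, "codebook rows must match wavenumber axis length")
    if (ncol(object@classWeights) != nneu)
        msg <- c(msg, "classWeights and codebook must have equal neuron count")
    if (nrow(object@classWeights) != length(object@classNames))
        msg <- c(msg, "classWeights rows must match classNames")
    if (!length(object@classNames) || anyDuplicated(object@classNames))
        msg <- c(msg, "classNames must be non-empty and unique")
    if (nrow(object@positions) != nneu || ncol(object@positions) != 2L)
        msg <- c(msg, "positions must be neurons x 2")
    if (any(!is.finite(object@codebook)) || any(!is.finite(object@classWeights)))
        msg <- c(msg, "all weights must be finite")
    if (length(msg)) msg else TRUE
})

#' Per-class SOM discriminant index over the wavenumber axis
#'
#' The result of [computeSOMDI()]: for each class, a vector over wavenumber
#' channels whose magnitude reflects how strongly that channel drives the
#' class's separation on the map — a representation that reads like a
#' spectrum and can be compared across classes to identify discriminating
#' Raman bands.
#'
#' @slot wavenumbers numeric spectral axis.
#' @slot index numeric matrix, channels x classes, each column scaled to unit
#'   maximum magnitude.
#' @slot classNames character class labels (column order of `index`).
#' @export
setClass("SOMDIResult",
    representation(wavenumbers = "numeric", index = "matrix",
                   classNames = "character"))

setValidity("SOMDIResult", function(object) {
    msg <- character()
    if (nrow(object@index) != length(object@wavenumbers))
        msg <- c(msg, "index rows must match wavenumber axis")
    if (ncol(object@index) != length(object@classNames))
        msg <- c(msg, "index columns must match classNames")
    if (any(!is.finite(object@index)))
        msg <- c(msg, "index values must be finite")
    if (length(msg)) msg else TRUE
})

#' Repeated-evaluation report: per-run metrics and aggregate summary
#'
#' @slot perRun data.frame with one row per run: sensitivity, specificity,
#'   ppv, npv, accuracy (percent).
#' @slot summary data.frame with mean and sample sd (n-1 denominator) per
#'   metric.
#' @slot confusions list of per-run confusion count vectors
#'   (tp, fp, tn, fn).
#' @slot positiveClass character scalar, the class counted as positive.
#' @slot nRuns integer.
#' @export
setClass("EvaluationReport",
    representation(perRun = "data.frame", summary = "data.frame",
                   confusions = "list", positiveClass = "character",
                   nRuns = "integer"))

setMethod("show", "RamanSpectra", function(object) {
    wn <- wavenumbers(object)
    cat(sprintf("RamanSpectra: %d spectra x %d channels (%g-%g cm^-1)\n",
                ncol(object), nrow(object), min(wn), max(wn)))
    if (ncol(object)) {
        cl <- table(classLabels(object))
        cat("  classes:",
            paste(sprintf("%s (%d)", names(cl), as.integer(cl)),
                  collapse = ", "), "\n")
        cat("  patients:", length(unique(patientIds(object))), "\n")
    }
})

setMethod("show", "SOMModel", function(object) {
    cfg <- object@config
    cat(sprintf("SOMModel: %dx%d hexagonal lattice, %d channels, classes: %s\n",
                cfg$rows, cfg$cols, nrow(object@codebook),
                paste(object@classNames, collapse = ", ")))
    cat(if (object@trained)
        sprintf("  trained, %d epochs, final quantisation error %.4g\n",
                length(object@trainingLog),
                object@trainingLog[length(object@trainingLog)])
        else "  untrained\n")
})

setMethod("show", "SOMDIResult", function(object) {
    cat(sprintf("SOMDIResult: %d channels x %d classes (%s)\n",
                nrow(object@index), length(object@classNames),
                paste(object@classNames, collapse = ", ")))
})

setMethod("show", "EvaluationReport", function(object) {
    cat(sprintf("EvaluationReport: %d runs, positive class '%s'\n",
                object@nRuns, object@positiveClass))
    print(object@summary, row.names = FALSE)
})
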