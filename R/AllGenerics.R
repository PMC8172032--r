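#' Accessors for RamanSpectra and downstream result objects
#'
#' `wavenumbers` returns the shared Raman-shift axis (cm^-1);
#' `intensityMatrix` the channels x spectra intensity matrix;
#' `patientIds`, `classLabels` and `spectrumIndex` the per-spectrum
#' metadata columns.
#'
#' @param x a [RamanSpectra-class], [SOMModel-class] or
#'   [SOMDIResult-class] object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))
#' @rdname accessors
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))
#' @rdname accessors
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))
#' @rdname accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))
#' @rdname accessors
#' @export
setGeneric("spectrumIndex", function(x) standardGeneric("spectrumIndex"))
#' @rdname accessors
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))

#' @rdname accessors
#' @export
setMethod("wavenumbers", "RamanSpectra", function(x)
    as.numeric(SummarizedExperiment::rowData(x)$wavenumber))
#' @rdname accessors
#' @export
setMethod("intensityMatrix", "RamanSpectra", function(x)
    SummarizedExperiment::assay(x, "intensity"))
#' @rdname accessors
#' @export
setMethod("patientIds", "RamanSpectra", function(x)
    as.character(SummarizedExperiment::colData(x)$patient_id))
#' @rdname accessors
#' @export
setMethod("classLabels", "RamanSpectra", function(x)
    as.character(SummarizedExperiment::colData(x)$class_label))
#' @rdname accessors
#' @export
setMethod("spectrumIndex", "RamanSpectra", function(x)
    as.integer(SummarizedExperiment::colData(x)$spectrum_index))
#' @rdname accessors
#' @export
setMethod("wavenumbers", "SOMModel", function(x) x@wavenumbers)
#' @rdname accessors
#' @export
setMethod("classNames", "SOMModel", function(x) x@classNames)
#' @rdname accessors
#' @export
setMethod("wavenumbers", "SOMDIResult", function(x) x@wavenumbers)
#' @rdname accessors
#' @export
setMethod("classNames", "SOMDIResult", function(x) x@classNames)

#' @rdname accessors
#' @export
setGeneric("somdiMatrix", function(x) standardGeneric("somdiMatrix"))
#' @rdname accessors
#' @export
setMethod("somdiMatrix", "SOMDIResult", function(x) {
    m <- x@index
    colnames(m) <- x@classNames
    m
})

#' @rdname accessors
#' @export
setGeneric("runMetrics", function(x) standardGeneric("runMetrics"))
#' @rdname accessors
#' @export
setMethod("runMetrics", "EvaluationReport", function(x) x@perRun)

#' @rdname accessors
#' @export
setGeneric("metricsSummary", function(x) standardGeneric("metricsSummary"))
#' @rdname accessors
#' @export
setMethod("metricsSummary", "EvaluationReport", function(x) x@summary)

#' @rdname accessors
#' @export
setGeneric("confusions", function(x) standardGeneric("confusions"))
#' @rdname accessors
#' @export
setMethod("confusions", "EvaluationReport", function(x) x@confusions)
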