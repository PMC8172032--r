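#' Read Raman spectra from a text file
#'
#' Two dialects are supported. `two_column_text`: whitespace- or
#' comma-delimited (wavenumber, intensity) pairs, one spectrum per file —
#' the layout of typical instrument exports. `matrix_csv`: first column
#' wavenumber, each subsequent column one spectrum, optional header row.
#'
#' @param path file to read.
#' @param dialect `"two_column_text"` or `"matrix_csv"`.
#' @param patientId,classLabel metadata applied to all spectra in the file.
#' @return A [RamanSpectra-class] object with the axis as read (not yet
#'   aligned to any common axis).
#' @export
readSpectrumFile <- function(path, dialect = c("two_column_text", "matrix_csv"),
                             patientId = "unknown", classLabel = "unlabelled") {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (dialect == "two_column_text") {
        toks <- strsplit(trimws(lines), "[,[:space:]]+")
        mat <- matrix(NA_real_, length(toks), 2L)
        for (i in seq_along(toks)) {
            v <- suppressWarnings(as.numeric(toks[[i]]))
            if (length(v) < 2L || any(is.na(v[1:2])))
                stop(sprintf("parse error at line %d of %s: '%s'",
                             i, path, lines[i]))
            mat[i, ] <- v[1:2]
        }
        wn <- mat[, 1L]
        ints <- matrix(mat[, 2L], ncol = 1L)
    } else {
        first <- strsplit(trimws(lines[1L]), ",")[[1L]]
        hasHeader <- any(is.na(suppressWarnings(as.numeric(first))))
        body <- if (hasHeader) lines[-1L] else lines
        rows <- strsplit(trimws(body), ",")
        ncols <- length(rows[[1L]])
        mat <- matrix(NA_real_, length(rows), ncols)
        for (i in seq_along(rows)) {
            v <- suppressWarnings(as.numeric(rows[[i]]))
            if (length(v) != ncols || any(is.na(v)))
                stop(sprintf("parse error at line %d of %s",
                             i + hasHeader, path))
            mat[i, ] <- v
        }
        wn <- mat[, 1L]
        ints <- mat[, -1L, drop = FALSE]
    }
    if (any(diff(wn) <= 0))
        stop("non-monotone wavenumber axis in ", path)
    ramanSpectra(ints, wn, patientId = patientId, classLabel = classLabel)
}

#' Interpolate spectra from several sources onto one common axis
#'
#' Each input's spectra are linearly interpolated onto `commonAxis`
#' (identity when the axes already agree to within 1e-6 cm^-1) and the
#' results concatenated in input order; nothing is dropped.
#'
#' @param spectra a list of [RamanSpectra-class] objects (or a single one).
#' @param commonAxis numeric target axis; every input axis must cover its
#'   full range.
#' @return A single [RamanSpectra-class] on `commonAxis`.
#' @export
assembleCollection <- function(spectra, commonAxis) {
    if (methods::is(spectra, "RamanSpectra")) spectra <- list(spectra)
    commonAxis <- as.numeric(commonAxis)
    parts <- lapply(spectra, function(rs) {
        wn <- wavenumbers(rs)
        if (length(wn) == length(commonAxis) &&
            max(abs(wn - commonAxis)) <= 1e-6)
            return(intensityMatrix(rs))
        if (min(wn) > min(commonAxis) + 1e-9 ||
            max(wn) < max(commonAxis) - 1e-9)
            stop(sprintf(
                "axis of patient %s (%g-%g) does not cover common axis (%g-%g)",
                patientIds(rs)[1L], min(wn), max(wn),
                min(commonAxis), max(commonAxis)))
        apply(intensityMatrix(rs), 2L, function(y)
            approx(wn, y, xout = commonAxis)$y)
    })
    ints <- do.call(cbind, parts)
    ramanSpectra(ints, commonAxis,
                 patientId = unlist(lapply(spectra, patientIds)),
                 classLabel = unlist(lapply(spectra, classLabels)),
                 spectrumIndex = unlist(lapply(spectra, spectrumIndex)))
}

#' Write / read a RamanSpectra collection as a plain-text directory
#'
#' `writeCollection` stores `intensities.csv` (first column wavenumber, one
#' column per spectrum, full `%.17g` precision) and `manifest.csv` (spectrum
#' column name, patient_id, class_label, spectrum_index).
#' `readCollection` reverses it exactly: the round trip is the identity on
#' intensities, axis and metadata.
#'
#' @param x a [RamanSpectra-class] object.
#' @param dir directory to create/read.
#' @return `writeCollection` returns `dir` invisibly; `readCollection`
#'   returns a [RamanSpectra-class].
#' @export
writeCollection <- function(x, dir) {
    stopifnot(methods::is(x, "RamanSpectra"))
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
        stop("cannot create directory ", dir)
    ints <- intensityMatrix(x)
    con <- file(file.path(dir, "intensities.csv"), "w")
    on.exit(close(con))
    writeLines(paste(c("wavenumber", colnames(ints)), collapse = ","), con)
    body <- cbind(sprintf("%.17g", wavenumbers(x)),
                  if (ncol(ints)) apply(ints, 2L, sprintf, fmt = "%.17g"))
    writeLines(apply(body, 1L, paste, collapse = ","), con)
    manifest <- data.frame(column = colnames(ints),
                           patient_id = patientIds(x),
                           class_label = classLabels(x),
                           spectrum_index = spectrumIndex(x))
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    invisible(dir)
}

#' @rdname writeCollection
#' @export
readCollection <- function(dir) {
    fi <- file.path(dir, "intensities.csv")
    fm <- file.path(dir, "manifest.csv")
    if (!file.exists(fi) || !file.exists(fm))
        stop("not a collection directory (missing intensities.csv/manifest.csv): ",
             dir)
    tab <- read.csv(fi, check.names = FALSE)
    manifest <- read.csv(fm, colClasses = c(patient_id = "character",
                                            class_label = "character"))
    wn <- tab[[1L]]
    ints <- as.matrix(tab[, -1L, drop = FALSE])
    if (ncol(ints) != nrow(manifest))
        stop("manifest/intensity column count mismatch in ", dir)
    ramanSpectra(ints, wn,
                 patientId = if (nrow(manifest)) manifest$patient_id else "unknown",
                 classLabel = if (nrow(manifest)) manifest$class_label else "unlabelled",
                 spectrumIndex = manifest$spectrum_index)
}

#' Default shared wavenumber axis
#'
#' The fingerprint-region axis used throughout: 550-1670 cm^-1.  The
#' channel spacing of the source instrument is not fixed by the acquisition
#' protocol, so it is configurable; 1 cm^-1 is the default.
#'
#' @param low,high axis endpoints in cm^-1.
#' @param step channel spacing in cm^-1.
#' @return numeric vector of Raman shifts.
#' @export
defaultAxis <- function(low = 550, high = 1670, step = 1)
    seq(low, high, by = step)
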