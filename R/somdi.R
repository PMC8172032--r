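#' Compute the self-organising map discriminant index
#'
#' For class `c` the index is the mask-weighted mean over neurons of the
#' spectral weight vectors, `sum_n m_c(n) * w(n) / sum_n m_c(n)`, where the
#' mask `m_c(n)` is the neuron's class weight for `c` when `c` is that
#' neuron's dominant class and zero otherwise (set `mask = "none"` for the
#' unmasked class-weight-weighted mean).  Averaging rather than summing
#' keeps the index independent of how many neurons a class happens to
#' dominate, so classes remain comparable band by band.  The result is
#' scaled to unit maximum magnitude, giving a
#' representation that reads like a spectrum: large values mark wavenumbers
#' that drive a class's separation on the map.
#'
#' With `scaling = "global_max"` (default) one joint maximum over all
#' classes is used, so values remain comparable *between* classes — the
#' property a relative-band-intensity table relies on.  `"class_max"`
#' rescales every class to its own unit maximum instead; note that this
#' cancels any between-class difference at bands whose class amplitude
#' ratio matches the dominant band's, so class-wise scaling is only useful
#' for comparing band positions, not intensities.
#'
#' @param model a trained [SOMModel-class].
#' @param mask `"dominant"` (default) or `"none"`.
#' @param scaling `"global_max"` (default) or `"class_max"`.
#' @return a [SOMDIResult-class].
#' @export
computeSOMDI <- function(model, mask = c("dominant", "none"),
                         scaling = c("global_max", "class_max")) {
    mask <- match.arg(mask)
    scaling <- match.arg(scaling)
    stopifnot(methods::is(model, "SOMModel"))
    if (!model@trained)
        stop("SOMDI requires a trained model (no dominant classes yet)")
    cw <- model@classWeights
    if (mask == "dominant") {
        dom <- apply(cw, 2L, which.max)
        keep <- matrix(0, nrow(cw), ncol(cw))
        keep[cbind(dom, seq_len(ncol(cw)))] <- 1
        cw <- cw * keep
    }
    tot <- rowSums(cw)
    tot[tot == 0] <- 1  # class dominating no neuron: all-zero index
    idx <- model@codebook %*% t(cw / tot)  # channels x classes
    if (scaling == "global_max") {
        m <- max(abs(idx))
        if (m > 0) idx <- idx / m
    } else {
        for (j in seq_len(ncol(idx))) {
            m <- max(abs(idx[, j]))
            if (m > 0) idx[, j] <- idx[, j] / m
        }
    }
    colnames(idx) <- model@classNames
    methods::new("SOMDIResult", wavenumbers = model@wavenumbers,
                 index = idx, classNames = model@classNames)
}

#' Top discriminating Raman bands between two classes
#'
#' Greedy peak picking on `|SOMDI_a - SOMDI_b|`: repeatedly select the
#' largest remaining channel whose wavenumber is at least `minSeparation`
#' cm^-1 from every previously selected one, `k` times; the result is
#' returned sorted by wavenumber — the structure of a relative-band-
#' intensity table.
#'
#' @param result a [SOMDIResult-class].
#' @param classA,classB class names present in `result`.
#' @param k number of bands to report.
#' @param minSeparation minimum spacing between reported bands, cm^-1
#'   (default 20; reported tissue bands sit much further apart).
#' @return data.frame with columns wavenumber, somdi_a, somdi_b, score
#'   (= `|somdi_a - somdi_b|`), sorted by wavenumber.
#' @export
topDiscriminatingBands <- function(result, classA, classB, k = 8L,
                                   minSeparation = 20) {
    stopifnot(methods::is(result, "SOMDIResult"), k >= 1L)
    for (cl in c(classA, classB))
        if (!cl %in% result@classNames)
            stop("unknown class name: ", cl)
    wn <- result@wavenumbers
    a <- result@index[, match(classA, result@classNames)]
    b <- result@index[, match(classB, result@classNames)]
    score <- abs(a - b)
    chosen <- integer(0)
    avail <- rep(TRUE, length(wn))
    for (i in seq_len(k)) {
        if (!any(avail)) break
        cand <- which(avail)
        pick <- cand[which.max(score[cand])]
        chosen <- c(chosen, pick)
        avail <- avail & abs(wn - wn[pick]) >= minSeparation
    }
    chosen <- chosen[order(wn[chosen])]
    data.frame(wavenumber = wn[chosen], somdi_a = a[chosen],
               somdi_b = b[chosen], score = score[chosen])
}

#' Export a SOMDI result as CSV
#'
#' One row per wavenumber, one column per class.
#'
#' @param result a [SOMDIResult-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSOMDI <- function(result, path) {
    stopifnot(methods::is(result, "SOMDIResult"))
    df <- data.frame(wavenumber = result@wavenumbers,
                     result@index, check.names = FALSE)
    colnames(df) <- c("wavenumber", result@classNames)
    write.csv(df, path, row.names = FALSE)
    invisible(path)
}
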