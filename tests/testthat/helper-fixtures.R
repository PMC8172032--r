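# Small in-code fixtures shared across the suite.

# Two well-separated classes on a short axis, with patient structure:
# class "a" peaks at channel ~1/3, class "b" at ~2/3 of the axis.
makeSeparableCollection <- function(nPatientsPerClass = 3L,
                                    spectraPerPatient = 10L,
                                    nch = 60L, noise = 0.05, seed = 1L) {
    set.seed(seed)
    wn <- seq(600, 600 + nch - 1)
    tmplA <- exp(-(seq_len(nch) - nch / 3)^2 / 18)
    tmplB <- exp(-(seq_len(nch) - 2 * nch / 3)^2 / 18)
    ints <- NULL
    pid <- lab <- character(0)
    for (cl in c("a", "b")) {
        tmpl <- if (cl == "a") tmplA else tmplB
        for (p in seq_len(nPatientsPerClass)) {
            m <- exp(rnorm(1, 0, 0.05))
            block <- replicate(spectraPerPatient,
                               m * tmpl + rnorm(nch, 0, noise))
            ints <- cbind(ints, block)
            pid <- c(pid, rep(sprintf("%s_P%d", cl, p), spectraPerPatient))
            lab <- c(lab, rep(cl, spectraPerPatient))
        }
    }
    ramanSpectra(ints, wn, patientId = pid, classLabel = lab)
}

# Tiny two-band synthetic config for fast end-to-end checks.
tinySyntheticConfig <- function(nPatientsByClass = c(a = 3L, b = 3L),
                                spectraPerPatient = 8L, ...,
                                ampA = c(3, 1), ampB = c(1, 3)) {
    bands <- list(
        bandSpec(700, c(a = ampA[1], b = ampB[1])),
        bandSpec(900, c(a = ampA[2], b = ampB[2])),
        bandSpec(800, c(a = 1.5, b = 1.5)))  # shared filler
    syntheticConfig(bands, nPatientsByClass,
                    axis = seq(600, 1000, by = 2),
                    spectraPerPatient = spectraPerPatient, ...)
}
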