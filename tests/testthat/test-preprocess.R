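wnTest <- seq(550, 1049)

test_that("despiking recovers an injected spike and nothing else", {
    y <- rep(1, 200)
    y[77] <- 1000
    rs <- ramanSpectra(y, seq(550, 749), "P1", "x")
    out <- despikeSpectra(rs)
    expect_equal(out$flagged[[1L]], 77L)
    expect_equal(as.numeric(intensityMatrix(out$spectra)), rep(1, 200))
})

test_that("smooth noiseless bands are never flagged", {
    y <- 3 / (1 + ((wnTest - 800) / 8)^2)  # Lorentzian, amplitude 3
    out <- despikeSpectra(ramanSpectra(y, wnTest, "P1", "x"),
                          zThreshold = 8)
    expect_length(out$flagged[[1L]], 0L)
    expect_equal(as.numeric(intensityMatrix(out$spectra)), y)
})

test_that("despiking is idempotent and touches only flagged channels", {
    set.seed(11)
    y <- 2 / (1 + ((wnTest - 900) / 8)^2) + rnorm(length(wnTest), 0, 0.05)
    spikeAt <- c(40L, 310L)
    y[spikeAt] <- y[spikeAt] + 30
    rs <- ramanSpectra(y, wnTest, "P1", "x")
    once <- despikeSpectra(rs)
    expect_setequal(once$flagged[[1L]], spikeAt)
    untouched <- setdiff(seq_along(y), once$flagged[[1L]])
    expect_equal(intensityMatrix(once$spectra)[untouched, 1L],
                 y[untouched], ignore_attr = TRUE)
    twice <- despikeSpectra(once$spectra)
    expect_length(twice$flagged[[1L]], 0L)
})

test_that("despike window and threshold arguments are validated", {
    rs <- ramanSpectra(1:5, 550:554, "P1", "x")
    expect_error(despikeSpectra(rs, window = 7), "larger than spectrum")
    expect_error(despikeSpectra(rs, window = 4), "odd")
    expect_error(despikeSpectra(rs, zThreshold = 0), "positive")
})

test_that("ALS baseline recovers a peak-free ramp within 1% of its range", {
    ramp <- seq(0, 10, length.out = length(wnTest))
    rs <- ramanSpectra(ramp, wnTest, "P1", "x")
    out <- baselineALS(rs)
    corrected <- as.numeric(intensityMatrix(out$corrected))
    expect_lt(max(abs(corrected)), 0.01 * diff(range(ramp)))
})

test_that("ALS preserves a narrow peak on a ramp within 5% of true height", {
    ramp <- seq(2, 8, length.out = length(wnTest))
    peak <- 5 * exp(-(wnTest - 800)^2 / (2 * 6^2))
    out <- baselineALS(ramanSpectra(ramp + peak, wnTest, "P1", "x"))
    got <- bandIntensity(out$corrected, 800, 10)[[1L]]
    expect_lt(abs(got - 5) / 5, 0.05)
})

test_that("ALS of zero input is zero, and parameters are validated", {
    rs <- ramanSpectra(rep(0, 50), 550:599, "P1", "x")
    out <- baselineALS(rs)
    expect_equal(as.numeric(out$baseline), rep(0, 50))
    expect_equal(as.numeric(intensityMatrix(out$corrected)), rep(0, 50))
    expect_error(baselineALS(rs, lambda = -1), "lambda")
    expect_error(baselineALS(rs, p = 0.7), "p must")
})

test_that("re-correcting an already-corrected peak-free spectrum is near-identity", {
    ramp <- seq(0, 10, length.out = length(wnTest))
    once <- baselineALS(ramanSpectra(ramp, wnTest, "P1", "x"))$corrected
    twice <- baselineALS(once)$corrected
    rms <- function(v) sqrt(mean(v^2))
    delta <- rms(intensityMatrix(twice) - intensityMatrix(once))
    expect_lt(delta, 0.01 * rms(ramp))  # relative to the signal scale
})

test_that("cropping keeps the closed interval and repeats idempotently", {
    wn <- seq(400, 1800)
    rs <- ramanSpectra(matrix(seq_along(wn)), wn, "P1", "x")
    cr <- cropSpectra(rs, 550, 1670)
    expect_gte(min(wavenumbers(cr)), 550)
    expect_lte(max(wavenumbers(cr)), 1670)
    expect_true(all(c(550, 1670) %in% wavenumbers(cr)))
    again <- cropSpectra(cr, 550, 1670)
    expect_identical(intensityMatrix(again), intensityMatrix(cr))
    expect_error(cropSpectra(rs, 2000, 2100), "does not intersect")
    full <- cropSpectra(rs, 400, 1800)
    expect_identical(intensityMatrix(full), intensityMatrix(rs))
})

test_that("normalisation modes behave as stated", {
    rs <- ramanSpectra(c(3, 4), c(550, 551), "P1", "x")
    expect_equal(as.numeric(intensityMatrix(
        normaliseSpectra(rs, "vector_l2"))), c(0.6, 0.8))
    expect_identical(intensityMatrix(normaliseSpectra(rs, "none")),
                     intensityMatrix(rs))
    zero <- ramanSpectra(c(0, 0), c(550, 551), "Pz", "x")
    expect_error(normaliseSpectra(zero, "area"), "Pz")
    # unit l2 norm property over random spectra
    set.seed(21)
    for (i in 1:10) {
        m <- ramanSpectra(rnorm(30), 550:579, "P", "x")
        expect_equal(sum(intensityMatrix(
            normaliseSpectra(m, "vector_l2"))^2), 1, tolerance = 1e-9)
    }
    ar <- normaliseSpectra(ramanSpectra(runif(30, 1, 2), 550:579, "P", "x"),
                           "area")
    y <- as.numeric(intensityMatrix(ar))
    expect_equal(sum(diff(550:579) * (head(y, -1) + y[-1]) / 2), 1,
                 tolerance = 1e-9)
})

test_that("full chain recovers planted structure and annotates failures", {
    cfg <- tinySyntheticConfig(spectrumNoiseSd = 0, patientAmplitudeSd = 0,
                               spikeRate = 0.5, seed = 5L)
    sim <- simulateCollection(cfg)
    pp <- runPreprocess(sim$spectra,
                        preprocessConfig(cropLow = 600, cropHigh = 1000,
                                         normalisation = "none"))
    flagged <- lapply(strsplit(pp$audit$channels, ";"),
                      function(v) as.integer(v[nzchar(v)]))
    chk <- truthCheck(sim, flagged = flagged, corrected = pp$spectra)
    expect_equal(chk$spikeRecall, 1.0)
    expect_equal(chk$spikeFalsePositives, 0L)
    expect_lt(chk$maxRatioErrPct, 10)  # coarse 2 cm^-1 axis; study-scale
                                       # recovery is asserted elsewhere at 5%
    expect_equal(nrow(pp$audit), ncol(sim$spectra))

    # a corrupt (all-zero) spectrum is reported with its patient id
    bad <- ramanSpectra(cbind(rep(0, 201), runif(201)), seq(600, 1000, 2),
                        patientId = c("Pbad", "Pok"), classLabel = "x")
    expect_error(runPreprocess(bad, preprocessConfig(cropLow = 600,
                                                     cropHigh = 1000)),
                 "Pbad")
})

test_that("pass-through config leaves a flat-baseline collection at its cropped input", {
    # Gaussian bands: tails vanish fast, so the estimated background under a
    # zero-baseline spectrum is essentially zero and only crop acts.
    bands <- list(bandSpec(700, c(a = 3, b = 1), shape = "gaussian"),
                  bandSpec(900, c(a = 1, b = 3), shape = "gaussian"))
    cfg <- syntheticConfig(bands, c(a = 3L, b = 3L),
                           axis = seq(600, 1000, 2), spectraPerPatient = 8L,
                           spectrumNoiseSd = 0, patientAmplitudeSd = 0,
                           spikeRate = 0, baselineCoef = 0, seed = 2L)
    sim <- simulateCollection(cfg)
    pp <- runPreprocess(sim$spectra,
                        preprocessConfig(cropLow = 650, cropHigh = 950,
                                         normalisation = "none"))
    cropped <- cropSpectra(sim$spectra, 650, 950)
    # zero baseline, no spikes, no normalisation: only ALS runs, and its
    # baseline under pure peaks is near zero
    expect_equal(sum(pp$audit$n_spikes), 0L)
    expect_equal(intensityMatrix(pp$spectra), intensityMatrix(cropped),
                 tolerance = 0.02)
})

test_that("band intensity is the window maximum", {
    wn <- 900:1100
    y <- 3.30 * exp(-(wn - 1003)^2 / (2 * 5^2))
    rs <- ramanSpectra(y, wn, "P1", "x")
    expect_equal(bandIntensity(rs, 1003, 5)[[1L]], 3.30, tolerance = 1e-6)
    flat <- ramanSpectra(rep(4.2, 201), wn, "P1", "x")
    expect_equal(bandIntensity(flat, 1000, 5)[[1L]], 4.2)
    expect_error(bandIntensity(rs, 2000, 5), "does not intersect")
})
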