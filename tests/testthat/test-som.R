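test_that("hex distance matches the axial closed form and is symmetric", {
    expect_equal(hexDistance(c(0, 0), c(0, 0)), 0)
    expect_equal(hexDistance(c(0, 0), c(1, 1)), 2)
    expect_equal(hexDistance(c(0, 0), c(1, -1)), 1)  # shared-axis neighbour
    set.seed(9)
    for (i in 1:20) {
        a <- sample(-5:5, 2)
        b <- sample(-5:5, 2)
        expect_equal(hexDistance(a, b), hexDistance(b, a))
    }
})

test_that("initialisation is seeded, counted and validated", {
    rng <- rbind(rep(0, 8), rep(1, 8))
    cfg <- somConfig(rows = 4, cols = 5, seed = 3L)
    m1 <- initSOM(cfg, seq(550, 557), c("a", "b"), rng)
    m2 <- initSOM(cfg, seq(550, 557), c("a", "b"), rng)
    expect_identical(m1@codebook, m2@codebook)
    expect_equal(ncol(m1@codebook), 20L)
    expect_true(all(colSums(m1@classWeights) == 1))
    expect_true(all(m1@codebook >= 0 & m1@codebook <= 1))
    expect_error(initSOM(cfg, seq(550, 557), character(0), rng), "non-empty")
    expect_error(initSOM(somConfig(rows = 1, cols = 1, initialRadius = 1,
                                   finalRadius = 0.5), 550:557,
                         c("a", "b"), rng), "at least as many neurons")
})

test_that("findBMU agrees with a brute-force oracle and breaks ties low", {
    rng <- rbind(rep(-1, 12), rep(1, 12))
    model <- initSOM(somConfig(rows = 5, cols = 5, seed = 8L),
                     seq_len(12), "a", rng)
    # exact match wins
    x <- model@codebook[, 17L]
    expect_equal(findBMU(model, x), 17L)
    # all-identical neurons: lowest index
    tied <- model
    tied@codebook <- matrix(0.5, 12, 25)
    expect_equal(findBMU(tied, runif(12)), 1L)
    # oracle over 200 random instances
    set.seed(14)
    for (i in 1:200) {
        m <- model
        m@codebook <- matrix(rnorm(12 * 25), 12, 25)
        x <- rnorm(12)
        oracle <- which.min(colSums((m@codebook - x)^2))
        expect_identical(findBMU(m, x), as.integer(oracle))
    }
    expect_error(findBMU(model, rnorm(5)), "channels")
})

test_that("training is deterministic and reduces quantisation error", {
    coll <- makeSeparableCollection(seed = 2L)
    cfg <- somConfig(rows = 6, cols = 6, nEpochs = 30L, seed = 5L)
    m1 <- trainSOM(coll, cfg)
    m2 <- trainSOM(coll, cfg)
    expect_identical(m1@codebook, m2@codebook)
    expect_identical(m1@classWeights, m2@classWeights)
    qe <- m1@trainingLog
    expect_length(qe, 30L)
    expect_lt(qe[30L], qe[1L])
    # trend: transient increases allowed, bounded at 5%
    expect_true(all(diff(qe) <= 0.05 * qe[-length(qe)]))
})

test_that("a single sample is a fixed point of the shrinking map", {
    one <- ramanSpectra(matrix(rnorm(20), 20, 1), 550:569, "P1", "a")
    cfg <- somConfig(rows = 1, cols = 1, nEpochs = 300L,
                     initialRadius = 1, finalRadius = 1e-3, seed = 1L)
    # one class keeps the 1x1 lattice legal
    m <- trainSOM(one, cfg)
    expect_lt(max(abs(m@codebook[, 1L] - intensityMatrix(one)[, 1L])), 1e-3)
})

test_that("classification scores are normalised and ties go to the first class", {
    coll <- makeSeparableCollection(seed = 3L)
    m <- trainSOM(coll, somConfig(rows = 6, cols = 6, nEpochs = 30L,
                                  seed = 6L))
    out <- classifySpectra(m, coll)
    expect_true(all(abs(rowSums(out$scores) - 1) < 1e-9))
    expect_true(all(out$scores >= 0))
    # tie-break: uniform class weights pick the first class
    tied <- m
    tied@classWeights <- matrix(0.5, 2, ncol(m@codebook))
    pred <- classifySpectra(tied, coll)$class
    expect_true(all(pred == classNames(m)[1L]))
    expect_error(classifySpectra(m, matrix(0, 3, 1)), "channels")
})

test_that("held-out accuracy on separable classes is at least 95%", {
    coll <- makeSeparableCollection(nPatientsPerClass = 4L,
                                    spectraPerPatient = 15L, seed = 4L)
    sp <- splitTrainTest(coll, splitPlan(seed = 7L))
    m <- trainSOM(coll[, sp$train], somConfig(rows = 6, cols = 6,
                                              nEpochs = 40L, seed = 9L))
    pred <- classifySpectra(m, coll[, sp$test])$class
    expect_gte(mean(pred == classLabels(coll)[sp$test]), 0.95)
})

test_that("neuron class map reflects dominant weights and clusters spatially", {
    coll <- makeSeparableCollection(seed = 8L)
    m <- trainSOM(coll, somConfig(rows = 6, cols = 6, nEpochs = 30L,
                                  seed = 2L))
    nm <- neuronClassMap(m)
    expect_equal(nrow(nm), 36L)
    expect_setequal(unique(nm$class), c("a", "b"))
    k <- apply(m@classWeights, 2L, which.max)
    expect_equal(nm$weight, m@classWeights[cbind(k, seq_along(k))])
    # each class's dominant neurons contain a connected cluster of >= 2
    for (cl in c("a", "b")) {
        pos <- as.matrix(nm[nm$class == cl, c("q", "r")])
        d <- outer(seq_len(nrow(pos)), seq_len(nrow(pos)), function(i, j)
            hexDistance(pos[i, , drop = FALSE], pos[j, , drop = FALSE]))
        expect_true(any(d == 1))
    }
    # degenerate: one class only
    oneClass <- coll[, classLabels(coll) == "a"]
    m1 <- trainSOM(oneClass, somConfig(rows = 3, cols = 3, nEpochs = 10L,
                                       seed = 1L))
    expect_true(all(neuronClassMap(m1)$class == "a"))
})

test_that("model serialisation round-trips exactly", {
    coll <- makeSeparableCollection(seed = 6L)
    m <- trainSOM(coll, somConfig(rows = 4, cols = 4, nEpochs = 10L,
                                  seed = 4L))
    d <- withr::local_tempdir()
    writeSOMModel(m, d)
    back <- readSOMModel(d)
    expect_identical(back@codebook, m@codebook)
    expect_identical(back@classWeights, m@classWeights)
    expect_equal(back@wavenumbers, m@wavenumbers)
    expect_identical(back@classNames, m@classNames)
    expect_equal(back@trainingLog, m@trainingLog)
    expect_equal(back@config[names(m@config)], m@config)
})
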