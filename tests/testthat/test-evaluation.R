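balancedCollection <- function(n = 50L, seed = 1L)
    makeSeparableCollection(nPatientsPerClass = 5L,
                            spectraPerPatient = as.integer(n / 5), seed = seed)

test_that("spectrum-level stratified split hits the 80/20 arithmetic", {
    coll <- balancedCollection()  # 50 + 50
    sp <- splitTrainTest(coll, splitPlan(seed = 3L))
    labs <- classLabels(coll)
    expect_length(sp$train, 80L)
    expect_length(sp$test, 20L)
    expect_equal(as.numeric(table(labs[sp$train])), c(40, 40))
    expect_equal(as.numeric(table(labs[sp$test])), c(10, 10))
    expect_setequal(c(sp$train, sp$test), seq_len(100))
    sp2 <- splitTrainTest(coll, splitPlan(seed = 3L))
    expect_identical(sp, sp2)
})

test_that("patient-level splits never leak a patient across sides", {
    coll <- makeSeparableCollection(nPatientsPerClass = 5L,
                                    spectraPerPatient = 10L, seed = 2L)
    for (s in 1:5) {
        sp <- splitTrainTest(coll, splitPlan(unit = "patient", seed = s))
        pid <- patientIds(coll)
        expect_length(intersect(pid[sp$train], pid[sp$test]), 0L)
    }
    tiny <- ramanSpectra(matrix(rnorm(8), 2), c(550, 551),
                         patientId = c("P1", "P1", "P1", "P2"),
                         classLabel = c("a", "a", "b", "b"))
    expect_error(splitTrainTest(tiny, splitPlan(unit = "patient")),
                 "patients")
})

test_that("stratified folds partition indices with per-class balance", {
    labs <- rep(c("x", "y"), c(60, 40))
    folds <- stratifiedKFold(labs, 10, seed = 4L)
    expect_length(folds, 10L)
    for (f in folds) {
        expect_equal(sum(labs[f] == "x"), 6L)
        expect_equal(sum(labs[f] == "y"), 4L)
    }
    expect_setequal(unlist(folds), seq_along(labs))
    expect_equal(sum(lengths(folds)), length(labs))  # disjoint + complete

    labs101 <- c(labs, "x")
    folds101 <- stratifiedKFold(labs101, 10, seed = 4L)
    expect_equal(sort(unique(lengths(folds101))), c(10L, 11L))
    expect_equal(sum(lengths(folds101) == 11L), 1L)

    expect_error(stratifiedKFold(rep(c("x", "y"), c(60, 5)), 10), "fewer")
})

test_that("oversampling equalises to the majority and retains every index", {
    labs <- rep(c("A", "B"), c(330, 90))
    aug <- oversampleTraining(seq_along(labs), labs, seed = 5L)
    expect_equal(as.numeric(table(labs[aug])), c(330, 330))
    expect_true(all(seq_along(labs) %in% aug))
    expect_equal(aug[seq_along(labs)], seq_along(labs))  # originals first

    bal <- rep(c("A", "B"), each = 50)
    expect_identical(oversampleTraining(seq_along(bal), bal, 1L),
                     seq_along(bal))
    expect_error(oversampleTraining(integer(0), labs), "empty")
})

test_that("confusion metrics match hand computation and flag undefined cases", {
    m <- metricsFromConfusion(c(tp = 9, fn = 1, tn = 8, fp = 2))
    expect_equal(m$sensitivity, 90)
    expect_equal(m$specificity, 80)
    expect_equal(m$ppv, 900 / 11)
    expect_equal(m$npv, 800 / 9)
    expect_equal(m$accuracy, 85)

    perfect <- metricsFromConfusion(c(tp = 5, fn = 0, tn = 5, fp = 0))
    expect_true(all(as.numeric(perfect) == 100))

    deg <- metricsFromConfusion(c(tp = 0, fn = 0, tn = 7, fp = 3))
    expect_true(is.na(deg$sensitivity))
    expect_equal(deg$specificity, 70)
    expect_equal(deg$accuracy, 70)
})

test_that("metrics agree with exact rational arithmetic on random matrices", {
    set.seed(6)
    for (i in 1:20) {
        cm <- c(tp = sample(0:50, 1), fp = sample(0:50, 1),
                tn = sample(0:50, 1), fn = sample(0:50, 1))
        if (sum(cm) == 0) cm["tp"] <- 1
        m <- metricsFromConfusion(cm)
        # cross-multiplied exactness: metric/100 * denominator == numerator
        chk <- function(val, num, den) {
            if (den == 0) expect_true(is.na(val))
            else expect_lt(abs(val * den - 100 * num), 1e-9)
        }
        chk(m$sensitivity, cm[["tp"]], cm[["tp"]] + cm[["fn"]])
        chk(m$specificity, cm[["tn"]], cm[["tn"]] + cm[["fp"]])
        chk(m$ppv, cm[["tp"]], cm[["tp"]] + cm[["fp"]])
        chk(m$npv, cm[["tn"]], cm[["tn"]] + cm[["fn"]])
        chk(m$accuracy, cm[["tp"]] + cm[["tn"]], sum(cm))
    }
})

test_that("cross-validation emits one row per fold with balanced held-out sets", {
    coll <- balancedCollection(seed = 7L)
    cv <- crossValidate(coll, somConfig(rows = 5, cols = 5, nEpochs = 15L,
                                        seed = 2L),
                        splitPlan(folds = 10, seed = 9L),
                        positiveClass = "a")
    expect_equal(nrow(cv$perFold), 10L)
    expect_true(all(cv$perFold$n_test == 10L))
    expect_gte(cv$meanAccuracy, 0.95)
    expect_equal(cv$positiveClass, "a")
})

test_that("shuffled labels drive accuracy to chance", {
    coll <- balancedCollection(n = 40L, seed = 8L)
    set.seed(31)
    shuffled <- coll
    SummarizedExperiment::colData(shuffled)$class_label <-
        sample(classLabels(coll))
    rep <- repeatedEvaluation(shuffled,
                              somConfig(rows = 5, cols = 5, nEpochs = 15L,
                                        seed = 4L),
                              splitPlan(seed = 11L), nRuns = 4L,
                              positiveClass = "a")
    acc <- metricsSummary(rep)$mean[metricsSummary(rep)$metric == "accuracy"]
    expect_gt(acc, 35)
    expect_lt(acc, 65)
})

test_that("repeated evaluation reports runs, aggregates and confusions deterministically", {
    coll <- balancedCollection(seed = 10L)
    cfg <- somConfig(rows = 5, cols = 5, nEpochs = 15L, seed = 1L)
    plan <- splitPlan(seed = 2L)
    r1 <- repeatedEvaluation(coll, cfg, plan, nRuns = 3L, positiveClass = "a")
    expect_equal(nrow(runMetrics(r1)), 3L)
    expect_equal(metricsSummary(r1)$metric,
                 c("sensitivity", "specificity", "ppv", "npv", "accuracy"))
    expect_true(all(metricsSummary(r1)$sd >= 0))
    expect_length(confusions(r1), 3L)
    expect_equal(sum(confusions(r1)[[1L]]), 20L)  # test-set size
    r2 <- repeatedEvaluation(coll, cfg, plan, nRuns = 3L, positiveClass = "a")
    expect_identical(runMetrics(r1), runMetrics(r2))
    expect_error(repeatedEvaluation(coll, cfg, plan, nRuns = 1L), "nRuns")
})
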