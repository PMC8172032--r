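#' Train/test split plan
#'
#' @param unit `"spectrum"` (each spectrum assigned independently — mirrors
#'   pulling 80 percent of the spectra at random) or `"patient"` (all of a
#'   patient's spectra stay on one side; recommended when 100 spectra per
#'   patient would otherwise leak patient identity across the split).
#' @param trainFraction fraction of units assigned to training (default
#'   0.8).
#' @param folds folds for cross-validation (default 10).
#' @param oversample logical: equalise class counts in training pools by
#'   sampling with replacement.
#' @param seed integer RNG seed.
#' @return a validated list of class `"SplitPlan"`.
#' @export
splitPlan <- function(unit = c("spectrum", "patient"), trainFraction = 0.8,
                      folds = 10L, oversample = TRUE, seed = 42L) {
    unit <- match.arg(unit)
    if (trainFraction <= 0 || trainFraction >= 1)
        stop("trainFraction must lie in (0, 1)")
    if (folds < 2L) stop("folds must be >= 2")
    structure(list(unit = unit, trainFraction = trainFraction,
                   folds = as.integer(folds), oversample = isTRUE(oversample),
                   seed = as.integer(seed)),
              class = "SplitPlan")
}

#' Stratified train/test split
#'
#' Random stratified split at the plan's unit.  Per-class training counts
#' are `round(trainFraction * n)` so proportions are within one unit of the
#' target; deterministic for a given seed.
#'
#' @param x a labelled [RamanSpectra-class].
#' @param plan a [splitPlan()] list.
#' @return list with integer column indices `train` and `test`.
#' @export
splitTrainTest <- function(x, plan = splitPlan()) {
    stopifnot(methods::is(x, "RamanSpectra"), inherits(plan, "SplitPlan"))
    labs <- classLabels(x)
    pid <- patientIds(x)
    set.seed(plan$seed)
    train <- integer(0)
    for (cl in sort(unique(labs))) {
        if (plan$unit == "spectrum") {
            units <- which(labs == cl)
            if (length(units) < 2L)
                stop(sprintf("class '%s' has %d spectra; need >= 2 to stratify",
                             cl, length(units)))
            pick <- sample(units, round(plan$trainFraction * length(units)))
            train <- c(train, pick)
        } else {
            pats <- unique(pid[labs == cl])
            if (length(pats) < 2L)
                stop(sprintf("class '%s' has %d patients; need >= 2 to stratify",
                             cl, length(pats)))
            pick <- sample(pats, round(plan$trainFraction * length(pats)))
            train <- c(train, which(pid %in% pick & labs == cl))
        }
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labs), train))
}

#' Stratified k-fold partition
#'
#' Shuffles each class (seeded) and deals its members round-robin across
#' folds, so per-class counts across folds differ by at most one and the
#' folds partition the full index set.
#'
#' @param labels character/factor vector of class labels.
#' @param k number of folds.
#' @param seed integer RNG seed.
#' @return list of `k` disjoint integer index vectors.
#' @export
stratifiedKFold <- function(labels, k = 10L, seed = 42L) {
    k <- as.integer(k)
    if (k < 2L) stop("k must be >= 2")
    labels <- as.character(labels)
    tab <- table(labels)
    small <- names(tab)[tab < k]
    if (length(small))
        stop(sprintf("class '%s' has fewer members (%d) than folds (%d)",
                     small[1L], tab[small[1L]], k))
    set.seed(seed)
    folds <- vector("list", k)
    for (cl in sort(unique(labels))) {
        idx <- sample(which(labels == cl))
        fold_of <- rep_len(seq_len(k), length(idx))
        for (f in seq_len(k))
            folds[[f]] <- c(folds[[f]], idx[fold_of == f])
    }
    lapply(folds, sort)
}

#' Oversample a training pool to class balance
#'
#' Minority classes are augmented by sampling with replacement (seeded)
#' until every class matches the majority count; every original index is
#' retained.
#'
#' @param indices integer vector of training indices.
#' @param labels class labels for the full data set (indexed by `indices`).
#' @param seed integer RNG seed.
#' @return augmented integer index vector (originals first).
#' @export
oversampleTraining <- function(indices, labels, seed = 42L) {
    if (!length(indices)) stop("empty training pool")
    labs <- as.character(labels)[indices]
    tab <- table(labs)
    target <- max(tab)
    set.seed(seed)
    extra <- integer(0)
    for (cl in sort(names(tab))) {
        need <- target - tab[[cl]]
        if (need > 0)
            extra <- c(extra,
                       sample(indices[labs == cl], need, replace = TRUE))
    }
    c(indices, extra)
}

#' Confusion counts for a positive class
#'
#' One-vs-rest confusion counts: the positive class is the disease-active
#' label by default, so sensitivity is the detection rate of disease
#' activity.
#'
#' @param predicted,truth character vectors of predicted and true labels.
#' @param positiveClass the label counted as positive.
#' @return named integer vector `c(tp, fp, tn, fn)`.
#' @export
confusionCounts <- function(predicted, truth, positiveClass) {
    stopifnot(length(predicted) == length(truth), length(truth) > 0L)
    p <- predicted == positiveClass
    t <- truth == positiveClass
    c(tp = sum(p & t), fp = sum(p & !t), tn = sum(!p & !t), fn = sum(!p & t))
}

#' Confusion-matrix metrics, in percent
#'
#' sensitivity = tp/(tp+fn), specificity = tn/(tn+fp), ppv = tp/(tp+fp),
#' npv = tn/(tn+fn), accuracy = (tp+tn)/total, each times 100.  A metric
#' with zero denominator is reported as `NA` (undefined) rather than
#' aborting.
#'
#' @param cm named numeric vector with elements tp, fp, tn, fn.
#' @return one-row data.frame: sensitivity, specificity, ppv, npv, accuracy.
#' @export
metricsFromConfusion <- function(cm) {
    cm <- cm[c("tp", "fp", "tn", "fn")]
    if (any(is.na(cm)) || any(cm < 0) || sum(cm) == 0)
        stop("confusion counts must be non-negative with positive total")
    rate <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
    data.frame(
        sensitivity = rate(cm[["tp"]], cm[["tp"]] + cm[["fn"]]),
        specificity = rate(cm[["tn"]], cm[["tn"]] + cm[["fp"]]),
        ppv = rate(cm[["tp"]], cm[["tp"]] + cm[["fp"]]),
        npv = rate(cm[["tn"]], cm[["tn"]] + cm[["fn"]]),
        accuracy = rate(cm[["tp"]] + cm[["tn"]], sum(cm)))
}

.pickPositiveClass <- function(classes, positiveClass = NULL) {
    if (!is.null(positiveClass)) {
        if (!positiveClass %in% classes)
            stop("positiveClass '", positiveClass, "' not among labels")
        return(positiveClass)
    }
    hit <- grep("active|pre", classes, ignore.case = TRUE, value = TRUE)
    if (length(hit)) hit[1L] else sort(classes)[1L]
}

#' Stratified k-fold cross-validation of the SOM classifier
#'
#' For each fold: the remaining folds form the training pool (oversampled
#' to class balance when the plan says so), a SOM is trained on it, the
#' held-out fold is classified, and confusion-matrix metrics are recorded.
#'
#' @param train a labelled [RamanSpectra-class] (typically the 80 percent
#'   training portion of a split).
#' @param somCfg a [somConfig()] list; fold `f` trains with seed
#'   `somCfg$seed + f`.
#' @param plan a [splitPlan()] list (`folds`, `oversample`, `seed` used).
#' @param positiveClass label counted as positive; defaults to the
#'   disease-active-like label.
#' @return list with `perFold` (data.frame: fold, n_test, the five metrics)
#'   and `meanAccuracy` (fraction in `[0, 1]`).
#' @export
crossValidate <- function(train, somCfg = somConfig(), plan = splitPlan(),
                          positiveClass = NULL) {
    stopifnot(methods::is(train, "RamanSpectra"))
    labs <- classLabels(train)
    classes <- sort(unique(labs))
    positiveClass <- .pickPositiveClass(classes, positiveClass)
    folds <- stratifiedKFold(labs, plan$folds, plan$seed)
    rows <- vector("list", length(folds))
    for (f in seq_along(folds)) {
        res <- tryCatch({
            tr <- setdiff(seq_along(labs), folds[[f]])
            if (plan$oversample)
                tr <- oversampleTraining(tr, labs, plan$seed + f)
            cfg <- somCfg
            cfg$seed <- somCfg$seed + f
            model <- trainSOM(train[, tr], cfg, classNames = classes)
            pred <- classifySpectra(model, train[, folds[[f]]])$class
            metricsFromConfusion(
                confusionCounts(pred, labs[folds[[f]]], positiveClass))
        }, error = function(e)
            stop(sprintf("fold %d: %s", f, conditionMessage(e)),
                 call. = FALSE))
        rows[[f]] <- cbind(fold = f, n_test = length(folds[[f]]), res)
    }
    perFold <- do.call(rbind, rows)
    list(perFold = perFold, meanAccuracy = mean(perFold$accuracy) / 100,
         positiveClass = positiveClass)
}

#' Repeated split/train/test evaluation
#'
#' Repeats the full protocol `nRuns` times with run-derived seeds
#' (`plan$seed + run`, `somCfg$seed + run`): stratified train/test split,
#' optional oversampling of the training pool, SOM training, classification
#' of the held-out test spectra, and confusion-matrix metrics.  Reports
#' per-run metrics, their mean and sample standard deviation (n - 1
#' denominator), and each run's confusion counts.
#'
#' @param x a labelled [RamanSpectra-class].
#' @param somCfg a [somConfig()] list.
#' @param plan a [splitPlan()] list.
#' @param nRuns number of repetitions (>= 2; default 10).
#' @param positiveClass label counted as positive (default: the
#'   disease-active-like label).
#' @param keepModels retain each run's trained [SOMModel-class] in the
#'   report's `models` element.
#' @return an [EvaluationReport-class]; when `keepModels = TRUE` the
#'   trained models are attached as `attr(report, "models")`.
#' @export
repeatedEvaluation <- function(x, somCfg = somConfig(), plan = splitPlan(),
                               nRuns = 10L, positiveClass = NULL,
                               keepModels = FALSE) {
    stopifnot(methods::is(x, "RamanSpectra"))
    nRuns <- as.integer(nRuns)
    if (nRuns < 2L) stop("nRuns must be >= 2")
    labs <- classLabels(x)
    classes <- sort(unique(labs))
    positiveClass <- .pickPositiveClass(classes, positiveClass)
    rows <- vector("list", nRuns)
    cms <- vector("list", nRuns)
    models <- if (keepModels) vector("list", nRuns)
    for (r in seq_len(nRuns)) {
        run <- tryCatch({
            pl <- plan
            pl$seed <- plan$seed + r
            sp <- splitTrainTest(x, pl)
            tr <- sp$train
            if (plan$oversample)
                tr <- oversampleTraining(tr, labs, pl$seed)
            cfg <- somCfg
            cfg$seed <- somCfg$seed + r
            model <- trainSOM(x[, tr], cfg, classNames = classes)
            pred <- classifySpectra(model, x[, sp$test])$class
            cm <- confusionCounts(pred, labs[sp$test], positiveClass)
            list(metrics = metricsFromConfusion(cm), cm = cm, model = model)
        }, error = function(e)
            stop(sprintf("run %d: %s", r, conditionMessage(e)),
                 call. = FALSE))
        rows[[r]] <- cbind(run = r, run$metrics)
        cms[[r]] <- run$cm
        if (keepModels) models[[r]] <- run$model
    }
    perRun <- do.call(rbind, rows)
    metricNames <- c("sensitivity", "specificity", "ppv", "npv", "accuracy")
    summ <- data.frame(
        metric = metricNames,
        mean = vapply(metricNames, function(m) mean(perRun[[m]]), 0),
        sd = vapply(metricNames, function(m) sd(perRun[[m]]), 0))
    report <- methods::new("EvaluationReport", perRun = perRun,
                           summary = summ, confusions = cms,
                           positiveClass = positiveClass, nRuns = nRuns)
    if (keepModels) attr(report, "models") <- models
    report
}
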