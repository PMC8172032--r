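#' SOM training configuration
#'
#' Hyperparameters of the hexagonal Kohonen map.  Learning rate and
#' neighbourhood radius both decay exponentially from their initial to their
#' final value over the total number of sample presentations
#' (`nEpochs * nSamples`).  Class channels are updated with the same
#' neighbourhood factor, scaled by `classWeightScale`, and never enter
#' best-matching-unit distances.
#'
#' @param rows,cols lattice dimensions (default 10 x 10).
#' @param nEpochs passes over the training data (default 100).
#' @param initialLearningRate,finalLearningRate alpha schedule endpoints,
#'   0 < final <= initial <= 1 (defaults 0.5 -> 0.01).
#' @param initialRadius,finalRadius neighbourhood sigma endpoints in
#'   hex-distance units; defaults max(rows, cols)/2 -> 1.
#' @param classWeightScale non-negative multiplier on class-channel updates
#'   (default 1).
#' @param seed integer RNG seed controlling initialisation and presentation
#'   order.
#' @return a validated list of class `"SOMConfig"`.
#' @export
somConfig <- function(rows = 10L, cols = 10L, nEpochs = 100L,
                      initialLearningRate = 0.5, finalLearningRate = 0.01,
                      initialRadius = max(rows, cols) / 2, finalRadius = 1,
                      classWeightScale = 1, seed = 42L) {
    rows <- as.integer(rows); cols <- as.integer(cols)
    if (rows < 1L || cols < 1L) stop("rows and cols must be positive")
    if (nEpochs < 1L) stop("nEpochs must be positive")
    if (initialLearningRate <= 0 || initialLearningRate > 1)
        stop("initialLearningRate must lie in (0, 1]")
    if (finalLearningRate <= 0 || finalLearningRate > initialLearningRate)
        stop("finalLearningRate must lie in (0, initialLearningRate]")
    if (initialRadius <= 0) stop("initialRadius must be positive")
    if (finalRadius <= 0 || finalRadius > initialRadius)
        stop("finalRadius must lie in (0, initialRadius]")
    if (classWeightScale < 0) stop("classWeightScale must be non-negative")
    structure(list(rows = rows, cols = cols, nEpochs = as.integer(nEpochs),
                   initialLearningRate = initialLearningRate,
                   finalLearningRate = finalLearningRate,
                   initialRadius = initialRadius, finalRadius = finalRadius,
                   classWeightScale = classWeightScale,
                   seed = as.integer(seed)),
              class = "SOMConfig")
}

#' Hexagonal grid distance between axial coordinates
#'
#' `(|dq| + |dr| + |dq + dr|) / 2`, the number of steps between two cells of
#' a hexagonal lattice in axial coordinates.
#'
#' @param a,b numeric vectors `c(q, r)` or two-column matrices of axial
#'   coordinates (rows paired).
#' @return non-negative integer distance(s).
#' @export
hexDistance <- function(a, b) {
    a <- matrix(as.numeric(a), ncol = 2L)
    b <- matrix(as.numeric(b), ncol = 2L)
    dq <- a[, 1L] - b[, 1L]
    dr <- a[, 2L] - b[, 2L]
    (abs(dq) + abs(dr) + abs(dq + dr)) / 2
}

# Axial coordinates of a rows x cols hex lattice, row-major, "odd-r" offset
# rows shifted so neighbouring rows interleave.
.hexPositions <- function(rows, cols) {
    rr <- rep(seq_len(rows) - 1L, each = cols)
    cc <- rep(seq_len(cols) - 1L, times = rows)
    cbind(q = cc - rr %/% 2L, r = rr)
}

# neurons x neurons matrix of squared hex distances
.hexDist2 <- function(pos) {
    n <- nrow(pos)
    d <- outer(seq_len(n), seq_len(n), function(i, j)
        hexDistance(pos[i, , drop = FALSE], pos[j, , drop = FALSE]))
    d^2
}

#' Initialise a SOM from training-data channel ranges
#'
#' Spectral weights are drawn uniformly from the per-channel `[min, max]`
#' range of the training data; class weights start uniform at
#' `1/nClasses`.  Deterministic for a given `config$seed`.
#'
#' @param config a [somConfig()] list.
#' @param wavenumbers numeric spectral axis.
#' @param classNames character vector of class labels (order fixes the
#'   class-channel layout and classification tie-break).
#' @param dataRange 2 x channels matrix: per-channel min (row 1) and max
#'   (row 2) of the training data.
#' @return an untrained [SOMModel-class].
#' @export
initSOM <- function(config, wavenumbers, classNames, dataRange) {
    stopifnot(inherits(config, "SOMConfig"))
    if (!length(classNames)) stop("class list must be non-empty")
    if (anyDuplicated(classNames)) stop("classNames must be unique")
    nch <- length(wavenumbers)
    nneu <- config$rows * config$cols
    if (nneu < length(classNames))
        stop("lattice must have at least as many neurons as classes")
    if (!is.matrix(dataRange) || nrow(dataRange) != 2L ||
        ncol(dataRange) != nch)
        stop("dataRange must be a 2 x channels matrix")
    set.seed(config$seed)
    codebook <- matrix(runif(nch * nneu, dataRange[1L, ], dataRange[2L, ]),
                       nch, nneu)
    classW <- matrix(1 / length(classNames), length(classNames), nneu)
    methods::new("SOMModel", codebook = codebook, classWeights = classW,
                 positions = .hexPositions(config$rows, config$cols),
                 wavenumbers = as.numeric(wavenumbers),
                 classNames = as.character(classNames),
                 config = unclass(config), trainingLog = numeric(0),
                 trained = FALSE)
}

#' Best-matching unit
#'
#' Index of the neuron whose spectral weight vector is Euclidean-nearest to
#' each input (class weights excluded); ties go to the lowest index.
#'
#' @param model a [SOMModel-class].
#' @param x numeric vector (one spectrum) or channels x spectra matrix.
#' @return integer neuron index (1-based), one per input spectrum.
#' @export
findBMU <- function(model, x) {
    stopifnot(methods::is(model, "SOMModel"))
    if (is.vector(x)) x <- matrix(x, ncol = 1L)
    if (nrow(x) != nrow(model@codebook))
        stop(sprintf("input has %d channels, model expects %d",
                     nrow(x), nrow(model@codebook)))
    cpp_find_bmu(model@codebook, x) + 1L
}

#' Train a class-augmented SOM
#'
#' Online Kohonen training: every epoch visits all spectra in a freshly
#' shuffled (seeded) order; each presentation moves every neuron's spectral
#' weights toward the sample and its class weights toward the sample's
#' one-hot label, scaled by the decaying learning rate and a Gaussian
#' neighbourhood of the best-matching unit on the hex lattice.  The
#' training log records per-epoch mean quantisation error (mean Euclidean
#' distance of samples to their BMU at presentation).
#'
#' @param data a labelled [RamanSpectra-class]; every class needs at least
#'   one spectrum.
#' @param config a [somConfig()] list.
#' @param classNames optional fixed class order; defaults to the sorted
#'   distinct labels in `data`.
#' @return a trained [SOMModel-class].
#' @export
trainSOM <- function(data, config = somConfig(), classNames = NULL) {
    stopifnot(methods::is(data, "RamanSpectra"),
              inherits(config, "SOMConfig"))
    if (ncol(data) == 0L) stop("training data is empty")
    labs <- classLabels(data)
    if (is.null(classNames)) classNames <- sort(unique(labs))
    if (!all(labs %in% classNames))
        stop("data contains labels missing from classNames")
    X <- intensityMatrix(data)
    rng <- apply(X, 1L, range)  # 2 x channels
    model <- initSOM(config, wavenumbers(data), classNames, rng)
    n <- ncol(X)
    order0 <- matrix(vapply(seq_len(config$nEpochs),
                            function(e) sample.int(n) - 1L, integer(n)),
                     nrow = n)
    fit <- cpp_train_som(model@codebook, model@classWeights, X,
                         match(labs, classNames) - 1L, order0,
                         .hexDist2(model@positions),
                         config$initialLearningRate,
                         config$finalLearningRate,
                         config$initialRadius, config$finalRadius,
                         config$classWeightScale)
    model@codebook <- fit$codebook
    model@classWeights <- fit$classWeights
    model@trainingLog <- as.numeric(fit$qe)
    model@trained <- TRUE
    model
}

#' Classify spectra with a trained SOM
#'
#' Each spectrum is assigned its best-matching unit's class-weight vector,
#' normalised to sum 1, as a score vector; the predicted class is the
#' argmax (first class wins ties).
#'
#' @param model a trained [SOMModel-class].
#' @param x a [RamanSpectra-class], numeric vector, or channels x spectra
#'   matrix on the model's axis.
#' @return list with `class` (character vector) and `scores`
#'   (spectra x classes matrix, rows summing to 1).
#' @export
classifySpectra <- function(model, x) {
    stopifnot(methods::is(model, "SOMModel"))
    if (!model@trained) stop("model is untrained")
    if (methods::is(x, "RamanSpectra")) x <- intensityMatrix(x)
    if (is.vector(x)) x <- matrix(x, ncol = 1L)
    bmu <- findBMU(model, x)
    sc <- t(model@classWeights[, bmu, drop = FALSE])
    tot <- rowSums(sc)
    tot[tot == 0] <- 1  # degenerate neuron: fall back to uniform-equivalent
    sc <- sc / tot
    colnames(sc) <- model@classNames
    list(class = model@classNames[apply(sc, 1L, which.max)], scores = sc)
}

#' Dominant class per neuron
#'
#' The data behind map visualisations: for every neuron its lattice
#' position, strongest class and that class's weight.
#'
#' @param model a trained [SOMModel-class].
#' @return data.frame with columns q, r, class, weight (row order =
#'   neuron order).
#' @export
neuronClassMap <- function(model) {
    stopifnot(methods::is(model, "SOMModel"))
    k <- apply(model@classWeights, 2L, which.max)
    data.frame(q = model@positions[, 1L], r = model@positions[, 2L],
               class = model@classNames[k],
               weight = model@classWeights[cbind(k, seq_along(k))])
}

#' Serialise / restore a SOM model as plain text
#'
#' Weights are written at full `%.17g` precision so the round trip is exact.
#'
#' @param model a [SOMModel-class].
#' @param dir directory to create/read.
#' @return `writeSOMModel` returns `dir` invisibly; `readSOMModel` the
#'   restored [SOMModel-class].
#' @export
writeSOMModel <- function(model, dir) {
    stopifnot(methods::is(model, "SOMModel"))
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
        stop("cannot create directory ", dir)
    meta <- list(config = model@config, classNames = model@classNames,
                 wavenumbers = model@wavenumbers,
                 trainingLog = model@trainingLog, trained = model@trained)
    jsonlite::write_json(meta, file.path(dir, "model.json"),
                         auto_unbox = TRUE, digits = NA)
    .writeMat <- function(m, f)
        writeLines(apply(matrix(sprintf("%.17g", m), nrow(m)), 1L,
                         paste, collapse = ","), file.path(dir, f))
    .writeMat(model@codebook, "codebook.csv")
    .writeMat(model@classWeights, "class_weights.csv")
    invisible(dir)
}

#' @rdname writeSOMModel
#' @export
readSOMModel <- function(dir) {
    meta <- jsonlite::read_json(file.path(dir, "model.json"),
                                simplifyVector = TRUE)
    .readMat <- function(f) {
        rows <- strsplit(readLines(file.path(dir, f)), ",")
        matrix(as.numeric(unlist(rows)), length(rows), byrow = TRUE)
    }
    cfg <- meta$config
    cfg[c("rows", "cols", "nEpochs", "seed")] <-
        lapply(cfg[c("rows", "cols", "nEpochs", "seed")], as.integer)
    methods::new("SOMModel", codebook = .readMat("codebook.csv"),
                 classWeights = .readMat("class_weights.csv"),
                 positions = .hexPositions(cfg$rows, cfg$cols),
                 wavenumbers = as.numeric(meta$wavenumbers),
                 classNames = as.character(meta$classNames), config = cfg,
                 trainingLog = as.numeric(meta$trainingLog),
                 trained = isTRUE(meta$trained))
}
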