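# Negative-binomial simulation engine used by the benchmark studies and
# the selector's training grid.
#
# Generative model: X_{kig} ~ NB(d_kg * s_i * lambda_g, phi) with
# s ~ Uniform[0.2, 2.2], lambda ~ Exponential(mean 25), and, for DE genes
# only, log d_kg ~ Normal(0, sigma^2) drawn independently per class
# (non-DE genes have d = 1 in every class).  phi = 0 means exact Poisson
# sampling.  Each entry is then independently replaced by 0 with
# probability p0 (uniform excess-zero masking).

#' Simulate an RNA-seq count dataset
#'
#' Draws a gene x sample count matrix from the NB generative model above.
#' Classes are as balanced as `n` allows (sizes differ by at most 1).
#' Supplying `truth` (from a previous call) reuses its `lambda`, `d` and
#' DE gene set so that independent test samples can be drawn from the
#' same population; sample-level quantities (size factors, counts, zero
#' mask) are drawn fresh.
#'
#' @param K number of classes (2 or 3 in the benchmark studies).
#' @param n total number of samples.
#' @param G number of genes.
#' @param deRate fraction of genes that are differentially expressed.
#' @param sigma standard deviation of log d_kg for DE genes.
#' @param phi NB dispersion (variance mu + phi mu^2); 0 = Poisson.
#' @param p0 excess-zero probability in `[0, 1)`.
#' @param lambdaMean mean of the exponential gene-abundance distribution.
#' @param sRange range of the uniform size-factor distribution.
#' @param seed optional integer seed (local to this call).
#' @param truth optional truth list from a previous call to reuse the
#'   gene-level population parameters.
#' @return list with `counts` (G x n integer matrix), `labels` (1..K
#'   integer vector) and `truth` (list: `s`, `lambda`, `d`, `deGenes`,
#'   `phi`, `p0`).
#' @examples
#' sim <- simulateCounts(n = 10, G = 20, phi = 0.5, seed = 1)
#' dim(sim$counts)
#' @export
simulateCounts <- function(K = 2, n = 50, G = 100, deRate = 0.2,
        sigma = 0.2, phi = 0, p0 = 0, lambdaMean = 25,
        sRange = c(0.2, 2.2), seed = NULL, truth = NULL) {
    stopifnot(K >= 2, n >= K, G >= 1, deRate >= 0, deRate <= 1,
        sigma >= 0, phi >= 0, p0 >= 0, p0 < 1, lambdaMean > 0)
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
        set.seed(seed)
    }
    sizes <- rep(n %/% K, K) + c(rep(1, n %% K), rep(0, K - n %% K))
    labels <- rep(seq_len(K), times = sizes)
    if (is.null(truth)) {
        lambda <- stats::rexp(G, rate = 1 / lambdaMean)
        nDE <- round(deRate * G)
        deGenes <- if (nDE > 0) sort(sample.int(G, nDE)) else integer(0)
        d <- matrix(1, K, G)
        if (length(deGenes))
            d[, deGenes] <- exp(matrix(
                stats::rnorm(K * length(deGenes), 0, sigma),
                K, length(deGenes)))
    } else {
        lambda <- truth$lambda; d <- truth$d; deGenes <- truth$deGenes
        phi <- truth$phi; p0 <- truth$p0
    }
    s <- stats::runif(n, sRange[1], sRange[2])
    mu <- t(d)[, labels, drop = FALSE] * rep(s, each = G) * lambda
    counts <- if (phi > 0)
        matrix(stats::rnbinom(G * n, mu = mu, size = 1 / phi), G, n)
    else
        matrix(stats::rpois(G * n, lambda = mu), G, n)
    if (p0 > 0)
        counts[matrix(stats::runif(G * n) < p0, G, n)] <- 0L
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(paste0("g", seq_len(G)), paste0("s", seq_len(n)))
    list(counts = counts, labels = labels,
        truth = list(s = s, lambda = lambda, d = d, deGenes = deGenes,
            phi = phi, p0 = p0))
}

#' Simulate a matched training/test pair
#'
#' Draws the gene-level population (`lambda`, `d`, DE set) once, then a
#' training set of `n` samples and an independent test set of `nTest`
#' samples from it.
#'
#' @inheritParams simulateCounts
#' @param nTest test-set size (default `n`, the benchmark convention).
#' @return list with `train` and `test`, each as [simulateCounts()].
#' @export
simulateTrainTest <- function(K = 2, n = 50, G = 100, deRate = 0.2,
        sigma = 0.2, phi = 0, p0 = 0, nTest = n, lambdaMean = 25,
        sRange = c(0.2, 2.2), seed = NULL) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
        set.seed(seed)
    }
    train <- simulateCounts(K, n, G, deRate, sigma, phi, p0,
        lambdaMean, sRange)
    test <- simulateCounts(K, nTest, G, deRate, sigma, phi, p0,
        lambdaMean, sRange, truth = train$truth)
    list(train = train, test = test)
}

# Mean test misclassification of the four classifiers over `reps`
# independent train/test draws at one parameter setting.
.benchmarkCell <- function(K = 2, n = 50, G = 100, deRate = 0.2,
        sigma = 0.2, phi = 0, p0 = 0, reps = 100, nTest = n,
        methods = .METHODS) {
    errs <- matrix(NA_real_, reps, length(methods),
        dimnames = list(NULL, methods))
    for (r in seq_len(reps)) {
        tt <- simulateTrainTest(K = K, n = n, G = G, deRate = deRate,
            sigma = sigma, phi = phi, p0 = p0, nTest = nTest)
        fits <- .fitAllMethods(tt$train$counts, tt$train$labels)
        for (m in methods) {
            pr <- predict(fits[[m]], tt$test$counts)
            errs[r, m] <- misclassificationRate(pr$index, tt$test$labels)
        }
    }
    colMeans(errs)
}

# Grid definitions for the six benchmark studies (scaled replicas: the
# study design is fixed, the rep count is the caller's choice).
.studyGrids <- list(
    `1` = list(vary = "phi", grid = c(0, 0.2, 0.4, 0.6, 0.8, 1),
        fixed = list(n = 50, G = 100, deRate = 0.2, p0 = 0)),
    `2` = list(vary = "p0", grid = c(0.1, 0.15, 0.2, 0.25, 0.3),
        fixed = list(n = 50, G = 100, deRate = 0.2, phi = 0)),
    `3` = list(vary = "n", grid = c(8, 16, 30, 50, 100, 200, 300),
        fixed = list(G = 100, deRate = 0.2, phi = 0, p0 = 0.3)),
    `4` = list(vary = "G", grid = c(50, 100, 200, 300),
        fixed = list(n = 50, deRate = 0.2, phi = 0, p0 = 0.1)),
    `5` = list(vary = "deRate", grid = c(0.1, 0.2, 0.4, 0.6, 0.8),
        fixed = list(n = 8, G = 100, phi = 0.5, p0 = 0)),
    `6` = list(vary = NULL, grid = NULL,
        fixed = list(G = 100, deRate = 0.4)))

#' Run a benchmark study
#'
#' Replicates one of the six benchmark studies: mean test
#' misclassification of the four classifiers over `reps` fresh
#' train/test draws at each grid point.  `n` is the training-set size;
#' the test set matches it.  Studies vary, in order: (1) dispersion,
#' (2) excess-zero probability, (3) sample size, (4) gene count,
#' (5) DE rate, and (6) the full (n, phi, p0) cross.  All studies use
#' sigma = 0.2 and K = 2 unless overridden.
#'
#' @param study integer 1..6.
#' @param reps replicates per grid point (the full-scale design uses
#'   1000; 100 reproduces the qualitative trends at a fraction of the
#'   cost).
#' @param seed optional integer seed.
#' @param grid optional replacement for the varied parameter's grid
#'   (study 6: a data.frame with columns `n`, `phi`, `p0`).
#' @param ... fixed-parameter overrides passed to the simulator
#'   (e.g. `K = 3`, `sigma`).
#' @return data.frame with the grid columns and mean error columns
#'   `err_plda`, `err_nblda`, `err_ziplda`, `err_zinblda`.
#' @export
runStudy <- function(study, reps = 100, seed = NULL, grid = NULL, ...) {
    stopifnot(study %in% 1:6)
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
        set.seed(seed)
    }
    cfg <- .studyGrids[[as.character(study)]]
    fixed <- utils::modifyList(cfg$fixed, list(...))
    if (study == 6) {
        if (is.null(grid))
            grid <- expand.grid(n = c(8, 50, 100),
                phi = seq(0.001, 1.001, by = 0.2),
                p0 = c(0.001, 0.1, 0.3))
        cells <- grid
    } else {
        if (is.null(grid)) grid <- cfg$grid
        cells <- stats::setNames(data.frame(grid), cfg$vary)
    }
    errs <- matrix(NA_real_, nrow(cells), 4)
    for (i in seq_len(nrow(cells))) {
        args <- utils::modifyList(fixed, as.list(cells[i, , drop = FALSE]))
        args$reps <- reps
        errs[i, ] <- do.call(.benchmarkCell, args)
    }
    colnames(errs) <- paste0("err_", tolower(.METHODS))
    cbind(cells, as.data.frame(errs))
}
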