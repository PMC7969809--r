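# Meta-model: sweep the (n, phi, p0) grid, label each cell with the
# best-performing classifier, train a decision tree / random forest on
# the labels, and recommend a classifier for a new dataset from its
# estimated attributes.

#' Build the classifier-benchmark meta-table
#'
#' For every cell of the (n, phi, p0) grid, simulates `reps` independent
#' train/test pairs (K = 2, `G` genes, `deRate` DE fraction,
#' sigma = 0.2), records the four classifiers' mean test
#' misclassification rates, and labels the cell with the method
#' attaining the minimum.  Ties are broken by model simplicity:
#' PLDA < NBLDA < ZIPLDA < ZINBLDA.  The full-scale design uses the
#' default grids (n = 8..100 step 8, phi = 0.001..1.001 step 0.1,
#' p0 = 0..0.6 step 0.05) at 1000 reps; coarser grids and fewer reps
#' reproduce the same decision regions at a fraction of the cost.
#'
#' @param nGrid,phiGrid,p0Grid grid coordinates.
#' @param reps simulation replicates per cell.
#' @param seed optional integer seed.
#' @param G,deRate,sigma,K simulation parameters for every cell.
#' @param nTest test-set size per replicate.  The training size n is the
#'   grid feature; the test set is only Monte-Carlo evaluation
#'   machinery, so a fixed, larger test set (default 100) sharpens each
#'   cell's error estimates — and hence the winner labels — at a given
#'   replicate budget without changing what is estimated.
#' @param verbose print one progress line per grid cell.
#' @return data.frame with columns `n`, `phi`, `p0`, `err_plda`,
#'   `err_nblda`, `err_ziplda`, `err_zinblda`, `winner`.
#' @export
buildMetaTable <- function(nGrid = seq(8, 100, by = 8),
        phiGrid = seq(0.001, 1.001, by = 0.1),
        p0Grid = seq(0, 0.6, by = 0.05),
        reps = 1000, seed = NULL, G = 100, deRate = 0.4, sigma = 0.2,
        K = 2, nTest = 100, verbose = FALSE) {
    stopifnot(length(nGrid) > 0, length(phiGrid) > 0, length(p0Grid) > 0)
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
        set.seed(seed)
    }
    cells <- expand.grid(n = nGrid, phi = phiGrid, p0 = p0Grid,
        KEEP.OUT.ATTRS = FALSE)
    errs <- matrix(NA_real_, nrow(cells), 4)
    for (i in seq_len(nrow(cells))) {
        errs[i, ] <- .benchmarkCell(K = K, n = cells$n[i], G = G,
            deRate = deRate, sigma = sigma, phi = cells$phi[i],
            p0 = cells$p0[i], reps = reps, nTest = nTest)
        if (verbose)
            message(sprintf("cell %d/%d (n=%d phi=%.3f p0=%.2f): %s",
                i, nrow(cells), cells$n[i], cells$phi[i], cells$p0[i],
                paste(sprintf("%.3f", errs[i, ]), collapse = " ")))
    }
    colnames(errs) <- paste0("err_", tolower(.METHODS))
    # which.min takes the first minimum: column order encodes the
    # simplicity tie-break PLDA < NBLDA < ZIPLDA < ZINBLDA
    winner <- .METHODS[apply(errs, 1, which.min)]
    cbind(cells, as.data.frame(errs), winner = winner)
}

#' Train a classifier-selector on a meta-table
#'
#' Fits a decision tree ([rpart::rpart], Gini impurity, depth and
#' leaf-size limits below) or a random forest
#' ([randomForest::randomForest]) on features (n, phi, p0) with the
#' winner labels as target.  The resubstitution error is reported for
#' both; for forests the out-of-bag error is additionally stored, since
#' a forest of fully grown trees reproduces its training labels almost
#' perfectly and the OOB estimate is its conventional training-error
#' summary.
#'
#' @param metaTable a data.frame from [buildMetaTable()] (columns `n`,
#'   `phi`, `p0`, `winner`).
#' @param kind `"tree"` or `"forest"`.
#' @param maxDepth,minBucket tree limits (depth 6, minimum 5 cells per
#'   leaf: the published decision regions are shallow).
#' @param nTree forest size (500).
#' @param seed optional integer seed (forest bootstrap).
#' @return a [ClassifierSelector-class].
#' @export
fitSelector <- function(metaTable, kind = c("tree", "forest"),
        maxDepth = 6, minBucket = 5, nTree = 500, seed = NULL) {
    kind <- match.arg(kind)
    if (nrow(metaTable) == 0) stop("empty meta-table")
    need <- c("n", "phi", "p0", "winner")
    if (!all(need %in% names(metaTable)))
        stop("meta-table must have columns ", paste(need, collapse = ", "))
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
        set.seed(seed)
    }
    df <- data.frame(n = metaTable$n, phi = metaTable$phi,
        p0 = metaTable$p0,
        winner = factor(metaTable$winner, levels = .METHODS))
    df$winner <- droplevels(df$winner)
    if (nlevels(df$winner) < 2) {
        warning("meta-table has a single winner label; selector is constant")
        fit <- structure(list(constant = levels(df$winner)),
            class = "constantSelector")
        return(new("ClassifierSelector", kind = kind, fit = fit,
            metaTable = as.data.frame(metaTable), resubError = 0,
            oobError = if (kind == "forest") 0 else NA_real_))
    }
    if (kind == "tree") {
        fit <- rpart::rpart(winner ~ n + phi + p0, data = df,
            method = "class", parms = list(split = "gini"),
            control = rpart::rpart.control(maxdepth = maxDepth,
                minbucket = minBucket, minsplit = 2 * minBucket,
                cp = 0.01, xval = 0))
        pred <- stats::predict(fit, df, type = "class")
        resub <- mean(as.character(pred) != as.character(df$winner))
        oob <- NA_real_
    } else {
        fit <- randomForest::randomForest(winner ~ n + phi + p0,
            data = df, ntree = nTree)
        pred <- stats::predict(fit, df)
        resub <- mean(as.character(pred) != as.character(df$winner))
        oob <- mean(as.character(stats::predict(fit)) !=
            as.character(df$winner))
    }
    new("ClassifierSelector", kind = kind, fit = fit,
        metaTable = as.data.frame(metaTable), resubError = resub,
        oobError = oob)
}

#' Estimate the selector's dataset attributes
#'
#' Computes the three features the selector decides on: the sample count
#' n, a scalar dispersion estimate (the median of the per-gene ZINB
#' dispersion MLEs), and an excess-zero estimate (the observed zero
#' fraction minus the mean model-implied structural NB zero mass,
#' floored at 0).
#'
#' @param counts gene x sample count matrix.
#' @param labels class labels.
#' @return named numeric vector `c(n, phi, p0)`.
#' @export
estimateDatasetAttributes <- function(counts, labels) {
    v <- validateCounts(counts, labels)
    counts <- v$counts; labels <- v$labels
    s <- totalCountSizeFactors(counts)
    lam <- estimateLambda(counts, s)
    d <- estimateClassDifference(counts, labels, s, lam)
    phi <- estimateDispersionZINB(counts, labels, s, lam, d)
    G <- nrow(counts)
    mu <- t(d)[, labels, drop = FALSE] * rep(s, each = G) * lam
    zmass <- ifelse(phi > 0, exp(-log1p(mu * phi) / phi), exp(-mu))
    p0 <- max(0, mean(counts == 0) - mean(zmass))
    c(n = ncol(counts), phi = unname(stats::median(phi)), p0 = p0)
}

#' Recommend a classifier for a dataset
#'
#' Estimates the dataset's attributes with
#' [estimateDatasetAttributes()] and runs them through a fitted
#' selector.
#'
#' @param selector a [ClassifierSelector-class].
#' @param counts,labels the dataset.
#' @return list with `method` (one of the four classifier names) and
#'   `attributes` (the estimated `c(n, phi, p0)`).
#' @export
recommendClassifier <- function(selector, counts, labels) {
    att <- estimateDatasetAttributes(counts, labels)
    nd <- data.frame(n = att[["n"]], phi = att[["phi"]], p0 = att[["p0"]])
    pred <- if (inherits(selector@fit, "constantSelector"))
        selector@fit$constant
    else if (selector@kind == "tree")
        stats::predict(selector@fit, nd, type = "class")
    else stats::predict(selector@fit, nd)
    list(method = as.character(pred), attributes = att)
}
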