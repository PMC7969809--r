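# The four discriminant scores and the fit/predict orchestration.
#
# Every score is the log class-conditional likelihood of a test vector
# plus the log prior, with the class-independent constant dropped
# identically across classes.  Classification is by Bayes' rule: pick the
# class with the highest score, breaking exact ties toward the smallest
# class index.

.METHODS <- c("PLDA", "NBLDA", "ZIPLDA", "ZINBLDA")

# Excess-zero probabilities for an m-sample score evaluation: N is the
# per-sample depth vector, mu a G x m matrix of cell means, phi a
# length-G dispersion vector (recycled row-wise).
.zeroProbMatrix <- function(model, N, mu, phi) {
    G <- nrow(mu)
    if (model@kind == "none") return(array(0, dim(mu)))
    if (model@kind == "constant") return(array(model@p0, dim(mu)))
    q <- stats::plogis(model@alpha +
        model@beta1 * rep(N / model@refDepth, each = G) +
        model@beta2 * mu)
    z <- exp(ifelse(phi > 0, -log1p(mu * phi) / phi, -mu))
    z <- pmin(z, 1 - 1e-12)
    pmin(pmax((q - z) / (1 - z), 0), 1 - 1e-12)
}

# Score matrix (m samples x K classes) for a set of test count vectors.
# All four score formulas are evaluated with G x m matrix operations; a
# length-G vector recycled against such a matrix applies per gene.
.scoreMatrix <- function(model, X) {
    d <- model@d
    K <- nrow(d); G <- ncol(d)
    if (nrow(X) != G)
        stop("test matrix has ", nrow(X), " genes; model expects ", G)
    m <- ncol(X)
    storage.mode(X) <- "double"
    N <- colSums(X)
    sStar <- N / model@trainGrandTotal
    if (any(N == 0)) {
        warning("all-zero test sample; using smallest training size factor")
        sStar[N == 0] <- min(model@sizeFactors)
    }
    lam <- model@lambda
    meth <- model@method
    phi <- if (length(model@phi)) model@phi else rep(0, G)
    Znz <- X > 0
    idxZ <- which(!Znz); idxNZ <- which(Znz)
    scores <- matrix(NA_real_, m, K)
    for (k in seq_len(K)) {
        dk <- d[k, ]
        mu <- (dk * lam) %o% sStar          # G x m cell means
        if (meth == "PLDA") {
            sk <- drop(crossprod(X, log(dk))) - sStar * sum(lam * dk)
        } else {
            usePhi <- if (meth == "ZIPLDA") rep(0, G) else phi
            pos <- usePhi > 0
            invP <- ifelse(pos, 1 / usePhi, 0)     # per-gene 1/phi
            notP <- as.numeric(!pos)
            l1 <- log1p(mu * usePhi)
            logZMass <- -(l1 * invP + mu * notP)   # log NB/Poisson zero mass
            kern <- X * (log(dk) - l1) + logZMass
            if (meth == "NBLDA") {
                sk <- .colSums(kern, G, m)
            } else {
                p <- .zeroProbMatrix(model@zeroModel, N, mu, usePhi)
                # where p = 0 the mixture mass is the plain zero mass;
                # computing it directly avoids exp/log underflow
                zt <- ifelse(p > 0, log(p + (1 - p) * exp(logZMass)),
                    logZMass)
                nzt <- log(pmax(1 - p, 1e-12)) + kern
                zt[idxNZ] <- 0
                nzt[idxZ] <- 0
                sk <- .colSums(zt + nzt, G, m)
            }
        }
        scores[, k] <- sk + log(model@priors[k])
    }
    scores
}

# per-class score vector for one test sample
.scoreVector <- function(model, xStar, sStar = NULL) {
    x <- matrix(as.numeric(xStar), ncol = 1)
    if (is.null(sStar) && sum(xStar) == 0)
        warning("all-zero test sample; using smallest training size factor")
    drop(suppressWarnings(.scoreMatrix(model, x)))
}

.scoresResult <- function(scores) {
    list(scores = scores, predicted = which.max(scores))
}

#' Poisson LDA discriminant score
#'
#' \eqn{d_k(x^*) = \sum_g X^*_g \log d_{kg} -
#' \hat s^* \sum_g \lambda_g d_{kg} + \log \pi_k} (class-independent
#' constant dropped).
#'
#' @param xStar length-G test count vector.
#' @param model a fitted [CountClassifier-class]; its `d`, `lambda`,
#'   `priors` and `trainGrandTotal` are used regardless of its `method`
#'   tag, so reduction checks between methods can reuse one model.
#' @return list with `scores` (length-K) and `predicted` (argmax index,
#'   smallest index on ties).
#' @export
scorePLDA <- function(xStar, model) {
    m <- model; m@method <- "PLDA"
    .scoresResult(.scoreVector(m, xStar))
}

#' Negative binomial LDA discriminant score
#'
#' \eqn{d_k(x^*) = \sum_g X^*_g[\log d_{kg} -
#' \log(1 + \hat s^*\lambda_g d_{kg}\phi_g)] -
#' \sum_g \phi_g^{-1}\log(1 + \hat s^*\lambda_g d_{kg}\phi_g) +
#' \log \pi_k}.  Genes with phi = 0 contribute their Poisson-limit terms.
#'
#' @inheritParams scorePLDA
#' @return as [scorePLDA()].
#' @export
scoreNBLDA <- function(xStar, model) {
    if (!length(model@phi)) stop("model has no dispersion estimates")
    m <- model; m@method <- "NBLDA"
    .scoresResult(.scoreVector(m, xStar))
}

#' Zero-inflated Poisson LDA discriminant score
#'
#' Zero genes contribute \eqn{\log(\hat p + (1-\hat p)e^{-\mu})}; nonzero
#' genes contribute \eqn{-\mu + \log(1-\hat p) + X^*\log d}, with
#' \eqn{\mu = d_{kg}\hat s^*\lambda_g} and \eqn{\hat p} from the zero
#' model at the test sample's own library size.
#'
#' @inheritParams scorePLDA
#' @return as [scorePLDA()].
#' @export
scoreZIPLDA <- function(xStar, model) {
    if (model@zeroModel@kind == "none") stop("model has no zero model")
    m <- model; m@method <- "ZIPLDA"
    .scoresResult(.scoreVector(m, xStar))
}

#' Zero-inflated negative binomial LDA discriminant score
#'
#' Zero genes contribute the mixture mass
#' \eqn{\log[(1-\hat p)(1+\mu\phi)^{-1/\phi} + \hat p]}; nonzero genes
#' contribute \eqn{\log(1-\hat p)} plus the NB kernel
#' \eqn{X^*[\log d - \log(1+\hat s^*\lambda d\phi)] -
#' \phi^{-1}\log(1+\hat s^*\lambda d\phi)}.  Genes with phi = 0 use the
#' Poisson-limit forms, making the score reduce exactly to the
#' zero-inflated Poisson score there.
#'
#' @inheritParams scorePLDA
#' @return as [scorePLDA()].
#' @export
scoreZINBLDA <- function(xStar, model) {
    if (!length(model@phi)) stop("model has no dispersion estimates")
    if (model@zeroModel@kind == "none") stop("model has no zero model")
    m <- model; m@method <- "ZINBLDA"
    .scoresResult(.scoreVector(m, xStar))
}

#' Fit a count-model discriminant classifier
#'
#' Orchestrates the estimators: total-count size factors, per-gene
#' abundances, class-difference factors under the Gamma(1, 1) prior, and
#' then only what the chosen method needs — per-gene NB dispersion for
#' NBLDA, ZINB dispersion plus the logistic zero model for ZINBLDA, the
#' zero model alone for ZIPLDA.  Priors are the empirical class
#' frequencies \eqn{\pi_k = n_k/n}.
#'
#' @param counts gene x sample training matrix (matrix, data.frame or
#'   `SummarizedExperiment`).
#' @param labels class labels (any type; coded 1..K in first-appearance
#'   order).
#' @param method one of `"PLDA"`, `"NBLDA"`, `"ZIPLDA"`, `"ZINBLDA"`.
#' @param beta Gamma prior hyperparameter for the class-difference
#'   factors.
#' @param phiBounds dispersion search interval.
#' @return a [CountClassifier-class].
#' @examples
#' sim <- simulateCounts(n = 20, G = 50, sigma = 0.5, seed = 1)
#' fit <- fitCountClassifier(sim$counts, sim$labels, "PLDA")
#' fit
#' @export
fitCountClassifier <- function(counts, labels,
        method = c("PLDA", "NBLDA", "ZIPLDA", "ZINBLDA"),
        beta = 1, phiBounds = c(1e-8, 1e3)) {
    method <- match.arg(method)
    v <- validateCounts(counts, labels)
    counts <- v$counts; labels <- v$labels
    s <- totalCountSizeFactors(counts)
    lam <- estimateLambda(counts, s)
    d <- estimateClassDifference(counts, labels, s, lam, beta = beta)
    priors <- v$classSizes / sum(v$classSizes)
    phi <- numeric(0)
    zm <- new("ZeroInflationModel", kind = "none")
    if (method == "NBLDA")
        phi <- estimateDispersionNB(counts, labels, s, lam, d,
            bounds = phiBounds)
    if (method == "ZINBLDA")
        phi <- estimateDispersionZINB(counts, labels, s, lam, d,
            bounds = phiBounds)
    if (method %in% c("ZIPLDA", "ZINBLDA"))
        zm <- fitZeroLogistic(counts, labels, s, lam, d)
    new("CountClassifier", method = method, d = d,
        sizeFactors = s, lambda = lam, phi = phi, zeroModel = zm,
        priors = priors, trainGrandTotal = sum(counts),
        geneIds = rownames(counts), classLevels = v$levels,
        flaggedGenes = as.integer(v$allZeroGenes))
}

# Fit all four classifiers at once, sharing the common estimators
# (size factors, lambda, d, priors, the zero model for both
# zero-inflated methods).  Used by the benchmark loops, where refitting
# the shared parts four times would dominate the runtime.
.fitAllMethods <- function(counts, labels, beta = 1,
        phiBounds = c(1e-8, 1e3)) {
    v <- validateCounts(counts, labels)
    counts <- v$counts; labels <- v$labels
    s <- totalCountSizeFactors(counts)
    lam <- estimateLambda(counts, s)
    d <- estimateClassDifference(counts, labels, s, lam, beta = beta)
    priors <- v$classSizes / sum(v$classSizes)
    phiNB <- estimateDispersionNB(counts, labels, s, lam, d,
        bounds = phiBounds)
    # for genes without observed zeros the ZINB plug-in zero probability
    # is 0 and its profile likelihood coincides with the NB one, so the
    # NB estimate can be reused and only zero-containing genes need the
    # second search
    zf <- rowMeans(counts == 0)
    phiZINB <- phiNB
    if (any(zf > 0)) {
        gz <- which(zf > 0)
        phiZINB[gz] <- estimateDispersionZINB(
            counts[gz, , drop = FALSE], labels, s, lam[gz],
            d[, gz, drop = FALSE], zeroProbs = zf[gz],
            bounds = phiBounds)
    }
    zm <- fitZeroLogistic(counts, labels, s, lam, d)
    base <- function(method, phi, zeroModel)
        new("CountClassifier", method = method, d = d, sizeFactors = s,
            lambda = lam, phi = phi, zeroModel = zeroModel,
            priors = priors, trainGrandTotal = sum(counts),
            geneIds = rownames(counts), classLevels = v$levels,
            flaggedGenes = as.integer(v$allZeroGenes))
    none <- new("ZeroInflationModel", kind = "none")
    list(PLDA = base("PLDA", numeric(0), none),
        NBLDA = base("NBLDA", phiNB, none),
        ZIPLDA = base("ZIPLDA", numeric(0), zm),
        ZINBLDA = base("ZINBLDA", phiZINB, zm))
}

#' Predict class labels for test samples
#'
#' Computes the fitted method's discriminant score for every test sample
#' and assigns each to the class with the highest score (smallest class
#' index on exact ties).  The test size factor of each sample is its
#' total count over the training grand total.
#'
#' @param object a fitted [CountClassifier-class].
#' @param newdata length-G vector, or gene x sample matrix of test
#'   samples.
#' @param ... unused.
#' @return list with `class` (factor of predicted labels in the training
#'   level set), `index` (1..K integer codes) and `scores`
#'   (samples x K matrix).
#' @export
setMethod("predict", "CountClassifier", function(object, newdata, ...) {
    if (is.null(dim(newdata))) newdata <- matrix(newdata, ncol = 1)
    newdata <- .asCountMatrix(newdata)
    if (nrow(newdata) != ncol(object@d))
        stop("test matrix has ", nrow(newdata),
            " genes; model expects ", ncol(object@d))
    scores <- .scoreMatrix(object, newdata)
    dimnames(scores) <- list(colnames(newdata), object@classLevels)
    idx <- max.col(scores, ties.method = "first")
    list(class = factor(object@classLevels[idx],
            levels = object@classLevels),
        index = idx, scores = scores)
})

#' Misclassification rate
#'
#' Fraction of predictions differing from the true labels.
#'
#' @param predicted,truth equal-length label vectors (compared as
#'   character, so factor/character/integer codings mix freely).
#' @return a number in `[0, 1]`.
#' @export
misclassificationRate <- function(predicted, truth) {
    if (length(predicted) != length(truth))
        stop("prediction and truth lengths differ")
    mean(as.character(predicted) != as.character(truth))
}
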