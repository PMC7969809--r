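# Parameter estimators shared by the four classifiers.  The mean model is
# mu_{kig} = d_kg * s_i * lambda_g throughout: total-count size factors s,
# per-gene abundances lambda, class-difference factors d with a
# Gamma(beta, beta) prior (beta = 1), per-gene NB dispersion by bounded
# likelihood maximisation, and a logistic depth/mean model for the
# excess-zero probability.

#' Total-count size factors for training samples
#'
#' The size factor of sample i is its library size divided by the grand
#' total of the training matrix, so the factors of a training set always
#' sum to 1.
#'
#' @param counts gene x sample count matrix (or `SummarizedExperiment`).
#' @return positive length-n vector summing to 1, named by sample.
#' @examples
#' x <- cbind(s1 = c(10, 20), s2 = c(30, 40))
#' totalCountSizeFactors(x)  # 0.3, 0.7
#' @export
totalCountSizeFactors <- function(counts) {
    counts <- .asCountMatrix(counts)
    tot <- colSums(counts)
    if (any(tot == 0))
        stop("all-zero sample(s): ",
            paste(colnames(counts)[tot == 0], collapse = ", "),
            " (size factor would be 0)")
    tot / sum(tot)
}

#' Size factor of a test sample
#'
#' The test sample's total count divided by the *training* grand total, so
#' test and training samples share one depth scale.  An all-zero test
#' vector has no depth information; it is assigned the smallest training
#' factor with a warning.
#'
#' @param xStar length-G count vector of the test sample.
#' @param trainGrandTotal grand total of the training matrix.
#' @param trainSizeFactors training size factors (fallback for the
#'   all-zero case).
#' @return positive scalar (may exceed any training factor).
#' @export
testSizeFactor <- function(xStar, trainGrandTotal, trainSizeFactors = NULL) {
    stopifnot(trainGrandTotal > 0)
    tot <- sum(xStar)
    if (tot == 0) {
        warning("all-zero test sample; using smallest training size factor")
        if (is.null(trainSizeFactors))
            stop("all-zero test sample and no training size factors supplied")
        return(min(trainSizeFactors))
    }
    tot / trainGrandTotal
}

#' Per-gene abundance estimates
#'
#' \eqn{\hat\lambda_g = \sum_i X_{ig} / \sum_i \hat s_i}.  Under
#' total-count factors the denominator is 1 and this is the gene's total
#' training count; the ratio form keeps the estimator consistent if other
#' factors are ever plugged in.
#'
#' @param counts gene x sample count matrix.
#' @param sizeFactors training size factors.
#' @return non-negative length-G vector, named by gene.
#' @export
estimateLambda <- function(counts, sizeFactors) {
    counts <- .asCountMatrix(counts)
    rowSums(counts) / sum(sizeFactors)
}

#' Class-difference factors with a Gamma prior
#'
#' Posterior-mean estimate
#' \eqn{\hat d_{kg} = (\sum_{i \in k} X_{ig} + \beta) /
#' (\sum_{i \in k} s_i \lambda_g + \beta)} under a Gamma(beta, beta)
#' prior.  The prior (beta = 1 by default) keeps \eqn{\hat d_{kg}} finite
#' and positive even for genes with zero class totals, so all-zero genes
#' never need to be dropped.
#'
#' @param counts gene x sample count matrix.
#' @param labels 1..K integer class labels.
#' @param sizeFactors,lambda estimates from [totalCountSizeFactors()] and
#'   [estimateLambda()].
#' @param beta positive prior hyperparameter (default 1).
#' @return K x G positive matrix.
#' @export
estimateClassDifference <- function(counts, labels, sizeFactors, lambda,
        beta = 1) {
    counts <- .asCountMatrix(counts)
    stopifnot(beta > 0)
    K <- max(labels)
    G <- nrow(counts)
    d <- matrix(NA_real_, K, G, dimnames = list(NULL, rownames(counts)))
    for (k in seq_len(K)) {
        in.k <- labels == k
        num <- rowSums(counts[, in.k, drop = FALSE]) + beta
        den <- sum(sizeFactors[in.k]) * lambda + beta
        d[k, ] <- num / den
    }
    d
}

# ZINB log-likelihood of one gene as a function of log(phi), with the
# excess-zero probability p held fixed.  mu, x, p are cell-level vectors.
.phiProfileLogLik <- function(logPhi, x, mu, p) {
    phi <- exp(logPhi)
    invPhi <- 1 / phi
    l1 <- log1p(mu * phi)
    zero <- x == 0
    ll <- 0
    if (any(zero))
        ll <- sum(log(p[zero] + (1 - p[zero]) * exp(-invPhi * l1[zero])))
    if (any(!zero)) {
        xn <- x[!zero]; mun <- mu[!zero]; pn <- p[!zero]; ln <- l1[!zero]
        ll <- ll + sum(log1p(-pn) + lgamma(xn + invPhi) - lgamma(invPhi) -
            lgamma(xn + 1) + xn * (log(mun * phi) - ln) - invPhi * ln)
    }
    ll
}

# Golden-section maximisation of the per-gene profile likelihood on
# log(phi), run for all genes simultaneously.  Iteration count is fixed
# by the interval width and the 1e-8 tolerance on log(phi).  The
# likelihood is evaluated with matrix-level operations: recycling a
# length-G vector against a G x n matrix applies it row-wise
# (column-major order), the per-gene broadcast needed here.
.phiGoldenSearch <- function(counts, mu, p, bounds) {
    G <- nrow(counts); nc <- ncol(counts)
    Z <- counts == 0
    idxZ <- which(Z); idxNZ <- which(!Z)
    lgx1 <- lgamma(counts + 1)
    logMu <- suppressWarnings(log(mu))   # -Inf only in zero cells
    pPos <- p > 0
    f <- function(logPhi) {
        phi <- exp(logPhi)
        invPhi <- 1 / phi
        l1 <- log1p(mu * phi)
        w <- -l1 * invPhi                 # log NB zero mass
        zt <- if (any(pPos)) log(p + (1 - p) * exp(w)) else w
        if (any(pPos) && !all(pPos))
            zt[!pPos, ] <- w[!pPos, ]     # avoid log(0) when exp(w) underflows
        nzt <- log1p(-p) + lgamma(counts + invPhi) - lgamma(invPhi) -
            lgx1 + counts * (logMu + logPhi - l1) - invPhi * l1
        # each branch only contributes on its own cells; -Inf/NaN from
        # the other branch (mu = 0 in zero cells) must not leak in
        nzt[idxZ] <- 0
        zt[idxNZ] <- 0
        .rowSums(zt + nzt, G, nc)
    }
    gr <- (sqrt(5) - 1) / 2
    a <- rep(log(bounds[1]), G); b <- rep(log(bounds[2]), G)
    x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
    f1 <- f(x1); f2 <- f(x2)
    nIter <- ceiling(log(1e-8 / (b[1] - a[1])) / log(gr))
    for (it in seq_len(nIter)) {
        up <- f1 < f2          # maximum lies in [x1, b]
        a[up] <- x1[up]; x1[up] <- x2[up]; f1[up] <- f2[up]
        b[!up] <- x2[!up]; x2[!up] <- x1[!up]; f2[!up] <- f1[!up]
        newX <- ifelse(up, a + gr * (b - a), b - gr * (b - a))
        fNew <- f(newX)
        x2[up] <- newX[up]; f2[up] <- fNew[up]
        x1[!up] <- newX[!up]; f1[!up] <- fNew[!up]
    }
    xOpt <- (a + b) / 2
    list(logPhi = xOpt, objective = f(xOpt),
        atLower = f(rep(log(bounds[1]), G)))
}

# Method-of-moments dispersion start value for the fallback path.
.phiMoM <- function(x) {
    m <- mean(x)
    if (m <= 0) return(1e-3)
    max((stats::var(x) - m) / m^2, 1e-3)
}

#' Per-gene ZINB dispersion by profile likelihood
#'
#' Maximises the zero-inflated negative binomial log-likelihood of each
#' gene over the dispersion, holding the excess-zero probability at its
#' plug-in value (by default the gene's observed zero fraction) and the
#' means at \eqn{\hat\mu_{kig} = \hat d_{kg}\hat s_i \hat\lambda_g}.  A
#' golden-section search on log(phi) over `bounds` replaces closed-form
#' score equations, which the mixture does not admit; genes whose optimum
#' sits at the lower bound (no evidence of overdispersion) are reported as
#' phi = 0.  Dispersion is pooled across classes: all training samples of
#' a gene enter one likelihood, each with its own class mean.
#'
#' @param counts gene x sample count matrix.
#' @param labels 1..K integer class labels.
#' @param sizeFactors,lambda,d upstream estimates.
#' @param zeroProbs per-gene fixed excess-zero probabilities; default the
#'   observed zero fraction per gene.  Scalars are recycled.
#' @param phiInit optional per-gene start values; only used by the
#'   fallback when the bounded search fails (default method of moments).
#' @param bounds search interval for phi (default `c(1e-8, 1e3)`).
#' @return non-negative length-G vector of dispersion estimates.
#' @seealso [estimateDispersionNB()] for the zero-frozen special case.
#' @export
estimateDispersionZINB <- function(counts, labels, sizeFactors, lambda, d,
        zeroProbs = NULL, phiInit = NULL, bounds = c(1e-8, 1e3)) {
    counts <- .asCountMatrix(counts)
    G <- nrow(counts); n <- ncol(counts)
    if (is.null(zeroProbs)) zeroProbs <- rowMeans(counts == 0)
    zeroProbs <- rep_len(zeroProbs, G)
    zeroProbs <- pmin(zeroProbs, 1 - 1e-12)
    # cell means: mu[g, i] = d[label_i, g] * s_i * lambda_g
    mu <- t(d)[, labels, drop = FALSE] *
        rep(sizeFactors, each = G) * lambda
    storage.mode(counts) <- "double"
    opt <- .phiGoldenSearch(counts, mu, zeroProbs, bounds)
    phi <- exp(opt$logPhi)
    # genes whose search collapses onto the lower bound carry no
    # evidence of overdispersion; the position test is robust where
    # likelihood differences at 1/phi ~ 1e8 drown in lgamma rounding
    phi[opt$logPhi <= log(bounds[1]) + 1e-3] <- 0
    phi[which(opt$atLower >= opt$objective)] <- 0
    # below ~1e-6 the likelihood is flat to rounding at 1/phi > 1e6;
    # such values are numerically indistinguishable from the bound
    phi[phi < 1e-6] <- 0
    degenerate <- rowSums(counts) == 0 | rowSums(mu) == 0
    phi[degenerate] <- 0
    bad <- !is.finite(opt$objective) & !degenerate
    if (any(bad)) {
        warning("dispersion search failed for ", sum(bad),
            " gene(s); using method-of-moments value")
        phi[bad] <- if (is.null(phiInit))
            apply(counts[bad, , drop = FALSE], 1, .phiMoM)
        else phiInit[bad]
    }
    names(phi) <- rownames(counts)
    phi
}

#' Per-gene NB dispersion
#'
#' The zero-frozen special case of [estimateDispersionZINB()]: the same
#' bounded likelihood maximisation with the excess-zero probability fixed
#' at 0 for every gene, i.e. a plain negative binomial fit around the
#' shared mean decomposition.  Used by NBLDA.
#'
#' @inheritParams estimateDispersionZINB
#' @return non-negative length-G vector.
#' @export
estimateDispersionNB <- function(counts, labels, sizeFactors, lambda, d,
        phiInit = NULL, bounds = c(1e-8, 1e3)) {
    estimateDispersionZINB(counts, labels, sizeFactors, lambda, d,
        zeroProbs = 0, phiInit = phiInit, bounds = bounds)
}

#' Logistic model linking zero probability to depth and mean
#'
#' Fits the binomial-logit regression of the zero indicator
#' \eqn{I(X_{kig} = 0)} on the sample's relative sequencing depth
#' \eqn{N_{ki}/N_{ref}} and the fitted cell mean \eqn{\hat\mu_{kig}},
#' over all gene x sample cells of the training matrix.  The reference
#' depth \eqn{N_{ref}} is the library size of the first sample of class 1
#' in input order.  A zero-free matrix yields the degenerate constant
#' model with p = 0; complete separation triggers a ridge-penalised refit.
#'
#' @param counts gene x sample count matrix.
#' @param labels 1..K integer class labels.
#' @param sizeFactors,lambda,d upstream estimates.
#' @return a [ZeroInflationModel-class] of kind `"logistic"` (or
#'   `"constant"` with p0 = 0 when the matrix has no zeros).
#' @export
fitZeroLogistic <- function(counts, labels, sizeFactors, lambda, d) {
    counts <- .asCountMatrix(counts)
    G <- nrow(counts)
    depths <- colSums(counts)
    refDepth <- depths[which(labels == 1)[1]]
    z <- as.numeric(as.vector(counts == 0))
    if (!any(z == 1)) {
        zm <- constantZeroModel(0)
        zm@refDepth <- unname(refDepth)
        return(zm)
    }
    if (all(z == 1)) stop("all counts are zero; cannot fit zero model")
    mu <- as.vector(t(d)[, labels, drop = FALSE] *
        rep(sizeFactors, each = G) * lambda)
    rel <- rep(depths / refDepth, each = G)
    X <- cbind(`(Intercept)` = 1, rel = rel, mu = mu)
    # Extreme fitted probabilities alone are expected here (large-mean
    # cells legitimately have near-zero zero probability); only failure
    # to converge or unbounded coefficients signal separation.
    fit <- withCallingHandlers(
        stats::glm.fit(X, z, family = stats::binomial(),
            control = stats::glm.control(maxit = 15)),
        warning = function(w) invokeRestart("muffleWarning"))
    cf <- fit$coefficients
    sdX <- pmax(apply(X[, -1, drop = FALSE], 2, stats::sd), 1e-12)
    if (!fit$converged || any(!is.finite(cf)) ||
        any(abs(cf[-1]) * sdX > 100)) {
        warning("zero-model logistic fit unstable; ridge-penalized refit")
        rfit <- glmnet::glmnet(X[, -1, drop = FALSE], z,
            family = "binomial", alpha = 0, lambda = 1e-3)
        cf <- c(rfit$a0, as.numeric(rfit$beta))
    }
    new("ZeroInflationModel", kind = "logistic",
        alpha = unname(cf[1]), beta1 = unname(cf[2]), beta2 = unname(cf[3]),
        refDepth = unname(refDepth), p0 = NA_real_)
}

#' Excess-zero probability for a cell
#'
#' Inverts the logistic total-zero model into the structural
#' (excess-zero) probability of the ZINB mixture:
#' with \eqn{q = p_1/(1+p_1)} the model's total zero probability
#' (\eqn{p_1 = \exp\{\alpha + \beta_1 N/N_{ref} + \beta_2 \mu\}}) and
#' \eqn{z = (1+\mu\phi)^{-1/\phi}} the NB zero mass (\eqn{e^{-\mu}} in the
#' Poisson limit phi = 0), the excess-zero probability is
#' \eqn{\hat p = (q - z)/(1 - z)}, clamped to `[0, 1 - 1e-12]`.  A total
#' zero fraction below the structural NB mass clamps to 0.
#'
#' @param model a [ZeroInflationModel-class].
#' @param depth library size N of the target sample.
#' @param mu cell mean(s) \eqn{\mu}; vectorised.
#' @param phi dispersion(s), recycled against `mu`; `phi = 0` selects the
#'   Poisson zero mass.
#' @return vector of probabilities in `[0, 1)`.
#' @export
predictZeroProb <- function(model, depth, mu, phi = 0) {
    n <- max(length(mu), length(phi))
    mu <- rep_len(mu, n); phi <- rep_len(phi, n)
    if (model@kind == "none") return(rep(0, n))
    if (model@kind == "constant") return(rep(model@p0, n))
    q <- stats::plogis(model@alpha + model@beta1 * depth / model@refDepth +
        model@beta2 * mu)
    z <- ifelse(phi > 0, exp(-log1p(mu * phi) / phi), exp(-mu))
    z <- pmin(z, 1 - 1e-12)
    p <- (q - z) / (1 - z)
    pmin(pmax(p, 0), 1 - 1e-12)
}
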