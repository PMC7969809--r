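# Shared fixtures: small random classifier models and brute-force
# likelihood oracles built from stats::dpois / stats::dnbinom, kept
# independent of the package's score-formula implementations.

# A random small fitted-model object.  Scales are kept modest (mu of
# order 1-10) so that Taylor-limit comparisons at tiny phi/p are sharp.
randomToyModel <- function(K = 2, G = 5, phi = NULL, zeroModel = NULL,
        priors = NULL) {
    d <- matrix(exp(rnorm(K * G, 0, 0.3)), K, G)
    lambda <- runif(G, 0.5, 5)
    s <- runif(max(4, K * 2), 0.5, 1.5)
    s <- s / sum(s)
    if (is.null(priors)) {
        priors <- runif(K, 0.5, 1.5)
        priors <- priors / sum(priors)
    }
    if (is.null(zeroModel))
        zeroModel <- new("ZeroInflationModel", kind = "none")
    if (is.null(phi)) phi <- numeric(0)
    new("CountClassifier", method = "PLDA", d = d,
        sizeFactors = s, lambda = lambda, phi = phi,
        zeroModel = zeroModel, priors = priors, trainGrandTotal = 100,
        geneIds = paste0("g", seq_len(G)),
        classLevels = as.character(seq_len(K)),
        flaggedGenes = integer(0))
}

# Brute-force per-class log likelihood + log prior from the literal
# probability mass functions.  `p` is the K x G matrix of excess-zero
# probabilities (0 for the non-inflated models).
oracleScores <- function(method, x, model, p = NULL) {
    K <- nrow(model@d); G <- ncol(model@d)
    sStar <- sum(x) / model@trainGrandTotal
    if (is.null(p)) p <- matrix(0, K, G)
    phi <- if (length(model@phi)) model@phi else rep(0, G)
    vapply(seq_len(K), function(k) {
        mu <- model@d[k, ] * sStar * model@lambda
        ll <- 0
        for (g in seq_len(G)) {
            fg <- if (method %in% c("PLDA", "ZIPLDA") || phi[g] == 0)
                stats::dpois(x[g], mu[g])
            else
                stats::dnbinom(x[g], size = 1 / phi[g], mu = mu[g])
            pg <- if (method %in% c("ZIPLDA", "ZINBLDA")) p[k, g] else 0
            mass <- if (x[g] == 0) pg + (1 - pg) * fg else (1 - pg) * fg
            ll <- ll + log(mass)
        }
        ll + log(model@priors[k])
    }, numeric(1))
}

# Score differences relative to class 1 (the dropped constant cancels).
relScores <- function(s) s - s[1]
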