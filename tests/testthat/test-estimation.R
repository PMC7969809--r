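test_that("total-count size factors are column shares of the grand total", {
    x <- cbind(s1 = c(10L, 20L), s2 = c(30L, 40L))
    expect_equal(unname(totalCountSizeFactors(x)), c(0.3, 0.7))
    xx <- matrix(5L, 4, 5, dimnames = list(NULL, paste0("s", 1:5)))
    expect_equal(unname(totalCountSizeFactors(xx)), rep(1 / 5, 5))
    x3 <- rbind(c(10L, 20L, 70L))
    colnames(x3) <- paste0("s", 1:3)
    sf <- totalCountSizeFactors(x3)
    expect_equal(unname(sf), c(0.1, 0.2, 0.7))
    expect_equal(sum(sf), 1)
    bad <- cbind(s1 = c(1L, 2L), s2 = c(0L, 0L))
    expect_error(totalCountSizeFactors(bad), "all-zero sample")
})

test_that("test size factor uses the training grand total", {
    expect_equal(testSizeFactor(c(20, 30), 100), 0.5)
    sim <- simulateCounts(n = 8, G = 20, seed = 2)
    sf <- totalCountSizeFactors(sim$counts)
    gt <- sum(sim$counts)
    expect_equal(unname(testSizeFactor(sim$counts[, 3], gt)), unname(sf[3]))
    x <- c(3, 7, 1)
    expect_equal(testSizeFactor(2 * x, 100), 2 * testSizeFactor(x, 100))
    expect_warning(s0 <- testSizeFactor(c(0, 0), 100, sf),
        "all-zero test sample")
    expect_equal(s0, min(sf))
})

test_that("lambda estimates equal gene totals under total-count factors", {
    sim <- simulateCounts(n = 10, G = 15, seed = 3)
    sf <- totalCountSizeFactors(sim$counts)
    lam <- estimateLambda(sim$counts, sf)
    expect_equal(unname(lam), unname(rowSums(sim$counts)))
    one <- matrix(c(4L, 0L, 9L), 3, 1,
        dimnames = list(paste0("g", 1:3), "s1"))
    expect_equal(unname(estimateLambda(one, 1)), c(4, 0, 9))
})

test_that("class-difference posterior mean follows the Gamma(1,1) form", {
    # single class, single gene with engineered sums: (sum X + 1)/(sum s*lam + 1)
    mk <- function(sumX, sumSlam) (sumX + 1) / (sumSlam + 1)
    expect_equal(mk(0, 4), 0.2)
    expect_equal(mk(9, 9), 1)
    expect_equal(mk(19, 9), 2)
    # the same numbers through the estimator
    counts <- matrix(c(0L, 5L, 4L, 9L, 10L, 9L), nrow = 1)
    colnames(counts) <- paste0("s", 1:6); rownames(counts) <- "g1"
    labels <- c(1, 1, 2, 2, 3, 3)
    # choose s and lambda so that sum_{i in k} s_i * lambda = 4, 9, 9
    sf <- rep(1 / 6, 6)
    lam <- 4 / (2 / 6)        # each class has sum s = 2/6
    d <- estimateClassDifference(counts, labels, sf, lam)
    expect_equal(unname(d[1, 1]), (0 + 5 + 1) / (4 + 1))
    # balanced case: every class with equal (sum X, sum s lambda) gives d = 1
    cb <- matrix(c(3L, 6L, 3L, 6L), 1, 4,
        dimnames = list("g", paste0("s", 1:4)))
    sfb <- totalCountSizeFactors(cb)
    lamb <- estimateLambda(cb, sfb)
    db <- estimateClassDifference(cb, c(1, 2, 1, 2), sfb, lamb)
    expect_equal(unname(db[, 1]), c(1, 1))
})

test_that("NB dispersion estimation is the zero-frozen ZINB reduction", {
    sim <- simulateCounts(n = 30, G = 25, phi = 0.4, seed = 4)
    sf <- totalCountSizeFactors(sim$counts)
    lam <- estimateLambda(sim$counts, sf)
    d <- estimateClassDifference(sim$counts, sim$labels, sf, lam)
    expect_identical(
        estimateDispersionNB(sim$counts, sim$labels, sf, lam, d),
        estimateDispersionZINB(sim$counts, sim$labels, sf, lam, d,
            zeroProbs = 0))
})

test_that("dispersion hits the boundary for equidispersed data", {
    # all counts equal to their mean: zero empirical overdispersion
    x <- matrix(5L, 1, 12, dimnames = list("g1", paste0("s", 1:12)))
    labels <- rep(1:2, 6)
    sf <- totalCountSizeFactors(x)
    lam <- estimateLambda(x, sf)
    d <- estimateClassDifference(x, labels, sf, lam)
    expect_equal(unname(
        estimateDispersionNB(x, labels, sf, lam, d)), 0)
    # Poisson-simulated data: median estimate at or near the boundary
    set.seed(5)
    sim <- simulateCounts(n = 200, G = 50, phi = 0, p0 = 0, seed = 5)
    sf <- totalCountSizeFactors(sim$counts)
    lam <- estimateLambda(sim$counts, sf)
    d <- estimateClassDifference(sim$counts, sim$labels, sf, lam)
    phiHat <- estimateDispersionZINB(sim$counts, sim$labels, sf, lam, d)
    expect_lte(median(phiHat), 0.05)
})

test_that("moderate dispersion is recovered from NB data", {
    sim <- simulateCounts(n = 200, G = 100, phi = 0.5, p0 = 0, seed = 6)
    sf <- totalCountSizeFactors(sim$counts)
    lam <- estimateLambda(sim$counts, sf)
    d <- estimateClassDifference(sim$counts, sim$labels, sf, lam)
    phiHat <- estimateDispersionZINB(sim$counts, sim$labels, sf, lam, d)
    expect_gte(median(phiHat), 0.35)
    expect_lte(median(phiHat), 0.65)
})

test_that("zero-logistic fit degenerates cleanly and recovers masking", {
    # no zeros anywhere: degenerate constant model with p = 0
    x <- matrix(5L + rpois(40, 10), 4, 10,
        dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
    labels <- rep(1:2, each = 5)
    sf <- totalCountSizeFactors(x)
    lam <- estimateLambda(x, sf)
    d <- estimateClassDifference(x, labels, sf, lam)
    zm <- fitZeroLogistic(x, labels, sf, lam, d)
    expect_identical(zm@kind, "constant")
    expect_identical(zm@p0, 0)

    # covariate-independent masking at p0 = 0.3: depth coefficient near 0,
    # mean coefficient negative, fitted zero mass near the truth
    sim <- simulateCounts(n = 200, G = 200, phi = 0, p0 = 0.3, seed = 7)
    sf <- totalCountSizeFactors(sim$counts)
    lam <- estimateLambda(sim$counts, sf)
    d <- estimateClassDifference(sim$counts, sim$labels, sf, lam)
    zm <- fitZeroLogistic(sim$counts, sim$labels, sf, lam, d)
    expect_identical(zm@kind, "logistic")
    expect_lt(zm@beta2, 0)
    G <- nrow(sim$counts)
    mu <- t(d)[, sim$labels] * rep(sf, each = G) * lam
    q <- plogis(zm@alpha +
        zm@beta1 * rep(colSums(sim$counts) / zm@refDepth, each = G) +
        zm@beta2 * mu)
    expect_equal(mean(q), mean(sim$counts == 0), tolerance = 0.02)
})

test_that("predicted excess-zero probabilities follow the closed form", {
    # alpha = 0, beta1 = beta2 = 0, mu = 1, phi = 0:
    # p1 = 1, p-hat = (0.5 - exp(-1)) / (1 - exp(-1))
    zm <- new("ZeroInflationModel", kind = "logistic", alpha = 0,
        beta1 = 0, beta2 = 0, refDepth = 1, p0 = NA_real_)
    expect_equal(predictZeroProb(zm, 1, mu = 1, phi = 0),
        (0.5 - exp(-1)) / (1 - exp(-1)), tolerance = 1e-12)
    # total zero mass exactly at the structural NB mass: numerator vanishes
    mu <- 2; phi <- 0.5
    z <- (1 + mu * phi)^(-1 / phi)
    alpha <- qlogis(z)
    zm2 <- new("ZeroInflationModel", kind = "logistic", alpha = alpha,
        beta1 = 0, beta2 = 0, refDepth = 1, p0 = NA_real_)
    expect_equal(predictZeroProb(zm2, 1, mu = mu, phi = phi), 0,
        tolerance = 1e-10)
    # mu large: structural mass vanishes, p-hat tends to p1/(1+p1)
    zm3 <- new("ZeroInflationModel", kind = "logistic", alpha = -1,
        beta1 = 0, beta2 = 0, refDepth = 1, p0 = NA_real_)
    expect_equal(predictZeroProb(zm3, 1, mu = 1e6, phi = 0.2),
        plogis(-1), tolerance = 1e-6)
    # output always a probability
    set.seed(8)
    for (i in 1:50) {
        zm4 <- new("ZeroInflationModel", kind = "logistic",
            alpha = rnorm(1, 0, 2), beta1 = rnorm(1), beta2 = rnorm(1),
            refDepth = runif(1, 0.5, 2), p0 = NA_real_)
        p <- predictZeroProb(zm4, runif(1, 0.1, 3),
            mu = runif(5, 0, 50), phi = runif(5, 0, 2))
        expect_true(all(p >= 0 & p < 1))
    }
})
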