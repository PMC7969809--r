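test_that("PLDA score matches the hand-evaluated two-class example", {
    # K=2, G=1: X*=3, s*=1, lambda=2, d=(1,2), equal priors
    m <- randomToyModel(K = 2, G = 1, priors = c(0.5, 0.5))
    m@d <- matrix(c(1, 2), 2, 1)
    m@lambda <- 2
    m@trainGrandTotal <- 3   # makes s* = sum(x)/3 = 1
    s <- scorePLDA(3, m)
    expect_equal(s$scores[1] - s$scores[2], -3 * log(2) + 2,
        tolerance = 1e-12)
    expect_identical(s$predicted, 2L)
})

test_that("symmetric models tie and resolve to the first class", {
    m <- randomToyModel(K = 3, G = 4, priors = rep(1 / 3, 3))
    m@d <- matrix(1, 3, 4)
    s <- scorePLDA(c(2, 0, 1, 5), m)
    expect_true(all(abs(s$scores - s$scores[1]) < 1e-12))
    expect_identical(s$predicted, 1L)
})

test_that("NBLDA score matches independent scalar arithmetic", {
    m <- randomToyModel(K = 2, G = 1, phi = 1, priors = c(0.5, 0.5))
    m@d <- matrix(c(1, 2), 2, 1)
    m@lambda <- 2
    m@trainGrandTotal <- 3
    s <- scoreNBLDA(3, m)
    hand <- (3 * (0 - log(3)) - log(3)) -
        (3 * (log(2) - log(5)) - log(5))
    expect_equal(s$scores[1] - s$scores[2], hand, tolerance = 1e-12)
})

test_that("ZIPLDA handles all-zero and saturated zero inflation", {
    m <- randomToyModel(K = 2, G = 1, zeroModel = constantZeroModel(0.4),
        priors = c(0.5, 0.5))
    m@d <- matrix(c(1, 2), 2, 1)
    m@lambda <- 2
    # all-zero test vector: s* falls back to the smallest training factor
    sStar <- min(m@sizeFactors)
    s <- suppressWarnings(scoreZIPLDA(0, m))
    hand <- vapply(c(1, 2), function(dk)
        log(0.4 + 0.6 * exp(-dk * sStar * 2)) + log(0.5), numeric(1))
    expect_equal(s$scores, hand, tolerance = 1e-12)
    # p -> 1: scores collapse to the log priors
    m2 <- randomToyModel(K = 2, G = 3,
        zeroModel = constantZeroModel(1 - 1e-13), priors = c(0.7, 0.3))
    s2 <- suppressWarnings(scoreZIPLDA(c(0, 0, 0), m2))
    expect_equal(s2$scores, log(c(0.7, 0.3)), tolerance = 1e-5)
    expect_identical(s2$predicted, 1L)
})

test_that("the four scores reduce into each other at the boundaries", {
    set.seed(42)
    for (i in 1:20) {
        K <- sample(2:3, 1); G <- sample(3:8, 1)
        m <- randomToyModel(K, G, phi = rep(0, G),
            zeroModel = constantZeroModel(0))
        x <- rpois(G, 2)
        pl <- scorePLDA(x, m)$scores
        expect_equal(scoreNBLDA(x, m)$scores, pl, tolerance = 1e-12)
        expect_equal(scoreZIPLDA(x, m)$scores, pl, tolerance = 1e-12)
        expect_equal(scoreZINBLDA(x, m)$scores, pl, tolerance = 1e-12)
        # phi = 0 freezes ZINBLDA to ZIPLDA for any zero model
        m2 <- m; m2@zeroModel <- constantZeroModel(0.3)
        expect_equal(scoreZINBLDA(x, m2)$scores,
            scoreZIPLDA(x, m2)$scores, tolerance = 1e-12)
        # p = 0 freezes ZINBLDA to NBLDA for any dispersion
        m3 <- m; m3@phi <- runif(G, 0.2, 1)
        expect_equal(scoreZINBLDA(x, m3)$scores,
            scoreNBLDA(x, m3)$scores, tolerance = 1e-12)
    }
})

test_that("fitting runs only the estimators the method needs", {
    sim <- simulateCounts(n = 16, G = 30, phi = 0.3, p0 = 0.1, seed = 9)
    fit <- fitCountClassifier(sim$counts, sim$labels, "PLDA")
    expect_length(fit@phi, 0)
    expect_identical(fit@zeroModel@kind, "none")
    expect_equal(unname(fit@priors), c(0.5, 0.5))
    fitN <- fitCountClassifier(sim$counts, sim$labels, "NBLDA")
    expect_length(fitN@phi, 30)
    fitZ <- fitCountClassifier(sim$counts, sim$labels, "ZINBLDA")
    expect_identical(fitZ@zeroModel@kind, "logistic")
})

test_that("ZINBLDA on a zero-free matrix degenerates to NBLDA predictions", {
    set.seed(10)
    x <- matrix(10L + rpois(300, 30), 10, 30,
        dimnames = list(paste0("g", 1:10), paste0("s", 1:30)))
    labels <- rep(1:2, 15)
    fitZ <- fitCountClassifier(x, labels, "ZINBLDA")
    expect_identical(fitZ@zeroModel@kind, "constant")
    expect_identical(fitZ@zeroModel@p0, 0)
    fitN <- fitCountClassifier(x, labels, "NBLDA")
    test <- matrix(10L + rpois(50, 30), 10, 5,
        dimnames = list(paste0("g", 1:10), paste0("t", 1:5)))
    expect_identical(predict(fitZ, test)$index, predict(fitN, test)$index)
})

test_that("resubstitution on a separable simulation is near-perfect", {
    sim <- simulateCounts(n = 40, G = 100, phi = 0, p0 = 0, sigma = 1,
        deRate = 0.3, seed = 11)
    fit <- fitCountClassifier(sim$counts, sim$labels, "PLDA")
    pr <- predict(fit, sim$counts)
    expect_lte(misclassificationRate(pr$index, sim$labels), 0.05)
})

test_that("relabeling the fitted classes permutes predictions consistently", {
    sim <- simulateCounts(n = 20, G = 40, sigma = 0.6, seed = 12)
    fit <- fitCountClassifier(sim$counts, sim$labels, "PLDA")
    swapped <- fit
    swapped@d <- fit@d[c(2, 1), ]
    swapped@priors <- fit@priors[c(2, 1)]
    swapped@classLevels <- fit@classLevels[c(2, 1)]
    p1 <- predict(fit, sim$counts)
    p2 <- predict(swapped, sim$counts)
    expect_identical(p2$index, c(2L, 1L)[p1$index])
})

test_that("an overwhelming prior dominates any bounded score difference", {
    m <- randomToyModel(K = 2, G = 4, priors = c(1 - 1e-12, 1e-12))
    set.seed(13)
    for (i in 1:10)
        expect_identical(scorePLDA(rpois(4, 3), m)$predicted, 1L)
})

test_that("predict validates gene dimensions", {
    sim <- simulateCounts(n = 10, G = 20, seed = 14)
    fit <- fitCountClassifier(sim$counts, sim$labels, "PLDA")
    expect_error(predict(fit, matrix(1L, 5, 2)), "genes")
})

test_that("misclassification rate is the mismatch fraction", {
    expect_equal(misclassificationRate(c(1, 2, 1), c(1, 2, 1)), 0)
    expect_equal(misclassificationRate(c(1, 1), c(2, 2)), 1)
    expect_equal(misclassificationRate(c(1, 2, 2, 2), c(1, 2, 2, 1)), 0.25)
    expect_error(misclassificationRate(1:3, 1:4), "lengths differ")
})
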