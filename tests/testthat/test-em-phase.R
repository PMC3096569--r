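test_that("genotype tabulation handles missing and corner cases", {
    t <- genotypeTableFromCalls(c(0, 1, 2), c(0, 1, 2))
    expect_equal(diag(genotypeCounts(t)), c(`0` = 1, `1` = 1, `2` = 1))
    expect_equal(sum(genotypeCounts(t)), 3)

    t <- genotypeTableFromCalls(c(1, NA), c(1, 1))
    expect_equal(sum(genotypeCounts(t)), 1)
    expect_equal(genotypeCounts(t)[2, 2], 1)
    expect_equal(t@nExcluded, 1L)

    t <- genotypeTableFromCalls(c(2, 2, 0, 0), c(2, 0, 2, 0))
    cts <- genotypeCounts(t)
    expect_equal(unname(cts[c(1, 3), c(1, 3)]), matrix(1, 2, 2))

    expect_error(genotypeTableFromCalls(0:1, 0:2), "same length")
    expect_error(genotypeTableFromCalls(c(0, 3), c(0, 0)), "outside")
})

test_that("EM reduces to direct counting when phase is unambiguous", {
    # no double heterozygotes anywhere: closed form in one iteration
    cts <- matrix(c(1, 2, 0, 3, 0, 1, 0, 2, 1), 3, 3)
    cts[2, 2] <- 0
    fit <- emHaplotypeFreqs(GenotypeTable(cts))
    expect_true(converged(fit))
    expect_equal(iterations(fit), 1L)
    # counting oracle: haplotypes per cell are determined
    n <- sum(cts)
    count11 <- 2 * cts[3, 3] + cts[3, 2] + cts[2, 3]
    count12 <- 2 * cts[3, 1] + cts[3, 2] + cts[2, 1]
    count21 <- 2 * cts[1, 3] + cts[2, 3] + cts[1, 2]
    count22 <- 2 * cts[1, 1] + cts[2, 1] + cts[1, 2]
    expect_equal(unname(haploFreqs(fit)),
                 c(count11, count12, count21, count22) / (2 * n))

    # opposite-corner homozygotes give complete coupling
    cts <- matrix(0, 3, 3); cts[1, 1] <- 1; cts[3, 3] <- 1
    fit <- emHaplotypeFreqs(GenotypeTable(cts))
    expect_equal(unname(haploFreqs(fit)), c(0.5, 0, 0, 0.5))
    expect_equal(r2(ldFromHaplotypes(fit@freqs)), 1)
})

test_that("EM agrees with the 1-D grid-search likelihood oracle", {
    # the spec's hard case: only corner homozygotes plus double hets
    cts <- matrix(0, 3, 3)
    cts[3, 3] <- 3; cts[1, 1] <- 3; cts[2, 2] <- 4
    fit <- emHaplotypeFreqs(GenotypeTable(cts))
    oracle <- gridSearchMLE(cts)
    expect_equal(unname(haploFreqs(fit)["f11"]), oracle$f11, tolerance = 1e-4)
    expect_equal(logLik(fit), oracle$loglik, tolerance = 1e-6)

    # random small tables
    set.seed(202)
    for (i in 1:25) {
        cts <- randomGenotypeTable(n = sample(10:60, 1))
        margins <- c(sum(cts[2:3, ]) + sum(cts[3, ]),
                     sum(cts[, 2:3]) + sum(cts[, 3]))
        if (any(margins == 0)) next   # monomorphic: LD fit not of interest
        fit <- emHaplotypeFreqs(GenotypeTable(cts))
        oracle <- gridSearchMLE(cts)
        expect_gte(logLik(fit), oracle$loglik - 1e-4)
    }
})

test_that("EM log-likelihood is non-decreasing at every iteration", {
    set.seed(203)
    for (i in 1:1000) {
        cts <- randomGenotypeTable(n = sample(5:80, 1))
        fit <- emHaplotypeFreqs(GenotypeTable(cts), trace = TRUE)
        tr <- fit@trace
        expect_true(all(diff(tr) >= -1e-10))
    }
})

test_that("EM recovers known haplotype frequencies at large n", {
    truth <- c(0.4, 0.1, 0.2, 0.3)
    set.seed(204)
    n <- 10000L
    ests <- replicate(20, {
        pm <- PairModel(LocusModel(0.5), LocusModel(0.6),
                        D = 0.4 - 0.5 * 0.6, n = n)
        d <- simulateAlternative(pm)
        haploFreqs(emHaplotypeFreqs(genotypeTableFromCalls(d$gA, d$gB)))
    })
    m <- rowMeans(ests)
    mcse <- apply(ests, 1, stats::sd) / sqrt(ncol(ests))
    expect_true(all(abs(m - truth) < 3 * mcse + 1e-12))
})

test_that("observed log-likelihood matches the multinomial pmf and flags zeros", {
    # unambiguous table evaluated at its own MLE: multinomial log-pmf kernel
    cts <- matrix(0, 3, 3); cts[1, 1] <- 2; cts[3, 3] <- 2
    fit <- emHaplotypeFreqs(GenotypeTable(cts))
    ll <- observedLogLik(GenotypeTable(cts), fit@freqs)
    expect_equal(ll, 2 * log(0.5^2) + 2 * log(0.5^2))

    # positive count on a zero-probability cell
    h <- HaplotypeFreqs(0.5, 0, 0, 0.5, N = 8)
    cts[1, 3] <- 1
    expect_warning(ll <- observedLogLik(GenotypeTable(cts), h), "probability 0")
    expect_identical(ll, -Inf)

    # one EM step from anywhere never decreases the likelihood
    set.seed(205)
    for (i in 1:50) {
        cts <- randomGenotypeTable(n = 40)
        t <- GenotypeTable(cts)
        fit1 <- emHaplotypeFreqs(t, maxIter = 1L)
        fit2 <- emHaplotypeFreqs(t, maxIter = 2L)
        expect_gte(logLik(fit2), logLik(fit1) - 1e-10)
    }
})
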