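test_that("HWD genotype probabilities follow the parameterization", {
    expect_equal(unname(genotypeProbs(0.5)), c(0.25, 0.5, 0.25))
    # positive DH removes heterozygotes under this algebra
    expect_equal(unname(genotypeProbs(0.5, DH = 0.05)), c(0.30, 0.40, 0.30))
    expect_equal(unname(genotypeProbs(0.9)), c(0.81, 0.18, 0.01))
    # probabilities always sum to 1 on a feasible grid
    for (p1 in c(0.1, 0.3, 0.5, 0.8)) {
        rng <- mcld:::.feasibleDH(p1)
        for (DH in seq(rng["lo"] + 1e-6, rng["hi"] - 1e-6, length.out = 7)) {
            pr <- genotypeProbs(p1, DH)
            expect_equal(sum(pr), 1)
            expect_true(all(pr >= 0 & pr <= 1))
        }
    }
    # infeasible DH errors and reports the feasible range
    expect_error(genotypeProbs(0.5, DH = 0.3), "must lie in")
    expect_error(LocusModel(0.9, DH = -0.5), "must lie in")
})

test_that("null simulator matches product-multinomial expectations", {
    d <- simulateNull(0.5, 0.5, n = 10000, seed = 301)
    # double homozygote (2,2) has probability 0.0625 under HWE p = q = 0.5
    phat <- mean(d$gA == 2 & d$gB == 2)
    se <- sqrt(0.0625 * (1 - 0.0625) / 10000)
    expect_lt(abs(phat - 0.0625), 3 * se)
    # marginal allele frequency
    se.p <- sqrt(0.5 * 0.5 / 20000)
    expect_lt(abs(mean(d$gA) / 2 - 0.5), 3 * se.p)

    # determinism
    d2 <- simulateNull(0.5, 0.5, n = 10000, seed = 301)
    expect_identical(d, d2)

    # independence: G-test of the 9-cell table has ~ chi-square(4) scale
    tab <- table(factor(d$gA, 0:2), factor(d$gB, 0:2))
    suppressWarnings(ct <- stats::chisq.test(tab, correct = FALSE))
    expect_gt(ct$p.value, 1e-4)
})

test_that("phased null record has the product haplotype law", {
    d <- simulateNull(0.6, 0.3, n = 20000, seed = 302, phased = TRUE)
    h <- d$haplotypes
    N <- sum(h)
    expect_equal(N, 40000)
    # f11 -> p1*q1 under independence
    se <- sqrt(0.18 * 0.82 / N)
    expect_lt(abs(h[["n11"]] / N - 0.6 * 0.3), 3 * se)
    # phased record is consistent with the genotype margins
    expect_equal(h[["n11"]] + h[["n12"]], sum(d$gA))
    expect_equal(h[["n11"]] + h[["n21"]], sum(d$gB))
})

test_that("alternative simulator hits the target haplotype frequencies", {
    # D = 0.0625 (D' = 0.25) at p1 = q1 = 0.5: P(B1|A1) = 0.625
    pm <- PairModel(LocusModel(0.5), LocusModel(0.5), D = 0.0625, n = 10000)
    d <- simulateAlternative(pm, seed = 303, phased = TRUE)
    N <- sum(d$haplotypes)
    f11 <- d$haplotypes[["n11"]] / N
    se <- sqrt(0.3125 * (1 - 0.3125) / N)
    expect_lt(abs(f11 - 0.3125), 3 * se)

    # phased r2 recovers D^2/(p1 p2 q1 q2)
    s <- ldFromHaplotypes(HaplotypeFreqs(d$haplotypes / N, N = N))
    target <- 0.0625^2 / (0.5^4)
    expect_lt(abs(r2(s) - target), 0.02)

    # D = 0 collapses to independence: f11 ~ p1*q1
    pm0 <- PairModel(LocusModel(0.5), LocusModel(0.5), D = 0, n = 10000)
    d0 <- simulateAlternative(pm0, seed = 304, phased = TRUE)
    f11.0 <- d0$haplotypes[["n11"]] / sum(d0$haplotypes)
    expect_lt(abs(f11.0 - 0.25), 3 * sqrt(0.25 * 0.75 / 20000))

    # infeasible D rejected with the bound in the message
    expect_error(PairModel(LocusModel(0.5), LocusModel(0.5), D = 0.3,
                           n = 100), "\\|D\\| must be")
})

test_that("dprimeToD inverts the D' normalization", {
    expect_equal(dprimeToD(0.5, 0.5, 0.25), 0.0625)
    expect_equal(dprimeToD(0.5, 0.5, 0), 0)
    # round trip through the LD computation
    set.seed(305)
    for (i in 1:50) {
        p1 <- stats::runif(1, 0.1, 0.9); q1 <- stats::runif(1, 0.1, 0.9)
        dp <- stats::runif(1, 0, 0.9)
        sgn <- sample(c(-1, 1), 1)
        D <- dprimeToD(p1, q1, dp, sign = sgn)
        f <- c(p1 * q1 + D, p1 * (1 - q1) - D,
               (1 - p1) * q1 - D, (1 - p1) * (1 - q1) + D)
        s <- ldFromHaplotypes(HaplotypeFreqs(f, N = 100))
        expect_equal(Dprime(s), dp, tolerance = 1e-9)
        expect_equal(Dcoef(s), D, tolerance = 1e-12)
    }
})
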