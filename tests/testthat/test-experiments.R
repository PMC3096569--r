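test_that("naive chi-square size is inflated under the null at every level", {
    ts <- typeIStudy(n = 500, reps = 400, seed = 501)
    res <- studyResults(ts)
    expect_true(all(res$rate > res$alpha))
    expect_true(all(res$inflation > 1))
    expect_equal(res$se, sqrt(res$rate * (1 - res$rate) / 400))
})

test_that("phase-known statistic restores chi-square calibration", {
    ts <- typeIStudy(n = 1000, reps = 1000, seed = 502, phaseKnown = TRUE)
    res <- studyResults(ts)
    a <- res$rate[res$alpha == 0.05]
    expect_lt(abs(a - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("power is monotone in D' and calibrated at D' = 0", {
    ps <- powerStudy(dprimeGrid = c(0, 0.05, 0.1, 0.2), n = 1000,
                     reps = 500, alphas = 0.05, seed = 503)
    res <- studyResults(ps)
    pw <- res$power[order(res$dprime)]
    # non-decreasing within 3 binomial SE
    expect_true(all(diff(pw) > -3 * sqrt(0.25 / 500)))
    expect_lt(abs(pw[1] - 0.05), 3 * sqrt(0.05 * 0.95 / 500))
    expect_gt(pw[length(pw)], 0.9)
})

test_that("studies are reproducible for identical configuration and seed", {
    a <- powerStudy(dprimeGrid = c(0, 0.1), reps = 100, n = 300,
                    alphas = 0.05, seed = 504)
    b <- powerStudy(dprimeGrid = c(0, 0.1), reps = 100, n = 300,
                    alphas = 0.05, seed = 504)
    expect_identical(studyResults(a), studyResults(b))
    expect_identical(a@cutoffs, b@cutoffs)
    t1 <- typeIStudy(reps = 100, n = 300, seed = 505)
    t2 <- typeIStudy(reps = 100, n = 300, seed = 505)
    expect_identical(studyResults(t1), studyResults(t2))
})

test_that("empirical cutoff uses the (1-alpha)(R+1) order statistic", {
    x <- as.numeric(1:999)
    expect_equal(mcld:::.empiricalCutoff(x, 0.05), 950)
    expect_equal(mcld:::.empiricalCutoff(x, 0.5), 500)
    # at R = 10000, alpha = 0.001 this is the 10th-largest value
    y <- as.numeric(1:10000)
    expect_equal(mcld:::.empiricalCutoff(y, 0.001), 9991)
})

test_that("comparison hook reproduces the naive test and degenerate rules", {
    # naive chi-square through the hook matches typeIStudy's rate at D' = 0
    hk <- comparisonHook(naiveChisqTest, dprimeGrid = 0, n = 500,
                         reps = 400, alphas = 0.05, seed = 506)
    ts <- typeIStudy(n = 500, reps = 400, alphas = 0.05, seed = 506)
    hr <- studyResults(hk)$power
    tr <- studyResults(ts)$rate
    expect_lt(abs(hr - tr), 3 * sqrt(0.2 * 0.8 / 400) * 2)

    # constant-reject has power one everywhere
    always <- function(gA, gB, alphas) rep(TRUE, length(alphas))
    hk1 <- comparisonHook(always, dprimeGrid = c(0, 0.1), n = 100,
                          reps = 20, alphas = c(0.05, 0.01), seed = 507)
    expect_true(all(studyResults(hk1)$power == 1))

    # phase-known chi-square is calibrated when fed true haplotype draws
    # (checked via typeIStudy's phaseKnown mode above)
})

test_that("HWD at the typed locus raises power at matched D'", {
    hwe <- powerStudy(DH = 0, dprimeGrid = c(0, 0.05), reps = 800,
                      alphas = 0.05, seed = 508)
    hwd <- powerStudy(DH = 0.05, dprimeGrid = c(0, 0.05), reps = 800,
                      alphas = 0.05, seed = 508)
    p.hwe <- studyResults(hwe)$power[studyResults(hwe)$dprime == 0.05]
    p.hwd <- studyResults(hwd)$power[studyResults(hwd)$dprime == 0.05]
    expect_gt(p.hwd, p.hwe - 3 * sqrt(0.25 / 800))
})
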