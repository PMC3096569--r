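## Simulation studies: type-I error of the naive chi-square reference for
## Nr^2 under haplotype estimation, and power of the Monte Carlo test.

.binomSE <- function(p, n) sqrt(p * (1 - p) / n)

## per-arm sub-seed derived from a master seed so arms are order-independent
.armSeed <- function(seed, arm) {
    if (is.null(seed)) return(NULL)
    (as.numeric(seed) * 1009 + arm * 9973) %% 2147483647
}

## empirical upper-alpha critical value: the ceiling((1-alpha)(R+1))-th
## order statistic of the null sample
.empiricalCutoff <- function(x, alpha) {
    R <- length(x)
    k <- pmin(ceiling((1 - alpha) * (R + 1)), R)
    sort(x, partial = k)[k]
}

## simulate `reps` null replicates and return Nr^2 from EM fits (and,
## optionally, from the true phased haplotype counts)
.nullNr2Sample <- function(a, b, n, reps, seed = NULL, phaseKnown = FALSE) {
    if (!is.null(seed)) set.seed(seed)
    tab <- matrix(0, 9L, reps)
    phasedNr2 <- if (phaseKnown) numeric(reps) else NULL
    for (r in seq_len(reps)) {
        d <- simulateNull(a, b, n, phased = phaseKnown)
        tab[, r] <- tabulate(d$gA + 3L * d$gB + 1L, nbins = 9L)
        if (phaseKnown) {
            h <- d$haplotypes
            N <- sum(h)
            phasedNr2[r] <- tryCatch(
                ldFromHaplotypes(HaplotypeFreqs(h / N, N = N))@Nr2,
                error = function(e) 0)
        }
    }
    out <- list(em = .nr2Batch(tab)$nr2)
    if (phaseKnown) out$phased <- phasedNr2
    out
}

#' Type-I error of the naive chi-square test with estimated haplotypes
#'
#' Simulates pairs of independent SNPs (no LD), estimates haplotype
#' frequencies per replicate by EM, and measures how often the naive test
#' — referring Nr^2 to the chi-square(1) distribution — rejects at each
#' nominal level. With unphased data the estimation step adds variability
#' that the chi-square reference ignores, so the empirical size is far
#' above nominal; with `phaseKnown = TRUE` the statistic is instead
#' computed from the simulator's true haplotype counts, which restores
#' calibration and isolates haplotype estimation as the cause of the
#' inflation.
#'
#' @param p1,q1 Allele-1 frequencies at the two SNPs.
#' @param DHA,DHB HWD coefficients at the two SNPs (0 = HWE).
#' @param n Individuals per replicate.
#' @param reps Number of simulation replicates.
#' @param alphas Nominal significance levels.
#' @param seed Optional RNG seed.
#' @param phaseKnown Compute Nr^2 from true haplotype counts instead of
#'   EM estimates (control experiment).
#' @return A [StudyReport-class] whose `results` has columns `alpha`,
#'   `rate` (empirical size), `se` and `inflation` (rate/alpha); the
#'   replicate Nr^2 sample is kept in `nullSample()`.
#' @examples
#' typeIStudy(n = 200, reps = 100, seed = 1)
#' @export
typeIStudy <- function(p1 = 0.5, q1 = 0.5, DHA = 0, DHB = 0, n = 1000,
                       reps = 10000, alphas = c(0.05, 0.01, 0.001),
                       seed = NULL, phaseKnown = FALSE) {
    stopifnot(reps >= 1, all(alphas > 0 & alphas < 1))
    sam <- .nullNr2Sample(LocusModel(p1, DHA), LocusModel(q1, DHB),
                          n, reps, seed = .armSeed(seed, 0L),
                          phaseKnown = phaseKnown)
    nr2 <- if (phaseKnown) sam$phased else sam$em
    cut <- stats::qchisq(alphas, df = 1, lower.tail = FALSE)
    rate <- vapply(cut, function(cc) mean(nr2 > cc), numeric(1))
    res <- data.frame(alpha = alphas, rate = rate,
                      se = .binomSE(rate, reps), inflation = rate / alphas)
    new("StudyReport", results = res, statistics = nr2,
        cutoffs = stats::setNames(cut, alphas),
        params = list(kind = "type1", p1 = p1, q1 = q1, DHA = DHA,
                      DHB = DHB, n = n, reps = reps, alphas = alphas,
                      seed = seed, phaseKnown = phaseKnown))
}

#' Power of the Monte Carlo LD test across a grid of D' values
#'
#' Measures the power of the empirical-null test: first a calibration arm
#' at D' = 0 yields the null Nr^2 sample, whose upper-alpha empirical
#' quantiles become the critical values; then, for each D' in the grid,
#' genotypes are simulated by the two-step conditional sampler
#' ([simulateAlternative()]) and the exceedance proportion over each
#' cutoff is reported. All arms share the same null cutoffs, mirroring a
#' single reference distribution under no LD; the D' = 0 grid arm is
#' simulated independently of the cutoff arm, so its reported "power" is
#' an honest estimate of the achieved size.
#'
#' @param p1,q1 Allele-1 frequencies.
#' @param DH HWD coefficient of SNP A (applied in all arms; SNP B is
#'   generated conditionally and is HWE conditionally on A).
#' @param dprimeGrid D' values, each in [0, 1] and feasible for the
#'   allele frequencies; should include 0.
#' @param n Individuals per replicate.
#' @param reps Replicates per arm.
#' @param alphas Nominal significance levels.
#' @param seed Optional RNG seed; per-arm substreams are derived from it
#'   so arms are reproducible in any order.
#' @return A [StudyReport-class] with columns `dprime`, `alpha`, `power`,
#'   `se`; the null-arm Nr^2 sample and the cutoffs are retained.
#' @examples
#' powerStudy(dprimeGrid = c(0, 0.1), n = 200, reps = 100, seed = 1)
#' @export
powerStudy <- function(p1 = 0.5, q1 = 0.5, DH = 0,
                       dprimeGrid = seq(0, 0.25, by = 0.025), n = 1000,
                       reps = 10000, alphas = c(0.05, 0.01, 0.001),
                       seed = NULL) {
    stopifnot(reps >= 1, all(alphas > 0 & alphas < 1),
              all(dprimeGrid >= 0 & dprimeGrid <= 1))
    locA <- LocusModel(p1, DH)
    ## calibration arm: null sample at D' = 0 provides the critical values
    nullNr2 <- .armNr2(locA, q1, D = 0, n = n, reps = reps,
                       seed = .armSeed(seed, 0L))
    cut <- vapply(alphas, function(a) .empiricalCutoff(nullNr2, a),
                  numeric(1))
    rows <- vector("list", length(dprimeGrid))
    for (i in seq_along(dprimeGrid)) {
        D <- dprimeToD(p1, q1, dprimeGrid[i])
        nr2 <- .armNr2(locA, q1, D = D, n = n, reps = reps,
                       seed = .armSeed(seed, i))
        pow <- vapply(cut, function(cc) mean(nr2 > cc), numeric(1))
        rows[[i]] <- data.frame(dprime = dprimeGrid[i], alpha = alphas,
                                power = pow, se = .binomSE(pow, reps))
    }
    res <- do.call(rbind, rows)
    new("StudyReport", results = res, statistics = nullNr2,
        cutoffs = stats::setNames(cut, alphas),
        params = list(kind = "power", p1 = p1, q1 = q1, DH = DH,
                      dprimeGrid = dprimeGrid, n = n, reps = reps,
                      alphas = alphas, seed = seed))
}

## one power-study arm: reps replicates of the conditional sampler -> Nr^2
.armNr2 <- function(locA, q1, D, n, reps, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    pm <- PairModel(locA, LocusModel(q1), D = D, n = n)
    tab <- matrix(0, 9L, reps)
    for (r in seq_len(reps)) {
        d <- simulateAlternative(pm)
        tab[, r] <- tabulate(d$gA + 3L * d$gB + 1L, nbins = 9L)
    }
    .nr2Batch(tab)$nr2
}

#' Run a study grid through a user-supplied LD test
#'
#' Plug-in driver for side-by-side power comparisons: `testFn` receives
#' each replicate's genotype vectors and the vector of nominal levels and
#' returns a logical rejection indicator per level. The same simulation
#' design as [powerStudy()] (or, with `dprimeGrid = 0` only, the null
#' design of [typeIStudy()]) is run through the supplied test.
#'
#' @param testFn `function(gA, gB, alphas) -> logical vector` of
#'   rejections, one per alpha.
#' @inheritParams powerStudy
#' @return A [StudyReport-class] with columns `dprime`, `alpha`, `power`,
#'   `se` for the supplied test.
#' @examples
#' comparisonHook(naiveChisqTest, dprimeGrid = 0, n = 200, reps = 50,
#'                alphas = 0.05, seed = 1)
#' @export
comparisonHook <- function(testFn, p1 = 0.5, q1 = 0.5, DH = 0,
                           dprimeGrid = seq(0, 0.25, by = 0.025), n = 1000,
                           reps = 1000, alphas = c(0.05, 0.01, 0.001),
                           seed = NULL) {
    stopifnot(is.function(testFn))
    locA <- LocusModel(p1, DH)
    rows <- vector("list", length(dprimeGrid))
    for (i in seq_along(dprimeGrid)) {
        D <- dprimeToD(p1, q1, dprimeGrid[i])
        pm <- PairModel(locA, LocusModel(q1), D = D, n = n)
        s <- .armSeed(seed, i)
        if (!is.null(s)) set.seed(s)
        rej <- matrix(FALSE, reps, length(alphas))
        for (r in seq_len(reps)) {
            d <- simulateAlternative(pm)
            rej[r, ] <- as.logical(testFn(d$gA, d$gB, alphas))
        }
        pow <- colMeans(rej)
        rows[[i]] <- data.frame(dprime = dprimeGrid[i], alpha = alphas,
                                power = pow, se = .binomSE(pow, reps))
    }
    res <- do.call(rbind, rows)
    new("StudyReport", results = res, statistics = numeric(0),
        cutoffs = numeric(0),
        params = list(kind = "comparison", p1 = p1, q1 = q1, DH = DH,
                      dprimeGrid = dprimeGrid, n = n, reps = reps,
                      alphas = alphas, seed = seed))
}

#' Naive chi-square LD test as a plug-in for [comparisonHook()]
#'
#' EM haplotype estimation followed by comparison of Nr^2 against the
#' chi-square(1) upper-alpha quantile — the test whose size inflation the
#' type-I study measures.
#'
#' @param gA,gB Genotype vectors.
#' @param alphas Nominal levels.
#' @return Logical rejection per alpha.
#' @export
naiveChisqTest <- function(gA, gB, alphas) {
    fit <- emHaplotypeFreqs(genotypeTableFromCalls(gA, gB))
    nr2 <- tryCatch(ldFromHaplotypes(fit@freqs)@Nr2, error = function(e) 0)
    nr2 > stats::qchisq(alphas, df = 1, lower.tail = FALSE)
}

#' Write a StudyReport's result table as TSV
#'
#' @param x A [StudyReport-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @importFrom utils write.table
#' @export
writeStudyReport <- function(x, path) {
    stopifnot(is(x, "StudyReport"))
    write.table(format(x@results, digits = 6, trim = TRUE), path,
                sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
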