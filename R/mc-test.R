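## Monte Carlo (bootstrap) LD test.
##
## Under the null of no LD the genotypes at the two SNPs are independent,
## so a null sample is built by resampling each SNP's single-locus
## genotypes with replacement and re-pairing them: whole genotypes are
## resampled, never individual alleles, which preserves each locus's HWD
## structure and is what keeps the test valid whether or not the loci are
## in HWE.

## Nr^2 for a batch of flattened tables via the shared EM engine.
## Monomorphic (degenerate) tables get statistic 0. Returns list(nr2,
## degenerate).
.nr2Batch <- function(tab, tol = 1e-8, maxIter = 1000L) {
    fit <- .emBatch(tab, tol = tol, maxIter = maxIter)
    f <- fit$f
    p1 <- f["f11", ] + f["f12", ]
    q1 <- f["f11", ] + f["f21", ]
    denom <- p1 * (1 - p1) * q1 * (1 - q1)
    degen <- denom <= 0
    D <- f["f11", ] - p1 * q1
    r2 <- ifelse(degen, 0, pmin(D^2 / ifelse(degen, 1, denom), 1))
    list(nr2 = fit$N * r2, degenerate = degen)
}

#' Bootstrap null distribution of the Nr^2 statistic
#'
#' Generates the distribution of Nr^2 under the null hypothesis of no LD
#' by resampling: in each of `B` replicates the n single-locus genotypes
#' are independently resampled with replacement at SNP A and at SNP B and
#' re-paired into n two-locus genotypes, destroying any between-locus
#' association while preserving each locus's genotype distribution; the
#' replicate's 3 x 3 table is then fitted by [emHaplotypeFreqs()] and
#' Nr^2 computed as for the observed data. A replicate in which a
#' resampled locus comes out monomorphic contributes the degenerate value
#' 0 (no evidence of LD); the count of such replicates is available from
#' the attribute `"nDegenerate"`.
#'
#' @param gA,gB Equal-length genotype vectors (0/1/2/NA copies of allele
#'   1); individuals missing either genotype are dropped first.
#' @param B Number of bootstrap replicates.
#' @param seed Optional RNG seed; given the seed, `B` and the input
#'   order, the null sample is reproducible.
#' @param chunk Internal batch size balancing speed and memory.
#' @return Numeric vector of `B` null Nr^2 values, with attribute
#'   `nDegenerate`.
#' @seealso [mcLDTest()]
#' @export
bootstrapNull <- function(gA, gB, B = 10000L, seed = NULL, chunk = 500L) {
    if (length(gA) != length(gB))
        stop("gA and gB must have the same length")
    .checkCalls(gA, "gA"); .checkCalls(gB, "gB")
    keep <- !(is.na(gA) | is.na(gB))
    gA <- as.integer(gA[keep]); gB <- as.integer(gB[keep])
    n <- length(gA)
    if (n < 2L) stop("fewer than 2 complete individuals")
    stopifnot(B >= 1L)
    if (!is.null(seed)) set.seed(seed)
    nr2 <- numeric(B)
    nDegen <- 0L
    done <- 0L
    while (done < B) {
        k <- min(chunk, B - done)
        ## iid resampling at each locus; elementwise pairing of the two
        ## independently resampled vectors is a random re-pairing
        rA <- gA[sample.int(n, n * k, replace = TRUE)]
        rB <- gB[sample.int(n, n * k, replace = TRUE)]
        cell <- rA + 3L * rB + 1L
        off <- rep(seq_len(k) - 1L, each = n) * 9L
        tab <- matrix(tabulate(cell + off, nbins = 9L * k), nrow = 9L)
        res <- .nr2Batch(tab)
        nr2[done + seq_len(k)] <- res$nr2
        nDegen <- nDegen + sum(res$degenerate)
        done <- done + k
    }
    attr(nr2, "nDegenerate") <- nDegen
    nr2
}

#' Monte Carlo test of linkage disequilibrium for a SNP pair
#'
#' Tests LD between two bi-allelic SNPs from unphased genotypes. The
#' observed statistic Nr^2 is computed from the EM haplotype-frequency
#' fit (N = 2n chromosomes); its null distribution is generated by
#' [bootstrapNull()], and the p-value is the add-one exceedance
#' proportion (1 + #\{null >= observed\}) / (B + 1), so it is never
#' exactly zero and `1/(B + 1)` is the smallest attainable value. Because
#' the null distribution is estimated rather than assumed chi-square, the
#' test keeps its nominal type-I error rate despite the variability that
#' haplotype estimation adds, and it remains valid under single-locus
#' Hardy-Weinberg disequilibrium.
#'
#' @inheritParams bootstrapNull
#' @return An [MCTestResult-class]; `pValue()`, `r2()`, `Dprime()` and
#'   `nullSample()` extract the components.
#' @examples
#' d <- simulateAlternative(
#'     PairModel(LocusModel(0.5), LocusModel(0.5), D = 0.05, n = 300),
#'     seed = 7)
#' mcLDTest(d$gA, d$gB, B = 199, seed = 7)
#' @export
mcLDTest <- function(gA, gB, B = 10000L, seed = NULL) {
    if (length(gA) != length(gB))
        stop("gA and gB must have the same length")
    keep <- !(is.na(gA) | is.na(gB))
    gA <- gA[keep]; gB <- gB[keep]
    n <- length(gA)
    if (n < 2L) stop("fewer than 2 complete individuals")
    t <- genotypeTableFromCalls(gA, gB)
    fit <- emHaplotypeFreqs(t)
    obs <- tryCatch(ldFromHaplotypes(fit@freqs),
                    error = function(e) stop("LD test undefined: ",
                                             conditionMessage(e)))
    nullSample <- bootstrapNull(gA, gB, B = B, seed = seed)
    p <- (1 + sum(nullSample >= obs@Nr2)) / (B + 1)
    new("MCTestResult", observed = obs, nullSample = as.numeric(nullSample),
        pValue = p, B = as.integer(B),
        seed = if (is.null(seed)) NA_real_ else as.numeric(seed),
        nDegenerate = attr(nullSample, "nDegenerate"), n = as.integer(n))
}
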