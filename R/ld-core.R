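#' LD statistics from haplotype frequencies
#'
#' Computes the standard pairwise linkage-disequilibrium summaries from the
#' four haplotype frequencies of two bi-allelic SNPs: the disequilibrium
#' coefficient D = f11 - p1*q1, Lewontin's normalized D' = |D|/Dmax with
#' Dmax = min(p1*q2, p2*q1) when D > 0 and min(p1*q1, p2*q2) when D < 0,
#' the squared allele correlation r^2 = D^2 / (p1*p2*q1*q2), and the test
#' statistic Nr^2 where N is the number of chromosomes. On a phased sample
#' Nr^2 equals the Pearson chi-square statistic of the 2 x 2 haplotype
#' contingency table.
#'
#' @param h A [HaplotypeFreqs-class] object.
#' @return An [LDStats-class] object.
#' @details D = 0 gives D' = 0 by convention (avoiding 0/0). Both loci
#'   must be polymorphic (0 < p1 < 1 and 0 < q1 < 1); LD is undefined at a
#'   monomorphic locus and an error is raised, leaving policy to the
#'   caller.
#' @examples
#' h <- HaplotypeFreqs(0.40, 0.10, 0.20, 0.30, N = 100)
#' ldFromHaplotypes(h)   # D = 0.1, D' = 0.5, r2 = 1/6
#' @export
ldFromHaplotypes <- function(h) {
    stopifnot(is(h, "HaplotypeFreqs"))
    f <- h@freqs
    p1 <- f[["f11"]] + f[["f12"]]
    q1 <- f[["f11"]] + f[["f21"]]
    p2 <- 1 - p1
    q2 <- 1 - q1
    if (p1 <= 0 || p1 >= 1 || q1 <= 0 || q1 >= 1)
        stop("LD undefined: monomorphic locus (p1 = ", signif(p1, 6),
             ", q1 = ", signif(q1, 6), ")")
    D <- f[["f11"]] - p1 * q1
    Dmax <- if (D > 0) min(p1 * q2, p2 * q1)
            else if (D < 0) min(p1 * q1, p2 * q2)
            else NA_real_
    Dprime <- if (D == 0) 0 else abs(D) / Dmax
    r2 <- D^2 / (p1 * p2 * q1 * q2)
    new("LDStats", D = unname(D), Dmax = ifelse(is.na(Dmax), 0, Dmax),
        Dprime = unname(min(Dprime, 1)), r2 = unname(min(r2, 1)),
        Nr2 = unname(h@N * min(r2, 1)), N = h@N)
}

#' Naive chi-square p-value for the Nr^2 statistic
#'
#' Upper-tail probability of the chi-square distribution with 1 degree of
#' freedom. This is the reference distribution Nr^2 follows when haplotypes
#' are directly observed; when haplotype frequencies are estimated from
#' unphased genotypes the statistic does NOT follow this distribution and
#' the resulting test is badly anticonservative — the function exists to
#' reproduce that naive test in the type-I error study, and [mcLDTest()]
#' is the valid alternative.
#'
#' @param stat Nonnegative statistic value(s).
#' @return Upper-tail chi-square(1) probability for each value.
#' @examples
#' chisqPvalueNaive(3.841459)   # ~0.05
#' @seealso [mcLDTest()], [typeIStudy()]
#' @importFrom stats pchisq
#' @export
chisqPvalueNaive <- function(stat) {
    if (any(is.na(stat)) || any(stat < 0))
        stop("stat must be nonnegative")
    pchisq(stat, df = 1, lower.tail = FALSE)
}
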