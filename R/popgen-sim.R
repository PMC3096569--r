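#' Single-locus genotype probabilities under Hardy-Weinberg disequilibrium
#'
#' Genotype probabilities for a bi-allelic locus with allele frequency
#' `p1` and HWD coefficient `DH`:
#' (P(2 copies), P(1 copy), P(0 copies)) =
#' (p1^2 + DH, 2 p1 p2 - 2 DH, p2^2 + DH). The heterozygote probability
#' decreases as DH increases under this parameterization.
#'
#' @param m A [LocusModel-class], or an allele frequency `p1`.
#' @param DH HWD coefficient, used only when `m` is numeric.
#' @return Named numeric vector of the probabilities of carrying 2, 1 and
#'   0 copies of allele 1.
#' @examples
#' genotypeProbs(0.5, DH = 0.05)   # c(0.30, 0.40, 0.30)
#' @export
genotypeProbs <- function(m, DH = 0) {
    if (is.numeric(m)) m <- LocusModel(m, DH)
    stopifnot(is(m, "LocusModel"))
    p1 <- m@p1; p2 <- 1 - p1
    pr <- c(`2` = p1^2 + m@DH, `1` = 2 * p1 * p2 - 2 * m@DH,
            `0` = p2^2 + m@DH)
    msg <- .checkLocusProbs(p1, m@DH)
    if (!is.null(msg)) stop(msg)
    pmin(pmax(pr, 0), 1)
}

## draw n single-locus genotypes (copies of allele 1) from a LocusModel
.drawGenotypes <- function(m, n) {
    sample(c(2L, 1L, 0L), n, replace = TRUE, prob = genotypeProbs(m))
}

#' Simulate two independent SNPs (the no-LD null)
#'
#' Draws joint genotypes for `n` individuals at two bi-allelic SNPs under
#' the null hypothesis of no LD: the 9-cell joint genotype distribution is
#' the product of the two single-locus genotype distributions, each given
#' by its [LocusModel-class] (HWE when `DH = 0`, HWD otherwise).
#'
#' @param a,b [LocusModel-class] objects for SNP A and SNP B (or allele
#'   frequencies, promoted to HWE models).
#' @param n Number of diploid individuals.
#' @param seed Optional RNG seed for reproducibility.
#' @param phased Also return the true chromosome-level haplotype counts
#'   `c(n11, n12, n21, n22)` (alleles are assigned to homologous
#'   chromosomes at random, which under independence reproduces the joint
#'   haplotype law).
#' @return List with integer vectors `gA`, `gB` (copies of allele 1 per
#'   individual) and, if `phased`, `haplotypes`.
#' @examples
#' d <- simulateNull(LocusModel(0.5), LocusModel(0.5), n = 100, seed = 1)
#' table(d$gA, d$gB)
#' @export
simulateNull <- function(a, b, n, seed = NULL, phased = FALSE) {
    if (is.numeric(a)) a <- LocusModel(a)
    if (is.numeric(b)) b <- LocusModel(b)
    stopifnot(n >= 1)
    if (!is.null(seed)) set.seed(seed)
    gA <- .drawGenotypes(a, n)
    gB <- .drawGenotypes(b, n)
    out <- list(gA = gA, gB = gB)
    if (phased) {
        ## split each genotype into two chromosome alleles; the B pair is
        ## permuted at random so double heterozygotes land in coupling or
        ## repulsion with probability 1/2 each, as independence implies
        a1 <- as.integer(gA >= 1L)        # chromosome 1 carries A1 if any
        a2 <- gA - a1
        hetB <- gB == 1L
        flip <- stats::runif(n) < 0.5
        b1 <- ifelse(hetB, as.integer(flip), as.integer(gB == 2L))
        b2 <- gB - b1
        out$haplotypes <- .countHaplotypes(a1, a2, b1, b2)
    }
    out
}

.countHaplotypes <- function(a1, a2, b1, b2) {
    h <- c(n11 = sum(a1 & b1) + sum(a2 & b2),
           n12 = sum(a1 & !b1) + sum(a2 & !b2),
           n21 = sum(!a1 & b1) + sum(!a2 & b2),
           n22 = sum(!a1 & !b1) + sum(!a2 & !b2))
    h
}

#' Simulate two SNPs with a given level of gametic disequilibrium
#'
#' Two-step sampler for the LD alternative. Step 1 draws each
#' individual's SNP-A genotype from the HWD genotype probabilities of
#' `locusA`. Step 2 places the two A alleles on the two homologous
#' chromosomes (heterozygotes carry one each) and, for each chromosome,
#' draws the B allele from the conditional distribution implied by the
#' target disequilibrium `D`: P(B1|A1) = q1 + D/p1 and
#' P(B1|A2) = q1 - D/p2. The resulting true haplotype frequencies are
#' f11 = p1 q1 + D, f12 = p1 q2 - D, f21 = p2 q1 - D, f22 = p2 q2 + D;
#' SNP B is in HWE conditionally on SNP A. With `D = 0` the sampler
#' coincides in law with [simulateNull()] with SNP B under HWE.
#'
#' @param pm A [PairModel-class].
#' @param seed Optional RNG seed.
#' @param phased Also return the true haplotype counts.
#' @return List with `gA`, `gB` and, if `phased`, `haplotypes`.
#' @examples
#' pm <- PairModel(LocusModel(0.5), LocusModel(0.5), D = 0.0625, n = 500)
#' d <- simulateAlternative(pm, seed = 1)
#' @export
simulateAlternative <- function(pm, seed = NULL, phased = FALSE) {
    stopifnot(is(pm, "PairModel"))
    if (!is.null(seed)) set.seed(seed)
    n <- pm@n
    p1 <- pm@locusA@p1; q1 <- pm@locusB@p1; D <- pm@D
    c1 <- min(max(q1 + D / p1, 0), 1)       # P(B1 | A1)
    c2 <- min(max(q1 - D / (1 - p1), 0), 1) # P(B1 | A2)
    gA <- .drawGenotypes(pm@locusA, n)
    ## chromosome 1 carries A1 whenever the individual has one (het
    ## assignment is exchangeable, so a fixed rule is distributionally
    ## irrelevant and keeps replays exact)
    a1 <- as.integer(gA >= 1L)
    a2 <- gA - a1
    b1 <- as.integer(stats::runif(n) < ifelse(a1 == 1L, c1, c2))
    b2 <- as.integer(stats::runif(n) < ifelse(a2 == 1L, c1, c2))
    out <- list(gA = gA, gB = b1 + b2)
    if (phased) out$haplotypes <- .countHaplotypes(a1, a2, b1, b2)
    out
}

#' Convert D' to the disequilibrium coefficient D
#'
#' Maps Lewontin's normalized D' back to D for given allele frequencies:
#' D = sign * D' * Dmax, with Dmax = min(p1*q2, p2*q1) for positive D and
#' min(p1*q1, p2*q2) for negative D.
#'
#' @param p1,q1 Allele-1 frequencies at the two SNPs, in (0, 1).
#' @param dprime Normalized disequilibrium, in [0, 1].
#' @param sign +1 or -1, the direction of the association.
#' @return The coefficient D.
#' @examples
#' dprimeToD(0.5, 0.5, 0.25)   # 0.0625
#' @export
dprimeToD <- function(p1, q1, dprime, sign = 1) {
    stopifnot(p1 > 0, p1 < 1, q1 > 0, q1 < 1,
              dprime >= 0, dprime <= 1, sign %in% c(-1, 1))
    dmax <- if (sign > 0) min(p1 * (1 - q1), (1 - p1) * q1)
            else min(p1 * q1, (1 - p1) * (1 - q1))
    sign * dprime * dmax
}
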