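#' @import methods
NULL

.FREQ_TOL <- 1e-9

#' Haplotype frequencies at two bi-allelic SNPs
#'
#' Holds the four haplotype frequencies f(A1B1), f(A1B2), f(A2B1), f(A2B2)
#' for a pair of bi-allelic SNPs, together with the number of chromosomes
#' `N` they were estimated from (twice the number of diploid individuals).
#' Frequencies must be nonnegative and sum to one; a deviation from one of
#' less than 1e-9 is renormalized by the constructor, anything larger is an
#' error.
#'
#' @slot freqs Named numeric vector `c(f11, f12, f21, f22)`.
#' @slot N Number of chromosomes in the sample (nonnegative).
#'
#' @seealso [HaplotypeFreqs()], [ldFromHaplotypes()], [haploFreqs()]
#' @export
setClass("HaplotypeFreqs",
    representation(freqs = "numeric", N = "numeric"),
    validity = function(object) {
        f <- object@freqs
        if (length(f) != 4L)
            return("freqs must have length 4 (f11, f12, f21, f22)")
        if (anyNA(f) || any(f < 0))
            return("haplotype frequencies must be nonnegative and non-missing")
        if (abs(sum(f) - 1) > .FREQ_TOL)
            return(sprintf("haplotype frequencies sum to %.12f, not 1", sum(f)))
        if (length(object@N) != 1L || is.na(object@N) || object@N < 0)
            return("N must be a single nonnegative number of chromosomes")
        TRUE
    })

#' Construct a HaplotypeFreqs object
#'
#' @param f11,f12,f21,f22 Frequencies of haplotypes A1B1, A1B2, A2B1, A2B2.
#'   Alternatively `f11` may be a numeric vector of length 4.
#' @param N Number of chromosomes the frequencies refer to (2 x individuals).
#'
#' @return A [HaplotypeFreqs-class] object.
#' @examples
#' h <- HaplotypeFreqs(0.40, 0.10, 0.20, 0.30, N = 100)
#' haploFreqs(h)
#' @export
HaplotypeFreqs <- function(f11, f12 = NULL, f21 = NULL, f22 = NULL, N = 0) {
    f <- if (length(f11) == 4L && is.null(f12)) as.numeric(f11)
         else c(f11, f12, f21, f22)
    if (anyNA(f) || any(f < 0))
        stop("haplotype frequencies must be nonnegative and non-missing")
    dev <- abs(sum(f) - 1)
    if (dev > .FREQ_TOL)
        stop(sprintf("haplotype frequencies sum to %.12f (deviation %.3g > 1e-9)",
                     sum(f), dev))
    if (dev > 0 && sum(f) > 0) f <- f / sum(f)
    names(f) <- c("f11", "f12", "f21", "f22")
    new("HaplotypeFreqs", freqs = f, N = as.numeric(N))
}

#' Pairwise linkage-disequilibrium summary statistics
#'
#' The LD coefficient D = f11 - p1*q1, its frequency-dependent bound Dmax,
#' the normalized coefficient D' = |D|/Dmax, the squared allele correlation
#' r^2 = D^2/(p1 p2 q1 q2) and the test statistic Nr^2, where N is the
#' number of chromosomes.
#'
#' @slot D Signed gametic disequilibrium coefficient, in [-0.25, 0.25].
#' @slot Dmax Bound on |D| given the allele frequencies.
#' @slot Dprime Normalized |D|/Dmax, in [0, 1].
#' @slot r2 Squared allele correlation, in [0, 1].
#' @slot Nr2 Test statistic N * r^2.
#' @slot N Number of chromosomes.
#'
#' @seealso [ldFromHaplotypes()]
#' @export
setClass("LDStats",
    representation(D = "numeric", Dmax = "numeric", Dprime = "numeric",
                   r2 = "numeric", Nr2 = "numeric", N = "numeric"),
    validity = function(object) {
        if (object@r2 < -1e-12 || object@r2 > 1 + 1e-12)
            return("r2 outside [0, 1]")
        if (object@Dprime < -1e-12 || object@Dprime > 1 + 1e-12)
            return("Dprime outside [0, 1]")
        TRUE
    })

#' Joint genotype counts at two bi-allelic SNPs
#'
#' A 3 x 3 table of individual counts indexed by copies of allele A1
#' (rows, 0/1/2) and copies of allele B1 (columns, 0/1/2). This table is
#' the sufficient statistic for two-locus haplotype-frequency estimation;
#' only the double-heterozygote cell (1,1) is phase-ambiguous.
#'
#' @slot counts 3 x 3 matrix of nonnegative integer counts.
#' @slot nExcluded Individuals dropped because either genotype was missing.
#'
#' @seealso [genotypeTableFromCalls()], [emHaplotypeFreqs()]
#' @export
setClass("GenotypeTable",
    representation(counts = "matrix", nExcluded = "integer"),
    validity = function(object) {
        cts <- object@counts
        if (!all(dim(cts) == c(3L, 3L)))
            return("counts must be a 3 x 3 matrix")
        if (anyNA(cts) || any(cts < 0) || any(cts != round(cts)))
            return("counts must be nonnegative integers")
        TRUE
    })

#' Construct a GenotypeTable from a 3 x 3 count matrix
#'
#' @param counts 3 x 3 matrix of counts, rows = copies of A1 (0,1,2),
#'   columns = copies of B1 (0,1,2).
#' @param nExcluded Number of individuals excluded for missingness.
#' @return A [GenotypeTable-class] object.
#' @export
GenotypeTable <- function(counts, nExcluded = 0L) {
    counts <- matrix(as.numeric(counts), 3L, 3L,
                     dimnames = list(A1copies = 0:2, B1copies = 0:2))
    new("GenotypeTable", counts = counts, nExcluded = as.integer(nExcluded))
}

#' Result of the two-locus EM haplotype-frequency fit
#'
#' @slot freqs The fitted [HaplotypeFreqs-class].
#' @slot loglik Final observed-data multinomial log-likelihood.
#' @slot iterations Number of EM iterations performed.
#' @slot converged Whether the frequency change fell below tolerance.
#' @slot trace Per-iteration log-likelihood values (empty unless requested).
#'
#' @seealso [emHaplotypeFreqs()]
#' @export
setClass("EMResult",
    representation(freqs = "HaplotypeFreqs", loglik = "numeric",
                   iterations = "integer", converged = "logical",
                   trace = "numeric"))

#' Result of the Monte Carlo LD test
#'
#' @slot observed [LDStats-class] computed from the EM fit on the data.
#' @slot nullSample The B bootstrap Nr^2 statistics forming the null
#'   distribution.
#' @slot pValue Add-one empirical p-value, (1 + exceedances)/(B + 1).
#' @slot B Number of bootstrap replicates.
#' @slot seed RNG seed used (NA if none supplied).
#' @slot nDegenerate Bootstrap replicates in which a resampled locus was
#'   monomorphic (statistic set to 0).
#' @slot n Number of complete individuals used.
#'
#' @seealso [mcLDTest()]
#' @export
setClass("MCTestResult",
    representation(observed = "LDStats", nullSample = "numeric",
                   pValue = "numeric", B = "integer", seed = "numeric",
                   nDegenerate = "integer", n = "integer"),
    validity = function(object) {
        if (object@pValue <= 0 || object@pValue > 1)
            return("pValue must lie in (0, 1]")
        if (length(object@nullSample) != object@B)
            return("nullSample length must equal B")
        TRUE
    })

#' Single-locus genotype model with Hardy-Weinberg disequilibrium
#'
#' Genotype probabilities are parameterized by the allele frequency `p1`
#' and an HWD coefficient `DH`: P(2 copies) = p1^2 + DH,
#' P(1 copy) = 2 p1 p2 - 2 DH, P(0 copies) = p2^2 + DH. `DH = 0` is
#' Hardy-Weinberg equilibrium.
#'
#' @slot p1 Frequency of allele 1, in (0, 1).
#' @slot DH Signed HWD coefficient.
#'
#' @seealso [LocusModel()], [genotypeProbs()], [simulateNull()]
#' @export
setClass("LocusModel",
    representation(p1 = "numeric", DH = "numeric"),
    validity = function(object) {
        if (length(object@p1) != 1L || is.na(object@p1) ||
            object@p1 <= 0 || object@p1 >= 1)
            return("p1 must be a single value in (0, 1)")
        msg <- .checkLocusProbs(object@p1, object@DH)
        if (!is.null(msg)) return(msg)
        TRUE
    })

.feasibleDH <- function(p1) {
    p2 <- 1 - p1
    c(lo = max(-p1^2, -p2^2, p1 * p2 - 0.5), hi = p1 * p2)
}

.checkLocusProbs <- function(p1, DH) {
    pr <- c(p1^2 + DH, 2 * p1 * (1 - p1) - 2 * DH, (1 - p1)^2 + DH)
    if (any(pr < -1e-12) || any(pr > 1 + 1e-12)) {
        rng <- .feasibleDH(p1)
        return(sprintf(
            "genotype probabilities outside [0,1]; for p1 = %g, DH must lie in [%g, %g]",
            p1, rng["lo"], rng["hi"]))
    }
    NULL
}

#' Construct a LocusModel
#'
#' @param p1 Frequency of allele 1, in (0, 1).
#' @param DH HWD coefficient (default 0, i.e. HWE). Must keep all three
#'   genotype probabilities in [0, 1].
#' @return A [LocusModel-class] object.
#' @examples
#' genotypeProbs(LocusModel(0.5, DH = 0.05))
#' @export
LocusModel <- function(p1, DH = 0) {
    new("LocusModel", p1 = as.numeric(p1), DH = as.numeric(DH))
}

#' Two-SNP model for the LD alternative simulator
#'
#' Couples a [LocusModel-class] for SNP A with allele frequency `q1` at
#' SNP B and a gametic disequilibrium coefficient `D`, so that the true
#' haplotype frequencies are f11 = p1 q1 + D, f12 = p1 q2 - D,
#' f21 = p2 q1 - D, f22 = p2 q2 + D. SNP B alleles are generated per
#' chromosome from the conditional probabilities P(B1|A1) = q1 + D/p1 and
#' P(B1|A2) = q1 - D/p2, so SNP B is in HWE conditionally; `locusB@DH` is
#' not used by the alternative simulator.
#'
#' @slot locusA [LocusModel-class] for SNP A.
#' @slot locusB [LocusModel-class] for SNP B (supplies q1).
#' @slot D Signed gametic disequilibrium coefficient.
#' @slot n Number of diploid individuals to simulate.
#'
#' @seealso [PairModel()], [simulateAlternative()], [dprimeToD()]
#' @export
setClass("PairModel",
    representation(locusA = "LocusModel", locusB = "LocusModel",
                   D = "numeric", n = "integer"),
    validity = function(object) {
        p1 <- object@locusA@p1; q1 <- object@locusB@p1
        D <- object@D
        cond <- c(q1 + D / p1, (1 - q1) - D / p1,
                  q1 - D / (1 - p1), (1 - q1) + D / (1 - p1))
        if (any(cond < -1e-12) || any(cond > 1 + 1e-12)) {
            dmax <- if (D >= 0) min(p1 * (1 - q1), (1 - p1) * q1)
                    else min(p1 * q1, (1 - p1) * (1 - q1))
            return(sprintf(
                "conditional allele probabilities outside [0,1]; |D| must be <= %g for p1 = %g, q1 = %g",
                dmax, p1, q1))
        }
        if (object@n < 1L) return("n must be >= 1")
        TRUE
    })

#' Construct a PairModel
#'
#' @param locusA,locusB [LocusModel-class] objects (or allele frequencies,
#'   which are promoted to HWE models).
#' @param D Gametic disequilibrium coefficient; see [dprimeToD()] to derive
#'   it from D'.
#' @param n Number of diploid individuals to simulate.
#' @return A [PairModel-class] object.
#' @examples
#' pm <- PairModel(LocusModel(0.5), LocusModel(0.5), D = 0.0625, n = 1000)
#' @export
PairModel <- function(locusA, locusB, D = 0, n = 1000) {
    if (is.numeric(locusA)) locusA <- LocusModel(locusA)
    if (is.numeric(locusB)) locusB <- LocusModel(locusB)
    new("PairModel", locusA = locusA, locusB = locusB,
        D = as.numeric(D), n = as.integer(n))
}

#' Report from a type-I error or power study
#'
#' @slot results Data frame of per-(dprime, alpha) rejection proportions
#'   with binomial standard errors (and inflation factors for type-I
#'   studies).
#' @slot statistics The Nr^2 sample from the null (D' = 0) arm, retained so
#'   empirical cutoffs can be reused.
#' @slot cutoffs Named numeric vector of empirical critical values per
#'   alpha (power studies only).
#' @slot params List of the study configuration used.
#'
#' @seealso [typeIStudy()], [powerStudy()]
#' @export
setClass("StudyReport",
    representation(results = "data.frame", statistics = "numeric",
                   cutoffs = "numeric", params = "list"))

#' In-memory genotype matrix read from a file
#'
#' @slot sampleIDs Character vector of sample identifiers (rows).
#' @slot snpIDs Character vector of SNP identifiers (columns), unique.
#' @slot calls Integer matrix, individuals x SNPs, values 0/1/2/NA counting
#'   copies of the coded allele.
#' @slot source Source path and format tag.
#'
#' @seealso [readTSVMatrix()], [writeTSVMatrix()]
#' @export
setClass("GenotypeMatrix",
    representation(sampleIDs = "character", snpIDs = "character",
                   calls = "matrix", source = "character"),
    validity = function(object) {
        if (nrow(object@calls) != length(object@sampleIDs))
            return("calls rows must match sampleIDs")
        if (ncol(object@calls) != length(object@snpIDs))
            return("calls columns must match snpIDs")
        if (anyDuplicated(object@snpIDs))
            return("snpIDs must be unique")
        ok <- object@calls %in% c(0L, 1L, 2L) | is.na(object@calls)
        if (!all(ok)) return("calls must be 0, 1, 2 or NA")
        TRUE
    })
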