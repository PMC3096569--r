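#' Accessors for mcld result objects
#'
#' Small accessor generics following the usual Bioconductor pattern:
#' `haploFreqs()` returns the four haplotype frequencies, `chromosomes()`
#' the chromosome count N, `Dcoef()`, `Dprime()`, `r2()` and `Nr2()` the LD
#' summaries, `pValue()`, `nullSample()` and `nDegenerate()` the Monte
#' Carlo test components, `genotypeCounts()` the 3 x 3 count table, and
#' `iterations()` / `converged()` the EM diagnostics.
#'
#' @param x An mcld object ([HaplotypeFreqs-class], [LDStats-class],
#'   [EMResult-class], [MCTestResult-class], [GenotypeTable-class] or
#'   [StudyReport-class], as applicable).
#' @return The component named by the accessor.
#' @name accessors
#' @aliases haploFreqs chromosomes Dcoef Dprime r2 Nr2 pValue nullSample
#'   nDegenerate genotypeCounts iterations converged studyResults
#' @examples
#' h <- HaplotypeFreqs(0.40, 0.10, 0.20, 0.30, N = 100)
#' s <- ldFromHaplotypes(h)
#' r2(s)
#' Dprime(s)
NULL

#' @rdname accessors
#' @export
setGeneric("haploFreqs", function(x) standardGeneric("haploFreqs"))
#' @rdname accessors
#' @export
setGeneric("chromosomes", function(x) standardGeneric("chromosomes"))
#' @rdname accessors
#' @export
setGeneric("Dcoef", function(x) standardGeneric("Dcoef"))
#' @rdname accessors
#' @export
setGeneric("Dprime", function(x) standardGeneric("Dprime"))
#' @rdname accessors
#' @export
setGeneric("r2", function(x) standardGeneric("r2"))
#' @rdname accessors
#' @export
setGeneric("Nr2", function(x) standardGeneric("Nr2"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("nullSample", function(x) standardGeneric("nullSample"))
#' @rdname accessors
#' @export
setGeneric("nDegenerate", function(x) standardGeneric("nDegenerate"))
#' @rdname accessors
#' @export
setGeneric("genotypeCounts", function(x) standardGeneric("genotypeCounts"))
#' @rdname accessors
#' @export
setGeneric("iterations", function(x) standardGeneric("iterations"))
#' @rdname accessors
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))
#' @rdname accessors
#' @export
setGeneric("studyResults", function(x) standardGeneric("studyResults"))

## HaplotypeFreqs
#' @rdname accessors
setMethod("haploFreqs", "HaplotypeFreqs", function(x) x@freqs)
#' @rdname accessors
setMethod("chromosomes", "HaplotypeFreqs", function(x) x@N)
#' @rdname accessors
setMethod("haploFreqs", "EMResult", function(x) x@freqs@freqs)
#' @rdname accessors
setMethod("chromosomes", "EMResult", function(x) x@freqs@N)
#' @rdname accessors
setMethod("chromosomes", "LDStats", function(x) x@N)

## LDStats
#' @rdname accessors
setMethod("Dcoef", "LDStats", function(x) x@D)
#' @rdname accessors
setMethod("Dprime", "LDStats", function(x) x@Dprime)
#' @rdname accessors
setMethod("r2", "LDStats", function(x) x@r2)
#' @rdname accessors
setMethod("Nr2", "LDStats", function(x) x@Nr2)

## MCTestResult
#' @rdname accessors
setMethod("pValue", "MCTestResult", function(x) x@pValue)
#' @rdname accessors
setMethod("nullSample", "MCTestResult", function(x) x@nullSample)
#' @rdname accessors
setMethod("nDegenerate", "MCTestResult", function(x) x@nDegenerate)
#' @rdname accessors
setMethod("r2", "MCTestResult", function(x) x@observed@r2)
#' @rdname accessors
setMethod("Dprime", "MCTestResult", function(x) x@observed@Dprime)
#' @rdname accessors
setMethod("Nr2", "MCTestResult", function(x) x@observed@Nr2)

## GenotypeTable / EMResult
#' @rdname accessors
setMethod("genotypeCounts", "GenotypeTable", function(x) x@counts)
#' @rdname accessors
setMethod("iterations", "EMResult", function(x) x@iterations)
#' @rdname accessors
setMethod("converged", "EMResult", function(x) x@converged)

#' @describeIn accessors Observed-data log-likelihood of an EM fit.
#' @param object,... For the `logLik` method: an [EMResult-class] and
#'   ignored further arguments.
#' @importFrom stats logLik
#' @export
setMethod("logLik", "EMResult", function(object, ...) object@loglik)

## StudyReport
#' @rdname accessors
setMethod("studyResults", "StudyReport", function(x) x@results)
#' @rdname accessors
setMethod("nullSample", "StudyReport", function(x) x@statistics)

## show methods -------------------------------------------------------------

setMethod("show", "HaplotypeFreqs", function(object) {
    cat("HaplotypeFreqs (N =", object@N, "chromosomes)\n")
    print(round(object@freqs, 6))
})

setMethod("show", "LDStats", function(object) {
    cat("LDStats: D =", signif(object@D, 6),
        " D' =", signif(object@Dprime, 6),
        " r2 =", signif(object@r2, 6),
        " Nr2 =", signif(object@Nr2, 6),
        " (N =", object@N, ")\n")
})

setMethod("show", "GenotypeTable", function(object) {
    cat("GenotypeTable:", sum(object@counts), "individuals")
    if (object@nExcluded > 0)
        cat(" (", object@nExcluded, " excluded for missingness)", sep = "")
    cat("\n")
    print(object@counts)
})

setMethod("show", "EMResult", function(object) {
    cat("EMResult:", object@iterations, "iterations,",
        if (object@converged) "converged" else "NOT converged",
        "| logLik =", signif(object@loglik, 8), "\n")
    print(round(object@freqs@freqs, 6))
})

setMethod("show", "MCTestResult", function(object) {
    o <- object@observed
    cat("Monte Carlo LD test (", object@n, " individuals, B = ",
        object@B, " bootstrap replicates)\n", sep = "")
    cat("  r2 =", signif(o@r2, 4), " D' =", signif(o@Dprime, 4),
        " Nr2 =", signif(o@Nr2, 6), "\n")
    cat("  p-value =", format(object@pValue, digits = 4),
        if (object@pValue <= 1 / object@B) "(minimum attainable given B)" else "",
        "\n")
    if (object@nDegenerate > 0)
        cat("  ", object@nDegenerate,
            "degenerate (monomorphic) bootstrap replicates\n")
})

setMethod("show", "LocusModel", function(object) {
    cat("LocusModel: p1 =", object@p1, " DH =", object@DH,
        "| genotype probs:", paste(signif(genotypeProbs(object), 6),
                                   collapse = " "), "\n")
})

setMethod("show", "PairModel", function(object) {
    cat("PairModel: p1 =", object@locusA@p1, "(DH =", object@locusA@DH,
        ") q1 =", object@locusB@p1, " D =", object@D,
        " n =", object@n, "\n")
})

setMethod("show", "StudyReport", function(object) {
    cat("StudyReport (", object@params$kind, ")\n", sep = "")
    print(object@results, row.names = FALSE)
})

setMethod("show", "GenotypeMatrix", function(object) {
    cat("GenotypeMatrix:", length(object@sampleIDs), "samples x",
        length(object@snpIDs), "SNPs from", object@source[1], "\n")
})
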