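## Two-locus EM for haplotype frequencies from unphased genotype counts.
##
## The engine is written over a 9 x R matrix of flattened 3 x 3 tables so
## that simulation studies (thousands of tables) and the bootstrap null
## (B tables per test) run through one vectorized code path; the exported
## scalar emHaplotypeFreqs() is a thin wrapper over a one-column batch.
##
## Flattened cell order (column-major over the 3 x 3 table, rows = copies
## of A1, cols = copies of B1):
##   1:(0,0) 2:(1,0) 3:(2,0) 4:(0,1) 5:(1,1) 6:(2,1) 7:(0,2) 8:(1,2) 9:(2,2)
## Cell (1,1) — the double heterozygote — is the only phase-ambiguous cell.

#' Tabulate joint genotype counts from two call vectors
#'
#' Builds the 3 x 3 joint genotype table over individuals with both calls
#' non-missing (pairwise deletion); the number excluded is recorded.
#'
#' @param gA,gB Equal-length vectors of genotypes coded as copies of
#'   allele 1 (0, 1, 2) with `NA` for missing.
#' @return A [GenotypeTable-class].
#' @examples
#' genotypeTableFromCalls(c(0, 1, 2), c(0, 1, 2))
#' @export
genotypeTableFromCalls <- function(gA, gB) {
    if (length(gA) != length(gB))
        stop("gA and gB must have the same length")
    .checkCalls(gA, "gA"); .checkCalls(gB, "gB")
    keep <- !(is.na(gA) | is.na(gB))
    cts <- matrix(tabulate(gA[keep] + 3 * gB[keep] + 1L, nbins = 9L), 3L, 3L)
    GenotypeTable(cts, nExcluded = sum(!keep))
}

.checkCalls <- function(g, name) {
    bad <- !(g %in% c(0, 1, 2)) & !is.na(g)
    if (any(bad))
        stop(name, " contains values outside {0, 1, 2, NA}: ",
             paste(unique(g[bad])[seq_len(min(3, sum(bad)))], collapse = ", "))
    invisible(TRUE)
}

## Batch EM over flattened tables. `tab`: 9 x R numeric matrix.
## Returns list(f: 4 x R matrix rows f11,f12,f21,f22; iterations; converged;
## p1, q1 sample allele frequencies).
.emBatch <- function(tab, tol = 1e-8, maxIter = 1000L) {
    if (is.null(dim(tab))) tab <- matrix(tab, nrow = 9L)
    R <- ncol(tab)
    n <- colSums(tab)
    if (any(n < 1)) stop("each table must contain at least one individual")
    twoN <- 2 * n
    ## deterministic haplotype contributions from unambiguous cells
    kc11 <- 2 * tab[9L, ] + tab[6L, ] + tab[8L, ]
    kc12 <- 2 * tab[3L, ] + tab[6L, ] + tab[2L, ]
    kc21 <- 2 * tab[7L, ] + tab[8L, ] + tab[4L, ]
    kc22 <- 2 * tab[1L, ] + tab[2L, ] + tab[4L, ]
    nh <- tab[5L, ]                      # double heterozygotes
    p1 <- (kc11 + kc12 + nh) / twoN      # sample allele frequencies
    q1 <- (kc11 + kc21 + nh) / twoN
    ## linkage-equilibrium start
    f11 <- p1 * q1
    f12 <- p1 * (1 - q1)
    f21 <- (1 - p1) * q1
    f22 <- (1 - p1) * (1 - q1)
    iterations <- integer(R)
    active <- rep(TRUE, R)
    iter <- 0L
    while (any(active) && iter < maxIter) {
        iter <- iter + 1L
        a <- active
        num <- f11[a] * f22[a]
        den <- num + f12[a] * f21[a]
        w <- ifelse(den > 0, num / den, 0.5)
        n11 <- (kc11[a] + w * nh[a]) / twoN[a]
        n12 <- (kc12[a] + (1 - w) * nh[a]) / twoN[a]
        n21 <- (kc21[a] + (1 - w) * nh[a]) / twoN[a]
        n22 <- (kc22[a] + w * nh[a]) / twoN[a]
        delta <- pmax(abs(n11 - f11[a]), abs(n12 - f12[a]),
                      abs(n21 - f21[a]), abs(n22 - f22[a]))
        f11[a] <- n11; f12[a] <- n12; f21[a] <- n21; f22[a] <- n22
        ## tables without double heterozygotes hit the counting estimate
        ## (the exact MLE) in one update
        done <- delta < tol | nh[a] == 0
        iterations[a][done] <- iter
        active[a] <- !done
    }
    iterations[active] <- maxIter
    list(f = rbind(f11 = f11, f12 = f12, f21 = f21, f22 = f22),
         iterations = iterations, converged = !active, p1 = p1, q1 = q1,
         N = twoN)
}

#' EM estimate of two-locus haplotype frequencies
#'
#' Maximum-likelihood haplotype frequencies from a 3 x 3 table of unphased
#' joint genotype counts. Every cell except the double heterozygote
#' contributes known haplotype counts; each double heterozygote is split
#' in the E-step between the coupling phase \{A1B1, A2B2\} with weight
#' w = f11 f22 / (f11 f22 + f12 f21) and the repulsion phase
#' \{A1B2, A2B1\} with weight 1 - w, and the M-step sets the frequencies
#' to expected haplotype counts / 2n. Iteration starts from the
#' linkage-equilibrium point (products of sample allele frequencies) and
#' stops when the largest absolute frequency change drops below `tol`.
#'
#' @param t A [GenotypeTable-class] (or 3 x 3 count matrix).
#' @param tol Convergence tolerance on the frequency change.
#' @param maxIter Maximum EM iterations; if reached, `converged(result)`
#'   is `FALSE` but the result is still returned.
#' @param trace Record the observed-data log-likelihood at every
#'   iteration (slower; for diagnostics).
#' @return An [EMResult-class]; `chromosomes()` of the embedded
#'   frequencies is 2n.
#' @examples
#' t <- GenotypeTable(matrix(c(3, 0, 0, 0, 4, 0, 0, 0, 3), 3, 3))
#' emHaplotypeFreqs(t)
#' @export
emHaplotypeFreqs <- function(t, tol = 1e-8, maxIter = 1000L, trace = FALSE) {
    if (is.matrix(t)) t <- GenotypeTable(t)
    stopifnot(is(t, "GenotypeTable"))
    tab <- as.vector(t@counts)
    if (sum(tab) < 1) stop("n = 0: empty genotype table")
    if (!trace) {
        fit <- .emBatch(matrix(tab, 9L, 1L), tol = tol, maxIter = maxIter)
        h <- HaplotypeFreqs(fit$f[, 1L], N = fit$N[1L])
        return(new("EMResult", freqs = h,
                   loglik = observedLogLik(t, h),
                   iterations = fit$iterations[1L],
                   converged = fit$converged[1L], trace = numeric(0)))
    }
    ## traced scalar path: one explicit EM loop recording the log-likelihood
    n <- sum(tab); twoN <- 2 * n
    kc11 <- 2 * tab[9L] + tab[6L] + tab[8L]
    kc12 <- 2 * tab[3L] + tab[6L] + tab[2L]
    kc21 <- 2 * tab[7L] + tab[8L] + tab[4L]
    kc22 <- 2 * tab[1L] + tab[2L] + tab[4L]
    nh <- tab[5L]
    p1 <- (kc11 + kc12 + nh) / twoN
    q1 <- (kc11 + kc21 + nh) / twoN
    f <- c(p1 * q1, p1 * (1 - q1), (1 - p1) * q1, (1 - p1) * (1 - q1))
    ll <- .loglikFlat(tab, f)
    iter <- 0L; conv <- FALSE
    while (iter < maxIter) {
        iter <- iter + 1L
        num <- f[1L] * f[4L]; den <- num + f[2L] * f[3L]
        w <- if (den > 0) num / den else 0.5
        fn <- c(kc11 + w * nh, kc12 + (1 - w) * nh,
                kc21 + (1 - w) * nh, kc22 + w * nh) / twoN
        ll <- c(ll, .loglikFlat(tab, fn))
        if (max(abs(fn - f)) < tol || nh == 0) { f <- fn; conv <- TRUE; break }
        f <- fn
    }
    h <- HaplotypeFreqs(f, N = twoN)
    new("EMResult", freqs = h, loglik = ll[length(ll)],
        iterations = iter, converged = conv, trace = ll)
}

## log-likelihood on a flattened table, f = c(f11, f12, f21, f22)
.loglikFlat <- function(tab, f) {
    pr <- c(f[4L]^2,                      # (0,0)
            2 * f[2L] * f[4L],            # (1,0)
            f[2L]^2,                      # (2,0)
            2 * f[3L] * f[4L],            # (0,1)
            2 * f[1L] * f[4L] + 2 * f[2L] * f[3L],  # (1,1)
            2 * f[1L] * f[2L],            # (2,1)
            f[3L]^2,                      # (0,2)
            2 * f[1L] * f[3L],            # (1,2)
            f[1L]^2)                      # (2,2)
    pos <- tab > 0
    if (any(pos & pr <= 0)) return(-Inf)
    sum(tab[pos] * log(pr[pos]))
}

#' Observed-data log-likelihood of a genotype table
#'
#' Multinomial log-likelihood of the nine unphased genotype cells under
#' haplotype frequencies `h`, with cell probabilities given by random
#' union of haplotypes (HWE at the haplotype level), e.g.
#' P(double heterozygote) = 2 f11 f22 + 2 f12 f21. Cells with zero
#' probability and zero count contribute nothing; a zero-probability cell
#' with a positive count yields `-Inf` with a warning.
#'
#' @param t A [GenotypeTable-class] (or 3 x 3 count matrix).
#' @param h A [HaplotypeFreqs-class].
#' @return The log-likelihood (scalar; possibly `-Inf`).
#' @export
observedLogLik <- function(t, h) {
    if (is.matrix(t)) t <- GenotypeTable(t)
    stopifnot(is(t, "GenotypeTable"), is(h, "HaplotypeFreqs"))
    ll <- .loglikFlat(as.vector(t@counts), unname(h@freqs))
    if (is.infinite(ll))
        warning("a genotype cell with positive count has probability 0 under h")
    ll
}
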