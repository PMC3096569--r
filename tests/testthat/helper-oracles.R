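# Independent oracles used across the suite. These never call the code
# paths they are checking.

# Pearson chi-square statistic of a phased 2x2 haplotype count table,
# computed from observed-vs-expected cell counts.
pearsonChi2 <- function(h) {
    m <- matrix(h, 2L, 2L)            # rows allele A, cols allele B
    N <- sum(m)
    expd <- outer(rowSums(m), colSums(m)) / N
    sum((m - expd)^2 / expd)
}

# Random phased haplotype count vector (all four counts >= 1 so both loci
# are polymorphic and the chi-square is defined).
randomHaploCounts <- function(N = 200) {
    repeat {
        f <- stats::runif(4)
        h <- as.vector(stats::rmultinom(1, N, f / sum(f)))
        margins <- c(h[1] + h[2], h[3] + h[4], h[1] + h[3], h[2] + h[4])
        if (all(margins > 0) && all(margins < N)) return(h)
    }
}

# Random small unphased genotype table.
randomGenotypeTable <- function(n = 30) {
    f <- stats::runif(4); f <- f / sum(f)
    pr <- c(f[4]^2, 2 * f[2] * f[4], f[2]^2,
            2 * f[3] * f[4], 2 * f[1] * f[4] + 2 * f[2] * f[3],
            2 * f[1] * f[2], f[3]^2, 2 * f[1] * f[3], f[1]^2)
    matrix(stats::rmultinom(1, n, pr), 3L, 3L)
}

# Exhaustive 1-D maximization of the observed-data multinomial likelihood
# over f11 with the margins fixed at the sample allele frequencies (the
# only free parameter of the two-locus fit). Fine grid plus local refine.
gridSearchMLE <- function(counts, gridSize = 20001L) {
    tab <- as.vector(counts)
    n <- sum(tab)
    p1 <- (2 * sum(counts[3, ]) + sum(counts[2, ])) / (2 * n)
    q1 <- (2 * sum(counts[, 3]) + sum(counts[, 2])) / (2 * n)
    lo <- max(0, p1 + q1 - 1); hi <- min(p1, q1)
    ll <- function(f11) {
        f <- c(f11, p1 - f11, q1 - f11, 1 - p1 - q1 + f11)
        f[abs(f) < 1e-15] <- 0
        if (any(f < 0)) return(-Inf)
        pr <- c(f[4]^2, 2 * f[2] * f[4], f[2]^2,
                2 * f[3] * f[4], 2 * f[1] * f[4] + 2 * f[2] * f[3],
                2 * f[1] * f[2], f[3]^2, 2 * f[1] * f[3], f[1]^2)
        pos <- tab > 0
        if (any(pr[pos] <= 0)) return(-Inf)
        sum(tab[pos] * log(pr[pos]))
    }
    grid <- seq(lo, hi, length.out = gridSize)
    vals <- vapply(grid, ll, numeric(1))
    best <- grid[which.max(vals)]
    step <- (hi - lo) / (gridSize - 1)
    fine <- seq(max(lo, best - step), min(hi, best + step),
                length.out = 2001L)
    fvals <- vapply(fine, ll, numeric(1))
    f11 <- fine[which.max(fvals)]
    list(f11 = f11, loglik = max(fvals), p1 = p1, q1 = q1)
}

# Write a tiny VCF fixture; gts is a character matrix (sites x samples).
writeVCFFixture <- function(path, ids, ref, alt, gts) {
    samples <- paste0("S", seq_len(ncol(gts)))
    header <- c("##fileformat=VCFv4.2",
                "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", samples),
                      collapse = "\t"))
    rows <- vapply(seq_along(ids), function(i)
        paste(c("1", 1000L + i, ids[i], ref[i], alt[i], ".", "PASS", ".",
                "GT", gts[i, ]), collapse = "\t"), character(1))
    writeLines(c(header, rows), path)
    path
}
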