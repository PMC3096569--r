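---
title: "Testing linkage disequilibrium with estimated haplotypes: methods and design"
author: "mcld"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing linkage disequilibrium with estimated haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcld)
```

## The problem

Two bi-allelic SNPs A and B carry alleles $A_1/A_2$ and $B_1/B_2$ with
frequencies $p_1, p_2$ and $q_1, q_2$. Linkage disequilibrium is the
non-random association of alleles on the same haplotype, measured by

$$D = f_{11} - p_1 q_1,$$

where $f_{11}$ is the frequency of the $A_1B_1$ haplotype. Because $D$'s
range depends on allele frequencies, two normalizations are standard:
Lewontin's $D' = |D| / D_{\max}$ with
$D_{\max} = \min(p_1 q_2, p_2 q_1)$ for $D > 0$ and
$\min(p_1 q_1, p_2 q_2)$ for $D < 0$, and the squared allele correlation

$$r^2 = \frac{D^2}{p_1 p_2 q_1 q_2}.$$

With phase-known data and $N$ chromosomes, $N r^2$ equals the Pearson
$\chi^2$ statistic of the $2\times 2$ haplotype table, so $N r^2$ referred
to $\chi^2_1$ is the textbook LD test. The suite verifies this identity to
$10^{-9}$ against an independent observed-vs-expected computation.

Population data are unphased. A double heterozygote
$A_1A_2\,B_1B_2$ is compatible with the coupling pair
$\{A_1B_1, A_2B_2\}$ and the repulsion pair $\{A_1B_2, A_2B_1\}$; all
other genotype cells determine their haplotypes. Haplotype frequencies
must therefore be estimated before $r^2$ can be computed, and that
estimation step is the crux: the sampling variability of the estimator is
not accounted for by the $\chi^2_1$ reference, and the naive test's size
is badly inflated — increasingly so at stringent levels, exactly where
genome-wide analyses operate (see "What the studies show" below).

## Haplotype-frequency estimation (EM)

`emHaplotypeFreqs()` maximizes the multinomial likelihood of the nine
unphased genotype cells, whose probabilities are the random-union
(haplotype-level HWE) products, e.g.
$P(\text{double het}) = 2 f_{11} f_{22} + 2 f_{12} f_{21}$. The E-step
splits each double heterozygote between coupling, with weight
$w = f_{11} f_{22} / (f_{11} f_{22} + f_{12} f_{21})$, and repulsion with
weight $1 - w$; the M-step divides expected haplotype counts by $2n$.
Design choices, each of which the suite exercises:

* **Initialization** at the linkage-equilibrium point
  $f = (\hat p_1 \hat q_1, \hat p_1 \hat q_2, \hat p_2 \hat q_1,
  \hat p_2 \hat q_2)$ — deterministic and unbiased toward either phase.
  The two-locus likelihood, profiled over the single free parameter
  $f_{11}$ (the margins stay fixed at the sample allele frequencies
  throughout EM), is unimodal except in contrived boundary cases; the
  tests confirm agreement with an exhaustive grid search of the profile
  likelihood to $10^{-4}$.
* **Convergence** when no frequency moves by more than $10^{-8}$
  (at most 1000 iterations) — far below anything that affects $N r^2$ at
  the sample sizes involved. Tables without double heterozygotes reach
  the closed-form counting estimate in one update.
* **Ascent** — the observed-data log-likelihood is non-decreasing at
  every iteration (`trace = TRUE` records it), a property test over
  random tables.
* **HWE inside the likelihood** even when the data are generated under
  HWD. This is deliberate: single-locus HWD biases likelihood-based
  haplotype estimation, and the HWD arms of the studies measure precisely
  that effect. The *test* below does not rely on the likelihood being
  correctly specified.
* **Missing data**: individuals missing either genotype are dropped
  before tabulation (pairwise deletion).
* A degenerate (monomorphic) margin makes $r^2$ undefined;
  `ldFromHaplotypes()` signals an error and leaves policy to the caller.

## The Monte Carlo test

Under $H_0$ (no LD) the genotype at SNP A is independent of the genotype
at SNP B. `bootstrapNull()` therefore resamples the $n$ observed
single-locus genotypes with replacement at A, independently at B, and
pairs them to form a pseudo-sample with no between-locus association but
the observed single-locus genotype distributions — crucially, whole
genotypes are resampled, never alleles, so any HWD at each locus is
preserved and the test is valid with or without HWE. Each replicate is
pushed through the same EM-plus-$N r^2$ pipeline as the observed data;
`mcLDTest()` reports

$$p = \frac{1 + \#\{N r^2_{(b)} \ge N r^2_{\text{obs}}\}}{B + 1},$$

the standard add-one Monte Carlo estimator: never exactly zero, minimum
$1/(B+1)$, ties counted conservatively. Two further conventions:

* Since both loci are resampled i.i.d., pairing the two resampled vectors
  elementwise *is* a uniformly random re-pairing; no extra permutation is
  needed.
* A bootstrap replicate in which a locus comes out monomorphic gets the
  degenerate value 0 (no evidence of LD) and is counted in
  `nDegenerate`; re-drawing instead would distort the allele-frequency
  variance of the null sample. At $n = 1000$ and common alleles the event
  essentially never occurs.
* One seedable RNG stream per invocation makes results exactly
  reproducible given `(seed, B, input order)`.

## Simulators

`simulateNull()` draws the two SNPs independently, each from the
HWD-parameterized genotype distribution

$$P(2, 1, 0 \text{ copies}) = (p_1^2 + D_H,\; 2 p_1 p_2 - 2 D_H,\;
p_2^2 + D_H),$$

so the 9-cell joint distribution is the product multinomial. We implement
this algebra exactly as written, under which heterozygosity *decreases*
with increasing $D_H$; descriptions of the parameterization elsewhere
sometimes state the opposite sign convention, and the algebra, being
testable, wins. The feasible range
$D_H \in [\max(-p_1^2, -p_2^2, p_1 p_2 - \tfrac12),\; p_1 p_2]$ is
enforced with the bound reported in the error message.

`simulateAlternative()` generates LD in two steps: SNP-A genotypes from
the distribution above; then, per homologous chromosome, the B allele
from the conditional law $P(B_1 \mid A_1) = q_1 + D/p_1$,
$P(B_1 \mid A_2) = q_1 - D/p_2$, giving true haplotype frequencies
$f_{11} = p_1 q_1 + D$ and so on. Consequences worth noting: SNP B is in
HWE conditionally on A (its alleles are drawn independently across the
two chromosomes), and the assignment of a heterozygote's A alleles to
chromosomes is exchangeable, so a fixed assignment rule is used to keep
replays exact. The phased record (`phased = TRUE`) exposes the true
haplotype counts, which the consistency tests and the phase-known control
use. `dprimeToD()` maps a target $D'$ to $D$ for given frequencies.

What the generator does *not* emulate: genotyping error, missingness
structure, population stratification, or linkage to further loci. Passing
tests show the test behaves correctly for clean bi-allelic genotypes from
one homogeneous population; they say nothing about robustness to those
artifacts.

## The studies and their design

`typeIStudy()` simulates independent SNP pairs, runs EM per replicate,
and reports how often $N r^2$ exceeds fixed $\chi^2_1$ cutoffs — the
naive test's empirical size — plus inflation factors (rate/level). With
`phaseKnown = TRUE` the statistic is instead computed from the true
haplotype counts; this control restores calibration and isolates
estimation variability as the cause of the inflation.

`powerStudy()` first runs a D′ = 0 arm and takes the empirical
upper-$\alpha$ quantiles of its $N r^2$ sample as critical values — the
$\lceil (1-\alpha)(R+1) \rceil$-th order statistic, the standard Monte
Carlo critical-value convention (at $R = 10{,}000$ and
$\alpha = 0.001$, the 10th-largest value). Every D′ arm, including an
independent D′ = 0 arm whose "power" is the achieved size, is then
scored against those shared cutoffs. Sharing one null reference across
arms (rather than bootstrapping per replicate) is the study design; the
per-pair test itself (`mcLDTest()`) bootstraps its own null.
`comparisonHook()` runs the same simulated arms through any user-supplied
test for side-by-side columns. Per-arm sub-seeds are derived from the
master seed so arms reproduce in any order.

Study defaults mirror the conditions of interest: $p_1 = q_1 = 0.5$
(maximizing the double-heterozygote frequency, hence the phase-ambiguity
effect), $n = 1000$ individuals, $10{,}000$ replicates, levels
$0.05/0.01/0.001$, and $D_H = 0.05$ for HWD scenarios (a moderate
heterozygote deficit chosen once as a representative departure; results
are compared qualitatively across the HWE/HWD arms, not cell by cell).
The test suite runs the same designs at 2,000 replicates with
3-binomial-SE tolerances; the doubly nested calibration check uses 2,000
outer replicates with $B = 2{,}000$ bootstrap replicates each.

## What the studies show

At desk scale the package reproduces the power profile of the
empirical-null test: size $\approx 0.05$ at D′ = 0, power $\approx 0.89$
at D′ = 0.1, saturation at D′ = 0.25 ($p_1 = q_1 = 0.5$, $n = 1000$,
$\alpha = 0.05$), higher power under HWD than HWE at matched D′, and the
phase-known control sits at the nominal level. The naive $\chi^2_1$ test
is anticonservative at every level, with inflation growing as the level
shrinks (empirical size roughly $0.16 / 0.07 / 0.02$ at nominal
$0.05 / 0.01 / 0.001$ in our implementation — a 3- to 20-fold inflation).
The acceptance script (`scripts/acceptance.R`) recomputes all of these
from scratch.

## Numerical notes and limitations

* Frequencies are validated to sum to one within $10^{-9}$ (tiny
  deviations renormalized, larger ones rejected); $D = 0$ maps to
  $D' = 0$ by convention to avoid $0/0$.
* The EM engine is vectorized across many 3×3 tables (one batch for a
  whole bootstrap or study arm), which is what makes the nested
  simulations cheap without compiled code; the scalar and batch paths
  share the same update.
* $N r^2$ is capped at $N$ ( $r^2 \le 1$ ) against floating-point
  overshoot at boundary estimates.
* Single pair, two alleles: no multi-locus haplotypes, no composite-LD
  statistic, no confidence intervals on $r^2$, no multiple-testing
  adjustment across pairs.
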