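---
title: "IBD mapping with multi-individual clusters: models, parameters, and design notes"
author: "ibdscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IBD mapping with multi-individual clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The statistical model

`ibdscan` tests whether the level of identity-by-descent (IBD) sharing at a
genomic location explains phenotypic variance in a quantitative trait
observed on a population sample of N individuals.  The model is the linear
mixed model of variance-component linkage analysis,

$$Y = X\beta + G + Q_l + \varepsilon,$$

with fixed-effect covariates $X\beta$ (an intercept always included), a
genome-wide polygenic effect $G \sim N(0, \Psi\sigma_a^2)$, a
location-specific effect $Q_l \sim N(0, \Phi_l\sigma_Q^2)$, and independent
environmental noise $\varepsilon \sim N(0, I\sigma_\varepsilon^2)$, so that

$$\mathrm{Var}(Y) = V = \Psi\sigma_a^2 + \Phi_l\sigma_Q^2 +
I\sigma_\varepsilon^2 .$$

$\Psi$ (the *global IBD matrix*) carries twice the kinship coefficient for
each pair, with coefficients below 0.044 — relationships beyond third
degree — set to zero for sparsity.  $\Phi_l$ (the *local IBD matrix*)
carries the proportion of alleles (0, 1/2, or 1) that each pair shares IBD
at position $l$, with unit diagonal.  Association at $l$ is the
variance-component hypothesis test $H_0: \sigma_Q^2 = 0$ against
$H_1: \sigma_Q^2 > 0$, using the restricted-likelihood (REML) ratio
statistic $W = 2(\hat\ell_1 - \hat\ell_0)$, i.e. $2\ln 10$ times the LOD
score.  Because $\sigma_Q^2 = 0$ lies on the boundary of the parameter
space, the null distribution of $W$ is the 1/2:1/2 mixture of a point mass
at zero and $\chi^2_1$; the per-test p-value is
$\tfrac12\Pr(\chi^2_1 \ge W)$ for $W > 0$ and 1 at $W = 0$.

## Local matrices from multi-individual IBD clusters

$\Phi_l$ is built from a *cluster field*: at a genomic position, every one
of the 2N haplotypes carries a cluster identifier, and haplotypes sharing
an identifier are mutually IBD there.  `clusterAtPosition()` computes this
partition directly from phased haplotypes: two haplotypes are related when
they share an identical allele sequence over a marker interval of at least
`L` cM that contains the focal position and reaches at least `T` cM beyond
it on each side; the partition is the transitive closure of that relation.
`L` (haplotype length threshold) and `T` (trimming threshold) control the
stringency: larger values can only refine the partition.  The package
accepts `0 < T <= L/2`; the boundary value `T = L/2` is the most stringent
usable trimming and is included because the reference settings `L = 2, T =
1` use it.

Positions within `T` of a chromosome end can never satisfy the trimming
requirement on the short side, so a shared interval that runs into the end
of the chromosome satisfies the requirement on that side.  Without this
rule no position within `T` of an end could ever cluster, which would
leave the ends of every chromosome untestable in a genome scan.

With the allocation matrix $A_l$ (entry $(i,k)$ = proportion of individual
$i$'s haplotypes in cluster $k$), $\Phi_l = 2 A_l A_l^\top$ with the
diagonal forced to exactly 1.  Columns of singleton clusters may be
dropped without changing any off-diagonal entry.  The construction is
symmetric and positive semidefinite for outbred input (no individual's two
haplotypes mutually IBD); should self-IBD occur, affected entries are
capped at 1 and the Cholesky jitter policy below covers the (rare)
resulting indefiniteness.  Region tests average the positional matrices at
selected locations within the region — for the 0.05 cM power-study
regions, its start and end — which preserves symmetry, the unit diagonal,
and positive semidefiniteness by convexity.

## REML evaluation and optimization

The restricted log-likelihood

$$\ell = -\tfrac{N-p}{2}\ln 2\pi - \tfrac12\ln|V| - \tfrac12\ln|X^\top
V^{-1}X| - \tfrac12(Y - X\hat\beta)^\top V^{-1}(Y - X\hat\beta)$$

is evaluated block by block: individuals connected by a nonzero entry of
$\Psi$ or $\Phi_l$ form small blocks (connected components of the combined
sparsity graph), singletons are aggregated in closed form, and each block
contributes through a dense Cholesky factorization.  The additive constant
is fixed across hypotheses so it cancels in $W$.  The analytic REML
gradient is computed the same way, which makes one evaluation linear in
the number of blocks and cubic only in the largest block size.

Maximization is BFGS on the log-variance scale, which makes the
non-negativity constraints implicit while allowing boundary optima: a
log-coordinate resting at its floor ($10^{-10}\,\mathrm{Var}(Y)$) with a
downhill gradient counts as converged, estimates below
$10^{-8}\,\mathrm{Var}(Y)$ snap to exactly zero, and the remaining free
components are re-polished with the snapped ones fixed.  Standalone fits
(`fitREML`) use four deterministic starts: equal split, residual-dominant,
additive-dominant, and local-variance-dominant.  The fourth start was
added after a test case exposed a boundary mode with nearly all variance
on $\Phi_l$ ($\sigma_a^2 \approx \sigma_\varepsilon^2 \approx 0$) that the
other three miss; REML surfaces for this model are genuinely multimodal.
Convergence uses a gradient tolerance of $10^{-6}$ with a 200-iteration
cap per start plus a value-based stop for the nearly flat
$\sigma_a^2/\sigma_\varepsilon^2$ ridge that appears when $\Psi$ is close
to the identity.

Genome scans fit tens of thousands of alternative models per phenotype,
so the scan path (`genomeScan`, the experiment drivers) uses a
score-adaptive shortcut: at each position the gradient of the restricted
likelihood with respect to $\sigma_Q^2$ is evaluated at the null solution;
when it is non-positive the boundary is a stationary maximum and a single
boundary start suffices (the typical case under the null), otherwise one
warm start from the null solution is climbed with slightly relaxed
tolerances.  On validation draws the scan-path $W$ agrees with the
exhaustive multi-start fit to about $10^{-2}$ in the worst case and
$3\times10^{-4}$ on average, which is negligible against the genome-wide
critical values ($W^* \approx 15$) the scans are compared to.

Degenerate inputs: a constant trait is an error; non-convergence is
flagged on the result (scans continue and report `NA` for such positions
rather than aborting).  When a thresholded $\Psi$ block fails its
Cholesky, diagonal jitter of $10^{-8}$ then $10^{-6}$ is added with a
message; the likelihood evaluator itself retries with a jitter of
$10^{-10}\,\mathrm{Var}$ before giving up.

# Genome-wide multiple testing

Scan statistics at nearby positions are strongly dependent because the
same IBD segments span them.  Standardized statistics $Z_l$ are modeled as
a stationary Ornstein–Uhlenbeck process,
$\mathrm{cov}(Z_{l_i}, Z_{l_j}) = e^{-\alpha|l_i - l_j|}$, restarting
independently on each chromosome; the observed statistics are the squared
positive truncation $W_l = Z_l^2 1\{Z_l > 0\}$ (*modified OU process*).
The correlation between $W$ values at distance $d$ has the closed form

$$f(\rho) = \frac{2\pi\rho^2 + 6\rho\sqrt{1 - \rho^2} +
(2 + 4\rho^2)\arcsin\rho}{5\pi}, \qquad \rho = e^{-\alpha d},$$

derived here from bivariate-normal quadrant moments ($E W = 1/2$,
$\mathrm{Var}\,W = 5/4$) because the typeset source of the expression is
corrupted; the derivation satisfies the exact quadrant identity
$2q(\rho) + 2q(-\rho) = 1 + 2\rho^2$ and is certified against a
$10^6$-draw Monte-Carlo oracle in the test suite before use.

The decay parameter is estimated from null scans
(`estimateAlpha`): for lags $d = 0.1, \dots, 1.0$ cM, all
within-chromosome pairs at lag $d$ are pooled (never across a chromosome
boundary), their sample correlation is inverted through $f$ by bisection,
and $\hat\alpha$ is the slope of the no-intercept, unweighted regression
of $-\log\hat\rho(d)$ on $d$.  Confidence intervals resample chromosomes
with replacement (default 10,000 replicates), pooling per-chromosome
sufficient statistics, with the 2.5th/97.5th percentiles as the interval.

The genome-wide threshold (`genomeThreshold`) simulates the modified OU
process along the scanned genome as a stationary AR(1) sequence per
chromosome ($Z_0 \sim N(0,1)$,
$Z_{k+1} = rZ_k + \sqrt{1 - r^2}\,\eta_k$, $r = e^{-\alpha\,\mathrm{spacing}}$),
takes the 95% quantile of the per-replicate maximum of $W$ over (default)
10,000 replicates as the critical value $W^*$, and converts it to the
per-test threshold $p^* = \tfrac12\Pr(\chi^2_1 \ge W^*)$.  $p^*$ always
lies between the Bonferroni threshold and the nominal level: positive
dependence makes Bonferroni conservative.

# The synthetic-data generator

`simulatePopulation()` drives the msprime coalescent simulator (bundled
python script; chromosomes simulated independently; uniform map implied by
equal per-bp mutation and recombination rates of $10^{-8}$, emitted
explicitly).  The full-scale preset is 5,000 individuals and 30
chromosomes of 100 cM under a three-epoch approximation of a large
outbred (UK-like) population history: deep size 24,000, ancestral size
10,000, exponential growth to 1,000,000 over the last 300 generations.
The exact published demographic parameters are not reproduced here; the
growth epoch is what controls the density of recent (long) IBD, which is
the feature the mapping method consumes.

Desk-scale runs cannot use the full-scale demography unchanged: at a few
hundred samples it leaves only a handful of individuals per position
inside IBD clusters, and the variance-component test then carries almost
no information (its null distribution degenerates far from the boundary
mixture).  The `"scaled"` preset is therefore a constant population of
size 10,000 (the ancestral epoch size) chosen so that a 200-individual sample has roughly the same
*fraction of individuals involved in multi-individual IBD clusters per
position* (about a third at `L = 2, T = 0.25`) as the full-scale study's
1,000-individual samples — that fraction, not the per-haplotype segment
count, governs the information content of each test.  The choice was made
from regime diagnostics (cluster occupancy, block-size distributions)
before the acceptance experiments were run.

Phenotypes follow $Y = X c + g + \sum_l \theta_l q_l + \varepsilon$ with
$g \sim N(0, \hat\Psi)$ drawn by block-wise Cholesky factorization, and
$q_l$ the minor-allele dosage.  Causal regions of 0.05 cM are selected
uniformly among windows containing at least 4 variants of the target MAF
class (common, low-frequency; half designated causal at random) or at
least 8 (rare, ultra-rare; a random quarter causal).  The effect-size rule
is $\theta_l = \sqrt{c/(2\,\mathrm{MAF}_l(1 - \mathrm{MAF}_l))}$ with $c =
0.05$, so each causal variant contributes 0.05 to the trait variance; the
printed source of this rule lacks an unambiguous radical, and the
square-root reading is adopted because per-variant equal-variance scaling
is the standard construction and keeps the power ordering across MAF
classes stable.  The linear reading remains selectable
(`thetaRule = "linear"`).

MAF classes use the bounds common (>10%), low-frequency (1–10%), rare
(0.05–1%), ultra-rare (<0.05% but present).  At desk scale the ultra-rare
bound falls below the sample resolution $1/2N$; it is then raised to
$2.5/2N$ (capped at 0.005), i.e. "at most two copies in the sample", which
preserves the class's meaning: variants that are present but effectively
untypeable.  SNP arrays are built by dropping all variants with MAF < 1%
and all causal variants, then sampling up to 30,000 markers per
chromosome.

The structured fixture generator (`generateStructuredFixture`) emits
cluster fields and kinship tables directly, with ground truth known, so
the test machinery runs in seconds without a coalescent backend.  Its
defaults describe a cohort enriched for close relatives (40% of
individuals in pairs with kinship 0.125 or 0.25): the boundary-mixture
null of the LOD test presumes an interior-identified genome-wide variance
component, and with only a handful of related pairs $\sigma_a^2$ is so
weakly identified that the point mass at $W = 0$ visibly exceeds 1/2 in
finite samples.  This was diagnosed with an independent dense optimizer
(ruling out an optimization artifact) and the fixture regime chosen on
that principle.  Clusters never contain both haplotypes of one individual
(outbred domain).

## What the generators do and do not emulate

The coalescent backend produces realistic IBD length structure,
site-frequency spectra and linkage, but uses a uniform recombination map,
no genotyping error, no phasing error, and independent chromosomes (hence
no cross-chromosome relatedness; the single-variant comparator therefore
omits a relatedness adjustment, which is appropriate for these data and
not for real cohorts).  The structured fixture reproduces only the
cluster/kinship geometry, not haplotype sequences.  Passing tests on these
worlds demonstrate internal correctness and calibration under the model's
assumptions — not robustness to array genotyping artifacts, phasing
error, or fine-scale recombination-rate variation in real data.

# Scan drivers and experiments

`genomeScan` tests every grid point (default spacing 0.1 cM), using the
nearest cluster field when the exact position has none (IBD states change
slowly along the chromosome).  Consecutive positions with identical
partitions share one local matrix and one fit; deduplication plus the
shared null fit (the null model does not depend on position) is what makes
replicate-heavy experiments tractable.  `twoStepScan` runs a coarse 1 cM
pass, takes the top 10 positions per chromosome by ascending p-value,
merges overlapping 1 cM zoom windows, and repeats at 0.1 cM inside them;
the coarse stage uses single-position tests.  The per-position statistics
are identical between stages and to the full scan (selection does not
alter them), which the suite checks.

`type1Experiment` simulates null phenotypes, scans, derives each
replicate's genome-wide threshold from its own scan (decay-parameter
estimate, then the Monte-Carlo max-statistic quantile), and reports
family-wise rejection rates for the OU threshold and for Bonferroni
(0.05 / number of tests).  `powerExperiment` selects a causal region per
replicate, simulates the phenotype, tests the region via the averaged
endpoint matrices against the genome-wide threshold, and runs the
single-variant comparator (minimum p over the region's array markers
against $5\times10^{-8}$).  A replicate counts as detected when the
region test's p-value reaches the threshold.

## Problem sizes used by the packaged experiments

The packaged acceptance experiments run the study at a reduced scale
chosen once: a pool of 200 individuals over 5 chromosomes of 50 cM under
the `"scaled"` demography, scans at 0.1 cM, 80 null-phenotype replicates
for the family-wise error experiment (with the binomial confidence band
evaluated at that replicate count), and 50 replicates per MAF class for
power (per-variant variance 0.25, i.e. the full-scale 0.05 scaled by the
five-fold sample-size reduction so that per-region signals stay at a
detectable order), with per-replicate thresholds from 10,000 Monte-Carlo
max-statistic draws.  Power regions reuse the nearest precomputed scan
fields for their endpoint matrices, the same nearest-position rule the
scan itself uses.  The null-mixture calibration uses the structured fixture at
N = 300 with 2,000 replicates.  Full-scale runs (5,000 individuals, 30
chromosomes, 1,000 replicates) use the same code paths with the default
configuration objects.

# Known limitations

- The likelihood-ratio scan refits the alternative model at every
  position; score-type statistics would be faster but are out of scope.
- Binary traits, gene–environment interaction terms, and inbreeding
  (local matrices with diagonal 2) are not supported.
- The pairwise segment detector is exact for error-free phased data; it
  has no genotype-error tolerance, so its output on real array data will
  fragment segments (the upstream tools it mirrors handle errors).
- Kinship estimation from segments uses genetic (cM) lengths and the
  IBD1/IBD2 decomposition; very close inbred relationships are outside
  its domain.
- The multiple-testing adjustment models statistic correlations as
  stationary along the genome; strong local irregularities (e.g. near
  centromeres of real maps) are averaged over.
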