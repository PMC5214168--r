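---
title: "Multilocus selection scans with popselscan: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilocus selection scans with popselscan: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popselscan)
```

# The problem

A recurring design in plant and animal population genetics contrasts a
small panel of *candidate* genes — here, genes of the kind implicated in a
phenotype such as salt tolerance, sequenced in two closely related species
plus an outgroup — against a set of *reference* loci sampled from the same
chromosomes. Demography (bottlenecks, structure, migration) moves every
locus in the genome; selection moves individual loci. The reference panel
therefore calibrates a genomewide null, and candidate loci are interrogated
with a battery of complementary tests:

* **Diversity outlier scan** — is a candidate's silent-site diversity
  $\pi_{sil}$ or site-frequency-spectrum summary (Tajima's $D$) extreme
  relative to neutral coalescent simulations calibrated on the reference
  loci?
* **$\pi_{T-S}$ differentiation** — is between-species differentiation at
  the locus larger than neutral coalescent variation allows?
* **HKA** — across loci, is within-species polymorphism proportional to
  between-species divergence, as strict neutrality predicts?
* **mlHKA** — a per-locus selection factor $k$ scaling diversity, tested by
  likelihood ratio.
* **MK / Poisson random field** — do replacement (amino-acid-changing)
  sites show an excess or deficit of fixed differences relative to silent
  sites, summarised as a population-scaled selection coefficient
  $\gamma = 2N_e s$ with hierarchical Bayesian sharing across loci?

`popselscan` implements this battery end to end: alignment handling and
site classification, the statistics, the coalescent simulation machinery
behind every null distribution, and a synthetic-data generator with known
truth so each estimator can be validated without any external data.

# Data model

A locus is a gap-aware multiple sequence alignment of phased haplotypes
from one or two species, plus exactly one outgroup sequence, with an exon
annotation (0-based, half-open intervals on alignment coordinates, plus
strand and frame). Minus-strand genes are reverse-complemented at load
time so all downstream code sees the coding strand.

Columns containing an alignment gap in any row are excluded, as are
columns containing an ambiguous base (`N`): a conservative column-wise rule
that keeps site denominators identical across every statistic and across
species subsets of the same alignment. Remaining columns are `coding` or
`noncoding`; coding columns are mapped to codons and receive fractional
synonymous/nonsynonymous site weights by enumerating the three possible
mutations at each codon position under the standard genetic code
(Nei–Gojobori counting) on the *reference haplotype* (the first ingroup
row). Mutations creating stop codons count as nonsynonymous; a reference
codon that is itself a premature stop is skipped with a warning.

Variant effects are judged one variant at a time on the reference codon
background: a variant is synonymous or nonsynonymous according to whether
swapping the two segregating alleles (or the ingroup vs outgroup allele,
for fixed differences) changes the encoded amino acid. "Silent" means
synonymous **plus** noncoding throughout. Tri-allelic columns are retained
as a single segregating site — consistent with the infinite-sites tests
downstream — with the effect taken from the most frequent derived allele;
their positions are recorded for audit.

# Statistics

For a species subset with $n$ chromosomes and $L$ analyzable sites in the
chosen class:

* $S$ — number of variant columns attributed to the class;
* $\hat\theta_W = S / (a_n L)$ with $a_n = \sum_{i=1}^{n-1} 1/i$;
* $\pi$ — mean pairwise difference per site, computed from per-column
  allele counts;
* Tajima's $D$ with the canonical 1989 constants; undefined at $S = 0$
  and propagated as `NA`, never as zero;
* divergence — mean per-site difference between each ingroup haplotype and
  the outgroup, raw by default (matching common DnaSP practice), with a
  Jukes–Cantor option.

**A note on the neutral mean of Tajima's $D$.** Under the neutral
coalescent, $E[\hat\pi] = E[S/a_1] = \theta$, so the *numerator* of $D$ has
exactly zero expectation; the normalisation, however, divides by a random
quantity correlated with the numerator, and the resulting statistic has a
small negative mean (about $-0.08$ to $-0.10$ at $n = 50$, $\theta = 5$,
i.e. roughly a tenth of its standard deviation). The test suite asserts
closeness to zero on the statistic's own scale; an assertion at
Monte-Carlo-standard-error resolution would fail for any correct
implementation, as we verified against an independent coalescent simulator.

**FST.** Differentiation among populations is
$F_{ST} = 1 - \bar H_w / H_t$ summed over analyzable columns, where
$\bar H_w$ is the unweighted mean within-population heterozygosity
($1 - \sum_a p_a^2$ at population allele frequencies, no sample-size
correction) and $H_t$ the pooled-frequency heterozygosity. The uncorrected
form is deliberate: it makes $F_{ST}$ of populations with identical allele
frequencies exactly zero, at the price of a small upward bias when
per-population sample sizes are low — with the unbiased pairwise form the
same configuration is strictly negative. The AMOVA-weighted estimator
produced by Arlequin in analyses of this kind is not reproduced exactly
(its distance model varies by configuration); the permutation machinery is
the same — the
add-one p-value over 10,000 shuffles of sequences among populations by
default. Diversity statistics and $\pi_{T-S}$ keep the standard unbiased
pairwise $\pi$.

# Coalescent machinery

All null distributions flow from a standard neutral coalescent without
recombination (an explicit modelling commitment, not a default): with $k$
lineages the waiting time is exponential with rate $k(k-1)/2$, time in
units of $2N_e$ generations, and $\theta = 4N_e\mu$ per locus, so mutations
fall at rate $\theta/2$ per unit branch length and $E[S] = \theta a_n$.
This convention is pinned by calibration tests ($E[S]$, $E[\pi]$, tree
height and total length against closed forms) because it is the single
most error-prone choice in this literature. Two mutation modes are
provided: Poisson at fixed $\theta$, and exactly-$S$ multinomial placement
conditional on the genealogy (the standard approach for fixed-$S$
confidence-interval simulation). An ms-compatible text writer exposes
replicates to external tools.

# The two scans

**Reference-calibrated outlier scan.** Each null replicate draws one
reference locus uniformly, takes its per-site silent $\hat\theta_W$ and
silent length $L$, simulates a genealogy at the focal sample size, drops
mutations at $\hat\theta L$, and records $(\pi_{sil}, D)$. Resampling
per-locus estimates rather than their mean deliberately propagates
genomewide heterogeneity into the null. A candidate is flagged when its
$(\pi_{sil}, D_{sil})$ point falls outside the empirical 95%
highest-density region of the simulated cloud, computed by density-ranking
the cells of a $50 \times 50$ histogram; marginal percentiles are reported
alongside so the simpler one-dimensional rule can be applied. The
histogram rule needs on the order of $10^4$ null points to be stable —
with substantially fewer, sparsely populated interior cells leave the
accepted region and the scan over-flags; the default replicate count is
$10^4$ (published analyses used $10^5$; both are configurable).

**$\pi_{T-S}$.** For a two-species locus, $\pi_T$ is the diversity of the
pooled sample, $\pi_S$ the mean within-species diversity, and
$\pi_{T-S} = \pi_T - \pi_S$. The null holds the pooled sample panmictic:
each replicate simulates a genealogy of the pooled size conditioned on the
observed total $S$ (no recombination), splits chromosomes into two
pseudo-species of the observed sizes by fixed block (fixed, not random,
for determinism — exchangeability makes the choice irrelevant in
distribution), and recomputes the difference; significance is judged
against the 2.5%/97.5% replicate quantiles. Loci with $S = 0$ are reported
as skipped, not tested.

# HKA and mlHKA

The multilocus HKA test uses the single-species layout forced by the
published analysis's degrees of freedom (10 loci, $df = 9$): per locus,
silent polymorphism $S_i$ within the focal species and silent divergence
$D_i$ to the outgroup. The method-of-moments system
$E[S_i] = \theta_i a_{n_i}$, $E[D_i] = \theta_i (T + 1)$ — the $+1$ is the
ancestral coalescent contribution, with the relative ancestral size fixed
at 1 because no second-species polymorphism enters — is solved by a
monotone one-dimensional root in $T$ (per-locus $\theta_i$ then follow in
closed form). The statistic sums
$(O - E)^2/\mathrm{Var}$ over both cells with
$\mathrm{Var}(S_i) = \hat S_i + \hat\theta_i^2 b_{n_i}$ and
$\mathrm{Var}(D_i) = \hat D_i + \hat\theta_i^2$, and is referred to
$\chi^2_{L-1}$; a parametric bootstrap (coalescent polymorphism, Poisson
divergence, full refit per replicate) gives a simulation p-value that does
not lean on the asymptotic reference.

mlHKA places a Poisson likelihood on the counts,
$$S_i \sim \mathrm{Pois}(k_i \theta_i a_{n_i}), \qquad
  D_i \sim \mathrm{Pois}(\theta_i (T + k_i)),$$
with the selection factor $k_i$ scaling diversity and the
ancestral-polymorphism share of divergence; $T$ is fixed (default 15, the
published value for this species trio, overridable).
Because $T$ is fixed the likelihood separates by locus and
$\hat\theta_i(k) = (S_i + D_i)/(k a_{n_i} + T + k)$ in closed form, so
fitting one free $k$ is an exact one-dimensional profile maximisation in
$\log k$ (grid bracket + Brent polish). The neutral point $k = 1$ is always
evaluated, so a converged free fit can never fall below the nested neutral
fit and the likelihood-ratio statistic is guaranteed non-negative; if a
caller supplies externally produced log-likelihoods in the wrong order,
`lrt()` reports an invalid result with a diagnostic rather than a negative
number — mirroring how the original tooling's failed optimisations surface
in published tables.

# MK tables and the Poisson random field

Per locus, variants are polarized against the outgroup and partitioned
into the $2 \times 2$ layout: silent/replacement $\times$
polymorphic/fixed ($P_s, P_n, D_s, D_n$). The PRF model gives independent
Poisson counts with intensities
$$P_s \sim \theta_s a_n, \quad D_s \sim \theta_s(\tau + 1), \quad
  P_n \sim \theta_r a_n G(\gamma, n), \quad
  D_n \sim \theta_r(\tau + 1) H(\gamma),$$
where $H(\gamma) = 2\gamma/(1 - e^{-2\gamma})$ is the relative fixation
rate ($H(0) = 1$ handled explicitly) and $G(\gamma, n)$ is the relative
expected number of selected polymorphisms observable in $n$ sampled
chromosomes, obtained by integrating the stationary sojourn density
$f(q;\gamma) = (1 - e^{-2\gamma(1-q)}) / ((1 - e^{-2\gamma})\,q(1-q))$
against the sampling factor $1 - q^n - (1-q)^n$ and normalising by the
neutral value $a_n$. The $1/q$ and $1/(1-q)$ endpoint singularities are
removable after multiplication by the sampling factor; adaptive quadrature
with explicit endpoint limits evaluates the integral, cross-checked in the
tests against brute-force Riemann sums to $10^{-6}$.

Two shape facts matter for interpretation and are asserted as tests:
$G$ *increases* toward 2 with positive $\gamma$ (advantageous variants
transit at detectable frequencies), while $H$ grows linearly — so the
polymorphism-to-fixation ratio $G/H$ falls monotonically, which is the
signal the MK contrast exploits; under negative $\gamma$, $G$ falls
monotonically below 1. The divergence weighting between lineages is fixed
at 1: with a single outgroup, fixations cannot be apportioned to branches.

The hierarchical model places $\gamma_i \sim N(\mu_{class}, \sigma^2)$
with one $\mu$ per locus class (candidate vs reference), a flat prior on
each $\mu$, flat priors on the positive $\theta$'s, and $\sigma^2 = 4$ by
default (the original software's hyperparameters are unpublished; the
value is configurable and the results are insensitive for well-measured
loci). The sampler is Metropolis-within-Gibbs: both $\theta$'s and the
class means are conjugate draws (Gamma and Normal), and each $\gamma_i$
takes a vectorised random-walk Metropolis step with $G$ evaluated through
a cached interpolation grid (step 0.05 over $[-25, 25]$, exact quadrature
outside; interpolation error $\sim 10^{-4}$, far below the Monte Carlo
noise of any practical chain). Default desk-scale chains run $10^5$
cycles, $10^3$ burn-in, thinning 10; the original software's $10^7$-cycle
settings are reachable through the same arguments. Acceptance rates
outside (1%, 99%) trigger a warning; a NaN likelihood is a hard error with
state. Loci with all-zero replacement counts are retained — the
hierarchical prior handles them; no pseudo-counts are added. One caveat
discovered during validation and worth keeping in mind: for a *single*
locus fit in isolation with weak counts, the flat $\theta_r$ prior leaves
a $\gamma^{-2}$ right tail on the marginal posterior, whose mean is not
finite; the hierarchical setting (several loci sharing a class mean) is
the supported use, and there the posterior is well behaved.

# The synthetic-data generator

The generator emulates the statistical structure the estimators assume,
at the level of summary intensities rather than forward simulation —
sufficient for validating the estimators and orders of magnitude faster.
Its defaults are the study conditions the package is designed around:
10 candidate + 16 reference loci; 80 and 50 chromosomes in species 1
and 2; candidate loci of 4–9 kb with ~35% coding, reference loci of
0.4–0.7 kb with ~50% coding; per-site silent diversity 0.0034 and 0.0053;
outgroup divergence $T = 15$; 11 and 6 populations per species.

Per locus, a two-species island-model structured coalescent is simulated
(within-deme coalescence, migration at rate `mig/2` per lineage, species
merging into one ancestral pool at $\tau$, an outgroup lineage joining at
$T$). Two calibration choices keep the dial-to-outcome mapping exact:

* the within-species process is time-normalised so the mean pairwise
  coalescence time equals $k \cdot ne_{rel}$ exactly (island-model mean
  pair time is $1 + (1 - 1/d)(d-1)/mig$ before normalisation), so the
  configured per-site $\theta$ translates directly into expected
  within-species diversity while `mig` controls $F_{ST}$;
* the default migration rates (55 and 62) were fixed by direct Monte Carlo
  at the default sample design so realized mean $F_{ST}$ across reference
  loci sits near 0.26 and 0.15 — the analytic island formula
  under-predicts the realized estimator value because the uncorrected
  heterozygosity estimator is upward-biased at 7–8 chromosomes per deme.

The species split is $\tau = 6$ (units of $2N_e$ of species 1), deep
enough that species 2's $1.56\times$ slower coalescent is essentially
complete before the merge; with a shallower split the ancestral pool
truncates deep lineages and realized diversity undershoots the
configured $\theta$.

Selection dials: $k_i$ rescales the within-species time scale of a locus
(diversity scaling, the mlHKA quantity); replacement mutations are placed
with branch-dependent intensity — $\theta_r G(\gamma_i, n)$ on branches
whose mutation would segregate within a species, $\theta_r H(\gamma_i)$ on
branches producing only fixed differences — reproducing the PRF contrast
the MK machinery estimates. Mutations are threaded onto a random ancestral
sequence through an exon layout built from codon families (GTx, TCx, CCx,
ACx, GCx, GGx) whose third positions are four-fold degenerate and whose
first/second positions admit only amino-acid-changing single-base
mutations, so each mutation's intended effect class is realised by
position alone; every position is hit at most once (infinite sites).

What the generator does **not** emulate: intragenic recombination (all
nulls assume none, so this is consistent rather than limiting), indel
evolution and alignment error, sequencing/phasing error, gene conversion,
selection at linked sites, and GC-biased substitution. Passing tests on
synthetic data therefore validate the estimators under the model the
tests themselves assume — they do not certify robustness of the
scientific conclusions to recombination or demographic misspecification
in real data.

# Numerical and design choices

* Coordinates 0-based half-open internally; GFF input converted on read.
* Undefined statistics propagate as `NA` markers, never silently as 0.
* The HKA moment root is solved to $10^{-12}$; degenerate tables (all
  $S = 0$ or all $D = 0$) are flagged as boundary fits rather than
  silently extrapolated.
* All randomness flows from one master seed through named substreams
  (a deterministic string-hash of the stage name), so pipeline stages are
  independently rerunnable and reruns are byte-identical.
* Problem sizes in the shipped tests are desk-scale by design: $10^4$
  replicates for calibration and null distributions, 500 trials for size
  control, 50 datasets for recovery, $2 \times 10^4$-cycle MK-PRF chains.
  The corresponding full-scale settings ($10^5$ simulations,
  $10^7$ cycles) are plain argument changes.

# Known limitations

* The FST estimator is the uncorrected heterozygosity ratio, not
  Arlequin's AMOVA $\Phi_{ST}$; values at small per-population sample
  sizes run high, and permutation p-values — not the point estimates —
  should carry inferential weight.
* The outlier scan's null resamples reference-locus point estimates of
  $\theta$, so estimation noise from short reference loci widens the null
  cloud; with few, short reference loci the scan is conservative.
* mlHKA fixes $T$; misspecifying it biases $k$ multiplicatively across
  loci (the likelihood-ratio contrast between loci is less sensitive).
* The PRF divergence intensity treats all fixed differences as one class;
  without a second outgroup, lineage-specific fixation cannot be modelled.
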