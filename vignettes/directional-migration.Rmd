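---
title: "Directional differentiation and relative migration: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directional differentiation and relative migration: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dirmig)
```

## The model

Symmetric differentiation measures compare two allele frequency vectors
directly. `dirmig` makes them directional through a *hypothetical pool
of migrants*: for populations with frequency vectors $\mathbf a$ and
$\mathbf b$ over a shared allele space, the pool has frequencies

$$f_i(\mathbf a, \mathbf b) = \gamma\sqrt{a_i b_i}, \qquad
  \gamma = \Big(\sum_i \sqrt{a_i b_i}\Big)^{-1},$$

with $\gamma = 0$ (an *empty* pool) when no allele is shared. The
normalized geometric mean is the simplest member of a whole family of
functions satisfying four requirements that the pool concept imposes:
symmetry in the parents; support restricted to alleles present in both
populations (an allele absent from one population cannot have been
exchanged between them); preservation of allele proportions when one
population's frequencies are a scaled copy of the other's on the shared
support (what pure one-way flow produces at neutral loci); and
normalization to a probability vector. Each requirement is enforced by a
property-style test in the package.

The directional statistic for the ordered pair $(i, j)$ is
$b_{ij} = E(\mathbf a_i, f(\mathbf a_i, \mathbf a_j))$, where $E$ is a
symmetric differentiation measure — here Nei's $G_{ST}$ or Jost's $D$ in
their plug-in (biased) vector forms

$$G_{ST} = \frac{|\mathbf a - \mathbf f|^2}{4 - |\mathbf a + \mathbf f|^2},
 \qquad
  D = \frac{|\mathbf a - \mathbf f|^2}{|\mathbf a|^2 + |\mathbf f|^2}.$$

A *low* $b_{ij}$ means population $i$ resembles the pool it shares with
$j$ — the signature of a source — so low values indicate high potential
gene flow $i \to j$. The row is the source, the column the target, and
the worked three-allele example in `README.md` pins this orientation in
the test suite so it cannot silently flip.

Under island-model equilibrium assumptions each statistic maps to a
(relative) migration rate, $c_{ij} = (1/G_{ST} - 1)/4$ or
$c_{ij} = (1 - D)/D$, and the matrix is divided by its largest
off-diagonal entry. Only *relative* rates are reported: the absolute
island-model conversions are too sensitive to equilibrium and
demographic assumptions to be taken literally, while their ranking is
much more robust.

## Multilocus combination

All statistics are computed per locus and only then combined — never on
frequencies averaged across loci. For $G_{ST}$ the multilocus value is
Nei's ratio of sums $\sum_l D_{ST,l} / \sum_l H_{T,l}$.

For $D$ the package's directional engine uses the Jost formula on
locus-averaged heterozygosities,
$D = 2(\bar H_T - \bar H_S)/(1 - \bar H_S)$, rather than a harmonic
mean of per-locus values. The reason is structural, not cosmetic: at
any locus where the focal population is monomorphic for an allele the
partner also carries, the pool equals the focal frequencies *exactly*
and the per-locus $D$ is exactly zero. Such loci are routine in
microsatellite panels. A harmonic mean across loci is annihilated by a
single zero, so with realistic panels both directions of most pairs
would collapse to zero and the directional signal would be destroyed —
in simulation, directional calls under the harmonic rule plateau around
79% where the averaged form reaches 95%+. The harmonic mean (with the
zero-limit convention and an option to drop zero loci) remains
available in `multilocus_combine()` for ordinary pairwise work. Loci
where either member of a pair has no observed alleles are dropped for
that pair; loci with data but an empty pool enter with differentiation
1 (for $D$ this falls out of the formulas with $\mathbf f = 0$; for
$G_{ST}$ the locus is entered with $D_{ST,l} = H_{T,l}$). If *all* loci
of a pair have empty pools both directions are 1 and the pair's
relative migration is 0.

## Numerical choices

* **Zero differentiation.** $b_{ij} = 0$ (a population identical to its
  pool) would make both island transforms infinite. The statistic is
  clamped at `eps = 1e-6` before inversion, so the zero-differentiation
  direction receives the matrix maximum (relative migration 1 after
  normalization) and arithmetic stays finite. `eps` is exposed as an
  argument of `relative_migration()`.
* **Diagonal.** $b_{ii}$ is formally 0, which would become a spurious
  maximal self-migration after the transform; diagonals are stored as
  `NA` and excluded from the normalization maximum.
* **Normalization** is over the full off-diagonal matrix, not per row,
  so all entries share one scale.
* **Degenerate inputs.** All-zero frequency columns (no data for a
  population at a locus) are tracked via observed-copy counts and
  excluded pairwise; a population with no data at *any* locus is an
  error naming it. If every off-diagonal differentiation equals 1 the
  relative migration matrix is all zeros with a warning rather than a
  division error.

## The bootstrap asymmetry test

The resampling unit is the individual (the whole multilocus genotype),
drawn with replacement within each population with the original sample
sizes preserved; this keeps linkage between loci intact and matches
standard genetic bootstrap practice. For each of `n_boot` replicates
(default 1000) allele frequencies, pools, and both directional
statistics of every pair are recomputed. Percentile intervals at
`alpha = 0.05` (probabilities 0.025 and 0.975, quantile method) are
formed per direction on the multilocus statistic — the quantity that is
actually plotted and interpreted — and a pair is significantly
asymmetric when the two intervals do not overlap. The comparison is
made on the differentiation scale; because the island transforms are
strictly decreasing this induces the same ordering as comparing
relative migration. No multiple-testing correction is applied across
pairs. Results are deterministic given `seed`; replicates that lose all
data in a population (possible only with missing data) are redrawn a
bounded number of times.

## What the simulator emulates — and what it does not

`simulate_dataset()` draws each locus independently from the
structured coalescent at stationarity: $n$ demes of $2N$ gene copies,
within-deme pairwise coalescence at rate $1/2N$ per generation, and
backward migration rates $m_{ij}$ (the probability that a lineage in
deme $i$ traces its parent to deme $j$ — note that backward direction
is the mirror of forward gene flow: simulated flow from B into A means
A-lineages migrate into B backward in time). Mutations fall as a
Poisson process at rate $\mu$ per lineage-generation and follow the
unbounded stepwise model (repeat count ±1 with equal probability) from
an arbitrary root of 100 repeats; all statistics are invariant to the
offset. Diploids are formed by random pairing of sampled copies. Demes
that can never exchange migrants are joined at deeply separated times
(gap $5000/\mu$ generations) with a warning, which makes their alleles
effectively unrelated; a hard cap on event counts guards
near-non-ergodic migration matrices. The simulator is validated against
the closed-form stepwise-mutation equilibrium heterozygosity
$H = 1 - 1/\sqrt{1 + 2\theta}$, $\theta = 4N\mu$.

Default parameters are the validation study's conditions: $N = 1000$
diploids per deme, $\mu = 5\times10^{-4}$ (a typical vertebrate
microsatellite rate, giving $\theta = 2$), gene-flow rates
$m \in \{0.00025, 0.005, 0.05\}$ spanning strong structure to
near-panmixia under $F_{ST} \approx 1/(4Nm+1)$, sample sizes 10–100
diploids, 10–100 loci. Two cautions on that anchor: the $F_{ST}$
correspondence is an infinite-allele, mutation-free idealization — with
$\theta = 2$ and stepwise homoplasy the realized equilibrium $G_{ST}$
at $m = 0.00025$ is ~0.15, not 0.5, for any faithful simulation — and
the direction experiments label "correct" by the simulated dominant
direction, ties counting as incorrect.

The simulator deliberately omits: recombination within loci, sequence
or SNP mutation models, unequal deme sizes, non-equilibrium demography
(bottlenecks, founder events, growth), and selection. Passing power
studies on these simulations therefore shows that the method recovers
direction under *equilibrium, neutral, equal-size* conditions; it says
nothing about robustness to recent founder effects or size asymmetries
(see limitations).

## Problem sizes used in the shipped checks

The package's own validation runs are scaled for a desktop: 200
coalescent replicates per power scenario (the original study used
1000), which bounds the Monte-Carlo half-width of a percent near 95% to
about ±3 points; the five-deme directed-ring demonstration (circular
stepping stone, $m = 5\times10^{-4}$) uses 50 loci and 50 diploids per
deme — the center of the power-study grid — with 1000 bootstrap
replicates and 20 simulation replicates. At that scale the
population-level relative migration of indirect (two-step) ring edges
is ≈0.39–0.45, just below the 0.5 filter threshold, so individual
replicates occasionally retain one such edge or miss one ring edge; the
stable property, and the one the test asserts, is that all five
simulated edges are recovered and every retained edge points along the
simulated flow (directly or one hop ahead). Indirect flow through
intermediate demes is genuine in a ring that has been exchanging
migrants for many generations, which is why a filter threshold is
needed to isolate the direct pattern at all.

## Known limitations

* **High gene flow.** At $m = 0.05$ ($F_{ST}\sim0.005$) the
  homogenizing effect of migration leaves little directional signal;
  correct-direction rates stay well below the levels reached at
  moderate flow, improving only slowly with sample size and locus
  count.
* **Founder effects and shared history.** The method reads private and
  low-frequency alleles as evidence of absent gene flow. A recently
  founded population shares most of its (reduced) allele set with its
  source while the source keeps many private alleles — a pattern the
  method can misread as strong asymmetric migration from the founded
  population toward the source. Interpretation in systems with known
  colonization history requires care.
* **Unequal population sizes.** Allele frequency impact is not weighted
  by deme size; with strongly uneven sizes the relative migration
  values are hard to interpret. Size- or reproductive-value-weighted
  pools are a natural extension but are not implemented.
* **Relative, not absolute.** The island-model transforms are used only
  up to the matrix maximum; no absolute $N_e m$ should be quoted from
  these outputs.
* **Rare-allele sampling.** Low-frequency alleles are underestimated in
  small samples, which can slightly inflate migration estimates; since
  the bias applies to all populations alike, the *relative* values are
  less affected.
* The effective-migrant statistic that blends $G_{ST}$ and $D$
  information (Alcala and co-workers) is a documented extension point;
  only $G_{ST}$ and $D$ are implemented here.
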