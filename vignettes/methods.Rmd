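---
title: "Models and methods behind msatclones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind msatclones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msatclones)
```

# The biological model

Obligately parthenogenetic lizard lineages of hybrid origin start life as
an F1 between a maternal and a paternal bisexual species. That founding
genotype is "frozen": barring mutation and gene conversion, every
descendant carries one allele from each parental gene pool at every
locus. Three measurable consequences drive everything in this package:

1. **Heterozygote excess.** Because the parental pools differ, the
   founder is heterozygous nearly everywhere, and clonal reproduction
   preserves this, so observed heterozygosity (OH) exceeds the
   Hardy–Weinberg expectation (EH) computed from the lineage's own allele
   frequencies.
2. **Clonal redundancy.** Most individuals of a lineage share one or a
   few multilocus genotypes; variation within a lineage reflects
   stepwise microsatellite mutation and loss of heterozygosity (LOH),
   not recombination.
3. **Genotype sharing across species is informative.** If two nominal
   parthenogenetic species carry the same multilocus genotype, either
   they share a founding hybrid or the genotype was assembled twice
   independently. The probability of the latter can be computed from the
   parental allele frequencies, and it shrinks geometrically with the
   number of loci involved.

# Formation and coincidence probabilities

Let $p_{li}$ be the frequency of allele $i$ at locus $l$ in the paternal
bisexual population and $q_{lj}$ the corresponding maternal frequency.
A hybrid founder receives one paternal and one maternal gamete, so for a
heterozygous locus with alleles $i \ne j$ the per-locus formation factor
is

$$f_l = p_{li} q_{lj} + p_{lj} q_{li},$$

the sum over the two possible parental phases. Unlinked loci multiply:
the probability of a multilocus genotype $L$ over $n$ loci is
$P_{(L,n)} = \prod_l f_l$, equivalently a sum over all $2^n$ gamete-phase
assignments. `hybrid_formation_prob()` implements the factorized product;
`enumerate_formation_prob()` implements the $2^n$ enumeration and exists
purely as an independent oracle — the test suite checks the two agree to
$10^{-12}$ on a thousand random frequency draws.

**Homozygous loci.** A homozygous locus $i/i$ in a hybrid clone admits
two readings. Under random union both gametes must carry $i$:
$f_l = p_{li} q_{li}$. The conservative reading treats the homozygosity
as *post-hoc conversion*: the founder was heterozygous and one of its two
founding alleles — either with equal probability — was later retained,
giving

$$f_l = \frac{p_{li} + q_{li}}{2}.$$

Since $(p+q)/2 \ge pq$ always, conversion mode never understates the
coincidence probability; it is the default (`hom_mode = "conversion"`).

**Coincidence.** Independent origins are independent trials: the
probability that the same genotype is formed in each of $k \in \{2, 3\}$
lineages is the product of the per-lineage formation probabilities,
reducing to $P^k$ when the lineages share parental pools. The
implementation accepts distinct parental pairs per lineage because real
pairs of parthenogens can have different maternal ancestors; supplying
the same pair twice recovers plain squaring exactly.

**Idealized curves.** `theoretical_curves()` evaluates the four standard
illustration scenarios with every allele frequency set to a common value
(default ½): two unisexuals (all factors ½ per locus, squared), a
parthenogen vs a bisexual population in HWE (formation times
$\prod 2pq$ or $\prod p^2$), and two parthenogens via conversion. The
bisexual-comparison compositions are this package's documented reading:
formation probability multiplied by the Hardy–Weinberg genotype
frequency of the same genotype in the bisexual population.

**Triploid gametes.** The probability that a triploid's meiosis passes
all univalents to one pole — producing a balanced gamete that could seed
a new diploid clonal lineage after a backcross — is $0.5^{x-1}$ for
haploid chromosome number $x$; `triploid_balanced_gamete_prob(19)`
returns $3.8147\times10^{-6}$, i.e. one in $2^{18} = 262{,}144$.

# Distances and clonal statistics

**Bruvo distance.** For two alleles separated by $x$ repeat units,
$d = 1 - 2^{-|x|}$. Allele sizes in bp are converted to repeat counts via
per-locus motif length and an optional flank offset
(`to_repeat_units()`); sizes ≥ 0.25 repeat units off the ladder are
flagged. For diploid genotypes the per-locus distance is the minimum over
the two one-to-one allele pairings of the mean allele distance (the
minimal-assignment variant; no polyploid genome-addition machinery is
needed because the genotyped individuals are diploid), and genotype
distance averages over commonly scored loci (pairwise deletion —
defensible here because individuals carry at most three missing loci).
Pairs with no commonly scored locus are flagged `NA`, never silently 0.

**Minimum spanning networks.** Individuals are collapsed to unique
multilocus genotypes (node size = multiplicity), an MST is built, and
every non-tree edge whose weight ties the maximum-weight edge on the MST
path between its endpoints (relative tolerance `tie_tol = 1e-9`) is
retained, so equally good alternative connections are not hidden by an
arbitrary tie-break. Node and edge orderings are lexicographic, making
network files byte-reproducible.

**Neighbor joining.** `nj_tree()` delegates the agglomeration to
`ape::nj` — a faithful, widely validated implementation — and adds the
package's contract on top: negative branch lengths are clamped to zero
with the deficit shifted to the sister branch (preserving tip-to-tip path
lengths), and undefined distances are a hard error with advice rather
than silent imputation.

**Rarefied allelic richness** uses hypergeometric rarefaction to a
common number of gene copies $g$:
$AR_l = \sum_a [1 - \binom{n-n_a}{g}/\binom{n}{g}]$. The default $g$ is
the smallest per-locus scored copy count across the compared groups —
the standardization size is otherwise a free choice, and comparability
across groups is what matters.

**Heterozygosity.** EH uses the small-sample correction
$\frac{n}{n-1}(1-\sum p^2)$; a locus scored in fewer than two
individuals is flagged undefined rather than contributing 0, because a
zero would masquerade as information. Overall homozygosity (`hoz`) is a
pooled per-call proportion, so `OH_locus + hoz` need not equal 1 exactly
when loci differ in scoring depth.

**Clone census.** Distinct-genotype counts follow the clonal-census
convention that an individual with any missing call is its own genotype
class — missing data could hide a real difference, and for census
purposes the conservative direction is to split, not lump. The distance
between the two most common genotypes depends on a tie-break when clone
frequencies tie; ties are broken by lexicographic genotype key and
therefore reproducibly.

**Shared-genotype discovery** enumerates all locus subsets up to
`max_loci = 6` (the deepest overlap worth reporting in panels of ten
loci; $\sum_{k\le6}\binom{10}{k} = 847$ subsets is cheap) and keeps
genotypes carried in ≥ 2 groups at carrier frequency ≥ `min_freq = 0.05`.
Carrier frequency is carriers over individuals *scored at all subset
loci* — individuals missing a subset locus leave the denominator, which
is the convention implied by carrier/scored ratios in published tables.
Non-maximal hits (a genotype that is just the restriction of a reported
longer genotype in the same groups) are suppressed. Group-mean
shared-allele proportions exclude undefined pairs rather than
zero-filling them.

# The synthetic-data generator

The generator states one world and keeps it:

* **Panel shape** (`simulate_community()`): 7 parthenogenetic groups
  (sample sizes 44, 29, 27, 17, 19, 14, 15), 4 maternal populations and
  2 paternal species, 10 loci with di-/tetranucleotide motifs, per-call
  missing rate 0.124 — the shape of a real community-scale STR study of
  hybrid parthenogens. Two sister pairs share a founder (one pair
  diverged further by backcrossing), three lineages are independent.
* **Parental pools** are drawn from symmetric Dirichlet frequencies on
  ladder-spaced allele sizes; maternal and paternal pools sit on
  disjoint ladder ranges, the idealized signature of well-diverged
  parental species, so founders are heterozygous everywhere. Real
  parental species share some alleles; a green test on this generator
  therefore establishes the machinery, not robustness to allele-pool
  overlap.
* **Clonal propagation**: each sampled individual descends independently
  from the founder (star genealogy — no shared drift within a lineage),
  for `G = 50` generations by default, with per-locus per-generation
  stepwise mutation `mu = 0.005` and conversion `conv = 0.005`. The
  literature's per-locus mutation estimate for these markers reaches
  0.1428 per generation, but that is an upper estimate from highly
  mutable loci; 0.005 keeps clones recognizable over 50 generations
  (expected ~22% of loci touched), which is what the empirical clone
  frequency spectra look like. No conversion-rate estimate exists; 0.005
  is a deliberate free-parameter default explored explicitly in tests.
* **Mutation model** is strict single-step SMM (±1 repeat unit, equal
  sign probability), the field default and the model under which Bruvo
  distance is interpretable.
* **Conversion** makes a heterozygous locus homozygous for one of its
  alleles (paternal allele kept with probability `conversion_bias`,
  default 0.5); converting a homozygous locus is a no-op. This is
  whole-locus LOH, not tract-level gene conversion.
* **Reproducibility.** All stochastic operations take explicit integer
  seeds and use R's Mersenne–Twister. A counter-based generator was
  considered (it parallelizes better) but no such generator ships with
  base R or the declared dependencies, and R's default RNG is already
  contractually stable across platforms and versions for a fixed seed,
  which is the property the tests rely on. Every mutation/conversion
  event is logged and `replay` of the log reproduces the emitted
  genotypes exactly.
* **Missing data** are masked per call at the nominal rate, with an
  individual's mask redrawn if it would exceed the 3-missing-locus cap;
  this truncation pulls the realized missing fraction slightly (≈ 0.8
  percentage points) below the nominal rate, which the tests account
  for.

# Numerical and design choices

* Rarefaction binomials are computed in log space (`lchoose`) to avoid
  overflow at large copy numbers.
* Frequencies are stored as exact ratios of integer counts; sum-to-one
  is asserted at $10^{-12}$.
* Alleles absent from a parental frequency table yield formation
  probability 0 *with a machine-readable flag* rather than an error: a
  zero sampled frequency does not prove ancestral absence. (A
  pseudo-frequency smoothing option was considered and rejected for the
  default because it silently changes reported probabilities.)
* MSN tie tolerance is relative ($10^{-9}$) plus the same absolute
  epsilon for zero-weight edges.
* The pipeline (`run_pipeline()`) performs no multiple-testing
  adjustment on the many genotype × locus-subset combinations examined —
  coincidence probabilities are reported raw, with the number of
  combinations logged so a reader can adjust externally.
* The pipeline's coincidence stage pools the paternal species by sample
  size (`pool_groups(..., "by_sample")`) and uses each parthenogen's own
  maternal population; equal-weight pooling is exposed because the
  choice is not forced by theory.

# Known limitations

* Diploids only. Triploid backcross products are summarized by the
  balanced-gamete probability, not simulated cytogenetically.
* No coalescent history for the bisexual species: parental frequencies
  are inputs. Consequently "parental" frequencies estimated from
  present-day samples stand in for the (unknowable) frequencies at the
  time of hybridization — the same caveat the coincidence argument
  itself carries.
* The enumeration oracle is exponential by design and refuses more than
  20 loci.
* Bruvo distance assumes strict ladder spacing; off-ladder alleles are
  rounded (and flagged), which can understate distances for imperfect
  repeats.
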