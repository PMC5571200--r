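---
title: "Methods: haplotypes, AMOVA, tag homology and clock dating in seriolapop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotypes, AMOVA, tag homology and clock dating in seriolapop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seriolapop)
```

`seriolapop` implements the marker analyses used to ask whether Pacific
yellowtail kingfish (*Seriola lalandi*) form one species or several recently
diverged populations: mtDNA COI haplotype structure, microsatellite
diversity, SNP/DArT marker screening, hierarchical AMOVA, and
molecular-clock dating. This vignette explains the statistical models, the
parameters that matter, the design choices that were genuinely open, and
what the synthetic-data generators do and do not emulate.

## Haplotype tables and diagnostic sites

A `haplotype_table` is the in-memory form of a printed "variable sites of
haplotypes" table: the 1-based positions of the polymorphic columns, a
reference state row, per-haplotype states at those columns, and
per-population copy counts. `collapse_haplotypes()` and `expand_table()`
are mutual inverses on haplotype content, which lets a published table
drive every downstream analysis without access to the deposited sequences.
The package ships such a table for the 604 nt COI fragment of 244 Pacific
kingfish (15 haplotypes, 28 variable sites, regions NW Pacific / NE
Pacific / South Pacific). Per-country compositions inside the NE and South
Pacific regions were never published, so the packaged table resolves
populations at region level; the NW Pacific region is the single Japanese
population, which is why NW-level quantities (e.g. its haplotype
diversity) are exactly recoverable while per-country diversity inside the
other regions is not.

Two conventions were open and are fixed as follows. The reference row of a
collapsed table is the first haplotype in input order (a published table
keeps its own reference row, which the fixture stores explicitly), and
positions are 1-based relative to the trimmed fragment. `N` and `-` are
treated as missing everywhere: they never count as states when deciding
whether a column is polymorphic, and a diagnostic-site query errors rather
than guesses when a focal group has only missing data at a site.

A site is *diagnostic* for a group when every sampled sequence of the
group carries one and the same state and no sequence outside carries it —
fixation inside, absence outside. On the packaged table the three queries
(Northern vs Southern Hemisphere, NW vs rest, NE vs rest) return 5, 5 and
3 sites.

`regenerate_from_frequencies()` converts printed haplotype frequencies
back into a sequence multiset. Counts are `round(f * n)`; when rounding
does not conserve `n`, a largest-remainder adjustment is applied with
first-listed precedence (the earliest-listed haplotype keeps its copy on
ties). This reproduces, e.g., 233 copies from an 80% haplotype in a sample
of 291, and resolves `{0.5, 0.5}` of 7 as `{4, 3}`.

## Diversity estimators

Haplotype (gene) diversity uses Nei's unbiased estimator
$h = \frac{n}{n-1}\bigl(1 - \sum_i p_i^2\bigr)$ with Nei's
sampling-variance formula for its SD. Nucleotide diversity is the
DnaSP-style unweighted average over all $\binom{n}{2}$ sequence pairs,
$\pi = k / L$, computed from haplotype counts (the table-weighted and
expanded-alignment computations agree to machine precision, which is
tested). Published per-population $\pi$ values for this system are not
asserted anywhere: the printed value for the Japanese sample (0.060%) is
not matched by any standard estimator given its haplotype composition
(all give 0.053–0.057%), so those table cells are treated as
non-reproducible.

Codominant summaries per locus are the allele count $N_a$, observed
heterozygosity $H_O$, Nei's unbiased expected heterozygosity
$H_E = \frac{2n}{2n-1}\bigl(1-\sum_a q_a^2\bigr)$ (also reported as gene
diversity $g$), and $F_{IS} = (H_E - H_O)/H_E$, averaged across loci. A
monomorphic locus has undefined $F_{IS}$; it is reported as 0 with an
explicit flag rather than dropped. Missing means either allele missing;
the individual is excluded locus-wise.

The Hardy–Weinberg test is a seeded Monte-Carlo allele-shuffling test: the
$2n$ alleles of a locus are re-paired at random, and the two-sided
statistic is the absolute deviation of the heterozygote count from its
exact permutation expectation
$E = n\bigl(1 - \sum_a \frac{n_a(n_a-1)}{2n(2n-1)}\bigr)$. The p-value
uses the add-one rule and counts ties as extreme, so it is conservative on
a coarse lattice; with a few hundred individuals or more the lattice is
fine and the null p-values are close to uniform, which the test suite
checks by simulation (1,000 loci of 2,000 individuals, 199 permutations
each — sizes chosen so the lattice spacing is small relative to the
Kolmogorov–Smirnov band).

## Distances, AMOVA and F_ST

All differentiation statistics operate on pairwise distance matrices.
Sequences use the count of differing non-missing sites; dominant marker
rows use simple mismatch; SNP genotype rows use summed genotype
differences. For codominant genotypes the default unit is the **allele
copy**, not the individual: the matrix has $2N$ rows and the two stored
copies of each individual enter as separate units (the sums of squares are
invariant to their arbitrary phase). This choice is deliberate: a
two-level AMOVA on diploid *genotype* distances estimates $2F/(1+F)$
rather than $F$, because the squared difference of population means enters
with both allele copies while the within variance is per-allele. With
allele units the Phi-statistic recovers the Balding–Nichols $F_{ST}$
cleanly, which is verified by parameter-recovery simulation. The
individual-level 0/1/2 allele-mismatch distance remains available via
`unit = "individual"`.

`amova()` implements the Excoffier-style decomposition from squared
distances. By convention the supplied matrix is treated as already squared
(`squared = TRUE`), which is the right reading for mismatch counts — each
differing site contributes 1 to the squared Euclidean distance of an
indicator embedding. Variance components come from the method-of-moments
equations for the two-level (populations) or three-level (regions /
populations / individuals) design; individually negative components are
reported as computed, and percentages are relative to the summed
components, so they total 100 even then. When the data are completely
homogeneous (all distances zero) the Phi ratios are 0/0; they are reported
as 0, reading "no structure" rather than propagating NaN.

Permutation significance follows the standard schemes: individuals across
the whole design for $\Phi_{ST}$, individuals among populations within
regions for $\Phi_{SC}$, whole populations among regions for $\Phi_{CT}$;
1,000 permutations by default, with a mandatory seed and the add-one rule
$(b+1)/(B+1)$, so p-values are never exactly zero and their null
distribution is uniform on the achievable grid (also verified by
simulation). `pairwise_fst()` runs the two-population analysis for every
pair; estimates are not truncated at zero. A permutation floor of
$1/(B+1)$ is only reachable when group sizes make a tie with the observed
partition improbable; with very small groups (a handful of individuals)
the achievable p is bounded away from the floor, which is a property of
permutation tests, not of the implementation.

## Marker QC and population-unique markers

The QC chain applies, in order: (1) drop markers missing in more than 5%
of the samples of *any* population (inclusive at exactly 5%); (2) drop all
markers sharing a sequence-tag locus with another marker; (3) drop samples
missing more than 100 marker calls (strict: exactly 100 is kept). The
order is the order the rules are stated in; each filter is idempotent and
the chain is a fixed point. Thresholds are configurable.

A marker is unique to a focal group when present in at least 95% of the
focal individuals (pooled) and in at most 5% of the individuals of *every
other population, checked per population*. The per-population form of the
5% condition is a deliberate design choice: pooling the remainder would
allow a marker fixed in a very small non-focal population (the Japanese
DArT sample had two fish) to slip under the 5% slack of a large pooled
remainder, making "unique" sets mutually inconsistent. Fractions use
non-missing denominators; a marker with no called focal individuals is
ineligible; the absence polarity applies the same rule to inverted calls.

## SNP-tag homology and clock dating

Each retained genotyping-by-sequencing marker is a single SNP on a
consensus tag of fixed length $l$ (70 bp here). For a pair of diploid
samples compared at $n$ co-called markers, the tag-sequence homology is

$$H_s = 1 - \frac{\sum s_v}{2\,n\,l},$$

where $\sum s_v$ counts varying SNPs across both alleles: opposite
homozygotes contribute 2, heterozygote vs homozygote 1, identical
genotypes 0. The $2n$ denominator counts the aligned allele pairs (two per
marker); missing markers drop out of numerator and denominator alike.
Population-level dissimilarity ($1 - H_s$, in percent) is the mean over
all unordered sample pairs within or between populations. Unordered pairs
are a choice (the symmetric mean); the alternative ordered-pair reading
changes nothing for between-population cells and is not distinguishable
for within-population cells either, since the statistic is symmetric in
the pair.

Sequence divergence between population groups is the count-weighted mean
p-distance (1 − identity) over all cross-group sequence pairs — plain
p-distances, not K2P, since the published divergence percentages are
defined that way (model-corrected distances belong to tree building, which
is out of scope). `clock_date()` converts percent divergence to time at a
constant rate, by default the conventional mtDNA clock of 2% per million
years, so a 2.43% maximum between-hemisphere divergence dates to about
1.2 MYA; `rate_ratio()` reports the mtDNA/nuclear rate ratio (about 4 for
this system, versus ~10 in primates).

## Synthetic data: what it emulates, what it does not

The three generators draw from independent streams of one master seed and
record ground truth, so every analysis stage has a closed-loop test.

* `simulate_coi()` emulates the *structure* of the real haplotype table:
  a root sequence, planted fixed differences per partition (defaults 5
  hemisphere / 5 NW / 3 NE), and low-frequency private haplotypes per
  region (about one mutated site each at the default
  `mu = 0.003`). Haplotype copies are sampled multinomially with every
  haplotype guaranteed one copy, so planted diagnostics are recoverable by
  construction. Default sample sizes mirror the study design
  (15/26/76/50/48/29 across Japan, USA, Mexico, Chile, NSW, SA; 604 nt).
  It is a spectrum-level generator, not a coalescent: no recombination-free
  genealogy, no mutation-rate heterogeneity, no sequencing error.
* `simulate_msat()` draws ancestral allele frequencies from a flat
  Dirichlet and population frequencies from the multi-allele
  Balding–Nichols model at `fst_target` (default 0.2, 9 loci, 8 alleles),
  with HWE genotypes. It emulates drift-driven differentiation only — no
  stepwise mutation, so R_ST-style analyses are out of scope by design.
* `simulate_markers()` mirrors the DArTseq design (Japan 2, Mexico 38,
  Chile 20, NSW 48, SA 44; 70 bp tags) with hierarchical Balding–Nichols
  background divergence (between-hemisphere F = 0.2, within F = 0.05,
  intermediate ancestral frequencies) and plants 3/3/20/2
  population-unique markers for Japan/Mexico/Northern/Southern, plus
  high-missingness markers and samples and multi-marker tags so each QC
  rule fires. The moderate background divergence is what keeps the
  planted-recovery guarantee: strong hemispheric F pushes Balding–Nichols
  frequencies to the boundaries and generates accidental fixed markers,
  which real, QC-filtered marker panels of this size did not show.
  Single-population planted sets leave one focal individual as a
  non-carrier when the group is large enough, so a Mexico-only marker does
  not simultaneously clear the pooled 95% bar of the Northern group it
  belongs to.

Passing closed-loop tests on these generators shows the estimators recover
the structure they model — categorical fixed differences, beta-distributed
frequency divergence, block missingness. They say nothing about alignment
error, null alleles, paralogous tags, or marker ascertainment in real
pipelines.

## Numerical and scale choices

Simulation-based tests use the smallest sizes at which the checked
property is stable: parameter recovery at 2 × 50 diploids × 500 biallelic
loci, null-uniformity of AMOVA p-values at 200 replicates of 16
individuals, HWE null-uniformity at 1,000 loci of 2,000 individuals with
199 permutations. Reported precision follows the conventions of the
source tables: divergences to 2 decimals of a percent, clock dates to 1
decimal of a MY.

## A worked reference run

```{r}
rep <- reproduce_reference()
rep$comparison
round(unclass(rep$divergence), 2)
round(rep$clock_mya, 1)
```

The reproduction pipeline recovers 15 haplotypes, 28 polymorphic sites,
diagnostic splits 5/5/3 and a NW Pacific haplotype diversity of 0.343 from
the packaged table, and dates the maximum between-region divergence
(about 2.3% between NW and South Pacific at region level) to roughly 1.2
million years under the 2%/MY clock.

## Known limitations

Region-level pooling in the packaged table means per-country statistics
for the NE and South Pacific cannot be recomputed from it. AMOVA assumes
the supplied (squared) distances are Euclidean-embeddable; mismatch counts
are, but user-supplied matrices are not checked. The HWE test's
conservative tie handling matters for small samples. No tree building,
Bayesian dating, or Bayesian clustering is provided — those analyses need
genuinely different machinery and are deliberately out of scope.
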