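---
title: "Models and design of the sexrec analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design of the sexrec analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexrec)
```

This vignette explains the statistical models behind each analysis stage,
the tunable parameters and their defaults, what the synthetic-data generator
does and does not emulate, and the design decisions taken where the methods
left genuine choices open.

## The biological setting

In species with young XY systems the sex chromosome pair is homomorphic:
X and Y differ at scattered nucleotide positions inside a region where
X/Y recombination has ceased in males (the Y stratum), while the rest of
the pair still recombines. Three independent data types reveal such a
system: male and female sequencing pools diverge in allele frequency over
the stratum; a pedigree shows suppressed male recombination there; and
expressed Y alleles mark genetically male individuals in RNA-seq. The
package implements all three, plus downstream contrasts of diversity and
repeat content between the male-only and female-only recombining
territories, and a molecular clock for the stratum age.

## Pool-seq delta allele frequency

Each pool is modelled as reads drawn binomially from the pool allele
frequency, with Poisson depths around the mean. For a SNP with allelic
depths (ref, alt) per pool, `compute_daf()` forms the alternate-allele
frequencies and their absolute difference dAF, excluding SNPs below the
per-pool depth floor (`min_depth = 10`). `window_scan()` averages dAF in
non-overlapping windows (default 500 kb; the terminal partial window is
kept), computes the genome mean and SD *over window means* (matching the
horizontal reference lines of a window-level Manhattan plot, and keeping
the flag threshold insensitive to per-SNP noise), flags windows with
`Z >= 3` and ranks chromosomes by maximum window mean. Window means are
unweighted across SNPs; depth weighting is available behind a flag.

`extract_sexlinked()` implements the sex-linked SNP filter: `dAF > 0.40`
with the female pool fixed for one allele. "Fixed" is the literal observed
frequency 0 or 1 after the depth filter; a tolerance argument exists but
defaults to off. At 30–100x depth this filter is deliberately conservative:
a true Y-linked SNP has male-pool frequency exactly 0.5 (every male is X/Y
heterozygous), and the binomial probability of observing `dAF <= 0.40` at
depth d is non-negligible until d is several hundred (about 2.8% at d = 100).
Recovery of the Y-stratum truth set therefore saturates only in the deep
or exact-depth limit; this is a property of the filter, not of the
implementation.

## Genetic sexing from expressed alleles

`build_allele_ratio_matrix()` turns expressed allele counts at sex-linked
SNPs into per-sample alt-allele (Y-allele) fractions. Cells without
coverage are *missing*, not zero — otherwise coverage dropouts would pull
XY samples toward the XX cluster. SNPs where one allele is never observed
in any sample are dropped, since they cannot separate the groups.
`assign_genetic_sex()` clusters samples by average-linkage hierarchical
clustering on Euclidean distances computed over pairwise-complete entries
(rescaled to the full SNP dimension), cuts the tree at two groups and
labels as XY the group with the higher mean Y-allele ratio; the difference
of group means is returned as a confidence measure. The procedure is
invariant to row and column permutations.

## Differential expression between genetic sexes

`de_scan()` normalises to counts-per-million and tests per gene on the
log2(CPM + 1) scale with a two-sided Student t-test (Welch behind a flag).
Testing on the log scale is the minimal choice that makes the test
calibrated when expression noise is multiplicative (log-normal), which the
generator's null genes are; the acceptance suite verifies a 5% type-I rate
on 2000 null genes. Genes constant across all samples get ratio 0 and
p = 1; p-values are floored at the smallest positive double so the
`p in (0, 1]` contract holds even for degenerate zero-variance contrasts.
No multiple-testing correction is applied to the ranking; a
Benjamini–Hochberg column is emitted alongside.

`call_allelic_imbalance()` retains SNPs where both alleles are seen (>= 1
read) in at least `ceiling(6/7 n)` of the XY samples and flags those whose
higher-count allele is identical in every informative sample, ties breaking
consistency. Note the null behaviour: a perfectly balanced SNP shows a
consistent sign in all seven samples with probability 2(1/2)^7 ~ 1.6%
*independent of depth*, so over hundreds of tested SNPs a handful of
chance calls is expected; the tests therefore assert recovery of truly
imbalanced spike-ins rather than absence of chance positives.

## Crossover detection and sex-specific maps

Markers are taken in fixed assembly order; no de-novo ordering or
genotype-likelihood phasing is performed (the package consumes phased
grandparental-origin vectors, from the generator or an external phaser).
`detect_crossovers()` records a phase switch only when the new phase is
supported by at least `min_support = 2` consecutive informative markers,
the standard guard against genotyping-error singletons; missing calls are
skipped. A crossover is therefore undetectable only when it sits within
`min_support` markers of a chromosome end or of a second crossover — at
100-kb marker spacing a negligible fraction of events.

`build_sex_maps()` converts events to per-interval map distance
`100 x events / meioses` cM per parental sex and accumulates along the
chromosome. No Haldane/Kosambi mapping function is applied: with dense
markers and short intervals, recombinant fractions are additive to
excellent approximation, and the quantity of interest is the landscape,
not long-range map distance. `cumulative_curves()` rescales each sex's map
to its total, the standard visualisation of heterochiasmy.

## Region classification (FRR/MRR/BR/NR)

`classify_regions()` computes per-window (500 kb) male and female rates in
cM/Mb and classifies each window: NR when both rates are below
`eps_cm_per_mb = 0.5`; FRR or MRR when one sex carries at least
`one_sex_frac = 0.9` of the summed rate; BR otherwise. Two smoothing steps
deal with Poisson sparsity of crossovers — at 90 meioses and ~3 cM/Mb a
500-kb window inside a genuinely recombining region still shows zero
events ~20% of the time:

* no-event runs of up to `max_nr_gap = 4` windows flanked by one class are
  absorbed into it (a long NR run is still emitted as NR);
* at each FRR|MRR junction the boundary is placed inside the gap between
  the two regions' nearest events at the point dividing it in inverse
  proportion to the adjoining event rates, then snapped to the window
  grid. Under exponential waiting distances on both sides this estimator
  is unbiased, and its error exceeds one window only when an
  exceptionally long event gap spans the true boundary (probability well
  under 1% per junction at the default study scale).

A terminal-window guard drops cM from chromosome-end windows whose rate
exceeds 10x the chromosome median, the usual protection against map-end
inflation; it is configurable and disabled with `prune_terminal = Inf`.
`region_rate_stats()` summarises extents, per-class own-sex rates, the
MRR/FRR rate ratio and centromere-in-FRR coincidence.

## Windowed nucleotide diversity

Per-site heterozygosity from read counts uses the unbiased estimator
`He = 2 c1 c2 / (d(d-1))`, whose expectation is 2p(1-p) under binomial
read sampling at true allele frequency p; sites need MQ >= 20 and depth
in [10, 50] (the upper bound screens collapsed repeats; set
`max_depth = Inf` for the coverage-limited variant). Window diversity
divides the summed He by the number of *passing sites* by default, so
depth dropouts do not deflate the estimate; division by window length is
available via `per_bp = TRUE` — both conventions exist in the literature
and the default is the per-covered-site reading. Sites with more than two
alleles are expected to be reduced upstream to their two most frequent
counts (sequencing error dominates third alleles at pool-seq depths).
`contrast_regions()` joins windows to region classes by midpoint and
reports per-class distributions, per-chromosome log2 M-values and the
genome-level MRR/FRR fold. `liftover_contrast()` classifies another
species' windows through a paired-interval map (linear interpolation
within pairs, reverse-oriented pairs supported), assigning the reference
class covering the majority of the mapped footprint; ties or unmapped
windows are excluded.

## Repeat densities

`parse_repeatmasker()` reads the standard `.out` dialect, taking the text
before the first `/` of the class/family column as the repeat class.
Overlap-flagged rows are retained: densities, not copy numbers, are
measured. `window_density()` merges overlapping elements *within* a class
before counting coverage (so duplicated hits cannot exceed a window), but
keeps classes as independent tracks; elements spanning window boundaries
contribute proportionally. Z-transformation is per class over all windows
(mean 0, SD 1 by construction; classes with zero variance are flagged
degenerate), and the MRR/FRR contrast plus a signed distance-to-junction
trend table support the usual positional-bias plots.

## Y-stratum dating and insertion anatomy

`count_y_specific()` counts sites where the Y haplotype differs from the X
while X matches the outgroup — changes polarised to the Y lineage. Neutral
sites are the total minus the nonsynonymous-labelled ones (functional
labels are consumed, not computed). `estimate_y_age()` applies
`T = (S/L) / mu x g` with no factor-of-two correction: the counted sites
are Y-lineage-specific derived alleles, so divergence accrues on one
lineage only. Because standing variation present at recombination arrest
inflates S, the estimate is an upper bound; no standing-variation
correction is attempted. The stratum length L is always an explicit
argument (default use: 1e7 for a ~10-Mb stratum), never hardcoded.

`check_ltr_boundaries()` tests for the TG..CA LTR hallmark; the motif is
orientation-symmetric (the reverse complement of TG..CA is again TG..CA),
so intact elements pass regardless of insertion orientation, and the
minus-strand report can only arise for asymmetric, e.g. clipped, inputs.
`find_tsd()` compares the k bp immediately flanking the insertion for k
from 6 down to 4 and returns the longest exact duplication; exact matching
is the appropriate default for recent insertions, with a mismatch-tolerant
mode left to future need. `check_empty = TRUE` verifies by re-excision
that the empty-site allele carries a single motif copy.

## The synthetic-data generator

The generator's defaults are the study conditions the analyses assume:

* **Genome**: 24 chromosomes totalling ~600 Mb; the sex chromosome
  (chr13) is 27 Mb with its FRR — and Y stratum — spanning the first
  15 Mb. Every chromosome is tiled by one FRR (~70% of its length) and
  one MRR, with boundaries on the 500-kb window grid and the orientation
  alternating between chromosomes; the centromere sits mid-FRR.
* **Recombination**: 49 cM per sex per chromosome (the scale of the one
  chromosome whose maps the motivating system quantifies, and consistent
  with ~50 cM per linkage group in flatfish female maps), spread uniformly
  over each sex's region; Poisson crossover counts without interference —
  counts, not spacings, drive every downstream statistic.
* **Pools**: ten full siblings per sex from one cross; four parental
  haplotypes per autosomal locus (parent genotypes drawn from a shared
  population frequency), which reproduces the reduced transmitted
  diversity of a single-family design. Y-stratum SNPs marked divergent
  (60%) put the Y allele at expected frequency 0.5 in the male pool and 0
  in females. Depths are Poisson(30) with binomial allele sampling; the
  `exact` mode returns the infinite-depth, infinite-pool limit in which
  observed frequencies equal their parental expectations.
* **Pedigree**: three parents (one sire, two dams) and 90 offspring by
  default, i.e. 90 meioses per parental sex; a full-sib layout is
  available. Markers every 100 kb; 2% of phase calls masked missing.
* **Expression**: 12 samples (7 XY, 5 XX), 2000 background genes with
  log-normal noise (sigma 0.4 on log2), one male-only gene expressed high
  in every XY sample and at ~0 in XX; expressed allele counts at 200
  Y-stratum SNPs with six imbalance spike-ins (three X-skewed, three
  Y-skewed at 0.15/0.85).
* **Pileup**: one site every 10 bp; a site is polymorphic with the
  probability that makes expected He equal the configured per-class
  diversity (minor allele frequencies uniform on 0.1–0.5); 5% of sites
  carry low MQ to exercise the filter.
* **Repeats**: six classes at 10–20 elements/Mb, SINEs twice as dense in
  FRRs, simple and low-complexity repeats twice as dense in MRRs, others
  unbiased; geometric-tailed element lengths around 300 bp.
* **Insertion loci**: TG..CA elements with 4–6 nt TSDs; negative-control
  loci are rejection-sampled so no accidental 4–6-mer duplication flanks
  the insertion (without this, ~0.4% of random loci would carry a chance
  4-mer match and "zero detections on controls" would not be a meaningful
  truth statement).

One integer seed governs everything; each generator derives its own
sub-stream, so outputs are byte-identical across runs and independent of
call order.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: read-level errors and mapping artefacts
(alignability, duplicated regions), linkage disequilibrium between pool
SNPs within windows, crossover interference, overdispersed expression
counts, batch or developmental-stage structure in RNA-seq, and repeat
nesting/fragmentation. The recovery results certify the estimators under
the stated sampling models, not robustness to upstream artefacts.

## Problem sizes used in the checks

The automated checks run the full 24-chromosome genome for the pool scan
(20 seeds), the pedigree stage at 90 offspring, diversity recovery on two
chromosomes (~6 million sites), repeats genome-wide (~55k elements), and
200 insertion loci; these sizes keep every stage's sampling error well
inside its tolerance while the whole suite completes in a few minutes.

## Known limitations

* The sex-linked SNP filter's recovery is depth-limited by design (see
  above); studies wanting near-complete Y-SNP recovery at moderate depth
  should lower `daf_min` and accept more autosomal noise.
* Region classification resolves boundaries to about one window at
  realistic event densities; sub-window boundary placement would require
  denser meioses, not a different estimator.
* The Y-age clock ignores standing variation and assumes a constant
  per-generation mutation rate and generation time; it is an upper bound.
* `liftover_contrast()` interpolates linearly within interval pairs and
  ignores alignment quality; very coarse interval maps blur class
  assignment near junctions.
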