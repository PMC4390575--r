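---
title: "Methods: genotype QC and population genomics for inbred line panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype QC and population genomics for inbred line panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Panels of sequenced inbred lines are a workhorse of *Drosophila* population
and quantitative genetics: each line is a (nearly) homozygous genome that
can be phenotyped repeatedly. After a dozen generations of sib-pair
inbreeding a line should be homozygous almost everywhere — yet real panels
show long contiguous stretches of heterozygous calls ("het blocks"),
actively maintained when a heterozygous chromosomal inversion traps
recessive deleterious alleles on both haplotypes and prevents the region
from inbreeding to fixation. Any genotype-quality filter for such a panel
must therefore be *context dependent*: a heterozygous call inside a het
block is plausibly real; the same call outside one is almost certainly an
error. `inbredvar` implements that analysis chain — block segmentation,
class-wise filtering, orthogonal read-count validation, IBD scanning,
inversion genotyping and association, ancestral-state polarization, and
population-genetic summaries — together with a synthetic-cohort simulator
that provides ground truth for every stage.

## The synthetic cohort

The simulator (`simulate_cohort()`) generates the statistical structure the
pipeline assumes, not a mechanistic population history:

* **Site frequencies.** Each variant site draws an ancestral (= reference)
  derived-allele frequency from a density proportional to $1/p$ on
  $[10^{-3}, 1-10^{-3}]$ by inverse-CDF sampling. Under binomial sampling
  of $n$ haploid lines this gives the standard neutral expectation
  $E[\xi_k] \propto 1/k$ for the unfolded spectrum, which is what the SFS
  calibration checks assume. The truncation at $10^{-3}$ keeps the
  singleton deficit below ~2% at $n = 20$.
* **Population structure.** Per population, frequencies are drawn from a
  Balding–Nichols Beta distribution with parameter $F$:
  $p_i \sim \mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$, so Hudson's
  $F_{ST}$ between two populations with parameters $F_1, F_2$ has
  expectation $(F_1 + F_2)/2$. $F = 0$ short-circuits to the ancestral
  frequency exactly.
* **Lines.** Inbred lines are drawn directly as genotypes (homozygous with
  probability given by the population frequency); the inbreeding *outcome*
  is what the pipeline consumes, so no pedigree is simulated. Residual
  heterozygosity outside blocks (`het_rate_outside`, default $10^{-3}$)
  and spurious heterozygous calls (`error_het_rate`, default
  $5\times10^{-3}$) are planted separately, because only the latter should
  be removed by filtering.
* **Het blocks and inversions.** Planted inversions are explicit config
  (span, per-population heterozygous and homozygous carrier
  probabilities). A line carrying an inversion heterozygous gets the full
  span as a planted het block, inside which calls are heterozygous with
  probability `het_rate_in_block` (default 0.40). Block sizes are whatever
  the configured spans are; no size mixture is fitted, since real panels
  show a broad bimodal size distribution that is itself driven by which
  inversions segregate.
* **Qualities and flags.** GQ scores are drawn from class-specific
  Beta(·,·)·99 distributions; spurious hets draw from a lower-GQ
  distribution (Beta(1.5, 3)) than genuine calls (Beta(9, 1)), so the
  GQ-versus-validation relationship the filters exploit exists in
  simulation. Sites harbouring an error het are recalibration-flagged with
  elevated probability (0.05 baseline + 0.25 boost).
* **Read counts, breakpoint evidence, outgroups.** Deep-coverage counts
  are Poisson depth with binomial alternate reads at $\{\epsilon, 1/2,
  1-\epsilon\}$ by true genotype; inversion evidence is Poisson reads per
  chromosome copy per evidence class; outgroups carry the ancestral allele
  mutated away with a per-outgroup divergence probability.

What the simulator deliberately omits: recombination maps, selection,
realistic demography, linked sites (sites are exchangeable given their
frequencies), alignment and mapping artefacts, and restriction-site
dropout for reduced-representation data. Passing recovery tests therefore
demonstrates that the *procedures* are correct under their stated
assumptions, not that real data meet those assumptions.

Because the ancestral allele is always the simulated reference, unfolded
spectra reduce to alternate-allele counts once polarized; the polarization
machinery is still exercised against genuinely diverged outgroups, and
derived-allele bookkeeping handles the ref-ancestral and alt-ancestral
cases symmetrically (and is unit-tested on both).

## Het-block segmentation

`call_het_blocks()` runs a two-state maximum-score dynamic program
(Viterbi) over each chromosome's ordered non-missing SNP calls for one
line. State *inbred* emits a heterozygous call with probability
`p_het_inbred` (default 0.005), state *block* with `p_het_block` (default
0.25); every state switch costs `switch_cost` (default 12 natural-log
units, i.e. a block must accumulate roughly $2\times12$ log-units of
emission evidence to be worth opening and closing). Block runs are snapped
to their outermost heterozygous sites, widened by half the chromosome's
median inter-SNP spacing on each side (so adjacent windows of evidence
meet), merged within `merge_gap_bp` (200 kb), and filtered by
`min_block_bp` (100 kb) and `min_het_sites` (20).

Defaults were chosen so that blocks from ~300 kb up to whole-arm scale at
in-block het rates of 0.2 and above are recovered with base-pair precision
and recall above 0.95 on simulated cohorts at SNP densities of 1/200 bp;
the switch cost sets the minimum evidence for a block and the two emission
probabilities set the contrast. All five knobs are exposed. Segmentation
runs on *pre-filter* genotypes: blocks must be known before the
het-outside-blocks filter, which would otherwise erase its own evidence.
The X chromosome is segmented like the autosomes. Chromosomes never merge,
including across arm boundaries.

The DP is exact: on short inputs it is tested against exhaustive
enumeration of all paths with at most two switches, and its score can only
match or beat that restricted oracle.

## Genotype filtering

`filter_policy()` encodes class-wise rules applied first-match-wins; the
rule set must be *total* (every combination of variant type, genotype
class, block context and recalibration flag matched), which is checked at
construction. The defaults:

| class | context | rule |
|---|---|---|
| SNP het | outside blocks | masked unconditionally |
| SNP het | inside blocks | GQ ≥ 60 |
| SNP hom | unflagged site | GQ ≥ 30 |
| SNP hom | flagged site | GQ ≥ 60 |
| indel het | outside blocks | masked unconditionally |
| indel het | inside blocks | GQ = 99 only |
| indel hom | any | GQ ≥ 60 |

The het-indel rule is fixed by design (only the maximal-quality in-block
class clears a 75% validation bar on deep-coverage data); the remaining
GQ cutoffs are defaults standing in for thresholds that would be
recalibrated per dataset against a validation set. Composition order is
fixed and documented: class rules → SNP-near-indel masking → region masks.
Each step is idempotent and can only decrease the genotype count.

SNP-near-indel masking is per line: a SNP genotype is masked iff the same
line carries a non-missing, non-reference indel call within 5 nt
(inclusive, measured between VCF POS anchors — the metric for multi-base
indels is not otherwise defined). Region masks remove uncallable sites for
all lines and, within each labelled IBD segment, the calls of the
lexicographically second line of the pair (arbitrary but deterministic;
the pair contributes one representative to population statistics).

Sites rendered invariant by filtering are flagged rather than dropped, and
the report carries both counts, since summaries may reasonably use either
convention.

## Read-ratio validation

`read_ratio_call()` is the deep-coverage caller: a site needs strictly
more than 100 reads; an allele is supported iff its read fraction strictly
exceeds 10%; both supported → het, one → the corresponding homozygote.
Both inequalities are strict as specified, and the caller is tested
against exhaustive enumeration of every (depth ≤ 300, alt count)
combination. With exactly two alleles and positive depth the fractions sum
to 1, so at least one allele is always supported and the "neither" branch
is unreachable above the depth cut. `concordance()` stratifies validation
rates by genotype class, block context, GQ bin and recalibration flag —
the strata in which validation rates genuinely differ in this kind of
data.

## IBD scanning

`call_ibd()` tiles chromosomes with 100 kb windows and computes, for every
within-population pair, the identity of non-missing homozygous calls
(sites inside either line's het blocks are excluded as uninformative for
line-level ancestry). Windows with ≥ 20 comparable sites and identity
≥ 0.995 are chained, bridging at most one non-passing window; chains are
clipped against a user-supplied exclusion mask (pericentromeric
low-recombination regions, which accumulate spurious identity) and
segments shorter than 1 Mb are dropped. The method is a transparent
windowed-identity chain rather than a probabilistic IBD model; at the
panel's scale (long, near-perfect segments between single pairs) the
simple method recovers planted segments to within one window and is
monotone in both thresholds.

## Inversion genotyping and association

`genotype_inversion()` maps breakpoint-read evidence to genotypes: reads
supporting the inversion breakpoint and reads bridging the reference
sequence each count as "present" at ≥ 2 reads (no count threshold is
dictated by the evidence model; 2 rejects singleton artefacts while
keeping sensitivity);
both present → heterozygous, inversion only → homozygous, reference only
→ absent, neither → unresolved. `associate()` marks a heterozygous call
"in block" iff any breakpoint interval overlaps a het block of that line —
breakpoints, not the whole inverted span, because the breakpoints of a
block-causing inversion necessarily sit inside the block they maintain
(full-span overlap is available as the `inv_span` alternative).
Explanatory power per population is the fraction of large blocks (default
cut 2 Mb) overlapped by the breakpoint span of at least one heterozygous
inversion of the same line.

## Polarization and site classes

`polarize()` is a weighted vote, not a phylogenetic likelihood: the
posterior for an allele is the summed weight of outgroups carrying it,
normalized over outgroups carrying either segregating allele; outgroups
carrying a third allele are uninformative. A site is polarized iff the
winning allele is one of the two segregating alleles and its posterior
reaches 0.70 — chosen so the canonical 2-vs-1 disagreement among three
equal outgroups (posterior 2/3) is excluded. A normalized score is all the
downstream 70% rule needs; a likelihood model would add branch lengths the
package has no data to fit.

`classify_sites()` reimplements site-class logic on a simplified gene
model (CDS/intron/UTR intervals plus a reference sequence): codon
degeneracy from the standard genetic code (tested against an independent
all-64-codon enumeration), `fourfold` for positions where all four
nucleotides are synonymous, `small_intron` for interiors of introns ≤ 65
bp with an 8 bp buffer at each splice edge (common practice for
*Drosophila*, where the small-intron class is used as a neutral
reference; both configurable). The "neutral" class is fourfold ∪
small_intron.

## Population-genetic estimators

Inbred lines contribute **one allele copy each**: `haploidize()` maps
homozygous calls to their allele and heterozygous calls to missing (het
calls survive filtering only inside blocks, where the line is not a
haploid draw from the population). Per window (10 kb / 5 kb stride;
500 bp / 250 bp on the small 4th chromosome; terminal partial windows
kept and flagged):

$$\pi = \frac{1}{L}\sum_{\text{sites}} \frac{2k_i(n_i-k_i)}{n_i(n_i-1)},
\qquad \hat\theta_W = \frac{S}{a_n L}, \qquad a_n = \sum_{i=1}^{n-1}\frac1i,$$

with per-site sample sizes $n_i$ in $\pi$ and the window's modal $n$ for
$\hat\theta_W$ and Tajima's $D$ (documented approximation for missing
data; both match brute-force oracles exactly on complete data).
Polymorphism/divergence uses, as divergence, the fraction of window sites
whose outgroup consensus differs from the within-sample major allele —
alignment-based divergence over all (including invariant) columns is not
reproducible without a multi-species alignment, so this proxy undercounts
fixed differences and is flagged as such.

$F_{ST}$ is Hudson's estimator as a genome-wide ratio of averages,
$1 - \overline{H_w}/\overline{H_b}$ with the unbiased
$2p(1-p)\,n/(n-1)$ within-heterozygosity; the estimator is stated openly
since panel-style data do not dictate one. The finite-sample correction
makes the $F = 0.10$ recovery unbiased, at the price that two *mirrored*
finite samples score exactly $-1/(n-1)$ rather than 0 — the familiar
small-negative-values behaviour of unbiased $F_{ST}$ estimators. Per-window averaging is available but
not the default.

The SFS uses complete cases at the stratum's modal sample size (integer
counts, exact per-stratum conservation); class balancing subsamples
without replacement to the smallest class, reproducibly under a seed. LD
decay is mean $r^2$ of allele indicators on pairwise-complete lines,
binned by distance, with reproducible pair subsampling, excluding
chromosome 4 (non-recombining). Private high-frequency derived alleles
require frequency ≥ 20% in the focal population, exactly 0 elsewhere,
< 20% missing data per population, and polarization posterior ≥ 0.70.
Wilcoxon/ANOVA/Tukey comparisons over window statistics are a thin
reporting layer over `stats`.

## Numerical and edge-case conventions

* Coordinates: sites are 1-based (VCF); all interval outputs are 0-based
  half-open (BED). Interval algebra is delegated to
  IRanges/GenomicRanges and checked against a per-bp bitmap oracle.
* Multiallelic VCF records split into biallelic records (other-alternate
  genotypes become missing; split origin flagged).
* Tajima's $D$ is undefined (reported missing) when $S = 0$ and at
  $n = 2$, where its variance constants vanish.
* Windows with zero callable bp report missing statistics, not zeros.
* Chromosome sets are configuration throughout; nothing merges across
  chromosomes.
* Every stochastic component takes an explicit seed and is bit-reproducible.

## Problem sizes

The bundled analyses and checks run at desk scale by design: cohorts of
20–40 lines on 0.4–20 Mb chromosomes at SNP densities of 1/200–1/500 bp,
ten replicate seeds for calibration checks. These sizes give the
calibration bands quoted above (e.g. $F_{ST}$ recovery to ±0.02,
block recovery ≥ 0.95) comfortable margins while keeping any single stage
under a minute on one core.

## Known limitations

* The simulator's exchangeable-sites model cannot test haplotype-scale
  artefacts (e.g. reference bias inside inversions) or LD beyond the
  sampling null.
* The filter GQ cutoffs are sensible defaults, not recalibrated values; on
  real data they should be re-derived from a validation set exactly as the
  concordance machinery supports.
* The windowed IBD chain has one-window endpoint resolution and no
  statistical significance model.
* The polarization vote ignores phylogeny; with few, unequally diverged
  outgroups a likelihood method would polarize more sites at equal
  accuracy.
* Divergence (and hence poly/div) is computed from variant-site outgroup
  mismatches only, understating per-bp divergence relative to a full
  alignment.
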