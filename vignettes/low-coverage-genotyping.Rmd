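---
title: "Models and design of the lcgeno toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design of the lcgeno toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcgeno)
```

## The genotype-probability model

For a biallelic SNP with `nRef` reference-allele reads and `nAlt`
alternative-allele reads, and a per-base sequencing error rate $e$, the
three genotype likelihoods are

$$p(0) = (1-e)^{n_{Ref}} e^{n_{Alt}}, \qquad
  p(1) = 0.5^{\,n_{Ref}+n_{Alt}}, \qquad
  p(2) = e^{n_{Ref}} (1-e)^{n_{Alt}},$$

scaled to sum to 1. The model assumes reads are independent draws from the
two chromosomes of a diploid genotype, with a symmetric error process that
flips an observed allele with probability $e$; it has no allele-frequency
prior, so a site with no reads is maximally uncertain $(1/3, 1/3, 1/3)$.
The default $e = 0.01$ is the conventional post-filtering Illumina error
rate; it is a model parameter, not an estimate made from the data. All
probability computation is done in log space so that high-coverage sites
(thousands of reads) do not underflow.

Calling modes and their rules:

* **best-guess** — argmax of the scaled probabilities; no-call at depth 0 or
  on an exact tie (which cannot arise for valid $e$ and unequal counts, so
  the tie rule only codifies determinism).
* **p90 / p98** — the argmax only if its probability *strictly* exceeds
  0.90 / 0.98. Strict comparison matters at the boundary: a single-read site
  has maximum probability $0.99/1.5 = 0.66$ and is never called.
* **presence/absence** — an allele is "present" from a single read, so both
  alleles present ⇒ heterozygote, one ⇒ homozygote, none ⇒ no-call.
  This is best-guess calling in the limit $e \to 0^+$ (tested against
  $e = 10^{-9}$ over all counts with depth ≤ 12), and is the most sensitive
  mode to contamination-like artefacts such as index hopping.

## The pruning-bias emulator

Graph-based variant callers assemble local haplotypes into a read-threading
graph and prune paths supported by fewer reads than a threshold (default 2).
The reference haplotype is always present in the graph regardless of
support. When the alternative path at a low-coverage site is pruned, its
reads are re-scored against the surviving haplotypes — only the reference —
and are counted as reference reads. The emulator applies exactly this
arithmetic to a count pair:

```{r}
emulate_pruning(data.frame(nRef = c(0, 2, 0), nAlt = c(1, 1, 2)))
```

`(0,1) → (1,0)` and `(2,1) → (3,0)`, while `(0,2)` survives because support
2 meets the threshold. Two deliberate choices:

* The rule uses *strictly smaller than* the threshold. Descriptions of the
  pruning step vary between "smaller" and "equal or smaller", but the
  worked arithmetic above (one supporting read pruned, two retained, with a
  threshold of 2) is only consistent with strict comparison, so that is
  what the emulator implements.
* The transformation is asymmetric — the alternative allele is never
  augmented by pruned reference reads — because the reference path cannot be
  pruned. The asymmetry *is* the bias mechanism: at error-free 1x
  heterozygous sites, best-guess calls split 50/50 between the homozygotes
  without pruning and become 100% reference homozygote with it.

## Allele-count extraction

`extract_allele_counts()` performs a filtered pileup (via Rsamtools) at each
listed site and counts reads whose aligned base equals the reference or the
alternative allele; any other base, a deletion or an N contributes nothing,
and a read contributes at most once per site. Default filters: MAPQ ≥ 20,
properly paired, primary alignments only, duplicates excluded, no
base-quality threshold. Duplicate exclusion is a package decision — the
upstream duplicate-marking step exists to enable it, and standard pileup
practice excludes them — and can be disabled. Overlapping mates are counted
as two observations; this is the simplest contract, and the simulated reads
carry a `fragment_id` so a fragment-level collapse can be layered on if
needed. Externally everything is 1-based (VCF/FASTA convention).

## Concordance

Given truth and called dosage vectors, pairs with a missing value on either
side are excluded from every denominator. Genotype concordance is the
percentage of exact dosage matches; allele concordance treats each unphased
genotype as a pair of alleles, of which $2 - |d_{true} - d_{call}|$ match,
so a hom/het error costs half as much as a hom/hom flip. Excluding no-calls
from the denominator (rather than scoring them as errors) is what makes the
stricter probability thresholds *raise* concordance while shrinking the
number of calls — the trade-off the thresholds exist to expose. The
confusion matrix is column-normalised: entry $(x\mid y)$ is the percentage
of called-$x$ among called pairs with true genotype $y$. Coverage strata
default to 1x–5x singleton bins plus a pooled 6–10x bin; depth 0 and depths
above 10 are excluded under the defaults (configurable via `bins`).

## Index-hopping simulation and estimation

Index hopping misassigns reads between samples multiplexed in one flow-cell
lane. The simulator reassigns each *fragment* independently with probability
$h$ to a sample drawn uniformly from the other $n-1$ samples; mates move
together because hopping is a library-fragment phenomenon (a pair shares one
index pair). Fragment counts and multiplex-wide per-site allele totals are
conserved by construction.

The estimator is a calibration-curve inversion. For a grid of known hop
levels (default 0, 0.1, 0.5, 1, 2, 5%), an independently re-simulated read
set is hop-injected at that level and the nine confusion percentages
("called|true") of presence/absence calls against truth are recorded. Each
variable's response is regressed on the level — ordinary least squares,
degree 1 for raw percentages, degree 2 for ilr-transformed responses — and
the fit is inverted at the observed value. Percentages are compositional, so
the ilr balances

$$\sqrt{2/3}\,\ln\frac{c_{ok}}{\sqrt{c_{e1} c_{e2}}}
  \qquad\text{and}\qquad
  \frac{1}{\sqrt 2}\,\ln\frac{c_{ok}}{c_{err}}$$

map them to an unconstrained scale where polynomial regression is defensible;
they are scale-invariant, so counts and percentages give identical values.
Zero parts make an ilr undefined and raise an error rather than being
silently pseudo-counted — a zero cell means the calibration grid is too
small for that variable, and perturbing it would corrupt the inversion.
For the quadratic inverse, the root must lie within the calibrated level
span (the response curves are monotone there, so at most one interior root
occurs; ties resolve to the smaller root). Heterozygote variables are nearly
flat in $h$ — hops into a heterozygote mostly re-create an allele already
present — so only homozygote variables carry calibration information; the
toolkit reports one estimate per variable rather than forcing a pooled
value, leaving the aggregation (mean, range) to the analyst.

## The tailored-reference assay

Alignment favours reads matching the reference genome. To isolate this
effect, `build_tailored_reference()` writes a genome with the alternative
allele substituted at every SNP site (validating that the input genome
carries the declared reference base; the operation is an involution when
re-applied with alleles swapped). After aligning the same reads to both
genomes, counts are combined in four ways: REF (original genome only), ALT
(tailored only), CIS (each allele counted from the alignment where it
matched the reference — the favourable case) and TRANS (the unfavourable
case). All tables are kept in *original* orientation — `nRef` always counts
the original reference allele — which is the single most error-prone
convention in the assay and is therefore recorded in the counts-TSV header.
`alignment_bias_summary()` reports, per allele,
$100\,(\bar c_{fav} - \bar c_{unfav})/\bar c_{fav}$: the proportion of reads
lost when the genome carries the opposite allele. The favourable mean is the
natural denominator (the loss is measured relative to the alignment that
could have kept the reads). Realignment itself is out of scope: the module's
contract starts at the two BAMs or count tables, as an external aligner
(e.g. BWA-MEM) produces them.

## The synthetic-data generator

The generator emulates exactly the statistical structure the analyses
assume: truth dosages drawn under Hardy-Weinberg from per-site allele
frequencies (default frequencies uniform on [0.05, 0.5], a panel of
segregating array-like SNPs); per sample-site read depth
Poisson(`mean_coverage`), matching the canonical model for realized coverage
under random sampling of reads; a symmetric per-base error flipping the
transmitted allele with probability `error_rate` (default 0.01, consistent
with the calling model); all reads MAPQ 60, properly paired, primary,
non-duplicate. Each simulated read covers exactly one site — the analyses
operate on per-site allele counts, so read length, fragment-size
distributions, GC bias, mapping error and multi-site reads are deliberately
not modelled. Consequently, passing tests demonstrate the *pipeline
arithmetic* (count extraction, calling, concordance, hop bookkeeping) and
the *statistical identities*, not robustness to alignment artefacts in real
data; the tailored-reference assay exists precisely because real alignment
is not simulated. `write_fixture()` materialises a simulation as sorted,
indexed single-base-read BAMs, a sites-only VCF v4.2, an indexed FASTA with
the reference alleles planted, and a truth TSV, so the BAM-facing code path
is exercised end to end.

## Numerical and scale choices

* Probabilities in log space; normalisation subtracts the row maximum.
* Ties and thresholds use strict comparisons, as discussed above.
* Hop levels are expressed in percent everywhere user-facing.
* Test and demonstration problem sizes: the distributional checks use
  10,000 draws (3-standard-error bands); the hop-recovery check uses one
  multiplex of 20 samples × 20,000 sites at 2x with a true rate of 1.5%,
  re-estimated over 10 independent read simulations against the six-level
  calibration grid, with a ±0.5 percentage-point acceptance band on the
  mean of the four well-populated homozygote variables ("0|0", "1|0",
  "1|2", "2|2"; the "2|0"/"0|2" variables need double hops and are too
  sparse at this scale to regress stably).
* Seeds: every stochastic entry point takes an explicit `seed`; grid
  functions derive per-level sub-seeds so levels are independent but
  reproducible.

## Known limitations

* No allele-frequency or pedigree prior in the genotype model (by design —
  downstream imputation tools consume the raw probabilities).
* The hop estimator assumes a truth-genotype panel (a second, higher-quality
  assay of the same samples) is available to compute concordance against.
* Single-base simulated reads cannot express multi-SNP haplotype effects on
  alignment, indels, or soft-clipping; CRAM input and indel sites are out of
  scope throughout.
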