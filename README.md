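# lcgeno

Genotype calling from low-coverage sequencing without reference-allele bias.

Low-coverage (~1-2x) whole-genome sequencing is the workhorse of large
genotyping efforts in animal and plant breeding and in population genetics:
many individuals are sequenced cheaply and genotypes are called (and later
imputed) from a handful of reads per site. At such depths, tools designed for
high-coverage data can misbehave. In particular, graph-based variant callers
*prune* haplotype paths supported by fewer reads than a threshold (by default
2) to remove sequencing errors. At 1x a genuine alternative allele is usually
supported by a single read, so its path is pruned and the read is re-scored
against the only surviving haplotype — the reference — turning a true
`(nRef = 0, nAlt = 1)` observation into `(nRef = 1, nAlt = 0)`. The result is
a strong, systematic bias towards the reference allele in the allele counts
stored in gVCF files, and through them in every downstream genotype.

`lcgeno` implements an unbiased calling pipeline and the simulation and
estimation machinery needed to quantify this and two related artefacts:

- **readcounts** — extract allele read counts for known biallelic SNP sites
  directly from aligned reads in BAM files (default filters: MAPQ >= 20,
  proper pairs only, no secondary alignments, no duplicates), bypassing the
  caller's pruned counts.
- **genotyper** — genotype probabilities from counts,
  `p(0) ∝ (1-e)^nRef · e^nAlt`, `p(1) ∝ 0.5^(nRef+nAlt)`,
  `p(2) ∝ e^nRef · (1-e)^nAlt`, scaled to sum to 1 (error rate `e = 0.01` by
  default); best-guess, p > 0.90, p > 0.98 and presence/absence calling
  modes; plus an emulator of the pruning bias for study at the count level.
- **concordance** — genotype and allele concordance against truth genotypes,
  with a called-vs-true confusion matrix stratified by site coverage
  (1x ... 6-10x).
- **refswap** — a tailored reference genome (alternative allele substituted
  at every SNP site) and REF/ALT/CIS/TRANS combinations of dual-alignment
  counts, to measure alignment bias.
- **hopping** — simulation of index hopping (random reassignment of
  fragments between multiplexed samples) and estimation of the hop rate by
  inverse regression of concordance percentages — linear for raw
  percentages, quadratic for their isometric log-ratio (ilr) transforms
  `√(2/3)·ln(c_ok/√(c_e1·c_e2))` and `(1/√2)·ln(c_ok/c_err)`.
- **synthfix** — a synthetic-data generator (Hardy-Weinberg truth genotypes,
  Poisson per-site coverage, per-base errors) that writes standard
  BAM/VCF/FASTA/TSV files, so the whole toolkit runs without external data.

## Worked example

Simulate 10 samples at 5,000 SNP sites sequenced at 2x, call best-guess
genotypes from the raw counts, and compare with the same counts passed
through the pruning-bias emulator:

```r
library(lcgeno)

truth  <- simulate_truth(n_samples = 10, n_sites = 5000, seed = 1)
reads  <- simulate_reads(truth, mean_coverage = 2, error_rate = 0.01, seed = 2)
tal    <- tally_allele_counts(reads)
counts <- data.frame(nRef = as.vector(tal$nRef), nAlt = as.vector(tal$nAlt))

calls <- call_genotypes(counts, mode = "best-guess", e = 0.01)
concordance_stats(as.vector(truth$genotypes), calls$dosage)
#> n called: 43175
#> genotype concordance: 79.25%
#> allele concordance: 89.52%
#> confusion (% of true-genotype column):
#>         0     1     2
#>   0 97.88 26.83  0.38
#>   1  1.82 46.46  1.68
#>   2  0.30 26.71 97.95

biased <- call_genotypes(counts, mode = "best-guess", e = 0.01, prune = 2)
concordance_stats(as.vector(truth$genotypes), biased$dosage)
#> genotype concordance: 67.86%
#> allele concordance: 82.43%
```

Without pruning, heterozygotes miscalled at low depth split evenly between
the two homozygotes (26.8% vs 26.7%) — the expected behaviour when a 1x site
shows only one of the two alleles. With pruning emulated, 68.7% of true
heterozygotes are called reference homozygotes versus 11.3% alternative, and
overall concordance drops by more than 11 points: the counts themselves have
been biased towards the reference allele.

Estimating an unknown index-hopping rate (here simulated at 1.5%) from a
calibration grid of known levels, using presence/absence calls of the
hop-sensitive homozygote variables:

```r
obs_reads   <- inject_hopping(simulate_reads(truth, 2, 0.01, seed = 3),
                              h = 0.015, seed = 4)
observed    <- multiplex_concordance(obs_reads, truth)
calibration <- hop_calibration_grid(truth, seed = 5)   # levels 0 ... 5%
estimate_hopping(calibration, observed,
                 variables = c("0|0", "1|0", "1|2", "2|2"))
#>  variable estimate r_squared
#>       0|0     1.38      0.99
#>       1|0     1.39      0.99
#>       1|2     1.70      0.95
#>       2|2     1.71      0.97
```

The per-variable estimates bracket the simulated 1.5% (mean 1.54%).

A command-line front end covering the same operations is installed at
`system.file("cli", "lcgeno", package = "lcgeno")`; see
`lcgeno <command> --help`.

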