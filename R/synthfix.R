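#' Simulate a truth set of diploid genotypes at biallelic SNP sites
#'
#' Draws per-site alternative-allele frequencies from `maf` and then genotype
#' dosages for every sample under Hardy-Weinberg equilibrium: the dosage at a
#' site with alternative-allele frequency `p` is `Binomial(2, p)`.
#'
#' @param n_samples number of diploid samples (>= 1).
#' @param n_sites number of biallelic SNP sites (>= 1).
#' @param maf alternative-allele frequency specification: a single value in
#'   \[0, 1\] used for all sites, a vector of length `n_sites`, or a function
#'   `f(n)` returning `n` frequencies. The default draws frequencies uniformly
#'   on \[0.05, 0.5\], mimicking a panel of segregating array SNPs.
#' @param contig contig name used for all sites.
#' @param spacing distance in bp between consecutive sites (positions are
#'   `spacing, 2*spacing, ...`, 1-based, strictly increasing).
#' @param seed integer seed; if non-`NULL` the simulation is reproducible.
#'
#' @return An object of class `truth_set`: a list with elements
#'   `sites` (data.frame `contig`, `pos`, `ref`, `alt`),
#'   `genotypes` (integer matrix samples x sites with entries in 0/1/2),
#'   `allele_freqs` (numeric, per site), `samples` (sample ids) and `seed`.
#' @examples
#' ts <- simulate_truth(4, 10, maf = 0.3, seed = 1)
#' table(ts$genotypes)
#' @export
simulate_truth <- function(n_samples, n_sites, maf = NULL, contig = "chr1",
                           spacing = 100L, seed = NULL) {
  if (length(n_samples) != 1L || is.na(n_samples) || n_samples < 1)
    stop("n_samples must be a positive integer")
  if (length(n_sites) != 1L || is.na(n_sites) || n_sites < 1)
    stop("n_sites must be a positive integer")
  n_samples <- as.integer(n_samples)
  n_sites <- as.integer(n_sites)
  if (!is.null(seed)) set.seed(seed)

  freqs <- if (is.null(maf)) {
    stats::runif(n_sites, 0.05, 0.5)
  } else if (is.function(maf)) {
    maf(n_sites)
  } else if (length(maf) == 1L) {
    rep(as.numeric(maf), n_sites)
  } else {
    as.numeric(maf)
  }
  if (length(freqs) != n_sites || any(freqs < 0 | freqs > 1))
    stop("maf must yield one frequency in [0, 1] per site")

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  # alt drawn from the three non-reference bases
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  sites <- data.frame(
    contig = rep(contig, n_sites),
    pos = as.integer(spacing) * seq_len(n_sites),
    ref = ref, alt = unname(alt),
    stringsAsFactors = FALSE
  )

  samples <- sprintf("S%03d", seq_len(n_samples))
  geno <- matrix(
    stats::rbinom(n_samples * n_sites, 2L, rep(freqs, each = n_samples)),
    nrow = n_samples, ncol = n_sites, dimnames = list(samples, NULL)
  )
  structure(
    list(sites = sites, genotypes = geno, allele_freqs = freqs,
         samples = samples, seed = seed),
    class = "truth_set"
  )
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("truth_set: %d samples x %d sites on %s\n",
              length(x$samples), nrow(x$sites), paste(unique(x$sites$contig), collapse = ",")))
  invisible(x)
}

#' Simulate sequencing reads over a truth set
#'
#' Emits single-site read observations for a multiplex of samples. The number
#' of reads a sample receives at a site is `Poisson(mean_coverage)`,
#' independently per sample-site pair. Each read transmits one of the two
#' chromosomes of the true genotype (the alternative allele with probability
#' dosage/2) and the observed allele equals the transmitted allele with
#' probability `1 - error_rate`, the opposite allele otherwise. All reads are
#' emitted with mapping quality 60, properly paired, primary and
#' non-duplicate; each fragment yields one counted observation.
#'
#' @param truth a [simulate_truth()] `truth_set`.
#' @param mean_coverage target mean reads per sample-site (>= 0).
#' @param error_rate per-base sequencing error probability in \[0, 0.5).
#' @param seed integer seed for reproducibility.
#'
#' @return An object of class `multiplex_read_set`: a list with `samples`,
#'   `sites` (copied from the truth set) and `fragments`, a data.frame with
#'   one row per read carrying `fragment_id`, `true_sample`, `assigned_sample`,
#'   `site_idx`, `observed_allele` ("ref"/"alt"), `mapq`, `proper_pair`,
#'   `secondary`, `duplicate`.
#' @examples
#' ts <- simulate_truth(2, 5, maf = 0.5, seed = 1)
#' rs <- simulate_reads(ts, mean_coverage = 2, error_rate = 0.01, seed = 2)
#' head(rs$fragments)
#' @export
simulate_reads <- function(truth, mean_coverage = 2, error_rate = 0.01,
                           seed = NULL) {
  stopifnot(inherits(truth, "truth_set"))
  if (mean_coverage < 0) stop("mean_coverage must be non-negative")
  if (error_rate < 0 || error_rate >= 0.5)
    stop("error_rate must be in [0, 0.5)")
  if (!is.null(seed)) set.seed(seed)

  n_samples <- length(truth$samples)
  n_sites <- nrow(truth$sites)
  depth <- stats::rpois(n_samples * n_sites, mean_coverage)
  n_reads <- sum(depth)

  # sample-major grid: entry (i, j) at position (j - 1) * n_samples + i
  sample_idx <- rep(rep(seq_len(n_samples), n_sites), depth)
  site_idx <- rep(rep(seq_len(n_sites), each = n_samples), depth)

  if (n_reads > 0) {
    dosage <- truth$genotypes[cbind(sample_idx, site_idx)]
    transmitted_alt <- stats::rbinom(n_reads, 1L, dosage / 2)
    flipped <- stats::rbinom(n_reads, 1L, error_rate)
    observed_alt <- as.logical(bitwXor(transmitted_alt, flipped))
  } else {
    observed_alt <- logical(0)
  }

  fragments <- data.frame(
    fragment_id = seq_len(n_reads),
    true_sample = truth$samples[sample_idx],
    assigned_sample = truth$samples[sample_idx],
    site_idx = site_idx,
    observed_allele = ifelse(observed_alt, "alt", "ref"),
    mapq = rep(60L, n_reads),
    proper_pair = rep(TRUE, n_reads),
    secondary = rep(FALSE, n_reads),
    duplicate = rep(FALSE, n_reads),
    stringsAsFactors = FALSE
  )
  structure(
    list(samples = truth$samples, sites = truth$sites, fragments = fragments,
         seed = seed),
    class = "multiplex_read_set"
  )
}

#' @export
print.multiplex_read_set <- function(x, ...) {
  cat(sprintf("multiplex_read_set: %d fragments, %d samples, %d sites\n",
              nrow(x$fragments), length(x$samples), nrow(x$sites)))
  invisible(x)
}

#' Tally per-sample, per-site allele read counts from a simulated read set
#'
#' Counts reads by `assigned_sample` (so reads moved by index hopping are
#' credited to the sample they were misassigned to).
#'
#' @param reads a `multiplex_read_set`.
#' @return A list of two integer matrices `nRef` and `nAlt`
#'   (samples x sites, rownames = sample ids).
#' @export
tally_allele_counts <- function(reads) {
  stopifnot(inherits(reads, "multiplex_read_set"))
  n_samples <- length(reads$samples)
  n_sites <- nrow(reads$sites)
  fr <- reads$fragments
  si <- match(fr$assigned_sample, reads$samples)
  cell <- (fr$site_idx - 1L) * n_samples + si
  is_ref <- fr$observed_allele == "ref"
  nbins <- n_samples * n_sites
  n_ref <- matrix(tabulate(cell[is_ref], nbins), nrow = n_samples,
                  dimnames = list(reads$samples, NULL))
  n_alt <- matrix(tabulate(cell[!is_ref], nbins), nrow = n_samples,
                  dimnames = list(reads$samples, NULL))
  list(nRef = n_ref, nAlt = n_alt)
}

# Render reads of one sample as SAM and convert to a sorted, indexed BAM.
# Reads are written as single-base alignments (1M) flagged paired and
# properly paired; `secondary`, `duplicate` and `proper_pair` columns set the
# corresponding SAM flag bits. `base` gives the literal base carried.
write_read_bam <- function(df, contig_lengths, bam_path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)))
  flag <- 1L + 64L +                       # paired, first in pair
    ifelse(df$proper_pair, 2L, 0L) +
    ifelse(df$secondary, 256L, 0L) +
    ifelse(df$duplicate, 1024L, 0L)
  body <- if (nrow(df)) {
    sprintf("%s\t%d\t%s\t%d\t%d\t1M\t=\t%d\t0\t%s\tI",
            df$qname, flag, df$contig, df$pos, df$mapq, df$pos, df$base)
  } else character(0)
  sam <- sub("\\.bam$", ".sam", bam_path)
  writeLines(c(hdr, body), sam)
  dest <- Rsamtools::asBam(sam, destination = sub("\\.bam$", "", bam_path),
                           overwrite = TRUE, indexDestination = TRUE)
  unlink(sam)
  invisible(dest)
}

#' Write a synthetic dataset as standard-format files
#'
#' Materialises a truth set and read set as the files the rest of the toolkit
#' (and external tools) consume: one coordinate-sorted indexed BAM per sample,
#' a sites-only VCF v4.2, a reference FASTA (with index) whose bases agree
#' with the sites' reference alleles, and a truth-genotype TSV with columns
#' `sample`, `contig`, `pos`, `dosage`. Reads are written by
#' `assigned_sample`, so hop-injected read sets produce hop-affected BAMs.
#'
#' @param truth a `truth_set`.
#' @param reads a `multiplex_read_set` over the same truth set.
#' @param out_dir output directory (created if needed).
#' @param fasta_seed seed for the random non-site reference bases, so the
#'   FASTA is reproducible independently of when it is written.
#' @return Invisibly, a list of the paths written: `bam` (named by sample),
#'   `vcf`, `fasta`, `truth_tsv`.
#' @export
write_fixture <- function(truth, reads, out_dir, fasta_seed = 1L) {
  stopifnot(inherits(truth, "truth_set"), inherits(reads, "multiplex_read_set"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)

  sites <- truth$sites
  contigs <- unique(sites$contig)
  contig_lengths <- vapply(contigs, function(ct) {
    p <- sites$pos[sites$contig == ct]
    as.integer(if (length(p)) max(p) + 100L else 1000L)
  }, integer(1))
  names(contig_lengths) <- contigs
  if (length(contigs) == 0) {
    contig_lengths <- c(chr1 = 1000L)
  }

  # reference FASTA: random background with the declared ref allele at sites
  set.seed(fasta_seed)
  seqs <- Biostrings::DNAStringSet(vapply(names(contig_lengths), function(ct) {
    s <- sample(c("A", "C", "G", "T"), contig_lengths[[ct]], replace = TRUE)
    here <- sites$contig == ct
    s[sites$pos[here]] <- sites$ref[here]
    paste(s, collapse = "")
  }, character(1)))
  fasta <- file.path(out_dir, "reference.fa")
  Biostrings::writeXStringSet(seqs, fasta)
  Rsamtools::indexFa(fasta)

  # sites-only VCF v4.2
  vcf <- file.path(out_dir, "sites.vcf")
  vcf_lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
            contig_lengths),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  if (nrow(sites))
    vcf_lines <- c(vcf_lines, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                                      sites$contig, sites$pos, sites$ref,
                                      sites$alt))
  writeLines(vcf_lines, vcf)

  # truth genotypes, long format
  truth_tsv <- file.path(out_dir, "truth.tsv")
  tt <- data.frame(
    sample = rep(truth$samples, times = nrow(sites)),
    contig = rep(sites$contig, each = length(truth$samples)),
    pos = rep(sites$pos, each = length(truth$samples)),
    dosage = as.vector(truth$genotypes),
    stringsAsFactors = FALSE
  )
  utils::write.table(tt, truth_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # one BAM per sample, written by assigned sample
  fr <- reads$fragments
  base <- ifelse(fr$observed_allele == "ref",
                 sites$ref[fr$site_idx], sites$alt[fr$site_idx])
  bam_paths <- character(0)
  for (s in truth$samples) {
    keep <- fr$assigned_sample == s
    df <- data.frame(
      qname = sprintf("frag%07d", fr$fragment_id[keep]),
      contig = sites$contig[fr$site_idx[keep]],
      pos = sites$pos[fr$site_idx[keep]],
      mapq = fr$mapq[keep],
      base = base[keep],
      proper_pair = fr$proper_pair[keep],
      secondary = fr$secondary[keep],
      duplicate = fr$duplicate[keep],
      stringsAsFactors = FALSE
    )
    bam <- file.path(out_dir, paste0(s, ".bam"))
    write_read_bam(df, contig_lengths, bam)
    bam_paths[s] <- bam
  }

  invisible(list(bam = bam_paths, vcf = vcf, fasta = fasta,
                 truth_tsv = truth_tsv))
}

#' Read a truth-genotype TSV written by [write_fixture()]
#'
#' @param path TSV with columns `sample`, `contig`, `pos`, `dosage`.
#' @return data.frame with those columns.
#' @export
read_truth <- function(path) {
  tt <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample", "contig", "pos", "dosage")
  if (!all(need %in% names(tt)))
    stop("truth table must have columns: ", paste(need, collapse = ", "))
  tt
}
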