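#' Build a tailored (allele-swapped) reference genome
#'
#' Writes a copy of the reference FASTA in which every listed variant site
#' carries the alternative allele instead of the reference allele. Aligning
#' reads against both genomes and comparing the allele counts isolates the
#' alignment component of reference-allele bias: against the tailored genome
#' it is the alternative-allele reads that enjoy the mismatch-free alignment.
#' Sequence lengths are unchanged (SNPs only). Applying the operation twice
#' with ref/alt swapped restores the original sequence.
#'
#' @param fasta input reference FASTA path (contigs named as in `sites`).
#' @param sites data.frame `contig`, `pos`, `ref`, `alt`; at every site the
#'   genome base must equal `ref` (validated), and duplicate sites are
#'   rejected.
#' @param out output FASTA path; a `.fai` index is written alongside.
#' @return `out`, invisibly.
#' @export
build_tailored_reference <- function(fasta, sites, out) {
  validate_sites(sites)
  genome <- Biostrings::readDNAStringSet(fasta)
  # FASTA headers may carry descriptions after the contig name
  names(genome) <- sub("\\s.*$", "", names(genome))
  missing_contig <- setdiff(unique(sites$contig), names(genome))
  if (length(missing_contig))
    stop("contig absent from FASTA: ", paste(missing_contig, collapse = ", "))
  for (ct in unique(sites$contig)) {
    here <- sites$contig == ct
    pos <- sites$pos[here]
    if (any(pos > length(genome[[ct]])))
      stop("site beyond contig end: ", ct, ":", max(pos))
    found <- strsplit(as.character(Biostrings::extractAt(
      genome[[ct]], IRanges::IRanges(pos, width = 1L))), NULL)
    found <- vapply(found, `[`, character(1), 1L)
    bad <- found != sites$ref[here]
    if (any(bad)) {
      i <- which(bad)[1]
      stop("genome base does not match declared ref allele at ",
           ct, ":", pos[i], " (found ", found[i], ", expected ",
           sites$ref[here][i], ")")
    }
    genome[[ct]] <- Biostrings::replaceLetterAt(
      genome[[ct]], pos, sites$alt[here])
  }
  Biostrings::writeXStringSet(genome, out)
  Rsamtools::indexFa(out)
  invisible(out)
}

#' Combine allele counts from original- and tailored-reference alignments
#'
#' Both input tables must be expressed in original-reference orientation:
#' `nRef` counts the allele that is the reference allele of the *original*
#' genome, in both tables (extraction against the tailored genome relabels
#' accordingly, since the tailored genome's reference base is the original
#' alternative allele). The four modes are:
#' \describe{
#'   \item{REF}{counts from the original-genome alignment, unchanged.}
#'   \item{ALT}{counts from the tailored-genome alignment, unchanged.}
#'   \item{CIS}{the favourable combination — `nRef` from the original-genome
#'     alignment, `nAlt` from the tailored-genome alignment: each allele
#'     counted from the alignment in which it matched the reference.}
#'   \item{TRANS}{the unfavourable combination — `nRef` from the
#'     tailored-genome alignment, `nAlt` from the original-genome alignment.}
#' }
#'
#' @param counts_ref_aln counts table from the original-genome alignment
#'   (columns `sample`, `contig`, `pos`, `nRef`, `nAlt`, ...).
#' @param counts_alt_aln counts table from the tailored-genome alignment,
#'   keyed identically, original orientation.
#' @param mode one of `"REF"`, `"ALT"`, `"CIS"`, `"TRANS"`.
#' @return a counts table in the layout of `counts_ref_aln` with
#'   `nRef`/`nAlt` combined per `mode`.
#' @examples
#' a <- data.frame(sample = "S", contig = "chr1", pos = 1, nRef = 5, nAlt = 2)
#' b <- data.frame(sample = "S", contig = "chr1", pos = 1, nRef = 4, nAlt = 3)
#' combine_counts(a, b, "CIS")$nRef    # 5
#' combine_counts(a, b, "TRANS")$nAlt  # 2
#' @export
combine_counts <- function(counts_ref_aln, counts_alt_aln,
                           mode = c("REF", "ALT", "CIS", "TRANS")) {
  mode <- match.arg(mode)
  aligned <- align_count_tables(counts_ref_aln, counts_alt_aln)
  a <- aligned$a; b <- aligned$b
  out <- a
  if (mode == "ALT") {
    out$nRef <- b$nRef; out$nAlt <- b$nAlt
  } else if (mode == "CIS") {
    out$nAlt <- b$nAlt
  } else if (mode == "TRANS") {
    out$nRef <- b$nRef
  }
  out
}

# join two counts tables on (sample, contig, pos); error on any mismatch
align_count_tables <- function(a, b) {
  key <- function(d) paste(d$sample, d$contig, d$pos, sep = ":")
  ka <- key(a); kb <- key(b)
  bad <- c(setdiff(ka, kb), setdiff(kb, ka))
  if (length(bad))
    stop("count tables are not keyed identically; first offending key: ",
         bad[1])
  list(a = a, b = b[match(ka, kb), , drop = FALSE])
}

# relative loss of the disfavoured alignment, in percent of the favourable
# mean count
pct_not_aligned <- function(mean_favourable, mean_unfavourable) {
  100 * (mean_favourable - mean_unfavourable) / mean_favourable
}

#' Summarise alignment bias from dual-reference allele counts
#'
#' For each allele, compares its mean per-site read count between the
#' alignment in which the reference genome carried that allele (favourable)
#' and the alignment in which it carried the opposite allele (unfavourable).
#' The statistic `100 * (mean_fav - mean_unfav) / mean_fav` is the proportion
#' of reads that did not align when the reference genome carried the opposite
#' allele. With a truth table, means are additionally stratified by true
#' genotype.
#'
#' @param counts_ref_aln,counts_alt_aln counts tables from the original- and
#'   tailored-genome alignments, keyed identically, original orientation.
#' @param truth optional data.frame `sample`, `contig`, `pos`, `dosage` of
#'   true genotypes, enabling per-genotype stratification.
#' @return data.frame with one row per allele x group (`overall` plus
#'   `true=0/1/2` when truth is given): `allele`, `group`,
#'   `mean_favourable`, `mean_unfavourable`, `pct_not_aligned`.
#' @export
alignment_bias_summary <- function(counts_ref_aln, counts_alt_aln,
                                   truth = NULL) {
  aligned <- align_count_tables(counts_ref_aln, counts_alt_aln)
  a <- aligned$a; b <- aligned$b
  if (!nrow(a)) stop("empty count tables")
  groups <- list(overall = rep(TRUE, nrow(a)))
  if (!is.null(truth)) {
    key <- function(d) paste(d$sample, d$contig, d$pos, sep = ":")
    dos <- truth$dosage[match(key(a), key(truth))]
    for (g in 0:2) groups[[paste0("true=", g)]] <- !is.na(dos) & dos == g
  }
  rows <- lapply(names(groups), function(g) {
    sel <- groups[[g]]
    data.frame(
      allele = c("reference", "alternative"),
      group = g,
      mean_favourable = c(mean(a$nRef[sel]), mean(b$nAlt[sel])),
      mean_unfavourable = c(mean(b$nRef[sel]), mean(a$nAlt[sel])),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$pct_not_aligned <- pct_not_aligned(out$mean_favourable,
                                         out$mean_unfavourable)
  out
}
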