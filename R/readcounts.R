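#' Read filters applied during allele-count extraction
#'
#' Defaults reproduce the count-extraction step of the unbiased genotyping
#' pipeline: reads with mapping quality below 20, reads not mapped in a
#' proper pair and secondary alignments are excluded. Duplicate-flagged reads
#' are also excluded by default (standard pileup practice); no base-quality
#' filter is applied by default.
#'
#' @param min_mapq minimum mapping quality (reads with MAPQ strictly below
#'   this are excluded); non-negative.
#' @param require_proper_pair exclude reads not mapped in a proper pair.
#' @param drop_secondary exclude secondary alignments.
#' @param drop_duplicates exclude duplicate-marked reads.
#' @param min_baseq minimum base quality at the site; non-negative.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_mapq = 20L, require_proper_pair = TRUE,
                          drop_secondary = TRUE, drop_duplicates = TRUE,
                          min_baseq = 0L) {
  if (min_mapq < 0 || min_baseq < 0)
    stop("min_mapq and min_baseq must be non-negative")
  structure(list(min_mapq = as.integer(min_mapq),
                 require_proper_pair = isTRUE(require_proper_pair),
                 drop_secondary = isTRUE(drop_secondary),
                 drop_duplicates = isTRUE(drop_duplicates),
                 min_baseq = as.integer(min_baseq)),
            class = "filter_config")
}

validate_sites <- function(sites) {
  need <- c("contig", "pos", "ref", "alt")
  if (!is.data.frame(sites) || !all(need %in% names(sites)))
    stop("sites must be a data.frame with columns: ",
         paste(need, collapse = ", "))
  bases <- c("A", "C", "G", "T")
  bad <- !(sites$ref %in% bases) | !(sites$alt %in% bases) |
    sites$ref == sites$alt | is.na(sites$pos) | sites$pos < 1
  if (any(bad))
    stop("malformed site at ", sites$contig[which(bad)[1]], ":",
         sites$pos[which(bad)[1]],
         " (ref/alt must be distinct single bases in A/C/G/T, pos >= 1)")
  key <- paste(sites$contig, sites$pos)
  if (anyDuplicated(key))
    stop("duplicate site: ", key[which(duplicated(key))[1]])
  invisible(sites)
}

#' Extract per-site allele read counts directly from a BAM file
#'
#' The count-extraction step of the unbiased genotyping pipeline: for each
#' listed biallelic SNP site, counts the reads passing the filters whose
#' aligned base at the site equals the reference allele (`nRef`) or the
#' alternative allele (`nAlt`). Reads showing any other base, a deletion or N
#' at the site contribute nothing; each read contributes at most one
#' observation per site. Counting from the alignments bypasses the allele
#' counts stored in gVCF files by graph-based variant callers, whose pruning
#' step biases them towards the reference allele at low coverage.
#'
#' @param bam path to a coordinate-sorted, indexed BAM file.
#' @param sites data.frame with columns `contig`, `pos` (1-based), `ref`,
#'   `alt` — e.g. from [read_sites()] or a `truth_set`'s `sites`.
#' @param filters a [filter_config()].
#' @param sample sample label for the output (default: BAM basename).
#' @param max_depth maximum pileup depth examined per site.
#' @return data.frame with one row per site, in input site order: `sample`,
#'   `contig`, `pos`, `ref`, `alt`, `nRef`, `nAlt`.
#' @examples
#' \dontrun{
#' sites <- read_sites("sites.vcf")
#' counts <- extract_allele_counts("S001.bam", sites)
#' }
#' @export
extract_allele_counts <- function(bam, sites, filters = filter_config(),
                                  sample = NULL, max_depth = 10000L) {
  stopifnot(inherits(filters, "filter_config"))
  validate_sites(sites)
  if (!file.exists(bam)) stop("BAM file not found: ", bam)
  bai <- c(paste0(bam, ".bai"), sub("\\.bam$", ".bai", bam))
  if (!any(file.exists(bai)))
    stop("BAM index (.bai) not found for: ", bam,
         " -- sort and index the file first")
  header <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  missing_contig <- setdiff(unique(sites$contig), names(header))
  if (length(missing_contig))
    stop("contig absent from BAM header: ",
         paste(missing_contig, collapse = ", "))
  if (is.null(sample))
    sample <- sub("\\.bam$", "", basename(bam))

  gr <- GenomicRanges::GRanges(sites$contig,
                               IRanges::IRanges(sites$pos, width = 1L))
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isProperPair = if (filters$require_proper_pair) TRUE else NA,
    isSecondaryAlignment = if (filters$drop_secondary) FALSE else NA,
    isDuplicate = if (filters$drop_duplicates) FALSE else NA
  )
  sbp <- Rsamtools::ScanBamParam(which = gr, flag = flag)
  pp <- Rsamtools::PileupParam(
    max_depth = as.integer(max_depth),
    min_base_quality = filters$min_baseq,
    min_mapq = filters$min_mapq,
    min_nucleotide_depth = 1L,
    distinguish_strands = FALSE,
    distinguish_nucleotides = TRUE,
    include_deletions = FALSE,
    include_insertions = FALSE
  )
  p <- Rsamtools::pileup(bam, scanBamParam = sbp, pileupParam = pp)

  site_key <- paste(sites$contig, sites$pos)
  row_of <- match(paste(as.character(p$seqnames), p$pos), site_key)
  n_ref <- integer(nrow(sites))
  n_alt <- integer(nrow(sites))
  is_ref <- as.character(p$nucleotide) == sites$ref[row_of]
  is_alt <- as.character(p$nucleotide) == sites$alt[row_of]
  keep <- !is.na(row_of)
  if (any(keep & is_ref)) {
    agg <- tapply(p$count[keep & is_ref], row_of[keep & is_ref], sum)
    n_ref[as.integer(names(agg))] <- agg
  }
  if (any(keep & is_alt)) {
    agg <- tapply(p$count[keep & is_alt], row_of[keep & is_alt], sum)
    n_alt[as.integer(names(agg))] <- agg
  }
  data.frame(sample = sample, contig = sites$contig, pos = sites$pos,
             ref = sites$ref, alt = sites$alt,
             nRef = as.integer(n_ref), nAlt = as.integer(n_alt),
             stringsAsFactors = FALSE)
}

#' Read a biallelic-SNP site list from a VCF file
#'
#' Only CHROM/POS/REF/ALT are used; rows whose REF or ALT is not a single
#' A/C/G/T base (indels, multi-allelic records) are dropped.
#'
#' @param vcf path to a VCF v4.2 file (plain or bgzipped).
#' @return data.frame `contig`, `pos`, `ref`, `alt`, in file order.
#' @export
read_sites <- function(vcf) {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0)
    return(data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      stringsAsFactors = FALSE))
  sites <- data.frame(contig = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  bases <- c("A", "C", "G", "T")
  sites[sites$ref %in% bases & sites$alt %in% bases &
          sites$ref != sites$alt, , drop = FALSE]
}

#' Default coverage strata used in the concordance tables
#'
#' Depths 1-5 each form their own stratum, depths 6-10 are pooled, and depths
#' of 0 or above 10 are excluded.
#'
#' @return data.frame with columns `lo`, `hi`, `label`.
#' @export
default_strata <- function() {
  data.frame(lo = c(1L, 2L, 3L, 4L, 5L, 6L),
             hi = c(1L, 2L, 3L, 4L, 5L, 10L),
             label = c("1x", "2x", "3x", "4x", "5x", "6-10x"),
             stringsAsFactors = FALSE)
}

#' Assign site depths to coverage strata
#'
#' @param depth vector of site depths (`nRef + nAlt`).
#' @param bins data.frame with columns `lo`, `hi`, `label` defining disjoint
#'   integer depth ranges; defaults to [default_strata()]. Depths covered by
#'   no bin map to `"excluded"`.
#' @return character vector of stratum labels.
#' @examples
#' coverage_stratum(c(0, 1, 7, 11))
#' @export
coverage_stratum <- function(depth, bins = default_strata()) {
  if (!is.data.frame(bins) || !all(c("lo", "hi", "label") %in% names(bins)))
    stop("bins must be a data.frame with columns lo, hi, label")
  if (any(bins$lo > bins$hi) || any(bins$lo < 1))
    stop("each bin needs 1 <= lo <= hi")
  o <- order(bins$lo)
  if (nrow(bins) > 1 && any(bins$hi[o][-nrow(bins)] >= bins$lo[o][-1]))
    stop("overlapping coverage bins")
  out <- rep("excluded", length(depth))
  for (i in seq_len(nrow(bins))) {
    hit <- !is.na(depth) & depth >= bins$lo[i] & depth <= bins$hi[i]
    out[hit] <- bins$label[i]
  }
  out
}

#' Write / read the counts TSV dialect
#'
#' Columns: `sample`, `contig`, `pos`, `ref`, `alt`, `nRef`, `nAlt`. An
#' optional `# orientation:` comment header records whether `nRef` counts the
#' original reference allele (see [combine_counts()]).
#'
#' @param counts data.frame in the counts layout.
#' @param path output TSV path.
#' @param orientation free-text orientation note, recorded as a comment line.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, orientation = "original") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# orientation: ", orientation), con)
  utils::write.table(counts, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
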