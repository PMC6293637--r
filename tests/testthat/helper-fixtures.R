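# build a tiny indexed BAM from a read table; columns default to passing reads
make_bam <- function(reads, contig_lengths = c(chr1 = 1000L),
                     dir = withr::local_tempdir(.local_envir = parent.frame())) {
  defaults <- data.frame(qname = sprintf("r%03d", seq_len(nrow(reads))),
                         contig = "chr1", pos = 1L, mapq = 60L, base = "A",
                         proper_pair = TRUE, secondary = FALSE,
                         duplicate = FALSE, stringsAsFactors = FALSE)
  for (col in names(reads)) defaults[[col]] <- reads[[col]]
  bam <- file.path(dir, "fixture.bam")
  lcgeno:::write_read_bam(defaults, contig_lengths, bam)
  bam
}

one_site <- function(pos = 10L, ref = "A", alt = "G") {
  data.frame(contig = "chr1", pos = as.integer(pos), ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

# all (nRef, nAlt) pairs with depth <= max_depth
count_grid <- function(max_depth = 12L) {
  g <- expand.grid(nRef = 0:max_depth, nAlt = 0:max_depth)
  g[g$nRef + g$nAlt <= max_depth, ]
}
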