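test_that("truth simulation respects monomorphic frequencies and rejects bad sizes", {
  expect_true(all(simulate_truth(20, 50, maf = 0, seed = 1)$genotypes == 0L))
  expect_true(all(simulate_truth(20, 50, maf = 1, seed = 1)$genotypes == 2L))
  expect_error(simulate_truth(0, 10), "positive")
  expect_error(simulate_truth(10, 0), "positive")
  expect_error(simulate_truth(10, 5, maf = 1.5), "frequency")
})

test_that("genotypes follow Hardy-Weinberg proportions", {
  # heterozygote fraction at maf 0.5 within 3 binomial SE of 2pq = 0.5
  ts <- simulate_truth(10000, 1, maf = 0.5, seed = 42)
  het <- mean(ts$genotypes == 1L)
  expect_lt(abs(het - 0.5), 3 * sqrt(0.25 / 10000))

  # chi-square goodness of fit against (p^2, 2pq, q^2) at maf 0.3
  ts <- simulate_truth(10000, 1, maf = 0.3, seed = 7)
  obs <- tabulate(ts$genotypes + 1L, 3L)
  p <- 0.3
  gof <- chisq.test(obs, p = c((1 - p)^2, 2 * p * (1 - p), p^2))
  expect_gt(gof$p.value, 0.01)

  # site positions strictly increasing, dosages confined to 0/1/2
  expect_true(all(diff(ts$sites$pos) > 0))
  expect_true(all(ts$genotypes %in% 0:2))
})

test_that("read simulation matches its Poisson and error model", {
  ts <- simulate_truth(1, 10000, maf = 0.5, seed = 3)
  rs <- simulate_reads(ts, mean_coverage = 2, error_rate = 0.01, seed = 4)
  mean_depth <- nrow(rs$fragments) / 10000
  expect_lt(abs(mean_depth - 2), 3 * sqrt(2 / 10000))

  expect_identical(nrow(simulate_reads(ts, 0, seed = 1)$fragments), 0L)
  expect_error(simulate_reads(ts, -1), "non-negative")
  expect_error(simulate_reads(ts, 2, error_rate = 0.6), "error_rate")

  # error-free reads over homozygous-reference truth carry only ref alleles
  ts0 <- simulate_truth(5, 200, maf = 0, seed = 5)
  rs0 <- simulate_reads(ts0, 3, error_rate = 0, seed = 6)
  expect_true(all(rs0$fragments$observed_allele == "ref"))

  # at homozygous sites the alt-read fraction converges to the error rate
  rs_err <- simulate_reads(ts0, 5, error_rate = 0.1, seed = 8)
  frac <- mean(rs_err$fragments$observed_allele == "alt")
  n <- nrow(rs_err$fragments)
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / n))
})

test_that("same seed reproduces the simulation bitwise", {
  a <- simulate_truth(8, 30, seed = 11)
  b <- simulate_truth(8, 30, seed = 11)
  expect_identical(a, b)
  expect_identical(simulate_reads(a, 2, seed = 12)$fragments,
                   simulate_reads(b, 2, seed = 12)$fragments)

  rs <- simulate_reads(a, 2, seed = 12)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- write_fixture(a, rs, d1)
  f2 <- write_fixture(a, rs, d2)
  expect_identical(readLines(f1$truth_tsv), readLines(f2$truth_tsv))
})

test_that("fixture files round-trip through the standard-format readers", {
  ts <- simulate_truth(2, 15, maf = 0.4, seed = 21)
  rs <- simulate_reads(ts, 3, error_rate = 0, seed = 22)
  d <- withr::local_tempdir()
  fx <- write_fixture(ts, rs, d)

  sites <- read_sites(fx$vcf)
  expect_identical(sites[c("contig", "pos", "ref", "alt")],
                   ts$sites[c("contig", "pos", "ref", "alt")])
  truth <- read_truth(fx$truth_tsv)
  expect_identical(nrow(truth), 2L * 15L)
  expect_identical(truth$dosage[truth$sample == "S002"],
                   unname(ts$genotypes["S002", ]))

  # extraction with all-passing reads recovers the generator tallies exactly
  tal <- tally_allele_counts(rs)
  for (s in ts$samples) {
    cnt <- extract_allele_counts(fx$bam[[s]], sites, sample = s)
    expect_identical(cnt$nRef, unname(tal$nRef[s, ]))
    expect_identical(cnt$nAlt, unname(tal$nAlt[s, ]))
  }

  # FASTA carries the declared reference allele at every site
  genome <- Biostrings::readDNAStringSet(fx$fasta)
  found <- substring(as.character(genome[["chr1"]]), ts$sites$pos,
                     ts$sites$pos)
  expect_identical(found, ts$sites$ref)
})

test_that("an empty truth set yields a valid header-only VCF", {
  ts <- simulate_truth(1, 1, maf = 0, seed = 1)
  ts$sites <- ts$sites[0, ]
  ts$genotypes <- ts$genotypes[, 0, drop = FALSE]
  rs <- structure(list(samples = ts$samples, sites = ts$sites,
                       fragments = simulate_reads(simulate_truth(1, 1, seed = 1),
                                                  0, seed = 1)$fragments),
                  class = "multiplex_read_set")
  d <- withr::local_tempdir()
  fx <- write_fixture(ts, rs, d)
  expect_identical(nrow(read_sites(fx$vcf)), 0L)
})

test_that("hand-built counts survive the BAM round trip", {
  # 1 sample, 1 site, 3 ref reads + 2 alt reads -> (3, 2)
  bam <- make_bam(data.frame(pos = 10L,
                             base = c("A", "A", "A", "G", "G")))
  cnt <- extract_allele_counts(bam, one_site(10, "A", "G"))
  expect_identical(c(cnt$nRef, cnt$nAlt), c(3L, 2L))
})
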