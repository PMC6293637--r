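#' Genotype and allele concordance between true and called dosages
#'
#' Pairs where either side is missing (no-call) are excluded from every
#' percentage. Genotype concordance is the percentage of called pairs whose
#' dosages match exactly. Allele concordance is the percentage of matched
#' alleles: an unphased diploid genotype shares `2 - |d_true - d_call|` of
#' its two alleles with the call, so a hom/het mismatch still matches one
#' allele of two. The confusion matrix entry (x|y) is the percentage of
#' called-x among the called pairs with true genotype y (columns sum to 100).
#'
#' @param true,called dosage vectors in 0/1/2 with `NA` for missing/no-call,
#'   aligned elementwise.
#' @return list of class `concordance_stats`: `n_called`,
#'   `genotype_concordance`, `allele_concordance`, `confusion` (3x3 percent
#'   matrix, rows = called, cols = true), `counts` (3x3 integer matrix).
#' @examples
#' concordance_stats(c(0, 0, 1, 1, 2), c(0, 1, 1, 1, 0))
#' @export
concordance_stats <- function(true, called) {
  if (length(true) != length(called))
    stop("true and called must have equal length")
  ok <- !is.na(true) & !is.na(called)
  true <- true[ok]; called <- called[ok]
  if (any(c(true, called) %ni% 0:2))
    stop("dosages must be 0, 1 or 2")
  n <- length(true)
  counts <- table(factor(called, 0:2), factor(true, 0:2))
  col_n <- colSums(counts)
  confusion <- sweep(counts, 2, ifelse(col_n > 0, col_n, NA), "/") * 100
  structure(list(
    n_called = n,
    genotype_concordance = if (n) 100 * mean(true == called) else NA_real_,
    allele_concordance = if (n) 100 * mean((2 - abs(true - called)) / 2)
                         else NA_real_,
    confusion = as.matrix(unclass(confusion)),
    counts = as.matrix(unclass(counts))
  ), class = "concordance_stats")
}

`%ni%` <- function(x, table) !(x %in% table)

#' @export
print.concordance_stats <- function(x, digits = 2, ...) {
  cat(sprintf("n called: %d\ngenotype concordance: %.*f%%\nallele concordance: %.*f%%\n",
              x$n_called, digits, x$genotype_concordance, digits,
              x$allele_concordance))
  cat("confusion (% of true-genotype column):\n")
  print(round(x$confusion, digits))
  invisible(x)
}

#' Flatten a confusion matrix into named "called|true" variables
#'
#' @param stats a `concordance_stats` object (or a `concordance_table`, whose
#'   overall block is used).
#' @return named numeric vector with names `"0|0"`, `"1|0"`, ..., `"2|2"`
#'   (called|true), in true-genotype-major order.
#' @export
concordance_variables <- function(stats) {
  if (inherits(stats, "concordance_table")) stats <- stats$overall
  stopifnot(inherits(stats, "concordance_stats"))
  cf <- stats$confusion
  out <- as.vector(cf)  # column-major: true genotype major
  names(out) <- paste0(rep(rownames(cf), times = 3), "|",
                       rep(colnames(cf), each = 3))
  out
}

#' Coverage-stratified concordance between keyed truth and call tables
#'
#' Joins a truth table and a call table on `(sample, contig, pos)` and
#' computes [concordance_stats()] overall and, optionally, within coverage
#' strata. The overall block uses every called pair; each stratum block uses
#' the pairs carrying that label (the label `"excluded"` gets no block).
#'
#' @param truth data.frame `sample`, `contig`, `pos`, `dosage` (true
#'   genotypes; `NA` = missing).
#' @param calls data.frame `sample`, `contig`, `pos`, `dosage` (calls; `NA` =
#'   no-call), keyed identically to `truth`.
#' @param strata optional data.frame `sample`, `contig`, `pos`, `stratum`
#'   (e.g. built with [coverage_stratum()] from a counts table), keyed like
#'   the other two.
#' @return list of class `concordance_table`: `overall` (a
#'   `concordance_stats`) and `strata` (named list of `concordance_stats`).
#' @export
build_concordance <- function(truth, calls, strata = NULL) {
  key <- function(d) paste(d$sample, d$contig, d$pos, sep = ":")
  kt <- key(truth); kc <- key(calls)
  bad <- c(setdiff(kt, kc), setdiff(kc, kt))
  if (length(bad))
    stop("truth/call tables are not keyed identically; first offending key: ",
         bad[1])
  m <- match(kt, kc)
  true <- truth$dosage
  called <- calls$dosage[m]
  out <- list(overall = concordance_stats(true, called), strata = list())
  if (!is.null(strata)) {
    ks <- key(strata)
    sm <- strata$stratum[match(kt, ks)]
    labs <- setdiff(unique(stats::na.omit(sm)), "excluded")
    # keep natural depth order where the default labels are used
    pref <- default_strata()$label
    labs <- c(intersect(pref, labs), setdiff(labs, pref))
    out$strata <- lapply(labs, function(l) {
      concordance_stats(true[!is.na(sm) & sm == l],
                        called[!is.na(sm) & sm == l])
    })
    names(out$strata) <- labs
  }
  structure(out, class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, digits = 2, ...) {
  fmt <- function(s) sprintf("n=%d  genotype=%.*f%%  allele=%.*f%%",
                             s$n_called, digits, s$genotype_concordance,
                             digits, s$allele_concordance)
  cat("overall: ", fmt(x$overall), "\n", sep = "")
  for (l in names(x$strata))
    cat(sprintf("  %-7s %s\n", l, fmt(x$strata[[l]])))
  invisible(x)
}

#' Write a concordance table as long-format TSV
#'
#' One row per (stratum, true, called) cell with the pair count and the
#' column-normalised percentage, plus `overall` rows; percentages are written
#' with 2 decimals.
#'
#' @param ct a `concordance_table` or `concordance_stats`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_concordance <- function(ct, path) {
  if (inherits(ct, "concordance_stats"))
    ct <- structure(list(overall = ct, strata = list()),
                    class = "concordance_table")
  blocks <- c(list(overall = ct$overall), ct$strata)
  rows <- do.call(rbind, lapply(names(blocks), function(l) {
    s <- blocks[[l]]
    data.frame(stratum = l,
               true = rep(0:2, each = 3), called = rep(0:2, times = 3),
               n = as.vector(s$counts),
               percent = sprintf("%.2f", as.vector(s$confusion)),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
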