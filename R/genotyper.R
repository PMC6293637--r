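#' Genotype probabilities from allele read counts
#'
#' For a biallelic site with `nRef` reference-allele reads and `nAlt`
#' alternative-allele reads, and a per-base sequencing error rate `e`, the
#' unscaled genotype likelihoods are
#' \deqn{p(0) = (1-e)^{nRef} e^{nAlt},\quad
#'       p(1) = 0.5^{nRef+nAlt},\quad
#'       p(2) = e^{nRef} (1-e)^{nAlt},}
#' for the reference homozygote (dosage 0), heterozygote (1) and alternative
#' homozygote (2). The three values are scaled to sum to 1. Computation is in
#' log space, so deep sites do not underflow. At depth 0 all three
#' probabilities are 1/3.
#'
#' @param nRef,nAlt non-negative integer vectors of equal length (or length
#'   1, recycled).
#' @param e sequencing error rate, strictly inside (0, 0.5). The default 0.01
#'   is the conventional post-filtering Illumina error rate.
#' @return numeric matrix with columns `p0`, `p1`, `p2`, rows summing to 1.
#' @examples
#' genotype_probabilities(1, 0)        # (0.66, 0.3333, 0.0067)
#' genotype_probabilities(30, 0)       # hom-ref with near certainty
#' @export
genotype_probabilities <- function(nRef, nAlt, e = 0.01) {
  if (length(e) != 1 || is.na(e) || e <= 0 || e >= 0.5)
    stop("e must be a single value in (0, 0.5)")
  n <- max(length(nRef), length(nAlt))
  nRef <- rep_len(as.numeric(nRef), n)
  nAlt <- rep_len(as.numeric(nAlt), n)
  if (any(nRef < 0 | nAlt < 0 | is.na(nRef) | is.na(nAlt)))
    stop("allele counts must be non-negative")
  lp <- cbind(p0 = nRef * log1p(-e) + nAlt * log(e),
              p1 = (nRef + nAlt) * log(0.5),
              p2 = nRef * log(e) + nAlt * log1p(-e))
  m <- apply(lp, 1, max)
  p <- exp(lp - m)
  p / rowSums(p)
}

# log-likelihoods allowing e == 0 (presence/absence limit); 0 * log(0) := 0
loglik_matrix <- function(nRef, nAlt, e) {
  xlog <- function(k, p) ifelse(k == 0, 0, k * log(p))
  cbind(p0 = xlog(nRef, 1 - e) + xlog(nAlt, e),
        p1 = (nRef + nAlt) * log(0.5),
        p2 = xlog(nRef, e) + xlog(nAlt, 1 - e))
}

#' Call genotypes from allele read counts
#'
#' Four calling modes:
#' \describe{
#'   \item{`best-guess`}{the most probable genotype, however small its
#'     probability; no-call at depth 0 or on an exact tie of the maxima.}
#'   \item{`p90` / `p98`}{the most probable genotype only if its scaled
#'     probability strictly exceeds 0.90 / 0.98, else no-call.}
#'   \item{`presence`}{presence/absence calling: a single read of each allele
#'     suffices to declare the allele present, so a site is heterozygous when
#'     both `nRef > 0` and `nAlt > 0`, homozygous when only one allele is
#'     seen, and no-call at depth 0. Equivalent to best-guess calling in the
#'     zero-error limit.}
#' }
#'
#' @param nRef,nAlt non-negative integer vectors (recycled to equal length).
#' @param mode one of `"best-guess"`, `"p90"`, `"p98"`, `"presence"`.
#' @param e sequencing error rate used for the probabilities; must be in
#'   (0, 0.5) for the probabilistic modes.
#' @return data.frame with columns `dosage` (integer 0/1/2, `NA` = no-call),
#'   `p0`, `p1`, `p2` (scaled probabilities; `NA` in presence mode at e = 0)
#'   and `mode`.
#' @examples
#' call_genotype(10, 1, mode = "presence")$dosage   # 1: heterozygote
#' call_genotype(10, 0, mode = "presence")$dosage   # 0: homozygote
#' call_genotype(1, 0, mode = "p90")$dosage         # NA: max p = 0.66
#' @export
call_genotype <- function(nRef, nAlt,
                          mode = c("best-guess", "p90", "p98", "presence"),
                          e = 0.01) {
  mode <- match.arg(mode)
  n <- max(length(nRef), length(nAlt))
  nRef <- rep_len(as.numeric(nRef), n)
  nAlt <- rep_len(as.numeric(nAlt), n)
  if (any(nRef < 0 | nAlt < 0 | is.na(nRef) | is.na(nAlt)))
    stop("allele counts must be non-negative")
  depth <- nRef + nAlt

  if (mode == "presence") {
    dosage <- rep(NA_integer_, n)
    dosage[nRef > 0 & nAlt > 0] <- 1L
    dosage[nRef > 0 & nAlt == 0] <- 0L
    dosage[nRef == 0 & nAlt > 0] <- 2L
    p <- if (e > 0 && e < 0.5) genotype_probabilities(nRef, nAlt, e)
         else matrix(NA_real_, n, 3, dimnames = list(NULL, c("p0", "p1", "p2")))
    return(data.frame(dosage = dosage, p0 = p[, 1], p1 = p[, 2], p2 = p[, 3],
                      mode = mode, stringsAsFactors = FALSE))
  }

  p <- genotype_probabilities(nRef, nAlt, e)
  pmaxv <- pmax(p[, 1], p[, 2], p[, 3])
  # exact tie of the maxima (incl. depth 0, where all three are 1/3)
  tie <- (abs(p[, 1] - pmaxv) < 1e-12) + (abs(p[, 2] - pmaxv) < 1e-12) +
    (abs(p[, 3] - pmaxv) < 1e-12) > 1
  argmax <- max.col(p, ties.method = "first") - 1L
  dosage <- ifelse(depth == 0 | tie, NA_integer_, argmax)
  if (mode == "p90") dosage[!is.na(dosage) & pmaxv <= 0.90] <- NA_integer_
  if (mode == "p98") dosage[!is.na(dosage) & pmaxv <= 0.98] <- NA_integer_
  data.frame(dosage = as.integer(dosage), p0 = p[, 1], p1 = p[, 2],
             p2 = p[, 3], mode = mode, stringsAsFactors = FALSE)
}

#' Emulate the reference-allele bias of read-threading-graph pruning
#'
#' Graph-based variant callers prune haplotype paths supported by fewer reads
#' than a threshold (default 2) to remove likely sequencing errors. At low
#' coverage this re-attributes weakly supported alternative alleles to the
#' reference: when the alternative path is pruned, its reads are subsequently
#' matched against the only surviving haplotype — the reference — and counted
#' as reference reads. The emulator applies exactly that transformation to an
#' allele-count table: if `nAlt < min_pruning`, the counts become
#' `(nRef + nAlt, 0)`; otherwise they are unchanged. The reference path is
#' never pruned (it is always present in the caller's graph), which is why
#' the operation is deliberately asymmetric.
#'
#' @param counts data.frame with columns `nRef` and `nAlt` (other columns are
#'   passed through unchanged).
#' @param min_pruning pruning threshold, >= 1; a path survives when its read
#'   support is at least this many reads.
#' @return `counts` with `nRef`/`nAlt` replaced by the post-pruning counts.
#' @examples
#' emulate_pruning(data.frame(nRef = 0, nAlt = 1))   # -> (1, 0)
#' emulate_pruning(data.frame(nRef = 2, nAlt = 1))   # -> (3, 0)
#' emulate_pruning(data.frame(nRef = 0, nAlt = 2))   # unchanged
#' @export
emulate_pruning <- function(counts, min_pruning = 2L) {
  if (length(min_pruning) != 1 || is.na(min_pruning) || min_pruning < 1)
    stop("min_pruning must be a single integer >= 1")
  if (!is.data.frame(counts) || !all(c("nRef", "nAlt") %in% names(counts)))
    stop("counts must be a data.frame with columns nRef and nAlt")
  pruned <- which(counts$nAlt < min_pruning)
  counts$nRef[pruned] <- counts$nRef[pruned] + counts$nAlt[pruned]
  counts$nAlt[pruned] <- 0L
  counts
}

#' Call genotypes for a whole counts table
#'
#' Convenience wrapper: optionally applies the pruning emulator, then calls
#' [call_genotype()] row-wise over a counts table.
#'
#' @param counts data.frame in the counts layout (at least `nRef`, `nAlt`).
#' @param mode,e passed to [call_genotype()].
#' @param prune if non-`NULL`, apply [emulate_pruning()] with this threshold
#'   before calling.
#' @return `counts` with columns `dosage`, `p0`, `p1`, `p2`, `mode` appended.
#' @export
call_genotypes <- function(counts, mode = "best-guess", e = 0.01,
                           prune = NULL) {
  if (!is.null(prune)) counts <- emulate_pruning(counts, prune)
  cbind(counts, call_genotype(counts$nRef, counts$nAlt, mode = mode, e = e))
}
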