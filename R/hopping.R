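#' Down-sample a read set
#'
#' Keeps each fragment independently with probability `fraction`, emulating
#' the random sampling of reads that occurs during sequencing (e.g. drawing
#' ~1/15 of 30x reads to obtain 2x data). Each invocation draws
#' independently.
#'
#' @param reads a `multiplex_read_set`.
#' @param fraction keep probability in \[0, 1\].
#' @param seed integer seed.
#' @return a `multiplex_read_set` containing the kept fragments.
#' @export
downsample <- function(reads, fraction, seed = NULL) {
  stopifnot(inherits(reads, "multiplex_read_set"))
  if (length(fraction) != 1 || is.na(fraction) || fraction < 0 || fraction > 1)
    stop("fraction must be a single probability in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  keep <- stats::runif(nrow(reads$fragments)) < fraction
  reads$fragments <- reads$fragments[keep, , drop = FALSE]
  reads
}

#' Inject index hopping into a multiplexed read set
#'
#' Each fragment is independently reassigned with probability `h` to a sample
#' drawn uniformly from the other samples in the multiplex; both mates of a
#' fragment move together (index hopping is a library-fragment phenomenon —
#' the pair shares one index pair). The total fragment count and the per-site
#' allele totals across the whole multiplex are conserved: hopping moves
#' reads between samples, it does not create or destroy them.
#'
#' @param reads a `multiplex_read_set` with at least two samples when
#'   `h > 0`.
#' @param h hop probability in \[0, 1\].
#' @param seed integer seed.
#' @return a `multiplex_read_set` with `assigned_sample` updated.
#' @export
inject_hopping <- function(reads, h, seed = NULL) {
  stopifnot(inherits(reads, "multiplex_read_set"))
  if (length(h) != 1 || is.na(h) || h < 0 || h > 1)
    stop("h must be a single probability in [0, 1]")
  n_samples <- length(reads$samples)
  if (h > 0 && n_samples < 2)
    stop("index hopping requires a multiplex of at least two samples")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(reads$fragments)
  hop <- stats::runif(n) < h
  if (any(hop)) {
    cur <- match(reads$fragments$assigned_sample[hop], reads$samples)
    # uniform over the other n-1 samples: draw an offset 1..n-1 and wrap
    offset <- sample.int(n_samples - 1L, sum(hop), replace = TRUE)
    reads$fragments$assigned_sample[hop] <-
      reads$samples[(cur - 1L + offset) %% n_samples + 1L]
  }
  reads
}

#' Isometric log-ratio of a 3-part concordance composition
#'
#' `sqrt(2/3) * ln(c_correct / sqrt(c_err_a * c_err_b))`: the balance of the
#' correct-call percentage against the two error percentages for one true
#' genotype. Scale-invariant, so raw counts and percentages give the same
#' value.
#'
#' @param c_correct,c_err_a,c_err_b strictly positive parts (percentages or
#'   counts); vectors are accepted elementwise.
#' @return numeric ilr value(s).
#' @examples
#' ilr_3part(98.45, 1.42, 0.13)   # 4.44
#' @export
ilr_3part <- function(c_correct, c_err_a, c_err_b) {
  parts <- cbind(c_correct, c_err_a, c_err_b)
  if (any(!is.finite(parts)) || any(parts <= 0))
    stop("ilr parts must be strictly positive and finite; ",
         "use a pseudo-count explicitly if a part is zero")
  sqrt(2 / 3) * log(c_correct / sqrt(c_err_a * c_err_b))
}

#' Isometric log-ratio of a 2-part concordance composition
#'
#' `(1/sqrt(2)) * ln(c_correct / c_err)`: the balance of the correct
#' homozygous-call percentage against one error percentage.
#'
#' @param c_correct,c_err strictly positive parts.
#' @return numeric ilr value(s).
#' @examples
#' ilr_2part(98.45, 1.42)   # 3.00
#' @export
ilr_2part <- function(c_correct, c_err) {
  parts <- cbind(c_correct, c_err)
  if (any(!is.finite(parts)) || any(parts <= 0))
    stop("ilr parts must be strictly positive and finite; ",
         "use a pseudo-count explicitly if a part is zero")
  (1 / sqrt(2)) * log(c_correct / c_err)
}

#' Regress a concordance response on the simulated hop level
#'
#' Ordinary least squares of a response (a concordance percentage, or its ilr
#' transform) on the simulated index-hopping level, linear (`degree = 1`) or
#' quadratic (`degree = 2`). Percentage responses are conventionally fitted
#' with degree 1 and ilr responses with degree 2.
#'
#' @param levels hop levels in percent; distinct, at least `degree + 2` of
#'   them.
#' @param responses response values at those levels.
#' @param degree 1 or 2.
#' @return object of class `hop_fit`: `degree`, `coefficients` (intercept,
#'   slope and, for degree 2, curvature), `r_squared`, `levels`, `responses`.
#' @examples
#' f <- fit_level_regression(c(0, 0.1, 0.5, 1, 2, 5),
#'                           c(99.62, 99.53, 99.28, 98.99, 98.20, 96.34))
#' f$r_squared   # 0.999
#' @export
fit_level_regression <- function(levels, responses, degree = 1L) {
  if (!degree %in% c(1L, 2L)) stop("degree must be 1 or 2")
  if (length(levels) != length(responses))
    stop("levels and responses must have equal length")
  if (anyDuplicated(levels)) stop("levels must be distinct")
  if (length(levels) < degree + 1)
    stop("need at least degree + 1 calibration points")
  if (any(!is.finite(levels)) || any(!is.finite(responses)))
    stop("levels and responses must be finite")
  fit <- if (degree == 1L) stats::lm(responses ~ levels)
         else stats::lm(responses ~ levels + I(levels^2))
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient calibration design")
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((responses - mean(responses))^2)
  structure(list(degree = degree,
                 coefficients = unname(stats::coef(fit)),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 levels = levels, responses = responses),
            class = "hop_fit")
}

#' @export
print.hop_fit <- function(x, ...) {
  cat(sprintf("hop_fit degree %d: coef = (%s), R^2 = %.4f\n", x$degree,
              paste(signif(x$coefficients, 5), collapse = ", "),
              x$r_squared))
  invisible(x)
}

#' Invert a calibration fit at an observed response
#'
#' Solves the fitted calibration curve for the hop level that would produce
#' the observed response. For a linear fit this is
#' `(observed - intercept) / slope`; for a quadratic fit it is the real root
#' of the fitted polynomial lying within the calibrated level span (the
#' smaller such root if two qualify — in practice the response curves are
#' monotone over the span, so at most one interior root occurs).
#'
#' @param fit a `hop_fit`.
#' @param observed observed response value (single number).
#' @return estimated hop level, in percent.
#' @examples
#' f <- fit_level_regression(c(0, 0.1, 0.5, 1, 2, 5),
#'                           c(0.04, 0.08, 0.10, 0.14, 0.23, 0.59))
#' estimate_hop_level(f, 0.18)   # 1.28
#' @export
estimate_hop_level <- function(fit, observed) {
  stopifnot(inherits(fit, "hop_fit"), length(observed) == 1,
            is.finite(observed))
  cf <- fit$coefficients
  if (fit$degree == 1L) {
    if (abs(cf[2]) < .Machine$double.eps)
      stop("zero slope: the response does not depend on the hop level")
    return(unname((observed - cf[1]) / cf[2]))
  }
  roots <- polyroot(c(cf[1] - observed, cf[2], cf[3]))
  real <- Re(roots[abs(Im(roots)) < 1e-8])
  lo <- min(fit$levels); hi <- max(fit$levels)
  inside <- real[real >= lo - 1e-9 & real <= hi + 1e-9]
  if (!length(inside))
    stop("observed response outside calibrated range: no real root in [",
         lo, ", ", hi, "]")
  unname(min(inside))
}

#' Build a calibration grid of concordance variables over hop levels
#'
#' For each level in `levels`, simulates an independent read set over `truth`
#' (fresh down-sampling noise per level, as when the data are down-sampled
#' independently before each hop simulation), injects index hopping at that
#' level, tallies allele counts per assigned sample, calls genotypes, and
#' records the nine confusion percentages "called|true" against the truth
#' genotypes.
#'
#' @param truth a `truth_set`.
#' @param levels hop levels in percent (e.g. `c(0, 0.1, 0.5, 1, 2, 5)`).
#' @param mean_coverage,error_rate passed to [simulate_reads()].
#' @param mode calling mode; presence/absence is the most hop-sensitive and
#'   is the default.
#' @param e error rate for probabilistic calling modes.
#' @param seed integer seed; per-level sub-seeds are derived from it.
#' @return data.frame `level` (percent), `variable` ("called|true"), `value`
#'   (percent).
#' @export
hop_calibration_grid <- function(truth, levels = c(0, 0.1, 0.5, 1, 2, 5),
                                 mean_coverage = 2, error_rate = 0.01,
                                 mode = "presence", e = 0.01, seed = 1L) {
  stopifnot(inherits(truth, "truth_set"))
  if (any(levels < 0 | levels > 100)) stop("levels must be percentages")
  out <- lapply(seq_along(levels), function(i) {
    sub_seed <- (seed + 7919L * i) %% .Machine$integer.max
    rs <- simulate_reads(truth, mean_coverage, error_rate, seed = sub_seed)
    rs <- inject_hopping(rs, levels[i] / 100, seed = sub_seed + 1L)
    v <- multiplex_concordance(rs, truth, mode = mode, e = e)
    data.frame(level = levels[i], variable = names(v), value = unname(v),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Concordance variables of a read set against its truth genotypes
#'
#' Tallies allele counts per assigned sample, calls genotypes and returns the
#' nine confusion percentages "called|true" (see
#' [concordance_variables()]).
#'
#' @param reads a `multiplex_read_set`.
#' @param truth the `truth_set` it was simulated from.
#' @param mode,e passed to [call_genotype()].
#' @return named numeric vector of confusion percentages.
#' @export
multiplex_concordance <- function(reads, truth, mode = "presence", e = 0.01) {
  tal <- tally_allele_counts(reads)
  calls <- call_genotype(as.vector(tal$nRef), as.vector(tal$nAlt),
                         mode = mode, e = e)
  concordance_variables(
    concordance_stats(as.vector(truth$genotypes), calls$dosage))
}

#' Estimate the index-hopping level from a calibration grid
#'
#' Fits each concordance variable's calibration curve on the hop level and
#' inverts it at the observed value, reporting one estimate per variable plus
#' the fit's coefficient of determination. Variables whose observed or
#' calibration values are missing are skipped.
#'
#' @param calibration data.frame `level`, `variable`, `value` (e.g. from
#'   [hop_calibration_grid()]).
#' @param observed named numeric vector of observed values (names matching
#'   `variable`), or a data.frame `variable`, `value`.
#' @param degree regression degree (1 for raw percentages, 2 for ilr
#'   responses).
#' @param variables which variables to use; defaults to all shared between
#'   calibration and observed.
#' @return data.frame `variable`, `estimate` (percent), `r_squared`.
#' @export
estimate_hopping <- function(calibration, observed, degree = 1L,
                             variables = NULL) {
  if (is.data.frame(observed))
    observed <- stats::setNames(observed$value, observed$variable)
  if (is.null(variables))
    variables <- intersect(unique(calibration$variable), names(observed))
  rows <- lapply(variables, function(v) {
    cal <- calibration[calibration$variable == v, ]
    obs <- observed[[v]]
    if (!nrow(cal) || !is.finite(obs) || any(!is.finite(cal$value)))
      return(NULL)
    fit <- fit_level_regression(cal$level, cal$value, degree = degree)
    est <- tryCatch(estimate_hop_level(fit, obs), error = function(e) NA_real_)
    data.frame(variable = v, estimate = est, r_squared = fit$r_squared,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
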