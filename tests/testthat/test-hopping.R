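make_reads <- function(n_samples = 4, n_sites = 50, coverage = 3, seed = 1) {
  ts <- simulate_truth(n_samples, n_sites, maf = 0.4, seed = seed)
  list(truth = ts,
       reads = simulate_reads(ts, coverage, error_rate = 0.01,
                              seed = seed + 1))
}

test_that("down-sampling keeps fragments binomially and handles the extremes", {
  rs <- make_reads()$reads
  expect_identical(downsample(rs, 1, seed = 1)$fragments, rs$fragments)
  expect_identical(nrow(downsample(rs, 0, seed = 1)$fragments), 0L)
  expect_error(downsample(rs, 1.2), "probability")

  big <- make_reads(10, 2000, coverage = 7.5, seed = 5)$reads  # ~150k reads
  n <- nrow(big$fragments)
  kept <- nrow(downsample(big, 1 / 15, seed = 6)$fragments)
  expect_lt(abs(kept - n / 15), 3 * sqrt(n * (1 / 15) * (14 / 15)))
})

test_that("hop injection moves fragments but conserves the multiplex", {
  rs <- make_reads(6, 100, coverage = 4)$reads

  none <- inject_hopping(rs, 0, seed = 2)
  expect_identical(none$fragments$assigned_sample,
                   none$fragments$true_sample)

  all_hop <- inject_hopping(rs, 1, seed = 3)
  expect_true(all(all_hop$fragments$assigned_sample !=
                    all_hop$fragments$true_sample))
  expect_true(all(all_hop$fragments$assigned_sample %in% rs$samples))

  some <- inject_hopping(rs, 0.3, seed = 4)
  # fragment count and per-site multiplex-wide allele totals conserved
  expect_identical(nrow(some$fragments), nrow(rs$fragments))
  before <- tally_allele_counts(rs)
  after <- tally_allele_counts(some)
  expect_equal(colSums(after$nRef), colSums(before$nRef))
  expect_equal(colSums(after$nAlt), colSums(before$nAlt))

  # hop fraction matches h within binomial noise
  big <- make_reads(10, 2000, coverage = 5, seed = 7)$reads
  hopped <- inject_hopping(big, 0.05, seed = 8)
  n <- nrow(big$fragments)
  frac <- mean(hopped$fragments$assigned_sample !=
                 hopped$fragments$true_sample)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n))

  solo <- make_reads(1, 10)$reads
  expect_error(inject_hopping(solo, 0.1), "two samples")
  expect_no_error(inject_hopping(solo, 0))
})

test_that("isometric log-ratios reproduce the reference concordance balances", {
  # observed presence/absence concordance of true reference homozygotes
  expect_equal(round(ilr_3part(98.45, 1.42, 0.13), 2), 4.44)
  expect_equal(round(ilr_2part(98.45, 1.42), 2), 3.00)
  # true heterozygotes and alternative homozygotes
  expect_equal(round(ilr_3part(52.62, 24.15, 23.23), 2), 0.65)
  expect_equal(round(ilr_2part(98.10, 1.71), 2), 2.86)
  # simulated 5% hop level
  expect_equal(round(ilr_3part(96.34, 3.29, 0.37), 2), 3.65)

  # equal parts balance to zero; zero parts are rejected, not perturbed
  expect_equal(ilr_3part(7, 7, 7), 0)
  expect_equal(ilr_2part(0.2, 0.2), 0)
  expect_error(ilr_3part(98, 1, 0), "positive")
  expect_error(ilr_2part(98, -1), "positive")

  # scale invariance: counts and percentages give identical values
  expect_equal(ilr_3part(984.5, 14.2, 1.3), ilr_3part(98.45, 1.42, 0.13))
  expect_equal(ilr_2part(50, 3), ilr_2part(5, 0.3))
})

test_that("calibration regressions fit and invert as ordinary least squares", {
  lv <- c(0, 0.1, 0.5, 1, 2, 5)

  # exactly collinear points: perfect linear fit
  f <- fit_level_regression(lv, 10 - 2 * lv, degree = 1)
  expect_equal(f$r_squared, 1)
  expect_equal(f$coefficients, c(10, -2), tolerance = 1e-10)

  # three non-collinear points: quadratic interpolates exactly
  f2 <- fit_level_regression(c(0, 1, 2), c(1, 0, 3), degree = 2)
  expect_equal(f2$r_squared, 1)

  # hom-ref correct-call concordance column of the reference calibration
  f3 <- fit_level_regression(lv, c(99.62, 99.53, 99.28, 98.99, 98.20, 96.34))
  expect_equal(round(f3$r_squared, 3), 0.999)

  expect_error(fit_level_regression(c(0, 0, 1), c(1, 2, 3)), "distinct")
  expect_error(fit_level_regression(0, 1, degree = 1), "calibration points")
  expect_error(fit_level_regression(c(0, 1), c(1, 2), degree = 2),
               "calibration points")
  expect_error(fit_level_regression(lv, lv, degree = 3), "degree")
})

test_that("inverse prediction recovers reference hop-level estimates", {
  lv <- c(0, 0.1, 0.5, 1, 2, 5)
  # hom-alt called hom-ref (double-hop signature)
  f <- fit_level_regression(lv, c(0.04, 0.08, 0.10, 0.14, 0.23, 0.59))
  expect_equal(estimate_hop_level(f, 0.18), 1.28, tolerance = 0.01)
  # hom-alt called het
  f2 <- fit_level_regression(lv, c(0.47, 0.52, 0.92, 1.33, 2.16, 4.75))
  expect_equal(estimate_hop_level(f2, 1.71), 1.45, tolerance = 0.01)

  # inverting the fit at its own prediction returns the level
  pred2 <- sum(f$coefficients * c(1, 2))
  expect_equal(estimate_hop_level(f, pred2), 2, tolerance = 1e-9)

  # quadratic inversion: root must lie inside the calibrated span
  fq <- fit_level_regression(lv, 5 - lv + 0.05 * lv^2, degree = 2)
  expect_equal(estimate_hop_level(fq, 5 - 1.5 + 0.05 * 1.5^2), 1.5,
               tolerance = 1e-6)
  expect_error(estimate_hop_level(fq, 100), "calibrated range")

  flat <- fit_level_regression(c(0, 1, 2, 3), c(2, 2, 2, 2))
  expect_error(estimate_hop_level(flat, 2.5), "zero slope")
})

test_that("homozygote concordance decreases with the injected hop level", {
  ts <- simulate_truth(10, 4000, seed = 55)
  grid <- hop_calibration_grid(ts, levels = c(0, 2, 5), mean_coverage = 2,
                               seed = 56)
  v00 <- grid$value[grid$variable == "0|0"]
  expect_gt(v00[1], v00[3])
  v22 <- grid$value[grid$variable == "2|2"]
  expect_gt(v22[1], v22[3])

  # per-variable estimation plumbing: recover an interior observation
  obs <- multiplex_concordance(
    inject_hopping(simulate_reads(ts, 2, 0.01, seed = 57), 0.02, seed = 58),
    ts)
  est <- estimate_hopping(grid, obs, variables = c("0|0", "2|2"))
  expect_identical(est$variable, c("0|0", "2|2"))
  expect_true(all(est$estimate > 0 & est$estimate < 5))
})
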