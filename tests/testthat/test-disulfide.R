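test_that("the exponential generator follows the closed form", {
  tab <- simulate_disulfide_timecourse(3, 85, 0.3, c(0, 5), noise_sd = 0)
  expect_equal(tab$percent_disulfide[1], 3)
  expect_equal(tab$percent_disulfide[2], 85 - 82 * exp(-1.5))
  far <- simulate_disulfide_timecourse(3, 85, 0.3, 1e6, noise_sd = 0)
  expect_equal(far$percent_disulfide, 85)
  expect_error(simulate_disulfide_timecourse(-1, 85, 0.3, 0:5), "\\[0, 100\\]")
  # clipping to [0, 100]
  noisy <- simulate_disulfide_timecourse(1, 99, 0.5, 0:50, noise_sd = 10,
                                         seed = 2)
  expect_true(all(noisy$percent_disulfide >= 0 &
                    noisy$percent_disulfide <= 100))
})

test_that("noise-free time courses are recovered exactly", {
  tab <- simulate_disulfide_timecourse(3, 85, 0.3,
                                       c(0, 1, 2, 4, 8, 15, 30, 60))
  f <- fit_timecourse(tab)
  expect_equal(f$p0, 3, tolerance = 1e-6)
  expect_equal(f$p_inf, 85, tolerance = 1e-6)
  expect_equal(f$k, 0.3, tolerance = 1e-6)
  expect_equal(f$initial_rate, 0.3 * 82, tolerance = 1e-4)
  expect_false(f$flagged)
  expect_error(fit_timecourse(tab[1:3, ]), "at least 4")
  # decreasing data permitted
  dec <- simulate_disulfide_timecourse(80, 20, 0.2, c(0, 2, 5, 10, 30))
  fd <- fit_timecourse(dec)
  expect_lt(fd$p_inf, fd$p0)
})

test_that("flat data flag an unidentifiable rate", {
  flat <- tibble::tibble(time_min = c(0, 5, 10, 20, 40),
                         percent_disulfide = rep(10, 5))
  f <- fit_timecourse(flat)
  expect_true(f$flagged)
  expect_equal(f$p0, f$p_inf, tolerance = 1)
})

test_that("final extent is recovered within 3 percent under 2 percent noise", {
  errs <- vapply(1:20, function(s) {
    tab <- simulate_disulfide_timecourse(3, 85, 0.3,
                                         c(0, 1, 2, 4, 8, 15, 30, 60),
                                         noise_sd = 2, seed = s)
    fit_timecourse(tab)$p_inf - 85
  }, 0)
  expect_lt(max(abs(errs)), 3)
})

test_that("fold ratios reproduce the per-mutant rate arithmetic", {
  expect_equal(round(rate_ratio(22.97, 5.27), 1), 4.4)
  expect_equal(round(rate_ratio(13.13, 5.27), 1), 2.5)
  expect_equal(round(rate_ratio(22.97, 13.13), 1), 1.7)
  tab <- simulate_disulfide_timecourse(3, 85, 0.3, c(0, 2, 5, 10, 30, 60))
  f <- fit_timecourse(tab)
  expect_equal(rate_ratio(f, f), 1.0)
  expect_error(rate_ratio(f, 0), "zero")
})

test_that("rate ratios are reparameterization-invariant for shared amplitudes", {
  # two mutants with the same amplitude: ratio of k equals ratio of rates
  t1 <- fit_timecourse(simulate_disulfide_timecourse(5, 80, 0.4,
                                                     c(0, 1, 3, 6, 12, 30)))
  t2 <- fit_timecourse(simulate_disulfide_timecourse(5, 80, 0.1,
                                                     c(0, 1, 3, 6, 12, 30)))
  expect_equal(rate_ratio(t1, t2), t1$k / t2$k, tolerance = 1e-6)
})

test_that("replicate statistics give exact means, SEM and calibrated tests", {
  mk <- function(pf, s) fit_timecourse(
    simulate_disulfide_timecourse(3, pf, 0.3, c(0, 1, 3, 6, 12, 30, 60),
                                  noise_sd = 2, seed = s))
  fits <- list(mk(85, 1), mk(85, 2), mk(85, 3), mk(40, 4), mk(40, 5), mk(40, 6))
  rs <- replicate_stats(fits, rep(c("a", "b"), each = 3))
  # hand-computed mean/SEM for one parameter
  va <- vapply(fits[1:3], `[[`, 0, "p_inf")
  row <- dplyr::filter(rs$summary, group == "a", parameter == "p_inf")
  expect_equal(row$mean, mean(va))
  expect_equal(row$sem, stats::sd(va) / sqrt(3))
  # different final extents are detected
  pv <- dplyr::filter(rs$tests, parameter == "p_inf")$p_value
  expect_lt(pv, 0.01)
  # identical replicates: SEM 0
  same <- list(mk(85, 9), mk(85, 9), mk(85, 9))
  rs2 <- replicate_stats(same, rep("a", 3))
  expect_true(all(rs2$summary$sem == 0))
  expect_warning(replicate_stats(fits[1:2], c("a", "b")), "single replicate")
})

test_that("null p-values are uniform across seeds", {
  # groups drawn from the same distribution: KS test on 200 null p-values
  pvals <- vapply(1:200, function(s) {
    va <- tandemfret:::with_seed(s, rnorm(3, 85, 2))
    vb <- tandemfret:::with_seed(s + 1000, rnorm(3, 85, 2))
    stats::t.test(va, vb)$p.value
  }, 0)
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})
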