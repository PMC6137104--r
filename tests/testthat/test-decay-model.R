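test_that("donor model evaluates the multi-exponential decay", {
  d1 <- single_donor(4)
  expect_equal(donor_model_eval(d1, 0), 1.0)
  expect_equal(donor_model_eval(d1, 4), exp(-1))
  d2 <- test_donor()
  expect_equal(donor_model_eval(d2, 2),
               0.2 * exp(-2 / 1.5) + 0.8 * exp(-2 / 4.1))
  # numerical Laplace-transform cross-check: integral of I(t) equals the
  # species-weighted lifetime
  expect_equal(stats::integrate(function(t) donor_model_eval(d2, t),
                                0, Inf)$value,
               sum(c(0.2, 0.8) * c(1.5, 4.1)), tolerance = 1e-6)
  expect_error(donor_model_eval(d2, -1), "non-negative")
})

test_that("FRET rate and efficiency follow the R^6 law", {
  expect_equal(fret_efficiency(52, 52), 0.5)
  expect_equal(fret_efficiency(2 * 52, 52), 1 / 65)
  expect_lt(fret_rate(1e4, 52, 4), 1e-12)
  # consistency E = k / (k + 1/tau)
  k <- fret_rate(45, 52, 4)
  expect_equal(fret_efficiency(45, 52), k / (k + 1 / 4))
  expect_error(fret_rate(-1, 52, 4), "positive")
})

test_that("Gaussian-state decay matches quadrature limits and an oracle", {
  d <- test_donor()
  t <- c(0.5, 2, 5)
  # width 0 reduces to the single-distance expression
  q <- 1 + (52 / 45)^6
  direct <- 0.2 * exp(-t * q / 1.5) + 0.8 * exp(-t * q / 4.1)
  expect_equal(state_decay(45, 0, d, 52, t), direct)
  # distant state reduces to the bare donor decay
  expect_equal(state_decay(5000, 0, d, 52, t), donor_model_eval(d, t),
               tolerance = 1e-9)
  # fine-Riemann oracle for the truncated-Gaussian distance average (the
  # default adaptive quadrature silently misses the narrow support)
  ds <- single_donor(4)
  r <- seq(27, 77, by = 0.001)
  w <- stats::dnorm(r, 52, 5); w <- w / sum(w)
  oracle <- sum(w * exp(-1 * (1 + (52 / r)^6)))
  expect_equal(state_decay(52, 5, ds, 52, 4), oracle, tolerance = 1e-4)
})

test_that("model_counts reduces correctly for delta IRF and pure no-FRET", {
  n <- 512; dt <- 0.0488
  delta_irf <- make_irf(0, 0, n, dt)
  d <- test_donor()
  st <- state_spec(1, 45, 3, no_fret_fraction = 0, r0 = 52)
  mu <- model_counts(st, d, delta_irf$counts, dt, 1e6, 0)
  tgrid <- (seq_len(n) - 1) * dt
  direct <- state_decay(45, 3, d, 52, tgrid)
  expect_equal(mu, 1e6 * direct / sum(direct), tolerance = 1e-12)
  # no-FRET fraction 1 is exactly the donor-only model
  st1 <- state_spec(1, 45, 3, no_fret_fraction = 1 - 1e-12, r0 = 52)
  irf <- small_irf(n, dt)
  expect_equal(model_counts(st1, d, irf$counts, dt, 1e6, 2),
               donor_counts(d, irf$counts, dt, 1e6, 2), tolerance = 1e-9)
})

test_that("IRF convolution matches a 10x-oversampled direct convolution", {
  # the discrete model value in channel c estimates the intensity at the
  # channel boundary c*dt (self-consistent because the IRF is represented on
  # the same grid); the dense brute-force convolution is evaluated there
  n <- 2048; dt <- 0.0122
  irf <- make_irf(0.25, 2, n, dt)
  d <- test_donor()
  st <- state_spec(c(0.6, 0.4), c(42, 60), c(3, 4), 0.1, 52)
  mu <- model_counts(st, d, irf$counts, dt, 1, 0)

  # brute-force direct (time-domain) convolution on the same grid checks
  # the FFT path exactly
  tgrid <- (seq_len(n) - 1) * dt
  dec <- (1 - 0.1) * (0.6 * state_decay(42, 3, d, 52, tgrid) +
                        0.4 * state_decay(60, 4, d, 52, tgrid)) +
    0.1 * donor_model_eval(d, tgrid)
  direct <- numeric(n)
  for (j in which(irf$counts > 1e-16)) {
    direct[j:n] <- direct[j:n] + irf$counts[j] * dec[1:(n - j + 1)]
  }
  direct <- direct / sum(direct)
  signal <- mu > max(mu) * 1e-3
  expect_lt(max(abs(mu[signal] - direct[signal]) / mu[signal]), 1e-10)

  # closed-form cross-check for a single-exponential donor
  sigma <- 0.25 / (2 * sqrt(2 * log(2)))
  tau <- 4
  mu1 <- tandemfret:::donor_counts(single_donor(tau), irf$counts, dt, 1, 0)
  erfc <- function(x) 2 * stats::pnorm(-x * sqrt(2))
  closed <- function(t) {
    0.5 * exp(sigma^2 / (2 * tau^2) - (t - 2) / tau) *
      erfc((sigma / tau - (t - 2) / sigma) / sqrt(2))
  }
  ref <- closed(seq_len(n) * dt); ref <- ref / sum(ref)
  s1 <- mu1 > max(mu1) * 1e-3
  expect_lt(max(abs(mu1[s1] - ref[s1]) / mu1[s1]), 1e-3)
})

test_that("state and donor specs enforce their invariants", {
  expect_error(donor_spec(c(0.5, 0.6), c(1, 4)), "sum to 1")
  expect_error(donor_spec(1, -2), "positive")
  expect_error(state_spec(c(0.5, 0.4), c(40, 50), c(1, 1)), "sum to 1")
  expect_error(state_spec(1, -40, 1), "positive")
  expect_error(state_spec(1, 40, -1), "non-negative")
  expect_error(state_spec(1, 40, 1, no_fret_fraction = 1), "\\[0, 1\\)")
})
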