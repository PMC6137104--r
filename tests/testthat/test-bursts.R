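static_kinetics <- function(R = 45) {
  # vanishing forward rate: effectively a single static state
  two_state_kinetics(c(R, 80), 1e-9, 10)
}

test_that("burst selection recovers generated bursts with their photons", {
  d <- single_donor(4)
  kin <- two_state_kinetics(c(45, 60), 2, 2)
  stream <- simulate_bursts(kin, d, 52, brightness = 100, n_bursts = 200,
                            seed = 8)
  bt <- select_bursts(stream, min_photons = 60)
  # >= 95% of generated bursts with >= 60 photons are recovered with all
  # their photons in one selected burst
  gen_sizes <- table(stream$burst_id)
  eligible <- as.integer(names(gen_sizes)[gen_sizes >= 60])
  hit <- vapply(eligible, function(b) {
    rows <- which(stream$burst_id == b)
    any(vapply(bt$rows, function(r) all(rows %in% r), TRUE))
  }, TRUE)
  expect_gte(mean(hit), 0.95)
  # photon conservation: every selected photon belongs to exactly one burst
  all_rows <- unlist(bt$rows)
  expect_equal(length(all_rows), length(unique(all_rows)))
  expect_error(select_bursts(dplyr::arrange(stream, .data$microtime_ns)),
               "sorted")
  empty <- select_bursts(stream[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("one dense cluster above threshold yields exactly one burst", {
  stream <- tibble::tibble(macrotime_ms = seq(0, 0.79, by = 0.01),
                           microtime_ns = 1, channel = "D")
  expect_equal(nrow(select_bursts(stream, 60, 0.05)), 1)
  expect_equal(nrow(select_bursts(stream, 100, 0.05)), 0)
})

test_that("burst indicators match the static and fast-exchange expectations", {
  d <- single_donor(4)
  # static state at E = 0.5 (R = R0)
  kin <- static_kinetics(52)
  stream <- simulate_bursts(kin, d, 52, n_bursts = 300, seed = 9)
  ind <- burst_indicators(select_bursts(stream), donor_tau0 = 4)
  expect_equal(median(ind$fdfa[!ind$flagged]), 1.0, tolerance = 0.1)
  # donor-only bursts: lifetime near tau_D0
  kin0 <- static_kinetics(500)
  s0 <- simulate_bursts(kin0, d, 52, n_bursts = 150, seed = 10)
  i0 <- burst_indicators(select_bursts(s0), donor_tau0 = 4)
  # donor-only bursts have no acceptor photons, so they are fdfa-flagged but
  # their lifetimes are defined
  expect_true(all(!is.finite(i0$fdfa)))
  expect_equal(mean(i0$tau_f_ns[!is.na(i0$tau_f_ns)]), 4, tolerance = 0.15)
})

test_that("fast two-state exchange gives the intensity-weighted mean lifetime", {
  # quenched lifetimes 1 and 3 ns from a 4 ns donor
  d <- single_donor(4)
  r1 <- 52 * 3^(-1 / 6); r2 <- 52 * 3^(1 / 6)
  kin <- two_state_kinetics(c(r1, r2), 50, 50)   # exchange much faster than burst
  stream <- simulate_bursts(kin, d, 52, brightness = 120, n_bursts = 400,
                            seed = 12)
  ind <- burst_indicators(select_bursts(stream), donor_tau0 = 4)
  # photon-weighted: donor flux weights the 50/50 time split by (1-E) per
  # state, i.e. by tau; <tau>_f = (tau1^2+tau2^2)/(tau1+tau2) = 2.5
  expect_equal(mean(ind$tau_f_ns[!ind$flagged]), 2.5, tolerance = 0.12)
})

test_that("static FRET line passes the closed-form anchor points", {
  ds <- single_donor(4)
  sl <- static_fret_line(ds, 52)
  # E -> 0: tau_f -> donor tau_f, F_D/F_A -> large
  expect_equal(sl$tau_f_ns[which.min(sl$efficiency)], 4, tolerance = 0.01)
  expect_gt(max(sl$fdfa), 500)
  # at R = R0 (E = 0.5): the point (tau0/2, 1)
  i <- which.min(abs(sl$efficiency - 0.5))
  expect_equal(sl$tau_f_ns[i], 2, tolerance = 0.01)
  expect_equal(sl$fdfa[i], 1, tolerance = 0.01)
})

test_that("dynamic line endpoints sit exactly on the static line", {
  d <- test_donor()
  dl <- dynamic_fret_line(42, 60, d, 52)
  ep <- attr(dl, "endpoints")
  # endpoints at x=1 and x=0 equal the state points
  expect_equal(dl$tau_f_ns[dl$x1 == 1], ep$tau_f_ns[1], tolerance = 1e-12)
  expect_equal(dl$fdfa[dl$x1 == 0], ep$fdfa[2], tolerance = 1e-12)
  # and those state points lie on the static line parameterisation
  E <- fret_efficiency(c(42, 60), 52)
  expect_equal(ep$tau_f_ns,
               (1 - E) * donor_mean_lifetimes(d)[["tau_f"]],
               tolerance = 1e-9)
  expect_equal(ep$fdfa, (1 - E) / E, tolerance = 1e-9)
  # midpoint moment arithmetic for a single-exponential donor
  ds <- single_donor(4)
  r1 <- 52 * 3^(-1 / 6); r2 <- 52 * 3^(1 / 6)
  dl2 <- dynamic_fret_line(r1, r2, ds, 52, n = 501)
  mid <- which.min(abs(dl2$x1 - 0.5))
  expect_equal(dl2$tau_f_ns[mid], 2.5, tolerance = 1e-6)
})

test_that("2D histogram conserves bursts between grid and marginals", {
  d <- single_donor(4)
  kin <- two_state_kinetics(c(45, 60), 3, 3)
  stream <- simulate_bursts(kin, d, 52, n_bursts = 150, seed = 14)
  ind <- burst_indicators(select_bursts(stream), donor_tau0 = 4)
  h <- fret_histogram2d(ind)
  expect_equal(sum(h$grid$count), h$n_bursts)
  expect_equal(sum(h$tau_marginal$count), h$n_bursts)
  expect_equal(sum(h$fdfa_marginal$count), h$n_bursts)
  expect_equal(h$n_flagged + h$n_bursts, nrow(ind))
  he <- fret_histogram2d(ind[0, ])
  expect_equal(sum(he$grid$count), 0)
})

test_that("static bursts land on the static line; dynamic bursts move off it", {
  ds <- single_donor(4)
  sl <- static_fret_line(ds, 52)
  fbr <- exp(seq(log(0.25), log(10), length.out = 41))
  lw <- log(fbr[2]) - log(fbr[1])
  # three static distances: 2D mode on the line within one bin (cell-centre
  # quantisation adds up to half a bin per axis)
  for (R in c(44, 52, 62)) {
    stream <- simulate_bursts(static_kinetics(R), ds, 52, brightness = 250,
                              n_bursts = 2000, seed = 100 + R, mean_gap = 2)
    ind <- burst_indicators(select_bursts(stream), donor_tau0 = 4)
    h <- fret_histogram2d(ind, tau_breaks = seq(0, 4.4, length.out = 41),
                          fdfa_breaks = fbr)
    mode <- h$grid[which.max(h$grid$count), ]
    fd_line <- stats::approx(sl$tau_f_ns, sl$fdfa, xout = mode$tau_mid)$y
    expect_lt(abs(log(mode$fdfa_mid) - log(fd_line)) / lw, 1.5)
  }
  # intermediate exchange: population maximum off the static line
  kin <- two_state_kinetics(c(42, 62), 5, 5)
  stream <- simulate_bursts(kin, ds, 52, brightness = 250, n_bursts = 1500,
                            seed = 15, mean_gap = 2)
  ind <- burst_indicators(select_bursts(stream), donor_tau0 = 4)
  h <- fret_histogram2d(ind, tau_breaks = seq(0, 4.4, length.out = 41),
                        fdfa_breaks = fbr)
  mode <- h$grid[which.max(h$grid$count), ]
  fd_line <- stats::approx(sl$tau_f_ns, sl$fdfa, xout = mode$tau_mid)$y
  expect_gt(abs(log(mode$fdfa_mid) - log(fd_line)) / lw, 2)
})

test_that("time-window PDA separates static from dynamic data", {
  ds <- single_donor(4)
  # static single state: chi2r flat in the window size
  st_stream <- simulate_bursts(static_kinetics(52), ds, 52, n_bursts = 8000,
                               seed = 16, mean_gap = 2)
  model <- state_spec(1, 52, 0, 0, 52)
  pda_s <- pda_time_window(st_stream, c(0.5, 1, 2, 4), model)
  expect_true(all(pda_s$chi2r > 0.6 & pda_s$chi2r < 1.4))
  expect_lt(attr(pda_s, "ratio"), 1.3)
  expect_equal(attr(pda_s, "verdict"), "static")

  # two-state exchange at 5/ms: the static-mixture model fails, and
  # differently so across windows
  kin <- two_state_kinetics(c(42, 62), 2.5, 2.5)
  dy_stream <- simulate_bursts(kin, ds, 52, n_bursts = 1500, seed = 17,
                               mean_gap = 2)
  model2 <- state_spec(c(0.5, 0.5), c(42, 62), c(0, 0), 0, 52)
  pda_d <- pda_time_window(dy_stream, c(0.5, 1, 2, 4), model2)
  expect_gt(attr(pda_d, "ratio"), 1.5)
  expect_equal(attr(pda_d, "verdict"), "dynamic")

  expect_error(pda_time_window(st_stream, 1, model), "at least 2")
  expect_error(pda_time_window(st_stream, c(1, 1e9), model), "span")
})
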