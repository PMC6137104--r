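#' TCSPC decay histogram
#'
#' Light tabular container for a time-correlated single photon counting
#' histogram: one row per channel with the channel mid-time and the photon
#' count (or, for an instrument response function, a unit-area profile).
#'
#' @param counts Numeric vector of per-channel counts.
#' @param dt Channel width in ns (> 0).
#' @param irf Optional companion IRF profile (numeric vector, same length).
#' @param background Flat background level in counts/channel.
#'
#' @return A tibble of class `decay_histogram` with columns `channel`,
#'   `time_ns`, `counts`; the channel width, IRF and background travel as
#'   attributes `dt`, `irf`, `background`.
#' @export
decay_histogram <- function(counts, dt, irf = NULL, background = 0) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (!is.null(irf) && length(irf) != length(counts)) {
    stop("IRF length must match counts length", call. = FALSE)
  }
  n <- length(counts)
  out <- tibble::tibble(channel = seq_len(n),
                        time_ns = (seq_len(n) - 1) * dt,
                        counts = counts)
  attr(out, "dt") <- dt
  attr(out, "irf") <- irf
  attr(out, "background") <- background
  class(out) <- c("decay_histogram", class(out))
  out
}

hist_dt <- function(hist) attr(hist, "dt")
hist_irf <- function(hist) attr(hist, "irf")

#' Evaluate the intrinsic donor decay
#'
#' Relative donor fluorescence intensity `sum_i x_i exp(-t / tau_i)` for a
#' one- or two-exponential donor model, normalised to 1 at `t = 0`.
#'
#' @param donor A [donor_spec()].
#' @param t Times in ns (>= 0).
#' @return Relative intensity in `(0, 1]`, same length as `t`.
#' @examples
#' donor_model_eval(donor_spec(1, 4), c(0, 4))
#' @export
donor_model_eval <- function(donor, t) {
  stopifnot(inherits(donor, "donor_spec"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  drop(exp(-outer(t, 1 / donor$lifetimes)) %*% donor$fractions)
}

#' FRET rate and transfer efficiency
#'
#' The rate of resonance energy transfer for a donor with lifetime `tau` at
#' donor-acceptor distance `R` is `k_RET = (1/tau) * (R0/R)^6`; the transfer
#' efficiency is `E = 1 / (1 + (R/R0)^6)` and is independent of `tau`.
#'
#' @param R Interdye distance in Angstrom (> 0).
#' @param r0 Foerster radius in Angstrom.
#' @param tau Donor lifetime in ns.
#' @return `fret_rate()`: transfer rate in 1/ns. `fret_efficiency()`:
#'   efficiency in `(0, 1)`.
#' @examples
#' fret_efficiency(52, 52)    # 0.5 at the Foerster radius
#' @export
fret_rate <- function(R, r0, tau) {
  if (any(R <= 0)) stop("R must be positive", call. = FALSE)
  (1 / tau) * (r0 / R)^6
}

#' @rdname fret_rate
#' @export
fret_efficiency <- function(R, r0) {
  if (any(R <= 0)) stop("R must be positive", call. = FALSE)
  1 / (1 + (R / r0)^6)
}

# Distance-quadrature nodes and weights for one Gaussian-distributed state.
# Nodes live on an absolute 0.5-A lattice covering mean +/- 5 sigma (truncated
# to R > 0, renormalised); a zero-width state is a single node at the mean.
# Using an absolute lattice lets the fitter precompute one decay basis shared
# by all states of a variant.
.r_step <- 0.5

state_quadrature <- function(mean_distance, width) {
  if (width < 1e-9) {
    return(list(r = mean_distance, w = 1))
  }
  lo <- max(.r_step, mean_distance - 5 * width)
  hi <- mean_distance + 5 * width
  r <- seq(ceiling(lo / .r_step) * .r_step, hi, by = .r_step)
  if (length(r) == 0) r <- max(.r_step, round(mean_distance / .r_step) * .r_step)
  w <- stats::dnorm(r, mean_distance, width)
  if (sum(w) <= 0) {
    r <- r[which.min(abs(r - mean_distance))]
    w <- 1
  }
  list(r = r, w = w / sum(w))
}

#' Decay of one Gaussian-distributed FRET state
#'
#' Relative donor intensity for a single conformational state whose interdye
#' distance is Gaussian-distributed (truncated to `R > 0` and renormalised):
#' every donor component is quenched by the same FRET rate factor
#' `1 + (R0/R)^6`, so the decay is the distance-average of
#' `sum_i x_i exp(-t/tau_i * (1 + (R0/R)^6))`.
#'
#' @param mean_distance Mean interdye distance in Angstrom.
#' @param width Distance-distribution standard deviation in Angstrom (>= 0;
#'   0 gives the single-distance expression).
#' @param donor A [donor_spec()].
#' @param r0 Foerster radius in Angstrom.
#' @param t Times in ns.
#' @return Relative intensity, same length as `t`.
#' @export
state_decay <- function(mean_distance, width, donor, r0, t) {
  stopifnot(inherits(donor, "donor_spec"))
  if (width < 0) stop("width must be >= 0", call. = FALSE)
  q <- state_quadrature(mean_distance, width)
  quench <- 1 + (r0 / q$r)^6
  out <- numeric(length(t))
  for (j in seq_along(q$r)) {
    out <- out + q$w[j] *
      drop(exp(-outer(t, quench[j] / donor$lifetimes)) %*% donor$fractions)
  }
  out
}

# Linear convolution of a decay with the IRF on the channel grid, truncated
# to the first n channels, via FFT with zero padding.
irf_convolve <- function(irf, decay) {
  n <- length(decay)
  m <- stats::nextn(2L * n, 2L)
  f <- Re(stats::fft(stats::fft(c(irf, rep(0, m - n))) *
                       stats::fft(c(decay, rep(0, m - n))), inverse = TRUE)) / m
  pmax(f[seq_len(n)], 0)
}

#' Expected TCSPC counts for a multi-state FRET model
#'
#' Forward model shared by the synthetic-data generator and the decay fitter:
#' the state-superposed decay (FRET-active Gaussian states plus a
#' `no_fret_fraction` donor-only term) is convolved with the instrument
#' response function, scaled so the decay contributes `total_counts` expected
#' photons, and a flat background is added.
#'
#' @param states A [state_spec()].
#' @param donor A [donor_spec()].
#' @param irf Unit-area IRF profile (numeric vector, one entry per channel).
#' @param dt Channel width in ns.
#' @param total_counts Expected total decay photons.
#' @param background Flat background in counts/channel.
#' @return Numeric vector of expected counts per channel (all `>= background`).
#' @export
model_counts <- function(states, donor, irf, dt, total_counts, background = 0) {
  stopifnot(inherits(states, "state_spec"), inherits(donor, "donor_spec"))
  if (abs(sum(irf) - 1) > 1e-6) {
    stop("IRF must be unit-normalised", call. = FALSE)
  }
  n <- length(irf)
  t <- (seq_len(n) - 1) * dt
  decay <- numeric(n)
  for (g in seq_along(states$fractions)) {
    decay <- decay + (1 - states$no_fret_fraction) * states$fractions[g] *
      state_decay(states$distances[g], states$widths[g], donor, states$r0, t)
  }
  decay <- decay + states$no_fret_fraction * donor_model_eval(donor, t)
  conv <- irf_convolve(irf, decay)
  total_counts * conv / sum(conv) + background
}

# Expected counts for a pure donor-only sample (used by the donor generator
# and donor fitter; same convolution/scaling conventions as model_counts).
donor_counts <- function(donor, irf, dt, total_counts, background = 0) {
  n <- length(irf)
  t <- (seq_len(n) - 1) * dt
  conv <- irf_convolve(irf, donor_model_eval(donor, t))
  total_counts * conv / sum(conv) + background
}

# Precomputed decay basis for fast fitting: IRF-convolved decays for every
# distance on the absolute 0.5-A lattice in [r_min, r_max], plus a donor-only
# column. A model evaluation is then a single matrix-vector product with the
# states' quadrature weights, exactly reproducing model_counts because the
# quadrature nodes are the same lattice.
build_decay_basis <- function(donor, r0, irf, dt, r_min = 0.5, r_max = 260) {
  n <- length(irf)
  t <- (seq_len(n) - 1) * dt
  r <- seq(ceiling(r_min / .r_step) * .r_step, r_max, by = .r_step)
  quench <- 1 + (r0 / r)^6
  cols <- matrix(0, n, length(r) + 1)
  donor_decay <- donor_model_eval(donor, t)
  for (j in seq_along(r)) {
    d <- drop(exp(-outer(t, quench[j] / donor$lifetimes)) %*% donor$fractions)
    cols[, j] <- irf_convolve(irf, d)
  }
  cols[, length(r) + 1] <- irf_convolve(irf, donor_decay)
  list(r = r, basis = cols, n = n, r0 = r0)
}

# Expected counts from a decay basis for FRET-state parameters. Only the
# columns with nonzero quadrature weight enter the product.
basis_counts <- function(bas, fractions, distances, widths, no_fret,
                         total_counts, background) {
  m <- length(bas$r)
  w <- numeric(m + 1)
  for (g in seq_along(fractions)) {
    q <- state_quadrature(distances[g], widths[g])
    idx <- round((q$r - bas$r[1]) / .r_step) + 1
    ok <- idx >= 1 & idx <= m
    wq <- q$w[ok] / sum(q$w[ok])
    w[idx[ok]] <- w[idx[ok]] + (1 - no_fret) * fractions[g] * wq
  }
  w[m + 1] <- no_fret
  nz <- which(w != 0)
  conv <- drop(bas$basis[, nz, drop = FALSE] %*% w[nz])
  total_counts * conv / sum(conv) + background
}

# Poisson deviance between observed counts and model expectations; the
# figure of merit reported as chi^2_r is deviance / dof.
poisson_deviance <- function(counts, mu) {
  mu <- pmax(mu, 1e-12)
  term <- ifelse(counts > 0, counts * log(counts / mu), 0)
  2 * sum(mu - counts + term)
}
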