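#' Gaussian instrument response function on a TCSPC channel grid
#'
#' Builds a unit-area Gaussian IRF profile (the temporal response of the
#' excitation/detection chain) sampled on the channel grid by integrating the
#' Gaussian over each channel.
#'
#' @param fwhm Full width at half maximum in ns (> 0).
#' @param t0 Pulse position in ns.
#' @param n_channels Number of TCSPC channels. Default 4096.
#' @param dt Channel width in ns. Default 0.0122 ns (a 50 ns window).
#'
#' @return A [decay_histogram()] whose `counts` column is the unit-area
#'   profile.
#' @examples
#' irf <- make_irf(0.25, 2)
#' sum(irf$counts)  # 1
#' @export
make_irf <- function(fwhm, t0, n_channels = 4096, dt = 0.0122) {
  if (fwhm < 0) stop("fwhm must be >= 0", call. = FALSE)
  if (n_channels * dt <= t0 + 5 * fwhm) {
    stop("channel grid too short for the pulse: need n_channels * dt > t0 + 5 * fwhm",
         call. = FALSE)
  }
  edges <- (0:n_channels) * dt
  if (fwhm < 1e-12) {
    profile <- numeric(n_channels)
    profile[min(n_channels, max(1, findInterval(t0, edges)))] <- 1
  } else {
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    profile <- diff(stats::pnorm(edges, t0, sigma))
    profile <- profile / sum(profile)
  }
  decay_histogram(profile, dt)
}

#' Canonical synthetic FRET-variant network
#'
#' Interdye distances of the default ten-variant, three-state synthetic
#' network used throughout the package. Each variant (a donor/acceptor
#' labeling-site pair) sees the three conformational states at different
#' distances; which state is nearest or farthest varies across variants
#' (as it does for a real labeling network spanning a domain interface), and
#' within every variant the state distances are at least 10 Angstrom apart
#' so each variant is conformation-sensitive. All distances lie in the
#' FRET-sensitive band around the Foerster radius.
#'
#' @return A list of 10 length-3 numeric vectors (Angstrom); element `g` of
#'   each vector is the distance of shared state `g` (states ordered by
#'   descending population).
#' @export
variant_network_distances <- function() {
  s1 <- c(40, 62, 36, 55, 48, 66, 44, 58, 38, 52)
  s2 <- c(52, 42, 58, 38, 64, 42, 60, 36, 50, 66)
  s3 <- c(64, 52, 46, 66, 38, 54, 34, 48, 62, 40)
  lapply(seq_len(10), function(i) c(s1[i], s2[i], s3[i]))
}

#' Simulate a donor-only TCSPC decay
#'
#' Poisson-noise counts around the IRF-convolved multi-exponential donor
#' model plus a flat background, emulating an ensemble donor-only control
#' measurement.
#'
#' @param donor A [donor_spec()].
#' @param irf IRF as returned by [make_irf()].
#' @param n_photons Expected total decay photons (> 0).
#' @param background_rate Flat background in counts/channel.
#' @param seed Integer seed; all randomness is local to the call.
#'
#' @return A [decay_histogram()] carrying the IRF and background as
#'   attributes.
#' @export
simulate_donor_decay <- function(donor, irf, n_photons, background_rate = 0,
                                 seed = NULL) {
  stopifnot(inherits(donor, "donor_spec"), inherits(irf, "decay_histogram"))
  if (n_photons <= 0) stop("n_photons must be positive", call. = FALSE)
  dt <- hist_dt(irf)
  mu <- donor_counts(donor, irf$counts, dt, n_photons, background_rate)
  counts <- with_seed(seed, stats::rpois(length(mu), mu))
  decay_histogram(counts, dt, irf = irf$counts, background = background_rate)
}

#' Simulate a donor-acceptor TCSPC decay
#'
#' Counts are drawn from exactly the forward model the decay fitter uses
#' ([model_counts()]): a superposition of Gaussian-distributed FRET states
#' plus a no-FRET donor term, convolved with the IRF, with Poisson counting
#' noise. Generator and fitter therefore share one model-evaluation code
#' path.
#'
#' @param states A [state_spec()].
#' @inheritParams simulate_donor_decay
#' @return A [decay_histogram()].
#' @export
simulate_da_decay <- function(states, donor, irf, n_photons,
                              background_rate = 0, seed = NULL) {
  stopifnot(inherits(states, "state_spec"), inherits(donor, "donor_spec"),
            inherits(irf, "decay_histogram"))
  if (n_photons <= 0) stop("n_photons must be positive", call. = FALSE)
  dt <- hist_dt(irf)
  mu <- model_counts(states, donor, irf$counts, dt, n_photons, background_rate)
  counts <- with_seed(seed, stats::rpois(length(mu), mu))
  decay_histogram(counts, dt, irf = irf$counts, background = background_rate)
}
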