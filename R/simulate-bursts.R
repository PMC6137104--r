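#' Simulate single-molecule photon bursts with two-state exchange
#'
#' Emulates the photon stream of single molecules diffusing through a
#' confocal volume while exchanging between two conformational states. Each
#' burst has an exponentially distributed duration; the state trajectory
#' within a burst is a continuous-time two-state Markov chain started from
#' its stationary distribution; photons arrive as a Poisson process at the
#' given brightness. Each photon is assigned a detection channel (donor or
#' acceptor, with acceptor probability equal to the state's FRET efficiency)
#' and a microtime drawn from the state-conditional decay: donor photons from
#' the FRET-quenched donor decay, acceptor photons from the transfer-time
#' plus acceptor-lifetime convolution.
#'
#' The burst envelope is phenomenological; no diffusion or optics of the
#' confocal volume is simulated.
#'
#' @param kin A [two_state_kinetics()].
#' @param donor A [donor_spec()].
#' @param r0 Foerster radius in Angstrom.
#' @param brightness Detected photons per ms during a burst. Default 100.
#' @param mean_burst_duration Mean burst duration in ms. Default 1.
#' @param n_bursts Number of bursts to generate.
#' @param seed Integer seed.
#' @param acceptor_lifetime Acceptor fluorescence lifetime in ns. Default 1.
#' @param mean_gap Mean inter-burst gap in ms (sets the macrotime spacing).
#'
#' @return A tibble of photons, one row each, sorted by macrotime:
#'   `burst_id` (ground-truth generating burst), `macrotime_ms`,
#'   `microtime_ns`, `channel` (`"D"`/`"A"`), `state` (ground-truth state at
#'   emission). Attribute `true_E` holds the two state efficiencies.
#' @export
simulate_bursts <- function(kin, donor, r0, brightness = 100,
                            mean_burst_duration = 1, n_bursts = 200,
                            seed = NULL, acceptor_lifetime = 1,
                            mean_gap = 20) {
  stopifnot(inherits(kin, "two_state_kinetics"), inherits(donor, "donor_spec"))
  if (brightness <= 0) stop("brightness must be positive", call. = FALSE)
  if (mean_burst_duration <= 0) {
    stop("mean_burst_duration must be positive", call. = FALSE)
  }
  E <- fret_efficiency(kin$distances, r0)
  quench <- 1 + (r0 / kin$distances)^6    # lifetime reduction factor per state
  k12 <- kin$forward_rate; k21 <- kin$backward_rate
  p1_stat <- k21 / (k12 + k21)

  with_seed(seed, {
    out <- vector("list", n_bursts)
    t_cursor <- 0
    for (b in seq_len(n_bursts)) {
      t_cursor <- t_cursor + stats::rexp(1, 1 / mean_gap)
      dur <- stats::rexp(1, 1 / mean_burst_duration)
      n_ph <- stats::rpois(1, brightness * dur)
      if (n_ph == 0) { next }
      t_ph <- sort(stats::runif(n_ph, 0, dur))

      # state trajectory: jump times of the two-state chain across [0, dur]
      s <- if (stats::runif(1) < p1_stat) 1L else 2L
      jump_t <- numeric(0); jump_s <- integer(0)
      tt <- 0; cur <- s
      repeat {
        tt <- tt + stats::rexp(1, if (cur == 1L) k12 else k21)
        if (tt >= dur) break
        cur <- 3L - cur
        jump_t <- c(jump_t, tt); jump_s <- c(jump_s, cur)
      }
      st <- if (length(jump_t) == 0) {
        rep(s, n_ph)
      } else {
        c(s, jump_s)[findInterval(t_ph, jump_t) + 1L]
      }

      is_acc <- stats::runif(n_ph) < E[st]
      micro <- numeric(n_ph)
      # component choice weighted by fluorescence flux of the quenched donor
      tau_q <- outer(donor$lifetimes, 1 / quench)   # [component, state]
      for (state in 1:2) {
        idx <- which(st == state)
        if (length(idx) == 0) next
        wts <- donor$fractions * tau_q[, state]
        comp <- sample.int(length(donor$fractions), length(idx),
                           replace = TRUE, prob = wts)
        t_exc <- stats::rexp(length(idx), rate = 1 / tau_q[comp, state])
        a <- is_acc[idx]
        micro[idx][!a] <- t_exc[!a]
        micro[idx][a] <- t_exc[a] +
          stats::rexp(sum(a), rate = 1 / acceptor_lifetime)
      }
      out[[b]] <- tibble::tibble(
        burst_id = b,
        macrotime_ms = t_cursor + t_ph,
        microtime_ns = micro,
        channel = ifelse(is_acc, "A", "D"),
        state = st)
      t_cursor <- t_cursor + dur
    }
    stream <- dplyr::bind_rows(out)
    attr(stream, "true_E") <- E
    attr(stream, "quench") <- quench
    stream
  })
}
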