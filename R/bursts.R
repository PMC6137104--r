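#' Select photon bursts from a single-molecule photon stream
#'
#' Burst search by the inter-photon-time criterion: maximal runs of photons
#' whose consecutive gaps are all `<= max_interphoton` and which contain at
#' least `min_photons` photons become bursts.
#'
#' @param stream Photon tibble with columns `macrotime_ms`, `microtime_ns`,
#'   `channel` (sorted by macrotime).
#' @param min_photons Minimum photons per burst. Default 60.
#' @param max_interphoton Maximum allowed inter-photon gap in ms. Default
#'   0.1 (at the default 100 photons/ms brightness this keeps both
#'   burst-splitting and burst-merging probabilities below 1 percent).
#'
#' @return A `burst_table` tibble, one row per burst: photon counts per
#'   channel, macrotime span, a `donor_microtimes` list-column and a `rows`
#'   list-column of photon row indices (for tracing photons back to the
#'   stream).
#' @export
select_bursts <- function(stream, min_photons = 60, max_interphoton = 0.1) {
  mt <- stream$macrotime_ms
  if (is.unsorted(mt)) stop("photon stream must be sorted by macrotime", call. = FALSE)
  n <- length(mt)
  if (n == 0) {
    return(tibble::tibble(burst = integer(), n_photons = integer(),
                          n_donor = integer(), n_acceptor = integer(),
                          t_start_ms = numeric(), t_end_ms = numeric(),
                          duration_ms = numeric(),
                          donor_microtimes = list(), rows = list()))
  }
  run <- cumsum(c(TRUE, diff(mt) > max_interphoton))
  keep_runs <- which(tabulate(run) >= min_photons)
  rows_by_run <- split(seq_len(n), run)[as.character(keep_runs)]
  out <- purrr::imap(rows_by_run, function(rows, nm) {
    ch <- stream$channel[rows]
    tibble::tibble(
      n_photons = length(rows),
      n_donor = sum(ch == "D"),
      n_acceptor = sum(ch == "A"),
      t_start_ms = mt[rows[1]],
      t_end_ms = mt[rows[length(rows)]],
      donor_microtimes = list(stream$microtime_ns[rows][ch == "D"]),
      rows = list(rows))
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(burst = integer(), n_photons = integer(),
                          n_donor = integer(), n_acceptor = integer(),
                          t_start_ms = numeric(), t_end_ms = numeric(),
                          duration_ms = numeric(),
                          donor_microtimes = list(), rows = list()))
  }
  res <- dplyr::mutate(res, burst = dplyr::row_number(),
                       duration_ms = .data$t_end_ms - .data$t_start_ms,
                       .before = 1)
  class(res) <- c("burst_table", class(res))
  res
}

# Maximum-likelihood single-exponential lifetime from photon arrival times.
# With an observation window [0, T] the MLE solves
#   mean(t) = tau - T / (exp(T/tau) - 1);
# without truncation it is the sample mean.
mle_exp_lifetime <- function(t, window_ns = NULL) {
  m <- mean(t)
  if (is.null(window_ns) || !is.finite(window_ns)) return(m)
  f <- function(tau) tau - window_ns / (exp(window_ns / tau) - 1) - m
  tryCatch(stats::uniroot(f, c(m * 0.5, window_ns * 10))$root,
           error = function(e) m)
}

#' Per-burst FRET indicators
#'
#' Computes the two indicators plotted against each other in multiparameter
#' fluorescence detection: the corrected donor/acceptor intensity ratio
#' `F_D/F_A` and the fluorescence-weighted average donor lifetime
#' `<tau_D(A)>_f`, estimated per burst by maximum likelihood from the donor
#' photon microtimes.
#'
#' @param bursts A `burst_table` from [select_bursts()].
#' @param donor_tau0 Unquenched donor fluorescence-weighted lifetime in ns
#'   (reference; carried into the output).
#' @param gamma Detection/quantum-yield correction applied to the donor
#'   channel. Default 1 (ideal).
#' @param min_donor_photons Bursts with fewer donor photons get `NA` lifetime
#'   and are flagged. Default 10.
#' @param window_ns Optional microtime observation window for the truncated
#'   MLE.
#'
#' @return The burst table with added columns `fdfa` (`Inf` and flagged when
#'   the burst has zero acceptor photons), `tau_f_ns` and `flagged`.
#' @export
burst_indicators <- function(bursts, donor_tau0, gamma = 1,
                             min_donor_photons = 10, window_ns = NULL) {
  fdfa <- gamma * bursts$n_donor / bursts$n_acceptor   # Inf when n_acceptor=0
  tau <- purrr::map_dbl(bursts$donor_microtimes, function(t) {
    if (length(t) < min_donor_photons) return(NA_real_)
    mle_exp_lifetime(t, window_ns)
  })
  dplyr::mutate(bursts, fdfa = fdfa, tau_f_ns = tau,
                donor_tau0 = donor_tau0,
                flagged = !is.finite(fdfa) | is.na(tau))
}

# Fluorescence-weighted mean lifetime of a donor uniformly quenched to
# efficiency E (every component scaled by 1-E).
tau_f_at_efficiency <- function(donor, E) {
  (1 - E) * donor_mean_lifetimes(donor)[["tau_f"]]
}

#' Static FRET line
#'
#' Locus of `(⟨tau⟩_f, F_D/F_A)` for molecules resting in a single state,
#' parameterised by the interdye distance. Because every donor component is
#' quenched by the same FRET rate factor, the transfer efficiency is
#' component-uniform and the line has the exact form
#' `⟨tau⟩_f = (1-E) ⟨tau⟩_f0`, `F_D/F_A = gamma (1-E)/E`.
#'
#' @param donor A [donor_spec()] fitted from donor-only bursts.
#' @param r0 Foerster radius in Angstrom.
#' @param gamma Detection correction. Default 1.
#' @param n Number of samples along the line.
#'
#' @return A `fret_line` tibble with columns `distance`, `efficiency`,
#'   `tau_f_ns`, `fdfa`; attribute `kind = "static"`.
#' @export
static_fret_line <- function(donor, r0, gamma = 1, n = 512) {
  E <- seq(0.001, 0.999, length.out = n)
  out <- tibble::tibble(
    distance = r0 * ((1 - E) / E)^(1 / 6),
    efficiency = E,
    tau_f_ns = tau_f_at_efficiency(donor, E),
    fdfa = gamma * (1 - E) / E)
  attr(out, "kind") <- "static"
  class(out) <- c("fret_line", class(out))
  out
}

#' Dynamic FRET line between two states
#'
#' Locus of `(⟨tau⟩_f, F_D/F_A)` for molecules exchanging between two states
#' faster than the burst duration, parameterised by the time fraction `x`
#' spent in state 1: the lifetime is the fluorescence-weighted average
#' `(x tau1^2 + (1-x) tau2^2) / (x tau1 + (1-x) tau2)` over the species
#' lifetimes, the intensity ratio follows the species-averaged photon fluxes.
#' Its endpoints lie exactly on the static line.
#'
#' @param distance1,distance2 Interdye distances (Angstrom) of the two
#'   states (distinct).
#' @inheritParams static_fret_line
#' @return A `fret_line` tibble with columns `x1` (fraction in state 1),
#'   `tau_f_ns`, `fdfa`; attribute `kind = "dynamic"`.
#' @export
dynamic_fret_line <- function(distance1, distance2, donor, r0, gamma = 1,
                              n = 512) {
  if (isTRUE(all.equal(distance1, distance2))) {
    warning("identical states: dynamic line degenerates to a point")
  }
  E <- fret_efficiency(c(distance1, distance2), r0)
  x <- seq(0, 1, length.out = n)
  taus <- donor$lifetimes
  frs <- donor$fractions
  num <- den <- fl_d <- fl_a <- numeric(n)
  for (s in 1:2) {
    w <- if (s == 1) x else 1 - x
    tq <- taus * (1 - E[s])
    num <- num + w * sum(frs * tq^2)
    den <- den + w * sum(frs * tq)
    fl_d <- fl_d + w * (1 - E[s])
    fl_a <- fl_a + w * E[s]
  }
  out <- tibble::tibble(x1 = x, tau_f_ns = num / den,
                        fdfa = gamma * fl_d / fl_a)
  attr(out, "kind") <- "dynamic"
  attr(out, "endpoints") <- tibble::tibble(
    distance = c(distance1, distance2),
    tau_f_ns = tau_f_at_efficiency(donor, E),
    fdfa = gamma * (1 - E) / E)
  class(out) <- c("fret_line", class(out))
  out
}

#' Two-dimensional burst-indicator histogram with marginals
#'
#' Bins unflagged bursts on the `(⟨tau⟩_f, F_D/F_A)` plane and returns the
#' grid together with the 1D marginals shown along the axes of such plots.
#'
#' @param indicators Output of [burst_indicators()].
#' @param tau_breaks,fdfa_breaks Bin edges; defaults span the unflagged data
#'   with 40 bins.
#'
#' @return A list of class `fret_histogram2d`: `grid` (tibble `tau_mid`,
#'   `fdfa_mid`, `count`), `tau_marginal`, `fdfa_marginal`, `n_bursts`,
#'   `n_flagged`.
#' @export
fret_histogram2d <- function(indicators, tau_breaks = NULL,
                             fdfa_breaks = NULL) {
  ok <- dplyr::filter(indicators, !.data$flagged)
  if (nrow(ok) == 0) {
    if (is.null(tau_breaks)) tau_breaks <- seq(0, 5, length.out = 41)
    if (is.null(fdfa_breaks)) fdfa_breaks <- seq(0, 10, length.out = 41)
  }
  if (is.null(tau_breaks)) {
    tau_breaks <- seq(0, max(ok$tau_f_ns) * 1.05, length.out = 41)
  }
  if (is.null(fdfa_breaks)) {
    fdfa_breaks <- seq(0, max(ok$fdfa) * 1.05, length.out = 41)
  }
  mid <- function(b) (b[-1] + b[-length(b)]) / 2
  ti <- cut(ok$tau_f_ns, tau_breaks, include.lowest = TRUE, labels = FALSE)
  fi <- cut(ok$fdfa, fdfa_breaks, include.lowest = TRUE, labels = FALSE)
  keep <- !is.na(ti) & !is.na(fi)
  tab <- table(factor(ti[keep], seq_along(mid(tau_breaks))),
               factor(fi[keep], seq_along(mid(fdfa_breaks))))
  grid <- tidyr::expand_grid(tau_mid = mid(tau_breaks),
                             fdfa_mid = mid(fdfa_breaks))
  grid$count <- as.vector(t(matrix(tab, nrow = nrow(tab))))
  structure(list(
    grid = grid,
    tau_marginal = tibble::tibble(tau_mid = mid(tau_breaks),
                                  count = as.vector(rowSums(tab))),
    fdfa_marginal = tibble::tibble(fdfa_mid = mid(fdfa_breaks),
                                   count = as.vector(colSums(tab))),
    tau_breaks = tau_breaks, fdfa_breaks = fdfa_breaks,
    n_bursts = nrow(ok), n_flagged = sum(indicators$flagged)),
    class = "fret_histogram2d")
}

#' Time-window photon distribution analysis (PDA)
#'
#' Tests for dynamic averaging by slicing the photon stream into fixed time
#' windows of several sizes, histogramming the per-window FRET signal, and
#' comparing it with the shot-noise-limited (binomial mixture) distribution
#' expected for the given static multi-state model. For static molecules the
#' reduced chi-square is window-size independent; conformational exchange on
#' the window timescale makes it change systematically with window size.
#'
#' @param stream Photon tibble (`macrotime_ms`, `channel`).
#' @param window_sizes Window sizes in ms (at least 2). Default
#'   `c(0.5, 1, 2, 4)`.
#' @param model A [state_spec()] describing the static hypothesis.
#' @param gamma Detection correction. Default 1.
#' @param min_photons Minimum photons for a window to be used. Default 20.
#' @param n_bins Upper cap on the number of equal-expected-probability bins
#'   of the acceptor-fraction histogram (the bin count otherwise adapts to
#'   one bin per ~25 windows). Default 1000.
#' @param ratio_threshold Max/min chi2r ratio above which the verdict is
#'   `"dynamic"`. Default 1.5.
#'
#' @return A tibble (`window_ms`, `n_windows`, `chi2r`) with attributes
#'   `ratio` and `verdict` (`"dynamic"`/`"static"`).
#' @export
pda_time_window <- function(stream, window_sizes = c(0.5, 1, 2, 4), model,
                            gamma = 1, min_photons = 20, n_bins = 1000,
                            ratio_threshold = 1.5) {
  stopifnot(inherits(model, "state_spec"))
  if (length(window_sizes) < 2) {
    stop("need at least 2 window sizes for a dynamics verdict", call. = FALSE)
  }
  span <- diff(range(stream$macrotime_ms))
  if (any(window_sizes > span)) {
    stop("window size exceeds the acquisition span", call. = FALSE)
  }
  E <- fret_efficiency(model$distances, model$r0)
  eps <- E / (E + gamma * (1 - E))          # acceptor detection probability
  wts <- (1 - model$no_fret_fraction) * model$fractions
  if (model$no_fret_fraction > 0) {
    eps <- c(eps, 0)
    wts <- c(wts, model$no_fret_fraction)
  }

  res <- purrr::map_dfr(window_sizes, function(w) {
    win <- floor(stream$macrotime_ms / w)
    na <- tapply(stream$channel == "A", win, sum)
    nn <- tapply(rep(1L, nrow(stream)), win, sum)
    keep <- nn >= min_photons
    na <- na[keep]; nn <- nn[keep]
    n_win <- length(nn)

    # expected probability mass of the acceptor fraction k/N under the
    # static binomial mixture, over every value the data can take
    vals_list <- list(); p_list <- list()
    for (N in unique(nn)) {
      m <- sum(nn == N)
      k <- 0:N
      pk <- colSums(wts * t(vapply(eps, function(e) stats::dbinom(k, N, e),
                                   numeric(N + 1))))
      vals_list[[length(vals_list) + 1]] <- k / N
      p_list[[length(p_list) + 1]] <- m * pk
    }
    tab <- tibble::tibble(value = unlist(vals_list), p = unlist(p_list))
    tab <- dplyr::summarise(dplyr::group_by(tab, .data$value),
                            p = sum(.data$p), .groups = "drop")
    tab <- dplyr::arrange(tab, .data$value)

    # equal-expected-probability bins: the chi-square then has one degree of
    # freedom per bin regardless of how concentrated the distribution is
    nb <- min(max(20L, n_win %/% 25L), n_bins)
    cum <- cumsum(tab$p) / sum(tab$p)
    tab$bin <- pmin(floor(cum * nb * (1 - 1e-12)) + 1L, nb)
    expd <- tapply(tab$p, factor(tab$bin, seq_len(nb)), sum, default = 0)
    expd <- unname(expd) * n_win / sum(tab$p)

    obs_val <- na / nn
    bin_of <- tab$bin[match(obs_val, tab$value)]
    obs <- tabulate(bin_of, nb)

    # pool adjacent bins until every pooled bin expects >= 5 counts; a
    # deficient trailing group is merged backward
    pool <- integer(nb); cur <- 1; acc <- 0
    for (j in seq_len(nb)) {
      pool[j] <- cur; acc <- acc + expd[j]
      if (acc >= 5 && j < nb) { cur <- cur + 1; acc <- 0 }
    }
    if (acc < 5 && cur > 1) pool[pool == cur] <- cur - 1
    o <- tapply(obs, pool, sum); e <- tapply(expd, pool, sum)
    ok <- e > 0
    chi2 <- sum((o[ok] - e[ok])^2 / e[ok])
    dof <- max(sum(ok) - 1, 1)
    tibble::tibble(window_ms = w, n_windows = n_win, chi2r = chi2 / dof)
  })
  ratio <- max(res$chi2r) / min(res$chi2r)
  attr(res, "ratio") <- ratio
  attr(res, "verdict") <- if (ratio > ratio_threshold) "dynamic" else "static"
  res
}
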