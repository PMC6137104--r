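#' Replica-exchange Metropolis sampling on a toy landscape
#'
#' Samples a one-dimensional toy potential with parallel Metropolis chains at
#' several temperatures; configuration swaps between neighbouring
#' temperatures are attempted every `exchange_interval` steps with the
#' standard replica-exchange acceptance probability
#' `min(1, exp((beta_i - beta_j) (U_i - U_j)))`. This reproduces the role of
#' replica-exchange molecular dynamics in landscape reconstruction; the
#' sampler is a Metropolis walker, not a dynamics engine.
#'
#' @param pot A [potential_spec()].
#' @param temperatures Temperatures in K (strictly increasing). A single
#'   temperature is allowed only with `exchange = FALSE`.
#' @param n_steps Monte-Carlo steps per replica.
#' @param exchange_interval Steps between swap attempts. Default 50.
#' @param seed Integer seed.
#' @param step_sd Proposal standard deviation (reduced units). Default 0.3.
#' @param save_every Save a frame every this many steps. Default 10.
#' @param exchange Attempt replica swaps. Default `TRUE`.
#' @param x0 Initial coordinate for every replica. Default at the (first)
#'   well.
#'
#' @return A `replica_trajectories` tibble: `replica`, `temperature_K`,
#'   `frame`, `coordinate`, `energy_kcal`. Attributes: `temperatures`,
#'   `swap_acceptance`.
#' @export
sample_toy_landscape <- function(pot, temperatures, n_steps,
                                 exchange_interval = 50, seed = NULL,
                                 step_sd = 0.3, save_every = 10,
                                 exchange = TRUE, x0 = NULL) {
  stopifnot(inherits(pot, "potential_spec"))
  temperatures <- as.numeric(temperatures)
  if (is.unsorted(temperatures, strictly = TRUE)) {
    stop("temperatures must be strictly increasing", call. = FALSE)
  }
  nr <- length(temperatures)
  if (exchange && nr < 2) {
    stop("replica exchange needs at least 2 temperatures", call. = FALSE)
  }
  beta <- 1 / (.kB * temperatures)
  if (is.null(x0)) {
    x0 <- if (pot$kind == "harmonic") 0 else pot$well_positions[1]
  }
  n_frames <- if (n_steps <= 0) 0L else n_steps %/% save_every
  if (n_frames == 0L) {
    return(structure(tibble::tibble(replica = integer(),
                                    temperature_K = numeric(),
                                    frame = integer(), coordinate = numeric(),
                                    energy_kcal = numeric()),
                     temperatures = temperatures, swap_acceptance = NA_real_,
                     class = c("replica_trajectories", class(tibble::tibble()))))
  }

  with_seed(seed, {
    x <- rep(x0, nr)
    u <- potential_energy(pot, x)
    xs <- matrix(NA_real_, n_frames, nr)
    us <- matrix(NA_real_, n_frames, nr)
    att <- 0; acc <- 0
    fr <- 0L
    for (step in seq_len(n_steps)) {
      xp <- x + stats::rnorm(nr, 0, step_sd)
      up <- potential_energy(pot, xp)
      take <- log(stats::runif(nr)) < -beta * (up - u)
      x[take] <- xp[take]; u[take] <- up[take]
      if (exchange && nr >= 2 && step %% exchange_interval == 0) {
        start <- if ((step %/% exchange_interval) %% 2 == 0) 1L else 2L
        if (start <= nr - 1) {
          for (i in seq(start, nr - 1, by = 2)) {
            att <- att + 1
            if (log(stats::runif(1)) <
                  (beta[i] - beta[i + 1]) * (u[i] - u[i + 1])) {
              acc <- acc + 1
              tmp <- x[i]; x[i] <- x[i + 1]; x[i + 1] <- tmp
              tmp <- u[i]; u[i] <- u[i + 1]; u[i + 1] <- tmp
            }
          }
        }
      }
      if (step %% save_every == 0) {
        fr <- fr + 1L
        xs[fr, ] <- x; us[fr, ] <- u
      }
    }
    out <- tibble::tibble(
      replica = rep(seq_len(nr), each = n_frames),
      temperature_K = rep(temperatures, each = n_frames),
      frame = rep(seq_len(n_frames), nr),
      coordinate = as.vector(xs),
      energy_kcal = as.vector(us))
    attr(out, "temperatures") <- temperatures
    attr(out, "swap_acceptance") <- if (att > 0) acc / att else NA_real_
    class(out) <- c("replica_trajectories", class(out))
    out
  })
}

# Deterministic compact bead cluster: nx*ny*nz lattice, spacing in Angstrom.
bead_block <- function(nx, ny, nz, spacing = 3.8) {
  g <- tidyr::expand_grid(ix = seq_len(nx), iy = seq_len(ny), iz = seq_len(nz))
  tibble::tibble(x = (g$ix - (nx + 1) / 2) * spacing,
                 y = (g$iy - (ny + 1) / 2) * spacing,
                 z = (g$iz - (nz + 1) / 2) * spacing)
}

#' Toy two-domain tandem structures with known interdomain contacts
#'
#' Builds a coarse-bead stand-in for a tandem of two rigid domains in a
#' `"closed"`, `"open"` or `"separated"` arrangement: two 36-bead lattice
#' domains with residue identifiers in the ranges of the two PDZ domains,
#' positioned at increasing centre-of-mass separation. The open arrangement
#' is additionally slid sideways so its contact interface involves different
#' residue pairs than the closed one. The ground-truth interdomain contact
#' list at the given cutoff is returned alongside.
#'
#' @param conformation `"closed"`, `"open"` or `"separated"`.
#' @param cutoff Contact cutoff in Angstrom for the ground-truth list.
#'   Default 5.5.
#' @param jitter Per-bead Gaussian positional noise in Angstrom. Default 0.
#' @param seed Seed for the jitter.
#'
#' @return A list: `structure` (tibble `residue`, `domain`, `element`, `x`,
#'   `y`, `z`, `mass`), `contacts` (tibble `res1`, `res2`), `conformation`,
#'   `com_distance`.
#' @export
make_toy_tandem <- function(conformation = c("closed", "open", "separated"),
                            cutoff = 5.5, jitter = 0, seed = NULL) {
  conformation <- match.arg(conformation)
  d1 <- bead_block(3, 3, 4)
  d2 <- bead_block(3, 3, 4)
  gap <- c(closed = 4.4, open = 4.8, separated = 60)[[conformation]]
  shift_x <- max(d1$x) - min(d2$x) + gap
  d2$x <- d2$x + shift_x
  if (conformation == "open") d2$y <- d2$y + 2 * 3.8   # different interface
  str <- tibble::tibble(
    residue = c(61:96, 155:190),
    domain = rep(c("PDZ1", "PDZ2"), each = 36),
    element = "BEAD",
    x = c(d1$x, d2$x), y = c(d1$y, d2$y), z = c(d1$z, d2$z),
    mass = 110)
  if (jitter > 0) {
    str <- with_seed(seed, dplyr::mutate(
      str,
      x = .data$x + stats::rnorm(dplyr::n(), 0, jitter),
      y = .data$y + stats::rnorm(dplyr::n(), 0, jitter),
      z = .data$z + stats::rnorm(dplyr::n(), 0, jitter)))
  }
  doms <- list(PDZ1 = 61:151, PDZ2 = 155:249)
  cm <- contact_frequency_map(list(str), doms, cutoff = cutoff)
  contacts <- dplyr::select(dplyr::filter(cm, .data$frequency > 0),
                            "res1", "res2")
  com <- interdomain_com_distance(str, doms)
  list(structure = str, contacts = contacts, conformation = conformation,
       com_distance = com)
}
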