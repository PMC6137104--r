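#' Donor fluorophore decay specification
#'
#' Describes the intrinsic (no-acceptor) donor de-excitation as a one- or
#' two-exponential decay, the model used for donor-only control samples.
#'
#' @param fractions Numeric vector of species fractions (must sum to 1).
#' @param lifetimes Numeric vector of fluorescence lifetimes in ns (> 0),
#'   same length as `fractions` (1 or 2 components).
#'
#' @return An object of class `donor_spec`.
#' @examples
#' donor_spec(c(0.2, 0.8), c(1.5, 4.1))
#' @export
donor_spec <- function(fractions, lifetimes) {
  fractions <- as.numeric(fractions)
  lifetimes <- as.numeric(lifetimes)
  if (length(fractions) != length(lifetimes)) {
    stop("`fractions` and `lifetimes` must have the same length", call. = FALSE)
  }
  if (!length(fractions) %in% 1:2) {
    stop("donor model must have 1 or 2 components", call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("donor fractions must sum to 1", call. = FALSE)
  }
  if (any(fractions < 0)) stop("donor fractions must be non-negative", call. = FALSE)
  if (any(lifetimes <= 0)) stop("donor lifetimes must be positive", call. = FALSE)
  structure(list(fractions = fractions, lifetimes = lifetimes),
            class = "donor_spec")
}

#' @export
print.donor_spec <- function(x, ...) {
  cat("<donor_spec> ", length(x$fractions), " component(s)\n", sep = "")
  for (i in seq_along(x$fractions)) {
    cat(sprintf("  x = %.4f  tau = %.4f ns\n", x$fractions[i], x$lifetimes[i]))
  }
  invisible(x)
}

#' Species-averaged and fluorescence-averaged donor lifetimes
#'
#' @param donor A [donor_spec()].
#' @return Named numeric vector with `tau_x` (species-weighted mean lifetime)
#'   and `tau_f` (fluorescence-weighted mean lifetime).
#' @export
donor_mean_lifetimes <- function(donor) {
  stopifnot(inherits(donor, "donor_spec"))
  x <- donor$fractions
  tau <- donor$lifetimes
  c(tau_x = sum(x * tau), tau_f = sum(x * tau^2) / sum(x * tau))
}

#' Multi-state FRET model specification
#'
#' Describes a superposition of Gaussian-distributed FRET states (each with a
#' population fraction, mean interdye distance and distance-distribution
#' width), plus a no-FRET fraction accounting for molecules with an inactive
#' acceptor, and the Foerster radius of the dye pair.
#'
#' @param fractions Fractions of the FRET-active states (sum to 1).
#' @param distances Mean interdye distances in Angstrom (> 0).
#' @param widths Distance-distribution standard deviations in Angstrom (>= 0).
#' @param no_fret_fraction Fraction of molecules showing no energy transfer,
#'   in `[0, 1)`.
#' @param r0 Foerster radius in Angstrom. Default 52 Angstrom, typical for the
#'   Alexa 488 / Alexa 647 pair.
#'
#' @return An object of class `state_spec`.
#' @examples
#' state_spec(c(0.435, 0.324, 0.241), c(45, 55, 70), c(4, 5, 8),
#'            no_fret_fraction = 0.15)
#' @export
state_spec <- function(fractions, distances, widths,
                       no_fret_fraction = 0, r0 = 52) {
  fractions <- as.numeric(fractions)
  distances <- as.numeric(distances)
  widths <- as.numeric(widths)
  n <- length(fractions)
  if (length(distances) != n || length(widths) != n) {
    stop("fractions, distances and widths must have equal length", call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("state fractions must sum to 1", call. = FALSE)
  }
  if (any(fractions < 0)) stop("state fractions must be non-negative", call. = FALSE)
  if (any(distances <= 0)) stop("mean distances must be positive", call. = FALSE)
  if (any(widths < 0)) stop("widths must be non-negative", call. = FALSE)
  if (no_fret_fraction < 0 || no_fret_fraction >= 1) {
    stop("no_fret_fraction must be in [0, 1)", call. = FALSE)
  }
  if (r0 <= 0) stop("r0 must be positive", call. = FALSE)
  structure(list(fractions = fractions, distances = distances, widths = widths,
                 no_fret_fraction = no_fret_fraction, r0 = r0),
            class = "state_spec")
}

#' @export
print.state_spec <- function(x, ...) {
  cat("<state_spec> ", length(x$fractions), " FRET state(s), R0 = ",
      x$r0, " A\n", sep = "")
  for (i in seq_along(x$fractions)) {
    cat(sprintf("  x = %.4f  <R> = %6.2f A  sigma = %5.2f A\n",
                x$fractions[i], x$distances[i], x$widths[i]))
  }
  cat(sprintf("  no-FRET fraction = %.4f\n", x$no_fret_fraction))
  invisible(x)
}

#' Two-state exchange kinetics for burst simulation
#'
#' A continuous-time two-state Markov model of conformational exchange on the
#' sub-millisecond timescale probed by diffusing single molecules.
#'
#' @param distances Length-2 vector of interdye distances (Angstrom) for the
#'   two states.
#' @param forward_rate Rate from state 1 to state 2, in 1/ms (> 0).
#' @param backward_rate Rate from state 2 to state 1, in 1/ms (> 0).
#'
#' @return An object of class `two_state_kinetics`.
#' @export
two_state_kinetics <- function(distances, forward_rate, backward_rate) {
  if (length(distances) != 2 || any(distances <= 0)) {
    stop("distances must be two positive values", call. = FALSE)
  }
  if (forward_rate <= 0 || backward_rate <= 0) {
    stop("exchange rates must be positive", call. = FALSE)
  }
  structure(list(distances = as.numeric(distances),
                 forward_rate = forward_rate, backward_rate = backward_rate),
            class = "two_state_kinetics")
}

#' One-dimensional toy potential for replica-exchange sampling
#'
#' Stand-in energy landscape used by [sample_toy_landscape()]: either a
#' harmonic well or a symmetric double well along a reduced coordinate.
#'
#' @param kind `"harmonic"` or `"double_well"`.
#' @param stiffness Harmonic stiffness in kcal/mol per unit^2 (harmonic only).
#' @param well_positions Length-2 vector of well positions in reduced units
#'   (double well only).
#' @param barrier_height Barrier height in kcal/mol at the midpoint between
#'   the wells (double well only; >= 0).
#'
#' @return An object of class `potential_spec`; callable via
#'   [potential_energy()].
#' @export
potential_spec <- function(kind = c("harmonic", "double_well"),
                           stiffness = 1, well_positions = c(-1, 1),
                           barrier_height = 3) {
  kind <- match.arg(kind)
  if (kind == "harmonic" && stiffness <= 0) {
    stop("stiffness must be positive", call. = FALSE)
  }
  if (kind == "double_well") {
    if (barrier_height < 0) stop("barrier height must be >= 0", call. = FALSE)
    if (length(well_positions) != 2 || well_positions[1] == well_positions[2]) {
      stop("two distinct well positions required", call. = FALSE)
    }
  }
  structure(list(kind = kind, stiffness = stiffness,
                 well_positions = sort(as.numeric(well_positions)),
                 barrier_height = barrier_height),
            class = "potential_spec")
}

#' Evaluate a toy potential
#'
#' @param pot A [potential_spec()].
#' @param x Coordinate values (reduced units).
#' @return Potential energy in kcal/mol, same length as `x`.
#' @export
potential_energy <- function(pot, x) {
  stopifnot(inherits(pot, "potential_spec"))
  if (pot$kind == "harmonic") {
    0.5 * pot$stiffness * x^2
  } else {
    m <- mean(pot$well_positions)
    c2 <- (diff(pot$well_positions) / 2)^2
    pot$barrier_height * ((x - m)^2 - c2)^2 / c2^2
  }
}

#' Boltzmann constant in kcal/mol/K
#' @keywords internal
.kB <- 0.0019872041

# Run `expr` with a private RNG state seeded by `seed`, restoring the caller's
# global random state afterwards. All stochastic generators route through this
# so seeds are explicit arguments and no global state leaks.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}
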