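#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a donor-only decay fit
#'
#' @param x A `donor_fit`.
#' @param ... Unused.
#' @return One row per model parameter: `term`, `estimate`, `std_error`.
#' @export
#' @method tidy donor_fit
tidy.donor_fit <- function(x, ...) {
  k <- length(x$donor$fractions)
  terms <- c(if (k == 2) "fraction_1",
             paste0("lifetime_", seq_len(k)), "background")
  est <- c(if (k == 2) x$donor$fractions[1], x$donor$lifetimes, x$background)
  tibble::tibble(term = terms, estimate = est,
                 std_error = x$se[seq_along(terms)])
}

#' @rdname tidy.donor_fit
#' @export
#' @method glance donor_fit
glance.donor_fit <- function(x, ...) {
  tibble::tibble(chi2r = x$chi2r, deviance = x$deviance, dof = x$dof,
                 n_components = length(x$donor$fractions),
                 converged = x$converged)
}

#' Tidy a multi-state DA decay fit
#'
#' @param x A `da_fit`.
#' @param ... Unused.
#' @return One row per FRET state plus the no-FRET term.
#' @export
#' @method tidy da_fit
tidy.da_fit <- function(x, ...) {
  s <- x$states
  k <- length(s$fractions)
  tibble::tibble(
    state = c(seq_len(k), NA),
    term = c(rep("fret_state", k), "no_fret"),
    fraction = c(s$fractions, s$no_fret_fraction),
    distance = c(s$distances, NA),
    width = c(s$widths, NA),
    se_distance = c(x$se_distance, NA),
    se_width = c(x$se_width, NA))
}

#' @rdname tidy.da_fit
#' @export
#' @method glance da_fit
glance.da_fit <- function(x, ...) {
  tibble::tibble(chi2r = x$chi2r, deviance = x$deviance, dof = x$dof,
                 n_states = length(x$states$fractions),
                 no_fret = x$states$no_fret_fraction,
                 degenerate = x$degenerate, converged = x$converged)
}

#' Tidy a global shared-fraction fit
#'
#' @param x A `global_da_fit`.
#' @param ... Unused.
#' @return The per-variant state tibble (`variant`, `state`, `fraction`,
#'   `distance`, `width`).
#' @export
#' @method tidy global_da_fit
tidy.global_da_fit <- function(x, ...) x$variants

#' @rdname tidy.global_da_fit
#' @export
#' @method glance global_da_fit
glance.global_da_fit <- function(x, ...) {
  tibble::tibble(joint_chi2r = x$joint_chi2r, deviance = x$deviance,
                 dof = x$dof, n_par = x$n_par,
                 n_variants = length(x$chi2r),
                 n_states = length(x$fractions),
                 converged = x$converged)
}

#' Tidy a disulfide kinetics fit
#'
#' @param x A `disulfide_fit`.
#' @param ... Unused.
#' @return One row per parameter with estimate and standard error.
#' @export
#' @method tidy disulfide_fit
tidy.disulfide_fit <- function(x, ...) {
  tibble::tibble(term = c("p0", "p_inf", "k", "initial_rate"),
                 estimate = c(x$p0, x$p_inf, x$k, x$initial_rate),
                 std_error = unname(x$se[c("p0", "p_inf", "k",
                                           "initial_rate")]))
}

#' @rdname tidy.disulfide_fit
#' @export
#' @method glance disulfide_fit
glance.disulfide_fit <- function(x, ...) {
  tibble::tibble(sigma = stats::sd(x$residuals), n = length(x$residuals),
                 flagged = x$flagged, converged = x$converged)
}
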