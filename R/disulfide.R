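#' Simulate a disulfide-formation time course
#'
#' Percent disulfide versus time under single-exponential kinetics,
#' `P(t) = P_inf + (P_0 - P_inf) exp(-k t)`, with homoscedastic Gaussian
#' noise, clipped to `[0, 100]` — emulating triplicate gel-densitometry
#' measurements of an oxidation reaction.
#'
#' @param p0 Initial percent disulfide, in `[0, 100]`.
#' @param p_inf Final percent disulfide, in `[0, 100]`.
#' @param k Rate constant in 1/min.
#' @param times Time points in minutes.
#' @param noise_sd Gaussian noise SD in percent. Default 0.
#' @param seed Integer seed.
#' @param replicate Replicate id recorded in the table. Default 1.
#'
#' @return A `kinetics_table` tibble: `replicate`, `time_min`,
#'   `percent_disulfide`.
#' @export
simulate_disulfide_timecourse <- function(p0, p_inf, k, times, noise_sd = 0,
                                          seed = NULL, replicate = 1) {
  if (p0 < 0 || p0 > 100 || p_inf < 0 || p_inf > 100) {
    stop("p0 and p_inf must be in [0, 100]", call. = FALSE)
  }
  mu <- p_inf + (p0 - p_inf) * exp(-k * times)
  val <- with_seed(seed, mu + stats::rnorm(length(times), 0, noise_sd))
  tibble::tibble(replicate = replicate, time_min = as.numeric(times),
                 percent_disulfide = pmin(pmax(val, 0), 100))
}

#' Fit a single-exponential disulfide-formation time course
#'
#' Nonlinear least squares of `P(t) = P_f + (P_0 - P_f) exp(-k t)`, reporting
#' the initial and final extent, the rate constant `k` (1/min) and the
#' initial rate `k (P_f - P_0)` (percent/min) with standard errors.
#' Monotonically decreasing data are permitted (`P_f < P_0`). Flat data make
#' `k` unidentifiable; the fit is then flagged and `P_f ~ P_0`.
#'
#' @param table Tibble with columns `time_min` and `percent_disulfide`
#'   (>= 4 points; strictly increasing times within a replicate).
#' @return An object of class `disulfide_fit` with elements `p0`, `p_inf`,
#'   `k`, `initial_rate`, `se` (named vector), `flagged`, `converged`,
#'   `fitted`, `residuals`.
#' @export
fit_timecourse <- function(table) {
  tt <- table$time_min
  y <- table$percent_disulfide
  if (length(tt) < 4) stop("need at least 4 time points", call. = FALSE)
  if (any(tt < 0)) stop("times must be non-negative", call. = FALSE)

  p0_init <- y[which.min(tt)]
  pf_init <- y[which.max(tt)]
  span <- pf_init - p0_init
  k_init <- if (abs(span) > 1e-8) {
    # time to half change as a crude 1/k
    half <- p0_init + span / 2
    th <- suppressWarnings(stats::approx(y, tt, xout = half, ties = mean)$y)
    if (is.finite(th) && th > 0) log(2) / th else 0.2
  } else 0.2

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ pf + (p0 - pf) * exp(-k * tt),
      start = list(p0 = p0_init, pf = pf_init, k = max(k_init, 1e-3)),
      lower = c(0, 0, 0), upper = c(100, 100, 50),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  if (is.null(fit)) {
    co <- c(p0 = p0_init, pf = pf_init, k = NA_real_)
    se <- c(p0 = NA_real_, pf = NA_real_, k = NA_real_)
    flagged <- TRUE; converged <- FALSE
    fitted_vals <- rep(mean(y), length(y))
  } else {
    co <- stats::coef(fit)
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) rep(NA_real_, 3))
    names(se) <- names(co)
    converged <- fit$convInfo$isConv %||% TRUE
    # flat data: amplitude indistinguishable from zero makes k meaningless
    flagged <- abs(co[["pf"]] - co[["p0"]]) < max(2 * stats::sd(y), 1e-6) &&
      abs(span) < 1e-6
    fitted_vals <- stats::fitted(fit)
  }
  rate <- unname(co[["k"]] * (co[["pf"]] - co[["p0"]]))
  se_rate <- if (all(is.finite(se[c("k", "p0", "pf")]))) {
    amp <- co[["pf"]] - co[["p0"]]
    sqrt((amp * se[["k"]])^2 + (co[["k"]] * se[["pf"]])^2 +
           (co[["k"]] * se[["p0"]])^2)
  } else NA_real_
  structure(list(p0 = unname(co[["p0"]]), p_inf = unname(co[["pf"]]),
                 k = unname(co[["k"]]), initial_rate = rate,
                 se = c(p0 = unname(se[["p0"]]), p_inf = unname(se[["pf"]]),
                        k = unname(se[["k"]]), initial_rate = se_rate),
                 flagged = flagged, converged = converged,
                 data = table, fitted = fitted_vals,
                 residuals = y - fitted_vals),
            class = "disulfide_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.disulfide_fit <- function(x, ...) {
  cat(sprintf("<disulfide_fit> P0 = %.2f%%  Pinf = %.2f%%  k = %.3f /min  rate = %.2f %%/min%s\n",
              x$p0, x$p_inf, x$k, x$initial_rate,
              if (x$flagged) "  [flagged]" else ""))
  invisible(x)
}

#' Fold difference between two disulfide-formation rates
#'
#' Ratio of initial rates (percent/min) of two fits; display convention is
#' one decimal place.
#'
#' @param fit_a,fit_b `disulfide_fit` objects (or numbers, taken as rates).
#' @return The unrounded fold ratio `rate_a / rate_b`.
#' @export
rate_ratio <- function(fit_a, fit_b) {
  ra <- if (inherits(fit_a, "disulfide_fit")) fit_a$initial_rate else fit_a
  rb <- if (inherits(fit_b, "disulfide_fit")) fit_b$initial_rate else fit_b
  if (!is.finite(rb) || rb == 0) stop("denominator rate is zero", call. = FALSE)
  ra / rb
}

#' Replicate statistics and pairwise tests for kinetics fits
#'
#' Mean and standard error of the mean per group for each fit parameter,
#' plus two-sided unpaired t-tests between every pair of groups on each
#' parameter.
#'
#' @param fits List of `disulfide_fit` objects.
#' @param groups Character/factor vector assigning each fit to a mutant
#'   group (>= 2 replicates per group for SEM).
#' @return A list: `summary` tibble (`group`, `parameter`, `mean`, `sem`,
#'   `n`, `flagged`) and `tests` tibble (`group_a`, `group_b`, `parameter`,
#'   `p_value`).
#' @export
replicate_stats <- function(fits, groups) {
  stopifnot(length(fits) == length(groups))
  vals <- purrr::map2_dfr(fits, groups, function(f, g) {
    tibble::tibble(group = as.character(g),
                   parameter = c("p0", "p_inf", "k", "initial_rate"),
                   value = c(f$p0, f$p_inf, f$k, f$initial_rate))
  })
  summary <- dplyr::summarise(
    dplyr::group_by(vals, .data$group, .data$parameter),
    mean = mean(.data$value),
    sem = stats::sd(.data$value) / sqrt(dplyr::n()),
    n = dplyr::n(), .groups = "drop")
  summary$flagged <- summary$n < 2
  if (any(summary$flagged)) {
    warning("groups with a single replicate have undefined SEM")
  }
  gs <- unique(as.character(groups))
  tests <- list()
  if (length(gs) >= 2) {
    pairs <- utils::combn(gs, 2)
    for (p in seq_len(ncol(pairs))) {
      for (par in c("p0", "p_inf", "k", "initial_rate")) {
        va <- vals$value[vals$group == pairs[1, p] & vals$parameter == par]
        vb <- vals$value[vals$group == pairs[2, p] & vals$parameter == par]
        pv <- if (length(va) >= 2 && length(vb) >= 2 &&
                  (stats::sd(va) > 0 || stats::sd(vb) > 0)) {
          stats::t.test(va, vb, var.equal = FALSE)$p.value
        } else NA_real_
        tests[[length(tests) + 1]] <- tibble::tibble(
          group_a = pairs[1, p], group_b = pairs[2, p],
          parameter = par, p_value = pv)
      }
    }
  }
  list(summary = summary, tests = dplyr::bind_rows(tests))
}
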