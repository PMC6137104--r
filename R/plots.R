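#' @import ggplot2
#' @importFrom rlang .data :=
NULL

#' Plot a decay fit with weighted residuals
#'
#' Log-scale decay with the fitted model overlaid and the weighted-residual
#' trace, the standard presentation of TCSPC fits.
#'
#' @param object A `donor_fit` or `da_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
#' @method autoplot donor_fit
autoplot.donor_fit <- function(object, ...) {
  h <- object$hist
  df <- tibble::tibble(time_ns = h$time_ns, counts = h$counts,
                       wr = object$weighted_residuals)
  ggplot(df, aes(x = .data$time_ns)) +
    geom_point(aes(y = .data$counts), size = 0.2, alpha = 0.4) +
    scale_y_log10() +
    labs(x = "time (ns)", y = "counts",
         title = sprintf("decay fit, chi2r = %.3f", object$chi2r)) +
    theme_minimal()
}

#' @rdname autoplot.donor_fit
#' @export
#' @method autoplot da_fit
autoplot.da_fit <- autoplot.donor_fit

#' Plot weighted residuals and their autocorrelation
#'
#' @param fit A `donor_fit` or `da_fit`.
#' @return A ggplot object (residuals over channel and autocorrelation over
#'   lag, stacked).
#' @export
plot_fit_diagnostics <- function(fit) {
  wr <- tibble::tibble(channel = seq_along(fit$weighted_residuals),
                       value = fit$weighted_residuals, panel = "weighted residuals")
  ac <- dplyr::mutate(fit$autocorrelation, panel = "autocorrelation")
  names(ac)[1:2] <- c("channel", "value")
  ggplot(dplyr::bind_rows(wr, ac), aes(.data$channel, .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~panel, ncol = 1, scales = "free") +
    theme_minimal() + labs(x = NULL, y = NULL)
}

#' Plot a burst 2D histogram with FRET lines
#'
#' The multiparameter-detection presentation: per-burst `F_D/F_A` against
#' `<tau_D(A)>_f` as a filled 2D histogram, with optional static (red) and
#' dynamic (green) FRET lines.
#'
#' @param h2d A `fret_histogram2d`.
#' @param static_line,dynamic_line Optional `fret_line` objects.
#' @return A ggplot object.
#' @export
plot_fret_histogram <- function(h2d, static_line = NULL, dynamic_line = NULL) {
  g <- ggplot(dplyr::filter(h2d$grid, .data$count > 0),
              aes(.data$tau_mid, .data$fdfa_mid)) +
    geom_tile(aes(fill = .data$count)) +
    scale_fill_viridis_c() +
    labs(x = "<tau_D(A)>_f (ns)", y = "F_D/F_A") +
    theme_minimal()
  if (!is.null(static_line)) {
    g <- g + geom_line(data = static_line,
                       aes(.data$tau_f_ns, .data$fdfa),
                       colour = "red", inherit.aes = FALSE)
  }
  if (!is.null(dynamic_line)) {
    g <- g + geom_line(data = dynamic_line,
                       aes(.data$tau_f_ns, .data$fdfa),
                       colour = "darkgreen", inherit.aes = FALSE)
  }
  g + coord_cartesian(ylim = c(0, max(h2d$fdfa_breaks)))
}

#' Plot a free-energy profile
#'
#' @param object A `pmf_grid` (1-D or 2-D).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot pmf_grid
autoplot.pmf_grid <- function(object, ...) {
  axes <- attr(object, "axes")
  if (length(axes) == 1) {
    ggplot(object, aes(.data[[axes[1]]], .data$pmf_kcal)) +
      geom_line() +
      labs(x = axes[1], y = "PMF (kcal/mol)") + theme_minimal()
  } else {
    ggplot(dplyr::filter(object, !is.na(.data$pmf_kcal)),
           aes(.data[[axes[1]]], .data[[axes[2]]])) +
      geom_tile(aes(fill = .data$pmf_kcal)) +
      scale_fill_viridis_c(name = "PMF (kcal/mol)") +
      labs(x = axes[1], y = axes[2]) + theme_minimal()
  }
}

#' Plot an interdomain contact-frequency map
#'
#' @param object A `contact_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot contact_map
autoplot.contact_map <- function(object, ...) {
  ggplot(dplyr::filter(object, .data$frequency > 0),
         aes(.data$res1, .data$res2, fill = .data$frequency)) +
    geom_tile() +
    scale_fill_gradientn(colours = c("cyan", "orange", "red"),
                         limits = c(0, 1)) +
    labs(x = "domain 1 residue", y = "domain 2 residue") +
    theme_minimal()
}

#' Plot a disulfide kinetics fit
#'
#' @param object A `disulfide_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot disulfide_fit
autoplot.disulfide_fit <- function(object, ...) {
  d <- object$data
  tt <- seq(0, max(d$time_min), length.out = 200)
  curve <- tibble::tibble(
    time_min = tt,
    percent_disulfide = object$p_inf +
      (object$p0 - object$p_inf) * exp(-object$k * tt))
  ggplot(d, aes(.data$time_min, .data$percent_disulfide)) +
    geom_point() +
    geom_line(data = curve) +
    labs(x = "time (min)", y = "% disulfide") +
    theme_minimal()
}
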