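logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' WHAM free-energy profile from replica-exchange trajectories
#'
#' Weighted histogram analysis method over multiple temperatures: per-replica
#' free-energy shifts are iterated to self-consistency, the density of states
#' is reweighted to the target temperature, and the potential of mean force
#' `-k_B T ln p` is returned min-shifted to zero. All accumulation is done in
#' log space, so a single replica at the target temperature reduces exactly
#' to Boltzmann inversion of its histogram.
#'
#' @param trajs A `replica_trajectories` tibble (columns `replica`,
#'   `temperature_K`, `coordinate` and/or other coordinate columns,
#'   `energy_kcal`).
#' @param coords Character vector of 1 or 2 coordinate column names, or a
#'   function mapping the trajectory tibble to a tibble of coordinates.
#'   Default `"coordinate"`.
#' @param bins Number of bins per coordinate axis. Default 100.
#' @param target_T Target temperature in K. Default 300.
#' @param tol Convergence tolerance on the free-energy shifts. Default 1e-7.
#' @param max_iter Iteration cap. Default 1e5.
#' @param equilibration Fraction of initial frames discarded per replica.
#'   Default 0.125.
#' @param energy_bins Number of energy bins. Default 100.
#'
#' @return A `pmf_grid` tibble: one row per coordinate bin with the bin
#'   centre(s), `pmf_kcal` (`NA` for unsampled bins, flagged via
#'   `n_samples = 0`), and `n_samples`. Attributes: `target_T`, `converged`,
#'   `iterations`, `f_shifts`, `axes`.
#' @export
wham_pmf <- function(trajs, coords = "coordinate", bins = 100, target_T = 300,
                     tol = 1e-7, max_iter = 1e5, equilibration = 0.125,
                     energy_bins = 100) {
  if (nrow(trajs) == 0) stop("empty trajectories", call. = FALSE)
  trajs <- dplyr::group_by(trajs, .data$replica)
  trajs <- dplyr::filter(trajs, dplyr::row_number() >
                           floor(equilibration * dplyr::n()))
  trajs <- dplyr::ungroup(trajs)

  cvals <- if (is.function(coords)) {
    tibble::as_tibble(coords(trajs))
  } else {
    trajs[, coords, drop = FALSE]
  }
  n_ax <- ncol(cvals)
  if (!n_ax %in% 1:2) stop("1 or 2 coordinate axes supported", call. = FALSE)

  temps <- sort(unique(trajs$temperature_K))
  beta <- 1 / (.kB * temps)
  k_of <- match(trajs$temperature_K, temps)
  Nk <- tabulate(k_of, length(temps))

  E <- trajs$energy_kcal
  e_edges <- seq(min(E), max(E) + 1e-9, length.out = energy_bins + 1)
  e_mid <- (e_edges[-1] + e_edges[-length(e_edges)]) / 2
  e_bin <- pmin(findInterval(E, e_edges, rightmost.closed = TRUE), energy_bins)

  ax_edges <- lapply(seq_len(n_ax), function(a) {
    v <- cvals[[a]]
    seq(min(v), max(v) + 1e-9, length.out = bins + 1)
  })
  ax_bin <- lapply(seq_len(n_ax), function(a) {
    pmin(findInterval(cvals[[a]], ax_edges[[a]], rightmost.closed = TRUE), bins)
  })

  # energy-marginal histograms drive the f iteration
  He <- tabulate(e_bin, energy_bins)
  lHe <- ifelse(He > 0, log(He), -Inf)
  f <- numeric(length(temps))
  it <- 0; converged <- FALSE
  while (it < max_iter) {
    it <- it + 1
    # log D(E) = logsumexp_k [log N_k + f_k - beta_k E]
    lD <- vapply(seq_along(e_mid), function(e) {
      logsumexp(log(Nk) + f - beta * e_mid[e])
    }, 0)
    lOmega_e <- lHe - lD
    f_new <- -vapply(seq_along(temps), function(k) {
      logsumexp(lOmega_e - beta[k] * e_mid)
    }, 0)
    f_new <- f_new - f_new[1]
    if (max(abs(f_new - f)) < tol) { f <- f_new; converged <- TRUE; break }
    f <- f_new
  }
  if (!converged) {
    warning("WHAM did not converge in ", max_iter,
            " iterations (check energy-histogram overlap between neighbouring temperatures)")
  }

  lD <- vapply(seq_along(e_mid), function(e) {
    logsumexp(log(Nk) + f - beta * e_mid[e])
  }, 0)
  beta_t <- 1 / (.kB * target_T)

  cell <- ax_bin[[1]]
  if (n_ax == 2) cell <- cell + (ax_bin[[2]] - 1) * bins
  n_cells <- bins^n_ax
  # log P(cell) = logsumexp over frames grouped by (cell, E-bin)
  lw <- -lD[e_bin] - beta_t * e_mid[e_bin]     # per-frame log weight
  wmax <- max(lw)
  Pcell <- vapply(split(lw, factor(cell, seq_len(n_cells))), function(v) {
    if (length(v) == 0) return(0)
    sum(exp(v - wmax))
  }, 0)
  nsamp <- tabulate(cell, n_cells)
  Pcell <- unname(Pcell)
  lP <- ifelse(Pcell > 0, log(Pcell), -Inf)
  pmf <- -(.kB * target_T) * (lP - max(lP))
  pmf[nsamp == 0] <- NA_real_

  mids <- lapply(ax_edges, function(e) (e[-1] + e[-length(e)]) / 2)
  ax_names <- names(cvals)
  if (n_ax == 1) {
    out <- tibble::tibble(!!ax_names[1] := mids[[1]],
                          pmf_kcal = pmf, n_samples = nsamp)
  } else {
    g <- tidyr::expand_grid(a2 = mids[[2]], a1 = mids[[1]])  # cell = a1 fastest
    out <- tibble::tibble(!!ax_names[1] := rep(mids[[1]], times = bins),
                          !!ax_names[2] := rep(mids[[2]], each = bins),
                          pmf_kcal = pmf, n_samples = nsamp)
  }
  attr(out, "target_T") <- target_T
  attr(out, "converged") <- converged
  attr(out, "iterations") <- it
  attr(out, "f_shifts") <- f
  attr(out, "axes") <- ax_names
  class(out) <- c("pmf_grid", class(out))
  out
}

#' Interdye distance density from a two-axis PMF
#'
#' Integrates the Boltzmann weights `exp(-E_PMF / k_B T)` of a 2-D free
#' energy surface over its first (interdomain-distance) axis and
#' renormalises over the second (interdye-distance) axis, giving the
#' simulated counterpart of a FRET distance distribution.
#'
#' @param pmf A 2-D `pmf_grid` from [wham_pmf()].
#' @return Tibble with the interdye-axis bin centres, `prob` (sums to 1) and
#'   `density` (per Angstrom).
#' @export
pmf_to_distance_density <- function(pmf) {
  axes <- attr(pmf, "axes")
  if (is.null(axes) || length(axes) != 2) {
    stop("a 2-D PMF (interdomain x interdye axes) is required", call. = FALSE)
  }
  target_T <- attr(pmf, "target_T")
  w <- exp(-pmf$pmf_kcal / (.kB * target_T))
  w[is.na(w)] <- 0
  d <- tibble::tibble(axis2 = pmf[[axes[2]]], w = w)
  d <- dplyr::summarise(dplyr::group_by(d, .data$axis2), w = sum(.data$w),
                        .groups = "drop")
  bw <- if (nrow(d) > 1) diff(d$axis2[1:2]) else 1
  tibble::tibble(!!axes[2] := d$axis2, prob = d$w / sum(d$w),
                 density = d$w / sum(d$w) / bw)
}

as_domain_rows <- function(frame, residues, label) {
  rows <- which(frame$residue %in% residues)
  if (length(rows) == 0) {
    stop("no atoms found for domain ", label, " (residues ",
         min(residues), "-", max(residues), ")", call. = FALSE)
  }
  rows
}

#' Interdomain centre-of-mass distance
#'
#' Euclidean distance between the mass-weighted centroids of two residue
#' sets.
#'
#' @param frame Structure tibble with columns `residue`, `x`, `y`, `z` and
#'   optionally `mass` (default 1 per atom).
#' @param domain_defs List of two residue-id vectors, e.g.
#'   `list(PDZ1 = 61:151, PDZ2 = 155:249)`.
#' @return Distance in Angstrom.
#' @export
interdomain_com_distance <- function(frame, domain_defs = pdz_domains()) {
  m <- if ("mass" %in% names(frame)) frame$mass else rep(1, nrow(frame))
  coms <- lapply(seq_along(domain_defs), function(i) {
    rows <- as_domain_rows(frame, domain_defs[[i]], names(domain_defs)[i])
    w <- m[rows] / sum(m[rows])
    c(sum(frame$x[rows] * w), sum(frame$y[rows] * w), sum(frame$z[rows] * w))
  })
  sqrt(sum((coms[[1]] - coms[[2]])^2))
}

#' Default tandem domain boundaries
#'
#' Residue ranges for the two PDZ domains of the PSD-95 tandem construct
#' (residues 61-249); configurable wherever used.
#' @export
pdz_domains <- function() list(PDZ1 = 61:151, PDZ2 = 155:249)

# Minimum interatomic distance per interdomain residue pair for one frame.
residue_pair_mindist <- function(frame, rows1, rows2) {
  p1 <- as.matrix(frame[rows1, c("x", "y", "z")])
  p2 <- as.matrix(frame[rows2, c("x", "y", "z")])
  d2 <- outer(rowSums(p1^2), rowSums(p2^2), "+") - 2 * p1 %*% t(p2)
  d <- sqrt(pmax(d2, 0))
  r1 <- frame$residue[rows1]; r2 <- frame$residue[rows2]
  md <- tapply(as.vector(d),
               list(res1 = r1[row(d)], res2 = r2[col(d)]), min)
  tibble::tibble(res1 = as.integer(rownames(md)[row(md)]),
                 res2 = as.integer(colnames(md)[col(md)]),
                 min_dist = as.vector(md))
}

#' Interdomain residue contact frequency map
#'
#' A residue pair (one residue per domain) is in contact in a frame iff any
#' interdomain heavy-atom pair is within `cutoff`; the map records the
#' fraction of frames in contact for every interdomain residue pair.
#'
#' @param frames A structure tibble or a list of them (one per frame).
#' @param domain_defs List of two residue-id vectors.
#' @param cutoff Contact cutoff in Angstrom. Default 5.5.
#' @return A `contact_map` tibble (`res1`, `res2`, `frequency`); attribute
#'   `cutoff`.
#' @export
contact_frequency_map <- function(frames, domain_defs = pdz_domains(),
                                  cutoff = 5.5) {
  if (is.data.frame(frames)) frames <- list(frames)
  if (length(frames) == 0) stop("need at least one frame", call. = FALSE)
  per_frame <- purrr::map(frames, function(fr) {
    rows1 <- as_domain_rows(fr, domain_defs[[1]], names(domain_defs)[1])
    rows2 <- as_domain_rows(fr, domain_defs[[2]], names(domain_defs)[2])
    md <- residue_pair_mindist(fr, rows1, rows2)
    dplyr::mutate(md, contact = as.numeric(.data$min_dist <= cutoff))
  })
  out <- dplyr::bind_rows(per_frame)
  out <- dplyr::summarise(dplyr::group_by(out, .data$res1, .data$res2),
                          frequency = mean(.data$contact), .groups = "drop")
  attr(out, "cutoff") <- cutoff
  class(out) <- c("contact_map", class(out))
  out
}

#' Fraction of native contacts (Q-value)
#'
#' Fraction of a reference ("native") interdomain contact list present in a
#' frame, using the same any-heavy-atom-within-cutoff contact rule as
#' [contact_frequency_map()].
#'
#' @param frame Structure tibble.
#' @param native_contacts Tibble with columns `res1`, `res2` (non-empty).
#' @param cutoff Contact cutoff in Angstrom. Default 5.5.
#' @return Q in `[0, 1]`.
#' @export
q_fraction <- function(frame, native_contacts, cutoff = 5.5) {
  if (nrow(native_contacts) == 0) {
    stop("native contact list is empty", call. = FALSE)
  }
  rows1 <- which(frame$residue %in% native_contacts$res1)
  rows2 <- which(frame$residue %in% native_contacts$res2)
  md <- residue_pair_mindist(frame, rows1, rows2)
  j <- dplyr::left_join(native_contacts, md, by = c("res1", "res2"))
  mean(!is.na(j$min_dist) & j$min_dist <= cutoff)
}

frame_xyz <- function(frame, selection = NULL) {
  m <- as.matrix(frame[, c("x", "y", "z")])
  if (!is.null(selection)) m <- m[selection, , drop = FALSE]
  m
}

#' Root-mean-square deviation after optimal superposition
#'
#' Kabsch least-squares superposition (SVD of the covariance, with the
#' proper-rotation determinant correction) followed by the RMSD of the
#' aligned coordinates.
#'
#' @param frame_a,frame_b Structure tibbles with equal atom counts over the
#'   selection.
#' @param selection Optional atom row indices used for both frames.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(frame_a, frame_b, selection = NULL) {
  A <- frame_xyz(frame_a, selection)
  B <- frame_xyz(frame_b, selection)
  if (nrow(A) != nrow(B)) stop("atom-count mismatch", call. = FALSE)
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  s <- svd(crossprod(A, B))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((A %*% t(R) - B)^2)))
}

#' Representative frame of an ensemble
#'
#' The frame with the smallest average RMSD (after optimal superposition) to
#' all other frames in the selection; ties broken by lowest frame index.
#'
#' @param frames List of structure tibbles (>= 2).
#' @param selection Optional subset of frame indices to consider.
#' @param atom_selection Optional atom row indices for the RMSD.
#' @return Frame index (into `frames`).
#' @export
representative_frame <- function(frames, selection = NULL,
                                 atom_selection = NULL) {
  if (is.null(selection)) selection <- seq_along(frames)
  if (length(selection) < 2) stop("need at least 2 frames", call. = FALSE)
  n <- length(selection)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- rmsd(frames[[selection[i]]],
                                 frames[[selection[j]]], atom_selection)
    }
  }
  selection[which.min(rowMeans(D) * n / (n - 1))]
}

# Deterministic near-uniform sphere points (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Sphere-point SASA: each atom is expanded by the probe radius and the
#' fraction of test points on its sphere not buried inside any neighbour's
#' expanded sphere contributes to the area.
#'
#' @param structure Structure tibble (`x`, `y`, `z` plus `element`/`radius`).
#' @param probe Probe radius in Angstrom. Default 1.4.
#' @param n_points Test points per atom. Default 960.
#' @return Total SASA in Angstrom^2.
#' @export
shrake_rupley_sasa <- function(structure, probe = 1.4, n_points = 960) {
  xyz <- frame_xyz(structure)
  r <- atom_radii(structure) + probe
  n <- nrow(xyz)
  sp <- sphere_points(n_points)
  total <- 0
  for (i in seq_len(n)) {
    pts <- sweep(sp * r[i], 2, xyz[i, ], "+")
    d2 <- outer(rowSums(xyz^2), numeric(0))
    free <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      dd <- sum((xyz[i, ] - xyz[j, ])^2)
      if (dd >= (r[i] + r[j])^2) next
      cj <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      free <- free & cj > r[j]^2
      if (!any(free)) break
    }
    total <- total + 4 * pi * r[i]^2 * mean(free)
  }
  total
}

#' Buried surface area between two domains
#'
#' `BSA = SASA(domain1) + SASA(domain2) - SASA(complex)` (full difference,
#' not halved), by the Shrake-Rupley method.
#'
#' @param frame Structure tibble.
#' @param domain_defs List of two residue-id vectors.
#' @param probe Probe radius in Angstrom. Default 1.4.
#' @param n_points Sphere points per atom. Default 960.
#' @return BSA in Angstrom^2 (clipped at 0).
#' @export
buried_surface_area <- function(frame, domain_defs = pdz_domains(),
                                probe = 1.4, n_points = 960) {
  rows1 <- as_domain_rows(frame, domain_defs[[1]], names(domain_defs)[1])
  rows2 <- as_domain_rows(frame, domain_defs[[2]], names(domain_defs)[2])
  s1 <- shrake_rupley_sasa(frame[rows1, ], probe, n_points)
  s2 <- shrake_rupley_sasa(frame[rows2, ], probe, n_points)
  s12 <- shrake_rupley_sasa(frame[c(rows1, rows2), ], probe, n_points)
  max(s1 + s2 - s12, 0)
}

#' Correlate experimental and simulated distances
#'
#' Ordinary (or error-weighted) least-squares line through experimental
#' versus simulated distances, reporting slope, intercept and R^2.
#'
#' @param experimental Tibble with column `distance` (Angstrom) and optional
#'   `error`, or a numeric vector.
#' @param simulated Numeric vector of simulated distances, same length.
#' @param weighted Use `1/error^2` weights when errors are present. Default
#'   `TRUE`.
#' @return Tibble with `slope`, `intercept`, `r_squared`, `n`.
#' @export
correlate_distances <- function(experimental, simulated, weighted = TRUE) {
  if (is.numeric(experimental)) {
    experimental <- tibble::tibble(distance = experimental)
  }
  y <- experimental$distance
  if (length(y) != length(simulated) || length(y) < 3) {
    stop("need equal-length inputs with at least 3 points", call. = FALSE)
  }
  w <- if (weighted && "error" %in% names(experimental) &&
           all(experimental$error > 0)) 1 / experimental$error^2 else NULL
  fit <- stats::lm(y ~ simulated, weights = w)
  tibble::tibble(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 n = length(y))
}

#' Debye screening length of an electrolyte
#'
#' `lambda_D = sqrt(eps0 eps_r k_B T / (2 N_A e^2 I))` for a monovalent
#' electrolyte of ionic strength `I`, returned in nm.
#'
#' @param ionic_strength Ionic strength in mol/L. Default 0.1.
#' @param dielectric Relative dielectric constant. Default 80 (water).
#' @param temperature Temperature in K. Default 300.
#' @return Debye length in nm.
#' @examples
#' debye_length(0.1, 80, 300)   # ~0.96 nm
#' @export
debye_length <- function(ionic_strength = 0.1, dielectric = 80,
                         temperature = 300) {
  if (ionic_strength <= 0 || dielectric <= 0 || temperature <= 0) {
    stop("all arguments must be positive", call. = FALSE)
  }
  eps0 <- 8.8541878128e-12    # F/m
  e <- 1.602176634e-19        # C
  kb <- 1.380649e-23          # J/K
  na <- 6.02214076e23         # 1/mol
  I_m3 <- ionic_strength * 1000 * na   # particles/m^3
  sqrt(eps0 * dielectric * kb * temperature / (2 * I_m3 * e^2)) * 1e9
}
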