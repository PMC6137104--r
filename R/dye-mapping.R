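#' United-atom van der Waals radii (Angstrom)
#'
#' Radii used for accessible-volume clash tests and Shrake-Rupley surface
#' areas; elements not in the table fall back to 1.8 A.
#'
#' @export
vdw_radii <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8,
               SE = 1.9, BEAD = 1.8)

atom_radii <- function(structure) {
  if ("radius" %in% names(structure)) return(structure$radius)
  if ("element" %in% names(structure)) {
    r <- vdw_radii[toupper(structure$element)]
    r[is.na(r)] <- 1.8
    return(unname(r))
  }
  rep(1.8, nrow(structure))
}

#' Accessible volume of a tethered dye
#'
#' Geometric model of all sterically allowed dye positions for a fluorophore
#' attached through a flexible linker (single-sphere AV1 model). On a cubic
#' grid around the attachment atom, a point is accessible iff (i) a linker
#' path of width `linker_width` can reach it from the attachment point within
#' `linker_length` without clashing with structure atoms, and (ii) a dye
#' sphere of radius `dye_radius` centred there does not clash either. Path
#' lengths are shortest paths (Dijkstra) on the 26-neighbour grid lattice.
#'
#' @param structure Tibble with atom coordinates `x`, `y`, `z` (Angstrom) and
#'   optionally `element` or `radius` columns.
#' @param attachment_atom Row index of the attachment atom in `structure`.
#' @param linker_length Linker length in Angstrom. Default 20.
#' @param linker_width Linker width in Angstrom. Default 4.5.
#' @param dye_radius Dye radius in Angstrom. Default 3.5.
#' @param grid_spacing Grid spacing in Angstrom. Default 1.0.
#'
#' @return An `av_cloud` tibble of accessible points (`x`, `y`, `z`) with
#'   attributes `spacing`, `attachment`, `volume` (A^3) and `mean_position`.
#' @export
compute_av <- function(structure, attachment_atom, linker_length = 20,
                       linker_width = 4.5, dye_radius = 3.5,
                       grid_spacing = 1.0) {
  if (attachment_atom < 1 || attachment_atom > nrow(structure)) {
    stop("attachment atom does not exist", call. = FALSE)
  }
  if (linker_length <= dye_radius) {
    stop("linker_length must exceed dye_radius", call. = FALSE)
  }
  att <- as.numeric(structure[attachment_atom, c("x", "y", "z")])
  atoms <- structure[-attachment_atom, , drop = FALSE]
  radii <- atom_radii(structure)[-attachment_atom]

  g1 <- seq(-linker_length, linker_length, by = grid_spacing)
  nG <- length(g1)
  pts <- as.matrix(tidyr::expand_grid(x = att[1] + g1, y = att[2] + g1,
                                      z = att[3] + g1))
  # minimum clearance of each grid point from any structure atom surface
  clearance <- rep(Inf, nrow(pts))
  if (nrow(atoms) > 0) {
    ax <- atoms$x; ay <- atoms$y; az <- atoms$z
    reach <- max(radii) + max(linker_width / 2, dye_radius) + grid_spacing
    near <- which(ax > min(pts[, 1]) - reach & ax < max(pts[, 1]) + reach &
                    ay > min(pts[, 2]) - reach & ay < max(pts[, 2]) + reach &
                    az > min(pts[, 3]) - reach & az < max(pts[, 3]) + reach)
    for (i in near) {
      d <- sqrt((pts[, 1] - ax[i])^2 + (pts[, 2] - ay[i])^2 +
                  (pts[, 3] - az[i])^2) - radii[i]
      clearance <- pmin(clearance, d)
    }
  }
  within_reach <- sqrt(rowSums(sweep(pts, 2, att)^2)) <= linker_length
  path_free <- clearance >= linker_width / 2 & within_reach
  dye_free <- clearance >= dye_radius

  # shortest linker paths on the 26-neighbour lattice restricted to
  # path-free points, seeded at the grid point nearest the attachment
  idx <- which(path_free)
  if (length(idx) == 0) stop("no accessible points: buried site", call. = FALSE)
  rank_of <- integer(nrow(pts)); rank_of[idx] <- seq_along(idx)
  coord <- arrayInd(idx, c(nG, nG, nG))
  key <- function(m) (m[, 3] - 1) * nG * nG + (m[, 2] - 1) * nG + m[, 1]
  present <- logical(nG^3); present[key(coord)] <- TRUE

  # neighbourhood out to (2,1,1)-type offsets: the lattice shortest-path
  # metric then overestimates Euclidean lengths by < 2%, compensated by the
  # matching slack on the linker length below
  offsets <- as.matrix(tidyr::expand_grid(dx = -2:2, dy = -2:2, dz = -2:2))
  nrm2 <- rowSums(offsets^2)
  keep <- nrm2 > 0 & nrm2 <= 6
  # drop collinear multiples of shorter offsets
  keep <- keep & !(nrm2 == 4 & apply(offsets, 1, function(v) sum(v != 0) == 1))
  offsets <- offsets[keep, , drop = FALSE]
  offsets <- offsets[seq_len(nrow(offsets) / 2), , drop = FALSE]  # half-shell
  edges <- list(); wts <- list()
  for (j in seq_len(nrow(offsets))) {
    nb <- sweep(coord, 2, offsets[j, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= nG & nb[, 2] >= 1 & nb[, 2] <= nG &
      nb[, 3] >= 1 & nb[, 3] <= nG
    ok[ok] <- present[key(nb[ok, , drop = FALSE])]
    if (!any(ok)) next
    from <- seq_along(idx)[ok]
    to <- rank_of[idx[ok] + offsets[j, 1] + (offsets[j, 2] +
                                               offsets[j, 3] * nG) * nG]
    edges[[j]] <- rbind(from, to)
    wts[[j]] <- rep(grid_spacing * sqrt(sum(offsets[j, ]^2)), sum(ok))
  }
  el <- t(do.call(cbind, edges))
  gr <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(gr)$weight <- unlist(wts)
  nv_missing <- length(idx) - igraph::vcount(gr)
  if (nv_missing > 0) gr <- igraph::add_vertices(gr, nv_missing)

  d_att <- sqrt(colSums((t(pts[idx, ]) - att)^2))
  seed_rank <- which.min(d_att)
  pl <- as.vector(igraph::distances(gr, v = seed_rank))
  path_len <- pl + d_att[seed_rank]

  acc <- idx[path_len <= 1.02 * linker_length & dye_free[idx]]
  if (length(acc) == 0) stop("no accessible points: buried site", call. = FALSE)
  out <- tibble::as_tibble(as.data.frame(pts[acc, , drop = FALSE]))
  names(out) <- c("x", "y", "z")
  attr(out, "spacing") <- grid_spacing
  attr(out, "attachment") <- att
  attr(out, "volume") <- nrow(out) * grid_spacing^3
  attr(out, "mean_position") <- colMeans(out)
  class(out) <- c("av_cloud", class(out))
  out
}

#' Interdye distance statistics between two accessible volumes
#'
#' Three distance statistics used when relating structures to FRET: the
#' mean-position distance `R_mp`, the mean interdye distance `<R_DA>` over
#' position pairs, and the FRET-averaged distance
#' `R0 (<E>^-1 - 1)^(1/6)` with the efficiency averaged over pairs.
#'
#' @param av1,av2 `av_cloud` objects from [compute_av()].
#' @param r0 Foerster radius in Angstrom for the FRET average. Default 52.
#' @param n_pairs Number of Monte-Carlo point pairs when the full cross
#'   product is larger. Default 1e6.
#' @param seed Seed for the pair subsample. Default 1.
#' @param breaks Distance histogram breaks (defaults to 50 bins).
#'
#' @return A list: `r_mp`, `mean_r`, `fret_averaged_r`, `mean_efficiency`
#'   and a normalised `histogram` tibble (`distance`, `density`).
#' @export
interdye_stats <- function(av1, av2, r0 = 52, n_pairs = 1e6, seed = 1,
                           breaks = NULL) {
  if (nrow(av1) == 0 || nrow(av2) == 0) stop("empty AV cloud", call. = FALSE)
  m1 <- attr(av1, "mean_position"); m2 <- attr(av2, "mean_position")
  if (is.null(m1)) m1 <- colMeans(av1[, c("x", "y", "z")])
  if (is.null(m2)) m2 <- colMeans(av2[, c("x", "y", "z")])
  r_mp <- sqrt(sum((m1 - m2)^2))

  n1 <- nrow(av1); n2 <- nrow(av2)
  if (as.double(n1) * n2 <= n_pairs) {
    i <- rep(seq_len(n1), times = n2); j <- rep(seq_len(n2), each = n1)
  } else {
    ij <- with_seed(seed, cbind(sample.int(n1, n_pairs, replace = TRUE),
                                sample.int(n2, n_pairs, replace = TRUE)))
    i <- ij[, 1]; j <- ij[, 2]
  }
  d <- sqrt((av1$x[i] - av2$x[j])^2 + (av1$y[i] - av2$y[j])^2 +
              (av1$z[i] - av2$z[j])^2)
  mean_e <- mean(1 / (1 + (d / r0)^6))   # E -> 1 as d -> 0
  if (is.null(breaks)) breaks <- seq(0, max(d) * 1.02, length.out = 51)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  list(r_mp = r_mp, mean_r = mean(d),
       fret_averaged_r = r0 * (1 / mean_e - 1)^(1 / 6),
       mean_efficiency = mean_e,
       histogram = tibble::tibble(distance = h$mids, density = h$density))
}

#' Orientation-factor distribution from a wobbling-in-cone model
#'
#' Converts residual anisotropies of donor and acceptor into cone
#' half-angles and samples the FRET orientation factor kappa^2 by Monte
#' Carlo: cone axes uniform on the sphere, transition dipoles uniform within
#' each cone. Returns the distribution, its mean, and the multiplicative
#' bounds it implies on FRET-derived distances relative to the isotropic
#' assumption `<kappa^2> = 2/3`.
#'
#' @param r0 Fundamental anisotropy (same for both dyes), in `(0, 0.4]`.
#' @param rinf_donor,rinf_acceptor Residual anisotropies (`0 <= rinf <= r0`).
#' @param n_samples Monte-Carlo samples. Default 1e6.
#' @param seed Seed. Default 1.
#' @param probs Quantiles used for the kappa^2 bounds. Default
#'   `c(0.025, 0.975)`.
#'
#' @return A list of class `kappa2_model`: `cone_donor`, `cone_acceptor`
#'   (degrees), `mean_kappa2`, `kappa2_bounds`, `distance_factors`
#'   (`(kappa2/(2/3))^(1/6)` at the bounds) and a normalised `histogram`.
#' @export
kappa2_wobbling_cone <- function(r0, rinf_donor, rinf_acceptor,
                                 n_samples = 1e6, seed = 1,
                                 probs = c(0.025, 0.975)) {
  if (rinf_donor > r0 || rinf_acceptor > r0) {
    stop("residual anisotropy cannot exceed r0", call. = FALSE)
  }
  th_d <- cone_half_angle(rinf_donor, r0)
  th_a <- cone_half_angle(rinf_acceptor, r0)
  k2 <- with_seed(seed, {
    dip <- function(theta_deg, n) {
      ax <- random_unit_vectors(n)
      cone_dip <- function(axis, ct_min) {
        u <- stats::runif(n, ct_min, 1)       # cos within the cone
        phi <- stats::runif(n, 0, 2 * pi)
        s <- sqrt(1 - u^2)
        local <- cbind(s * cos(phi), s * sin(phi), u)
        rotate_to_axis(local, axis)
      }
      cone_dip(ax, cos(theta_deg * pi / 180))
    }
    d1 <- dip(th_d, n_samples)
    d2 <- dip(th_a, n_samples)
    # separation vector fixed along z
    (rowSums(d1 * d2) - 3 * d1[, 3] * d2[, 3])^2
  })
  q <- stats::quantile(k2, probs, names = FALSE)
  h <- graphics::hist(k2, breaks = seq(0, 4, length.out = 161), plot = FALSE)
  structure(list(cone_donor = th_d, cone_acceptor = th_a,
                 mean_kappa2 = mean(k2),
                 kappa2_bounds = q,
                 distance_factors = (q / (2 / 3))^(1 / 6),
                 histogram = tibble::tibble(kappa2 = h$mids,
                                            density = h$density)),
            class = "kappa2_model")
}

random_unit_vectors <- function(n) {
  u <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - u^2)
  cbind(s * cos(phi), s * sin(phi), u)
}

# Rotate vectors given in a frame whose +z is `axis` into the lab frame.
rotate_to_axis <- function(local, axis) {
  # orthonormal frame (e1, e2, axis) per row
  ref <- cbind(-axis[, 2], axis[, 1], 0)
  degen <- abs(axis[, 3]) > 0.999
  ref[degen, ] <- matrix(rep(c(1, 0, 0), sum(degen)), ncol = 3, byrow = TRUE)
  e1 <- ref - axis * rowSums(ref * axis)
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(axis[, 2] * e1[, 3] - axis[, 3] * e1[, 2],
              axis[, 3] * e1[, 1] - axis[, 1] * e1[, 3],
              axis[, 1] * e1[, 2] - axis[, 2] * e1[, 1])
  local[, 1] * e1 + local[, 2] * e2 + local[, 3] * axis
}

#' Combine fit and orientation uncertainty on a FRET distance
#'
#' Adds, in quadrature, the statistical fitting error and the distance error
#' induced by kappa^2 uncertainty, `R * |1 - (kappa2_bound/(2/3))^(1/6)|`,
#' for each kappa^2 bound. Bounds are reported asymmetrically.
#'
#' @param fit_error Statistical fit error in Angstrom (>= 0).
#' @param kappa2_bounds Length-2 kappa^2 bounds (lower, upper).
#' @param R Distance in Angstrom.
#' @return Tibble (`bound`, `kappa2`, `kappa_error`, `total_error`) in
#'   Angstrom.
#' @export
propagate_distance_error <- function(fit_error, kappa2_bounds, R) {
  if (fit_error < 0) stop("fit_error must be >= 0", call. = FALSE)
  factors <- (kappa2_bounds / (2 / 3))^(1 / 6)
  kerr <- R * abs(1 - factors)
  tibble::tibble(bound = c("lower", "upper")[seq_along(kappa2_bounds)],
                 kappa2 = kappa2_bounds,
                 kappa_error = kerr,
                 total_error = sqrt(fit_error^2 + kerr^2))
}
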