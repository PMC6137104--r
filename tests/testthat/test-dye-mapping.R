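test_that("wobbling-in-cone relation has the right limits", {
  expect_equal(cone_residual_factor(90), 0)
  expect_equal(cone_residual_factor(0), 1)
  ct <- cos(30 * pi / 180)
  expect_equal(cone_residual_factor(30), (ct * (1 + ct) / 2)^2)
  # inverse
  expect_equal(cone_half_angle(0.38 * cone_residual_factor(30), 0.38), 30,
               tolerance = 1e-9)
})

test_that("anisotropy decay simulation obeys the cone limits", {
  a <- simulate_anisotropy_decay(0.38, 90, 1, 4, 1e6, seed = 3)
  expect_equal(a$r_inf, 0)
  b <- simulate_anisotropy_decay(0.38, 0, 1, 4, 1e6, seed = 3)
  expect_equal(b$r_inf, 0.38)
  expect_error(simulate_anisotropy_decay(0.5, 30, 1, 4, 1e5), "0.4")
  # reconstructed anisotropy from high-count expected decays approaches r_inf
  cc <- simulate_anisotropy_decay(0.38, 30, 0.5, 4, 5e7, seed = 4,
                                  n_channels = 1024, dt = 0.0488)
  late <- 200:600
  r_est <- (cc$parallel$counts[late] - cc$perpendicular$counts[late]) /
    (cc$parallel$counts[late] + 2 * cc$perpendicular$counts[late])
  expect_equal(mean(r_est), 0.38 * cone_residual_factor(30), tolerance = 0.02)
})

test_that("accessible volume in free space is a ball centred on the site", {
  empty <- tibble::tibble(x = numeric(), y = numeric(), z = numeric(),
                          element = character())
  anchor <- tibble::tibble(x = 0, y = 0, z = 0, element = "C")
  av <- compute_av(anchor, 1, linker_length = 10, linker_width = 4.5,
                   dye_radius = 3.5, grid_spacing = 1)
  expect_equal(unname(attr(av, "mean_position")), c(0, 0, 0),
               tolerance = 0.05)
  expect_equal(attr(av, "volume"), 4 / 3 * pi * 10^3, tolerance = 0.05)
  expect_error(compute_av(anchor, 5, 10), "does not exist")
  expect_error(compute_av(anchor, 1, linker_length = 2, dye_radius = 3.5),
               "exceed")
})

test_that("a wall halves the accessible volume and displaces the mean", {
  # dense atom wall whose clearance boundary (z >= -0.5) passes half a grid
  # cell below the attachment at the origin: the accessible region is the
  # upper half-ball in cell-volume terms
  wall <- tidyr::expand_grid(x = seq(-16, 16, 0.5), y = seq(-16, 16, 0.5))
  wall <- tibble::tibble(x = wall$x, y = wall$y, z = -4.45, element = "C")
  structure <- dplyr::bind_rows(tibble::tibble(x = 0, y = 0, z = 0,
                                               element = "C"), wall)
  av <- compute_av(structure, 1, linker_length = 10, linker_width = 4.5,
                   dye_radius = 2.25, grid_spacing = 1)
  mp <- attr(av, "mean_position")
  expect_gt(mp[["z"]], 2)
  # analytic accessible volume: spherical cap above the clearance plane
  # z = -0.5 (height r + 0.5); approximately the half-ball
  h <- 10.5
  cap_vol <- pi * h^2 * (3 * 10 - h) / 3
  expect_lt(abs(attr(av, "volume") - cap_vol) / cap_vol, 0.05)
  expect_lt(abs(attr(av, "volume") - 2 / 3 * pi * 1000) / (2 / 3 * pi * 1000),
            0.08)
  # Monte-Carlo rejection-sampling oracle with the same accessibility rule
  ns <- 6e5
  smp <- tandemfret:::with_seed(7, {
    u <- matrix(stats::runif(3 * ns, -10, 10), ncol = 3)
    u[rowSums(u^2) <= 100, ]
  })
  clear <- smp[, 3] >= -4.45 + 1.7 + 2.25
  mc_vol <- 4 / 3 * pi * 10^3 * mean(clear)
  expect_lt(abs(attr(av, "volume") - mc_vol) / mc_vol, 0.05)
})

test_that("AV statistics are invariant to rigid motion of the structure", {
  set.seed(2)
  atoms <- tibble::tibble(x = rnorm(30, 0, 4), y = rnorm(30, 0, 4),
                          z = rnorm(30, 0, 4), element = "C")
  av1 <- compute_av(atoms, 1, linker_length = 12)
  # rotate 30 deg about z and translate
  th <- pi / 6
  rot <- dplyr::mutate(atoms,
                       xn = cos(th) * x - sin(th) * y + 5,
                       yn = sin(th) * x + cos(th) * y - 2,
                       x = xn, y = yn, z = z + 3)
  av2 <- compute_av(rot[, c("x", "y", "z", "element")], 1, linker_length = 12)
  expect_equal(attr(av1, "volume"), attr(av2, "volume"),
               tolerance = 0.03)
})

test_that("interdye statistics match exact enumeration on small clouds", {
  p1 <- tibble::tibble(x = 0, y = 0, z = 0)
  p2 <- tibble::tibble(x = 40, y = 0, z = 0)
  s <- interdye_stats(p1, p2)
  expect_equal(s$r_mp, 40)
  expect_equal(s$mean_r, 40)
  expect_equal(s$fret_averaged_r, 40)
  # identical co-located clouds: Jensen gap
  cl <- tidyr::expand_grid(x = c(0, 3.5), y = c(0, 3.5), z = c(0, 3.5))
  s2 <- interdye_stats(cl, cl)
  expect_equal(s2$r_mp, 0, tolerance = 1e-12)
  expect_gt(s2$mean_r, 0)
  # brute-force double-loop oracle for the mean distance and mean efficiency
  cl2 <- dplyr::mutate(cl, x = x + 20)
  s3 <- interdye_stats(cl, cl2, r0 = 52)
  dists <- as.vector(sqrt(outer(cl$x, cl2$x, "-")^2 +
                            outer(cl$y, cl2$y, "-")^2 +
                            outer(cl$z, cl2$z, "-")^2))
  expect_equal(s3$mean_r, mean(dists), tolerance = 1e-9)
  expect_equal(s3$mean_efficiency, mean(1 / (1 + (dists / 52)^6)),
               tolerance = 1e-9)
  expect_error(interdye_stats(p1[0, ], p2), "empty")
})

test_that("kappa2 sampling hits the isotropic average and frozen-limit width", {
  iso <- kappa2_wobbling_cone(0.38, 0, 0, n_samples = 4e5, seed = 5)
  expect_equal(iso$mean_kappa2, 2 / 3, tolerance = 0.005)
  expect_equal(iso$cone_donor, 90)
  # frozen dyes: static isotropic kappa2, wide support
  fro <- kappa2_wobbling_cone(0.38, 0.38, 0.38, n_samples = 4e5, seed = 6)
  expect_equal(fro$cone_donor, 0, tolerance = 1e-6)
  expect_gt(fro$kappa2_bounds[2], 2)
  expect_lt(fro$kappa2_bounds[1], 0.1)
  expect_error(kappa2_wobbling_cone(0.3, 0.35, 0.1), "exceed")
  # independent MC oracle at 30-degree cones (direct resampling, own stream)
  mod <- kappa2_wobbling_cone(0.38, 0.38 * cone_residual_factor(30),
                              0.38 * cone_residual_factor(30),
                              n_samples = 4e5, seed = 7)
  oracle <- tandemfret:::with_seed(1234, {
    n <- 4e5
    samp_cone <- function(theta) {
      ax <- tandemfret:::random_unit_vectors(n)
      u <- stats::runif(n, cos(theta * pi / 180), 1)
      phi <- stats::runif(n, 0, 2 * pi)
      loc <- cbind(sqrt(1 - u^2) * cos(phi), sqrt(1 - u^2) * sin(phi), u)
      tandemfret:::rotate_to_axis(loc, ax)
    }
    d1 <- samp_cone(30); d2 <- samp_cone(30)
    mean((rowSums(d1 * d2) - 3 * d1[, 3] * d2[, 3])^2)
  })
  expect_equal(mod$mean_kappa2, oracle, tolerance = 0.01)
})

test_that("distance-error propagation combines terms in quadrature", {
  # kappa2 bounds exactly 2/3: only the fit error remains
  p <- propagate_distance_error(1.5, c(2 / 3, 2 / 3), 50)
  expect_equal(p$total_error, c(1.5, 1.5))
  # zero fit error, upper bound 4/3: R (2^(1/6) - 1)
  p2 <- propagate_distance_error(0, c(2 / 3, 4 / 3), 50)
  expect_equal(p2$total_error[2], 50 * (2^(1 / 6) - 1))
  # 1 A fit with a 2 A kappa term: sqrt(5)
  k2 <- (2 / 3) * (1 + 2 / 50)^6    # bound chosen so kappa error is 2 A
  p3 <- propagate_distance_error(1, c(2 / 3, k2), 50)
  expect_equal(p3$total_error[2], sqrt(5), tolerance = 1e-9)
  expect_error(propagate_distance_error(-1, c(2 / 3, 1), 50), ">= 0")
})
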