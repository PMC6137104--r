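test_that("interdomain COM distance is exact on constructed geometry", {
  fr <- mini_frame(rbind(c(0, 0, 0), c(10, 0, 0)), c(61, 155))
  doms <- list(d1 = 61, d2 = 155)
  expect_equal(interdomain_com_distance(fr, doms), 10)
  # translation invariance
  fr2 <- dplyr::mutate(fr, x = x + 3, y = y - 7, z = z + 1)
  expect_equal(interdomain_com_distance(fr2, doms), 10)
  # mass weighting
  fr3 <- mini_frame(rbind(c(0, 0, 0), c(4, 0, 0), c(12, 0, 0)),
                    c(61, 61, 155))
  fr3$mass <- c(1, 3, 1)
  expect_equal(interdomain_com_distance(fr3, doms), 12 - 3)
  expect_error(interdomain_com_distance(fr, list(d1 = 61, d2 = 999)),
               "no atoms")
})

test_that("contact map matches a brute-force all-pairs recomputation", {
  tt <- make_toy_tandem("closed", jitter = 0.3, seed = 9)
  frames <- lapply(1:5, function(i) make_toy_tandem("closed", jitter = 0.4,
                                                    seed = i)$structure)
  cm <- contact_frequency_map(frames, cutoff = 5.5)
  # single frame gives only 0/1 frequencies
  cm1 <- contact_frequency_map(frames[[1]], cutoff = 5.5)
  expect_true(all(cm1$frequency %in% c(0, 1)))
  # O(N^2) oracle over frames and residue pairs
  doms <- pdz_domains()
  for (pair_row in sample(seq_len(nrow(cm)), 20)) {
    r1 <- cm$res1[pair_row]; r2 <- cm$res2[pair_row]
    freq <- mean(vapply(frames, function(fr) {
      a <- fr[fr$residue == r1, c("x", "y", "z")]
      b <- fr[fr$residue == r2, c("x", "y", "z")]
      dmin <- min(sqrt(outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2 +
                         outer(a$z, b$z, "-")^2))
      dmin <= 5.5
    }, TRUE))
    expect_equal(cm$frequency[pair_row], freq)
  }
  expect_error(contact_frequency_map(list()), "at least one")
})

test_that("Q-value counts exactly the native pairs within cutoff", {
  # two-residue domains engineered so exactly half the native pairs survive
  xyz_ref <- rbind(c(0, 0, 0), c(0, 5, 0), c(4, 0, 0), c(4, 5, 0))
  ref <- mini_frame(xyz_ref, c(61, 62, 155, 156))
  native <- contact_frequency_map(ref, list(a = 61:62, b = 155:156),
                                  cutoff = 5.5)
  native <- dplyr::filter(native, frequency == 1)[, c("res1", "res2")]
  expect_equal(nrow(native), 2)        # the two facing pairs (diagonals are 6.4 A)
  # move residue 156 far away: pair (62,156) breaks, (61,155) survives
  xyz_half <- xyz_ref; xyz_half[4, ] <- c(40, 0, 0)
  half <- mini_frame(xyz_half, c(61, 62, 155, 156))
  expect_equal(q_fraction(half, native), 0.5)
  expect_error(q_fraction(ref, native[0, ]), "empty")
})

test_that("Kabsch RMSD removes rigid motion and matches an oracle", {
  set.seed(11)
  A <- mini_frame(matrix(rnorm(30), ncol = 3), 1:10)
  expect_equal(rmsd(A, A), 0)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  B <- A
  xyzB <- as.matrix(A[, c("x", "y", "z")]) %*% R
  B$x <- xyzB[, 1] + 5; B$y <- xyzB[, 2] - 3; B$z <- xyzB[, 3] + 11
  expect_lt(rmsd(A, B), 1e-9)
  # independent oracle: bio3d superposition on a deformed copy
  C <- dplyr::mutate(B, x = x + c(rep(0, 5), rep(1.5, 5)))
  ours <- rmsd(A, C)
  xa <- as.vector(t(as.matrix(A[, c("x", "y", "z")])))
  xc <- as.vector(t(as.matrix(C[, c("x", "y", "z")])))
  fitted <- suppressWarnings(bio3d::fit.xyz(fixed = xa, mobile = xc))
  oracle <- sqrt(mean(colSums(matrix((fitted - xa)^2, nrow = 3))))
  expect_equal(ours, oracle, tolerance = 1e-6)
  expect_error(rmsd(A, A[1:5, ]), "mismatch")
})

test_that("representative frame minimises mean pairwise RMSD", {
  base <- matrix(rnorm(24, sd = 3), ncol = 3)
  mk <- function(shift) mini_frame(base + shift, 1:8)
  frames <- list(mk(0), mk(2), mk(4.2))     # B midway between A and C
  # shifts are removed by superposition; deform instead
  mk2 <- function(s) {
    m <- base; m[1, 1] <- m[1, 1] + s
    mini_frame(m, 1:8)
  }
  frames <- list(mk2(0), mk2(2), mk2(4.2))
  expect_equal(representative_frame(frames), 2)
  # identical frames: tie broken by lowest index
  expect_equal(representative_frame(list(mk2(1), mk2(1), mk2(1))), 1)
  # invariance to reordering up to relabeling
  expect_equal(representative_frame(frames[c(3, 2, 1)]), 2)
  expect_error(representative_frame(frames[1]), "at least 2")
})

test_that("Shrake-Rupley SASA and buried surface area match analytic values", {
  one <- tibble::tibble(x = 0, y = 0, z = 0, radius = 2)
  s <- shrake_rupley_sasa(one, probe = 1.4, n_points = 960)
  expect_equal(s, 4 * pi * (2 + 1.4)^2, tolerance = 0.01)

  # two overlapping spheres: analytic via spherical caps
  r <- 2 + 1.4; d <- 2.5
  two <- tibble::tibble(x = c(0, d), y = 0, z = 0, radius = 2)
  # exposed area of each sphere: 2 pi r (r + d/2) ... cap height h = r - d/2
  cap <- 2 * pi * r * (r - d / 2)
  analytic <- 2 * (4 * pi * r^2 - cap)
  expect_equal(shrake_rupley_sasa(two, 1.4, 960), analytic, tolerance = 0.02)

  # BSA via the same pair, as two one-atom "domains"
  fr <- tibble::tibble(residue = c(61, 155), element = "BEAD",
                       x = c(0, d), y = 0, z = 0, radius = 2, mass = 1)
  doms <- list(a = 61, b = 155)
  bsa <- buried_surface_area(fr, doms, probe = 1.4, n_points = 960)
  expect_equal(bsa, 2 * cap, tolerance = 0.02 * 2 * cap + 1)
  # symmetry under domain relabeling
  expect_equal(bsa, buried_surface_area(fr, rev(doms), 1.4, 960))
  # distant domains bury nothing
  fr2 <- dplyr::mutate(fr, x = c(0, 50))
  expect_equal(buried_surface_area(fr2, doms), 0)
})

test_that("distance correlation reproduces closed-form least squares", {
  x <- c(30, 40, 50, 60, 70)
  out <- correlate_distances(x, x)
  expect_equal(out$slope, 1)
  expect_equal(out$r_squared, 1)
  out2 <- correlate_distances(rep(42, 5), x)
  expect_equal(out2$r_squared, 0)
  # closed-form oracle on noisy pairs
  set.seed(13)
  sim <- runif(10, 35, 70)
  exp_d <- 0.9 * sim + 3 + rnorm(10)
  o <- correlate_distances(exp_d, sim)
  sxx <- sum((sim - mean(sim))^2)
  sxy <- sum((sim - mean(sim)) * (exp_d - mean(exp_d)))
  slope <- sxy / sxx
  r2 <- sxy^2 / (sxx * sum((exp_d - mean(exp_d))^2))
  expect_equal(o$slope, slope, tolerance = 1e-12)
  expect_equal(o$r_squared, r2, tolerance = 1e-12)
  expect_error(correlate_distances(x[1:2], x[1:2]), "at least 3")
})

test_that("Debye length matches the SI closed form and scaling law", {
  ld <- debye_length(0.1, 80, 300)
  expect_equal(round(ld), 1)
  expect_equal(ld, 0.96, tolerance = 0.02)
  expect_equal(debye_length(0.4, 80, 300), ld / 2, tolerance = 1e-12)
  # direct SI evaluation
  direct <- sqrt(8.8541878128e-12 * 80 * 1.380649e-23 * 300 /
                   (2 * 0.1 * 1000 * 6.02214076e23 *
                      (1.602176634e-19)^2)) * 1e9
  expect_equal(ld, direct, tolerance = 1e-12)
  expect_error(debye_length(-1), "positive")
})

test_that("Q mutual exclusivity holds for disjoint toy interfaces", {
  cl <- make_toy_tandem("closed")
  op <- make_toy_tandem("open")
  # interfaces are disjoint residue-pair sets
  shared <- dplyr::inner_join(cl$contacts, op$contacts,
                              by = c("res1", "res2"))
  expect_equal(nrow(shared), 0)
  # frames dominated by one interface score low on the other
  expect_gt(q_fraction(cl$structure, cl$contacts), 0.8)
  expect_lt(q_fraction(cl$structure, op$contacts), 0.5)
  expect_gt(q_fraction(op$structure, op$contacts), 0.8)
  expect_lt(q_fraction(op$structure, cl$contacts), 0.5)
})
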