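#' @importFrom stats optim pf dnorm rpois
NULL

# Stick-breaking map from K-1 free parameters in (0,1) to a K-simplex, so
# fitted state fractions sum to 1 at every optimizer step.
stick_to_simplex <- function(v) {
  k <- length(v) + 1
  f <- numeric(k)
  rem <- 1
  for (j in seq_along(v)) {
    f[j] <- rem * v[j]
    rem <- rem - f[j]
  }
  f[k] <- rem
  f
}

simplex_to_stick <- function(f) {
  k <- length(f)
  if (k == 1) return(numeric(0))
  v <- numeric(k - 1)
  rem <- 1
  for (j in seq_len(k - 1)) {
    v[j] <- min(max(f[j] / rem, 1e-6), 1 - 1e-6)
    rem <- rem - f[j]
  }
  v
}

fit_diagnostics <- function(counts, mu, n_par) {
  wr <- (counts - mu) / sqrt(pmax(mu, 1e-12))
  dof <- length(counts) - n_par
  dev <- poisson_deviance(counts, mu)
  list(weighted_residuals = wr,
       autocorrelation = residual_autocorrelation(wr),
       chi2r = dev / dof,
       deviance = dev,
       dof = dof)
}

#' Fit a donor-only TCSPC decay
#'
#' Maximum-likelihood (Poisson deviance) fit of a one- or two-exponential
#' donor model convolved with the IRF, with a floated flat background. The
#' reported figure of merit `chi2r` is deviance divided by the degrees of
#' freedom.
#'
#' @param hist A [decay_histogram()] with its IRF attribute set.
#' @param n_components 1 or 2 exponential components.
#' @param n_starts Number of bounded random restarts.
#' @param seed Seed for the restart jitter.
#'
#' @return An object of class `donor_fit`: the fitted [donor_spec()]
#'   (`$donor`), background, standard errors, convergence flag and
#'   diagnostics (`$chi2r`, `$weighted_residuals`, `$autocorrelation`).
#' @export
fit_donor_only <- function(hist, n_components = 2, n_starts = 3, seed = 1) {
  stopifnot(inherits(hist, "decay_histogram"))
  if (!n_components %in% 1:2) stop("n_components must be 1 or 2", call. = FALSE)
  irf <- hist_irf(hist)
  if (is.null(irf)) stop("histogram carries no IRF", call. = FALSE)
  counts <- hist$counts
  dt <- hist_dt(hist)
  n <- length(counts)
  total <- sum(counts)

  # crude moment start: mean arrival time past the IRF peak
  t <- hist$time_ns
  t_peak <- t[which.max(irf)]
  w <- counts * (t > t_peak)
  tau0 <- max(0.3, min(15, sum(w * (t - t_peak)) / max(sum(w), 1)))

  obj <- function(par) {
    if (n_components == 1) {
      donor <- donor_spec(1, par[1])
      bg <- par[2]
    } else {
      donor <- donor_spec(c(par[1], 1 - par[1]), par[2:3])
      bg <- par[4]
    }
    mu <- donor_counts(donor, irf, dt, max(total - n * bg, 1), bg)
    poisson_deviance(counts, mu)
  }
  bg_hi <- max(total / n, 1e-6)
  if (n_components == 1) {
    lower <- c(0.05, 0); upper <- c(20, bg_hi)
    base_start <- c(tau0, 0.01 * bg_hi)
  } else {
    lower <- c(1e-3, 0.05, 0.05, 0); upper <- c(1 - 1e-3, 20, 20, bg_hi)
    base_start <- c(0.4, 0.5 * tau0, 1.3 * tau0, 0.01 * bg_hi)
  }
  fits <- with_seed(seed, {
    lapply(seq_len(n_starts), function(i) {
      start <- base_start
      if (i > 1) {
        jit <- stats::runif(length(start), 0.6, 1.6)
        start <- pmin(pmax(base_start * jit, lower + 1e-8), upper - 1e-8)
      }
      tryCatch(optim(start, obj, method = "L-BFGS-B", lower = lower,
                     upper = upper, control = list(maxit = 500)),
               error = function(e) NULL)
    })
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) stop("donor fit failed on all starts", call. = FALSE)
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]

  par <- best$par
  if (n_components == 1) {
    donor <- donor_spec(1, par[1]); bg <- par[2]
  } else {
    ord <- order(par[2:3])
    fr <- c(par[1], 1 - par[1])[ord]
    donor <- donor_spec(fr, par[2:3][ord]); bg <- par[4]
  }
  mu <- donor_counts(donor, irf, dt, max(total - n * bg, 1), bg)
  dg <- fit_diagnostics(counts, mu, length(par))

  se <- tryCatch({
    h <- stats::optimHess(par, obj)
    sqrt(pmax(diag(2 * solve(h)), 0))
  }, error = function(e) rep(NA_real_, length(par)))

  structure(list(donor = donor, background = bg, se = se,
                 converged = best$convergence == 0,
                 chi2r = dg$chi2r, deviance = dg$deviance, dof = dg$dof,
                 weighted_residuals = dg$weighted_residuals,
                 autocorrelation = dg$autocorrelation,
                 hist = hist),
            class = "donor_fit")
}

#' @export
print.donor_fit <- function(x, ...) {
  cat("<donor_fit> chi2r =", round(x$chi2r, 4),
      if (!x$converged) "(NOT converged)", "\n")
  print(x$donor)
  cat(sprintf("  background = %.4g counts/channel\n", x$background))
  invisible(x)
}

# Shared machinery: deviance of one DA histogram for a state parameter block
# (distances, widths, no_fret, background) and fixed fractions, on a
# precomputed decay basis.
da_block_deviance <- function(block, fractions, bas, counts, total) {
  k <- length(fractions)
  distances <- block[seq_len(k)]
  widths <- block[k + seq_len(k)]
  no_fret <- block[2 * k + 1]
  bg <- block[2 * k + 2]
  mu <- basis_counts(bas, fractions, distances, widths, no_fret,
                     max(total - bas$n * bg, 1), bg)
  poisson_deviance(counts, mu)
}

# Nonparametric initialisation for multi-state fits. The expected counts are
# linear in the per-distance amplitudes over the decay basis, so maximising
# the Poisson likelihood over a free non-negative amplitude vector (plus a
# donor-only and a flat-background column) is convex; Richardson-Lucy/EM
# iterations solve it monotonically. The recovered distance distribution is
# converted to population weights (columns differ in brightness), far-distance
# mass (E < 0.05) is pooled with the donor-only column into the no-FRET
# fraction, and a weighted 1-D Gaussian mixture summarises the rest into k
# states.
em_distance_init <- function(bas, counts, k, n_iter = 1200) {
  B <- cbind(bas$basis, 1)
  cs <- colSums(B)
  Bn <- sweep(B, 2, cs, "/")
  w <- rep(sum(counts) / ncol(Bn), ncol(Bn))
  for (it in seq_len(n_iter)) {
    mu <- drop(Bn %*% w)
    w <- w * drop(crossprod(Bn, counts / pmax(mu, 1e-300)))
  }
  m <- length(bas$r)
  bg <- w[m + 2] / bas$n
  pop <- w[seq_len(m + 1)] / cs[seq_len(m + 1)]
  pop <- pop / sum(pop)
  r_nf <- bas$r0 * 19^(1 / 6)          # E < 0.05 is no-FRET-like
  far <- bas$r > r_nf
  no_fret <- min(sum(pop[seq_len(m)][far]) + pop[m + 1], 0.9)
  wt <- pop[seq_len(m)][!far]
  rs <- bas$r[!far]
  if (sum(wt) <= 0) {
    return(list(fractions = rep(1 / k, k),
                distances = seq(0.8, 1.2, length.out = k) * bas$r0,
                widths = rep(4, k), no_fret = no_fret, background = bg))
  }
  # weighted quantile seeds, then weighted GMM on the distance distribution
  ord <- order(rs)
  cw <- cumsum(wt[ord]) / sum(wt)
  km <- vapply(seq_len(k), function(g) {
    rs[ord][which.min(abs(cw - (2 * g - 1) / (2 * k)))]
  }, 0)
  ks <- rep(3, k); kp <- rep(1 / k, k)
  for (it in seq_len(200)) {
    dens <- vapply(seq_len(k), function(g) {
      kp[g] * stats::dnorm(rs, km[g], ks[g])
    }, numeric(length(rs)))
    resp <- dens / pmax(rowSums(dens), 1e-300)
    for (g in seq_len(k)) {
      wg <- wt * resp[, g]
      sg <- sum(wg)
      if (sg <= 0) next
      kp[g] <- sg / sum(wt)
      km[g] <- sum(wg * rs) / sg
      ks[g] <- sqrt(sum(wg * (rs - km[g])^2) / sg)
    }
  }
  list(fractions = kp / sum(kp), distances = km,
       widths = pmin(pmax(ks, 0.8), 12), no_fret = no_fret,
       background = max(bg, 1e-6))
}

# All points of the k-simplex on a grid of the given step (compositions of
# 1/step parts).
simplex_grid <- function(k, step = 0.1) {
  nparts <- round(1 / step)
  rec <- function(k_left, remaining) {
    if (k_left == 1) return(matrix(remaining, 1, 1))
    out <- list()
    for (a in 0:remaining) {
      sub <- rec(k_left - 1, remaining - a)
      out[[length(out) + 1]] <- cbind(a, sub)
    }
    do.call(rbind, out)
  }
  rec(k, nparts) * step
}

# Jacobian of the stick-breaking map (rows: fractions, cols: free params).
stick_jacobian <- function(v) {
  k <- length(v) + 1
  f <- stick_to_simplex(v)
  J <- matrix(0, k, k - 1)
  for (i in seq_len(k)) {
    for (j in seq_len(k - 1)) {
      if (j < i) {
        J[i, j] <- -f[i] / (1 - v[j])
      } else if (j == i && i < k) {
        J[i, j] <- f[i] / v[i]
      }
    }
  }
  J
}

# Deviance and analytic gradient for one DA histogram. The model is linear
# in the quadrature weights w over the precomputed basis B, so the deviance
# gradient needs one extra matrix-vector product (crossprod(B, .)) plus the
# analytic derivatives of the truncated-Gaussian weights with respect to each
# state's mean and width. Node-set changes at the +/- 5 sigma edges carry
# dnorm weight ~1e-6 and are ignored.
da_eval <- function(block, fractions, bas, counts, total) {
  k <- length(fractions)
  distances <- block[seq_len(k)]
  widths <- block[k + seq_len(k)]
  no_fret <- block[2 * k + 1]
  bg <- block[2 * k + 2]
  n <- bas$n
  m <- length(bas$r)

  w <- numeric(m + 1)
  quads <- vector("list", k)
  for (g in seq_len(k)) {
    q <- state_quadrature(distances[g], widths[g])
    idx <- round((q$r - bas$r[1]) / .r_step) + 1
    ok <- idx >= 1 & idx <= m
    r <- q$r[ok]; idx <- idx[ok]
    phi <- dnorm(r, distances[g], widths[g])
    Z <- sum(phi)
    wq <- phi / Z
    dphi_dm <- phi * (r - distances[g]) / widths[g]^2
    dphi_ds <- phi * ((r - distances[g])^2 / widths[g]^2 - 1) / widths[g]
    quads[[g]] <- list(idx = idx, wq = wq,
                       dwq_dm = (dphi_dm - wq * sum(dphi_dm)) / Z,
                       dwq_ds = (dphi_ds - wq * sum(dphi_ds)) / Z)
    w[idx] <- w[idx] + (1 - no_fret) * fractions[g] * wq
  }
  w[m + 1] <- no_fret

  # only columns with nonzero weight (plus the donor column, which the
  # no-FRET gradient always needs) enter the matrix products
  nz <- sort(unique(c(unlist(lapply(quads, `[[`, "idx")), m + 1L)))
  Bnz <- bas$basis[, nz, drop = FALSE]
  conv <- drop(Bnz %*% w[nz])
  S <- sum(conv)
  Traw <- total - n * bg
  Tc <- max(Traw, 1)
  mu <- Tc * conv / S + bg
  mu_safe <- pmax(mu, 1e-12)
  dev <- poisson_deviance(counts, mu)
  gvec <- 2 * (1 - counts / mu_safe)

  grad_conv <- (Tc / S) * gvec - (Tc * sum(gvec * conv) / S^2)
  grad_w_nz <- drop(crossprod(Bnz, grad_conv))
  pos_of <- function(idx) match(idx, nz)

  grad_b <- sum(gvec * (if (Traw > 1) (-n * conv / S + 1) else 1))
  grad_nf <- grad_w_nz[pos_of(m + 1L)]
  grad_f <- numeric(k); grad_d <- numeric(k); grad_s <- numeric(k)
  for (g in seq_len(k)) {
    qd <- quads[[g]]
    gw <- grad_w_nz[pos_of(qd$idx)]
    grad_f[g] <- (1 - no_fret) * sum(gw * qd$wq)
    grad_nf <- grad_nf - fractions[g] * sum(gw * qd$wq)
    grad_d[g] <- (1 - no_fret) * fractions[g] * sum(gw * qd$dwq_dm)
    grad_s[g] <- (1 - no_fret) * fractions[g] * sum(gw * qd$dwq_ds)
  }
  list(dev = dev,
       grad_block = c(grad_d, grad_s, grad_nf, grad_b),
       grad_fractions = grad_f)
}

# Width upper bound 8 A: a Gaussian state is one conformation broadened by
# linker flexibility; larger widths describe multi-state heterogeneity and
# are outside the model's semantics.
da_bounds <- function(k, bg_hi) {
  list(lower = c(rep(15, k), rep(0.5, k), 0, 0),
       upper = c(rep(150, k), rep(8, k), 0.95, bg_hi))
}

# optimizer scaling: stick parameters O(0.1), distances O(10), widths O(1),
# no-FRET fraction O(0.1), background O(bg)
da_parscale <- function(k, bg_hi) {
  c(rep(10, k), rep(1, k), 0.1, max(0.1 * bg_hi, 1e-3))
}

da_random_start <- function(k, r0, bg_hi) {
  c(sort(stats::runif(k, 0.65 * r0, 1.45 * r0)),
    stats::runif(k, 3, 9),
    stats::runif(1, 0.02, 0.3),
    0.01 * bg_hi)
}

# Stepwise multi-state fitting engine on a decay basis: models with 1..k
# states are fitted in sequence, each initialised from (i) the EM
# deconvolution summary, (ii) splits of every state of the preceding model
# (the practice of increasing the state count until residuals are flat), and
# (iii) random draws; the best start is polished. Returns the final
# optimum, its parameter vector c(stick fractions, distances, widths,
# no_fret, background), and the objective closure.
da_fit_engine <- function(bas, counts, total, k_target, r0, bg_hi,
                          n_starts = 10, seed = 1) {
  make_obj <- function(k) {
    function(par) {
      v <- par[seq_len(k - 1)]
      block <- par[(k - 1) + seq_len(2 * k + 2)]
      da_eval(block, stick_to_simplex(v), bas, counts, total)$dev
    }
  }
  make_gr <- function(k) {
    function(par) {
      v <- par[seq_len(k - 1)]
      block <- par[(k - 1) + seq_len(2 * k + 2)]
      ev <- da_eval(block, stick_to_simplex(v), bas, counts, total)
      c(if (k > 1) drop(crossprod(stick_jacobian(v), ev$grad_fractions)),
        ev$grad_block)
    }
  }
  split_starts <- function(par, k_prev) {
    f <- stick_to_simplex(par[seq_len(k_prev - 1)])
    b <- par[(k_prev - 1) + seq_len(2 * k_prev + 2)]
    d <- b[seq_len(k_prev)]; w <- b[k_prev + seq_len(k_prev)]
    nf <- b[2 * k_prev + 1]; bg <- b[2 * k_prev + 2]
    starts <- list()
    for (g in seq_len(k_prev)) {
      delta <- max(1.5 * w[g], 4)
      dn <- c(d[-g], d[g] - delta, d[g] + delta)
      wn <- c(w[-g], rep(max(w[g] / 1.5, 1.5), 2))
      fn <- c(f[-g], f[g] / 2, f[g] / 2)
      starts[[length(starts) + 1]] <- c(simplex_to_stick(fn), dn, wn, nf, bg)
    }
    for (dnew in c(0.72 * r0, 1.28 * r0)) {
      dn <- c(d, dnew); wn <- c(w, 3)
      fn <- c(f * 0.85, 0.15)
      starts[[length(starts) + 1]] <- c(simplex_to_stick(fn), dn, wn, nf, bg)
    }
    starts
  }

  with_seed(seed, {
    prev <- NULL
    res <- NULL
    for (k in seq_len(k_target)) {
      bnd <- da_bounds(k, bg_hi)
      lower <- c(rep(1e-4, k - 1), bnd$lower)
      upper <- c(rep(1 - 1e-4, k - 1), bnd$upper)
      ps <- c(rep(0.1, max(k - 1, 0)), da_parscale(k, bg_hi))
      obj <- make_obj(k); gr <- make_gr(k)

      em <- em_distance_init(bas, counts, k)
      o <- order(em$distances)
      starts <- list(c(simplex_to_stick(em$fractions[o]), em$distances[o],
                       em$widths[o], em$no_fret, min(em$background, bg_hi)))
      if (!is.null(prev)) starts <- c(starts, split_starts(prev, k - 1))
      n_rand <- max(n_starts - length(starts), 2)
      for (s in seq_len(n_rand)) {
        starts[[length(starts) + 1]] <-
          c(simplex_to_stick(rep(1 / k, k)), da_random_start(k, r0, bg_hi))
      }
      cand <- lapply(starts, function(p0) {
        p0 <- pmin(pmax(p0, lower + 1e-8), upper - 1e-8)
        tryCatch(optim(p0, obj, gr = gr, method = "L-BFGS-B", lower = lower,
                       upper = upper,
                       control = list(maxit = 200, parscale = ps)),
                 error = function(e) NULL)
      })
      cand <- Filter(Negate(is.null), cand)
      if (length(cand) == 0) stop("DA fit failed on all starts", call. = FALSE)
      vals <- vapply(cand, `[[`, 0, "value")
      # tie-break: lowest deviance, then lowest parameter norm
      ord <- order(vals, vapply(cand, function(f) sum(f$par^2), 0))
      res <- optim(cand[[ord[1]]]$par, obj, gr = gr, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = if (k == k_target) 1000 else 400,
                                  parscale = ps))
      prev <- res$par
    }
    res$obj <- make_obj(k_target)
    res
  })
}

#' Fit a donor-acceptor decay with Gaussian-distributed FRET states
#'
#' Poisson maximum-likelihood fit of [model_counts()] to a DA histogram with
#' the donor model fixed from its donor-only control. Fractions are
#' parameterised on the simplex; states are returned sorted by descending
#' fraction.
#'
#' @param hist A [decay_histogram()] (with IRF attribute).
#' @param donor Fixed [donor_spec()] from the matching donor-only fit.
#' @param n_states Number of FRET-active states.
#' @param r0 Foerster radius in Angstrom.
#' @param n_starts Random multi-starts for the bounded quasi-Newton search.
#' @param seed Seed for the multi-start draws.
#'
#' @return An object of class `da_fit` containing the fitted [state_spec()]
#'   (`$states`), standard errors, `chi2r`, diagnostics, and a `degenerate`
#'   flag when states collapse onto each other.
#' @export
fit_da_single <- function(hist, donor, n_states = 3, r0 = 52,
                          n_starts = 10, seed = 1) {
  stopifnot(inherits(hist, "decay_histogram"), inherits(donor, "donor_spec"))
  counts <- hist$counts
  irf <- hist_irf(hist)
  if (is.null(irf)) stop("histogram carries no IRF", call. = FALSE)
  dt <- hist_dt(hist)
  n <- length(counts)
  total <- sum(counts)
  bg_hi <- max(total / n, 1e-6)
  k <- n_states
  bas <- build_decay_basis(donor, r0, irf, dt)

  bnd <- da_bounds(k, bg_hi)
  lower <- c(rep(1e-4, max(k - 1, 0)), bnd$lower)
  upper <- c(rep(1 - 1e-4, max(k - 1, 0)), bnd$upper)

  best <- da_fit_engine(bas, counts, total, k, r0, bg_hi, n_starts, seed)
  par <- best$par
  obj <- best$obj
  v <- par[seq_len(k - 1)]
  fractions <- stick_to_simplex(v)
  block <- par[(k - 1) + seq_len(2 * k + 2)]
  distances <- block[seq_len(k)]
  widths <- block[k + seq_len(k)]
  no_fret <- block[2 * k + 1]
  bg <- block[2 * k + 2]

  o <- order(fractions, decreasing = TRUE)
  states <- state_spec(fractions[o], distances[o], widths[o], no_fret, r0)
  mu <- model_counts(states, donor, irf, dt, max(total - n * bg, 1), bg)
  dg <- fit_diagnostics(counts, mu, length(par))

  se_all <- tryCatch({
    h <- stats::optimHess(par, obj)
    sqrt(pmax(diag(2 * pseudo_inverse(h)), 0))
  }, error = function(e) rep(NA_real_, length(par)))
  se_dist <- se_all[(k - 1) + seq_len(k)][o]
  se_width <- se_all[(k - 1) + k + seq_len(k)][o]

  # states whose distance separation is within the sum of their widths are
  # one population described twice
  os <- order(distances)
  sep <- diff(distances[os])
  wsum <- widths[os][-k] + widths[os][-1]
  degenerate <- any(sep < pmax(wsum, 1)) || any(fractions < 0.01)

  structure(list(states = states, donor = donor, background = bg,
                 se_distance = se_dist, se_width = se_width,
                 converged = best$convergence == 0, degenerate = degenerate,
                 chi2r = dg$chi2r, deviance = dg$deviance, dof = dg$dof,
                 weighted_residuals = dg$weighted_residuals,
                 autocorrelation = dg$autocorrelation, hist = hist),
            class = "da_fit")
}

# Moore-Penrose pseudo-inverse (for near-singular Hessians at simplex edges).
pseudo_inverse <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * max(s$d)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.da_fit <- function(x, ...) {
  cat("<da_fit> chi2r =", round(x$chi2r, 4),
      if (x$degenerate) "(degenerate states)",
      if (!x$converged) "(NOT converged)", "\n")
  print(x$states)
  invisible(x)
}

#' Global multi-variant fit with a shared population distribution
#'
#' Fits all donor-acceptor variants jointly. Shared across variants: the
#' state-fraction vector, the state widths (every variant carries the same
#' dye pair, so a state's distance-distribution width is a property of the
#' state, not of the labeling site) and the no-FRET fraction (the
#' acceptor-inactive proportion of a common labeling chemistry). Free per
#' variant: the state mean distances and the flat background. The joint
#' Poisson deviance is minimised in stages: a nonparametric (EM)
#' initialisation per variant, a scan of shared-fraction candidates in which
#' every variant block is re-solved from an exhaustive coarse grid of
#' ordered distance tuples, Nelder-Mead refinement of the fractions, a
#' thorough per-variant re-solve in which candidate tuples are
#' distance-polished before ranking (the step that resolves which distance
#' belongs to which population slot), and a joint bounded quasi-Newton
#' polish with a block-structured analytic gradient, followed by escape
#' rounds that re-solve the blocks at the fitted shared parameters.
#'
#' @param hists List of DA [decay_histogram()]s (equal channel grids).
#' @param donors List of fixed [donor_spec()]s, one per histogram.
#' @param n_states Number of shared FRET-active states.
#' @param r0 Foerster radius in Angstrom.
#' @param seed Seed (the search itself is deterministic; kept for interface
#'   stability).
#' @param maxit Iteration cap for the joint refinement.
#'
#' @return An object of class `global_da_fit`: shared `fractions`, `widths`
#'   and `no_fret`, a tibble `$variants` (variant, state, fraction,
#'   distance, width), per-variant `background` and `chi2r`, and the joint
#'   `deviance`, `dof` and `joint_chi2r`.
#' @export
fit_da_global <- function(hists, donors, n_states = 3, r0 = 52,
                          seed = 1, maxit = 3000) {
  nv <- length(hists)
  if (length(donors) != nv) stop("one donor model per histogram", call. = FALSE)
  dts <- vapply(hists, hist_dt, 0)
  ns <- vapply(hists, nrow, 0L)
  if (length(unique(dts)) != 1 || length(unique(ns)) != 1) {
    stop("inconsistent channel grids across variants", call. = FALSE)
  }
  dt <- dts[1]; n <- ns[1]
  k <- n_states

  counts <- lapply(hists, function(h) h$counts)
  totals <- vapply(counts, sum, 0)
  bas <- lapply(seq_len(nv), function(i) {
    build_decay_basis(donors[[i]], r0, hist_irf(hists[[i]]), dt)
  })
  bg_hi <- max(totals / n)
  bnd <- da_bounds(k, bg_hi)
  w_lo <- bnd$lower[k + 1]; w_hi <- bnd$upper[k + 1]

  # parameter layout: [stick v (k-1)] [shared widths (k)] [shared no-FRET]
  # [per variant: distances (k), background]
  n_sh <- (k - 1) + k + 1
  vbsz <- k + 1
  lower <- c(rep(1e-4, k - 1), rep(w_lo, k), 0,
             rep(c(rep(15, k), 0), nv))
  upper <- c(rep(1 - 1e-4, k - 1), rep(w_hi, k), 0.95,
             rep(c(rep(150, k), bg_hi), nv))
  sub_lower <- c(rep(15, k), 0)
  sub_upper <- c(rep(150, k), bg_hi)
  sub_ps <- c(rep(10, k), max(0.1 * bg_hi, 1e-3))
  par_ps <- c(rep(0.1, k - 1), rep(1, k), 0.1, rep(sub_ps, nv))
  sub_idx <- function(i) n_sh + (i - 1) * vbsz + seq_len(vbsz)

  all_perms <- function(k) {
    if (k == 1) return(list(1L))
    out <- list()
    for (p in all_perms(k - 1)) {
      for (pos in seq_len(k)) out[[length(out) + 1]] <- append(p, k, pos - 1)
    }
    out
  }
  perms <- all_perms(k)

  # per-variant nonparametric (EM) initialisation; all state-assignment
  # permutations of its distances are kept as candidate starts
  ems <- lapply(seq_len(nv), function(i) {
    em <- em_distance_init(bas[[i]], counts[[i]], k)
    subs <- lapply(perms, function(pm) {
      pmin(pmax(c(em$distances[pm], min(em$background, bg_hi)),
                sub_lower + 1e-8), sub_upper - 1e-8)
    })
    o <- order(em$distances)
    list(fractions = em$fractions[o], no_fret = em$no_fret,
         sub_perms = subs, sub = subs[[1]])
  })
  subs <- lapply(ems, `[[`, "sub")
  f0 <- rowMeans(vapply(ems, `[[`, numeric(k), "fractions"))
  f0 <- pmax(f0 / sum(f0), 2e-4)
  w0 <- rep(3, k)
  nf0 <- min(max(stats::median(vapply(ems, `[[`, 0, "no_fret")), 0), 0.9)

  # coarse distance grid: precomputed basis responses of a narrow Gaussian
  # state at each grid distance make the raw deviance of a candidate tuple a
  # k-column matrix-vector product, so an exhaustive ordered-tuple scan per
  # fraction candidate is affordable
  grid_d <- seq(0.65 * r0, 1.4 * r0, by = 4)
  grid_w <- 2.5
  profiles <- lapply(seq_len(nv), function(i) {
    vapply(grid_d, function(dd) {
      q <- state_quadrature(dd, grid_w)
      idx <- round((q$r - bas[[i]]$r[1]) / .r_step) + 1
      drop(bas[[i]]$basis[, idx, drop = FALSE] %*% q$w)
    }, numeric(n))
  })
  donor_col <- lapply(seq_len(nv), function(i) {
    bas[[i]]$basis[, length(bas[[i]]$r) + 1]
  })
  tuple_idx <- local({
    sets <- utils::combn(seq_along(grid_d), k, simplify = FALSE)
    sets <- Filter(function(s) k == 1 || min(diff(grid_d[s])) >= 6, sets)
    out <- list()
    for (s in sets) for (p in perms) out[[length(out) + 1]] <- s[p]
    out
  })
  best_tuple_sub <- function(i, fr, nf, n_keep = 2) {
    bg <- subs[[i]][k + 1]
    Tc <- max(totals[i] - n * bg, 1)
    base <- nf * donor_col[[i]]
    raw <- vapply(tuple_idx, function(tp) {
      conv <- (1 - nf) * drop(profiles[[i]][, tp, drop = FALSE] %*% fr) + base
      poisson_deviance(counts[[i]], Tc * conv / sum(conv) + bg)
    }, 0)
    lapply(tuple_idx[order(raw)[seq_len(n_keep)]], function(tp) {
      pmin(pmax(c(grid_d[tp], bg), sub_lower + 1e-8), sub_upper - 1e-8)
    })
  }

  full_block <- function(sb, w, nf) c(sb[seq_len(k)], w, nf, sb[k + 1])
  sub_eval <- function(i, fr, w, nf, sb) {
    da_eval(full_block(sb, w, nf), fr, bas[[i]], counts[[i]], totals[i])
  }
  opt_sub <- function(i, fr, w, nf, start_sb, maxit_inner) {
    optim(start_sb, function(sb) sub_eval(i, fr, w, nf, sb)$dev,
          gr = function(sb) {
            g <- sub_eval(i, fr, w, nf, sb)$grad_block
            c(g[seq_len(k)], g[2 * k + 2])
          },
          method = "L-BFGS-B", lower = sub_lower, upper = sub_upper,
          control = list(maxit = maxit_inner, parscale = sub_ps))
  }
  # distance-only polish (background, no-FRET, widths held): used to rank
  # candidate tuples fairly -- their raw deviance is dominated by the
  # grid-snap distance error, which would otherwise drown out the
  # state-assignment signal
  opt_dist <- function(i, fr, w, nf, sb0, maxit_inner = 15) {
    bg <- sb0[k + 1]
    o <- optim(sb0[seq_len(k)],
               function(dd) sub_eval(i, fr, w, nf, c(dd, bg))$dev,
               gr = function(dd) {
                 sub_eval(i, fr, w, nf, c(dd, bg))$grad_block[seq_len(k)]
               },
               method = "L-BFGS-B", lower = rep(15, k), upper = rep(150, k),
               control = list(maxit = maxit_inner, parscale = rep(10, k)))
    list(par = c(o$par, bg), value = o$value)
  }
  # reliable block solve at fixed shared parameters: grid tuples (raw
  # ranked; in thorough mode distance-polished before ranking), assignment
  # permutations of the current block and of the EM distances, and the
  # current block itself, the best few fully polished
  solve_sub <- function(i, fr, w, nf, maxit_inner = 150, thorough = FALSE) {
    raw_of <- function(sb) {
      da_block_deviance(full_block(sb, w, nf), fr, bas[[i]], counts[[i]],
                        totals[i])
    }
    em_best <- ems[[i]]$sub_perms[[
      which.min(vapply(ems[[i]]$sub_perms, raw_of, 0))]]
    cur <- subs[[i]]
    cur_perms <- lapply(perms, function(pm) {
      c(cur[seq_len(k)][pm], cur[k + 1])
    })
    tuple_starts <- best_tuple_sub(i, fr, nf,
                                   n_keep = if (thorough) 40 else 2)
    if (thorough) {
      polished <- lapply(c(tuple_starts, cur_perms), function(s0) {
        opt_dist(i, fr, w, nf, s0)
      })
      vals <- vapply(polished, `[[`, 0, "value")
      tuple_starts <- lapply(polished[order(vals)[1:3]], `[[`, "par")
    } else {
      tuple_starts <- c(tuple_starts,
                        cur_perms[which.min(vapply(cur_perms, raw_of, 0))])
    }
    starts <- c(tuple_starts, list(em_best, subs[[i]]))
    fits <- lapply(starts, function(s0) {
      tryCatch(opt_sub(i, fr, w, nf, s0, maxit_inner),
               error = function(e) NULL)
    })
    fits <- Filter(Negate(is.null), fits)
    fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  }
  profile_solve <- function(fr, w, nf, maxit_inner = 150, thorough = FALSE) {
    dev <- 0
    for (i in seq_len(nv)) {
      o <- solve_sub(i, fr, w, nf, maxit_inner, thorough = thorough)
      subs[[i]] <<- o$par
      dev <- dev + o$value
    }
    dev
  }
  # warm profile over the stick parameters for Nelder-Mead refinement
  profile_dev <- function(v, w, nf, maxit_inner = 40) {
    fr <- stick_to_simplex(pmin(pmax(v, 1e-4), 1 - 1e-4))
    sum(vapply(seq_len(nv), function(i) {
      o <- opt_sub(i, fr, w, nf, subs[[i]], maxit_inner)
      subs[[i]] <<- o$par
      o$value
    }, 0))
  }

  if (k > 1) {
    fgrid <- simplex_grid(k, 0.1)
    fgrid <- fgrid[apply(fgrid, 1, function(f) {
      all(diff(f) <= 1e-9) && all(f >= 0.05)
    }), , drop = FALSE]
    fgrid <- rbind(fgrid, sort(f0, decreasing = TRUE))
    best_val <- Inf; best_fr <- NULL; best_subs <- subs
    for (ci in seq_len(nrow(fgrid))) {
      val <- profile_solve(fgrid[ci, ], w0, nf0)
      if (val < best_val) {
        best_val <- val; best_fr <- fgrid[ci, ]; best_subs <- subs
      }
    }
    subs <- best_subs
    v0 <- simplex_to_stick(best_fr)
    nm <- if (k == 2) {
      optim(v0, profile_dev, w = w0, nf = nf0, method = "Brent",
            lower = 1e-4, upper = 1 - 1e-4)
    } else {
      optim(v0, profile_dev, w = w0, nf = nf0, method = "Nelder-Mead",
            control = list(maxit = 40, reltol = 1e-9))
    }
    v_prof <- pmin(pmax(nm$par, 1e-4), 1 - 1e-4)
    profile_solve(stick_to_simplex(v_prof), w0, nf0, thorough = TRUE)
  } else {
    v_prof <- numeric(0)
    profile_solve(1, w0, nf0, thorough = TRUE)
  }

  par0 <- c(v_prof, w0, nf0, unlist(subs))
  par0 <- pmin(pmax(par0, lower + 1e-8), upper - 1e-8)

  # joint deviance and analytic gradient: per-variant sub-blocks are
  # independent; the shared stick, width and no-FRET parameters accumulate
  # every variant's contribution
  eval_par <- function(par) {
    v <- par[seq_len(k - 1)]
    w <- par[(k - 1) + seq_len(k)]
    nf <- par[n_sh]
    fr <- stick_to_simplex(v)
    J <- stick_jacobian(v)
    g <- numeric(length(par))
    dev <- 0
    gf <- numeric(k); gw <- numeric(k); gnf <- 0
    for (i in seq_len(nv)) {
      sb <- par[sub_idx(i)]
      ev <- da_eval(full_block(sb, w, nf), fr, bas[[i]], counts[[i]],
                    totals[i])
      dev <- dev + ev$dev
      gb <- ev$grad_block
      g[sub_idx(i)] <- c(gb[seq_len(k)], gb[2 * k + 2])
      gw <- gw + gb[k + seq_len(k)]
      gnf <- gnf + gb[2 * k + 1]
      gf <- gf + ev$grad_fractions
    }
    g[seq_len(k - 1)] <- drop(crossprod(J, gf))
    g[(k - 1) + seq_len(k)] <- gw
    g[n_sh] <- gnf
    list(dev = dev, grad = g)
  }
  cache <- new.env()
  obj <- function(par) {
    ev <- eval_par(par)
    cache$par <- par; cache$ev <- ev
    ev$dev
  }
  grad <- function(par) {
    if (!is.null(cache$par) && identical(cache$par, par)) return(cache$ev$grad)
    eval_par(par)$grad
  }

  joint_ctrl <- list(maxit = maxit, parscale = par_ps, lmm = 20)
  # coordinate-descent cycles: thorough per-variant re-solve at the current
  # shared parameters, then a joint quasi-Newton polish of everything; the
  # polished shared parameters seed the next cycle. Stops when a cycle no
  # longer improves the joint deviance.
  fit <- NULL
  v_cur <- v_prof
  w_cur <- w0
  nf_cur <- nf0
  for (cycle in 1:4) {
    if (cycle > 1) {
      profile_solve(stick_to_simplex(v_cur), w_cur, nf_cur,
                    maxit_inner = 250, thorough = TRUE)
    }
    par_c <- pmin(pmax(c(v_cur, w_cur, nf_cur, unlist(subs)),
                       lower + 1e-8), upper - 1e-8)
    fit_c <- optim(par_c, obj, gr = grad, method = "L-BFGS-B",
                   lower = lower, upper = upper, control = joint_ctrl)
    if (is.null(fit) || fit_c$value < fit$value - 0.5) {
      fit <- fit_c
    } else {
      if (fit_c$value < fit$value) fit <- fit_c
      break
    }
    v_cur <- fit$par[seq_len(k - 1)]
    w_cur <- fit$par[(k - 1) + seq_len(k)]
    nf_cur <- fit$par[n_sh]
    subs <- lapply(seq_len(nv), function(i) fit$par[sub_idx(i)])
  }
  par <- fit$par
  fractions <- stick_to_simplex(par[seq_len(k - 1)])
  widths <- par[(k - 1) + seq_len(k)]
  no_fret <- par[n_sh]
  o <- order(fractions, decreasing = TRUE)

  variants <- list(); bg <- numeric(nv)
  chi2r_v <- numeric(nv); dev_v <- numeric(nv)
  for (i in seq_len(nv)) {
    sb <- par[sub_idx(i)]
    variants[[i]] <- tibble::tibble(
      variant = i, state = seq_len(k),
      fraction = fractions[o], distance = sb[seq_len(k)][o],
      width = widths[o])
    bg[i] <- sb[k + 1]
    st <- state_spec(fractions[o], sb[seq_len(k)][o], widths[o],
                     no_fret, r0)
    mu <- model_counts(st, donors[[i]], hist_irf(hists[[i]]), dt,
                       max(totals[i] - n * bg[i], 1), bg[i])
    dev_v[i] <- poisson_deviance(counts[[i]], mu)
    chi2r_v[i] <- dev_v[i] / (n - vbsz - 2 * k / nv)
  }
  dof_joint <- nv * n - length(par)
  structure(list(fractions = fractions[o], widths = widths[o],
                 no_fret = no_fret,
                 variants = dplyr::bind_rows(variants),
                 background = bg,
                 chi2r = chi2r_v, deviance = sum(dev_v),
                 joint_chi2r = sum(dev_v) / dof_joint, dof = dof_joint,
                 n_par = length(par), r0 = r0,
                 converged = fit$convergence == 0,
                 em_inits = ems),
            class = "global_da_fit")
}

#' @export
print.global_da_fit <- function(x, ...) {
  cat("<global_da_fit> joint chi2r =", round(x$joint_chi2r, 4), "\n")
  cat("shared fractions:", paste(sprintf("%.3f", x$fractions), collapse = ", "),
      "\n")
  print(x$variants, n = 12)
  invisible(x)
}

#' Nested-model F-test on fit figures of merit
#'
#' Compares a smaller (fewer-parameter) against a bigger nested model via the
#' F statistic `((chi2_s - chi2_b)/(dof_s - dof_b)) / (chi2_b/dof_b)` and
#' returns the confidence level `P(F' <= F)` that the improvement is real.
#'
#' @param chi2_small,dof_small Figure of merit (unreduced) and degrees of
#'   freedom of the smaller model.
#' @param chi2_big,dof_big Same for the bigger model (`dof_big < dof_small`).
#' @return Confidence level in `[0, 1)`.
#' @export
ftest_compare <- function(chi2_small, dof_small, chi2_big, dof_big) {
  if (dof_big >= dof_small) {
    stop("bigger model must have fewer degrees of freedom", call. = FALSE)
  }
  if (chi2_small <= 0 || chi2_big <= 0) {
    stop("chi2 values must be positive", call. = FALSE)
  }
  f <- ((chi2_small - chi2_big) / (dof_small - dof_big)) / (chi2_big / dof_big)
  if (!is.finite(f) || f <= 0) return(0)
  pf(f, dof_small - dof_big, dof_big)
}

#' Normalised autocorrelation of fit residuals
#'
#' @param residuals Numeric vector of (weighted) residuals, >= 100 values.
#' @param lag_max Maximum lag; defaults to `length(residuals) %/% 4`.
#' @return Tibble with columns `lag` and `autocorrelation`
#'   (`autocorrelation[lag == 0]` is 1).
#' @export
residual_autocorrelation <- function(residuals, lag_max = NULL) {
  n <- length(residuals)
  if (n < 100) stop("need at least 100 residual channels", call. = FALSE)
  if (all(residuals == 0)) stop("degenerate all-zero residuals", call. = FALSE)
  if (is.null(lag_max)) lag_max <- n %/% 4
  ac <- stats::acf(residuals, lag.max = lag_max, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  tibble::tibble(lag = 0:lag_max, autocorrelation = ac)
}
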