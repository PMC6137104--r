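#' Read and write decay histograms as TSV
#'
#' Two-column tab-separated files (`time_ns`, `counts`), comment lines
#' starting with `#`. The channel width is inferred from the time column on
#' read.
#'
#' @param hist A [decay_histogram()].
#' @param path File path.
#' @param irf Optional IRF profile to attach on read.
#' @return `write_decay_tsv()` the path, invisibly; `read_decay_tsv()` a
#'   [decay_histogram()].
#' @export
write_decay_tsv <- function(hist, path) {
  utils::write.table(hist[, c("time_ns", "counts")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_decay_tsv
#' @export
read_decay_tsv <- function(path, irf = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  dt <- stats::median(diff(d$time_ns))
  decay_histogram(d$counts, dt, irf = irf)
}

#' Read and write photon streams as TSV
#'
#' One row per photon: `burst_id`, `macrotime_ms`, `microtime_ns`,
#' `channel`.
#'
#' @param stream Photon tibble (from [simulate_bursts()]).
#' @param path File path.
#' @return `write_photons_tsv()` the path, invisibly; `read_photons_tsv()`
#'   the photon tibble sorted by macrotime.
#' @export
write_photons_tsv <- function(stream, path) {
  cols <- intersect(c("burst_id", "macrotime_ms", "microtime_ns", "channel"),
                    names(stream))
  utils::write.table(stream[, cols], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_photons_tsv
#' @export
read_photons_tsv <- function(path) {
  d <- tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                           comment.char = "#"))
  dplyr::arrange(d, .data$macrotime_ms)
}

#' Read a structure from PDB into the package's tabular form
#'
#' Thin wrapper around [bio3d::read.pdb()] returning the tidy structure
#' tibble used throughout (`residue`, `chain`, `element`, `x`, `y`, `z`,
#' `mass`); 1-based PDB residue numbering is preserved verbatim.
#'
#' @param path PDB file path.
#' @param heavy_only Drop hydrogens. Default `TRUE`.
#' @return Structure tibble.
#' @export
read_pdb_structure <- function(path, heavy_only = TRUE) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  if (heavy_only) at <- at[!at$elesy %in% "H", ]
  masses <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, H = 1.008,
              P = 30.974)
  m <- masses[at$elesy]
  m[is.na(m)] <- 12.011
  tibble::tibble(residue = at$resno, chain = at$chain,
                 element = at$elesy, atom_name = at$elety,
                 x = at$x, y = at$y, z = at$z, mass = unname(m))
}

#' Write a structure tibble to PDB
#'
#' Coarse-bead structures are written as CA pseudo-atoms so standard viewers
#' can read them.
#'
#' @param structure Structure tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pdb_structure <- function(structure, path) {
  n <- nrow(structure)
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(structure[, c("x", "y", "z")]))),
                   resno = structure$residue,
                   resid = rep("ALA", n),
                   elety = rep("CA", n),
                   chain = rep("A", n))
  invisible(path)
}

#' Run the full synthetic pipeline
#'
#' Generates synthetic inputs and executes every analysis stage in order:
#' TCSPC simulation, donor-only fits, global multi-state fit, burst
#' simulation with FRET lines and time-window PDA, replica-exchange sampling
#' with a WHAM profile, and disulfide kinetics. All stages derive their
#' seeds from the single `seed` argument, so the numeric summary is
#' reproducible bit-for-bit.
#'
#' @param config Named list overriding defaults; see
#'   [pipeline_default_config()].
#' @param seed Global seed.
#' @return A list of per-stage results plus a tibble `summary` of headline
#'   numbers.
#' @export
run_pipeline <- function(config = list(), seed = 1) {
  cfg <- utils::modifyList(pipeline_default_config(), config)
  bad <- setdiff(names(config), names(pipeline_default_config()))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  irf <- make_irf(cfg$irf_fwhm, cfg$irf_t0, cfg$n_channels, cfg$dt)
  donor <- donor_spec(cfg$donor_fractions, cfg$donor_lifetimes)

  nv <- cfg$n_variants
  hists <- vector("list", nv); donor_fits <- vector("list", nv)
  for (i in seq_len(nv)) {
    dh <- simulate_donor_decay(donor, irf, cfg$donor_photons, cfg$background,
                               seed = seed * 1000 + i)
    donor_fits[[i]] <- fit_donor_only(dh, 2, seed = seed * 1000 + i)
    st <- state_spec(cfg$fractions, cfg$variant_distances[[i]], cfg$widths,
                     cfg$no_fret, cfg$r0)
    hists[[i]] <- simulate_da_decay(st, donor, irf, cfg$da_photons,
                                    cfg$background, seed = seed * 2000 + i)
  }
  gl <- fit_da_global(hists, lapply(donor_fits, `[[`, "donor"),
                      n_states = length(cfg$fractions), r0 = cfg$r0,
                      seed = seed)

  kin <- two_state_kinetics(cfg$burst_distances, cfg$exchange_forward,
                            cfg$exchange_backward)
  stream <- simulate_bursts(kin, donor, cfg$r0, cfg$brightness,
                            cfg$mean_burst_duration, cfg$n_bursts,
                            seed = seed + 7)
  bursts <- burst_indicators(
    select_bursts(stream, cfg$min_photons, cfg$max_interphoton),
    donor_tau0 = donor_mean_lifetimes(donor)[["tau_f"]])
  sline <- static_fret_line(donor, cfg$r0)
  dline <- dynamic_fret_line(cfg$burst_distances[1], cfg$burst_distances[2],
                             donor, cfg$r0)
  pda_model <- state_spec(c(0.5, 0.5), cfg$burst_distances, c(0, 0),
                          r0 = cfg$r0)
  pda <- pda_time_window(stream, cfg$pda_windows, pda_model)

  pot <- potential_spec("double_well", well_positions = cfg$well_positions,
                        barrier_height = cfg$barrier_height)
  trajs <- sample_toy_landscape(pot, cfg$temperatures, cfg$re_steps,
                                seed = seed + 11)
  pmf <- wham_pmf(trajs, target_T = cfg$target_T, bins = cfg$pmf_bins)

  ds_fits <- lapply(seq_along(cfg$disulfide_truth), function(i) {
    p <- cfg$disulfide_truth[[i]]
    tab <- simulate_disulfide_timecourse(p$p0, p$p_inf, p$k,
                                         cfg$disulfide_times, cfg$disulfide_sd,
                                         seed = seed + 100 + i)
    fit_timecourse(tab)
  })
  names(ds_fits) <- names(cfg$disulfide_truth)

  summary <- tibble::tibble(
    quantity = c("joint_chi2r",
                 paste0("fraction_", seq_along(gl$fractions)),
                 "pda_ratio", "swap_acceptance",
                 paste0("rate_", names(ds_fits))),
    value = c(gl$joint_chi2r, gl$fractions, attr(pda, "ratio"),
              attr(trajs, "swap_acceptance"),
              vapply(ds_fits, `[[`, 0, "initial_rate")))
  list(config = cfg, global_fit = gl, donor_fits = donor_fits,
       bursts = bursts, static_line = sline, dynamic_line = dline,
       pda = pda, pmf = pmf, disulfide = ds_fits, summary = summary)
}

#' Default pipeline configuration
#'
#' Every stage parameter with the package defaults; override any subset via
#' the `config` argument of [run_pipeline()].
#' @return Named list.
#' @export
pipeline_default_config <- function() {
  list(
    irf_fwhm = 0.25, irf_t0 = 2, n_channels = 4096, dt = 0.0122,
    donor_fractions = c(0.2, 0.8), donor_lifetimes = c(1.5, 4.1),
    donor_photons = 2e6, da_photons = 2e6, background = 2,
    n_variants = 3,
    fractions = c(0.435, 0.324, 0.241),
    variant_distances = variant_network_distances(),
    widths = c(2, 2.5, 3), no_fret = 0.1, r0 = 52,
    burst_distances = c(45, 60), exchange_forward = 2.5,
    exchange_backward = 2.5, brightness = 100, mean_burst_duration = 1,
    n_bursts = 300, min_photons = 60, max_interphoton = 0.1,
    pda_windows = c(0.5, 1, 2, 4),
    well_positions = c(-1, 1), barrier_height = 3,
    temperatures = c(275, 287, 300, 315, 330, 345, 360, 375),
    re_steps = 20000, target_T = 300, pmf_bins = 60,
    disulfide_times = c(0, 0.5, 1, 2, 4, 8, 15, 30, 60),
    disulfide_sd = 2,
    disulfide_truth = list(
      interface = list(p0 = 11.6, p_inf = 84.58, k = 22.97 / (84.58 - 11.6)),
      positive = list(p0 = 4.5, p_inf = 46.94, k = 13.13 / (46.94 - 4.5)),
      negative = list(p0 = 3.37, p_inf = 3.69, k = 0.3)))
}
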