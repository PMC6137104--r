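---
title: "Models and methods behind tandemfret"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tandemfret}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

tandemfret implements a hybrid workflow for resolving the limiting
conformational states and sub-millisecond dynamics of a two-domain protein
(the motivating system is a PDZ-domain tandem) from three complementary
measurements: ensemble time-correlated single photon counting (TCSPC) of
FRET-labeled variants, single-molecule multiparameter fluorescence detection
(MFD) of freely diffusing molecules, and conformational-landscape analysis
of replica-exchange simulations, cross-validated by disulfide-formation
kinetics. Because raw photon streams and trajectories of this kind are
rarely public, the package ships a synthetic-data module that generates
every input with the statistical structure the analysis assumes; every
claim the test suite makes is therefore a parameter-recovery or
property-based statement about that generative model, not about any
particular laboratory's data.

## The ensemble decay model

A donor-only control is modeled as a one- or two-exponential decay
\(I_D(t) = \sum_i x_i e^{-t/\tau_{D,i}}\). For a donor-acceptor variant,
each conformational state \(g\) contributes a Gaussian distribution
\(p_g(R)\) of interdye distances (mean \(\langle R\rangle_g\), width
\(\sigma_g\), truncated to \(R>0\) and renormalised). FRET adds
\(k_{RET} = \tau^{-1}(R_0/R)^6\) to every donor component's decay rate, so
all donor species are quenched by the same factor and the state decay is

\[
I_g(t) = \int p_g(R)\, \sum_i x_i\,
  e^{-\frac{t}{\tau_{D,i}}\left[1+(R_0/R)^6\right]} dR .
\]

The full decay is the population-weighted superposition of the states plus
a no-FRET term (molecules with an inactive acceptor decay like donor-only),
convolved with the instrument response function, scaled to the expected
photon count, over a flat background. The same forward model
(`model_counts()`) generates the synthetic data and is fitted to it, so
generator/fitter identity holds to machine precision — a property verified
bit-for-bit in the tests.

Distance integrals use an absolute 0.5-Angstrom lattice covering
\(\pm 5\sigma\); anchoring the quadrature nodes to a fixed lattice lets the
fitter precompute one IRF-convolved decay basis per variant, after which a
model evaluation is a single matrix-vector product and the deviance
gradient is one more. Parameters then optimise in milliseconds rather than
seconds, which is what makes the global analysis below tractable on one
CPU.

### Objective and figures of merit

Fits maximise the Poisson likelihood (equivalently minimise the deviance
\(2\sum_c \mu_c - n_c + n_c\ln(n_c/\mu_c)\)); this is the correct objective
in the low-count decay tails where Gaussian weighting biases lifetimes. The
reported figure of merit `chi2r` is deviance per degree of freedom. Note
that for Poisson data the expected deviance per channel is slightly above 1
when channel means are small (the low-count tail contributes
\(\approx 1 + 1/(6\mu)\)), so `chi2r` of a correctly specified model sits a
few percent above unity on a 50-ns window with a ~2-count background; model
comparison is therefore always relative (nested F-tests), never against an
absolute `chi2r = 1`.

### The global fit and how it is optimised

Fitting each variant alone is ill-posed in the populations: with free
per-variant fractions, widths and a no-FRET term, near-equal-likelihood
solutions with very different state decompositions exist (the test suite
demonstrates this degeneracy deliberately). The pipeline therefore fixes
one population vector shared by all ten variants — `fit_da_global()` — with
per-variant distances and background. The state *widths* and the *no-FRET
fraction* are also shared across variants: every variant carries the same
dye pair and linkers, so the distance-distribution width of a
conformational state is a property of that state, not of the labeling
site; and the no-FRET term models acceptor-inactive molecules, a property
of the common acceptor lot and labeling chemistry. This is not only
parsimony — with those quantities free per variant the joint likelihood
turns out to be non-identifiable in the state *assignments* (which
distance belongs to which population slot): wrong-assignment solutions
reach deviances within noise of, or below, the true decomposition because
per-variant width and no-FRET freedom absorbs the mismatch, while with
them shared the true assignment wins by two orders of magnitude more
deviance than the noise scale. For the same reason a single state's width
is bounded above by 8 Angstrom: a broader Gaussian describes multi-state
heterogeneity, which the state count is supposed to capture.

The likelihood surface of such mixture models is multimodal, mostly through
state-assignment permutations (which distance belongs to which shared
population slot) and wide-width compensation minima. The optimiser attacks
this in stages, all sharing one analytic-gradient deviance kernel:

1. *Nonparametric initialisation.* Because the expected counts are linear
   in per-distance amplitudes over the decay basis, maximising the Poisson
   likelihood over a free non-negative amplitude vector is convex;
   Richardson-Lucy iterations give a blur-limited distance distribution
   whose population weights, far-distance mass (pooled into the no-FRET
   fraction) and Gaussian-mixture summary seed the parametric stages. (The
   single-variant fitter `fit_da_single()` additionally fits 1, 2, then 3
   states, seeding each stage from splits of the previous one — the
   standard practice of increasing the state count.)
2. *Fraction-simplex scan.* With the shared parameters fixed the variants
   decouple, so candidate fraction vectors on a coarse simplex grid are
   compared with every variant block re-solved per candidate; Nelder-Mead
   refines the best candidate.
3. *Assignment resolution.* At the scanned fractions, every variant block
   is re-solved from an exhaustive coarse grid of ordered distance tuples;
   because the raw tuple deviance is dominated by grid-snap error, the top
   tuples get a short continuous distance polish before ranking. This is
   the step that resolves which distance belongs to which population slot.
4. *Coordinate-descent cycles.* A long bounded quasi-Newton (L-BFGS-B)
   polish over all ~45 parameters with a block-structured analytic gradient
   (the fraction/width trade-off forms a narrow curved valley that needs
   thousands of cheap iterations), alternating with renewed per-variant
   re-solves at the updated shared parameters, until a cycle stops
   improving the joint deviance.

Fractions are parameterised by stick-breaking, so they sum to one at every
optimizer step; states are reported sorted by descending fraction; ties in
multi-start selection break by lowest deviance, then lowest parameter norm.

### The synthetic variant network

The default network (`variant_network_distances()`) has ten variants, three
shared states at populations 43.5/32.4/24.1%, Gaussian widths of 2, 2.5 and
3 Angstrom, a 10% no-FRET fraction, \(R_0 = 52\) Angstrom, a two-exponential
donor (0.2/1.5 ns, 0.8/4.1 ns), a 0.25-ns-FWHM Gaussian IRF and a flat
background of 2 counts/channel at \(2\times10^7\) photons per variant.
Distances span the FRET-sensitive band (34-66 Angstrom); which state is
nearest or farthest varies across variants, as it does for a real labeling
network that probes a domain interface from several directions — this
permutation variety is what pins the shared populations; and within every
variant the three state distances are at least 10 Angstrom apart, because a
variant whose states nearly coincide carries no assignment information (a
limitation real networks share: some label pairs are simply insensitive to
the conformational change). Widths of 2-3 Angstrom describe the spread a
flexibly tethered dye adds to a defined conformational state; state
separations below roughly twice these widths are not resolvable at this
photon budget, which is a resolution statement about the method, not about
the optimiser. Recovery tests and the acceptance analysis run this network
on a 1024-channel, 48.8-ps grid (the same 50-ns window as the 4096-channel
acquisition default; fit information at these lifetimes is photon-limited,
not channel-limited).

Model selection mirrors the experimental logic: the three-state global fit
is compared with the two-state fit by an F-test on the deviance figures of
merit, and the same comparison on data generated from only two states must
not reach significance.

## Burst analysis and FRET lines

The burst simulator emits photons of single molecules crossing a confocal
volume: exponential burst durations (mean 1 ms), a constant detected
brightness (100 photons/ms) while the molecule is in the volume, a
two-state continuous-time Markov chain for the conformational state, a
detection channel drawn with acceptor probability \(E\) of the current
state, and microtimes drawn from the state-conditional decay. The burst
envelope is phenomenological; no point-spread function or diffusion is
simulated, and only donor-excitation photons are emitted (no pulsed
interleaved acceptor-check channel).

Burst selection uses an inter-photon-time criterion (all gaps at most
0.1 ms, at least 60 photons; at the default brightness this keeps both
burst-splitting and burst-merging probabilities below 1 percent). Per burst, the intensity indicator
\(F_D/F_A\) is the corrected donor/acceptor count ratio, and
\(\langle\tau_{D(A)}\rangle_f\) is a per-burst maximum-likelihood
single-exponential lifetime from the donor microtimes, which estimates the
fluorescence-weighted average lifetime.

Because the decay model quenches every donor component equally, the
transfer efficiency is component-uniform and the static FRET line is exact:
\(\langle\tau\rangle_f = (1-E)\,\langle\tau\rangle_{f,0}\) against
\(F_D/F_A = \gamma\,(1-E)/E\). (The third-order polynomial mapping between
species- and fluorescence-weighted lifetimes that is conventional when
\(E\) must be inferred from \(\langle\tau\rangle_x\) is unnecessary here.)
The dynamic line between two states follows the fluorescence-weighted
moment average
\(\langle\tau\rangle_f = (x\tau_1^2 + (1-x)\tau_2^2)/(x\tau_1+(1-x)\tau_2)\)
with intensities from species-averaged photon fluxes; its endpoints lie on
the static line to machine precision.

Time-window photon distribution analysis (PDA) slices the stream into fixed
windows (defaults 0.5, 1, 2, 4 ms), histograms the per-window acceptor
fraction (a monotone transform of \(F_D/F_A\)) and compares it with the
binomial mixture expected from a static multi-state model. Bins are
equal-expected-probability bins over the values the acceptor fraction can
take (one bin per ~25 windows, pooled so each compared bin expects at least
5 counts): with fixed-width bins the concentrated acceptor-fraction
distribution would populate only a handful of bins and the reduced
chi-square would be too noisy for its across-window comparison to mean
anything. For static molecules the
reduced chi-square is window-independent; exchange on the window timescale
makes it vary, and a max/min ratio above 1.5 declares dynamics. On static
data this verdict's false-positive behaviour is governed by shot noise
only.

## Dye modeling and distance uncertainty

`compute_av()` implements a single-sphere accessible-volume model: on a
1-Angstrom grid, a dye position is allowed if a linker path (width 4.5
Angstrom, length 20 Angstrom — typical maleimide-linker values for the
Alexa 488/647 pair) reaches it without clashing and the dye sphere (radius
3.5 Angstrom) fits; path lengths are Dijkstra shortest paths on the
26-neighbour lattice. Interdye statistics report the mean-position
distance, the pairwise mean distance and the FRET-averaged distance, which
differ systematically (Jensen gaps) and are all emitted so either can be
compared with decay-derived distances.

Orientation uncertainty uses a wobbling-in-cone model: residual
anisotropies map to cone half-angles via
\(r_\infty/r_0 = [\tfrac12\cos\theta(1+\cos\theta)]^2\), and the \(\kappa^2\)
distribution is sampled with cone axes uniform on the sphere and transition
dipoles uniform within each cone. With uniformly distributed axes the mean
is exactly 2/3 for any cone angle; what the cones control is the width of
the distribution, hence the asymmetric multiplicative bounds
\((\kappa^2/(2/3))^{1/6}\) applied to distances. Distance uncertainties
combine the statistical fit error with the \(\kappa^2\)-induced error in
quadrature and are reported as asymmetric bounds.

## Landscape analysis

The toy sampler runs parallel Metropolis chains at the eight temperatures
275-375 K with neighbour swaps every 50 steps using the standard
replica-exchange acceptance rule. It is a sampler, not dynamics: it
reproduces the statistical role of replica exchange (correct per-
temperature Boltzmann ensembles with enhanced barrier crossing), which is
all WHAM consumes. The double-well default (wells at ±1, 3 kcal/mol
barrier) mirrors a two-basin closed-like/open-like landscape with a
low barrier.

WHAM iterates the per-replica free-energy shifts on energy-binned
histograms in log space until the largest change is below 1e-7, reweights
to 300 K, and min-shifts the potential of mean force to zero; unsampled
bins stay `NA` with a zero sample count rather than being interpolated. The
log-space formulation makes the single-replica case collapse exactly to
Boltzmann inversion of the histogram, which the tests assert bin-for-bin,
and leaves the PMF invariant under constant energy shifts to 1e-10.
Two-axis PMFs (interdomain distance x interdye distance, linear maps of
the reduced coordinate in the toy) integrate Boltzmann weights over the
interdomain axis to give the simulated interdye-distance density.

Structural metrics operate on tidy atom tables: interdomain centre-of-mass
distances (mass-weighted, default domain boundaries residues 61-151 and
155-249, configurable), residue contact-frequency maps (any heavy-atom
pair within 5.5 Angstrom; the cutoff is configurable because published
analyses rarely state it), Q-values against native contact lists,
representative-frame selection by minimum mean pairwise RMSD (Kabsch
superposition, ties to the lowest index), and buried surface area as the
full difference SASA(A)+SASA(B)-SASA(AB) by Shrake-Rupley with 960 sphere
points and a 1.4-Angstrom probe. The toy tandem generator builds two
36-bead rigid lattice domains in closed, open or separated arrangements
with disjoint closed/open interfaces, so Q-value mutual exclusivity can be
demonstrated exactly.

## Disulfide kinetics

Time courses follow \(P(t) = P_f + (P_0-P_f)e^{-kt}\) with homoscedastic
Gaussian noise (gel densitometry error is approximately additive), fitted
by Levenberg-Marquardt nonlinear least squares with both the rate constant
\(k\) (1/min) and the initial rate \(k(P_f-P_0)\) (%/min) reported — the
%/min convention is what rate-fold comparisons between mutants use.
Flat time courses leave \(k\) unidentifiable and are flagged rather than
forced. Replicate summaries give per-parameter means and SEM with pairwise
unpaired two-sided t-tests.

## Numerical choices and degenerate inputs

* IRF convolution is FFT-based with zero padding; a zero-FWHM IRF is a
  delta at the pulse channel.
* Truncated-Gaussian quadrature nodes changing at the ±5-sigma window edge
  carry dnorm weight ~1e-6; their effect on the analytic gradient is
  ignored.
* Zero-acceptor bursts give an infinite \(F_D/F_A\) and are flagged and
  excluded from 2D histograms but counted in the report; bursts with fewer
  than 10 donor photons get no lifetime.
* All stochastic generators take an explicit seed and restore the caller's
  RNG state; nothing reads or leaves global random state.
* Empty photon streams, zero-step samplers and empty burst tables return
  empty tibbles rather than erroring; buried labeling sites (empty
  accessible volume) are an explicit error.

## Problem sizes used by the tests and acceptance analysis

The recovery study runs ten variants at \(2\times10^7\) photons each on a
1024-channel grid with one fit per model order; WHAM checks use 1.2e5
(harmonic, four temperatures) and 1e6 (double-well, eight temperatures)
total frames; burst checks use 250-600 bursts at 100 photons/ms; kappa-squared
Monte Carlo uses 1e6-2e6 samples. These sizes were chosen so each
statistical tolerance is several standard errors wide under the generative
model.

## Limitations

The synthetic module emulates the statistical structure of the
measurements, not their instrumental pathologies: no detector afterpulsing
or dead time, no spectral crosstalk or direct acceptor excitation (the
gamma, crosstalk and direct-excitation corrections default to ideal and are
exposed for real data), a phenomenological burst envelope, and an
implicit-solvent-free toy landscape in one reduced coordinate. Passing
tests therefore certify the analysis pipeline — model identity, estimator
calibration, optimiser reliability — under these idealised conditions;
they do not certify the idealisations themselves against a real
instrument. Width/state-separation limits discussed above bound what the
decay analysis can resolve at realistic photon budgets, and per-variant
(non-global) fits should be treated as exploratory precisely because of
the population degeneracy the tests exhibit.
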