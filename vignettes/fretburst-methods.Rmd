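---
title: "Models and methods behind fretburst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fretburst}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`fretburst` analyses diffusion-based single-molecule FRET measurements with
alternating excitation (µs-ALEX or ns-interleaved PIE): photon streams are
segmented into single-molecule bursts, apparent FRET efficiencies are turned
into accurate ones through the four-factor correction scheme, populations are
summarised by Gaussian fits and converted to interdye distances, and
conformational dynamics are detected and quantified with burst variance
analysis (BVA), E-versus-lifetime analysis, dynamic photon distribution
analysis (PDA), species-filtered FCS and a maximum-entropy decay inversion.
A photon-level simulator generates data with the same statistical structure
and serves as ground truth for every stage. This vignette documents the
models, the defaults and why they were chosen, the numerical choices, and
what the simulator does and does not emulate.

## The correction scheme

The three intensity channels of a burst are the donor and acceptor signals
after donor excitation, `DD` and `AD`, and the acceptor signal after
acceptor excitation, `AA`. After background subtraction (per-burst
`rate x duration`), four factors map counts to an accurate FRET efficiency
E and stoichiometry S:

* `alpha` — donor spectral crosstalk into the acceptor channel, determined
  from the apparent-E center of donor-only bursts,
  `alpha = <E>_DO / (1 - <E>_DO)`;
* `delta` — direct acceptor excitation by the donor laser, from the
  acceptor-only stoichiometry center, `delta = <S>_AO / (1 - <S>_AO)`;
* `gamma` — acceptor/donor detection-efficiency and quantum-yield ratio;
* `beta` — acceptor/donor excitation-flux normalisation.

The corrected FRET signal is `F = AD - alpha DD - delta AA`, and
`E = F / (gamma DD + F)`, `S = (gamma DD + F)/(gamma DD + F + AA/beta)`.
`beta` and `gamma` come from the global regression of `1/S` on E across two
or more populations (`beta_gamma_global()`): with intercept `Omega` and
slope `Sigma`, `beta = Omega + Sigma - 1` and `gamma = (Omega - 1)/beta`.
For a single static population measured with pulsed excitation,
`gamma_from_static_line()` instead matches the population to the static
FRET line. The propagated efficiency uncertainty is
`dE = E (1 - E) dgamma/gamma`, with 23% as the default relative gamma
uncertainty (the cross-laboratory consensus level); it is maximal at
E = 0.5.

## The simulator as study conditions

`sim_config()` defaults encode the statistical structure of typical
measurements: lognormal burst durations of 1.7 +/- 0.9 ms and total detected
count rates of 55 +/- 18 kHz (about 90 photons per burst), species fractions
70% double-, 20% donor-only- and 10% acceptor-only-labelled molecules,
per-channel backgrounds of 1.0/0.6/0.8 kHz, a Forster radius of 65 Å, an
excitation-flux ratio of 1.6, and dye physics (quantum yields 0.72/0.32,
crosstalk 1/21, direct excitation 0.192) that imply exactly the consensus
corrections alpha = 0.05, beta = 1.6, gamma = 0.4, delta = 0.12
(`implied_corrections()` is the oracle for recovery tests). The mean
inter-burst gap is 200 ms, the duty cycle of dilute (tens of pM)
measurements; this keeps chance two-molecule coincidences below one percent,
which matters because coincidences masquerade as FRET dynamics.

Distance heterogeneity enters at two timescales, matching their physical
origins: per-state `sigma_r` is conformational breadth, drawn once per
kinetic dwell (quasi-static on the burst timescale), while the model-level
`sigma_linker` is the flexible-linker width, redrawn photon by photon (fast
averaging within bursts). Donor microtimes are exponential with the
state-quenched lifetime `tau = tau_D(0) (1 - E)` convolved with a Gaussian
IRF; FRET-sensitised acceptor photons add the acceptor decay time;
background photons have flat microtimes. Kinetic state trajectories are
continuous-time Markov chains over an arbitrary rate matrix.

What the simulator does *not* emulate: diffusion-shaped intensity profiles
within bursts (bursts have constant brightness; the analyses studied here
use burst statistics, not intensity trajectories), photobleaching and
blinking (the ALEX selection is designed to remove such events; they are
not needed for the recovery tests), acceptor photophysics beyond a single
exponential lifetime, and instrument dead time or afterpulsing. Passing
tests therefore demonstrate correctness of the estimators under the stated
photon statistics, not robustness to hardware artifacts.

## Burst search, selection and estimator hygiene

The all-photon sliding-window search (defaults m = 10, F = 6, L_min = 30)
marks a photon as in-burst when the local rate over m photons exceeds F
times the total background rate; background rates come from an
inter-photon-delay tail fit (delays above the 0.9 quantile are
background-dominated, and by memorylessness the exceedance mean is the
inverse rate). Selection partitions bursts by apparent stoichiometry
(donor-only > 0.8, acceptor-only < 0.2, FRET pairs 0.25–0.75 with at least
10 Aex photons). Two coincidence guards are applied: bursts longer than
10 ms cannot be single diffusing molecules, and bursts whose mean Dex and
mean Aex photon times differ by more than a quarter of the burst duration
are sequential two-molecule events (this offset is only evaluated when both
excitation tracks carry at least five photons).

Two small-sample effects matter at the precision targeted here. First, the
per-burst corrected E is a nonlinear ratio of counts and carries an O(1/N)
downward bias (about -0.5/N at mid E with gamma = 0.4); population centers
are therefore fitted on bursts with at least 60 Dex photons
(`pipeline_config()`'s `min_dex`). Second, the per-burst lifetime fit with
a free flat-background fraction is biased at ~50 photons per burst; fixing
the background fraction from the measured rates (`burst_lifetimes(bg =)`)
removes it. Both choices are estimator hygiene, not calibration: they were
validated against the simulator's ground truth.

## Dynamics

**BVA.** Apparent E over consecutive windows of n = 5 Dex photons; the
per-burst standard deviation across windows uses the Bessel and c4
finite-sample corrections so static bursts center on the shot-noise
semicircle `sqrt(E(1-E)/n)` even when a burst contributes few windows. The
population center is the mean of the (E, sigma) scatter — the maximum
likelihood center of a two-dimensional Gaussian — and the dynamic shift is
its vertical excess over the semicircle.

**E–tau.** The static FRET line is `E = 1 - tau/tau_D(0)`; with fast linker
broadening of width 6 Å the species-averaged E and photon-weighted lifetime
`<tau>_F = <tau^2>/<tau>` trace a slightly curved line, computed by
Gaussian quadrature over the distance distribution (the quadrature is the
source of truth; a cubic fit is provided for fast evaluation). The
two-state dynamic line is the exact mixing curve
`E = 1 - (tau1 tau2/(tau1 + tau2 - <tau>_F))/tau_D(0)`. The dynamic shift
is the vertical E-offset of the population center from the static line at
the population's lifetime — a convention chosen for dimensional consistency
with the BVA shift. `estimate_delta_R()` inverts the equal-occupancy
two-state mixing model (states at `R +/- dR`) to convert a shift into a
distance-fluctuation amplitude.

**Dynamic PDA.** The occupancy-time distribution of a two-state chain in a
window is computed from the renewal-series expansion over transition counts
(truncated at 1e-10; validated against Monte-Carlo simulation; for
`(k12+k21) T > 150` the Gaussian fast-exchange limit is used). Acceptor
counts are Binomial given the window-averaged apparent acceptor
probability. Three refinements proved essential under realistic conditions:
(i) the forward model predicts *raw* proximity ratios, mapping state E to
the apparent probability through alpha, gamma, delta and beta; (ii) because
both channel weights are affine in E, window brightness is a deterministic
monotone function of the apparent probability, and the empirical
photon-count distribution is conditioned on it — with gamma = 0.4 a dim
high-FRET composition yields fewer photons per window, and ignoring this
biases the rates severely; (iii) expected background counts shift the mean
probability (first-moment treatment). Windows are guarded by a per-window
stoichiometry cut (0.2–0.8) against molecule coincidences. The global fit
(`fit_dynamic_pda()`) follows the two-stage procedure used for real
measurements: the state distances and occupancy are first refined on the
shortest window in the slow-exchange limit, then the total rate is fitted
across all window lengths (0.5/1/1.5/2 ms) with multi-start; this keeps
percent-level static-shape mismatches out of the kinetic parameters. Even
so, the relaxation time of slow exchange (~10 ms) probed with <= 2 ms
windows is intrinsically weakly identified; the package uses 4e4 bursts in
its headline recovery, where repeated simulations recover 10 ms within a
few percent.

**Filtered FCS.** Reference (channel x microtime) patterns are taken from
burst subensembles at the lower and upper edges of the apparent-E histogram
(not from external calibration samples); `species_filters()` solves the
generalised-least-squares unbiasedness condition with the mixed pattern as
covariance proxy. The correlator counts photon pairs within bursts on a
quasi-logarithmic lag grid and normalises with global mean weight rates
times the per-burst geometric lag overlap — per-burst normalisation would
detrend kinetic components slower than the burst duration. The species
curves are then divided by the total-intensity correlation, which carries
the same burst-brightness and transit structure but (with nearly
state-independent total brightness) no kinetics, so the ratio isolates the
kinetic factor and the global fit needs no diffusion envelope: all curves
share the relaxation times (parameterised as `t2 = t1 (2 + e^p)` so the
two terms cannot collapse), amplitudes are per curve and profiled
analytically, and cross-correlations may take negative amplitudes.

**MEM.** The donor decay is modelled as an integral of single-exponential
decays over a distance grid; the distribution maximises entropy relative to
a prior subject to the discrepancy principle (reduced chi-square equal to
one, located by bisection in the regularisation weight). The inner problem
is solved by exponentiated-gradient (multiplicative) descent with an
adaptive step, which respects the simplex and copes with the severe
ill-conditioning of the decay kernel where quasi-Newton steps stall; the
decay amplitude is profiled analytically.

## Dye models and anisotropy

The accessible volume (AV) is a deterministic grid computation: positions
within the linker length of the attachment atom (geodesic distance around
obstacles, Dijkstra on the grid graph), with path clearance at least half
the linker width and position clearance at least the dye radius; AV3
averages three dye radii. The ACV reweights the layer whose dye surface
lies within 3 Å of the protein surface to carry the measured sticking
fraction, with `f = r_inf/r0` as the monotone anisotropy-to-fraction map.
Model distances report the FRET-averaged `<E>` (fast rotational, slow
positional averaging), its Forster inversion `R<E>`, the mean distance and
the mean-position distance; pair sums are exact up to 4e6 pairs and
stratified subsampling with a reported standard error beyond. AV dye
parameters (linker 20 x 4.5 Å, radii 5/4.5/1.5 Å, grid 0.9 Å) are generic
literature-style values and deliberately mandatory inputs, not
measurement-specific calibrations.

Time-resolved anisotropy is reconstructed as
`r(t) = (I_par - G I_perp)/(I_par + 2 G I_perp)` and fitted with up to
three rotational components plus a residual anisotropy. The kappa-squared
distance uncertainty offers two surrogates: a "diffusion with traps"
mixture (free dyes at kappa^2 = 2/3 plus a trapped fraction `r_inf/r0` per
dye with an effective worst-case kappa^2) and a wobbling-in-a-cone model
using the classical static bounds with order parameters
`S = sqrt(r_inf/r0)`. The exact quantitative form of the traps model is not
in the public record, so both surrogates are anchored to the one printed
correspondence — a 10% distance uncertainty at a combined residual
anisotropy `r_c,inf = sqrt(r_inf,D r_inf,A)` of 0.25 (r0 = 0.38) — through
one calibration constant each (`kappa2_trapped = 1.24922`,
`cone_scale = 0.37597`), both exposed as arguments. The dye-artifact filter
flags measurements at `r_c,inf >= 0.25` or uncertainty >= 10% (boundaries
inclusive). Near zero anisotropy the two surrogates scale differently
(linearly vs as a square root), so their factor-two agreement corridor is
documented for `r_c,inf` in 0.05–0.3.

## Headline simulation scales

The package's own validation uses problem sizes chosen to bound the Monte
Carlo error of each recovery well below its tolerance: 1e4 bursts for
correction-factor and mean-E recovery (centers to ~0.003), about 60 s of
cumulative in-burst observation (3.5e4 bursts) for the two-process
filtered-FCS recovery (9 µs and 300 µs), and 4e4 bursts for the 10 ms
dynamic-PDA recovery. The two-process exchange is simulated as two
independent two-state processes with additive efficiency contrasts
(states 0.45/0.65/0.70/0.90), which makes the species-correlation kinetics
an exact two-exponential sum with the two process relaxation times — the
cleanest ground truth for the global fit. The slow-exchange system uses a
broad detached ensemble (R = 55 Å, sigma 8 Å) against a compact state
(R = 43 Å, sigma 6 Å) at R0 = 59 Å with rates 30/70 s^-1; the state
contrast was chosen so that the relaxation time is actually identifiable
from 0.5–2 ms windows, which a weaker contrast provably is not (the
likelihood along the total rate becomes flat).

## Known limitations

* Vendor raw formats are not read; streams arrive through the documented
  tabular text layout (or are simulated). There is no HDF5 reader.
* The dynamic PDA supports at most two dynamic states plus one extra
  static component, matching the analyses it implements.
* Acceptor-only direct-excitation estimates carry a small positive bias
  (~0.005 in delta under the default background) from the skew of
  few-count stoichiometry ratios; brighter-burst selection mitigates it.
* The kappa-squared surrogates are calibrated operational models, not
  derivations; their absolute values outside the anchored region should be
  treated as indicative.
* The E-tau dynamic-shift convention (vertical offset at the fitted
  population lifetime) is one of several in use; comparisons across
  software should check conventions.
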