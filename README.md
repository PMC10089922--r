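# fretburst

Single-molecule FRET (smFRET) on freely diffusing molecules measures
distances and conformational dynamics of biomolecules one molecule at a
time: each passage through a confocal volume produces a photon burst whose
donor/acceptor composition encodes the FRET efficiency *E* and hence the
interdye distance through the Förster relation
*R*⟨*E*⟩ = *R*₀ (1/⟨*E*⟩ − 1)^(1/6). Getting *accurate* efficiencies —
comparable across instruments and laboratories — requires alternating
excitation (µs-ALEX or PIE) and a four-factor correction scheme:

- **α** — donor spectral crosstalk into the acceptor channel,
- **β** — donor/acceptor excitation-flux normalisation,
- **γ** — acceptor/donor detection-efficiency × quantum-yield ratio,
- **δ** — direct acceptor excitation by the donor laser,

with background-subtracted counts combined as
*F* = I_AD − α I_DD − δ I_AA, *E* = *F*/(γ I_DD + *F*),
*S* = (γ I_DD + *F*)/(γ I_DD + *F* + I_AA/β). The γ uncertainty dominates
the cross-laboratory spread and propagates as Δ*E* = *E*(1−*E*)·Δγ/γ.

`fretburst` implements this analysis end to end for R users:

- photon-stream data model and plain-text I/O (`photon_stream`,
  `read_photons`/`write_photons`, `assign_excitation`, `channel_counts`);
- background estimation, all-photon burst search and ALEX-based selection
  with coincidence guards (`estimate_background`, `search_bursts`,
  `select_bursts`);
- correction-factor determination and application (`alpha_from_donor_only`,
  `delta_from_acceptor_only`, `beta_gamma_global`,
  `gamma_from_static_line`, `accurate_E_S`, `efficiency_uncertainty`);
- Gaussian population fits, cross-replicate consensus statistics and
  Förster distance conversion (`fit_gaussians`, `consensus`,
  `efficiency_to_distance`);
- dynamics: burst variance analysis (`bva`), E–lifetime analysis with
  static/dynamic FRET lines and dynamic shifts (`burst_lifetimes`,
  `static_fret_line`, `dynamic_fret_line`, `dynamic_shift_etau`,
  `estimate_delta_R`), dynamic photon distribution analysis
  (`pda_windows`, `pda_predict`, `fit_dynamic_pda`), species-filtered FCS
  (`reference_patterns`, `species_filters`, `correlate_bursts`, `fit_fcs`)
  and maximum-entropy inversion of donor decays
  (`mem_distance_distribution`);
- accessible-volume / accessible-contact-volume dye clouds on PDB
  structures and model–experiment distance comparison (`compute_av`,
  `compute_acv`, `model_distances`, `compare_model_experiment`);
- time-resolved anisotropy fits, the combined residual anisotropy, the
  κ²-based distance-uncertainty estimate and the dye-artifact filter
  (`fit_anisotropy`, `combined_residual_anisotropy`,
  `kappa2_distance_uncertainty`, `dye_artifact_filter`);
- a photon-level simulator of diffusing labelled molecules
  (`simulate_bursts`) whose `implied_corrections()` provide exact ground
  truth for every recovery test, and a pipeline orchestrator
  (`run_pipeline`, `consensus_report`).

## Worked example

Simulate an apo/holo pair of measurements (true efficiencies 0.49 and
0.67, consensus-style dye physics) and run the full pipeline — background,
burst search, ALEX selection, correction factors from the data themselves,
Gaussian population fits and distances:

```r
library(fretburst)

mk <- function(E, seed) simulate_bursts(sim_config(
  n_bursts = 3000, model = kinetic_model(data.frame(E = E)), seed = seed))
sims <- list(apo = mk(0.49, 11), holo = mk(0.67, 12))

report <- run_pipeline(sims, pipeline_config())
report$corrections
#> corrections: alpha=0.05397 beta=1.52 gamma=0.4212 delta=0.1298
#>    alpha/delta from donor-/acceptor-only populations; beta/gamma from
#>    global 1/S vs E regression over 2 population centers
```

The estimated factors sit close to the simulation's implied truth
(α = 0.05, β = 1.6, γ = 0.4, δ = 0.12). Per dataset:

```r
for (nm in names(report$datasets)) {
  d <- report$datasets[[nm]]
  cat(sprintf("%s: n_fret=%d  <E> = %.3f  R<E> = %.1f +/- %.1f A\n",
      nm, d$n_fret, d$fit$components$mean, d$distances$R, d$distances$dR))
}
#> apo: n_fret=724  <E> = 0.457  R<E> = 66.9 +/- 2.6 A
#> holo: n_fret=674  <E> = 0.647  R<E> = 58.8 +/- 2.3 A
```

`<E>` is the Gaussian-fit center of the corrected FRET-pair population
(here slightly below truth because the small demo uses the pipeline's own
estimated γ), `R<E>` its Förster conversion with the γ-propagated
uncertainty. At this demo scale the centers carry a few-thousandths of
statistical error; the package's tests run the same recovery at 10⁴ bursts,
where centers land within ±0.01 of truth.

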