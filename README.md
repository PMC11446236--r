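# smfretr

Single-molecule FRET (smFRET) trace simulation, selection, and
conformational state-occupancy analysis, built for subtype-comparison
studies of NMDA receptors (GluN1 probe sites on receptors with different
GluN2 subunits) but applicable to any two-channel donor/acceptor trace
data with the same structure.

smFRET reports the distance between two fluorophores through the Förster
relation E = 1/(1 + (r/R₀)⁶) (R₀ = 51 Å for AF555/AF647). Per-receptor
traces of donor and acceptor emission at 10 frames/s are corrected for
channel gain (γ_A = 1.2) and donor→acceptor crosstalk (χ = 0.15),
screened for single-molecule behavior (single-step photobleaching per
fluorophore, FRET lifetime > 50 frames, constant total fluorescence,
donor–acceptor anti-correlation), pooled into per-movie histograms
(first 50 valid frames per trace, bin width 0.02) that are averaged with
SEM across replicate movies, and decomposed into three fixed-mean
Gaussian components (μ = 0.3, 0.5, 0.7) whose Simpson's-rule area shares
are the reported percent state occupancies. Because no public trace data
exist for these experiments, the package includes a full simulator
(Markov state dynamics, stochastic two-site labeling, photobleaching
with donor dequenching, crosstalk/gain/noise) plus a library of
published subtype × probe-site × ligand-condition state models, so every
pipeline stage is testable against known ground truth.

## Worked example

Simulate four replicate movies of the GluN2D receptor probed at the
GluN1 NTD (W56) in the apo-like condition, select traces, and quantify
the conformational distribution:

```r
library(smfretr)

model <- condition_model("GluN2D", "NTD-W56", "apo_like")
model
#> <state_model> GluN2D / NTD-W56 / apo_like
#>    label mean_fret width mean_dwell_frames occupancy
#>  splayed      0.18  0.05                20       0.8
#>  compact      0.60  0.05                20       0.2

hists <- lapply(1:4, function(m) {
  sim <- simulate_movie(model, 150, n_frames = 800,
                        movie_id = sprintf("movie%d", m), seed = 100 + m)
  sel <- select_traces(sim$traces)
  trace_histogram(sel$traces)
})
ens <- average_histograms(hists)

round(quartile_summary(hists)$mean, 3)
#>  q25  q50  q75
#> 0.12 0.22 0.36

fit <- fit_trimodal(ens)
round(component_occupancies(fit), 1)
#>  low  mid high
#> 87.5  0.0 12.5

sprintf("splayed (E < 0.35) mass: %.1f%%", 100 * histogram_mass_below(ens, 0.35))
#> "splayed (E < 0.35) mass: 75.0%"
```

The quartiles sit low (median 0.22) because the splayed ~0.18 state
dominates; the trimodal fit attributes ~87% of its area to the low
component and the direct low-FRET mass (75%) tracks the generating 80%
splayed occupancy. Expected efficiencies for candidate structural
distances come from the same Förster parameters the analysis uses:

```r
fret_from_distance(c(40, 51, 70))
#> 0.811 0.500 0.130
distance_from_fret(0.5)
#> 51
```

File-based runs use the same machinery: `cli_simulate()` writes
tab-separated trace files plus a manifest, `cli_process()` turns trace
files into QC reports, ensemble histograms, quartiles, and occupancy
tables, and `cli_predict_fret()` converts distance lists or PDB
residue pairs (β-carbons by default) into expected efficiencies. A thin
shell front end for the three subcommands is installed at
`inst/cli/smfret.R`.

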