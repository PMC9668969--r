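# fluxfep

Analysis toolkit for leaflet-specific phospholipid modulation of pentameric
ligand-gated ion channels (pLGICs), built around the prokaryotic model
channel ELIC. The package covers the three computational stages of a
combined stopped-flow / alchemical-simulation study:

1. **Stopped-flow flux kinetics** — thallium-quench fluorescence traces
   from sequential-mixing liposome assays are fit with a stretched
   exponential, `F(t) = F∞ + (F0 − F∞)·exp[−(t/τ)^β]`, and the
   instantaneous Tl⁺ influx rate is taken as
   `k = (β/τ)·(t/τ)^(β−1)` at t = 2 ms. Rates across agonist-to-Tl⁺ delay
   times give activation/desensitization time courses; desensitization is
   summarized by a biexponential fit and its amplitude-weighted time
   constant `τ_w = (A1τ1 + A2τ2)/(A1 + A2)`; peak rates across agonist
   concentrations give Hill dose-response fits (EC₅₀, n).
2. **Alchemical free-energy estimation** — bidirectional (interleaved
   double-wide sampling) per-window work samples are reduced with
   exponential-averaging (EXP) and Bennett-acceptance-ratio (BAR)
   estimators, decorrelated by statistical-inefficiency subsampling, and
   accumulated across the λ schedule, with the field's convergence
   diagnostics: first-half/second-half comparison (pass at ≤ ~1 kcal/mol)
   and per-window forward/backward hysteresis δ_λ with a sign-runs
   randomness check. The distance-to-bound-configuration (DBC) coordinate
   (glycerol-atom RMSD after Kabsch superposition of the protein frame) and
   its percentile-based restraint wall are included.
3. **Lipid-site allosteric model** — state-dependent lipid transformation
   free energies (bound site vs bulk membrane) are combined through the
   thermodynamic cycle `ΔΔG = ΔG_bound − ΔG_bulk`, converted to relative
   binding constants `K^{ab} = exp(−ΔΔG/RT)`, and propagated to site
   occupancies `p^a ∝ K_a·x_a`, the POPG mole fraction at half occupancy
   (x₅₀) along a 2 POPC : 1 POPE : x POPG titration, and the
   conformational-stability landscape
   `Δlog(p_open/p_closed)` over the ternary POPC/POPE/POPG simplex
   (zero at pure POPC by construction).

Every input class has a seeded synthetic generator with recorded ground
truth (stretched-exponential traces, delay series, Hill dose series,
Crooks-consistent Gaussian work samples, rigid-motion coordinate
snapshots), so the full pipeline is testable offline.

## Worked example

```r
library(fluxfep)

## lipid-site thermodynamics from the packaged free-energy table
tb <- load_packaged_table()
k_wt <- affinity_matrix(tb, "WT_CA")      # non-conducting conformation
k_e5 <- affinity_matrix(tb, "ELIC5_CA")   # open-channel conformation

k_wt$K["POPC", "POPG"]                    # 21158.85  (POPG vs POPC, WT site)
k_e5$K["POPC", "POPG"]                    # 3077629   (POPG vs POPC, open site)

x50(k_wt)$x50                             # 0.01193894  (~1e-2)
x50(k_e5)$x50                             # 3.21211e-06 (~1e-5 within a decade)

stability_ratio(k_e5, k_wt, composition(1, 0, 0))  # 0   (pure-POPC reference)
stability_ratio(k_e5, k_wt, composition(0, 0, 1))  # 4.98 (pure POPG, natural log)
```

The K values say the open-channel site binds POPG ~3×10⁶-fold more tightly
than POPC while the non-conducting site prefers it only ~2×10⁴-fold, so
trace amounts of POPG (mole fraction ~3×10⁻⁶) half-saturate the open-state
site and anionic lipid shifts the conformational equilibrium toward the
open channel (Δlog = +4.98 at pure POPG).

```r
## flux kinetics on synthetic data with known truth
sc <- gating_scenario(seed = 2026)                 # A1=0.7 τ1=2s, A2=0.3 τ2=20s
tc <- build_time_course(gen_delay_series(sc))
tc$peak_rate                                       # 17.49  (truth 17.5 1/s)
tc$desensitization$weighted_tau                    # 7.543  (truth 7.4 s)

## BAR on Crooks-consistent synthetic work samples
ser <- gen_fep_dataset(fep_scenario(2.0, work_sd = 1,
                                    samples_per_window = 5000, seed = 42))
bar_estimate(ser$windows[[1]])
#> <dg_estimate> BAR: 2.01737 +/- 0.0106 kcal/mol (n_eff ~ 1924.1)
```

## Command line

```sh
Rscript -e 'quit(status = fluxfep::ffk_cli())' \
  thermo-x50 --table inst/extdata/lipid_transform_free_energies.tsv \
  --conformation WT_CA
# x50(WT_CA) = 0.0119389 (path coordinate x = 0.0362496)
```

Subcommands: `simulate-trace`, `simulate-fep`, `fit-flux`, `timecourse`,
`doseresponse`, `fep-estimate`, `fep-diagnose`, `dbc-profile`,
`thermo-occupancy`, `thermo-x50`, `thermo-map`; global flags `--seed`,
`--config`, `--out`. A wrapper script is installed at `exec/fluxfep`
inside the package library.

## Vignette

`vignettes/fluxfep-methods.Rmd` documents the models, assumptions, tunable
parameters, the synthetic-data world and its limits, and the numerical
choices (optimizer bounds, BAR root-finding, percentile conventions).
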