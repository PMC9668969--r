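---
title: "fluxfep: models, assumptions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fluxfep: models, assumptions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxfep)
```

# Scope

`fluxfep` implements the analysis layer of a study of leaflet-specific
phospholipid modulation of the model pentameric ligand-gated ion channel
ELIC: stopped-flow thallium-flux kinetics, post-processing of alchemical
free-energy perturbation (FEP) work samples, and a mass-action allosteric
model that turns state-dependent lipid binding free energies into
occupancy curves and conformational-stability landscapes. It does not run
simulations or acquire data; its inputs are fluorescence traces, work
tables, and a small table of transformation free energies.

# Stopped-flow flux kinetics

## Model

In the sequential-mixing assay, proteoliposomes loaded with the
Tl⁺-sensitive fluorophore ANTS are mixed with agonist, then after a delay
`d` with a Tl⁺ quench buffer. Quenching follows the empirical stretched
exponential

$$F(t) = F_\infty + (F_0 - F_\infty)\,e^{-(t/\tau)^\beta},$$

and channel activity is summarized by the instantaneous influx rate

$$k = \frac{\beta}{\tau}\left(\frac{t_{eval}}{\tau}\right)^{\beta-1},
\qquad t_{eval} = 2\ \mathrm{ms},$$

the time derivative of the stretched exponent evaluated early enough that
vesicle heterogeneity has not yet distorted the decay. `k` depends only on
$(\tau, \beta)$ and is therefore invariant to fluorescence rescaling.
Rates as a function of delay trace out activation (fast, unresolved at
this protocol's first delay of 10 ms) and desensitization, the latter fit
as $A_1 e^{-d/\tau_1} + A_2 e^{-d/\tau_2}$ and summarized by the
amplitude-weighted time constant
$\tau_w = (A_1\tau_1 + A_2\tau_2)/(A_1+A_2)$. Peak rates across agonist
concentrations are fit with a Hill curve with the bottom pinned at zero.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| fit window | (0, 0.1) | s | the first 0.1 s of the quench record; later times go multi-phasic in real vesicle populations |
| `t_eval` | 0.002 | s | early-time rate convention; configurable |
| β bounds | (0.05, 1.5] | — | stretched regime plus mild super-exponential slack |
| τ bounds | (1e-5, 1e3) | s | generous instrument-plausible range |
| control subtraction | off unless a control is supplied | — | no-agonist leak rate subtraction, recorded when applied |

Fit initialization is data-driven: $F_0$ = first sample, $F_\infty$ =
mean of the last 5 % of the window, $\tau$ = time to 1/e of the amplitude,
$\beta = 0.9$, plus a second start that assumes the quench runs to zero
(see *Numerical choices*).

## The truncation problem for slow traces

When $\tau$ far exceeds the fit window, the window sees only the onset of
the decay and two models become indistinguishable: a small fast quench
that has finished, and the beginning of a large slow quench. Both fit the
window to within noise but imply very different rates. `build_time_course`
therefore checks every window fit against the trace *beyond* the window
and refits over the full record when the extrapolation fails (RMSE beyond
the window exceeding three times the in-window RMSE plus 0.1 % of $F_0$).
This is exact for the synthetic world, where the stretched exponential
holds over the whole record; for real traces that deviate at long times
the check can be disabled (`extend_slow = FALSE`), at the cost of noisier
slow-trace rates.

# Alchemical free-energy estimation

## Estimators

Each λ window carries forward and reverse work samples (interleaved
double-wide sampling). Two estimators are implemented from scratch:

* **EXP** (Zwanzig): $\Delta G = -RT\,\log\langle e^{-W/RT}\rangle$,
  computed by log-sum-exp; the backward estimate is sign-corrected into
  the forward convention so that, for a converged window, forward and
  backward values agree.
* **BAR** (Bennett): $\Delta G$ solves the self-consistency condition over
  logistic (Fermi) weights of both directions with the
  $RT\log(n_F/n_R)$ offset, found by bracketed root finding
  (`uniroot`, tolerance 1e-10 kcal/mol on a bracket padded 50 kcal/mol
  beyond the sample range). The statistical error is the standard
  asymptotic variance of the Fermi-weighted sums.

Window estimates accumulate by summation, errors in quadrature, with the
running partial sum reported as the cumulative profile versus λ.
Replicas aggregate as mean ± SEM for n ≥ 2, or pass through a single
replica with its own BAR error (the two regimes that occur in practice for
membrane-only and protein-site transformations, respectively).

## Convergence diagnostics

* **Half-split**: accumulate the first and second temporal halves of the
  raw (pre-subsampling) work series independently; pass when they agree
  within 1 kcal/mol.
* **Hysteresis**: $\delta_\lambda$ = forward EXP − backward EXP per
  window. Converged series have small $\delta_\lambda$ scattered randomly
  in λ; a Wald–Wolfowitz sign-runs statistic quantifies the randomness.
  Note the sign convention: because the backward estimate is
  sign-corrected to the forward convention, a systematic +1 kcal/mol shift
  of the backward work produces $\delta_\lambda \approx +1$.
* **Statistical inefficiency**: $g = 1 + 2\sum_t (1-t/N)\rho_t$ with the
  autocorrelation sum truncated at its first non-positive term, computed
  by FFT; work series are subsampled with stride $\lceil g\rceil$ before
  estimation (half-splitting happens before subsampling). A constant
  series has $g = 1$ by convention.
* **Overlap**: the effective sample size per direction is the *sum* of
  Fermi weights at the BAR solution (≈ n/2 for perfect overlap, → 0 for
  disjoint distributions). Below 10 in either direction the estimate is
  returned with a warning and the error inflated to at least half the
  forward/backward EXP spread. The concentration form
  $(\sum f)^2/\sum f^2$ was rejected: for disjoint distributions all
  weights are equally tiny and it reports ≈ n.

## The DBC coordinate

The bound state of a site lipid is defined by the
distance-to-bound-configuration: snapshots are superposed on the
reference protein-frame atoms by Kabsch's algorithm (SVD with a
determinant correction, so reflections are never produced), and the DBC is
the RMSD of the lipid glycerol atoms under that transform. Collinear frame
atoms are rejected (the superposition is underdetermined). The flat-bottom
restraint wall is placed at an empirical percentile of unbiased-simulation
DBC values — 95th by default, linear-interpolation convention (R type 7),
which corresponds to 6 Å in the source system.

# The lipid-site allosteric model

## From free energies to binding constants

The table of transformation free energies holds
$\Delta G^{a\to b}$ per *environment* — either a bulk membrane
composition or a bound conformation (`WT_CA`, the non-conducting
agonist-bound state; `ELIC5_CA`, the open-channel state of a
gain-of-function variant). Antisymmetry
$\Delta G^{a\to b} = -\Delta G^{b\to a}$ is enforced on read and
conflicting duplicates are an error. The thermodynamic cycle

$$\Delta\Delta G^{a\to b}_{Bulk\to M} =
  \Delta G_M^{a\to b} - \Delta G_{Bulk}^{a\to b}$$

gives the free energy of swapping a bound lipid `a` for a bulk lipid `b`,
converted to relative binding constants
$K_M^{ab} = \exp(-\Delta\Delta G^{a\to b}/RT)$ at 303.15 K (the simulation
temperature; the conversion temperature is a package argument since it is
not otherwise pinned). Matrices are built from a common reference species
(POPE, the shared origin of the packaged transformations), which makes
them cycle-consistent to machine precision by construction:
$K^{ab}K^{ba} = 1$ and $K^{ab}K^{bc} = K^{ac}$.

## Occupancy, x₅₀, stability

Assuming (i) two conformations, (ii) at most three lipid species with
$\sum_s x_s = 1$, (iii) independent sites, and (iv) negligible probability
of an empty site, occupancies are Boltzmann weights
$p^a = K_a x_a / \sum_s K_s x_s$. Along the titration path
2 POPC : 1 POPE : x POPG (mole fractions $(2, 1, x)/(3+x)$), the POPG
occupancy is monotone in x and x₅₀ — the POPG mole fraction at half
occupancy — is found by bisection in log x. x₅₀ is reported as the
normalized fraction $x/(3+x)$ (reading "mole fraction" literally), with
the raw path coordinate alongside; at these magnitudes the two are
numerically indistinguishable.

The conformational-stability landscape is

$$\Delta\log\frac{p_{open}}{p_{closed}} =
  \log\frac{x_C + K^{CE}_{open}x_E + K^{CG}_{open}x_G}
           {x_C + K^{CE}_{closed}x_E + K^{CG}_{closed}x_G},$$

identically zero at pure POPC (the reference composition) for any valid
table — the one quantity the acceptance report pins exactly. Natural log
internally; base-10 display offered (the zero reference is
base-invariant). Maps are evaluated on a barycentric simplex grid with
$r(r+1)/2$ points at resolution $r$.

Two open choices were resolved as follows: the bulk reference row for each
conformation's ΔΔG defaults to the 2:1:1 POPC:POPE:POPG mixture (the
composition behind the published occupancy curves), with other bulk rows
selectable; and table uncertainties propagate by Monte Carlo (independent
Gaussian draws per directed entry, full recomputation per draw,
percentile intervals), since no propagation method is prescribed for the
± values.

# The synthetic-data world

The generators emulate, with known ground truth:

* stretched-exponential quenching with additive Gaussian noise (a stated
  modelling choice — photon-counting noise is out of scope);
* delay series in which the true rate follows
  $r(d) \propto (1 - e^{-d/\tau_{act}})(A_1 e^{-d/\tau_1} +
  A_2 e^{-d/\tau_2})$, normalized so the grid maximum equals the scenario
  peak rate, with each trace's τ solved so the 2 ms rate equation
  reproduces $r(d)$ at fixed β;
* Hill dose-response records;
* per-window Gaussian work pairs
  $W_F \sim N(\Delta G + \sigma^2/2RT, \sigma^2)$,
  $W_R \sim N(-\Delta G + \sigma^2/2RT, \sigma^2)$, which satisfy the
  Crooks fluctuation relation exactly (verified empirically in the suite
  by the binned log-density-ratio slope);
* rigid-motion coordinate snapshots with glycerol-only jitter whose RMS is
  the exact DBC ground truth.

Defaults state the experimental protocol: delays log-spaced 10 ms – 25 s,
5 replicates per delay, β = 0.85 (no fitted (τ, β) values are published,
so this is plausible rather than calibrated), peak rate 17.5 s⁻¹,
activation τ = 5 ms (activation is faster than the first delay; any value
well below 10 ms is equivalent), trace noise 0.5 % of amplitude for the
delay series — typical of averaged ANTS stopped-flow records, and chosen
because at several-percent noise the slow-trace rates are information-limited
within the 0.1 s window and the delay protocol itself becomes
non-identifiable. Per-generator random streams are derived from the
scenario seed, so adding one output class never perturbs another, and
identical seeds give byte-identical output.

What a green test does **not** establish: the generators contain no
vesicle-size heterogeneity, no multi-phasic quench, no photon noise, no
instrument dead time, and no correlated FEP work samples beyond what the
subsampling tests construct; recovery results bound estimator behaviour in
this idealized world only. The packaged transformation free energies are
*inputs* from microsecond-scale simulations and are not reproducible at
desk scale; everything downstream of the table is what the package
computes.

# Numerical choices

* Units package-wide: seconds, kcal/mol, Kelvin, Ångström, mole fraction;
  R = 0.0019872041 kcal/(mol·K).
* Stretched-exponential fitting profiles the two linear parameters
  ($F_\infty$ and the amplitude) at each $(\log\tau, \beta)$ and optimizes
  the remaining 2-D problem by L-BFGS-B inside the box, followed by a
  Nelder-Mead polish clamped back into the box. Both linear parameters are
  constrained non-negative — fluorescence cannot be negative and a quench
  cannot have negative amplitude — which removes an amplitude-blow-up
  ridge that otherwise fits truncated slow traces with absurd parameters.
* Exponential-decay fits run from three starts with amplitudes bounded
  non-negative and time constants bounded by 3× the observed delay span
  (slower components are not identifiable from the data); components are
  ordered by ascending τ, ties broken by descending amplitude.
* Degenerate inputs fail loudly and early: constant rate data refuse a
  decay fit, flat dose-response data return a flagged non-converged Hill
  fit, a single delay refuses an explicit desensitization fit, empty work
  directions name the offending windows, and λ-coverage gaps name the gap.
* Time origin is the Tl⁺ mixing event; instrument dead time is not
  modelled.

# Limitations

* No Markov gating-scheme simulation; the delay-series generator is a
  phenomenological rate envelope.
* No MBAR multi-state estimation, soft-core potential math, or restraint
  free-energy corrections beyond the DBC definition itself.
* The allosteric model is limited to three lipid species and two
  conformations by assumption, and yields relative (not standard-state)
  binding constants.
* The NAMD output parser covers a documented subset of the `.fepout`
  dialect (window headers plus `FepEnergy:` records, with strict
  alternation under interleaved double-wide sampling); it is a
  convenience, not a general parser.
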