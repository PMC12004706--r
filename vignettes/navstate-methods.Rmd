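---
title: "Methods: the navstate gating model and analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the navstate gating model and analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navstate)
```

# Scope

`navstate` studies state-dependent inhibition of voltage-gated sodium
channels in the modulated-receptor framework: a drug binds resting
channels with dissociation constant $K_R$ and inactivated channels with
$K_I \ll K_R$, so its apparent potency tracks the voltage-dependent
availability of the channel. The package provides (i) the voltage-clamp
protocols used to interrogate this behaviour, (ii) a mechanistic
generator of synthetic peak-current tables, and (iii) the analysis stack
that turns such tables — synthetic or instrument-derived — into
$K_R$, $K_I$ and the fold state-preference $K_R / K_I$.

# The channel + drug model

## States and transitions

Seven states: closed `C`, open `O`, fast-inactivated `IF`,
slow-inactivated `IS`, and drug-bound counterparts `CB`, `IFB`, `ISB` of
the three non-conducting conformations. There is deliberately **no
drug-bound open state**: the model describes highly hydrophobic
compounds that reach the pore-facing site through the lipid phase and
interact with resting and inactivated conformations only. A single
aggregated closed state is used; that is sufficient for peak-current
phenomenology, which is all the analyses consume.

Free-state transitions:

* `C ⇌ O` — activation, rates $r_{act}\,e^{\pm(V - V_a)/2s_a}$ with
  midpoint $V_a = -32$ mV and slope $s_a = 7$ mV;
* `O → IF` — open-state fast inactivation, constant rate $k_{oi}$;
* `C ⇌ IF` — closed-state inactivation, rates
  $r_{ssi}\,e^{\pm(V - V_i)/2s_i}$ with $V_i = -80$ mV, $s_i = 8$ mV, so
  that the equilibrium availability is exactly the Boltzmann
  $h(V) = 1/(1+e^{(V - V_i)/s_i})$ that the steady-state inactivation
  (SSI) analysis assumes;
* `IF ⇌ IS` — slow inactivation, voltage-independent first-order rates
  $k_{fs}, k_{sf}$.

Voltage-dependent rate *pairs* are capped at `rate_cap` by scaling both
members jointly, preserving their ratio. This matters: a per-rate cap
would distort equilibria at strongly depolarised potentials and break
detailed balance in the binding cycles.

## Drug binding

All binding edges share one association rate constant $k_{on}$
(per µM per s); unbinding is $k_{on} K_R$ from `CB` and $k_{on} K_I$
from `IFB` and `ISB`. Gating among bound states mirrors the free states,
with the closed/inactivated equilibrium multiplied by $K_R/K_I$ — the
thermodynamic statement that the drug stabilises inactivation by exactly
the ratio of its state affinities. The scaling is split symmetrically
(`sqrt(K_R/K_I)` on each rate). Every cycle of the resulting graph
satisfies microscopic reversibility; the test suite checks the
`C → CB → IFB → IF → C` cycle product and the bound/free equilibrium
ratio numerically at voltages on both sides of the rate cap.

Two consequences used as oracles throughout the tests:

* at equilibrium the apparent IC50 at availability $h$ is
  $1/(h/K_R + (1-h)/K_I)$ (`equilibrium_apparent_ic50()`), and simulated
  long-equilibration block matches it to well under 2% absolute;
* the slowest non-zero eigenvalue of the generator at a fixed holding
  potential is the drug-equilibration relaxation rate, which the
  block-kinetics analysis (`Tau_Observed`) recovers.

## Default calibration

| parameter | default | rationale |
|---|---|---|
| `act_v_half`, `act_slope` | −32 mV, 7 mV | places the IV peak at −25 mV on the 5 mV grid |
| `r_act` | 1.6 /ms | fast activation; slow enough that subthreshold open-state flux barely distorts the SSI curve (fitted vehicle midpoint within ~2.5 mV of −80) |
| `k_oi` | 1.6 /ms | open-state decay constant ≈ 0.6 ms at −25 mV, inside the 0.5–1 ms band typical of fast Nav inactivation |
| `ssi_v_half`, `ssi_slope` | −80 mV, 8 mV | vehicle inactivation at −100 mV ≈ 7.6%, inside the 5–10% band |
| `r_ssi` | 0.06 /ms | fast-inactivation recovery τ ≈ 1.4 ms at −120 mV |
| `k_fs`, `k_sf` | 1e−4, 5e−4 /ms | slow inactivation entry τ 10 s, exit τ 2 s; see limitations |
| `K_R`, `K_I`, `k_on` | 108 µM, 3.6 µM, 0.002 (µM·s)⁻¹ | 30-fold inactivated-state preference; block equilibration τ ≈ 15 s at 30 µM, i.e. tens of seconds as observed for slow hydrophobic blockers |
| `g_max`, `C_m`, `E_Na` | 50 nS, 15 pF, +68 mV | nA-scale currents ~100 pA/pF; Nernst potential of 145/10 mM Na⁺ at 22 °C |
| noise, rundown | σ = 5%, 1%/min | multiplicative peak noise and compound-independent decay, so vehicle normalisation has something real to remove |

The slow-inactivation ratio $k_{fs}/k_{sf} = 0.2$ keeps the equilibrium
slow-inactivated pool small. This is a deliberate trade-off: the
four-state analysis feeds on the *measured 500 ms SSI curve* as its
availability source, and a large equilibrium IS pool would make the true
availability during long holding periods deviate substantially from that
curve, degrading the very identity the analysis relies on. The cost is
that slow-inactivation availability curves saturate around 15–17%
depth — shallower than real Nav1.7 — while still shifting with prepulse
duration and hyperpolarising strongly under drug.

# Protocols

Six protocol kinds are built declaratively (`build_protocol()`), each an
ordered list of contiguous piecewise-constant segments with exactly one
`test` segment per sweep. Defaults follow standard practice: activation
and SSI step from −120 to +25 mV in 5 mV increments (500 ms steps /
prepulses), slow SSI uses 1/3/5/10 s prepulses with a 100 ms recovery
step, recovery uses 20/500/5000 ms conditioning with a log-spaced
interval ladder (1 ms – 10 s), the use-dependence protocol runs
4 × 180 × 20 ms pulses to 0 mV at 1 Hz from holding potentials −110 to
−80 mV with a 10 s reset to −120 mV between intervals, and the kinetics
protocol pulses once per 5 s for 3 min.

Three timing parameters were genuinely open and are worth recording:

* **Interval equilibration (200 ms).** Each use-dependence interval
  opens with a 200 ms hold at the new potential before pulse 1. This is
  more than ten gating time constants (so the vehicle train starts from
  the proper availability) but under 5% of a drug-binding time constant
  (so the first pulse remains essentially tonic-block-free, which is the
  defining observation of the protocol). Both a zero-length and a
  many-second equilibration break one or the other property.
* **Activation inter-sweep holding (150 ms).** With the slow binding
  kinetics above, drug bound during a 500 ms step unbinds substantially
  during a long rest at −120 mV (effective off-rate ~0.18 /s). A fast IV
  — 0.65 s sweep-to-sweep, as plate-based instruments run it — retains
  the use-dependent component and yields the ~50% maximal-conductance
  reduction at 30 µM that a slow IV cannot. Vehicle gating recovers
  completely within 150 ms at −120 mV, so the vehicle IV is unaffected.
  All other protocols keep a 5 s inter-sweep interval.
* **Kinetics sampling (one pulse / 5 s).** Sparse sampling keeps the
  pulses themselves from contributing use-dependent block to the
  equilibration estimate.

# The synthetic-data generator

`generate_dataset()` separates the deterministic model response (run
once per protocol × concentration) from the observation model applied
per cell: a log-normal conductance scale (CV 25%), Gaussian capacitance
(CV 15%), multiplicative Gaussian peak noise (σ 5%), per-cell rundown
rate drawn around 1%/min, and log-normal seal attributes (membrane
resistance around 900 MΩ, series resistance around 4.5 MΩ) that make the
strict QC filters (>500 MΩ, <10 MΩ, >500 pA) genuinely reject a
realistic fraction of cells. Every cell carries exactly one
concentration. Per-cell seeds derive from the master seed and the
(concentration, replicate) indices, so enlarging a design never perturbs
existing cells.

What the generator does **not** emulate: series-resistance and leak
artefacts, liquid-junction offsets, temperature effects, stochastic
single-channel noise, cell-to-cell gating variability, and trace-level
noise (noise enters at the peak level only). Passing tests therefore
demonstrate correctness of the analysis logic under a faithful
modulated-receptor world with realistic measurement noise — not
robustness to every failure mode of real recordings.

# Analysis design decisions

* **Availability source.** The four-state fit uses the Boltzmann fitted
  to the *vehicle* 500 ms SSI data of the same run (config-switchable to
  the closed-form default curve). Using the measured curve keeps the
  estimator self-consistent: small systematic deviations of the
  simulated SSI from the nominal Boltzmann (subthreshold open-state
  flux) enter both the data and the availability model and largely
  cancel.
* **Weighting of the four-state fit.** Fitted IC50s are log-normally
  distributed and span more than a decade between −110 and −80 mV. An
  unweighted least-squares fit of $1/IC50$ is dominated by the most
  depolarised point — which carries the *least* information about
  $K_R$ — and is both biased and unstable for the fold preference.
  The default therefore minimises relative misfit (weight $IC50^2$ on
  the $1/IC50$ scale); `weights = "absolute"` reproduces the unweighted
  fit. Non-negativity is enforced by closed-form boundary refits.
* **Equilibrium response.** The "last pulse" of each interval is taken
  as the mean of the final three pulses (the block time course is flat
  there), matching the convention of measuring fractional inhibition as
  the mean of the last points of an equilibrated time course; the first
  pulse is pulse 1 exactly.
* **Hill slope handling.** Free slope by default; the slope is fixed to
  1 when the free fit leaves it undetermined (relative standard error
  above 50%) or when only two concentrations are available. Curves whose
  maximal pooled inhibition is below 5% are flagged "no inhibition"
  rather than fitted, and such voltages are excluded from the four-state
  fit by default (a censored mode enters them at the highest tested
  concentration instead).
* **Open-state τ window.** The mono-exponential is fitted from the point
  where the current has decayed to half its peak: near the extremum the
  residual activation eigenmode cancels part of the inactivation
  relaxation and inflates the apparent τ. With this window the fitted τ
  agrees with the slow eigenvalue of the C/O/IF subsystem to a few
  percent.
* **Boltzmann floor.** Slow-inactivation availability saturates above
  zero, so SSI fits at prepulse durations beyond 500 ms free the lower
  asymptote; the classical two-state form (floor 0) is kept everywhere
  else.
* **QC boundary convention.** Strict inequalities: a cell exactly at a
  threshold is excluded.

# Numerical choices

Propagation through a constant-voltage segment is the exact matrix
exponential; the protocol runner uses a cached eigendecomposition per
(voltage, concentration) with a `Matrix::expm()` fallback if the
eigenvector matrix is ill-conditioned. Peaks are located on a grid that
is dense (0.05 ms) over the first 12 ms of a test segment and sparse
beyond, after a 0.5 ms capacitive blanking window. All fitters are
bounded Levenberg–Marquardt least squares started from fixed grids
(deterministic; ties broken by the lexicographically smallest parameter
vector), with standard errors from the Jacobian at the optimum.
Occupancy conservation is monitored, not enforced: a full protocol run
conserves probability to better than 1e−8 without renormalisation.

# Known limitations

* The two-parameter modulated-receptor model cannot reproduce *zero*
  first-pulse inhibition at every holding potential once concentrations
  approach the resting-state IC50: the inter-interval reset at −120 mV
  cannot unbind below the −120 mV equilibrium block. First-pulse
  tonic-block freedom holds exactly for the first interval and at
  moderate concentrations.
* The vehicle pulse train at depolarised holdings sags by a few percent
  over 180 s as the slow-inactivated pool settles; vehicle normalisation
  removes this common-mode drift downstream.
* Fast-SSI shifts under drug are kinetically limited in this protocol
  (a 500 ms prepulse binds little drug), so they are small though
  correctly ordered; the slow-SSI protocols show the large
  concentration-dependent hyperpolarisation.
* $K_R$ is intrinsically ill-conditioned from four voltages: its
  confidence region is wide even with the relative weighting, which is
  why the headline stochastic check targets the fold preference at ±30%.

# Problem sizes used in the tests

The test suite runs the full default experiment once (6 concentrations ×
8 cells + vehicle, 4 × 180 pulses, 5% noise, seed 1234) for the
end-to-end recovery check, and uses reduced pulse counts (12–60) and
cell counts (1–8) for the property and unit tests; the Hill noise-
robustness property uses 200 seeded repetitions at 8 replicates per
concentration. These sizes were chosen so the entire suite exercises
every stage in a few minutes on one CPU.
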