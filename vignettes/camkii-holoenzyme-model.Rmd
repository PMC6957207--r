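---
title: "A rule-based multi-state model of the CaMKII holoenzyme"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A rule-based multi-state model of the CaMKII holoenzyme}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camkiisim)
```

## The model

Ca^2+^/calmodulin-dependent protein kinase II (CaMKII) is a dodecameric
holoenzyme — two stacked hexamer rings of catalytic subunits — central to
synaptic plasticity. Each subunit can independently dock against the
central hub, open into a catalytically active conformation, bind
calmodulin (CaM) in two steps, autophosphorylate its ring neighbor at
Thr-286, phosphorylate itself at Thr-306, and bind protein phosphatase
(PP). Enumerated naively this gives 72 states per subunit (33 after
structural constraints) and an astronomically large holoenzyme state
space, which rules out explicit reaction networks. `camkiisim` instead
represents each subunit as five flags and advances the system by guarded
*rules* — the approach used by particle-based simulators such as MCell,
StochSim and NFsim — in a well-mixed compartment of 0.0328 fL.

The five flags and their transitions:

| flag | states | transitions (rate) |
|---|---|---|
| docking | docked / undocked | undock 0.63 s^-1^; dock 35 s^-1^ (requires CaM-unbound, uThr-306) |
| conformation | inactive / active | activate 2×10^4^ s^-1^ (unconditional); inactivate 10^7^ s^-1^ (requires not fully CaM-bound, not pThr-286) |
| CaM | unbound / initial / full | bind 10^8^ M^-1^s^-1^ (undocked, uThr-306); release 590 s^-1^; compact 350 s^-1^ (requires active); de-compact 4×10^-3^ s^-1^ |
| Thr-286 | uT286 / pT286 / PP-bound | autophosphorylation 1 s^-1^ per active+undocked kinase neighbor (substrate also active+undocked); PP on 3×10^6^ M^-1^s^-1^; PP off 0.5 s^-1^; catalysis 2 s^-1^ |
| Thr-306 | uT306 / pT306 | 0.02 s^-1^ (active, CaM-unbound); irreversible |

Two structural couplings drive the biology. First, the conformational
flicker: an unstimulated subunit is active only
$p_\mathrm{act} = k_\mathrm{act}/(k_\mathrm{act}+k_\mathrm{inact}) \approx 0.002$
of the time, so every "active"-gated step is rare until the subunit is
*stabilised* by full CaM binding or pThr-286. Second, in the default
**exclusive** variant, bound CaM and bound PP sterically exclude one
another on the regulatory domain, so CaM occupancy protects pThr-286
from dephosphorylation — the mechanism the model exists to probe. The
**non-exclusive** variant differs in exactly two guard clauses
(`serialize_rules()` diffs them), nothing else.

### Docking rates: the reading we adopted

The source literature for the docking flag is ambiguous: the same
paragraph assigns 35 s^-1^ to "the docked-to-undocked transition" and
then calls 0.63 s^-1^ the undocking rate. We adopt the only reading
consistent with the stated derivation of the docking equilibrium
constant: K~docking~ = 1.8×10^6^/10^8^ = 0.018 is the *undocked* fraction,
so docking (undocked→docked) proceeds at 35 s^-1^, undocking at
0.63 s^-1^, and the effective CaM association rate of a holoenzyme
subunit is 10^8^ × 0.018 ≈ 1.8×10^6^ M^-1^s^-1^ — exactly the published
full-length-CaMKII measurement that the two-step docking model is built
to explain. The CME oracle pins the resulting stationary undocked
fraction at 0.0177. The opposite reading (subunits mostly undocked)
would make the effective CaM on-rate equal the peptide value and destroy
that rationale.

This choice has a large quantitative consequence, discussed under
*Known limitations* below.

## Engines

Three interchangeable schemes advance the same rule system
(`engine_config(scheme = ...)`):

* **`ssa`** — exact stochastic simulation (Gillespie direct method).
  Stimulus edges and timed events are hard barriers the clock never
  jumps across. Exact, but it resolves every 10^7^ s^-1^ conformational
  flicker event, which costs roughly 5×10^5^ events per subunit-second.
* **`qssa`** (default) — the flicker of *unstabilised* subunits is
  marginalised: every rule gated on "active" carries a factor
  p~act~ ≈ 0.002 per unstabilised gated participant (the
  autophosphorylation rule can carry it twice — substrate and kinase);
  stabilised subunits carry factor 1. The reported active count is the
  expected value `#stabilised + p_act × #unstabilised`. The reduction is
  justified by the ≥10^3^ separation between the flicker and every
  other rate; the test suite verifies QSSA against exact SSA at 3-SE
  tolerance.
* **`fixed_step`** — the MCell-like per-step Bernoulli scheme: each
  eligible rule instance fires independently with
  $p = 1-e^{-a\,\Delta t}$ per step, conflicting firings on one subunit
  are resolved by a uniformly random winner. The engine refuses any
  configuration with p > 0.1 (with the flicker active that means
  Δt ≤ ~10^-8^ s; the historical 10^-7^ s step would put the
  inactivation probability at 0.63 per step, a discretisation we decline
  to reproduce). Because the per-step probabilities are constant between
  state changes, the number of silent steps is geometric and is sampled
  in closed form — the scheme is distributionally identical to stepping
  one Δt at a time but costs O(events), which is what makes Δt = 10^-8^
  runs affordable.

Replicate r of an ensemble always runs with seed `base_seed + r - 1`,
so every ensemble is bit-reproducible from its configuration
(`run_replicates()`, `simulate_camkii()`).

Bimolecular constants are converted to per-pair hazards as
$k_{on}/(N_A V)$; with the default volume, 22.8 µM CaM is 450 discrete
molecules, 0.86 µM PP is 17, and 1.52 µM CaMKII is 30 holoenzymes (360
subunits, 18.24 µM).

## Stimulus

Free CaM is driven between apo-CaM and fully saturated CaM4 by a pair of
square-wave forcing functions standing in for Ca^2+^ flux. The nominal
conversion rate (10^8^ s^-1^) exceeds every other rate by ≥10^5^, so by
default the conversion is applied deterministically in batch at phase
edges (`stochastic_forcing = TRUE` samples it instead; the difference is
unobservable at the recording resolution). Protocols: continuous bolus,
finite bolus, and pulse trains with onsets at t = k/f (first pulse at
t = 0 — the published iteration indexing is ambiguous, and onset-at-zero
makes different frequencies directly comparable) and a default 10 ms
width. Subunit-bound CaM is never touched by the forcing; a CaM released
during an inactivating phase joins the apo pool.

Timed events: `kinase_inhibitor` (saturating K252a, modelled as an
instantaneous flag on all subunits because the published experiment uses
a dose chosen to bind every subunit and never reports an on-rate; it
blocks both the substrate and — by default — the kinase role, a
distinction invisible at saturation), `phosphatase_inhibitor` (sets the
PP catalytic rate to zero while deliberately preserving PP binding
dynamics), and `chelate_Ca` (9-state model only).

## Variants

* `exclusivity`: exclusive vs non-exclusive CaM/PP binding (above).
* `dof`: autophosphorylation degrees of freedom. Within a ring with
  positions 0-5 ordered counter-clockwise, the kinase of substrate *i*
  is (i+1) mod 6 (DOF 1); DOF 2 adds (i-1) mod 6; DOF 3 adds the
  directly apposed subunit of the other ring, both directions. The
  direction convention is fixed but arbitrary by symmetry.
* the **9-state-1-step** CaM model: docking and activation flags are
  removed ("active" ≡ CaM-bound), CaM carries explicit per-lobe Ca^2+^
  occupancy (3×3 states), each state binds CaMKII in one step with
  state-specific kinetics, and CaM *trapping* multiplies the affinity
  for pThr-286 subunits by 1000 — implemented as a koff division,
  because the published constraint is an affinity change and
  trapping-literature kinetics attribute it to slowed dissociation.
  Ca^2+^ may bind and unbind CaM while CaM is subunit-bound; this is
  what lets apo-CaM remain bound (and keep excluding PP) after
  chelation. Trapping is applied to all CaM states by default
  (`trap_sub_saturated`); the effect of trapping on sub-saturated states
  is an open experimental question, so a toggle is provided. The
  shipped rate file anchors the printed affinities (apo-CaM K~D~
  1.45 mM, CaM~2C~ 7.4 µM, trapped apo-CaM 1.45 µM, PP1 0.166 µM);
  the per-lobe Ca^2+^ kinetics are synthetic placeholders tagged with
  the literature source they should be transcribed from. Thr-306 is
  carried but has no transition rule here: its guard (active while
  CaM-unbound) is unsatisfiable when activation is CaM binding.

## Observables

`count_flags()` takes an exact census (pT286 excludes PP-bound subunits
by default — the flag is read literally; a toggle includes them).
`ensemble_stats()` gives pointwise means with SEM = SD/√N.
`fit_decay_constant()` fits ln(trace) vs time by least squares on a
window, [5, 120] s by default — the published decay constants
(−0.0004 "stable" vs −0.006 "fast") come with no stated procedure or
units, so this convention is documented and configurable; it reproduces
the intended qualitative contrast (−0.0004 ≈ 5% loss over 120 s, −0.006
≈ 50% loss over 100 s). `frequency_response()` is an ordinary
least-squares endpoint fit (endpoints read at t = 20 s). Consecutive
pT286 runs (`pT286_run_lengths()`) are maximal cyclic runs per hexamer
ring, with PP-bound subunits counting as phosphorylated.

## The oracle

`derive_parameters()` recomputes every derived constant from its primary
measurements (K~docking~ = 0.018, k~undock~ = 0.63 s^-1^,
k~off~ = 590 s^-1^, occupancy ratio 1.1×10^-5^, K~M~ = 8.3×10^-7^ M,
p~act~ ≈ 0.002) independently of the rate table; the tests assert the
two never drift apart.

`enumerate_cme()` builds the exact chemical master equation of a 1-3
subunit instance by breadth-first reachability from the R rule table —
the guards and effects themselves, not the C++ engine — with the free
pools part of the global state, so the oracle also validates the
per-pair propensity convention. Transients are integrated with `lsoda`
(analytic Jacobian, atol 10^-12^); stationary distributions solve
Q^T^p = 0 with the normalisation row substituted. The engines are
validated against the oracle at 3-SE tolerance on a 1-subunit all-flags
instance (full rates) and a 2-subunit kinase→substrate chain. For the
chain, the flicker rates are scaled down 1000-fold *at constant
p~act~* — the stiffness is a cost, not a behavior, and the reduction
leaves every marginal the oracle checks unchanged while making both
routes affordable.

## Problem sizes

The shipped presets mirror the published protocols (30 holoenzymes,
450 CaM, 17 PP; 20 s or 120 s; pulse frequencies 1-50 Hz). The package
runs its validation and acceptance ensembles at 5 replicates on the QSSA
engine — about 2-6 s per 20-120 s replicate at full size — rather than
the 50 replicates × 0.1 µs fixed-step of the original spatial runs; SEM
bands in the tests are computed from the actual replicate count. Exact
SSA is used for validation windows (small systems or sub-second spans);
the 9-state simulator is plain R and is intended for desk-scale
instances (tens of CaM, hundreds of Ca^2+^) — the Ca^2+^–CaM lobe
flicker makes the full 2000-Ca^2+^ preset impractical without a
compiled path, which we have not needed for any validated quantity.

## Known limitations

* **Well-mixed.** The original model is spatial-stochastic; it was run
  with a deliberately fast diffusion constant so that spatial effects
  would not confound the kinetics, which is exactly the regime in which
  mass-action-per-volume propensities are the effective model. Spatial
  localisation, realistic spine geometries and diffusion-limited
  rebinding are out of scope.
* **Quantitative tension in the validation targets.** Under the literal
  rate table the loading pathway into the fully-CaM-bound state has an
  effective per-subunit rate of
  $k_\mathrm{full} \approx k_\mathrm{compact}\, p_\mathrm{act}\, \pi_\mathrm{initial} \approx 350 \times 0.002 \times 0.064 \approx 0.045\ \mathrm{s^{-1}}$
  under a saturating bolus (π~initial~ is the stationary share of the
  docked↔undocked↔initially-bound chain). That caps bolus
  autophosphorylation at t = 20 s near 20-30% of subunits — the package
  computes ~21% — whereas the published benchmark for the same protocol
  is >80%. The published endpoints are not mutually consistent either:
  the same study reports a near-linear frequency response passing ~5%
  pThr-286 at 10 Hz (10 ms pulses, 1% duty), which extrapolates to
  far below 80% at duty 1. We chose to keep the rule table and rates
  literal rather than recalibrate any constant toward one endpoint at
  the expense of the others; the acceptance suite states each published
  number as-is and reports honestly which ones this faithful
  re-derivation reproduces (the mechanistic contrasts — exclusivity
  ordering, inhibitor responses, monotone frequency dependence) and
  which it does not (the absolute magnitudes that depend on the loading
  rate).
* **Thr-305, subunit exchange, actin binding** and inter-holoenzyme
  interactions are not modelled; pThr-306 has no reverse transition.
* The 9-state Ca^2+^ lobe kinetics ship as labelled synthetic
  placeholders (anchored affinities are exact); transcribing the full
  measured set is a data-entry task the file format supports.

## A worked example

```{r example, eval = FALSE}
ens <- simulate_camkii(
  n_holo = 30, n_CaM = 450, n_PP = 17,
  engine = engine_config(scheme = "qssa", t_end = 20, seed = 1,
                         n_replicates = 5),
  protocol = stimulus_protocol("continuous_bolus"))
st <- ensemble_stats(ens, "pT286")
tail(st, 1)                      # endpoint mean and SEM (counts of 360)
peak_uM <- max(st$mean) / (AVOGADRO * DEFAULT_VOLUME) * 1e6
```

The full experiment presets (`available_presets()`) reproduce each
published protocol; `run_experiment("fig6_exclusivity", seed = 1)`
writes trajectories, summaries, a config echo and a log into a
self-describing run directory.
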