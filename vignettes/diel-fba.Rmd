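---
title: "Modelling diel phototroph metabolism with linked time point models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling diel phototroph metabolism with linked time point models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dielfba)
```

## The model

Conventional flux balance analysis (FBA) treats metabolism as a single
steady state and so averages away everything a phototroph does over a day:
fixing carbon and banking storage compounds while the light lasts, then
respiring those reserves through the night. `dielfba` resolves the diel
cycle by replicating a base genome-scale model into K *time point models*
(TPMs), each a pseudo-steady-state snapshot of one interval (2 h by
default), and linking them with irreversible **transfer reactions**: one per
eligible metabolite per boundary k → k+1, moving that metabolite's surplus
forward in time. Consumption in a TPM can therefore never exceed what the
TPM itself produces plus what earlier TPMs handed over — metabolite
inventories cannot go negative. A closing transfer from TPM K back to TPM 1
(on by default) makes the cycle periodic: the state the last TPM hands over
is the state the first one starts from.

Within each TPM the usual FBA constraints hold: S v = 0 for every
metabolite instance, bounds on every reaction instance. Light is modelled
by phase bounds — CO2 and photon uptake are capped (1.1 and 60
mmol gDW⁻¹ hr⁻¹ by default) in the first `n_light` TPMs and shut to zero in
the dark, while a basal ATP maintenance demand (10 mmol gDW⁻¹ hr⁻¹) applies
in every TPM. A single biomass drain, active only in the configured TPM
(the last dark one by default), collects precursors in fixed proportions;
the precursors themselves may be produced in any TPM and ride the transfer
chain to the drain.

Because every metabolite travels forward around a ring, transfer reactions
could cycle material indefinitely. The solve cascade removes this freedom
in three stages:

1. **Biomass maximisation** — a single LP (MILP with diazotrophy, below).
2. **Transfer-minimising pFBA** — with biomass pinned to its maximum by an
   equality, minimise the summed flux of all transfer reactions, yielding
   the transfer budget *f*. This both breaks cycles and makes the transfer
   fluxes interpretable as minimal accumulation/consumption inventories.
3. **Flux variability analysis (FVA)** — per reaction instance, minimise
   and maximise its flux with biomass still pinned and total transfer flow
   capped at *f*, giving the envelope of alternative optima.

### Pigment coupling

Photosynthetic flux is only available where photosynthetic machinery
exists. The pigment (chlorophyll) stock available in TPM k is estimated
from its transfer fluxes: the average pigment present is half the
difference between what leaves for k+1 and what arrived from k−1.
Each configured photosynthesis reaction instance obeys

v_photo,k ≤ ½ · M_C · (v_pigment,k→k+1 − v_pigment,k−1→k),

with M_C = 1000, a constant large enough that the constraint only gates
photosynthesis on pigment accumulation rather than stoichiometrically
limiting it. One subtlety is forced by the algebra rather than chosen: the
k−1 term must be **absent at TPM 1**. Since photosynthesis fluxes are
non-negative, each coupling row requires its transfer difference to be
non-negative, and around a closed ring those differences telescope to
exactly zero — a fully cyclic k−1 term would therefore pin every
photosynthesis flux to zero. Treating TPM 1 as the cycle start (the
transfer is a *cumulative* inventory, restarting each dawn) keeps the
constraint meaningful; the wrap-around transfer still exists for mass
balance. In acyclic (debug) mode the last TPM has no outgoing boundary and
hence no coupling row.

### Transcriptome-derived bounds

Time-resolved expression enters through the E-flux "valve" scheme. Per
gene, each TPM's value is divided by that gene's maximum over the cycle —
a deliberately linear max-normalisation, with no sigmoid or other
nonlinear transform. Gene ratios fold into one ratio per reaction through
its gene–protein–reaction rule: isozymes (`or`) contribute the largest
ratio, complex subunits (`and`) the smallest. The scaled upper bound of a
core instance is `min(current_ub, base_ub · a_jk)`: the *base-model* bound
is what gets scaled, while the `min` keeps structural constraints (dark
shutoffs, biomass placement) intact under a ratio of 1. Lower bounds are
left unscaled, exactly as the constraint is written as an upper-bound
inequality; a `scale_reversible` switch applies symmetric |LB| scaling
(classic E-flux) for sensitivity analysis, since the source formulation is
silent on reversible reactions. Reactions with no rule, and genes absent
from the table, default to a ratio of 1; transfer reactions, exchanges, and
the biomass drain are never scaled.

For the scaling to mean anything the unscaled bounds must be finite
capacities, not the ±10,000 "effectively unbounded" sentinel.
`capacity_bounds()` reproduces the canonical derivation: FVA of the
*unsegmented* lights-on base model under the configured uptake and
maintenance bounds gives each reaction's largest feasible flux range, and
the attained maximum becomes its capacity. Lower bounds are relaxed to
`min(fva_min, 0)` so no reaction is ever forced on, and exchanges and the
biomass drain are exempt (the diel optimum pools production across phases
and may legitimately exceed any single-phase biomass maximum). Capacity
bounds are always derived from the wild-type model; deriving them from an
already-crippled mutant (say, with its nitrogen source closed) would bake
the lesion into every capacity.

### Diazotrophy

Nitrogenase is irreversibly inhibited by oxygen, so an engineered
nitrogen-fixing phototroph must keep fixation away from oxygen in time.
The extension adds the fixation reaction (16 ATP and 8 reducing
equivalents per N2) plus its exchange and diffusion-transport chain to
every TPM, and imposes per-TPM mutual exclusion with binary indicators:

- LB·y ≤ v ≤ UB·y for the fixation instance and for the O2 transfer
  k → k+1 (each reaction's own bounds serve as big-M values, keeping the
  relaxation tight);
- y_n2,k + y_o2,k ≤ 1.

Only the inter-TPM O2 *carry-over* is gated — an O2 molecule exported to
the environment within the TPM never meets nitrogenase — the extracellular
O2 exchange is deliberately not restricted. After the MILP finds the
optimal fixation schedule, the binaries are frozen at the incumbent and the
pFBA/FVA stages re-run as plain LPs (a flag allows FVA over free binaries
for sensitivity checks, at considerable cost). Strain comparison classifies
each reaction instance from the two FVA envelopes alone: `upregulated` /
`downregulated` when the ranges fail to overlap beyond the tolerance,
`switched` when both ranges exclude zero with opposite signs, `essential`
when a range is strictly positive or strictly negative; unique-reaction
counts deduplicate by base reaction across TPMs.

### Downstream analyses

- **Active bounds**: an instance whose FVA maximum sits at its
  expression-scaled bound (within τ·max(1, |bound|)) *and* whose ratio is
  below 1 is a constraint that limits the optimum. Structural zeros (dark
  uptakes, displaced biomass instances) are explicitly not counted.
- **Flux control coefficients**: each constricted bound x is tightened by
  1% and biomass re-maximised; C = (Δv/Δx)·(x/v) from the finite
  difference. Tightening (rather than relaxing) is the default direction
  because tightening a binding constraint is guaranteed to probe it.
  Slack bounds give exactly 0; infeasible perturbations give `NA`
  (undefined), never 0.
- **Metabolite–metabolite correlation**: per-TPM maximum FVA transfer
  fluxes, normalised per metabolite by the cycle maximum, serve as level
  proxies. Pairwise Spearman coefficients use the explicit rank-product
  formula with mid-ranks for ties; two-sided p-values use the t
  approximation at all n (the field-standard large-sample form; at the
  default 12 TPMs the approximation error is far below the 0.05 decision
  threshold). Insignificant pairs are retained but flagged. No
  multiple-testing correction by default, with Benjamini–Hochberg behind a
  flag.
- **Category aggregation / normalised profiles**: transfer envelopes are
  summed per annotation category and TPM (unannotated metabolites fall
  into `unclassified`; declared-but-empty categories appear as all-zero
  profiles so the partition always conserves the total), and per-TPM series
  are normalised by their cycle maximum.

## Numerical choices

- All LPs and MILPs are solved by HiGHS through `scipy.optimize.milp`,
  invoked as a batched subprocess (`inst/python/highs_backend.py`); an FVA
  run, all noise replicates' first stages, or all FCC perturbations travel
  as one process call. JSON carries the sparse triplets; magnitudes ≥ 1e30
  encode unbounded.
- Zero-flux tolerance τ = 1e-6 mmol gDW⁻¹ hr⁻¹ everywhere a flux is
  classified (loop detection, essentiality, overlap, active bounds, FCC).
- The biomass fix in stages 2–3 is an exact equality; if the solver
  reports infeasibility on numerical grounds the fix is retried once with
  a 1e-6 relative slack and a warning.
- The transfer cap is `≤ f` exactly, with f carried at full solver
  precision. FVA results are contractually independent of target order.
- Photons and protons are excluded from transfer *structurally* (no
  transfer reactions exist for them), not by zero bounds: a proton
  gradient carried across TPMs would be an untenable energy store.
- Noise robustness adds per-gene Gaussian noise (SD equal to the SD of
  that gene's normalised series) in *normalised-ratio space*, clamped to
  [0, 1] — the constraint consumes ratios, so that is the space in which
  "one standard deviation" is well defined. Metabolite–boundary pairs with
  baseline transfer below τ are excluded from the relative-deviation mean
  (the exclusion count is reported) and infeasible replicates are recorded
  and dropped rather than averaged as zeros.

## What the toy fixtures emulate — and what they do not

`make_toy_gsm()` builds a ~19-reaction phototroph: photon/CO2/O2/ammonia
exchanges, a pigment-gated linear electron chain (NADPH + O2) and cyclic
photophosphorylation (ATP), carbon fixation at the canonical 18 ATP +
12 NADPH per hexose, respiration at 30 ATP per hexose, a glycogen-analogue
storage polymer worth six hexose units, ATP maintenance, and a biomass
drain over hexose, pigment, ammonia, and ATP. Integer stoichiometry keeps
oracle LPs exact; a carbon-count audit over the stoichiometry passes by
construction. Two features are deliberate: storage is six-fold cheaper to
transfer than free hexose, so the parsimony objective *must* route
overnight carbon through the storage pool (the accumulate-then-drain shape
is a forced, assertable outcome); and the reversible CO2 transporter
replaces an uptake/export pair that would otherwise form a
thermodynamically infeasible two-reaction cycle. Synthetic expression
series are sinusoids on a baseline, phased to peak mid-light or mid-dark,
discretised to TPMs.

What passing tests on these fixtures show is that the *machinery* is
correct: the cascade equals an independently assembled dense-matrix LP, the
MILP equals exhaustive enumeration, scaling and statistics match oracles.
What they cannot show is biological fidelity at genome scale: the toy has
no thylakoid/periplasm compartmentalisation, no photorespiration or
photodamage, one pigment species, a single aggregate biomass equation, and
its growth rate (≈0.37 hr⁻¹, carbon-limited with full CO2 recycling) is not
that of a real cyanobacterium. Conclusions about a real organism require a
real reconstruction read through `read_sbml()`.

## Problem sizes and defaults used in the shipped analyses

The test suite exercises K = 4–6 fixtures (≤ 30 base reactions, ≤ 360
variables) so each LP solves in milliseconds and the whole suite stays
interactive; the acceptance script runs the full standard instance — K = 12,
6 light TPMs, bounds 1.1/60/10, M_C = 1000, biomass in TPM 12, capacity
bounds from the wild-type lights-on model, 10 noise replicates — which the
package treats as its reference configuration. All randomness (expression
fixtures, noise) flows from a single seed argument.

## Known limitations

- No loopless-FBA MILP on the diel model: loop checking is offered on the
  base model (as an FVA with exchanges closed); the transfer-sum
  minimisation is what suppresses inter-TPM cycling.
- TPM durations are uniform; sub-TPM kinetics and time-varying biomass
  composition are out of scope by design.
- The MILP freeze means reported diazotroph FVA envelopes are conditional
  on the incumbent fixation schedule; alternative optimal schedules (if
  any) are not enumerated by default.
- The Python/HiGHS subprocess is a hard runtime dependency; solver
  selection is limited to what scipy ships.
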