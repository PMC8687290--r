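---
title: "Kinetic modelling of the xiamenmycin biosynthetic network: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modelling of the xiamenmycin biosynthetic network: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ximflux)
```

## The model

Xiamenmycin A (XiaA) is a prenylated benzopyran assembled from three
precursors — 4-hydroxybenzoate from the shikimate pathway, geranyl
pyrophosphate from the methylerythritol-phosphate (MEP) pathway, and
L-threonine from the aspartate pathway — all of which draw on central carbon
metabolism of the engineered *Streptomyces lividans* producer. The packaged
model covers glycolysis/gluconeogenesis, the TCA cycle, the pentose
phosphate pathway, serine biosynthesis, the respiratory chain, and the three
precursor pathways: 86 internal metabolites, 82 internal reactions, 3
maintenance pseudo-reactions (ATP, NADH and NADPH turnover) and 19 exchange
pseudo-reactions connecting the network to a buffered external pseudo-species.

Mass balance is expressed through the stoichiometric matrix $S$ (86 × 104):

$$\frac{dx}{dt} = S\,u + b = f(x, V),$$

where $x$ are metabolite concentrations (normalised units; no concentration
data are published for this system, so concentrations are dimensionless
throughout), $u$ the reaction fluxes, and $b$ the boundary terms. Almost all
of $b$ is realised as pseudo-reactions whose fluxes are pinned per feeding
condition; three biomass demands have no pseudo-reaction of their own
(coenzyme A +0.23, ammonium +0.06/+0.1, phosphate +0.19996/+0.2) and enter
as constant supply terms on the metabolite. Without these three terms the
published flux table violates mass balance by exactly those amounts — the
CoA moiety (CoA/acetyl-CoA/succinyl-CoA) is exported at 0.23 per unit time
with nothing returning it — so the supply terms are part of the boundary
specification, not a fitting device.

Two feeding conditions are shipped. Both pin the growth-precursor drains and
maintenance fluxes; the xiamenmycin export is −0.05 (glucose) or −0.07
(glucose plus glycerol). Nutrient uptakes (glucose, and glycerol in the
combined condition) and overflow exports (CO2, acetate) are left free: they
are model outputs.

### Reaction equations and orientation

Reaction equations are parsed strictly left-to-right; the arrow glyph only
sets the `reversible` flag, and net direction lives in the sign of the flux.
This convention is forced by the data: the ATP-synthase row is printed as
`ATP <- ADP + 2 H + Pi` with a negative flux, which balances the proton and
adenylate nodes only under sign-carrying left-to-right stoichiometry.

### The reaction-65 variants

As printed, reaction 65 reads `OAA + NH4 + Succ <-> Asp + Fum` and breaks
mass balance at five nodes (Glu, NH4, Succ, Fum, alpha-ketoglutarate) by
±0.05–0.07 — exactly the flux it carries. The aspartate aminotransferase form
`OAA + Glu <-> Asp + a-KG` restores balance at every node, and is the
default (`corrected_r65`). The printed form is retained (`as_printed`)
because `validate_model()` uses it to demonstrate the transcription audit.
Note that OAA itself balances under both variants (each consumes one OAA),
so it is *not* among the flagged nodes.

## The generic rate law

Every kinetic reaction uses one saturable reversible form,

$$u = \frac{V_F \prod_i A_i/K_i - V_B \prod_j P_j/K_j}
          {f_1 \prod_i (1 + A_i/K_i) + f_2 \prod_j (1 + P_j/K_j)},$$

with one Michaelis-like constant per participant occurrence (a coefficient
of 2 contributes two identical occurrences). The weights are
$f_1 = V_F/(V_F+V_B)$ and $f_2 = V_B/(V_F+V_B)$; they sum to one, and at
$V_B = 0$ the law collapses to irreversible Michaelis–Menten — the two
properties that pin down this orientation. The swapped orientation is
available behind `orientation = "swapped"` for sensitivity analysis.

Parameter choices:

* `K = 1` for every occurrence. No K values are published; with
  concentrations in normalised units of order one, K = 1 places every
  reaction in the responsive part of its saturation curve.
* `VF = VB = 0.4` as initial values for every adaptable velocity, matching
  the published protocol.
* Irreversible glyphs are honoured kinetically: a `->` reaction has
  $V_B = 0$ fixed (and `<-` fixes $V_F = 0$), so it can never run backwards.
  Free uptake reactions see the buffered external species at concentration 1.
* Pinned boundary drains enter as constants, not rate laws.

## Lyapunov-gradient regulation

The stabiliser adapts the maximal velocities by gradient descent on

$$\psi(x, V) = f(x,V)^\top D^{-1} f(x,V), \qquad
  W\,\frac{dV}{dt} = -\nabla_V\, \psi,$$

a diffusion-weighted squared steady-state residual: $\psi \ge 0$ everywhere
and $\psi = 0$ exactly at steady states. The diagonal weights follow the
rule that smaller compounds diffuse faster, $D_m = 1/\max(\text{carbon}_m, 1)$,
so heavy intermediates such as XiaA (21 carbons) are weighted 21× more
strongly than CO2. This $\psi$ arises from the surrogate Lyapunov gradient
$\nabla_x \phi = -D^{-1} f$, which is exact to leading order near a steady
state; the full nonequilibrium potential is not identifiable from the
published material, and `D` is a swappable argument for users who have one.
$\nabla_V \psi = 2 f^\top D^{-1} S\, \partial u/\partial V$ uses the
closed-form derivative of the rate law and is verified against central
finite differences to relative 1e-6 in the test suite.

### Two execution modes

`stabilize()` offers two modes.

**Coupled** (the default): $x$ and $V$ are integrated simultaneously with a
stiff BDF integrator, the direct transcription of the regulation ODE. This
is the mode used for all toy networks, where it converges quickly and the
descent of $\psi$, the recovery of closed-form steady states, and the
negativity of the Jacobian spectrum are all asserted in the tests.

**Quasi-static**: the velocities are regulated at frozen metabolite amounts
by box-constrained quasi-Newton descent of $\psi$ (analytic gradient,
$V \ge V_{\min}$), alternating with metabolite-relaxation windows integrated
with a compiled right-hand side. The adaptive descent step is a
state-dependent positive scalar realisation of the modulation weight
$W(x,V)$, which the formulation leaves open. Because the model has more
adaptable velocities (142) than internal metabolites (86), the frozen-state
minimum of $\psi$ is generically an exact steady state, so the first sweep
does most of the work and the relaxation windows check self-consistency.

On the packaged network the coupled mode is impractical: the early
transient — growth drains of up to 2.5 units against initial capacities of
0.4 — forces step sizes near 0.5 time units through a 1e5-unit horizon, hours
of wall time without reaching threshold. The quasi-static mode converges to
$\max|S u + b| \le 3\times 10^{-6}$ in a few seconds per condition, honours
every pinned drain exactly, and lands on the structurally forced fluxes to
within 2e-6. It is therefore the default for `run_pipeline()` and the mode
used in the package's own end-to-end tests.

### Numerical guards

* **Concentration floor.** During regulation, downhill motion of a
  metabolite tapers smoothly to zero across a layer above `x_floor = 0.01`
  (1% of a typical normalised pool). This matters: with a much smaller
  floor, a drain that transiently exceeds kinetic capacity empties the ATP
  pool, every ATP-dependent rate and *its velocity gradient* vanish
  multiplicatively (including glucose uptake), and the regulation deadlocks
  in a starved state it can no longer sense. A floor two orders below
  typical pool sizes keeps every gradient responsive without influencing
  converged states, which are checked against the un-floored $f$.
* **Velocity clamp.** $V \ge V_{\min} = 10^{-6}$ keeps the rate law defined;
  the approach to the clamp is tapered (C1 smoothstep) so the regulation
  right-hand side stays continuous.
* **Steady-state threshold.** `atol_steady` defaults to 1e-6 on
  $\max|f|$; the full-model pipeline uses 1e-4, the tolerance at which the
  five-decimal rounding of the published drains becomes the dominant error
  source anyway.
* **Simulation clipping.** Plain simulation (`simulate_model()`) clips
  concentrations at zero when the integrator undershoots below `-10 * atol`
  and counts the events.

### Stability reporting

`stability_report()` returns the real parts of the numeric Jacobian
$\partial f/\partial x$ at the final state, after setting aside the
structural zero modes contributed by conserved moieties (NAD/NADH,
adenylates, CoA pool, and so on — 12 in the packaged model). On toy chains
the non-structural spectrum is strictly negative. On the packaged network
the steady state found from unit initial concentrations carries two weakly
non-negative real parts (≈ +0.004): the regulated network satisfies the flux
balance exactly but is not certified asymptotically stable at that
operating point. The report makes this visible rather than hiding it; users
can re-run from other initial states (`x0 = "random"` with a seed) or
supply their own `D`.

## Structural forced fluxes

Independently of all kinetics, pinning the boundary drains determines part
of the flux distribution outright: `forced_fluxes()` computes one solution
of $S u + b = 0$ with the pinned coordinates fixed and classifies each free
flux by whether the nullspace of the free columns vanishes in that
coordinate (absolute tolerance 1e-9 on unit-norm basis vectors). The whole
xiamenmycin backbone is forced: shikimate pathway 0.05/0.07, MEP chain
0.10/0.14, threonine branch 0.05/0.07 under glucose / glucose+glycerol.
Coupled NAD(P)H-isozyme pairs (shikimate dehydrogenase 43/64, HMBPP
reductase 58/63, homoserine dehydrogenase 68/71) are individually free —
they form two-reaction cycles through the transhydrogenase — but their net
conversions are forced, which the returned nullspace makes checkable.
The pinned system's feasibility is accepted up to a least-squares residual
of 1e-4: the five-decimal rounding of the published fluxes leaves genuine
residuals of order 1e-5 along exactly conserved directions such as total
phosphate.

The bridge between the layers — the regulated kinetic solution reproducing
every structurally forced flux — is asserted in the acceptance tests.

## Carbon accounting

Carbon counts ship as an editable fixture column and satisfy
`carbon_balance_report()` exactly for all internal and maintenance
reactions: XiaA carries 21 carbons (7 from 4-hydroxybenzoate + 10 from GPP +
4 from threonine), cofactors their full skeletons (NAD 21, CoA 21, FAD 27),
and zero-carbon species (NH4, Pi, protons) are allowed. Carbon conversion
efficiency is

$$\eta = 100 \cdot \frac{c_{\text{XiaA}} \cdot |u_{\text{export}}|}
  {\sum_s c_s \cdot u_s},$$

with the product flux taken from the export pseudo-reaction (not the
terminal ligase) so exogenous-supply scenarios stay correct. On the
published flux columns this gives 20.5% on glucose and 26.9% on the
combined medium; reported values use round-half-up to integer percent
(27%). The glucose figure is published as "20%", consistent with
truncation rather than rounding; the raw value is always retained. The
published "28.8% on glucose in the combined media" could not be reproduced
under any carbon bookkeeping tried (21 C gives 35.2%) and is excluded.
Production enhancement between conditions is the relative change of the
export magnitude, +40% here, and is scale-invariant.

## Synthetic networks

The generators provide the analytic ground truth the test-suite leans on:

* `make_linear_chain()` — irreversible Michaelis–Menten chain with constant
  input and drain $d$; closed form $x_i^\ast = K_i d/(V_{F,i} - d)$.
* `make_branched_toy()` — one source, two competing drains; the branch split
  is structurally free when only the input is pinned (one-dimensional
  nullspace) and forced when both drains are pinned.
* `make_random_network()` — seeded connected networks with a cofactor couple
  whose stoichiometric rows sum to zero, guaranteeing a conserved moiety and
  a structural zero mode.

These toys emulate saturable enzymatic conversion, conserved cofactor
moieties, and pinned boundary drains. They do not emulate allosteric
regulation, gene expression, thermodynamic constraints, or realistic
genome-scale topology — so a green suite shows the algorithms are correct on
their stated mathematics, not that the biological model captures everything
about the organism.

## Problem sizes and reproducibility

The shipped analyses run the full 86 × 104 network for the structural and
balance layers, full-network quasi-static stabilisation for both
conditions, and toy networks of 2–8 metabolites for every closed-form and
property check; the random-network regression uses twenty 6-metabolite,
8-reaction instances. All randomness (random initial concentrations,
network generation) flows through explicit integer seeds, and a pipeline
run records its configuration, seed and flux hashes in a JSON manifest, so
identical seeds give identical bundles.

## Known limitations

* Free fluxes (glucose uptake, CO2 and acetate overflow) depend on the
  unpublished K values and potential; the package reproduces the forced
  backbone exactly and the free fluxes only approximately (kinetic
  efficiencies 21.1% / 26.2% versus 20.5% / 26.9% from the published
  columns).
* The regulated steady state of the full network is not certified locally
  stable (two weak non-negative modes); see `stability_report()`.
* The Lyapunov potential is a surrogate; users with the true potential can
  pass their own `D`.
* Element balancing covers carbon only; charge, phosphate and nitrogen
  bookkeeping are implicit in the transcription checks but not enforced per
  reaction.
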