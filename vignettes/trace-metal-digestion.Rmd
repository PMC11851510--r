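---
title: "Modelling, calibrating and optimizing trace metals in batch anaerobic digestion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling, calibrating and optimizing trace metals in batch anaerobic digestion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admetal)
```

## The model

`admetal` simulates a lab-scale batch anaerobic digester as a system of 80
ordinary differential equations: 13 microbial biomass pools, 3 hydrolytic
enzymes, 4 particulate and 4 monomeric substrate pools, 4 volatile fatty
acid (VFA) totals, 8 dissolved inorganic pools, the proton concentration,
2 lumped counter-ions, 13 ionic trace-metal totals, 20 mineral precipitates,
5 headspace gas amounts and 3 cumulative gas volumes. An algebraic layer of
54 registered quantities (speciation fractions, pH and temperature factors,
transfer coefficients, partial pressures, flows) is evaluated alongside;
`state_names()` and `algebraic_registry()` enumerate both.

Biochemistry follows the familiar four-stage picture. Hydrolysis of
carbohydrates, proteins and lipids is first order in the corresponding
enzyme, Michaelis–Menten in the particulate substrate, and non-competitively
inhibited by total VFA. Each microbial group grows at

$$\mu_j = \mu_{j,\max}(T)\,\prod_s \frac{c_s}{k_{M}+c_s}\; f_{pH,j}\;
\frac{c_{Nio}}{K_{M,Nio}+c_{Nio}}\;\frac{c_{Pio}}{K_{M,Pio}+c_{Pio}}\;
\prod_i \frac{K_{inh,i}}{K_{inh,i}+c_i},$$

with 16 Monod pairings and 25 growth-inhibition pairings (H2 on the
H2-producing fermenters and acetogens, free H2S on acetogens, methanogens
and sulfate reducers, free NH3 on the acetoclastic methanogens, and ionic
Cu, Zn, Cr, Pb, Ni on butyrate degraders and acetoclastic methanogens). The
pH dependence is the bell-shaped Michaelis function parameterized by
`pK_lo < pK_up`; the temperature dependence is a linear tent
$\max(0, \mu_{\max,T_{opt}} - \alpha\,|T - T_{opt}|)$ with a hard cutoff at
`T_max` — the linear form is forced by the units of $\alpha$
(1/(°C·day)). Decay of group $j$ runs at $b_{dec,j}\,\mu_{j,\max}(T)\,X_j$
(decay prescribed as a fraction of the maximal growth rate) and is recycled
to the particulate pools.

Together these give the 187 calibratable constants, grouped as 13+3 initial
biomass/enzyme concentrations, 13 maximal growth rates, 13 decay fractions,
26 pH parameters, 13 temperature slopes, 13+13 optimal/maximal
temperatures, 3+3 hydrolysis constants, 16 Monod constants, 26 inhibition
constants, 2 nutrient limitation constants, 10 gas-transfer parameters and
20 crystallization rate constants (`default_parameter_bounds()`).

## Trace-metal chemistry

pH comes from a full charge balance over the speciated acid–base systems
(four VFAs, ammonium, carbonate, sulfide, sulfate, phosphate, nitrite), the
thirteen metal cations with their assigned charges, and a lumped
cation/anion pair that closes the balance at the configured initial pH. Two
equivalent realizations are available: `ph_mode = "resolve"` (default)
re-solves the balance by a warm-started Newton iteration at every
right-hand-side evaluation, and `"ode"` integrates the proton concentration
by the chain rule. The dedicated solver `solve_ph()` brackets and polishes
the root to a residual below 1e-12 eq/L. We default to re-solving because
the per-step clipping of negative excursions is invisible to the chain rule
and slowly biases the integrated proton state (about 0.1 pH early in a
batch on the coarse grids used here).

Twenty precipitates (8 carbonates, 6 sulfides, 4 phosphates, struvite and
K-struvite) grow at $k_{cryst}\,(\max(0, \Pi^{1/\nu} - K_{sp}^{1/\nu}))^2$
where $\Pi$ is the ion product ($\nu$ = 2, 2, 5, 3, 3 respectively). Two
deliberate choices:

* **Supersaturation clamp.** The squared driving force is clamped at zero
  below saturation, so nothing precipitates from undersaturated solution
  and precipitates are terminal sinks (no dissolution).
* **Driving species for sulfides.** At digester pH a realistic second
  sulfide dissociation constant leaves almost no free S²⁻, which would make
  the Fe → FeS → H2S-removal pathway numerically inert. The sulfide driving
  force therefore uses the ionized pool HS⁻ + S²⁻ (g S/L); the registry
  option `sulfide_species = "S2"` restores the strict interpretation.

Elemental bookkeeping uses the stoichiometric weights of the rate laws
(3 metal and 2 phosphate units per M₃(PO₄)₂, one unit otherwise, struvite
consuming Mg, NH4-N and PO4-P, K-struvite consuming K, Mg and P), so the
total of each element across its ionic and precipitate pools is a linear
invariant of the ODE system — conserved to machine precision by any
Runge–Kutta method, which the test suite checks at 1e-8 relative over a
60-day reference run.

Concentration scales: inorganic C, N, P and S pools are carried as element
mass (g C/L, g N/L, ...), metals as g metal/L, dissolved CH4/H2 as gas
mass. Solubility products and Henry constants are stated on those scales in
the overridable constants registry (`chem_constants()`); activity
coefficients are unity and ionic-strength corrections are out of scope.

## Gas phase

Five gases (CH4, CO2, H2, H2S, NH3) transfer between liquid and headspace
at $(K_{La,a}T + K_{La,b})(c_{free} - K_H p)$ and the headspace is held at
the configured total pressure: while at pressure, the molar outflow equals
the net molar inflow, split across gases by mole fraction. Because this
makes total moles a linear invariant, the partial pressures sum to
`p_total` to machine precision whenever biogas flows; a projection step
after each accepted step credits any residual excess to the cumulative
volumes exactly. The headspace starts at `p_total`; since only the five
tracked gases exist in the model, the default initial composition is pure
CO2 (a headspace "free" of every tracked gas cannot be at pressure), and
the startup period during which CO2 dissolves into the liquid produces no
outflow, as in a freshly sealed bottle.

## Numerical design

Integration is fixed-step RK4 (default `dt = 0.01` d) or forward Euler,
with tiny negative excursions clipped to zero after each step. Several
model-design constants were chosen once so that the reference (midpoint)
design is well inside the stability region of the explicit integrators and
satisfies the default biogas-quality caps:

* per-gas transfer-coefficient bounds (smaller for CO2, H2S, NH3 than for
  CH4/H2);
* effective Henry constants for H2S (1.0 g S/(L·bar)) and NH3
  (2.0 g N/(L·bar)) — the physical NH3 constant against a 0.1 L headspace
  yields a dissolution feedback rate of order 1e5/day, which no explicit
  scheme can follow at practical step sizes;
* H2 yield fractions of 0.03–0.06% by mass and `kM_H2` bounds of
  0.02–0.2 g/L, giving a hydrogen pool that is produced in traces and
  mostly consumed by hydrogenotrophs.

The fixed stoichiometric yield table (`default_stoichiometry()`) is
ADM1-inspired and closes every reaction to total mass 1 (including an
explicit water term); it is deliberately *not* part of the 187 calibrated
constants and can be overridden. Small availability guards (Monod factors
with K = 1e-3 g/L) keep the hydrogenotrophic methanogens from drawing
inorganic carbon, and the generic sulfate reducers from drawing acetate,
below zero on coarse grids.

## Calibration

The deviation objective is the time integral of the squared normalized
mismatch between simulated and measured methane flow, evaluated by the
trapezoid rule on the measurement grid with the simulation linearly
interpolated onto it. Seven constraints accompany it: an initial-biomass
cap, two arctan-smoothed envelope integrals penalizing flow below
`k_LO`·measured or above `k_UP`·measured, a methane-volume relation, and
three biogas-quality caps (H2, H2S, NH3 fractions). The smoothed step is
$H(x) = 1/2 + \arctan(10kx)/\pi$; the $1/\pi$ factor is needed for the
limits 0/1 and can be switched off for the raw arctan form. For
the methane-volume constraint we use a positive weight by default, so the
constraint caps the overshoot of simulated over measured CH4 volume at
fraction `phi_CH4`; with the published negative-weight convention and a
shortfall fraction in (0,1) the constraint could not be satisfied even by a
perfect fit, so the sign is exposed in the configuration rather than
hard-wired.

Sensitivity screening draws uniform random designs in the normalized unit
cube (5 designs per parameter by default), and scores each parameter by the
max-normalized absolute Pearson correlation between its sampled values and
the deviation functional. The staged active-set calibration then walks a
non-increasing threshold schedule (default {0.2, 0.1, 0.001, 0}): each
stage optimizes the parameters whose importance factor reaches the
threshold, freezing the rest, and warm-starts from the previous optimum, so
the stagewise objective never regresses; the final stage activates all 187
parameters.

The optimizer is a sequential strictly convex separable approximation of
the moving-asymptotes family: forward-difference gradients of the combined
(objective, constraints) evaluator, asymptotes adapted from the oscillation
pattern of the two most recent iterates, a dual solve of each separable
subproblem, move limits per iteration, and a merit-based backtracking
acceptance rule (the step toward the incumbent is halved while the trial
point is not strictly better) that keeps progress monotone in the 60-187
dimensional calibration stages.

**Identifiability caveat.** Several parameter pairs are confounded on a
single fixed-temperature batch flow curve. The transfer coefficients are
exactly confounded: only `KLa_a * T + KLa_b` enters the model, so at one
reactor temperature no amount of flow data can apportion a correction
between the two coordinates. Enzyme levels pair with their hydrolysis
constants (the rate depends on the product), and initial biomass pairs with
the maximal growth rate (a timing shift). In the calibration
self-consistency study (ten globally most important parameters displaced
+20%, noise-free synthetic measurements), the staged schedule reduces the
deviation objective by four orders of magnitude with a non-increasing
stagewise pattern, but the displaced parameters individually return only to
within about 10-14% of truth — the residual spread lives on these
compensation manifolds and is a property of the study design, not of the
optimizer. Point recovery of such coordinates would require data at more
than one temperature or independent measurements of the confounded partner.

## Synthetic measurements and what the tests show

The measured flow series of the three reference bioreactors exist only as
published figures, so the package generates its own study conditions: the
reference reactor (1 L liquid, 0.1 L headspace, 35 °C, pH 8, 1.0059 bar)
with the manure feedstock composition, simulated under known parameters
and sampled daily (the measurement cadence), optionally with multiplicative
mean-one lognormal noise (σ = 0.1 by default, matching the visual scatter
of published series; σ = 0 for the noise-free self-consistency runs). These
synthetic series reproduce the structure of real measurements — daily
cadence, non-negative flows, multiplicative scatter — but not instrument
drift, missing days, or model error (the generator is the model itself), so
passing self-consistency tests demonstrates internal correctness of the
calibration machinery, not fidelity of the model to any real digester.

Problem sizes in the tests and in the acceptance script are the package's
own scaled-down study conditions: a 12-day batch on the Euler dt = 0.025 d
grid for calibration self-consistency (with 3 random designs per parameter
in the screening step and capped per-stage iterations), 10-day batches for
perturbation and dosage studies, and the 60-day reference horizon where
only a single simulation is needed. The vignette-level claims above are all
recomputed by the test suite or the acceptance script; none are quoted
results.

## Dosage optimization

Eleven feedstock metal concentrations (Ca, K, Mg, Na, Fe, Co in g/L; Cr,
Ni, Pb, Cu, Zn in mg/L) form the design space, with lower bounds at 10% of
the initial concentrations (removal limit) and upper bounds representing
supplementation. Three cases: A maximizes the time-integrated biogas
volume; B additionally penalizes cumulative H2S and caps its biogas
fraction; C promotes the time-integrated CH4 volume with H2S penalty and
caps on the H2S, H2 and NH3 fractions. Objective weights default to the
reciprocal initial-design magnitudes, making every term O(1); all weights
and caps are configuration. The published optimal dosages depend on
calibrated parameter values that are not reproducible here, so they ship
only as a reference bounds table (`b1_tm_bounds()`), and the package's own
dosage results are checked for mechanism (more Fe ⇒ no more H2S; nested
cases ⇒ ordered optimal biogas volumes) rather than numeric agreement.

## Known limitations

Batch operation only (no CSTR/fed-batch), no spatial gradients, unit
activity coefficients, no redox chemistry for Cr/Se (they enter the charge
balance only, with fixed assigned signs), no precipitate dissolution, and an
explicit fixed-step integrator that relies on the bounded stiffness of the
shipped parameter ranges — configurations far outside them may require a
smaller `dt` or fail with a clear instability error.
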