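---
title: "Methods: RuBP-regulated carbonic anhydrase in a model carboxysome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RuBP-regulated carbonic anhydrase in a model carboxysome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carboxsim)
```

# The scientific problem

α-carboxysomes concentrate CO₂ around Rubisco by importing cytosolic
HCO₃⁻ and converting it to CO₂ in the lumen with a shell-bound carbonic
anhydrase (CA). In at least some cyanobacterial lineages this CA is not
constitutively active: it is switched on allosterically by Rubisco's own
substrate, RuBP. `carboxsim` implements the three quantitative pieces
needed to study that regulation — the ¹⁸O-exchange activity statistic by
which CA activity is measured, dose–response models for the activation
curve, and a compartmental reaction-diffusion model of a single
carboxysome in which the CA can be made RuBP-dependent.

# The activation function

The regulation is modelled as a Hill function acting multiplicatively on
*both* CA rate constants:

$$f([\mathrm{RuBP^{4-}}]) =
\frac{[\mathrm{RuBP^{4-}}]^h}{K_{1/2}^h + [\mathrm{RuBP^{4-}}]^h},$$

with defaults $K_{1/2} = 18\ \mu M$ and $h = 2.214$, the wild-type
activation parameters. Because hydration and dehydration are scaled by
the same factor, regulation changes how fast the CO₂/HCO₃⁻ couple
relaxes, never where its equilibrium lies — an invariant the test suite
checks explicitly. We evaluate the literal formula with no basal floor:
at vanishing RuBP the catalysed reaction turns off completely (the
compartment retains only whatever background interconversion its own
`ca_factor = 1` term would provide — none, in the lumen, where the CA
term *is* the interconversion pathway). A clamped nonzero floor was
considered for numerical robustness and rejected: the steady-state solver
handles the fully-off limit without difficulty, and a floor would blur
the biological claim being modelled.

# CA kinetics and units

The interconversion rate laws are
$v_+ = \mathrm{CAf}\cdot k_1 [\mathrm{CO_2}]$ and
$v_- = \mathrm{CAf}\cdot k_2 [\mathrm{HCO_3^-}][\mathrm{H^+}]$ with
$k_1 = 0.05$, $k_2 = 100$ and a catalytic enhancement
$\mathrm{CAf} = 10^5$ in the lumen (1 elsewhere). The rate coefficients
are given without units in their source, so the package fixes a
convention: **concentrations in mM, time in seconds**, making $k_1$ s⁻¹
and $k_2$ mM⁻¹s⁻¹. The implied equilibrium constant
$k_1/k_2 = 5\times10^{-4}$ mM corresponds to a CO₂/HCO₃⁻ p$K_a$ of 6.3,
the physiological value — which is the consistency check that pins the
convention down. All state variables, including H⁺, are carried in mM
(pH 8.0 ⇔ $10^{-5}$ mM).

# The compartment model

Three compartments: an external reservoir clamped at 20 mM HCO₃⁻, pH 8.0,
0.25 mM O₂ (air-equilibrated water at 25 °C; "atmospheric" is not a
number, so this is the package's choice) and the swept RuBP level; an
unstirred boundary layer (default 10× the lumen volume); and the 100 nm
carboxysome lumen holding 5.68 mM Rubisco active sites. The external free
CO₂ is clamped at 0.01 mM — far below the 0.4 mM that would equilibrate
with 20 mM HCO₃⁻ at pH 8 — because the cytosol of an air-grown cell is
held out of equilibrium by CO₂ fixation and the absence of cytosolic CA;
this disequilibrium is what gives the carboxysome something to
concentrate.

Rubisco follows Michaelis–Menten kinetics with competitive O₂ inhibition
at the CO₂ site and independent RuBP saturation
($k_{catC} = 9.4\,s^{-1}$, $K_{M,CO_2} = 169\,\mu M$,
$K_{M,O_2} = 1.4$ mM, $k_{catO} = 1.42\,s^{-1}$,
$K_{M,RuBP} = 40\,\mu M$). The rate equation itself is not printed in the
source material; this form is the standard one for the model lineage the
parameters come from, and oxygenation mirrors it with the gas roles
swapped.

## Proton stoichiometry

Carboxylation is modelled as consuming one CO₂ and one RuBP and releasing
**two** protons (`n_h_carboxylation = 2`, configurable 0–2). At
carboxysomal pH the reaction is
RuBP⁴⁻ + CO₂ + H₂O → 2 PGA³⁻ + 2 H⁺, and these protons matter: they are
what drives net CA dehydration (HCO₃⁻ + H⁺ → CO₂) and therefore luminal
CO₂ elevation. With a single released proton the net dehydration flux is
capped by the tiny transmembrane proton influx available at pH 8, the
lumen cannot elevate CO₂ above the external level, and the
equilibrium-constrained CA drives the lumen strongly alkaline — neither
of which matches the behaviour the model exists to reproduce. Oxygenation
consumes one RuBP and is treated as proton-neutral. Reaction products
(PGA, phosphoglycolate) are sinks, not state variables.

## Transport

Permeabilities of the antecedent model are not restated in the source, so
the package uses per-species first-order exchange coefficients
(s⁻¹, referenced to the receiving compartment volume), all exposed in the
configuration. Defaults across the shell: CO₂ 100, HCO₃⁻ 100, H⁺ 1000,
O₂ 100, RuBP 10 s⁻¹; across the external/unstirred interface, 1000 s⁻¹
for everything. The reasoning: the shell must retard CO₂ relative to the
lumen's fixation capacity (≈100 s⁻¹ effective first-order consumption at
low CO₂) or there is no CO₂-concentrating function at all; protons are
small and highly mobile; RuBP is a bulky tetra-anion and the slowest
permeant. Because these values are not measurements, every model-level
conclusion the package tests is directional or invariant-based
(regulated vs unregulated orderings, monotonicity, conservation), which
are robust across wide ranges of these coefficients; absolute fluxes and
the exact pH excursion are not claims.

## RuBP speciation

The CA modulation argument is the luminal concentration of the
tetra-anion RuBP⁴⁻. The fractionation scheme is a single effective
ionisation (Henderson–Hasselbalch, default p$K_{a,\mathrm{eff}}$ = 6.7,
near the terminal phosphate ionisations of sugar bisphosphates): at pH 8
about 95% of RuBP is counted as RuBP⁴⁻. A `"full"` mode treats all RuBP
as deprotonated. Rubisco saturation uses total RuBP.

## Luminal RuBP: transported and consumed

Luminal RuBP is a dynamic species — delivered across the shell and
consumed by carboxylation and oxygenation — rather than clamped at the
external value, because its depletion feeds back on both Rubisco and the
CA modulation. A `clamp_rubp = TRUE` mode reproduces the simpler
clamped-RuBP variant for comparison.

# Steady-state solving

The 10-dimensional stiff ODE system is integrated to quiescence with
`deSolve::lsoda` and then polished by a damped Newton iteration on the
steady-state equations (central-difference Jacobian; minimum-norm
pseudo-inverse step when the Jacobian is rank-deficient, as in closed
systems whose conservation laws make the fixed point a manifold).
Convergence is declared when $\max_i |dx_i/dt| < 10^{-10}$ mM/s; the
fixed evaluation order makes results deterministic, and non-convergence
is an explicit error carrying the residual. Sweeps warm-start each RuBP
level from the previous solution. Newton steps are projected onto the
nonnegative orthant, which is also the physical state space.

# Dose–response fitting

Fits use bounded Levenberg–Marquardt least squares (`minpack.lm`) with a
deterministic multi-start grid — $K_{1/2}$ starts at five quantiles of
the concentration grid, $h$ starts at {0.5, 1, 2, 4} — taking the
lowest-RSS convergent fit, which makes results reproducible and robust to
local minima. Replicates enter as individual points rather than
pre-averaged means (averaging is a display convention, and pre-averaging
discards the error structure). Positivity is enforced by bounds
($h \le 20$ as a sanity cap). Model ranking uses AICc, since R² alone
cannot penalise the biphasic model's extra parameter; both are reported.
Constant curves are returned as flagged degenerate results
(basal = $v_{max}$ = mean) rather than errors. Reported uncertainties are
asymptotic standard errors from the least-squares fit and are labelled as
such.

# The MIMS statistic

Enrichment sums the six channels m/z 44–49 (44/46/48 = ¹²C with 0/1/2
¹⁸O; 45/47/49 = ¹³C counterparts) as ¹⁸O atoms over total oxygen atoms,
making it invariant to any per-point rescaling of all channels
(instrument gain drifts cancel). "log" in the activity statistic is taken
as the natural log, so the fitted slope *is* the first-order rate
constant; a log₁₀ reporting mode divides by ln 10. Segments exclude a
configurable post-addition equilibration gap (default 0.5 min) because
rates are defined at chemical equilibrium and the moments after an
addition are not at equilibrium; rates are reported as absolute values.

# What the generators emulate — and what they do not

`simulate_mims_trace` produces piecewise-exponential enrichment decay
with per-segment rates, realised as channel intensities via a binomial
allocation of each molecule's two oxygens (¹⁸O count ~ Binomial(2, E))
split 95:5 between ¹³C and ¹²C channels, with multiplicative log-normal
channel noise (MIMS intensities are positive). It does not emulate
instrument drift, CO₂ consumption in the cuvette, or the full
¹⁸O-exchange reaction network — so passing tests validate the estimator
on its own statistical model, not instrument artefact handling.

`generate_response_curve` adds Gaussian noise with sd =
`noise_sd` × $v_{max}$ (full-scale relative, default 2%). Point-relative
noise would make zero-activity points noiseless, which no rate assay is;
full-scale noise is the more honest emulation of a MIMS-derived rate.
`generate_mutant_panel` emits one curve per qualitative variant class
(wild-type sigmoidal, constitutive, biphasic, dead) with documented truth
parameters.

All generators are seeded through R's default Mersenne–Twister RNG, so
fixed seeds reproduce byte-identical outputs across platforms.

# Problem sizes

The test suite and acceptance script use: 20-point log-spaced RuBP sweeps
over 0.1 µM–5 mM for the regulated/unregulated comparison; 100–200 seeded
synthetic dose-response curves (12 concentrations × 3 replicates, 2%
noise) for estimator-calibration checks; and 500 Monte-Carlo traces at 1%
channel noise for MIMS estimator calibration. These sizes were chosen so
each statistical claim is measured with sampling error comfortably below
the tolerance being asserted.

# Known limitations

- The compartment model is well-mixed per compartment; no spatial
  gradients within the lumen, no shell pore structure.
- No buffering: H⁺ is a free species, so absolute pH excursions are upper
  bounds on what a buffered lumen would show; orderings between model
  variants are the robust output.
- Transport coefficients are plausible defaults, not measurements
  (directional conclusions only).
- The dose-response layer fits phenomenological models; it does not
  resolve enzyme mechanism, redox modulation, or global fits across
  variants.
- SBML export of the reaction network is not provided.
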