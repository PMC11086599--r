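# carboxsim

Quantitative tools for studying how ribulose-1,5-bisphosphate (RuBP)
allosterically switches on the carbonic anhydrase (CA) of cyanobacterial
α-carboxysomes, and what that regulation does to carboxysome function.

The package is aimed at researchers working on CO₂-concentrating
mechanisms (CCMs) and carboxysome biochemistry. It covers the three
quantitative layers of that problem:

1. **¹⁸O-exchange MIMS assays** (`mims_assay` layer). CA activity is
   measured by membrane inlet mass spectrometry as the washout of ¹⁸O from
   a ¹³C-labelled, ¹⁸O-enriched bicarbonate pool. The package computes the
   ¹⁸O atom-fraction enrichment of measured CO₂ at each time point,

   *E* = Σᵢ aᵢ·nᵢ(¹⁸O) / (2 Σᵢ aᵢ),

   over the six isotopologue channels (m/z 44–49), and reports per-segment
   activity as the absolute slope of ln *E* against time
   (Log_Enrich·min⁻¹), segmented at the protein- and effector-addition
   events.

2. **Dose–response fitting** (`dose_response` layer). Activity as a
   function of [RuBP] is fitted with a Hill model
   *v* = *v*ₘₐₓ·xʰ/(K½ʰ + xʰ), its hyperbolic (Michaelis–Menten, h = 1)
   special case, and a biphasic extension *v* = basal +
   (*v*ₘₐₓ − basal)·xʰ/(K½ʰ + xʰ) for constitutively active variants;
   models are ranked by AICc with R² reported alongside. Wild-type-like
   activation has K½ ≈ 18 µM and Hill slope h ≈ 2.2.

3. **A carboxysome reaction-diffusion model** (`carboxysome_model`
   layer). A three-compartment steady-state model (clamped external
   reservoir ↔ unstirred layer ↔ carboxysome lumen) of CO₂, HCO₃⁻, H⁺, O₂
   and RuBP, with Michaelis–Menten Rubisco kinetics (competitive O₂
   inhibition) and CA interconversion *v*₊ = CAf·k₁·[CO₂],
   *v*₋ = CAf·k₂·[HCO₃⁻][H⁺] confined to the lumen (CAf = 10⁵). In the
   regulated variant both CA rate constants are multiplied by the Hill
   activation factor [RuBP⁴⁻]ʰ/(K½ʰ + [RuBP⁴⁻]ʰ) evaluated at the luminal
   RuBP⁴⁻ concentration. Sweeping external RuBP from 0.1 µM to 5 mM
   reproduces the regulatory phenotype: unchanged carboxylation at high
   RuBP, but a lumen held closer to external pH (more acidic than the
   alkaline unregulated lumen) when RuBP is scarce.

Every user-facing function takes a data frame and returns a tibble, so
analyses compose with the pipe; fitted objects have `tidy()`/`glance()`
methods and `autoplot()`/`plot_sweep()` visualisations.

## Worked example

```r
library(carboxsim)

# 1. An 18O-washout assay of an RuBP-dependent CA: background rate,
#    no jump on protein addition, large jump on RuBP addition.
tr <- simulate_mims_trace(rates = c(0.01, 0.012, 0.48), seed = 42)
relative_rate_profile(segment_rates(tr))
#> # A tibble: 3 × 6
#>   segment       t_start t_end n_points rate_per_min relative_rate
#> 1 pre_protein       0       5      101       0.0101        0.0211
#> 2 post_protein      5.5    10       91       0.0118        0.0246
#> 3 post_effector    10.5    15       91       0.480         1

# 2. Fit the RuBP response curve.
curve <- generate_response_curve(model = "hill", noise_sd = 0.02, seed = 1)
fit <- fit_hill(curve)
fit
#> <dose_fit: hill> n = 36, R^2 = 0.9986, AICc = -284.6
#>    v_max = 0.9987, k_half_uM = 17.41, h = 2.246

# 3. Sweep external RuBP through the regulated carboxysome model.
sw <- run_rubp_sweep(carboxysome_model(regulated = TRUE),
                     rubp_levels_mM = rubp_sweep_grid(6))
dplyr::select(sw, rubp_mM, kcat_c_eff_s, ca_flux_mM_s, ph_cbx, co2_c)
#> # A tibble: 6 × 5
#>    rubp_mM kcat_c_eff_s ca_flux_mM_s ph_cbx  co2_c
#> 1 0.0001       0.000109    0.0000495   8.33 0.0100
#> 2 0.000871     0.000951    0.00801     8.19 0.0100
#> 3 0.00758      0.00841     0.0981      9.06 0.0105
#> 4 0.0660       0.0810      0.923       9.37 0.0147
#> 5 0.574        0.897      10.2         8.79 0.0615
#> 6 5            5.82       66.1         8.03 0.344
```

The segment table shows the biphasic assay signature of an
RuBP-dependent CA (activity appears only after effector addition); the
fit recovers the activation constant near 18 µM with a cooperative Hill
slope; the sweep shows net CA dehydration flux rising with RuBP, luminal
CO₂ climbing from the external 0.01 mM to 0.34 mM (the CCM), effective
carboxylation approaching its high-RuBP plateau, and luminal pH pinned
near the external 8.0 when the CA is switched off at low RuBP.

An end-to-end configured run (paired regulated/unregulated sweeps written
as tidy CSVs plus a JSON summary) is one call:

```r
run_sweep(load_config(), output_dir = "out")
```

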