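---
title: "Methods: the adcsim multiscale ADC model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the adcsim multiscale ADC model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

adcsim simulates the disposition and effect of antibody-drug conjugates
(ADCs) across three scales — a cell incubation, a tumor-bearing mouse,
and a HER2+ cancer patient — with one shared mechanistic core. This
vignette records the model equations in words, the assumptions behind
them, the provenance of the default parameter values, the numerical
choices, and what the test suite does and does not establish.

## State representation and units

All species are tracked as amounts in nmol; concentrations are derived
by dividing by the relevant volume at output time. The canonical unit
system is nM for concentrations, days for time, liters for systemic
volumes, mm³ for tumor volume, and cm for transport geometry.
Configuration files carry explicit units for every entry and are
converted once on load; a restricted unit vocabulary is accepted and
anything else is rejected rather than guessed. Representing receptors
as amounts (rather than concentrations) keeps receptor mass invariant
when compartment volumes change, which is what makes the conservation
tests sharp.

## Cellular model

ADC in the medium deconjugates in a single first-order step (k_dec) to
naked antibody plus DAR payload equivalents. ADC and antibody bind
surface HER2 monovalently and competitively; bound and free receptor
internalize, recycle, and degrade with separate rate constants. Key
assumptions, each a deliberate design choice:

- **Receptor homeostasis.** Total HER2 (surface + endosomal, free +
  complexed) is constant: synthesis exactly replaces degraded and (in
  vivo) shed receptor, entering the free surface pool.
- **Payload release.** Degradation of the internalized HER2:ADC complex
  releases DAR payload equivalents into the endo/lysosomal pool and
  destroys antibody and receptor (the receptor being replaced by
  synthesis). A cleavable linker adds a k_cleave route that releases
  payload while converting the complex to HER2:antibody — the antibody
  survives cleavage and can recycle. Recycling itself carries the
  payload back intact; nothing is lost on a recycling round-trip.
- **Payload transport.** Endo/lysosome-to-cytosol escape and
  medium-to-cell re-entry share one first-order constant (k_in), a
  simplification of what is, at least for lysine-MCC-DM1, an active
  transport step. Efflux (k_out) is passive. In the cytosol the payload
  binds its target (tubulin or TOPO-1) reversibly; free target is
  computed by conservation from a fixed total concentration.
- **No elimination in vitro.** The incubation is closed, so total
  payload equivalents and total receptor are exactly conserved — the
  backbone of the conservation test suite (relative drift below 1e-6 is
  enforced; the integrator typically achieves 1e-12).

## Systemic and tumor model

ADC, antibody, and payload each follow two-compartment kinetics with
first-order elimination in both compartments and deconjugation
everywhere. Payload released by deconjugation or by catabolism on
healthy cells enters the free payload pool of the same compartment; no
transport step is interposed. The human model adds two sink families:

- **Soluble HER2.** Membrane receptor on healthy cells and tumor cells
  sheds at k_shed into soluble pools that bind ADC and antibody with
  the membrane affinity, distribute between central and peripheral
  compartments with the antibody distribution rates, and are eliminated
  with half-lives t½(sHER2) and t½(sHER2:Ab). Complex elimination
  destroys the bound drug (no re-release). Shed tumor receptor enters
  the central soluble pool; the model does not keep a separate tumor
  interstitial soluble pool.
- **Healthy-cell membrane HER2.** Central and peripheral healthy-cell
  populations carry the full binding/trafficking cycle at a much lower
  receptor count per cell (`r_healthy_per_cell`, default 1e4 against
  2e4–1e6 on tumor cells).

The mouse model is the same structure with both sink families zeroed
(trastuzumab does not bind rodent Her2), so the reduction test — human
model with human-only features off reproduces the mouse model exactly —
is structural rather than approximate.

Tumor uptake follows the Krogh-cylinder lineage: a surface exchange
term 6D/R² and a vascular term 2·P·R_cap/R_krogh², applied to the
concentration difference between plasma and the accessible tumor
interstitium (tumor amount / (V_tumor·ε)). The two terms are **summed**
by default, so the surface route dominates small radii and the vascular
route large ones with a smooth crossover; a hard switch (the dominant
term only) is available for sensitivity checks. Exchange rates are
recomputed from the instantaneous tumor volume inside the right-hand
side, which closes the loop between tumor shrinkage and drug delivery.
Receptor totals on tumor cells scale with the whole live cell mass
N1+N2+N3+N4 — committed cells still express, bind, and internalize.
Growing tumor adds receptor at the drug-free surface/endosome split;
mass exiting the cascade removes receptors, intracellular payload, and
bound target in proportion, so nothing concentrates spuriously as the
tumor shrinks.

## Tumor growth inhibition

Growth of the proliferating mass N1 is
k_exp·N1 / (1 + (k_exp·V/k_lin)^ψ)^(1/ψ) · (1 − V/V_max) with
k_exp = ln2/t_double and ψ = 20, which makes the exponential-to-linear
transition sharp; the logistic factor caps V at V_max. Killing is
Michaelis-Menten in the intracellular unconjugated payload
concentration — by default cytosolic free plus target-bound payload per
intracellular volume, with a configuration switch to free-only — and
moves mass from N1 into a transit cascade of three non-proliferating
states. Each transit step leaves at 3/τ so the cascade is Erlang-3 with
mean delay exactly τ (a `single_transit` switch gives the 1/τ variant).
Mass leaving N4 is removed from the system; there is no payload return
from lysed cells.

## Default parameter values

Printed constants adopted directly: ψ = 20; four tumor cell states; an
effective intracellular tubulin concentration of 65 nM for the DM1
models (the published effective value — far below biochemical tubulin
estimates, which over-buffer the payload); antibody elimination
half-life 11.6 days; payload half-lives 3.5 h (DM1) and 0.8 h (DXd);
HER2 strata of 2e4 and 1e6 receptors/cell; trial emulations of 95
patients at 3.6 mg/kg Q3W for 14 months (T-DM1 phase 2), 184 at
5.4 mg/kg for 20 months and 373 at 5.4 mg/kg for 29 months (T-DXd
phase 2/3); and n = 1000 LHS samples in the sensitivity study.

Everything else is a package default chosen once from literature-typical
values: trastuzumab association 7.3e5 M⁻¹s⁻¹ with Kd ≈ 0.5 nM;
HER2 internalization 6/day with a high recycling fraction
(10/day recycle vs 2.8/day degrade); Krogh geometry R_cap = 8 µm,
R_krogh = 75 µm with antibody D = 0.022 cm²/day, P = 334 µm/day and
void fractions 0.24 (antibody) / 0.44 (payload); tumor cell density
5e5 cells/mm³ at 1 pL per cell; mouse plasma 1 mL, human central volume
3 L. DAR is 3.5 (T-DM1) and 8 (T-DXd); T-DXd deconjugates an order of
magnitude slower (stable linker) and releases payload by cleavage at
2/day; the DM1 catabolite is membrane-impermeant (slow efflux,
0.14/day) while DXd is permeable in both directions — which is what
makes intracellular DM1 accumulate far above the medium and DXd wash
out quickly.

The kill parameters deserve an explicit note. The mouse defaults
(k_kill 0.2/day, kc50 4 µM for T-DM1; 0.25/day, 150 nM for T-DXd) were
set so the simulated xenograft dose-response looks like the published
class behavior: little effect at 1 mg/kg, growth inhibition at
3 mg/kg, regression with post-treatment regrowth at 10–15 mg/kg. The
human defaults are **not** copied 1:1 from the mouse values: because
this model (like its lineage) has no spatial penetration barrier, the
delivered intracellular payload in a patient-scale tumor is high enough
that mouse-calibrated potency would eradicate every virtual tumor. The
shipped human kill parameters are instead calibrated so the virtual
populations show clinically plausible heterogeneity — most high-HER2
patients responding, HER2-low T-DM1 patients progressing, T-DXd active
in both strata. This is a generator-level modeling choice, documented
here once and not tuned thereafter.

Inter-patient variability uses median-preserving lognormals
(sdlog = sqrt(log(1+CV²))). CVs of 0.3 on t_double, k_lin and k_kill
and 2.0 on kc50 encode the observation that potency heterogeneity must
be large to reproduce the spread of clinical response. Dropout is
exponential at 0.001/day and assessments are every six weeks — both
assumptions, labeled as such in the trial configs, since the emulated
trials do not report them. RECIST classification is against baseline
(not nadir) in the priority order CR > PD > PR > SD, with PD requiring
both a >20% and a >5 mm diameter increase; events are recorded at the
assessment where progression is first observed (interval-censored onto
the assessment grid).

## Numerical choices

- Right-hand sides are compiled C used through deSolve's compiled-model
  interface; `lsoda` with rtol 1e-8 / atol 1e-10 nmol is the default.
  Sweeps (fits, PRCC, trials) use rtol 1e-6 / atol 1e-9 for speed.
- Bolus doses are exact state increments applied through integrator
  events; the output row at the dose time reports the pre-dose state.
  Infusions integrate piecewise with a zero-order source term.
- The tumor volume is floored at 1e-9 mm³ inside the right-hand side so
  the surface-exchange term and the per-volume concentrations stay
  finite for vanishing tumors; free intracellular target is clamped at
  zero if shrinkage transiently overshoots the conservation bound.
- Fitting works on log-transformed parameters with box bounds
  (Levenberg-Marquardt via minpack.lm). The finite-difference step is
  widened (`epsfcn = 1e-6`) so numerical Jacobians stay above the ODE
  solver noise floor; with the default machine-epsilon step the search
  stalls at its starting point on simulation-based objectives.
- Log-scale residuals are the default objective (PK spans decades and
  the noise is multiplicative); proportional and absolute residuals are
  available. Predictions are floored at 1e-12 before taking logs.
- PRCC adjusts ranks by QR-based linear regression; a rank-deficient
  adjusted design is an error naming the collinear parameters rather
  than a silent pseudo-inverse.

## The synthetic-data generator and what the tests show

`generate_fixture()` simulates a known-parameter configuration, samples
it at stated times, and applies median-preserving multiplicative
lognormal noise; the generating truth rides along as metadata. The
recovery tests use two synthetic studies fixed once: a single-dose
mouse antibody PK study (12 sampling points from 1 h to 21 days, 10%
noise, deconjugation off, truth k12 = 1.0/day, k21 = 0.25/day — an
identifiable two-compartment design with a clear distribution phase)
and a five-arm TGI study (vehicle, 1, 3, 10, 30 mg/kg weekly ×3,
sampled every 3 days to day 63 at 12% noise), whose dose range brackets
kc50 so that maximal kill and potency separate. Twenty replicate fits
recover (k_elim, k12, k21) within 15% and (k_kill, kc50, t_double)
within 25% median relative error.

What passing these tests shows: the estimator is consistent when the
model generating the data is the model being fitted, at realistic noise
and design. What it does not show: anything about structural model
error, real assay error models (additive floors, BLQ censoring),
inter-animal variability, or digitization error in literature data —
real calibrations face all four. Similarly, the virtual-trial tests
establish internal properties (reproducibility, product-limit
correctness, the potency ordering) — not that the shipped populations
reproduce any specific clinical PFS curve, which would require the
unpublished censoring patterns of the real trials.

## Problem sizes

The test suite runs the conservation sweep at 20 random parameter
draws, the estimator-equivalence checks on 50 random cohorts and 5 toy
matrices, recovery at 20 replicates per study, the sensitivity ranking
at 80–100 LHS samples, and the ordering trial at 200 patients per arm;
the full suite completes in under two minutes on one core. The shipped
PRCC configuration uses the full n = 1000 when run through
`run_prcc_study(prcc_spec(...), default_config("prcc_tdm1"))` or the
CLI.

## Known limitations

No spatial payload or ADC gradients within the tumor (no binding-site
barrier), hence no penetration-limited dose-response; no bystander
killing of antigen-negative cells; no ADCC/ADCP or immune effects; a
single mean-DAR pool rather than a DAR-species distribution, and no
DAR-dependent clearance; no FcRn recycling or immunogenicity; soluble
receptor confined to systemic compartments. These match the intended
scope: a transparent, testable backbone connecting cellular mechanism
to population outcome.
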