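# adcsim

A quantitative systems pharmacology (QSP) simulator for antibody-drug
conjugates (ADCs), written for modelers who need to connect in vitro
cellular disposition data, mouse PK and tumor growth inhibition (TGI)
studies, and clinical trial outcomes within one mechanistic model. The
shipped defaults parameterize two HER2-targeting ADCs with the same
antibody backbone but different linker-payloads: trastuzumab emtansine
(T-DM1, non-cleavable linker, maytansinoid payload) and trastuzumab
deruxtecan (T-DXd, cleavable linker, camptothecin payload).

## The model

The simulator is a modular ODE system in amounts (nmol), days, and nM:

- **Cellular disposition** — the ADC deconjugates extracellularly
  (k_dec), and ADC and naked antibody compete for monovalent binding to
  surface HER2 (k_on, k_off). Bound and free receptor internalize
  (k_endo), recycle (k_rec) or degrade (k_deg) in an endo/lysosomal
  compartment; total receptor is held constant by synthesis. Payload is
  released on degradation (DAR equivalents per antibody) and, for
  cleavable linkers, by linker cleavage (k_cleave). Released payload
  escapes to the cytosol (k_in), binds its intracellular target (tubulin
  for DM1 at an effective 65 nM; TOPO-1 for DXd), and leaves the cell by
  passive diffusion (k_out).
- **Systemic PK** — two-compartment kinetics for ADC, antibody and free
  payload with deconjugation in every compartment and physiological
  volumes. The human model adds soluble HER2 shed from tumor and
  healthy-cell membranes (a circulating drug sink with its own
  half-life) and membrane HER2 on healthy cells in the central and
  peripheral compartments (target-mediated drug disposition).
- **Tumor disposition** — a Krogh-cylinder uptake model: surface
  exchange 6D/R² dominates for small avascular tumors, vascular exchange
  2·P·R_cap/R_krogh² for large vascularized ones (summed by default),
  with void fractions ε per species and exchange rates recomputed from
  the current tumor volume at every step.
- **TGI** — tumor growth switches from exponential (doubling time
  t_double) to linear (k_lin) under a ψ-controlled switch (ψ = 20) with
  a logistic cap at V_max. Killing is Michaelis-Menten in the
  intracellular unconjugated payload concentration
  (k_kill·C/(kc50 + C)), acts on the proliferating mass N1, and routes
  dying cells through a three-step transit cascade N2→N3→N4 whose mean
  delay is τ. Tumor volume is N1+N2+N3+N4.
- **Calibration** — Levenberg-Marquardt least squares on log-scale
  residuals, with parameters shared across datasets or local to one
  (e.g. a per-ADC deconjugation rate in a joint fit).
- **Global sensitivity** — Latin hypercube sampling and partial rank
  correlation coefficients (LHS-PRCC) on tumor volume AUC.
- **Virtual trials** — lognormal inter-patient variability on t_double,
  k_lin, k_kill and kc50, RECIST classification of the equivalent
  spherical diameter at scheduled assessments, exponential dropout
  censoring, and a product-limit PFS curve.

## Worked example

Mouse TGI dose-response for T-DM1 (200 mm³ N87-like xenograft, 3 weekly
doses), followed by a virtual phase-2 trial in HER2-low patients:

```r
library(adcsim)

cfg <- default_config("tdm1_mouse")
model <- couple_tumor(build_mouse_pk(cfg$molecule, cfg$system), cfg$tgi)
grid <- sort(unique(c(seq(0, 42, by = 1), c(0, 7, 14))))
for (d in c(0, 3, 10)) {
  tv <- simulate_tgi(model, regimen(d, interval = 7, n_doses = 3), grid)
  cat(sprintf("dose %2g mg/kg: V(21) = %6.0f  V(42) = %6.0f mm^3\n",
              d, tv$tumor_volume[tv$time == 21],
              tv$tumor_volume[tv$time == 42]))
}
#> dose  0 mg/kg: V(21) =    620  V(42) =   1002 mm^3
#> dose  3 mg/kg: V(21) =    183  V(42) =    266 mm^3
#> dose 10 mg/kg: V(21) =     80  V(42) =     33 mm^3

res <- run_trial(default_config("trial_tdm1_ph2"), seed = 1,
                 her2_receptors_per_cell = 2e4)
res
#> <trial_result> 95 patients (HER2 2e+04/cell): 33 events, median PFS not reached d
pfs_at(res$pfs, 182.6)   # PFS at 6 months, percent
#> [1] 96.5
```

Vehicle tumors grow along the exponential-to-linear growth curve;
3 mg/kg slows growth while 10 mg/kg drives regression with regrowth
after the last dose — the dose-dependence produced by intracellular
payload saturating the kill term. The virtual trial classifies each
patient's simulated diameter every six weeks and accumulates progression
events into the PFS curve (`res$pfs`); `plot_pfs(res)` draws it.

A thin CLI over the same functions is shipped at `inst/cli/adcsim.R`
(`simulate-invitro`, `simulate-pk`, `simulate-tgi`, `fit`, `prcc`,
`trial`, `make-fixture`), each taking `--config`, `--seed`, `--out`.

## Configuration

All parameters live in YAML configs with explicit units
(`inst/extdata/config/`): `tdm1_mouse`, `tdxd_mouse`, `tdm1_human`,
`tdxd_human`, `tdm1_invitro`, trial emulations (`trial_tdm1_ph2`,
`trial_tdxd_ph2`, `trial_tdxd_ph3`) and an LHS-PRCC study
(`prcc_tdm1`). Values are converted to canonical units (nM, day, L,
mm³, cm) and schema-validated on load; unknown keys or units are
rejected. See the methods vignette (`vignettes/adcsim-methods.Rmd`) for
the modeling assumptions and the provenance of every default.
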