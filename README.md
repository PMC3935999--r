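# pdz3kit

Salt-bridge occupancy, ITC thermodynamics and chemical-shift-perturbation
analysis for PDZ-domain ligand recognition.

## The scientific problem

The third PDZ domain (PDZ3) of the postsynaptic scaffolding protein
PSD-95 binds C-terminal peptide motifs such as the high-affinity
consensus hexapeptide KKETAV. Unlike canonical PDZ folds, PDZ3 carries an
extra C-terminal helix (alpha-3, residues ~394–403 in full-length PSD-95
numbering) packed against the core away from the binding groove. Ligand
affinity is governed by an interplay of salt bridges: the ligand's
N-terminal lysines (positions −4, −5) engage acidic residues of the
beta2–beta3 loop (329–334), while the same loop residue Glu334 can
instead pair with Arg399 of the alpha-3 helix, anchoring the helix to the
core ("docked"). Post-translational modifications in this region —
phosphorylation of Tyr397, succinimide cyclization of Asp332 (a −18 Da
water loss) — rebalance the network and tune affinity.

`pdz3kit` is for structural biologists and biophysicists who need the
computational layer of such a study as tested, reusable code:

* **Salt-bridge detection** on multi-frame structures (multi-model PDB or
  in-memory trajectories) under two geometric criteria — the minimum
  anchor-carbon cross distance (< 5 Å, strict) or the charged-group mass
  center distance (< 4 Å) — with per-pair occupancies
  (frequency of formation), "at least one of" aggregates, a helix
  docked/undocked classifier (`1 −` the union occupancy of
  Glu334–Arg399 and Lys355–Glu401), and distance time series.
* **ITC one-site analysis**: the exact single-site quadratic with
  perfusion-cell displacement bookkeeping, dilution subtraction,
  nonlinear fitting of (n, K_d, ΔH), and the decomposition
  ΔG = RT ln K_d, −TΔS = ΔG − ΔH (R = 1.9872×10⁻³ kcal·mol⁻¹·K⁻¹).
* **CSP mapping**: combined amide perturbations
  Δδ_HN = √((Δδ_H)² + (Δδ_N/5)²) between free and bound peak lists,
  low/medium/high binning at 0.2 / 0.5 ppm, and per-region summaries
  over the domain's secondary-structure elements.
* **Seeded synthetic-data generators** — two-state Markov contact
  trajectories with competition groups, noisy titration isotherms,
  fast-exchange peak lists — each with a machine-readable truth record,
  so the whole pipeline is testable offline.

See `vignettes/pdz3kit-methods.Rmd` for the model details, defaults and
design choices.

## Worked example

Simulate a wild-type-like ITC titration (70 µM protein in the cell,
900 µM KKETAV in the syringe, 19 × 2 µL injections at 25 °C), fit it,
and decompose the energetics:

```r
library(pdz3kit)

sched <- injection_schedule(rep(2, 19), syringe_conc = 900e-6,
                            cell_conc_initial = 70e-6)
sim <- gen_itc_experiment(itc_spec(one_site_params(0.99, 1.5e-6, -9.8),
                                   sched, noise_sd = 0.2,
                                   dilution_heat = -0.6, seed = 42))
fit <- fit_one_site(sim$isotherm)   # blank heats subtracted automatically
thermo_table(fit$params$Kd, fit$params$dH, label = "simulated WT")
#>          label Kd_uM     dH minus_TdS     dG     T
#> 1 simulated WT 1.311 -9.718     1.693 -8.025 298.1
```

The fit recovers the generating parameters (n = 0.982, K_d = 1.31 µM,
ΔH = −9.72 kcal·mol⁻¹ from noisy data; exact to <0.1% when noise-free).
ΔG ≈ −8.0 kcal·mol⁻¹ means micromolar binding driven by enthalpy with an
entropic penalty (−TΔS > 0).

Simulate a contact trajectory configured to wild-type occupancies and
tabulate bridge formation:

```r
sp <- demo_wt_trajectory_spec(n_frames = 5000, seed = 42)
g <- gen_contact_trajectory(sp)
occupancy_table(g$trajectory, sp$pairs, attr(sp, "aggregates"))
#>            category                       label percent
#> 1   ligand-b2b3loop              Lys(-5)-Glu331    22.1
#> 2   ligand-b2b3loop              Lys(-5)-Glu334    35.9
#> 3   ligand-b2b3loop              Lys(-4)-Glu331    30.0
#> ...
#> 9    a3helix-domain               Glu334-Arg399    39.2
#> 10   a3helix-domain               Lys355-Glu401    44.9
#> 11        aggregate            PDZ3-Lys(-4)(-5)    74.1
#> 12        aggregate non-formation:helix-bridges    33.4

helix_undocked_fraction(g$trajectory)
#> [1] 0.3336
```

Each percent is the fraction of frames in which that bridge is formed
under the 5-Å anchor-carbon criterion; the last row — identical to
`helix_undocked_fraction()` — is the fraction of frames with the alpha-3
helix detached from the domain core. Estimates fluctuate around the
configured occupancies within dwell-corrected sampling error
(`occupancy_se()`).

A full simulate → analyse → report run:

```r
run_pipeline(list(out_dir = "demo-run", seed = 1))
# or from the shell:
#   Rscript -e 'pdz3kit::pdz3kit_cli()' run --out demo-run --seed 1
```

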