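---
title: "Methods: salt-bridge occupancy, ITC thermodynamics and CSP mapping for PDZ3"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: salt-bridge occupancy, ITC thermodynamics and CSP mapping for PDZ3}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdz3kit)
```

## The system and what the package computes

The third PDZ domain (PDZ3) of the scaffolding protein PSD-95 carries an
extra C-terminal helix (alpha-3, roughly residues 394-403 in full-length
PSD-95 numbering) that packs against the domain core away from the
peptide-binding groove. Binding of C-terminal peptide ligands such as the
consensus hexapeptide KKETAV (numbered -5 to 0, with 0 the C-terminal
Val) is modulated by a network of salt bridges: the ligand's N-terminal
lysines engage acidic residues of the beta2-beta3 loop (residues
329-334), while the same loop residue Glu334 can instead pair with
Arg399 of the alpha-3 helix. Post-translational modifications near this
interface (Tyr397 phosphorylation, succinimide cyclization of Asp332)
shift the balance of these interactions.

`pdz3kit` implements the computational layer of such a study as a
reusable pipeline:

1. **Salt-bridge occupancy analysis** of multi-frame structures
   (trajectories), with a docked/undocked classifier for the alpha-3
   helix.
2. **One-set-of-identical-sites ITC** modelling and fitting, with
   dilution correction and the free-energy/entropy decomposition.
3. **Chemical-shift-perturbation (CSP) mapping** from free/bound amide
   peak lists, with three-bin classification and per-region summaries.
4. **Synthetic-data generators** that emulate the statistical structure
   of each input, so the full pipeline is testable with no external data.

## Salt-bridge criteria

Two geometric definitions are supported, applied per frame with a strict
`<` at the cutoff:

* **Anchor-carbon criterion** (default, cutoff 5 Å): a bridge is formed
  when the *minimum* distance over the 2x2 cross pairs of "anchor
  carbons" — the two last carbons before the formally charged atoms —
  is below the cutoff.
* **Charged-center criterion** (cutoff 4 Å): formed when the
  mass-weighted centers of the two charged-atom groups are closer than
  the cutoff.

The anchor-carbon table is a documented choice, since the geometric
definition does not enumerate atoms: Lys {CD,CE} (charged NZ), Arg
{CD,CZ} (guanidinium NE/NH1/NH2), Glu {CG,CD} (OE1/OE2), Asp {CB,CG}
(OD1/OD2), C-terminal carboxylate {CA,C} (O/OXT), N-terminal ammonium
{CA,CB} ({CA,C} for Gly), phospho-Tyr {CE1,CE2} (phosphate oxygens).
All of this is overridable through `default_charge_scheme()`. Taking the
*minimum* cross distance and a strict inequality is the most permissive
reading of "the two last carbons were closer than the cutoff"; ties sit
on a measure-zero set and cannot affect occupancies in practice.

Modified residues keep their standard three-letter codes and carry a
separate modification tag (`phospho-Tyr`, `succinimide`), so any plain
PDB reader still parses the files; a succinimide tag removes the Asp
side-chain charge from the scheme.

One published table labels the helix bridge "Glu334-Asp399" while the
accompanying text calls residue 399 an Arg; residue 399 *is* an Arg and
only Glu334-Arg399 is supported here.

## Occupancy statistics

`occupancy()` is the fraction of frames with the contact formed;
`any_of_occupancy()` is the fraction of frames in which at least one of
a set of contacts is formed (used for the aggregate "ligand engaged by
Lys(-4) or Lys(-5)" rows). The helix is classified *docked* in a frame
when at least one of Glu334-Arg399 or Lys355-Glu401 is formed;
`helix_undocked_fraction()` is exactly `1 - any_of` of those two
bridges.

Because contact series are autocorrelated, the package provides a
dwell-corrected standard error: for a two-state Markov chain with
stationary occupancy $\pi$ and mean formed dwell $d$ frames, the lag-1
autocorrelation is $\rho = 1 - q_{01} - q_{10}$ (with $q_{10} = 1/d$,
$q_{01} = \pi q_{10}/(1-\pi)$), giving an effective sample size
$n(1-\rho)/(1+\rho)$. All statistical recovery tests use three such
standard errors.

## ITC model

Units: volumes in µL, concentrations in M, per-injection heats in µcal,
energies in kcal/mol. For injection $i$ of volume $\Delta V$ into a
perfusion cell of volume $V_0$ (default 200 µL, the nominal active
volume of the instrument class used; configurable), total concentrations
follow the mean-concentration displacement convention

$$M_i (V_0 + \tfrac{\Delta V}{2}) = M_{i-1} (V_0 - \tfrac{\Delta V}{2}),
\qquad
X_i (V_0 + \tfrac{\Delta V}{2}) = X_{i-1} (V_0 - \tfrac{\Delta V}{2})
 + X_s \Delta V,$$

i.e. material pushed out leaves at the mean of the pre- and
post-injection concentrations. Bound complex comes from the exact
single-site quadratic with site concentration $S = n M$:

$$[PL] = \tfrac12\left(S + X + K_d - \sqrt{(S + X + K_d)^2 - 4SX}\right),$$

and the observed heat differences the cumulative bound heat
$Q_i = [PL]_i V_0 \Delta H$ with a credit for complex displaced during
the injection: $q_i = Q_i - Q_{i-1} + \frac{\Delta V}{V_0}\,
\frac{Q_i + Q_{i-1}}{2}$.

Two limits anchor the implementation: with $K_d \to 0$ and excess
protein each injection's heat is $\Delta H$ times the moles injected,
and the cumulative heat approaches $n M_0 V_0 \Delta H$ at saturation.
The second limit is exact only for tight binding: at finite $K_d$ a
small deficit (about 0.5% for the wild-type-like condition) remains
because some protein is displaced from the cell before it saturates.
The test suite probes the conservation limit at $K_d = 1$ nM for this
reason, and checks mid-titration heats against an independent bisection
solver of the binding polynomial.

`fit_one_site()` minimizes squared residuals over $(n, \log K_d,
\Delta H)$ with Nelder-Mead followed by a BFGS polish and up to three
perturbed restarts. Starting values are data-driven: $\Delta H$ from the
first-injection heat, $n$ from the molar ratio at half-cumulative heat,
$K_d$ from a mid-range Wiseman $c \approx 20$. A warning is emitted
when the fitted $c = n[\mathrm{cell}]/K_d$ leaves the well-conditioned
1-1000 window. On noise-free forward-model data the fit is a fixed
point to better than 0.1%.

## Thermodynamic decomposition and sign conventions

$\Delta G = RT\ln K_d$ with $R = 1.9872\times10^{-3}$ kcal/mol/K and a
1 M reference state; $-T\Delta S = \Delta G - \Delta H$ holds exactly by
construction in `thermo_table()`. For published rows printed at fixed
precision, `thermo_table_printed()` takes the decomposition verbatim so
condition comparisons reproduce printed arithmetic exactly.

`compare_conditions(a, b)` returns *signed* differences `b - a` and the
fold-change `Kd_a/Kd_b`. Published prose often quotes both members of a
comparison as positive magnitudes by implicitly flipping the direction
per quantity (e.g. an enthalpic penalty *at low pH* alongside an
entropic penalty *at high pH*); the package keeps one signed convention
and leaves the direction choice to the caller.

## CSP mapping

The combined amide perturbation is
$\Delta\delta_{HN} = \sqrt{(\Delta\delta_H)^2 +
(\Delta\delta_N/5)^2}$. The 15N weight 1/5 is the dominant convention
for backbone amides; the exact weight used in the emulated study is not
recoverable from its text (the equation appears only as an image), so
the factor is an explicit argument (`n_scale`, default 0.2; 0.14
reproduces the other common convention). Perturbations are classified
low/medium/high on $[0,0.2)$, $[0.2,0.5)$, $[0.5,\infty)$ ppm, boundary
values going to the upper bin so that "higher than 0.5" is the open
lower edge of the top class; the bins map to the conventional
blue/yellow/red structure colouring. Residues present in only one peak
list are reported as unmatched, never dropped.

Only the beta2-beta3 loop (329-334) and alpha-3 helix (394-403) region
boundaries are pinned by the study; the other entries of
`default_region_map()` (beta2 323-328, beta3 336-341, alpha2 369-378)
are conventional approximations and overridable.

## What the generators emulate — and what they do not

**Contact trajectories.** Each candidate bridge follows a two-state
Markov chain with prescribed stationary occupancy and mean formed dwell
(default 50 frames — a placeholder, as the emulated simulations publish
no autocorrelation data), initialized from the stationary distribution
to avoid burn-in. Bridges sharing a partner (Glu334 engaged either by
ligand Lys(-5) or by Arg399) form a *competition group*: a per-frame
categorical draw guarantees at most one member formed per frame and
honours marginal occupancies, at the cost of dwell fidelity inside the
group — a documented trade-off.

Geometry realizes states exactly: residues are reduced to the atoms the
criteria need, clustered within 0.15 Å of a center point, and centers
are placed along a spanning tree of the pair graph at 4.0 Å (formed) or
7.0 Å (broken), plus Gaussian jitter (default sd 0.05 Å) that the spec
validator guarantees can never cross the 5-Å cutoff. Because every
configured pair is a tree edge whose length is set exactly, the pair
graph must be a *forest*; cyclic configurations are rejected. The
bundled wild-type demo configuration drops the Lys403-Glu334 pair
(printed occupancy 0.0% in the wild type) precisely because it closes
the one cycle in the published pair set.

Two consequences deserve emphasis. First, the default formed distance
of 4.0 Å sits exactly on the charged-center cutoff (4 Å, strict
inequality), so dual-criterion agreement checks use a well-separated
3.5 Å formed distance instead; the default stays at 4.0 Å because the
default criterion is the 5-Å anchor rule, for which 4.0 Å is
comfortably interior. Second, a green statistical test establishes that
the *detector and estimators* are correct against the generator's truth
record — it cannot establish anything about force fields, water models,
or the real dynamics of PDZ3, which are explicit non-goals.

**ITC experiments** add a constant dilution heat and Gaussian noise to
the forward model, with an independently noised blank, so dilution
subtraction and parameter recovery can be scored against exact truth.

**Titration peak lists** place observed shifts at the fast-exchange
population-weighted average, `free + fraction_bound * dd_max`, with the
fraction bound from the exact single-site quadratic at each titration
point; only endpoints feed the headline profile, matching how such
titrations are reported.

All generators are byte-deterministic under a fixed seed and emit truth
records sufficient to score any downstream estimate.

## Numerical choices and degenerate inputs

* Strict `<` at both cutoffs; percents reported to one decimal.
* Occupancy of an empty series, peak lists sharing no residues, and
  mismatched series lengths are errors, not silent NAs; empty regions
  summarize to zero-count rows with a warning.
* The fitter works in $\log K_d$ to keep the constant positive;
  non-convergence raises an error carrying the last iterate.
* Configs are JSON; validation reports *all* violations, not the first.
* Pipeline outputs are plain tab-delimited tables plus a JSON run
  report with md5 checksums and a config echo sufficient to reproduce
  the run (the report itself records wall time and is therefore the one
  file excluded from byte-identity comparisons).

## Known limitations

* The trajectory generator cannot realize cyclic distance-constraint
  sets, and within competition groups dwell times are not controlled.
* The anchor-carbon table for termini and phospho groups is a
  documented convention, not an observed one.
* The ITC model covers a single set of identical sites only; no
  multi-site or competitive schemes, and no baseline integration of raw
  power traces (inputs are integrated heats).
* CSP analysis assumes fast exchange and does no peak picking or
  assignment transfer.
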