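# thrombosim

Simulation of tissue-factor-initiated thrombin generation from an
individual's measured plasma composition, with a protein C (PC) pathway
module, thrombogram parameter extraction, cohort-level summaries, and
pedigree-aware variance-component statistics.

## The scientific problem

Venous thromboembolism risk is multicausal: clinically identical PC levels
can hide very different procoagulant phenotypes, because thrombin
generation depends jointly on the whole panel of pro- and anticoagulant
factors.  One way to integrate a subject's factor panel into a phenotype is
to simulate their plasma in a mechanistic clotting model.  This package
does that for the nine-factor panel fII, fV, fVII, fVIII, fIX, fX, AT,
TFPI and PC:

* **Kinetic model.** The Hockin–Jones–Everse–Mann (2002) mass-action model
  of the extrinsic coagulation cascade (34 species, 42 rate constants),
  extended with a PC-pathway module: thrombomodulin (Tm) binding to
  thrombin (IIa) and meizothrombin (mIIa), PC activation by both Tm
  complexes, AT inhibition of the IIa–Tm complex, and APC-mediated
  inactivation of the cofactors fVa and fVIIIa.  The network is shipped as
  a plain-text, row-provenanced transcription
  (`inst/extdata/synthetic_model/`); the PC-module rate constants are
  literature-guided synthetic choices, documented as such.
* **Simulation.** Each subject's panel (converted to nM; percent-of-mean
  inputs are scaled by the physiologic means) initializes the ODE system
  with a 5 pM tissue-factor trigger and 1 nM Tm; a built-in stiff
  Rosenbrock integrator with analytic Jacobian reports every species at
  1 s intervals over 20 minutes.
* **Thrombogram parameters.** Each total-active-thrombin trace
  (`[IIa] + 1.2·[mIIa]`) is reduced to MaxL, TMaxL (peak level and time),
  MaxR, TMaxR (peak rate and time), AUC (µM·s), and clot time CT (first
  crossing of 10 nM).
* **Cohort pipeline.** Inclusion filtering (anticoagulant use, unconfirmed
  events, ...), per-subject simulation with and without the PC pathway,
  group-stratified mean (SD) tables, and mean ± SD envelope curves.
* **Statistics.** Group contrasts with a polygenic mixed model:
  `y = Xβ + g + e`, `cov(g) = 2Φσ²g` from recursive pedigree kinship Φ,
  ML likelihood-ratio tests for group effects adjusted for age and sex
  (Almasy & Blangero 1998).
* **Synthetic cohort.** Because no individual-level data ship with the
  package, a generator emulates a large PC-deficient kindred: 364 subjects
  (81 PC-mutation carriers / 283 non-carriers with printed sex splits),
  moment-matched truncated-normal factor marginals per group, an optional
  514-member raw roster with the study's exclusion counts, and a
  multi-generation pedigree for the statistics.

## Worked example

```r
library(thrombosim)

model <- default_model()
ctrl  <- mean_physiologic_composition()   # Table of physiologic means
tc    <- simulate_subject(model, ctrl)    # 5 pM TF, 1 nM Tm, 1200 s
compute_metrics(tc)
#> MaxL 276 nM @ 961 s | MaxR 2.05 nM/s @ 892 s | AUC 64.8 uM*s | CT 655.6 s

# remove the PC feedback: more thrombin, earlier clotting
compute_metrics(simulate_subject(model, ctrl, sim_config(include_pc = FALSE)))
#> MaxL 374 nM @ 713 s | MaxR 2.8 nM/s @ 646 s | AUC 79.1 uM*s | CT 387.6 s

# carrier-level vs non-carrier-level PC, all else at the physiologic mean
low  <- ctrl; low$PC_nM  <- 47
high <- ctrl; high$PC_nM <- 110
compute_metrics(simulate_subject(model, low))$MaxL_nM    # 318.5
compute_metrics(simulate_subject(model, high))$MaxL_nM   # 185.2
```

The first block says: at mean physiologic composition the model clots
(10 nM thrombin) at ~11 min and peaks at ~276 nM thrombin; removing the PC
pathway raises the peak to ~374 nM and halves the clot time — the PC
module is a pure negative feedback.  The second block shows the carrier
phenotype: lowering PC from the non-carrier group mean (110 nM) to the
carrier group mean (47 nM) raises peak thrombin by ~70%.

Cohort-scale use:

```r
cohort  <- apply_inclusion_filters(generate_cohort(raw_roster = TRUE, seed = 1))
metrics <- run_cohort(cohort, model)            # both pathway arms + control
summarize_groups(metrics, cohort, "pc_mutation", by_sex = TRUE)

ped <- generate_pedigree(founder_pairs = 8, generations = 3,
                         mean_offspring = 3, seed = 1)
Phi <- kinship_matrix(ped)
```

A command-line interface with `simulate`, `cohort`, `validate-model`,
`synth` and `stats` subcommands is in `inst/cli/thrombosim` (see
`?thrombosim_cli`).

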