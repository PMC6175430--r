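# nfstoich

Neurofilament (Nf) isoform stoichiometry, translation energetics and
side-arm brush structure, as one tested R pipeline.

## The problem

Neurofilaments are obligate heteropolymers of light (NfL, 68 kDa, 543 aa),
medium (NfM, 150 kDa, 916 aa) and heavy (NfH, 200–210 kDa, 1020 aa)
subunits that polymerize in humans at a physiological stoichiometry of
NfL:NfM:NfH = 7:3:2. Blood immunoassays measure each subunit against its
own arbitrary calibrator, so raw plasma concentrations carry a systematic
per-assay scale error and their ratios are meaningless as printed. For
anyone studying subunit expression shifts in neurodegeneration (ALS in
particular), `nfstoich` provides:

* **Particle conversion** — g/L → mol/L (divide by molar mass) → particles/L
  (multiply by Avogadro's number, 6.0221415 × 10²³).
* **One-point stoichiometric calibration** — correction factors
  `x = 7/median(NfL)`, `y = 3/median(NfM)`, `z = 2/median(NfH)` computed on
  the control group cancel the assay scales; control medians land on 7:3:2
  exactly, and the disease group's calibrated medians become an
  interpretable stoichiometry (in ALS, an NfL-shifted "adaptive" ratio near
  24:2.4:1.6).
* **Translation cost model** — ATP (5 ATP/amino acid) and synthesis time
  (25 s/100 amino acids) per particle profile, plus a "luxury"
  counterfactual: the cheapest profile proportional to 7:3:2 in which no
  subunit falls below its observed level
  (`s = max(NfL/7, NfM/3, NfH/2)`).
* **Coarse-grained brush Monte Carlo** — Metropolis simulation (Rcpp core)
  of one-bead-per-residue Nf side-arms grafted on hard backbone cylinders
  (31 arms per 50 nm period), interacting by excluded volume and
  Debye–Hückel screened electrostatics at 150 mM, reporting per-species
  radii of gyration under control vs adaptive mixtures and two
  phosphorylation states.
* **Cohort statistics** — Shapiro–Wilk screening, Welch t / Mann–Whitney U,
  one-way GLM (ANOVA) with Kruskal–Wallis, Bonferroni-corrected post hoc
  contrasts gated on omnibus significance, and progression-rate analyses
  (rate = (48 − ALSFRS-r)/months; slow < 0.5, intermediate 0.5–1.0,
  fast > 1.0 points/month).
* **Synthetic cohort generator** — seeded log-normal cohorts with
  configurable group medians, assay-scale distortions and ALS clinimetrics,
  so the entire pipeline is testable without any external data.

## Worked example

```r
library(nfstoich)

cohort     <- generate_cohort(cohort_config(seed = 1))   # 29 controls + 60 ALS
profiles   <- particle_profiles(cohort)                  # particles per litre
cal        <- calibration_factors(profiles)              # x, y, z from controls
calibrated <- apply_calibration(profiles, cal)

cohort_stoichiometry(calibrated)
#> # A tibble: 2 × 4
#>   group     nfl   nfm   nfh
#> 1 ALS      24.4  2.37  1.58
#> 2 control   7    3     2

cohort_cost_table(calibrated)
#> # A tibble: 3 × 7
#>   scenario         group       n atp_mean atp_sd time_h_mean time_h_sd
#> 1 control-adaptive control    29   49237. 15786.       0.684     0.219
#> 2 ALS-adaptive     ALS        60   96071. 37826.       1.33      0.525
#> 3 ALS-luxury       ALS        60  169700. 84886.       2.36      1.18
```

Control medians are exactly 7:3:2 by construction; the ALS group recovers
the configured adaptive stoichiometry (24:2.4:1.6) from raw, assay-distorted
concentrations. The cost table shows the point of the counterfactual:
maintaining the physiological ratio ("ALS-luxury") would nearly double the
per-subject ATP and synthesis-time budget relative to the observed adaptive
composition, while the adaptive composition stays much closer to controls.

A single profile makes the arithmetic transparent: the profile (7, 3, 2)
costs `5 × (7·543 + 3·916 + 2·1020) = 42 945` ATP and
`8 589 aa × 0.25 s = 2 147.25 s`.

Brush simulation:

```r
res <- run_brush_simulation(brush_config(
  stoichiometry = nf_targets(),          # control mixture 7:3:2
  n_backbones = 1,
  arm_specs = scale_sidearms(sidearm_specs(), 0.25),
  species_assignment = "proportional",
  sweeps_equil = 30000, sweeps_prod = 6000, sample_every = 50,
  seed = 501), label = "control")
tidy(res)        # per-species mean ± SD radius of gyration (nm)
autoplot(res)    # bar plot with error bars
```

The end-to-end pipeline (`run_pipeline(pipeline_config(seed = 1))`)
chains all stages with per-stage sub-seeding and writes a JSON report; a
thin command-line wrapper lives in `inst/cli/nf-pipeline.R`.

## Documentation

The methods vignette (`vignettes/nf-stoichiometry.Rmd`) describes the
model assumptions, the synthetic-cohort design, the luxury-counterfactual
anchoring rule, the brush energy model and move set, equilibration
diagnostics, and the limitations of desk-scale runs.
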