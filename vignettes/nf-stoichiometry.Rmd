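---
title: "Neurofilament stoichiometry, translation energetics and brush structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neurofilament stoichiometry, translation energetics and brush structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfstoich)
library(dplyr)
```

## The scientific problem

Neurofilaments (Nf) are obligate heteropolymers of a light (NfL, 68 kDa,
543 aa), a medium (NfM, 150 kDa, 916 aa) and a heavy (NfH, 200–210 kDa,
1020 aa) subunit, polymerizing in humans at a physiological stoichiometry of
NfL:NfM:NfH = 7:3:2. Plasma immunoassays report each subunit on its own
arbitrary calibrator scale, so raw concentrations of the three subunits
cannot be compared directly: the raw control-group medians do not sit at
7:3:2, a purely systematic artefact. `nfstoich` implements the full analysis
chain around that observation:

1. **Particle conversion** — concentrations (g/L) are divided by the subunit
   molar mass and multiplied by Avogadro's number (6.0221415e23),
   giving particle counts per litre.
2. **One-point stoichiometric calibration** — per-channel correction factors
   `x = 7 / median(NfL)`, `y = 3 / median(NfM)`, `z = 2 / median(NfH)` are
   derived from control medians and applied to every subject. Control
   medians then sit at exactly 7:3:2 by construction, and any multiplicative
   assay distortion cancels; the disease group's calibrated medians become
   interpretable as a stoichiometry. In ALS this recovers a strongly
   NfL-shifted "adaptive" ratio near 24:2.4:1.6.
3. **Translation energetics** — each subunit costs 5 ATP per amino acid and
   25 s of synthesis/folding time per 100 amino acids, so a particle profile
   maps linearly onto ATP and time budgets. A "luxury" counterfactual asks
   what the same subject would spend if the physiological 7:3:2 ratio were
   maintained.
4. **Brush Monte Carlo** — a coarse-grained simulation of the unstructured
   C-terminal side-arms grafted on filament backbones quantifies the
   structural consequence of the stoichiometry shift via per-species radii
   of gyration.
5. **Cohort statistics** — Shapiro–Wilk screening, Welch t / Mann–Whitney U,
   one-way GLM (ANOVA) + Kruskal–Wallis, and Bonferroni-corrected post hoc
   contrasts gated on omnibus significance.

## The synthetic cohort generator

No subject-level concentration data are distributed with the package;
instead `generate_cohort()` draws cohorts with the statistical structure the
analysis assumes, so every downstream stage is testable offline.

Per assay (NfL, NfM, NfH-SMI35, NfH-SMI34) and group, concentrations follow
a log-normal law — strictly positive and right-skewed, the standard shape
for blood biomarkers — parameterized by its median and natural-log SD
(default 0.5, a geometric SD of ~1.65). Default group medians are derived
from underlying particle counts `target x 2.5e10 /L`: 7:3:2 for controls and
24:2.4:1.6 for ALS, which puts the control NfL median near 20 pg/mL and the
ALS median near 68 pg/mL — realistic plasma values. Each assay is then
multiplied by a calibrator distortion factor (defaults 1.0 / 0.35 / 2.0 /
2.0) emulating the arbitrary immunoassay scales that the one-point
calibration is designed to cancel.

**Sampling design.** The generator's default mode is *stratified*: each
group × assay sample is drawn by inverse-CDF on a randomly permuted,
per-stratum-jittered `(i - u_i)/n` grid. Marginally every value is
log-normal with the configured parameters, but realized cohort quantiles —
in particular the median, the quantity the calibration and stoichiometry
stages consume — match the configured distribution to well under 1%. This
is deliberate: the generator's purpose is to *encode known group medians as
study conditions* for a median-based pipeline, so the conditions should not
wobble with the seed. An `iid` mode provides ordinary independent draws for
power/type-I-error work.

ALS clinimetrics follow the published cohort profile: baseline ALSFRS-r
approximately normal with mean 34 and SD 6.5 (clamped to 0–48), onset site
with probabilities 0.25/0.73/0.02 (bulbar/limb/both), onset-to-baseline
interval log-normal with median 15 months, follow-up visit 6 months after
baseline with an ALSFRS-r decline drawn Poisson at the subject's own
progression rate. Progression rate is `(48 - ALSFRS-r)/months`; categories
are slow (< 0.5), intermediate (0.5–1.0, closed on both ends, since the
defining phrases are "< 0.5" and "more than 1.0") and fast (> 1.0)
points/month; disease stages are early (40–48), intermediate (25–39) and
late (≤ 24).

What the generator does **not** emulate: assay noise floors and LLoQ
censoring, cross-reactivity between phosphoforms, auto-antibody epitope
masking, age/sex covariate structure, or correlation between isoforms
within a subject. Passing tests therefore demonstrate the correctness of
the pipeline's arithmetic and statistics under the assumed distributional
shape, not robustness to those real-data complications.

## Calibration choices

* The NfH channel defaults to the SMI35 assay alone (`nfh_mode =
  "smi35_only"`); `"sum"` and `"smi34_only"` are available. Because both
  NfH assays observe the same particle pool in the generator, the choice
  cancels after calibration — a property the tests verify.
* Channels are combined **before** factors are computed.
* The sample median is the standard one (mean of the middle two order
  statistics for even n), making calibration exact by construction on the
  control group.
* Raw counts are particles/L; calibrated counts are treated as
  dimensionless stoichiometric shares.

```{r calib}
cohort <- generate_cohort(cohort_config(seed = 1))
profiles <- particle_profiles(cohort)
cal <- calibration_factors(profiles)
calibrated <- apply_calibration(profiles, cal)
cohort_stoichiometry(calibrated)
```

## The luxury counterfactual

The "luxury" scenario rescales a subject's calibrated profile onto the
physiological 7:3:2 ray. The anchoring rule is genuinely open — maintaining
a ratio does not say *at what level* — and the package's default (`anchor =
"max"`) takes the scale `s = max(NfL/7, NfM/3, NfH/2)`, the unique
7:3:2-proportional profile in which **no subunit falls below its observed
value**. The rationale: maintaining the physiological ratio means
synthesizing more of the deficient subunits, not discarding protein that
was measured in plasma. Alternatives (`"nfl"`: match observed NfL;
`"total"`: preserve total particle count) are exposed, and every run's
choice is recorded in the pipeline report. Note the ceiling this rule
implies: for an NfL-anchored ALS profile the luxury/adaptive ATP ratio is
at most 29448/16862.4 ≈ 1.75, so mean ratios well above that cannot arise
from any single-anchor construction.

```{r lux}
atp_cost(luxury_counterfactual(profile_tbl(24, 2.4, 1.6)))$atp_total /
  atp_cost(profile_tbl(24, 2.4, 1.6))$atp_total
```

Constants: 5 ATP per amino acid, 25 s per 100 amino acids; hours are
seconds/3600 with no further adjustment. These are order-of-magnitude
bookkeeping constants, not measurements; per-cohort absolute ATP means
depend on the (undistributed) subject-level data and are not reproduced
here — the package instead asserts the *properties* that survive the
counterfactual construction: per-subject luxury ≥ adaptive, exact linear
oracles (profile (7,3,2) costs 42 945 ATP and 2 147.25 s), and a scenario
GLM in which the luxury mean significantly exceeds both others.

## The brush Monte Carlo model

The unstructured C-terminal tails are modelled one bead per residue (bead
diameter = bond length = 0.6 nm), grafted on hard backbone cylinders
(radius 5 nm) along the periodic z axis of a 200 x 200 x 50 nm box. The
nominal 1.6 nm grafting interval does not tile a 50 nm period, so the
package follows the integer count — 31 sites per backbone per period at
spacing 50/31 ≈ 1.613 nm. Species are assigned to graft sites from the
mixture (multinomially by default; a largest-remainder quota mode
guarantees rare species appear at small site counts). First beads are fixed
on the backbone surface at a uniform random azimuth for the whole run.

Interactions: hard-core excluded volume between non-bonded beads plus
Debye–Hückel screened Coulomb `l_B z_i z_j exp(-kappa r)/r` in kBT units
(Bjerrum length 0.714 nm; `kappa = sqrt(I[M])/0.304` per nm, i.e. a 0.785 nm
screening length at the fixed 150 mM ionic strength), truncated at 2.5 nm
(≈ 3 screening lengths, where even doubly charged bead pairs interact below
0.05 kBT) with minimum-image periodicity in all directions.
Side-arm lengths and charges are *synthetic design inputs*, supplied as an
editable TSV fixture: tail beads NfL 143 / NfM 510 / NfH 606 with
block-uniform charges summing to −25 / −43 / −44, and 0 / 13 / 44 KSP
serine beads that each gain −2 when the phosphorylated state is simulated.

Moves are single-bead crankshaft rotations (uniform angle about the axis
through the flanking beads) for interior beads and uniform sphere
re-orientation for terminal beads — both symmetric proposals accepted with
the Metropolis probability `min(1, exp(-dE))`, preserving bond lengths
exactly. Initial conformations are grown as self-avoiding walks with an
outward bias that decays after the first few beads, so chains start near
coil dimensions rather than as stretched rods (important for equilibration
speed). Energies are tracked incrementally and verified against
from-scratch recomputation to 1e-6 kBT; a Spearman drift diagnostic on the
arm-averaged radius of gyration over the last half of production warns when
a run is under-equilibrated.

**Problem sizes.** The package's own validation runs use one backbone and
quarter-scale arms (36/128/152 beads via `scale_sidearms(specs, 0.25)`)
with 30 000 equilibration and 6 000 production sweeps per mixture over a
few seeds. The equilibration length matters: local crankshaft dynamics
relaxes a chain on a timescale that grows roughly with the square of its
length, and the built-in drift diagnostic shows quarter-scale arms need
tens of thousands of sweeps before the arm-averaged radius of gyration
plateaus — under-equilibrated runs systematically misorder the mixtures
because the denser control brush relaxes more slowly. At these sizes the
species ordering of R_g and the stability of NfL across mixtures are
clearly resolved; the NfH mixture contrast is a small effect on top of
per-arm environmental variability (few NfH arms exist per adaptive-mixture
run by construction), so its direction is checked at fixed seeds while its
magnitude remains within sampling error at desk scale — consistent with
the "minimal" group differences the full-scale analysis reports. Full-length
arms with two backbones are supported but need correspondingly longer
equilibration. Printed F statistics from the original analysis are not
reproduction targets: they depend on a simulation count and degrees of
freedom that are not recoverable.

## Statistics conventions

"GLM" is one-way fixed-effects ANOVA (F with k−1, N−k df) — the analysis
reports only F and two dfs, and covariate adjustment is out of scope.
Kruskal–Wallis is computed alongside; post hoc pairwise Welch t tests run
only when the omnibus ANOVA is significant at 0.05, at a Bonferroni
threshold alpha/m stored at full precision (0.05/6 prints as 0.0083, 0.05/3
truncates to 0.016). Normality screening uses Shapiro–Wilk at 0.05 per
sample with a manual override.

## Reproducibility and numerical notes

* Every stochastic stage derives its own seed from the global seed and the
  stage name via a fixed polynomial string hash (`stage_seed()`), so adding
  a stage never perturbs another stage's stream; all seeds stay below 2^31.
* The Monte Carlo core consumes R's RNG stream, so a `brush_config` seed
  fully determines the trajectory, bit for bit.
* Degenerate inputs: zero concentrations propagate as zero counts; an
  all-zero profile has a zero luxury counterfactual; calibration refuses
  zero control medians and double application; crankshaft moves whose
  flanking beads coincide fall back to uniform sphere sampling (which
  preserves both bond lengths); cells with fewer than two observations are
  skipped (with a warning) in contrast tables.
* Known limitations: no explicit counterions or solvent, no assay noise
  model, no survival or longitudinal modelling, no inter-filament
  free-energy calculation.
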