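---
title: "Quantifying brain FDG-PET and the forebrain-to-hindbrain ratio as a prognostic index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying brain FDG-PET and the forebrain-to-hindbrain ratio as a prognostic index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhrpet)
```

## The scientific problem

After resuscitation from cardiac arrest, the brain suffers a global
hypoxic-ischemic insult (post-cardiac-arrest syndrome, PCAS). Deciding
early which subjects will recover is the central clinical problem, and
regional glucose metabolism imaged by FDG-PET within hours of the insult is
a candidate early marker: metabolic vulnerability increases stepwise from
the brainstem (least vulnerable) toward the cortex (most vulnerable), so
the *pattern* of uptake, not just its global level, carries prognostic
information.

`fhrpet` implements the full quantification-and-prognostication pipeline
for a rat PCAS model:

1. **SUV quantification.** A PET activity volume (kBq/ml) is converted to
   the standardized uptake value,
   \(\mathrm{SUV} = C_{\text{tissue}} / (D_{\text{inj}} / W)\),
   with injected dose \(D\) and body weight \(W\) and a 1 g/ml tissue
   density. Voxels are reduced to per-VOI means against a label atlas;
   left/right labels of paired structures are averaged, subregions (e.g. of
   the hippocampus) merged, and a dedicated whole-brain VOI quantified.
2. **Derived indices.** Per region: the SUV change
   \(\Delta\mathrm{SUV} = \mathrm{SUV}_{\text{baseline}} -
   \mathrm{SUV}_{\text{post-3h}}\) (positive = metabolic decline) and the
   whole-brain-normalized ratio
   \(\mathrm{SUVR} = \mathrm{SUV}_r / \mathrm{SUV}_{\text{whole brain}}\).
   Per subject: the forebrain-to-hindbrain ratio
   \(\mathrm{FHR} = \overline{\mathrm{SUVR}}_{\text{forebrain}} /
   \overline{\mathrm{SUVR}}_{\text{hindbrain}}\) (unweighted means over the
   two region sets; the whole-brain normalizer cancels, so FHR is identical
   whether computed from SUV or SUVR).
3. **Outcome labeling.** Post-2-week Morris water-maze swim time
   dichotomizes subjects: survivors under 50 s are `good`, all others —
   including subjects that died before testing — are `poor`.
4. **Inference.** Mann-Whitney tests compare groups per region, a Wilcoxon
   signed-rank test assesses the paired whole-brain decline, and the
   post-3-hour FHR is evaluated as a classifier by ROC analysis with a
   Youden-optimal cutoff.

Because the motivating study's per-animal scans are not public, the package
ships a calibrated digital phantom and cohort simulator, making the whole
pipeline testable end to end and usable for power/design exploration.

## Region scheme

Sixteen analysis VOIs are quantified (eleven cortical regions, hippocampus,
thalamus, midbrain, pons, medulla) plus the whole brain. The published
analysis never lists the forebrain/hindbrain membership, so the package had
to fix one: the default takes the anatomical forebrain (the eleven cortical
VOIs, hippocampus, thalamus) against the pons and medulla, with the
midbrain in neither set — it is anatomically the mesencephalon, and its
group contrast is weak in the published tables, so assigning it to either
set would be arbitrary. Both sets are plain configuration
(`region_scheme()`), and every report prints the sets actually used.

```{r scheme}
region_scheme()
```

## The synthetic cohort: what it emulates and how it is calibrated

`sample_cohort()` draws per-subject *true* regional SUV tables at two
timepoints (`baseline`, `post3h`) for a cohort of 8 good-outcome and 10
poor-outcome rats (3 of the poor pool dying before behavioral follow-up,
with both PET scans retained), behavioral records, and per-scan metadata
(injected dose ~ 9.5 ± 0.7 MBq, body weight ~ 372.5 ± 23.68 g).

All published calibration distributions are group-level medians with
interquartile ranges; the simulator treats each as a normal distribution
with `sd = IQR/1.349`, truncated to positive support by rejection (a
log-normal family is a configuration switch). The truncation matters only
in the far tail for these parameter values, so programmed medians are
preserved to well within Monte-Carlo error.

A subtlety forced a design decision: the published group tables are not
mutually consistent. Per-region SUV medians taken across animals do not
compose into the published SUVR medians (ratios of medians are not medians
of ratios), and the whole-brain median exceeds every regional median
(the whole-brain VOI includes tissue outside the sixteen analysis regions).
The simulator therefore has two calibration modes:

* **`ratio` (default).** Each subject draws a whole-brain SUV from the
  published whole-brain distribution and an independent SUVR profile from
  the published SUVR distributions; regional SUV is their product. The
  whole-brain draw *is* the shared per-subject global-metabolism effect:
  regional values correlate within animal, and the within-animal ratio
  structure — which is what the FHR measures — matches the published SUVR
  tables by construction. This is the mode under which the prognostic
  signal of the FHR is faithfully reproduced.
* **`direct`.** Regional SUVs are drawn from the published per-region SUV
  distributions with a shared subject effect (weight `subject_effect`,
  default 0.5) that induces within-animal correlation while leaving every
  marginal unchanged. This mode reproduces the per-region SUV table
  exactly, but because those marginals discard the within-animal ratio
  structure, group separation of the FHR is much weaker than in the ratio
  mode — an instructive illustration of why the ratio index needs
  within-animal calibration.

No baseline group table is published, so baseline uptake is
*reconstructed*, not measured: baseline = post-3-hour SUV plus a draw from
the published SUV-change distributions (which may be negative — regional
increases are allowed, and do occur for the hippocampus and medulla lower
quartiles). Positive-support rejection applies to the reconstructed
baseline as well.

Per-group post-2-week swim-time distributions are also unpublished; the
package programs `good` ~ median 40 s (IQR 8) and `poor` ~ median 90 s
(IQR 30), truncated to the 120-second trial cap. These choices place the
two groups on either side of the 50-second rule with the overall survivor
median near the published ~49 s, and give label agreement between the
generator's groups and threshold-assigned outcomes above 95%. Baseline
times/distances and post-2-week distances reuse the published overall
medians/IQRs; swim distance is recorded but never used for labeling.

## The imaging forward model

`build_atlas()` places schematic rectangular VOIs (mirrored across the
sagittal midplane for paired structures, with hippocampal subregion labels)
inside a superellipsoid brain mask on a 64 × 64 × 32 grid at 0.2 × 0.2 ×
0.8 mm spacing — the reconstruction grid of the motivating scanner
protocol. Remaining mask voxels form the dedicated whole-brain label, so
the whole-brain VOI is simulated and quantified as its own region, which is
what makes its published median (above all regional medians) reproducible.
Geometry is deliberately schematic: only label bookkeeping and
partial-volume behavior matter to the analyses; anatomical fidelity is a
non-goal, as are registration error, scatter, dead time and
sinogram/iterative-reconstruction simulation (synthetic volumes are in
atlas space by construction).

`render_scan()` fills each label with the activity concentration implied by
its true SUV and the scan's dose/weight, convolves with an isotropic
(in world units) Gaussian point-spread function of FWHM 1.3 mm — the
scanner's stated central resolution — and adds zero-mean Gaussian noise
proportional to local intensity (`noise_cv`, default 0.05, a typical
ROI-scale noise level for reconstructed small-animal FDG scans). With
noise and PSF set to zero, rendering followed by quantification recovers
every programmed value to machine precision; this exact round trip anchors
the quantification tests. With the realistic PSF, spill-over between VOIs
and the surrounding whole-brain label compresses regional contrast toward
the global mean — the classical partial-volume effect, reproduced here as
a monotone decrease of bias with region size. One practical consequence:
simulated FHR values are compressed toward 1 relative to the true tables,
so the Youden-optimal cutoff estimated from rendered scans sits below the
cutoff implied by the uncompressed published medians. This is a property
of any finite-resolution measurement of the index, not an artifact of the
pipeline.

## Statistical conventions

All conventions are recorded in the objects they affect:

* Quartiles by linear interpolation (R type 7); medians with IQRs
  everywhere.
* Mann-Whitney U uses mid-ranks for ties; U refers to the first (good)
  sample. Exact p by the full null distribution when the combined
  `n ≤ 16` and no ties are present; otherwise a tie-corrected normal
  approximation with continuity correction; a seeded Monte-Carlo
  permutation method is available. Two-sided p is twice the smaller
  one-sided tail, capped at 1.
* Wilcoxon signed-rank drops zero differences, reports the smaller sum,
  and switches from exact (`n ≤ 14`, untied magnitudes) to the
  tie-corrected normal approximation by the same rules.
* Per-region group tables are reported without multiplicity adjustment by
  default, matching the exploratory use of these tables; `p_adjust =
  "holm"` adds a familywise-adjusted column.
* ROC: candidate thresholds at midpoints between adjacent distinct scores
  (± infinite sentinels); calls are `score >= threshold`, higher FHR
  predicting the good outcome (the positive class, configurable). AUC by
  the trapezoid rule, hence exactly `U/(n1*n2)` with ties at half credit.
* Youden cutoff: maximizes `J = sens + spec - 1`; ties break toward the
  larger cutoff (favoring specificity of a good-outcome call). The
  reported cutoff uses the midpoint convention by default; an
  `"observed"` convention (smallest positive-calling observed score) is a
  switch, since published cutoffs from clinical ROC software may follow
  either.
* Outcome boundary: a swim time exactly at the threshold is `poor`
  (strict "less than" rule); the fixed 50-second rule is the default, the
  survivor-median rule is available (`outcome_mode = "median"`).
* The paired comparison of SUVR before/after the insult is not expressed
  through SUV-change ratios: a difference of ratios is not a ratio of
  differences, and the two operations are deliberately not interchanged
  anywhere.

## Determinism and problem sizes

Every stochastic operation takes an explicit seed and runs in a local RNG
scope; the pipeline splits one root seed deterministically per stage
(atlas, cohort, per-scan noise), so a configuration plus a seed reproduces
every table byte for byte. The test suite validates the exact tests by
exhaustive enumeration up to combined `n = 10`, compares exact against
permutation p-values on 500 larger instances, checks simulator calibration
with 200 subjects per group, and exercises the full imaging pipeline over
100 seeded cohorts of study size (8 vs 10) — sizes chosen so the complete
suite runs comfortably on a single CPU while keeping Monte-Carlo error
small relative to the tolerances tested.

## Known limitations

* The phantom's geometry is schematic; absolute partial-volume biases are
  not those of a real rat brain, only their qualitative structure.
* Voxel noise is Gaussian and independent; OSEM-reconstructed PET noise is
  spatially correlated and intensity-dependent in a more complex way.
* Baseline calibration is reconstructed from post-3-hour and SUV-change
  distributions (flagged above), not from measured baseline tables.
* Passing simulation tests demonstrates that the pipeline's operations are
  correct and that the published group structure is recoverable under the
  stated assumptions — it cannot validate the biological claim on new
  animals.
* No AUC confidence intervals (DeLong/bootstrap); the ROC output reports
  the point operating characteristics.
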