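# fhrpet

Regional FDG-PET quantification and forebrain-to-hindbrain ratio (FHR)
prognostication for post-cardiac-arrest brain injury, in R.

## What problem this solves

After resuscitation from cardiac arrest (post-cardiac-arrest syndrome,
PCAS), predicting which subjects will achieve a good neurological outcome
is the key clinical decision. Brain FDG-PET acquired a few hours after the
insult carries that information in its *regional pattern*: cortical
(forebrain) metabolism is most vulnerable to hypoxic-ischemic injury,
brainstem metabolism least. `fhrpet` implements the complete analysis
pipeline for a rat PCAS model, for imaging scientists who want to quantify
such scans, derive the prognostic index, and evaluate it — plus a
calibrated digital phantom and cohort simulator, because the motivating
study's per-animal scans are not public.

The quantities at its core:

- **SUV** — standardized uptake value,
  `SUV = C_tissue / (dose / weight)` (1 g/ml tissue density), computed
  voxelwise and reduced to per-VOI means against a label atlas, with
  left/right averaging of paired structures and subregion merging.
- **ΔSUV** — `SUV_baseline − SUV_post-3h` per region (positive =
  metabolic decline).
- **SUVR** — `SUV_region / SUV_whole-brain`, removing global scaling.
- **FHR** — `mean(SUVR over forebrain VOIs) / mean(SUVR over hindbrain
  VOIs)`; the whole-brain normalizer cancels, so SUV and SUVR give the
  same FHR. Higher FHR predicts a good outcome.
- Outcomes are labeled from post-2-week Morris water-maze swim time
  (survivors under 50 s = good; slower survivors and deaths = poor);
  groups are compared with exact Mann-Whitney / Wilcoxon signed-rank
  tests, and the post-3-hour FHR is evaluated by ROC analysis with a
  Youden-optimal cutoff.

## Worked example

```r
library(fhrpet)

# simulate a study-sized cohort (8 good / 10 poor incl. 3 deaths), render
# PET volumes at both timepoints, quantify, and analyze end to end
rep <- run_experiment(run_config(), seed = 1)
rep
```

```
PCAS FDG-PET study report
  subjects: 18 | outcome threshold: 50 s
  outcomes: good = 8, poor = 10 
  whole-brain baseline vs post-3h: W = 0 , p = 0.000214 
  post-3h FHR ROC: AUC = 0.95 | Youden cutoff = 1.089 (J = 0.9 )
  at cutoff: sensitivity = 1 , specificity = 0.9 
  forebrain set: insular cortex, auditory cortex, cingulate cortex, ...
  hindbrain set: pons, medulla 
```

Reading this: the simulated post-insult scans show the programmed global
metabolic decline (every subject's whole-brain SUV fell; signed-rank
`W = 0`, `p ≈ 2e-4`), and the post-3-hour FHR separates outcome groups
almost perfectly (AUC 0.95 here). The Youden-optimal cutoff from rendered
scans (≈1.09) sits below the cutoff implied by the published group medians
(the scanner point-spread function mixes neighboring tissue and compresses
the index toward 1 — see the methods vignette). Group-level FHRs computed
from the built-in published SUVR medians are 1.353 (good) and 0.913
(poor):

```r
sch <- region_scheme()
cal <- pcas_calibration("suvr")
fhr(setNames(cal$median[cal$group == "good"],
             cal$region[cal$group == "good"]), sch)
#> [1] 1.353457
```

`write_report(rep, "out/")` writes every table (regional group summaries
in the layout of the published tables, per-subject indices, ROC points,
outcome labels, provenance) as CSV/JSON; `analyze_tables()` accepts
externally quantified regional SUV CSVs in place of the imaging stage. A
thin command-line front end with `simulate` / `quantify` / `analyze` /
`report` / `run-all` subcommands lives at `inst/cli/fhrpet.R`.

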