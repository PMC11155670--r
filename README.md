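# ampain

Attention bias malleability (AM) analysis for pain reaction-time paradigms.

## The problem this package addresses

People who direct more attention to pain-related information tend to report
more pain and disability, but a stable attentional bias (AB) has proven to be
a weak predictor of pain outcomes. A newer idea is that what matters is
*malleability*: how readily a person's attentional preference shifts when the
environment starts rewarding attention toward — or away from — pain cues.

The measurement instrument is a five-block dot-probe paradigm. In each trial
a pain word and a neutral word appear briefly, then a probe replaces one of
them. In the three *assessment* blocks (96 trials, probe equally likely at
either word) the AB index is

```
AB = mean RT(incongruent) − mean RT(congruent)      [ms]
```

where *congruent* means the probe appeared at the pain word's location;
positive AB = attention toward pain. Between assessments sit two 288-trial
*training* blocks with a 100% contingency (probe always after the pain word,
or always after the neutral word, order counterbalanced). The malleability
indices are post-minus-pre changes in AB:

```
AM_Towards = AB(after towards training) − AB(before)
AM_Away    = AB(after away training)    − AB(before)
AM_Overall = |AB2 − AB1| + |AB3 − AB2|
```

`ampain` implements, as tested reusable code:

* **Synthetic data generation** with known ground truth: ex-Gaussian RTs
  with person-level bias and training-induced shifts, the full paradigm
  schedule, a 240-s random-interval-repetition (RIR) tone-detection task
  under alternating 24-s pain / no-pain episodes, and questionnaire
  batteries (PCS, DASS-21, GCPS, attention-to-pain).
* **Trial cleaning** exactly as dot-probe studies specify it: incorrect
  responses out, a 200–2000 ms response window, a 2.5 × unscaled-MAD rule
  around the block median within assessment blocks, and exclusion of
  participants under 75% accuracy — with a full per-rule audit report.
* **Scoring**: AB/AM indices per participant; RIR pain-interference deltas
  (RT and error-rate differences, pain minus no-pain) after anticipation
  (<100 ms), omission, episode-endpoint and one-sided 3-SD cleaning;
  questionnaire scale scores.
* **Inference**: two-step hierarchical OLS regressions reporting ΔR²,
  F-change `(ΔR²/df1)/((1−R²_full)/df2)`, standardized b, Cohen's
  f² = ΔR²/(1−R²_full), Bonferroni control (m = 3 indices per outcome), and
  index–trait Pearson correlation tables with significance stars.

## Worked example

```r
library(ampain)
run <- run_pipeline(cohort_config("study2", n_participants = 40, seed = 42))
cat(run_report(run), sep = "\n")
```

```
AM cohort report (study2, n = 40 retained)

Attention indices (ms):
  AB_Baseline  3.95 (16.34)
  AM_Away      -4.92 (18.75)
  AM_Towards   0.31 (18.70)
  AM_Overall   27.80 (19.77)

Correlations with individual-difference measures:
               pcs_total  dass_anxiety  dass_depression  dass_stress
  AB_Baseline      -0.03         -0.10             0.25        -0.11
  AM_Away          -0.06         0.39*            -0.28        0.39*
  ...

Hierarchical regressions:
  gcps_intensity ~ + am_towards_ms: dR2 = 0.05, F(1,35) = 1.95, p = 0.17, b* = 0.25, f2 = 0.06
  ...
```

Reading the output: the simulated cohort has essentially no mean baseline
bias (3.95 ms, SD 16.34) and small directional malleability means, yet a
clearly positive `AM_Overall` (27.80 ms) — the direction-agnostic index is a
sum of absolute values, so RT measurement noise alone keeps it above zero
(the vignette derives its noise floor). Each regression row is one step-2
test: the ΔR² added by one AM index over the controls (gender, age, baseline
AB), its F-change with degrees of freedom, the standardized coefficient and
Cohen's f²; none survives Bonferroni correction here, as expected for a
small cohort simulated with a modest outcome link. Starred correlations in a
40-person table at the nominal .05 level are the expected handful of false
positives.

`run_pipeline(..., out_dir = "...")` additionally writes the cohort CSVs,
the per-participant analysis table, the report as text and JSON, and a
manifest with the seed and MD5 digests of every output, so identical
configurations are verifiably byte-identical. A thin CLI wrapper over the
same functions ships in `inst/cli/ampain.R`
(`Rscript inst/cli/ampain.R full --study study2 --seed 1 --out runs/demo`).

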