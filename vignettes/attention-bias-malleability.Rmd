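---
title: "Measuring attention bias malleability: models, cleaning rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring attention bias malleability: models, cleaning rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampain)
```

## The constructs and the paradigm

The dot-probe paradigm operationalizes pain-related attentional bias (AB) as
a reaction-time contrast: a pain word and a neutral word are shown together,
a probe replaces one of them, and faster responses to probes at the pain
word's location indicate attention toward pain. Per assessment block,

$$AB = \overline{RT}_{\text{incongruent}} - \overline{RT}_{\text{congruent}} \quad [\text{ms}],$$

positive when attention favors pain words. *Attention bias malleability*
(AM) asks a different question than AB itself: how far does a person's bias
move when the task's contingencies start rewarding attention toward (or away
from) pain words? The five-block design — assessment, training, assessment,
training, assessment — yields three AB estimates, and the directional AM
indices are post-minus-pre differences across each training block, with the
direction labels assigned by the counterbalanced training order:

$$AM_{\text{towards}},\ AM_{\text{away}} \in \{AB_2-AB_1,\ AB_3-AB_2\}, \qquad
AM_{\text{overall}} = |AB_2-AB_1| + |AB_3-AB_2|.$$

A note on signs: described in words, these indices are sometimes phrased as
"subtracting the AB after training from the AB before training", which would
be pre-minus-post. We adopt post-minus-pre throughout, because it is the
convention under which the overall formula above is literally the sum of the
two absolute directional indices and under which towards-training produces
positive $AM_{\text{towards}}$ values. `compute_am_indices()` implements only
this convention.

## The generative model behind the simulator

The paradigm prescribes structure (`make_paradigm_schedule()` enforces it
exactly: 96-trial assessment blocks split 48/48 by congruency, 288-trial
fully contingent training blocks, each word pair used 4× per assessment and
12× per training block, pain-word position balanced top/bottom), but no
published generative model for the RTs exists. We chose:

* **Ex-Gaussian RTs** — normal($\mu$, $\sigma$) plus exponential($\tau$) —
  the standard descriptive model for response times, with defaults
  $\mu = 450$, $\sigma = 50$, $\tau = 100$ ms giving a mean around 550 ms
  and a realistic right tail.
* **Bias as a symmetric location shift.** A participant with true bias $b$
  responds $b/2$ faster on congruent and $b/2$ slower on incongruent
  trials, so the AB contrast recovers $b$ without attenuation.
* **Step-and-persist training dynamics.** After each training block the
  true bias shifts by `malleability × shift_towards_ms` (or
  `shift_away_ms`), cumulatively; shifts persist into all later blocks.
  Whether training effects persist into the final assessment is an
  assumption of ours, not an empirical claim — it is the simplest dynamic
  consistent with the scoring formulas, which treat each difference as the
  effect of the intervening training alone.
* **Counterbalancing** of training order, stimulus-list order (all six
  permutations cycled) and pain-first episode order is deterministic in the
  participant index, the simplest scheme consistent with "counterbalanced".

Cohort defaults (`cohort_config()`) were fixed once as the study conditions
the package targets: 53 healthy participants (laboratory study with the RIR
task and heat-pain outcomes) or 71 chronic-pain participants (online study
with the GCPS), baseline bias $\sim N(0, 15)$ ms, malleability
$\sim N(1, 0.5)$ truncated at zero, and small mean training shifts of
$\pm 5$ ms. The small shifts are deliberate: published directional AM means
are only a few ms with SDs near 28 ms, while overall AM means near 40 ms are
largely explained by the noise floor derived below — a generator with large
mean shifts would not resemble the data this instrument actually produces.
Questionnaire scale scores are drawn from the published cohort means/SDs and
then decomposed into integer item responses that sum to the drawn target
(PCS 13 items 0–4; DASS-21 three 7-item subscales 0–3; GCPS 0–10 items),
so item-level scoring is exercised end to end. In the chronic-pain
configuration the GCPS intensity/disability targets are linear in true
overall malleability (`beta_intensity`, `beta_disability` points per ms,
noise SD 20), so a configured null (`beta = 0`) really is a null.

What the simulator does **not** emulate: lexical properties of the word
stimuli (pairs are synthetic tokens), sequential dependencies and practice
or fatigue drifts within a session, speed–accuracy trade-offs (errors are
independent coin flips at the participant's error rate), and any dependence
of RT variance on bias. Passing tests therefore certify the scoring and
inference machinery and the paradigm's arithmetic, not the psychometrics of
real dot-probe data — notoriously including the low reliability of
difference scores, which the simulator reproduces only insofar as its noise
model implies it.

## Cleaning rules and their numerical edge cases

`clean_dotprobe()` applies, in order: (1) incorrect responses removed; (2)
RTs outside [200, 2000] ms removed; (3) within each participant ×
assessment block, RTs with $|RT - \text{median}| > 2.5 \times MAD$ removed,
where the MAD is the raw median absolute deviation from the block median —
**unscaled**, no 1.4826 normal-consistency factor, and two-sided; (4)
participants below 75% accuracy excluded. Decisions worth recording:

* **Accuracy denominator.** Accuracy is computed over all paradigm trials,
  assessment and training alike; the exclusion threshold is strict
  (`< 0.75`, so exactly 75% is retained).
* **Degenerate MAD.** If a block's MAD is 0 (e.g. identical RTs), the rule
  is skipped for that block; applying it literally would delete every
  off-median trial.
* **The MAD step is applied once.** Re-estimating the MAD on already
  filtered data shrinks the window, so iterating the rule to a fixed point
  would keep deleting tail trials; one pass is the field's practice and
  ours. A consequence is that the cleaning function is not mathematically
  idempotent — re-cleaning cleaned data can remove a few more trials via
  the MAD rule (and only via it); the test suite pins down exactly this
  behavior.
* **Attenuation of large biases.** Because the MAD window is computed per
  block rather than per congruency cell, a genuinely large bias (say 40 ms)
  places the two cells asymmetrically in the window and clipping shaves a
  few ms off the measured contrast. With the default noise model this
  attenuation is roughly 5–8 ms at a 40 ms shift and negligible at the
  small shifts typical of real data. Generator-recovery tests therefore
  validate the simulator against raw cell-mean contrasts, and the pipeline
  inherits the (documented) small conservative bias of the published rule.
* **Empty cells are errors, not NAs.** A participant left without congruent
  or incongruent trials in an assessment block triggers a named error (or
  an `empty_block` exclusion in cohort scoring) rather than a silent NA, so
  cohort summaries can never shrink unnoticed.

For the RIR tone task (`clean_rir()`): presses within 100 ms of onset are
anticipations; anticipations and omissions leave the RT set but count as
errors; the first and last tone of every 24-s episode are dropped ("block"
in the cleaning tradition of this task is read as the pain/no-pain episode,
10 per session); and timed RTs more than 3 SDs *above* the participant's
session mean are removed — the rule is one-sided as stated, computed on all
timed responses after anticipation/omission removal. Fewer than two timed
responses make the SD undefined; the rule is then skipped and flagged.
Error rates use the number of presented tones (endpoints excluded) as the
denominator, so anticipations and omissions each count once.

## The inferential layer

`hierarchical_regression()` fits two nested OLS models (controls; controls
plus one AM index) on complete cases and reports

$$F_{\text{change}} = \frac{\Delta R^2 / df_1}{(1 - R^2_{\text{full}}) / df_2},
\qquad f^2 = \frac{\Delta R^2}{1 - R^2_{\text{full}}},$$

with $df_1 = 1$ and $df_2 = n - p_{\text{full}} - 1$. Conventions fixed
here: the reported coefficient is the **standardized** beta (all variables
z-scored); gender enters as a female = 1 indicator; the Bonferroni family is
the three AM indices tested per outcome ($m = 3$), and published $f^2$
values computed by other software from rounded inputs will not always match
this formula exactly. The residual degrees of freedom are reported for the
t statistic; sources that print $t_{(n-1)}$ are using a different label for
the same fit. A focal predictor exactly collinear with the controls adds no
information and is reported as a zero step ($\Delta R^2 = 0$, $F = 0$,
$p = 1$, standardized b undefined) rather than an error; collinearity among
the controls themselves *is* an error naming the offending columns, since
the control block is then misspecified. Correlations are pairwise-complete
Pearson $r$ with $p$ from the $t$ transform on $n - 2$ df; zero-variance
columns yield flagged `NA` cells, never 0.

## The noise floor of the overall malleability index

Because $AM_{\text{overall}}$ sums absolute values, it is positively biased
under the null. If per-block AB estimates are independent with SD
$\sigma_{AB}$ and zero mean, each difference $AB_{k+1} - AB_k$ is
$N(0, 2\sigma_{AB}^2)$, its absolute value has the folded-normal mean
$\sqrt{2}\,\sigma_{AB}\sqrt{2/\pi}$, and

$$E[AM_{\text{overall}}] = 2\sqrt{2}\,\sigma_{AB}\sqrt{2/\pi} \approx 2.26\,\sigma_{AB}.$$

With roughly 44 retained trials per congruency cell and an RT SD of
$\sqrt{\sigma^2 + \tau^2} \approx 112$ ms, $\sigma_{AB} \approx 16$ ms and
the floor sits near 35 ms — the same order as published cohort means of
~40 ms. This is why a large $AM_{\text{overall}}$ mean is *not* evidence
that training moved anyone's bias. The acceptance checks verify the
simulated mean against this closed form within Monte-Carlo error (2,000
simulated participants with homogeneous noise parameters, so the
single-$\sigma_{AB}$ derivation applies exactly).

## Problem sizes and reproducibility

Every stochastic routine takes an explicit integer seed, saves and restores
the caller's RNG state, and cohorts are byte-identical under identical
(config, seed) — the run manifest records MD5 digests to make this
checkable. The shipped checks use: 100 random small datasets for the exact
F-change comparison against `anova()`'s residual-sum-of-squares route
(agreement to $10^{-10}$ relative); 2,000 null replicates at $n = 70$ for
type-I calibration at $\alpha = .05$; 500 replicates at $n = 71$ for ΔR²
recovery at a population value of .10; and 2,000 simulated participants for
the noise-floor check — sizes at which the Monte-Carlo error bands are a
few times smaller than the effects being verified, while a full run stays
in the minutes range on a single CPU.

## Known limitations

* Raw difference scores are used throughout, as in the source instrument;
  no reliability correction (e.g. split-half disattenuation) is applied,
  and none of the usual caveats about difference-score reliability are
  solved here.
* The published human-subject tables can only be reproduced from the
  original raw-data supplements, which this package cannot redistribute;
  the reproduction test documents the expected file layout and remains
  failing until those files are supplied.
* Heat-pain hardware, stimulus presentation software and word-stimulus
  semantics are out of scope; pain threshold/tolerance exist only as
  numeric outcome variables.
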