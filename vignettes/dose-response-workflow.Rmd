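---
title: "Dose-response curve smoothing and phospho-response classification"
author: "doseimpact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-response curve smoothing and phospho-response classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doseimpact)
```

## The experiment and the model

Isothermal dose-response thermal proteome profiling treats cells with a
compound across a concentration ladder at a fixed temperature. At 37 °C
the soluble fraction tracks constitutive protein abundance; under a heat
challenge at 52 °C it tracks thermal stability, which shifts when a ligand
binds. A parallel phosphopeptide enrichment tracks signalling. Every
entity (protein or phosphosite) therefore yields, per replicate and
temperature, a trace of reporter intensities over the dose ladder.

Traces are analysed as **fold changes relative to the untreated (first)
dose**, on **ordinal dose positions** $x_i = 1, \dots, n$ rather than
concentrations. The ordinal scale weights every dose step equally in the
smoother even though the ladder is close to geometric; it is also the
scale on which the run-length statistics below are meaningful.

Each trace is smoothed with a Nadaraya–Watson estimator under a Gaussian
kernel with bandwidth $b$:

$$d_k = \frac{x_k - x_i}{b}, \qquad
  wt_k = \frac{1}{\sqrt{2\pi}}e^{-d_k^2/2}, \qquad
  \hat y_i = \frac{\sum_{k=1}^n wt_k\, y_k}{\sum_{k=1}^n wt_k.}$$

The sum runs over *all* points including $k = i$, so each $\hat y_i$ is a
convex combination of the data: the fitted curve can never leave the range
of the observations, and a constant trace is reproduced exactly. No
sigmoidal model is assumed and no coefficient of determination gates any
result; the deliberate aim is to score non-sigmoidal (e.g. biphasic)
responses that saturating-dose methods discard.

Two families of statistics summarise a fitted curve:

* the **average slope**, the mean tangent over adjacent fitted pairs,
  $\frac{1}{n-1}\sum_i (\hat y_{i+1}-\hat y_i)/(x_{i+1}-x_i)$ — on equally
  spaced positions this telescopes to $(\hat y_n - \hat y_1)/(n-1)$;
* **run lengths**: the longest streaks of strictly increasing and strictly
  decreasing adjacent fitted pairs. Equal neighbours terminate both kinds
  of run; "upward trend" is read strictly so that numerically flat
  stretches never extend a run.

## Preprocessing rules

Applied in this order before any fitting:

1. phosphosites with localization probability **strictly below** 0.5 are
   removed (a site at exactly 0.5 is kept — the rule removes "lower
   than");
2. multiplicity variants of the same site (protein, position, residue)
   collapse to the best-localized row per replicate;
3. peptide rows of the same protein are **summed channel-wise** before
   fitting (aggregation precedes normalization; the two do not commute,
   and summed-then-normalized is the defined order);
4. an entity is kept, per temperature independently, only if **every dose
   channel is strictly positive in both replicates**; the completeness
   rule is applied per dose point, not to trace means;
5. user-specified outlier dose positions are dropped globally (the same
   positions for every trace, as channel-level artifacts warrant);
   surviving points keep their original ordinal labels so kernel
   distances stay on the design scale; at least 3 points must survive;
6. each trace is divided by its first-dose value, so it starts at exactly
   1.

## Response classification

Four thresholds with defaults $T = 0.3$, $C = 5$, $B = 3$, $E = 0.45$
drive a fixed-order decision procedure on the fitted curve:

1. fitted range $\le T$ → **NR** (non-responsive);
2. upward run $\ge B$ *and* downward run $\ge B$ *and*
   $|\hat y_n - \hat y_1| \le E \times \text{range}$ → **biphasic**;
3. average slope $> 0$ and upward run $\ge B$ → **hyper**;
4. average slope $< 0$ and downward run $\ge C$ → **hypo**;
5. otherwise **NR** — the four categories partition all curves, and a
   responsive-range curve with no qualifying run falls through to NR.

Design choices that were genuinely open, and how they were resolved:

* **Biphasic precedence.** Biphasic is tested before hyper/hypo: a bell
  curve always carries a small net slope, and testing the monotone
  classes first would absorb it into hyper or hypo. The choice is pinned
  by tests.
* **Biphasic run requirement.** Both arms use $B$ by default; the
  alternative of requiring $C$ on the downward arm is available as
  `run_config(biphasic_down_run = "C")`.
* **End-difference scaling.** The end condition compares
  $|\hat y_n - \hat y_1|$ against $E \times \text{fitted range}$ by
  default; the alternative reading against $E \times T$ is available as
  `run_config(end_rule = "threshold")`.
* **Replicates.** Each replicate is fitted and classified independently; a
  final responsive call requires the two categories to agree, and the
  entity's summary slope is always the replicate mean. The replicate
  count is fixed at two — more replicates raise an error rather than
  silently switching to a majority rule.

The phospho-response map plots each site's longest upward run of the
*mean* fitted curve (x) against its mean average slope (y). The longest
run was chosen over the total count of upward intervals as the x-axis
metric; `upward_interval_metric()` isolates the choice so it can be
swapped.

## Proteome impact and enrichment

Per protein the mean (over replicates) average slope at 37 °C and at
52 °C forms one point on the impact map. A protein is a **hit** when
either slope exceeds the threshold (default 0.5) **in magnitude** — the
two-sided reading, since destabilized and down-regulated proteins sit on
the negative side of the map; `run_config(hit_rule = "positive")` gives
the one-sided variant. A protein missing one temperature is kept with that
axis reported `NA` and the hit call made on the present axis. No
replicate-concordance requirement is imposed at the protein level; the
threshold applies to the replicate-mean slope only.

One structural consequence of first-dose normalization is worth noting:
a decreasing trace is bounded in $(0, 1]$, so its average slope can never
fall below $-1/(n-1) \approx -0.125$ on a 9-dose ladder, while an
increasing trace is unbounded above. With the default threshold of 0.5
the negative half of the impact map is therefore empty of hits on this
scale; destabilization manifests as a clearly negative — but small —
stability slope.

Gene-set over-representation uses the exact upper-tail hypergeometric
probability $p = \sum_{j\ge k}\binom{K}{j}\binom{N-K}{n-j}/\binom{N}{n}$
with the background $N$ being all identified proteins and each set
intersected with the background first. Significance is called on the raw
$p < 0.05$, as the method defines; a Benjamini–Hochberg column is emitted
alongside for the user but does not drive the flag.

## Tunable parameters

| parameter | default | units / scale | role |
|---|---|---|---|
| `bandwidth` (b) | 1.0 | ordinal dose positions | kernel width; 1.0 gives mild smoothing at unit spacing. Smaller tracks noise, larger flattens biphasic peaks |
| `range_T` (T) | 0.3 | fold-change units | responsiveness gate on the fitted range |
| `up_run_B` (B) | 3 | adjacent pairs | minimum upward streak for hyper and biphasic |
| `down_run_C` (C) | 5 | adjacent pairs | minimum downward streak for hypo |
| `end_factor_E` (E) | 0.45 | fraction | how closely a biphasic curve must return to its start |
| `hit_threshold` | 0.5 | fold change / dose step | impact-map hit gate |
| `min_localization` | 0.5 | probability | phosphosite confidence filter |

The bandwidth is deliberately user-facing (it is the one smoothing
parameter); all defaults can also be supplied via a flat key-value
configuration file (`read_run_config()`) or CLI flags.

## The synthetic-data generator

`synth_spec()`/`make_dataset()` emit datasets in the same MaxQuant-like
TSV schema the readers consume, with known generating labels, so every
downstream stage is testable without raw mass-spectrometry data. The
generator emulates:

* the 9-dose ladder (0–10 µM) with one reporter channel per dose;
* two biological replicates sharing each entity's pattern but not its
  noise draws;
* four phosphosite patterns — sigmoid rise (hyper, amplitude 0.6),
  mirrored fall (hypo, amplitude 1.0), Gaussian bell (biphasic, amplitude
  0.8) and flat — whose noise-free *fitted* ranges (0.55, 0.47, 0.57 at
  b = 1) clear the default T = 0.3 by at least 50 %, while flat stays
  well under it; amplitudes were fixed once from this margin requirement;
* protein patterns: thermally stabilized and abundance-responsive
  (amplitude 6, slope ≈ 0.63 > 0.5, truth hits), destabilized (negative
  stability slope, not a truth hit — see the normalization note above)
  and flat;
* multiplicative log-normal noise, $y_i = \text{base}\cdot
  s(x_i)\cdot e^{\varepsilon_i}$ with $\varepsilon_i \sim N(0,
  \sigma^2)$, default $\sigma = 0.05$ — reporter intensities are positive
  and heteroscedastic, and multiplicative noise keeps the completeness
  filter satisfiable.

Truth labels are defined by the generating pattern, never by post-hoc
classification, so recovery tests are not circular. What the generator
does **not** emulate: missing channels, co-isolation interference,
multi-plex batch effects, peptide-level variance within a protein, or any
spectrum-level artifact. Passing recovery tests therefore demonstrate the
correctness of the analytics, not robustness to every failure mode of
real data.

## Numerical choices and degenerate inputs

* The smoother is evaluated as a centered weighted mean, which is
  algebraically identical but keeps a constant trace exactly constant in
  floating point (no spurious runs of length 1 from last-ulp wobble).
* Internally all traces sharing positions and bandwidth are smoothed with
  one matrix product; tests pin its agreement with the per-trace path to
  1e-12. Test-suite and acceptance runs use up to 10,000 sites, which the
  matrix path processes in seconds.
* Bandwidth must be strictly positive; as $b \to 0^+$ the fit approaches
  the data pointwise, as $b \to \infty$ it approaches the trace mean.
* Fewer than 3 surviving dose points, a zero first-dose intensity, NA
  fold changes, or non-increasing positions are hard errors, not silent
  repairs. Malformed input rows are counted and reported; parsed plus
  rejected always equals total.
* Ties in fitted values break runs in both directions (strict
  inequalities throughout).

## Known limitations

* The 37 °C and 52 °C arms are analysed as independent curves; no joint
  model links abundance to stability.
* No EC50/IC50 or melting-point estimation — the average slope is
  deliberately a model-free summary on the ordinal scale, so its value
  depends on the dose ladder layout.
* Enrichment requires user-supplied gene sets; no pathway database is
  bundled, avoiding version drift.
* The classification thresholds are heuristics to be tuned per dataset;
  no significance measure is attached to a category call.
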