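---
title: "Responder classification and per-subject glyph charts for two-arm trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Responder classification and per-subject glyph charts for two-arm trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(visualdata)
```

## Why per-subject reporting

The standard results table of a randomized controlled trial reports group
means with standard deviations and omnibus p-values. That summary answers
"did the average change differ between arms?" but hides everything about
individual response: a significant mean improvement is compatible with a
quarter of subjects not responding and a further fraction actively worsening,
and a non-significant contrast is compatible with substantial responder
subgroups. `visualdata` implements the complementary, categorical view: every
subject's change on every outcome is classified as **improved**, **no
change**, **worsened** or **missing**, and the whole study is drawn as a grid
of per-subject glyph clusters — one large circle for the primary outcome and
small circles for the secondary outcomes, colored green / yellow / red /
gray. The conventional mean (SD) + ANOVA table is produced alongside, so the
two presentations can be contrasted for the same data.

## The classification model

For subject $i$ and outcome $j$ with observed pre- and post-intervention
values, the change score is $\Delta_{ij} = \text{post}_{ij} -
\text{pre}_{ij}$. A cell with a missing pre or post value is `MISSING` and no
rule is evaluated for it. Each outcome declares a *benefit direction* (there
is deliberately no default), and one of four cut-off rules:

* **Delta zero.** $\Delta = 0$ is `NO_CHANGE`; any nonzero change in the
  benefit direction is `IMPROVED`, otherwise `WORSENED`. Appropriate for
  outcomes that essentially always move under treatment; it knowingly
  ignores measurement error, which is why the MDD rule exists.
* **Risk threshold.** A clinically established minimum change $t > 0$:
  $|\Delta| \ge t$ in the benefit direction is `IMPROVED`, $|\Delta| \ge t$
  against it is `WORSENED`, smaller changes are `NO_CHANGE`. The boundary is
  inclusive — a change of exactly $t$ counts as a response — because the
  clinical phrasing of such thresholds ("a reduction of 3 mmHg") reads as
  attained at the stated value; the choice is documented here and pinned by
  tests so it stays auditable. A small registry ships with conventional
  values (blood pressure 3 mmHg, arterial stiffness 1 m/s, flow-mediated
  dilation 1 percentage point) and is user-extensible. The conventional
  resting-heart-rate criterion of 75 bpm is a *level*, not a change score,
  so it is excluded from the registry and requesting it raises an error
  rather than silently misclassifying.
* **Quantile split.** Tertiles ($k=3$) or quartiles ($k=4$) of the observed
  deltas: the extreme group in the benefit direction is `IMPROVED`, the
  opposite extreme `WORSENED`, the middle group(s) `NO_CHANGE`. Sample
  quantiles use the inclusive linear-interpolation definition
  (`stats::quantile` type 7). A delta lying exactly on a cut goes to the
  more central group, so fully degenerate data (all deltas identical) is all
  `NO_CHANGE`. Quantiles are computed **within each arm** by default: pooled
  quantiles would let an imbalance between arms leak into individual
  classification. A `scope: study` option pools them on request.
* **Minimal detectable difference (MDD).** The smallest individual change
  exceeding measurement error at confidence level $c$:
  $\mathrm{MDD} = z_{(1+c)/2}\,\sqrt{2}\,\mathrm{SEM}$, the $\sqrt{2}$
  arising because a change score accumulates the error of two measurements.
  The threshold is then applied exactly like a risk threshold. The SEM can
  be given directly or derived from test–retest reliability as
  $\mathrm{SEM} = \mathrm{SD}_{\text{baseline}}\sqrt{1 - \mathrm{ICC}}$.
  Default confidence is 0.95.

Per-arm response percentages use the full arm size (missing included) as the
denominator by default, so "25% showed no change" refers to the enrolled
arm, not the analyzable subset; `denominator: observed` switches to the
complete-case denominator.

## The conventional table

For contrast, `summary_table()` reproduces the familiar presentation: mean
(SD) per arm and timepoint plus time, group and interaction p-values from a
two-way mixed-design (split-plot) ANOVA — arm as the between-subjects
factor, time as the within-subjects factor — fitted via `stats::aov` with a
subject error stratum. Subjects missing either value of an outcome are
dropped for that outcome (listwise deletion; the count is reported).
Degenerate inputs are made explicit: an effect with zero sum of squares has
$F = 0$, $p = 1$. P-values below 0.001 display as `<0.001`; stored values
stay exact. No multiplicity correction is applied across outcomes — none is
performed in the table this mirrors. The test suite pins the implementation
to an independently coded cell-means sums-of-squares decomposition at
relative tolerance $10^{-10}$ and to a 10,000-shuffle permutation oracle
(arm relabelling for group and interaction, pre/post swaps for time); note
that with only 5 subjects per arm the between-arm permutation null is
supported on 252 points and genuinely sits up to about 0.1 from the
$F(1,8)$ reference, so close numerical agreement is only demanded at the
40-subject comparison.

## The glyph chart

Each subject is a cluster: the primary-outcome circle (default radius 12
user units) at the cluster origin and the secondary circles (default radius
ratio 0.45) at equal angular spacing on a 180° arc below it, pushed out far
enough that no two circles of a cluster can touch regardless of how many
secondaries there are. One panel per arm, stacked in configured arm order;
clusters flow left-to-right, top-to-bottom ordered by subject id (a
`sort_by = "status"` option groups responders first — the chart's reading
does not depend on subject order, so id order is the reproducible default).
Default palette: green `#1E8F4E`, yellow `#F2C200`, red `#D7301F`, gray
`#BDBDBD`, overridable in the config. Instead of pictogram artwork inside
the circles, an optional 1–2 character text label identifies outcomes;
labels preserve the identification function without bundling vector art.

Output is standalone SVG 1.1 with native y-down coordinates. Every glyph
circle carries `data-subject`, `data-outcome` and `data-status` attributes,
which makes the chart *invertible*: `svg_status_matrix()` recovers the exact
status matrix from the file, and the test suite uses this round trip as an
invariant. Rendering is deterministic — no timestamps, no generated ids —
so identical classified studies produce byte-identical files. The legend is
drawn with rectangles so that the number of `circle` elements always equals
the number of classified cells.

## The synthetic-study generator

No subject-level data accompanies the summary tables this package's worked
examples mirror, so the examples are *reconstructed*: `generate_study()`
produces a dataset whose per-arm responder mix is exact **and** whose
realized pre/post means and SDs round to the published cells at their
printed precision. The construction, per arm and outcome:

1. Baseline values are drawn from a normal distribution and affinely
   rescaled so the observed pre mean/SD match the target exactly. Normality
   is a conventional illustrative choice; nothing in the classification
   logic depends on it.
2. Each subject receives a response class. Under `baseline_rank` assignment
   (the default) responders are taken from the end of the baseline
   distribution with room to move toward the post target — the
   regression-to-the-mean pattern seen in real trial data, and the only
   assignment that keeps tightly constrained targets (e.g. a post SD
   smaller than the pre SD under bounded no-change boxes) feasible. The
   `random` strategy assigns classes independently of baseline and is used
   where delta–baseline independence matters more than tight moments, as in
   the renal-function example whose paired-test behaviour is part of the
   story.
3. Post values are found by alternating projection between (a) the box each
   subject's class imposes on its post value under the outcome's rule
   (improved above/below the threshold, no-change inside it — pinned to
   `post = pre` exactly for delta-zero — with a small interior margin of
   $10^{-6}\,\max(t,1)$, or $10^{-3}$ for the strict delta-zero
   inequalities, so later floating-point slop cannot flip a class) and
   (b) the set of vectors with exactly the target post mean and SD. The
   iteration (up to 5000 sweeps, convergence at $10^{-9}$) either converges
   or raises a constraint error explaining that the requested mix is
   incompatible with the requested moments; it never returns data that do
   not match their description. After generation the study is re-classified
   through the public path and the realized moments re-rounded as a
   contract check.

A responder mix cannot be *enforced* under the quantile rule — that rule
fixes its own group proportions — so the generator rejects the combination
rather than pretending.

The generator is a pure function of its spec including the seed, and the
caller's RNG stream is left untouched. Because the mix is enforced by
construction and the moments are matched by projection, the classification
counts and the rounded moments are seed-invariant; different seeds vary only
the individual values.

### The packaged example studies

* `fixture_f5()` — 20 subjects, one arm, one increase-is-better outcome
  (`renal_function`) under delta-zero: 12 improved / 5 no change / 3
  worsened, pre 97.1 (2.1), post 98.9 (3.7). The group mean improves
  significantly while 25% show no change and 15% worsen — the
  adverse-reaction pattern a means-only table cannot show.
* `fixture_f2()` — 80 subjects in two arms of 40, four vascular outcomes
  with mixed rules (3 mmHg blood-pressure threshold as primary; MDD with
  SEM 1.5 ms for heart-rate variability; 1 m/s and 1 percentage-point
  thresholds; two missing endothelial measurements). All 32 summary cells
  match their printed values at printed precision. The responder mixes are
  *not* published values: they are illustrative choices satisfying the
  narrated pattern (most experimental subjects respond on the primary
  outcome, few controls do, secondaries heterogeneous), checked for
  feasibility against the printed moments before being fixed.
* `fixture_f4()` — the "statistically significant but not clinically
  meaningful" case: interaction p < 0.001 for cerebral blood flow under a
  2 mL/min threshold, yet nobody worsens and most subjects show no
  clinically relevant change. The published table has the control arm
  carrying the blood-flow change; the fixture reproduces the numbers as
  printed.

Default seeds are 105, 102 and 104 respectively.

## Worked example

```{r example, eval = FALSE}
study <- fixture_f5()
cl <- classify_study(study)
response_counts(cl, "Intervention", "renal_function")
render_svg(layout_study(cl, columns_per_panel = 5), "renal.svg")

f2 <- fixture_f2()
summary_table(f2)
```

From the shell, the same pipeline is available through the bundled script
(`system.file("cli", "visualdata.R", package = "visualdata")`): `simulate`,
`classify`, `render`, `summarize`, with exit codes 0 / 2 (validation) /
3 (I/O).

## What the synthetic data does and does not show

The generator emulates: two-timepoint, two-arm (or single-arm) designs,
normal-ish baselines, prescribed responder mixes, prescribed missingness
counts, and exact low-order moments. It does not emulate: skewed or
heavy-tailed outcomes, floor/ceiling effects, informative dropout,
measurement error correlated across outcomes, or more than two timepoints.
Tests passing on these fixtures therefore demonstrate that the
classification, summarisation and rendering machinery is correct and
reproducible — not that any particular clinical conclusion generalises.
Problem sizes used throughout the suite (studies of 8–80 subjects, 1,000
randomized property datasets, 10,000 permutation shuffles) were chosen as
the smallest sizes at which every property is exercised meaningfully.

## Known limitations

* Two timepoints and flat CSV input only; no long format, crossover or
  covariates (out of scope by design).
* The delta-zero rule is implemented exactly as stated — stored-precision
  equality with 0 — although real data virtually never yields exact zeros;
  use MDD when measurement error matters.
* Statuses are descriptive: no inference is performed on responder
  proportions, and no multiplicity adjustment is offered.
* The level-based heart-rate criterion is unsupported pending a defensible
  change-score formulation.
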