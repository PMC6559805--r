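---
title: "Landmark analysis of meiotic progression: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark analysis of meiotic progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meiolandmark)
```

## The problem and the model

Live-cell imaging of Arabidopsis male meiocytes yields, per cell and per
frame, an annotation of five ordered morphological parameters: cell shape,
microtubule (MT) array, nucleus position, nucleolus position, and
chromatin/REC8 pattern. Each parameter advances through a fixed sequence of
discrete states (e.g. cell shape: rectangular, trapezoidal, oval, circular,
triangular, tetrad), and in wild type the advance is unidirectional — a
parameter never returns to an earlier state. The tuple of the five
parameter states at one time point is a *cellular state*, written
`a-b-c-d-e`. The wild-type ontology (6, 15, 7, 4, 8 states) spans 20,160
possible tuples, of which real data occupy only on the order of a hundred.

Raw state frequencies are a poor measure of biological importance: a state
that depicts a long phase (pachytene) accumulates far more frames than an
equally obligatory but short one (metaphase I). The *neighboring score*
removes this duration bias by comparing each observed state with its
observed neighbors only:

$$\mathrm{score}(s) \;=\; \frac{\mathrm{count}(s) -
  \overline{\mathrm{count}}(N_s)}{\mathrm{sd}_{\mathrm{pop}}(\mathrm{count}(N_s))}$$

where $N_s$ is the set of *observed* states differing from $s$ by exactly
±1 in at least one and at most two parameters. States with score strictly
above 1 are *landmarks* — convergence points every cell passes through;
the remaining observed states are *transition states*, the variable routes
between landmarks.

## Conventions where the formula is silent

Several cases are undefined by the formula; the package fixes them
explicitly and records them in every output manifest:

* **Standard deviation.** The population (divide-by-$n$) form. The common
  numeric stacks default to it, and it is validated against the published
  zygotene-landmark score (A3, `2-2-2-3-3`: count 497, score 1.32) whenever
  the archived reference table is available (see the acceptance test).
  Whether the original analysis used the sample form instead is not
  documented; the choice is isolated in one function.
* **Zero neighbor spread.** If all observed neighbors share one count, the
  score is $+\infty$ (sentinel) when the state's count exceeds it, 0 when
  equal, $-\infty$ when below. The $+\infty$ sentinel exceeds any landmark
  threshold — a clearly dominant state stays a landmark.
* **No observed neighbor.** $+\infty$ with a distinct flag
  (`no_neighbors`), so isolated states are reported, not dropped.
* **Threshold.** Strictly greater than 1.
* **Frequencies** are percentages of *complete* observations only; rows
  with any unannotated parameter (CSV value `"n"`, `NA` internally) never
  enter state counts, but they are first-class data elsewhere (they feed
  co-occurrence denominators and break transition adjacency).

## Resampling

Movies were acquired at 3–15 min intervals; co-occurrence counting first
puts all trajectories on a common grid (default 15 min, the coarsest
interval). The package subsamples: a grid is anchored at each trajectory's
first frame and the nearest original observation to each grid point is
retained, ties resolved toward the earlier frame, at most one observation
per grid point. Nothing is interpolated — the output is always a
subsequence of the input, so no fabricated states can enter any count.

## Co-occurrence normalisation

For a parameter pair, cell $(i, j)$ counts retained observations with both
parameters annotated. Column totals, however, include observations where
the *partner* parameter is unannotated. Normalised columns therefore sum
to the column's non-missing fraction, not to 1 — this is deliberate and
prominent in the class documentation, because it is the literal reading of
the normalisation rule and it changes how the heat maps must be read.

## Bootstrap

Stability of scores and landmark calls is assessed by resampling the
complete observations with replacement to 1.5× the original size
(default), rescoring, and repeating (default 1000×; the recovery tests use
200). Two conventions are decisions, recorded in the output metadata: the
resampling unit is the individual observation row (cell-level resampling
is a plausible alternative the package does not implement), and a state
absent from a replicate simply contributes nothing to that replicate's
statistics — per-state summaries aggregate over the replicates containing
the state. $+\infty$ sentinels are excluded from mean/sd/quantiles and
tallied separately to keep summaries finite; they count toward the
landmark fraction.

## Transition network and the off-scheme rule

Edges are direct observed changes: consecutive complete frames of one cell
with different states. Persistence is not an edge, and any incomplete
frame breaks adjacency — a bridged edge could span several real
transitions. The "fits the landmark scheme" flag is an explicit
formalisation of an informal notion: a state is compliant iff, for some
consecutive landmark pair, every parameter lies within the closed interval
spanned by that pair. The exported metadata labels it as an
interpretation; the published off-scheme percentage used an unstated
criterion and is not a target here.

## Durations

Timelines come from landmark-labelled trajectories (either labelled
directly, or via `assignLandmarks()` on an annotated dataset). The
duration of landmark $L$ is onset-to-onset: the time of the first frame
labelled with the *next* landmark minus the time of the first frame
labelled $L$. This is the only convention consistent with the folding
rule that transition frames between two landmarks belong to the preceding
landmark. Censoring rules:

* a run starting at the first frame of a movie is left-censored (its true
  onset predates the movie);
* the final landmark of a series is right-censored (no next onset);
* runs of missing frames are bridged iff flanked by the same landmark,
  otherwise both flanking occurrences are censored (whether the original
  analysis bridged such gaps is undocumented; the rule is recorded in
  output metadata);
* a cell contributes records only if it has at least two observed onsets,
  and a cell whose labels regress against the declared landmark order is
  skipped with a warning.

On a fully observed trajectory these rules make the complete durations sum
exactly to last onset − first onset (a conservation law the tests assert).
Censored occurrences are reported, not summarised; there is no
survival-analysis treatment. Box-plot outliers use the 1.5×IQR rule.

## The synthetic generator

The generator exists so that every stage is testable without microscopy
data; its defaults are the study conditions, fixed once:

* **Shape.** 169 cells over 35 anthers (wild type); each anther is one
  movie with its own frame interval, drawn from {3, 5, 10, 15} min with
  weights (.05, .15, .4, .4) so that cells carry on the order of 110–130
  frames, and its own window of U(600, 1800) min placed over the ~37 h
  timeline — movies capture subsections of meiosis, as in the study.
* **Dwells.** Per-landmark gamma dwell times (CV 0.3, truncated at one
  frame) with means from the published wild-type timeline: A1 510 min,
  A2 90, A3/A4 180 each, A5/A6 285 each, A7 180, A8 60, A9 60, A10/A11
  120 each, paired phases split evenly. Only medians/boxplots are
  published, so any right-skewed positive law is defensible; gamma gives
  two-parameter control.
* **Routes.** Between consecutive landmarks the differing parameters
  advance one unit step at a time in a uniformly random interleaving —
  the "alternative routes" structure — with each intermediate state held
  for an exponential dwell of mean 2 min. Published data constrain no
  transition-state dwell; 2 min is a test-power placeholder chosen so
  that the folding rule's additive bias (≈2 intermediates × 2 min) stays
  well under 15% of the shortest 60-min landmark dwell. It is not
  presented as biology.
* **Landmark tuples.** Only the zygotene landmark A3 (`2-2-2-3-3`) and
  START (`1-1-1-1-1`) are published as tuples; the other rows of
  `wtLandmarkPath()` are synthetic stand-ins. They are designed so that
  consecutive landmarks are never neighbors of each other (≥3 differing
  unit steps, or one parameter jumping by 2). This matters for
  identifiability: if two adjacent landmarks were neighbors, the shorter
  one's score would be depressed by the longer one's count and planted
  landmarks would not be cleanly recoverable. A corollary of the chosen
  spacing (gaps of 2–4 unit steps) is that every possible intermediate
  state has at least one landmark among its neighbors, which pins
  transition-state scores far below 1.
* **Missingness.** Whole frames are dropped with probability 0.32 and
  individual parameters with 0.033, reproducing the study's observed
  fractions (~32% fully unannotated rows, ~42% rows with ≥1 unannotated
  parameter).
* **tam scenario.** Two routes through a shared trunk (population A via
  the ectopic-MT landmark at weight 0.458, population B at 0.542), 62
  cells over 19 anthers, extended leptotene and late-prophase dwells, no
  meiosis II landmarks. Labels and tuples are illustrative stand-ins.

Ground truth (routes, realised dwells, noiseless frames) is emitted next
to every dataset, and a JSON sidecar can be written with
`writeGroundTruth()`.

What the generator does *not* emulate: optics (photobleaching, focal
drift), annotator behaviour (its missingness is independent per frame and
parameter, whereas real missingness clusters in time and by parameter),
back-and-forth mis-annotation, or biological regression. Passing recovery
tests therefore shows that the pipeline inverts its own generative
assumptions at realistic sample sizes and noise levels — not that those
assumptions hold in any particular experiment.

## Problem sizes and numerical choices in the tests

The recovery tests run the full default wild-type shape (~20,000 rows) with
200 bootstrap replicates; property suites use 10,000 random state pairs
and dozens of random count tables; unit fixtures are hand-sized. Dwell
recovery is checked on a generator variant with near-complete labels
(`pParamMissing = 0`, `pFrameMissing = 0.05`): this emulates the movies
that were annotated with the landmark system *directly* for the timeline
analyses, where a frame's landmark is nearly always assignable. Under the
five-parameter missingness regime (~42% incomplete rows), the censoring
rules above discard most occurrences — correctly, but leaving too few
records for a meaningful recovery comparison; the vignette states this so
the choice is transparent.

Degenerate inputs are defined, not rejected: empty datasets yield empty
score tables; an all-missing trajectory contributes nothing anywhere; a
single observed state is an (infinite-score) landmark; empty co-occurrence
columns are flagged rather than divided by zero.

## Known limitations

* The landmark labels A1–A11 are user-supplied annotations on extracted
  states; the package does not name landmarks automatically.
* Censored durations are discarded (as in the original analysis), so mean
  dwells are conditional on complete observation; systematically long
  landmarks are under-sampled by short movies.
* The off-scheme flag is an interpretation (see above).
* The neighboring score treats parameters symmetrically and at unit
  spacing; ontologies whose states are not approximately equally spaced
  in "progression distance" would need a rescaled neighbor relation.
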