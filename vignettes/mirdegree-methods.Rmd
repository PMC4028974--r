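---
title: "Ranking dysregulated miRNAs by target network centrality: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking dysregulated miRNAs by target network centrality: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirdegree)
```

## The problem and the model

Differential-expression screens of microRNAs produce long candidate lists,
and the usual triage — carry forward the most extremely dysregulated miRNAs —
ignores what those miRNAs actually regulate. A miRNA with a modest 2.5-fold
shift that represses hub proteins of the protein–protein interaction (PPI)
network can matter more than a 100-fold shift in a miRNA whose targets are
peripheral. mirdegree operationalizes that idea with a deliberately simple
score: for each dysregulated miRNA $m$ with validated target set $T(m)$,

$$S(m) \;=\; \sum_{t \in T(m) \cap V(G)} \deg_G(t),$$

the sum of PPI node degrees over its validated targets present in the graph
$G$. Candidates are miRNAs with large $S(m)$; a quadrant plot of
$\log_{10}$ fold change against $S(m)$ separates high-connectivity oncomiRs
(up in the tumorigenic condition) from high-connectivity suppressors (lost
in it). The score makes no causal claim: it is a prioritization statistic
for deciding which miRNAs to validate at the bench.

The supporting analysis has three legs, each implemented as its own module:

1. **Network centralities.** Degree, closeness and stress profiles of a
   targeted subnetwork versus a size-matched random-protein baseline show
   whether miRNA targets are preferentially central.
2. **Pathway over-representation.** Hypergeometric tests with Bonferroni
   correction ask whether the targets concentrate in coherent pathways.
3. **Expression processing.** qPCR Ct plates from two conditions, profiled
   in duplicate, become 2^-ddCt fold changes; only concordantly >2-fold
   miRNAs are called dysregulated and ranked.

## Centrality definitions and numerics

All graphs are simple and undirected with unit edge lengths; self-loops are
dropped at construction and duplicate edges collapsed.

* **Degree** is the incident-edge count.
* **Closeness** is the unnormalized reciprocal farness restricted to the
  node's connected component: $C(v) = 1/\sum_{u \in \mathrm{comp}(v), u \ne v}
  d(v,u)$, with $C(v) = 0$ for isolated nodes. Distances to other components
  are excluded rather than treated as infinite — the convention of the
  CentiScaPe era of network-biology tools. A consequence worth knowing:
  larger components mechanically give smaller closeness values, so closeness
  is comparable within a graph, not across graphs of different size.
* **Stress** counts, over all unordered pairs $\{s,t\}$ with $s \ne v \ne t$,
  the shortest $s$–$t$ paths through $v$: $\sigma_{st}(v) = \sigma_{sv}
  \sigma_{vt}$ when $d(s,v)+d(v,t)=d(s,t)$, else 0. Each unordered pair is
  counted once; leaves and isolated nodes score 0.

Stress uses one BFS per source with Brandes-style accumulation of path
counts ($O(nm)$ total), so exact values are cheap up to the few-thousand-node
graphs this package is meant for. Path counts are accumulated in double
precision; they are exact integers well past any graph size that is sensible
here. The test suite checks all three centralities against an independent
oracle that enumerates every shortest path explicitly (via igraph) on graphs
of up to 20 nodes, closeness to 1e-12 and the counts exactly.

Seed subnetworks come in two flavours. `induced` (the default, and the
reproducible choice) keeps the seeds and every edge among them. `bridged`
additionally recruits any non-seed node lying on a shortest path of length
at most `max_bridge_len` (default 2) between two seeds — a transparent
stand-in for the shortest-path expansion that literature-mining tools
perform, which is not reproducible from a fixed edge list.

## Statistics

The targeted-versus-random comparison reports a classical one-way ANOVA per
metric, mirroring common practice, and a two-sided permutation test on the
difference in means with add-one smoothing,
$p = (1 + \#\{|\Delta_\pi| \ge |\Delta|\})/(n_{\mathrm{perm}}+1)$. The
permutation p-value is the one to interpret: degree and stress distributions
are heavy-tailed, and ANOVA's normality assumption fails badly on them.
When a metric has no variation at all in either graph (stress on a triangle,
say), the comparison reports $F = 0$, $p = 1$ rather than erroring.

Over-representation is the one-sided hypergeometric tail
$P(X \ge k)$ with population = background universe, successes = pathway
members in the background, draws = query genes in the background. The
Bonferroni multiplier is the number of gene sets actually tested — those
with a non-empty background intersection — not the raw GMT size, since sets
with no background members cannot produce a p-value at all. Significance is
declared at corrected $p < 0.05$. No FDR option is provided on purpose: the
workflow this package reproduces specifies Bonferroni.

## The qPCR model

Fold changes follow the 2^-ddCt model with amplification efficiency fixed at
2 and no efficiency correction. Processing order matters and is fixed:

1. **Interplate calibration.** Each plate's offset is its mean spike-in
   calibrator Ct minus the grand mean of the per-plate means; detected Ct
   values are reduced by their plate's offset and calibrator rows dropped.
2. **Global-mean normalization.** dCt = Ct − mean over all detected,
   non-calibrator assays in that (sample, replicate). This is the
   standard normalizer for genome-scale miRNA panels, where no fixed
   reference gene is trustworthy.
3. **Fold change.** Per replicate, ddCt = dCt(case) − dCt(reference) and
   fold = 2^−ddCt; the consensus is the geometric mean over replicates.

Undetected wells (empty, "Undetermined", or Ct at/above the detection limit,
default 37 cycles) propagate explicitly: case-undetected folds floor at 0
(reported 0.00 — such miRNAs stay in the ranking, placed at
$-\log_{10}$(`fc_cap`) on the log axis, flagged); reference-undetected folds
cap at `fc_cap` (default $2^{12}$, flagged); both-undetected replicates are
uninformative, and a miRNA undetected everywhere is dropped with a log
entry. Floored/capped replicates are excluded from the geometric mean when
the remaining replicates agree in direction; if they disagree, the consensus
is undefined and the miRNA cannot be called dysregulated.

The dysregulation call is deliberately strict: **every** replicate fold must
be ≥ 2 or every one ≤ 0.5. Requiring concordance across the duplicate RNA
inputs is what keeps the false-positive rate negligible at realistic noise
(a false call needs the same ±1-cycle ddCt error in both replicates, a
many-sigma event at 0.2-cycle noise). The oncomiR/suppressor boundary sits
at consensus fold 1 (log ratio 0), matching the quadrant plot's vertical
line.

## Ranking conventions

The quadrant threshold on $S(m)$ defaults to the arithmetic mean over the
ranked miRNAs (`degree_threshold("mean")`); a fixed value reproduces
published figures drawn with a round-number line. Ranks sort by $S(m)$
descending with ties broken by normalized miRNA id ascending, so output is
bit-stable. Degrees default to the full user-supplied global PPI —
reproducible and monotone-comparable — with `degrees_from: seed-network`
available to mimic subnetwork-based variants. Whether to sum over all
validated targets or only expressed ones is exposed through the universe
filter; the pipeline default filters to the expressed universe first,
consistent with restricting the analysis to the tissue's transcriptome.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` fixes the study conditions; the defaults are chosen once,
as follows, and the tests run under them.

* **Graph**: Barabási–Albert preferential attachment, 500 nodes, 2 edges per
  new node — a connected scale-free graph, the canonical null model for PPI
  degree heterogeneity.
* **Targets**: each of 40 miRNAs draws 10 distinct targets with probability
  ∝ (degree+1)^α; α = 1 plants the hub-targeting signal, α = 0 is the
  uniform control. The +1 keeps isolated nodes sampleable.
* **Plates**: two samples (reference "P69", case "M12") × two RNA-input
  replicates, one plate per combination, each with a spike-in calibrator
  ("UniSp3") that carries the plate offset and no biology. Baselines are
  uniform on 18–30 cycles, Ct noise is homoscedastic Gaussian (default sd
  0.2 cycles, the standard qPCR assumption), plate offsets default to
  uniform ±1.5 cycles, and the detection limit is 37 cycles.
* **Conservation of total content**: planted case-sample effects are
  balanced by spreading the equivalent Ct mass over the null miRNAs
  (a shift of sum(effects)/n_null cycles). This models the compositional
  constraint under which global-mean normalization is unbiased, so a
  noiseless run recovers planted folds exactly; the nulls carry the small
  dilution shift — exactly the artifact real global-mean-normalized panels
  show when many miRNAs move in one direction.

What the generator does **not** emulate: database redundancy and curation
noise in interaction tables, literature-mining artifacts in the PPI,
heavy-tailed or Ct-dependent qPCR noise, plate-position effects, and
amplification-efficiency variation. Passing tests therefore demonstrate that
the algorithms recover a planted truth under the stated noise model — not
that any particular biological dataset will behave as cleanly.

Problem sizes used by the test suite and the acceptance script — 500-node
graphs with 40 miRNAs per class for the hub-bias property (100 seeds),
120-miRNA panels over 20 seeds for filter sensitivity/specificity, 1,000
null queries for enrichment calibration — are the package's chosen
demonstration scales: large enough for the Monte-Carlo margins quoted in the
tests, small enough to re-run casually.

## Degenerate inputs and tie-breaks

* Empty interaction files load as empty tables with a warning; an empty
  seed set, universe, or background is an argument error.
* ANOVA on fully constant data is an argument error at the function level;
  the profile comparison catches the constant case itself (F = 0).
* `fold_changes(reference, reference)` returns consensus 1 everywhere.
* An empty dysregulated set ranks to an empty table with a warning, not an
  error, so pipelines on null data complete.
* All randomness flows through explicit integer seeds (`withr::with_seed`);
  nothing touches the global RNG state.

## Known limitations

The degree sum treats all validated targets equally — no weighting by
interaction confidence, target expression, or repression strength — and is
sensitive to study bias in both the interaction databases and the PPI
(well-studied proteins have more recorded edges). Closeness values are not
comparable across graphs of different size (see above). The published
absolute centrality values and dysregulation counts that motivated this
design depended on literature-mined networks and array data that cannot be
rebuilt from fixed inputs; the package therefore validates those claims as
properties on synthetic data with planted ground truth, and reproduces the
published ranking itself exactly from the packaged fixture via
`replay_fixture()`.
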