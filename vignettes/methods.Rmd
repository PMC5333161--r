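---
title: "Correlation mapping of time-series multi-omics from cell culture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation mapping of time-series multi-omics from cell culture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The analysis problem

Batch cultures of producer cell lines (the motivating system is CHO-K1
cultured with 0, 5 or 10 mM added lactate) are profiled over a few days on
three levels at once: intracellular metabolite concentrations (LC-MS/MS,
µM, typically days 0–5), transcript abundances (RNA-seq FPKM, typically
days 0–3, because library prep lags the metabolite sampling), and culture
metrics — cell number and extracellular glucose and lactate. The question
is which metabolites and genes move together over the culture, and which
of them respond to a dose-like perturbation of the medium.

pathcorr implements a deliberately simple, fully reproducible answer built
on one similarity measure: Pearson's correlation coefficient between
replicate-mean time courses. The stages are

1. **Pattern classification** — a rule-based surrogate for sorting
   trajectories by eye into *increase*, *decrease*, *variable*, *constant*
   and *unclassified*.
2. **All-pairs correlation** — metabolite–metabolite, gene–gene and
   metabolite–gene matrices, with the three culture metrics inserted on
   both axes.
3. **Correlation-profile clustering** — each entity's feature vector is
   its row of the square correlation matrix; UPGMA on Euclidean distances,
   cut into flat clusters, keeping the two largest as clusters A and B
   (I/II on the metabolite axis, 1/2 on the gene axis); an integrated
   heatmap with marginal dendrograms.
4. **Pathway projection** — a metabolic map in which metabolites are
   nodes and genes label reaction edges; cluster A is drawn orange,
   cluster B light blue; metabolites absent from the analysis stay white
   and genes grey.
5. **Comparative mapping** — per entity, the correlation `r` between its
   control and perturbed time course, displayed in five bins:
   bold red (`r > 0.9`), red (`0.5 < r ≤ 0.9`), green (`0 ≤ r ≤ 0.5`),
   blue (`−0.5 ≤ r < 0`), bold blue (`r < −0.5`); plus a colour-variation
   table contrasting two comparisons (e.g. control/5 mM vs control/10 mM).

## Statistical choices and their rationale

**Replicate means, not pooled replicates.** Correlations are computed on
the per-time replicate means. The designs this targets report averaged
triplicates, and each heatmap cell is one number per entity pair; pooling
replicate points would mix replicate noise into the temporal signal and
inflate the effective sample size.

**Grid intersection, never interpolation.** Metabolite and gene profiles
live on different day grids (0–5 vs 0–3). Cross-kind correlations use
exactly the shared time points (the four shared days in the default
design). Interpolation would fabricate data on the faster grid; dropping
to the intersection only costs degrees of freedom. The minimum admissible
shared grid defaults to 3 points (`min_grid`), the smallest length for
which `r` is defined in any informative way — the gene grid itself has
only 4 points, so demanding more would exclude the gene axis entirely.

**No p-values.** With 4–6 time points, correlation p-values would be
nearly meaningless and multiplicity correction across thousands of pairs
would dominate the analysis. The method uses `r` magnitudes only, as an
ordering and display device, not as inference.

**NA semantics.** A profile constant on the evaluation grid has zero
variance; its correlations are `NA`, never ±1. Downstream, `NA` renders
as the "absent" style (white node / grey edge) and is imputed as 0 (sign
neutral) only inside clustering feature vectors, with a logged warning.

## Pattern classifier

For a mean series `v` with `m = max(|v|)`, relative steps
`s_t = (v[t+1]−v[t])/m`, net change `net = (v[T]−v[1])/m` and
`CV = sd(v)/|mean(v)|`, the rules are, in order: constant if
`CV < const_cv`; increase if `net ≥ net_change` and no step below
`−step_tol`; decrease mirrored; variable if the relative range is at
least `net_change` while `|net| < net_change`; otherwise unclassified.
Defaults: `const_cv = 0.10`, `net_change = 0.20`, `step_tol = 0.05`.

These thresholds are this package's formalization of a judgement
originally made by eye; they are exposed in the configuration precisely
because they are conventions, not estimates. All three are relative
quantities, so classification is invariant under rescaling a profile by
any positive constant — a unit change can never change a label. There is
no principled boundary between "variable" and "unclassified"; the rule
above (large excursion, small net drift) is a choice and is documented as
such.

## Clustering and the two-largest-cluster rule

Correlation-profile clustering uses average linkage (UPGMA) on Euclidean
distances between matrix rows. Neither the linkage nor the metric is
canonical for this analysis; both are configurable, and UPGMA/Euclidean
were chosen as the least surprising defaults for heatmap work. Entities
are sorted lexicographically before clustering so the merge tree is
independent of input order, and size ties in cluster extraction resolve
toward the cluster whose smallest member sorts first; cluster A is the
one containing the lexicographically smallest entity. These tie-breaks
buy bit-reproducible outputs across platforms and locales.

The flat cut keeps the **two largest** clusters and marks the rest
unassigned. The pipeline default is `k = 3`, not 2, for a geometric
reason: with culture metrics inserted, extracellular glucose (a monotone
decrease) is strongly *anti*-correlated with the rising block of
entities, and in correlation-profile feature space an anti-correlated
entity is far from both blocks. At `k = 2` such an outlier can capture
one of the two clusters outright — at zero noise the decisive merge is an
exact distance tie, so the outcome even depends on label collation order.
Cutting at `k = 3` and keeping the two largest clusters leaves the
outlier in the unassigned remainder; in simulation this recovers the
planted bipartition in 200/200 seeds at replicate noise of 0, 5 and 10%.
`two_largest_clusters()` itself defaults to `k = 2`, which is correct for
a pure two-block input.

## The display palette and bins

The palette is fixed (orange `#F5A623`, light blue `#9BD7E5`, red
`#D0021B`, green `#2E9E3F`, blue `#2257C4`, white `#FFFFFF`, grey
`#BDBDBD`) so renders are testable bit-exactly. The five comparative bins
keep their deliberate asymmetry — the positive side splits at 0.9 and
0.5, the negative side only at −0.5 — and are not symmetrized. The strict
inequalities of the published legend leave `r ∈ {0.9, 0.5, 0, −0.5}`
formally unassigned; boundaries here attach to the inner (weaker) bin and
0 joins the weak-positive bin, which is the conservative closure (a
boundary value never gets the stronger styling). Strong bins scale node
radius ×1.6 and edge width ×2.5; size/boldness encodes exactly the two
strong bins, not a continuous scale. An edge aggregating several genes
(isozymes) takes the bin of the gene with the most extreme `|r|` in
comparative maps; in cluster maps a gene-cluster conflict on one edge is
drawn grey and logged rather than silently resolved.

## Synthetic data: what it emulates and what it does not

The generator reproduces the *statistical shape* of the study design:
daily sampling (days 0–5 metabolites/culture, 0–3 genes), triplicates,
three dose conditions, four planted temporal classes, two planted
correlation blocks, and dose-monotone divergence from control. Defaults
(34 metabolites, 40 genes) echo the size of a central-metabolism panel.

- **Base shapes.** Increase is a logistic ramp rescaled to 0.1→1.0
  (steepness 1.5/day); decrease is its mirror; constant is flat;
  *variable* is a single-peak bump rising from 0.1 to a peak at the grid
  midpoint and returning to 0.1 (for an even number of points the two
  middle points share the maximum). The midpoint peak is a deliberate
  choice: on a uniform grid the rescaled logistic is odd about the grid
  midpoint and the symmetric bump is even, so their correlation is
  exactly zero on *both* grids — an off-centre peak cannot get below
  |r| ≈ 0.13 on a 4-point grid, which would violate the generator's own
  cross-block |r| ≤ 0.1 guarantee. `generate_synthetic()` verifies the
  bound for any user-supplied shape pairing and refuses violating pairs.
- **Blocks and amplitudes.** Entities alternate between the two blocks;
  within a block everyone shares the block shape scaled by a per-entity
  amplitude drawn log-uniformly from [10, 1000] µM/FPKM, so within-block
  correlations are exactly 1 before noise.
- **Culture metrics.** Cell number uses the bump (planted in that block),
  lactate the ramp (planted in that block), glucose the mirrored ramp.
  Glucose stays outside the blocks: its shape is r = −1 against the ramp
  block on any grid, so planting it would break the cross-block bound.
- **Dose.** A condition with perturbation strength `p` blends each
  affected entity's shape toward the other block's shape with weight `p`
  (defaults 0, 0.3, 0.7 for the three conditions); because the shapes are
  orthogonal, the control correlation decays monotonically in `p`, which
  is what makes "more strong-red under the milder dose" a provable
  property rather than an observation.
- **Noise.** Replicate noise is multiplicative log-normal with mean
  exactly 1 and relative SD `noise_cv` (default 0.05): concentrations and
  FPKM are positive with scale-proportional error.

What the generator does *not* emulate: mechanistic kinetics or flux
coupling, heteroscedastic measurement error across the dynamic range,
missing values, batch effects, or the correlated (non-block) structure of
a real metabolic network. Passing the planted-recovery tests therefore
shows the pipeline is correct and stable under its own assumptions, not
that two clusters is the right description of any real culture.

## Numerical and degenerate-input policy

Pearson values are clamped to [−1, 1] against floating-point excursions;
matrix entries match a definitional double-loop implementation to 1e-12.
Equality-critical outputs (CSV, JSON, SVG, GraphML) contain no
timestamps, and every stage manifest records parameter values, the seed
and md5 hashes of its text outputs, so a rerun with the same
configuration is byte-identical (verified in the test suite). Layouts for
maps without coordinates come from a seeded force-directed embedding.
Fewer than 3 time points, mismatched vector lengths, unknown conditions,
dangling map edges and duplicate measurements are all hard errors;
absence from the analysis is never an error, it is a style (white/grey).

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the pipeline end-to-end on
the default design (34 metabolites + 40 genes + 3 culture metrics, 3
conditions) at zero noise, and use 15 + 15 entities over 20 seeds for the
noisy recovery and dose-monotonicity checks — sizes chosen to exercise
every code path at interactive runtimes while keeping all planted
guarantees exact.

## Known limitations

- Pearson on 3–6 points is a display statistic; near-boundary bins flip
  under modest noise (visible as bin agreement slightly below 1 in noisy
  pipeline runs), and no uncertainty is attached to any `r`.
- The two-cluster reading is enforced by construction; data with three or
  more genuine orientations will park everything else in "unassigned"
  rather than revealing it.
- KGML import is best-effort (compounds → nodes, one edge per
  substrate–product pair, gene graphics names as labels); curated maps in
  the native JSON format are the first-class path.
- GO/PANTHER enrichment is out of scope by design: the package exports
  sorted per-cluster gene lists for external submission.
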