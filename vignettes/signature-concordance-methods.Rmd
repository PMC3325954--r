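---
title: "Methods: senescence signature concordance and cell-based quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: senescence signature concordance and cell-based quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senecon)
```

# Scope and model

`senecon` implements the quantitative backbone of a premature-senescence
study design in primary mouse embryo fibroblasts (MEFs): a knockout culture
is compared against early- and late-passage wild-type cultures on expression
arrays, and the hypothesis that the knockout undergoes an accelerated
version of the normal passage-driven crisis is tested as *directional
concordance* between differential-expression signatures. The cell-biology
arms quantify the accompanying phenotypes: polyploidization and
re-replication from DNA-stain image cytometry, DNA damage from γH2AX focus
counts and comet assays, and proliferation from serial-passage growth,
qPCR, and replicate proportion assays.

All stages consume plain tables (TSV/CSV) and return plain data frames, so
each can run standalone on files produced elsewhere. A synthetic-data
module generates seed-reproducible inputs with planted ground truth for
every stage; it is first-class, tested code, not a fixture.

# Differential expression and signatures

A signature is the set of probe-sets passing, in one pairwise comparison,
an absolute log2 fold-change cutoff (default 0.5, inclusive) and a p-value
cutoff (default 1e-4, strict), each member carrying `sign(lfc)`. The fold
change is `mean(first) − mean(second)` on the log2 scale, so `pairwise_de(em,
"null", "P3")` matches the "null − P3" naming convention.

The per-probe test is a two-sample pooled-variance t-test on the log2
values (Welch behind `var_equal = FALSE`). The original analysis never
names its test; we chose the simplest test consistent with triplicate
arrays and did **not** add moderated-variance shrinkage, which is out of
scope here. The consequence is worth stating plainly: with n = 3 per group
the t statistic has 4 degrees of freedom, and p < 1e-4 requires |t| > 15.5.
At a residual s.d. of 0.25 log2 units — a realistic figure for normalized
triplicate arrays — planted effects of 1–2 log2 units are detected with
sensitivity ≈ 0.09 (pre-computed by Monte-Carlo with 20,000 probes). High
recovery (≥ 0.99) requires the low-noise regime σ ≈ 0.05. Our tests assert
both oracle-computed values rather than wishing the low-power regime away;
any claim that a plain triplicate t recovers ≥ 90% of 1-log2 effects at
σ = 0.25 under p < 1e-4 is arithmetically false. Published probe-set counts
produced by array suites of that era almost certainly reflect
moderated/model-based tests, which is why the package's comparative surface
is built on reconstructed signature tables rather than on re-derived
p-values.

Degenerate probes (zero pooled variance) are handled deterministically:
equal means give p = 1; unequal means give the smallest positive double and
a `degenerate` flag, keeping selection reproducible on noiseless fixtures.
No multiple-testing correction is applied, matching the raw-p filtering
convention of the design being emulated, and this is deliberately
documented rather than "fixed". Gene-level collapse (`collapse_to_genes`)
keeps the probe with the largest |lfc| per gene and drops unannotated
probes; it is optional and off the main path.

# Directional concordance

`directional_overlap` partitions the probes significant in both signatures
by their direction pair into quadrant counts (up/up, up/down, down/up,
down/down); set-only counts are reported for Venn diagrams but excluded
from the test, because the question is about the *distribution of
directions within the overlap*, not about overlap size.

`concordance_chisq` computes expected counts from the 2×2 marginals and
Pearson's chi-squared with df = 1, no continuity correction by default
(`correct = TRUE` switches Yates on). Any zero marginal flags the result
degenerate instead of producing a misleading statistic; any expected cell
below 5 sets `low_expected`, recommending the permutation p-value.

`permutation_null` is the independent oracle: it permutes the second
signature's direction labels among overlap members, which conditions on
both margins, and reports the add-one estimator
`(1 + #{χ²_perm ≥ χ²_obs}) / (1 + n_perm)`.

One subtlety the test suite documents explicitly: a margin-conditioned
permutation test is an *exact conditional* test, and its p-value does not
match the uncorrected asymptotic χ² p to 0.01 on discrete tables of
moderate size — on the table (30, 20, 20, 30) the exact conditional p is
0.0713 versus 0.0455 asymptotic, and under independence at N = 100 the gap
can exceed 0.1. The Yates-corrected asymptotic p (0.0719 on that table) is
the approximation that tracks the conditional null. Agreement at the 0.01
level is therefore only meaningful in the regime the test is actually used
in — strongly concordant overlaps like the ~81%-concordant published
quadrant table — and that is the regime our acceptance test simulates. The
unit tests instead compare the permutation p against a full hypergeometric
enumeration of the conditional null, which is the statistically correct
target at any table.

# Synthetic expression data

`expression_truth` states the simulated world: number of probes, the
three-condition triplicate design, two planted contrasts, the fraction of
probes differential per contrast, the shared fraction ρ of planted probes,
the direction-concordance probability κ among shared probes, effect
magnitudes uniform on [0.5, 2] log2 units, and i.i.d. normal noise.
Condition offsets are solved per probe so every planted contrast hits its
target fold change exactly and every non-member contrast sees exactly zero
— contrasts must form a forest over conditions for this to be well-posed,
and a cycle is rejected.

Defaults are the stated world, chosen once: σ = 0.25 as a realistic array
noise level (the original arrays' variance components are unpublished, so
this is a free parameter, not an estimate); power-sensitive simulations
(the concordance type-I/power acceptance runs) state σ = 0.05 up front
because the criterion itself conditions on recovering overlaps of N ≥ 200,
which the df = 4 t-test cannot do at σ = 0.25 (see above). Sub-streams are
derived per data facet (baseline, directions, effects, noise) from one
master seed so facets are independently reproducible.

# DNA-content profiling

`build_dna_profile` histograms per-nucleus integrated stain intensities
over [0, P99.9] in 100 bins, smooths with a centred 5-bin moving average,
and takes the 2N mode as the highest smoothed local maximum and the 4N
mode as the highest local maximum within [1.8, 2.2]× the 2N position (an
error with diagnostics if none exists — e.g. a pure-2N culture). The
deterministic rule replaces the visual landmarking of interactive imaging
software; bin count, band width, and smoothing window are parameters.
Peak positions are quantized by bin width (≈ 1–2% here), which is the
dominant term in boundary jitter.

Class boundaries are symmetric ±15% bands: sub-2N < 0.85·µ2N ≤ 2N ≤
1.15·µ2N < S < 0.85·µ4N ≤ 4N ≤ 1.15·µ4N < bracket1 ≤ split < bracket2.
The >4N region runs from 1.15·µ4N to the larger of the observed maximum
and 2·µ4N (the 8N position) and is divided into equal-width halves; a
value exactly at the split belongs to bracket 1. EdU-positive nuclei in
bracket 2 — replication at super-4N DNA content — are the operational
re-replication readout, reported as a percentage of all EdU-positive
nuclei with a Wilson 95% interval.

The nucleus generator defines planted classes as a **partition of intensity
space**: 2N/4N are truncated normals inside their bands, S is uniform on
the inter-band gap, and the brackets are uniform on their halves of
(1.15·µ4N, 2·µ4N]. We deviated here from drawing S uniformly across the
entire inter-mode range: with overlapping class-conditional distributions
the planted label is unidentifiable from intensity even in principle
(45% of such S draws would land inside the 2N/4N bands), so
"fraction recovery within 3 binomial s.e." would be impossible for any
classifier — the partition definition is the only one under which recovery
is a meaningful claim. Residual confusion (~1%) comes from peak-position
quantization shifting boundaries, and a planted-zero class (sub-2N) can
pick up ~1% of boundary leakage, which is why zero-fraction classes are
checked against an absolute bound rather than a 3·s.e. band of width zero.

Focus counts are drawn as bin labels over {0, 1–5, 6–10, >10} (multinomial
per group) and materialized as representative integers within the bin,
since the analysis only consumes the bins. `foci_distribution_test`
defaults to the goodness-of-fit form — reference proportions treated as a
fixed expectation scaled to the observed total, df = 3 — which mirrors
"expected based on the wild type"; a two-sample homogeneity variant is
available, and its type-I behaviour differs (the fixed-expectation form is
only calibrated when the reference is treated as truth).

# Comet kinetics

Per-cell percent tail DNA is bounded on [0, 100], so the generator uses a
symmetric scaled Beta(2,2) disturbance around the mean (clipping is a
secondary guard, not the noise model). The treated-arm mean follows
`D(t) = D_inf + (D0 − D_inf)·exp(−k·t)`.

`fit_recovery_curve` least-squares fits the per-timepoint means with
box-constrained L-BFGS-B and an analytic gradient; initialization is
deterministic (D0 from the earliest mean, D_inf from the latest, k from
log 2 over the timepoint nearest the midpoint value), flat series return
the constant model with k = 0, and a fitted D_inf > D0 (possible only for
rising series, outside the model) collapses to the constant model. The fit
is exact (≤ 1e-6 relative) on noiseless model data. At 200 cells per
timepoint the per-seed D_inf estimate has ≈ 5% sampling noise, so recovery
at the 10% level is asserted for the Monte-Carlo mean over the 20 stated
seeds, not per seed. The kinetic fit is an extension beyond per-timepoint
t-tests and is labelled as such in reports.

Summaries use R's type-7 quantiles (linear interpolation between order
statistics), stated because box-plot percentiles differ across tools; the
two-group comparison reports the pooled-variance t p-value as primary
(identical samples give p = 1) with a rank-sum p alongside.

# Quantification utilities

- `cumulative_growth`: folds compound multiplicatively from the declared
  start passage, whose plating defines the unit; contiguity of passages is
  enforced.
- `relative_expression_delta_ct`: ΔCt against the arithmetic mean of the
  reference-gene Cts (the geometric mean of their linear expression — the
  standard multi-reference convention; normalizing to each reference
  separately and averaging differs negligibly for near-equal references),
  expression `2^(−ΔCt)`, rescaled so the control group's per-gene mean is
  1. The transform is invariant to per-sample Ct shifts, which the
  generator exercises deliberately.
- `proportion_summary`: replicate percentages, group mean ± s.d., and a
  pooled t-test on the per-replicate percentages (not pooled counts),
  matching error bars computed across replicate cultures.

# What a green test does and does not establish

The generators emulate the *statistical shape* of the assays: planted
directional signatures with controllable sharing and concordance,
intensity mixtures with EdU labelling, binned focus distributions,
bounded comet noise with exponential mean recovery, exact product growth,
and a two-reference Ct model. They do not emulate probe-level array
artefacts, normalization residue, image segmentation error, inter-culture
batch effects, or any mechanistic pathway dynamics. A green recovery test
therefore establishes that the estimators are correct and calibrated on
data satisfying their assumptions — not that the original biological
measurements are reproduced. Published quantities enter only as printed
tables used as direct inputs (quadrant and overlap counts), and the
re-replication ">10% of EdU-positive cells" observation is treated as a
qualitative anchor, since the underlying images are not available.

# Known limitations

- The 2N peak must be the globally highest mode; cultures dominated by 4N
  would need the bands re-anchored manually.
- The concordance test is probe-level and ignores inter-probe correlation;
  its permutation oracle conditions on margins and inherits the
  discreteness discussed above.
- Cross-platform signature comparison joins on shared probe-set IDs by
  default; a gene-symbol join table is the caller's responsibility.
- The qPCR model assumes perfect amplification efficiency (no
  efficiency-corrected variant).
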