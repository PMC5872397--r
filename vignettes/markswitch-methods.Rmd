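---
title: "Methods: calibrated mark calling and switching analysis"
author: "markswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibrated mark calling and switching analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markswitch)
```

# The measurement model

A cytosine can be unmodified (u), methylated (5mC), hydroxymethylated
(5hmC), or formylated/carboxylated (5fC/5caC, measured jointly). The three
bisulfite chemistries each report a different composite of these states at a
site with true fractions $(m, h, f)$, $m + h + f \le 1$:

| assay | modified-state read | probability of the modified state |
|-------|--------------------|-----------------------------------|
| BS  | unconverted C | $m + h + (u + f)(1 - c)$ |
| TAB | unconverted C | $h\,[\pi + (1-\pi)(1-\omega)] + m(1-\omega) + (u+f)(1-c)$ |
| MAB | T | $c\,[f + u\,(1-\mu)]$ |

with $c$ the bisulfite conversion efficiency, $\omega$ the Tet1 oxidation
efficiency, $\pi$ the 5hmC glucosylation-protection efficiency, and $\mu$
the M.SssI methylation efficiency. With perfect chemistry these reduce to
the composites the assays are named for: BS $\to m + h$, TAB $\to h$,
MAB $\to f$. The modification level at a site is always the plain ratio
$\hat m = k/n$ of modified-state reads to total reads (`score_sites()`).

Defaults: $\omega = 0.9704$, $\pi = 1$, $\mu = 0.9620$ — the calibration
values this workflow assumes for its chemistry, as measured by spike-in
controls. The bisulfite conversion efficiency defaults to $c = 1$, because
the spike-in efficiencies are *end-to-end, read-level* measurements: any
conversion failure is already absorbed in them, and setting $c < 1$ on top
would double-count that error.

## Spike-in calibration

`estimate_efficiency()` pools reads over all positions of one control of
known state and estimates the efficiency as the fraction of reads
consistent with successful chemistry: for unmethylated lambda DNA under MAB
this is the C fraction (M.SssI succeeded), for a fully-5mC control under
TAB the T fraction (oxidation succeeded), for a fully-5hmC control under
TAB the C fraction (protection succeeded). The 95% CI is the normal
approximation to a binomial proportion; at the $2\times10^5$ observations a
deep-sequenced spike-in provides, its half-width is about 0.09 percentage
points, far below the differences that matter here.

## The 5fC/5caC binomial caller

Under MAB a T read arises from true 5fC/5caC or from an M.SssI failure
(rate $\varepsilon = 1 - \mu = 0.038$ at the default calibration).
`call_5fc_5cac()` computes, per site, the upper-tail binomial p-value
$P(X \ge k)$ for $X \sim \mathrm{Binomial}(n, \varepsilon)$ and calls the
site when $n \ge 20$ and $p < 0.1$.

Two conventions needed fixing:

* **Tail convention.** "One minus the binomial CDF at the T count" is
  ambiguous between $P(X \ge k)$ and $P(X > k)$. The inclusive tail
  $P(X \ge k) = 1 - F(k-1)$ is the default — it asks whether the observed
  count or anything more extreme exceeds the failure expectation, and it is
  the conservative choice ($p$-values are larger). The exclusive tail is
  available via `tail = "exclusive"`.
* **Multiple testing.** The conventional screen uses the raw $p < 0.1$; no
  correction is applied by default. `adjust = TRUE` switches the gate to
  Benjamini–Hochberg q-values for users who prefer FDR control.

Because the test is discrete, the null call rate at coverage 20–100 sits
*below* the nominal 0.1 (verified by simulation in the test suite); the
caller is conservative, not anti-conservative.

## Coverage floors

Following the conventions this pipeline adopts, the CpG filter is strict
(`n > 10`: a site at exactly 10× is dropped) while the MAB caller's floor
is inclusive (`n >= 20`), and the non-CpG floor is inclusive (`n >= 10`).
The asymmetry is deliberate and documented at each function.

# Cutoffs and their presets

All thresholds are ratios on $[0,1]$ (differences of read fractions).

* **Tiers** (`tier_sites()`): high/low at 0.6/0.2 for 5mC, 0.15/0.05 for
  5hmC, 0.2/0.1 for 5fC/5caC; boundary values fall in `medium`, so the
  three tiers partition every table.
* **Site-scope differentials**: 0.2/0.05/0.05 (`"default"` preset) or the
  stricter 0.25 for 5mC (`"strict"`, used for switching-quadrant scatter
  analyses).
* **Region-scope differentials** (promoter or enhancer averages):
  0.15/0.02/0.02.
* **Promoter-vs-expression analyses**: 0.1/0.025/0.025
  (`"promoter-expression"`).

These presets intentionally coexist — the workflow they formalise uses
different stringencies for different analyses — and the discrepancy is
preserved rather than resolved; `cutoff_preset()` also accepts custom
vectors. Group levels are unweighted means of per-sample ratios (matching
"average change" semantics); `method = "pooled"` pools raw counts instead,
which weights samples by depth.

Promoters are TSS1500 windows: 1,500 bp upstream of the TSS to the TSS,
strand-aware (array-annotation nomenclature); the width is configurable.

# Switching quadrants, codes and enrichment

`classify_switch_pairs()` joins two delta tables over a *shared* site
universe (mismatched universes are an error, not a silent intersection) and
assigns each site one of the nine direction pairs; the 3×3 counts always
sum to the shared-site count. `switch_codes()` extends this to the 27
three-mark codes. Enrichment over genomic features
(`feature_enrichment()`) and chromatin states (`state_colocalization()`) is
a ratio of proportions,
$e = \frac{\text{events in } f / \text{events}}{\text{universe in } f /
\text{universe}}$, chosen over a count normalised by feature size alone
because it is invariant to the overall event rate and to feature size. A
direction with zero events, or a feature with no universe sites, yields
`NA` — enrichment is undefined there, not zero. Sites outside every state
segment are tallied in an `unassigned` row so the row marginals always
account for every scored site.

# Interval machinery

Intervals are 0-based half-open tibbles throughout; the overlap engine is
GenomicRanges/IRanges behind the tibble surface. `overlap_fraction()`
computes coverage against the *union* of the partner set: abutting or
overlapping peaks never double-count, and the result is monotone and
order-independent. Tissue-specific enhancer stratification
(`stratify_tissue_specific()`) first applies the peak-quality filter
(FDR < 0.01 strict, enrichment score ≥ 30 inclusive) to every tissue, then
labels a focal peak *shared* when at least 60% of it is covered by another
tissue's filtered peaks. The 60% rule is evaluated on the focal peak only
(not reciprocally): that is the plainest reading of "60% of a single peak
from one tissue overlapped with another", and the reciprocal variant can be
obtained by running the function with the tissues exchanged.

Gene assignment (`assign_genes()`) is a symmetric fixed window on the
region-to-TSS distance (defaults 50 kb, with 10 kb as the common proximal
variant). This deliberately replaces regulatory-domain heuristics of
ontology web tools with a rule that is transparent and testable; distance
is zero when the TSS lies inside the region.

# Expression and survival screens

`tet_coexpression()` gates genes on a Pearson correlation p-value
(< 0.05, two-sided t transform) *and* a dynamic-range requirement —
log2 fold change between the highest- and lowest-expressing sample > 0.5 —
so that flat genes cannot pass on correlation alone. A pseudocount of 0.1
on the ratio keeps the range defined at zero expression (expression units
are FPKM-like, where zeros are common); constant genes are *skipped*
(correlation undefined), not failed. `promoter_mark_correlation()` applies
the analogous gates to region-level modification (p < 0.01, max−min ≥ 0.1).

`logrank_median_split()` splits patients at the median expression and
compares the halves with the standard log-rank test
(`survival::survdiff`); a gene passes at p < 0.05 *and* expression above
zero in more than half of patients. Proportional-hazards effect sizes are
deliberately out of scope — the log-rank gate is the decision rule
implemented, and Cox modelling can be layered on externally. Degenerate
inputs (no events; a half smaller than two) report `NA` rather than
erroring, so matrix-level screens (`logrank_screen()`) never abort on one
bad gene.

Expression change classification uses
$\log_2\!\frac{\bar x_B + pc}{\bar x_A + pc}$ with pseudocount 1 and a
q-value gate. Q-values are consumed from the caller when available (the
intended source is an external differential-expression run); the internal
fallback — Welch t-test with Benjamini–Hochberg across genes, used only
when both groups have ≥ 2 replicates — is a documented deviation suitable
for the replicate counts the generator produces, not a replacement for a
count-model DE engine.

# Non-CpG analysis

Non-CpG methylation is analysed strand-specifically and unmerged: a CpA on
the plus strand and the CpT it faces on the minus strand are distinct
sites. `classify_context()` reads the context from the reference base
following the cytosine on its own strand (complemented logic on the minus
strand); neighbouring `N` or out-of-range positions are unclassifiable and
skipped. The high-modification tier uses the single cutoff $m > 0.4$ — no
medium tier, matching the single-threshold convention for non-CpG work —
and differential calls use 0.2 between cell classes and 0.1 across a
differentiation time course.

# The synthetic-data generator

`generate_truth()` draws per-site true levels for the two cell classes
from Beta distributions (defaults: a broad, high-mean distribution for 5mC,
low-mean for 5hmC, very low for 5fC/5caC), constrained to the simplex
$m + h + f \le 1$ — the three marks are mutually exclusive chemical states
of one cytosine, so their fractions cannot sum beyond one. Switching events
are planted as configured per-mark deltas at a random subset of sites, with
the reference level re-drawn inside the feasible box so the delta fits the
simplex in both classes; all other sites drift by truncated Gaussian noise
capped at 80% of each mark's cutoff, so no unplanted site can cross a
differential threshold in truth. Planted quadrant labels are recorded from
the same direction rule the classifiers use, which makes label consistency
a testable identity rather than an approximation.

Coverage is negative binomial (mean 50, size 5 by default): RRBS coverage
is overdispersed, and the exact distribution is not prescribed by the
conventions above — only the coverage floors are. Poisson is available as
the `size = Inf` limit. Chromosomes are named `chrS1..chrSn` to make clear
no real coordinates are implied.

`generate_regulatory_landscape()` places peaks in disjoint genomic slots:
shared peaks are byte-identical across tissues (overlap fraction 1) and
specific peaks never overlap another tissue's peaks (fraction 0), so
planted labels are exactly recoverable at any threshold in (0, 1] — the
stratifier is tested against a discrete truth rather than a borderline one.
An unsatisfiable peak density (more slots requested than the genome holds)
errors rather than silently overlapping. The chromatin-state segmentation
tiles the genome without overlap; gene annotations carry strand-aware
TSS1500 promoters.

`generate_expression_survival()` plants co-expressed genes on a latent
Gaussian scale, $z_i = r\,z_{\mathrm{driver}} + \sqrt{1-r^2}\,e_i$, so the
target Pearson correlation is exact in expectation and `target_r = 1`
yields exact affine copies. Survival times are exponential per
median-split group with a configured hazard ratio; censoring times are
exponential with rate chosen so the expected event fraction equals the
configured rate exactly per group.

**What the generator does not emulate** — and therefore what passing tests
do not demonstrate about real data: read-level artefacts (PCR duplication,
strand bias, mapping error), restriction-fragment structure of coverage,
spatial autocorrelation of methylation along the genome, correlated
biological variation between marks at a site beyond the simplex constraint,
and heavy-tailed expression distributions. The generator validates the
*inference machinery* under the model the pipeline assumes; claims about
real tissue require real data.

# Numerical choices and degenerate inputs

* Boundary conventions: tiers use strict inequalities with boundaries in
  `medium`; differential directions use strict inequalities with the
  boundary in `0`; the 60% sharing rule and the score ≥ 30 filter are
  inclusive; the FDR < 0.01 filter is strict.
* Ties in variable-site selection break by genomic order (chromosome, then
  position), making `select_top_variable()` deterministic.
* The sample tree uses Euclidean distance with average linkage — no
  algorithm is prescribed by the conventions this package follows, and
  average linkage on Euclidean distance is the common default for
  methylation-profile dendrograms; both are arguments.
* `k > n` counts, empty site intersections, unknown cell types, zero-length
  intervals, overlapping segmentations and invalid fractions are errors
  that name the offence; constant genes and event-free survival tables are
  *reported* (`skipped`, `NA`) rather than raised, because they occur
  routinely inside genome-wide screens.
* A derived pure-5mC column (BS minus TAB, clipped at zero) is available
  via `subtract_5hmc()` but is not default output: the per-site difference
  of two noisy ratios is unstable at modest coverage, and the default
  reporting keeps assays separate.

# Test scales and a power note

The test suite runs entirely on synthetic data at deliberately small
scales: truth sets of 200–1,500 sites, cohorts of 2–5 lines per class,
spike-ins of $5\times10^3$–$2\times10^5$ observations, 30–150 Monte-Carlo
replicates per calibration check, and 1,000-instance brute-force oracle
sweeps for the interval and enrichment arithmetic. These sizes keep the
whole suite under a couple of minutes while leaving Monte-Carlo margins
well inside the asserted tolerances.

One recovery bound deserves its arithmetic spelled out. Quadrant recovery
is asserted at F1 ≥ 0.9 for planted deltas at *twice* the strict cutoffs
(Δ5mC = −0.5, Δ5hmC = ±0.1) with coverage ≥ 30. At deltas of only 1.5× the
5hmC cutoff, the decision margin is $0.075 - 0.05 = 0.025$, while the
standard error of a group-mean delta at realistic depth (3–5 samples per
group, ~60–80× coverage, $p \approx 0.15$) is about 0.03 — the margin and
the noise are the same size, recall plateaus near 0.8, and no
implementation could clear 0.9 there. At 2× the cutoff the margin doubles
and recovery clears the bound with room; the planted deltas are therefore
set at 2×, comfortably inside the "at least 1.5×" regime the recovery
property is meant to exercise.

# Known limitations

* 5fC and 5caC are measured as a sum; disambiguating them needs chemistry
  not modelled here.
* BS-derived "5mC" is really 5mC+5hmC; whether to subtract TAB is left to
  the user (`subtract_5hmc()`), and all cutoffs are interpreted on the
  composite.
* The internal Welch+BH fallback for expression q-values is not a
  count-based DE model.
* The log-rank screen provides detection, not effect sizes or covariate
  adjustment.
* Peak calling, chromatin-state model training, alignment and motif
  analysis are consumed as inputs, never re-implemented.
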