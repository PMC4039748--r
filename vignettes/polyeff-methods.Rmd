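---
title: "Methods: transcription and translation efficiency from polysome profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcription and translation efficiency from polysome profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyeff)
```

## The design and the two effect estimates

The experiment profiled here fractionates cell lysates into polysomal
(ribosome-bound) and non-polysomal (free) mRNA pools at two timepoints
(0 h and 6 h after a differentiation stimulus) with r replicate arrays per
fraction-by-time cell, yielding log2 intensities for four design cells per
gene. Writing `p0, p6, np0, np6` for the per-gene cell means,

- translation efficiency: `TL = (p6 − p0) − (np6 − np0)`,
- transcription efficiency: `TC = (p6 + np6)/2 − (p0 + np0)/2`.

Both are linear contrasts of the four cell means of a saturated gene-wise
model. The two definitions are linked by exact reconstruction identities
`p6 − p0 = TC + TL/2` and `np6 − np0 = TC − TL/2`, which the test suite
asserts to 1e-12; the synthetic generator builds its population means from
these identities, so "planted TL = x" means the population contrast equals
x exactly.

Assumptions worth stating explicitly: intensities are already
log-transformed so array effects are additive; replicate noise is gene-wise
normal with a variance shared across the four cells (one pooled residual
variance per gene, `d_g = N − 4` df); and each effect is tested as a single
contrast per gene rather than as a difference of two separately-tested fold
changes — one test, one p-value, one fdr per gene and effect.

## Spike-in normalization

Between-array offsets are removed using spike-in control probes: each
sample is shifted so its spike-in median matches a grand centre. Two
choices here were genuinely open:

- *median, not mean*, over the spike-ins of a sample — robust to a single
  corrupted control probe;
- the grand centre is the *median of the per-sample spike-in medians*
  (not the pooled median of all spike-in values). With this centre the
  operation is exactly idempotent — re-normalizing is a no-op, and
  per-sample spike-in medians agree exactly afterwards — while the pooled
  median is only approximately stable under re-centring.

All probes of a sample, spike-ins included, are shifted by the same
constant, which is also how the generator applies its per-array offsets;
in a balanced design TC and TL are invariant under any global shift, so
normalization matters for variance estimation (shared offsets otherwise
inflate every gene's pooled within-cell variance by the same amount) more
than for the effect estimates themselves.

All samples are normalized jointly; whether the original arrays were
aligned per fraction instead is not recoverable from the published
description, and joint alignment is the weaker assumption.

## The moderated t-test

Gene-wise variances are unstable at small r, so they are shrunk toward a
scaled inverse-chi-square prior `σ²_g ~ s0²·d0/χ²(d0)` fitted across genes
by method of moments on `e_g = log(s²_g) − ψ(d_g/2) + log(d_g/2)`:
`d0` solves `ψ′(d0/2) = var(e) − mean(ψ′(d_g/2))` and
`s0² = exp(mean(e) + ψ(d0/2) − log(d0/2))`. The trigamma equation is
solved by a damped Newton iteration on the strictly decreasing trigamma
(tolerance 1e-10, positivity-clamped); trigamma monotonicity guarantees a
unique root. When the observed dispersion of `e_g` does not exceed its
sampling expectation the prior is degenerate (`d0 = ∞`, all posterior
variances equal `s0²`) and the test becomes a z-statistic. Genes with
`s²_g = 0` are excluded from the moment fit (their log is undefined) but
still tested, shrunk fully toward the prior through the posterior formula.

The moderated statistic is `t = effect / sqrt(s̃²·Σc²_i/r_i)` with
`s̃² = (d0·s0² + d_g·s²_g)/(d0 + d_g)` on `d0 + d_g` df; the contrast
scale is `4/r` for TL (coefficients ±1 on the four cell means) and `1/r`
for TC (±1/2), generalized to unequal cell sizes as `Σc²_i/r_i`. p-values
are two-sided — the classification needs both directions. Degenerate
`s̃² = 0` (possible only when prior and sample variance both vanish)
yields p = 0 (p = 1 for a zero effect) with a warning rather than NaN.

Benjamini–Hochberg adjustment is applied per effect over the non-spike-in
genes; spike-in probes are reported with their statistics but excluded
from prior estimation and from the multiple-testing family, since control
probes are not discoveries.

## Nine-group classification

An effect is called up (down) when its fdr is strictly below 0.05 and,
where the fold-change rule applies, its absolute log2 value strictly
exceeds 1; otherwise unchanged. Strict inequalities are deliberate: a
borderline gene with TL = 0.41 and fdr = 0.06 stays unchanged under every
rule variant. The fold-change gate is configurable (`apply_lfc_to`:
`"both"`, `"TC_only"`, `"neither"`) because published borderline-case
discussion is compatible with the gate not having been applied to TL; the
default applies it to both effects. The 3×3 cross of statuses defines
groups 1–9 (1 = TC:up/TL:up, …, 9 = TC:unchanged/TL:unchanged), which
partition the gene list by construction; the marginal counts (TC-up,
TC-down, TL-up, TL-down, only-transcriptional, only-translational) are
sums of group sizes. The net-effect score is simply `TC + TL`, a log2
summary of the combined change in expected protein output.

## TOP motif scanning

A 5'TOP motif is modelled as `C`, then an uninterrupted run of at least 3
pyrimidines (`C`/`T`), closed by `G`. The scan is anchored at position 1
(the 5' terminus — the biology of TOP regulation is cap-adjacent) and
after each motif resumes at the next base, so consecutive motifs chain
without gaps; it stops at the first non-opening position. The minimum
interior run of 3 is the smallest seen among published examples (`C TCT G`)
and is configurable; no maximum is imposed. Coordinates are 1-based
inclusive throughout. The greedy maximal-run scan needs no backtracking:
`G` terminates any pyrimidine run, so the scanner is provably equivalent
to iterating the regular expression `^C[CT]{3,}G`, and the test suite
checks that equivalence on 10,000 random sequences. Non-anchored
(internal) motifs are available behind `anchored = FALSE` but are off by
default. A gene is TOP-bearing if any of its transcripts carries an
anchored motif; transcripts with ≥2 chained motifs are flagged separately.

## Enrichment tests

Both enrichment analyses are Fisher's exact test on 2×2 tables built over
a universe of genes, with hypergeometric probabilities computed through
log-gamma factorials. The two-sided p sums the probabilities of all tables
with the observed margins whose probability is at most the observed one
times `1 + 1e-7` — the relative guard protects against floating-point ties
in that comparison; the one-sided p is the upper hypergeometric tail.
One boundary fact is easy to get wrong: for the balanced table
(1,1,1,1) the two-sided p is exactly 1 but the upper tail is 5/6, and the
tests pin both values against full enumeration.

- **TOP enrichment** compares each regulation group among the groups of
  interest (1–8 by default, matching the universe used for GO) against
  the remaining ones, on TOP-bearing status. Default sidedness is
  two-sided (odds ratio ≠ 1); note that with a strong planted enrichment
  in one group the complement's rate is inflated, so other groups can be
  significantly *depleted* under the two-sided test — specificity claims
  should use the one-sided variant. Genes without an available UTR are
  excluded from the universe and counted in a message. Significance is
  `p < 0.05` (strict).
- **GO enrichment** is the classic gene-count test: per term of a
  namespace (BP or MF), group genes versus the reference list, using
  true-path propagated annotations (is_a edges only — the classic variant
  tests gene counts, and part_of edges are not part of this analysis).
  The reference list defaults to the genes of groups 1–8 that carry at
  least one annotation in the namespace; terms with no annotated universe
  gene are skipped rather than reported at p = 1. One-sided (greater)
  p-values, significance `p ≤ 0.05`, no multiple-testing adjustment —
  the slight α-convention mismatch with the TOP test is preserved
  deliberately, and output is ordered by p ascending with ties broken by
  term id for determinism.

Gene identity: classification operates per transcript/probe, but GO
counting collapses to one gene symbol per gene, matching how multiple
probes of one gene are reported in groups while gene counts enter the
contingency tables.

## The synthetic generator

`simulate_expression()` emulates the statistical structure the tests
assume: genes are apportioned to the nine groups by largest-remainder
rounding of the configured proportions (defaults follow the published
group sizes of the adipogenesis time course, 813:754:25:660:10:87:358:37:2536);
nonzero effects draw magnitudes Uniform(1.25, 3.0) — straddling the
|log2FC| > 1 call threshold so the rule is genuinely exercised — with
signs set by the group; variances draw from the conjugate
inverse-chi-square prior (defaults d0 = 4, s0² = 0.05 log2², a moderately
informative prior typical of small-sample array fits), replicates are
normal, and every sample gets one additive offset (sd 0.3 log2) applied
to all probes so spike-in normalization has something real to remove.
Defaults use r = 3 replicates — the published description does not state
its replicate count, and r = 3 is the common minimal arrayed design; the
layout is generic over r ≥ 2. `simulate_utrs()` plants an anchored motif
(C + 3–12 pyrimidines + G + a 20–200 nt tail) in TOP-flagged genes and
redraws random sequences for unflagged genes until position 1 opens no
motif; the default motif probabilities (0.5 in group 1, 0.05 elsewhere)
create a detectable planted enrichment. `simulate_ontology()` grows a
rooted random DAG (each later term takes 1–2 earlier parents) with
background annotation probability 0.05 and a 5× odds multiplier for
target genes at the planted terms.

What the generator does *not* emulate: probe-level microarray artifacts
(dye bias, background, saturation), correlated genes, fraction-specific
variances, composition effects, or any fidelity to a particular deposited
dataset — noise magnitudes are set for testability. Passing tests
therefore demonstrate that the machinery is correct under its own model
assumptions, not that those assumptions hold for any given real array
experiment.

## Test problem sizes and tolerances

The property suites run at sizes chosen to make the statistical checks
sharp yet quick: Fisher vs full enumeration on 1,000 tables with margins
≤ 30; BH vs the quadratic step-up oracle on 1,000 vectors; scanner vs
regex on 10,000 sequences of length ≤ 50; propagation vs transitive
closure on 50-term DAGs; prior recovery at 10,000 genes (d0 within ±25%,
s0² within ±10% — method-of-moments precision at that n); a 20-run global
null at 2,000 genes (empirical fdr-call rate ≤ 0.07); 20-run group-label
recovery at effects ±2, σ² = 0.02, r = 3 (≥90%); and a 100-run planted-TOP
power check at 500 genes (group-1 detection ≥95%). Prior-recovery checks
run on spike-in-normalized data because shared array offsets add a common
component to every pooled variance that the normalization stage is there
to remove.

## Known limitations

- The pooled four-cell variance assumes homoskedastic fractions; strongly
  fraction-dependent noise would call for separate variances.
- Only additive (log-scale) array effects are modelled and removed;
  intensity-dependent distortions need loess/quantile methods that are
  intentionally out of scope.
- The TOP definition is a pragmatic regular-language approximation of
  UTRscan's pattern; motifs starting a few bases downstream of the cap
  are not counted by default because every published example chain starts
  at position 1.
- Enrichment p-values are reported raw by design; with hundreds of GO
  terms the `p ≤ 0.05` calls are descriptive, not family-wise guarantees.
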