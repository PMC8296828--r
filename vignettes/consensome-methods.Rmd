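---
title: "Methods: consensomes, HCT intersections, and the synthetic corpus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensomes, HCT intersections, and the synthetic corpus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consensnet)
```

# The analysis in one page

`consensnet` asks which upstream signaling-pathway nodes — typically
transcription factors assayed as ChIP-Seq IP antigens — plausibly drive a
differential-expression signature, here the signature separating
weight-gain *prone* from weight-gain *resistant* cohorts under
antipsychotic treatment.

The chain is:

1. **Gene sets.** From a per-gene DE table (fold change `fc` =
   prone/resistant, unadjusted `p`), the *up* set is
   `{fc > 1.25 and p < 0.05}` and the *down* set
   `{fc < 0.75 and p < 0.05}`, both with strict inequalities and on the
   unadjusted p-value.
2. **Consensomes.** For each node, genes are ranked by the mean of their
   peak strengths across that node's datasets and the ranking is
   expressed in percentiles.
3. **HCTs.** Genes in the top 5% of a node's consensome (percentile
   cutoff 95) are its high-confidence transcriptional targets.
4. **Intersection statistics.** Each node's HCT set is tested against the
   query set with the one-sided hypergeometric tail `P(X >= k)`; the
   sample odds ratio `ad/(bc)` summarises effect size; q-values are
   Benjamini–Hochberg, adjusted across all nodes of one analysis in a
   single batch, with significance flagged at q < 0.05 and q < 0.01.
5. **Follow-ups.** Phenotype enrichment among significant nodes (the
   universe is the set of *tested nodes*, membership decided on the genes
   encoding the nodes), cross-species overlap via ortholog maps,
   enzyme-class enrichment, and percentile conservation matrices.

The key modelling assumption throughout is the hypergeometric null: query
and target sets are exchangeable draws from a shared finite universe.
The universe size is therefore a real parameter, not a formality: the
package defaults to 30,000 for mouse gene-level tests (a conservative
transcribed-gene count) and 24,703 for tests against a curated
signaling-pathway annotation universe, and records the value used in
every output. For synthetic runs the simulated universe size is used, so
calibration statements are exact rather than flattering.

# Numerical and policy choices

**Absent records are zeros.** A dataset that assigned no peak strength to
a gene contributes 0 to that gene's mean for the node — absence of a
detected peak is treated as evidence of absence, matching an average
"across available datasets". Genes whose mean is 0 are then dropped from
the node's list entirely: they are *not targeted*, not bottom-ranked, and
they do not inflate `M` (the consensome size).

**Percentiles and ties.** With competition ranks `r = 1..M` (best = 1),
`percentile = 100 (M - r_min) / M`, where `r_min` is the best position of
a gene's tie block: tied genes share their block's maximum percentile, so
the HCT boundary is all-or-none across a tie. Percentiles live in
`[0, 100)` and are invariant to rescaling all strengths.

**The HCT boundary.** Membership is the tie-expanded top
`M - floor(cutoff * M / 100)` genes. For `M` divisible by 20 at cutoff 95
this is exactly the top 5% (`M/20` genes), i.e. `{percentile >= 95}`; for
small consensomes it rounds *up*, so a 19-gene consensome keeps its top
gene rather than returning an empty HCT set. (The arithmetic is done as
`M - floor(cutoff*M/100 + 1e-9)` because the naive
`ceiling((1 - cutoff/100) * M)` picks up floating-point drift — at
`M = 100` it yields 6, not 5.)

**Odds ratios.** The reported odds ratio is the closed-form sample
cross-product ratio, defined as 0 at zero overlap and flagged `Inf` when
a margin is exhausted. Fisher-test implementations report the conditional
maximum-likelihood estimate instead, which differs for small cells; it is
available via `or_method = "conditional"`. Because published odds ratios
rarely state which estimator produced them, tests in this package treat
printed ORs as consistency checks on margins, not exact targets.

**Down-set cutoff.** `fc_down` defaults to 0.75. A symmetric reading of
"FC > ±1.25" would give 1/1.25 = 0.8; both are plain arguments, and the
default follows the threshold stated where the down set is defined
precisely. The two differ only for genes with 0.75 < fc < 0.8.

**Cohorting.** Weight gain is last-day minus day-0 body weight; the k
largest gainers are prone and, among the remainder, the k smallest are
resistant. Ties break by ascending animal id (prone first), which makes
the assignment invariant to row order and keeps the two cohorts disjoint
even when one tie block spans both boundaries. Intake comparisons use the
across-days average per animal, matching a "g/day average" reading.

**ΔΔCt.** Housekeeping aggregation is the arithmetic mean of the
housekeeping Ct values, equivalent to the geometric mean of their
expression levels. `RQ = 2^-ΔΔCt` with the reference group's mean ΔCt as
baseline, so the reference group's geometric-mean RQ is 1 by
construction; adding a constant to every Ct (a global rescaling of
expression) leaves all RQs unchanged. A Shapiro–Wilk normality check is
available per gene but the screen never branches on it by default.

**Welch + two-stage FDR.** The per-gene screen uses Welch's
unequal-variance t test and flags discoveries with the two-stage
step-up procedure of Benjamini, Krieger and Yekutieli (stage one at
`q/(1+q)`, null-count estimate `m0 = m - r1`, stage two at
`q/(1+q) * m/m0`), at FDR 0.10 by default. One property worth spelling
out: the two-stage procedure is *not* uniformly at least as powerful as
plain BH. When stage one rejects nothing it stops, even where BH at the
nominal level would reject (p = (0.024, 1) at FDR 0.05 is a minimal
example); the superset relation is guaranteed only when stage one rejects
at least `m q/(1+q)` hypotheses. Our tests assert the faithful
transcription (cross-checked against an independent implementation of the
published procedure), the counterexample, and the conditional superset —
not the folklore unconditional one.

**Degenerate inputs.** Zero-variance-in-both-groups genes give `t = 0,
p = 1` when means agree and an error otherwise; `p = 0` entering the
double-log transform is clipped to 1e-300 and flagged; points with
`p >= 0.999` or OR = 0 are returned as explicitly unplottable rather than
silently dropped; a per-node overlap failure inside a batch is reported
in that row's `error` column without aborting the other nodes.

# What the synthetic generator emulates

The generator reproduces the *design* of the motivating study at desk
scale, with planted ground truth:

* **Cohort:** 40 animals, 14 days, top-5/bottom-5 cohorting; planted
  prone total gain Normal(6.3, 0.3) g versus resistant Normal(1.3, 0.3) g
  (the group means of the study design it emulates), intermediates at the
  midpoint; intake 3.1 vs 2.6 g/day. Trajectory endpoints carry the drawn
  gain exactly, so the noiseless limit recovers planted cohorts exactly.
* **Corpus:** each node's true targets get log-normal peak strengths
  (median 10, log-sd `noise_sd`) in every one of its 2–5 datasets;
  non-targets get sparse exponential background records with mean
  `noise_sd` and per-dataset inclusion probability `background_rate`.
  Tying the background scale to `noise_sd` makes `noise_sd = 0` a true
  noiseless limit in which background vanishes and consensome ranking is
  exact.
* **DE table:** planted prone genes draw log2 fold changes from
  Normal(`de_effect_lfc`, `noise_sd`), resistant genes mirrored, nulls
  from Normal(0, `noise_sd`); p-values are the two-sided normal tail of
  the observed effect at scale `noise_sd`, hence exactly Uniform(0,1)
  under the null and an exact null table at `de_effect_lfc = 0`. A
  `driver_enrichment` fraction of prone genes is drawn from the driver
  nodes' true targets — this is the dial that makes drivers recoverable.
* **Maps:** orthologs are identity-up-to-case (mouse Title-case to human
  UPPER-case) with configurable dropped and one-to-many fractions;
  phenotype sets cover driver nodes at a configurable rate.

Every generator draws from `seed` plus a fixed per-generator offset, so
outputs are bit-stable for a given configuration and adding one generator
call never perturbs another's stream.

What it does **not** emulate: read-level sequencing noise, count
overdispersion and library-size effects (DE summary statistics are drawn
directly), correlated co-regulation between nodes, gene-length or
GC biases in peak assignment, and real ortholog complexity beyond random
drop/duplication. Passing recovery and calibration tests therefore
demonstrates that the *statistical machinery* is correct and calibrated
under its own null — not that real ChIP-Atlas corpora meet these
assumptions.

# Effect sizes, defaults, and test problem sizes

No effect-size distributions are published for the motivating data, so
synthetic defaults were chosen once as field-plausible values and left
alone: `de_effect_lfc = 1` (a two-fold planted change),
`noise_sd = 0.5`, `driver_enrichment = 0.5` by default and 0.8 in
recovery experiments, `target_strength = 10` against a background mean of
`noise_sd`.

The validation experiments run at sizes chosen to make their statistical
claims sharp while staying desk-scale, and those sizes are part of the
stated conditions: null calibration uses 200 replicate corpora of 100
nodes over a 500-gene universe (about 20,000 node tests, so the
binomial-error band around the 5% FDR target is ±0.3%); planted-driver
recovery uses 100 seeds at 1,000 genes / 20 nodes with
`driver_enrichment = 0.8`; the two-species driver-conservation check uses
40 seeds at 600 genes / 10 nodes; enumeration checks of the overlap test
cover every margin up to a 12-gene universe.

# Known limitations

* The hypergeometric model ignores between-node HCT correlation, so
  q-values are exchangeable-null calibrated, not network-aware.
* The consensome mean treats datasets as exchangeable replicates; batch
  or lab effects in a real corpus are not modelled. Whether a public
  corpus averages over all datasets or only those detecting the gene is
  a dialect choice — this package averages over all of a node's datasets.
* Ortholog mapping under the `"any"` policy can inflate set sizes for
  expanded families; universes for cross-species tests must be chosen by
  the caller for publication-grade claims.
* The conservation matrix's default inclusion rule ("HCT in at least one
  species") is the permissive reading of an ambiguous convention; the
  strict rule (`"both"`) is available and the choice is recorded in the
  result's attributes.
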