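---
title: "Methods: cross-model transcriptome concordance"
author: "xconcord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-model transcriptome concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xconcord)
```

This vignette documents the statistical models behind `xconcord`, the
assumptions they make, the tunable parameters and why their defaults are
what they are, what the synthetic-data generator does and does not
emulate, and the design decisions taken where the methodology left genuine
freedom.

## Study design and data model

The package targets the paired-model time-course design used in
comparative striatal transcriptomics of Huntington's disease mouse models:
two genotypes (wild-type vs mutant) profiled at three ages (6, 12, 18
months) with around five animals per (genotype, age) cell, repeated in a
second model on a different array platform, the two platforms linked
through ortholog (homolog-group) identifiers. The unit of analysis is the
probeset; several probesets may interrogate one gene. Input matrices are
assumed to be post-normalisation log2 intensities with no missing values —
the reader refuses to impute, because silent imputation would corrupt the
variance-moderation machinery downstream. Each (genotype, time) cell must
hold at least two samples so within-cell variances are estimable.

The data are *pseudo-longitudinal*: different animals at each age, not
repeated measures. All models here are fixed-effects and treat samples as
independent; no longitudinal correlation structure is fitted.

## Moderated-t differential expression

For a two-group contrast (always oriented MUT − WT, or later − earlier
age, so that "down in mutant" is a negative log2FC), each probeset gets an
ordinary pooled two-sample estimate: log2 fold change `b_g`, pooled
variance `s²_g` on `d_g = n₁ + n₂ − 2` df. The empirical-Bayes layer
assumes the gene-wise true variances follow a scaled inverse-chi-square
prior `σ²_g ~ d₀·s₀²/χ²(d₀)`. Under that prior `log s²_g` has mean
`log s₀² + ψ(d_g/2) − log(d_g/2) − ψ(d₀/2) + log(d₀/2)` and variance
`ψ′(d_g/2) + ψ′(d₀/2)`, which gives the method-of-moments estimator used
by `estimate_prior()`: solve `ψ′(d₀/2) = var(log s²) − mean(ψ′(d_g/2))`
for `d₀` (the left side is strictly decreasing, so monotone root-finding
on `[0.1, 10⁶]` suffices), then read `s₀²` off the mean with the digamma
bias correction. If the observed dispersion of `log s²` does not exceed
its pure sampling dispersion the prior is degenerate: `d₀ = ∞`, every
probeset gets `s₀²`, and the reference distribution becomes normal.
Zero variances are excluded from the moment fit; all-zero variance data
is an error rather than a silent answer.

The moderated statistic is `t = b_g / √(s̃²_g (1/n₁ + 1/n₂))` with
`s̃²_g = (d₀ s₀² + d_g s²_g)/(d₀ + d_g)`, referred to `t` with `d₀ + d_g`
df. Setting `d₀ = 0` recovers the classical pooled t exactly — the test
suite asserts this to 10⁻⁹ — and the package's t/p values match `limma`'s
when given `limma`'s own fitted prior. Multiple testing uses
Benjamini–Hochberg step-up (`stats::p.adjust`), checked against a
brute-force implementation. Fold-change magnitude is reported as
`AbsFC = 2^|log2FC|` (linear scale, always ≥ 1), serialized to 3 decimal
places. Ranking is ascending p with ties broken by descending |log2FC|,
then probeset id — fully deterministic, because the ranked list is the
input to the cross-dataset stage.

Per-age genotype contrasts use only the samples of that age (no pooling of
variance across ages); this is the natural reading of a per-timepoint
test, though a shared-variance variant would gain df — flagged as a
sensitivity-analysis candidate rather than implemented.

## Genotype-by-time screen and trajectory patterns

`genotype_time_anova()` fits, per probeset, the two-way fixed-effects
model with genotype, age (categorical) and their interaction, and reports
the extra-sum-of-squares F-test of *all genotype-containing terms* against
the age-only model. This is a deliberate stand-in for a dedicated
time-course ANOVA estimator: the downstream use — extract FDR < 0.05
genes, then tag trajectories — only requires a calibrated screen for
genotype-dependent expression over the time course, which the per-gene
two-way ANOVA provides exactly (the F equals a direct least-squares oracle
to 10⁻⁸ in the tests, and its null p-values are uniform). Implementation
is via shared projection matrices (one QR per design, not per gene), so
5000 genes screen in well under a second.

Significant probesets are then classified per genotype by correlating the
per-age means with the standardized monotone "up" template over the
ordered age index ((−1, 0, +1) for three ages); "down" is its negation, so
one Pearson correlation decides both. The call is no-change when the
amplitude (max − min of per-age means) falls below `min_amp` or |r| falls
below `r_min`; constant profiles (undefined correlation) are no-change.
Defaults: `r_min = 0.8` — with three time points this excludes strongly
non-monotone shapes while tolerating noise on a monotone trend — and
`min_amp = 0.1` log2 units (≈ 7% linear change), below the smallest
fold changes that reach significance in studies of this size, so the
amplitude gate only removes biologically negligible wiggle. Raw per-age
means are used rather than model coefficients; with a saturated
genotype × age model the fitted cell means equal the raw means anyway.

Gene-level aggregation: a gene inherits its probesets' pattern when they
agree; probesets disagreeing on the pattern make the gene "mixed", and
mixed-pattern genes are excluded from the pattern table entirely (they
have no well-defined cell). Genes with an unambiguous pattern but
disagreeing direction signs stay in their cell and are excluded only from
the down/up tallies — hence down + up ≤ cell count, with marginal
consistency asserted on every construction. The genotype direction is the
sign of the average MUT − WT difference across all ages.

## Cross-dataset concordance

Comparing ranked lists across platforms or species requires collapsing to
a shared namespace first: probesets → unique genes (keep the entry with
smallest p; ties by larger |log2FC|, then probeset id), then genes →
homolog groups, collapsing multi-gene groups within a dataset by best p
*before* crossing namespaces — mirroring the convert-to-unique-gene-ids,
then-to-homolog-ids order of operations. Unmapped genes are recorded and
excluded, never silently dropped.

The top-N overlap test is an upper-tail hypergeometric `P[X ≥ k]`. The
universe is the dominant unstated degree of freedom in any such analysis,
so it is an explicit, reported policy: default "intersection of the two
collapsed lists" (both lists must have been able to contain the gene),
with "union" and "fixed N" available. A permutation null (resample the
top-A set uniformly from the universe, `p = (1 + #exceed)/(reps + 1)`,
default 10⁴ reps giving a 10⁻⁴ floor) cross-checks the analytic null; the
two agree within Monte-Carlo error in the tests.

The concordance profile takes dataset A's top K = 200 entries (the scale
at which a focused signature is visible), locates each in dataset B's
full ranking, bins the positions into consecutive 1000-gene rank bins,
and splits each bin count by sign agreement of the fold changes.
Frequencies are fractions of K, so bin frequencies plus the unmapped
fraction sum to one — an invariant asserted to 10⁻¹² on every
construction. Concordant mass concentrated in the first bins is the
visual signature of a shared program; negating every sign in B swaps the
concordant and discordant series exactly.

## Genotype × model interaction

To find genes whose mutant effect *differs* between models, probesets are
averaged to one gene-level profile per study (best-p selection inside this
fit would condition on significance and bias the interaction test), ages
are pooled (the reported quantity is a single per-model fold change), each
gene is median-centred within study — cosmetic, since any per-model shift
is absorbed by the model main effect, as the shift-invariance test
verifies — and the least-squares model
`expression ~ genotype + model + genotype:model` is fitted per gene. The
reported p is the extra-sum-of-squares F of the interaction term, which
for a single coefficient equals its squared-t test. Divergent genes are
those with interaction p below 0.05 and `|FC_A − FC_B|` strictly above
0.20 log2 units, ranked by descending difference: the strict 0.20 bound
keeps the list to effects of at least ~15% relative difference.

## Conditional gene-set enrichment

Gene sets live on a DAG with the true-path rule (a gene annotated to a
term belongs to all its ancestors; propagation is validated against a
brute-force closure oracle). The conditional test processes terms
children-before-parents (reverse topological order, ties broken by term
id so the result is independent of insertion order): each term's
propagated set, restricted to the analysis universe, is tested by
upper-tail hypergeometric; when a term's unadjusted p falls below
`alpha_condition = 0.05`, its genes are removed from every ancestor's set
before the ancestor is tested, in a single bottom-up pass (no iteration).
A parent therefore only reaches significance on signal not already
explained by a child — on nested fixtures the conditioned parent's p
provably rises. Reported `count`/`global` are the post-conditioning
intersection sizes; BH adjustment across terms gives the "FDR p" column.

"Genetic similarity" between terms is the Jaccard index of their gene
sets (the standard enrichment-map choice; an overlap-coefficient option
exists because the two diverge for nested sets). Cluster structure comes
from average-linkage agglomeration on 1 − similarity, cut at the coarsest
grouping in which every cluster's mean pairwise similarity reaches the
threshold (0.9 for tight redundancy groups, 0.5 for themes); each cluster
is represented by its most significant term (ties: larger set, then term
id). The cut is found by scanning dendrogram cuts from coarse to fine,
which the tests confirm against exhaustive evaluation of all cuts.

## The synthetic-data generator

`simulate_paired_models()` generates the design the analyses expect:
per-gene expression
`y = μ_g + β_g·I(MUT) + γ_g(genotype)·t + ε, ε ~ N(0, σ²_g)`, with `t`
the 0-based ordered age index — trajectory classification is rank-based,
so month spacing carries no information and is deliberately not modelled —
`σ²_g` drawn from the scaled inverse-chi-square prior (so the moderation
assumptions hold *exactly*, and prior recovery is a fair test),
`β_g` the planted genotype effect, and per-genotype slopes `γ` encoding
up/flat/down trajectories. DE genes are planted in both models with the
same sign (shared fraction), with opposite sign (discordant fraction), or
in one model only; the two studies live on disjoint probeset and gene
namespaces joined by a generated ortholog map covering a configurable
fraction of genes. A companion generator plants enrichment signal in a
random gene-set DAG by odds-weighted sampling of DE genes.

Defaults mirror the emulated study at desk scale: 5000 genes (vs ~25k
probesets on a real array), 5 replicates per cell, ages 6/12/18 months,
baseline 7 log2 units, |log2FC| ~ N(0.4, 0.15²) — the magnitude range of
significant changes in studies of this size — 8% DE genes, 70% shared /
5% discordant (the emulated model pair is strongly concordant), variance
prior d₀ = 4, s₀² = 0.05, trajectory slope 0.25 log2/step, 85% mappable
genes. One master seed drives named substreams (one per study/component),
so adding a generator does not perturb the draws of another and every
artifact is bit-reproducible from the seed.

What the generator does **not** emulate — and therefore what passing
tests cannot certify about real data: probe-level effects and
normalisation artefacts (inputs are assumed post-normalisation), batch
and sex effects, correlated genes (all genes are independent given the
design), heavy-tailed noise, annotation errors in real ortholog maps, and
the non-random structure of real GO term overlaps.

## Numerical choices and degenerate inputs

- Prior root-finding: `uniroot` on `d₀ ∈ [0.1, 10⁶]` at tolerance 10⁻¹⁰;
  dispersion at or below the sampling floor → `d₀ = ∞` (normal
  reference), never a negative prior.
- Zero moderated variance: t is ±∞ with p = 0 (p = 1 when the fold change
  is also 0) plus a warning — a loud answer rather than NaN.
- Constant trajectories: correlation undefined → treated as r = 0 → NC.
- Equal-|r| template ties resolve to NC (conservative; with the two
  antisymmetric templates an exact tie means no monotone preference).
- Ranking and topological ties always break on identifiers, so every
  output is reproducible byte for byte.
- ANOVA and interaction fits use one QR per design shared across genes;
  residual sums of squares are clipped at 0 against floating-point
  cancellation.

## Problem sizes used by the test suite

Unit fixtures run at 3–200 probesets. The calibration and recovery checks
use: 5000-gene null studies (type-I of the moderated contrast), 2000-gene
ANOVA nulls, 10⁴-gene prior recovery at d₀ ∈ {4, 10}, 200 seeds × 20
terms for enrichment calibration, 400 seeds of top-1000 overlaps in a
3000-group universe (where the discrete test's achievable level, 0.049,
is essentially nominal — at small universes the hypergeometric is visibly
conservative and a calibration check would measure discreteness, not
error), and 20 seeds per level for the shared-fraction dose-response.
These sizes make the whole suite run in well under a minute while keeping
Monte-Carlo error far inside the asserted bands.

## Known limitations

- The genotype-by-time screen is a per-gene two-way ANOVA, not a
  functional time-course estimator; with only three ages this loses
  little, but it would not scale to dense time series.
- Interaction testing pools ages; a per-age variant would detect
  age-restricted divergence (the pooled fold changes are what the
  divergent-gene table reports, so the pooled test matches the report).
- The overlap p-value depends on the universe policy; published overlap
  p-values are generally not reproducible without knowing the original
  universe, which is why the policy is always attached to the result.
- Enrichment `count` is genes after probeset collapse, not probesets;
  with many-to-one annotation the two differ.
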