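---
title: "Nominating cell-surface immunotherapy targets in MYCN-amplified neuroblastoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nominating cell-surface immunotherapy targets in MYCN-amplified neuroblastoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycnfunnel)
```

## The problem

High-risk neuroblastoma with focal *MYCN* amplification has few good
immunotherapeutic handles: what is needed is a cell-surface protein that is
strongly overexpressed when the driver is amplified and essentially silent in
normal tissue outside the central nervous system (an antibody or antibody-drug
conjugate will not cross the blood-brain barrier, so CNS expression is
tolerable where systemic expression is not). `mycnfunnel` implements the
computational funnel that turns tumor expression cohorts, MYCN ChIP-seq peak
sets, promoter sequence, and annotation tables into a short ranked list of
such candidates:

1. **Differential overexpression on two platforms.** Genes must pass a
   stratified screen on an RNA-seq count cohort *and* on an intensity
   (array-style) cohort.
2. **Plasma-membrane designation** from subcellular-localization confidence
   scores.
3. **A TSS-proximal E-box** (the CACGTG hexamer bound by MYC-family basic
   helix-loop-helix factors) in the gene's promoter.
4. **MYCN occupancy**: a significant, blacklist-free ChIP peak over the
   promoter window, and specifically over the E-box.
5. **Normal-tissue expression limited to the CNS.**
6. **Not secreted** (a secreted product cannot be targeted on the membrane).

The six stages are conjunctive, so survivor sets are nested and the final set
does not depend on stage order; the intermediate counts do, and the order is
fixed as listed.

## The differential-expression model

Counts are transformed to log2 counts-per-million with the usual offsets,

$$y_{gs} = \log_2\!\frac{c_{gs} + 0.5}{L_s + 1}\cdot 10^6,$$

where $L_s$ is the library size of sample $s$. Because the variance of
log-counts depends systematically on the mean, each observation receives a
precision weight from a fitted mean-variance trend: per-gene residual
standard deviations from a two-group fit are square-rooted (a quarter-root of
the variance, which symmetrises the trend), smoothed against average log
count by `lowess` (span 0.5, the conventional default, exposed as an
argument), and the trend value at each observation's fitted log-count is
inverted to a weight $w = \hat\sigma^{-4}$.

The screen statistic is a weighted two-group moderated t. Per gene the
weighted fit gives $\widehat{\mathrm{logFC}}_g$ (high minus low group — the
sign convention everywhere in the package) and a residual variance $s_g^2$ on
$d = n - 2$ degrees of freedom. Residual variances are shrunk towards a
common prior $s_0^2$ with prior degrees of freedom $d_0$, estimated by moment
matching of the scaled-F distribution of the $s_g^2$ on the log scale (a
Newton solve of the trigamma equation); the posterior variance is

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},$$

and $t_g = \widehat{\mathrm{logFC}}_g / (\tilde s_g \cdot
\mathrm{se}_{u,g})$ is referred to $t_{d + d_0}$. The two limits are exposed
for verification: `prior_df = 0` collapses to the ordinary weighted t,
`prior_df = Inf` to a z-like statistic with the pooled variance. The test
suite checks the whole weighted pipeline against the reference
voom/limma implementation to near machine precision, and checks the limits
against direct formulas.

Benjamini-Hochberg supplies adjusted p-values, and the screen keeps genes
with `log_fc > 1` **and** `adj_p < 0.05`, both strict. Strictness at the
fold-change boundary is deliberate: a gene at exactly 1.0 fails. (The
adjusted-p boundary is not specified by convention; strict was chosen for
symmetry.)

### Stratification

Two modes mirror the two platforms:

* `by_status`: amplified samples form the high group, non-amplified the low
  group; samples of unknown status are a configuration error rather than a
  silent exclusion.
* `by_quantile`: samples are ranked by the driver gene's expression
  (ascending, with sample identifier as tie-break so the assignment is
  deterministic under reordering and ties); the top `floor(0.15 n)`
  (minimum 2) are high, the bottom the same count low, the rest excluded.
  The two tails are taken from one ordering, so they can never overlap when
  `2k <= n`; smaller cohorts are an error.

## Regulatory evidence

All genomic coordinates are 0-based half-open (BED convention) internally;
1-based inputs must be converted at the boundary. Overlap of `[a, b)` and
`[c, d)` means `a < d && c < b`: adjacent intervals do not overlap, and a
single base pair of overlap is enough both to blacklist a peak and to call an
E-box occupied.

* **"TSS-proximal"** has no standard numeric definition; the package
  defaults to ±1000 bp around the TSS, strand-oriented (upstream extends
  right for minus-strand genes) and clipped at coordinate 0. Both extents
  are arguments.
* **Motif set**: canonical CACGTG only by default. The hexamer is its own
  reverse complement, so one forward scan is strand-agnostic; degenerate
  E-boxes (e.g. CATGTG) can be added explicitly and are then scanned on both
  strands with duplicate positions collapsed. Overlapping occurrences are
  all reported.
* **Peak filtering**: `q_value <= 0.05` (inclusive, the common peak-calling
  convention; narrowPeak column 9 is decoded as -log10 q per the ENCODE
  specification) and zero tolerance for blacklist overlap.
* **Consensus across cell lines** defaults to "any line" (`min_lines = 1`);
  published screens of this kind aggregate a handful of amplified discovery
  lines without stating a quorum, so the quorum is an argument rather than an
  assumption.
* Occupancy at an E-box requires peak-motif interval overlap, not summit
  containment: the evidence this mirrors is stated at the level of occupied
  E-boxes, not summit positions. `ebox_occupied` implies
  `mycn_bound_near_tss` by construction, and the funnel rejects inputs that
  violate the implication.

A deliberately small local-Poisson caller (`toy_local_poisson_caller`) turns
coverage vectors into peak fixtures for tests: per-position Poisson upper
tails against the maximum of local control means and the global control mean,
BH across positions, significant runs merged. It is a fixture generator, not
a re-implementation of a production peak caller, and alignment, duplicate
removal and fragment-size estimation are all out of scope.

## Annotation filters

* **Membrane designation**: the maximum confidence score (integer 0-5)
  across a gene's GO cellular-component categories must be attained by
  "Plasma membrane" or "Cell surface" (case-insensitive, synonym list
  configurable) and be at least 3. A membrane category *sharing* the
  maximum with another category passes — the rule constrains only the max's
  association, and encoding it any other way would silently drop genes with
  tied evidence.
* **Limited normal expression**: at or below a threshold (default 1.0,
  TPM-like; there is no canonical numeric definition of "limited", so it is
  configuration, not inference) in every non-CNS tissue; CNS tissues are
  unconstrained. The CNS tissue list is likewise configuration.
* **Not secreted**: the negation of a per-gene secreted flag.

Each filter is a pure predicate — order-independent, idempotent — and their
conjunction equals sequential filtering in any order, which the test suite
asserts.

## The candidate matrix and ranking

`assemble_candidates()` admits a gene if it passes **both** platform screens
and the membrane designation; the other four flags are evidence columns, with
genes absent from a source getting `FALSE` (never `NA`). One asymmetry is
intentional: a gene whose *array* log fold change is missing is admitted on
its array adjusted p-value alone. The bundled example matrix
(`nb_candidate_matrix()`) contains exactly such a gene (NME1), retained in
the published screen despite the missing array fold change.

The final survivors are ranked by ascending RNA-seq adjusted p-value, ties
by descending RNA-seq log fold change, then gene identifier. On the bundled
matrix the two candidate statistics disagree with the narrative choice in
the screen this matrix reproduces: NME1's adjusted p (1.17e-6) is smaller
than CAMKV's (2.02e-6), while CAMKV's fold change (1.73) is larger than
NME1's (1.00) and CAMKV was the nominated target. The package does not
silently resolve this: the default ranking key is `adj_p` (which puts NME1
first), `rank_by = "log_fc"` puts CAMKV first, and both statistics are
carried in the report so the choice is visible. The qualitative
consideration that also favoured CAMKV — nm23-H1, the NME1 product, has
diffuse subcellular localization — is knowledge external to the data tables
and is deliberately not encoded as a rule.

A related documentation note: in the bundled matrix eight genes carry the
occupied-E-box flag, which is what the tabulated evidence supports; a
narrative recap of the same screen quotes four. The package follows the
tabulated flags and leaves the discrepancy visible rather than adjudicating
it.

## What the simulators emulate — and what they do not

`simulate_cohort()` draws negative-binomial counts with variance
$\mu + \phi\mu^2$ (dispersion $\phi = 0.1$ by default, a typical bulk
RNA-seq value), per-gene log-normal baseline means (median 100), and plants a
multiplicative effect of $2^{1.5}$ on 50 of 2000 target genes and $2^{3}$ on
the driver in the amplified 40-60% of 60 samples. The planted driver effect
is large on purpose so that status-based and quantile-based stratification
select concordant groups, as they do in real amplified cohorts. The
defaults emulate a mid-sized tumor cohort with a strong driver; the planted
target effect of 1.5 log2 units straddles the screen's fold-change threshold
of 1 so that recovery is informative rather than trivial.

`simulate_genome()` lays non-overlapping 2-kb promoters along one synthetic
chromosome, with random sequence at 40% GC and one exact CACGTG planted at a
recorded offset in a random subset of promoters (background occurrences
arise by chance, roughly once per 2 kb at default GC, and are reported by
the scanner like any other hit — only planted ones carry truth labels).
`simulate_chip()` gives amplified cell lines a 150-bp peak centred on every
planted E-box at a configurable q-value, plus uniform decoy peaks; non-
amplified lines get decoys only. `simulate_annotations()` plants membrane,
CNS-restricted and secreted flags independently per gene and emits
schema-compatible localization and tissue tables.

What passing tests on these simulations shows: the statistical machinery is
calibrated (type-I error ≈ 0.05 under the global null; zero screen survivors
after BH in almost every null cohort), the planted signal is recovered
(sensitivity ≥ 0.9, false-discovery proportion ≤ 0.1 through the complete
funnel), and every fast path agrees with a brute-force oracle. What it does
not show: behaviour under batch effects, library-composition bias,
correlated genes, read-level ChIP artefacts, enhancer (non-promoter)
occupancy, or annotation errors — none of which the generators model. Real
cohort statistics (specific fold changes, the driver-candidate correlation
of a given tumor set) require the external data and are represented here
only by the bundled candidate matrix and by a known-correlation generator
that checks the correlation operation itself at the published sample size
(n = 150, correlation 0.6).

## Numerical choices

* Residual standard deviations are floored at 1e-8 before trend fitting so
  zero-variance genes yield large-but-finite weights.
* Genes with zero or non-positive residual variance are excluded from the
  prior moment-matching.
* The trigamma inverse is solved by Newton iteration with the standard
  large/small-argument closed forms.
* Expression matrices reject missing values outright; imputation is out of
  scope. Counts and FPKM must be non-negative; log-scale intensities may be
  negative.
* TSV/narrowPeak/BED readers validate on entry (duplicate identifiers,
  non-numeric cells with coordinates, `end <= start`) and round-trip exactly
  with their writers; q-value decoding (`10^{-q_{log10}}`) and re-encoding
  are mutual inverses.

## Problem sizes used by the checks

The simulation-backed tests and the acceptance script run 2000-gene,
60-sample cohorts (10 seeds for the null calibration and 10 for end-to-end
recovery), 1000 random 2-kb promoters for the scanner-vs-enumeration
equivalence, and 50 replicates of the n = 150 correlation surrogate — sizes
at which every estimate above is stable to well within its stated margin
while the whole suite stays fast on a single CPU.

## Known limitations

* The design matrix is two-group only; covariates, batch correction and
  multi-factor designs are out of scope.
* Array preprocessing (RMA) is upstream: intensity matrices are accepted
  as-is.
* No enhancer analysis: occupancy is assessed in promoter windows only.
* The membrane/secretion/tissue filters are only as good as the annotation
  tables supplied; the package consumes schema-compatible exports rather
  than querying live databases.
* `dplyr` operations on an expression matrix can drop its `unit` attribute;
  rebuild with `expression_matrix()` after heavy manipulation.
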