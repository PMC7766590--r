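---
title: "Methods: signature reversal and pharmacovigilance screening in cindr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature reversal and pharmacovigilance screening in cindr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cindr)
```

`cindr` nominates repositioning candidates against cisplatin-induced
nephrotoxicity by intersecting two independent screens: chemicals whose
perturbation signatures *reverse* a cross-dataset toxicity signature, and
co-medications associated with *reduced* reporting odds of acute kidney
injury among cisplatin adverse-event reports. This vignette explains the
models behind each stage, the parameters that matter, what the synthetic
generators do and do not emulate, and the numerical choices made where the
design was open.

## 1. Differential expression and the cross-dataset signature

### Normalization

Library composition and depth differences are removed with trimmed-ratio
scale factors (`normalize_counts()`): the reference pseudo-sample is the
per-gene geometric mean over samples, restricted to genes observed in every
sample; each sample's factor is the exponentiated trimmed mean of its log
ratios to that reference, with 30% trimmed **from each tail** (the
convention of R's `mean(trim =)`), then rescaled so the factors' geometric
mean is exactly 1. Normalized counts are counts divided by the factor. On
exactly proportional libraries this reduces to the closed form: a sample at
twice the depth of another gets factors $(2^{-1/2}, 2^{1/2})$.

### The test

`test_differential_expression()` fits, per gene, a two-group
negative-binomial model with variance $\mu + \phi\mu^2$. Dispersion is
estimated by method of moments from the pooled within-group variance of
normalized counts, then shrunk toward the across-gene common value (the
median over genes with pooled mean ≥ 1) with weight 0.7 on the common
value — individual 4-sample estimates are far too noisy on their own, while
the common value alone ignores genuine mean–dispersion structure. The Wald
statistic is the log ratio of group means (pseudo-count 0.5, which also
defines the fold-change sign at zero counts) over its delta-method standard
error $\sqrt{(1/\mu_1 + \phi')/n_1 + (1/\mu_2 + \phi')/n_2}$, referred to
the standard normal. Genes with zero counts everywhere get $p = 1$ and zero
fold change. The package's property tests verify empirically that null
simulations at $n = 4$ per group yield approximately uniform p-values
(Kolmogorov–Smirnov distance below 0.05 at 2000 genes) and ≤ 2% of genes at
$q < 0.01$, while 4-fold planted effects at dispersion 0.1 are recalled at
well over 80% — the regime the pipeline is designed for.

Multiplicity is handled by Benjamini–Hochberg (`bh_adjust()`, a validated
wrapper over `stats::p.adjust`); the default per-dataset threshold is
$q < 0.01$, configurable via `fdr`.

### Ortholog mapping and intersection

Mouse-labelled datasets are mapped to human symbols through a two-column
table (`map_orthologs()`). Two silent failure modes are made explicit:
unmapped source symbols are dropped and reported, and a human symbol
receiving *conflicting* directions from different sources is dropped and
reported, preserving the up/down disjointness invariant. One-to-many
sources expand to all targets (maximizing recall; spurious extra targets
cannot survive the intersection because the human dataset never calls
them). The final signature (`intersect_signatures()`) keeps a gene as up
(down) only if every dataset calls it up (down); a gene with mixed
directions across datasets is excluded from both sets by construction.

Whether the FDR threshold should be applied per dataset before intersection
or jointly is genuinely open; `cindr` applies it per dataset, matching how
per-dataset DE tools are normally run, and exposes `fdr` so the choice is
visible.

### Enrichment

`enrich_gene_sets()` is a one-sided hypergeometric over-representation test
(upper tail, i.e. probability of at least the observed overlap) of the
signature against a user-supplied GMT collection within an explicit
universe, BH-adjusted across sets. It replaces external enrichment services
with a self-contained equivalent; it does not model gene-set overlap or
network structure.

## 2. Connectivity scoring

`weighted_enrichment_score()` is the weighted Kolmogorov–Smirnov running
sum with weight exponent 1 on |score|: genes sorted by score descending
(ties broken lexicographically by gene id for determinism), query hits add
$|s_g|/\sum_{hits}|s_g|$, misses subtract $1/(N - N_h)$, and ES is the
extremum of largest magnitude, preferring the positive extremum on ties (up
to a $10^{-12}$ rounding guard — exact ±ties do occur in floating point).
`combined_score()` sets WTCS to $(ES_{up} - ES_{down})/2$ when the two
halves disagree in sign (or either is zero) and 0 otherwise: a coherent
reversal must push the up genes down *and* the down genes up.
`normalize_scores()` divides, within each group and sign, by the mean
absolute score of same-sign members, making scores comparable across
groups; `tau_percentile()` is the signed percentage of touchstone |NCS|
values *strictly* below |NCS| (strict so that NCS = 0 gives exactly tau =
0). The default touchstone is the whole supplied library; the selection
keeps tau below 0, configurable via `tau_threshold`.

These formulas follow the published connectivity-map scoring family; the
package reimplements them rather than calling an external catalog service,
so results depend on the user's own reference library, not on any
particular catalog version. Cell-line summarization across multiple
contexts is out of scope (the `group` label supports per-context
normalization only).

## 3. The pharmacovigilance screen

Reports arrive as three `$`-delimited tables (DEMO/DRUG/REAC) joined on
`primaryid`. Cases are deduplicated to the most recent report — realized as
the highest `caseversion`, ties broken by highest `primaryid`, since
version ordering is the recoverable recency signal in this dialect (no date
fields). Verbatim drug strings are normalized (trim, uppercase, collapse
whitespace) and collated to ATC level-5 codes through a synonym table, so
spelling and salt variants of one substance count once per case; unmapped
strings are dropped and counted rather than silently lost.

Within the cohort of cases containing the causative drug, each
co-medication appearing in at least `min_exposed` cases (default 3, a
conventional disproportionality floor) is cross-classified against the
indexed reaction and scored with the reporting odds ratio and its Woolf
log-normal 95% interval ($z = 1.959964$). Any zero cell triggers the
Haldane–Anscombe +0.5 correction on all four cells, flagged in the output;
a table with an empty exposed or unexposed margin is flagged undefined and
excluded. A **protective signal** is an upper bound below 1. No
multiple-testing correction is applied by default — the screen mirrors the
interval-only criterion traditional in disproportionality analysis — but
`adjust = TRUE` adds BH q-values for users who want them. Drug roles
(suspect vs concomitant) are not modelled; every drug on a case counts as
co-administered.

## 4. Candidate intersection

Perturbagen display names and ATC codes live in different vocabularies;
`harmonize_names()` aligns them through a user-supplied mapping table after
normalizing names and stripping common salt suffixes. There is no
authoritative in-scope vocabulary bridging the two spaces, so the mapping
is an explicit input (the synthetic scenario generates its own);
unmappable perturbagens remain connectivity-only identities rather than
being guessed. `intersect_candidates()` annotates every identity with its
sources and sorts in-both candidates first by (tau ascending, CI upper
bound ascending). `run_pipeline()` orchestrates the stages, writes all
intermediate artifacts plus a JSON summary and a seeded run log, and
degrades to a connectivity-only report when pharmacovigilance inputs are
absent.

## 5. What the synthetic generators emulate

The generators exist so that every downstream stage can be scored against
planted truth without any external download. Their defaults are the study
conditions under which the package's operating characteristics are tested;
they are synthetic conventions chosen to be realistic for the field, not
estimates of any particular dataset.

**Counts** (`transcriptome_sim_spec()`): three studies (two mouse-labelled,
one human), 2000 genes, 4 samples per group, NB dispersion 0.1, baseline
means log-uniform over $2^3..2^{10}$, a shared planted signature of 100 up
+ 50 down genes at |log2 FC| = 2 with consistent sign across studies, plus
5% study-private DE genes per study with random sign (so only the shared
signature survives intersection). The accompanying ortholog table omits 5%
of genes and gives another 5% a spurious extra target, exercising the
mapping edge cases. Not emulated: read-level data, batch effects,
mean-dependent dispersion trends, correlated genes.

**Reports** (`faers_sim_spec()`): 200,000 cases; cisplatin on 10% of them;
eight co-medications assigned independently by prevalence — one protective
(odds multiplier 0.3 at prevalence 0.2), one risk (3.0), six null. The
indexed reaction fires per case with probability
$\mathrm{logit}^{-1}(\mathrm{logit}(p_0) + \sum \log m_d)$ over
co-medications present, with $p_0 = 0.3$ in cisplatin cases and 0.05
otherwise; three distractor reactions per case are drawn from a 20-term
vocabulary. 10% of cases are emitted twice, the earlier version's drug
list perturbed with probability 0.5, so deduplication mistakes are
observable. Not emulated: reporting dynamics over time, MedDRA hierarchies,
drug–drug interactions beyond independent multiplicative odds,
suspect/concomitant roles.

**Library** (`library_sim_spec()`): 200 perturbagens × 1000 genes of
i.i.d. N(0, 1) scores; 5 reversers and 5 mimickers additionally shift the
query genes by ±5·`reversal_strength` score units (amplitude 5 is fixed so
that strength in (0, 1] spans weak-to-strong signals on a z-score-like
scale). Not emulated: correlated gene modules, dose series, cell-context
heterogeneity.

Because the planted effects are clean and independent, passing tests
demonstrate that the machinery is correct and has the intended operating
characteristics under its own model; they do not demonstrate robustness to
the correlation structure, annotation noise and reporting biases of real
catalogs and report databases.

## 6. Numerical choices and degenerate inputs

- Deterministic ranking everywhere ties can occur (gene ids
  lexicographically; candidate sorts break ties by identity).
- All simulation entry points are pure functions of their spec (seeded with
  `withr::with_seed`); the pipeline derives independent sub-seeds per
  generator from the master seed.
- A query set whose library scores are all zero falls back to equal hit
  weights; all-zero normalization groups stay zero; an all-zero sample is a
  hard error naming the sample; a signature empty after filtering to the
  library universe is a hard error listing the dropped genes.
- Problem sizes in the test suite (2000-gene studies, 200-perturbagen
  libraries, 200,000-case report sets, 20 replicate seeds for each
  operating characteristic) were chosen as the smallest sizes at which the
  binomial/NB noise in the measured rates is comfortably below the margins
  being asserted.

## 7. Known limitations

- The DE method is a deliberately compact NB Wald test; it reproduces the
  class of result of established count-based DE tools, not any tool's exact
  output.
- Tau percentiles are only as meaningful as the supplied touchstone; with
  small libraries the percentile scale is coarse (steps of 100/N).
- The ROR is a disproportionality statistic on spontaneous reports: it is
  not a causal effect estimate, and the screen inherits every reporting
  bias of the source database.
- Name harmonization is table-driven; real catalog-to-ATC matching needs a
  curated mapping and typically manual review.
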