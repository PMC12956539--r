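---
title: "Methods: single-cell eQTL Mendelian randomization with scmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell eQTL Mendelian randomization with scmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scmr)
```

## The problem scmr addresses

Immune dysregulation is increasingly implicated in degenerative diseases of
the cervical spine, and single-cell eQTL resources make it possible to ask
*in which immune cell type* a gene's expression matters. `scmr` implements a
summary-statistics pipeline for this question: cis-eQTL effects measured per
gene and per cell type serve as genetic instruments, a disease GWAS supplies
the outcome associations, and two-sample Mendelian randomization (MR)
estimates the causal effect of expression on disease risk in each lineage.
Downstream stages grade the evidence (two-level significance tiers,
Steiger directionality, Bayesian colocalization), summarize cell-type
specificity (normalized Shannon entropy), and translate hits into candidate
targets (weighted evidence scores, protein-interaction hub ranking).

Everything operates on summary statistics; no individual-level genotypes or
expression matrices are touched. A seeded synthetic generator reproduces
the statistical structure of the real setting so that every stage is
testable offline with known ground truth.

## Causal model and estimators

For gene $g$ in cell type $c$, let $\hat\beta_{Xj}, \sigma_{Xj}$ be the
marginal effect of variant $j$ on expression and its SE, and
$\hat\beta_{Yj}, \sigma_{Yj}$ the same for the outcome. Under the linear
instrumental-variable model with causal effect $\theta$,
$\beta_{Yj} = \theta\,\beta_{Xj}$ for every valid instrument.

* **Wald ratio** (one instrument): $\hat\theta = \hat\beta_Y/\hat\beta_X$
  with first-order SE $\sigma_Y/|\hat\beta_X|$. A second-order SE adding
  the exposure-noise term is available via `second_order = TRUE`; it
  matters when instrument strength is marginal.
* **IVW** ($k \ge 2$): weighted regression of $\hat\beta_Y$ on
  $\hat\beta_X$ through the origin with weights $1/\sigma_{Yj}^2$.
* **LD-aware IVW**: generalized least squares with outcome covariance
  $\Sigma = D R D$, $D = \mathrm{diag}(\sigma_Y)$, $R$ the instrument
  correlation (LD) matrix. With $R = I$ this equals IVW exactly.
* **MR-Egger** ($k \ge 3$): the same regression with a free intercept after
  orienting instruments to non-negative exposure effects; a nonzero
  intercept indicates directional pleiotropy.
* **Weighted median** ($k \ge 3$): the weighted median of per-instrument
  ratios, consistent when valid instruments carry at least half the
  weight; its SE comes from a parametric bootstrap that always requires an
  explicit seed.

### Uncertainty: dispersion scaling with t inference

IVW standard errors are the fixed-effect value scaled by the residual
dispersion, $\widehat{\sigma} = \sqrt{Q/(k-1)}$ with $Q$ Cochran's
statistic, and p-values/CIs use a $t_{k-1}$ reference distribution. This
is the exact weighted-least-squares convention: under the null the test
statistic is exactly $t_{k-1}$, so the test holds its 5% size, and under
over-dispersion (which arises generically here, because the eQTL cohort is
three orders of magnitude smaller than the outcome GWAS, so the neglected
exposure-noise term $\theta^2\sigma_X^2$ dominates $\sigma_Y^2$) the CI
absorbs the extra variance and retains close to nominal coverage. We
deliberately do **not** floor the dispersion at 1 (the convention of some
meta-analysis tooling, paired with normal quantiles): in simulation at this
package's default study conditions that pairing loses 4–5 points of CI
coverage, while flooring combined with $t$ quantiles makes the null test
conservative by half. One caveat of the unfloored estimate: degenerate
inputs such as an instrument entered twice with identical outcome values
make $Q = 0$ and collapse the dispersion estimate; the LD-aware estimator's
ridge keeps the point estimate correct, but the SE of such a locus is not
meaningful (and real duplicated instruments should not survive clumping).

### Instrument selection

Candidates must pass, in order: (1) cis-association significance
$p < 5\times10^{-5}$; (2) greedy LD clumping at $r^2 \le 0.001$ — variants
ranked by p-value, each accepted only if unlinked with everything already
accepted (ties broken lexicographically so results are order-independent);
(3) strength $F = (\hat\beta_X/\sigma_X)^2 \ge 10$, the conventional
weak-instrument bar, applied as "keep iff $F \ge 10$". All three cutoffs
are configuration, not constants; an $r^2$ cutoff of 0.01 is a documented
alternative some analyses use. The variance-explained form
$F = (n-2)r^2/(1-r^2)$ is provided separately (`f_statistic_r2()`). LD is
always consumed as a user- or generator-supplied per-locus correlation
matrix; the package never computes LD from genotype panels, and pre-pruned
"conditionally independent" eQTL sets can simply omit the matrix.

### Harmonization

Outcome rows are aligned to the exposure effect allele: direct matches kept
as-is, swapped or strand-flipped non-palindromic alleles negated (and
frequency mirrored), irreconcilable alleles dropped with a recorded reason.
Palindromic (A/T, C/G) variants cannot be resolved by letters alone; the
default policy drops them, and an optional frequency policy orients them
when both allele frequencies are outside $0.5 \pm 0.08$. Matching is by
variant id only — summary-statistics sets rarely share genome builds, and
id-matching is the minimal assumption. Harmonization is idempotent and
invariant to the outcome file's allele orientation; both properties are
tested.

### Steiger directionality and significance tiers

Each instrument must explain more variance in expression than in the
outcome: $r^2 = z^2/(z^2 + n - 2)$ per trait, pass iff
$r^2_{\text{exp}} > r^2_{\text{out}}$ (strict, so exact ties fail).
Estimates are then graded with the two-level rule: $p < 0.0003$ (0.05
divided over 150 genes, floored to one significant digit) globally
significant; $0.0003 \le p < 0.003$ (0.05 over 14 cell types) potentially
relevant; the rest non-significant. Benjamini–Hochberg adjusted p-values
are reported alongside at both levels (within cell type and global) — the
fixed printed thresholds drive the tier labels, the BH columns support
alternative decision rules.

## Colocalization

`coloc_abf()` asks whether the eQTL and GWAS signals at a locus share one
causal variant, assuming at most one causal variant per trait. Per-variant
Wakefield log approximate Bayes factors
$\mathrm{lABF} = \tfrac12[\log(1-r) + r z^2]$, $r = W/(W + V)$, feed the
five-hypothesis enumeration (H0 none, H1/H2 one trait, H3 both-distinct,
H4 shared), with priors $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ and
prior effect SD 0.15 (per phenotype SD) for quantitative traits or 0.2 on
the log-odds scale for case-control — the documented defaults of the
field's standard implementation, all exposed in `coloc_input()`. All
hypothesis sums run in log space with log-sum-exp; 200-variant loci
overflow plain arithmetic. A locus is labeled colocalized at
$\mathrm{PPH4} > 0.8$, the usual evidence bar. Single-variant loci have an
empty H3 sum; the result sets PPH3 to zero and warns rather than failing.

## Entropy-based cell-type specificity

For each gene with qualifying MR estimates (default: tiers at
$p < 0.003$) in $n \ge 2$ lineages, absolute effects are normalized to
proportions $p_i$ and scored as
$$H = -\sum_i p_i \log_2 p_i \,/\, \log_2 n,$$
so $H \in [0, 1]$ with 0 a single-lineage effect and 1 a perfectly uniform
one. $H < 0.5$ is labeled lineage-specific, $H > 0.8$ diffuse, the band
between intermediate (the outer bands are the published convention; the
middle band needs a name for a total classification). $H < 0.2$ is
additionally flagged as highly specific for reporting. Lineages where a
gene was never tested are excluded from both the sum and $n$: treating
"not measured" as "no effect" would deflate entropy artificially. Ranking
is ascending in $H$ with ties broken by descending mean $|\beta|$, then
symbol.

## Target prioritization and network ranking

Four evidence criteria — prior disease-associated genetic evidence,
membership in disease-relevant pathways, an existing drug, and structural
druggability — carry weights $+2, +1, +1, +0.5$. Disease evidence is
weighted highest as the most direct biological validation; druggability
lowest, as feasibility rather than relevance. Scores $\ge 4$ are
high-priority, 3–3.5 medium, $\le 2.5$ low — a complete partition of the
reachable scores $\{0, 0.5, \dots, 4.5\}$. Drug evidence comes from a
static annotation-table snapshot (columns `gene`, `drug_id`,
`interaction_type`, `source`, `druggable_class`); genes absent from it are
annotated "undrugged". No live database is queried.

The interaction network keeps edges at confidence $\ge 0.7$ (STRING's
0–1000 integers are auto-rescaled), deduplicates undirected pairs to their
maximum score, and ranks genes by unweighted, pair-normalized betweenness
centrality, ties broken by degree then symbol; the top ten are the
conventional hub set. `core_candidates()` intersects hubs with high- and
medium-priority genes and annotates each with its best PPH4.

## The synthetic generator

`simulate_locus()` generates summary statistics directly from closed-form
relations rather than simulating individuals: on standardized scales
(expression variance 1, standardized genotypes), each of `n_causal_eqtl`
variants receives an expression effect of magnitude `sqrt(eqtl_var)`
(random sign), marginal effects propagate through AR(1) LD as $R\,b$, SEs
take the large-sample form $1/\sqrt{n}$, and sampling noise is drawn
$\mathrm{MVN}(0, R/n)$ — so z-scores are standard normal under the null
(tested by Kolmogorov–Smirnov). Outcome effects are
$\theta \cdot R\,b$ plus optional direct (pleiotropic) effects on a
configurable fraction of variants, plus GWAS-scale noise. Defaults encode
the targeted study: 14 immune cell types, an eQTL cohort of 982 donors,
and an outcome GWAS of 50,000 (a desk-scale stand-in for a cohort of
484,598; `n_gwas` reaches the full size when wanted — MR algebra only sees
betas and SEs, so the outcome's binary-trait scale is not modeled). Each
per-variant causal variant explains 5% of expression variance by default,
giving $z \approx 7$ and $F \approx 49$ — strong lead-eQTL territory, so
selection retains them. Every draw is deterministic: locus streams derive
from the config seed plus the gene/cell-type labels, and the caller's RNG
state is restored afterwards.

What the generator deliberately does not emulate: binary-outcome logistic
effects, genotype-level LD estimation error, allele-frequency-dependent
power, cross-cell-type correlation of eQTL effects, and multi-signal loci.
Passing tests therefore demonstrate the estimators' statistical
correctness under the stated model, not robustness to every artifact of
real summary statistics.

`simulate_coloc_pair()` plants one shared causal variant (truth H4) or two
variants in negligible LD ($r^2 < 0.01$, truth H3) with causal $z = 8$.
`simulate_annotations()` draws seeded evidence tables and a random
interaction graph with planted hubs at roughly three times the background
degree.

## Problem sizes and numerical choices

The shipped test suite runs at sizes chosen to exercise the statistics
honestly while staying desk-scale: estimator recovery at 500 replicates of
10-instrument loci (mean IVW estimate within 0.02 of $\theta = 0.3$; CI
coverage inside [0.92, 0.97]); null size at 2,000 replicates (rejection
rate inside [0.04, 0.06]); colocalization medians over 100 replicates of
200-variant loci; Steiger pass rates over 200 replicates; exhaustive
betweenness oracles up to 7 nodes; an exhaustive-enumeration coloc oracle
at 50 variants.

Numerical specifics worth knowing: the LD-aware estimator ridges the LD
diagonal from $10^{-6}$ up to $10^{-3}$ (tenfold steps) before declaring a
locus ill-conditioned; greedy clumping breaks p-value ties
lexicographically; the weighted median interpolates the weighted CDF with
the midpoint convention; TSV output carries 6 significant digits (below
estimator noise, lossless on round trip at that precision); entropy uses
the $0\log 0 = 0$ convention; all-zero profiles and single-lineage genes
are errors, not zeros.

## Known limitations

Estimates inherit every assumption of two-sample MR: no unmodeled
horizontal pleiotropy beyond what Egger/weighted-median sensitivity
analyses can flag, instrument relevance, and no reciprocal causation
beyond what Steiger filtering detects. The colocalization model assumes a
single causal variant per trait per locus. Conditional independence of
supplied eQTL instruments is taken on trust from the input. The
prioritization weights are a transparent heuristic, not calibrated effect
sizes; changing them reorders candidates, and the defaults are kept only
for comparability with the established convention.
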