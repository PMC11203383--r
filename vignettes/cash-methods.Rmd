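---
title: "Scoring differential expression with microarray games: methods and design"
author: "cashr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring differential expression with microarray games: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cashr)
```

## The problem

Small two-group expression studies — a handful of patient biopsies against a
handful of controls — are the worst case for gene-wise testing. Per-gene
variances are estimated from 2–10 values, multiple-testing correction over
tens of thousands of genes is brutal, and a single aberrant array cell can
inflate a variance estimate enough to hide a real effect. In practice,
classical pipelines (Welch's t-test, empirical-Bayes moderated t, BH
correction) frequently report *zero* significant genes on such cohorts.

`cashr` implements an alternative scoring of gene relevance built on
cooperative game theory — Comparative Analysis of Shapley values (CASh) —
alongside the classical tests it is meant to complement, with a synthetic
data generator that makes the whole pipeline testable with known ground
truth.

## The microarray game

Expression is first *booleanized* against the control group. For each gene,
let $m_c$ and $s_c$ be the mean and standard deviation (denominator $n-1$)
of its control-sample values. A value $x$ is coded as

* over-expressed: $x \ge m_c + s_c$,
* under-expressed: $x < m_c - s_c$,

giving one boolean matrix $B \in \{0,1\}^{n \times k}$ per direction. The
boundary is deliberately asymmetric (`>=` for over, strict `<` for under)
and is applied literally even when $s_c = 0$ (the rule degenerates to a
comparison against the mean; such genes are flagged). Thresholds always come
from the controls, also when the control columns themselves are coded.

The *support* of array $j$ is the gene set $sp(B_{\cdot j}) = \{i : B_{ij} =
1\}$. The microarray game on player set $N$ (the genes) has characteristic
function

$$ w(T) \;=\; \frac{c(\Theta(T))}{k}, \qquad
   \Theta(T) = \{\, j : sp(B_{\cdot j}) \subseteq T,\; sp(B_{\cdot j}) \neq
   \emptyset \,\}, $$

the fraction of arrays whose abnormality pattern is fully explained by
coalition $T$. The Shapley value
$\phi_i = \frac{1}{n!}\sum_{\pi} \left[ w(P(\pi,i) \cup \{i\}) - w(P(\pi,i)) \right]$
averages each gene's marginal contribution over all orderings. Because $w$
decomposes into unanimity games (one per nonempty column support), the value
collapses to a closed form computable in $O(nk)$:

$$ \phi_i = \frac{1}{k} \sum_{j\,:\,i \in sp(B_{\cdot j})}
   \frac{1}{|sp(B_{\cdot j})|}. $$

`shapley_closed_form()` implements this; `shapley_permutation_oracle()`
implements the defining permutation average in exact integer arithmetic
(every $w \cdot k$ is a count, so values are rationals over $n!\,k$) and is
used as an independent oracle in the test suite — the two agree exactly,
checked exhaustively for small games and on random matrices. Efficiency
($\sum_i \phi_i = w(N)$), the null-player and symmetry axioms, and
additivity over column partitions are asserted on random games in exact
rationals. The permutation oracle refuses $n > 10$.

## The CASh procedure

`run_cash()` chains five stages:

1. **Prescreen.** Genes with a raw p-value below `prescreen_alpha` (0.05, or
   0.01 for the restrictive variant) from a classical test are retained.
   The default test is Welch's; `ebayes` selects the moderated t. The raw —
   not adjusted — p-value is used: this stage is a coarse filter, not an
   inference.
2. **Per-condition games.** The prescreened matrix is booleanized in each
   direction; the boolean columns are split by group and a microarray game
   is built per condition. The contrast is $\Delta\phi_i = \phi^{case}_i -
   \phi^{ctrl}_i$ (over-direction: case-specific over-expression;
   under-direction: case-specific under-expression).
3. **Bootstrap null.** Under the null of sample exchangeability the group
   labels are uninformative, so the booleanized columns of both groups are
   pooled and each of `n_boot` (default 1000) iterations redraws $k_{case}$
   and $k_{ctrl}$ columns with replacement and recomputes the contrast. The
   one-sided p-value is $p_i = \left(1 + \#\{b : \Delta\phi^{*}_{i,b} \ge
   \Delta\phi_i\}\right) / (n_{boot} + 1)$, bounded below by
   $1/(n_{boot}+1)$ and deterministic given the seed.
4. **Correction.** BH adjustment, applied within each direction over the
   prescreened family (use `apply_fdr = TRUE` to threshold the adjusted
   p-value; the default thresholds the raw bootstrap p at `p_threshold`,
   which itself defaults to the prescreen cutoff).
5. **Calling.** A gene is called when its (possibly adjusted) bootstrap p is
   below the threshold *and* its linear fold change exceeds the gate
   (`|signed FC| > 2`, i.e. $|\log_2 FC| > 1$). Over-direction calls are
   `up`, under-direction calls are `down`; a gene significant in both
   directions keeps the direction with the larger $\Delta\phi$, ties broken
   by larger $|\log_2 FC|$, then in favour of `over`.

The bootstrap scheme deserves a note. Several resampling nulls were
evaluated during design. Per-gene permutation of boolean profiles is exactly
calibrated gene-by-gene, but with $k = 10$ arrays its p-values are so
discrete (atoms no finer than $1/\binom{10}{5}$) that the aggregate
rejection rate at 0.05 falls to ~0.002 — useless for calibration claims.
Within-group column bootstrap is neither better calibrated nor more
powerful. The pooled exchangeability scheme used here has marginally uniform
p-values on null data (measured rejection fraction ≈ 0.033–0.036 at
nominal 0.05; the slight conservatism comes from ties in the $\ge$ count and
the $+1$ correction). Its one caveat is documented under *Limitations*.

## Classical comparators

`welch_t()` is the vectorized gene-wise Welch test (Welch–Satterthwaite
degrees of freedom, two-sided Student p). Genes with zero variance in both
groups are *flagged*, not dropped — equal means give $t = 0, p = 1$,
differing means give the smallest representable p — so gene counts are
conserved through the pipeline.

`moderated_t()` implements the standard two-group empirical-Bayes moderated
t: pooled within-group variance $s_g^2$ on $d_g = k_1 + k_2 - 2$ degrees of
freedom, shrunk towards a prior,

$$ \tilde{s}_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}, \qquad
   \tilde{t}_g = \frac{\bar{x}_{case} - \bar{x}_{ctrl}}
   {\tilde{s}_g \sqrt{1/k_1 + 1/k_2}}, $$

referred to Student's t on $d_0 + d_g$ df. The prior $(d_0, s_0^2)$ is
fitted by moment matching of $\log s_g^2$ against the scaled-F law
(digamma/trigamma equations); this standard fit is delegated to
`limma::fitFDist()`, while the statistic itself is computed here and
cross-checked against `limma::eBayes()` in the tests. The limits are exact:
$d_0 = 0$ reproduces the ordinary pooled t, $d_0 = \infty$ (returned when
the log-variances have no excess dispersion) sets every
$\tilde{s}_g^2 = s_0^2$ and uses the normal reference. With fewer than 10
genes no prior is estimable and the function falls back to the pooled t
with a message.

Fold changes use the signed convention: $\log_2 FC$ is the case-minus-control
mean difference, and the linear value is reported as $-1/FC$ when $FC < 1$,
so the conventional $|FC| > 2$ gate is symmetric on the log scale.

## Enrichment

`fisher_ora()` tests over-representation of a query list in user-supplied
GMT gene sets by the one-sided hypergeometric tail (Fisher's exact test,
alternative "greater"), BH-corrected across sets, significance at
FDR < 0.05; `top_terms()` keeps the ten best terms per category (adjusted p
ascending, ties by larger overlap, then name). The universe defaults to the
genes on the analyzed matrix. No identifier mapping, GO-graph propagation or
web services are involved: the collection is whatever the user supplies.

## The synthetic generator

`simulate_expression()` emulates the data structure the method assumes:

* gene variances $\sigma_g^2 \sim s_0^2 d_0 / \chi^2_{d_0}$ (the scaled
  inverse-chi-square prior underlying the empirical-Bayes model, so
  `estimate_variance_prior()` has a recoverable ground truth);
* baselines $\mu_g \sim N(\mu_0, 1)$ on the log2 scale;
* a designated fraction of true DEGs with an additive shift
  $\pm\,\delta$ in the case group, sign Bernoulli(½) per gene;
* optional contamination: a fixed number of cells (sampled without
  replacement) shifted by $\pm\,m\,\sigma_g$ — the heavy-tailed outlier
  failure mode the bootstrap stage is designed to absorb.

One seeded stream is consumed in a fixed order (gene parameters → DEG
assignment → noise → outliers), so a configuration is perfectly
reproducible and partial regeneration is impossible by design.

**Default conditions.** `prior_df = 4`, `prior_var = 0.5` (typical per-gene
log2 SD ≈ 0.7) and `effect_log2 = 1.5` (about three-fold). These emulate
small cohorts of human tissue biopsies, where inter-individual biological
variability dominates: in that regime a 5-vs-5 Welch/BH analysis detects
essentially nothing even for three-fold effects — which is precisely the
setting the method targets, and the regime in which game-based scoring
shows its advantage. Technical-replicate designs (log2 SD ≈ 0.2) would make
classical tests nearly perfectly powered and are not the intended use case.
The generator does *not* emulate probe-level effects, spatial artifacts,
batch structure or inter-gene correlation; passing tests demonstrate
correctness of the computation and calibration under this model, not
performance on any particular real dataset.

## Numerical and interface choices

* Game arithmetic is exact: $w \cdot k$ is always an integer count, and both
  Shapley implementations expose an exact rational mode used by the tests;
  floating point enters only at reporting.
* Duplicated gene identifiers are collapsed on loading by keeping the row
  with the largest mean intensity (a deterministic local convention; probe
  annotation services are out of scope). Missing values are rejected, not
  imputed.
* Result tables are written with 17 significant digits so a write–read
  round trip is bit-identical.
* Bootstrap p-values, BH adjustment and fold-change gates are all pure
  functions of (data, config, seed); `run_pipeline()` therefore produces
  byte-identical `summary.json` across runs with the same configuration.
* Degenerate inputs are handled explicitly: empty prescreen sets yield a
  clean empty result (not an error), constant matrices yield zero PCA
  scores with a flag, and the zero-SD booleanization rule is applied
  literally with a flag.

## Problem sizes used in the checks

The packaged checks run the method at deliberately modest scales chosen to
give stable Monte-Carlo estimates: null calibration at 2000 genes × (5+5)
samples with 1000 bootstrap iterations; prior recovery at 2000 genes;
the contamination benchmark at 1000 genes with 50 true DEGs, 5% of cells
contaminated at 4σ, five seeded replicates; exhaustive game oracles for
$n \le 3, k \le 2$ plus 200 random games with $n \le 6, k \le 4$.

## Limitations

* **Selection re-use.** The bootstrap null is built from the prescreened
  matrix, i.e. from genes already selected for extremity. On *pure null*
  data this combination can still call a handful of genes at biopsy-scale
  variance: the most separated null genes reach the bootstrap floor
  $1/(n_{boot}+1)$ in groups, and once ≥2 tie there, BH at a family of ~100
  passes them; the fold-change gate stops blocking because selection also
  inflates $|\log_2 FC|$. The method trades strict null purity for
  sensitivity in regimes where classical tests detect nothing; treat CASh
  calls as a robust *ranking* with approximate FDR control rather than an
  exact FDR guarantee, and prefer the `apply_fdr = TRUE` variant when
  false positives are costly.
* With ~5 arrays per group the bootstrap p-value floor is reached quickly;
  p-values are coarse and should not be over-interpreted beyond the calling
  threshold.
* No covariate or confounder adjustment: the game is built from group
  labels alone.
* The comparison assumes already-normalized log2 matrices; no preprocessing
  (RMA, quality control, probe annotation) is performed.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_expression(sim_config(
  n_genes = 1000, k_case = 5, k_control = 5,
  deg_fraction = 0.05, effect_log2 = 1.5,
  outlier_rate = 0.05, outlier_sd_multiple = 4, seed = 1))

res <- run_cash(sim$expr, sim$design,
                cash_config(prescreen_alpha = 0.05, n_boot = 1000, seed = 1))
res           # prescreen, bootstrap and calling summary
head(res$degs)

welch <- welch_t(sim$expr, sim$design)
sum(welch$p_adj < 0.05)   # what the classical comparator finds
```
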