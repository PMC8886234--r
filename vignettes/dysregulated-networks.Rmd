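---
title: "Dysregulated network analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dysregulated network analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dysnet)
library(dplyr)
```

## The model

Differential-expression analysis treats genes one at a time, but a tumor
transcriptome can rewire regulation without any single gene crossing a
fold-change threshold, and conversely two genes can both shift strongly
while their regulatory relationship stays intact. `dysnet` therefore works
at the level of *edges* of a directed gene influence network (a curated
graph of regulator-to-target relations). For an edge $i \to j$ and a sample
$s$, the **regulation strength** is the log expression ratio

$$r_{ij}(s) = \log_b \frac{g_i(s) + c}{g_j(s) + c},$$

with $g$ the linear-scale expression, $c$ a pseudocount and $b$ the log
base (2 by default, so a unit of $r$ is one doubling of the ratio). The
intuition: a regulator expressed far above its target exerts, or at least
can exert, stronger influence than one expressed below it.

The **dysregulation strength** of an edge is the absolute difference of
group means,

$$ds_{ij} = \left|\bar r_{ij}^{\,T} - \bar r_{ij}^{\,N}\right|,$$

over tumor ($T$) and normal ($N$) samples. Edges with $p \le 10^{-4}$ (on
the two-sample test below) **and** $ds \ge 2$ form the **dysregulated
network** (DN); with $b = 2$, $ds \ge 2$ means the average expression
ratio changed at least four-fold. A gene's **dysregulation score** is the
sum of $ds$ over its retained out-edges,

$$d_i = \sum_{j \in \mathrm{out}(i)} ds_{ij},$$

so hubs whose whole out-star is perturbed dominate. Genes are ranked by
$d_i$ and the **key genes** are the shortest rank prefix whose cumulative
normalized score reaches 60%; the key genes and their dysregulated
interactions form the **key dysregulated network** (KDN).

Downstream, the KDN is interrogated three ways: candidate driver genes are
ranked by greedily covering expression-outlier events reachable from
mutations through the influence network; pathway and drug-target gene
sets are scored by the upper-tail hypergeometric test (enrichment score
$-\log_{10} p$, with drug targets expanded by their first-order network
neighbors); and each top-scored gene is assessed as a prognostic marker by
a median-expression split and a log-rank test.

## The edge test

The per-edge response is the vector of per-sample $r_{ij}$ values, and the
group comparison is either Welch's $t$-test or (default) a **moderated
$t$-test**: the pooled within-group variance $s^2$ of each edge is shrunk
toward a prior,

$$\tilde s^2 = \frac{d_0 s_0^2 + d\, s^2}{d_0 + d},$$

and the statistic is referred to a Student-$t$ with $d_0 + d$ degrees of
freedom. The prior $(d_0, s_0^2)$ is a scaled inverse-chi-square fitted
across *all* edges by the standard method of moments on log variances:
the excess of $\mathrm{var}(\log s^2)$ over its sampling floor
$\psi'(d/2)$ determines $d_0$ through the trigamma function (solved by a
Newton iteration), and the mean of the corrected log variances determines
$s_0^2$. When the spread of variances is at or below the floor the fit
returns $d_0 = \infty$, i.e. complete pooling; at the other extreme
$d_0 = 0$ recovers the ordinary pooled $t$-test. The test suite checks
this machinery against an independent empirical-Bayes implementation
(`limma`) on a shared simulated matrix, and checks the Welch path against
`t.test`; both agree to near machine precision.

Shrinkage matters here because edges vastly outnumber samples and the
edge-wise variances are themselves noisy: unshrunken small variances
otherwise produce spuriously extreme statistics at the $10^{-4}$
threshold.

## Tunable parameters

| Parameter | Default | Units / range | Role |
|---|---|---|---|
| `log_base` | 2 | — | base for $r$, $ds$, fold changes and planted deltas |
| `pseudocount` | 0 | expression units | offset $c$; must be > 0 when zeros occur |
| `edge_p_threshold` | 1e-4 | probability | DN significance cut (raw p by default) |
| `ds_threshold` | 2 | log units | DN effect-size cut (4-fold at base 2) |
| `deg_p_threshold` | 1e-4 | probability | DEG significance cut |
| `deg_fc_threshold` | 1.5 | linear fold | DEG effect-size cut |
| `key_fraction` | 0.6 | (0, 1] | cumulative-score cutoff for key genes |
| `outlier_z_threshold` | 2 | normal-group SDs | outlier call for driver ranking |
| `test_method` | moderated | — | `moderated` or `welch` |
| `multiple_testing` | none | — | optional BH adjustment of edge p-values |

Notable defaults and why:

* **Pseudocount 0.** The log-ratio is unbiased only without an offset; a
  pseudocount compresses ratios at the low-expression end and would bias
  $ds$ below the true effect for weakly expressed targets. Since the
  generator (and most normalized matrices) are strictly positive, the
  default adds nothing; data containing zeros trigger a hard error that
  instructs setting `pseudocount > 0` rather than silently coercing.
* **Raw p-values at 1e-4.** The DN rule filters on the unadjusted
  p-value together with a large effect-size floor; BH adjustment is
  available through `multiple_testing = "BH"` for calibrated FDR control.
* **Key-gene boundary.** The prefix rule uses $\ge$: a gene whose
  cumulative share lands exactly on the cutoff is included, and ranking
  ties are broken lexicographically by gene ID so the selection is
  deterministic.
* **KDN mode.** `out_edges` (default) keeps all DN out-edges of key
  genes, consistent with $d_i$ being defined on out-edges; `induced`
  restricts to edges between key genes.
* **Degree and betweenness conventions.** `network_summary()` reports the
  total-degree average $2E/N$ over genes incident to at least one retained
  edge, and directed, unnormalized betweenness counts.
* **Universe for enrichment.** The background is the genes present in
  both the expression matrix and the influence network — the set an edge
  test could in principle have selected from. Drug-target neighborhoods
  are expanded ignoring edge direction, since drug action is not confined
  to the regulatory direction of the curated graph.
* **Median split.** Samples exactly at the median expression go to the
  low group; the cutoff is never optimized over candidate thresholds, so
  the log-rank p-value retains its nominal meaning for a single gene.

## What the synthetic generator emulates

`simulate_network()` draws per-gene out-degrees from a Pareto-weighted
configuration model (tail exponent 1.5, targets uniform without
replacement). This reproduces the property that matters for the method —
a heavy-tailed out-degree with a few dominant regulators, as in curated
pathway-derived influence networks — while giving direct control of the
expected edge count. It does not attempt to match other topological
features of curated graphs (reciprocity, motif structure, assortativity).

`simulate_expression()` draws per-gene log2 baselines uniformly on
[4, 12] and i.i.d. Normal(mu, sigma = 0.5) per-sample values — a
log-normal expression model chosen for positivity and right-skew. A
planted edge shifts its *target's* tumor mean by $-\delta$ (default 3
log2 units), so the planted edge's expected $ds$ equals $\delta$ exactly
and exactly one endpoint is differentially expressed — the configuration
that dominates real dysregulated edges, since two endpoints moving
together leave the ratio unchanged. The returned ground truth lists
*every* edge with exactly one shifted endpoint as dysregulated (shifting
a gene perturbs all its incident ratios, not only the requested edge);
sensitivity and false-positive rates in the tests are measured against
that complete set. An optional co-shift moves both endpoints of an edge
together, producing DEG pairs whose edge is *not* dysregulated — the case
that separates edge-level from gene-level analysis.

`simulate_mutations()` plants drivers with per-sample mutation
probability 0.3 against a passenger rate of 0.01, and flags each mutated
driver's direct targets for outlier injection (+3 log2 units, i.e. 6
noise SDs) in the paired expression matrix — direct targets only, because
the event-cover stage links mutations to outliers through single network
edges. `simulate_survival()` draws exponential event times (baseline
hazard 0.1) with the hazard multiplied for samples above the planted
gene's median expression, and censors each subject independently with the
requested probability at a uniform time before its event.

What passing these tests does **not** show about real data: the generator
has no library-size or batch effects, no correlation between genes beyond
the planted shifts, no copy-number signal, Gaussian log-expression noise,
and proportional hazards by construction. Recovery rates on it are upper
bounds for what heterogeneous cohorts would give; the value of the
synthetic route is exactness of the ground truth, not realism.

## Numerical choices and degenerate inputs

* Zero-variance edges under the moderated test are excluded from the
  prior fit and shrink to the prior variance; a zero difference with zero
  variance reports $p = 1$ rather than NaN.
* p-values are clamped to $(0, 1]$; enrichment scores are finite because
  the hypergeometric tail is never exactly zero at double precision
  within the supported universe sizes.
* The trigamma inverse uses closed-form limits for extreme arguments
  ($y > 10^7$, $y < 10^{-6}$) and Newton iteration to relative
  $10^{-10}$ otherwise.
* Greedy driver ranking breaks coverage ties by gene ID ascending and
  removes covered events immediately, so each outlier event is counted
  at most once; the ranking is invariant to input row order.
* The log-rank test flags the comparison untestable (p = 1) when no
  events occur or the variance term vanishes; the median split flags
  constant genes untestable instead of fabricating a one-group test.
* All generators restore the caller's RNG state and are pure functions of
  their arguments and seed; the pipeline manifest records config, seed
  and input checksums, and a rerun is byte-identical.

## Problem sizes in the test suite

The calibration and recovery tests run at 1000 genes / ~10,000 edges with
50+50 (null) and 100+100 (planted) samples; prior recovery uses 10,000
simulated variances; the survival calibration uses 1000 null replicates
of 30+30 subjects and 100 powered replicates at hazard ratio 4 with 200
subjects; oracle comparisons (greedy cover, hypergeometric enumeration,
betweenness) run on instances small enough for exhaustive search (up to
12 events, universes up to 12 genes, graphs up to 8 nodes). These sizes
give binomial error bars comfortably inside the asserted bands while the
whole suite stays fast.

## Known limitations

* The edge test treats per-sample ratios of different edges as separate
  responses; edges sharing a gene are correlated, so network-wide
  empirical type-I rates fluctuate slightly more than the independent
  binomial bound suggests (the suite's bands absorb this).
* With `pseudocount = 0` the method requires strictly positive input;
  sparse single-cell matrices would need a pseudocount and would inherit
  its low-expression bias.
* Average betweenness on large DNs costs all-pairs shortest paths; for
  the ~5000-gene networks this method targets that is seconds, but it is
  the pipeline's asymptotic bottleneck.
* The top-gene survival screen reports uncorrected log-rank p-values
  (the minimum over k genes is flagged as such); under the null the
  minimum of 10 independent p-values falls below 0.05 about 40% of the
  time, so the flag is a screening aid, not an inference.
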