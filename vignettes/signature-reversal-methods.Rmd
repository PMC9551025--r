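---
title: "Methods: transcriptome-driven drug repurposing by signature reversal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptome-driven drug repurposing by signature reversal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigrev)
```

## The problem and the overall design

`sigrev` implements a widely used class of bioinformatics study for
case-control transcriptomics — typified by tumour-versus-normal RNA-seq in
colorectal cancer — whose goal is to nominate existing drugs that might
*reverse* a disease expression program. The workflow is a chain of five
analyses:

1. **Differential expression** on raw counts in each of two independent
   cohorts (e.g. a large registry cohort and a small published cohort).
2. **Direction-consistent intersection** of the two cohorts' DEG calls:
   only genes significant *in the same direction in both* survive, the
   consensus illustrated by the usual two-set Venn diagram.
3. **Over-representation analysis** (ORA) of the consensus DEGs against
   user-supplied gene-set collections (GO/KEGG-style, supplied as GMT).
4. **Interaction-network hub ranking**: the consensus DEGs are projected
   onto a STRING-style weighted interaction network, edges below a
   combined-score threshold are removed, and genes are ranked by degree;
   the top-degree genes are the *hub genes*.
5. **Survival screening** of the hubs (median-expression dichotomisation +
   log-rank), and **signature-reversal drug scoring** of a CREEDS-style
   drug-perturbation library against the consensus signature, including
   per-gene drug queries for each survival-significant hub.

Every stage consumes and produces plain tabular data (tibbles, TSV, GMT),
so stages can be run separately or through `run_pipeline()`.

Because the real inputs of such studies (TCGA, GEO, STRING, CREEDS) are
large, versioned, external resources, the package ships a seeded
synthetic-data generator (`simulate_study()` and the per-stage
`simulate_*()` functions) that plants known DEGs, hubs, a prognostic gene
and reversal drugs. All statistical claims made by the test suite are
claims about recovery of this planted truth and about calibration under
the generator's null — see "What the simulations do and do not show".

## Differential expression: a self-contained NB Wald test

The DE stage is deliberately a small, fully documented negative-binomial
pipeline rather than a wrapper around a large external tool, so that every
number it produces can be checked against closed forms and parameter
recovery:

* **Size factors** (`size_factors()`): median-of-ratios. For sample $j$,
  $\hat s_j = \mathrm{median}_g\, c_{gj}/(\prod_{j'} c_{gj'})^{1/m}$ over
  genes positive in all samples. One subtlety worth stating: scaling one
  sample's counts by $c$ also scales the geometric-mean reference by
  $c^{1/m}$, so individual factors change by $c^{(m-1)/m}$ while factor
  *ratios* change by exactly $c$ — depth normalisation is only ever
  defined up to a common constant.
* **Dispersion** (`estimate_dispersion()`): method of moments under
  $\mathrm{Var} = \mu + \alpha\mu^2$,
  $\hat\alpha = \max\{(s^2_w - \hat\mu)/\hat\mu^2,\ 10^{-8}\}$ with
  $s^2_w$ the pooled within-group variance of normalized counts. The
  floor ($10^{-8}$) absorbs Poisson-like and constant genes; it is far
  below any biologically plausible overdispersion, so it never influences
  a non-degenerate estimate.
* **Effect and test** (`de_test()`): $\widehat{\mathrm{lfc}} =
  \log_2\frac{\bar x_{case}+\tfrac12}{\bar x_{ctrl}+\tfrac12}$ (the 0.5
  pseudo-count keeps zero-mean groups finite), with a delta-method
  standard error from the fitted NB variance of each group mean, a
  two-sided normal (Wald) p-value, and BH q-values. Genes with zero
  counts in every sample are flagged `tested = FALSE` and excluded from
  the universe.
* **Thresholds** (`filter_degs()`): raw $p < 0.001$ and
  $|\mathrm{lfc}| \ge 2$, the conventional screening rule for this kind
  of study. The p-inequality is strict and the fold-change boundary is
  inclusive; significance uses the raw p-value (q-values are reported for
  information only). We note the convention is ambiguous in much of the
  applied literature; the strict-raw-p reading is documented here rather
  than guessed silently.

This estimator is intentionally simpler than shrinkage-based DE tools: no
dispersion shrinkage across genes, no outlier filtering, no independent
filtering. Its validation is therefore *parameter recovery on simulated
data*, not equality with any external tool: at the study-scale settings
(2000 genes, 10 vs 10, $\mu = 100$, $\alpha = 0.1$, planted
$\mathrm{lfc} = 3$) it recovers $\ge 90\%$ of planted genes while calling
$\le 0.5\%$ of null genes, with null p-values uniform to Kolmogorov
distance $< 0.05$. At smaller group sizes or much larger dispersions the
normal Wald approximation will degrade before a shrinkage estimator
would; that regime is outside what the tests certify.

## The hypergeometric kernel

ORA and drug scoring share one statistic, the upper hypergeometric tail
$P(X \ge k)$ for $X \sim \mathrm{Hyp}(N, K, n)$, implemented in
`hypergeom_tail()` by log-space accumulation of the pmf
(`lchoose` terms combined with a log-sum-exp), so that screen-scale
p-values of order $10^{-100}$ are representable without underflow. The
implementation is checked against exhaustive enumeration for every
$(N \le 25, K, n, k)$ to relative error below $10^{-12}$, and against
`stats::phyper` at screen scale.

For ORA (`ora()`), each set is tested with $K = |set \cap universe|$,
$n = |query|$, $k = |set \cap query|$. The universe defaults to the genes
the DE stage actually tested — using all annotated genes instead would
inflate enrichment for sets containing unmeasured genes. Up- and
down-regulated DEGs are analysed separately by `ora_degs()` (with a
`combined` flag), mirroring the usual two-panel presentation.

## Network hubs

`build_network()` keeps interactions with combined score $\ge$ 0.7 (the
"minimum required score" convention of STRING exports is read as
inclusive) between genes in the DEG whitelist; `hub_genes()` ranks by
degree with ties broken lexicographically so the ranking is reproducible
under relabeling. Degree is fixed as the centrality — it is the measure
conventionally reported for "top hub genes" bar charts — and other
centralities are out of scope. STRING's 0–1000 integer score dialect is
auto-detected (any score > 1) and rescaled once; the normalisation is
idempotent.

## Survival screening

`km_estimate()` is the standard product-limit estimator; at tied times
deaths precede censorings, and with no censoring the curve reduces
exactly to $1 - \mathrm{ECDF}$. Some applied papers describe "weighted"
Kaplan–Meier curves without defining weights; this package implements
the standard unweighted estimator and records the ambiguity here.
`logrank_test()` is the ordinary $O\!-\!E$ chi-square (1 df) with
hypergeometric variance; it agrees with `survival::survdiff` to machine
precision and with a label-permutation oracle within Monte-Carlo error.

The screen (`gene_survival_screen()`) dichotomises each gene at its
median — values strictly above the median are "high", ties go to "low"
(a deterministic rule that matters for discrete expression values) — and
tests high vs low by log-rank. Expression is size-factor-normalized
$\log_2(x+1)$; since a median split is invariant to monotone transforms,
this choice is cosmetic but fixed. Raw $p < 0.05$ defines significance,
matching single-gene reporting convention; a BH column is emitted but not
used for the call. Under a 1000-gene null the screen's type-I error at
$\alpha = 0.05$ falls within (0.035, 0.065).

## Signature-reversal drug scoring

For each drug with up/down perturbation sets, `reversal_test()` computes
two tails: drug-down vs disease-up ($p^{up}_{rev}$) and drug-up vs
disease-down ($p^{down}_{rev}$), both within one shared universe — the
intersection of the DE-tested universe and the drug library's universe,
applied identically to every drug so p-values are comparable. A drug is a
*candidate* when either p is strictly below 0.05. Design choices worth
stating:

* No multiple-testing correction enters the candidate rule (the
  conventional raw-p screen); `bh_q` is emitted alongside.
* Drugs with an empty relevant direction score $p = 1$ rather than being
  dropped, keeping the ranking total.
* `drugs_for_gene()` implements the per-gene query used for a prognostic
  hub: drugs whose *opposite*-direction set contains the gene, ranked by
  the corresponding directional reversal p.

**Discreteness of the null candidate rate.** Because the hypergeometric
test is discrete, its exact size at nominal level 0.05 is the largest
achievable tail probability below 0.05, which can sit well below 0.05.
At the default screening geometry (universe 5000, signature size 50,
disease sets of 276 up / 264 down genes — the consensus-DEG scale typical
of two-cohort tumour studies) the exact per-direction null rates are
about 0.019 and 0.046. The calibration tests therefore compare the
empirical decoy rate to this *exact enumerated level* (and verify it
never exceeds nominal), rather than to 0.05 itself; no continuous-level
5% is attainable by any exact discrete test at these sizes.

## The synthetic-data generator

The generator's defaults define the study conditions used throughout the
tests and are not tuned per test:

| Component | Model | Defaults |
|---|---|---|
| Counts | NB, $\mathrm{Var}=\mu+\alpha\mu^2$; planted genes shift the case mean by $2^{\pm lfc}$ | $\mu = 100$, $\alpha = 0.1$, $lfc = 3$, 2000 genes |
| Cohorts | shared planted truth, independent noise | 100 vs 50 and 10 vs 10 |
| Survival | exponential, hazard $h_0 e^{\beta z}$, $z = \mathbb{1}\{\text{expr} > \text{median}\}$ | $h_0 = 0.002/\text{day}$, $\beta = \log 4$, 20% censoring |
| Network | Erdős–Rényi background + hubs wired to random partners | mean background degree 2, hub degree 30 |
| Drug library | decoys uniform; planted drugs draw their down (up) set from disease up (down) genes | 249 drugs, 50 genes/direction, 3 planted |

Notes on individual choices:

* Censoring is independent exponential with per-subject rate
  $h_i \cdot r/(1-r)$, which gives censoring probability exactly $r$ for
  every subject regardless of group — the simplest mechanism satisfying
  the independent-censoring assumption of KM while hitting the requested
  rate exactly.
* The survival covariate enters *dichotomised at the median*, i.e. the
  generator's model coincides with the analysis model of the screen; the
  planted $\beta$ is then exactly the log hazard ratio the log-rank test
  targets.
* `simulate_network()` accepts a `partner_pool`: in the end-to-end
  scenario the planted hubs' partners are drawn from the planted DEG
  module, reflecting the biological expectation that a disease module is
  internally wired. Without this, whitelisting to DEGs would sever a
  hub's edges and the hub-ranking branch would be untestable by
  construction.
* Scores on planted hub edges are drawn in $[0.7, 1]$ (never severed by
  the default threshold); background scores are uniform on $[0.4, 1]$.
* The two-cohort sizes (100 vs 50 and 10 vs 10) echo the registry-plus-
  small-cohort shape typical of these studies at a scale where the whole
  pipeline runs in seconds; the drug library's 249 signatures mirror the
  scale of a published screen.

**What passing tests show, and what they do not.** The generator omits,
by design, GC and length bias, batch effects, library-size heterogeneity
beyond scalar factors, correlated genes, non-exponential hazards and
informative censoring. Recovery and calibration results therefore
certify the *statistical machinery* — that each stage finds what its
model says it should find, at the advertised error rates — not
robustness to real-data artifacts. On real data, upstream QC and batch
handling remain the analyst's responsibility.

## Numerical and degenerate-input conventions

* `hypergeom_tail` sums in log space from the observed $k$ upward;
  $k$ at or below the support minimum returns exactly 1.
* BH adjustment is step-up with capping, delegated to
  `stats::p.adjust(method = "BH")`. It is worth noting that BH is *not*
  idempotent on general already-adjusted vectors (re-adjusting a strictly
  increasing q-vector inflates it toward its maximum); it is a fixed
  point on tied/flat profiles.
* All-zero genes: untested, `NA` statistics, excluded from the universe.
* Constant expression vectors cannot be median-split and yield `NA` in
  the survival screen (an error when called directly).
* Log-rank with a single subject at risk contributes zero variance at
  that time; a pooled dataset with no events is an error.
* Ties everywhere are broken lexicographically (hub ranking, result
  ordering), making every output order deterministic.
* Empty-stage propagation in `run_pipeline()`: an empty DEG intersection
  produces empty-but-valid downstream tables and a report with zero
  counts rather than an error.

## Problem sizes used by the checks

The test-suite and acceptance-script runs use: 2000-gene cohorts for DE
recovery; $\le 25$-item universes for exact enumeration; 1000 genes for
the survival null screen ($n = 200$ subjects); 100 independent seeds for
hub and reversal-drug recovery (200-node and 5000-gene universes
respectively); 1000 decoy drugs for null calibration; and the default
`simulate_study()` scale for the end-to-end run. These sizes were chosen
as the smallest at which the binomial/Monte-Carlo error of each rate is
comfortably below the margin being asserted.

## Known limitations

* The Wald DE test is asymptotic; with fewer than ~5 samples per group
  or dispersions far above 1 its calibration degrades.
* ORA treats gene sets as flat lists; no ontology-topology correction.
* The survival screen fits no covariates (no Cox model); it answers the
  same marginal question as the conventional two-curve figure.
* Reversal scoring uses overlap tests only, not rank-based connectivity
  scores; the two approaches can order drugs differently when signatures
  are graded rather than binary.
* Gene identifiers are opaque case-sensitive strings; no symbol mapping
  is performed.
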