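---
title: "Community typing of microbiome count tables by topic modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community typing of microbiome count tables by topic modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbtopics)
```

## The model

Differential abundance testing compares one taxon at a time between patient
and control groups, but microbial phenotypes are often carried by
*communities* of taxa whose members individually never reach significance.
`mbtopics` treats each 16S sample as a document and each genus as a term,
and fits latent Dirichlet allocation (LDA) to a genus-level count table
$N \in \mathbb{N}^{D \times V}$ ($D$ samples, $V$ genera):

* each of $K$ topics (community types) is a distribution over genera,
  $\beta_k \sim \mathrm{Dirichlet}(\eta)$, collected in the $K \times V$
  matrix $\beta$;
* each sample draws a topic mixture $\theta_d \sim \mathrm{Dirichlet}(\alpha)$;
* each read draws a topic $z \sim \mathrm{Multinomial}(\theta_d)$ and then a
  genus $\sim \mathrm{Multinomial}(\beta_z)$.

LDA was chosen over hard-clustering community typing (e.g. Dirichlet
multinomial mixtures) because samples get *fractional* membership across
community types, which matches how real gut communities overlap.

Inference is variational EM on the count-collapsed likelihood. The E-step
iterates, per sample,
$\phi_{dvk} \propto \beta_{kv}\exp(\psi(\gamma_{dk}))$ and
$\gamma_{dk} = \alpha_k + \sum_v n_{dv}\phi_{dvk}$
to a fixed point; the M-step sets
$\beta_{kv} \propto \eta + \sum_d n_{dv}\phi_{dvk}$ and, by default,
re-estimates a symmetric $\alpha$ by a damped Newton step on the Dirichlet
part of the bound. Both steps are fully vectorized over samples, so fits on
tables of a few hundred samples take fractions of a second.

The reported objective (`elbo_trace`) is the variational bound *including*
the topic-term smoothing term $\eta \sum_{kv}\log\beta_{kv}$. With this
definition the M-step update above is the exact maximizer of the objective
in $\beta$, so every EM iteration is provably non-decreasing — the property
the test suite asserts on every fit. Omitting the smoothing term would leave
the trace only approximately monotone.

## Parameters that matter

* `k` — the number of community types. Chosen by `tune_topic_number()`
  (below) or fixed by the analyst.
* `alpha` (initial document-topic prior) — default $50/k$, re-estimated
  during fitting (`estimate_alpha = TRUE`). On microbiome tables the
  estimate typically shrinks to $\ll 1$, i.e. samples dominated by a few
  community types.
* `eta` (topic-term smoothing) — fixed symmetric $0.1$. Keeps every genus
  probability strictly positive (needed for the log-scale quantities) while
  letting topics stay sparse.
* Convergence — relative ELBO change $< 10^{-4}$ (at most 100 EM
  iterations), per-sample mean absolute change of $\gamma$ $< 10^{-6}$ (at
  most 50 inner iterations). These defaults favour speed during grid
  search; for final fits and for cross-cohort validation we recommend (and
  the validation suite uses) `em_tol = 1e-6`, `max_em_iters = 200`,
  `n_restarts = 3`, which measurably reduces local-optimum artifacts
  (duplicated or blended topics).
* `n_restarts` — independent seeded initializations, keeping the best final
  ELBO. One restart mirrors a single seeded fit per dataset; restarts are
  the cheap insurance against local optima.

Initialization perturbs the corpus term frequencies multiplicatively with
unit-mean exponential noise per topic — strong enough to break symmetry,
weak enough to start near the data.

## Choosing the number of topics

`tune_topic_number()` fits one seeded model per candidate $k$ and evaluates
two criteria, both minimized:

* **topic density** (`cao_juan_metric`) — the mean cosine similarity over
  all topic pairs of $\beta$; redundant topics push it toward 1;
* **spectral divergence** (`arun_metric`) — the symmetric KL divergence
  between the normalized singular-value spectrum of $\beta$ and the
  normalized read-weighted topic mass $\ell^\top\gamma$, both sorted
  descending, entries floored at $10^{-12}$ inside the logarithms.

`combine_dataset_optima()` averages the per-metric argmins across cohorts
and rounds half-up, mirroring the practice of selecting one common topic
number for an exploratory/validation pair.

**A caution from our own simulations.** On corpora with well-separated
sparse topics, both criteria penalize *overfitting* sharply (duplicate
topics raise the density; near-zero singular values blow up the
divergence), but only the density criterion reliably penalizes
*underfitting*: a merged low-$k$ model keeps its few blended topics nearly
orthogonal, and its singular-value spectrum tracks its topic-mass spectrum
closely, so the spectral divergence can be smallest at the grid floor. In
the package's validation runs (true $K = 5$, grid $2..10$) the density
argmin falls in $\{4,5,6\}$ in 8/10 seeds while the spectral-divergence
argmin does so in only 2–3/10. Treat the two metrics as an
overfitting guard plus a density curve to be read jointly — inspect
`plot()` of the tuning object rather than trusting either argmin blindly.

## From probabilities to read counts

`assign_reads_to_topics()` multiplies each sample's topic probabilities
$\gamma_d$ by its read depth, producing a samples × topics table whose rows
sum to the sample depths — the "document-term matrix" that downstream
differential abundance consumes. By default the products are left
fractional (`rounding = "none"`); `rounding = "nearest"` applies
largest-remainder apportionment so each row still sums to the integer depth
exactly (ties broken by topic index). The choice is recorded in the
output's attributes; the downstream test adds its own pseudocount and
accepts either.

## Differential abundance

`linda_test()` implements a bias-corrected compositional linear model. For
feature $j$ (a topic or a genus) and sample $i$,
$y_{ij} = \log_2\!\big((n_{ij} + 0.5)/N_i\big)$ is regressed on the group
indicator (plus optional covariates) by least squares. Because only
relative abundances are observed, a change in any feature shifts *every*
feature's log relative abundance; assuming most features are null, this
common shift is the mode of the fitted coefficients, estimated by Gaussian
kernel density (Silverman's rule, 512-point grid spanning the coefficient
range) and subtracted. Corrected coefficients over their standard errors
are referred to a $t$ distribution with the residual degrees of freedom.
Winsorization is deliberately not implemented. Features whose transformed
values are identical in every sample have no standard error; they get
$p = 1$ and a `degenerate` flag rather than an error.

Two properties are verified by simulation in the test suite: type-I error
at $\alpha = 0.05$ stays within $0.05 \pm 0.025$ under an overdispersed
null, and under a planted 4-fold compositional effect the unchanged
features' corrected effects center on zero while the planted feature is
detected in $\ge 90\%$ of replicates.

**Validity domain.** The mode correction presumes a *majority* of null
features. With very few features (e.g. $K \le 8$ topics) and a third of
them truly shifted, the coefficient ensemble is bimodal with comparable
cluster weights and the KDE mode can lock onto the wrong cluster, inverting
the sign pattern. Keep the fraction of plausibly-shifted topics well below
one half, or read the `bias` attribute critically.

`genus_level_screen()` is the conventional companion analysis: total-sum
scaling to $10^6$ reads, per-genus two-sided Wilcoxon rank-sum tests
(midranks for ties; the exact null distribution when the combined sample
size is $\le 12$ and tie-free, the corrected normal approximation
otherwise), Benjamini–Hochberg adjustment. Both analyses call a feature
significant only when $p \le 0.05$ *and* $q \le 0.25$, and BH is applied
within each analysis family (topics and genera separately, per cohort).

## Cross-cohort validation

Community types found in an exploratory cohort are validated against a
model fitted independently on a second cohort. Topic-term rows are
expressed over the *union* vocabulary with zeros for absent genera —
deliberately *not* renormalized, because renormalizing would inflate
similarity between topics concentrated on the shared genera. Every pair
with cosine $\ge 0.80$ (inclusive; configurable) is kept; matching is
many-to-many, and community types are the connected components of the
bipartite match graph, which reproduces the empirically observed
several-to-one topic structure. `validated_communities()` annotates each
component with per-cohort significance and direction; the default rule
(`"exploratory-significant"`) calls a community validated when it contains
a significant exploratory topic that matched across cohorts, and
`"both-significant"` additionally demands a significant partner on the
validation side (provably a subset).

## The synthetic-data generator

`generate_dataset()` draws cohorts from exactly the generative process the
model assumes, with two epidemiological twists: a binary case/control label
whose effect enters through the document-topic prior mass (a *prevalence*
shift of the affected community types, not a change of their genus
content), and, via `generate_paired_datasets()`, a subset of topic-term
rows planted verbatim in both cohorts, optionally with a random subset of
genera dropped from the second cohort's observed table to emulate cohorts
retaining different genus sets after independent filtering.

Defaults mirror the scale of published two-cohort genus tables: 60 samples,
170 genera, 8 topics, log-normal read depths around $2 \times 10^4$
(`sdlog = 0.3`), $\alpha_0 = 0.5$ (samples dominated by a few communities),
$\eta_0 = 0.1$ (sparse, distinct topics), half the samples cases.

What the generator does *not* emulate: phylogenetic correlation between
genera, sequencing error, zero-inflation beyond multinomial sampling,
uneven case/control depth distributions, or batch effects. Passing the
simulation suite therefore demonstrates that the pipeline's machinery is
correct under its own assumptions — not that those assumptions hold for any
particular real dataset.

## Numerical choices and degenerate inputs

* The low-abundance filter reads its threshold as *pooled relative
  abundance* (feature total over grand total) with a strict `<`, applied
  per cohort. A presence-fraction reading of the conventional $10^{-5}$
  cutoff would be unattainable in cohorts of fewer than $10^5$ samples, so
  the relative-abundance reading is the only coherent one; the rule is
  recorded in every `filter_report`.
* E-step underflow guards: the per-term mixture mass is floored at
  $10^{-300}$ before division; the estimated $\alpha$ is clamped to
  $[10^{-4}, 10^{4}]$.
* With a sparse fitted prior ($\alpha < 1$) the per-sample variational
  problem is multimodal: `predict()` on the training table reproduces the
  fitted mixtures for the bulk of samples but may settle in a different
  local optimum for genuinely ambiguous ones.
* Empty samples are rejected at load; zero-sum samples are rejected by TSS;
  zero topic rows cannot occur (smoothing keeps $\beta > 0$).
* All randomness is seeded and restored (`fit_lda`, the generator and
  `run_pipeline` never perturb the caller's RNG state); reruns of
  `run_pipeline()` under one configuration are byte-identical, and no
  timestamps are written into run directories.

## Problem sizes used by the validation suite

The test suite and `scripts/acceptance.R` validate the pipeline at sizes
chosen to exercise the estimators well inside a single-CPU minute budget:
topic recovery on one $200 \times 100$ corpus with 5 planted topics at
depth $10^4$ (mean matched cosine $\ge 0.9$); tuning over $k = 2..10$ on
ten such corpora; LinDA calibration on 200 null replicates of 100 features
with 20 + 20 samples and power on 50 replicates at 50 per group;
cross-cohort matching on twenty 60-sample cohort pairs sharing 3 of 8
topics; and the full pipeline on a 100-sample pair with 2 shared
case-enriched topics. Larger corpora only improve the margins.

## Known limitations

* The spectral-divergence tuning criterion is blind to underfitting (see
  above); topic-number selection should weigh both criteria and the curves.
* The compositional bias correction needs a majority of null features;
  topic tables with few topics and widespread true shifts violate this.
* In the near-binary prevalence regime (sparse $\alpha$), renormalization
  makes strong enrichments induce apparent depletions of unrelated topics;
  the correction removes the common shift but cohort-specific topics can
  still reach significance on their own. Cross-cohort validation is the
  intended guard: unshared topics do not match and therefore never
  validate.
* VEM finds local optima; use restarts and fixed seeds, and compare ELBOs.
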