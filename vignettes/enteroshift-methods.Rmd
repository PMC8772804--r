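---
title: "EnteroShift: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EnteroShift: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(EnteroShift)
```

EnteroShift analyses paired-visit gut-metagenome cohorts: read-level
taxonomic consolidation, diversity and ordination statistics, Dirichlet
multinomial mixture (DMM) enterotyping with Bact2 dysbiosis labelling,
adjusted clinical association models, longitudinal transition analysis, gut
metabolic module scoring, and propensity-matched supplement comparisons.
This vignette documents the models behind each stage, the parameters that
matter, what the synthetic generator does and does not emulate, and the
design choices made where the design was genuinely open.

## 1. The community model

A sample's species counts are modelled as Dirichlet-multinomial (DM):
proportions $p \sim \mathrm{Dirichlet}(\alpha_k)$ for its latent community
component $k$, then counts $x \mid p \sim \mathrm{Multinomial}(n, p)$. A
cohort is a $K$-component mixture with weights $\pi$. Two properties make
this the right backbone for the whole pipeline:

* **Aggregation closure.** If $p \sim \mathrm{Dir}(\alpha)$, summing species
  into genera gives $\mathrm{Dir}$ with summed parameters, and a
  hypergeometric subsample of a multinomial is multinomial. So genus
  collapsing and rarefaction keep the data exactly DM — the enterotyping
  model is correctly specified downstream of the taxprofile stage.
* **Overdispersion.** The total mass $A_k = \sum_j \alpha_{kj}$ controls
  between-sample spread around the expected composition
  $\alpha_k / A_k$: small $A_k$ means wide Dirichlet scatter, fewer observed
  species at fixed depth, lower evenness. The dysbiotic Bact2 archetype is
  encoded exactly this way (see §5).

## 2. DMM fitting and model-order selection

`fitDMM()` runs EM. The E-step computes responsibilities
$\gamma_{ik} \propto \pi_k \, \mathrm{DM}(x_i \mid \alpha_k)$; the M-step
updates $\pi_k = \overline{\gamma_{\cdot k}}$ and takes one
responsibility-weighted Minka fixed-point pass per component,

$$\alpha_{kj} \leftarrow \alpha_{kj}
\frac{\sum_i \gamma_{ik}\,[\psi(x_{ij}+\alpha_{kj}) - \psi(\alpha_{kj})]}
     {\sum_i \gamma_{ik}\,[\psi(n_i+A_k) - \psi(A_k)]},$$

floored at $10^{-10}$ for numerical safety with empty taxa. One fixed-point
pass per iteration is a generalised EM, so the observed-data log-likelihood
is non-decreasing — asserted as a property test. Initialisation: the first
restart seeds responsibilities from k-means on row-normalised profiles, the
remaining restarts (default `nRestarts = 5`) from random responsibilities;
the DM mixture likelihood is multimodal and the k-means start is usually,
but not always, in the right basin. Convergence: relative log-likelihood
change below `tol = 1e-6`, `maxIter = 500`.

**Model evidence.** `selectK()` scores each candidate $K$ with a Laplace
approximation at the fitted mode,
$\log Z \approx \ell(\hat\theta) + \log \pi_0(\hat\theta) + \tfrac{d}{2}\log 2\pi
- \tfrac12 \log |H|$. The Hessian of the weighted DM log-likelihood is
diagonal-plus-rank-one per component, so $\log|H|$ costs $O(NJ)$ via the
matrix determinant lemma. Two choices deserve explanation:

* **A vague exponential prior** (rate `alphaPriorRate = 0.01`, prior mean
  100 per parameter — flat over the plausible concentration range) supplies
  the prior-density factor $\log \pi_0(\hat\theta)$. Without it the evidence
  has no per-parameter Occam term and systematically prefers spurious extra
  components: in development, a prior-free version selected $K=5$ on a true
  $K=4$ cohort by spending 20 parameters on a single outlying sample, and
  $K=2$ on single-component data, while BIC chose correctly in both cases.
  The exponential prior has zero curvature, so the Hessian algebra is
  unchanged; $\log(0.01) \approx -4.6$ per parameter is comparable to
  BIC's $-\tfrac12\log N$ at the cohort sizes this package targets.
* **Degenerate components fall back to BIC.** Laplace assumes an interior,
  well-populated mode. A component whose effective sample size
  $\sum_i \gamma_{ik}$ is smaller than its free-parameter count, or whose
  Hessian block is not negative definite, voids the approximation; that $K$
  is scored by the unit-information surrogate
  ($\tfrac{d}{2}\log N$ replacing $\tfrac12\log|H|$) on the same
  prior-inclusive scale, and the `laplaceOK` slot records the fallback.
  Mixture weights always contribute $\tfrac{K-1}{2}\log N$.

Parameters floored at the $10^{-10}$ boundary are not counted as free.

## 3. Enterotype labelling

`labelComponents()` formalises the usual verbal description of the four
states. With expected compositions $m_k = \alpha_k / A_k$ (collapsed to
genus if the fit is at species level):

1. the component with the largest Faecalibacterium share is **Rum**;
2. of the rest, the largest Bifidobacterium share is **Bif**;
3. among remaining Bacteroides-dominated components (Bacteroides is the top
   genus of $m_k$), the one with the *lower* Shannon entropy of $m_k$ is
   **Bact2**, the other **Bact1**. A single remaining Bacteroides-dominated
   component is Bact2 only if its expected entropy is the minimum across
   all components — the dysbiosis label requires the low-diversity property,
   not just Bacteroides dominance.
4. anything left is `Other_i`; all-identical components label as `Other`
   with a warning.

Entropy of the expected composition, not realised richness, drives the
Bact1/Bact2 split: it is a property of the fitted model, deterministic given
the fit, and matches the low-evenness characterisation of Bact2. Marker
genus names are configurable for catalogues that spell them differently.

## 4. Ecology and permutation statistics

Alpha diversity refuses unrarefied input (richness is depth-biased).
Bray-Curtis is computed on row-normalised profiles; `pcoa()` is classical
scaling with negative-eigenvalue mass reported, and constrained analyses use
only positive-eigenvalue axes (no Lingoes/Cailliez correction by default) so
$R^2$ stays in $[0,1]$, mirroring common dbRDA practice. dbRDA $R^2$ is the
fraction of positive-axis inertia captured by the covariate hat matrix;
adjusted $R^2$ uses the Ezekiel formula; p-values come from permuting
covariate rows against the pseudo-F (floored at $1/(n_{perm}+1)$, default
999 permutations).

`dbrdaStepwise()` follows the forward-selection convention of stepwise
ordination tools: a candidate enters only if its permutation p-value passes
`alphaIn` *and* the cumulative adjusted $R^2$ stays at or below the
full-model adjusted $R^2$. A consequence worth knowing: when one dominant
driver faces a scope of pure-noise candidates, the full-model adjusted
$R^2$ fluctuates around the driver-only value and the scope rule can refuse
all terms — the reference implementation in the field behaves identically.
The rule works as intended when the scope contains covariates with real,
if weaker, effects (the realistic situation for clinical covariate panels).

PERMANOVA uses the Anderson partition of squared distances; with `strata`
(e.g. subject ids for paired visits) permutations are restricted within
strata, which is the package's default reading of a paired visit test — the
unrestricted variant is available by omitting strata. For Euclidean
embeddable distance matrices the single-covariate dbRDA $R^2$ and the
PERMANOVA $R^2$ coincide, which the tests assert.

## 5. The synthetic generator: a stated world

`generatorConfig()` defaults encode the cohort the analysis was designed
for; they are not tuned to tests.

* **Archetypes** (20 genera × 8 species each, geometric within-genus
  weights): Bact1 — Bacteroides-heavy at total mass $A = 120$; Bact2 —
  more Bacteroides-dominated at $A = 35$ (the low mass is what plants low
  richness/evenness; the richness link goes through the concentration, not
  through conditioning on realised richness, avoiding circularity); Rum —
  Faecalibacterium-dominated at $A = 200$; Bif — Bifidobacterium-enriched at
  $A = 100$.
* **Mixture weights** default to Bact2 = 0.194, the reported baseline
  prevalence; the remainder splits 0.30 / 0.30 / 0.206.
* **Covariates** are drawn from the published baseline marginals (age 50.6
  (9.9) y, weight 90.5 (16.3) kg, 20.9% male, 5 recruitment centres, ...);
  BMI is derived from weight and height so the obesity classes stay
  consistent. Correlations beyond those planted are zero — only marginals
  are published.
* **Covariate-to-component logits default to zero.** The study reports
  *fitted* associations (e.g. RR 1.08 per BMI unit), not a generative
  model; planting them by default would shift the marginal Bact2 share away
  from its mixture weight through the softmax nonlinearity and break the
  prevalence contract the tests rely on. Planting is opt-in via
  `plantedLogits` (e.g. a younger/female tilt for Bif). Coefficient-recovery
  tests use the dedicated `simulateLogisticCohort()`, which plants log-odds
  exactly.
* **Visits.** A configurable fraction (default 163/263) receives a second
  visit; the new component is drawn from LMP-specific transition matrices
  whose Bact2 rows default to the reported exit pattern (44% to Bact1, 39%
  staying, under supplementation); per-species log fold-changes (A.
  muciniphila up, E. rectale down, ...) and a +0.25 log-concentration gain
  for baseline-Bact2 subjects plant the low-diversity improvement. Weight
  at the second visit is exactly 90% of baseline (the programme's target),
  other clinical shifts follow the published paired deltas with noise.
* **Read tables** plant false positives at rate 0.1 with confirmation
  identities from a low distribution (0.62 (0.10)) against 0.92 (0.03) for
  true calls, plus 0.5% human-flagged reads.

What the generator does **not** emulate: real taxonomic correlation
structure beyond the four archetypes, sequencing error models, within-genus
ecological differences, covariate-covariate correlations, informative
missingness. A green test therefore establishes that the statistical
machinery recovers what it assumes, not that the biological conclusions of
any particular cohort are correct.

## 6. Statistical modules: conventions and edge cases

* **"Relative risk"** is `exp(beta)` from the logistic model — the
  operational usage of the study this package mirrors. Strictly it is an
  odds ratio; at ~20% prevalence the two differ, and the documentation says
  so rather than silently "correcting" it. Separation is detected
  (non-convergence, |β| > 15 or SE > 100) and flagged.
* **Feature filter** reading: "keep iff relative abundance ≥ 5·10⁻⁴ in
  ≥ 20% of samples" — the only reading of the (grammatically ambiguous)
  published criterion that removes rare low-abundance features.
* **Two-step read filter defaults** `minIdentity = 0.80`,
  `minAlignedFraction = 0.50`: the published cut-offs are unstated; these
  are permissive enough for long-read error rates and separate the
  fixture's planted identity distributions. Multi-candidate reads collapse
  to the highest classifier score, ties to the lexicographically smallest
  taxon (deterministic).
* **Rarefaction** is without replacement (multivariate hypergeometric),
  excluding below-depth samples rather than keeping them unrarefied; the
  publication is silent, this is standard practice.
* **Median split** assigns at-or-below-median to "low"; the threshold is
  computed on the full baseline cohort and applied to the paired subset,
  because the reported median derives from all baseline samples.
* **Between-stratum fold-change test** is a two-sample rank-sum test even
  though the source figure's caption names a signed-rank test — a paired
  test cannot compare two independent strata; the within-stratum change
  *is* tested by signed rank.
* **Transition test** compares V1 vs V2 marginal label prevalences by
  chi-square (matching the published usage, which treats the two visits as
  independent samples); a Stuart–Maxwell marginal-homogeneity option
  provides the paired-rigour alternative.
* **LMM** uses REML random intercepts via lme4 with Wald tests on the visit
  coefficient; an LMP random factor with fewer than 2 levels silently
  reduces to the subject-only model (logged); zero-variance features and
  fits lme4 cannot evaluate return flagged degenerate rows instead of
  errors.
* **Module scoring** (median over step abundances, 2/3 step-coverage
  cutoff) follows the published gut-metabolic-module framework; the curated
  module database is proprietary and not redistributed — definitions are
  user-supplied in a plain-text format, and the generator ships a synthetic
  fixture. Both the cutoff and the aggregation (median/sum) are
  configurable.
* **Matching** is greedy 1:1 without replacement, descending propensity
  order, ties by subject id. The equal-sized groups of the source analysis
  force without-replacement semantics even though the R package it used
  defaults to with-replacement. Balance improvement through selection
  requires the larger arm as donor pool; when the smaller arm is the
  control pool (47 vs 116) every control is used and the pair count equals
  the control count.
* **Missing clinical values** propagate as NA and are dropped pairwise per
  model with the dropped count logged (the publication is silent on
  missingness).
* **BH families**: one family per analysis table (all features of one
  contrast); exact family boundaries are unstated in the source.

## 7. Reproducibility

All randomised stages consume `stageSeed(masterSeed, stageName)` — an
FNV-1a-derived 31-bit stream per stage — so pipeline bundles are
bit-identical across reruns with the same configuration, which the test
suite asserts. Every bundle carries `configHash` and `seed`.

## 8. Known limitations

* Enterotype labelling assumes the marker genera are present in the fitted
  universe; catalogues lacking them need a custom `markers` map.
* The Laplace evidence depends on the vague-prior rate in its
  constant-per-parameter term; rates orders of magnitude away from the
  default would shift the model-order boundary for weakly separated
  components (well-separated cohorts are insensitive).
* No variational or MCMC DMM fitting; no UniFrac or other phylogeny-aware
  distances (no tree in this design); no with-replacement or optimal
  matching; no time-to-event modelling of the weight-loss duration.
* The package is driven from R: the exported functions and the two pipeline
  wrappers are the interface; there is no shell entry point.
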