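---
title: "Linked neural-network mediation analysis for censored survival data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linked neural-network mediation analysis for censored survival data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survmediate)
```

## The question the package answers

Suppose the expression of a driver gene panel predicts patient survival, and a
curated gene set (an apoptosis pathway, an immune-response signature, ...) is
suspected of *carrying* that effect. `survmediate` quantifies this with a
linked-network experiment built from three models, all trained in the same
cross-validation partition:

1. **Direct model** — a survival network mapping the driver panel's expression
   to a scalar log-hazard, trained with a Cox partial-likelihood loss.
2. **Multitask model** — a feed-forward regression network predicting the
   mediator set's expression from the driver panel.
3. **Mediator survival model** — a survival network trained on the mediator
   set's *observed* expression, independently of the multitask model.

On a held-out fold, composing (2) and (3) — predicted mediator expression fed
into the pre-trained mediator survival net — yields a "mediated" hazard for
every test patient. The **percent mediated effect (PME)** is the censored
concordance of these composed hazards computed *only on the patient pairs the
direct model ranked correctly*. A PME near 1 means the direct effect survives
being routed through the mediator set; near 0.5 means the composition carries
no information about those pairs; near 0 means the composition actively
reverses the direct ranking (inverse mediation). Pairs the direct model got
wrong are ignored because they say nothing about mediation of the direct
effect.

## Model and loss

A survival network outputs one number per patient, the log-hazard $h_i$;
larger $h_i$ predicts earlier death. Training minimizes the negative log Cox
partial likelihood with Breslow tie handling,

$$\mathcal{L}(h) = -\sum_{i:\,\delta_i = 1}\Big[h_i -
  \log \sum_{j:\,t_j \ge t_i} e^{h_j}\Big],$$

summed (not averaged) over events — the choice only rescales gradients, and
ADAM's per-parameter normalization absorbs it. The loss is invariant to adding
a constant to all hazards, so only the *ranking* of patients is identified;
everything downstream (concordance, PME) respects this.

Concordance follows the censoring-aware pairwise definition: a pair is
*comparable* iff the two follow-up times differ and the earlier time belongs
to an observed death. Among comparable pairs, concordant means the earlier
death had the strictly higher hazard, and the index is
concordant / (concordant + discordant). Two declared tie rules (the
definition's verbal form is silent on both): deaths at exactly tied times are
not comparable (no ordering was observed), and pairs with exactly tied hazards
count in neither the numerator nor the denominator but are reported
separately. "Ranked correctly", for the PME restriction, uses the same
concordant rule.

## Networks

Both network families share one engine: ReLU hidden layers, a linear output
layer, He initialization, ADAM, minibatch training, inverted dropout (survival
nets only), and full determinism from a single config seed (weight init, batch
shuffling and dropout masks all derive from it). With no hidden layers the
survival net *is* a Cox proportional-hazards model fit by stochastic gradient
— the test suite verifies the recovered coefficient matches
`survival::coxph` — which anchors the implementation to a classical oracle.

Minibatch Cox training evaluates the partial likelihood within each batch;
batches containing no event are skipped. The per-epoch training log is always
the full-data loss in evaluation mode (dropout off), so convergence is
monitored on a fixed quantity.

The multitask network has two hidden layers of 100 units by default and one
linear regression output per mediator gene; the loss is the unweighted sum of
per-gene mean squared errors, which is reasonable because every target is
z-scaled. It supports decoupled (AdamW-style) weight decay, default 0.05 and
deliberately higher (≈2) in the mediation presets: mediator expression is
largely *unpredictable* from a small driver panel, and without shrinkage the
network memorizes sample noise whose out-of-sample ripple degrades the
composed ranking (this matters most in the inverse-mediation regime, where the
composed signal is weak by construction).

Hyperparameter search covers the four tuned dimensions — dropout rate, single
hidden-layer width, batch size, epochs — with a seeded sequential model-based
strategy: half the budget explores at random, then candidates are proposed by
an inverse-distance-weighted surrogate over the evaluated configs; a pure
random search sits behind the same interface. The selection criterion is
concordance on an inner holdout split of the training fold, never the test
fold.

## Preprocessing and leakage control

Raw expression is FPKM-like and non-negative, so the log transform is
`log1p` (a pseudo-count is required because 0 is a legal value). Z-scaling
uses the per-gene mean and *population* (n-denominator) standard deviation —
one fixed, documented estimator. Crucially, scaling statistics are computed on
the **training fold only** and applied to both folds; a test that perturbs
test-fold columns and asserts unchanged parameters guards this. Genes constant
on a training fold are dropped for that fold. Models never impute: any gene
entering any model must pass `filter_complete()` (present with zero missing
values across all patients). Median/quartile stratification cut points, by
contrast, intentionally come from the full cohort, because they define patient
groups for descriptive Kaplan-Meier curves rather than a predictive model.

## Statistical calibration

Per mediator set and fold, the PME is compared against a **randomized-hazard
null**: each test patient receives an i.i.d. standard-normal hazard and the
restricted concordance is recomputed; 50 replicates across 10 folds give 500
null points with mean 0.5 by symmetry. A two-sided Wilcoxon signed-rank test,
paired by fold, compares the mediator's per-fold PMEs with each null
replicate's, giving 50 p-values whose median is reported. The **simulated p**
then asks how extreme that median is: 10,000 fresh random-hazard functions are
pushed through the identical machinery against the same 50 nulls, and the
simulated p is the fraction of their median p-values at or below the observed
one.

The signed-rank test uses the exact distribution for up to 12 tie-free pairs
(zero differences dropped and counted, Wilcoxon's original rule) and the
normal approximation with continuity and tie corrections otherwise; the exact
branch is verified against full enumeration of all $2^n$ sign assignments.
Because per-fold PMEs are ratios of small integer counts, exact ties across
paired folds are common, so the approximate branch does real work — this is
why the implementation handles ties explicitly rather than assuming
continuity.

Concordance benchmarking (separate from mediation) compares each named gene
set's cross-validated concordance against 50 random same-size gene sets via
one-sided signed-rank tests, reporting how many of the 50 are beaten at
p ≤ 0.05. Five folds are the benchmarking default; ten folds the mediation
default; both are exposed.

## The synthetic world

`generate_cohort()` plants a known mediation structure so every pipeline stage
is testable without external data:

- Driver $D_i \sim N(0,1)$; the driver panel adds `n_affected = 11` genes
  $s_j D_i + \varepsilon$ with alternating-sign loadings drawn from
  $\pm U(0.6, 1.4)$, mimicking up/down-regulated knockdown panels.
- A **mediator** set's genes are $w_k D_i + \varepsilon$, $w_k \sim U(0.7,
  1.3)$, and contribute $-1.5 \times \mathrm{mean}_k(H_{ik})$ to the
  log-hazard (higher driver, lower hazard: the protective-driver default).
- An **inverse mediator** set loads on a single mixed factor $M = D + 2U$
  with $U \sim N(0,1)$ a set-level latent pathway activity independent of the
  driver, and contributes $+0.45 \times \mathrm{mean}_k(H_{ik})$. The mixing
  is deliberate: if the genes exposed $D$ and $U$ separably, a flexible
  network could disentangle them and the composition would re-align with the
  direct model. Because only $M$ is visible, the observed hazard association
  (dominated by $U$) is *reversed* relative to the driver path — the
  anti-mediation regime, whose oracle PME on this world is ≈ 0.12.
- A **null** set and 200 background genes are independent noise.
- Event times are exponential with rate
  $\lambda_0 e^{r_i}$ ($\lambda_0 = \log 2 / 900$ per day, a glioma-like
  median survival), censoring is independent exponential ($4 \times 10^{-4}$
  per day, ≈ 2/3 of patients dying in follow-up at zero risk), and observed
  time is the minimum. Exponential rather than Weibull times keep
  proportional hazards exact, so Cox-recovery tests are clean.
- Stored expression is $e^{\text{latent}}$ (positive, raw scale), so the
  pipeline's log + z-scaling path is genuinely exercised. All randomness
  derives from one seed through labelled stream splitting, so adding a
  mediator set never perturbs another set's draws.

What the generator does *not* emulate: RNA-seq count noise (negative
binomial), batch effects, correlated censoring, non-proportional hazards. A
green test on this world establishes that the machinery recovers planted
structure, not that it would recover biology from real cohorts.

## Numerical and design choices

- Breslow tie handling throughout (loss, gradient, classical fits), with a
  numerically stable log-sum-exp over risk sets.
- `optimize_hyperparameters` evaluates failures as `NA` and errors only if
  every budgeted run fails.
- A composed model whose hazards tie on *every* restricted pair (possible for
  null sets whose predictions collapse) yields an undefined per-fold PME,
  which is excluded from summaries; Wilcoxon pairing drops such folds.
- Model archives are JSON with flat column-major weight storage, so
  round-trips are byte-order unambiguous.
- Exit codes for the CLI: 0 ok, 1 input error, 2 runtime failure.

## Known limitations

Two findings from this implementation deserve emphasis.

First, **a truly uninformative mediator set does not behave like the
randomized-hazard null.** The multitask net and the mediator survival net are
both fit on the same training fold; the multitask fit touches the gene noise
$\varepsilon_k$ through its inputs-to-target correlations, and the mediator
survival fit touches the same $\varepsilon_k$ through its outcome
associations. Their composition therefore reconstructs a faint but
*systematic* copy of the direct signal even when the mediator genes carry no
information at all — in the default synthetic world a null set's median PME
sits near 0.65–0.7, above the randomized band (and its simulated p can be
"significant"). The randomized-hazard null calibrates the *pair-counting*
machinery, not the *double-fitting* optimism. Practical reading: treat the
randomized control as a lower bar, compare candidate mediator sets against
*matched random gene sets* pushed through the same composition when absolute
calibration matters, and treat PMEs in the 0.5–0.7 range as inconclusive. The
corresponding acceptance check is intentionally left failing rather than
widened, with this analysis as the explanation.

Second, the inverse-mediation regime is only *constructible* when the
reversed hazard association comes from a latent factor the driver panel
cannot predict; with a single shared driver, consistent observational fits
always compose into alignment. This is why the synthetic inverse set mixes in
the latent $U$, and it is also a caveat for interpreting real-data inverse
mediation: it implies an unmeasured co-regulator.

Scaled-down settings in the test suite (fewer epochs, narrower layers,
simulated p at 200–500 draws instead of 10,000) trade precision for runtime;
the package defaults are larger and are the ones a real analysis should use.
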